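test_that("a pixel equal to a training atom is classified with zero residual", {
  set.seed(3)
  A <- matrix(abs(rnorm(5 * 24)) + 0.2, 5, 24)
  d <- src_dictionary(A, rep(1:4, each = 6))
  y <- d$matrix[, 13] * 2.5                    # class 3 atom, scaled
  dec <- classify_pixel(d, y, solver_config(K0 = 1))
  expect_equal(dec$predicted_class, 3)
  expect_equal(unname(dec$residual_by_class["3"]), 0, tolerance = 1e-10)
  expect_true(all(dec$residual_by_class >= 0))
  expect_equal(dec$predicted_class,
               as.integer(names(which.min(dec$residual_by_class))))
})

test_that("perturbations within a class span stay in that class", {
  d <- axis_dictionary(n = 5, per_class = 6, m = 3)
  y <- c(1, 0.02, 0.01, 0, 0)                  # near the class-1 axis
  dec <- classify_pixel(d, y, solver_config(K0 = 2))
  expect_equal(dec$predicted_class, 1)
  # verify every class residual directly from the solved coefficients
  X <- dec$solution$coefficients
  for (cl in 1:3) {
    cols <- which(d$class_of_column == cl)
    r <- sqrt(sum((y - d$matrix[, cols] %*% X[cols, ])^2))
    expect_equal(unname(dec$residual_by_class[as.character(cl)]), r,
                 tolerance = 1e-12)
  }
  expect_lt(dec$residual_by_class["1"], min(dec$residual_by_class[-1]))
})

test_that("each class residual is at least the full-support residual", {
  set.seed(13)
  d <- suppressWarnings(
    src_dictionary(matrix(abs(rnorm(5 * 30)), 5, 30), rep(1:5, 6)))
  for (i in 1:10) {
    y <- abs(rnorm(5))
    dec <- classify_pixel(d, y, solver_config(K0 = 4))
    expect_true(all(dec$residual_by_class >=
                      dec$solution$residual_norm - 1e-10))
  }
})

test_that("a patch of one class atom gets that class with zero residual", {
  set.seed(23)
  d <- suppressWarnings(
    src_dictionary(matrix(abs(rnorm(5 * 40)) + 0.1, 5, 40),
                   rep(1:8, each = 5)))
  Y <- d$matrix[, 33] %*% t(runif(9, 0.5, 2))  # class 7 atom, 9 pixels
  dec <- classify_patch(d, Y, solver_config(K0 = 1))
  expect_equal(dec$predicted_class, 7)
  expect_equal(unname(dec$residual_by_class["7"]), 0, tolerance = 1e-9)
})

test_that("classify_patch with s = 1 equals classify_pixel", {
  set.seed(33)
  d <- suppressWarnings(
    src_dictionary(matrix(abs(rnorm(5 * 30)), 5, 30), rep(1:6, 5)))
  for (i in 1:10) {
    y <- abs(rnorm(5))
    a <- classify_pixel(d, y, solver_config(K0 = 3))
    b <- classify_patch(d, matrix(y, ncol = 1), solver_config(K0 = 3))
    expect_identical(a$predicted_class, b$predicted_class)
    expect_equal(a$residual_by_class, b$residual_by_class,
                 tolerance = 1e-12)
  }
})

test_that("majority structure dominates the joint patch decision", {
  # two well-separated classes; 8 patch columns from class 2, 1 outlier
  d <- axis_dictionary(n = 5, per_class = 6, m = 2)
  set.seed(43)
  Y <- cbind(matrix(rep(c(0, 1, 0, 0, 0), 8), 5) + abs(rnorm(40, 0, 0.05)),
             c(1, 0, 0, 0, 0))                 # outlier from class 1
  dec <- classify_patch(d, Y, solver_config(K0 = 2))
  expect_equal(dec$predicted_class, 2)
  # oracle: per-class residuals by exhaustive least squares on the support
  sup <- dec$solution$support
  for (cl in 1:2) {
    cols <- intersect(sup, which(d$class_of_column == cl))
    r <- if (length(cols)) {
      Ai <- d$matrix[, cols, drop = FALSE]
      sqrt(sum((Y - Ai %*% dec$solution$coefficients[cols, , drop = FALSE])^2))
    } else sqrt(sum(Y^2))
    expect_equal(unname(dec$residual_by_class[as.character(cl)]), r,
                 tolerance = 1e-12)
  }
})

test_that("noiseless cells are classified essentially perfectly", {
  cell <- simulate_mfish_cell(image_size = c(64, 64), m = 8, noise_sd = 0,
                              seed = 5)
  fit <- suppressWarnings(mfish_src(cell, fraction = 0.5, seed = 1))
  pred <- predict(fit, cell, s = 1, config = solver_config(K0 = 1))
  r <- rcc(pred, cell$truth, fit$test_coords)
  expect_gte(r$overall_rcc, 0.99)
})

test_that("an all-background mask yields an all-zero label image", {
  cell <- simulate_mfish_cell(image_size = c(32, 32), m = 3, noise_sd = 0,
                              seed = 6)
  fit <- suppressWarnings(mfish_src(cell, fraction = 0.5, seed = 1))
  pred <- classify_image(cell$channels, matrix(FALSE, 32, 32),
                         fit$dictionary)
  expect_true(all(pred == 0L))
})

test_that("predicted labels never contain the overlap code 255", {
  cell <- simulate_mfish_cell(image_size = c(64, 64), m = 6, noise_sd = 0.4,
                              regions_per_class = 2, overlap_fraction = 0.1,
                              seed = 8)
  fit <- suppressWarnings(mfish_src(cell, fraction = 0.2, seed = 1))
  pred <- predict(fit, cell, s = 9)
  expect_true(all(pred %in% c(0L, fit$dictionary$classes)))
  expect_false(any(pred == 255L))
  # identical inputs give identical predictions
  pred2 <- predict(fit, cell, s = 9)
  expect_identical(pred, pred2)
})

test_that("classify_image agrees with per-pixel classify_patch calls", {
  cell <- simulate_mfish_cell(image_size = c(32, 32), m = 4, noise_sd = 0.3,
                              seed = 10)
  fit <- suppressWarnings(mfish_src(cell, fraction = 0.3, seed = 2))
  mask <- cell$truth != 0
  pred <- classify_image(cell$channels, mask, fit$dictionary, s = 9)
  idx <- which(mask, arr.ind = TRUE)
  for (k in sample(nrow(idx), 15)) {
    p <- extract_patch(cell$channels, mask, idx[k, ], side = 3)
    dec <- classify_patch(fit$dictionary, p)
    expect_identical(pred[idx[k, 1], idx[k, 2]],
                     as.integer(dec$predicted_class))
  }
})

test_that("mask/image shape mismatches are rejected", {
  cell <- simulate_mfish_cell(image_size = c(32, 32), m = 3, noise_sd = 0,
                              seed = 6)
  fit <- suppressWarnings(mfish_src(cell, fraction = 0.5, seed = 1))
  expect_error(classify_image(cell$channels, matrix(TRUE, 16, 32),
                              fit$dictionary), "dimensions")
})
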