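# dense eigendecomposition oracle on the 3V x 3V covariance, viable for V <= 50
dense_pca_oracle <- function(coord_list) {
  X <- do.call(rbind, lapply(coord_list, as.vector))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen(C, symmetric = TRUE)
  list(mean = colMeans(X), values = eig$values, vectors = eig$vectors)
}

tiny_population <- function(n = 10, V = 20, seed = 99) {
  set.seed(seed)
  base <- matrix(rnorm(V * 3), V, 3) * 10
  lapply(seq_len(n), function(i) base + matrix(rnorm(V * 3, sd = 1), V, 3))
}

test_that("PCA model matches a dense eigendecomposition oracle", {
  shapes <- tiny_population()
  model <- build_model(lapply(shapes, as_corresponded), n_components = 5)
  oracle <- dense_pca_oracle(shapes)
  expect_equal(model$mean_shape, oracle$mean, tolerance = 1e-10)
  expect_equal(model$variances, oracle$values[1:5], tolerance = 1e-8)
  # subspace agreement: projections onto the oracle basis have unit overlap
  for (k in 1:5) {
    overlap <- abs(sum(model$components[, k] * oracle$vectors[, k]))
    expect_equal(overlap, 1, tolerance = 1e-6)
  }
  # orthonormality and trace conservation
  expect_lt(max(abs(crossprod(model$components) - diag(5))), 1e-8)
  total <- sum(dense_pca_oracle(shapes)$values)
  expect_equal(model$total_variance, total, tolerance = 1e-6)
})

test_that("two training shapes give one component along their difference", {
  shapes <- tiny_population(n = 2)
  model <- build_model(lapply(shapes, as_corresponded), n_components = 1)
  diffv <- as.vector(shapes[[1]]) - as.vector(shapes[[2]])
  overlap <- abs(sum(model$components[, 1] * diffv / sqrt(sum(diffv^2))))
  expect_equal(overlap, 1, tolerance = 1e-10)
  # variance of 2 points symmetric about the mean: half the squared distance
  expect_equal(model$variances[1], sum(diffv^2) / 2, tolerance = 1e-10)
})

test_that("identical training shapes give a degenerate model", {
  one <- tiny_population(n = 1)[[1]]
  model <- build_model(lapply(1:4, function(i) as_corresponded(one)), n_components = 2)
  expect_equal(model$variances, c(0, 0), tolerance = 1e-12)
  expect_equal(ssmrec:::unflatten(model$mean_shape), one, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("model construction validates its inputs", {
  shapes <- tiny_population(n = 5)
  expect_error(build_model(shapes[1]), "at least 2")
  expect_error(build_model(shapes, n_components = 5), "n_components")
  mixed <- c(lapply(shapes[1:4], as_corresponded),
             list(corresponded_shape(matrix(0, 7, 3))))
  expect_error(build_model(mixed, 2), "mismatched")
  partial <- as_corresponded(shapes[[1]])
  partial$valid_mask[1] <- FALSE
  expect_error(build_model(c(shapes[2:5], list(partial)), 2), "fully valid")
})

test_that("project and synthesize satisfy the subspace identities", {
  shapes <- tiny_population()
  model <- build_model(lapply(shapes, as_corresponded), n_components = 5)
  # project(mean) = 0
  b0 <- project(model, corresponded_shape(ssmrec:::unflatten(model$mean_shape)))
  expect_lt(max(abs(b0$b)), 1e-10)
  # project(mean + 2 sd_1 PC1) = (2 sd_1, 0, ...)
  sd1 <- sqrt(model$variances[1])
  x <- model$mean_shape + 2 * sd1 * model$components[, 1]
  b <- project(model, corresponded_shape(ssmrec:::unflatten(x)))
  expect_equal(b$b[1], 2 * sd1, tolerance = 1e-8)
  expect_lt(max(abs(b$b[-1])), 1e-8)
  # synthesize(0) = mean
  expect_equal(synthesize(model, rep(0, 5))$coordinates,
               ssmrec:::unflatten(model$mean_shape), tolerance = 1e-12)
  # synthesize o project is idempotent
  s1 <- synthesize(model, project(model, as_corresponded(shapes[[3]]), clamp = FALSE))
  s2 <- synthesize(model, project(model, s1, clamp = FALSE))
  expect_equal(s1$coordinates, s2$coordinates, tolerance = 1e-9)
})

test_that("full-rank PCA reconstructs training shapes exactly", {
  shapes <- tiny_population(n = 8)
  model <- build_model(lapply(shapes, as_corresponded), n_components = 7)
  for (s in shapes[c(1, 5)]) {
    rec <- synthesize(model, project(model, as_corresponded(s), clamp = FALSE))
    expect_lt(max(abs(rec$coordinates - s)), 1e-6)
  }
})

test_that("masked projection recovers known coefficients from 70% support", {
  shapes <- tiny_population(n = 12, V = 40)
  model <- build_model(lapply(shapes, as_corresponded), n_components = 5)
  set.seed(11)
  b_true <- rnorm(5, sd = sqrt(model$variances))
  x <- synthesize(model, b_true)
  mask <- rep(FALSE, 40); mask[sample(40, 28)] <- TRUE
  b_est <- project(model, x, mask = mask, clamp = FALSE)
  expect_lt(max(abs(b_est$b - b_true) / pmax(abs(b_true), 1e-9)), 0.01)
  # underdetermined mask errors out
  tiny_mask <- rep(FALSE, 40); tiny_mask[1:3] <- TRUE
  expect_error(project(model, x, mask = tiny_mask), "underdetermined")
})

test_that("coefficient clamping flags and limits implausible scores", {
  shapes <- tiny_population()
  model <- build_model(lapply(shapes, as_corresponded), n_components = 3)
  x <- model$mean_shape + 10 * sqrt(model$variances[1]) * model$components[, 1]
  b <- project(model, corresponded_shape(ssmrec:::unflatten(x)))
  expect_true(b$clamped[1])
  expect_equal(abs(b$b[1]), 3 * sqrt(model$variances[1]))
})

test_that("compactness is a valid cumulative spectrum", {
  shapes <- tiny_population(n = 8)
  model <- build_model(lapply(shapes, as_corresponded), n_components = 7)
  cv <- compactness(model)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[7], 1, tolerance = 1e-9)   # K = n - 1 explains everything
  oracle <- dense_pca_oracle(shapes)
  expect_equal(cv, cumsum(oracle$values[1:7]) / sum(oracle$values), tolerance = 1e-8)
  m1 <- build_model(lapply(shapes[1:2], as_corresponded), n_components = 1)
  expect_equal(compactness(m1), 1, tolerance = 1e-12)
})

test_that("models persist through save and load", {
  shapes <- tiny_population()
  model <- build_model(lapply(shapes, as_corresponded), n_components = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_equal(back$mean_shape, model$mean_shape)
  expect_equal(back$components, model$components)
  expect_equal(back$variances, model$variances)
})
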