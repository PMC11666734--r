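test_that("a complete intact shape reconstructs to its subspace projection", {
  fix <- big_model()
  model <- fix$model
  shape <- fix$pop$meshes[[5]]
  rec <- reconstruct_fracture(model, shape)
  # oracle: plain projection/synthesis of the same (trivially corresponded)
  # coordinates; the pipeline must land within its own tolerance of it
  oracle <- synthesize(model, project(model, as_corresponded(shape), clamp = FALSE))
  expect_lt(rmse(rec$reconstructed, oracle), 0.25)
  expect_gt(rec$fraction_valid, 0.95)
  # output lies exactly in the model subspace
  x <- as.vector(rec$reconstructed$coordinates) - model$mean_shape
  resid <- x - model$components %*% crossprod(model$components, x)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("coefficients of a model-generated shape are recovered from fragments", {
  fix <- big_model()
  model <- fix$model
  b_true <- rep(0, 15)
  b_true[1:3] <- c(1, -0.67, 0.5) * sqrt(model$variances[1:3])
  shape <- synthesize(model, b_true)
  smesh <- triangle_mesh(shape$coordinates, fix$template$mesh$faces)
  fr <- simulate_fracture(smesh, fracture_spec(2, 0.10, 0, 0, seed = 2))
  rec <- reconstruct_fracture(model, fr$merged)
  rel <- abs(rec$coefficients$b[1:3] - b_true[1:3]) / abs(b_true[1:3])
  expect_lt(max(rel), 0.10)
  expect_lt(rmse(rec$reconstructed, shape), 0.5)
})

test_that("reconstruction rejects empty fragment input", {
  fix <- big_model()
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(integer(0), 0, 3), name = ""),
                     class = "triangle_mesh")
  expect_error(reconstruct_fracture(fix$model, empty), "empty")
})

test_that("sparse fragments trigger the low-support warning", {
  fix <- big_model()
  m <- fix$template$mesh
  # keep only ~15% of the surface
  cent <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
             m$vertices[m$faces[, 3], ]) / 3
  d <- cent %*% c(0, 0, 1)
  keep <- which(d > stats::quantile(d, 0.85, type = 7))
  sliver <- ssmrec:::subset_faces(m, keep)
  expect_warning(reconstruct_fracture(fix$model, sliver,
                                      reg_params = nonrigid_params(max_corr_dist = 5)),
                 "25")
})

test_that("the contralateral route recovers a mirrored training shape", {
  fix <- big_model()
  model <- fix$model
  shape <- fix$pop$meshes[[9]]
  mirrored <- mirror_sagittal(shape, plane_point = colMeans(shape$vertices))
  truth <- reconstruct_from_contralateral(model, mirrored)
  err <- sqrt(rowSums((truth$coordinates - shape$vertices)^2))
  expect_lt(median(err), 0.5)
  expect_gte(mean(truth$valid_mask), 0.99)
})

test_that("the contralateral route is self-consistent on the mirrored mean", {
  fix <- big_model()
  model <- fix$model
  meanm <- mean_mesh(model)
  mirrored <- mirror_sagittal(meanm, plane_point = colMeans(meanm$vertices))
  out <- reconstruct_from_contralateral(model, mirrored)
  err <- sqrt(rowSums((out$coordinates - meanm$vertices)^2))
  expect_lt(median(err), 0.1)
  expect_true(all(out$valid_mask))
  expect_error(reconstruct_from_contralateral(model,
    structure(list(vertices = matrix(0, 0, 3), faces = matrix(integer(0), 0, 3),
                   name = ""), class = "triangle_mesh")), "empty")
})

test_that("displacing a fragment harms less than deleting it entirely", {
  fix <- big_model()
  model <- fix$model
  b_true <- rep(0, 15)
  b_true[1:2] <- c(0.8, -0.6) * sqrt(model$variances[1:2])
  shape <- synthesize(model, b_true)
  smesh <- triangle_mesh(shape$coordinates, fix$template$mesh$faces)
  err_disp <- numeric(0); err_del <- numeric(0)
  for (s in 1:6) {
    # same single cut plane per seed; in one arm the smaller fragment is
    # rigidly displaced (<= max_corr_dist / 2), in the other it is removed
    fr_disp <- simulate_fracture(smesh, fracture_spec(1, 0, 5, 5, seed = s))
    fr_still <- simulate_fracture(smesh, fracture_spec(1, 0, 0, 0, seed = s))
    areas <- vapply(fr_still$fragments, mesh_area, numeric(1))
    largest_only <- fr_still$fragments[[which.max(areas)]]
    rd <- suppressWarnings(reconstruct_fracture(model, fr_disp$merged))
    rl <- suppressWarnings(reconstruct_fracture(model, largest_only))
    err_disp <- c(err_disp, sqrt(sum((rd$coefficients$b - b_true)^2)))
    err_del <- c(err_del, sqrt(sum((rl$coefficients$b - b_true)^2)))
  }
  expect_lt(median(err_disp), median(err_del))
})
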