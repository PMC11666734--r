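test_that("the synthetic template is deterministic, closed and landmarked", {
  a <- make_template(2L)
  b <- make_template(2L)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$landmarks$regions, b$landmarks$regions)
  expect_true(is_watertight(a$mesh))
  expect_equal(max(mesh_components(a$mesh)), 1)
  counts <- vapply(a$landmarks$regions, length, integer(1))
  expect_equal(unname(counts[c("iliopectineal_line", "quadrilateral_plate",
                               "ischial_body_line", "acetabular_diameter",
                               "weight_bearing_dome")]),
               c(12L, 12L, 8L, 4L, 30L))
  expect_equal(sum(counts), 66L)
  # constructed arc radius stored in the metadata is recovered exactly
  co <- a$mesh$vertices[a$landmarks$regions$iliopectineal_line, ]
  expect_equal(as.numeric(fit_circle_radius(co)),
               a$landmarks$truth$iliopectineal_radius, tolerance = 1e-6)
  expect_error(make_template(1L), ">= 2")
})

test_that("the full-resolution template has enough vertices", {
  tpl <- big_template()
  expect_gte(nrow(tpl$mesh$vertices), 2000)
  # overall scale is in the tens of millimetres, like a hemipelvis
  diag <- ssmrec:::bbox_diagonal(tpl$mesh)
  expect_gt(diag, 60); expect_lt(diag, 150)
})

test_that("population generation honours its specification and seed", {
  tpl <- small_template()
  spec <- population_spec(n_shapes = 8, n_modes = 2, mode_stddevs = c(4, 2),
                          seed = 5)
  p1 <- generate_population(tpl$mesh, spec)
  p2 <- generate_population(tpl$mesh, spec)
  expect_identical(p1$meshes[[3]]$vertices, p2$meshes[[3]]$vertices)
  expect_identical(p1$coefficients, p2$coefficients)
  expect_equal(length(p1$meshes), 8)
  # modes orthogonal with norm sqrt(V): unit RMS displacement per coefficient
  V <- nrow(tpl$mesh$vertices)
  G <- crossprod(p1$modes)
  expect_equal(G, diag(2) * V, tolerance = 1e-8, ignore_attr = TRUE)
  # shape i really is template + modes %*% coefficients_i
  disp <- ssmrec:::unflatten(as.vector(p1$modes %*% p1$coefficients[2, ]))
  expect_equal(p1$meshes[[2]]$vertices, tpl$mesh$vertices + disp, tolerance = 1e-12)
  expect_error(population_spec(n_shapes = 2, n_modes = 3,
                               mode_stddevs = c(3, 2, 1)), "n_shapes")
  expect_error(population_spec(mode_stddevs = c(1, 2, 3)), "descending")
})

test_that("a model built on generated shapes recovers the true subspace", {
  fix <- big_model()
  model <- fix$model
  pop <- fix$pop
  # principal angles between the true and fitted 3-mode subspaces
  Qt <- qr.Q(qr(pop$modes))
  Qf <- model$components[, 1:3]
  sv <- svd(crossprod(Qt, Qf))$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 10)
  # fitted variances equal the drawn coefficients' sample variances exactly
  # (modes are orthogonal with norm sqrt(V), so the PCA eigenvalues are the
  # eigenvalues of the coefficient sample covariance times V)
  V <- nrow(fix$template$mesh$vertices)
  cov_eig <- sort(eigen(stats::cov(pop$coefficients), symmetric = TRUE,
                        only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(model$variances[1:3], cov_eig * V, tolerance = 1e-8)
  # remaining variance is numerically zero (only 3 true modes)
  expect_lt(model$variances[4] / model$variances[1], 1e-10)
})

test_that("zero-variance population degenerates to copies of the template", {
  tpl <- small_template()
  spec <- population_spec(n_shapes = 4, n_modes = 1, mode_stddevs = 1e-12, seed = 1)
  pop <- generate_population(tpl$mesh, spec)
  expect_equal(pop$meshes[[4]]$vertices, tpl$mesh$vertices, tolerance = 1e-9)
})

test_that("fracture simulation conserves surface and reports deletion", {
  tpl <- small_template()
  # no deletion, no displacement: fragments tile the original surface
  fr0 <- simulate_fracture(tpl$mesh, fracture_spec(2, 0, 0, 0, seed = 1))
  expect_equal(mesh_area(fr0$merged), mesh_area(tpl$mesh), tolerance = 0.01)
  expect_equal(fr0$achieved_delete_fraction, 0)
  # deterministic per seed
  fr1 <- simulate_fracture(tpl$mesh, fracture_spec(2, 0.2, 4, 4, seed = 9))
  fr2 <- simulate_fracture(tpl$mesh, fracture_spec(2, 0.2, 4, 4, seed = 9))
  expect_identical(fr1$merged$vertices, fr2$merged$vertices)
  expect_error(fracture_spec(delete_fraction = 0.96), "delete_fraction")
})

test_that("achieved deletion tracks the requested fraction", {
  tpl <- small_template()
  for (target in c(0.15, 0.35, 0.5)) {
    achieved <- vapply(1:20, function(s) {
      simulate_fracture(tpl$mesh,
                        fracture_spec(2, target, 0, 0, seed = s))$achieved_delete_fraction
    }, numeric(1))
    expect_lt(abs(median(achieved) - target), 0.1)
  }
})
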