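test_that("rmse follows the closed forms and is a metric", {
  a <- corresponded_shape(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(rmse(a, a), 0)
  b <- corresponded_shape(rbind(c(3, 4, 0), c(1, 1, 1)))
  expect_equal(rmse(a, b, indices = 1), 5)
  # two pairs with distances 1 and 7 -> sqrt((1+49)/2) = 5
  c2 <- corresponded_shape(rbind(c(1, 0, 0), c(8, 1, 1)))
  expect_equal(rmse(a, c2), 5)
  expect_equal(rmse(b, a, indices = 1), rmse(a, b, indices = 1))  # symmetric
  expect_error(rmse(a, b, indices = integer(0)), "empty")
  # triangle inequality on random corresponded triples
  set.seed(4)
  for (i in 1:20) {
    x <- corresponded_shape(matrix(rnorm(30), 10, 3))
    y <- corresponded_shape(matrix(rnorm(30), 10, 3))
    z <- corresponded_shape(matrix(rnorm(30), 10, 3))
    expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
  }
})

test_that("distance maps agree with rmse and respond to translation", {
  m <- small_template()$mesh
  a <- as_corresponded(m)
  expect_equal(distance_map(a, a)$per_vertex_distance, rep(0, nrow(m$vertices)))
  b <- corresponded_shape(m$vertices + rep(c(2, 0, 0), each = nrow(m$vertices)))
  dm <- distance_map(a, b)
  expect_equal(dm$per_vertex_distance, rep(2, nrow(m$vertices)))
  expect_equal(dm$summary$rmse, rmse(a, b))
  expect_gte(dm$summary$max, dm$summary$rmse)
})

test_that("polyline length sums segments and ignores orientation", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(polyline_length(sq), 3)
  expect_equal(polyline_length(sq[4:1, ]), polyline_length(sq))
  expect_error(polyline_length(rbind(c(0, 0, 0))), "at least 2")
})

test_that("circle fitting matches circumscribed-circle cases", {
  p <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  r <- fit_circle_radius(p)
  expect_equal(as.numeric(r), 1, tolerance = 1e-9)
  expect_equal(attr(r, "center"), c(1, 0, 0), tolerance = 1e-9)
  expect_error(fit_circle_radius(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("circle fitting is exact for points on a tilted 3D circle", {
  # radius-40 circle on a tilted plane
  e1 <- c(1, 0, 0); e2 <- c(0, cos(0.6), sin(0.6))
  center <- c(5, -3, 7)
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  pts <- t(sapply(th, function(t) center + 40 * (cos(t) * e1 + sin(t) * e2)))
  expect_equal(as.numeric(fit_circle_radius(pts)), 40, tolerance = 1e-6)
  # invariance under rigid motion
  tr <- rigid_transform(rot_z(33), c(10, 20, -5))
  expect_equal(as.numeric(fit_circle_radius(apply_transform(pts, tr))), 40,
               tolerance = 1e-8)
})

test_that("noisy circle fits recover the radius within 2 mm", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  th <- seq(0, 1.5 * pi, length.out = 12)  # an arc, as for a bony line
  set.seed(7)
  errs <- replicate(200, {
    pts <- t(sapply(th, function(t) 40 * (cos(t) * e1 + sin(t) * e2))) +
      matrix(rnorm(36, sd = 0.5), 12, 3)
    abs(as.numeric(fit_circle_radius(pts)) - 40)
  })
  expect_lt(median(errs), 2)
})

test_that("acetabular diameter matches the circumscribed-circle geometry", {
  th <- c(0, 0.5, 2, 4)
  pts <- t(sapply(th, function(t) 25 * c(cos(t), sin(t), 0)))
  expect_equal(acetabular_diameter(pts), 50, tolerance = 1e-9)
  # square of side s: circumscribed diameter = s * sqrt(2)
  s <- 3
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(acetabular_diameter(sq), s * sqrt(2), tolerance = 1e-9)
  expect_equal(acetabular_diameter(sq[c(3, 1, 4, 2), ]), s * sqrt(2),
               tolerance = 1e-9)   # order invariance
  expect_error(acetabular_diameter(sq[1:3, ]), "exactly 4")
})

test_that("quadrilateral slope measures plane inclination in degrees", {
  axis <- c(0, 0, 1)
  # coplanar points with normal parallel to the axis -> 0 degrees
  flat <- cbind(rnorm(12), rnorm(12), 0)
  expect_equal(quadrilateral_slope(flat, axis), 0, tolerance = 1e-8)
  # plane tilted 45 degrees
  t45 <- cbind(seq_len(12), rep(c(0, 1, 2), 4), seq_len(12))
  expect_equal(quadrilateral_slope(t45, axis), 45, tolerance = 1e-8)
  # axis negation invariance
  expect_equal(quadrilateral_slope(t45, -axis), 45, tolerance = 1e-8)
  expect_error(quadrilateral_slope(cbind(1:5, 1:5, 1:5), axis), "degenerate")
})

test_that("clinical parameters recover the constructed template geometry", {
  tpl <- small_template()
  shape <- as_corresponded(tpl$mesh)
  p <- clinical_parameters(shape, tpl$landmarks)
  truth <- tpl$landmarks$truth
  expect_equal(p$iliopectineal_length, truth$iliopectineal_length, tolerance = 1e-6)
  expect_equal(p$iliopectineal_radius, truth$iliopectineal_radius, tolerance = 1e-6)
  expect_equal(p$ischial_length, truth$ischial_length, tolerance = 1e-6)
  expect_equal(p$ischial_radius, truth$ischial_radius, tolerance = 1e-6)
  expect_equal(p$acetabular_diameter, truth$acetabular_diameter, tolerance = 1e-6)
  expect_equal(p$quadrilateral_slope, truth$quadrilateral_slope, tolerance = 1e-6)
  # deterministic: same input, same output
  expect_identical(p, clinical_parameters(shape, tpl$landmarks))
  # differences with itself are zero
  expect_equal(unname(compare_parameters(p, p)), rep(0, 6))
})

test_that("clinical parameters are invariant under rigid motion", {
  tpl <- small_template()
  tr <- rigid_transform(rot_z(25), c(4, -7, 2))
  moved <- apply_transform(tpl$mesh, tr)
  axis_moved <- as.vector(tr$rotation %*% tpl$landmarks$reference_axis)
  p0 <- clinical_parameters(as_corresponded(tpl$mesh), tpl$landmarks)
  p1 <- clinical_parameters(as_corresponded(moved), tpl$landmarks,
                            reference_axis = axis_moved)
  expect_equal(unname(compare_parameters(p0, p1)), rep(0, 6), tolerance = 1e-8)
})

test_that("parameter comparison is an elementwise absolute difference", {
  tpl <- small_template()
  p <- clinical_parameters(as_corresponded(tpl$mesh), tpl$landmarks)
  q <- p; q$iliopectineal_length <- p$iliopectineal_length - 3
  d <- compare_parameters(p, q)
  expect_equal(unname(d["iliopectineal_length"]), 3)
  expect_equal(compare_parameters(p, q), compare_parameters(q, p))
})

test_that("landmark sets validate the 66-coordinate layout", {
  tpl <- small_template()
  lm <- tpl$landmarks
  expect_equal(vapply(lm$regions, length, integer(1)),
               c(iliopectineal_line = 12L, quadrilateral_plate = 12L,
                 ischial_body_line = 8L, acetabular_diameter = 4L,
                 weight_bearing_dome = 30L))
  expect_equal(length(landmark_indices(lm)), 66L)
  expect_equal(anyDuplicated(landmark_indices(lm)), 0L)
  bad <- lm$regions; bad$acetabular_diameter <- bad$acetabular_diameter[1:3]
  expect_error(landmark_set(bad), "4 landmarks")
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$regions, lm$regions)
  expect_equal(back$reference_axis, lm$reference_axis)
})

test_that("summarize_values matches a direct sorted-interpolation oracle", {
  expect_equal(summarize_values(c(1, 2, 3))$median, 2)
  s <- summarize_values(rep(4, 10))
  expect_equal(s$q75 - s$q25, 0)
  quantile_oracle <- function(x, p) {
    # type-7: linear interpolation between order statistics
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(12)
  for (n in c(3, 5, 8, 13, 20)) {
    x <- rnorm(n)
    s <- summarize_values(x)
    expect_equal(s$median, quantile_oracle(x, 0.5), tolerance = 1e-12)
    expect_equal(s$q25, quantile_oracle(x, 0.25), tolerance = 1e-12)
    expect_equal(s$q75, quantile_oracle(x, 0.75), tolerance = 1e-12)
  }
  expect_error(summarize_values(numeric(0)), "non-empty")
})

# exhaustive enumeration of group assignments; the independent oracle for the
# exact Mann-Whitney p-value
mwu_permutation_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  vals <- c(a, b)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - m * (m + 1) / 2
  }
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(m))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

test_that("Mann-Whitney U matches hand-computed and enumerated references", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # identical groups: p = 1 under the normal approximation (forced by ties)
  r2 <- mann_whitney_u(rep(1:3, 2), rep(1:3, 2))
  expect_equal(r2$p_value, 1, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p agrees with full permutation enumeration", {
  set.seed(21)
  for (m in 2:6) {
    for (n in 2:6) {
      a <- round(rnorm(m), 6)   # continuous draws: no ties
      b <- round(rnorm(n, mean = 0.8), 6)
      ours <- mann_whitney_u(a, b)
      expect_equal(ours$method, "exact")
      expect_equal(ours$p_value, mwu_permutation_oracle(a, b), tolerance = 1e-10)
    }
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6)
  b <- c(2, 3, 3, 4, 5, 7, 8, 9)
  ours <- mann_whitney_u(a, b)
  expect_equal(ours$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})
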