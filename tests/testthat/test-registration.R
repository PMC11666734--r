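test_that("rigid transforms compose, invert, and apply exactly", {
  t1 <- rigid_transform(rot_z(30), c(1, -2, 3))
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
  # inverse composes to identity
  id <- compose_transforms(t1, invert_transform(t1))
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  # identity and pure translation behave as expected
  p <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(apply_transform(p, rigid_transform()), p)
  expect_equal(apply_transform(p, rigid_transform(diag(3), c(1, 0, 0)))[1, ],
               c(1, 0, 0))
  # distances preserved
  m <- small_template()$mesh
  tm <- apply_transform(m, t1)
  i <- c(1, 5, 9); j <- c(2, 6, 10)
  expect_equal(sqrt(rowSums((tm$vertices[i, ] - tm$vertices[j, ])^2)),
               sqrt(rowSums((m$vertices[i, ] - m$vertices[j, ])^2)),
               tolerance = 1e-12)
})

test_that("rigid ICP recovers a known 10 degree / 5 mm transform", {
  m <- small_template()$mesh
  truth <- rigid_transform(rot_z(10), c(5, 0, 0))
  target <- apply_transform(m, truth)
  est <- rigid_icp(m, target)
  expect_lt(rotation_angle_deg(crossprod(est$rotation, truth$rotation)), 0.1)
  expect_lt(sqrt(sum((est$translation - truth$translation)^2)), 0.1)
})

test_that("rigid ICP on identical meshes is the identity", {
  m <- small_template()$mesh
  est <- rigid_icp(m, m)
  expect_lt(rotation_angle_deg(est$rotation), 0.01)
  expect_lt(sqrt(sum(est$translation^2)), 0.01)
})

test_that("rigid ICP aligns a vertex subset with small residual", {
  m <- small_template()$mesh
  set.seed(3)
  keep <- sort(sample(nrow(m$faces), round(0.6 * nrow(m$faces))))
  part <- ssmrec:::subset_faces(m, keep)
  part <- apply_transform(part, rigid_transform(rot_z(5), c(2, 1, 0)))
  est <- rigid_icp(part, m, trim = 0.1)
  resid <- attr(est, "residual")
  expect_lt(resid, mean(edge_lengths(m)))
})

test_that("non-rigid registration of a mesh onto itself is the identity map", {
  m <- small_template()$mesh
  cs <- nonrigid_icp(m, m, rigid_prealign = FALSE)
  expect_lt(max(abs(cs$coordinates - m$vertices)), 1e-3)
  expect_true(all(cs$valid_mask))
})

test_that("non-rigid registration recovers a known smooth 3 mm deformation", {
  m <- big_template()$mesh
  vn <- vertex_normals(m)
  g <- 3 * sin(2 * pi * (m$vertices %*% c(0.5, 0.6, 0.62)) / 60)
  deformed <- triangle_mesh(m$vertices + vn * as.vector(g), m$faces)
  cs <- nonrigid_icp(m, deformed, rigid_prealign = FALSE)
  err <- sqrt(rowSums((cs$coordinates - deformed$vertices)^2))
  expect_gte(mean(err < 0.5), 0.95)
})

test_that("vertices over a deleted region are flagged invalid", {
  m <- big_template()$mesh
  cent <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
             m$vertices[m$faces[, 3], ]) / 3
  keep <- which(cent[, 1] < 0)
  half <- ssmrec:::subset_faces(m, keep)
  deleted_verts <- setdiff(seq_len(nrow(m$vertices)), unique(as.vector(m$faces[keep, ])))
  cs <- nonrigid_icp(m, half, nonrigid_params(max_corr_dist = 3))
  expect_gte(mean(!cs$valid_mask[deleted_verts]), 0.90)
  kept_verts <- unique(as.vector(m$faces[keep, ]))
  expect_gte(mean(cs$valid_mask[kept_verts]), 0.95)
})

test_that("registration parameter validation", {
  expect_error(nonrigid_params(stiffness_schedule = c(1, 5)), "descending")
  expect_error(nonrigid_params(stiffness_schedule = numeric(0)), "descending")
  expect_error(nonrigid_params(max_corr_dist = 0), "max_corr_dist")
  m <- small_template()$mesh
  expect_error(nonrigid_icp(m, triangle_mesh(diag(3) * 0, matrix(integer(0), 0, 3))),
               "empty")
})

test_that("registration is deterministic", {
  m <- small_template()$mesh
  vn <- vertex_normals(m)
  g <- 2 * sin(m$vertices[, 3] / 10)
  deformed <- triangle_mesh(m$vertices + vn * g, m$faces)
  a <- nonrigid_icp(m, deformed)
  b <- nonrigid_icp(m, deformed)
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$valid_mask, b$valid_mask)
})
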