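#' @importFrom Matrix Diagonal sparseMatrix rowSums
#' @importFrom Rcpp sourceCpp
#' @useDynLib ssmrec, .registration = TRUE
NULL

# run code with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# icosahedron + midpoint subdivision onto the unit sphere
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ek <- key(e[, 1], e[, 2])
    uk <- !duplicated(ek)
    mididx <- stats::setNames(nrow(v) + seq_len(sum(uk)), ek[uk])
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(.rowSums(mids^2, nrow(mids), 3))
    v <- rbind(v, mids)
    m12 <- mididx[key(f[, 1], f[, 2])]
    m23 <- mididx[key(f[, 2], f[, 3])]
    m31 <- mididx[key(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(m12, f[, 2], m23),
               cbind(m23, f[, 3], m31), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = unname(f))
}

# radial profile of the synthetic hemipelvis: a flanged, dented, twisted
# ellipsoid, star-shaped about the origin so that every direction u maps to
# exactly one surface point rho(u) * u
hemipelvis_rho <- function(u) {
  axes <- c(42, 30, 26)
  w_wing <- unit3(c(0, 0.25, 1))    # iliac-wing flange, superior
  w_cup <- c(1, 0, 0)               # acetabular dent, lateral
  w_isch <- unit3(c(0, -0.3, -1))   # ischial bulge, inferior
  ang <- function(w) acos(pmin(1, pmax(-1, u %*% w)))
  g <- 0.45 * exp(-ang(w_wing)^2 / (2 * 0.45^2)) -
       0.22 * exp(-ang(w_cup)^2 / (2 * 0.35^2)) +
       0.30 * exp(-ang(w_isch)^2 / (2 * 0.40^2)) +
       0.08 * u[, 2] * u[, 3]       # gentle twist so no plane of symmetry
  r_ell <- 1 / sqrt(.rowSums(sweep(u, 2, axes, "/")^2, nrow(u), 3))
  as.vector(r_ell * (1 + g))
}

surface_point <- function(u) {
  u <- matrix(u, ncol = 3L)
  u <- u / sqrt(.rowSums(u^2, nrow(u), 3))
  u * hemipelvis_rho(u)
}

# circumscribed circle of three 3D points: exact center, radius, plane basis
circumcircle3d <- function(p1, p2, p3) {
  a <- p2 - p1; b <- p3 - p1
  n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  nn <- sum(n^2)
  if (nn < 1e-18) stop("collinear points for circumcircle")
  aa <- sum(a^2); bb <- sum(b^2)
  # center = p1 + (|a|^2 (b x n) + |b|^2 (n x a)) / (2 |n|^2)
  bxn <- c(b[2] * n[3] - b[3] * n[2], b[3] * n[1] - b[1] * n[3], b[1] * n[2] - b[2] * n[1])
  nxa <- c(n[2] * a[3] - n[3] * a[2], n[3] * a[1] - n[1] * a[3], n[1] * a[2] - n[2] * a[1])
  center <- p1 + (aa * bxn + bb * nxa) / (2 * nn)
  radius <- sqrt(sum((p1 - center)^2))
  e1 <- unit3(p1 - center)
  nhat <- unit3(n)
  e2 <- c(nhat[2] * e1[3] - nhat[3] * e1[2], nhat[3] * e1[1] - nhat[1] * e1[3],
          nhat[1] * e1[2] - nhat[2] * e1[1])
  list(center = center, radius = radius, e1 = e1, e2 = e2, normal = nhat)
}

# n points on the circumcircle of the exact surface points along directions
# u_start, u_mid, u_end, spread between the angles of start and end
arc_points <- function(u_start, u_mid, u_end, n) {
  s <- surface_point(rbind(u_start, u_mid, u_end))
  cc <- circumcircle3d(s[1, ], s[2, ], s[3, ])
  angle_of <- function(p) atan2(sum((p - cc$center) * cc$e2), sum((p - cc$center) * cc$e1))
  a0 <- angle_of(s[1, ])   # = 0 by construction of e1
  a2 <- angle_of(s[3, ])
  am <- angle_of(s[2, ])
  # walk from a0 to a2 through am
  if (am < 0) { a2 <- -abs(a2); } else a2 <- abs(a2)
  th <- seq(a0, a2, length.out = n)
  pts <- t(vapply(th, function(t) cc$center + cc$radius * (cos(t) * cc$e1 + sin(t) * cc$e2),
                  numeric(3)))
  list(points = pts, radius = cc$radius, center = cc$center)
}

#' Synthetic hemipelvis template with ground-truth landmarks
#'
#' Generates a deterministic, smooth, closed surface that evokes a left
#' hemipelvis — a flanged (iliac wing), dented (acetabular cup) and twisted
#' ellipsoid — together with the five clinical landmark regions placed on
#' constructed geometry whose parameters are known exactly: the
#' iliopectineal and ischial body line landmarks lie on exact circular arcs
#' (so their lengths and curvature radii are known), the four acetabular rim
#' landmarks lie on an exact circle (known diameter), and the twelve
#' quadrilateral-plate landmarks lie in a plane of known inclination to the
#' superior-inferior axis. Landmark-carrying mesh vertices are snapped onto
#' the exact constructed positions, which is what makes the clinical
#' parameter operators exactly testable. The stylised anatomy is synthetic
#' by design, not patient-derived.
#'
#' @param subdivisions mesh refinement level; `3` gives ~2500 vertices and a
#'   ~80 mm bone. Deterministic: same input, bit-identical output.
#' @return list with `mesh` (a [triangle_mesh()]), `landmarks` (a
#'   [landmark_set()] with `truth` filled in).
#' @export
make_template <- function(subdivisions = 3L) {
  if (subdivisions < 2L) stop("subdivisions must be >= 2")
  ico <- icosphere(subdivisions + 1L)
  v <- surface_point(ico$vertices)
  mesh <- triangle_mesh(v, ico$faces, name = sprintf("synthetic_template_s%d", subdivisions))

  # --- constructed landmark geometry -----------------------------------------
  # iliopectineal line: 12 points on an exact arc running anterior-superior
  ip <- arc_points(unit3(c(0.25, 0.45, 0.86)), unit3(c(0.55, 0.72, 0.42)),
                   unit3(c(0.62, 0.62, -0.48)), 12L)
  # ischial body line: 8 points on an exact arc in the inferior region
  isch <- arc_points(unit3(c(0.55, -0.25, -0.80)), unit3(c(0.28, -0.52, -0.81)),
                     unit3(c(-0.08, -0.62, -0.78)), 8L)
  # acetabular rim: circle through three exact surface points around the cup
  rot_about <- function(axis, theta, vec) {
    a <- unit3(axis)
    vec * cos(theta) + c(a[2] * vec[3] - a[3] * vec[2],
                         a[3] * vec[1] - a[1] * vec[3],
                         a[1] * vec[2] - a[2] * vec[1]) * sin(theta) +
      a * sum(a * vec) * (1 - cos(theta))
  }
  rim_dir <- function(theta) rot_about(c(1, 0, 0), theta, unit3(c(cos(0.54), sin(0.54), 0)))
  rim3 <- surface_point(rbind(rim_dir(0), rim_dir(2 * pi / 3), rim_dir(4 * pi / 3)))
  rim_cc <- circumcircle3d(rim3[1, ], rim3[2, ], rim3[3, ])
  rim_pts <- t(vapply(seq(0, 3 * pi / 2, by = pi / 2), function(t) {
    rim_cc$center + rim_cc$radius * (cos(t) * rim_cc$e1 + sin(t) * rim_cc$e2)
  }, numeric(3)))
  # quadrilateral plate: 12 coplanar points at an exact 55 degree slope
  slope_deg <- 55
  n_q <- c(-sin(slope_deg * pi / 180), 0, cos(slope_deg * pi / 180))
  c_q <- surface_point(c(-1, 0.05, -0.1))
  e1q <- unit3(c(cos(slope_deg * pi / 180), 0, sin(slope_deg * pi / 180)))
  e2q <- c(0, 1, 0)
  hexa <- function(r, off) t(vapply(off + seq(0, 5) * pi / 3, function(t) {
    c_q + r * (cos(t) * e1q + sin(t) * e2q)
  }, numeric(3)))
  quad_pts <- rbind(hexa(12, 0), hexa(6, pi / 6))

  # --- snap nearest mesh vertices onto the exact landmark positions ----------
  used <- integer(0)
  snap <- function(pts) {
    idx <- integer(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      d2 <- .rowSums(sweep(v, 2, pts[i, ])^2, nrow(v), 3)
      d2[used] <- Inf
      j <- which.min(d2)
      v[j, ] <<- pts[i, ]
      used <<- c(used, j)
      idx[i] <- j
    }
    idx
  }
  regions <- list(
    iliopectineal_line = snap(ip$points),
    quadrilateral_plate = snap(quad_pts),
    ischial_body_line = snap(isch$points),
    acetabular_diameter = snap(rim_pts)
  )
  # weight-bearing dome: 30 vertices in the superior cap of the cup (no snap)
  cupax <- unit3(c(1, 0, 0.35))
  angs <- acos(pmin(1, (v / sqrt(.rowSums(v^2, nrow(v), 3))) %*% cupax))
  angs[used] <- Inf
  regions$weight_bearing_dome <- order(angs)[1:30]
  mesh$vertices <- v

  truth <- list(
    iliopectineal_radius = ip$radius,
    iliopectineal_length = polyline_length(ip$points),
    ischial_radius = isch$radius,
    ischial_length = polyline_length(isch$points),
    acetabular_diameter = 2 * rim_cc$radius,
    quadrilateral_slope = slope_deg,
    reference_axis = c(0, 0, 1)
  )
  list(mesh = mesh,
       landmarks = landmark_set(regions, reference_axis = c(0, 0, 1), truth = truth))
}

#' Population specification
#'
#' Parameters of the synthetic training population: number of shapes, number
#' of independent smooth deformation modes, their standard deviations (mm,
#' RMS per-vertex displacement per mode, strictly descending), the spatial
#' wavelength of the deformation fields, and the seed.
#'
#' @param n_shapes population size (>= n_modes + 1).
#' @param n_modes number of true deformation modes.
#' @param mode_stddevs descending positive mode scales (mm RMS per vertex).
#' @param deformation_smoothness spatial wavelength of the fields (mm).
#' @param seed integer RNG seed.
#' @return a `population_spec`.
#' @export
population_spec <- function(n_shapes = 40L, n_modes = 3L,
                            mode_stddevs = c(6, 3, 1.5),
                            deformation_smoothness = 60, seed = 1L) {
  if (length(mode_stddevs) != n_modes) stop("need one stddev per mode")
  if (any(mode_stddevs <= 0) || any(diff(mode_stddevs) >= 0))
    stop("mode_stddevs must be positive and strictly descending")
  if (n_shapes < n_modes + 1L) stop("n_shapes must be >= n_modes + 1")
  structure(list(n_shapes = as.integer(n_shapes), n_modes = as.integer(n_modes),
                 mode_stddevs = as.numeric(mode_stddevs),
                 deformation_smoothness = as.numeric(deformation_smoothness),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic training population
#'
#' Produces `n_shapes` variants of the template, each
#' `template + sum_k c_ik f_k` with coefficients drawn from
#' `N(0, stddev_k^2)` and smooth band-limited displacement fields `f_k`
#' (sinusoids of the stated wavelength in random directions) that are
#' mutually orthogonalised and normalised to unit RMS per-vertex
#' displacement. The true mode matrix and drawn coefficients are returned so
#' recovery can be verified against known truth. Reproducible by seed.
#'
#' @param template a [triangle_mesh()] (typically from [make_template()]).
#' @param spec a [population_spec()].
#' @return list with `meshes` (list of [triangle_mesh()] in template
#'   correspondence), `modes` (3V x K orthogonal matrix, columns of norm
#'   sqrt(V)), `coefficients` (n x K), `true_variances` (K; the population
#'   PCA eigenvalues implied by the construction, `stddev_k^2 * V`).
#' @export
generate_population <- function(template, spec = population_spec()) {
  V <- n_vertices(template)
  K <- spec$n_modes
  lambda <- spec$deformation_smoothness
  vn <- cpp_vertex_normals(template$vertices, template$faces - 1L)
  with_seed(spec$seed, {
    raw <- matrix(0, 3 * V, K)
    for (k in seq_len(K)) {
      wave <- unit3(stats::rnorm(3))
      phase <- stats::runif(1, 0, 2 * pi)
      g <- sin(2 * pi * (template$vertices %*% wave) / lambda + phase)
      # surface-normal displacement: the observable component of shape change
      raw[, k] <- as.vector(vn * as.vector(g))  # column-major: x, y, z blocks
    }
    Q <- qr.Q(qr(raw))
    modes <- Q * sqrt(V)  # unit RMS per-vertex displacement per unit coefficient
    coeff <- matrix(stats::rnorm(spec$n_shapes * K), spec$n_shapes, K)
    coeff <- sweep(coeff, 2, spec$mode_stddevs, "*")
  })
  meshes <- lapply(seq_len(spec$n_shapes), function(i) {
    disp <- unflatten(as.vector(modes %*% coeff[i, ]))
    triangle_mesh(template$vertices + disp, template$faces,
                  name = sprintf("%s_pop%03d", template$name, i))
  })
  list(meshes = meshes, modes = modes, coefficients = coeff,
       true_variances = spec$mode_stddevs^2 * V, spec = spec)
}

#' Fracture specification
#'
#' Parameters of a simulated fracture: number of random cut planes through
#' the bone interior, the target fraction of surface area deleted (lost
#' comminution), and the maximum rigid displacement and rotation applied to
#' the detached fragments.
#'
#' @param n_cut_planes number of cut planes.
#' @param delete_fraction target deleted surface-area fraction in `[0, 0.95)`.
#' @param displacement_mm maximum fragment translation (mm).
#' @param displacement_deg maximum fragment rotation (degrees).
#' @param seed integer RNG seed.
#' @return a `fracture_spec`.
#' @export
fracture_spec <- function(n_cut_planes = 2L, delete_fraction = 0.15,
                          displacement_mm = 5, displacement_deg = 5, seed = 1L) {
  if (delete_fraction < 0 || delete_fraction >= 0.95)
    stop("delete_fraction must be in [0, 0.95)")
  if (displacement_mm < 0 || displacement_deg < 0) stop("displacements must be >= 0")
  structure(list(n_cut_planes = as.integer(n_cut_planes),
                 delete_fraction = as.numeric(delete_fraction),
                 displacement_mm = as.numeric(displacement_mm),
                 displacement_deg = as.numeric(displacement_deg),
                 seed = as.integer(seed)),
            class = "fracture_spec")
}

rodrigues <- function(axis, theta) {
  a <- unit3(axis)
  Kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * Kx %*% Kx
}

#' Simulate a fracture of a closed shape
#'
#' Partitions the surface by random planes through the interior into
#' fragments, deletes a contiguous region of roughly `delete_fraction` of
#' the surface area (grown from a random seed face, emulating lost or
#' unusable fragments), and rigidly displaces every fragment except the
#' largest within the specified bounds. The input shape is the ground truth.
#'
#' @param shape a closed [triangle_mesh()].
#' @param spec a [fracture_spec()].
#' @return list with `fragments` (list of [triangle_mesh()]), `merged`
#'   (their [merge_fragments()] union), `ground_truth` (the input),
#'   `achieved_delete_fraction`.
#' @export
simulate_fracture <- function(shape, spec = fracture_spec()) {
  validate_mesh(shape)
  f <- shape$faces
  v <- shape$vertices
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
             v[f[, 3], , drop = FALSE]) / 3
  ab <- v[f[, 2], ] - v[f[, 1], ]
  ac <- v[f[, 3], ] - v[f[, 1], ]
  areas <- sqrt(.rowSums(cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])^2,
                         nrow(f), 3)) / 2
  total_area <- sum(areas)
  origin <- colMeans(v)
  res <- with_seed(spec$seed, {
    normals <- matrix(stats::rnorm(3 * spec$n_cut_planes), ncol = 3)
    offsets <- matrix(stats::runif(3 * spec$n_cut_planes, -0.1, 0.1) *
                        bbox_diagonal(shape) / 3, ncol = 3)
    deleted <- rep(FALSE, nrow(f))
    if (spec$delete_fraction > 0) {
      adj <- face_adjacency(f)
      seedf <- sample.int(nrow(f), 1)
      q <- seedf
      acc <- 0
      while (length(q) > 0 && acc < spec$delete_fraction * total_area) {
        cur <- q[1]; q <- q[-1]
        if (deleted[cur]) next
        deleted[cur] <- TRUE
        acc <- acc + areas[cur]
        q <- c(q, adj[[cur]][!deleted[adj[[cur]]]])
      }
    }
    disp <- lapply(seq_len(2^spec$n_cut_planes), function(i) {
      list(R = rodrigues(stats::rnorm(3),
                         stats::runif(1, 0, spec$displacement_deg * pi / 180)),
           t = unit3(stats::rnorm(3)) * stats::runif(1, 0, spec$displacement_mm))
    })
    list(normals = normals, offsets = offsets, deleted = deleted, disp = disp)
  })
  keep <- which(!res$deleted)
  code <- rep(0L, nrow(f))
  for (j in seq_len(spec$n_cut_planes)) {
    nj <- unit3(res$normals[j, ])
    side <- (sweep(cent, 2, origin + res$offsets[j, ]) %*% nj) > 0
    code <- code * 2L + as.integer(side)
  }
  groups <- split(keep, code[keep])
  sizes <- vapply(groups, function(g) sum(areas[g]), numeric(1))
  largest <- which.max(sizes)
  fragments <- lapply(seq_along(groups), function(i) {
    fr <- subset_faces(shape, groups[[i]], name = sprintf("%s_frag%d", shape$name, i))
    if (i != largest && (spec$displacement_mm > 0 || spec$displacement_deg > 0)) {
      d <- res$disp[[i]]
      ctr <- colMeans(fr$vertices)
      fr$vertices <- sweep(sweep(fr$vertices, 2, ctr) %*% t(d$R), 2, -(ctr + d$t))
    }
    fr
  })
  list(fragments = fragments,
       merged = merge_fragments(fragments, name = paste0(shape$name, "_fractured")),
       ground_truth = shape,
       achieved_delete_fraction = sum(areas[res$deleted]) / total_area)
}

# faces sharing an edge; list of integer vectors
face_adjacency <- function(f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste0(pmin(e[, 1], e[, 2]), "_", pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(f)), 3L)
  pairs <- split(fid, key)
  adj <- vector("list", nrow(f))
  for (p in pairs) {
    if (length(p) == 2L) {
      adj[[p[1]]] <- c(adj[[p[1]]], p[2])
      adj[[p[2]]] <- c(adj[[p[2]]], p[1])
    }
  }
  adj
}
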