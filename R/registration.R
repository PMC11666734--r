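#' Rigid transform
#'
#' A proper rigid-body motion: `x -> R x + t` with `det(R) = +1` (no
#' scaling, no reflection).
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation length-3 translation in mm.
#' @return a `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(crossprod(t$rotation, t$translation)))
}

#' @rdname rigid_transform
#' @param a,b transforms; returns the composition "a after b".
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to a mesh or point matrix
#'
#' Preserves all pairwise distances exactly (up to floating point).
#'
#' @param mesh a [triangle_mesh()] or an `n x 3` point matrix.
#' @param t a [rigid_transform()].
#' @return the transformed object of the same type.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is_triangle_mesh(mesh)) {
    v <- transform_points(mesh$vertices, t)
    return(triangle_mesh(v, mesh$faces, name = mesh$name))
  }
  transform_points(as.matrix(mesh), t)
}

transform_points <- function(p, t) {
  sweep(p %*% t(t$rotation), 2, -t$translation)
}

# least-squares rigid fit (Kabsch/Umeyama without scaling) of rows of S onto T
kabsch <- function(S, T, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(S))
  w <- weights / sum(weights)
  cs <- colSums(S * w); ct <- colSums(T * w)
  H <- crossprod(sweep(S, 2, cs) * w, sweep(T, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Rigid iterative closest point alignment
#'
#' Aligns `source` onto `target` with a proper rigid transform by iterating
#' closest-point correspondence and a weighted Kabsch fit; the objective
#' (mean closest-point distance) is non-increasing. No scaling is applied.
#' Initialisation is the centroid shift.
#'
#' To make partial-to-full alignment robust (fragments onto a template), the
#' worst-matching correspondences can be trimmed via `trim`.
#'
#' @param source,target [triangle_mesh()] objects (`source` is moved).
#' @param max_iters iteration cap.
#' @param tol convergence tolerance on the change of mean residual (mm).
#' @param trim fraction in `[0, 0.5]` of worst correspondences ignored in the
#'   fit (0 = plain ICP).
#' @return a [rigid_transform()] with attributes `"residual"` (final mean
#'   closest-point distance, mm) and `"n_iterations"`.
#' @export
rigid_icp <- function(source, target, max_iters = 300L, tol = 1e-5, trim = 0) {
  validate_mesh(source); validate_mesh(target)
  if (n_faces(source) == 0L || n_faces(target) == 0L)
    stop("rigid_icp needs two non-empty meshes")
  grid <- surface_index(target)
  S <- source$vertices
  t_cur <- rigid_transform(diag(3), colMeans(target$vertices) - colMeans(S))
  prev <- Inf
  iters <- 0L
  for (i in seq_len(max_iters)) {
    iters <- i
    X <- transform_points(S, t_cur)
    q <- cpg_query(grid, X)
    d <- q$dist
    w <- rep(1, length(d))
    if (trim > 0) w[d > stats::quantile(d, 1 - trim, type = 7)] <- 0
    obj <- mean(d)
    if (is.finite(prev) && prev - obj < tol) break
    prev <- obj
    t_cur <- kabsch(S, q$points, weights = w)
  }
  X <- transform_points(S, t_cur)
  resid <- mean(cpg_query(grid, X)$dist)
  if (resid > 0.5 * bbox_diagonal(target))
    warning("rigid_icp: poor overlap after alignment (mean residual ",
            signif(resid, 3), " mm); returning centroid alignment quality fit")
  attr(t_cur, "residual") <- resid
  attr(t_cur, "n_iterations") <- iters
  t_cur
}

#' Non-rigid ICP parameters
#'
#' Knobs of the template-to-target non-rigid registration: an annealed,
#' strictly descending stiffness schedule, the correspondence gates
#' (distance and normal compatibility) and the global smoothing weight.
#' Fragments displaced further than `max_corr_dist` should not drag the
#' template, hence the 10 mm default gate.
#'
#' @param stiffness_schedule strictly descending positive weights; each level
#'   runs up to `inner_iterations` correspondence/solve rounds.
#' @param inner_iterations per-level iteration cap.
#' @param max_corr_dist correspondence rejection distance (mm).
#' @param max_normal_angle correspondence rejection angle (degrees).
#' @param smoothing_weight global multiplier on the Laplacian regulariser.
#' @param point_weight weight in `(0, 1]` of the point-to-point part of the
#'   data term; the remainder is point-to-plane. A small value constrains
#'   surface mismatch along the target normal while leaving tangential
#'   positions to the regulariser, which suppresses the tangential sliding
#'   that pure closest-point matching cannot control.
#' @param tangential_weight weight anchoring the tangential component of
#'   each vertex's displacement to the rest shape. Tangential motion is
#'   invisible to closed-surface geometric matching (any smooth tangential
#'   reparametrisation fits equally well), so without this anchor the
#'   fixed-point iteration drifts along the surface; the anchor selects the
#'   minimal-tangential-motion correspondence.
#' @return a `nonrigid_params` list.
#' @export
nonrigid_params <- function(stiffness_schedule = c(100, 50, 20, 10, 5, 2),
                            inner_iterations = 10L,
                            max_corr_dist = 10,
                            max_normal_angle = 60,
                            smoothing_weight = 0.5,
                            point_weight = 0.1,
                            tangential_weight = 0.1) {
  if (length(stiffness_schedule) == 0L || any(stiffness_schedule <= 0) ||
      any(diff(stiffness_schedule) >= 0))
    stop("stiffness_schedule must be strictly descending and positive")
  if (max_corr_dist <= 0) stop("max_corr_dist must be > 0")
  if (smoothing_weight <= 0) stop("smoothing_weight must be > 0")
  if (point_weight <= 0 || point_weight > 1) stop("point_weight must be in (0, 1]")
  if (tangential_weight < 0) stop("tangential_weight must be >= 0")
  structure(list(stiffness_schedule = as.numeric(stiffness_schedule),
                 inner_iterations = as.integer(inner_iterations),
                 max_corr_dist = as.numeric(max_corr_dist),
                 max_normal_angle = as.numeric(max_normal_angle),
                 smoothing_weight = as.numeric(smoothing_weight),
                 point_weight = as.numeric(point_weight),
                 tangential_weight = as.numeric(tangential_weight)),
            class = "nonrigid_params")
}

#' Corresponded shape
#'
#' A shape expressed on the template topology: one 3D point per template
#' vertex, plus a per-vertex flag saying whether that point was supported by
#' actual target data (`TRUE`) or carried by regularisation only (`FALSE`).
#'
#' @param coordinates `V x 3` matrix (template vertex order), mm.
#' @param valid_mask logical vector of length `V`.
#' @param template_id identifier of the template the vertex order refers to.
#' @return a `corresponded_shape` object.
#' @export
corresponded_shape <- function(coordinates, valid_mask = NULL, template_id = "") {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be V x 3")
  if (!all(is.finite(coordinates))) stop("non-finite coordinates")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nrow(coordinates))
  if (length(valid_mask) != nrow(coordinates)) stop("valid_mask length mismatch")
  structure(list(coordinates = coordinates, valid_mask = as.logical(valid_mask),
                 template_id = as.character(template_id)[1]),
            class = "corresponded_shape")
}

#' @export
#' @method print corresponded_shape
print.corresponded_shape <- function(x, ...) {
  cat(sprintf("corresponded_shape on '%s': %d vertices, %.1f%% with data support\n",
              x$template_id, nrow(x$coordinates), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Non-rigid iterative closest point registration
#'
#' Deforms the template onto a target surface, producing dense point-to-point
#' correspondence. Each round finds closest points on the target for the
#' current template vertices, gates them by distance and normal
#' compatibility, and solves for the total displacement field `D` from the
#' rest shape, `(W + alpha L) D = W (c - v)` per coordinate, where `L` is the
#' symmetrically normalised graph Laplacian of the template and the
#' stiffness `alpha` anneals down the schedule. Regularising the total
#' displacement (rather than per-round increments) keeps vertices without a
#' valid correspondence — beyond `max_corr_dist`, or facing away by more
#' than `max_normal_angle` — anchored to the smooth extension of their
#' neighbours' motion instead of slowly creeping onto the wrong surface,
#' which is what lets a full template be registered to the partial surface
#' of a fractured bone. The registration direction is template onto target
#' throughout.
#'
#' Deterministic: grid queries and sparse Cholesky solves only.
#'
#' @param template [triangle_mesh()] defining topology and rest shape.
#' @param target [triangle_mesh()] to register onto (may be partial).
#' @param params a [nonrigid_params()].
#' @param initial_coords optional `V x 3` start coordinates for the template
#'   vertices (defaults to the template's own, after rigid pre-alignment).
#' @param rigid_prealign run [rigid_icp()] first.
#' @return a [corresponded_shape()] with attribute `"mean_valid_dist"`.
#' @export
nonrigid_icp <- function(template, target, params = nonrigid_params(),
                         initial_coords = NULL, rigid_prealign = TRUE) {
  validate_mesh(template)
  if (!is_triangle_mesh(target) || n_faces(target) == 0L)
    stop("empty target mesh")
  if (!inherits(params, "nonrigid_params")) stop("params must be nonrigid_params()")
  F0 <- faces0(template)
  X <- if (is.null(initial_coords)) template$vertices else as.matrix(initial_coords)
  if (rigid_prealign) {
    # align the (possibly partial) target onto the template — the well-posed
    # direction — and move the template by the inverse
    tmesh <- triangle_mesh(X, template$faces)
    tr <- rigid_icp(target, tmesh, trim = 0.2)
    X <- transform_points(X, invert_transform(tr))
  }
  grid <- surface_index(target)
  fn_target <- cpp_face_normals(target$vertices, faces0(target))
  cos_gate <- cos(params$max_normal_angle * pi / 180)
  V <- nrow(X)
  V0 <- X  # rest shape the displacement field is regularised against
  # 3V x 3V system in vertex-major ordering (x1,y1,z1,x2,...): Laplacian acts
  # per coordinate, the point-to-plane data term couples coordinates within a
  # vertex through the 3x3 blocks  w_i [beta I + (1-beta) n n']
  Lk <- Matrix::kronecker(normalized_laplacian(template), Matrix::Diagonal(3))
  bi <- rep(3 * (seq_len(V) - 1), each = 9L) + rep(rep(1:3, each = 3), V)
  bj <- rep(3 * (seq_len(V) - 1), each = 9L) + rep(rep(1:3, times = 3), V)
  sym <- function(a) methods::as(Matrix::forceSymmetric(a), "CsparseMatrix")
  # symbolic analysis once on the union pattern (a PD stand-in with dense
  # 3x3 blocks); per-round matrices have a pattern subset of this
  full_blocks <- matrix(rep(c(1, .5, .5, .5, 1, .5, .5, .5, 1), each = V), V, 9)
  A_full <- sym(Lk + Matrix::sparseMatrix(i = bi, j = bj, x = as.vector(t(full_blocks)),
                                          dims = c(3 * V, 3 * V)))
  ch <- Matrix::Cholesky(A_full, LDL = FALSE, super = TRUE)
  gate <- function(X) {
    q <- cpg_query(grid, X)
    vn <- cpp_vertex_normals(X, F0)
    fn <- fn_target[q$face + 1L, , drop = FALSE]
    # the normal gate only makes sense at a distance: a vertex already lying
    # on the target surface is a valid correspondence regardless
    valid <- q$dist < 1e-9 |
      (q$dist <= params$max_corr_dist & rowSums(vn * fn) >= cos_gate)
    list(q = q, valid = valid, n = fn)
  }
  beta <- params$point_weight
  mt <- params$tangential_weight
  eye <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = V), V, 9)
  datab <- NULL
  for (alpha in params$stiffness_schedule) {
    for (inner in seq_len(params$inner_iterations)) {
      g <- gate(X)
      if (!any(g$valid)) {
        warning("nonrigid_icp: no valid correspondences at stiffness ", alpha)
        break
      }
      if (inner == 1L) {
        # weights and normals are lagged within a stiffness level: the factor
        # is computed once per level, later rounds only refresh the
        # right-hand side with the new closest points
        w <- as.numeric(g$valid)
        # per-vertex 3x3 blocks (row-major): data term w [beta I + (1-beta) nn']
        # plus the tangential anchor mt (I - nn'), which has no right-hand
        # side (it pulls the tangential displacement toward zero)
        nn <- g$n
        nnT <- cbind(nn[, 1]^2, nn[, 1] * nn[, 2], nn[, 1] * nn[, 3],
                     nn[, 2] * nn[, 1], nn[, 2]^2, nn[, 2] * nn[, 3],
                     nn[, 3] * nn[, 1], nn[, 3] * nn[, 2], nn[, 3]^2)
        datab <- w * (beta * eye + (1 - beta) * nnT)
        blocks <- datab + mt * (eye - nnT)
        M <- Matrix::sparseMatrix(i = bi, j = bj, x = as.vector(t(blocks)),
                                  dims = c(3 * V, 3 * V))
        A <- sym(params$smoothing_weight * alpha * Lk + M)
        ch <- Matrix::update(ch, A)
      }
      r <- g$q$points - V0
      rb <- cbind(datab[, 1] * r[, 1] + datab[, 2] * r[, 2] + datab[, 3] * r[, 3],
                  datab[, 4] * r[, 1] + datab[, 5] * r[, 2] + datab[, 6] * r[, 3],
                  datab[, 7] * r[, 1] + datab[, 8] * r[, 2] + datab[, 9] * r[, 3])
      D <- matrix(as.numeric(Matrix::solve(ch, as.vector(t(rb)))), ncol = 3, byrow = TRUE)
      Xnew <- V0 + D
      delta <- max(abs(Xnew - X))
      X <- Xnew
      if (delta < 0.01) break
    }
  }
  g <- gate(X)
  out <- corresponded_shape(X, g$valid, template_id = template$name)
  attr(out, "mean_valid_dist") <- if (any(g$valid)) mean(g$q$dist[g$valid]) else NA_real_
  out
}
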