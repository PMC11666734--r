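#' Root mean square error between corresponded shapes
#'
#' RMSE over the Euclidean distances of corresponded vertex pairs, optionally
#' restricted to a vertex index subset (e.g. the 66 plate-fitting landmark
#' coordinates). Symmetric in its arguments.
#'
#' @param a,b [corresponded_shape()] objects (or `V x 3` matrices) on the
#'   same template.
#' @param indices optional vertex indices to restrict to.
#' @return RMSE in mm.
#' @export
rmse <- function(a, b, indices = NULL) {
  A <- as_corresponded(a)$coordinates
  B <- as_corresponded(b)$coordinates
  if (!all(dim(A) == dim(B))) stop("shapes are not on the same template")
  if (!is.null(indices)) {
    if (length(indices) == 0L) stop("empty index list")
    if (min(indices) < 1L || max(indices) > nrow(A)) stop("index out of range")
    A <- A[indices, , drop = FALSE]
    B <- B[indices, , drop = FALSE]
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-vertex distance map
#'
#' Corresponded vertex-pair distances plus a summary consistent with
#' [rmse()]; the per-vertex scalar can be written to PLY as a `quality`
#' property for colour-mapped display.
#'
#' @param a,b [corresponded_shape()] objects on the same template.
#' @return a `distance_map`: list with `per_vertex_distance` (mm) and
#'   `summary` (`rmse`, `mean`, `max`).
#' @export
distance_map <- function(a, b) {
  A <- as_corresponded(a)$coordinates
  B <- as_corresponded(b)$coordinates
  if (!all(dim(A) == dim(B))) stop("shapes are not on the same template")
  d <- sqrt(rowSums((A - B)^2))
  structure(list(per_vertex_distance = d,
                 summary = list(rmse = sqrt(mean(d^2)), mean = mean(d), max = max(d))),
            class = "distance_map")
}

#' Length of an open polyline
#'
#' Sum of consecutive segment lengths of ordered 3D points; used for the
#' iliopectineal and ischial body line lengths.
#'
#' @param points ordered `n x 3` matrix, `n >= 2`.
#' @return length in mm.
#' @export
polyline_length <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 2L) stop("polyline needs at least 2 points")
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# total-least-squares plane: list(center, basis e1,e2, normal, sv)
tls_plane <- function(points) {
  p <- as.matrix(points)
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  list(center = ctr, e1 = sv$v[, 1], e2 = sv$v[, 2], normal = sv$v[, 3], d = sv$d)
}

#' Radius of the best-fit circle through 3D points
#'
#' Projects the points onto their total-least-squares plane, fits a circle
#' algebraically (Kasa fit) and refines it by geometric Gauss-Newton. This
#' is the curvature radius used for the iliopectineal and ischial body
#' lines. Invariant under rigid motion and point order.
#'
#' @param points `n x 3` matrix, `n >= 3`, not collinear.
#' @return radius in mm, with attributes `"center"` (3D) and
#'   `"rms_residual"` (mm, in-plane).
#' @export
fit_circle_radius <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3L) stop("circle fit needs at least 3 points")
  pl <- tls_plane(p)
  if (pl$d[2] < 1e-9 * max(pl$d[1], 1))
    stop("collinear points: circle radius is infinite")
  q <- sweep(p, 2, pl$center) %*% cbind(pl$e1, pl$e2)  # in-plane 2D coords
  x <- q[, 1]; y <- q[, 2]
  # Kasa: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.coef(qr(A), x^2 + y^2)
  a <- sol[1]; b <- sol[2]
  r <- sqrt(sol[3] + a^2 + b^2)
  # geometric refinement: minimise sum (|p - c| - r)^2
  for (i in 1:50) {
    dx <- x - a; dy <- y - b
    di <- sqrt(dx^2 + dy^2)
    if (any(di < 1e-12)) break
    J <- cbind(-dx / di, -dy / di, -1)
    res <- di - r
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 3))
    step[is.na(step)] <- 0
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  center3d <- pl$center + a * pl$e1 + b * pl$e2
  structure(r, center = center3d,
            rms_residual = sqrt(mean((sqrt((x - a)^2 + (y - b)^2) - r)^2)))
}

#' Acetabular diameter from its four rim landmarks
#'
#' Twice the radius of the least-squares circle through the four acetabular
#' rim points (same fit as [fit_circle_radius()]).
#'
#' @param points `4 x 3` matrix.
#' @return diameter in mm.
#' @export
acetabular_diameter <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) != 4L) stop("acetabular diameter needs exactly 4 points")
  2 * as.numeric(fit_circle_radius(p))
}

#' Quadrilateral-plate slope
#'
#' Fits a total-least-squares plane to the quadrilateral-plate landmarks and
#' returns the dihedral angle between that plane and the plane orthogonal to
#' the reference (superior-inferior) axis, in `[0, 90]` degrees: coplanar
#' landmarks whose normal is parallel to the axis score 0 degrees. Invariant
#' under axis negation.
#'
#' @param points `n x 3` matrix, `n >= 3`, spanning a plane.
#' @param reference_axis unit 3-vector.
#' @return slope in degrees.
#' @export
quadrilateral_slope <- function(points, reference_axis = c(0, 0, 1)) {
  p <- as.matrix(points)
  axis <- as.numeric(reference_axis)
  na <- sqrt(sum(axis^2))
  if (na < 1e-12) stop("reference_axis must be non-zero")
  axis <- axis / na
  pl <- tls_plane(p)
  if (pl$d[2] < 1e-9 * max(pl$d[1], 1)) stop("degenerate (collinear) landmark plane")
  acos(pmin(1, abs(sum(pl$normal * axis)))) * 180 / pi
}

#' Landmark set of clinical regions
#'
#' Named clinical regions as ordered template vertex-index lists. The five
#' regions carry 12 + 12 + 8 + 4 + 30 = 66 landmarks: iliopectineal line,
#' quadrilateral plate, ischial body line, acetabular rim (diameter) and
#' weight-bearing acetabular dome (the dome contributes to regional RMSE
#' only, no scalar parameter).
#'
#' @param regions named list of integer vectors (1-based template vertex
#'   indices); line regions are ordered along the line.
#' @param reference_axis template superior-inferior axis for the slope.
#' @param truth optional list of constructed ground-truth parameter values
#'   (synthetic templates record these).
#' @return a `landmark_set`.
#' @export
landmark_set <- function(regions, reference_axis = c(0, 0, 1), truth = NULL) {
  expected <- c(iliopectineal_line = 12L, quadrilateral_plate = 12L,
                ischial_body_line = 8L, acetabular_diameter = 4L,
                weight_bearing_dome = 30L)
  for (nm in names(expected)) {
    if (is.null(regions[[nm]])) stop("missing landmark region '", nm, "'")
    if (length(regions[[nm]]) != expected[[nm]])
      stop("region '", nm, "' must have ", expected[[nm]], " landmarks, got ",
           length(regions[[nm]]))
  }
  all_idx <- unlist(regions[names(expected)], use.names = FALSE)
  if (length(all_idx) != 66L) stop("landmark set must total 66 indices")
  structure(list(regions = lapply(regions[names(expected)], as.integer),
                 reference_axis = as.numeric(reference_axis), truth = truth),
            class = "landmark_set")
}

#' @rdname landmark_set
#' @param path JSON file with fields `regions` (1-based indices) and
#'   `reference_axis`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(j$regions, reference_axis = j$reference_axis %||% c(0, 0, 1),
               truth = j$truth)
}

#' @rdname landmark_set
#' @param landmarks a `landmark_set` to write.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(regions = landmarks$regions,
                            reference_axis = landmarks$reference_axis,
                            truth = landmarks$truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' All landmark indices of a set
#' @param landmarks a [landmark_set()].
#' @return integer vector of the 66 template vertex indices.
#' @export
landmark_indices <- function(landmarks) {
  unlist(landmarks$regions, use.names = FALSE)
}

#' The six plate-fitting clinical parameters of a shape
#'
#' Extracts each landmark region by template index and measures: (1)
#' iliopectineal line length and curvature radius, (2) ischial body line
#' length and curvature radius, (3) acetabular diameter, (4) quadrilateral
#' slope. The weight-bearing dome carries no scalar parameter (it enters the
#' regional RMSE only). Because landmarks are template indices, the same
#' measurements apply to any shape in correspondence.
#'
#' @param shape a [corresponded_shape()].
#' @param landmarks a [landmark_set()].
#' @param reference_axis overrides the landmark file's axis if given.
#' @return a `clinical_parameters` list: `iliopectineal_length`,
#'   `iliopectineal_radius`, `ischial_length`, `ischial_radius`,
#'   `acetabular_diameter`, `quadrilateral_slope`.
#' @export
clinical_parameters <- function(shape, landmarks, reference_axis = NULL) {
  shape <- as_corresponded(shape)
  co <- shape$coordinates
  axis <- reference_axis %||% landmarks$reference_axis
  pts <- function(region) {
    idx <- landmarks$regions[[region]]
    if (is.null(idx)) stop("missing landmark region '", region, "'")
    co[idx, , drop = FALSE]
  }
  ip <- pts("iliopectineal_line")
  isch <- pts("ischial_body_line")
  structure(list(
    iliopectineal_length = polyline_length(ip),
    iliopectineal_radius = as.numeric(fit_circle_radius(ip)),
    ischial_length = polyline_length(isch),
    ischial_radius = as.numeric(fit_circle_radius(isch)),
    acetabular_diameter = acetabular_diameter(pts("acetabular_diameter")),
    quadrilateral_slope = quadrilateral_slope(pts("quadrilateral_plate"), axis)
  ), class = "clinical_parameters")
}

#' Absolute differences between two sets of clinical parameters
#'
#' Elementwise `|a - b|`; lengths, radii and diameter in mm, slope in
#' degrees. Symmetric.
#'
#' @param a,b `clinical_parameters` lists.
#' @return named numeric vector of absolute differences.
#' @export
compare_parameters <- function(a, b) {
  nm <- c("iliopectineal_length", "iliopectineal_radius", "ischial_length",
          "ischial_radius", "acetabular_diameter", "quadrilateral_slope")
  vapply(nm, function(k) abs(a[[k]] - b[[k]]), numeric(1))
}

#' Median and interquartile range
#'
#' Median with 25th and 75th percentile by linear interpolation between
#' order statistics (quantile type 7), the convention used to summarise
#' per-patient reconstruction errors.
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `q25`, `q75`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values))) stop("non-empty numeric values required")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(median = stats::median(values), q25 = q[1], q75 = q[2])
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups (e.g. reconstruction errors
#' of elementary vs associate fracture types). U is computed from midrank
#' sums; the two-sided p-value is exact (full enumeration of rank
#' assignments via the null distribution) when the pooled sample has at most
#' 12 observations and no ties, and otherwise uses the normal approximation
#' with tie and continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact_max pooled-size limit for the exact branch.
#' @return list with `U` (statistic of `group_a`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 12L) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (!has_ties && N <= exact_max) {
    # exact null distribution of U (pwilcox enumerates rank assignments)
    p_le <- stats::pwilcox(U, m, n)
    p_ge <- 1 - stats::pwilcox(U - 1, m, n)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- m * n / 2
  tie_term <- sum(ties^3 - ties)
  sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  if (sigma == 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma  # continuity correction toward the mean
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}
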