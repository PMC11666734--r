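#' Coerce to a corresponded shape
#'
#' A mesh that already shares the template's topology (e.g. a synthetic
#' population member, or the template itself) is trivially in correspondence.
#'
#' @param x a [triangle_mesh()] with the template's vertex count, a `V x 3`
#'   matrix, or a [corresponded_shape()].
#' @param template_id identifier to record.
#' @return a [corresponded_shape()].
#' @export
as_corresponded <- function(x, template_id = "") {
  if (inherits(x, "corresponded_shape")) return(x)
  if (is_triangle_mesh(x)) return(corresponded_shape(x$vertices, template_id = template_id))
  corresponded_shape(as.matrix(x), template_id = template_id)
}

flatten_shape <- function(s) as.vector(s$coordinates)  # column-major: all x, all y, all z

unflatten <- function(v) matrix(v, ncol = 3L)

#' Build a PCA statistical shape model
#'
#' Computes the point-distribution model of a population of corresponded
#' intact shapes: the arithmetic mean shape plus the leading eigenvectors
#' and eigenvalues of the sample covariance (divisor `n - 1`). The
#' decomposition runs as a thin SVD of the centred `n x 3V` data matrix, so
#' the `3V x 3V` covariance is never formed. Shapes keep absolute size in
#' mm (no Procrustes scaling): plate-fitting needs true dimensions.
#'
#' The default of 15 retained components follows the model used for
#' hemipelvis reconstruction, built from 200 intact left hemipelves.
#'
#' @param shapes list of [corresponded_shape()] (or objects coercible via
#'   [as_corresponded()]); all fully valid and on the same template.
#' @param n_components number of principal components to retain
#'   (`<= length(shapes) - 1`).
#' @param template optional [triangle_mesh()] recording the topology.
#' @return a `shape_model` with fields `mean_shape` (3V vector), `components`
#'   (3V x K orthonormal), `variances` (K, descending, mm^2),
#'   `total_variance`, `n_training` and `template`.
#' @export
build_model <- function(shapes, n_components = 15L, template = NULL) {
  if (length(shapes) < 2L) stop("need at least 2 training shapes")
  shapes <- lapply(shapes, as_corresponded)
  V <- nrow(shapes[[1]]$coordinates)
  for (s in shapes) {
    if (nrow(s$coordinates) != V) stop("training shapes have mismatched vertex counts")
    if (!all(s$valid_mask)) stop("training shapes must be fully valid (intact)")
  }
  n <- length(shapes)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > n - 1L)
    stop("n_components must be in [1, n_training - 1]")
  X <- do.call(rbind, lapply(shapes, flatten_shape))
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(Xc)))
  all_var <- sv$d[seq_len(min(n - 1L, length(sv$d)))]^2 / (n - 1)
  k <- n_components
  structure(list(
    mean_shape = mean_shape,
    components = sv$v[, seq_len(k), drop = FALSE],
    variances = all_var[seq_len(k)],
    total_variance = sum(all_var),
    n_training = n,
    template = template
  ), class = "shape_model")
}

#' @export
#' @method print shape_model
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d vertices, %d components, n_training = %d\n",
              length(x$mean_shape) / 3, length(x$variances), x$n_training))
  cat(sprintf("  explained variance: %.1f%%\n",
              100 * sum(x$variances) / x$total_variance))
  invisible(x)
}

#' Shape coefficients
#'
#' PC scores of one shape in a model, with per-component flags marking
#' scores clamped to the +/- 3 standard-deviation plausibility interval.
#'
#' @param b numeric K-vector of scores.
#' @param clamped logical K-vector.
#' @return a `shape_coefficients` object.
#' @export
shape_coefficients <- function(b, clamped = rep(FALSE, length(b))) {
  if (!all(is.finite(b))) stop("non-finite coefficients")
  structure(list(b = as.numeric(b), clamped = as.logical(clamped)),
            class = "shape_coefficients")
}

#' Project a shape into model space
#'
#' Without a mask, scores are the orthogonal projection
#' `b = components' (x - mean)`. With a mask (partial data, e.g. a fractured
#' shape), scores solve the least-squares problem restricted to the
#' coordinates of masked-in vertices. Scores are clamped to
#' `+/- 3 sqrt(variance_k)` unless `clamp = FALSE`; the clamp keeps
#' reconstructions statistically plausible when data are sparse.
#'
#' @param model a `shape_model`.
#' @param shape a [corresponded_shape()] on the model's template.
#' @param mask optional per-vertex logical; defaults to the shape's own
#'   `valid_mask` when that is not all-true.
#' @param clamp apply the 3-sigma clamp.
#' @return a [shape_coefficients()].
#' @export
project <- function(model, shape, mask = NULL, clamp = TRUE) {
  shape <- as_corresponded(shape)
  x <- flatten_shape(shape)
  if (length(x) != length(model$mean_shape)) stop("shape is not on the model template")
  if (is.null(mask) && !all(shape$valid_mask)) mask <- shape$valid_mask
  K <- ncol(model$components)
  if (is.null(mask)) {
    b <- as.vector(crossprod(model$components, x - model$mean_shape))
  } else {
    mask <- as.logical(mask)
    if (length(mask) * 3L != length(x)) stop("mask must have one flag per vertex")
    rows <- which(rep(mask, 3L))  # column-major flattening: x-block, y-block, z-block
    if (length(rows) < 3L * K)
      stop("underdetermined masked projection: ", length(rows),
           " coordinates for ", K, " components")
    P <- model$components[rows, , drop = FALSE]
    r <- (x - model$mean_shape)[rows]
    b <- qr.coef(qr(P), r)
    b[is.na(b)] <- 0
  }
  clamped <- rep(FALSE, K)
  if (clamp) {
    lim <- 3 * sqrt(pmax(model$variances, 0))
    clamped <- abs(b) > lim
    b <- pmin(pmax(b, -lim), lim)
  }
  shape_coefficients(b, clamped)
}

#' Synthesize a shape from model coefficients
#'
#' `x = mean + components b`, reshaped to `V x 3`; the result lies exactly in
#' the model subspace and is fully valid.
#'
#' @param model a `shape_model`.
#' @param coeffs a [shape_coefficients()] or bare numeric vector.
#' @return a [corresponded_shape()].
#' @export
synthesize <- function(model, coeffs) {
  b <- if (inherits(coeffs, "shape_coefficients")) coeffs$b else as.numeric(coeffs)
  if (length(b) != ncol(model$components)) stop("coefficient length mismatch")
  x <- model$mean_shape + as.vector(model$components %*% b)
  corresponded_shape(unflatten(x), template_id = template_id_of(model))
}

template_id_of <- function(model) {
  if (!is.null(model$template)) model$template$name else "model"
}

#' Mean shape of a model as a mesh
#'
#' Requires the model to carry its template topology.
#' @param model a `shape_model`.
#' @return a [triangle_mesh()].
#' @export
mean_mesh <- function(model) {
  if (is.null(model$template)) stop("model carries no template topology")
  triangle_mesh(unflatten(model$mean_shape), model$template$faces,
                name = template_id_of(model))
}

#' Compactness curve
#'
#' Cumulative fraction of total population variance explained by the first
#' k components, k = 1..K. Non-decreasing; reaches 1 when K = n - 1.
#'
#' @param model a `shape_model`.
#' @return numeric vector of cumulative explained-variance fractions.
#' @export
compactness <- function(model) {
  if (model$total_variance <= 0) return(rep(1, length(model$variances)))
  cumsum(model$variances) / model$total_variance
}

#' Save / load a shape model
#'
#' Persists the model as a single binary container (RDS) plus a JSON metadata
#' sidecar (`<path>.json`) recording vertex count, component count, training
#' size and explained variance for quick inspection without loading.
#'
#' @param model a `shape_model`.
#' @param path output path (conventionally `.rds`).
#' @return `path` (save) or the `shape_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(n_vertices = length(model$mean_shape) / 3,
               n_components = length(model$variances),
               n_training = model$n_training,
               explained_variance = sum(model$variances) / model$total_variance,
               template_id = template_id_of(model))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "shape_model")) stop("not a shape_model: ", path)
  model
}
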