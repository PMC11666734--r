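#' Reconstruct an intact shape from fracture fragments
#'
#' The core operation: given the merged fragment surfaces of a fractured
#' hemipelvis and a statistical shape model, estimate the intact pre-fracture
#' shape. The merged fragments are first rigidly aligned into model space
#' (partial-to-full trimmed ICP against the mean shape); then the method
#' alternates
#' \enumerate{
#'   \item correspondence of the current model-instance surface to the
#'     fragments: each template vertex takes its closest point on the
#'     fragment surfaces, gated by the distance and normal-compatibility
#'     thresholds of `reg_params` (vertices with no nearby, normal-compatible
#'     fragment surface are masked out);
#'   \item masked projection of those correspondences into the PC subspace
#'     with the 3-sigma clamp. The projection is plane-weighted: each valid
#'     vertex constrains the fit only along the fragment-surface normal at
#'     its correspondence. Closest-point matching determines the normal
#'     offset of a surface far more reliably than tangential placement
#'     (tangential sliding is invisible to closed-surface matching), so the
#'     plane weighting keeps tangential correspondence error out of the
#'     coefficients — the model subspace itself supplies the deformation
#'     prior, making a free-form registration inside the fitting loop
#'     unnecessary;
#'   \item synthesis of the new model instance.
#' }
#' Each outer round runs the correspondence/projection pair to a fixed point
#' and stops when the instance's mean coordinate change drops below `tol` or
#' after `max_outer` rounds. Re-corresponding from the current best instance
#' rather than a single pass lets correspondences recover from the poor
#' initial matches of the mean shape near displaced fragments. Fragments are
#' used where they lie; no automatic repositioning is attempted.
#'
#' When less than 25\% of the template finds data support, a warning is
#' issued: reconstructions from that little surface are known to degrade.
#'
#' @param model a [build_model()] result carrying its template.
#' @param fragments a [triangle_mesh()] of merged fragments (see
#'   [merge_fragments()]).
#' @param reg_params a [nonrigid_params()].
#' @param max_outer outer alternation cap.
#' @param tol convergence tolerance on mean vertex displacement (mm).
#' @param clamp apply the 3-sigma coefficient clamp.
#' @return a `reconstruction_result`: list with `reconstructed`
#'   ([corresponded_shape()] in the model subspace), `coefficients`,
#'   `fraction_valid`, `n_iterations`, `converged`, and
#'   `fragment_transform` (the final [rigid_transform()] mapping the input
#'   fragments into model space).
#' @export
reconstruct_fracture <- function(model, fragments, reg_params = nonrigid_params(),
                                 max_outer = 5L, tol = 0.1, clamp = TRUE) {
  if (!inherits(model, "shape_model")) stop("model must be a shape_model")
  if (is.null(model$template)) stop("model carries no template topology")
  if (!is_triangle_mesh(fragments) || n_faces(fragments) == 0L)
    stop("empty fragment mesh")
  template <- mean_mesh(model)
  cos_gate <- cos(reg_params$max_normal_angle * pi / 180)
  F0 <- faces0(template)
  inst <- template$vertices
  coeffs <- shape_coefficients(rep(0, ncol(model$components)))
  corr <- NULL
  converged <- FALSE
  iters <- 0L
  for (outer in seq_len(max_outer)) {
    iters <- outer
    # (re-)estimate the rigid pose of the fragments against the current
    # instance: aligning against the mean alone would absorb genuine shape
    # difference into a spurious rigid motion. The pose only needs to be
    # good enough for gating here — it is re-estimated every outer round —
    # so the ICP effort is capped
    tr <- rigid_icp(fragments, triangle_mesh(inst, template$faces), trim = 0.2,
                    max_iters = if (outer == 1L) 100L else 30L, tol = 1e-4)
    frag <- apply_transform(fragments, tr)
    fgrid <- surface_index(frag)
    fnormals <- face_normals(frag)
    correspond <- function(X) {
      q <- cpg_query(fgrid, X)
      vn <- cpp_vertex_normals(X, F0)
      nn <- fnormals[q$face + 1L, , drop = FALSE]
      valid <- q$dist < 1e-9 |
        (q$dist <= reg_params$max_corr_dist & rowSums(vn * nn) >= cos_gate)
      corresponded_shape(q$points, valid, template_id = template_id_of(model))
    }
    inst_prev <- inst
    for (round in seq_len(12L)) {
      corr <- correspond(inst)
      if (!any(corr$valid_mask)) {
        # nothing within the gates: keep the current estimate rather than
        # chase nothing (fatal only if it happens before any fit at all)
        if (outer == 1L && round == 1L) stop("no valid fragment correspondences")
        break
      }
      coeffs <- project_plane(model, corr, fgrid, fnormals, clamp = clamp)
      new_inst <- synthesize(model, coeffs)$coordinates
      delta <- mean(sqrt(rowSums((new_inst - inst)^2)))
      inst <- new_inst
      if (delta < tol / 4) break
    }
    if (mean(sqrt(rowSums((inst - inst_prev)^2))) < tol) { converged <- TRUE; break }
  }
  fraction_valid <- mean(corr$valid_mask)
  if (fraction_valid < 0.25)
    warning(sprintf(paste0("only %.0f%% of the template is supported by fragment",
                           " surface; reconstructions from >25%% missing data are",
                           " known to be less accurate"), 100 * fraction_valid))
  structure(list(
    reconstructed = corresponded_shape(inst, template_id = template_id_of(model)),
    coefficients = coeffs,
    fraction_valid = fraction_valid,
    n_iterations = iters,
    converged = converged,
    fragment_transform = tr
  ), class = "reconstruction_result")
}

# masked plane-weighted projection: solve for coefficients b minimising
# sum_i w_i (n_i . (mean_i + (P b)_i - c_i))^2 over the valid correspondences
# c (with n the fragment-surface normal at c), then clamp to +/- 3 sigma.
# Tangential registration error is orthogonal to n and drops out.
project_plane <- function(model, corr, fgrid, fnormals, clamp = TRUE) {
  X <- corr$coordinates
  V <- nrow(X)
  w <- as.numeric(corr$valid_mask)
  q <- cpg_query(fgrid, X)
  nn <- fnormals[q$face + 1L, , drop = FALSE]
  P <- model$components
  meanm <- unflatten(model$mean_shape)
  # rows of P for vertex i sit at i, i+V, i+2V (coordinate-major flattening)
  J <- nn[, 1] * P[seq_len(V), , drop = FALSE] +
       nn[, 2] * P[V + seq_len(V), , drop = FALSE] +
       nn[, 3] * P[2L * V + seq_len(V), , drop = FALSE]
  r <- rowSums(nn * (X - meanm))
  K <- ncol(P)
  A <- crossprod(J * w, J) + 1e-8 * diag(K)
  b <- as.vector(solve(A, crossprod(J * w, w * r)))
  clamped <- rep(FALSE, K)
  if (clamp) {
    lim <- 3 * sqrt(pmax(model$variances, 0))
    clamped <- abs(b) > lim
    b <- pmin(pmax(b, -lim), lim)
  }
  shape_coefficients(b, clamped)
}

#' @export
#' @method print reconstruction_result
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("reconstruction_result: %d outer iteration(s), %s, %.0f%% data support\n",
              x$n_iterations, if (x$converged) "converged" else "not converged",
              100 * x$fraction_valid))
  invisible(x)
}

#' Register the intact contralateral side as ground-truth comparator
#'
#' Mirrors an intact opposite-side mesh to the model's side, registers it to
#' the template, and returns the corresponded coordinates. The result is
#' deliberately NOT projected into the PC subspace: it serves as the ground
#' truth the subspace reconstruction is evaluated against.
#'
#' Registration is model-assisted: the SSM is first fitted to the (complete)
#' intact surface, and the free-form non-rigid registration then refines
#' from that fitted instance. Starting free-form registration from the mean
#' shape would leave several millimetres of correspondence error on shapes
#' far from the mean; from the fitted instance the residual deformation is
#' small and the free-form step recovers it accurately, while remaining
#' unconstrained by the subspace.
#'
#' @param model a `shape_model` carrying its template.
#' @param contralateral intact [triangle_mesh()] of the opposite side.
#' @param reg_params a [nonrigid_params()].
#' @param mirror logical; set `FALSE` if the mesh is already on the model
#'   side.
#' @param mirror_normal normal of the mirroring plane (the plane passes
#'   through the mesh centroid; rigid ICP absorbs the arbitrary offset).
#' @return a [corresponded_shape()].
#' @export
reconstruct_from_contralateral <- function(model, contralateral,
                                           reg_params = nonrigid_params(),
                                           mirror = TRUE,
                                           mirror_normal = c(1, 0, 0)) {
  if (!is_triangle_mesh(contralateral) || n_faces(contralateral) == 0L)
    stop("empty contralateral mesh")
  if (is.null(model$template)) stop("model carries no template topology")
  m <- contralateral
  if (mirror)
    m <- mirror_sagittal(m, plane_normal = mirror_normal,
                         plane_point = colMeans(m$vertices))
  # model-assisted initialisation: fit the SSM to the intact surface, bring
  # the mesh into model space with the fitted pose, then refine free-form
  fit <- reconstruct_fracture(model, m, reg_params = reg_params)
  m_aligned <- apply_transform(m, fit$fragment_transform)
  nonrigid_icp(mean_mesh(model), m_aligned, params = reg_params,
               initial_coords = fit$reconstructed$coordinates,
               rigid_prealign = FALSE)
}
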