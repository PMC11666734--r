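#' Triangle surface mesh
#'
#' Constructs the basic surface-mesh container used throughout the package: a
#' numeric `V x 3` vertex matrix in millimetres and an integer `F x 3` face
#' matrix of 1-based vertex indices with counter-clockwise (outward) winding.
#'
#' @param vertices numeric matrix (`V x 3`), coordinates in mm.
#' @param faces integer matrix (`F x 3`), 1-based vertex indices.
#' @param name optional free-text label.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  m <- structure(list(vertices = vertices, faces = faces, name = as.character(name)[1]),
                 class = "triangle_mesh")
  validate_mesh(m)
  m
}

#' @export
#' @method print triangle_mesh
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Validate triangle-mesh invariants
#'
#' Checks that all face indices are in range, no face is degenerate, and all
#' coordinates are finite. Called by the constructor; exported for re-checking
#' meshes after manual surgery.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen)) stop(sum(degen), " degenerate face(s) (repeated vertex index)")
  }
  invisible(mesh)
}

#' @rdname triangle_mesh
#' @param x object to test.
#' @export
is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# 0-based face matrix for the C++ kernels
faces0 <- function(mesh) mesh$faces - 1L

#' Edge lengths of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of unique-edge lengths in mm.
#' @export
edge_lengths <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Total surface area (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed enclosed volume (mm^3) by the divergence theorem
#'
#' Positive for a closed, outward-oriented surface.
#' @param mesh a `triangle_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  p <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * p[, 3] - b[, 3] * p[, 2]) -
      a[, 2] * (b[, 1] * p[, 3] - b[, 3] * p[, 1]) +
      a[, 3] * (b[, 1] * p[, 2] - b[, 2] * p[, 1])) / 6
}

#' Connected components of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer vector of 1-based component labels per vertex.
#' @export
mesh_components <- function(mesh) {
  cpp_vertex_components(n_vertices(mesh), faces0(mesh))
}

#' Watertightness test
#'
#' A mesh is watertight when every edge is shared by exactly two consistently
#' oriented faces.
#' @param mesh a `triangle_mesh`.
#' @export
is_watertight <- function(mesh) {
  if (n_faces(mesh) == 0L) return(FALSE)
  isTRUE(cpp_edge_audit(n_vertices(mesh), faces0(mesh))$watertight)
}

#' Mesh quality report
#'
#' Summarises vertex/face counts, edge-length statistics, watertightness and
#' component count; serialisable to JSON with [jsonlite::toJSON].
#'
#' @param mesh a `triangle_mesh`.
#' @return a `mesh_quality_report` list.
#' @export
mesh_quality <- function(mesh) {
  el <- if (n_faces(mesh) > 0L) edge_lengths(mesh) else numeric(0)
  structure(list(
    n_vertices = n_vertices(mesh),
    n_faces = n_faces(mesh),
    mean_edge_length = if (length(el)) mean(el) else NA_real_,
    edge_length_cv = if (length(el) > 1L) stats::sd(el) / mean(el) else NA_real_,
    is_watertight = is_watertight(mesh),
    n_connected_components = if (n_vertices(mesh)) max(mesh_components(mesh)) else 0L
  ), class = "mesh_quality_report")
}

#' Merge fracture fragments into one segmentation
#'
#' Concatenates several fragment meshes into a single mesh without welding:
#' vertex and face counts add up and each input fragment stays its own
#' connected component (unless fragments genuinely share vertices, which
#' disjoint fragments do not).
#'
#' @param fragments non-empty list of `triangle_mesh` objects.
#' @param name label for the merged mesh.
#' @return a `triangle_mesh`.
#' @export
merge_fragments <- function(fragments, name = "merged") {
  if (is_triangle_mesh(fragments)) fragments <- list(fragments)
  if (length(fragments) == 0L) stop("empty fragment list")
  for (fr in fragments) validate_mesh(fr)
  offs <- cumsum(c(0L, vapply(fragments, n_vertices, integer(1))))
  v <- do.call(rbind, lapply(fragments, `[[`, "vertices"))
  f <- do.call(rbind, lapply(seq_along(fragments), function(i) {
    fragments[[i]]$faces + offs[i]
  }))
  triangle_mesh(v, f, name = name)
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex across the plane given by a point and normal and
#' reverses face winding so outward normals stay outward. Applying the same
#' mirror twice is the identity. The default plane is the sagittal x = 0
#' plane of template space: all shapes in a model are expressed as one side
#' (left), and opposite-side inputs must be mirrored before registration.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane_normal non-zero 3-vector, normal of the mirror plane.
#' @param plane_point a point on the plane.
#' @return the mirrored `triangle_mesh`.
#' @export
mirror_sagittal <- function(mesh, plane_normal = c(1, 0, 0), plane_point = c(0, 0, 0)) {
  n <- as.numeric(plane_normal)
  if (length(n) != 3L || sqrt(sum(n^2)) < 1e-12) stop("plane_normal must be a non-zero 3-vector")
  n <- n / sqrt(sum(n^2))
  d <- sweep(mesh$vertices, 2, as.numeric(plane_point))
  v <- mesh$vertices - 2 * (d %*% n) %*% t(n)
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE],
                name = paste0(mesh$name, "_mirrored"))
}

#' Closest points on a mesh surface
#'
#' Projects query points onto the surface of `mesh` using a uniform-grid
#' accelerated exact point-to-triangle search.
#'
#' @param mesh a `triangle_mesh`.
#' @param query numeric `n x 3` matrix of query points.
#' @return list with `points` (`n x 3` projections), `dist` (mm) and `face`
#'   (1-based supporting face index).
#' @export
closest_on_surface <- function(mesh, query) {
  g <- surface_index(mesh)
  res <- cpg_query(g, as.matrix(query))
  res$face <- res$face + 1L
  res
}

# build the grid once and reuse the external pointer in hot loops
surface_index <- function(mesh) cpg_build(mesh$vertices, faces0(mesh))

#' Area-weighted per-vertex normals
#' @param mesh a `triangle_mesh`.
#' @return `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) cpp_vertex_normals(mesh$vertices, faces0(mesh))

face_normals <- function(mesh) cpp_face_normals(mesh$vertices, faces0(mesh))

bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

# submesh from a face subset (drops unreferenced vertices, keeps order)
subset_faces <- function(mesh, face_idx, name = mesh$name) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[keep] <- seq_along(keep)
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(remap[f], ncol = 3L), name = name)
}
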