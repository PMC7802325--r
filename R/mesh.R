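#' Construct a triangulated surface mesh
#'
#' `tri_mesh()` is the basic geometric container of the package: a set of 3D
#' vertices (in mm) and a set of triangular faces indexing them, with
#' consistent outward winding for closed surfaces. Organ-scale iso-surfaces
#' (cortex, ventricles) are carried as `tri_mesh` objects.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z), one row per
#'   vertex, in mm.
#' @param faces Integer matrix with 3 columns, one row per triangular face,
#'   indexing rows of `vertices` (1-based). Winding must be consistent and
#'   outward for closed meshes.
#' @param name Optional text label for the surface.
#' @param check If `TRUE` (default) validate face indices and reject
#'   degenerate (zero-area or repeated-index) faces.
#' @return An object of class `tri_mesh`: a list with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' cube <- make_solid("cube", list(side = 1))
#' mesh_volume(cube)
#' @export
tri_mesh <- function(vertices, faces, name = "", check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns (triangles only)")
  if (check) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
    if (nrow(faces) > 0L) {
      rng <- range(faces)
      if (rng[1] < 1L || rng[2] > nrow(vertices))
        stop("face index out of range: faces must index existing vertices")
      rep_idx <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
        faces[, 1] == faces[, 3]
      if (any(rep_idx))
        stop("degenerate face (repeated vertex index) at face ",
             which(rep_idx)[1])
      a2 <- face_areas(vertices, faces)
      if (any(a2 == 0))
        stop("degenerate face (zero area) at face ", which(a2 == 0)[1])
    }
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh>", if (nzchar(x$name)) paste0("'", x$name, "'") else "",
      "\n  vertices:", nrow(x$vertices), " faces:", nrow(x$faces),
      " closed:", is_closed_mesh(x), "\n")
  invisible(x)
}

# per-face areas; vectorized cross product
face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Test whether a mesh is a closed, consistently wound 2-manifold
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' faces, and consistently wound when the two faces traverse the edge in
#' opposite directions. Closedness is a precondition for [mesh_volume()].
#'
#' @param mesh A [tri_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_closed_mesh <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(FALSE)
  nv <- nrow(mesh$vertices)
  # directed edges encoded as doubles (exact below 2^53)
  from <- as.double(c(F[, 1], F[, 2], F[, 3]))
  to <- as.double(c(F[, 2], F[, 3], F[, 1]))
  dir_code <- from * (nv + 1) + to
  rev_code <- to * (nv + 1) + from
  !anyDuplicated(dir_code) && all(dir_code %in% rev_code)
}

#' Enclosed volume of a closed triangulated surface
#'
#' Computes the volume by the divergence theorem as a sum of signed
#' tetrahedra spanned by each face and the origin. The result is exact for
#' any closed triangulation and invariant under translation. The sign of the
#' sum is checked: outward winding yields a positive volume, and an inward
#' wound mesh raises an error rather than being silently negated.
#'
#' @param mesh A closed [tri_mesh()] with outward winding.
#' @return Enclosed volume in mm^3 (positive).
#' @examples
#' sph <- make_solid("sphere", list(radius = 1), refinement = 4)
#' mesh_volume(sph) # ~ 4*pi/3
#' @export
mesh_volume <- function(mesh) {
  if (!is_closed_mesh(mesh))
    stop("mesh is not closed: volume is undefined for open surfaces")
  v <- signed_volume(mesh$vertices, mesh$faces)
  if (v < 0)
    stop("mesh has inward winding (negative signed volume); ",
         "reorient faces outward")
  v
}

signed_volume <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a triangulated mesh
#'
#' Sum of triangle areas; defined for open and closed meshes and invariant
#' under rigid motion.
#'
#' @param mesh A [tri_mesh()].
#' @return Surface area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh$vertices, mesh$faces))
}

#' Define an oriented cutting plane
#'
#' Planes are used to separate the two lateral-ventricle lobes of a combined
#' ventricular surface at the midline (the anatomical role of the septum
#' pellucidum) before per-lobe sphericity is computed.
#'
#' @param point Numeric length-3: a point on the plane (mm).
#' @param normal Numeric length-3: plane normal; normalized to unit length.
#' @return An object of class `morph_plane`.
#' @export
plane <- function(point, normal) {
  point <- as.double(point); normal <- as.double(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("`point` and `normal` must be length-3 numeric")
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / nn), class = "morph_plane")
}

#' A labelled 3D measurement point
#'
#' Landmarks carry anatomical measurement points, e.g. pupil centres used
#' for the intraocular distance.
#'
#' @param position Numeric length-3 position (mm).
#' @param label Text label, e.g. `"pupil_left"`.
#' @return An object of class `landmark`.
#' @export
landmark <- function(position, label = "") {
  position <- as.double(position)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("landmark position must be 3 finite coordinates")
  structure(list(position = position, label = as.character(label)),
            class = "landmark")
}

#' Euclidean distance between two landmarks
#'
#' The intraocular distance of a sample is the 3D Euclidean distance between
#' the two pupil-centre landmarks.
#'
#' @param a,b [landmark()] objects.
#' @return Distance in mm.
#' @examples
#' landmark_distance(landmark(c(0, 0, 0)), landmark(c(1, 2, 2))) # 3
#' @export
landmark_distance <- function(a, b) {
  stopifnot(inherits(a, "landmark"), inherits(b, "landmark"))
  sqrt(sum((a$position - b$position)^2))
}

#' Read landmarks from CSV
#'
#' Expects a header row with columns `label,x,y,z`; coordinates in mm.
#'
#' @param path CSV file path.
#' @return A list of [landmark()] objects, named by label.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns label,x,y,z")
  lst <- lapply(seq_len(nrow(df)), function(i)
    landmark(c(df$x[i], df$y[i], df$z[i]), df$label[i]))
  stats::setNames(lst, df$label)
}

#' Write landmarks to CSV
#'
#' @param landmarks List of [landmark()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(
    label = vapply(landmarks, function(l) l$label, character(1)),
    x = vapply(landmarks, function(l) l$position[1], double(1)),
    y = vapply(landmarks, function(l) l$position[2], double(1)),
    z = vapply(landmarks, function(l) l$position[3], double(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
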