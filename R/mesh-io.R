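#' Read a triangulated mesh from an ASCII PLY, OFF or OBJ file
#'
#' Supports the ASCII dialects of the three formats; faces must be
#' triangles. Coordinates are taken to be in mm. The format is inferred from
#' the file extension unless given explicitly.
#'
#' @param path File path.
#' @param format One of `"ply"`, `"off"`, `"obj"`; default guesses from the
#'   extension.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "off", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "off", "obj"))
      stop("cannot infer mesh format from extension '", format, "'")
  }
  switch(format,
         ply = read_ply(path),
         off = read_off(path),
         obj = read_obj(path))
}

#' Write a triangulated mesh to an ASCII PLY, OFF or OBJ file
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path; extension selects the format unless `format`
#'   is given.
#' @param format One of `"ply"`, `"off"`, `"obj"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "off", "obj")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "off", "obj"))
      stop("cannot infer mesh format from extension '", format, "'")
  }
  V <- mesh$vertices; F <- mesh$faces
  vtxt <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(F)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(vtxt, con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
               con)
  } else if (format == "off") {
    writeLines(c("OFF", paste(nrow(V), nrow(F), 0L)), con)
    writeLines(vtxt, con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
               con)
  } else {
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  }
  invisible(path)
}

# tokenized numeric fields of non-empty, non-comment lines
mesh_lines <- function(path, comment = character()) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(comment))
    x <- x[!startsWith(x, comment)]
  x
}

read_off <- function(path) {
  x <- mesh_lines(path, comment = "#")
  if (!grepl("^OFF", x[1])) stop("not an OFF file: missing OFF header")
  # counts may share the OFF line or follow it
  hdr <- sub("^OFF\\s*", "", x[1])
  if (nzchar(hdr)) {
    counts <- as.integer(strsplit(hdr, "\\s+")[[1]])
    body <- x[-1]
  } else {
    counts <- as.integer(strsplit(x[2], "\\s+")[[1]])
    body <- x[-(1:2)]
  }
  nv <- counts[1]; nf <- counts[2]
  vv <- strsplit(body[seq_len(nv)], "\\s+")
  V <- matrix(as.double(unlist(lapply(vv, `[`, 1:3))), ncol = 3, byrow = TRUE)
  ff <- strsplit(body[nv + seq_len(nf)], "\\s+")
  F <- parse_face_rows(ff)
  tri_mesh(V, F)
}

read_ply <- function(path) {
  x <- readLines(path, warn = FALSE)
  if (!identical(trimws(x[1]), "ply")) stop("not a PLY file")
  hend <- which(trimws(x) == "end_header")[1]
  if (is.na(hend)) stop("malformed PLY: no end_header")
  hdr <- trimws(x[seq_len(hend)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  ev <- grep("^element\\s+vertex\\s+", hdr, value = TRUE)
  ef <- grep("^element\\s+face\\s+", hdr, value = TRUE)
  if (!length(ev) || !length(ef)) stop("malformed PLY: missing elements")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", ev[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", ef[1]))
  body <- trimws(x[-seq_len(hend)])
  body <- body[nzchar(body)]
  vv <- strsplit(body[seq_len(nv)], "\\s+")
  V <- matrix(as.double(unlist(lapply(vv, `[`, 1:3))), ncol = 3, byrow = TRUE)
  ff <- strsplit(body[nv + seq_len(nf)], "\\s+")
  F <- parse_face_rows(ff)
  tri_mesh(V, F)
}

read_obj <- function(path) {
  x <- mesh_lines(path, comment = "#")
  vl <- x[startsWith(x, "v ")]
  fl <- x[startsWith(x, "f ")]
  if (!length(vl) || !length(fl)) stop("not a usable OBJ file: need v and f lines")
  vv <- strsplit(sub("^v\\s+", "", vl), "\\s+")
  V <- matrix(as.double(unlist(lapply(vv, `[`, 1:3))), ncol = 3, byrow = TRUE)
  ftok <- strsplit(sub("^f\\s+", "", fl), "\\s+")
  nfv <- lengths(ftok)
  if (any(nfv != 3L))
    stop("non-triangular face at face ", which(nfv != 3L)[1],
         ": only triangle meshes are supported")
  # strip texture/normal refs: "3/1/2" -> "3"
  idx <- vapply(unlist(ftok), function(t) as.integer(strsplit(t, "/")[[1]][1]),
                integer(1))
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(V, F)
}

parse_face_rows <- function(ff) {
  nfv <- vapply(ff, function(r) as.integer(r[1]), integer(1))
  if (any(nfv != 3L))
    stop("non-triangular face at face ", which(nfv != 3L)[1],
         ": only triangle meshes are supported")
  F <- matrix(as.integer(unlist(lapply(ff, `[`, 2:4))), ncol = 3,
              byrow = TRUE) + 1L
  F
}
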