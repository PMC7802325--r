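# ---- Voronoi synthesis of apical lattices ----------------------------------
#
# Cells are computed one generator at a time by clipping a starting square
# with the perpendicular bisectors of the nearest other generators, taken in
# order of increasing distance. Clipping stops once the next candidate lies
# farther than twice the cell's current maximal vertex distance, which
# guarantees no remaining bisector can cut the polygon, so the construction
# is exact (not an approximation) provided enough candidates are examined;
# the candidate set is grown until the bound is met. Periodic tessellations
# replicate the generators across the 8 surrounding tiles so the domain
# wraps and no border cells exist.

# Sutherland-Hodgman clip of polygon `xy` (k x 2) against half-plane
# (p - m) . u <= 0; `ids` carries, per edge starting at vertex i, the id of
# the neighbour whose bisector created it (0 for the starting square).
clip_halfplane <- function(xy, ids, m, u, nbr_id) {
  d <- (xy[, 1] - m[1]) * u[1] + (xy[, 2] - m[2]) * u[2]
  inside <- d <= 0
  if (all(inside)) return(list(xy = xy, ids = ids, cut = FALSE))
  if (!any(inside)) return(list(xy = NULL, ids = NULL, cut = TRUE))
  k <- nrow(xy)
  nx <- c(2:k, 1L)
  out_xy <- matrix(0, k + 2L, 2)
  out_id <- integer(k + 2L)
  n_out <- 0L
  push <- function(p, id) {
    n_out <<- n_out + 1L
    out_xy[n_out, ] <<- p
    out_id[n_out] <<- id
  }
  for (i in seq_len(k)) {
    j <- nx[i]
    if (inside[i]) {
      if (inside[j]) {
        push(xy[i, ], ids[i])
      } else {
        t <- d[i] / (d[i] - d[j])
        push(xy[i, ], ids[i])
        push(xy[i, ] + t * (xy[j, ] - xy[i, ]), nbr_id)
      }
    } else if (inside[j]) {
      t <- d[i] / (d[i] - d[j])
      push(xy[i, ] + t * (xy[j, ] - xy[i, ]), ids[i])
    }
  }
  list(xy = out_xy[seq_len(n_out), , drop = FALSE],
       ids = out_id[seq_len(n_out)], cut = TRUE)
}

# exact Voronoi cell of `seeds[i, ]` among candidate points `cand` (matrix,
# with parallel id vector); start polygon must contain the true cell.
# Examines the k nearest candidates first and falls back to the full sorted
# list if the 2x-distance termination bound was not reached.
voronoi_cell <- function(p, cand, cand_ids, start_xy, start_ids, k = 48L) {
  d2 <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2
  if (length(d2) > k + 1L) {
    thr <- sort(d2, partial = k + 1L)[k + 1L]
    sel <- which(d2 <= thr)
    ord <- sel[order(d2[sel])]
  } else {
    ord <- order(d2)
  }
  repeat {
    xy <- start_xy; ids <- start_ids
    done <- FALSE
    for (o in ord) {
      if (d2[o] < 1e-24) next  # the generator itself
      rmax2 <- max((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
      if (d2[o] >= 4 * rmax2) { done <- TRUE; break }
      m <- (p + cand[o, ]) / 2
      u <- cand[o, ] - p
      cl <- clip_halfplane(xy, ids, m, u, cand_ids[o])
      if (is.null(cl$xy) || nrow(cl$xy) < 3L)
        stop("degenerate Voronoi cell")
      xy <- cl$xy; ids <- cl$ids
    }
    if (done || length(ord) == length(d2)) break
    ord <- order(d2)  # bound not reached within k nearest: use all
  }
  list(xy = xy, ids = ids)
}

voronoi_tessellate <- function(seeds, L, periodic) {
  n <- nrow(seeds)
  if (periodic) {
    # only seeds within a margin of the edge need periodic images; the
    # margin is generous relative to typical cell diameters and images are
    # also covered by the termination bound in voronoi_cell
    mar <- min(L / 2, 8 * L / sqrt(n))
    off <- as.matrix(expand.grid(dx = c(-L, 0, L), dy = c(-L, 0, L)))
    parts <- lapply(seq_len(nrow(off)), function(k) {
      dx <- off[k, 1]; dy <- off[k, 2]
      if (dx == 0 && dy == 0) return(cbind(seeds, seq_len(n)))
      keep <- rep(TRUE, n)
      if (dx < 0) keep <- keep & seeds[, 1] >= L - mar
      if (dx > 0) keep <- keep & seeds[, 1] <= mar
      if (dy < 0) keep <- keep & seeds[, 2] >= L - mar
      if (dy > 0) keep <- keep & seeds[, 2] <= mar
      if (!any(keep)) return(NULL)
      cbind(seeds[keep, 1, drop = FALSE] + dx,
            seeds[keep, 2, drop = FALSE] + dy, which(keep))
    })
    parts <- do.call(rbind, parts)
    cand <- parts[, 1:2, drop = FALSE]
    cand_ids <- as.integer(parts[, 3])
    half <- L / 2
  } else {
    cand <- seeds
    cand_ids <- seq_len(n)
  }
  cells <- vector("list", n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- seeds[i, ]
    if (periodic) {
      start_xy <- rbind(p + c(-half, -half), p + c(half, -half),
                        p + c(half, half), p + c(-half, half))
      start_ids <- rep(-9L, 4L)  # sentinel; must never survive
    } else {
      start_xy <- rbind(c(0, 0), c(L, 0), c(L, L), c(0, L))
      start_ids <- c(-1L, -2L, -3L, -4L)  # domain edges bottom/right/top/left
    }
    cl <- voronoi_cell(p, cand, cand_ids, start_xy, start_ids)
    if (periodic && any(cl$ids == -9L))
      stop("periodic Voronoi cell touched its starting box; ",
           "too few generators for the domain")
    cells[[i]] <- cl$xy
    nb <- unique(cl$ids[cl$ids > 0L & cl$ids != i])
    nbrs[[i]] <- sort(nb)
  }
  # symmetrize adjacency (guards against one-sided sliver edges)
  el_i <- rep.int(seq_len(n), lengths(nbrs))
  el_j <- unlist(nbrs, use.names = FALSE)
  if (length(el_i)) {
    a <- pmin(el_i, el_j); b <- pmax(el_i, el_j)
    pairs <- unique(a * (n + 1) + b)
    a <- floor(pairs / (n + 1)); b <- pairs %% (n + 1)
    nbrs <- split(c(b, a), c(a, b))
    full <- rep(list(integer(0)), n)
    full[as.integer(names(nbrs))] <- lapply(nbrs, function(v) sort(as.integer(v)))
    nbrs <- full
  }
  list(cells = cells, neighbours = nbrs)
}

polygon_area2 <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * A)
}

#' Construct a cell lattice
#'
#' The `cell_lattice` is the unit of apical packing analysis: a set of
#' simple 2D polygons (one per cell, coordinates in micrometres) with a
#' symmetric adjacency relation and a border flag marking cells that touch
#' the lattice boundary (border cells are excluded from all statistics, as
#' in segmented microscopy data where boundary cells are clipped).
#'
#' @param polygons List of k x 2 coordinate matrices (µm), one per cell,
#'   simple and positively oriented.
#' @param neighbours List of integer vectors: `neighbours[[i]]` are the cell
#'   ids adjacent to cell i. Must be symmetric.
#' @param is_border Logical vector: does the cell touch the boundary?
#' @param periodic Is the lattice periodic (no boundary)?
#' @param check Validate symmetry, simple positive-area polygons.
#' @return An object of class `cell_lattice`: a tibble of cells
#'   (`cell_id`, `polygon`, `neighbours`, `n_neighbours`, `area`,
#'   `is_border`) with attribute `periodic`.
#' @export
cell_lattice <- function(polygons, neighbours, is_border, periodic = FALSE,
                         check = TRUE) {
  n <- length(polygons)
  stopifnot(length(neighbours) == n, length(is_border) == n)
  areas <- vapply(polygons, polygon_area2, double(1))
  if (check) {
    if (any(areas <= 0))
      stop("cell polygons must be simple with positive (CCW) area")
    for (i in seq_len(n)) {
      for (j in neighbours[[i]]) {
        if (!(i %in% neighbours[[j]]))
          stop("adjacency is not symmetric between cells ", i, " and ", j)
      }
    }
  }
  cells <- tibble::tibble(
    cell_id = seq_len(n),
    polygon = polygons,
    neighbours = lapply(neighbours, as.integer),
    n_neighbours = lengths(neighbours),
    area = areas,
    is_border = as.logical(is_border))
  structure(list(cells = cells, periodic = isTRUE(periodic)),
            class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat("<cell_lattice> ", nrow(x$cells), " cells (",
      sum(!x$cells$is_border), " interior), ",
      if (x$periodic) "periodic" else "bounded", "\n", sep = "")
  invisible(x)
}

#' Generate a (Lloyd-relaxed) Voronoi cell lattice
#'
#' Emulates a segmented apical epithelial lattice: generators are placed
#' uniformly at random in a square domain, the Voronoi tessellation is
#' computed exactly, and each Lloyd relaxation step moves every generator
#' to its cell centroid and re-tessellates. More relaxation steps give a
#' more ordered packing (higher hexagon fraction, lower area disorder),
#' spanning the range from a fully disordered Poisson-Voronoi mosaic to a
#' near-crystalline one. In periodic mode the domain wraps, so there are no
#' border cells and the tessellation is trivalent with mean neighbour
#' number exactly 6 (Euler's relation); in bounded mode cells touching the
#' domain edge are border-flagged.
#'
#' @param n_cells Number of cells (>= 4).
#' @param relaxation_steps Number of Lloyd iterations (0 = Poisson-Voronoi).
#' @param seed RNG seed; fixed seed gives an identical lattice.
#' @param periodic Wrap the domain (default `FALSE`).
#' @param mean_cell_area Target mean cell area in µm^2 (default 20), sets
#'   the domain size.
#' @return A [cell_lattice()] with attribute `truth` holding the generator
#'   positions, the domain side length and the true adjacency.
#' @examples
#' lat <- make_voronoi_lattice(200, relaxation_steps = 2, seed = 1)
#' @export
make_voronoi_lattice <- function(n_cells, relaxation_steps = 0, seed = 1L,
                                 periodic = FALSE, mean_cell_area = 20) {
  if (n_cells < 4) stop("n_cells must be at least 4")
  L <- sqrt(n_cells * mean_cell_area)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  seeds <- cbind(stats::runif(n_cells, 0, L), stats::runif(n_cells, 0, L))
  for (it in seq_len(relaxation_steps)) {
    tess <- voronoi_tessellate(seeds, L, periodic)
    cen <- t(vapply(tess$cells, polygon_centroid, double(2)))
    if (periodic) cen <- cen %% L
    else {
      cen[, 1] <- pmin(pmax(cen[, 1], 0), L)
      cen[, 2] <- pmin(pmax(cen[, 2], 0), L)
    }
    seeds <- cen
  }
  tess <- voronoi_tessellate(seeds, L, periodic)
  is_border <- if (periodic) rep(FALSE, n_cells) else
    vapply(seq_len(n_cells), function(i) {
      xy <- tess$cells[[i]]
      any(xy[, 1] <= 1e-9 | xy[, 1] >= L - 1e-9 |
          xy[, 2] <= 1e-9 | xy[, 2] >= L - 1e-9)
    }, logical(1))
  lat <- cell_lattice(tess$cells, tess$neighbours, is_border,
                      periodic = periodic, check = FALSE)
  attr(lat, "truth") <- list(seeds = seeds, domain = L,
                             adjacency = tess$neighbours)
  lat
}
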