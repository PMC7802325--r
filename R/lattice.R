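# ---- label images and lattice statistics -----------------------------------

#' Rasterize a cell lattice to an integer label image
#'
#' Renders each cell polygon into a raster at the given pixel size, the
#' exchange format of segmentation tools: pixel value k > 0 means cell k,
#' 0 is background. Pixel centres are assigned to the polygon containing
#' them. Periodic lattices wrap around the image.
#'
#' @param lattice A [cell_lattice()].
#' @param pixel_size Requested pixel edge length in µm (default 0.2). The
#'   grid is chosen to tile the square domain exactly, so the realized
#'   pixel size (returned as the `pixel_size` attribute) may differ by a
#'   fraction of a percent.
#' @return Integer matrix (rows = y, columns = x) with attribute
#'   `pixel_size` (the realized pixel size).
#' @export
rasterize_lattice <- function(lattice, pixel_size = 0.2) {
  stopifnot(inherits(lattice, "cell_lattice"))
  polys <- lattice$cells$polygon
  all_xy <- do.call(rbind, polys)
  L <- attr(lattice, "truth")$domain %||% max(all_xy)
  npx <- max(1L, round(L / pixel_size))
  pixel_size <- L / npx
  img <- matrix(0L, nrow = npx, ncol = npx)
  ctr <- (seq_len(npx) - 0.5) * pixel_size
  for (i in seq_along(polys)) {
    xy <- polys[[i]]
    xr <- range(xy[, 1]); yr <- range(xy[, 2])
    cols <- which(ctr >= xr[1] - pixel_size & ctr <= xr[2] + pixel_size)
    rows <- which(ctr >= yr[1] - pixel_size & ctr <= yr[2] + pixel_size)
    if (lattice$periodic) {
      # allow polygons protruding past the domain to wrap
      cols <- seq(floor(xr[1] / pixel_size), ceiling(xr[2] / pixel_size))
      rows <- seq(floor(yr[1] / pixel_size), ceiling(yr[2] / pixel_size))
    }
    if (!length(cols) || !length(rows)) next
    px <- (cols - 0.5) * pixel_size
    py <- (rows - 0.5) * pixel_size
    g <- expand.grid(x = px, y = py)
    inside <- points_in_polygon(g$x, g$y, xy)
    if (!any(inside)) next
    gi <- expand.grid(col = cols, row = rows)[inside, , drop = FALSE]
    if (lattice$periodic) {
      gi$col <- ((gi$col - 1L) %% npx) + 1L
      gi$row <- ((gi$row - 1L) %% npx) + 1L
    }
    img[cbind(gi$row, gi$col)] <- i
  }
  attr(img, "pixel_size") <- pixel_size
  img
}

# vectorized even-odd (crossing number) point-in-polygon
points_in_polygon <- function(px, py, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (e in seq_along(x)) {
    if (y[e] == y2[e]) next
    cross <- ((y[e] > py) != (y2[e] > py)) &
      (px < (x2[e] - x[e]) * (py - y[e]) / (y2[e] - y[e]) + x[e])
    inside <- xor(inside, cross)
  }
  inside
}

#' Write / read a label image as 16-bit TIFF or PNG
#'
#' @param img Integer label matrix (values 0..65535).
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param pixel_size Pixel size in µm to re-attach on read.
#' @return `path` (write) or the integer matrix with `pixel_size` attribute
#'   (read).
#' @export
write_label_image <- function(img, path) {
  if (max(img) > 65535L) stop("more than 65535 labels")
  m <- img / 65535
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  else if (ext == "png")
    png::writePNG(m, path)
  else stop("unsupported label image format: ", ext)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path, pixel_size = 0.2) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported label image format: ", ext)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  img <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Reconstruct a cell lattice from an integer label image
#'
#' Rebuilds the polygonal lattice that segmentation software would export:
#' two cells are adjacent when their pixels share at least `min_contacts`
#' 4-connected pixel-edge contacts (the 2-contact default suppresses
#' spurious corner-touch adjacencies at finite resolution), cells touching
#' the image frame are flagged as border cells, and each cell's outline
#' polygon is traced from its label boundary.
#'
#' @param img Integer label matrix (0 = background, k > 0 = cell k).
#' @param pixel_size Pixel edge length in µm (default: the matrix's
#'   `pixel_size` attribute, else 0.2).
#' @param min_contacts Minimum shared pixel-edge contacts for adjacency
#'   (default 2).
#' @return A [cell_lattice()] (non-periodic).
#' @export
adjacency_from_labels <- function(img, pixel_size = NULL, min_contacts = 2L) {
  if (is.null(pixel_size)) pixel_size <- attr(img, "pixel_size") %||% 0.2
  img <- matrix(as.integer(img), nrow(img), ncol(img))
  labs <- sort(unique(as.vector(img)))
  labs <- labs[labs > 0L]
  if (!length(labs)) stop("empty label image: no cells")
  nmax <- max(labs)
  # 4-connected contacts between distinct positive labels
  h_a <- img[, -ncol(img)]; h_b <- img[, -1]
  v_a <- img[-nrow(img), ]; v_b <- img[-1, ]
  a <- c(h_a, v_a); b <- c(h_b, v_b)
  keep <- a > 0L & b > 0L & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  code <- as.double(lo) * (nmax + 1) + hi
  tab <- table(code)
  good <- as.double(names(tab))[tab >= min_contacts]
  lo <- floor(good / (nmax + 1)); hi <- good %% (nmax + 1)
  nbrs <- rep(list(integer(0)), length(labs))
  idx <- match(c(lo, hi), labs)
  other <- match(c(hi, lo), labs)
  sp <- split(other, idx)
  nbrs[as.integer(names(sp))] <- lapply(sp, function(v) sort(as.integer(v)))
  # border: labels present on the image frame
  frame <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  is_border <- labs %in% frame[frame > 0L]
  # polygons traced from label boundaries (pixel-accurate outlines)
  polys <- trace_label_polygons(img, labs, pixel_size)
  lat <- cell_lattice(polys, nbrs, is_border, periodic = FALSE,
                      check = FALSE)
  lat$cells$label <- labs
  # areas from pixel counts (exact raster measure)
  cnt <- tabulate(img[img > 0L], nbins = nmax)
  lat$cells$area <- cnt[labs] * pixel_size^2
  lat
}

# boundary polygon per label via EBImage contour tracing
trace_label_polygons <- function(img, labs, pixel_size) {
  oc <- EBImage::ocontour(t(img))
  polys <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    ct <- oc[[labs[k]]]
    if (is.null(ct) || nrow(ct) < 3L) {
      # single-pixel or tiny cell: use its pixel square
      w <- which(img == labs[k], arr.ind = TRUE)
      x <- w[1, 2]; y <- w[1, 1]
      ct <- cbind(c(x - 1, x, x, x - 1), c(y - 1, y - 1, y, y))
    }
    xy <- (ct + 0.5) * pixel_size
    if (polygon_area2(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
    polys[[k]] <- xy
  }
  polys
}

#' Interior-cell packing statistics of a lattice
#'
#' Computes the apical packing statistics over interior (non-border) cells:
#' the neighbour-number distribution and its mean, the Lewis table (mean
#' cell area per polygon class, normalized by the overall interior mean
#' area), the Aboav-Weaire table (mean neighbour count of a cell's
#' neighbours, per polygon class), and per-cell ellipse-fit aspect ratios.
#' Border cells are excluded from every statistic, but still contribute
#' their own neighbour counts to the Aboav averages of adjacent interior
#' cells.
#'
#' @param lattice A [cell_lattice()].
#' @return An object of class `lattice_stats`: list with
#'   `n_cells_interior`, `mean_neighbour_number`, `mean_area`,
#'   `neighbour_frequencies` (tibble `n`, `count`, `frequency`),
#'   `lewis_table` (tibble `n`, `count`, `mean_area`, `mean_rel_area`),
#'   `aboav_table` (tibble `n`, `count`, `m`), and `cells` (per interior
#'   cell: `cell_id`, `n`, `area`, `aspect_ratio`).
#' @export
interior_stats <- function(lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  cells <- lattice$cells
  interior <- !cells$is_border
  if (!any(interior)) stop("all cells are border cells")
  nn <- cells$n_neighbours
  ci <- cells[interior, ]
  m_i <- vapply(ci$neighbours, function(nb) mean(nn[nb]), double(1))
  ar <- vapply(ci$polygon, cell_aspect_ratio, double(1))
  per_cell <- tibble::tibble(cell_id = ci$cell_id, n = ci$n_neighbours,
                             area = ci$area, m = m_i, aspect_ratio = ar)
  overall_mean_area <- mean(per_cell$area)
  freq <- per_cell |>
    dplyr::count(.data$n, name = "count") |>
    dplyr::mutate(frequency = .data$count / sum(.data$count))
  lewis <- per_cell |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(count = dplyr::n(), mean_area = mean(.data$area),
                     .groups = "drop") |>
    dplyr::mutate(mean_rel_area = .data$mean_area / .env$overall_mean_area)
  aboav <- per_cell |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(count = dplyr::n(), m = mean(.data$m), .groups = "drop")
  structure(list(
    n_cells_interior = nrow(per_cell),
    mean_neighbour_number = mean(per_cell$n),
    mean_area = overall_mean_area,
    neighbour_frequencies = freq,
    lewis_table = lewis,
    aboav_table = aboav,
    cells = per_cell), class = "lattice_stats")
}

#' @export
print.lattice_stats <- function(x, ...) {
  cat("<lattice_stats> ", x$n_cells_interior, " interior cells; mean n = ",
      format(x$mean_neighbour_number, digits = 4), "; mean area = ",
      format(x$mean_area, digits = 4), " um^2\n", sep = "")
  print(x$neighbour_frequencies)
  invisible(x)
}

#' Make a regular hexagonal (honeycomb) lattice
#'
#' A perfectly ordered reference lattice: every interior cell is a regular
#' hexagon with 6 neighbours.
#'
#' @param rows,cols Numbers of hexagon rows and columns.
#' @param cell_area Area per hexagon (µm^2), default 20.
#' @return A [cell_lattice()] (non-periodic; outermost ring is
#'   border-flagged).
#' @export
make_hex_lattice <- function(rows, cols, cell_area = 20) {
  s <- sqrt(2 * cell_area / (3 * sqrt(3)))  # hexagon side
  w <- sqrt(3) * s
  ang <- pi / 6 + (0:5) * pi / 3
  hexagon <- cbind(s * cos(ang), s * sin(ang))
  centers <- list(); idx <- matrix(0L, rows, cols)
  k <- 0L
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    k <- k + 1L
    idx[r, cc] <- k
    centers[[k]] <- c((cc - 1) * w + (r %% 2) * w / 2, (r - 1) * 1.5 * s)
  }
  polys <- lapply(centers, function(cen) sweep(hexagon, 2, cen, `+`))
  nbrs <- vector("list", k)
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    me <- idx[r, cc]
    shift <- if (r %% 2 == 1) c(-1L, 0L) else c(0L, 1L)
    cand <- rbind(c(r, cc - 1), c(r, cc + 1),
                  c(r - 1, cc + shift[1]), c(r - 1, cc + shift[2]),
                  c(r + 1, cc + shift[1]), c(r + 1, cc + shift[2]))
    ok <- cand[, 1] >= 1 & cand[, 1] <= rows & cand[, 2] >= 1 &
      cand[, 2] <= cols
    nbrs[[me]] <- sort(idx[cand[ok, , drop = FALSE]])
  }
  is_border <- lengths(nbrs) < 6L
  cell_lattice(polys, nbrs, is_border, periodic = FALSE, check = TRUE)
}
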