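#' Split a closed mesh by a plane into two capped closed meshes
#'
#' Cuts a closed surface with an oriented plane, triangulates the cut
#' cross-section(s) by ear clipping, and returns the two halves as closed
#' meshes. This implements the separation of the combined lateral-ventricle
#' surface into left and right lobes at the midline, after which each lobe's
#' volume, area and sphericity are defined. Volumes of the halves sum to the
#' original volume (the two pieces partition the enclosed solid).
#'
#' Vertices lying numerically on the plane are classified to the positive
#' side, so the cut is always a generic transversal cut. Cut cross-sections
#' that are nested (annular) are not supported and raise an error; disjoint
#' multiple cross-sections (e.g. a plane meeting both lobes) are capped
#' independently.
#'
#' @param mesh A closed [tri_mesh()].
#' @param plane A [plane()]; the `positive` output lies on the side the
#'   normal points to.
#' @return A list with closed `tri_mesh` elements `positive` and `negative`.
#' @examples
#' sph <- make_solid("sphere", list(radius = 1), refinement = 3)
#' halves <- split_by_plane(sph, plane(c(0, 0, 0), c(0, 0, 1)))
#' mesh_volume(halves$positive) # ~ 2*pi/3
#' @export
split_by_plane <- function(mesh, plane) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(plane, "morph_plane"))
  if (!is_closed_mesh(mesh))
    stop("mesh is not closed: cannot split an open surface")
  V <- mesh$vertices
  F <- mesh$faces
  n <- plane$normal
  sd <- as.vector((V - matrix(plane$point, nrow(V), 3, byrow = TRUE)) %*% n)
  scale <- max(abs(sd), 1)
  eps <- 1e-9 * scale
  # on-plane vertices pushed to the positive side: keeps the cut transversal
  sd[abs(sd) <= eps] <- eps
  pos <- sd > 0
  if (all(pos) || all(!pos))
    stop("no intersection: plane does not cut the mesh")

  fs <- cbind(pos[F[, 1]], pos[F[, 2]], pos[F[, 3]])
  npos <- rowSums(fs)
  keep_pos <- which(npos == 3L)
  keep_neg <- which(npos == 0L)
  crossing <- which(npos == 1L | npos == 2L)

  # intersection vertices are shared per undirected cut edge
  nv0 <- nrow(V)
  edge_key <- function(i, j) ifelse(i < j, i * (nv0 + 1) + j, j * (nv0 + 1) + i)
  new_pts <- list(); new_key <- double(0)
  get_cut <- function(i, j) {
    k <- edge_key(i, j)
    hit <- match(k, new_key)
    if (!is.na(hit)) return(nv0 + hit)
    t <- sd[i] / (sd[i] - sd[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    new_key[length(new_key) + 1L] <<- k
    nv0 + length(new_pts)
  }

  pos_faces <- list(); neg_faces <- list()
  seg_a <- integer(0); seg_b <- integer(0)  # cut segments (vertex ids)
  for (fi in crossing) {
    v <- F[fi, ]
    p <- fs[fi, ]
    # rotate so the lone vertex is first
    if (npos[fi] == 1L) lone <- which(p) else lone <- which(!p)
    ord <- ((lone - 1L + 0:2) %% 3L) + 1L
    a <- v[ord[1]]; b <- v[ord[2]]; c <- v[ord[3]]
    pab <- get_cut(a, b)
    pca <- get_cut(a, c)  # edge c->a
    if (npos[fi] == 1L) {
      # a positive alone
      pos_faces[[length(pos_faces) + 1L]] <- c(a, pab, pca)
      neg_faces[[length(neg_faces) + 1L]] <- c(pab, b, c)
      neg_faces[[length(neg_faces) + 1L]] <- c(pab, c, pca)
      seg_a <- c(seg_a, pab); seg_b <- c(seg_b, pca)
    } else {
      # a negative alone
      neg_faces[[length(neg_faces) + 1L]] <- c(a, pab, pca)
      pos_faces[[length(pos_faces) + 1L]] <- c(pab, b, c)
      pos_faces[[length(pos_faces) + 1L]] <- c(pab, c, pca)
      seg_a <- c(seg_a, pca); seg_b <- c(seg_b, pab)
    }
  }
  allV <- rbind(V, do.call(rbind, new_pts))

  # chain cut segments into closed loops (each cut vertex appears in exactly
  # two segments); seg_a -> seg_b is oriented with the positive side on the
  # left when viewed against the plane normal
  loops <- chain_loops(seg_a, seg_b)

  # planar basis for the cut polygons
  u <- orth_basis(n)
  cap_pos <- list(); cap_neg <- list()
  loop2d <- lapply(loops, function(lp) {
    P <- allV[lp, , drop = FALSE]
    cbind(P %*% u$u, P %*% u$v)
  })
  if (length(loops) > 1L && any(nested_loops(loop2d)))
    stop("nested cut cross-sections (annular caps) are not supported")
  for (li in seq_along(loops)) {
    lp <- loops[[li]]
    xy <- loop2d[[li]]
    tris <- ear_clip(xy)  # triangles as index triples into lp, CCW in (u,v)
    ccw <- polygon_signed_area(xy) > 0
    for (ti in seq_len(nrow(tris))) {
      tri <- lp[tris[ti, ]]
      if (!ccw) tri <- rev(tri)
      # CCW in (u,v) basis has normal +n: that caps the NEGATIVE side
      cap_neg[[length(cap_neg) + 1L]] <- tri
      cap_pos[[length(cap_pos) + 1L]] <- rev(tri)
    }
  }

  Fpos <- rbind(F[keep_pos, , drop = FALSE],
                do.call(rbind, pos_faces), do.call(rbind, cap_pos))
  Fneg <- rbind(F[keep_neg, , drop = FALSE],
                do.call(rbind, neg_faces), do.call(rbind, cap_neg))
  list(positive = compact_mesh(allV, Fpos, paste0(mesh$name, "+")),
       negative = compact_mesh(allV, Fneg, paste0(mesh$name, "-")))
}

# drop unused vertices, reindex faces
compact_mesh <- function(V, F, name) {
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  F2 <- matrix(remap[F], ncol = 3)
  tri_mesh(V[used, , drop = FALSE], F2, name = name, check = FALSE)
}

orth_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

chain_loops <- function(seg_a, seg_b) {
  if (!length(seg_a)) stop("no intersection: empty cut")
  nxt <- seg_b[order(seg_a)]
  starts <- sort(seg_a)
  lookup <- function(id) nxt[match(id, starts)]
  used <- logical(length(seg_a))
  loops <- list()
  remaining <- seg_a
  taken <- rep(FALSE, length(seg_a))
  while (any(!taken)) {
    s <- seg_a[which(!taken)[1]]
    lp <- s
    cur <- s
    repeat {
      taken[match(cur, seg_a)] <- TRUE
      nx <- lookup(cur)
      if (is.na(nx)) stop("open cut chain: mesh cut is not a closed loop")
      if (nx == s) break
      lp <- c(lp, nx)
      cur <- nx
    }
    loops[[length(loops) + 1L]] <- lp
  }
  loops
}

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

nested_loops <- function(loop2d) {
  k <- length(loop2d)
  out <- logical(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && point_in_poly(loop2d[[i]][1, ], loop2d[[j]]))
      out[i] <- TRUE
  }
  out
}

point_in_poly <- function(p, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  crosses <- ((y > p[2]) != (y2 > p[2])) &
    (p[1] < (x2 - x) * (p[2] - y) / (y2 - y) + x)
  sum(crosses) %% 2 == 1
}

# ear-clip a simple polygon given as k x 2 coords; returns index triples
# (CCW winding in the input's orientation sense)
ear_clip <- function(xy) {
  k <- nrow(xy)
  if (k < 3L) stop("cut loop with fewer than 3 vertices")
  idx <- seq_len(k)
  if (polygon_signed_area(xy) < 0) idx <- rev(idx)
  tris <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      ia <- idx[(i - 2L) %% m + 1L]
      ib <- idx[(i - 1L) %% m + 1L]
      ic <- idx[i %% m + 1L]
      a <- xy[ia, ]; b <- xy[ib, ]; c <- xy[ic, ]
      cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (cr <= 0) next  # reflex or degenerate corner
      others <- setdiff(idx, c(ia, ib, ic))
      if (length(others) &&
          any(points_in_tri(xy[others, , drop = FALSE], a, b, c))) next
      tris <- rbind(tris, c(ia, ib, ic))
      idx <- idx[idx != ib]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L)
        stop("ear clipping failed: cut polygon may be self-intersecting")
      # fall back: drop the sharpest near-degenerate corner
      m <- length(idx)
      crs <- vapply(seq_len(m), function(i) {
        a <- xy[idx[(i - 2L) %% m + 1L], ]
        b <- xy[idx[(i - 1L) %% m + 1L], ]
        c <- xy[idx[i %% m + 1L], ]
        abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
      }, double(1))
      i <- which.min(crs)
      ia <- idx[(i - 2L) %% m + 1L]; ib <- idx[(i - 1L) %% m + 1L]
      ic <- idx[i %% m + 1L]
      tris <- rbind(tris, c(ia, ib, ic))
      idx <- idx[idx != ib]
    }
  }
  rbind(tris, idx)
}

points_in_tri <- function(P, a, b, c) {
  s1 <- (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
  s2 <- (c[1] - b[1]) * (P[, 2] - b[2]) - (c[2] - b[2]) * (P[, 1] - b[1])
  s3 <- (a[1] - c[1]) * (P[, 2] - c[2]) - (a[2] - c[2]) * (P[, 1] - c[1])
  (s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0)
}
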