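#' Generate a closed phantom solid with known ground truth
#'
#' Produces closed triangulated phantoms used throughout the synthetic
#' study: spheres and ellipsoids (subdivided icosahedra), cubes, hollow
#' cylinders (closed shells with inner and outer walls), and "blobs"
#' (spheres with a smooth random radial perturbation standing in for
#' irregular organ outlines). Where a closed form exists the analytic volume
#' and area are attached as ground truth.
#'
#' @param kind One of `"sphere"`, `"ellipsoid"`, `"cube"`,
#'   `"hollow_cylinder"`, `"blob"`.
#' @param params Named list of dimensions (mm): sphere `radius`; ellipsoid
#'   `semi_axes` (length 3); cube `side`; hollow_cylinder `r_in`, `r_out`,
#'   `length`; blob `radius`, `amplitude` (relative radial amplitude).
#' @param refinement Subdivision level for curved solids (icosphere level or
#'   angular resolution); higher is finer. Default 4.
#' @param seed RNG seed for the blob perturbation (ignored otherwise).
#' @return A [tri_mesh()] with attribute `truth`, a list holding analytic
#'   `volume` and `area` when available.
#' @examples
#' s <- make_solid("sphere", list(radius = 1), refinement = 4)
#' attr(s, "truth")$volume # 4*pi/3
#' @export
make_solid <- function(kind = c("sphere", "ellipsoid", "cube",
                                "hollow_cylinder", "blob"),
                       params = list(), refinement = 4, seed = 1L) {
  kind <- match.arg(kind)
  m <- switch(kind,
    sphere = {
      r <- params$radius %||% 1
      if (r <= 0) stop("sphere radius must be positive")
      m <- icosphere(refinement)
      m$vertices <- m$vertices * r
      truth(m, volume = 4 / 3 * pi * r^3, area = 4 * pi * r^2)
    },
    ellipsoid = {
      ax <- params$semi_axes %||% c(1, 1, 1)
      if (length(ax) != 3 || any(ax <= 0))
        stop("ellipsoid semi_axes must be 3 positive numbers")
      m <- icosphere(refinement)
      m$vertices <- sweep(m$vertices, 2, ax, `*`)
      truth(m, volume = 4 / 3 * pi * prod(ax), area = NA_real_)
    },
    cube = {
      s <- params$side %||% 1
      if (s <= 0) stop("cube side must be positive")
      m <- cube_mesh()
      m$vertices <- m$vertices * s
      truth(m, volume = s^3, area = 6 * s^2)
    },
    hollow_cylinder = {
      r_in <- params$r_in %||% 1
      r_out <- params$r_out %||% 1.2
      L <- params$length %||% 5
      if (r_in <= 0 || L <= 0) stop("cylinder dimensions must be positive")
      if (r_in >= r_out) stop("hollow cylinder requires r_in < r_out")
      nth <- max(16L, 2^refinement * 8L)
      m <- hollow_cylinder_mesh(r_in, r_out, L, nth)
      truth(m, volume = pi * (r_out^2 - r_in^2) * L, area = NA_real_,
            area_outer_wall = 2 * pi * r_out * L,
            area_inner_wall = 2 * pi * r_in * L,
            thickness = r_out - r_in)
    },
    blob = {
      r <- params$radius %||% 1
      amp <- params$amplitude %||% 0.1
      if (r <= 0) stop("blob radius must be positive")
      if (amp < 0) stop("blob amplitude must be non-negative")
      m <- icosphere(refinement)
      if (amp > 0) {
        f <- smooth_sphere_field(m$vertices, seed)
        m$vertices <- m$vertices * (r * (1 + amp * f))
      } else {
        m$vertices <- m$vertices * r
      }
      truth(m, volume = NA_real_, area = NA_real_)
    })
  m$name <- kind
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

truth <- function(mesh, ...) {
  attr(mesh, "truth") <- list(...)
  mesh
}

# smooth deterministic random field on the unit sphere: a sum of low-
# frequency plane waves, normalized to roughly unit amplitude
smooth_sphere_field <- function(dirs, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  K <- 6L
  w <- matrix(stats::rnorm(3 * K), K, 3)
  w <- w / sqrt(rowSums(w^2)) * stats::runif(K, 1, 3)
  ph <- stats::runif(K, 0, 2 * pi)
  amp <- stats::runif(K, 0.3, 1)
  f <- rep(0, nrow(dirs))
  for (k in seq_len(K))
    f <- f + amp[k] * sin(dirs %*% w[k, ] + ph[k])
  as.vector(f) / sum(abs(amp))
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(V) <- NULL
  # 12 triangles, outward winding
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (down)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 (up)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  tri_mesh(V, F, name = "cube")
}

# unit icosphere by repeated midpoint subdivision of an icosahedron
icosphere <- function(level = 4) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(max(0L, as.integer(level)))) {
    sub <- subdivide_tri(V, F)
    V <- sub$V; F <- sub$F
    V <- V / sqrt(rowSums(V^2))
  }
  tri_mesh(V, F, name = "icosphere", check = FALSE)
}

subdivide_tri <- function(V, F) {
  nv <- nrow(V)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  uk <- unique(key)
  mid_idx <- nv + match(key, uk)
  first <- match(uk, key)
  mids <- (V[e[first, 1], , drop = FALSE] + V[e[first, 2], , drop = FALSE]) / 2
  nf <- nrow(F)
  m12 <- mid_idx[seq_len(nf)]
  m23 <- mid_idx[nf + seq_len(nf)]
  m31 <- mid_idx[2 * nf + seq_len(nf)]
  F2 <- rbind(cbind(F[, 1], m12, m31),
              cbind(F[, 2], m23, m12),
              cbind(F[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(V = rbind(V, mids), F = F2)
}

# closed hollow cylinder: outer + inner side walls and two annular caps,
# axis along z from 0 to L
hollow_cylinder_mesh <- function(r_in, r_out, L, nth) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ring <- cbind(cos(th), sin(th))
  V <- rbind(cbind(r_out * ring, 0), cbind(r_out * ring, L),
             cbind(r_in * ring, 0), cbind(r_in * ring, L))
  i <- seq_len(nth); j <- c(i[-1], i[1])
  o0 <- 0L; o1 <- nth; i0 <- 2L * nth; i1 <- 3L * nth
  F <- rbind(
    # outer wall, outward = radially out
    cbind(o0 + i, o0 + j, o1 + i), cbind(o0 + j, o1 + j, o1 + i),
    # inner wall, outward = radially in
    cbind(i0 + i, i1 + i, i0 + j), cbind(i0 + j, i1 + i, i1 + j),
    # bottom annulus (z = 0), outward = -z
    cbind(o0 + i, i0 + i, o0 + j), cbind(o0 + j, i0 + i, i0 + j),
    # top annulus (z = L), outward = +z
    cbind(o1 + i, o1 + j, i1 + i), cbind(o1 + j, i1 + j, i1 + i))
  tri_mesh(V, F, name = "hollow_cylinder", check = FALSE)
}

# open side-wall cylinder (no caps), for wall-area measurement
cylinder_wall_mesh <- function(r, L, nth, outward = TRUE) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ring <- cbind(r * cos(th), r * sin(th))
  V <- rbind(cbind(ring, 0), cbind(ring, L))
  i <- seq_len(nth); j <- c(i[-1], i[1])
  F <- rbind(cbind(i, j, nth + i), cbind(j, nth + j, nth + i))
  if (!outward) F <- F[, c(1, 3, 2)]
  tri_mesh(V, F, name = "cylinder_wall", check = FALSE)
}

# closed surface of revolution about the x axis; profile rho(x) > 0 on the
# open interior, capped with pole fans at both ends (rho = 0 at ends)
revolve_mesh <- function(x, rho, nth, name = "revolve") {
  stopifnot(length(x) == length(rho), rho[1] == 0, rho[length(rho)] == 0,
            all(rho[c(-1, -length(rho))] > 0))
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ct <- cos(th); st <- sin(th)
  nin <- length(x) - 2L
  inner <- seq_len(nin) + 1L
  V <- matrix(0, nin * nth + 2L, 3)
  V[1, ] <- c(x[1], 0, 0)
  V[2, ] <- c(x[length(x)], 0, 0)
  row <- function(k) 2L + (k - 1L) * nth + seq_len(nth)
  for (k in seq_len(nin)) {
    V[row(k), 1] <- x[inner[k]]
    V[row(k), 2] <- rho[inner[k]] * ct
    V[row(k), 3] <- rho[inner[k]] * st
  }
  i <- seq_len(nth); j <- c(i[-1], i[1])
  Fs <- list()
  # start pole fan (outward normal faces -x); winding: pole, next, cur
  r1 <- 2L + i; r1n <- 2L + j
  Fs[[1]] <- cbind(1L, r1n, r1)
  for (k in seq_len(nin - 1L)) {
    a <- 2L + (k - 1L) * nth
    b <- 2L + k * nth
    Fs[[length(Fs) + 1L]] <- cbind(a + i, a + j, b + i)
    Fs[[length(Fs) + 1L]] <- cbind(a + j, b + j, b + i)
  }
  rl <- 2L + (nin - 1L) * nth
  Fs[[length(Fs) + 1L]] <- cbind(2L, rl + i, rl + j)
  tri_mesh(V, do.call(rbind, Fs), name = name, check = FALSE)
}
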