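# ---- two-lobed ventricle phantom -------------------------------------------
#
# The combined ventricular surface is modelled as the union of two equal
# prolate spheroids (semi-axis a along x, b transverse) centred at x = -c and
# x = +c with c < a, which is an axisymmetric dumbbell: at every axial
# position the union's cross-section radius is the larger of the two lobe
# radii. Splitting at the midline plane x = 0 returns each lobe as the
# truncated spheroid closed by the flat septal cap, which is exactly the
# entity whose sphericity the pipeline measures. Lobe elongation a/b is
# tuned by bisection so that the *mesh-measured* per-lobe sphericity matches
# the requested target.

# profile samples for one lobe (centre -c, cut at x = 0); polar-angle spaced
# so pole regions are well resolved; no sample lands exactly on x = 0, so the
# midline split is always transversal
lobe_profile <- function(a, b, c_off, nx) {
  t_cut <- acos(-c_off / a)
  t <- seq(0, t_cut, length.out = nx + 1)
  t <- t[-length(t)]                      # drop the x = 0 sample
  x <- -c_off - a * cos(t)
  rho <- b * sin(t)
  list(x = x, rho = rho)
}

dumbbell_mesh <- function(a, b, c_off, nx = 48, nth = 64) {
  l <- lobe_profile(a, b, c_off, nx)
  x <- c(l$x, rev(-l$x))
  rho <- c(l$rho, rev(l$rho))
  revolve_mesh(x, rho, nth, name = "ventricles")
}

# one lobe built directly for fast sphericity evaluation during tuning:
# truncated spheroid profile, a cylindrical stub from the last ring to the
# midline (matching the linear interpolation the dumbbell band is cut
# through), and a flat fan cap; geometry matches the split half of
# dumbbell_mesh up to the cap triangulation, which spans the same circle
half_lobe_sphericity <- function(a, b, c_off, nx = 48, nth = 64) {
  l <- lobe_profile(a, b, c_off, nx)
  # ring exactly at the midline with the last sampled radius (stub)
  l$x <- c(l$x, 0)
  l$rho <- c(l$rho, l$rho[length(l$rho)])
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ct <- cos(th); st <- sin(th)
  nin <- length(l$x) - 1L
  V <- matrix(0, nin * nth + 2L, 3)
  V[1, ] <- c(l$x[1], 0, 0)
  V[2, ] <- c(0, 0, 0)                     # cap centre
  for (k in seq_len(nin)) {
    r <- 2L + (k - 1L) * nth + seq_len(nth)
    V[r, 1] <- l$x[k + 1L]
    V[r, 2] <- l$rho[k + 1L] * ct
    V[r, 3] <- l$rho[k + 1L] * st
  }
  i <- seq_len(nth); j <- c(i[-1], i[1])
  Fs <- list(cbind(1L, 2L + j, 2L + i))
  for (k in seq_len(nin - 1L)) {
    ao <- 2L + (k - 1L) * nth; bo <- 2L + k * nth
    Fs[[length(Fs) + 1L]] <- cbind(ao + i, ao + j, bo + i)
    Fs[[length(Fs) + 1L]] <- cbind(ao + j, bo + j, bo + i)
  }
  rl <- 2L + (nin - 1L) * nth
  Fs[[length(Fs) + 1L]] <- cbind(2L, rl + i, rl + j)
  m <- tri_mesh(V, do.call(rbind, Fs), name = "lobe", check = FALSE)
  v <- signed_volume(m$vertices, m$faces)
  sphericity(v, mesh_area(m))
}

# choose elongation (and, for near-spherical targets, lobe overlap) so that
# mesh-measured lobe sphericity hits the target
tune_lobe_shape <- function(target_s, c_frac = 0.62, nx = 48, nth = 64,
                            tol = 1e-5) {
  if (target_s > 1)
    stop("targets geometrically unreachable: sphericity > 1")
  s_at <- function(e, cf) half_lobe_sphericity(e, 1, cf * e, nx, nth)
  s_max <- s_at(1, c_frac)
  if (target_s >= s_max) {
    # reduce overlap (push lobes apart) with spherical lobes
    cf_hi <- 0.96
    if (target_s >= s_at(1, cf_hi))
      return(list(e = 1, c_frac = cf_hi))
    cf <- stats::uniroot(function(cf) s_at(1, cf) - target_s,
                         c(c_frac, cf_hi), tol = 1e-6)$root
    return(list(e = 1, c_frac = cf))
  }
  e_hi <- 2
  while (s_at(e_hi, c_frac) > target_s && e_hi < 64) e_hi <- e_hi * 2
  if (s_at(e_hi, c_frac) > target_s)
    stop("targets geometrically unreachable: sphericity too low")
  e <- stats::uniroot(function(e) s_at(e, c_frac) - target_s,
                      c(1, e_hi), tol = tol)$root
  list(e = e, c_frac = c_frac)
}

#' Generate a synthetic brain with known morphometric ground truth
#'
#' Builds one phantom emulating the organ-scale anatomy the pipeline
#' measures: a closed irregular outer cortical surface (a smoothly
#' perturbed sphere) scaled to the target brain volume; a two-lobed
#' ventricular surface (two overlapping prolate spheroids joined at a
#' midline neck) whose lobe elongation is tuned so each lobe's
#' mesh-measured sphericity equals the target, and whose overall scale is
#' chosen so the shell-thickness formula evaluates to the target cortical
#' thickness; and two pupil landmarks placed exactly at the target
#' intraocular distance.
#'
#' @param targets Named list/row with `brain_volume` (mm^3), `sphericity`
#'   (per lobe), `cortical_thickness` (mm), `intraocular_distance` (mm).
#' @param sample_id,genotype Passed to [brain_sample()].
#' @param seed RNG seed for the cortical blob shape.
#' @param refinement Named list: `cortex` icosphere level (default 3),
#'   `nx`/`nth` ventricle profile and angular resolution (defaults 48/64).
#' @param blob_amplitude Relative radial irregularity of the outer surface
#'   (default 0.08).
#' @return A [brain_sample()] with attribute `truth` recording the targets
#'   and the realized meshes' measured values, and attribute `split_plane`
#'   (the midline [plane()]).
#' @export
make_brain_phantom <- function(targets, sample_id = "phantom",
                               genotype = "WT", seed = 1L,
                               refinement = list(), blob_amplitude = 0.08) {
  tg <- targets
  need <- c("brain_volume", "sphericity", "cortical_thickness",
            "intraocular_distance")
  if (!all(need %in% names(tg)))
    stop("targets must include ", paste(need, collapse = ", "))
  if (tg$brain_volume <= 0 || tg$cortical_thickness <= 0 ||
      tg$intraocular_distance <= 0 || tg$sphericity <= 0)
    stop("targets must be positive")
  cortex_lvl <- refinement$cortex %||% 3
  nx <- refinement$nx %||% 48
  nth <- refinement$nth %||% 64

  # outer cortical surface: blob scaled to the exact target volume
  outer <- make_solid("blob", list(radius = 1, amplitude = blob_amplitude),
                      refinement = cortex_lvl, seed = seed)
  v_out <- mesh_volume(outer)
  outer$vertices <- outer$vertices * (tg$brain_volume / v_out)^(1 / 3)
  outer$name <- "cortex_outer"
  v_b <- tg$brain_volume
  a_b <- mesh_area(outer)

  # ventricle shape: tune lobe sphericity, then scale for thickness
  shp <- tune_lobe_shape(tg$sphericity, nx = nx, nth = nth)
  vent0 <- dumbbell_mesh(shp$e, 1, shp$c_frac * shp$e, nx = nx, nth = nth)
  v_v0 <- mesh_volume(vent0)
  a_v0 <- mesh_area(vent0)
  h <- tg$cortical_thickness
  f <- function(s) v_v0 * s^3 + h * a_v0 / 2 * s^2 + (h * a_b / 2 - v_b)
  if (f(0) >= 0)
    stop("targets geometrically unreachable: thickness too large for ",
         "the target brain volume")
  s_max <- ((v_b * 0.999) / v_v0)^(1 / 3)
  if (f(s_max) <= 0)
    stop("targets geometrically unreachable: thickness too small")
  s <- stats::uniroot(f, c(0, s_max), tol = 1e-12)$root
  vent <- vent0
  vent$vertices <- vent$vertices * s
  vent$name <- "ventricular_surface"

  d <- tg$intraocular_distance
  pupils <- list(landmark(c(-d / 2, 0.8 * (3 * v_b / (4 * pi))^(1 / 3), 0),
                          "pupil_left"),
                 landmark(c(d / 2, 0.8 * (3 * v_b / (4 * pi))^(1 / 3), 0),
                          "pupil_right"))

  sample <- brain_sample(sample_id, genotype, outer, vent, pupils)
  attr(sample, "split_plane") <- plane(c(0, 0, 0), c(1, 0, 0))
  attr(sample, "truth") <- list(
    targets = tg[need],
    lobe_elongation = shp$e, lobe_overlap = shp$c_frac,
    ventricle_scale = s,
    brain_volume = v_b, brain_area = a_b,
    ventricle_volume = v_v0 * s^3, ventricle_area = a_v0 * s^2,
    lobe_volume = v_v0 * s^3 / 2)
  sample
}
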