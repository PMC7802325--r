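#' Sphericity of a closed 3D body
#'
#' Sphericity compares the surface area of a body to that of the
#' volume-equivalent sphere:
#' \deqn{S = \frac{\pi^{1/3} (6V)^{2/3}}{A}}
#' It equals 1 for a perfect sphere and is strictly below 1 for every other
#' closed surface (isoperimetric inequality). Applied per ventricular lobe
#' after midline separation.
#'
#' @param volume Enclosed volume (mm^3), positive.
#' @param area Surface area (mm^2), positive.
#' @return Dimensionless sphericity in (0, 1] (up to mesh discretization).
#' @examples
#' sphericity(4 * pi / 3, 4 * pi) # 1
#' sphericity(1, 6)               # unit cube, ~0.80600
#' @export
sphericity <- function(volume, area) {
  if (any(volume <= 0) || any(area <= 0))
    stop("sphericity requires positive volume and area")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Mean cortical wall thickness from volume and bounding areas
#'
#' Treats the cortical neuroepithelium as a hollow shell with volume
#' \eqn{V} bounded by an outer surface of area \eqn{A_{outer}} and an inner
#' (ventricular) surface of area \eqn{A_{inner}}, giving the mean wall
#' height
#' \deqn{h = \frac{2V}{A_{outer} + A_{inner}}}
#' For a hollow cylinder wall this is exactly the wall thickness
#' \eqn{r_{out} - r_{in}}; for strongly curved thick shells it carries a
#' small systematic thin-shell bias, which is documented rather than
#' corrected.
#'
#' @param v_cortex Shell (cortical) volume, mm^3.
#' @param a_outer Outer surface area, mm^2.
#' @param a_inner Inner surface area, mm^2.
#' @return Thickness in mm.
#' @examples
#' cortical_thickness(pi * (1.2^2 - 1) * 5, 2 * pi * 1.2 * 5, 2 * pi * 5) # 0.2
#' @export
cortical_thickness <- function(v_cortex, a_outer, a_inner) {
  if (any(v_cortex <= 0) || any(a_outer <= 0) || any(a_inner <= 0))
    stop("cortical_thickness requires positive volume and areas")
  2 * v_cortex / (a_outer + a_inner)
}

#' Assemble a brain sample from its surfaces and landmarks
#'
#' @param sample_id Text id.
#' @param genotype `"WT"` or `"HET"`.
#' @param cortex_outer Closed [tri_mesh()]: outer cortical surface.
#' @param ventricular_surface Closed [tri_mesh()]: combined two-lobed
#'   ventricular surface.
#' @param pupils List of two [landmark()]s at the pupil centres.
#' @return An object of class `brain_sample`.
#' @export
brain_sample <- function(sample_id, genotype = c("WT", "HET"),
                         cortex_outer, ventricular_surface, pupils) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(cortex_outer, "tri_mesh"),
            inherits(ventricular_surface, "tri_mesh"),
            length(pupils) == 2L)
  structure(list(sample_id = as.character(sample_id), genotype = genotype,
                 cortex_outer = cortex_outer,
                 ventricular_surface = ventricular_surface,
                 pupils = pupils),
            class = "brain_sample")
}

#' @export
print.brain_sample <- function(x, ...) {
  cat("<brain_sample>", x$sample_id, paste0("[", x$genotype, "]"),
      "\n  cortex faces:", nrow(x$cortex_outer$faces),
      " ventricle faces:", nrow(x$ventricular_surface$faces), "\n")
  invisible(x)
}

#' Compute the full organ-scale morphometric record for one brain
#'
#' Separates the ventricular surface into two lobes at the given midline
#' plane, then computes brain volume and area, per-lobe ventricular volume,
#' area and sphericity, cortical volume (brain volume minus total
#' ventricular volume), mean cortical thickness, and the intraocular
#' distance. The lobe on the side the plane normal points to is reported as
#' `right`.
#'
#' @param sample A [brain_sample()].
#' @param split_plane A [plane()] separating the two ventricular lobes.
#' @param lobe_thickness If `TRUE`, additionally report per-lobe cortical
#'   thickness computed by applying the same shell formula to the
#'   plane-split half shells (an interpretation: the halves include their
#'   cut caps).
#' @return A one-row tibble (the morphometric record).
#' @export
analyze_sample <- function(sample, split_plane, lobe_thickness = FALSE) {
  stopifnot(inherits(sample, "brain_sample"),
            inherits(split_plane, "morph_plane"))
  brain_volume <- mesh_volume(sample$cortex_outer)
  brain_area <- mesh_area(sample$cortex_outer)
  halves <- split_by_plane(sample$ventricular_surface, split_plane)
  right <- halves$positive; left <- halves$negative
  v_l <- mesh_volume(left); v_r <- mesh_volume(right)
  a_l <- mesh_area(left); a_r <- mesh_area(right)
  a_inner <- mesh_area(sample$ventricular_surface)
  cortical_volume <- brain_volume - (v_l + v_r)
  if (cortical_volume <= 0)
    stop("ventricular volume exceeds brain volume: inconsistent surfaces")
  s_l <- sphericity(v_l, a_l); s_r <- sphericity(v_r, a_r)
  if (max(s_l, s_r) > 1 + 1e-6)
    stop("computed sphericity exceeds 1: inconsistent mesh")
  rec <- tibble::tibble(
    sample_id = sample$sample_id,
    genotype = sample$genotype,
    brain_volume = brain_volume,
    cortical_volume = cortical_volume,
    ventricle_volume_left = v_l,
    ventricle_volume_right = v_r,
    brain_area = brain_area,
    ventricle_area_left = a_l,
    ventricle_area_right = a_r,
    ventricle_sphericity_left = s_l,
    ventricle_sphericity_right = s_r,
    cortical_thickness = cortical_thickness(cortical_volume, brain_area,
                                            a_inner),
    intraocular_distance = landmark_distance(sample$pupils[[1]],
                                             sample$pupils[[2]])
  )
  if (lobe_thickness) {
    bh <- split_by_plane(sample$cortex_outer, split_plane)
    ih <- halves
    th_side <- function(outer, inner) {
      v <- mesh_volume(outer) - mesh_volume(inner)
      cortical_thickness(v, mesh_area(outer), mesh_area(inner))
    }
    rec$cortical_thickness_right <- th_side(bh$positive, ih$positive)
    rec$cortical_thickness_left <- th_side(bh$negative, ih$negative)
  }
  rec
}

# metrics reported per animal vs pooled per ventricular lobe
brain_level_metrics <- c("brain_volume", "cortical_volume", "brain_area",
                         "cortical_thickness", "intraocular_distance")
lobe_level_metrics <- c(ventricle_volume = "ventricle_volume",
                        ventricle_area = "ventricle_area",
                        ventricle_sphericity = "ventricle_sphericity")

#' Per-genotype summaries of morphometric records
#'
#' Summarizes each metric by genotype as n, mean and sample SD (n - 1
#' denominator; SD is `NA` for singletons). Brain-level metrics (volumes,
#' areas, thickness, intraocular distance) are counted per animal;
#' ventricle-level metrics (lobe volume, area, sphericity) are pooled
#' across the two lobes, so a group of 2 brains contributes n = 4
#' ventricles.
#'
#' @param records Tibble of morphometric records from [analyze_sample()]
#'   (rows bind cleanly).
#' @return A tibble with columns `metric`, `genotype`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no morphometric records to summarize")
  brain <- records |>
    dplyr::select(dplyr::all_of(c("genotype",
                                  intersect(brain_level_metrics,
                                            names(records))))) |>
    tidyr::pivot_longer(-"genotype", names_to = "metric",
                        values_to = "value")
  lobe_cols <- grep("^ventricle_.*_(left|right)$", names(records),
                    value = TRUE)
  lobe <- if (length(lobe_cols)) {
    records |>
      dplyr::select("genotype", dplyr::all_of(lobe_cols)) |>
      tidyr::pivot_longer(-"genotype", names_to = "metric",
                          values_to = "value") |>
      dplyr::mutate(metric = sub("_(left|right)$", "", .data$metric))
  } else NULL
  dplyr::bind_rows(brain, lobe) |>
    dplyr::group_by(.data$metric, .data$genotype) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() >= 2, stats::sd(.data$value),
                                 NA_real_),
                     .groups = "drop") |>
    dplyr::arrange(.data$metric, .data$genotype)
}
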