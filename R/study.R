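# ---- two-genotype synthetic study ------------------------------------------

#' Study configuration for the two-genotype synthetic cohort
#'
#' Holds the generative parameters of a synthetic study: per genotype the
#' number of animals and the mean and SD of each organ-scale target metric
#' (per-sample values are drawn independently from normal distributions
#' truncated to physical ranges), plus the apical-lattice parameters. The
#' defaults are the group statistics of the embryonic Chd8 cohort the
#' pipeline is designed around: wild types with ventricular sphericity
#' 0.70 +/- 0.01, intraocular distance 1.75 +/- 0.002 mm, cortical
#' thickness 0.08 +/- 0.02 mm and brain volume 3.28 +/- 0.18 mm^3 (mean and
#' SD of the two reported animals, 3.41 and 3.15 mm^3), and heterozygotes
#' with 0.67 +/- 0.03, 1.85 +/- 0.10 mm, 0.10 +/- 0.03 mm and
#' 3.60 +/- 0.56 mm^3; cohort sizes 2 and 5. Lattice sizes default to the
#' cell counts of the two segmented samples (1031 and 3854) with no Lloyd
#' relaxation, whose hexagon fraction (~30%) matches the observed 29-31%.
#'
#' @param groups A tibble with one row per genotype and columns `genotype`,
#'   `n_samples`, `sphericity_mean`, `sphericity_sd`, `intraocular_mean`,
#'   `intraocular_sd`, `thickness_mean`, `thickness_sd`, `volume_mean`,
#'   `volume_sd`, `n_cells`, `relaxation_steps`. Omitted columns take the
#'   defaults above.
#' @param seed Master seed of the study.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = NULL, seed = 1L) {
  def <- tibble::tibble(
    genotype = c("WT", "HET"),
    n_samples = c(2L, 5L),
    sphericity_mean = c(0.70, 0.67), sphericity_sd = c(0.01, 0.03),
    intraocular_mean = c(1.75, 1.85), intraocular_sd = c(0.002, 0.10),
    thickness_mean = c(0.08, 0.10), thickness_sd = c(0.02, 0.03),
    volume_mean = c(3.28, 3.60), volume_sd = c(0.1838478, 0.56),
    n_cells = c(1031L, 3854L), relaxation_steps = c(0L, 0L))
  if (!is.null(groups)) {
    groups <- tibble::as_tibble(groups)
    if (!"genotype" %in% names(groups))
      stop("`groups` needs a genotype column")
    merged <- def[match(groups$genotype, def$genotype), ]
    if (anyNA(merged$genotype)) stop("genotype must be WT or HET")
    for (cl in setdiff(names(groups), "genotype"))
      merged[[cl]] <- groups[[cl]]
    def <- merged
  }
  sds <- def[grepl("_sd$", names(def))]
  if (any(unlist(sds) < 0)) stop("SDs must be non-negative")
  if (any(def$n_samples < 1)) stop("n_samples must be >= 1")
  structure(list(groups = def, seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> seed", x$seed, "\n")
  print(x$groups)
  invisible(x)
}

#' Read / write a study configuration as YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @param config A [study_config()].
#' @return The configuration (read) or `path` invisibly (write).
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path)
  else stop("unsupported config format: ", ext)
  study_config(tibble::as_tibble(lst$groups), seed = lst$seed %||% 1L)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- list(seed = config$seed, groups = as.data.frame(config$groups))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else if (ext == "json")
    jsonlite::write_json(lst, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else stop("unsupported config format: ", ext)
  invisible(path)
}

# normal draw truncated to an interval by resampling
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop("truncated normal draw failed: target mean ", mean,
       " incompatible with bounds [", lower, ", ", upper, "]")
}

#' Generate a synthetic two-genotype study with ground truth
#'
#' Draws per-sample target metrics from the configured group distributions,
#' builds a brain phantom and an apical lattice for every sample, and
#' (optionally) writes the study to disk in the exchange layout the
#' pipeline reads: per sample a directory with `cortex_outer.ply`,
#' `ventricles.ply`, `landmarks.csv` and `lattice.tif`, plus a top-level
#' `manifest.json` recording genotypes, file names, the midline split
#' plane, the full ground truth and the configuration. Fixed seed gives a
#' byte-identical study.
#'
#' @param config A [study_config()].
#' @param dir Output directory, or `NULL` (default) to keep the study in
#'   memory only.
#' @param lattices Generate apical lattices (default `TRUE`); organ-scale
#'   recovery experiments may switch them off.
#' @param pixel_size Label-image pixel size in µm (default 0.2).
#' @param refinement Passed to [make_brain_phantom()].
#' @return An object of class `synth_study`: list with `samples` (list of
#'   [brain_sample()]s), `lattices` (list of [cell_lattice()]s or `NULL`s),
#'   `truth` (tibble of drawn per-sample targets), `config`, `dir`.
#' @export
generate_study <- function(config = study_config(), dir = NULL,
                           lattices = TRUE, pixel_size = 0.2,
                           refinement = list()) {
  stopifnot(inherits(config, "study_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  g <- config$groups
  rows <- list(); samples <- list(); lats <- list()
  k <- 0L
  for (gi in seq_len(nrow(g))) {
    for (si in seq_len(g$n_samples[gi])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g$genotype[gi], si)
      tg <- list(
        sphericity = rtruncnorm1(g$sphericity_mean[gi], g$sphericity_sd[gi],
                                 0.05, 0.995),
        intraocular_distance = rtruncnorm1(g$intraocular_mean[gi],
                                           g$intraocular_sd[gi], 1e-3, Inf),
        cortical_thickness = rtruncnorm1(g$thickness_mean[gi],
                                         g$thickness_sd[gi], 1e-4, Inf),
        brain_volume = rtruncnorm1(g$volume_mean[gi], g$volume_sd[gi],
                                   1e-3, Inf))
      sub_seed <- sample.int(2^31 - 2, 2)
      ph <- make_brain_phantom(tg, sample_id = id,
                               genotype = g$genotype[gi],
                               seed = sub_seed[1], refinement = refinement)
      samples[[k]] <- ph
      lats[[k]] <- if (lattices)
        make_voronoi_lattice(g$n_cells[gi],
                             relaxation_steps = g$relaxation_steps[gi],
                             seed = sub_seed[2], periodic = FALSE)
      else NULL
      rows[[k]] <- tibble::tibble(
        sample_id = id, genotype = g$genotype[gi],
        target_sphericity = tg$sphericity,
        target_intraocular = tg$intraocular_distance,
        target_thickness = tg$cortical_thickness,
        target_volume = tg$brain_volume,
        phantom_seed = sub_seed[1], lattice_seed = sub_seed[2])
    }
  }
  study <- structure(list(samples = samples, lattices = lats,
                          truth = dplyr::bind_rows(rows), config = config,
                          dir = dir), class = "synth_study")
  if (!is.null(dir)) write_study(study, dir, pixel_size = pixel_size)
  study
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study>", length(x$samples), "samples (",
      paste(table(x$truth$genotype)[unique(x$truth$genotype)],
            unique(x$truth$genotype), collapse = " + "), ")\n")
  invisible(x)
}

write_study <- function(study, dir, pixel_size = 0.2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (k in seq_along(study$samples)) {
    s <- study$samples[[k]]
    sd <- file.path(dir, s$sample_id)
    dir.create(sd, showWarnings = FALSE)
    write_mesh(s$cortex_outer, file.path(sd, "cortex_outer.ply"))
    write_mesh(s$ventricular_surface, file.path(sd, "ventricles.ply"))
    write_landmarks(s$pupils, file.path(sd, "landmarks.csv"))
    has_lat <- !is.null(study$lattices[[k]])
    if (has_lat) {
      img <- rasterize_lattice(study$lattices[[k]], pixel_size = pixel_size)
      write_label_image(img, file.path(sd, "lattice.tif"))
    }
    pl <- attr(s, "split_plane")
    entries[[k]] <- list(
      sample_id = s$sample_id, genotype = s$genotype,
      dir = s$sample_id,
      cortex = "cortex_outer.ply", ventricles = "ventricles.ply",
      landmarks = "landmarks.csv",
      lattice = if (has_lat) "lattice.tif" else NULL,
      pixel_size = if (has_lat) pixel_size else NULL,
      split_plane = list(point = pl$point, normal = pl$normal),
      truth = attr(s, "truth")$targets)
  }
  manifest <- list(samples = entries,
                   config = list(seed = study$config$seed,
                                 groups = as.data.frame(study$config$groups)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
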