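# ---- pipeline orchestration -------------------------------------------------

#' Run the full morphometric pipeline over a study directory
#'
#' Reads a study laid out as written by [generate_study()] (or equivalent
#' user-supplied data with the same `manifest.json` contract), computes the
#' organ-scale record of every sample and, where a label image is present,
#' the apical-lattice statistics and packing-law fits, and writes the
#' result tables to `out_dir`:
#' \itemize{
#'   \item `morphometrics.csv` — one row per sample ([analyze_sample()]);
#'   \item `group_summary.csv` — one row per metric x genotype
#'     ([summarize_groups()]);
#'   \item `lattice_stats.csv` — one row per sample x polygon class;
#'   \item `law_tables.csv` — fitted packing-law coefficients per sample;
#'   \item `summary.json` — machine-readable mirror of all of the above;
#'   \item `run.log` — per-sample successes and failures.
#' }
#' A sample that fails (e.g. a corrupt mesh) is logged and skipped, never
#' aborting the run. Outputs contain no timestamps, so re-running on
#' identical inputs is byte-identical.
#'
#' @param study_dir Directory containing `manifest.json`.
#' @param out_dir Output directory (created; default
#'   `file.path(study_dir, "results")`).
#' @param aboav_form Aboav-Weaire reference form, see [aboav_expected()].
#' @param plots If `TRUE`, also write dot-plot and distribution PNGs.
#' @return `out_dir`, invisibly; the result tables are also returned as the
#'   attribute `results` (list of tibbles).
#' @export
run_pipeline <- function(study_dir, out_dir = file.path(study_dir, "results"),
                         aboav_form = c("standard", "literal"),
                         plots = FALSE) {
  aboav_form <- match.arg(aboav_form)
  mf_path <- file.path(study_dir, "manifest.json")
  if (!file.exists(mf_path))
    stop("no manifest.json in ", study_dir)
  manifest <- jsonlite::fromJSON(mf_path, simplifyDataFrame = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  recs <- list(); lat_rows <- list(); law_rows <- list()
  for (e in manifest$samples) {
    res <- tryCatch({
      sd <- file.path(study_dir, e$dir)
      cortex <- read_mesh(file.path(sd, e$cortex))
      vent <- read_mesh(file.path(sd, e$ventricles))
      lms <- read_landmarks(file.path(sd, e$landmarks))
      pupils <- lms[grepl("pupil", names(lms))]
      if (length(pupils) != 2L) pupils <- lms[1:2]
      pl <- plane(unlist(e$split_plane$point), unlist(e$split_plane$normal))
      smp <- brain_sample(e$sample_id, e$genotype, cortex, vent, pupils)
      rec <- analyze_sample(smp, pl)
      out <- list(rec = rec)
      if (!is.null(e$lattice)) {
        img <- read_label_image(file.path(sd, e$lattice),
                                pixel_size = e$pixel_size %||% 0.2)
        st <- interior_stats(adjacency_from_labels(img))
        out$lat <- dplyr::mutate(
          dplyr::left_join(st$neighbour_frequencies,
                           dplyr::left_join(st$lewis_table[c(
                             "n", "mean_area", "mean_rel_area")],
                             st$aboav_table[c("n", "m")], by = "n"),
                           by = "n"),
          sample_id = e$sample_id, genotype = e$genotype,
          .before = 1)
        lf <- tryCatch(empirical_law_tables(st, form = aboav_form),
                       error = function(err) NULL)
        if (!is.null(lf))
          out$law <- dplyr::mutate(lf$fits, sample_id = e$sample_id,
                                   genotype = e$genotype, .before = 1)
      }
      out
    }, error = function(err) err)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines,
                     paste0("FAIL ", e$sample_id, ": ",
                            conditionMessage(res)))
      next
    }
    log_lines <- c(log_lines, paste0("OK   ", e$sample_id))
    recs[[length(recs) + 1L]] <- res$rec
    if (!is.null(res$lat)) lat_rows[[length(lat_rows) + 1L]] <- res$lat
    if (!is.null(res$law)) law_rows[[length(law_rows) + 1L]] <- res$law
  }
  if (!length(recs))
    stop("no sample could be analyzed; see run.log in ", out_dir)
  records <- dplyr::bind_rows(recs)
  summary_tbl <- summarize_groups(records)
  lattice_tbl <- if (length(lat_rows)) dplyr::bind_rows(lat_rows) else
    tibble::tibble()
  law_tbl <- if (length(law_rows)) dplyr::bind_rows(law_rows) else
    tibble::tibble()
  readr::write_csv(records, file.path(out_dir, "morphometrics.csv"))
  readr::write_csv(summary_tbl, file.path(out_dir, "group_summary.csv"))
  readr::write_csv(lattice_tbl, file.path(out_dir, "lattice_stats.csv"))
  readr::write_csv(law_tbl, file.path(out_dir, "law_tables.csv"))
  jsonlite::write_json(
    list(morphometrics = records, group_summary = summary_tbl,
         lattice_stats = lattice_tbl, law_tables = law_tbl),
    file.path(out_dir, "summary.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  if (plots) write_pipeline_plots(records, lattice_tbl, out_dir)
  results <- list(morphometrics = records, group_summary = summary_tbl,
                  lattice_stats = lattice_tbl, law_tables = law_tbl,
                  log = log_lines)
  out <- out_dir
  attr(out, "results") <- results
  invisible(out)
}

write_pipeline_plots <- function(records, lattice_tbl, out_dir) {
  p1 <- plot_group_dots(records)
  ggplot2::ggsave(file.path(out_dir, "morphometrics.png"), p1,
                  width = 8, height = 5, dpi = 150)
  if (nrow(lattice_tbl)) {
    p2 <- ggplot2::ggplot(lattice_tbl,
                          ggplot2::aes(x = .data$n, y = .data$frequency,
                                       fill = .data$genotype)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~sample_id) +
      ggplot2::labs(x = "neighbour number n", y = "frequency") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, "neighbour_distribution.png"), p2,
                    width = 8, height = 5, dpi = 150)
  }
  invisible(NULL)
}

#' Between-genotype differences of the group summaries
#'
#' Tabulates, per metric, the two group means and their difference
#' (HET minus WT). With `test = TRUE` a Welch two-sample t-test is added;
#' it is labelled exploratory — the study design (n as low as 2) does not
#' support confirmatory inference, and no multiplicity correction is
#' applied.
#'
#' @param records Morphometric records ([analyze_sample()] rows).
#' @param test Add Welch t statistic and p-value (default `FALSE`).
#' @return A tibble: `metric`, `mean_WT`, `mean_HET`, `difference`, and
#'   with `test = TRUE` also `t`, `p_value`, `note`.
#' @export
compare_groups <- function(records, test = FALSE) {
  if (length(unique(records$genotype)) < 2L)
    stop("compare_groups needs both genotypes")
  summ <- summarize_groups(records)
  wide <- summ |>
    dplyr::select("metric", "genotype", "mean") |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "mean",
                       names_prefix = "mean_") |>
    dplyr::mutate(difference = .data$mean_HET - .data$mean_WT)
  if (test) {
    long <- records |>
      dplyr::select("genotype", dplyr::where(is.numeric)) |>
      tidyr::pivot_longer(-"genotype", names_to = "metric",
                          values_to = "value") |>
      dplyr::mutate(metric = sub("_(left|right)$", "", .data$metric))
    tests <- long |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(
        t = tryCatch(stats::t.test(
          value ~ genotype)$statistic, error = function(e) NA_real_),
        p_value = tryCatch(stats::t.test(
          value ~ genotype)$p.value, error = function(e) NA_real_),
        .groups = "drop")
    wide <- dplyr::left_join(wide, tests, by = "metric") |>
      dplyr::mutate(note = "exploratory Welch t-test, uncorrected")
  }
  wide
}
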