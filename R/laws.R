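#' Reference value of Lewis' law
#'
#' Lewis' law is the empirical linear relation between a cell's neighbour
#' number n and its class-mean apical area relative to the lattice mean:
#' \deqn{\bar A_n / \bar A = (n - 2) / 4}
#' so hexagons have exactly the mean area.
#'
#' @param n Integer neighbour number(s), >= 3.
#' @return Expected relative area \eqn{\bar A_n/\bar A}.
#' @examples
#' lewis_expected(6) # 1
#' @export
lewis_expected <- function(n) {
  if (any(n < 3)) stop("Lewis' law is defined for n >= 3")
  (n - 2) / 4
}

#' Reference value of Aboav-Weaire's law
#'
#' Aboav-Weaire's law relates a cell's neighbour number n to the mean
#' neighbour number m(n) of the cells around it: few-sided cells tend to
#' sit next to many-sided ones. The default (`form = "standard"`) is the
#' classical linear form of n m(n),
#' \deqn{n\,m(n) = 5n + 8 \quad\Leftrightarrow\quad m(n) = 5 + 8/n,}
#' under which m(n) increases toward 6 for large n. An alternative
#' decreasing variant, \eqn{m(n) = 5 - n/8}, is retained as
#' `form = "literal"` for comparison; the two coincide nowhere and the
#' standard form is the one consistent with observed epithelia.
#'
#' @param n Integer neighbour number(s), >= 3.
#' @param form `"standard"` (default) or `"literal"`.
#' @return Expected mean neighbour number m(n) of the neighbours.
#' @examples
#' aboav_expected(8)                   # 6
#' aboav_expected(8, form = "literal") # 4
#' @export
aboav_expected <- function(n, form = c("standard", "literal")) {
  form <- match.arg(form)
  if (any(n < 3)) stop("Aboav-Weaire's law is defined for n >= 3")
  switch(form, standard = 5 + 8 / n, literal = 5 - n / 8)
}

#' Empirical Lewis and Aboav-Weaire tables with weighted law fits
#'
#' Compares the observed per-polygon-class statistics of a lattice with the
#' two packing laws and fits each law's linear form by least squares
#' weighted by class counts: relative area \eqn{\bar A_n/\bar A} against n
#' (Lewis; reference slope 1/4, intercept -1/2) and \eqn{n\,m(n)} against n
#' (Aboav-Weaire; reference slope 5, intercept 8 in the standard form).
#' Only polygon classes with at least `min_class_count` cells enter the
#' fits.
#'
#' @param stats A [interior_stats()] result.
#' @param form Aboav-Weaire reference form, see [aboav_expected()].
#' @param min_class_count Minimum cells per polygon class (default 5).
#' @return An object of class `law_fit`: list with tibbles `lewis`
#'   (`n`, `count`, `observed`, `expected`), `aboav` (`n`, `count`,
#'   `observed_m`, `expected_m`, `observed_nm`, `expected_nm`) and `fits`
#'   (`law`, `slope`, `intercept`, `r_squared`, `n_classes`, `n_cells`).
#' @export
empirical_law_tables <- function(stats, form = c("standard", "literal"),
                                 min_class_count = 5L) {
  stopifnot(inherits(stats, "lattice_stats"))
  form <- match.arg(form)
  # polygon classes below the triangle are segmentation artifacts
  lew <- dplyr::filter(stats$lewis_table, .data$count >= min_class_count,
                       .data$n >= 3)
  abo <- dplyr::filter(stats$aboav_table, .data$count >= min_class_count,
                       .data$n >= 3)
  if (nrow(lew) < 3L)
    stop("need at least 3 polygon classes with >= ", min_class_count,
         " cells to fit packing laws")
  lewis <- tibble::tibble(n = lew$n, count = lew$count,
                          observed = lew$mean_rel_area,
                          expected = lewis_expected(lew$n))
  aboav <- tibble::tibble(n = abo$n, count = abo$count,
                          observed_m = abo$m,
                          expected_m = aboav_expected(abo$n, form),
                          observed_nm = abo$n * abo$m,
                          expected_nm = abo$n * aboav_expected(abo$n, form))
  wfit <- function(x, y, w) {
    fit <- stats::lm(y ~ x, weights = w)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared)
  }
  fl <- wfit(lewis$n, lewis$observed, lewis$count)
  fa <- wfit(aboav$n, aboav$observed_nm, aboav$count)
  fits <- tibble::tibble(
    law = c("lewis", "aboav_weaire"),
    slope = c(fl$slope, fa$slope),
    intercept = c(fl$intercept, fa$intercept),
    r_squared = c(fl$r_squared, fa$r_squared),
    n_classes = c(nrow(lewis), nrow(aboav)),
    n_cells = c(sum(lewis$count), sum(aboav$count)))
  structure(list(lewis = lewis, aboav = aboav, fits = fits, form = form),
            class = "law_fit")
}

#' @export
print.law_fit <- function(x, ...) {
  cat("<law_fit> packing-law fits (Aboav form:", x$form, ")\n")
  print(x$fits)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted packing-law coefficients
#'
#' @param x A `law_fit` from [empirical_law_tables()].
#' @param ... Unused.
#' @return A tibble with one row per fitted law: `law`, `slope`,
#'   `intercept`, `r_squared`, alongside the law's reference coefficients.
#' @export
tidy.law_fit <- function(x, ...) {
  ref <- tibble::tibble(
    law = c("lewis", "aboav_weaire"),
    reference_slope = c(0.25, if (x$form == "standard") 5 else NA_real_),
    reference_intercept = c(-0.5, if (x$form == "standard") 8 else NA_real_))
  dplyr::left_join(x$fits, ref, by = "law")
}

#' One-line summary of a packing-law fit
#'
#' @param x A `law_fit` from [empirical_law_tables()].
#' @param ... Unused.
#' @return A one-row tibble: class counts and the two laws' r-squared.
#' @export
glance.law_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$lewis),
    n_cells = sum(x$lewis$count),
    lewis_r_squared = x$fits$r_squared[x$fits$law == "lewis"],
    aboav_r_squared = x$fits$r_squared[x$fits$law == "aboav_weaire"])
}
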