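#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a piston beam fit
#'
#' @param x A `piston_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`term`, `estimate`).
#' @method tidy piston_fit
#' @export
tidy.piston_fit <- function(x, ...) {
  tibble::tibble(
    term = c("aperture_cm", "ka", "directivity_index_db", "offset_db"),
    estimate = c(x$aperture_cm, x$ka, x$directivity_index_db, x$offset_db)
  )
}

#' Glance at a piston beam fit
#'
#' @param x A `piston_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit summary statistics.
#' @method glance piston_fit
#' @export
glance.piston_fit <- function(x, ...) {
  tibble::tibble(
    aperture_cm = x$aperture_cm,
    directivity_index_db = x$directivity_index_db,
    fit_rss_db2 = x$fit_rss_db2,
    n_samples = nrow(x$samples),
    fc_khz = x$fc_khz
  )
}

#' Tidy Monte Carlo discrimination results
#'
#' @param x A `mc_discrimination` result.
#' @param ... Unused.
#' @return The per-size summary tibble with the criterion attached as a
#'   column.
#' @method tidy mc_discrimination
#' @export
tidy.mc_discrimination <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                criterion_khz = attr(x, "criterion_khz"))
}

#' Glance at Monte Carlo discrimination results
#'
#' @param x A `mc_discrimination` result.
#' @param ... Unused.
#' @return A one-row tibble: criterion, best accuracy, replacement flag.
#' @method glance mc_discrimination
#' @export
glance.mc_discrimination <- function(x, ...) {
  tibble::tibble(
    criterion_khz = attr(x, "criterion_khz"),
    max_percent_correct = max(x$percent_correct),
    n_sizes = nrow(x),
    replacement_used = attr(x, "replacement_used")
  )
}

#' Tidy a ROC criterion
#'
#' @param x A `roc_criterion`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy roc_criterion
#' @export
tidy.roc_criterion <- function(x, ...) {
  tibble::tibble(
    criterion_khz = x$criterion_khz,
    criterion_int_khz = x$criterion_int_khz,
    accuracy = x$accuracy, direction = x$direction,
    n_a = x$n_a, n_b = x$n_b
  )
}
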