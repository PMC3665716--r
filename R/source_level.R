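#' Back-calculate apparent source levels
#'
#' Inverts the propagation law for an accepted on-axis click: each received
#' level is incremented by the transmission loss
#' `TL = 20*log10(r) + alpha*r`, with `r` the localized range from the
#' source to the on-axis hydrophone and `alpha` the absorption coefficient
#' evaluated at a single representative frequency (conventionally the mean
#' centroid frequency of the species' clicks). Because the true off-axis
#' angle of the animal is unknown the results are apparent source levels.
#'
#' The localization must pass the range/error gate: clicks localized beyond
#' `max_range_m` or with a transmission-loss rms error of `max_tl_error_db`
#' or more are refused.
#'
#' @param received One-row tibble of received-click parameters (from
#'   [click_parameters()]): must carry `rl_pp_db`, `rl_rms_db`, `rl_efd_db`.
#' @param loc A `localization_result`, or a single numeric range in m (then
#'   no gate on TL error is possible and `tl_rms_error_db` is taken as 0).
#' @param alpha_db_m Absorption coefficient, dB/m.
#' @param max_range_m Range gate, m.
#' @param max_tl_error_db TL rms-error gate, dB.
#' @param range_m Optional explicit range override (e.g. range to the
#'   on-axis hydrophone rather than to the reference).
#' @return A one-row tibble: `sl_pp_db`, `sl_rms_db`, `sl_efd_db`, `tl_db`,
#'   `range_m`.
#' @export
apparent_source_level <- function(received, loc, alpha_db_m,
                                  max_range_m = 65, max_tl_error_db = 3,
                                  range_m = NULL) {
  if (is.numeric(loc)) {
    r <- loc
    tl_err <- 0
  } else {
    stopifnot(inherits(loc, "localization_result"))
    r <- if (is.null(range_m)) loc$range_to_reference else range_m
    tl_err <- loc$tl_rms_error_db
  }
  if (r > max_range_m || !is.finite(tl_err) || tl_err >= max_tl_error_db) {
    stop(sprintf(
      "gate failure: range %.1f m / TL rms error %.2f dB outside the %g m / <%g dB acceptance gate",
      r, tl_err, max_range_m, max_tl_error_db), call. = FALSE)
  }
  tl <- transmission_loss(r, alpha_db_m)
  tibble::tibble(
    sl_pp_db = received$rl_pp_db + tl,
    sl_rms_db = received$rl_rms_db + tl,
    sl_efd_db = received$rl_efd_db + tl,
    tl_db = tl, range_m = r
  )
}
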