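# Growth-rate / doubling-time arithmetic, per-day mutation-rate
# normalisation, and the EVOLVING vs STABLE call.

#' Doubling time from passage records
#'
#' Under the exponential-growth model with a constant number of cells per
#' plate at confluence, n passages in t days give `DT = t / n` days per
#' doubling (the log-ratio formulation is base-independent and reduces to
#' this ratio; the split ratio cancels).
#'
#' @param n number of passages (>= 1).
#' @param t days of culture (> 0).
#' @return doubling time in days.
#' @export
doubling_time <- function(n, t) {
  if (!all(is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stopf("n (passages) must be a positive integer")
  if (!all(is.finite(t)) || any(t <= 0)) stopf("t (days) must be > 0")
  t / n
}

#' Growth rate from doubling time
#'
#' `GR = ln(2) / DT` per day. Full precision is returned; for reproducing
#' printed tables round with [round_half_up()] to 2 decimals.
#'
#' @param dt doubling time in days (> 0).
#' @return growth rate per day.
#' @export
growth_rate <- function(dt) {
  if (!all(is.finite(dt)) || any(dt <= 0)) stopf("DT must be > 0")
  log(2) / dt
}

#' Per-day mutation rate
#'
#' Number of gained alterations divided by the elapsed time. `elapsed_days`
#' may be supplied directly (calendar days in culture, e.g. 90 for a T0 to
#' T90 comparison) or derived as `n_doublings * DT` — the two coincide,
#' which is why the rate is expressed per calendar day. A per-doubling rate
#' (`gained / n_doublings`) is reported alongside by [evolvability_call()]
#' for transparency.
#'
#' @param gained a `variant_catalog` of gained variants, or a plain count.
#' @param elapsed_days elapsed time in days (> 0).
#' @return alterations per day.
#' @export
mutation_rate <- function(gained, elapsed_days) {
  if (!is.finite(elapsed_days) || elapsed_days <= 0)
    stopf("elapsed_days must be > 0")
  count <- if (inherits(gained, "variant_catalog")) n_variants(gained)
  else as.numeric(gained)
  count / elapsed_days
}

#' EVOLVING vs STABLE classification
#'
#' A model acquiring at least `threshold` alterations per day (default 10,
#' a closed bound) is classified EVOLVING, otherwise STABLE.
#'
#' @param rate alterations per day (>= 0).
#' @param threshold classification bound (default 10).
#' @return `"EVOLVING"` or `"STABLE"` (vectorised).
#' @export
classify_evolvability <- function(rate, threshold = 10) {
  if (any(rate < 0)) stopf("rate must be >= 0")
  ifelse(rate >= threshold, "EVOLVING", "STABLE")
}

#' Full evolvability call for one sample
#'
#' @param sample_id sample label.
#' @param gained_count,lost_count numbers of gained/lost variants.
#' @param elapsed_days elapsed calendar days.
#' @param n_doublings optional number of doublings over the interval; when
#'   given, a per-doubling rate is reported too.
#' @param threshold EVOLVING bound in alterations/day (default 10).
#' @return one-row data.frame: sample, gained, lost, rate_per_day,
#'   rate_per_doubling, label.
#' @export
evolvability_call <- function(sample_id, gained_count, lost_count,
                              elapsed_days, n_doublings = NULL,
                              threshold = 10) {
  rate <- mutation_rate(gained_count, elapsed_days)
  data.frame(sample = sample_id, gained = gained_count, lost = lost_count,
             rate_per_day = rate,
             rate_per_doubling = if (is.null(n_doublings)) NA_real_
                                 else gained_count / n_doublings,
             label = classify_evolvability(rate, threshold),
             stringsAsFactors = FALSE)
}
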