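## Boltzmann-weighted scoring of candidate structures against reference
## CCS values, and the error/discrepancy statistics used in assignment
## reports.

#' Boltzmann constant in kcal/(mol K)
#' @export
K_BOLTZMANN_KCAL <- 1.987204e-3

#' Boltzmann mole fractions from relative energies
#'
#' P_i = exp(-RE_i / kT) / sum_j exp(-RE_j / kT), with
#' k = 1.987204e-3 kcal/(mol K) and T = 298 K by default.  The input must
#' already be shifted so min(RE) = 0 (the global-minimum convention).
#'
#' @param re relative energies, kcal/mol.
#' @param temperature absolute temperature, K.
#' @return A `glyccs_boltzmann` list: `re`, `temperature`, `p` (mole
#'   fractions summing to 1), `n`.
#' @export
boltzmann_weights <- function(re, temperature = 298) {
  if (length(re) == 0) stop("empty relative-energy vector", call. = FALSE)
  stopifnot(temperature > 0, all(is.finite(re)))
  if (abs(min(re)) > 1e-9)
    stop("relative energies must be shifted so min(RE) = 0", call. = FALSE)
  w <- exp(-re / (K_BOLTZMANN_KCAL * temperature))
  structure(list(re = re, temperature = temperature, p = w / sum(w),
                 n = length(re)),
            class = "glyccs_boltzmann")
}

#' Population-weighted average CCS
#'
#' Conformers within `population_window` kcal/mol of the global minimum
#' (inclusive) have non-negligible gas-phase population; their CCS values
#' are averaged with Boltzmann weights renormalized over that subset.
#' When only the global minimum falls inside the window, its CCS is
#' returned unchanged.
#'
#' @param ccs CCS values, A^2, one per conformer.
#' @param weights a [boltzmann_weights()] object (or a numeric RE vector,
#'   which is converted at 298 K).
#' @param population_window inclusion window, kcal/mol (default 3,
#'   inclusive).
#' @return Weighted-average CCS in A^2.
#' @export
weighted_ccs <- function(ccs, weights, population_window = 3) {
  if (is.numeric(weights)) weights <- boltzmann_weights(weights)
  if (length(ccs) != weights$n)
    stop("ccs and weights have different lengths", call. = FALSE)
  inside <- weights$re <= population_window
  p <- weights$p[inside] / sum(weights$p[inside])
  sum(p * ccs[inside])
}

#' Percent CCS error against a reference
#'
#' `|calc - ref| / ref * 100`, the parenthetical error statistic of the
#' assignment tables.
#'
#' @param calc computed CCS, A^2.
#' @param ref reference CCS, A^2 (> 0).
#' @return Percent error.
#' @export
percent_error <- function(calc, ref) {
  if (any(ref <= 0)) stop("reference CCS must be positive", call. = FALSE)
  abs(calc - ref) / ref * 100
}

#' Percent difference between two CCS values
#'
#' The symmetric discrepancy statistic `|a - b| / mean(a, b) * 100`,
#' used to quantify the disagreement between stepped-field and
#' single-field CCS determinations of the same ion.
#'
#' @param ccs_a,ccs_b CCS values, A^2 (> 0).
#' @return Percent difference (symmetric in its arguments).
#' @export
percent_difference <- function(ccs_a, ccs_b) {
  if (any(ccs_a <= 0) || any(ccs_b <= 0))
    stop("CCS values must be positive", call. = FALSE)
  abs(ccs_a - ccs_b) / ((ccs_a + ccs_b) / 2) * 100
}

## half-up rounding, matching the printed style of the bundled tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assignment success rate
#'
#' Counts report rows whose policy-selected percent error is at or below
#' the threshold.  Policies: `"averaged"` compares against the mean of
#' single- and stepped-field references (the headline metric),
#' `"best_of_methods"` selects, per system, whichever of the single or
#' stepped error is smaller, `"single"` and `"stepped"` use one method
#' only.
#'
#' @param rows data frame with percent-error columns `err_avg`,
#'   `err_single`, `err_stepped` (NA where no reference exists).
#' @param threshold success threshold in percent (default 3, the margin
#'   accounting for calibration error and inter-laboratory spread).
#' @param reference_policy see above.
#' @return List: `count`, `total`, `fraction`, `errors` (the
#'   policy-selected per-row errors).
#' @export
success_rate <- function(rows, threshold = 3,
                         reference_policy = c("averaged", "best_of_methods",
                                              "single", "stepped")) {
  reference_policy <- match.arg(reference_policy)
  if (nrow(rows) == 0) stop("empty report", call. = FALSE)
  err <- switch(reference_policy,
                averaged = rows$err_avg,
                single = rows$err_single,
                stepped = rows$err_stepped,
                best_of_methods = pmin(replace(rows$err_single,
                                               is.na(rows$err_single), Inf),
                                       replace(rows$err_stepped,
                                               is.na(rows$err_stepped), Inf)))
  if (anyNA(err) || any(!is.finite(err)))
    stop("a row has no reference under policy '", reference_policy, "'",
         call. = FALSE)
  list(count = sum(err <= threshold), total = length(err),
       fraction = mean(err <= threshold), errors = err)
}

#' Isomer CCS ordering report
#'
#' Reporting utility for isomer-discrimination checks: for each expected
#' relation (e.g. "the beta anomer is larger than the alpha anomer")
#' emits the sign of Omega(a) - Omega(b) and whether it matches.  Pairs
#' whose CCS difference is within the combined Monte-Carlo standard
#' errors are reported "indistinguishable"; a missing member marks the
#' row incomparable.
#'
#' @param ccs named numeric vector of CCS values, A^2.
#' @param pairs data frame with columns `a`, `b`, `relation`
#'   (`">"` or `"<"`).
#' @param se optional named numeric vector of standard errors (A^2).
#' @return Data frame: `a`, `b`, `relation`, `delta`, `status`
#'   (`"pass"`, `"fail"`, `"indistinguishable"`, `"incomparable"`).
#' @export
isomer_ordering <- function(ccs, pairs, se = NULL) {
  out <- pairs
  out$delta <- NA_real_
  out$status <- "incomparable"
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    if (!a %in% names(ccs) || !b %in% names(ccs) ||
        is.na(ccs[a]) || is.na(ccs[b])) next
    d <- unname(ccs[a] - ccs[b])
    out$delta[r] <- d
    tol <- 0
    if (!is.null(se))
      tol <- sqrt(sum(c(se[a], se[b])^2, na.rm = TRUE))
    if (abs(d) <= tol) {
      out$status[r] <- "indistinguishable"
    } else {
      want_larger <- pairs$relation[r] == ">"
      out$status[r] <- if ((d > 0) == want_larger) "pass" else "fail"
    }
  }
  out
}
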