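# Threshold searches: the drug price, or the relative risk of disability
# progression, at which a candidate sequence's net health benefit equals a
# reference sequence's NHB. Parity is defined under common random numbers
# (same cohort size and seed as the reference run), otherwise Monte-Carlo
# noise swamps the search. NHB is exactly affine in price (price enters
# only the linear cost accrual, trajectories are unchanged) and
# non-increasing in the relative risk.

default_threshold_sequence <- function(candidate_name, anchor_line) {
  switch(anchor_line,
         "1a" = sequence_spec(c(candidate_name, "CLA", "NAT", "ALE")),
         "2" = sequence_spec(c("INFB", candidate_name, "CLA", "ALE"),
                             line1b = "GLA"),
         stop("no default sequence template for anchor line ", anchor_line))
}

bisect_nhb <- function(f, lower, upper, tol, max_iter = 60L,
                       decreasing = TRUE) {
  f_lo <- f(lower); f_hi <- f(upper)
  trace <- data.frame(trial = c(lower, upper), nhb_diff = c(f_lo, f_hi))
  # f = candidate NHB - reference NHB, decreasing in the trial variable
  if (sign(f_lo) == sign(f_hi) && abs(f_lo) > tol && abs(f_hi) > tol)
    stop(sprintf(paste0("no NHB parity inside the bracket [%g, %g]: ",
                        "differences %.4f and %.4f have the same sign"),
                 lower, upper, f_lo, f_hi), call. = FALSE)
  lo <- lower; hi <- upper
  mid <- (lo + hi) / 2; f_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    trace <- rbind(trace, data.frame(trial = mid, nhb_diff = f_mid))
    if (abs(f_mid) <= tol) break
    pos_side_low <- if (decreasing) f_mid > 0 else f_mid < 0
    if (pos_side_low) lo <- mid else hi <- mid
  }
  list(value = mid, f_value = f_mid, trace = trace)
}

threshold_result <- function(variable, value, rounded, reference_nhb,
                             candidate_nhb, summary, trace, tol) {
  structure(list(variable = variable, threshold_value = value,
                 threshold_rounded = rounded,
                 reference_nhb = reference_nhb,
                 candidate_nhb_at_threshold = candidate_nhb,
                 candidate_summary = summary, search_trace = trace,
                 tol = tol),
            class = "dmtseq_threshold")
}

#' Solve for the cost-neutral annual drug price of a candidate
#'
#' Finds the annual acquisition price at which a sequence carrying the
#' candidate drug has the same net health benefit as a reference sequence,
#' by bisection over the price bracket. The candidate's first-year /
#' subsequent-year cost ratio is preserved when it has a known cost
#' schedule (`price_mode = "proportional"`, the trial price setting the
#' subsequent-year cost); with `"flat"` (the default for a drug without a
#' known schedule) the trial price applies to both. The threshold is also
#' reported rounded to the nearest 100 Euros.
#'
#' @param candidate A [dmt_definition()] with fully specified efficacy.
#' @param anchor_line `"1a"` or `"2"`: the line the candidate occupies.
#' @param reference_nhb NHB of the reference sequence, computed with the
#'   same `cohort_n` and `seed`.
#' @param params A [model_parameters()] object.
#' @param tol NHB parity tolerance in QALY units.
#' @param seed,cohort_n Common-random-number settings, shared with the
#'   reference run.
#' @param sequence Optional explicit [sequence_spec()] containing the
#'   candidate; defaults to the standard first-/second-line template.
#' @param price_bracket Search bracket in Euros.
#' @param price_mode `"proportional"` or `"flat"` (see above).
#' @return A `dmtseq_threshold` with the solved price, the search trace
#'   and the candidate's full cohort summary at the threshold.
#' @export
find_threshold_price <- function(candidate, anchor_line, reference_nhb,
                                 params, tol = 0.005, seed = 1L,
                                 cohort_n = params$cohort$n_patients,
                                 sequence = NULL,
                                 price_bracket = c(0, 2 * 22437),
                                 price_mode = NULL) {
  stopifnot(inherits(candidate, "dmt_definition"))
  if (is_unknown_efficacy(candidate$efficacy_cdp))
    stop("candidate efficacy must be fully specified; use find_threshold_rr ",
         "for a drug with unknown progression efficacy")
  if (is.null(price_mode)) {
    price_mode <- if (!is.na(candidate$annual_cost_first_year) &&
                      !is.na(candidate$annual_cost_subsequent) &&
                      candidate$annual_cost_subsequent > 0)
      "proportional" else "flat"
  }
  ratio <- if (price_mode == "proportional")
    candidate$annual_cost_first_year / candidate$annual_cost_subsequent else 1
  params$dmts[[candidate$name]] <- candidate
  if (is.null(sequence))
    sequence <- default_threshold_sequence(candidate$name, anchor_line)

  at_price <- function(p) {
    pk <- set_dmt_cost(params, candidate$name, first = p * ratio,
                       subsequent = p)
    simulate_cohort(sequence, pk, n = cohort_n, seed = seed)
  }
  sol <- bisect_nhb(function(p) at_price(p)$nhb - reference_nhb,
                    price_bracket[1], price_bracket[2], tol)
  summary <- at_price(sol$value)
  threshold_result("annual_price", sol$value, 100 * round(sol$value / 100),
                   reference_nhb, summary$nhb, summary, sol$trace, tol)
}

#' Solve for the efficacy-parity relative risk of a candidate
#'
#' For a drug whose effect on confirmed disability progression is unknown
#' but whose price is known (off-label rituximab), finds the relative risk
#' of 24-week confirmed disability progression versus placebo at which a
#' sequence carrying the drug matches a reference sequence's net health
#' benefit. Bisection over the RR bracket under common random numbers; the
#' threshold is also reported to two decimals.
#'
#' @param candidate A [dmt_definition()]; typically `efficacy_cdp` is the
#'   unknown sentinel and costs are known.
#' @param anchor_line `"1a"` or `"2"`.
#' @param reference_nhb NHB of the reference sequence (same `cohort_n`,
#'   same `seed`).
#' @param params A [model_parameters()] object.
#' @param tol NHB parity tolerance in QALY units.
#' @param seed,cohort_n Common-random-number settings.
#' @param sequence Optional explicit [sequence_spec()].
#' @param rr_bracket Search bracket for the relative risk.
#' @return A `dmtseq_threshold`.
#' @export
find_threshold_rr <- function(candidate, anchor_line, reference_nhb,
                              params, tol = 0.005, seed = 1L,
                              cohort_n = params$cohort$n_patients,
                              sequence = NULL,
                              rr_bracket = c(0.2, 1.2)) {
  stopifnot(inherits(candidate, "dmt_definition"))
  if (is.na(candidate$annual_cost_first_year))
    stop("candidate must have known costs to solve for its relative risk")
  params$dmts[[candidate$name]] <- candidate
  if (is.null(sequence))
    sequence <- default_threshold_sequence(candidate$name, anchor_line)

  at_rr <- function(rr) {
    pk <- set_dmt_rr(params, candidate$name, rr)
    simulate_cohort(sequence, pk, n = cohort_n, seed = seed)
  }
  sol <- bisect_nhb(function(rr) at_rr(rr)$nhb - reference_nhb,
                    rr_bracket[1], rr_bracket[2], tol)
  summary <- at_rr(sol$value)
  threshold_result("rr_cdp", sol$value, round(sol$value, 2),
                   reference_nhb, summary$nhb, summary, sol$trace, tol)
}

#' @export
print.dmtseq_threshold <- function(x, ...) {
  cat("Threshold analysis:",
      if (x$variable == "annual_price") "cost-neutral annual drug price"
      else "efficacy-parity relative risk of disability progression", "\n")
  if (x$variable == "annual_price") {
    cat(sprintf("  threshold: %.0f EUR/year (reported: %s EUR/year)\n",
                x$threshold_value,
                format(x$threshold_rounded, big.mark = ",")))
  } else {
    cat(sprintf("  threshold: %.4f (reported: %.2f)\n",
                x$threshold_value, x$threshold_rounded))
  }
  cat(sprintf("  reference NHB %.4f; candidate NHB at threshold %.4f (tol %.3f)\n",
              x$reference_nhb, x$candidate_nhb_at_threshold, x$tol))
  s <- x$candidate_summary
  cat(sprintf("  at threshold: %s lifetime drug costs, %s total costs, %.1f QALYs\n",
              format(round(s$costs$drug), big.mark = ","),
              format(round(s$costs$total), big.mark = ","), s$qalys))
  cat(sprintf("  search trace: %d evaluations\n", nrow(x$search_trace)))
  invisible(x)
}
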