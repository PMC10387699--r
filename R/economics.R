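# Cost and utility accrual, discounting, net health benefit.

#' Annual drug acquisition cost
#'
#' First-year price applies during the first year on the drug, the
#' subsequent-years price afterwards.
#'
#' @param dmt A [dmt_definition()].
#' @param years_on_dmt Completed years on the drug at the start of the cycle.
#' @return Euros per year.
#' @export
annual_drug_cost <- function(dmt, years_on_dmt) {
  if (any(years_on_dmt < 0)) stop("years_on_dmt must be >= 0")
  ifelse(years_on_dmt < 1, dmt$annual_cost_first_year,
         dmt$annual_cost_subsequent)
}

#' Accrue one cycle's undiscounted costs and utility
#'
#' Cycle cost = drug acquisition (zero off treatment) + administration and
#' monitoring + state healthcare cost + relapse cost per event + state
#' societal cost. Cycle QALY = state utility minus the relapse disutility
#' per event; large relapse decrements may push a cycle's QALY below zero
#' (utility decrements are additive, no flooring).
#'
#' @param state A [patient_state()] (the state occupied during the cycle).
#' @param outcome A `cycle_outcome` from [draw_cycle_outcome()].
#' @param dmt A [dmt_definition()] or `NULL` when off treatment.
#' @param econ An [economic_params()] object.
#' @param edss_levels EDSS state vector used to index the per-state tables
#'   (defaults to `0:9`).
#' @return List with `costs` (a `cost_breakdown`: drug, other_healthcare,
#'   societal, total) and `qaly`.
#' @export
accrue_cycle <- function(state, outcome, dmt, econ, edss_levels = 0:9) {
  i <- match(state$edss, edss_levels)
  drug <- if (is.null(dmt)) 0 else annual_drug_cost(dmt, state$years_on_current_dmt)
  ohc <- (if (is.null(dmt)) 0 else dmt$admin_cost + dmt$monitoring_cost) +
    econ$state_cost_healthcare_by_edss[i] +
    econ$relapse_cost * outcome$n_relapses
  soc <- econ$state_cost_societal_by_edss[i]
  qaly <- econ$utility_by_edss[i] - econ$relapse_disutility * outcome$n_relapses
  list(costs = cost_breakdown(drug, ohc, soc), qaly = qaly)
}

#' Cost breakdown
#'
#' @param drug,other_healthcare,societal Euro amounts; `total` is their sum.
#' @return An object of class `cost_breakdown`.
#' @export
cost_breakdown <- function(drug, other_healthcare, societal) {
  structure(list(drug = drug, other_healthcare = other_healthcare,
                 societal = societal,
                 total = drug + other_healthcare + societal),
            class = "cost_breakdown")
}

#' Discount a value to present value
#'
#' `value / (1 + rate)^cycle_index`; cycle 0 is undiscounted.
#'
#' @param value Amount (Euros or QALYs).
#' @param rate Annual discount rate (fraction, >= 0).
#' @param cycle_index Whole cycles since baseline (>= 0).
#' @return Discounted amount.
#' @export
discount <- function(value, rate, cycle_index) {
  if (any(rate < 0)) stop("discount rate must be >= 0")
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  value / (1 + rate)^cycle_index
}

#' Net health benefit
#'
#' `NHB = QALYs - costs / wtp`: the QALYs gained minus the QALYs the money
#' could have bought elsewhere at the willingness-to-pay threshold.
#'
#' @param qalys Discounted QALYs.
#' @param total_costs Discounted total costs (Euros).
#' @param wtp Willingness-to-pay per QALY (Euros, > 0).
#' @return NHB in QALY units.
#' @export
compute_nhb <- function(qalys, total_costs, wtp) {
  if (any(wtp <= 0)) stop("wtp must be > 0")
  qalys - total_costs / wtp
}

#' Combine cohort results by drug
#'
#' Unweighted arithmetic mean over sequences, field by field — each
#' sequence is assumed equally likely to be used in practice, so second-line
#' columns combine all sequences carrying a given drug divided by the
#' number of sequences.
#'
#' @param results Non-empty list of `dmtseq_cohort` results.
#' @param label Label for the combined column.
#' @return A `dmtseq_cohort` of field means.
#' @export
combine_by_dmt <- function(results, label = "combined") {
  if (length(results) == 0) stop("results must be a non-empty list")
  stopifnot(all(vapply(results, inherits, TRUE, "dmtseq_cohort")))
  m <- function(f) mean(vapply(results, function(r) r[[f]], 0), na.rm = TRUE)
  mc <- function(f) mean(vapply(results, function(r) r$costs[[f]], 0))
  structure(list(
    label = label,
    n = sum(vapply(results, function(r) as.numeric(r$n), 0)),
    seed = results[[1]]$seed,
    costs = list(drug = mc("drug"), other_healthcare = mc("other_healthcare"),
                 societal = mc("societal"), total = mc("total")),
    qalys = m("qalys"),
    nhb = m("nhb"),
    lifetime_relapses = m("lifetime_relapses"),
    time_to_edss6 = m("time_to_edss6"),
    fraction_reaching_edss6 = m("fraction_reaching_edss6"),
    time_in_line1 = m("time_in_line1"),
    life_years = m("life_years"),
    wtp = results[[1]]$wtp
  ), class = "dmtseq_cohort")
}
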