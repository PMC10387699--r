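# Model parameter types, defaults, validation and file I/O.

#' Efficacy estimate for a disease-modifying treatment
#'
#' A treatment-effect ratio with its 95% confidence interval. `measure`
#' states which hazard the ratio scales: `"IRR_ARR"` (incidence rate ratio
#' of the annualized relapse rate vs. placebo) or `"RR_CDP"` (relative risk
#' of 24-week confirmed disability progression vs. placebo).
#'
#' @param point Point estimate (ratio, > 0).
#' @param ci_low,ci_high 95% confidence limits, `0 < ci_low <= point <= ci_high`.
#' @param measure `"IRR_ARR"` or `"RR_CDP"`.
#' @return An object of class `efficacy_estimate`.
#' @export
efficacy_estimate <- function(point, ci_low = point, ci_high = point,
                              measure = c("IRR_ARR", "RR_CDP")) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(point), length(point) == 1L)
  if (!(ci_low > 0 && ci_low <= point && point <= ci_high))
    stop("efficacy_estimate: need 0 < ci_low <= point <= ci_high")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 measure = measure, unknown = FALSE),
            class = "efficacy_estimate")
}

#' Sentinel for an unknown efficacy estimate
#'
#' Used where a treatment effect has not been measured (the relative risk of
#' disability progression for rituximab). Deterministic simulation refuses to
#' run a sequence containing a drug with unknown efficacy unless the
#' threshold-analysis machinery supplies a trial value.
#'
#' @param measure Which measure is unknown.
#' @return An `efficacy_estimate` with `unknown = TRUE`.
#' @export
efficacy_unknown <- function(measure = c("RR_CDP", "IRR_ARR")) {
  measure <- match.arg(measure)
  structure(list(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 measure = measure, unknown = TRUE),
            class = "efficacy_estimate")
}

#' Test whether an efficacy estimate is the unknown sentinel
#' @param x An `efficacy_estimate`.
#' @return Logical.
#' @export
is_unknown_efficacy <- function(x) {
  inherits(x, "efficacy_estimate") && isTRUE(x$unknown)
}

LINE_LABELS <- c("1a", "1b", "2", "3", "4")

#' Define a disease-modifying treatment
#'
#' @param name Short identifier, e.g. `"OCR"`.
#' @param moa_class Mode-of-action class (e.g. `"anti-CD20"`,
#'   `"S1PR-modulator"`, `"interferon"`). Consecutive drugs in a sequence
#'   may not share a class when the grammar forbids it.
#' @param eligible_lines Character subset of `c("1a","1b","2","3","4")`.
#' @param efficacy_arr [efficacy_estimate()] with measure `"IRR_ARR"`.
#' @param efficacy_cdp [efficacy_estimate()] with measure `"RR_CDP"`, or
#'   [efficacy_unknown()].
#' @param annual_cost_first_year,annual_cost_subsequent Annual drug
#'   acquisition cost in Euros (list price); `NA` when not yet known.
#' @param admin_cost,monitoring_cost Annual administration and monitoring
#'   cost in Euros while on the drug.
#' @param ae_discontinuation_prob Annual probability of leaving the drug for
#'   adverse events.
#' @param synthetic Flag marking filler values that are not published list
#'   prices or trial estimates.
#' @return An object of class `dmt_definition`.
#' @export
dmt_definition <- function(name, moa_class, eligible_lines,
                           efficacy_arr, efficacy_cdp,
                           annual_cost_first_year, annual_cost_subsequent,
                           admin_cost = 0, monitoring_cost = 0,
                           ae_discontinuation_prob = 0,
                           synthetic = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            all(eligible_lines %in% LINE_LABELS),
            inherits(efficacy_arr, "efficacy_estimate"),
            inherits(efficacy_cdp, "efficacy_estimate"))
  if (efficacy_arr$measure != "IRR_ARR") stop("efficacy_arr must have measure IRR_ARR")
  if (efficacy_cdp$measure != "RR_CDP") stop("efficacy_cdp must have measure RR_CDP")
  structure(list(
    name = name, moa_class = moa_class,
    eligible_lines = as.character(eligible_lines),
    efficacy_arr = efficacy_arr, efficacy_cdp = efficacy_cdp,
    annual_cost_first_year = annual_cost_first_year,
    annual_cost_subsequent = annual_cost_subsequent,
    admin_cost = admin_cost, monitoring_cost = monitoring_cost,
    ae_discontinuation_prob = ae_discontinuation_prob,
    synthetic = isTRUE(synthetic)
  ), class = "dmt_definition")
}

#' Natural-history parameters
#'
#' Annual disease dynamics off treatment: EDSS transition probabilities,
#' relapse rates per state, per-state mortality multipliers and a background
#' life table. Death is handled outside the transition matrix, as a separate
#' absorbing flag scaled by the life table, so each matrix row is a
#' probability distribution over disease states only.
#'
#' @param edss_levels Integer vector of ordered EDSS states, usually `0:9`.
#' @param transition_matrix Row-stochastic annual matrix, rows = from-state,
#'   columns = to-state, in `edss_levels` order.
#' @param relapse_rate_by_edss Relapses per patient-year in each state.
#' @param mortality_multiplier_by_edss Hazard ratio (>= 1) applied to the
#'   life-table hazard in each state.
#' @param life_table `data.frame(age, hazard)` with annual all-cause
#'   mortality hazards by integer age.
#' @return An object of class `natural_history_params`.
#' @export
natural_history_params <- function(edss_levels, transition_matrix,
                                   relapse_rate_by_edss,
                                   mortality_multiplier_by_edss,
                                   life_table) {
  transition_matrix <- as.matrix(transition_matrix)
  structure(list(
    edss_levels = as.integer(edss_levels),
    transition_matrix = unname(transition_matrix),
    relapse_rate_by_edss = as.numeric(relapse_rate_by_edss),
    mortality_multiplier_by_edss = as.numeric(mortality_multiplier_by_edss),
    life_table = data.frame(age = as.integer(life_table$age),
                            hazard = as.numeric(life_table$hazard))
  ), class = "natural_history_params")
}

#' Economic parameters
#'
#' @param utility_by_edss Utility weight (<= 1) per EDSS state, non-increasing.
#' @param relapse_disutility QALY decrement per relapse event.
#' @param state_cost_healthcare_by_edss,state_cost_societal_by_edss Annual
#'   Euro costs per state, non-decreasing in EDSS.
#' @param relapse_cost One-off Euro cost per relapse event.
#' @param wtp Willingness-to-pay per QALY in Euros (the monetary value of a
#'   QALY; 50,000 in the Dutch MS setting).
#' @param discount_rate_costs,discount_rate_effects Annual discount rates
#'   (Dutch guideline: 4% for costs, 1.5% for effects).
#' @return An object of class `economic_params`.
#' @export
economic_params <- function(utility_by_edss, relapse_disutility,
                            state_cost_healthcare_by_edss,
                            state_cost_societal_by_edss,
                            relapse_cost, wtp = 50000,
                            discount_rate_costs = 0.04,
                            discount_rate_effects = 0.015) {
  structure(list(
    utility_by_edss = as.numeric(utility_by_edss),
    relapse_disutility = relapse_disutility,
    state_cost_healthcare_by_edss = as.numeric(state_cost_healthcare_by_edss),
    state_cost_societal_by_edss = as.numeric(state_cost_societal_by_edss),
    relapse_cost = relapse_cost, wtp = wtp,
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects
  ), class = "economic_params")
}

#' Clinical sequence-grammar rules
#'
#' Encodes which DMT sequences are clinically plausible: line eligibility,
#' the ban on consecutive same-mode-of-action switches, last-resort drugs
#' restricted to the final line, and whether the adverse-event branch
#' (line 1b) exists. When a high-efficacy drug opens the sequence, line 1b
#' is dropped.
#'
#' @param first_line_escalation_set,first_line_highefficacy_set DMT names
#'   allowed to open an escalation or high-efficacy-first sequence.
#' @param forbid_same_moa_consecutive Logical.
#' @param last_resort_only DMT names allowed only in the final line.
#' @param max_lines Maximum number of treatment lines including 1b (5 gives
#'   lines 1a, 1b, 2, 3, 4).
#' @param line1b_enabled Logical; ignored (forced off) for sequences opened
#'   by a high-efficacy drug.
#' @return An object of class `grammar_rules`.
#' @export
grammar_rules <- function(first_line_escalation_set = character(),
                          first_line_highefficacy_set = character(),
                          forbid_same_moa_consecutive = TRUE,
                          last_resort_only = character(),
                          max_lines = 5,
                          line1b_enabled = TRUE) {
  structure(list(
    first_line_escalation_set = as.character(first_line_escalation_set),
    first_line_highefficacy_set = as.character(first_line_highefficacy_set),
    forbid_same_moa_consecutive = isTRUE(forbid_same_moa_consecutive),
    last_resort_only = as.character(last_resort_only),
    max_lines = as.integer(max_lines),
    line1b_enabled = isTRUE(line1b_enabled)
  ), class = "grammar_rules")
}

#' Full model input
#'
#' Bundles the DMT set, natural history, economics, grammar and cohort
#' settings. Cohort defaults follow the study design: 10,000 treatment-naive
#' patients per sequence, starting age 29, baseline EDSS evenly distributed
#' over states 0 to 3.
#'
#' @param dmts Named list of [dmt_definition()] objects.
#' @param natural_history A [natural_history_params()] object.
#' @param economics An [economic_params()] object.
#' @param grammar A [grammar_rules()] object.
#' @param cohort List with `n_patients`, `start_age`, `baseline_edss_range`.
#' @param psa Optional list of PSA coefficients of variation
#'   (`cv_utility`, `cv_state_cost`, `cv_relapse_rate`).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(dmts, natural_history, economics, grammar,
                             cohort = list(n_patients = 10000L,
                                           start_age = 29L,
                                           baseline_edss_range = c(0L, 3L)),
                             psa = list(cv_utility = 0.05,
                                        cv_state_cost = 0.15,
                                        cv_relapse_rate = 0.15)) {
  if (is.null(names(dmts)) || any(names(dmts) == ""))
    names(dmts) <- vapply(dmts, `[[`, "", "name")
  structure(list(dmts = dmts, natural_history = natural_history,
                 economics = economics, grammar = grammar,
                 cohort = cohort, psa = psa),
            class = "model_parameters")
}

#' Retrieve a DMT definition by name
#' @param params A [model_parameters()] object.
#' @param name DMT name.
#' @return The `dmt_definition`.
#' @export
get_dmt <- function(params, name) {
  d <- params$dmts[[name]]
  if (is.null(d)) stop("unknown DMT name: ", name)
  d
}

#' Replace a DMT's annual drug cost
#' @param params A [model_parameters()] object.
#' @param name DMT name.
#' @param first,subsequent New first-year and subsequent-year costs (Euros).
#' @return Modified `model_parameters`.
#' @export
set_dmt_cost <- function(params, name, first, subsequent = first) {
  d <- get_dmt(params, name)
  d$annual_cost_first_year <- first
  d$annual_cost_subsequent <- subsequent
  params$dmts[[name]] <- d
  params
}

#' Supply a trial relative risk of disability progression for a DMT
#'
#' Replaces (or fills in, for a drug with unknown progression efficacy) the
#' relative risk of 24-week confirmed disability progression with a
#' degenerate estimate at `rr`. Used by the threshold search.
#'
#' @param params A [model_parameters()] object.
#' @param name DMT name.
#' @param rr Trial relative risk (> 0).
#' @return Modified `model_parameters`.
#' @export
set_dmt_rr <- function(params, name, rr) {
  d <- get_dmt(params, name)
  d$efficacy_cdp <- efficacy_estimate(rr, rr, rr, measure = "RR_CDP")
  params$dmts[[name]] <- d
  params
}

#' Anti-CD20 efficacy and Dutch cost defaults
#'
#' The network-meta-analysis efficacy estimates and 2022 Dutch list prices
#' for the four anti-CD20 monoclonal antibodies, as consumed by the model:
#' ocrelizumab (OCR), ofatumumab (OFA), ublituximab (UBL, list price not yet
#' known) and rituximab (RIT, off-label; its effect on disability
#' progression is treated as unknown). Administration/monitoring costs and
#' adverse-event rates are not part of these published inputs and default
#' to zero here; the synthetic generator supplies plausible values.
#'
#' @return Named list of four [dmt_definition()] objects.
#' @export
table1_defaults <- function() {
  cd20_lines <- c("1a", "2", "3", "4")
  list(
    OCR = dmt_definition("OCR", "anti-CD20", cd20_lines,
      efficacy_arr = efficacy_estimate(0.40, 0.30, 0.52, "IRR_ARR"),
      efficacy_cdp = efficacy_estimate(0.45, 0.31, 0.61, "RR_CDP"),
      annual_cost_first_year = 22437, annual_cost_subsequent = 22437),
    OFA = dmt_definition("OFA", "anti-CD20", cd20_lines,
      efficacy_arr = efficacy_estimate(0.30, 0.22, 0.42, "IRR_ARR"),
      efficacy_cdp = efficacy_estimate(0.55, 0.34, 0.88, "RR_CDP"),
      annual_cost_first_year = 23434, annual_cost_subsequent = 20086),
    UBL = dmt_definition("UBL", "anti-CD20", cd20_lines,
      efficacy_arr = efficacy_estimate(0.31, 0.21, 0.45, "IRR_ARR"),
      efficacy_cdp = efficacy_estimate(0.54, 0.27, 1.08, "RR_CDP"),
      annual_cost_first_year = NA_real_, annual_cost_subsequent = NA_real_),
    RIT = dmt_definition("RIT", "anti-CD20", cd20_lines,
      efficacy_arr = efficacy_estimate(0.36, 0.20, 0.64, "IRR_ARR"),
      efficacy_cdp = efficacy_unknown("RR_CDP"),
      annual_cost_first_year = 3802, annual_cost_subsequent = 2535)
  )
}

# ---- validation ------------------------------------------------------------

violation <- function(type, field, rule) {
  data.frame(type = type, field = field, rule = rule,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(type = character(), field = character(), rule = character(),
             stringsAsFactors = FALSE)
}

#' Validate model parameters
#'
#' Checks every type invariant and returns a data frame of violations, one
#' row per breach, naming the parameter type, field and rule. Reports,
#' never throws; an empty data frame means the parameters are valid.
#'
#' @param params A [model_parameters()] object.
#' @return `data.frame(type, field, rule)`; zero rows when valid.
#' @export
validate_parameters <- function(params) {
  v <- no_violations()
  add <- function(type, field, rule) {
    v <<- rbind(v, violation(type, field, rule))
  }

  for (d in params$dmts) {
    pre <- paste0("dmts[", d$name, "]")
    for (f in c("annual_cost_first_year", "annual_cost_subsequent",
                "admin_cost", "monitoring_cost")) {
      x <- d[[f]]
      if (!is.na(x) && x < 0)
        add("DMTDefinition", paste0(pre, ".", f), "cost must be >= 0")
    }
    p <- d$ae_discontinuation_prob
    if (is.na(p) || p < 0 || p > 1)
      add("DMTDefinition", paste0(pre, ".ae_discontinuation_prob"),
          "probability must lie in [0, 1]")
    for (f in c("efficacy_arr", "efficacy_cdp")) {
      e <- d[[f]]
      if (is_unknown_efficacy(e)) next
      if (!(e$ci_low > 0 && e$ci_low <= e$point && e$point <= e$ci_high))
        add("EfficacyEstimate", paste0(pre, ".", f),
            "need 0 < ci_low <= point <= ci_high")
    }
    if (is_unknown_efficacy(d$efficacy_arr))
      add("DMTDefinition", paste0(pre, ".efficacy_arr"),
          "relapse efficacy may not be unknown")
  }

  nh <- params$natural_history
  K <- length(nh$edss_levels)
  tm <- nh$transition_matrix
  if (!is.matrix(tm) || nrow(tm) != K || ncol(tm) != K) {
    add("NaturalHistoryParams", "transition_matrix",
        sprintf("must be a %dx%d matrix over the EDSS states", K, K))
  } else {
    rs <- rowSums(tm)
    bad <- which(abs(rs - 1) > 1e-9)
    for (i in bad)
      add("NaturalHistoryParams",
          sprintf("transition_matrix[row %d (EDSS %d)]", i, nh$edss_levels[i]),
          sprintf("row must sum to 1 (sums to %.6f)", rs[i]))
    if (any(tm < 0))
      add("NaturalHistoryParams", "transition_matrix",
          "probabilities must be >= 0")
  }
  if (length(nh$relapse_rate_by_edss) != K)
    add("NaturalHistoryParams", "relapse_rate_by_edss",
        "must have one rate per EDSS state")
  if (any(nh$relapse_rate_by_edss < 0))
    add("NaturalHistoryParams", "relapse_rate_by_edss", "rates must be >= 0")
  if (length(nh$mortality_multiplier_by_edss) != K)
    add("NaturalHistoryParams", "mortality_multiplier_by_edss",
        "must have one multiplier per EDSS state")
  if (any(nh$mortality_multiplier_by_edss < 1))
    add("NaturalHistoryParams", "mortality_multiplier_by_edss",
        "multipliers must be >= 1")
  lt <- nh$life_table
  if (any(lt$hazard <= 0))
    add("NaturalHistoryParams", "life_table.hazard", "hazards must be > 0")
  over40 <- lt$hazard[lt$age >= 40]
  if (length(over40) > 1 && any(diff(over40) < 0))
    add("NaturalHistoryParams", "life_table.hazard",
        "hazards must be non-decreasing above age 40")

  ec <- params$economics
  if (length(ec$utility_by_edss) != K)
    add("EconomicParams", "utility_by_edss", "must have one utility per EDSS state")
  if (any(ec$utility_by_edss > 1))
    add("EconomicParams", "utility_by_edss", "utilities must be <= 1")
  if (any(diff(ec$utility_by_edss) > 0))
    add("EconomicParams", "utility_by_edss",
        "utilities must be non-increasing in EDSS")
  for (f in c("state_cost_healthcare_by_edss", "state_cost_societal_by_edss")) {
    x <- ec[[f]]
    if (any(x < 0)) add("EconomicParams", f, "costs must be >= 0")
    if (any(diff(x) < 0))
      add("EconomicParams", f, "costs must be non-decreasing in EDSS")
  }
  if (!is.numeric(ec$wtp) || ec$wtp <= 0)
    add("EconomicParams", "wtp", "willingness-to-pay must be > 0")
  if (ec$relapse_disutility < 0)
    add("EconomicParams", "relapse_disutility", "must be >= 0")
  if (ec$relapse_cost < 0)
    add("EconomicParams", "relapse_cost", "must be >= 0")
  for (f in c("discount_rate_costs", "discount_rate_effects"))
    if (ec[[f]] < 0) add("EconomicParams", f, "discount rate must be >= 0")

  ch <- params$cohort
  if (is.null(ch$n_patients) || ch$n_patients < 4)
    add("ModelParameters", "cohort.n_patients", "must be >= 4")
  if (is.null(ch$start_age) || ch$start_age < 0 || ch$start_age >= 100)
    add("ModelParameters", "cohort.start_age", "must lie in [0, 100)")
  br <- ch$baseline_edss_range
  if (length(br) != 2 || br[1] > br[2] ||
      !all(br %in% params$natural_history$edss_levels))
    add("ModelParameters", "cohort.baseline_edss_range",
        "must be an interval of configured EDSS states")

  gr <- params$grammar
  known <- names(params$dmts)
  for (f in c("first_line_escalation_set", "first_line_highefficacy_set",
              "last_resort_only")) {
    missing <- setdiff(gr[[f]], known)
    if (length(missing))
      add("GrammarRules", f,
          paste0("unknown DMT name(s): ", paste(missing, collapse = ", ")))
  }
  v
}

# ---- serialization ---------------------------------------------------------

eff_to_list <- function(e) {
  if (is_unknown_efficacy(e)) return(list(measure = e$measure, unknown = TRUE))
  list(point = e$point, ci_low = e$ci_low, ci_high = e$ci_high,
       measure = e$measure)
}

eff_from_list <- function(x, where) {
  allowed <- c("point", "ci_low", "ci_high", "measure", "unknown")
  check_keys(x, allowed, where)
  if (isTRUE(x$unknown)) return(efficacy_unknown(x$measure))
  efficacy_estimate(x$point, x$ci_low, x$ci_high, x$measure)
}

check_keys <- function(x, allowed, where, required = character()) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("parameter file: unknown key(s) in %s: %s",
                 where, paste(extra, collapse = ", ")), call. = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("parameter file: missing required field '%s' in %s",
                 miss[1], where), call. = FALSE)
  invisible(TRUE)
}

#' Write model parameters to a structured-text file
#'
#' Serializes a full [model_parameters()] object to a YAML document with
#' sections `dmts`, `natural_history`, `economics`, `grammar`, `cohort`,
#' `psa`. The transition matrix can be written inline (default) or to a
#' delimited sidecar table (rows = from-EDSS, columns = to-EDSS).
#'
#' @param params A [model_parameters()] object.
#' @param path Output file.
#' @param transition_file Optional sidecar CSV path for the transition
#'   matrix; referenced from the YAML file by name.
#' @param dialect `"point"` or `"comma"` decimal separator for the sidecar.
#' @return `path`, invisibly.
#' @export
write_model_parameters <- function(params, path, transition_file = NULL,
                                   dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  nh <- params$natural_history
  nh_out <- list(
    edss_levels = nh$edss_levels,
    relapse_rate_by_edss = nh$relapse_rate_by_edss,
    mortality_multiplier_by_edss = nh$mortality_multiplier_by_edss,
    life_table = list(age = nh$life_table$age, hazard = nh$life_table$hazard)
  )
  if (is.null(transition_file)) {
    nh_out$transition_matrix <- lapply(seq_len(nrow(nh$transition_matrix)),
                                       function(i) nh$transition_matrix[i, ])
  } else {
    m <- nh$transition_matrix
    dimnames(m) <- list(nh$edss_levels, nh$edss_levels)
    utils::write.table(m, file = transition_file,
                       sep = if (dialect == "comma") ";" else ",",
                       dec = if (dialect == "comma") "," else ".",
                       col.names = NA, quote = FALSE)
    nh_out$transition_file <- basename(transition_file)
  }
  doc <- list(
    dmts = lapply(unname(params$dmts), function(d) list(
      name = d$name, moa_class = d$moa_class,
      eligible_lines = d$eligible_lines,
      efficacy_arr = eff_to_list(d$efficacy_arr),
      efficacy_cdp = eff_to_list(d$efficacy_cdp),
      annual_cost_first_year = d$annual_cost_first_year,
      annual_cost_subsequent = d$annual_cost_subsequent,
      admin_cost = d$admin_cost, monitoring_cost = d$monitoring_cost,
      ae_discontinuation_prob = d$ae_discontinuation_prob,
      synthetic = d$synthetic)),
    natural_history = nh_out,
    economics = unclass(params$economics),
    grammar = unclass(params$grammar),
    cohort = params$cohort,
    psa = params$psa
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load and validate model parameters from a file
#'
#' Reads the YAML schema written by [write_model_parameters()], checks it
#' structurally (unknown keys are errors; required fields must be present)
#' and then runs [validate_parameters()], stopping on any invariant breach.
#'
#' @param path Parameter file.
#' @param dialect Decimal dialect for a sidecar transition table.
#' @return A validated [model_parameters()] object.
#' @export
load_model_parameters <- function(path, dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("dmts", "natural_history", "economics", "grammar",
                    "cohort", "psa"),
             "top level",
             required = c("dmts", "natural_history", "economics",
                          "grammar", "cohort"))

  dmts <- lapply(doc$dmts, function(x) {
    check_keys(x, c("name", "moa_class", "eligible_lines", "efficacy_arr",
                    "efficacy_cdp", "annual_cost_first_year",
                    "annual_cost_subsequent", "admin_cost",
                    "monitoring_cost", "ae_discontinuation_prob",
                    "synthetic"),
               paste0("dmts entry '", x$name, "'"),
               required = c("name", "moa_class", "eligible_lines",
                            "efficacy_arr", "efficacy_cdp",
                            "annual_cost_first_year",
                            "annual_cost_subsequent"))
    dmt_definition(
      x$name, x$moa_class, unlist(x$eligible_lines),
      eff_from_list(x$efficacy_arr, paste0(x$name, ".efficacy_arr")),
      eff_from_list(x$efficacy_cdp, paste0(x$name, ".efficacy_cdp")),
      null_na(x$annual_cost_first_year), null_na(x$annual_cost_subsequent),
      x$admin_cost %||% 0, x$monitoring_cost %||% 0,
      x$ae_discontinuation_prob %||% 0, x$synthetic %||% FALSE)
  })
  names(dmts) <- vapply(dmts, `[[`, "", "name")

  nhx <- doc$natural_history
  check_keys(nhx, c("edss_levels", "transition_matrix", "transition_file",
                    "relapse_rate_by_edss", "mortality_multiplier_by_edss",
                    "life_table"),
             "natural_history",
             required = c("edss_levels", "relapse_rate_by_edss",
                          "mortality_multiplier_by_edss", "life_table"))
  if (!is.null(nhx$transition_matrix)) {
    tm <- do.call(rbind, lapply(nhx$transition_matrix, as.numeric))
  } else if (!is.null(nhx$transition_file)) {
    tf <- file.path(dirname(path), nhx$transition_file)
    tab <- utils::read.table(tf,
      sep = if (dialect == "comma") ";" else ",",
      dec = if (dialect == "comma") "," else ".",
      header = TRUE, row.names = 1, check.names = FALSE)
    tm <- as.matrix(tab)
  } else {
    stop("parameter file: missing required field 'transition_matrix' ",
         "(or 'transition_file') in natural_history", call. = FALSE)
  }
  check_keys(nhx$life_table, c("age", "hazard"), "natural_history.life_table",
             required = c("age", "hazard"))
  nh <- natural_history_params(
    unlist(nhx$edss_levels), tm,
    unlist(nhx$relapse_rate_by_edss),
    unlist(nhx$mortality_multiplier_by_edss),
    data.frame(age = unlist(nhx$life_table$age),
               hazard = unlist(nhx$life_table$hazard)))

  ecx <- doc$economics
  check_keys(ecx, c("utility_by_edss", "relapse_disutility",
                    "state_cost_healthcare_by_edss",
                    "state_cost_societal_by_edss", "relapse_cost", "wtp",
                    "discount_rate_costs", "discount_rate_effects"),
             "economics",
             required = c("utility_by_edss", "relapse_disutility",
                          "state_cost_healthcare_by_edss",
                          "state_cost_societal_by_edss", "relapse_cost",
                          "wtp", "discount_rate_costs",
                          "discount_rate_effects"))
  ec <- economic_params(unlist(ecx$utility_by_edss), ecx$relapse_disutility,
                        unlist(ecx$state_cost_healthcare_by_edss),
                        unlist(ecx$state_cost_societal_by_edss),
                        ecx$relapse_cost, ecx$wtp,
                        ecx$discount_rate_costs, ecx$discount_rate_effects)

  grx <- doc$grammar
  check_keys(grx, c("first_line_escalation_set", "first_line_highefficacy_set",
                    "forbid_same_moa_consecutive", "last_resort_only",
                    "max_lines", "line1b_enabled"),
             "grammar")
  gr <- grammar_rules(unlist(grx$first_line_escalation_set) %||% character(),
                      unlist(grx$first_line_highefficacy_set) %||% character(),
                      grx$forbid_same_moa_consecutive %||% TRUE,
                      unlist(grx$last_resort_only) %||% character(),
                      grx$max_lines %||% 5,
                      grx$line1b_enabled %||% TRUE)

  chx <- doc$cohort
  check_keys(chx, c("n_patients", "start_age", "baseline_edss_range"),
             "cohort",
             required = c("n_patients", "start_age", "baseline_edss_range"))
  cohort <- list(n_patients = as.integer(chx$n_patients),
                 start_age = as.integer(chx$start_age),
                 baseline_edss_range = as.integer(unlist(chx$baseline_edss_range)))

  psa <- doc$psa %||% list(cv_utility = 0.05, cv_state_cost = 0.15,
                           cv_relapse_rate = 0.15)
  check_keys(psa, c("cv_utility", "cv_state_cost", "cv_relapse_rate"), "psa")

  params <- model_parameters(dmts, nh, ec, gr, cohort, psa)
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    stop("parameter file failed validation:\n",
         paste(sprintf("  %s %s: %s", v$type, v$field, v$rule),
               collapse = "\n"), call. = FALSE)
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' @export
print.model_parameters <- function(x, ...) {
  cat("Treatment-sequence model parameters\n")
  cat(sprintf("  DMTs: %d (%s)\n", length(x$dmts),
              paste(names(x$dmts), collapse = ", ")))
  cat(sprintf("  EDSS states: %d-%d; cohort: %d patients, start age %d, baseline EDSS %d-%d\n",
              min(x$natural_history$edss_levels),
              max(x$natural_history$edss_levels),
              x$cohort$n_patients, x$cohort$start_age,
              x$cohort$baseline_edss_range[1], x$cohort$baseline_edss_range[2]))
  cat(sprintf("  WTP: %s EUR/QALY; discounting: %.1f%% costs, %.1f%% effects\n",
              format(x$economics$wtp, big.mark = ","),
              100 * x$economics$discount_rate_costs,
              100 * x$economics$discount_rate_effects))
  nv <- nrow(validate_parameters(x))
  cat(sprintf("  validation: %s\n",
              if (nv == 0) "OK" else sprintf("%d violation(s)", nv)))
  invisible(x)
}
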