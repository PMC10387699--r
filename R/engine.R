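# Patient-level microsimulation engine.
#
# Annual cycles from the starting age until death (or age 100). Within a
# cycle the event order is fixed: death -> relapses -> EDSS transition ->
# adverse event -> line switch -> discontinuation check. Costs and utility
# accrue on the state occupied during the cycle (no half-cycle correction);
# a patient who dies in a cycle accrues nothing for that cycle.
#
# Randomness: each patient owns an independent substream derived from
# (seed, patient index), with five uniforms per cycle (death, relapse
# count, progression occurrence, transition severity, adverse event).
# Because the substream depends only on (seed, index), cohorts run under
# different sequences or different treatment-effect values reuse identical
# draws — common random numbers — which makes paired comparisons and
# threshold searches nearly noise-free. The relapse count is the Poisson
# quantile of the relapse uniform, and "any EDSS worsening" happens when
# the progression uniform exceeds one minus the treatment-scaled worsening
# mass, so both outcomes are monotone in the treatment effect draw by draw.

MAX_AGE <- 100L
MILESTONE_EDSS <- 6L

# slot coding: 1 = line 1a, 2 = line 1b, 3..(L+1) = lines 2..4, 0 = off
SLOT_LABELS <- c("1a", "1b", "2", "3", "4")

patient_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 1000003
  as.integer((s * 1009 + as.numeric(index) * 7919) %% 2147483647) + 1L
}

patient_uniforms <- function(seed, index, n_cycles) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(patient_seed(seed, index))
  matrix(stats::runif(5L * n_cycles), nrow = n_cycles, ncol = 5L)
}

#' Scale a relapse rate by a treatment's incidence rate ratio
#'
#' @param base_rate Natural-history annualized relapse rate (events/year).
#' @param efficacy An [efficacy_estimate()] with measure `"IRR_ARR"`, or a
#'   bare numeric ratio.
#' @return Treated relapse rate `base_rate * IRR`.
#' @export
effective_relapse_rate <- function(base_rate, efficacy) {
  if (any(base_rate < 0)) stop("base relapse rate must be >= 0")
  ratio <- if (inherits(efficacy, "efficacy_estimate")) {
    if (efficacy$measure != "IRR_ARR")
      stop("efficacy must carry measure IRR_ARR")
    efficacy$point
  } else efficacy
  base_rate * ratio
}

#' Scale an annual progression probability by a relative risk
#'
#' Converts the annual probability of any EDSS worsening to a rate, scales
#' the rate by the relative risk of confirmed disability progression, and
#' converts back: `1 - exp(RR * log(1 - p))`. This is how a ratio measured
#' on 24-week confirmed progression is applied to an annual cycle.
#'
#' @param base_annual_prob Annual probability in `[0, 1)`.
#' @param efficacy An [efficacy_estimate()] with measure `"RR_CDP"`, or a
#'   bare numeric ratio. The unknown sentinel is refused.
#' @return Scaled annual probability.
#' @export
effective_progression_prob <- function(base_annual_prob, efficacy) {
  if (any(base_annual_prob < 0) || any(base_annual_prob >= 1))
    stop("base annual probability must lie in [0, 1)")
  if (inherits(efficacy, "efficacy_estimate")) {
    if (is_unknown_efficacy(efficacy))
      stop("efficacy_cdp is unknown for this drug; supply a trial value ",
           "via set_dmt_rr() or the threshold analysis")
    if (efficacy$measure != "RR_CDP")
      stop("efficacy must carry measure RR_CDP")
    rr <- efficacy$point
  } else rr <- efficacy
  1 - exp(rr * log1p(-base_annual_prob))
}

#' Construct a patient state
#'
#' @param age Current age in years.
#' @param edss Current EDSS state.
#' @param line Current line label (`"1a"`, `"1b"`, `"2"`, `"3"`, `"4"`) or
#'   `"OFF"` once the sequence is exhausted or treatment was discontinued.
#' @param alive Logical.
#' @param years_on_current_dmt Completed years on the current drug.
#' @param years_since_last_event Completed years since the last relapse or
#'   EDSS progression (not reset by treatment switches).
#' @param cumulative_relapses Lifetime relapse count so far.
#' @param time_to_edss6 Years from baseline to first entry of EDSS >= 6,
#'   or `NA` while not reached.
#' @param time_in_line1 Years spent in lines 1a/1b.
#' @param baseline_age Age at model entry (defaults to `age`); used to
#'   express `time_to_edss6` as years since baseline.
#' @return An object of class `patient_state`.
#' @export
patient_state <- function(age, edss, line = "1a", alive = TRUE,
                          years_on_current_dmt = 0,
                          years_since_last_event = 0,
                          cumulative_relapses = 0,
                          time_to_edss6 = NA_real_,
                          time_in_line1 = 0,
                          baseline_age = age) {
  structure(list(age = age, edss = edss, line = line, alive = alive,
                 baseline_age = baseline_age,
                 years_on_current_dmt = years_on_current_dmt,
                 years_since_last_event = years_since_last_event,
                 cumulative_relapses = cumulative_relapses,
                 time_to_edss6 = time_to_edss6,
                 time_in_line1 = time_in_line1),
            class = "patient_state")
}

#' Initialize a treatment-naive cohort
#'
#' All patients start at the configured age, alive, on line 1a with zeroed
#' counters. Baseline EDSS is assigned deterministically round-robin over
#' the configured range (default 0 to 3) so state counts differ by at most
#' one — an even distribution at diagnosis.
#'
#' @param params A [model_parameters()] object.
#' @param n Number of patients (>= 4).
#' @param seed Seed recorded for the cohort's substreams (assignment itself
#'   is deterministic).
#' @return List of [patient_state()] objects of length `n`.
#' @export
initialize_cohort <- function(params, n = params$cohort$n_patients,
                              seed = 1L) {
  if (n < 4) stop("n must be >= 4 (one patient per baseline EDSS state)")
  states <- baseline_edss_states(params, n)
  lapply(seq_len(n), function(i)
    patient_state(age = params$cohort$start_age, edss = states[i]))
}

baseline_edss_states <- function(params, n) {
  br <- params$cohort$baseline_edss_range
  pool <- seq.int(br[1], br[2])
  pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
}

#' Draw one cycle's events for a single patient
#'
#' Reference scalar implementation of the within-cycle draw, in the fixed
#' event order (death first; a death suppresses everything downstream).
#' Pass `u` (five uniforms) to replay a recorded substream; otherwise the
#' session RNG is consumed.
#'
#' @param state A [patient_state()].
#' @param dmt A [dmt_definition()] or `NULL` for natural history.
#' @param params A [model_parameters()] object.
#' @param u Optional numeric vector of five uniforms (death, relapse,
#'   progression, severity, adverse event).
#' @return List of class `cycle_outcome` with `n_relapses`,
#'   `edss_progressed`, `edss_new`, `adverse_event`, `died`.
#' @export
draw_cycle_outcome <- function(state, dmt, params, u = NULL) {
  if (!state$alive) stop("patient is dead")
  if (is.null(u)) u <- stats::runif(5)
  nh <- params$natural_history
  s_idx <- match(state$edss, nh$edss_levels)
  haz <- life_hazard_at(nh, state$age) * nh$mortality_multiplier_by_edss[s_idx]
  if (u[1] < 1 - exp(-haz)) {
    return(structure(list(n_relapses = 0L, edss_progressed = FALSE,
                          edss_new = state$edss, adverse_event = FALSE,
                          died = TRUE), class = "cycle_outcome"))
  }
  irr <- if (is.null(dmt)) 1 else dmt$efficacy_arr$point
  rr <- if (is.null(dmt)) 1 else {
    if (is_unknown_efficacy(dmt$efficacy_cdp))
      stop("efficacy_cdp is unknown for ", dmt$name,
           "; supply a trial value via set_dmt_rr() or the threshold analysis")
    dmt$efficacy_cdp$point
  }
  lam <- nh$relapse_rate_by_edss[s_idx] * irr
  n_rel <- stats::qpois(u[2], lam)
  row <- nh$transition_matrix[s_idx, ]
  K <- length(row)
  w <- if (s_idx < K) sum(row[(s_idx + 1L):K]) else 0
  wp <- if (w > 0) 1 - exp(rr * log1p(-w)) else 0
  worsen <- u[3] > 1 - wp
  cum <- cumsum(row)
  target <- if (worsen) (1 - w) + u[4] * w else u[4] * (1 - w)
  edss_new <- nh$edss_levels[min(sum(cum < target) + 1L, K)]
  ae <- !is.null(dmt) && u[5] < dmt$ae_discontinuation_prob
  structure(list(n_relapses = n_rel, edss_progressed = worsen,
                 edss_new = edss_new, adverse_event = ae, died = FALSE),
            class = "cycle_outcome")
}

life_hazard_at <- function(nh, age) {
  i <- match(floor(age), nh$life_table$age)
  if (is.na(i)) stop("life table does not cover age ", age)
  nh$life_table$hazard[i]
}

#' Apply end-of-cycle switching rules to a patient
#'
#' Event-driven switching: an adverse event on line 1a moves the patient to
#' line 1b when the sequence has one; any relapse, EDSS progression or
#' adverse event otherwise advances one line; past the final line the
#' patient goes off treatment and follows natural history. Also advances
#' age, EDSS, the event-free clock (relapse/progression reset it; an
#' adverse event alone does not), time-on-drug, time in line 1, and records
#' the first entry to EDSS >= 6.
#'
#' @param state A [patient_state()].
#' @param outcome A `cycle_outcome` from [draw_cycle_outcome()].
#' @param seq A [sequence_spec()].
#' @param rules A [grammar_rules()] object (line-1b availability).
#' @return The updated `patient_state`.
#' @export
apply_switch_rules <- function(state, outcome, seq, rules) {
  if (!state$alive) stop("patient is dead")
  if (outcome$died) {
    state$alive <- FALSE
    return(state)
  }
  on_line1 <- state$line %in% c("1a", "1b")
  state$cumulative_relapses <- state$cumulative_relapses + outcome$n_relapses
  if (on_line1) state$time_in_line1 <- state$time_in_line1 + 1
  state$age <- state$age + 1
  state$edss <- outcome$edss_new
  if (is.na(state$time_to_edss6) && state$edss >= MILESTONE_EDSS)
    state$time_to_edss6 <- state$age - state$baseline_age
  clinical_event <- outcome$n_relapses > 0 || outcome$edss_progressed
  state$years_since_last_event <-
    if (clinical_event) 0 else state$years_since_last_event + 1

  if (state$line != "OFF") {
    any_event <- clinical_event || outcome$adverse_event
    if (any_event) {
      state$line <- next_line(state$line, seq, outcome$adverse_event)
      state$years_on_current_dmt <- 0
    } else {
      state$years_on_current_dmt <- state$years_on_current_dmt + 1
    }
    if (state$line != "OFF" && check_discontinuation(state))
      state$line <- "OFF"
  }
  state
}

next_line <- function(line, seq, adverse_event) {
  L <- length(seq$lines)
  labels <- chain_labels(L)
  if (line == "1a" && adverse_event && seq$has_line1b) return("1b")
  if (line == "1b") {
    return(if (L >= 2) labels[2] else "OFF")
  }
  i <- match(line, labels)
  if (is.na(i) || i >= L) "OFF" else labels[i + 1]
}

#' Treatment discontinuation rule
#'
#' Patients aged 50 or older with at least 5 event-free years (no relapse
#' or EDSS progression) on a first- or second-line treatment, and patients
#' aged 70 or older with at least 10 event-free years on a third-line
#' treatment, stop their DMT permanently.
#'
#' @param state A [patient_state()].
#' @return Logical flag.
#' @export
check_discontinuation <- function(state) {
  if (!state$alive || state$line == "OFF") return(FALSE)
  (state$age >= 50 && state$years_since_last_event >= 5 &&
     state$line %in% c("1a", "1b", "2")) ||
    (state$age >= 70 && state$years_since_last_event >= 10 &&
       state$line == "3")
}

# ---- sequence slot tables --------------------------------------------------

# Returns per-slot vectors (slot 1 = 1a, 2 = 1b, 3..(L+1) = lines 2..4,
# plus a terminal OFF slot) of drug attributes for fast lookup.
build_slots <- function(seq, params) {
  L <- length(seq$lines)
  n_slots <- L + 1L   # slot 2 reserved for 1b even when absent
  drugs <- c(seq$lines[1],
             if (seq$has_line1b) seq$line1b else NA_character_,
             if (L > 1) seq$lines[2:L])
  labels <- c("1a", "1b", if (L > 1) chain_labels(L)[-1])
  used <- drugs[!is.na(drugs)]
  for (nm in used) {
    d <- get_dmt(params, nm)
    if (is_unknown_efficacy(d$efficacy_cdp))
      stop("sequence ", seq$label, " uses ", nm, " whose efficacy_cdp is ",
           "unknown; supply a trial value via set_dmt_rr() or run the ",
           "threshold analysis", call. = FALSE)
    if (is.na(d$annual_cost_first_year) || is.na(d$annual_cost_subsequent))
      stop("sequence ", seq$label, " uses ", nm, " whose annual cost is ",
           "unknown; set a price via set_dmt_cost() or run the ",
           "threshold analysis", call. = FALSE)
  }
  att <- function(f, default) {
    vapply(drugs, function(nm) {
      if (is.na(nm)) default else as.numeric(get_dmt(params, nm)[[f]])
    }, 0)
  }
  irr <- vapply(drugs, function(nm)
    if (is.na(nm)) 1 else get_dmt(params, nm)$efficacy_arr$point, 0)
  rr <- vapply(drugs, function(nm)
    if (is.na(nm)) 1 else get_dmt(params, nm)$efficacy_cdp$point, 0)
  list(
    n_slots = n_slots, labels = labels, drugs = drugs,
    has1b = seq$has_line1b, L = L,
    irr = c(irr, 1), rr = c(rr, 1),
    ae = c(att("ae_discontinuation_prob", 0), 0),
    cost_first = c(att("annual_cost_first_year", 0), 0),
    cost_sub = c(att("annual_cost_subsequent", 0), 0),
    admin = c(att("admin_cost", 0), 0),
    monit = c(att("monitoring_cost", 0), 0)
  )
}

# slot transition on an event; off_slot = n_slots + 1 (the appended neutral)
next_slot_vec <- function(slot, ae, slots) {
  off <- slots$n_slots + 1L
  out <- ifelse(slot == 1L,
                ifelse(ae & slots$has1b, 2L, 3L),
                ifelse(slot == 2L, 3L, slot + 1L))
  ifelse(out > slots$n_slots, off, out)
}

# ---- the vectorized cohort engine ------------------------------------------

run_engine <- function(seq, params, n, seed, keep_trajectories = FALSE,
                       keep_patients = FALSE, patient_indices = seq_len(n),
                       baseline_override = NULL) {
  nh <- params$natural_history
  ec <- params$economics
  slots <- if (is.null(seq)) NULL else build_slots(seq, params)
  off_slot <- if (is.null(slots)) 1L else slots$n_slots + 1L
  start_age <- params$cohort$start_age
  n_cycles <- MAX_AGE - start_age
  K <- length(nh$edss_levels)

  # per-patient uniform substreams derived from (seed, index)
  U <- array(0, dim = c(n, n_cycles, 5L))
  for (j in seq_len(n))
    U[j, , ] <- patient_uniforms(seed, patient_indices[j], n_cycles)

  lt_haz <- rep(NA_real_, MAX_AGE + 1L)
  lt_haz[nh$life_table$age + 1L] <- nh$life_table$hazard
  if (anyNA(lt_haz[(start_age:(MAX_AGE - 1L)) + 1L]))
    stop("life table must cover ages ", start_age, " to ", MAX_AGE - 1L)

  tm <- nh$transition_matrix
  cum_tm <- t(apply(tm, 1, cumsum))
  wmass <- vapply(seq_len(K), function(i)
    if (i < K) sum(tm[i, (i + 1L):K]) else 0, 0)

  if (is.null(baseline_override)) {
    # round-robin by patient index, so substream reuse keeps baselines aligned
    edss_val <- baseline_edss_states(params, max(patient_indices))[patient_indices]
  } else {
    edss_val <- rep_len(baseline_override, n)
  }
  edss <- match(edss_val, nh$edss_levels)   # 1-based state index
  alive <- rep(TRUE, n)
  slot <- rep(if (is.null(slots)) off_slot else 1L, n)
  years_on <- rep(0, n); yse <- rep(0, n)
  cum_rel <- rep(0, n); t_edss6 <- rep(NA_real_, n)
  t_line1 <- rep(0, n); life_years <- rep(0, n)
  acc_drug <- rep(0, n); acc_ohc <- rep(0, n); acc_soc <- rep(0, n)
  acc_qaly <- rep(0, n)

  milestone_idx <- match(MILESTONE_EDSS, nh$edss_levels)  # NA for toy models
  traj <- if (keep_trajectories) vector("list", n_cycles) else NULL

  if (is.null(slots)) {
    irr_s <- rep(1, off_slot); rr_s <- rep(1, off_slot); ae_s <- rep(0, off_slot)
    cf_s <- rep(0, off_slot); cs_s <- rep(0, off_slot)
    ad_s <- rep(0, off_slot); mo_s <- rep(0, off_slot)
    slot_lab <- "OFF"
  } else {
    irr_s <- slots$irr; rr_s <- slots$rr; ae_s <- slots$ae
    cf_s <- slots$cost_first; cs_s <- slots$cost_sub
    ad_s <- slots$admin; mo_s <- slots$monit
    slot_lab <- c(slots$labels, "OFF")
  }

  for (t in 0:(n_cycles - 1L)) {
    idx <- which(alive)
    if (!length(idx)) break
    age <- start_age + t
    u1 <- U[idx, t + 1L, 1L]
    h <- lt_haz[age + 1L] * nh$mortality_multiplier_by_edss[edss[idx]]
    die <- u1 < (1 - exp(-h))
    alive[idx[die]] <- FALSE
    sv <- idx[!die]
    if (length(sv)) {
      u2 <- U[sv, t + 1L, 2L]; u3 <- U[sv, t + 1L, 3L]
      u4 <- U[sv, t + 1L, 4L]; u5 <- U[sv, t + 1L, 5L]
      st <- edss[sv]; sl <- slot[sv]
      on_trt <- sl < off_slot
      irr <- irr_s[sl]; rr <- rr_s[sl]
      lam <- nh$relapse_rate_by_edss[st] * irr
      nrel <- stats::qpois(u2, lam)
      w <- wmass[st]
      wp <- ifelse(w > 0, 1 - exp(rr * log1p(-w)), 0)
      worsen <- u3 > 1 - wp
      target <- ifelse(worsen, (1 - w) + u4 * w, u4 * (1 - w))
      Crows <- cum_tm[st, , drop = FALSE]
      new_st <- pmin(rowSums(Crows < target) + 1L, K)
      ae <- on_trt & (u5 < ae_s[sl])

      # accrual on the state occupied during the cycle
      dfc <- 1 / (1 + ec$discount_rate_costs)^t
      dfe <- 1 / (1 + ec$discount_rate_effects)^t
      drug_cost <- ifelse(on_trt,
                          ifelse(years_on[sv] < 1, cf_s[sl], cs_s[sl]), 0)
      ohc <- ifelse(on_trt, ad_s[sl] + mo_s[sl], 0) +
        ec$state_cost_healthcare_by_edss[st] + ec$relapse_cost * nrel
      soc <- ec$state_cost_societal_by_edss[st]
      qaly <- ec$utility_by_edss[st] - ec$relapse_disutility * nrel
      acc_drug[sv] <- acc_drug[sv] + drug_cost * dfc
      acc_ohc[sv] <- acc_ohc[sv] + ohc * dfc
      acc_soc[sv] <- acc_soc[sv] + soc * dfc
      acc_qaly[sv] <- acc_qaly[sv] + qaly * dfe
      life_years[sv] <- life_years[sv] + 1
      cum_rel[sv] <- cum_rel[sv] + nrel
      t_line1[sv] <- t_line1[sv] + (sl <= 2L & on_trt)

      if (keep_trajectories) {
        traj[[t + 1L]] <- data.frame(
          patient = patient_indices[sv], cycle = t, age = age,
          edss = nh$edss_levels[st], line = slot_lab[sl],
          dmt = if (is.null(slots)) NA_character_ else slots$drugs[pmin(sl, off_slot - 1L)],
          on_treatment = on_trt, n_relapses = nrel, progressed = worsen,
          adverse_event = ae,
          drug_cost = drug_cost, other_healthcare_cost = ohc,
          societal_cost = soc, utility = qaly,
          stringsAsFactors = FALSE)
        traj[[t + 1L]]$dmt[!on_trt] <- NA_character_
      }

      # state update
      edss[sv] <- new_st
      if (!is.na(milestone_idx)) {
        hit <- is.na(t_edss6[sv]) & new_st >= milestone_idx
        t_edss6[sv[hit]] <- t + 1
      }
      clinical <- nrel > 0 | worsen
      yse[sv] <- ifelse(clinical, 0, yse[sv] + 1)
      any_event <- clinical | ae
      move <- on_trt & any_event
      if (any(move)) {
        sl2 <- sl
        sl2[move] <- next_slot_vec(sl[move], ae[move], slots)
        slot[sv] <- sl2
        years_on[sv] <- ifelse(move, 0, years_on[sv] + on_trt)
      } else {
        years_on[sv] <- years_on[sv] + on_trt
      }
      # discontinuation at the attained age
      sl3 <- slot[sv]
      on2 <- sl3 < off_slot
      lab3 <- slot_lab[sl3]
      att_age <- age + 1
      disc <- on2 & ((att_age >= 50 & yse[sv] >= 5 & lab3 %in% c("1a", "1b", "2")) |
                       (att_age >= 70 & yse[sv] >= 10 & lab3 == "3"))
      slot[sv[disc]] <- off_slot
    }
  }

  wtp <- ec$wtp
  total <- acc_drug + acc_ohc + acc_soc
  reached <- !is.na(t_edss6)
  res <- structure(list(
    label = if (is.null(seq)) "natural history" else seq$label,
    n = n, seed = seed,
    costs = list(drug = mean(acc_drug), other_healthcare = mean(acc_ohc),
                 societal = mean(acc_soc), total = mean(total)),
    qalys = mean(acc_qaly),
    nhb = mean(acc_qaly) - mean(total) / wtp,
    lifetime_relapses = mean(cum_rel),
    time_to_edss6 = if (any(reached)) mean(t_edss6[reached]) else NA_real_,
    fraction_reaching_edss6 = mean(reached),
    time_in_line1 = mean(t_line1),
    life_years = mean(life_years),
    wtp = wtp
  ), class = "dmtseq_cohort")
  if (keep_patients) {
    res$patients <- data.frame(
      patient = patient_indices, baseline_edss = edss_val,
      cost_drug = acc_drug, cost_other_healthcare = acc_ohc,
      cost_societal = acc_soc, cost_total = total, qalys = acc_qaly,
      life_years = life_years, relapses = cum_rel,
      time_to_edss6 = t_edss6, time_in_line1 = t_line1)
  }
  if (keep_trajectories)
    res$trajectories <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  res
}

#' Simulate one patient through a treatment sequence
#'
#' Runs the annual-cycle engine for a single patient on their own random
#' substream (derived from `seed` and `index`), returning the per-cycle
#' trajectory and the patient's lifetime summary. Deterministic given
#' `(seq, params, seed, index)`.
#'
#' @param seq A [sequence_spec()], or `NULL` for untreated natural history.
#' @param params A [model_parameters()] object.
#' @param seed Integer seed.
#' @param index Patient index within the cohort (determines the baseline
#'   EDSS via the round-robin assignment and the substream).
#' @return A list of class `dmtseq_trajectory` with elements `cycles`
#'   (one row per lived cycle) and `summary` (a one-patient cohort result).
#' @export
simulate_patient <- function(seq, params, seed = 1L, index = 1L) {
  res <- run_engine(seq, params, n = 1L, seed = seed,
                    keep_trajectories = TRUE, keep_patients = TRUE,
                    patient_indices = index)
  structure(list(cycles = res$trajectories, summary = res),
            class = "dmtseq_trajectory")
}

#' Simulate a cohort through a treatment sequence
#'
#' Runs `n` independent patients (each on a substream derived from
#' `(seed, patient index)`) through the sequence and averages their
#' discounted outcomes. Identical `(seq, params, n, seed)` give a
#' bit-identical result; cohorts run under different sequences but the same
#' `n` and `seed` share their random draws (common random numbers).
#'
#' @param seq A [sequence_spec()], or `NULL` for untreated natural history.
#' @param params A [model_parameters()] object.
#' @param n Cohort size (default from `params$cohort`).
#' @param seed Integer seed.
#' @param keep_patients Keep the per-patient lifetime summaries.
#' @param keep_trajectories Keep the per-cycle long table (large).
#' @return An object of class `dmtseq_cohort`: mean discounted cost
#'   components, mean discounted QALYs, net health benefit, lifetime
#'   relapses, time to EDSS 6 (mean over patients reaching it, with the
#'   fraction reaching reported alongside), time in line 1 and life years.
#' @export
simulate_cohort <- function(seq, params, n = params$cohort$n_patients,
                            seed = 1L, keep_patients = FALSE,
                            keep_trajectories = FALSE) {
  if (n < 1) stop("n must be >= 1")
  run_engine(seq, params, n = n, seed = seed,
             keep_trajectories = keep_trajectories,
             keep_patients = keep_patients)
}

#' Net health benefit of one sequence
#'
#' Convenience wrapper: simulate the cohort and return its NHB.
#'
#' @inheritParams simulate_cohort
#' @return Numeric NHB in QALY units.
#' @export
sequence_nhb <- function(seq, params, n = params$cohort$n_patients,
                         seed = 1L) {
  simulate_cohort(seq, params, n = n, seed = seed)$nhb
}

#' @export
print.dmtseq_cohort <- function(x, ...) {
  cat("Cohort result:", x$label, sprintf("(n = %d, seed = %d)\n", x$n, x$seed))
  eur <- function(v) format(round(v), big.mark = ",")
  cat(sprintf("  Total costs (Euros)            %s\n", eur(x$costs$total)))
  cat(sprintf("  Drug costs (Euros)             %s\n", eur(x$costs$drug)))
  cat(sprintf("  Other healthcare costs (Euros) %s\n", eur(x$costs$other_healthcare)))
  cat(sprintf("  Societal costs (Euros)         %s\n", eur(x$costs$societal)))
  cat(sprintf("  Total QALYs                    %.1f\n", x$qalys))
  cat(sprintf("  NHB                            %.2f\n", x$nhb))
  cat(sprintf("  Lifetime relapses              %.1f\n", x$lifetime_relapses))
  cat(sprintf("  Time to EDSS 6 (years)         %.1f (%.0f%% reach it)\n",
              x$time_to_edss6, 100 * x$fraction_reaching_edss6))
  cat(sprintf("  Time in line 1 (years)         %.1f\n", x$time_in_line1))
  cat(sprintf("  Life years                     %.1f\n", x$life_years))
  invisible(x)
}

#' @export
summary.dmtseq_cohort <- function(object, ...) object

#' @export
print.dmtseq_trajectory <- function(x, ...) {
  cat("Patient trajectory:", x$summary$label, "\n")
  cat(sprintf("  %d cycles lived, %.0f relapses, final EDSS %s\n",
              nrow(x$cycles), x$summary$lifetime_relapses,
              if (nrow(x$cycles)) x$cycles$edss[nrow(x$cycles)] else "-"))
  invisible(x)
}
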