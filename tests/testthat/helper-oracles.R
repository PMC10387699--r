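# Independent oracles, deliberately implemented without the engine.

# Deterministic Markov-cohort expectation for an UNTREATED cohort:
# occupancy-vector recursion with matrix products, the classical
# cohort-model computation. Event order mirrors the engine's definition
# (death first, then accrual on the start-of-cycle state, then transition)
# but the computation is expectation-based, not sampling-based.
markov_cohort_expectation <- function(params, max_age = 100L) {
  nh <- params$natural_history
  ec <- params$economics
  K <- length(nh$edss_levels)
  start_age <- params$cohort$start_age
  br <- params$cohort$baseline_edss_range
  pool <- seq.int(br[1], br[2])
  pi0 <- numeric(K)
  for (s in pool) pi0[match(s, nh$edss_levels)] <- 1 / length(pool)

  lt <- nh$life_table
  haz_at <- function(age) lt$hazard[match(age, lt$age)]

  pi <- pi0
  life_years <- 0; qalys <- 0; relapses <- 0; total_cost <- 0
  for (t in 0:(max_age - start_age - 1L)) {
    age <- start_age + t
    d <- 1 - exp(-haz_at(age) * nh$mortality_multiplier_by_edss)
    m <- pi * (1 - d)                       # survivors of this cycle
    dfe <- 1 / (1 + ec$discount_rate_effects)^t
    dfc <- 1 / (1 + ec$discount_rate_costs)^t
    lam <- nh$relapse_rate_by_edss
    life_years <- life_years + sum(m)
    qalys <- qalys + dfe * sum(m * (ec$utility_by_edss - ec$relapse_disutility * lam))
    relapses <- relapses + sum(m * lam)
    total_cost <- total_cost + dfc * sum(m * (ec$state_cost_healthcare_by_edss +
                                                ec$state_cost_societal_by_edss +
                                                ec$relapse_cost * lam))
    pi <- as.numeric(crossprod(nh$transition_matrix, m))
  }
  list(life_years = life_years, qalys = qalys, relapses = relapses,
       total_cost = total_cost)
}

# Brute-force sequence enumeration: all ordered drug subsets of the chain
# length, filtered junction by junction with is_valid_switch() plus the
# first-line opener rule, then all admissible line-1b attachments.
brute_force_sequences <- function(anchor, anchor_line, dmts, rules) {
  L <- min(4L, rules$max_lines - 1L)
  labels <- c("1a", "2", "3", "4")[seq_len(L)]
  anchor_pos <- match(anchor_line, labels)
  nms <- names(dmts)
  perms <- function(v, k) {
    if (k == 0) return(list(character()))
    out <- list()
    for (x in v) for (rest in perms(setdiff(v, x), k - 1))
      out[[length(out) + 1]] <- c(x, rest)
    out
  }
  labs <- character()
  first_ok <- function(nm) nm %in% c(rules$first_line_escalation_set,
                                     rules$first_line_highefficacy_set)
  opener_has_1b <- function(nm) rules$line1b_enabled &&
    nm %in% rules$first_line_escalation_set
  for (chain in perms(nms, L)) {
    if (chain[anchor_pos] != anchor) next
    if (anchor %in% chain[-anchor_pos]) next
    if (!first_ok(chain[1])) next
    ok <- TRUE
    for (i in seq_len(L - 1)) {
      if (!is_valid_switch(dmts[[chain[i]]], dmts[[chain[i + 1]]], rules,
                           labels[i + 1], is_final = (i + 1 == L))) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    labs <- c(labs, sequence_label(chain))
    if (opener_has_1b(chain[1])) {
      for (b in setdiff(nms, chain)) {
        if (!is_valid_switch(dmts[[chain[1]]], dmts[[b]], rules, "1b",
                             is_final = FALSE)) next
        if (L > 1 && !is_valid_switch(dmts[[b]], dmts[[chain[2]]], rules,
                                      "2", is_final = (L == 2))) next
        labs <- c(labs, sequence_label(chain, b))
      }
    }
  }
  sort(labs)
}
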