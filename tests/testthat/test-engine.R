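test_that("cohort initialization distributes baseline EDSS evenly and deterministically", {
  p <- synth_params()
  ch <- initialize_cohort(p, n = 10000)
  tab <- table(vapply(ch, `[[`, 0, "edss"))
  expect_identical(as.integer(tab), rep(2500L, 4))
  expect_true(all(vapply(ch, `[[`, 0, "age") == 29))
  expect_true(all(vapply(ch, `[[`, "", "line") == "1a"))

  ch4 <- initialize_cohort(p, n = 4)
  expect_identical(sort(vapply(ch4, `[[`, 0, "edss")), c(0, 1, 2, 3))
  ch7a <- initialize_cohort(p, n = 7)
  ch7b <- initialize_cohort(p, n = 7)
  tab7 <- table(vapply(ch7a, `[[`, 0, "edss"))
  expect_lte(max(tab7) - min(tab7), 1)
  expect_identical(ch7a, ch7b)
  expect_error(initialize_cohort(p, n = 3), ">= 4")
})

test_that("treatment effects scale relapse rates and progression probabilities", {
  expect_equal(effective_relapse_rate(0.5, efficacy_estimate(1)), 0.5)
  expect_equal(effective_relapse_rate(0.5, efficacy_estimate(0.40, 0.30, 0.52)), 0.20)
  expect_equal(effective_relapse_rate(0.5, efficacy_estimate(0.30, 0.22, 0.42)), 0.15)
  expect_error(effective_relapse_rate(-0.1, efficacy_estimate(1)), ">= 0")

  rr1 <- efficacy_estimate(1, measure = "RR_CDP")
  expect_equal(effective_progression_prob(0.10, rr1), 0.10)
  # probability -> rate -> scaled rate -> probability, frozen closed form
  expect_equal(effective_progression_prob(0.10, 0.45), 0.0463058267542,
               tolerance = 1e-10)
  expect_equal(effective_progression_prob(0, 0.45), 0)
  expect_error(effective_progression_prob(0.1, efficacy_unknown()), "unknown")
  expect_error(effective_progression_prob(1.0, rr1), "\\[0, 1\\)")
})

test_that("discontinuation rule gates on age, event-free years and line", {
  st <- function(age, yse, line) patient_state(age = age, edss = 2, line = line,
                                               years_since_last_event = yse)
  expect_true(check_discontinuation(st(50, 5, "2")))
  expect_true(check_discontinuation(st(50, 5, "1a")))
  expect_true(check_discontinuation(st(50, 5, "1b")))
  expect_false(check_discontinuation(st(49, 10, "1a")))
  expect_false(check_discontinuation(st(50, 4, "2")))
  expect_false(check_discontinuation(st(50, 5, "3")))
  expect_true(check_discontinuation(st(70, 10, "3")))
  expect_false(check_discontinuation(st(69, 10, "3")))
  expect_false(check_discontinuation(st(70, 10, "4")))
  off <- st(60, 20, "OFF")
  expect_false(check_discontinuation(off))
})

test_that("cycle outcomes respect limiting cases and the Poisson relapse law", {
  p <- synth_params()
  st <- patient_state(age = 40, edss = 3)

  # overwhelming mortality multiplier: death is (near) certain
  ph <- p
  ph$natural_history$mortality_multiplier_by_edss[] <- 1e9
  set.seed(1)
  died <- replicate(200, draw_cycle_outcome(st, NULL, ph)$died)
  expect_true(all(died))

  # a zero incidence rate ratio suppresses relapses entirely
  pz <- p
  pz$natural_history$life_table$hazard[] <- 1e-12
  zero_irr <- toy_dmt("Z", irr = 1e-12)
  set.seed(2)
  rel <- replicate(500, draw_cycle_outcome(st, zero_irr, pz)$n_relapses)
  expect_true(all(rel == 0))

  # base rate 0.4 scaled by IRR 0.40: mean relapses 0.16 within 3 SE
  pb <- pz
  pb$natural_history$relapse_rate_by_edss[] <- 0.4
  dmt <- toy_dmt("D", irr = 0.40)
  set.seed(3)
  n <- 10000
  rel <- replicate(n, draw_cycle_outcome(st, dmt, pb)$n_relapses)
  expect_lt(abs(mean(rel) - 0.16), 3 * sqrt(0.16 / n))
})

test_that("switching rules route events through the treatment lines", {
  p <- synth_params()
  esc <- sequence_spec(c("INFB", "OCR", "CLA", "ALE"), line1b = "GLA")
  out <- function(rel = 0, prog = FALSE, ae = FALSE)
    structure(list(n_relapses = rel, edss_progressed = prog, edss_new = 2,
                   adverse_event = ae, died = FALSE), class = "cycle_outcome")
  base <- patient_state(age = 30, edss = 2)

  # adverse event on line 1a diverts to line 1b
  s1 <- apply_switch_rules(base, out(ae = TRUE), esc, p$grammar)
  expect_identical(s1$line, "1b")
  # relapse advances a line; the event-free clock resets
  s2 <- apply_switch_rules(base, out(rel = 1), esc, p$grammar)
  expect_identical(s2$line, "2")
  expect_identical(s2$years_since_last_event, 0)
  expect_identical(s2$cumulative_relapses, 1)
  # no event: stay put, clocks advance
  s3 <- apply_switch_rules(base, out(), esc, p$grammar)
  expect_identical(s3$line, "1a")
  expect_identical(s3$years_since_last_event, 1)
  expect_identical(s3$years_on_current_dmt, 1)
  expect_identical(s3$time_in_line1, 1)
  # exhausting the final line goes off treatment
  s4 <- apply_switch_rules(patient_state(age = 45, edss = 3, line = "4"),
                           out(prog = TRUE), esc, p$grammar)
  expect_identical(s4$line, "OFF")
  # a high-efficacy sequence without 1b advances on adverse events
  hi <- ocr_first_line()
  s5 <- apply_switch_rules(base, out(ae = TRUE), hi, p$grammar)
  expect_identical(s5$line, "2")
})

test_that("ten undiscounted years at utility 0.782 yield 7.82 QALYs", {
  p <- flat_params(death_age = 39)
  tr <- simulate_patient(sequence_spec(c("X", "Y")), p, seed = 1, index = 1)
  expect_equal(tr$summary$qalys, 7.82, tolerance = 1e-12)
  expect_equal(tr$summary$life_years, 10)
  expect_equal(tr$summary$lifetime_relapses, 0)
  expect_identical(nrow(tr$cycles), 10L)
})

test_that("simulation is deterministic and a one-patient cohort matches the patient path", {
  p <- synth_params()
  s <- ocr_first_line()
  a <- simulate_cohort(s, p, n = 300, seed = 42)
  b <- simulate_cohort(s, p, n = 300, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_cohort(s, p, n = 300, seed = 43)
  expect_false(identical(a$qalys, c2$qalys))

  one <- simulate_cohort(s, p, n = 1, seed = 42)
  tr <- simulate_patient(s, p, seed = 42, index = 1)
  expect_equal(one$qalys, tr$summary$qalys)
  expect_equal(one$costs$total, tr$summary$costs$total)
  expect_equal(one$lifetime_relapses, tr$summary$lifetime_relapses)

  t1 <- simulate_patient(s, p, seed = 7, index = 5)
  t2 <- simulate_patient(s, p, seed = 7, index = 5)
  expect_identical(t1, t2)
})

test_that("the vectorized engine replays exactly through the scalar cycle operations", {
  p <- synth_params()
  s <- sequence_spec(c("INFB", "OCR", "CLA", "ALE"), line1b = "GLA")
  for (idx in c(2L, 3L, 8L)) {
    tr <- simulate_patient(s, p, seed = 11, index = idx)
    U <- dmtseq:::patient_uniforms(11, idx, 71)
    st <- patient_state(age = 29,
                        edss = dmtseq:::baseline_edss_states(p, idx)[idx])
    for (t in seq_len(nrow(tr$cycles))) {
      row <- tr$cycles[t, ]
      dmt <- if (is.na(row$dmt)) NULL else get_dmt(p, row$dmt)
      expect_identical(st$line, row$line)
      out <- draw_cycle_outcome(st, dmt, p, u = U[t, ])
      expect_false(out$died)
      expect_identical(out$n_relapses, row$n_relapses)
      expect_identical(out$edss_progressed, row$progressed)
      acc <- accrue_cycle(st, out, dmt, p$economics,
                          p$natural_history$edss_levels)
      expect_equal(acc$costs$drug, row$drug_cost)
      expect_equal(acc$costs$other_healthcare, row$other_healthcare_cost)
      expect_equal(acc$qaly, row$utility)
      st <- apply_switch_rules(st, out, s, p$grammar)
    }
    expect_equal(st$cumulative_relapses, tr$summary$lifetime_relapses)
    if (!is.na(tr$summary$time_to_edss6))
      expect_equal(st$time_to_edss6, tr$summary$time_to_edss6)
  }
})

test_that("sequences with unknown efficacy or unknown price refuse to simulate", {
  p <- synth_params()
  expect_error(simulate_cohort(sequence_spec(c("RIT", "CLA", "NAT", "ALE")),
                               p, n = 10, seed = 1),
               "efficacy_cdp is unknown")
  expect_error(simulate_cohort(sequence_spec(c("UBL", "CLA", "NAT", "ALE")),
                               p, n = 10, seed = 1),
               "cost is unknown")
  # the threshold machinery's edits make the same sequences runnable
  p2 <- set_dmt_rr(p, "RIT", 0.8)
  expect_s3_class(simulate_cohort(sequence_spec(c("RIT", "CLA", "NAT", "ALE")),
                                  p2, n = 10, seed = 1), "dmtseq_cohort")
})
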