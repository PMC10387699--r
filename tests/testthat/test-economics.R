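test_that("drug cost schedules distinguish first from subsequent years", {
  d <- table1_defaults()
  expect_equal(annual_drug_cost(d$OFA, 0), 23434)
  expect_equal(annual_drug_cost(d$OFA, 1), 20086)
  expect_equal(annual_drug_cost(d$OCR, 0), 22437)
  expect_equal(annual_drug_cost(d$OCR, 12), 22437)
  expect_equal(annual_drug_cost(d$RIT, 0), 3802)
  expect_equal(annual_drug_cost(d$RIT, 3), 2535)
  expect_error(annual_drug_cost(d$OCR, -1), ">= 0")
})

test_that("discounting follows the closed form and leaves cycle zero alone", {
  expect_equal(discount(100, 0, 17), 100)
  expect_equal(discount(100, 0.04, 0), 100)
  expect_equal(discount(100, 0.04, 1), 96.1538461538462, tolerance = 1e-12)
  expect_equal(sum(discount(rep(0.782, 10), 0, 0:9)), 7.82)
  # discounted total is below the undiscounted total once accrual passes cycle 0
  x <- rep(100, 20)
  expect_lt(sum(discount(x, 0.04, 0:19)), sum(x))
  expect_error(discount(1, -0.01, 1), ">= 0")
})

test_that("cycle accrual adds utilities and costs per the stated rules", {
  p <- synth_params()
  ec <- p$economics
  lev <- p$natural_history$edss_levels
  out0 <- structure(list(n_relapses = 0, edss_progressed = FALSE,
                         edss_new = 2, adverse_event = FALSE, died = FALSE),
                    class = "cycle_outcome")
  st <- patient_state(age = 35, edss = 2)

  a <- accrue_cycle(st, out0, NULL, ec, lev)
  expect_equal(a$qaly, 0.782)
  expect_equal(a$costs$drug, 0)
  expect_equal(a$costs$total,
               a$costs$drug + a$costs$other_healthcare + a$costs$societal)

  out2 <- out0; out2$n_relapses <- 2
  ec2 <- ec; ec2$relapse_disutility <- 0.05
  b <- accrue_cycle(st, out2, NULL, ec2, lev)
  expect_equal(b$qaly, 0.782 - 0.10)
  expect_equal(b$costs$other_healthcare,
               a$costs$other_healthcare + 2 * ec$relapse_cost)

  dmt <- get_dmt(p, "OCR")
  cc <- accrue_cycle(st, out0, dmt, ec, lev)
  expect_equal(cc$costs$drug, 22437)
  expect_equal(cc$costs$other_healthcare,
               a$costs$other_healthcare + dmt$admin_cost + dmt$monitoring_cost)
})

test_that("net health benefit arithmetic matches its definition", {
  expect_equal(compute_nhb(20.6, 531115, 50000), 9.9777, tolerance = 1e-10)
  expect_equal(compute_nhb(18.5, 511369, 50000), 8.27262, tolerance = 1e-10)
  expect_equal(compute_nhb(12.3, 0, 50000), 12.3)
  expect_error(compute_nhb(10, 1000, 0), "> 0")
  # strictly decreasing in costs, increasing in QALYs
  expect_lt(compute_nhb(20, 500001, 50000), compute_nhb(20, 500000, 50000))
  expect_gt(compute_nhb(20.01, 500000, 50000), compute_nhb(20, 500000, 50000))
})

test_that("combining results by drug takes unweighted field means", {
  p <- synth_params()
  a <- simulate_cohort(ocr_first_line(), p, n = 200, seed = 1,
                       keep_patients = TRUE)
  b <- simulate_cohort(sequence_spec(c("OCR", "NAT", "CLA", "ALE")), p,
                       n = 200, seed = 1, keep_patients = TRUE)
  expect_error(combine_by_dmt(list()), "non-empty")
  single <- combine_by_dmt(list(a))
  expect_equal(single$qalys, a$qalys)
  expect_equal(single$costs$total, a$costs$total)

  comb <- combine_by_dmt(list(a, b), label = "OCR")
  expect_equal(comb$qalys, (a$qalys + b$qalys) / 2)
  expect_equal(comb$nhb, (a$nhb + b$nhb) / 2)
  # with equal cohort sizes the mean of means equals the pooled-patient mean
  pooled <- rbind(a$patients, b$patients)
  expect_equal(comb$qalys, mean(pooled$qalys))
  expect_equal(comb$costs$total, mean(pooled$cost_total))
  expect_equal(comb$lifetime_relapses, mean(pooled$relapses))
})

test_that("cohort accrual is internally additive and responds to discounting", {
  p <- synth_params()
  s <- ocr_first_line()
  r <- simulate_cohort(s, p, n = 300, seed = 9)
  expect_equal(r$costs$total,
               r$costs$drug + r$costs$other_healthcare + r$costs$societal)
  expect_equal(r$nhb, r$qalys - r$costs$total / p$economics$wtp,
               tolerance = 1e-9)
  expect_lte(r$qalys, r$life_years)

  p0 <- p
  p0$economics$discount_rate_costs <- 0
  p0$economics$discount_rate_effects <- 0
  r0 <- simulate_cohort(s, p0, n = 300, seed = 9)
  expect_lt(r$costs$total, r0$costs$total)
  expect_lt(r$qalys, r0$qalys)
  expect_equal(r$lifetime_relapses, r0$lifetime_relapses)  # dynamics unchanged
})
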