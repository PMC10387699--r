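test_that("efficacy sampling matches the lognormal CI construction", {
  # degenerate interval: always the point value
  e0 <- efficacy_estimate(0.5)
  expect_true(all(sample_efficacy(e0, 100) == 0.5))

  e <- efficacy_estimate(0.40, 0.30, 0.52)   # sigma = log(0.52/0.30)/3.92
  set.seed(1)
  x <- sample_efficacy(e, 100000)
  q <- stats::quantile(x, c(0.025, 0.5, 0.975))
  expect_equal(unname(q[1]), 0.30, tolerance = 0.02)
  expect_equal(unname(q[3]), 0.52, tolerance = 0.02)
  expect_equal(unname(q[2]), 0.40, tolerance = 0.01)
  expect_error(sample_efficacy(efficacy_unknown()), "unknown")
})

test_that("identical arms under shared streams give exactly zero differences", {
  p <- synth_params()
  s <- ocr_first_line()
  psa <- run_psa(s, s, p, n_iterations = 15, cohort_n = 150, seed = 3)
  expect_true(all(psa$iterations$delta_qaly == 0))
  expect_true(all(psa$iterations$delta_cost == 0))
  expect_equal(psa$p_a_more_qalys, 0.5)        # all ties, counted half
  expect_equal(psa$p_a_cost_effective, 0.5)
})

test_that("cost-effectiveness probability behaves at its limits", {
  fake <- function(dq, dc) structure(list(iterations = data.frame(
    delta_qaly = dq, delta_cost = dc), wtp = 50000), class = "dmtseq_psa")
  # every iteration favours arm A
  expect_equal(ce_probability(fake(rep(1, 10), rep(-5, 10))), 1)
  # symmetric differences centred on zero: 0.5 within 3 binomial SE
  set.seed(4)
  dq <- stats::rnorm(500); dc <- stats::rnorm(500, sd = 1000)
  pr <- ce_probability(fake(dq, dc), wtp = 50000)
  expect_lt(abs(pr - 0.5), 3 * sqrt(0.25 / 500))
  # wtp -> infinity reduces to the QALY comparison
  r <- fake(dq, dc)
  expect_equal(ce_probability(r, wtp = 1e18),
               mean((dq > 0) + 0.5 * (dq == 0)))
  expect_error(ce_probability(fake(numeric(), numeric())), "no iterations")
})

test_that("a strictly costlier clone with equal efficacy is never cost-effective", {
  p <- synth_params()
  # clones with degenerate CIs so both arms share every sampled input
  base <- get_dmt(p, "OCR")
  mk <- function(nm, price) {
    d <- clone_dmt(base, nm, moa = paste0("clone-", nm))
    d$efficacy_arr <- efficacy_estimate(0.40)
    d$efficacy_cdp <- efficacy_estimate(0.45, measure = "RR_CDP")
    d$annual_cost_first_year <- price
    d$annual_cost_subsequent <- price
    d
  }
  p$dmts$EXP <- mk("EXP", 30000)
  p$dmts$CHP <- mk("CHP", 10000)
  sa <- sequence_spec(c("EXP", "CLA", "NAT", "ALE"))
  sb <- sequence_spec(c("CHP", "CLA", "NAT", "ALE"))
  psa <- run_psa(sa, sb, p, n_iterations = 10, cohort_n = 100, seed = 5)
  expect_true(all(psa$iterations$delta_qaly == 0))
  expect_true(all(psa$iterations$delta_cost > 0))
  expect_equal(psa$p_a_cost_effective, 0)          # cheaper arm wins always
  expect_equal(ce_probability(psa, wtp = 10), 0)
})

test_that("collapsing all uncertainty reproduces the deterministic run", {
  p <- synth_params()
  p$psa <- list(cv_utility = 0, cv_state_cost = 0, cv_relapse_rate = 0)
  for (nm in names(p$dmts)) {
    d <- p$dmts[[nm]]
    if (!is_unknown_efficacy(d$efficacy_arr))
      d$efficacy_arr <- efficacy_estimate(d$efficacy_arr$point)
    if (!is_unknown_efficacy(d$efficacy_cdp))
      d$efficacy_cdp <- efficacy_estimate(d$efficacy_cdp$point,
                                          measure = "RR_CDP")
    p$dmts[[nm]] <- d
  }
  sa <- ocr_first_line(); sb <- ofa_first_line()
  psa <- run_psa(sa, sb, p, n_iterations = 4, cohort_n = 120, seed = 8)
  # every iteration reduces to the deterministic run at its shared seed
  for (k in 1:4) {
    sk <- dmtseq:::iteration_seed(8, k)
    det_a <- simulate_cohort(sa, p, n = 120, seed = sk)
    det_b <- simulate_cohort(sb, p, n = 120, seed = sk)
    expect_equal(psa$iterations$qalys_a[k], det_a$qalys)
    expect_equal(psa$iterations$cost_a[k], det_a$costs$total)
    expect_equal(psa$iterations$delta_qaly[k], det_a$qalys - det_b$qalys)
  }
})

test_that("PSA sampling respects the joint-draw and monotone-dispersion structure", {
  p <- synth_params()
  set.seed(11)
  pk <- dmtseq:::sample_psa_params(p)
  # monotone invariants survive sampling
  expect_true(all(diff(pk$economics$utility_by_edss) <= 0))
  expect_true(all(diff(pk$economics$state_cost_healthcare_by_edss) >= 0))
  expect_true(all(pk$natural_history$relapse_rate_by_edss >= 0))
  # widening a CI widens the sampled spread
  wide <- efficacy_estimate(0.45, 0.20, 0.95, "RR_CDP")
  narrow <- efficacy_estimate(0.45, 0.40, 0.51, "RR_CDP")
  set.seed(12)
  sw <- stats::sd(sample_efficacy(wide, 5000))
  set.seed(12)
  sn <- stats::sd(sample_efficacy(narrow, 5000))
  expect_gt(sw, sn)
})

test_that("the cost-effectiveness plane exports deterministically", {
  p <- synth_params()
  s <- ocr_first_line()
  psa <- run_psa(s, ofa_first_line(), p, n_iterations = 3, cohort_n = 80,
                 seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_ce_plane(psa, f1)
  export_ce_plane(psa, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- utils::read.csv(f1)
  expect_identical(nrow(tab), 3L)
  expect_named(tab, c("iteration", "delta_qaly", "delta_cost"))

  png_file <- withr::local_tempfile(fileext = ".png")
  export_ce_plane(psa, f1, plot_file = png_file)
  expect_true(file.exists(png_file))
})
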