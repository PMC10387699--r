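# Threshold searches run at reduced cohort sizes: parity is defined under
# common random numbers, so the solved values are stable in n.

test_that("price search returns the reference drug's own price under self-parity", {
  p <- synth_params()
  n <- 800; seed <- 5
  ref_seq <- ocr_first_line()
  ref_nhb <- sequence_nhb(ref_seq, p, n = n, seed = seed)

  cand <- clone_dmt(get_dmt(p, "OCR"), "OCRX")
  p$dmts$OCRX <- cand
  th <- find_threshold_price(cand, "1a", ref_nhb, p, tol = 0.005,
                             seed = seed, cohort_n = n,
                             sequence = sequence_spec(c("OCRX", "CLA", "NAT", "ALE")))
  expect_lte(abs(th$candidate_nhb_at_threshold - ref_nhb), th$tol)
  # NHB is affine in price: the tolerance translates into a price band
  tr <- th$search_trace
  slope <- abs(diff(tr$nhb_diff[1:2]) / diff(tr$trial[1:2]))
  expect_lte(abs(th$threshold_value - 22437), th$tol / slope + 1)
  expect_equal(th$threshold_rounded %% 100, 0)
})

test_that("price search is monotone in candidate efficacy and NHB is affine in price", {
  p <- synth_params()
  n <- 800; seed <- 5
  ref_nhb <- sequence_nhb(ocr_first_line(), p, n = n, seed = seed)

  worse <- clone_dmt(get_dmt(p, "OCR"), "OCRW")
  worse$efficacy_cdp <- efficacy_estimate(0.75, measure = "RR_CDP")
  p$dmts$OCRW <- worse
  seq_w <- sequence_spec(c("OCRW", "CLA", "NAT", "ALE"))
  th_w <- find_threshold_price(worse, "1a", ref_nhb, p, seed = seed,
                               cohort_n = n, sequence = seq_w)
  expect_lt(th_w$threshold_value, 22437)

  # three-point collinearity of NHB(price) under shared streams
  prices <- c(5000, 15000, 25000)
  nhbs <- vapply(prices, function(pr) {
    pk <- set_dmt_cost(p, "OCRW", pr, pr)
    sequence_nhb(seq_w, pk, n = n, seed = seed)
  }, 0)
  mid_pred <- (nhbs[1] + nhbs[3]) / 2
  expect_equal(nhbs[2], mid_pred, tolerance = 1e-9)
})

test_that("relative-risk search recovers the reference drug's RR under self-parity", {
  p <- synth_params()
  n <- 1200; seed <- 6
  ref_nhb <- sequence_nhb(ocr_first_line(), p, n = n, seed = seed)

  cand <- clone_dmt(get_dmt(p, "OCR"), "OCRU")
  cand$efficacy_cdp <- efficacy_unknown("RR_CDP")
  p$dmts$OCRU <- cand
  th <- find_threshold_rr(cand, "1a", ref_nhb, p, tol = 0.005, seed = seed,
                          cohort_n = n,
                          sequence = sequence_spec(c("OCRU", "CLA", "NAT", "ALE")))
  expect_lte(abs(th$candidate_nhb_at_threshold - ref_nhb), th$tol)
  expect_lt(abs(th$threshold_value - 0.45), 0.05)
  expect_equal(th$threshold_rounded, round(th$threshold_value, 2))
})

test_that("a cheaper candidate may be worse on progression: threshold RR rises with price cuts", {
  p <- synth_params()
  n <- 800; seed <- 6
  ref_nhb <- sequence_nhb(ocr_first_line(), p, n = n, seed = seed)

  cand <- clone_dmt(get_dmt(p, "RIT"), "RITX")
  p$dmts$RITX <- cand
  seq_c <- sequence_spec(c("RITX", "CLA", "NAT", "ALE"))
  th_cheap <- find_threshold_rr(cand, "1a", ref_nhb, p, seed = seed,
                                cohort_n = n, sequence = seq_c)
  # the off-label price is far below the reference: progression efficacy may
  # be worse than the reference drug's RR and still reach NHB parity
  expect_gt(th_cheap$threshold_value, 0.45)

  half <- cand
  half$annual_cost_first_year <- cand$annual_cost_first_year / 2
  half$annual_cost_subsequent <- cand$annual_cost_subsequent / 2
  p$dmts$RITX <- half
  th_half <- find_threshold_rr(half, "1a", ref_nhb, p, seed = seed,
                               cohort_n = n, sequence = seq_c)
  expect_gte(th_half$threshold_value, th_cheap$threshold_value)
})

test_that("searches fail loudly when parity is unreachable on the bracket", {
  p <- synth_params()
  cand <- clone_dmt(get_dmt(p, "OCR"), "OCRX")
  p$dmts$OCRX <- cand
  expect_error(
    find_threshold_price(cand, "1a", reference_nhb = 1e6, params = p,
                         seed = 1, cohort_n = 100,
                         sequence = sequence_spec(c("OCRX", "CLA", "NAT", "ALE"))),
    "bracket")
  expect_error(find_threshold_price(get_dmt(p, "RIT"), "1a", 0, p),
               "unknown progression efficacy|fully specified")
  expect_error(find_threshold_rr(get_dmt(p, "UBL"), "1a", 0, p),
               "known costs")
})
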