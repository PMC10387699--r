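test_that("anti-CD20 defaults carry the published efficacy and cost values", {
  d <- table1_defaults()
  expect_named(d, c("OCR", "OFA", "UBL", "RIT"))

  expect_equal(d$OCR$efficacy_arr$point, 0.40)
  expect_equal(d$OCR$efficacy_arr$ci_low, 0.30)
  expect_equal(d$OCR$efficacy_arr$ci_high, 0.52)
  expect_equal(d$OCR$efficacy_cdp$point, 0.45)
  expect_equal(d$OCR$efficacy_cdp$ci_low, 0.31)
  expect_equal(d$OCR$efficacy_cdp$ci_high, 0.61)
  expect_equal(d$OCR$annual_cost_first_year, 22437)
  expect_equal(d$OCR$annual_cost_subsequent, 22437)

  expect_equal(d$OFA$efficacy_arr$point, 0.30)
  expect_equal(d$OFA$efficacy_cdp$point, 0.55)
  expect_equal(d$OFA$annual_cost_first_year, 23434)
  expect_equal(d$OFA$annual_cost_subsequent, 20086)

  expect_equal(d$UBL$efficacy_arr$point, 0.31)
  expect_equal(d$UBL$efficacy_cdp$ci_high, 1.08)
  expect_true(is.na(d$UBL$annual_cost_first_year))

  expect_equal(d$RIT$efficacy_arr$point, 0.36)
  expect_true(is_unknown_efficacy(d$RIT$efficacy_cdp))
  expect_equal(d$RIT$annual_cost_first_year, 3802)
  expect_equal(d$RIT$annual_cost_subsequent, 2535)
})

test_that("validation reports each invariant breach, naming field and rule", {
  p <- synth_params()
  expect_identical(nrow(validate_parameters(p)), 0L)

  bad <- p
  bad$economics$utility_by_edss[4] <- bad$economics$utility_by_edss[3] + 0.05
  v <- validate_parameters(bad)
  expect_identical(nrow(v), 1L)
  expect_match(v$field, "utility_by_edss")
  expect_match(v$rule, "non-increasing")

  bad <- p
  bad$dmts$OCR$ae_discontinuation_prob <- 1.2
  v <- validate_parameters(bad)
  expect_identical(nrow(v), 1L)
  expect_match(v$field, "ae_discontinuation_prob")
  expect_match(v$rule, "\\[0, 1\\]")

  bad <- p
  bad$natural_history$transition_matrix[3, 3] <-
    bad$natural_history$transition_matrix[3, 3] - 0.02
  v <- validate_parameters(bad)
  expect_identical(nrow(v), 1L)
  expect_match(v$field, "row 3")

  bad <- p
  bad$natural_history$mortality_multiplier_by_edss[5] <- 0.8
  expect_match(validate_parameters(bad)$rule, ">= 1")
})

test_that("parameters survive a write/load round-trip", {
  p <- synth_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_parameters(p, f)
  q <- load_model_parameters(f)

  expect_identical(names(q$dmts), names(p$dmts))
  for (nm in names(p$dmts)) {
    expect_equal(q$dmts[[nm]]$efficacy_arr$point, p$dmts[[nm]]$efficacy_arr$point,
                 tolerance = 1e-12)
    expect_identical(q$dmts[[nm]]$annual_cost_first_year,
                     p$dmts[[nm]]$annual_cost_first_year)
    expect_identical(q$dmts[[nm]]$eligible_lines, p$dmts[[nm]]$eligible_lines)
  }
  expect_equal(q$natural_history$transition_matrix,
               p$natural_history$transition_matrix, tolerance = 1e-12)
  expect_equal(q$economics$utility_by_edss, p$economics$utility_by_edss,
               tolerance = 1e-12)
  expect_identical(q$cohort$n_patients, p$cohort$n_patients)
  expect_true(is_unknown_efficacy(q$dmts$RIT$efficacy_cdp))
  expect_true(is.na(q$dmts$UBL$annual_cost_first_year))
})

test_that("round-trip through a decimal-comma sidecar matrix is faithful", {
  p <- synth_params()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "params.yaml")
  write_model_parameters(p, f, transition_file = file.path(dir, "tm.csv"),
                         dialect = "comma")
  q <- load_model_parameters(f, dialect = "comma")
  expect_equal(q$natural_history$transition_matrix,
               p$natural_history$transition_matrix, tolerance = 1e-12)
})

test_that("loading fails loud on missing fields, bad rows and unknown keys", {
  p <- synth_params()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "params.yaml")

  write_model_parameters(p, f)
  doc <- yaml::read_yaml(f)
  doc$economics$wtp <- NULL
  yaml::write_yaml(doc, f)
  expect_error(load_model_parameters(f), "wtp")

  write_model_parameters(p, f)
  doc <- yaml::read_yaml(f)
  doc$natural_history$transition_matrix[[2]][[2]] <-
    doc$natural_history$transition_matrix[[2]][[2]] - 0.02
  yaml::write_yaml(doc, f)
  expect_error(load_model_parameters(f), "row 2")

  write_model_parameters(p, f)
  doc <- yaml::read_yaml(f)
  doc$economics$unexpected_key <- 1
  yaml::write_yaml(doc, f)
  expect_error(load_model_parameters(f), "unknown key.*unexpected_key")
})

test_that("efficacy estimates enforce interval ordering; helpers edit DMTs", {
  expect_error(efficacy_estimate(0.4, 0.5, 0.6), "ci_low")
  expect_error(effective_progression_prob(0.1, efficacy_unknown()), "unknown")

  p <- synth_params()
  p2 <- set_dmt_cost(p, "OCR", 10000, 9000)
  expect_equal(get_dmt(p2, "OCR")$annual_cost_first_year, 10000)
  p3 <- set_dmt_rr(p, "RIT", 0.8)
  expect_false(is_unknown_efficacy(get_dmt(p3, "RIT")$efficacy_cdp))
  expect_equal(get_dmt(p3, "RIT")$efficacy_cdp$point, 0.8)
  expect_error(get_dmt(p, "NOPE"), "unknown DMT")
})
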