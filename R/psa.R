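# Probabilistic sensitivity analysis.
#
# Parameter uncertainty is propagated by repeatedly (i) drawing one joint
# set of inputs from their uncertainty distributions and (ii) running both
# compared sequences under that same draw with common random numbers, so
# the per-iteration difference isolates the effect of the sequences.
# Distribution families follow standard health-economic practice:
# lognormal for ratio parameters (the CIs define sigma), beta for
# utilities, gamma for costs and rates, with hyperparameters moment-matched
# from the point value and a coefficient of variation.

#' Sample a treatment-effect ratio from its confidence interval
#'
#' Draws from a lognormal distribution whose median equals the point
#' estimate and whose 2.5/97.5 percentiles match the reported 95% interval:
#' `sigma = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. A degenerate
#' interval returns the point value.
#'
#' @param est An [efficacy_estimate()]; the unknown sentinel is refused.
#' @param n Number of draws.
#' @return Numeric vector of sampled ratios.
#' @export
sample_efficacy <- function(est, n = 1L) {
  if (is_unknown_efficacy(est))
    stop("cannot sample an unknown efficacy estimate")
  sigma <- (log(est$ci_high) - log(est$ci_low)) / (2 * stats::qnorm(0.975))
  if (sigma == 0) return(rep(est$point, n))
  stats::rlnorm(n, meanlog = log(est$point), sdlog = sigma)
}

# moment matching ------------------------------------------------------------

rbeta_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  v <- min(sd^2, 0.95 * mean * (1 - mean))   # keep shapes positive
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  stats::rbeta(n, a, b)
}

rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

# One joint parameter draw, applied identically to every arm. Efficacy
# ratios are lognormal from their CIs; utilities beta (monotonicity in EDSS
# restored with cummin); state costs gamma (cummax); relapse rates gamma.
# The transition matrix, relapse cost/disutility and drug prices are fixed.
sample_psa_params <- function(params) {
  cv <- params$psa
  for (nm in names(params$dmts)) {
    d <- params$dmts[[nm]]
    if (!is_unknown_efficacy(d$efficacy_arr)) {
      x <- sample_efficacy(d$efficacy_arr)
      d$efficacy_arr <- efficacy_estimate(x, x, x, "IRR_ARR")
    }
    if (!is_unknown_efficacy(d$efficacy_cdp)) {
      x <- sample_efficacy(d$efficacy_cdp)
      d$efficacy_cdp <- efficacy_estimate(x, x, x, "RR_CDP")
    }
    params$dmts[[nm]] <- d
  }
  ec <- params$economics
  if (cv$cv_utility > 0) {
    u <- vapply(ec$utility_by_edss, function(m)
      rbeta_ms(1, m, cv$cv_utility * m), 0)
    ec$utility_by_edss <- cummin(pmin(u, 1))
  }
  if (cv$cv_state_cost > 0) {
    ec$state_cost_healthcare_by_edss <- cummax(vapply(
      ec$state_cost_healthcare_by_edss, function(m)
        rgamma_ms(1, m, cv$cv_state_cost * m), 0))
    ec$state_cost_societal_by_edss <- cummax(vapply(
      ec$state_cost_societal_by_edss, function(m)
        rgamma_ms(1, m, cv$cv_state_cost * m), 0))
  }
  params$economics <- ec
  if (cv$cv_relapse_rate > 0) {
    nh <- params$natural_history
    nh$relapse_rate_by_edss <- vapply(nh$relapse_rate_by_edss, function(m)
      rgamma_ms(1, m, cv$cv_relapse_rate * m), 0)
    params$natural_history <- nh
  }
  params
}

iteration_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1000000) * 1000 + k) %% 2147483647 + 1
}

#' Run a probabilistic sensitivity analysis for two sequences
#'
#' Per iteration: one joint parameter draw is applied to both arms, and
#' both cohorts are simulated with identical patient substreams (common
#' random numbers). With arm A equal to arm B every per-iteration
#' difference is therefore exactly zero. Defaults follow the study design:
#' 500 iterations of 1000 patients.
#'
#' @param seq_a,seq_b [sequence_spec()] objects (arm A and arm B).
#' @param params A [model_parameters()] object.
#' @param n_iterations Number of parameter draws.
#' @param cohort_n Patients per cohort per iteration.
#' @param seed Integer seed; iteration k uses a substream derived from
#'   `(seed, k)`.
#' @return An object of class `dmtseq_psa`: the per-iteration table,
#'   per-arm means, standard deviations and 2.5/97.5 percentiles of costs
#'   and QALYs, the probability that arm A yields more QALYs, and the
#'   cost-effectiveness probability at the model willingness-to-pay.
#' @export
run_psa <- function(seq_a, seq_b, params, n_iterations = 500L,
                    cohort_n = 1000L, seed = 1L) {
  rows <- vector("list", n_iterations)
  for (k in seq_len(n_iterations)) {
    it_seed <- iteration_seed(seed, k)
    set.seed(it_seed)
    pk <- sample_psa_params(params)
    a <- simulate_cohort(seq_a, pk, n = cohort_n, seed = it_seed)
    b <- simulate_cohort(seq_b, pk, n = cohort_n, seed = it_seed)
    rows[[k]] <- data.frame(
      iteration = k,
      qalys_a = a$qalys, cost_a = a$costs$total,
      qalys_b = b$qalys, cost_b = b$costs$total,
      delta_qaly = a$qalys - b$qalys,
      delta_cost = a$costs$total - b$costs$total)
  }
  iterations <- do.call(rbind, rows)
  arm_summary <- function(x) c(
    mean = mean(x), sd = stats::sd(x),
    lo = unname(stats::quantile(x, 0.025)),
    hi = unname(stats::quantile(x, 0.975)))
  res <- structure(list(
    label_a = seq_a$label, label_b = seq_b$label,
    iterations = iterations,
    n_iterations = n_iterations, cohort_n = cohort_n, seed = seed,
    wtp = params$economics$wtp,
    cost_a = arm_summary(iterations$cost_a),
    cost_b = arm_summary(iterations$cost_b),
    qalys_a = arm_summary(iterations$qalys_a),
    qalys_b = arm_summary(iterations$qalys_b),
    p_a_more_qalys = tie_aware_fraction(iterations$delta_qaly)
  ), class = "dmtseq_psa")
  res$p_a_cost_effective <- ce_probability(res, params$economics$wtp)
  res
}

tie_aware_fraction <- function(x) mean((x > 0) + 0.5 * (x == 0))

#' Probability that arm A is cost-effective at a willingness-to-pay
#'
#' Fraction of PSA iterations in which the incremental net monetary
#' benefit of arm A is positive, i.e. `delta_qaly - delta_cost / wtp > 0`;
#' exact ties count one half. As `wtp` grows without bound this tends to
#' the probability that arm A yields more QALYs.
#'
#' @param result A `dmtseq_psa` object.
#' @param wtp Willingness-to-pay per QALY (Euros).
#' @return Fraction in `[0, 1]`.
#' @export
ce_probability <- function(result, wtp = result$wtp) {
  it <- result$iterations
  if (is.null(it) || nrow(it) == 0) stop("PSA result has no iterations")
  tie_aware_fraction(it$delta_qaly - it$delta_cost / wtp)
}

#' Export the cost-effectiveness plane
#'
#' Writes the per-iteration incremental QALYs and costs as a delimited
#' table, and optionally renders the scatter with the willingness-to-pay
#' line through the origin.
#'
#' @param result A `dmtseq_psa` object.
#' @param path Output CSV path.
#' @param plot_file Optional PNG path for the rendered plane.
#' @param dialect Decimal dialect of the table.
#' @return `path`, invisibly.
#' @export
export_ce_plane <- function(result, path, plot_file = NULL,
                            dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  tab <- result$iterations[, c("iteration", "delta_qaly", "delta_cost")]
  utils::write.table(tab, path,
                     sep = if (dialect == "comma") ";" else ",",
                     dec = if (dialect == "comma") "," else ".",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    plot(result)
  }
  invisible(path)
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' @param x A `dmtseq_psa` object.
#' @param wtp Willingness-to-pay line to draw (dashed).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dmtseq_psa <- function(x, wtp = x$wtp, ...) {
  it <- x$iterations
  graphics::plot(it$delta_qaly, it$delta_cost,
                 xlab = sprintf("Incremental QALYs (%s vs %s)", x$label_a, x$label_b),
                 ylab = "Incremental costs (Euros)",
                 main = "Cost-effectiveness plane", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' @export
print.dmtseq_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis\n")
  cat(sprintf("  %s vs %s: %d iterations x %d patients (seed %d)\n",
              x$label_a, x$label_b, x$n_iterations, x$cohort_n, x$seed))
  fmt <- function(s, money = TRUE) {
    f <- function(v) if (money) format(round(v), big.mark = ",") else sprintf("%.1f", v)
    sprintf("%s ± %s [%s–%s]", f(s["mean"]), f(s["sd"]), f(s["lo"]), f(s["hi"]))
  }
  cat(sprintf("  Total costs A: %s\n", fmt(x$cost_a)))
  cat(sprintf("  Total costs B: %s\n", fmt(x$cost_b)))
  cat(sprintf("  Total QALYs A: %s\n", fmt(x$qalys_a, money = FALSE)))
  cat(sprintf("  Total QALYs B: %s\n", fmt(x$qalys_b, money = FALSE)))
  se <- sqrt(x$p_a_cost_effective * (1 - x$p_a_cost_effective) / x$n_iterations)
  cat(sprintf("  P(A more QALYs) = %.3f; P(A cost-effective at %s/QALY) = %.3f (binomial SE %.3f)\n",
              x$p_a_more_qalys, format(x$wtp, big.mark = ","),
              x$p_a_cost_effective, se))
  invisible(x)
}
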