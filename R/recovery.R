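# Re-estimating treatment effects from simulated patient-cycle data.

#' Recover treatment-effect ratios from pooled patient-cycles
#'
#' Internal-consistency check for the engine: given a per-cycle trajectory
#' dump, re-estimates (a) the incidence rate ratio of the annualized
#' relapse rate, from a Poisson regression of relapse counts on an offset
#' of the natural-history rate for the occupied EDSS state, and (b) the
#' relative risk of disability progression, from a binomial
#' complementary-log-log regression of the any-worsening indicator on an
#' offset of the natural-history cumulative worsening hazard (the
#' rate-scaling model `1 - exp(RR * log(1 - p))` is exactly a cloglog
#' model with that offset). Only cycles spent on the named drug are used.
#'
#' @param trajectories Per-cycle table from
#'   `simulate_cohort(..., keep_trajectories = TRUE)`.
#' @param params The [model_parameters()] used for the simulation.
#' @param dmt_name Drug whose effects are estimated.
#' @param level Confidence level for the Wald intervals.
#' @return List with elements `irr` and `rr_cdp`, each
#'   `c(estimate, lower, upper)`, and the patient-cycle count used.
#' @export
recover_efficacy <- function(trajectories, params, dmt_name, level = 0.95) {
  tr <- trajectories[!is.na(trajectories$dmt) & trajectories$dmt == dmt_name, ]
  if (nrow(tr) == 0) stop("no patient-cycles on ", dmt_name)
  nh <- params$natural_history
  K <- length(nh$edss_levels)
  s_idx <- match(tr$edss, nh$edss_levels)

  z <- stats::qnorm(1 - (1 - level) / 2)
  wald <- function(fit) {
    co <- summary(fit)$coefficients
    exp(co[1, 1] + c(0, -z, z) * co[1, 2])[c(1, 2, 3)]
  }

  base_rate <- nh$relapse_rate_by_edss[s_idx]
  fit_irr <- stats::glm(tr$n_relapses ~ 1, family = stats::poisson(),
                        offset = log(base_rate))
  irr <- wald(fit_irr)

  wmass <- vapply(seq_len(K), function(i)
    if (i < K) sum(nh$transition_matrix[i, (i + 1L):K]) else 0, 0)
  w <- wmass[s_idx]
  keep <- w > 0
  fit_rr <- stats::glm(tr$progressed[keep] ~ 1,
                       family = stats::binomial(link = "cloglog"),
                       offset = log(-log1p(-w[keep])))
  rr <- wald(fit_rr)

  list(irr = stats::setNames(irr, c("estimate", "lower", "upper")),
       rr_cdp = stats::setNames(rr, c("estimate", "lower", "upper")),
       n_cycles = nrow(tr))
}
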