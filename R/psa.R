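#' Scenario specification
#'
#' One row of the scenario grid: cost assumptions, horizon, CAC treatment
#' threshold, outcome definition, valuation of effects, event-rate
#' multiplier and cost-inclusion flags.
#'
#' @param cac_cost Mean CAC scan cost (USD; published grid uses 75/100/150/250).
#' @param statin_cost Mean annual statin cost (USD; 50/180/1000).
#' @param horizon 5 or 10 years.
#' @param treat_threshold `"ge1"` (treat any CAC) or `"ge100"`.
#' @param outcome `"CHD"` or `"CVD"`.
#' @param valuation `"events"` or `"qalys"`.
#' @param rate_multiplier 1 (base) or 2 (elevated-event-rate sensitivity).
#' @param include_indirect,include_incidentaloma Cost-inclusion flags.
#' @export
scenario_spec <- function(cac_cost = 100, statin_cost = 180, horizon = 5,
                          treat_threshold = c("ge1", "ge100"),
                          outcome = c("CHD", "CVD"),
                          valuation = c("events", "qalys"),
                          rate_multiplier = 1, include_indirect = FALSE,
                          include_incidentaloma = FALSE) {
  treat_threshold <- match.arg(treat_threshold)
  outcome <- match.arg(outcome)
  valuation <- match.arg(valuation)
  stopifnot(horizon %in% c(5, 10), cac_cost >= 0, statin_cost >= 0,
            rate_multiplier > 0)
  structure(list(cac_cost = cac_cost, statin_cost = statin_cost,
                 horizon = horizon, treat_threshold = treat_threshold,
                 outcome = outcome, valuation = valuation,
                 rate_multiplier = rate_multiplier,
                 include_indirect = include_indirect,
                 include_incidentaloma = include_incidentaloma),
            class = "scenario_spec")
}

scenario_strategies <- function(spec) {
  c("atp3", "treat_all",
    if (spec$treat_threshold == "ge1") "cac_ge1" else "cac_ge100")
}

scenario_ps <- function(spec, ...) {
  build_parameter_set(list(cost_cac_test = spec$cac_cost,
                           cost_statin_annual = spec$statin_cost), ...)
}

#' Evaluate one scenario
#'
#' Runs ATP III, treat-all and the scenario's CAC strategy on a shared
#' cohort (the exact published composition by default), and returns
#' per-strategy costs and effects (per 1,000 patients) plus the decision
#' label.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (cohort ages and any stochastic draws).
#' @param cohort Optional pre-built cohort; defaults to the exact n=1,619
#'   composition with the default age model.
#' @param engine `"expected_value"` (deterministic; used for decision
#'   labels) or `"microsimulation"`.
#' @param threshold Willingness-to-pay per unit effect for the label.
#' @param ps Optional parameter set (defaults to base case with the
#'   scenario's cost overrides).
#' @return A `scenario_result`: list with `spec`, `outcomes`, `costs`,
#'   `effects` (named per strategy, per 1,000) and `decision`.
#' @export
run_scenario <- function(spec, seed, cohort = NULL, engine = "expected_value",
                         threshold = 50000, ps = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(ps)) ps <- scenario_ps(spec)
  if (is.null(cohort)) {
    cohort <- generate_cohort(sum(mesa_joint_table()), seed = seed,
                              mode = "exact")
  }
  strategies <- scenario_strategies(spec)
  outcomes <- lapply(strategies, function(s) {
    run_strategy(cohort, s, ps, spec$horizon, spec$outcome,
                 spec$rate_multiplier, mode = engine, seed = seed)
  })
  names(outcomes) <- strategies
  costs <- vapply(outcomes, function(o) {
    accrue_costs(o, spec$include_indirect, spec$include_incidentaloma) * 1000 / o$n
  }, numeric(1))
  effects <- vapply(outcomes, outcome_effect, numeric(1),
                    valuation = spec$valuation)
  structure(list(spec = spec, outcomes = outcomes, costs = costs,
                 effects = effects,
                 decision = decision_label(costs, effects, threshold)),
            class = "scenario_result")
}

#' The published 52-scenario grid
#'
#' Rows 1-36 use base-case event rates (rows 18 and 36 add indirect costs
#' and the incidentaloma penalty); rows 37-52 use 2x event rates.
#'
#' @return Data frame keyed by `scenario` with one column per
#'   [scenario_spec()] field.
#' @export
default_scenario_grid <- function() {
  base16 <- function(outcome, first) {
    data.frame(
      scenario = first + 0:17,
      outcome = outcome,
      cac_cost = c(rep(100, 12), 75, 75, 150, 150, 250, 100),
      statin_cost = c(rep(180, 8), 50, 50, 1000, 1000, rep(180, 6)),
      horizon = c(5, 5, 5, 5, 10, 10, 10, 10, rep(5, 10)),
      treat_threshold = c("ge1", "ge1", "ge100", "ge100",
                          "ge1", "ge1", "ge100", "ge100",
                          "ge1", "ge1", "ge1", "ge100",
                          "ge1", "ge100", "ge1", "ge100", "ge1", "ge1"),
      valuation = c("events", "qalys", "events", "qalys",
                    "events", "qalys", "events", "qalys",
                    "events", rep("qalys", 9)),
      rate_multiplier = 1,
      include_indirect = c(rep(FALSE, 17), TRUE),
      include_incidentaloma = c(rep(FALSE, 17), TRUE)
    )
  }
  twox8 <- function(outcome, first) {
    data.frame(
      scenario = first + 0:7,
      outcome = outcome,
      cac_cost = 100, statin_cost = 180,
      horizon = rep(c(5, 5, 5, 5, 10, 10, 10, 10), 1),
      treat_threshold = rep(c("ge1", "ge1", "ge100", "ge100"), 2),
      valuation = rep(c("events", "qalys"), 4),
      rate_multiplier = 2,
      include_indirect = FALSE, include_incidentaloma = FALSE
    )
  }
  rbind(base16("CHD", 1), base16("CVD", 19), twox8("CHD", 37), twox8("CVD", 45))
}

#' Run a grid of scenarios
#'
#' @param grid Data frame of scenario fields (see [default_scenario_grid()]);
#'   an empty grid returns an empty table.
#' @param seed Integer seed (one shared cohort age draw per rate basis).
#' @param engine Engine mode passed to [run_scenario()].
#' @param threshold Willingness-to-pay per unit effect.
#' @return Data frame: one row per scenario with per-strategy costs and
#'   effects (per 1,000) and the decision label.
#' @export
run_scenario_grid <- function(grid = default_scenario_grid(), seed = 1,
                              engine = "expected_value", threshold = 50000) {
  cols <- c("scenario", "decision", "cost_atp3", "cost_treat_all", "cost_cac",
            "effect_atp3", "effect_treat_all", "effect_cac")
  if (nrow(grid) == 0) {
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  cohort <- generate_cohort(sum(mesa_joint_table()), seed = seed, mode = "exact")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    spec <- scenario_spec(g$cac_cost, g$statin_cost, g$horizon,
                          g$treat_threshold, g$outcome, g$valuation,
                          g$rate_multiplier, g$include_indirect,
                          g$include_incidentaloma)
    res <- run_scenario(spec, seed = seed, cohort = cohort, engine = engine,
                        threshold = threshold)
    cac_name <- setdiff(names(res$costs), c("atp3", "treat_all"))
    data.frame(scenario = g$scenario, decision = res$decision,
               cost_atp3 = res$costs[["atp3"]],
               cost_treat_all = res$costs[["treat_all"]],
               cost_cac = res$costs[[cac_name]],
               effect_atp3 = res$effects[["atp3"]],
               effect_treat_all = res$effects[["treat_all"]],
               effect_cac = res$effects[[cac_name]])
  })
  do.call(rbind, rows)
}

#' Probabilistic sensitivity analysis
#'
#' For each simulation: one parameter set sampled from the registered
#' distributions, one cohort resampled from the joint classification table,
#' and all strategies evaluated with common random numbers (the same
#' patient-level uniform streams across strategies, so adherent sets are
#' nested and event draws are shared).
#'
#' @param spec A [scenario_spec()].
#' @param n_sims Number of simulations (published analysis: 1,000).
#' @param n_patients Patients per simulation (published analysis: 2,000).
#' @param seed Master seed; per-simulation seeds are derived from it.
#' @param engine `"microsimulation"` (default, matching the published
#'   design) or `"expected_value"` (parameter + cohort-composition
#'   uncertainty only).
#' @param age_model Baseline age model.
#' @param common_random_numbers Set `FALSE` to give every strategy an
#'   independent uniform stream (for variance-reduction experiments).
#' @return A `psa_result`: `sims` (sim x strategy costs/effects per 1,000),
#'   `means`, and the scenario `spec`.
#' @export
run_psa <- function(spec, n_sims = 1000, n_patients = 2000, seed = 1,
                    engine = c("microsimulation", "expected_value"),
                    age_model = cacCEA::age_model(),
                    common_random_numbers = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "scenario_spec"), n_sims > 0, n_patients > 0)
  base_ps <- scenario_ps(spec)
  strategies <- scenario_strategies(spec)
  sim_seeds <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(.Machine$integer.max - 1L, n_sims * 3L), ncol = 3L)
  })
  rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    ps_s <- sample_parameter_set(base_ps, seed = sim_seeds[s, 1])
    coh <- generate_cohort(n_patients, age_model = age_model,
                           seed = sim_seeds[s, 2], mode = "sampling")
    strat_rows <- lapply(seq_along(strategies), function(j) {
      crn_seed <- if (common_random_numbers) sim_seeds[s, 3] else
        sim_seeds[s, 3] + j
      crn <- make_crn(n_patients, spec$horizon, crn_seed)
      o <- run_strategy(coh, strategies[j], ps_s, spec$horizon, spec$outcome,
                        spec$rate_multiplier, mode = engine, crn = crn)
      data.frame(
        sim = s, strategy = strategies[j],
        cost = accrue_costs(o, spec$include_indirect,
                            spec$include_incidentaloma) * 1000 / o$n,
        effect = outcome_effect(o, spec$valuation),
        events_per_1000 = unname(o$events_per_1000["total"]),
        qalys_per_1000 = o$disc_qalys_per_1000
      )
    })
    rows[[s]] <- do.call(rbind, strat_rows)
  }
  sims <- do.call(rbind, rows)
  means <- stats::aggregate(cbind(cost, effect) ~ strategy, sims, mean)
  structure(list(sims = sims, means = means, spec = spec,
                 n_sims = n_sims, n_patients = n_patients, engine = engine),
            class = "psa_result")
}

#' Break-even CAC test cost
#'
#' Bisection on the mean CAC test cost for the point at which the CAC
#' strategy's total discounted cost equals the ATP III strategy's (the
#' boundary where CAC testing stops being cost-saving). Uses the
#' deterministic expected-value engine on a fixed cohort, so the incremental
#' cost is a monotone increasing function of the test cost.
#'
#' @param spec Scenario to hold fixed while the CAC cost varies; defaults
#'   to the base case (180 USD statins, 5-year CVD horizon, treat CAC >= 1).
#' @param lower,upper Bracketing test costs (USD).
#' @param tol Absolute tolerance (USD).
#' @param seed Seed for the cohort age draw.
#' @return The break-even cost (USD per test).
#' @export
find_breakeven_cac_cost <- function(spec = scenario_spec(outcome = "CVD",
                                                         valuation = "qalys"),
                                    lower = 0, upper = 500, tol = 0.5,
                                    seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"), lower < upper, tol > 0)
  cohort <- generate_cohort(sum(mesa_joint_table()), seed = seed, mode = "exact")
  delta_cost <- function(cac_cost) {
    s <- spec
    s$cac_cost <- cac_cost
    res <- run_scenario(s, seed = seed, cohort = cohort,
                        engine = "expected_value")
    cac_name <- setdiff(names(res$costs), c("atp3", "treat_all"))
    res$costs[[cac_name]] - res$costs[["atp3"]]
  }
  f_lo <- delta_cost(lower)
  f_hi <- delta_cost(upper)
  if (sign(f_lo) == sign(f_hi)) {
    stop("no break-even point in [", lower, ", ", upper, "]: incremental ",
         "cost is ", if (f_hi < 0) "negative" else "positive",
         " at both bounds")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (sign(delta_cost(mid)) == sign(f_lo)) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario: %s %dy %s, CAC $%d, statin $%d, %sx rates>\n",
              x$spec$outcome, x$spec$horizon, x$spec$valuation,
              x$spec$cac_cost, x$spec$statin_cost, x$spec$rate_multiplier))
  df <- data.frame(cost_per_1000 = round(x$costs),
                   effect_per_1000 = round(x$effects, 2))
  print(df)
  cat("decision:", x$decision, "\n")
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d sims x %d patients, %s engine>\n",
              x$n_sims, x$n_patients, x$engine))
  print(x$means)
  invisible(x)
}
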