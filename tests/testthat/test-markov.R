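# Untreated cohort helper: run one strategy with nobody recommended so the
# engine's event accrual can be checked against closed forms.
run_untreated <- function(coh, ps, horizon, outcome, mode = "expected_value",
                          seed = 1) {
  run_strategy(coh, "atp3", ps, horizon, outcome, mode = mode, seed = seed)
}

test_that("cycle utility values match the published anchors and taper", {
  ps <- build_parameter_set()
  expect_equal(qaly_cycle_value(60, "healthy", ps), 0.82)
  expect_equal(qaly_cycle_value(60, "post_event_year1", ps, "CHD"),
               0.82 * 0.8351) # 0.684782
  expect_equal(qaly_cycle_value(60, "post_event_year2", ps, "CHD"),
               0.82 * (1 + 0.8351) / 2) # 0.752391
  expect_equal(qaly_cycle_value(60, "dead_event", ps), 0)
  expect_equal(qaly_cycle_value(60, "healthy", ps, on_statin = TRUE),
               0.82 * 0.99616)
  expect_equal(qaly_cycle_value(60, "healthy", ps, on_statin = TRUE,
                                mild_ae = TRUE, sae_year = TRUE),
               0.82 * 0.99616 * 0.9941 * 0.9553)
})

test_that("annual transition: absorbing states and zero hazards", {
  ps <- ps_no_mortality()
  healthy <- list(state = "healthy", on_statin = FALSE, mild_ae = FALSE,
                  sae_year = FALSE)
  out <- annual_transition(healthy, 0, 1, ps, 60, u = c(0.999999, 0.5))
  expect_equal(out$state, "healthy")
  dead <- list(state = "dead_other", on_statin = FALSE)
  expect_equal(annual_transition(dead, 0.5, 0.5, ps, 60)$state, "dead_other")
  # post-event states advance and never revert
  pe <- list(state = "post_event_year1", on_statin = FALSE)
  expect_equal(annual_transition(pe, 0.9, 1, ps, 60, u = c(0.9, 0.5))$state,
               "post_event_year2")
  # a guaranteed event with a sub-uniform under the case fatality is fatal
  ev <- annual_transition(healthy, 0.999, 1, ps, 60, u = c(1e-9, 0.01))
  expect_true(ev$event && ev$fatal_event)
  expect_error(annual_transition(healthy, 1.2, 1, ps, 60), "corrupted")
})

test_that("5-cycle cumulative event probability matches the closed form", {
  p <- 0.01920450 # high-stratum CVD annual risk
  ps <- ps_no_mortality(list(p_severe_ae = 0))
  coh <- single_stratum_cohort(1000, "high", age = 55)
  out <- run_untreated(coh, ps, 5, "CVD")
  expect_equal(unname(out$events_per_1000["total"]) / 1000,
               1 - (1 - p)^5, tolerance = 1e-12) # ~ 0.09243
})

test_that("zero hazards: no events; QALYs equal the discounted utility sum", {
  ps <- ps_no_mortality(list(p_severe_ae = 0))
  coh <- single_stratum_cohort(1, "zero", age = 60)
  coh_run <- assign_event_hazards(coh, c(zero = 0, low = 0, high = 0), "CVD")
  asg <- assign_treatment(coh_run, "atp3", ps, seed = 1)
  out <- run_cohort(coh_run, asg, ps, 5, "CVD")
  expect_equal(unname(out$events_per_1000["total"]), 0)
  # aging-aware closed form: u(60..64) discounted at 3%, first year undiscounted
  oracle <- sum(healthy_utility(60:64, ps) * 1.03^(-(0:4)))
  expect_equal(out$disc_qalys, oracle, tolerance = 1e-12)
  expect_equal(accrue_costs(out, TRUE, TRUE), 0)
})

test_that("5 on-statin years at $180 discount to $849.08", {
  ps <- ps_no_mortality(list(p_severe_ae = 0, adherence_no_cac = 1))
  coh <- single_stratum_cohort(1, "zero", eligible = TRUE, age = 60)
  coh_run <- assign_event_hazards(coh, c(zero = 0, low = 0, high = 0), "CVD")
  asg <- assign_treatment(coh_run, "atp3", ps, seed = 1)
  out <- run_cohort(coh_run, asg, ps, 5, "CVD")
  geometric <- 180 * sum(1.03^(-(0:4)))
  expect_equal(out$cost_components[["statin_annual"]], geometric,
               tolerance = 1e-12)
  expect_equal(round(geometric, 2), 849.08)
})

test_that("a fatal event contributes no QALYs from its cycle onward", {
  ps <- ps_no_mortality(list(cf_cvd_lt65 = 1)) # every event fatal under 65
  coh <- single_stratum_cohort(1, "high", age = 50)
  coh$annual_event_risk <- 1 - 1e-12 # event certain in cycle 0
  asg <- assign_treatment(coh, "atp3", ps, seed = 1)
  out <- run_cohort(coh, asg, ps, 5, "CVD")
  expect_equal(out$disc_qalys, 0, tolerance = 1e-6)
  expect_equal(unname(out$events_per_1000["fatal"]), 1000, tolerance = 1e-6)
})

test_that("state occupancy is conserved every cycle in both modes", {
  ps <- build_parameter_set()
  coh <- mesa_cohort(seed = 7)
  states <- c("healthy", "post_event_year1", "post_event_year2",
              "post_event_later", "dead_event", "dead_other",
              "dead_statin_ae", "dead_radiation")
  for (mode in c("expected_value", "microsimulation")) {
    out <- run_strategy(coh, "cac_ge1", ps, 10, "CVD", mode = mode, seed = 8)
    occ <- rowSums(out$cycle_trace[, states])
    expect_equal(occ, rep(1619, 10), tolerance = 1e-9)
    # fatal + nonfatal = total
    e <- out$events_per_1000
    expect_equal(unname(e["fatal"] + e["nonfatal"]), unname(e["total"]))
    expect_gte(out$disc_qalys, 0)
  }
})

test_that("microsimulation means agree with expected value within 3 SE", {
  ps <- build_parameter_set()
  n <- 1e5
  coh <- generate_cohort(n, seed = 12, mode = "sampling")
  for (s in c("atp3", "cac_ge1")) {
    ev <- run_strategy(coh, s, ps, 5, "CVD", mode = "expected_value", seed = 1)
    ms <- run_strategy(coh, s, ps, 5, "CVD", mode = "microsimulation", seed = 13)
    p <- ev$events_per_1000[["total"]] / 1000
    se <- 1000 * sqrt(p * (1 - p) / n)
    expect_lt(abs(ms$events_per_1000[["total"]] - ev$events_per_1000[["total"]]),
              3 * se)
    expect_lt(abs(ms$disc_qalys_per_1000 / ev$disc_qalys_per_1000 - 1), 0.01)
    expect_lt(abs(accrue_costs(ms) / accrue_costs(ev) - 1), 0.05)
  }
})

test_that("events are monotone in relative risk and adherence", {
  coh <- mesa_cohort(seed = 9)
  ev_total <- function(overrides) {
    ps <- build_parameter_set(overrides)
    run_strategy(coh, "cac_ge1", ps, 5, "CVD",
                 mode = "expected_value", seed = 1)$events_per_1000[["total"]]
  }
  base <- ev_total(list())
  expect_lt(ev_total(list(rr_moderate = 0.5, rr_intensive = 0.4)), base)
  expect_gt(ev_total(list(rr_moderate = 0.9, rr_intensive = 0.8)), base)
  expect_lt(ev_total(list(adherence_cac = 0.9)), base)
  expect_gt(ev_total(list(adherence_cac = 0.3)), base)
  # with no treatment benefit, all strategies project identical event counts
  ps1 <- build_parameter_set(list(rr_moderate = 1, rr_intensive = 1,
                                  p_severe_ae = 0))
  evs <- vapply(c("atp3", "treat_all", "cac_ge100"), function(s)
    run_strategy(coh, s, ps1, 5, "CHD", mode = "expected_value",
                 seed = 1)$events_per_1000[["total"]], numeric(1))
  # identical up to the (tiny) scan-radiation competing-risk pathway
  expect_lt(max(evs) - min(evs), 1e-3)
})

test_that("doubling the discount rate lowers discounted QALYs and costs", {
  coh <- mesa_cohort(seed = 10)
  run_r <- function(r) {
    ps <- build_parameter_set(list(discount_rate = r))
    run_strategy(coh, "treat_all", ps, 10, "CVD",
                 mode = "expected_value", seed = 1)
  }
  lo <- run_r(0.03)
  hi <- run_r(0.06)
  expect_lt(hi$disc_qalys, lo$disc_qalys)
  expect_lt(accrue_costs(hi, TRUE, TRUE), accrue_costs(lo, TRUE, TRUE))
  expect_lt(hi$disc_events_per_1000, lo$disc_events_per_1000)
  # undiscounted event counts are unaffected by the discount rate
  expect_equal(hi$events_per_1000, lo$events_per_1000)
})

test_that("untreated per-stratum event fractions calibrate to the source rates", {
  ps <- build_parameter_set()
  for (s in cac_strata()) {
    rate <- event_rates(ps, "CVD", 5)[[s]]
    coh <- single_stratum_cohort(1000, s, age = 55)
    out <- run_untreated(coh, ps, 5, "CVD")
    closed <- 1 - (1 - rate)^5
    frac <- out$events_per_1000[["total"]] / 1000
    # background mortality only attritions events downward, by a few percent
    expect_lte(frac, closed + 1e-12)
    expect_gt(frac, closed * 0.95)
  }
})

test_that("horizon and hazard preconditions are enforced", {
  ps <- build_parameter_set()
  coh <- mesa_cohort(seed = 1)
  hz <- assign_event_hazards(coh, ps, "CVD", 5)
  asg <- assign_treatment(hz, "atp3", ps, seed = 1)
  expect_error(run_cohort(hz, asg, ps, horizon = 7), "horizon")
  expect_silent(run_cohort(hz, asg, ps, horizon = 3, allow_any_horizon = TRUE))
  expect_error(run_cohort(coh, asg, ps, horizon = 5), "hazards")
  expect_error(run_cohort(hz, asg, ps, 5, mode = "microsimulation"), "seed")
})

test_that("cycle traces export as readable long-format text", {
  ps <- build_parameter_set()
  out <- run_strategy(mesa_cohort(seed = 1), "cac_ge1", ps, 5, "CHD",
                      mode = "expected_value", seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(out, path)
  back <- utils::read.delim(path)
  expect_equal(sort(unique(back$state)),
               sort(c(model_states <- c("healthy", "post_event_year1",
                                        "post_event_year2", "post_event_later",
                                        "dead_event", "dead_other",
                                        "dead_statin_ae", "dead_radiation"),
                      "qalys_disc")))
  occ0 <- back$occupancy[back$cycle == 0 & back$state != "qalys_disc"]
  expect_equal(sum(occ0), 1619) # full cohort accounted for in cycle 0
  healthy0 <- back$occupancy[back$state == "healthy" & back$cycle == 0]
  expect_gt(healthy0, 1550) # all but first-cycle events and deaths
})
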