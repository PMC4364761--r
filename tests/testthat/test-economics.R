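test_that("event direct costs enter the ledger at their published values", {
  ps <- ps_no_mortality(list(cf_chd_lt65 = 0, p_severe_ae = 0))
  # one untreated patient with a certain nonfatal CHD event in cycle 0
  coh <- single_stratum_cohort(1, "high", age = 50)
  coh$annual_event_risk <- 1 - 1e-12
  asg <- assign_treatment(coh, "atp3", ps, seed = 1)
  out <- run_cohort(coh, asg, ps, 5, "CHD")
  # event in the first (undiscounted) cycle: cost is the raw $64,400
  expect_equal(out$cost_components[["event_direct"]], 64400, tolerance = 1e-6)
  # untreated, never-event, no-CAC patient accrues no cost at all
  coh0 <- single_stratum_cohort(1, "zero", age = 50)
  coh0 <- assign_event_hazards(coh0, c(zero = 0, low = 0, high = 0), "CHD")
  out0 <- run_cohort(coh0, assign_treatment(coh0, "atp3", ps, seed = 1), ps, 5)
  expect_equal(accrue_costs(out0, TRUE, TRUE), 0)
})

test_that("cost-inclusion flags only ever add components", {
  ps <- build_parameter_set()
  out <- run_strategy(mesa_cohort(seed = 1), "cac_ge1", ps, 5, "CVD",
                      mode = "expected_value", seed = 1)
  base <- accrue_costs(out)
  expect_gt(accrue_costs(out, include_incidentaloma = TRUE), base)
  expect_gt(accrue_costs(out, include_indirect = TRUE), base)
  expect_equal(accrue_costs(out, TRUE, TRUE),
               base + out$cost_components[["incidentaloma"]] +
                 out$cost_components[["productivity_event"]] +
                 out$cost_components[["cac_time_cost"]])
  # incidentaloma penalty is the expected per-patient re-scan cost
  expect_equal(out$cost_components[["incidentaloma"]], 1619 * 0.08 * 250)
  expect_equal(out$cost_components[["cac_test"]], 1619 * 100)
})

test_that("pairwise comparison classifies dominance and thresholds correctly", {
  mk <- function(cost, effect) list(cost = cost, effect = effect)
  r <- compare_strategies(mk(90, 10.5), mk(100, 10))
  expect_equal(r$classification, "dominant")
  expect_true(is.na(r$icer))
  r2 <- compare_strategies(mk(1100, 10.1), mk(100, 10))
  expect_equal(r2$icer, 10000)
  expect_equal(r2$classification, "cost_effective_at_threshold")
  r3 <- compare_strategies(mk(6100, 10.1), mk(100, 10))
  expect_equal(r3$icer, 60000)
  expect_equal(r3$classification, "not_cost_effective")
})

test_that("comparison is antisymmetric under swapping the strategies", {
  mk <- function(cost, effect) list(cost = cost, effect = effect)
  set.seed(21)
  for (i in 1:20) {
    a <- mk(runif(1, 0, 1e6), runif(1, -50, 50))
    b <- mk(runif(1, 0, 1e6), runif(1, -50, 50))
    ab <- compare_strategies(a, b)
    ba <- compare_strategies(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_effect, -ba$delta_effect)
    if (ab$classification == "dominant") {
      expect_equal(ba$classification, "dominated")
    }
  }
})

test_that("CEAC matches a brute-force oracle and sums to one", {
  # three hand-written simulations, three strategies
  sims <- expand.grid(sim = 1:3, strategy = c("a", "b", "c"))
  sims$cost <- c(100, 120, 90, 150, 110, 130, 200, 100, 95)
  sims$effect <- c(1.0, 1.1, 0.9, 1.4, 1.0, 1.2, 1.3, 0.9, 1.0)
  grid <- c(0, 40, 100, 1000)
  curve <- ceac(sims, grid)
  # independent oracle: enumerate every (simulation, threshold) pair
  for (l in grid) {
    for (s in c("a", "b", "c")) {
      wins <- 0
      for (i in 1:3) {
        sub <- sims[sims$sim == i, ]
        nmb <- l * sub$effect - sub$cost
        top <- which(nmb == max(nmb))
        if (match(s, sub$strategy) %in% top) wins <- wins + 1 / length(top)
      }
      got <- curve$acceptance[curve$wtp == l & curve$strategy == s]
      expect_equal(got, wins / 3)
    }
  }
  sums <- tapply(curve$acceptance, curve$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(grid)))
  # degenerate cases
  one <- sims[sims$strategy == "a", ]
  expect_true(all(ceac(one, grid)$acceptance == 1))
  expect_error(ceac(sims[0, ], grid), "nrow")
})

test_that("at zero willingness-to-pay the cheapest strategy is accepted", {
  sims <- expand.grid(sim = 1:4, strategy = c("x", "y"))
  sims$cost <- c(10, 10, 10, 10, 20, 20, 20, 20) # x always cheapest
  sims$effect <- c(0, 0, 0, 0, 5, 5, 5, 5)
  curve <- ceac(sims, 0)
  expect_equal(curve$acceptance[curve$strategy == "x"], 1)
  # with equal costs, positive thresholds decide purely on effects
  sims$cost <- 10
  curve2 <- ceac(sims, 1)
  expect_equal(curve2$acceptance[curve2$strategy == "y"], 1)
})

test_that("decision labels reproduce the published vocabulary", {
  # CAC cheaper and more effective than both
  expect_equal(decision_label(
    costs = c(atp3 = 100, treat_all = 110, cac_ge1 = 90),
    effects = c(atp3 = 1, treat_all = 1.2, cac_ge1 = 1.3)),
    "CAC Dominates Both")
  # all alternatives above the threshold
  expect_equal(decision_label(
    costs = c(atp3 = 100, treat_all = 200, cac_ge1 = 210),
    effects = c(atp3 = 1, treat_all = 1.001, cac_ge1 = 1.001)),
    "ATP III (Status Quo)")
  # treat-all cheaper and more effective than ATP III only
  expect_equal(decision_label(
    costs = c(atp3 = 100, treat_all = 95, cac_ge100 = 90),
    effects = c(atp3 = 1, treat_all = 1.5, cac_ge100 = 0.9)),
    "Treat All Dominates ATP III")
  # within threshold: cost-effective with an ICER
  lab <- decision_label(
    costs = c(atp3 = 100, treat_all = 150, cac_ge100 = 160),
    effects = c(atp3 = 1, treat_all = 1.1, cac_ge100 = 1.05))
  expect_match(lab, "^Treat All Cost-Effective; ICER = \\$500$")
})
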