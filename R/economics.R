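#' Total discounted cost of a strategy outcome
#'
#' Sums the discounted cost ledger. Base-case costs comprise the CAC test,
#' annual statins, event direct medical costs and statin-complication costs.
#' Productivity costs (events and scan time) and the incidentaloma re-scan
#' penalty are sensitivity-analysis components included via flags.
#'
#' @param outcome A `strategy_outcome` from [run_cohort()].
#' @param include_indirect Include event productivity costs and the CAC
#'   scan time cost.
#' @param include_incidentaloma Include the expected re-scan penalty
#'   (fraction of scanned patients times follow-up cost).
#' @return Total discounted 2011 USD for the whole cohort.
#' @export
accrue_costs <- function(outcome, include_indirect = FALSE,
                         include_incidentaloma = FALSE) {
  stopifnot(inherits(outcome, "strategy_outcome"))
  cc <- outcome$cost_components
  total <- cc[["cac_test"]] + cc[["statin_annual"]] + cc[["event_direct"]] +
    cc[["ae_mild"]] + cc[["ae_severe"]]
  if (include_incidentaloma) total <- total + cc[["incidentaloma"]]
  if (include_indirect) {
    total <- total + cc[["productivity_event"]] + cc[["cac_time_cost"]]
  }
  total
}

# Effect of an outcome under a valuation, per 1,000 patients, oriented so
# that larger is better: averted events enter as minus the (discounted)
# event count; QALYs enter as discounted QALYs.
outcome_effect <- function(outcome, valuation = c("events", "qalys"),
                           discount_events = TRUE) {
  valuation <- match.arg(valuation)
  if (valuation == "qalys") {
    outcome$disc_qalys_per_1000
  } else if (discount_events) {
    -outcome$disc_events_per_1000
  } else {
    -unname(outcome$events_per_1000["total"])
  }
}

#' Pairwise incremental comparison of two strategies
#'
#' Computes incremental cost and effect of `a` relative to `b` (per 1,000
#' patients), classifies dominance, and otherwise reports the incremental
#' cost-effectiveness ratio and the decision at a willingness-to-pay
#' threshold. `a` dominates when it is cheaper and more effective; the ICER
#' is defined only when the deltas share a sign.
#'
#' @param a,b `strategy_outcome`s sharing horizon and outcome type, or lists
#'   with numeric `cost` and `effect` (per 1,000).
#' @param valuation `"events"` (averted first events) or `"qalys"`.
#' @param threshold Willingness-to-pay in USD per unit effect.
#' @param ... Passed to [accrue_costs()] (cost-inclusion flags).
#' @return A `comparison_result`: `delta_cost`, `delta_effect`, `icer`,
#'   `classification` (dominant / dominated / cost_effective_at_threshold /
#'   not_cost_effective), `threshold_used`.
#' @export
compare_strategies <- function(a, b, valuation = c("events", "qalys"),
                               threshold = 50000, ...) {
  valuation <- match.arg(valuation)
  ce <- function(x) {
    if (inherits(x, "strategy_outcome")) {
      list(cost = accrue_costs(x, ...) * 1000 / x$n,
           effect = outcome_effect(x, valuation))
    } else {
      stopifnot(is.numeric(x$cost), is.numeric(x$effect))
      x
    }
  }
  if (inherits(a, "strategy_outcome") && inherits(b, "strategy_outcome")) {
    stopifnot(a$horizon == b$horizon, a$outcome_type == b$outcome_type)
  }
  ca <- ce(a); cb <- ce(b)
  dc <- ca$cost - cb$cost
  de <- ca$effect - cb$effect
  icer <- if ((dc > 0 && de > 0) || (dc < 0 && de < 0)) dc / de else NA_real_
  classification <-
    if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (!is.na(icer) && de > 0 && icer <= threshold) "cost_effective_at_threshold"
    else "not_cost_effective"
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 classification = classification, threshold_used = threshold,
                 valuation = valuation),
            class = "comparison_result")
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, each simulation's accepted strategy
#' is the one maximising net monetary benefit (threshold x effect - cost);
#' acceptance is the fraction of simulations in which a strategy is
#' accepted, with ties split equally, so acceptance sums to 1 at every
#' threshold.
#'
#' @param psa_results Data frame with columns `sim`, `strategy`, `cost`,
#'   `effect` (one row per simulation x strategy), e.g. from [run_psa()].
#' @param wtp_grid Numeric vector of thresholds (USD per unit effect).
#' @return A `ceac_curve`: long data frame (`wtp`, `strategy`, `acceptance`).
#' @export
ceac <- function(psa_results, wtp_grid = seq(0, 150000, by = 5000)) {
  if (inherits(psa_results, "psa_result")) psa_results <- psa_results$sims
  stopifnot(all(c("sim", "strategy", "cost", "effect") %in% names(psa_results)),
            nrow(psa_results) > 0)
  strategies <- unique(psa_results$strategy)
  sims <- unique(psa_results$sim)
  cost <- matrix(NA_real_, length(sims), length(strategies),
                 dimnames = list(NULL, strategies))
  eff <- cost
  for (s in strategies) {
    rows <- psa_results[psa_results$strategy == s, ]
    i <- match(rows$sim, sims)
    cost[i, s] <- rows$cost
    eff[i, s] <- rows$effect
  }
  out <- do.call(rbind, lapply(wtp_grid, function(l) {
    nmb <- l * eff - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best) # ties split equally
    data.frame(wtp = l, strategy = strategies,
               acceptance = colMeans(share)[strategies],
               row.names = NULL)
  }))
  structure(out, class = c("ceac_curve", "data.frame"))
}

#' Decision label for a three-strategy comparison
#'
#' Applies the published decision vocabulary to mean costs and effects for
#' the status-quo comparator (ATP III) and two alternatives (treat all and a
#' CAC strategy): a strategy that is cheaper and more effective than both
#' others "Dominates Both"; otherwise the winner is the maximum
#' net-monetary-benefit strategy at the threshold, labelled "Dominates ATP
#' III" if it dominates the comparator, "Cost-Effective" with its ICER
#' against ATP III if that ICER is at or below the threshold, and
#' "ATP III (Status Quo)" when no alternative qualifies.
#'
#' @param costs,effects Named numeric vectors (names `atp3`, `treat_all`,
#'   and the CAC strategy), per 1,000 patients; effects oriented so larger
#'   is better.
#' @param threshold Willingness-to-pay per unit effect (USD).
#' @return Character label.
#' @export
decision_label <- function(costs, effects, threshold = 50000) {
  stopifnot(length(costs) == 3, identical(sort(names(costs)), sort(names(effects))),
            "atp3" %in% names(costs))
  effects <- effects[names(costs)]
  pretty <- c(atp3 = "ATP III", treat_all = "Treat All",
              cac_ge1 = "CAC", cac_ge100 = "CAC")
  disp <- function(s) if (s %in% names(pretty)) pretty[[s]] else s
  dominates <- function(x, y) costs[x] < costs[y] && effects[x] > effects[y]
  alts <- setdiff(names(costs), "atp3")
  for (s in alts) {
    if (all(vapply(setdiff(names(costs), s), function(o) dominates(s, o),
                   logical(1)))) {
      return(paste(disp(s), "Dominates Both"))
    }
  }
  nmb <- threshold * effects - costs
  winner <- names(costs)[which.max(nmb)]
  if (winner == "atp3") return("ATP III (Status Quo)")
  if (dominates(winner, "atp3")) return(paste(disp(winner), "Dominates ATP III"))
  icer <- (costs[winner] - costs["atp3"]) / (effects[winner] - effects["atp3"])
  if (is.finite(icer) && icer > 0 && icer <= threshold &&
      effects[winner] > effects["atp3"]) {
    return(sprintf("%s Cost-Effective; ICER = $%s", disp(winner),
                   format(round(icer), big.mark = ",", scientific = FALSE)))
  }
  "ATP III (Status Quo)"
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison: dCost = $%.0f, dEffect = %.2f %s /1000, %s%s>\n",
              x$delta_cost, x$delta_effect, x$valuation, x$classification,
              if (!is.na(x$icer)) sprintf(" (ICER $%.0f)", x$icer) else ""))
  invisible(x)
}
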