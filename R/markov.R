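#' @importFrom stats setNames
NULL

# Model states. First-event states are absorbing for event counting; the
# three post-event states implement the two-year linear taper of the
# event-related utility decrement.
model_states <- function() {
  c("healthy", "post_event_year1", "post_event_year2", "post_event_later",
    "dead_event", "dead_other", "dead_statin_ae", "dead_radiation")
}

# Competing risks within one annual cycle: each annual probability is
# converted to a rate (-log(1-p)), rates are summed, and the total exit
# probability 1-exp(-sum) is allocated proportionally to the rates. Avoids
# any event-ordering bias. Inputs are recycled vectors of probabilities.
competing_alloc <- function(p_event, p_other, p_sae, p_rad) {
  probs <- cbind(p_event, p_other, p_sae, p_rad)
  if (any(probs < 0) || any(probs >= 1)) {
    stop("single-cycle cause probabilities must lie in [0, 1); got a value ",
         "outside -- corrupted inputs")
  }
  rates <- -log1p(-probs)
  tot <- rowSums(rates)
  p_exit <- -expm1(-tot)
  share <- rates / ifelse(tot > 0, tot, 1)
  list(event = p_exit * share[, 1], other = p_exit * share[, 2],
       sae = p_exit * share[, 3], rad = p_exit * share[, 4],
       exit = p_exit)
}

# Annual radiation-induced cancer *death* probability for a scanned patient:
# the lifetime excess risk is spread uniformly over the latency window
# (linear approximation), and a cancer is fatal within the year w.p. the
# 1-year case fatality.
radiation_death_prob <- function(ps) {
  pget(ps, "radiation_lifetime_risk") / pget(ps, "radiation_latency_years") *
    pget(ps, "radiation_case_fatality")
}

#' Utility-years accrued in one cycle (pre-discount)
#'
#' Healthy patients accrue their age-interpolated utility, multiplied -- if
#' on statins -- by the general statin disutility, by the mild-complication
#' multiplier in a mild-complication year, and by the severe-complication
#' multiplier in a severe-adverse-event year. The year of a nonfatal event
#' applies the event multiplier m (CHD 0.8351 / CVD 0.8272 at base case),
#' the following year (1+m)/2 (linear two-year taper), and later years the
#' full healthy utility. Cycles are resolved before accrual, so a fatal
#' event contributes zero from its own cycle onward.
#'
#' @param attained_age Age during the cycle (clamped to the 50-90 utility
#'   anchor range).
#' @param state One of [model_states()].
#' @param ps A `parameter_set`.
#' @param outcome `"CHD"` or `"CVD"` (selects the event multiplier).
#' @param on_statin,mild_ae,sae_year Per-patient flags for the cycle.
#' @return Utility-years for the cycle.
#' @examples
#' qaly_cycle_value(60, "healthy", build_parameter_set()) # 0.82
#' @export
qaly_cycle_value <- function(attained_age, state, ps, outcome = c("CVD", "CHD"),
                             on_statin = FALSE, mild_ae = FALSE,
                             sae_year = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(state %in% model_states())
  u <- healthy_utility(attained_age, ps)
  m <- pget(ps, paste0("umult_", tolower(outcome), "_event"))
  base <- switch(state,
    healthy = u,
    post_event_year1 = u * m,
    post_event_year2 = u * (1 + m) / 2,
    post_event_later = u,
    0
  )
  if (state == "healthy") {
    if (on_statin) {
      base <- base * pget(ps, "umult_statin")
      if (mild_ae) base <- base * pget(ps, "umult_mild_ae")
    }
    if (sae_year) base <- base * pget(ps, "umult_severe_ae")
  }
  base
}

#' One annual transition for a single patient
#'
#' Resolves the competing risks of one cycle -- first event (fatal with the
#' age-specific case fatality), background mortality, severe statin adverse
#' event (on-statin only; fatal w.p. the severe-AE death probability,
#' survivors permanently discontinue statins), and radiation-induced cancer
#' death (scanned patients only) -- given two uniform draws. Dead states are
#' absorbing; post-event states face background mortality only and never
#' revert to healthy.
#'
#' @param patient List with `state` (one of [model_states()]), `on_statin`,
#'   `mild_ae`, `sae_year`.
#' @param annual_event_risk Annual first-event probability.
#' @param effective_rr Effective relative risk (1 if untreated).
#' @param ps A `parameter_set`.
#' @param attained_age Age at the transition.
#' @param u Two uniforms in [0,1): cause draw and sub-split draw.
#' @param outcome `"CHD"` or `"CVD"`.
#' @param cac_tested Whether the patient was CT-scanned.
#' @return The updated patient list, with logical `event`/`fatal_event`
#'   fields describing what happened this cycle.
#' @export
annual_transition <- function(patient, annual_event_risk, effective_rr, ps,
                              attained_age, u = stats::runif(2),
                              outcome = c("CVD", "CHD"), cac_tested = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(patient$state %in% model_states())
  out <- patient
  out$event <- FALSE
  out$fatal_event <- FALSE
  out$sae_year <- FALSE
  if (grepl("^dead", patient$state)) return(out)
  q_other <- life_qx(ps, attained_age)
  if (patient$state != "healthy") {
    if (u[1] < q_other) {
      out$state <- "dead_other"
    } else {
      out$state <- switch(patient$state,
        post_event_year1 = "post_event_year2",
        post_event_year2 = "post_event_later",
        post_event_later = "post_event_later")
    }
    return(out)
  }
  on_statin <- isTRUE(patient$on_statin)
  al <- competing_alloc(
    annual_event_risk * effective_rr, q_other,
    if (on_statin) pget(ps, "p_severe_ae") else 0,
    if (cac_tested) radiation_death_prob(ps) else 0
  )
  th <- cumsum(c(al$event, al$other, al$sae, al$rad))
  cf <- pget(ps, sprintf("cf_%s_%s", tolower(outcome),
                         if (attained_age < 65) "lt65" else "ge65"))
  if (u[1] < th[1]) {
    out$event <- TRUE
    out$fatal_event <- u[2] < cf
    out$state <- if (out$fatal_event) "dead_event" else "post_event_year1"
    out$on_statin <- FALSE
  } else if (u[1] < th[2]) {
    out$state <- "dead_other"
  } else if (u[1] < th[3]) {
    if (u[2] < pget(ps, "p_death_severe_ae")) {
      out$state <- "dead_statin_ae"
    } else {
      out$on_statin <- FALSE
      out$sae_year <- TRUE
    }
  } else if (u[1] < th[4]) {
    out$state <- "dead_radiation"
  }
  out
}

# Shared per-run constants pulled once from the parameter set.
engine_constants <- function(ps, outcome, cac_tested) {
  o <- tolower(outcome)
  list(
    r = pget(ps, "discount_rate"),
    cf_lt = pget(ps, paste0("cf_", o, "_lt65")),
    cf_ge = pget(ps, paste0("cf_", o, "_ge65")),
    m = pget(ps, paste0("umult_", o, "_event")),
    u_statin = pget(ps, "umult_statin"),
    u_mild = pget(ps, "umult_mild_ae"),
    u_sev = pget(ps, "umult_severe_ae"),
    p_mild = pget(ps, "p_mild_ae"),
    q_sae = pget(ps, "p_severe_ae"),
    p_sae_death = pget(ps, "p_death_severe_ae"),
    q_rad = if (cac_tested) radiation_death_prob(ps) else 0,
    c_statin = pget(ps, "cost_statin_annual"),
    c_nf = pget(ps, paste0("cost_", o, "_nonfatal")),
    c_f = pget(ps, paste0("cost_", o, "_fatal")),
    c_sae = pget(ps, "cost_severe_ae")
  )
}

# Deterministic (expected-value) propagation of one treatment branch.
# `w` is the per-patient probability mass carried by the branch; `rr` the
# branch's effective relative risk; `on_statin` whether the branch accrues
# statin cost, disutility and adverse-event risk.
#
# Cycle timing: transitions are resolved at the start of each cycle and
# utility/costs accrue to the resulting state, so the event year carries
# the first-year decrement, a death year accrues nothing, and the first
# cycle's draw uses the baseline age. Costs and QALYs accruing in cycle k
# are discounted by (1+r)^-k (first cycle undiscounted); discounted event
# *counts* are valued at the end of the cycle in which the event occurs,
# i.e. by (1+r)^-(k+1), the convention that reproduces the published event
# projections. Mild statin complications occur at
# initiation: their one-time cost and single decremented year fall in
# cycle 0. Severe-complication survivors spend the episode year on statin
# with the severe multiplier, then discontinue permanently.
ev_branch <- function(w, age0, risk, rr, on_statin, cac_tested, ps, horizon,
                      outcome) {
  k0 <- engine_constants(ps, outcome, cac_tested)
  n <- length(age0)
  hON <- if (on_statin) w else numeric(n)
  hOFF <- if (on_statin) numeric(n) else w
  hSAE <- numeric(n) # severe-AE episode year (still on statin this cycle)
  p1 <- p2 <- p3 <- numeric(n)
  dEv <- dOth <- dSae <- dRad <- numeric(n)
  mild_mult <- 1 - k0$p_mild * (1 - k0$u_mild)
  H <- horizon
  zero <- numeric(H)
  out <- list(events = zero, fatal = zero, nonfatal = zero,
              events_disc = zero, qaly_disc = zero, cost_statin = zero,
              cost_event = zero, cost_sae = zero, cost_prod = zero,
              trace = matrix(0, H, length(model_states()),
                             dimnames = list(NULL, model_states())))
  for (k in seq_len(H) - 1L) {
    df <- (1 + k0$r)^(-k)
    age <- age0 + k
    qo <- life_qx(ps, age)
    ## resolve transitions into cycle k
    hOFF <- hOFF + hSAE # episode over: discontinued, no residual benefit
    hSAE <- numeric(n)
    al_on <- competing_alloc(risk * rr, qo, k0$q_sae, k0$q_rad)
    al_off <- competing_alloc(risk, qo, 0, k0$q_rad)
    ev_on <- hON * al_on$event
    ev_off <- hOFF * al_off$event
    ev <- ev_on + ev_off
    cf <- ifelse(age < 65, k0$cf_lt, k0$cf_ge)
    fat <- ev * cf
    nonfat <- ev - fat
    sae <- hON * al_on$sae
    sae_dead <- sae * k0$p_sae_death
    hSAE <- sae - sae_dead
    oth <- hON * al_on$other + hOFF * al_off$other + (p1 + p2 + p3) * qo
    rad <- hON * al_on$rad + hOFF * al_off$rad
    hON <- hON * (1 - al_on$exit)
    hOFF <- hOFF * (1 - al_off$exit)
    p3 <- (p2 + p3) * (1 - qo)
    p2 <- p1 * (1 - qo)
    p1 <- nonfat
    dEv <- dEv + fat; dOth <- dOth + oth
    dSae <- dSae + sae_dead; dRad <- dRad + rad
    ## accrue cycle k in the resolved states
    u <- healthy_utility(age, ps)
    mm <- if (k == 0L) mild_mult else 1
    qaly_k <- (hON * mm + hSAE * mm * k0$u_sev) * u * k0$u_statin +
      hOFF * u + p1 * u * k0$m + p2 * u * (1 + k0$m) / 2 + p3 * u
    out$qaly_disc[k + 1] <- df * sum(qaly_k)
    out$cost_statin[k + 1] <- df * sum(hON + hSAE) * k0$c_statin
    out$trace[k + 1, ] <- c(sum(hON + hSAE + hOFF), sum(p1), sum(p2), sum(p3),
                            sum(dEv), sum(dOth), sum(dSae), sum(dRad))
    out$events[k + 1] <- sum(ev)
    out$fatal[k + 1] <- sum(fat)
    out$nonfatal[k + 1] <- sum(nonfat)
    out$events_disc[k + 1] <- sum(ev) / (1 + k0$r)^(k + 1)
    out$cost_event[k + 1] <- df * sum(fat * k0$c_f + nonfat * k0$c_nf)
    out$cost_sae[k + 1] <- df * sum(sae) * k0$c_sae
    out$cost_prod[k + 1] <- df * sum(ev * productivity_cost(age, outcome, ps))
  }
  out
}

# Stochastic (microsimulation) propagation of the whole cohort, drawing
# individual trajectories with a shared uniform stream (common random
# numbers when `crn` is reused across strategies). Mirrors ev_branch's
# cycle timing exactly.
microsim_run <- function(cohort, assignment, ps, horizon, outcome, cac_tested,
                         crn) {
  k0 <- engine_constants(ps, outcome, cac_tested)
  n <- nrow(cohort)
  H <- horizon
  age0 <- cohort$age
  risk <- cohort$annual_event_risk
  state <- rep(1L, n) # index into model_states()
  on_statin <- assignment$recommended & assignment$adherent
  mild_ae <- on_statin & (crn$u_mild < k0$p_mild)
  rr_t <- assignment$rr_treated
  zero <- numeric(H)
  out <- list(events = zero, fatal = zero, nonfatal = zero,
              events_disc = zero, qaly_disc = zero, cost_statin = zero,
              cost_event = zero, cost_sae = zero, cost_prod = zero,
              trace = matrix(0, H, length(model_states()),
                             dimnames = list(NULL, model_states())),
              n_mild_ae = sum(mild_ae))
  for (k in seq_len(H) - 1L) {
    df <- (1 + k0$r)^(-k)
    age <- age0 + k
    qo <- life_qx(ps, age)
    ## resolve transitions into cycle k
    u1 <- crn$u_trans[, k + 1]
    u2 <- crn$u_sub[, k + 1]
    healthy <- state == 1L
    al <- competing_alloc(risk * ifelse(on_statin, rr_t, 1), qo,
                          ifelse(on_statin, k0$q_sae, 0), k0$q_rad)
    t1 <- al$event; t2 <- t1 + al$other; t3 <- t2 + al$sae; t4 <- t3 + al$rad
    cf <- ifelse(age < 65, k0$cf_lt, k0$cf_ge)
    ev <- healthy & u1 < t1
    fat <- ev & u2 < cf
    nonfat <- ev & !fat
    oth_h <- healthy & !ev & u1 < t2
    sae <- healthy & u1 >= t2 & u1 < t3
    sae_dead <- sae & u2 < k0$p_sae_death
    sae_year <- sae & !sae_dead
    rad <- healthy & u1 >= t3 & u1 < t4
    post <- state %in% 2:4
    post_dead <- post & u1 < qo
    adv <- post & !post_dead
    state[adv & state == 3L] <- 4L # year2 -> later (before year1 -> year2)
    state[adv & state == 2L] <- 3L
    state[nonfat] <- 2L
    state[fat] <- 5L
    state[oth_h | post_dead] <- 6L
    state[sae_dead] <- 7L
    state[rad] <- 8L
    on_statin[ev] <- FALSE
    ## accrue cycle k in the resolved states
    u <- healthy_utility(age, ps)
    healthy_now <- state == 1L
    on_now <- healthy_now & on_statin # includes the severe-AE episode year
    umult <- ifelse(on_now, k0$u_statin *
                      ifelse(mild_ae & k == 0L, k0$u_mild, 1), 1) *
             ifelse(sae_year, k0$u_sev, 1)
    uy <- numeric(n)
    uy[healthy_now] <- (u * umult)[healthy_now]
    uy[state == 2L] <- (u * k0$m)[state == 2L]
    uy[state == 3L] <- (u * (1 + k0$m) / 2)[state == 3L]
    uy[state == 4L] <- u[state == 4L]
    out$qaly_disc[k + 1] <- df * sum(uy)
    out$cost_statin[k + 1] <- df * sum(on_now) * k0$c_statin
    out$trace[k + 1, ] <- tabulate(state, nbins = 8L)
    on_statin[sae] <- FALSE # discontinue after the episode year
    out$events[k + 1] <- sum(ev)
    out$fatal[k + 1] <- sum(fat)
    out$nonfatal[k + 1] <- sum(nonfat)
    out$events_disc[k + 1] <- sum(ev) / (1 + k0$r)^(k + 1)
    out$cost_event[k + 1] <- df * (sum(fat) * k0$c_f + sum(nonfat) * k0$c_nf)
    out$cost_sae[k + 1] <- df * sum(sae) * k0$c_sae
    out$cost_prod[k + 1] <- df * sum(productivity_cost(age, outcome, ps)[ev])
  }
  out
}

# Fresh uniform streams for one (cohort, simulation) pair; reused across
# strategies for common random numbers.
make_crn <- function(n, horizon, seed) {
  withr::with_seed(as.integer(seed), list(
    u_adh = stats::runif(n),
    u_mild = stats::runif(n),
    u_trans = matrix(stats::runif(n * horizon), n, horizon),
    u_sub = matrix(stats::runif(n * horizon), n, horizon)
  ))
}

#' Run a cohort through the Markov model under one strategy
#'
#' Advances the cohort through `horizon` annual cycles, accruing first
#' events (counted once per patient, undiscounted and 3%-discounted), QALYs
#' and a discounted cost ledger. In `"expected_value"` mode exact state
#' occupancy fractions are propagated per patient -- adherence and
#' mild-adverse-event indicators enter as probability weights, so the result
#' is deterministic. In `"microsimulation"` mode individual trajectories are
#' drawn from the assignment's adherence indicators and the supplied (or
#' seeded) uniform streams.
#'
#' @param cohort A `cohort` with hazards assigned ([assign_event_hazards()]).
#' @param assignment A `treatment_assignment` for the same cohort.
#' @param ps A `parameter_set`.
#' @param horizon 5 or 10 (years); other values need
#'   `allow_any_horizon = TRUE`.
#' @param outcome `"CHD"` or `"CVD"`; defaults to the cohort's hazard type.
#' @param mode `"expected_value"` or `"microsimulation"`.
#' @param seed Seed for microsimulation draws (ignored in expected-value
#'   mode).
#' @param crn Optional uniform streams from an internal generator, reused
#'   across strategies for common random numbers.
#' @param allow_any_horizon Permit horizons outside {5, 10}.
#' @return A `strategy_outcome`: events per 1,000 (total/fatal/nonfatal,
#'   undiscounted), discounted events per 1,000, discounted QALYs, the
#'   discounted cost ledger by component, and a per-cycle trace.
#' @export
run_cohort <- function(cohort, assignment, ps, horizon = 5, outcome = NULL,
                       mode = c("expected_value", "microsimulation"),
                       seed = NULL, crn = NULL, allow_any_horizon = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort"), inherits(assignment, "treatment_assignment"),
            nrow(cohort) == nrow(assignment))
  if (!horizon %in% c(5, 10) && !allow_any_horizon) {
    stop("horizon must be 5 or 10 years (use allow_any_horizon to override)")
  }
  if (is.null(outcome)) outcome <- attr(cohort, "outcome_type")
  if (is.na(outcome) || anyNA(cohort$annual_event_risk)) {
    stop("cohort has no event hazards; call assign_event_hazards() first")
  }
  cac_tested <- attr(assignment, "cac_tested")
  n <- nrow(cohort)
  if (mode == "expected_value") {
    w_treated <- ifelse(assignment$recommended, assignment$p_adherent, 0)
    parts <- list(
      ev_branch(w_treated, cohort$age, cohort$annual_event_risk,
                assignment$rr_treated, TRUE, cac_tested, ps, horizon, outcome),
      ev_branch(1 - w_treated, cohort$age, cohort$annual_event_risk, 1,
                FALSE, cac_tested, ps, horizon, outcome)
    )
    res <- parts[[1]]
    for (f in setdiff(names(res), "trace")) res[[f]] <- res[[f]] + parts[[2]][[f]]
    res$trace <- parts[[1]]$trace + parts[[2]]$trace
    n_mild <- sum(w_treated) * pget(ps, "p_mild_ae")
  } else {
    if (is.null(crn)) {
      if (is.null(seed)) stop("microsimulation requires a seed or crn streams")
      crn <- make_crn(n, horizon, seed)
    }
    res <- microsim_run(cohort, assignment, ps, horizon, outcome, cac_tested, crn)
    n_mild <- res$n_mild_ae
  }
  components <- c(
    cac_test = if (cac_tested) n * pget(ps, "cost_cac_test") else 0,
    statin_annual = sum(res$cost_statin),
    event_direct = sum(res$cost_event),
    ae_mild = n_mild * pget(ps, "cost_mild_ae"),
    ae_severe = sum(res$cost_sae),
    incidentaloma = if (cac_tested) {
      n * pget(ps, "incidentaloma_fraction") * pget(ps, "cost_incidentaloma")
    } else 0,
    productivity_event = sum(res$cost_prod),
    cac_time_cost = if (cac_tested) n * pget(ps, "cost_cac_time") else 0
  )
  trace <- data.frame(cycle = seq_len(horizon) - 1L, res$trace,
                      events = res$events, qalys_disc = res$qaly_disc,
                      check.names = FALSE)
  structure(list(
    strategy = attr(assignment, "strategy"),
    n = n, horizon = horizon, outcome_type = outcome, mode = mode,
    cac_tested = cac_tested,
    events_per_1000 = c(total = sum(res$events), fatal = sum(res$fatal),
                        nonfatal = sum(res$nonfatal)) * 1000 / n,
    disc_events_per_1000 = sum(res$events_disc) * 1000 / n,
    disc_qalys = sum(res$qaly_disc),
    disc_qalys_per_1000 = sum(res$qaly_disc) * 1000 / n,
    cost_components = components,
    cycle_trace = trace
  ), class = "strategy_outcome")
}

#' Convenience wrapper: hazards + treatment + run for one strategy
#'
#' @inheritParams run_cohort
#' @param strategy A [strategy_spec()] or name.
#' @param rate_multiplier Event-rate multiplier (2 for the elevated-rate
#'   sensitivity analyses).
#' @param crn Optional shared uniform streams (common random numbers).
#' @param seed Seed used for adherence (and microsimulation) draws when
#'   `crn` is not supplied.
#' @export
run_strategy <- function(cohort, strategy, ps, horizon = 5,
                         outcome = c("CHD", "CVD"), rate_multiplier = 1,
                         mode = "expected_value", seed = NULL, crn = NULL) {
  outcome <- match.arg(outcome)
  cohort <- assign_event_hazards(cohort, ps, outcome, horizon, rate_multiplier)
  asg <- assign_treatment(cohort, strategy, ps, seed = seed,
                          adherence_u = crn$u_adh)
  run_cohort(cohort, asg, ps, horizon, outcome, mode, seed = seed, crn = crn)
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome: %s, %d patients, %dy %s, %s>\n",
              x$strategy, x$n, x$horizon, x$outcome_type, x$mode))
  cat(sprintf("  first events /1000: %.1f (fatal %.1f), discounted %.1f\n",
              x$events_per_1000["total"], x$events_per_1000["fatal"],
              x$disc_events_per_1000))
  cat(sprintf("  discounted QALYs /1000: %.1f; direct cost /patient: $%.0f\n",
              x$disc_qalys_per_1000, accrue_costs(x) / x$n))
  invisible(x)
}

#' Export a per-cycle trace as long-format delimited text
#' @param outcome A `strategy_outcome`.
#' @param path File path.
#' @export
write_trace <- function(outcome, path) {
  tr <- outcome$cycle_trace
  long <- do.call(rbind, lapply(model_states(), function(s) {
    data.frame(cycle = tr$cycle, state = s, occupancy = tr[[s]])
  }))
  extra <- data.frame(cycle = tr$cycle, state = "qalys_disc",
                      occupancy = tr$qalys_disc)
  utils::write.table(rbind(long, extra), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
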