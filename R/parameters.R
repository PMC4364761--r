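#' Model parameter registry
#'
#' Every model parameter is housed here as a point estimate plus (where one is
#' modelled) a sampling distribution for probabilistic sensitivity analysis.
#' All monetary values are 2011 US dollars. Event risks are annual per-person
#' probabilities of a *first* CHD or CVD event by CAC stratum; the `_5y_`
#' entries are the annualised rates underlying the 5-year analyses and the
#' `_10y_` entries those underlying the 10-year analyses.
#'
#' Entries whose source table models no distribution (age-specific healthy
#' utilities, radiation parameters, the discount rate) are held fixed in PSA.
#'
#' @param ess_event_rates Effective sample size used to attach a beta
#'   distribution to the event-rate means (their published description gives a
#'   mean but no variance). Larger values give tighter PSA draws.
#' @keywords internal
parameter_registry <- function(ess_event_rates = 5000) {
  tri_pm20 <- function(v) dist_triangular(0.8 * v, v, 1.2 * v)
  gamma_half <- function(v) dist_gamma_ms(v, v / 2)
  rate <- function(v) list(value = v, dist = dist_beta_mean_ess(v, ess_event_rates))
  fixed <- function(v) list(value = v, dist = NULL)

  list(
    ## Annual first-event risks per CAC stratum (zero / low 1<=CAC<100 / high >=100)
    risk_cvd_5y_zero  = rate(0.00406206),
    risk_cvd_5y_low   = rate(0.01086766),
    risk_cvd_5y_high  = rate(0.01920450),
    risk_cvd_10y_zero = rate(0.00413593),
    risk_cvd_10y_low  = rate(0.01115809),
    risk_cvd_10y_high = rate(0.02060006),
    risk_chd_5y_zero  = rate(0.00201915),
    risk_chd_5y_low   = rate(0.00839575),
    risk_chd_5y_high  = rate(0.01676953),
    risk_chd_10y_zero = rate(0.00212544),
    risk_chd_10y_low  = rate(0.00756866),
    risk_chd_10y_high = rate(0.01639898),

    ## Statin effectiveness (relative risk of a first event while treated)
    rr_moderate = list(value = 0.65, dist = dist_triangular(0.55, 0.65, 0.75)),
    rr_intensive = list(value = 0.55, dist = dist_triangular(0.45, 0.55, 0.65)),

    ## Case fatality of a first event, by attained age at the event
    cf_chd_lt65 = list(value = 0.10000, dist = dist_beta(17, 153)),
    cf_chd_ge65 = list(value = 0.15714, dist = dist_beta(22, 118)),
    cf_cvd_lt65 = list(value = 0.10260, dist = dist_beta(16, 140)),
    cf_cvd_ge65 = list(value = 0.16265, dist = dist_beta(23, 118)),

    ## Statin adverse events
    p_mild_ae = list(value = 0.18, dist = dist_beta(252, 1148)),
    p_severe_ae = list(value = 1 / 18000, dist = dist_beta(5.6, 99994)),
    p_death_severe_ae = list(value = 0.09, dist = dist_beta(7.2, 73)),

    ## Adherence (probability of initiating and sustaining advised statins)
    adherence_no_cac = list(value = 0.55, dist = dist_triangular(0.40, 0.55, 1.00)),
    adherence_cac = list(value = 0.65, dist = dist_triangular(0.50, 0.65, 1.00)),

    ## CT radiation (no distribution modelled)
    radiation_lifetime_risk = fixed(0.00002),
    radiation_case_fatality = fixed(0.65),
    radiation_latency_years = fixed(25),

    ## Direct medical costs (2011 USD)
    cost_chd_nonfatal = list(value = 64400, dist = dist_gamma_ms(64400, 32200)),
    cost_chd_fatal    = list(value = 49000, dist = dist_gamma_ms(49000, 24500)),
    cost_cvd_nonfatal = list(value = 55700, dist = dist_gamma_ms(55700, 27850)),
    cost_cvd_fatal    = list(value = 43500, dist = dist_gamma_ms(43500, 21750)),
    cost_cac_test     = list(value = 100, dist = tri_pm20(100)),
    cost_statin_annual = list(value = 180, dist = tri_pm20(180)),
    cost_mild_ae   = list(value = 180, dist = dist_gamma_ms(180, 30)),
    cost_severe_ae = list(value = 6500, dist = dist_gamma_ms(6500, 3250)),
    cost_incidentaloma = list(value = 250, dist = dist_gamma_ms(250, 125)),
    incidentaloma_fraction = fixed(0.08),

    ## Indirect costs: age-anchored annual productivity cost of an event
    ## (sd = 50% of mean per source note); value column taken where the
    ## printed value and distribution mean disagree.
    prod_chd_age_40 = list(value = 6500, dist = gamma_half(6500)),
    prod_chd_age_50 = list(value = 5100, dist = gamma_half(5100)),
    prod_chd_age_60 = list(value = 1900, dist = gamma_half(1900)),
    prod_chd_age_70 = list(value = 500, dist = gamma_half(500)),
    prod_chd_age_80 = list(value = 200, dist = gamma_half(200)),
    prod_cvd_age_40 = list(value = 7900, dist = gamma_half(7900)),
    prod_cvd_age_50 = list(value = 6200, dist = gamma_half(6200)),
    prod_cvd_age_60 = list(value = 2300, dist = gamma_half(2300)),
    prod_cvd_age_70 = list(value = 600, dist = gamma_half(600)),
    prod_cvd_age_80 = list(value = 200, dist = gamma_half(200)),
    ## 1 hour at the median >=55 wage; printed gamma shape implies CV ~ 0.97
    cost_cac_time = list(value = 15.20, dist = dist_gamma_ms(15.20, 14.79)),

    ## Age-anchored healthy utilities (no distribution modelled)
    utility_age_50 = fixed(0.84),
    utility_age_60 = fixed(0.82),
    utility_age_70 = fixed(0.79),
    utility_age_80 = fixed(0.74),
    utility_age_90 = fixed(0.68),

    ## Multiplicative utility decrements
    umult_statin = list(value = 0.99616, dist = dist_triangular(0.99232, 0.99616, 1.0)),
    umult_mild_ae = list(value = 0.9941, dist = dist_triangular(0.9890, 0.9941, 0.9986)),
    umult_severe_ae = list(value = 0.9553, dist = dist_triangular(0.9233, 0.9553, 0.9808)),
    umult_chd_event = list(value = 0.8351, dist = dist_beta(102, 20)),
    umult_cvd_event = list(value = 0.8272, dist = dist_beta(180, 38)),

    discount_rate = fixed(0.03)
  )
}

#' Build the model parameter set
#'
#' Returns base-case point values for every registered parameter, with
#' scenario overrides applied, sampling distributions attached, and the
#' bundled life table loaded. Distributions for the CAC test and annual
#' statin costs are triangular at +/-20% around the (possibly overridden)
#' mean, so overriding `cost_cac_test = 250` also shifts its PSA spread.
#'
#' @param overrides Named list or vector of parameter values to override.
#'   Unknown names raise an error listing the valid names.
#' @param life_table Data frame with columns `age` and `qx` giving annual
#'   background (non-CHD/CVD) mortality; defaults to the bundled synthetic
#'   stand-in for the US 2011 life table.
#' @param ess_event_rates Effective sample size for event-rate beta
#'   distributions (see [parameter_registry()]).
#' @return An object of class `parameter_set`: list with `values` (named
#'   numerics), `dists` (named `dist_spec`s or NULL) and `life_table`.
#' @examples
#' ps <- build_parameter_set()
#' pget(ps, "rr_moderate") # 0.65
#' ps250 <- build_parameter_set(list(cost_cac_test = 250))
#' @export
build_parameter_set <- function(overrides = list(), life_table = NULL,
                                ess_event_rates = 5000) {
  reg <- parameter_registry(ess_event_rates)
  overrides <- as.list(overrides)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(reg))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           "\nvalid names are: ", paste(names(reg), collapse = ", "))
    }
    for (nm in names(overrides)) {
      v <- as.numeric(overrides[[nm]])
      reg[[nm]]$value <- v
      # costs varied +/-20% keep their relative spread around the new mean
      if (nm %in% c("cost_cac_test", "cost_statin_annual")) {
        reg[[nm]]$dist <- dist_triangular(0.8 * v, v, 1.2 * v)
      }
    }
  }
  if (is.null(life_table)) life_table <- default_life_table()
  validate_life_table(life_table)
  structure(list(
    values = vapply(reg, function(e) e$value, numeric(1)),
    dists = lapply(reg, function(e) e$dist),
    life_table = life_table
  ), class = "parameter_set")
}

#' Get a parameter value
#' @param ps A `parameter_set`.
#' @param name Parameter name.
#' @export
pget <- function(ps, name) {
  v <- ps$values[name]
  if (anyNA(v)) stop("unknown parameter name(s): ",
                     paste(name[is.na(v)], collapse = ", "))
  unname(v)
}

#' Draw one sampled parameter set for probabilistic sensitivity analysis
#'
#' Each entry with a modelled distribution is replaced by a single draw;
#' entries without one keep their point value. Draws are independent across
#' parameters (as in the source analysis) and reproducible given `seed`.
#'
#' @param ps A `parameter_set` from [build_parameter_set()].
#' @param seed Integer seed (required; the PSA driver supplies one per
#'   simulation).
#' @return A `parameter_set` whose `values` are the draws and whose
#'   distributions are collapsed to point masses.
#' @export
sample_parameter_set <- function(ps, seed) {
  stopifnot(inherits(ps, "parameter_set"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  out <- ps
  withr::with_seed(as.integer(seed), {
    for (nm in names(ps$dists)) {
      d <- ps$dists[[nm]]
      if (!is.null(d) && d$family != "point") {
        out$values[[nm]] <- dist_sample(d, 1L)
      }
    }
  })
  out$dists <- lapply(out$values, dist_point)
  attr(out, "sampled") <- TRUE
  out
}

#' Annual first-event risks by CAC stratum
#'
#' @param ps A `parameter_set`.
#' @param outcome `"CHD"` or `"CVD"`.
#' @param horizon 5 or 10; selects the rate basis matching the analysis
#'   horizon.
#' @return Named vector `c(zero=, low=, high=)`.
#' @export
event_rates <- function(ps, outcome = c("CHD", "CVD"), horizon = 5) {
  outcome <- match.arg(outcome)
  stopifnot(horizon %in% c(5, 10))
  key <- sprintf("risk_%s_%dy_%s", tolower(outcome), horizon,
                 c("zero", "low", "high"))
  stats::setNames(pget(ps, key), c("zero", "low", "high"))
}

#' Age-interpolated healthy utility
#'
#' Linear interpolation between the utility anchors at ages 50-90, clamped
#' to the boundary values outside that range.
#'
#' @param age Numeric vector of attained ages.
#' @param ps A `parameter_set` (defaults used if omitted).
#' @export
healthy_utility <- function(age, ps = NULL) {
  anchors_age <- c(50, 60, 70, 80, 90)
  if (is.null(ps)) {
    u <- c(0.84, 0.82, 0.79, 0.74, 0.68)
  } else {
    u <- pget(ps, paste0("utility_age_", anchors_age))
  }
  stats::approx(anchors_age, u, xout = age, rule = 2)$y
}

#' Age-interpolated annual productivity cost of an event
#'
#' Linear interpolation between the age anchors at 40-80, clamped outside.
#'
#' @param age Numeric vector of attained ages at the event.
#' @param outcome `"CHD"` or `"CVD"`.
#' @param ps A `parameter_set`.
#' @export
productivity_cost <- function(age, outcome = c("CHD", "CVD"), ps = NULL) {
  outcome <- match.arg(outcome)
  anchors_age <- c(40, 50, 60, 70, 80)
  if (is.null(ps)) ps <- build_parameter_set()
  v <- pget(ps, sprintf("prod_%s_age_%d", tolower(outcome), anchors_age))
  stats::approx(anchors_age, v, xout = age, rule = 2)$y
}

#' Read and validate a life table
#'
#' Two-column delimited text (`age`, `qx`) with annual all-cause mortality
#' probabilities. Rows may be in any order; the table is sorted by age and
#' must cover a contiguous integer age range with probabilities in [0, 1].
#'
#' @param path Path to the file. Lines starting with `#` are ignored.
#' @return Data frame with columns `age` and `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("integer", "numeric"))
  names(lt) <- c("age", "qx")
  lt <- lt[order(lt$age), , drop = FALSE]
  validate_life_table(lt)
  lt
}

#' @rdname read_life_table
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "us_life_table_2011_synthetic.tsv",
                              package = "cacCEA", mustWork = TRUE))
}

validate_life_table <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "qx") %in% names(lt)))
  if (any(diff(lt$age) != 1L)) {
    stop("life table ages must be contiguous; gap after age ",
         lt$age[which(diff(lt$age) != 1L)[1]])
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  invisible(lt)
}

# Vectorised background-mortality lookup; age floored and clamped to the
# table's range.
life_qx <- function(ps, age) {
  lt <- ps$life_table
  a <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  lt$qx[match(a, lt$age)]
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set: %d parameters, life table ages %d-%d%s>\n",
              length(x$values), min(x$life_table$age), max(x$life_table$age),
              if (isTRUE(attr(x, "sampled"))) ", sampled" else ""))
  invisible(x)
}
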