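#' CAC strata
#'
#' The three coronary artery calcium strata used throughout the model,
#' ordered by risk: `zero` (CAC = 0), `low` (1 <= CAC < 100), `high`
#' (CAC >= 100).
#'
#' @return Ordered factor levels as a character vector.
#' @export
cac_strata <- function() c("zero", "low", "high")

#' Joint ATP III eligibility-by-CAC classification table
#'
#' A 2x3 table of counts: rows are ATP III statin-eligible / not eligible,
#' columns the CAC strata in the order high, low, zero is *not* assumed --
#' columns must be named by stratum.
#'
#' @param eligible,not_eligible Named integer vectors with entries `zero`,
#'   `low`, `high`.
#' @return A `joint_table` object (matrix with a `total` attribute).
#' @examples
#' jt <- mesa_joint_table()
#' sum(jt) # 1619
#' @export
joint_table <- function(eligible, not_eligible) {
  strata <- cac_strata()
  stopifnot(all(strata %in% names(eligible)), all(strata %in% names(not_eligible)))
  m <- rbind(eligible = eligible[strata], not_eligible = not_eligible[strata])
  if (any(m < 0) || any(m != round(m))) stop("cell counts must be non-negative integers")
  structure(m, class = c("joint_table", class(m)))
}

#' @rdname joint_table
#' @details `mesa_joint_table()` returns the MESA intermediate-risk subsample
#'   composition (N = 1,619): 615 ATP III statin-eligible (193 with CAC >=
#'   100, 196 with 1 <= CAC < 100, 226 with CAC = 0) and 1,004 not eligible
#'   (256 / 294 / 454).
#' @export
mesa_joint_table <- function() {
  joint_table(
    eligible = c(zero = 226, low = 196, high = 193),
    not_eligible = c(zero = 454, low = 294, high = 256)
  )
}

#' Reclassification summary relative to a CAC treatment threshold
#'
#' For a treatment threshold of CAC >= 1 or CAC >= 100, computes the percent
#' of the population reclassified upward (not statin-eligible under ATP III
#' but at/above the CAC threshold), downward (eligible under ATP III but
#' below the threshold), and the net percent (upward minus downward).
#' Percentages are of the total population and are also returned rounded to
#' one decimal for reporting.
#'
#' @param table A [joint_table()].
#' @param threshold `"ge1"` (treat any CAC) or `"ge100"`.
#' @return List with `upward`, `downward`, `net` (exact) and `*_pct`
#'   (rounded to one decimal, in percent).
#' @examples
#' reclassification_summary(mesa_joint_table(), "ge1")$net_pct # 20.0
#' @export
reclassification_summary <- function(table, threshold = c("ge1", "ge100")) {
  threshold <- match.arg(threshold)
  stopifnot(inherits(table, "joint_table"))
  total <- sum(table)
  if (total <= 0) stop("zero total: reclassification percentages undefined")
  above <- if (threshold == "ge1") c("low", "high") else "high"
  below <- setdiff(cac_strata(), above)
  upward <- sum(table["not_eligible", above]) / total
  downward <- sum(table["eligible", below]) / total
  list(
    threshold = threshold,
    upward = upward, downward = downward, net = upward - downward,
    upward_pct = round(100 * upward, 1),
    downward_pct = round(100 * downward, 1),
    net_pct = round(100 * upward, 1) - round(100 * downward, 1)
  )
}

#' Baseline age model
#'
#' The source subsample's exact baseline age distribution is not published;
#' the default stand-in is a truncated normal on [45, 84] with mean 65 and
#' SD 8 (configurable). A fixed single age is supported for closed-form
#' tests.
#'
#' @param type `"truncnorm"` or `"fixed"`.
#' @param mean,sd Truncated-normal location and scale.
#' @param min,max Truncation bounds (years).
#' @param age Fixed age when `type = "fixed"`.
#' @export
age_model <- function(type = c("truncnorm", "fixed"), mean = 65, sd = 8,
                      min = 45, max = 84, age = NULL) {
  type <- match.arg(type)
  if (type == "fixed") {
    if (is.null(age)) stop("fixed age model requires `age`")
    stopifnot(age >= min, age <= max)
  } else {
    stopifnot(sd > 0, min < max)
  }
  structure(list(type = type, mean = mean, sd = sd, min = min, max = max,
                 age = age), class = "age_model")
}

sample_ages <- function(model, n) {
  stopifnot(inherits(model, "age_model"))
  if (model$type == "fixed") return(rep(model$age, n))
  # inverse-CDF truncated normal
  plo <- stats::pnorm(model$min, model$mean, model$sd)
  phi <- stats::pnorm(model$max, model$mean, model$sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), model$mean, model$sd)
}

#' Generate a synthetic intermediate-risk cohort
#'
#' Draws `n` patients whose joint (ATP III eligibility x CAC stratum)
#' frequencies follow the cell proportions of `table`. In `"exact"` mode,
#' `n` must equal the table total and every cell count is reproduced
#' exactly; in `"sampling"` mode cells are drawn multinomially. Ages are
#' drawn independently of stratum and eligibility (a documented
#' simplification) from `age_model`, truncated to its bounds.
#'
#' @param n Number of patients (> 0).
#' @param table A [joint_table()]; defaults to the MESA composition.
#' @param age_model An [age_model()].
#' @param seed Integer seed (required).
#' @param mode `"exact"` or `"sampling"`.
#' @return A data frame of class `cohort` with columns `id`, `age`,
#'   `atp3_eligible` (logical), `cac_stratum` (factor), and a placeholder
#'   `annual_event_risk` column (NA until [assign_event_hazards()]).
#' @export
generate_cohort <- function(n, table = mesa_joint_table(),
                            age_model = cacCEA::age_model(), seed,
                            mode = c("sampling", "exact")) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (length(n) != 1 || is.na(n) || n <= 0) stop("n must be a positive count")
  stopifnot(inherits(table, "joint_table"))
  cells <- as.vector(t(table)) # eligible zero,low,high then not_eligible ...
  labels <- expand.grid(cac_stratum = cac_strata(),
                        atp3_eligible = c(TRUE, FALSE),
                        KEEP.OUT.ATTRS = FALSE)[, 2:1]
  withr::with_seed(as.integer(seed), {
    if (mode == "exact") {
      if (n != sum(table)) {
        stop("exact mode requires n equal to the table total (", sum(table), ")")
      }
      counts <- cells
    } else {
      counts <- as.vector(stats::rmultinom(1, n, cells / sum(cells)))
    }
    idx <- rep(seq_len(nrow(labels)), counts)
    ages <- sample_ages(age_model, n)
  })
  out <- data.frame(
    id = seq_len(n),
    age = ages,
    atp3_eligible = labels$atp3_eligible[idx],
    cac_stratum = factor(labels$cac_stratum[idx], levels = cac_strata()),
    annual_event_risk = NA_real_
  )
  structure(out, class = c("cohort", "data.frame"),
            outcome_type = NA_character_, rate_multiplier = 1)
}

#' Assign per-patient annual first-event hazards
#'
#' Sets each record's `annual_event_risk` to `multiplier` times its CAC
#' stratum's annual rate, capped just below 1. The 2x multiplier implements
#' the elevated-event-rate sensitivity analyses.
#'
#' @param cohort A `cohort`.
#' @param rates Named vector `c(zero=, low=, high=)`, or a `parameter_set`
#'   (in which case `outcome` and `horizon` select the rates).
#' @param outcome `"CHD"` or `"CVD"`.
#' @param horizon 5 or 10 (rate basis).
#' @param multiplier Non-negative scalar rate multiplier.
#' @return The cohort with `annual_event_risk` filled and the outcome type
#'   and multiplier recorded as attributes.
#' @export
assign_event_hazards <- function(cohort, rates, outcome = c("CHD", "CVD"),
                                 horizon = 5, multiplier = 1) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(cohort, "cohort"), multiplier >= 0)
  if (inherits(rates, "parameter_set")) {
    rates <- event_rates(rates, outcome, horizon)
  }
  if (!all(cac_strata() %in% names(rates))) {
    stop("rates must be named for all strata: ",
         paste(setdiff(cac_strata(), names(rates)), collapse = ", "))
  }
  risk <- multiplier * unname(rates[as.character(cohort$cac_stratum)])
  cohort$annual_event_risk <- pmin(risk, 1 - 1e-12)
  attr(cohort, "outcome_type") <- outcome
  attr(cohort, "rate_multiplier") <- multiplier
  cohort
}

#' Cohort text I/O
#'
#' Cohorts round-trip through tab-delimited text with a header
#' (`id`, `age`, `atp3_eligible`, `cac_stratum`, `annual_event_risk`).
#'
#' @param cohort A `cohort`.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("id", "age", "atp3_eligible", "cac_stratum",
                  "annual_event_risk") %in% names(df)))
  df$cac_stratum <- factor(df$cac_stratum, levels = cac_strata())
  df$atp3_eligible <- as.logical(df$atp3_eligible)
  structure(df, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d patients, ages %.1f-%.1f, %d ATP III-eligible>\n",
              nrow(x), min(x$age), max(x$age), sum(x$atp3_eligible)))
  print(table(eligibility = ifelse(x$atp3_eligible, "eligible", "not_eligible"),
              stratum = x$cac_stratum))
  invisible(x)
}
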