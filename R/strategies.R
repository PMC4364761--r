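#' Risk-assessment and treatment strategies
#'
#' Four strategies are compared:
#' \describe{
#'   \item{atp3}{Status quo: moderate statins recommended to ATP III
#'     statin-eligible patients; adherence 55% (no CAC scan).}
#'   \item{treat_all}{Moderate statins recommended to every intermediate-risk
#'     patient; adherence 55%.}
#'   \item{cac_ge1}{All patients scanned; moderate statins for 1 <= CAC < 100,
#'     intensive for CAC >= 100, none for CAC = 0 (CAC trumps ATP III
#'     eligibility); adherence 65%.}
#'   \item{cac_ge100}{All patients scanned; intensive statins for CAC >= 100
#'     only; adherence 65%.}
#' }
#'
#' @param name Strategy name.
#' @return A `strategy_spec` with fields `name`, `cac_tested` and
#'   `adherence_key`.
#' @export
strategy_spec <- function(name = c("atp3", "treat_all", "cac_ge1", "cac_ge100")) {
  name <- match.arg(name)
  cac <- name %in% c("cac_ge1", "cac_ge100")
  structure(list(
    name = name,
    cac_tested = cac,
    adherence_key = if (cac) "adherence_cac" else "adherence_no_cac"
  ), class = "strategy_spec")
}

#' Assign treatment under a strategy
#'
#' Maps each patient to a recommendation and statin intensity per the
#' strategy's rule, records the strategy's adherence probability, and draws
#' a once-per-patient adherence indicator (fixed for the whole horizon; no
#' annual churn). Non-adherent patients are modelled as never-initiators:
#' no benefit, statin cost, disutility or statin adverse-event risk.
#'
#' @param cohort A `cohort`.
#' @param spec A [strategy_spec()] or strategy name.
#' @param ps A `parameter_set`.
#' @param seed Integer seed for the adherence draws (required).
#' @param adherence_u Optional vector of uniforms in [0,1), one per patient,
#'   used instead of fresh draws -- the common-random-numbers hook used by
#'   the PSA driver so that adherent sets are nested across strategies.
#' @return A data frame of class `treatment_assignment` with per-patient
#'   columns `recommended`, `intensity` (`none`/`moderate`/`intensive`),
#'   `p_adherent`, `adherent`, `rr_treated`, and attribute `cac_tested`.
#' @examples
#' ps <- build_parameter_set()
#' coh <- generate_cohort(1619, mode = "exact", seed = 1)
#' sum(assign_treatment(coh, "atp3", ps, seed = 1)$recommended) # 615
#' @export
assign_treatment <- function(cohort, spec, ps, seed = NULL, adherence_u = NULL) {
  if (is.character(spec)) spec <- strategy_spec(spec)
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "strategy_spec"),
            inherits(ps, "parameter_set"))
  s <- as.character(cohort$cac_stratum)
  recommended <- switch(spec$name,
    atp3 = cohort$atp3_eligible,
    treat_all = rep(TRUE, nrow(cohort)),
    cac_ge1 = s %in% c("low", "high"),
    cac_ge100 = s == "high"
  )
  intensity <- rep("none", nrow(cohort))
  intensity[recommended] <- "moderate"
  if (spec$name %in% c("cac_ge1", "cac_ge100")) {
    intensity[recommended & s == "high"] <- "intensive"
  }
  p_adh <- pget(ps, spec$adherence_key)
  if (is.null(adherence_u)) {
    if (is.null(seed)) stop("a seed is required unless adherence_u is supplied")
    adherence_u <- withr::with_seed(as.integer(seed), stats::runif(nrow(cohort)))
  }
  stopifnot(length(adherence_u) == nrow(cohort))
  adherent <- recommended & (adherence_u < p_adh)
  rr_treated <- ifelse(intensity == "intensive", pget(ps, "rr_intensive"),
                ifelse(intensity == "moderate", pget(ps, "rr_moderate"), 1))
  structure(data.frame(
    id = cohort$id,
    recommended = recommended,
    intensity = factor(intensity, levels = c("none", "moderate", "intensive")),
    p_adherent = ifelse(recommended, p_adh, 0),
    adherent = adherent,
    rr_treated = rr_treated
  ), class = c("treatment_assignment", "data.frame"),
     strategy = spec$name, cac_tested = spec$cac_tested)
}

#' Effective relative risk of an assignment entry
#'
#' Recommended, adherent patients receive their intensity's relative risk
#' (0.55 intensive, 0.65 moderate at base case); everyone else has effective
#' relative risk 1.
#'
#' @param assignment A `treatment_assignment` (vectorised over rows).
#' @param ps A `parameter_set`.
#' @return Numeric vector in (0, 1].
#' @export
effective_rr <- function(assignment, ps) {
  stopifnot(inherits(assignment, "treatment_assignment"))
  rr_mod <- pget(ps, "rr_moderate")
  rr_int <- pget(ps, "rr_intensive")
  out <- rep(1, nrow(assignment))
  act <- assignment$recommended & assignment$adherent
  out[act & assignment$intensity == "moderate"] <- rr_mod
  out[act & assignment$intensity == "intensive"] <- rr_int
  out
}

#' Assignment text I/O
#' @param assignment A `treatment_assignment`.
#' @param path File path.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
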