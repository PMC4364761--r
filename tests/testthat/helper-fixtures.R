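# Shared fixtures built in code: degenerate parameter sets and single-stratum
# cohorts used for closed-form checks.

zero_mortality_lt <- function() data.frame(age = 45:94, qx = 0)

# Parameter set with no background mortality and (optionally) no statin
# adverse-event hazard, for closed-form event and cost checks.
ps_no_mortality <- function(overrides = list()) {
  build_parameter_set(overrides, life_table = zero_mortality_lt())
}

# A cohort of n identical patients in one stratum, optionally all ATP III
# eligible, at a fixed age.
single_stratum_cohort <- function(n, stratum = "high", eligible = FALSE,
                                  age = 55, seed = 1) {
  elig <- not <- c(zero = 0, low = 0, high = 0)
  if (eligible) elig[stratum] <- n else not[stratum] <- n
  generate_cohort(n, joint_table(elig, not),
                  age_model(type = "fixed", age = age), seed = seed,
                  mode = "exact")
}

mesa_cohort <- function(seed = 1, ...) {
  generate_cohort(sum(mesa_joint_table()), seed = seed, mode = "exact", ...)
}
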