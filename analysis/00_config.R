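# Shared study configuration for the analysis scripts.
#
# One synthetic "study": a functional-response compilation of 2000
# experiments with 0.5 log10 units of observation noise on both parameters
# and a few percent of filter-exercising defect rows, plus mass-scaling
# tables of 400 observations per taxon group. Everything downstream is
# deterministic given this seed.

library(frpred)

STUDY_SEED <- 1234L

study_config <- function() {
  generator_config(
    n_records = 2000,
    n_scaling_obs_per_group = 400,
    frac_egg = 0.03, frac_low_handling = 0.01, frac_missing_mass = 0.02,
    seed = STUDY_SEED)
}

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

fit_study_laws <- function(tbl) {
  list(density = fit_scaling_laws(tbl, "density_per_m2", seed = STUDY_SEED + 1L),
       demand = fit_scaling_laws(tbl, "metabolic_kj_per_day",
                                 seed = STUDY_SEED + 2L))
}
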