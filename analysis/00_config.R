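# Shared settings for the analysis scripts. Everything downstream derives
# from this one seed; re-running any script reproduces its outputs exactly.

library(popafkit)

SEED <- 20260917L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# the stated world: an admixed array cohort of 200 samples at 20,000
# independent biallelic loci, three ancestral components at Fst ~ 0.1,
# flat Dirichlet admixture, 2% missingness, ~97% of loci in the known set
COHORT <- cohort_spec(n_samples = 200L, n_loci = 20000L, n_pops = 3L,
                      fst = 0.1, dirichlet_alpha = c(1, 1, 1),
                      missing_rate = 0.02, known_fraction = 0.97,
                      seed = SEED)

resim <- function() simulate_cohort(COHORT)
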