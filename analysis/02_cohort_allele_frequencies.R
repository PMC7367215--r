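# Stage 2: the local allele-frequency panel from the array cohort — the
# "breadth" resource later used to annotate WGS calls — with its estimation
# error benchmarked against the simulation truth.

source("analysis/00_config.R")

g <- read_genotype_matrix(file.path(OUT, "cohort_genotypes.tsv"))
panel <- build_panel(g, "LOCAL", min_call_rate = 0.95)
cat(sprintf("local panel: %d loci kept (%d dropped by call rate)\n",
            nrow(panel), attr(panel, "n_dropped_call_rate")))

write_af_panel(panel, file.path(OUT, "local_af.tsv"))
write_panel_vcf(panel, file.path(OUT, "local_af_sites.vcf"))

# error against the cohort-level truth AF under the admixture model
sim <- resim()
truth_af <- colMeans(sim$truth$admixture %*% sim$truth$pop_af)
idx <- match(paste(panel$chrom, panel$pos),
             paste(sim$truth$loci$chrom, sim$truth$loci$pos))
rmse <- sqrt(mean((panel$af - truth_af[idx])^2))
se <- mean(sqrt(truth_af * (1 - truth_af) / (2 * nrow(g$genotypes))))
cat(sprintf("panel AF RMSE vs truth: %.5f (mean binomial SE %.5f, ratio %.2f)\n",
            rmse, se, rmse / se))
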