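# Stage 1: generate the synthetic admixed cohort that stands in for the
# controlled-access study data, plus the annotation resources every later
# stage consumes (reference AF panels, known-sites set, pathogenicity
# table).

source("analysis/00_config.R")

sim <- resim()
cat(sprintf("cohort: %d samples x %d loci, %.2f%% missing entries\n",
            nrow(sim$genotypes$genotypes), ncol(sim$genotypes$genotypes),
            100 * mean(is.na(sim$genotypes$genotypes))))

write_genotype_matrix(sim$genotypes, file.path(OUT, "cohort_genotypes.tsv"))

panels <- emit_reference_panels(sim$truth, pops = c("POP1", "POP2", "POP3"),
                                n_ref = 5000L, out_dir = OUT)
cat(sprintf("reference panels (n_ref = 5000 each): %s\n",
            paste(basename(panels), collapse = ", ")))

write_known_sites(truth_known_sites(sim$truth),
                  file.path(OUT, "known_sites.tsv"))
cat(sprintf("known-sites set: %d of %d loci (%.1f%%)\n",
            sum(sim$truth$known), length(sim$truth$known),
            100 * mean(sim$truth$known)))

patho <- emit_pathogenicity_table(sim$truth$loci, seed = SEED,
                                  path = file.path(OUT, "pathogenicity.tsv"))
cat(sprintf("pathogenicity table: %d non-benign ClinVar, %d protein-altering\n",
            sum(patho$clinvar_class != "benign"),
            sum(patho$protein_altering)))
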