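# Stage 3: population structure. PCA over the cohort, supervised admixture
# for every sample against ancestry-group allele frequencies, selection of
# one central representative per group, and an IBS neighbor-joining tree
# placing the representatives among a cohort subsample.

source("analysis/00_config.R")

sim <- resim()
g <- sim$genotypes

model <- suppressWarnings(fit_pca(g, d = 2))
cat(sprintf("PCA: top-2 eigenvalues %.1f / %.1f\n",
            model$eigenvalues[1], model$eigenvalues[2]))
grouping <- sprintf("POP%d", max.col(sim$truth$admixture))
data.table::fwrite(data.table::data.table(
  sample_id = rownames(model$reference_coords), group = grouping,
  model$reference_coords), file.path(OUT, "pca_coords.tsv"), sep = "\t")

F <- population_frequencies(g, grouping)
reps <- select_representatives(model$reference_coords, sim$truth$admixture,
                               grouping)
cat("representatives (most central per ancestry group):\n")
for (i in seq_len(nrow(reps))) {
  fit <- supervised_admixture(g$genotypes[
    match(reps$sample_id[i], g$sample_ids), ], F)
  cat(sprintf("  %s: %s (centrality %.2f) Q = %s\n",
              reps$group[i], reps$sample_id[i], reps$centrality[i],
              paste(sprintf("%.2f", fit$Q), collapse = "/")))
}

rep_idx <- match(reps$sample_id, g$sample_ids)
extra <- setdiff(seq_len(nrow(g$genotypes)), rep_idx)[1:20]
d <- ibs_distance(g$genotypes[c(rep_idx, extra), ])
tree <- neighbor_joining(d)
write_newick(tree, file.path(OUT, "ibs_nj.nwk"))
cat(sprintf("IBS/NJ tree over %d samples written to %s\n",
            length(tree$tip.label), file.path(OUT, "ibs_nj.nwk")))
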