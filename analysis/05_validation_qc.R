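# Stage 5: validation. Array-vs-WGS genotype concordance through the
# filter cascade (missing / indel / multiallelic / palindromic / strand
# reconciliation), per-sample QC metrics (Het/Hom, Ti/Tv, known/novel),
# and the shared/distinct partition across the representatives.

source("analysis/00_config.R")

sim <- resim()
g <- sim$genotypes
grouping <- sprintf("POP%d", max.col(sim$truth$admixture))
model <- suppressWarnings(fit_pca(g, d = 2))
reps <- select_representatives(model$reference_coords, sim$truth$admixture,
                               grouping)
rep_idx <- match(reps$sample_id, g$sample_ids)
known <- read_known_sites(file.path(OUT, "known_sites.tsv"))

vcfs <- file.path(OUT, paste0(reps$sample_id, ".vcf"))
stopifnot(all(file.exists(vcfs)))  # produced by 04_prioritize_variants.R

for (i in seq_along(rep_idx)) {
  sid <- reps$sample_id[i]
  cc <- concordance(g$genotypes[rep_idx[i], ], g$loci, vcfs[i])
  qc <- sample_qc(vcfs[i], known_sites = known)
  write_qc_report(qc, json = file.path(OUT, paste0(sid, ".qc.json")))
  cat(sprintf(
    "%s: concordance %.2f%% over %d loci (%d palindromic dropped, %d strand-flipped); Ti/Tv %.2f; het:hom %.2f; novel %.1f%%\n",
    sid, cc$concordance_pct, cc$n_compared, cc$dropped_palindromic,
    cc$n_strand_flipped, qc$titv_all, qc$het_hom_ratio,
    100 * qc$n_novel / qc$total_variants))
}

part <- share_partition(vcfs, labels = reps$sample_id)
data.table::fwrite(part$table, file.path(OUT, "share_partition.tsv"),
                   sep = "\t")
cat(sprintf("share partition: union %d variants, %d shared by all; distinct: %s\n",
            part$union_size, part$shared_all,
            paste(sprintf("%s=%d", names(part$distinct_per_sample),
                          part$distinct_per_sample), collapse = ", ")))
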