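# Per-sample variant QC (SNP/indel split, Het/Hom, Ti/Tv, known/novel)
# and the multi-sample shared/distinct partition.

#' Classify a biallelic variant by allele lengths
#'
#' SNP iff both alleles are single bases; insertion iff the alt allele is
#' the longer; deletion otherwise. Vectorized.
#'
#' @param ref,alt character allele vectors.
#' @return character vector over \{SNP, insertion, deletion\}.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNP",
         ifelse(la > lr, "insertion", "deletion"))
}

#' Is a SNP substitution a transition?
#'
#' Transitions are A<->G and C<->T; the remaining eight ordered pairs are
#' transversions. Vectorized; symmetric in (ref, alt).
#'
#' @param ref,alt single-base allele vectors.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

titv <- function(ref, alt) {
  ti <- sum(is_transition(ref, alt))
  tv <- length(ref) - ti
  if (tv == 0L) NA_real_ else ti / tv
}

#' Per-sample variant QC report
#'
#' Computes the standard call-set health metrics: SNP/indel counts,
#' het/hom fractions and ratio (genotype 0/1 vs 1/1, phase ignored),
#' transition/transversion ratios over SNPs (overall and split by
#' known/novel), and the known/novel partition by exact
#' (chrom, pos, ref, alt) membership in the known-sites set. Unsplit
#' multiallelic records are rejected with a counted warning; records with
#' missing or half-call genotypes are excluded from het/hom fractions.
#'
#' @param vcf path to a single-sample VCF.
#' @param known_sites data.table of known loci (chrom, pos, ref, alt);
#'   NULL disables novelty classification.
#' @param het_hom_scope count het/hom over all variant records ("all",
#'   default) or SNPs only ("snp").
#' @return a list of class `sample_qc_report`.
#' @export
sample_qc <- function(vcf, known_sites = NULL,
                      het_hom_scope = c("all", "snp")) {
  het_hom_scope <- match.arg(het_hom_scope)
  v <- read_vcf(vcf)
  if (nrow(v) && all(is.na(v$gt))) stopf("VCF has no GT field")
  multi <- grepl(",", v$alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi) {
    warning(sprintf("rejected %d unsplit multiallelic records", n_multi))
    v <- v[!multi]
  }
  v[, "vtype" := classify_variant(ref, alt)]
  if (!is.null(known_sites)) {
    ks <- data.table::as.data.table(known_sites)
    kk <- locus_key(ks$chrom, ks$pos, ks$ref, ks$alt)
    v[, "known" := locus_key(chrom, pos, ref, alt) %in% kk]
  } else {
    v[, "known" := NA]
  }
  scope <- if (het_hom_scope == "snp") v$vtype == "SNP" else rep(TRUE, nrow(v))
  d <- v$dosage[scope]
  n_het <- sum(d == 1L, na.rm = TRUE)
  n_hom <- sum(d == 2L, na.rm = TRUE)
  snps <- v[vtype == "SNP"]
  rep <- list(
    total_variants = nrow(v),
    n_multiallelic_rejected = n_multi,
    n_snp = sum(v$vtype == "SNP"),
    n_indel = sum(v$vtype != "SNP"),
    n_het = n_het, n_hom = n_hom,
    het_fraction = if (n_het + n_hom > 0) n_het / (n_het + n_hom) else NA_real_,
    hom_fraction = if (n_het + n_hom > 0) n_hom / (n_het + n_hom) else NA_real_,
    het_hom_ratio = if (n_hom > 0) n_het / n_hom else NA_real_,
    titv_all = if (nrow(snps)) titv(snps$ref, snps$alt) else NA_real_,
    titv_known = if (!is.null(known_sites) && nrow(snps[known == TRUE])) {
      titv(snps[known == TRUE]$ref, snps[known == TRUE]$alt)
    } else NA_real_,
    titv_novel = if (!is.null(known_sites) && nrow(snps[known == FALSE])) {
      titv(snps[known == FALSE]$ref, snps[known == FALSE]$alt)
    } else NA_real_,
    n_known = if (!is.null(known_sites)) sum(v$known) else NA_integer_,
    n_novel = if (!is.null(known_sites)) sum(!v$known) else NA_integer_)
  class(rep) <- "sample_qc_report"
  rep
}

#' @export
print.sample_qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<sample_qc_report> %d variants (%d SNP / %d indel)\n",
    "  het:hom %.2f  Ti/Tv %.3f (known %.3f, novel %.3f)\n",
    "  known %s  novel %s\n"),
    x$total_variants, x$n_snp, x$n_indel, x$het_hom_ratio,
    x$titv_all, x$titv_known, x$titv_novel,
    format(x$n_known), format(x$n_novel)))
  invisible(x)
}

#' Write a QC report as JSON / TSV
#' @param report a `sample_qc_report`.
#' @param json,tsv output paths (either may be NULL).
#' @return the report, invisibly.
#' @export
write_qc_report <- function(report, json = NULL, tsv = NULL) {
  flat <- report[!vapply(report, is.null, logical(1))]
  if (!is.null(json)) {
    jsonlite::write_json(flat, json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv)) {
    data.table::fwrite(data.table::data.table(
      metric = names(flat), value = unlist(lapply(flat, format))),
      tsv, sep = "\t", quote = FALSE)
  }
  invisible(report)
}

#' Shared/distinct partition of several call sets
#'
#' Keys each file's variants by (chrom, pos, ref, alt) and assigns every
#' member of the union to exactly one presence-subset cell (one row per
#' nonempty subset bitmask). Bit i of the mask is set when sample i carries
#' the variant.
#'
#' @param vcfs character vector of VCF paths (or a list of data.tables with
#'   chrom, pos, ref, alt columns).
#' @param labels sample labels; defaults to file base names.
#' @return a list of class `share_partition`: `table` (mask, samples, n),
#'   `shared_all`, `distinct_per_sample`, `union_size`.
#' @export
share_partition <- function(vcfs, labels = NULL) {
  keysets <- lapply(vcfs, function(x) {
    dt <- if (is.character(x)) read_vcf(x) else data.table::as.data.table(x)
    unique(locus_key(dt$chrom, dt$pos, dt$ref, dt$alt))
  })
  s <- length(keysets)
  if (s < 1L) stopf("need at least one call set")
  if (is.null(labels)) {
    labels <- if (is.character(vcfs)) {
      sub("\\.vcf$", "", basename(vcfs))
    } else paste0("set", seq_len(s))
  }
  univ <- unique(unlist(keysets))
  mask <- integer(length(univ))
  for (i in seq_len(s)) {
    mask <- mask + bitwShiftL(1L, i - 1L) * (univ %in% keysets[[i]])
  }
  tab <- data.table::data.table(mask = mask)[, list(n = .N), by = "mask"]
  all_masks <- seq_len(bitwShiftL(1L, s) - 1L)
  tab <- merge(data.table::data.table(mask = all_masks), tab,
               by = "mask", all.x = TRUE)
  tab[is.na(n), "n" := 0L]
  tab[, "samples" := vapply(mask, function(m) {
    paste(labels[bitwAnd(m, bitwShiftL(1L, seq_len(s) - 1L)) != 0L],
          collapse = "+")
  }, character(1))]
  full <- bitwShiftL(1L, s) - 1L
  res <- list(
    table = tab[, c("mask", "samples", "n")],
    shared_all = tab[mask == full]$n,
    distinct_per_sample = stats::setNames(
      vapply(seq_len(s), function(i) {
        tab[mask == bitwShiftL(1L, i - 1L)]$n
      }, integer(1)), labels),
    union_size = length(univ),
    labels = labels)
  class(res) <- "share_partition"
  res
}

#' @export
print.share_partition <- function(x, ...) {
  cat(sprintf("<share_partition> %d sets, union %d, shared by all %d\n",
              length(x$labels), x$union_size, x$shared_all))
  invisible(x)
}
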