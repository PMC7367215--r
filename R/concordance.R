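# Array-vs-WGS genotype concordance with the validation filter cascade:
# missing values -> indels -> multiallelic loci -> strand confusion
# (palindromic pairs) -> allele reconciliation, then percent agreement on
# the intersection with the sequencing calls.

#' Is an allele pair strand-ambiguous (palindromic)?
#'
#' A/T and C/G SNPs read identically on both strands, so an array's strand
#' cannot be inferred from the alleles alone; these loci are dropped before
#' comparison ("strand confusion" filter). Vectorized.
#'
#' @param ref,alt single-base alleles.
#' @return logical vector.
#' @export
is_palindromic <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Reconcile array and WGS allele pairs
#'
#' Categories, tried in priority order: `match` (identical pairs),
#' `flip_match` (WGS pair is the complement — opposite strand),
#' `swap_match` (ref/alt exchanged; genotype recodes g -> 2 - g),
#' `flip_swap_match` (both), else `unresolved`. Vectorized.
#'
#' @param array_ref,array_alt array allele pair.
#' @param wgs_ref,wgs_alt sequencing allele pair.
#' @return character vector of categories.
#' @export
reconcile_alleles <- function(array_ref, array_alt, wgs_ref, wgs_alt) {
  cr <- unname(DNA_COMPLEMENT[wgs_ref])
  ca <- unname(DNA_COMPLEMENT[wgs_alt])
  out <- rep("unresolved", length(array_ref))
  out[array_ref == cr & array_alt == ca] <- "flip_match"
  out[array_ref == ca & array_alt == cr] <- "flip_swap_match"
  out[array_ref == wgs_alt & array_alt == wgs_ref] <- "swap_match"
  out[array_ref == wgs_ref & array_alt == wgs_alt] <- "match"
  out
}

#' Array-vs-WGS genotype concordance for one sample
#'
#' Applies the filter cascade to the array loci in order — missing array
#' genotype, array indel, multiallelic (duplicated position on either
#' side, or a comma ALT), palindromic pair — then intersects the survivors
#' with the VCF's SNV calls by (chrom, pos), reconciles alleles (with
#' complement/swap recoding), and scores agreement of the diploid
#' genotypes. Array loci with no SNV call in the VCF are excluded
#' (intersection semantics), not assumed hom-ref.
#'
#' @param array_genotypes integer dosage vector for the sample (0/1/2/NA).
#' @param array_loci data.table (chrom, pos, ref, alt), one row per entry
#'   of `array_genotypes`.
#' @param wgs_vcf path to the sample's VCF.
#' @param allele_level if TRUE, score agreement over the 2 alleles per
#'   locus (partial credit 0/0.5/1) instead of exact genotype identity.
#' @return a list of class `concordance_report`: the filter-cascade drop
#'   counts, `n_compared`, `n_agree`, `concordance_pct` (NA with
#'   `status = "undefined"` when nothing is comparable), and
#'   `n_strand_flipped`.
#' @export
concordance <- function(array_genotypes, array_loci, wgs_vcf,
                        allele_level = FALSE) {
  loci <- data.table::as.data.table(array_loci)
  stopifnot(nrow(loci) == length(array_genotypes))
  v <- read_vcf(wgs_vcf)

  n0 <- nrow(loci)
  g <- as.integer(array_genotypes)
  drop_missing <- is.na(g)
  drop_indel <- !drop_missing & classify_variant(loci$ref, loci$alt) != "SNP"
  dup_pos <- duplicated(loci[, c("chrom", "pos")]) |
    duplicated(loci[, c("chrom", "pos")], fromLast = TRUE)
  vcf_multi <- grepl(",", v$alt, fixed = TRUE)
  vcf_dup <- duplicated(v[, c("chrom", "pos")]) |
    duplicated(v[, c("chrom", "pos")], fromLast = TRUE)
  multi_pos_keys <- unique(c(
    paste(v$chrom[vcf_multi | vcf_dup], v$pos[vcf_multi | vcf_dup])))
  drop_multi <- !drop_missing & !drop_indel &
    (dup_pos | paste(loci$chrom, loci$pos) %in% multi_pos_keys)
  drop_palin <- !drop_missing & !drop_indel & !drop_multi &
    is_palindromic(loci$ref, loci$alt)
  pass <- !(drop_missing | drop_indel | drop_multi | drop_palin)

  vs <- v[!vcf_multi & !vcf_dup & classify_variant(ref, alt) == "SNP" &
            !is.na(dosage)]
  arr <- loci[pass]
  arr[, "g" := g[pass]]
  cmp <- merge(arr, vs[, c("chrom", "pos", "ref", "alt", "dosage")],
               by = c("chrom", "pos"), suffixes = c("_arr", "_wgs"))
  n_absent <- sum(pass) - nrow(cmp)
  if (nrow(cmp)) {
    cat_ <- reconcile_alleles(cmp$ref_arr, cmp$alt_arr,
                              cmp$ref_wgs, cmp$alt_wgs)
  } else {
    cat_ <- character(0)
  }
  unresolved <- cat_ == "unresolved"
  swap <- cat_ %in% c("swap_match", "flip_swap_match")
  flipped <- cat_ %in% c("flip_match", "flip_swap_match")
  cmp <- cmp[!unresolved]
  wgs_g <- cmp$dosage
  wgs_g[swap[!unresolved]] <- 2L - wgs_g[swap[!unresolved]]

  n_compared <- nrow(cmp)
  if (allele_level) {
    agree_units <- sum(2L - abs(cmp$g - wgs_g))
    total_units <- 2L * n_compared
    pct <- if (total_units > 0) 100 * agree_units / total_units else NA_real_
    n_agree <- sum(cmp$g == wgs_g)
  } else {
    n_agree <- sum(cmp$g == wgs_g)
    pct <- if (n_compared > 0) 100 * n_agree / n_compared else NA_real_
  }
  res <- list(
    n_array_loci = n0,
    dropped_missing = sum(drop_missing),
    dropped_indel = sum(drop_indel),
    dropped_multiallelic = sum(drop_multi),
    dropped_palindromic = sum(drop_palin),
    dropped_unresolved_strand = sum(unresolved),
    absent_from_vcf = n_absent,
    n_compared = n_compared,
    n_agree = n_agree,
    concordance_pct = pct,
    n_strand_flipped = sum(flipped & !unresolved),
    status = if (n_compared > 0) "ok" else "undefined",
    allele_level = allele_level)
  class(res) <- "concordance_report"
  res
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<concordance_report> %s: %.3f%% over %d loci (%d agree)\n",
    "  dropped: missing %d, indel %d, multiallelic %d, palindromic %d,",
    " unresolved %d; absent from VCF %d; strand-flipped %d\n"),
    x$status, x$concordance_pct, x$n_compared, x$n_agree,
    x$dropped_missing, x$dropped_indel, x$dropped_multiallelic,
    x$dropped_palindromic, x$dropped_unresolved_strand,
    x$absent_from_vcf, x$n_strand_flipped))
  invisible(x)
}
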