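# Local allele-frequency panel from the array cohort: the "breadth" side
# of the array + WGS synergy. AF is the alt-allele frequency among called
# alleles; AN counts called alleles (2 per called diploid sample).

#' Alt-allele frequency and allele number at one locus
#'
#' Missing genotypes are excluded from both numerator and denominator.
#'
#' @param genotypes integer dosage vector in `{0, 1, 2, NA}`.
#' @return list with `af` (in \[0,1\]) and `an` (called-allele count).
#'   An all-missing locus errors; [build_panel()] drops such loci instead.
#' @export
locus_af <- function(genotypes) {
  called <- !is.na(genotypes)
  an <- 2L * sum(called)
  if (an == 0L) stopf("locus has no called genotypes")
  list(af = sum(genotypes[called]) / an, an = an)
}

#' Build a population allele-frequency panel from an array cohort
#'
#' One record per locus passing the per-locus call-rate filter; loci with
#' no called genotypes are always excluded (their count is reported via the
#' `n_dropped_all_missing` attribute). The panel is sorted by (chrom, pos).
#'
#' @param g a [genotype_matrix()].
#' @param population population name for the panel.
#' @param min_call_rate minimum fraction of called samples per locus
#'   (default 0.95, a conventional array QC threshold).
#' @return an [af_panel()] with attributes `n_dropped_call_rate` and
#'   `n_dropped_all_missing`.
#' @export
build_panel <- function(g, population, min_call_rate = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  geno <- g$genotypes
  if (nrow(geno) == 0L || ncol(geno) == 0L) stopf("empty genotype matrix")
  n_called <- colSums(!is.na(geno))
  call_rate <- n_called / nrow(geno)
  all_missing <- n_called == 0L
  keep <- call_rate >= min_call_rate & !all_missing
  af <- colSums(geno, na.rm = TRUE)[keep] / (2 * n_called[keep])
  pan <- af_panel(data.table::data.table(
    g$loci[keep], af = unname(af), an = unname(2L * n_called[keep])),
    population)
  data.table::setattr(pan, "n_dropped_call_rate",
                      sum(!keep & !all_missing))
  data.table::setattr(pan, "n_dropped_all_missing", sum(all_missing))
  pan
}
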