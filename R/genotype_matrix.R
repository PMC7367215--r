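#' Construct a genotype matrix (samples x biallelic loci)
#'
#' The array-cohort container: an integer matrix of alt-allele dosages coded
#' 0/1/2 with `NA` for missing calls, together with per-locus metadata
#' (chromosome, 1-based position, ref and alt allele) and sample identifiers.
#'
#' @param genotypes integer matrix, samples in rows, loci in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt`; one row
#'   per matrix column. Locus keys `(chrom, pos, ref, alt)` must be unique.
#' @param sample_ids character vector, one per matrix row.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, loci, sample_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  loci <- data.table::as.data.table(loci)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(loci))) {
    stopf("loci must have columns chrom, pos, ref, alt")
  }
  if (nrow(loci) != ncol(genotypes)) {
    stopf("loci rows (%d) must match genotype columns (%d)",
          nrow(loci), ncol(genotypes))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  if (length(sample_ids) != nrow(genotypes)) {
    stopf("sample_ids length must match genotype rows")
  }
  keys <- locus_key(loci$chrom, loci$pos, loci$ref, loci$alt)
  if (anyDuplicated(keys)) stopf("duplicate locus keys in genotype matrix")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stopf("genotype codes must be 0, 1, 2 or NA")
  }
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- keys
  structure(list(genotypes = genotypes, loci = loci,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci; %.2f%% missing\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Write / read a genotype matrix as TSV
#'
#' Plain-text interchange format: one header column `sample_id`, then one
#' column per locus named `chrom:pos:ref:alt`; cells are dosages 0/1/2 with
#' `NA` for missing.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly (writer); a `genotype_matrix` (reader).
#' @export
write_genotype_matrix <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = g$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(g$genotypes))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  ids <- as.character(dt$sample_id)
  dt[, "sample_id" := NULL]
  keys <- names(dt)
  parts <- data.table::tstrsplit(keys, ":", fixed = TRUE)
  if (length(parts) != 4L) stopf("locus columns must be named chrom:pos:ref:alt")
  loci <- data.table::data.table(chrom = as.character(parts[[1]]),
                                 pos = as.integer(parts[[2]]),
                                 ref = as.character(parts[[3]]),
                                 alt = as.character(parts[[4]]))
  genotype_matrix(as.matrix(dt), loci, ids)
}

#' Read PLINK-text ped/map files into a genotype matrix
#'
#' Minimal reader for the classic whitespace-delimited ped/map pair. Alleles
#' at each locus are oriented so that `ref` is the major allele observed in
#' the file (map files carry no ref/alt); `0` in the ped encodes missing.
#'
#' @param ped,map paths to the .ped and .map files.
#' @return a [genotype_matrix()].
#' @export
read_pedmap <- function(ped, map) {
  mp <- data.table::fread(map, header = FALSE)
  if (ncol(mp) < 4L) stopf("map file needs 4 columns (chrom, id, cm, pos)")
  data.table::setnames(mp, 1:4, c("chrom", "id", "cm", "pos"))
  pd <- data.table::fread(ped, header = FALSE, colClasses = "character")
  m <- nrow(mp)
  if (ncol(pd) != 6L + 2L * m) {
    stopf("ped has %d columns; expected %d for %d map loci",
          ncol(pd), 6L + 2L * m, m)
  }
  ids <- pd[[2L]]
  a1 <- as.matrix(pd[, seq(7L, by = 2L, length.out = m), with = FALSE])
  a2 <- as.matrix(pd[, seq(8L, by = 2L, length.out = m), with = FALSE])
  ref <- alt <- character(m)
  geno <- matrix(NA_integer_, nrow(pd), m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    ok <- al != "0"
    tab <- sort(table(al[ok]), decreasing = TRUE)
    if (length(tab) == 0L) stopf("locus %d has no called alleles", j)
    ref[j] <- names(tab)[1L]
    alt[j] <- if (length(tab) >= 2L) names(tab)[2L] else "."
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] != ref[j]) + (a2[, j] != ref[j])
    geno[miss, j] <- NA_integer_
  }
  loci <- data.table::data.table(chrom = as.character(mp$chrom),
                                 pos = as.integer(mp$pos),
                                 ref = ref, alt = alt)
  genotype_matrix(geno, loci, ids)
}
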