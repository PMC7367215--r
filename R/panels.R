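# Allele-frequency panels and known-sites sets: TSV and sites-VCF formats.

#' Create an allele-frequency panel
#'
#' Per-locus alt-allele frequency and allele number for one named population
#' (a local array-derived panel or a gnomAD/GME-style reference panel).
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `af` (in \[0,1\]) and `an` (called-allele count, non-negative).
#' @param population population name.
#' @return an object of class `af_panel` (a data.table with attributes).
#' @export
af_panel <- function(records, population) {
  dt <- data.table::as.data.table(records)
  need <- c("chrom", "pos", "ref", "alt", "af", "an")
  if (!all(need %in% names(dt))) {
    stopf("panel needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(dt) && (min(dt$af) < 0 || max(dt$af) > 1)) {
    stopf("panel af outside [0, 1]")
  }
  if (nrow(dt) && min(dt$an) < 0) stopf("panel an must be >= 0")
  data.table::setorderv(dt, c("chrom", "pos"))
  data.table::setattr(dt, "population", population)
  data.table::setattr(dt, "class", c("af_panel", class(dt)))
  dt
}

#' @export
print.af_panel <- function(x, ...) {
  cat(sprintf("<af_panel> population=%s, %d loci\n",
              attr(x, "population"), nrow(x)))
  invisible(x)
}

#' Write / read an allele-frequency panel as TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, af, an. The population name is
#' carried in the filename by convention and passed explicitly on read.
#'
#' @param panel an [af_panel()].
#' @param path file path.
#' @param population population name (reader).
#' @return `path` invisibly (writer); an `af_panel` (reader).
#' @export
write_af_panel <- function(panel, path) {
  data.table::fwrite(panel[, c("chrom", "pos", "ref", "alt", "af", "an")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_af_panel
#' @export
read_af_panel <- function(path, population) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "ref", "alt")))
  af_panel(dt, population)
}

#' Write a panel as a sites-only VCF with AF/AN INFO keys
#'
#' The annotation-source form of the local panel: no genotypes, INFO carries
#' `AF` and `AN` so generic annotators can consume it.
#'
#' @param panel an [af_panel()].
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  ord <- order(chrom_rank(panel$chrom), panel$pos)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popafkit",
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Alt allele frequency">',
           '##INFO=<ID=AN,Number=1,Type=Integer,Description="Called allele number">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- paste(panel$chrom[ord], panel$pos[ord], ".", panel$ref[ord],
                panel$alt[ord], ".", "PASS",
                sprintf("AF=%s;AN=%d", format(panel$af[ord], digits = 10,
                                              scientific = FALSE, trim = TRUE),
                        as.integer(panel$an[ord])),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a known-sites set (dbSNP-style) as TSV
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path file path.
#' @return `path` invisibly (writer); a data.table keyed by locus (reader).
#' @export
write_known_sites <- function(sites, path) {
  dt <- data.table::as.data.table(sites)[, c("chrom", "pos", "ref", "alt")]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_known_sites
#' @export
read_known_sites <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE,
                    colClasses = list(character = c("chrom", "ref", "alt")))
}
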