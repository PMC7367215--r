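# Lightweight single-sample VCF 4.2 reader/writer. The pipeline writes
# custom INFO keys (LOCAL_AF, Z_GOV, TIER, ...) which rules out the heavy
# S4 writers; records are held as data.tables throughout.

#' Read a single-sample VCF into a data.table
#'
#' Parses a plain-text VCF 4.2 file with one sample column. Returns one row
#' per record with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#' `filter`, `info`, `gt` (the GT subfield) and `dosage` (alt-allele count:
#' 0, 1, 2, or NA for missing / half calls, phase ignored).
#'
#' @param path VCF file path.
#' @return a data.table of variant records.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stopf("malformed VCF (no #CHROM header line): %s", path)
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), qual = character(),
                                  filter = character(), info = character(),
                                  gt = character(), dosage = integer()))
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(fields) < 10L) stopf("VCF must have FORMAT and one sample column")
  fmt <- fields[[9L]]
  smp <- fields[[10L]]
  gt <- mapply(function(f, s) {
    keys <- strsplit(f, ":", fixed = TRUE)[[1]]
    vals <- strsplit(s, ":", fixed = TRUE)[[1]]
    i <- match("GT", keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }, fmt, smp, USE.NAMES = FALSE)
  data.table::data.table(
    chrom = as.character(fields[[1L]]),
    pos = as.integer(fields[[2L]]),
    id = as.character(fields[[3L]]),
    ref = as.character(fields[[4L]]),
    alt = as.character(fields[[5L]]),
    qual = as.character(fields[[6L]]),
    filter = as.character(fields[[7L]]),
    info = as.character(fields[[8L]]),
    gt = gt,
    dosage = gt_dosage(gt))
}

#' Alt-allele dosage from a GT string
#'
#' Phase is ignored (`0/1` is `1|0`); any half call or missing allele yields
#' `NA`; only alleles 0 and 1 are recognized (records must be biallelic).
#'
#' @param gt character vector of GT values such as "0/1", "1|1", "./.".
#' @return integer vector of dosages in `{0, 1, 2, NA}`.
#' @export
gt_dosage <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".") || any(!al %in% c("0", "1"))) {
      return(NA_integer_)
    }
    sum(al == "1")
  }, integer(1), USE.NAMES = FALSE)
}

#' Write variant records as a single-sample VCF 4.2 file
#'
#' @param records data.table with columns `chrom`, `pos`, `ref`, `alt` and
#'   either `gt` (GT strings) or `dosage` (0/1/2/NA); optional `id`, `info`.
#' @param path output file.
#' @param sample_id sample column name.
#' @param info_header character vector of extra `##INFO=...` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_id = "SAMPLE",
                      info_header = character()) {
  records <- data.table::as.data.table(records)
  gt <- if ("gt" %in% names(records)) records$gt else dosage_gt(records$dosage)
  id <- rep_len(if ("id" %in% names(records)) records$id else ".",
                nrow(records))
  info <- rep_len(if ("info" %in% names(records)) records$info else ".",
                  nrow(records))
  id[is.na(id) | !nzchar(id)] <- "."
  info[is.na(info) | !nzchar(info)] <- "."
  ord <- order(chrom_rank(records$chrom), records$pos)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popafkit",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           info_header,
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- paste(records$chrom[ord], records$pos[ord], id[ord],
                records$ref[ord], records$alt[ord], ".", "PASS",
                info[ord], "GT", gt[ord], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' GT string from an alt-allele dosage
#' @param dosage integer vector in `{0, 1, 2, NA}`.
#' @return character GT values ("0/0", "0/1", "1/1", "./.").
#' @export
dosage_gt <- function(dosage) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "0/0"
  out[!is.na(dosage) & dosage == 1L] <- "0/1"
  out[!is.na(dosage) & dosage == 2L] <- "1/1"
  out
}
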