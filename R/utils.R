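# internal helpers: seed substreams, validation, chromosome ordering

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' All stochastic outputs of the package draw from named substreams of one
#' global seed, so adding a new output never perturbs existing ones.
#'
#' @param seed integer global seed.
#' @param name character stream name, e.g. "cohort" or "vcf:3".
#' @return an integer in \[0, 2^31 - 2\] suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(paste(name, collapse = "|"))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# order chromosomes numerically where possible, lexically otherwise
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.integer(x))
  r <- ifelse(is.na(n), 1000L + as.integer(factor(x)), n)
  r
}

locus_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement simple alleles (A/C/G/T strings)
#' @param x character vector of alleles.
#' @return complemented alleles; non-ACGT characters are left untouched.
#' @keywords internal
complement_allele <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(ifelse(ch %in% names(DNA_COMPLEMENT), DNA_COMPLEMENT[ch], ch)),
          collapse = "")
  }, character(1))
}
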