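# Synthetic admixed cohort generator: the stand-in for controlled-access
# study data. K ancestral populations diverge from a shared ancestral allele
# frequency under the Balding-Nichols F-model; individuals mix ancestries
# with Dirichlet proportions; genotypes are binomial draws from the mixed
# allele frequency. Loci are independent biallelic SNPs (no LD).

#' Specify a synthetic admixed cohort
#'
#' @param n_samples number of diploid individuals.
#' @param n_loci number of independent biallelic array loci.
#' @param n_pops number of ancestral populations K.
#' @param fst Balding-Nichols divergence c in (0, 1): population allele
#'   frequencies are Beta(p(1-c)/c, (1-p)(1-c)/c) around ancestral p.
#' @param dirichlet_alpha length-K positive concentration for the per-sample
#'   admixture proportions Q.
#' @param missing_rate independent per-entry missingness probability.
#' @param known_fraction fraction of array loci present in the known-sites
#'   (dbSNP-style) set; the default emulates the ~97% known share reported
#'   for human WGS against dbSNP.
#' @param seed global integer seed; all outputs derive named substreams
#'   from it.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples, n_loci, n_pops = 3L, fst = 0.1,
                        dirichlet_alpha = rep(1, n_pops),
                        missing_rate = 0.02, known_fraction = 0.97,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
               n_pops = as.integer(n_pops), fst = fst,
               dirichlet_alpha = as.numeric(dirichlet_alpha),
               missing_rate = missing_rate, known_fraction = known_fraction,
               seed = as.integer(seed))
  if (spec$n_samples < 1L || spec$n_loci < 1L) {
    stopf("n_samples and n_loci must be positive")
  }
  if (spec$n_pops < 1L) stopf("n_pops must be >= 1")
  if (!(spec$fst > 0 && spec$fst < 1)) stopf("fst must lie in (0, 1)")
  if (length(spec$dirichlet_alpha) != spec$n_pops ||
      any(spec$dirichlet_alpha <= 0)) {
    stopf("dirichlet_alpha must be %d positive reals", spec$n_pops)
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    stopf("missing_rate must lie in [0, 1)")
  }
  if (spec$known_fraction < 0 || spec$known_fraction > 1) {
    stopf("known_fraction must lie in [0, 1]")
  }
  class(spec) <- "cohort_spec"
  spec
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# deterministic locus map: loci spread over 22 autosomes in contiguous
# blocks, sorted positions, alleles uniform over ordered ACGT pairs
# (palindromic A/T and C/G pairs occur at their natural 1/3 rate)
make_locus_table <- function(m) {
  chrom <- as.character(rep(1:22, length.out = 22)[
    ceiling(seq_len(m) / ceiling(m / 22))])
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(2e8L, length(idx)))
  }
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1), USE.NAMES = FALSE)
  data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Simulate an admixed genotyping-array cohort with known ground truth
#'
#' Draws ancestral allele frequencies uniform on (0.05, 0.95) (array loci
#' are ascertained polymorphic), population frequencies F (K x M) from the
#' Balding-Nichols Beta model, admixture proportions Q (N x K) from a
#' Dirichlet, and genotypes g ~ Binomial(2, q_i' f_m); entries are then set
#' missing independently. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (ancestral_af, pop_af F, admixture Q, true_genotypes, the
#'   known-sites mask, and the locus table).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples; m <- spec$n_loci; k <- spec$n_pops; c0 <- spec$fst
  loci <- with_substream(spec$seed, "loci", make_locus_table(m))
  p <- with_substream(spec$seed, "ancestral", stats::runif(m, 0.05, 0.95))
  f <- with_substream(spec$seed, "popaf", {
    matrix(stats::rbeta(k * m, shape1 = rep(p * (1 - c0) / c0, each = k),
                        shape2 = rep((1 - p) * (1 - c0) / c0, each = k)),
           nrow = k)
  })
  q <- with_substream(spec$seed, "admixture", rdirichlet(n, spec$dirichlet_alpha))
  pm <- q %*% f  # N x M per-individual allele frequency
  g <- with_substream(spec$seed, "genotypes", {
    matrix(stats::rbinom(n * m, 2L, as.vector(pm)), nrow = n)
  })
  true_g <- g
  if (spec$missing_rate > 0) {
    miss <- with_substream(spec$seed, "missing", {
      matrix(stats::runif(n * m) < spec$missing_rate, nrow = n)
    })
    g[miss] <- NA_integer_
  }
  known <- with_substream(spec$seed, "known",
                          stats::runif(m) < spec$known_fraction)
  ids <- sprintf("S%03d", seq_len(n))
  gm <- genotype_matrix(g, loci, ids)
  truth <- list(ancestral_af = p, pop_af = f, admixture = q,
                true_genotypes = true_g, known = known, loci = loci,
                sample_ids = ids, spec = spec)
  class(truth) <- "cohort_truth"
  list(genotypes = gm, truth = truth)
}

#' Known-sites set implied by the simulation ground truth
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @return a data.table of known loci (chrom, pos, ref, alt).
#' @export
truth_known_sites <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  truth$loci[truth$known, c("chrom", "pos", "ref", "alt")]
}

#' Emit a per-sample VCF from the simulation ground truth
#'
#' Writes the sample's non-hom-ref array genotypes plus `extra_loci`
#' WGS-only variants (absent from the array and the known-sites set), of
#' which a fraction are indels. Optional error processes exercise the
#' validation stages: `discordance_rate` swaps het and hom-alt on emitted
#' records (so every injected error remains comparable against the array);
#' `strand_flip_rate` writes a record with both alleles
#' complemented (the genotype is unchanged, emulating an opposite-strand
#' report).
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @param sample_index which sample (1-based).
#' @param out output VCF path.
#' @param extra_loci number of WGS-only variant records to add.
#' @param indel_fraction fraction of the extra records that are indels.
#' @param discordance_rate per-record probability of a genotype error at
#'   array loci.
#' @param strand_flip_rate per-record probability of writing an array-locus
#'   record on the complementary strand.
#' @return the output path, invisibly.
#' @export
emit_sample_vcf <- function(truth, sample_index, out, extra_loci = 0L,
                            indel_fraction = 0.2, discordance_rate = 0,
                            strand_flip_rate = 0) {
  stopifnot(inherits(truth, "cohort_truth"))
  n <- nrow(truth$admixture)
  if (sample_index < 1L || sample_index > n) {
    stopf("sample_index %d outside 1..%d", sample_index, n)
  }
  seed <- truth$spec$seed
  stream <- sprintf("vcf:%d", sample_index)
  g <- truth$true_genotypes[sample_index, ]
  recs <- with_substream(seed, stream, {
    keep <- !is.na(g) & g > 0L
    arr <- truth$loci[keep]
    arr[, "dosage" := g[keep]]
    if (discordance_rate > 0 && nrow(arr)) {
      hit <- stats::runif(nrow(arr)) < discordance_rate
      arr[hit, "dosage" := 3L - dosage]
    }
    if (strand_flip_rate > 0 && nrow(arr)) {
      fl <- stats::runif(nrow(arr)) < strand_flip_rate
      arr[fl, c("ref", "alt") := list(complement_allele(ref),
                                      complement_allele(alt))]
    }
    if (extra_loci > 0L) {
      ex_chrom <- as.character(sample(1:22, extra_loci, replace = TRUE))
      ex_pos <- 2e8L + sample.int(1e8L, extra_loci)
      is_indel <- stats::runif(extra_loci) < indel_fraction
      base <- sample(c("A", "C", "G", "T"), extra_loci, replace = TRUE)
      alt1 <- vapply(base, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }, character(1), USE.NAMES = FALSE)
      ins_tail <- vapply(seq_len(extra_loci), function(i) {
        paste(sample(c("A", "C", "G", "T"), sample(1:6, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
      is_ins <- stats::runif(extra_loci) < 0.5
      ref <- ifelse(is_indel & !is_ins, paste0(base, ins_tail), base)
      alt <- ifelse(is_indel & is_ins, paste0(base, ins_tail),
                    ifelse(is_indel, base, alt1))
      ex <- data.table::data.table(
        chrom = ex_chrom, pos = ex_pos, ref = ref, alt = alt,
        dosage = sample(1:2, extra_loci, replace = TRUE))
      arr <- rbind(arr, ex)
    }
    # a locus key can collide only between array and extras; extras live
    # beyond 2e8 so positions are disjoint by construction
    arr
  })
  write_vcf(recs, out, sample_id = truth$sample_ids[sample_index])
  invisible(out)
}

#' Emit reference allele-frequency panels around the true population AFs
#'
#' One TSV panel per requested population; the panel AF is a binomial
#' resample of size 2 * n_ref around the true population frequency,
#' emulating a finite reference cohort. `n_ref = Inf` writes the true
#' frequencies exactly.
#'
#' @param truth a `cohort_truth`.
#' @param pops population names; defaults to POP1..POPK.
#' @param n_ref diploid reference cohort size per population (recycled).
#' @param out_dir output directory.
#' @return named character vector of written panel paths.
#' @export
emit_reference_panels <- function(truth, pops = NULL, n_ref = 5000L,
                                  out_dir = ".") {
  stopifnot(inherits(truth, "cohort_truth"))
  k <- nrow(truth$pop_af)
  if (is.null(pops)) pops <- sprintf("POP%d", seq_len(k))
  if (length(pops) > k) stopf("more panel names than simulated populations")
  n_ref <- rep_len(n_ref, length(pops))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(pops)) {
    f <- truth$pop_af[i, ]
    if (is.finite(n_ref[i])) {
      an <- 2L * as.integer(n_ref[i])
      af <- with_substream(truth$spec$seed, paste0("panel:", pops[i]),
                           stats::rbinom(length(f), an, f) / an)
    } else {
      an <- .Machine$integer.max
      af <- f
    }
    pan <- af_panel(data.table::data.table(truth$loci, af = af, an = an),
                    pops[i])
    path <- file.path(out_dir, paste0(pops[i], "_af.tsv"))
    write_af_panel(pan, path)
    paths[pops[i]] <- path
  }
  paths
}

#' Simulate two structural-variant call sets and a background database
#'
#' Places `n_true` non-overlapping SVs of types DEL/INV/INS on one synthetic
#' chromosome; two callers each report a true SV independently with their
#' own sensitivity and Gaussian breakpoint jitter; the database holds a
#' known fraction of the true SVs (and nothing else), so novelty has ground
#' truth. Coordinates are 0-based half-open; insertions are points
#' (end = start) with a positive `size`.
#'
#' @param n_true number of true SVs.
#' @param genome_len chromosome length in bp.
#' @param jitter_sd breakpoint jitter standard deviation in bp.
#' @param sens_a,sens_b per-caller detection sensitivities.
#' @param db_fraction fraction of true SVs present in the database.
#' @param seed integer seed.
#' @return list with data.tables `truth`, `a`, `b`, `db`; caller tables
#'   carry `truth_id` for oracle checks.
#' @export
simulate_sv_callsets <- function(n_true = 200L, genome_len = 1e8,
                                 jitter_sd = 20, sens_a = 0.9, sens_b = 0.8,
                                 db_fraction = 0.865, seed = 1L) {
  if (n_true < 1L) stopf("n_true must be positive")
  with_substream(seed, "sv", {
    sizes <- pmax(50L, as.integer(round(stats::rlnorm(n_true, log(500), 1))))
    slot <- floor(genome_len / n_true)
    if (max(sizes) + 4 * (jitter_sd + 1) >= slot) {
      stopf("genome_len too small for %d non-overlapping SVs", n_true)
    }
    start <- as.integer((seq_len(n_true) - 1L) * slot +
                          sample.int(max(1L, slot - max(sizes) -
                                           4L * as.integer(jitter_sd + 1)),
                                     n_true, replace = TRUE))
    type <- sample(c("DEL", "INV", "INS"), n_true, replace = TRUE)
    end <- ifelse(type == "INS", start, start + sizes)
    truth <- data.table::data.table(
      truth_id = seq_len(n_true), chrom = "1", start = start, end = end,
      type = type, size = sizes)
    call_set <- function(sens, caller, stream) {
      with_substream(seed, stream, {
        det <- stats::runif(n_true) < sens
        cs <- truth[det]
        if (nrow(cs) && jitter_sd > 0) {
          js <- as.integer(round(stats::rnorm(nrow(cs), 0, jitter_sd)))
          je <- as.integer(round(stats::rnorm(nrow(cs), 0, jitter_sd)))
          cs[, "start" := pmax(0L, start + js)]
          cs[, "end" := ifelse(type == "INS", start,
                               pmax(start + 1L, end + je))]
          cs[, "size" := ifelse(type == "INS", size, end - start)]
        }
        cs[, "caller" := caller]
        cs
      })
    }
    a <- call_set(sens_a, "callerA", "sv:a")
    b <- call_set(sens_b, "callerB", "sv:b")
    in_db <- with_substream(seed, "sv:db", stats::runif(n_true) < db_fraction)
    db <- truth[in_db]
    db[, "caller" := "database"]
    list(truth = truth, a = a, b = b, db = db)
  })
}

#' Emit a pathogenicity annotation table for a set of loci
#'
#' Per-locus annotation flags drawn independently at the configured rates:
#' `clinvar_class` in \{benign, non_benign, pathogenic_or_risk\}, and logical
#' `sift_deleterious`, `polyphen_deleterious`, `protein_altering`.
#'
#' @param loci data.frame with chrom, pos, ref, alt.
#' @param rates named list of probabilities: `clinvar_non_benign`,
#'   `clinvar_pathogenic_or_risk`, `sift_deleterious`,
#'   `polyphen_deleterious`, `protein_altering`.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return the annotation data.table (written to `path` when given).
#' @export
emit_pathogenicity_table <- function(loci,
                                     rates = list(clinvar_non_benign = 3e-4,
                                                  clinvar_pathogenic_or_risk = 6e-5,
                                                  sift_deleterious = 1.2e-3,
                                                  polyphen_deleterious = 1.3e-3,
                                                  protein_altering = 7.7e-3),
                                     seed = 1L, path = NULL) {
  loci <- data.table::as.data.table(loci)[, c("chrom", "pos", "ref", "alt")]
  m <- nrow(loci)
  defaults <- list(clinvar_non_benign = 0, clinvar_pathogenic_or_risk = 0,
                   sift_deleterious = 0, polyphen_deleterious = 0,
                   protein_altering = 0)
  rates <- utils::modifyList(defaults, rates)
  bad <- unlist(rates) < 0 | unlist(rates) > 1
  if (any(bad)) stopf("rates must be probabilities")
  tab <- with_substream(seed, "patho", {
    u <- stats::runif(m)
    clinvar <- ifelse(u < rates$clinvar_pathogenic_or_risk, "pathogenic_or_risk",
                      ifelse(u < rates$clinvar_pathogenic_or_risk +
                               rates$clinvar_non_benign, "non_benign", "benign"))
    sift <- stats::runif(m) < rates$sift_deleterious
    # PolyPhen-damaging calls largely overlap SIFT's in practice; couple them
    poly <- sift | (stats::runif(m) < rates$polyphen_deleterious / 4)
    prot <- sift | (stats::runif(m) < rates$protein_altering)
    data.table::data.table(loci, clinvar_class = clinvar,
                           sift_deleterious = sift,
                           polyphen_deleterious = poly,
                           protein_altering = prot)
  })
  if (!is.null(path)) {
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  }
  tab
}

#' Read a pathogenicity annotation table
#' @param path TSV written by [emit_pathogenicity_table()].
#' @return a data.table keyed by chrom, pos, ref, alt.
#' @export
read_pathogenicity_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE,
                    colClasses = list(character = c("chrom", "ref", "alt")))
}

#' Write / read an SV call-set TSV
#'
#' Columns chrom, start, end, type, size, caller; coordinates 0-based
#' half-open. `dialect = "1-based"` on read converts 1-based inclusive
#' start/end to the internal convention.
#'
#' @param calls SV data.table.
#' @param path file path.
#' @param dialect coordinate dialect of the file on read.
#' @return `path` invisibly (writer); a data.table (reader).
#' @export
write_sv_tsv <- function(calls, path) {
  cols <- intersect(c("chrom", "start", "end", "type", "size", "caller"),
                    names(calls))
  data.table::fwrite(data.table::as.data.table(calls)[, cols, with = FALSE],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path, dialect = c("0-based", "1-based")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "type")))
  if (dialect == "1-based") {
    dt[, "start" := start - 1L]  # end inclusive == half-open end
  }
  dt
}
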