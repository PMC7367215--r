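# Variant prioritization with population-specific allele frequencies.
# The rarity statistic is the pooled two-proportion Z on allele counts:
# a variant markedly rarer locally than in a reference population (large
# negative Z) deserves scrutiny; a markedly more common one (large positive
# Z) is unlikely to be strongly deleterious.

Z_TIERS <- c(rare_strong = -4, rare = -1.96, common = 1.96, common_strong = 4)

#' Pooled two-proportion Z statistic on allele counts
#'
#' `pbar = (p1*n1 + p2*n2) / (n1 + n2)`;
#' `z = (p1 - p2) / sqrt(pbar * (1 - pbar) * (1/n1 + 1/n2))`, with n in
#' alleles (2 per diploid sample). Degenerate pooled proportions (pbar of 0
#' or 1, where both cohorts are fixed) give z = 0. Vectorized; no
#' continuity correction (the cutpoints are comparative, not inferential).
#'
#' @param p1,n1 local allele frequency and allele number.
#' @param p2,n2 reference allele frequency and allele number.
#' @return signed z, positive when the local frequency is the larger.
#' @export
zscore <- function(p1, n1, p2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("allele numbers must be positive")
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  den <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / den
  z[!is.finite(z) | den == 0] <- 0
  z
}

#' Governing Z across several reference populations
#'
#' `mode = "global"` expects a single z computed against the combined
#' (allele-count-pooled) reference panel and returns it. In
#' `"strictest_vs_all"` the variant only scores when every per-population z
#' shares one sign — "different from all world populations" — and then the
#' weakest (minimum |z|) is governing; any sign conflict yields 0.
#'
#' @param z numeric vector of per-population z values (for strictest mode)
#'   or the single combined-panel z (global mode).
#' @param mode aggregation rule.
#' @return a single numeric z, or `NA_real_` for an empty input (unscored).
#' @export
governing_z <- function(z, mode = c("global", "strictest_vs_all")) {
  mode <- match.arg(mode)
  z <- z[!is.na(z)]
  if (length(z) == 0L) return(NA_real_)
  if (mode == "global") {
    if (length(z) != 1L) stopf("global mode expects one combined-panel z")
    return(z)
  }
  if (all(z > 0) || all(z < 0)) z[which.min(abs(z))] else 0
}

#' Z tier at the standard cutpoints
#'
#' Ties at exactly |z| = threshold fall in the tail (the tails are printed
#' as inclusive inequalities). `NA` z (no local AF) maps to "unscored".
#'
#' @param z numeric vector of governing z values.
#' @return character vector over \{rare_strong, rare, neutral, common,
#'   common_strong, unscored\}.
#' @export
z_tier <- function(z) {
  out <- rep("neutral", length(z))
  out[z <= Z_TIERS[["rare"]]] <- "rare"
  out[z <= Z_TIERS[["rare_strong"]]] <- "rare_strong"
  out[z >= Z_TIERS[["common"]]] <- "common"
  out[z >= Z_TIERS[["common_strong"]]] <- "common_strong"
  out[is.na(z)] <- "unscored"
  out
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".",
         trimws(formatC(x, digits = digits, format = "g")))
}

#' Annotate a sample VCF with local and reference allele frequencies
#'
#' Joins the local panel and each reference panel by exact
#' (chrom, pos, ref, alt) key, computes per-population and governing Z,
#' assigns tiers, known/novel status and pathogenicity flags, and writes an
#' annotated VCF whose INFO field gains `LOCAL_AF`, `LOCAL_AN`,
#' `REF_AF_<POP>`, `Z_<POP>`, `Z_GOV`, `TIER`, `NOVEL` and, where the
#' annotation table covers the locus, `CLNCLASS`, `SIFT_DEL`, `PP_DEL`,
#' `PROT_ALT`. Variants absent from the local panel are `TIER=unscored`.
#'
#' @param vcf path to the sample VCF.
#' @param local the local [af_panel()].
#' @param refs named list of reference [af_panel()]s.
#' @param patho optional pathogenicity data.table
#'   (see [emit_pathogenicity_table()]).
#' @param known_sites optional known-sites data.table (chrom,pos,ref,alt).
#' @param out optional annotated-VCF output path.
#' @param mode z aggregation mode, see [governing_z()].
#' @param default_ref_an allele number substituted where a reference panel
#'   lacks AN (the default is a gnomAD-scale diploid-equivalent count).
#' @return a data.table of annotated variants (one row per record) with
#'   columns chrom, pos, ref, alt, dosage, variant_type, local_af, local_an,
#'   per-population ref_af/z columns, z_gov, tier, novelty and flags.
#' @export
annotate_vcf <- function(vcf, local, refs, patho = NULL, known_sites = NULL,
                         out = NULL, mode = c("global", "strictest_vs_all"),
                         default_ref_an = 2L * 125748L) {
  mode <- match.arg(mode)
  v <- read_vcf(vcf)
  multi <- grepl(",", v$alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d unsplit multiallelic records", sum(multi)))
    v <- v[!multi]
  }
  key <- c("chrom", "pos", "ref", "alt")
  ann <- v[, c(key, "dosage"), with = FALSE]
  ann[, "variant_type" := classify_variant(ref, alt)]
  loc <- as_panel_lookup(local, "local")
  ann <- merge(ann, loc, by = key, all.x = TRUE, sort = FALSE)
  if (length(refs) == 0L) stopf("at least one reference panel is required")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stopf("refs must be a named list of panels")
  }
  for (pop in names(refs)) {
    rp <- as_panel_lookup(refs[[pop]], paste0("ref_", pop))
    an_col <- paste0("ref_", pop, "_an")
    ann <- merge(ann, rp, by = key, all.x = TRUE, sort = FALSE)
    ann[is.na(get(an_col)) & !is.na(get(paste0("ref_", pop, "_af"))),
        (an_col) := default_ref_an]
  }
  scored <- !is.na(ann$local_af)
  zc <- matrix(NA_real_, nrow(ann), length(refs),
               dimnames = list(NULL, names(refs)))
  for (pop in names(refs)) {
    paf <- ann[[paste0("ref_", pop, "_af")]]
    pan <- ann[[paste0("ref_", pop, "_an")]]
    ok <- scored & !is.na(paf)
    if (any(ok)) {
      zc[ok, pop] <- zscore(ann$local_af[ok], ann$local_an[ok],
                            paf[ok], pan[ok])
    }
    ann[, (paste0("z_", pop)) := zc[, pop]]
  }
  if (mode == "global") {
    # combined reference: allele-count-weighted pooled panel
    afm <- as.matrix(ann[, paste0("ref_", names(refs), "_af"), with = FALSE])
    anm <- as.matrix(ann[, paste0("ref_", names(refs), "_an"), with = FALSE])
    anm[is.na(afm)] <- NA_real_
    tot_an <- rowSums(anm, na.rm = TRUE)
    comb_af <- rowSums(afm * anm, na.rm = TRUE) / tot_an
    ok <- scored & tot_an > 0
    zg <- rep(NA_real_, nrow(ann))
    zg[ok] <- zscore(ann$local_af[ok], ann$local_an[ok],
                     comb_af[ok], tot_an[ok])
    ann[, "z_gov" := zg]
  } else {
    ann[, "z_gov" := apply(zc, 1L, governing_z, mode = "strictest_vs_all")]
    ann[!scored, "z_gov" := NA_real_]
  }
  ann[, "tier" := z_tier(z_gov)]
  if (!is.null(known_sites)) {
    ks <- data.table::as.data.table(known_sites)[, key, with = FALSE]
    ks[, "known" := TRUE]
    ann <- merge(ann, ks, by = key, all.x = TRUE, sort = FALSE)
    ann[, "novelty" := ifelse(is.na(known), "novel", "known")]
    ann[, "known" := NULL]
  } else {
    ann[, "novelty" := NA_character_]
  }
  if (!is.null(patho)) {
    pt <- data.table::as.data.table(patho)
    ann <- merge(ann, pt, by = key, all.x = TRUE, sort = FALSE)
  } else {
    ann[, c("clinvar_class", "sift_deleterious", "polyphen_deleterious",
            "protein_altering") :=
          list(NA_character_, NA, NA, NA)]
  }
  data.table::setorderv(ann, c("chrom", "pos"))
  ann_out <- ann
  if (!is.null(out)) {
    write_annotated_vcf(v, ann, out, names(refs))
  }
  ann_out[]
}

as_panel_lookup <- function(panel, prefix) {
  dt <- data.table::as.data.table(panel)[, c("chrom", "pos", "ref", "alt",
                                             "af", "an")]
  if (anyDuplicated(dt, by = c("chrom", "pos", "ref", "alt"))) {
    stopf("panel key collision in %s panel", prefix)
  }
  data.table::setnames(dt, c("af", "an"),
                       paste0(prefix, c("_af", "_an")))
  dt
}

write_annotated_vcf <- function(v, ann, out, pops) {
  key <- c("chrom", "pos", "ref", "alt")
  m <- merge(v, ann, by = key, all.x = TRUE, sort = FALSE,
             suffixes = c("", ".ann"))
  info <- sprintf("TIER=%s", m$tier)
  has_local <- !is.na(m$local_af)
  info[has_local] <- sprintf(
    "LOCAL_AF=%s;LOCAL_AN=%d;Z_GOV=%s;%s",
    fmt_num(m$local_af[has_local]), as.integer(m$local_an[has_local]),
    fmt_num(m$z_gov[has_local]), info[has_local])
  for (pop in pops) {
    paf <- m[[paste0("ref_", pop, "_af")]]
    pz <- m[[paste0("z_", pop)]]
    hit <- !is.na(paf)
    info[hit] <- sprintf("%s;REF_AF_%s=%s;Z_%s=%s", info[hit], pop,
                         fmt_num(paf[hit]), pop, fmt_num(pz[hit]))
  }
  if (!all(is.na(m$novelty))) {
    info <- sprintf("%s;NOVEL=%d", info,
                    as.integer(!is.na(m$novelty) & m$novelty == "novel"))
  }
  hasp <- !is.na(m$clinvar_class)
  info[hasp] <- sprintf("%s;CLNCLASS=%s;SIFT_DEL=%d;PP_DEL=%d;PROT_ALT=%d",
                        info[hasp], m$clinvar_class[hasp],
                        as.integer(m$sift_deleterious[hasp]),
                        as.integer(m$polyphen_deleterious[hasp]),
                        as.integer(m$protein_altering[hasp]))
  recs <- m[, c(key, "gt"), with = FALSE]
  recs[, "info" := info]
  hdr <- c(
    '##INFO=<ID=LOCAL_AF,Number=A,Type=Float,Description="Local cohort alt AF">',
    '##INFO=<ID=LOCAL_AN,Number=1,Type=Integer,Description="Local cohort allele number">',
    '##INFO=<ID=Z_GOV,Number=A,Type=Float,Description="Governing two-proportion Z">',
    '##INFO=<ID=TIER,Number=A,Type=String,Description="Rarity tier at Z cutpoints 1.96 and 4">',
    '##INFO=<ID=NOVEL,Number=A,Type=Integer,Description="1 if absent from known-sites set">',
    '##INFO=<ID=CLNCLASS,Number=A,Type=String,Description="Clinical class">',
    '##INFO=<ID=SIFT_DEL,Number=A,Type=Integer,Description="SIFT deleterious flag">',
    '##INFO=<ID=PP_DEL,Number=A,Type=Integer,Description="PolyPhen deleterious flag">',
    '##INFO=<ID=PROT_ALT,Number=A,Type=Integer,Description="Protein-altering flag">',
    sprintf('##INFO=<ID=REF_AF_%s,Number=A,Type=Float,Description="Reference panel AF (%s)">',
            pops, pops),
    sprintf('##INFO=<ID=Z_%s,Number=A,Type=Float,Description="Two-proportion Z vs %s">',
            pops, pops))
  write_vcf(recs, out, sample_id = "SAMPLE", info_header = hdr)
}

#' Cross-tabulate rarity tiers against pathogenicity categories
#'
#' The Table-1-style summary: for each annotation category the number of
#' scored variants overall and in the two z tails. The all-scored category
#' uses the strong threshold (|z| >= 4); annotation categories use the
#' nominal threshold (|z| >= 1.96). Unscored variants (no local AF) are
#' excluded from every denominator; their count is reported separately.
#'
#' @param ann annotated variants from [annotate_vcf()].
#' @param t_af z threshold for the all-scored category (default 4).
#' @param t_anno z threshold for annotation categories (default 1.96).
#' @return a data.table with columns category, threshold, n_all, n_rare
#'   (z <= -t), n_common (z >= t), plus attribute `n_unscored`.
#' @export
summarize_priorities <- function(ann, t_af = 4, t_anno = 1.96) {
  ann <- data.table::as.data.table(ann)
  scored <- ann[!is.na(z_gov)]
  cats <- list(
    local_af_all = list(sel = rep(TRUE, nrow(scored)), t = t_af),
    clinvar_non_benign = list(
      sel = !is.na(scored$clinvar_class) &
        scored$clinvar_class %in% c("non_benign", "pathogenic_or_risk"),
      t = t_anno),
    clinvar_pathogenic_or_risk = list(
      sel = !is.na(scored$clinvar_class) &
        scored$clinvar_class == "pathogenic_or_risk",
      t = t_anno),
    sift_deleterious = list(
      sel = !is.na(scored$sift_deleterious) & scored$sift_deleterious == TRUE,
      t = t_anno),
    sift_polyphen_deleterious = list(
      sel = (!is.na(scored$sift_deleterious) & scored$sift_deleterious == TRUE) |
        (!is.na(scored$polyphen_deleterious) &
           scored$polyphen_deleterious == TRUE),
      t = t_anno),
    protein_altering = list(
      sel = !is.na(scored$protein_altering) & scored$protein_altering == TRUE,
      t = t_anno))
  rows <- lapply(names(cats), function(nm) {
    sel <- cats[[nm]]$sel
    t <- cats[[nm]]$t
    z <- scored$z_gov[sel]
    data.table::data.table(category = nm, threshold = t,
                           n_all = length(z),
                           n_rare = sum(z <= -t),
                           n_common = sum(z >= t))
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "n_unscored", nrow(ann) - nrow(scored))
  out
}

#' Write a priority summary as TSV and JSON
#' @param summary output of [summarize_priorities()].
#' @param tsv,json output paths (either may be NULL).
#' @return `summary`, invisibly.
#' @export
write_priority_summary <- function(summary, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) data.table::fwrite(summary, tsv, sep = "\t", quote = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(n_unscored = attr(summary, "n_unscored"),
           categories = summary),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(summary)
}
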