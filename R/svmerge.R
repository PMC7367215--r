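# Two-caller structural-variant intersection and novelty classification.
# Only calls supported by both callers survive; equivalence is reciprocal
# overlap for length events (DEL/INV) and a breakpoint-window + size-ratio
# rule for insertions (point events, for which reciprocal overlap is
# undefined). Coordinates are 0-based half-open throughout.

#' Reciprocal overlap of two intervals
#'
#' min(overlap/len(a), overlap/len(b)); 0 for disjoint or zero-length
#' inputs. Vectorized over aligned interval vectors.
#'
#' @param a_start,a_end,b_start,b_end 0-based half-open interval bounds.
#' @return numeric vector in \[0, 1\].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  la <- a_end - a_start
  lb <- b_end - b_start
  out <- ifelse(la > 0 & lb > 0, pmin(ov / la, ov / lb), 0)
  out
}

validate_sv <- function(calls, name) {
  calls <- data.table::copy(data.table::as.data.table(calls))
  need <- c("chrom", "start", "end", "type")
  if (!all(need %in% names(calls))) {
    stopf("%s needs columns %s", name, paste(need, collapse = ", "))
  }
  if (!"size" %in% names(calls)) {
    calls[, "size" := pmax(end - start, 1L)]
  }
  bad <- which(calls$end < calls$start | calls$size <= 0 |
                 (calls$type %in% c("DEL", "INV") &
                    calls$size != calls$end - calls$start))
  if (length(bad)) {
    stopf("%s has malformed intervals at rows: %s", name,
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  calls
}

# candidate pair score for greedy matching: reciprocal overlap for length
# events; for insertions a pseudo-score in (0,1] decreasing with breakpoint
# distance so ties prefer the nearest partner
sv_pair_score <- function(pairs, ro_min, ins_window, ins_size_ratio) {
  len_ev <- pairs$type != "INS"
  score <- numeric(nrow(pairs))
  score[len_ev] <- reciprocal_overlap(pairs$start_a[len_ev], pairs$end_a[len_ev],
                                      pairs$start_b[len_ev], pairs$end_b[len_ev])
  ins <- !len_ev
  if (any(ins)) {
    dist <- abs(pairs$start_a[ins] - pairs$start_b[ins])
    ratio <- pmin(pairs$size_a[ins], pairs$size_b[ins]) /
      pmax(pairs$size_a[ins], pairs$size_b[ins])
    ok <- dist <= ins_window & ratio >= ins_size_ratio
    score[ins] <- ifelse(ok, 1 - dist / (ins_window + 1), 0)
  }
  eligible <- logical(nrow(pairs))
  eligible[len_ev] <- score[len_ev] >= ro_min
  eligible[ins] <- score[ins] > 0
  list(score = score, eligible = eligible)
}

#' Intersect two SV call sets into consensus calls
#'
#' DEL/INV calls match when they share chrom and type with reciprocal
#' overlap >= `ro_min`; INS calls match when breakpoints lie within
#' `ins_window` bp and the size ratio min/max >= `ins_size_ratio`.
#' Matching is one-to-one and greedy by best overlap (nearest breakpoint
#' for insertions), ties broken by smaller caller-A start then caller-B
#' start; unmatched calls are discarded. The consensus interval is the
#' union of the two supports.
#'
#' @param a,b SV data.tables (chrom, start, end, type, size, ...).
#' @param ro_min reciprocal-overlap threshold (default 0.5).
#' @param ins_window insertion breakpoint window in bp.
#' @param ins_size_ratio minimum insertion size ratio.
#' @return data.table of merged SVs: chrom, start, end, type, size, the
#'   supporting coordinates from both callers, and (when present in the
#'   inputs) their `truth_id`s.
#' @export
intersect_callers <- function(a, b, ro_min = 0.5, ins_window = 100L,
                              ins_size_ratio = 0.5) {
  a <- validate_sv(a, "call set A")
  b <- validate_sv(b, "call set B")
  a[, "row_a" := .I]; b[, "row_b" := .I]
  pairs <- merge(
    a[, c("row_a", "chrom", "type", "start", "end", "size")],
    b[, c("row_b", "chrom", "type", "start", "end", "size")],
    by = c("chrom", "type"), allow.cartesian = TRUE,
    suffixes = c("_a", "_b"))
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    type = character(), size = integer(),
    start_a = integer(), end_a = integer(),
    start_b = integer(), end_b = integer())
  if (nrow(pairs) == 0L) return(empty)
  sc <- sv_pair_score(pairs, ro_min, ins_window, ins_size_ratio)
  pairs[, "score" := sc$score]
  pairs <- pairs[sc$eligible]
  if (nrow(pairs) == 0L) return(empty)
  data.table::setorderv(pairs, c("score", "start_a", "start_b"),
                        order = c(-1L, 1L, 1L))
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ra <- pairs$row_a[i]; rb <- pairs$row_b[i]
    if (!used_a[ra] && !used_b[rb]) {
      used_a[ra] <- used_b[rb] <- TRUE
      take[i] <- TRUE
    }
  }
  hits <- pairs[take]
  out <- data.table::data.table(
    chrom = hits$chrom,
    start = pmin(hits$start_a, hits$start_b),
    end = pmax(hits$end_a, hits$end_b),
    type = hits$type,
    start_a = hits$start_a, end_a = hits$end_a,
    start_b = hits$start_b, end_b = hits$end_b,
    ro = hits$score)
  out[, "size" := ifelse(type == "INS",
                         as.integer(round((hits$size_a + hits$size_b) / 2)),
                         end - start)]
  if ("truth_id" %in% names(a)) out[, "truth_id_a" := a$truth_id[hits$row_a]]
  if ("truth_id" %in% names(b)) out[, "truth_id_b" := b$truth_id[hits$row_b]]
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

#' Classify merged SVs as known or novel against a background database
#'
#' A merged SV is known when the database holds a record of the same type
#' and chromosome with reciprocal overlap >= `ro_min` (insertions: the
#' breakpoint-window/size-ratio rule). Tallies are grouped by type and
#' novelty.
#'
#' @param merged output of [intersect_callers()].
#' @param db database SV data.table (DGV-style).
#' @param ro_min,ins_window,ins_size_ratio matching thresholds, as in
#'   [intersect_callers()].
#' @return list with `calls` (merged + `novelty` column), `tally`
#'   (type x novelty counts) and `novel_fraction`.
#' @export
classify_novelty <- function(merged, db, ro_min = 0.5, ins_window = 100L,
                             ins_size_ratio = 0.5) {
  merged <- data.table::copy(data.table::as.data.table(merged))
  db <- validate_sv(db, "SV database")
  known <- logical(nrow(merged))
  if (nrow(db) && nrow(merged)) {
    merged[, "row_m" := .I]
    db[, "row_d" := .I]
    pairs <- merge(
      merged[, c("row_m", "chrom", "type", "start", "end", "size")],
      db[, c("row_d", "chrom", "type", "start", "end", "size")],
      by = c("chrom", "type"), allow.cartesian = TRUE,
      suffixes = c("_a", "_b"))
    if (nrow(pairs)) {
      sc <- sv_pair_score(pairs, ro_min, ins_window, ins_size_ratio)
      known[unique(pairs$row_m[sc$eligible])] <- TRUE
    }
    merged[, "row_m" := NULL]
  }
  merged[, "novelty" := ifelse(known, "known", "novel")]
  tally <- merged[, list(n = .N), by = c("type", "novelty")]
  data.table::setorderv(tally, c("type", "novelty"))
  list(calls = merged[], tally = tally[],
       novel_fraction = if (nrow(merged)) mean(!known) else NA_real_)
}

#' Write merged SVs as a symbolic-ALT VCF
#'
#' Records use symbolic alternate alleles (<DEL>, <INV>, <INS>) with END
#' and SVLEN INFO keys; POS is the 1-based base before the event per VCF
#' convention for symbolic records.
#'
#' @param merged merged SV data.table (optionally with `novelty`).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(merged, path) {
  merged <- data.table::as.data.table(merged)
  ord <- order(chrom_rank(merged$chrom), merged$start)
  m <- merged[ord]
  info <- sprintf("END=%d;SVLEN=%d", m$end,
                  ifelse(m$type == "DEL", -m$size, m$size))
  if ("novelty" %in% names(m)) {
    info <- sprintf("%s;NOVEL=%d", info, as.integer(m$novelty == "novel"))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popafkit",
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=INV,Description="Inversion">',
           '##ALT=<ID=INS,Description="Insertion">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=NOVEL,Number=1,Type=Integer,Description="1 if absent from background database">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- paste(m$chrom, m$start + 1L, ".", "N",
                paste0("<", m$type, ">"), ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
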