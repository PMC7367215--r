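# shared fixture builders: everything is generated in code, no data files

small_cohort <- function(n = 60, m = 1500, k = 3, fst = 0.15, seed = 42,
                         missing_rate = 0.02) {
  simulate_cohort(cohort_spec(n, m, n_pops = k, fst = fst,
                              missing_rate = missing_rate, seed = seed))
}

# hand-construct a tiny single-sample VCF from a record table
write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                          sample_id = "TOY") {
  write_vcf(data.table::as.data.table(records), path, sample_id = sample_id)
  path
}

toy_loci <- function(chrom, pos, ref, alt) {
  data.table::data.table(chrom = as.character(chrom), pos = as.integer(pos),
                         ref = ref, alt = alt)
}

# independent all-pairs greedy matcher used as the oracle for the merge
brute_force_merge <- function(a, b, ro_min = 0.5, ins_window = 100,
                              ins_size_ratio = 0.5) {
  score <- function(x, y) {
    if (x$chrom != y$chrom || x$type != y$type) return(-1)
    if (x$type == "INS") {
      dist <- abs(x$start - y$start)
      ratio <- min(x$size, y$size) / max(x$size, y$size)
      if (dist <= ins_window && ratio >= ins_size_ratio) {
        return(1 - dist / (ins_window + 1))
      }
      return(-1)
    }
    ov <- max(0, min(x$end, y$end) - max(x$start, y$start))
    ro <- min(ov / (x$end - x$start), ov / (y$end - y$start))
    if (ro >= ro_min) ro else -1
  }
  cand <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- score(a[i, ], b[j, ])
      if (s >= 0) cand[[length(cand) + 1]] <- list(i = i, j = j, s = s,
                                                   sa = a$start[i],
                                                   sb = b$start[j])
    }
  }
  if (!length(cand)) return(data.table::data.table())
  ord <- order(-vapply(cand, `[[`, numeric(1), "s"),
               vapply(cand, `[[`, numeric(1), "sa"),
               vapply(cand, `[[`, numeric(1), "sb"))
  used_a <- used_b <- integer(0)
  out <- list()
  for (k in ord) {
    p <- cand[[k]]
    if (p$i %in% used_a || p$j %in% used_b) next
    used_a <- c(used_a, p$i); used_b <- c(used_b, p$j)
    out[[length(out) + 1]] <- data.table::data.table(
      chrom = a$chrom[p$i], start = min(a$start[p$i], b$start[p$j]),
      end = max(a$end[p$i], b$end[p$j]), type = a$type[p$i])
  }
  data.table::rbindlist(out)
}
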