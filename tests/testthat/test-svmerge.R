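test_that("reciprocal overlap follows the min-of-both-fractions definition", {
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1.0)
  expect_equal(reciprocal_overlap(100, 200, 150, 250), 0.5)
  expect_equal(reciprocal_overlap(100, 200, 300, 400), 0.0)
  expect_equal(reciprocal_overlap(100, 100, 100, 200), 0.0)  # zero-length
  expect_equal(reciprocal_overlap(0, 100, 50, 100), 0.5)
})

test_that("caller intersection is exact on identity and disjoint inputs", {
  a <- data.table::data.table(chrom = c("1", "1", "2"),
                              start = c(100L, 5000L, 100L),
                              end = c(600L, 5000L, 900L),
                              type = c("DEL", "INS", "INV"),
                              size = c(500L, 120L, 800L))
  m <- intersect_callers(a, a)
  expect_equal(nrow(m), 3)
  expect_equal(m[order(chrom, start)]$start, c(100L, 5000L, 100L))
  expect_equal(m[order(chrom, start)]$end, c(600L, 5000L, 900L))

  b <- data.table::copy(a)[, chrom := c("3", "4", "5")]
  expect_equal(nrow(intersect_callers(a, b)), 0)

  # a DEL and an INV on the same interval never match across types
  x <- data.table::data.table(chrom = "1", start = 0L, end = 100L,
                              type = "DEL", size = 100L)
  y <- data.table::data.table(chrom = "1", start = 0L, end = 100L,
                              type = "INV", size = 100L)
  expect_equal(nrow(intersect_callers(x, y)), 0)

  expect_error(intersect_callers(
    data.table::data.table(chrom = "1", start = 10L, end = 5L,
                           type = "DEL", size = 5L), a), "malformed")
})

test_that("greedy intersection equals the all-pairs oracle on jittered call sets", {
  sets <- simulate_sv_callsets(n_true = 150, jitter_sd = 20, sens_a = 0.9,
                               sens_b = 0.8, db_fraction = 0.5, seed = 19)
  merged <- intersect_callers(sets$a, sets$b)
  oracle <- brute_force_merge(sets$a, sets$b)
  key <- function(x) sort(paste(x$chrom, x$start, x$end, x$type))
  expect_equal(key(merged), key(oracle))

  # symmetry: consensus intervals are identical both ways
  swapped <- intersect_callers(sets$b, sets$a)
  expect_equal(key(merged), key(swapped))

  # lowering the threshold never shrinks the merged set
  expect_gte(nrow(intersect_callers(sets$a, sets$b, ro_min = 0.3)),
             nrow(merged))

  # recall against truth approximates the product of sensitivities
  recall <- nrow(merged) / nrow(sets$truth)
  expect_lt(abs(recall - 0.72), 3 * sqrt(0.72 * 0.28 / 150) + 0.03)

  # jitter-free perfect callers reproduce the truth exactly
  perfect <- simulate_sv_callsets(n_true = 50, jitter_sd = 0, sens_a = 1,
                                  sens_b = 1, seed = 2)
  mp <- intersect_callers(perfect$a, perfect$b)
  expect_equal(key(mp), key(perfect$truth))
})

test_that("novelty classification against the database matches ground truth", {
  sets <- simulate_sv_callsets(n_true = 120, jitter_sd = 10, sens_a = 0.95,
                               sens_b = 0.9, db_fraction = 0.6, seed = 23)
  merged <- intersect_callers(sets$a, sets$b)

  none <- classify_novelty(merged, sets$db[0])
  expect_true(all(none$calls$novelty == "novel"))

  self <- classify_novelty(merged, merged)
  expect_true(all(self$calls$novelty == "known"))

  cls <- classify_novelty(merged, sets$db)
  # conservation: per-type tallies sum to the merged count
  expect_equal(sum(cls$tally$n), nrow(merged))
  # ground truth: a merged SV is known iff its true id is in the database
  truth_known <- cls$calls$truth_id_a %in% sets$db$truth_id
  expect_equal(cls$calls$novelty == "known", truth_known)

  # the VCF writer emits one symbolic record per merged call
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(cls$calls, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_equal(length(body), nrow(merged))
  expect_true(all(grepl("<DEL>|<INV>|<INS>", body)))
})

test_that("SV TSV round-trips including the 1-based dialect", {
  calls <- data.table::data.table(chrom = "1", start = c(9L, 99L),
                                  end = c(59L, 99L), type = c("DEL", "INS"),
                                  size = c(50L, 30L), caller = "x")
  path <- tempfile(fileext = ".tsv")
  write_sv_tsv(calls, path)
  back <- read_sv_tsv(path)
  expect_equal(back$start, calls$start)
  one_based <- read_sv_tsv(path, dialect = "1-based")
  expect_equal(one_based$start, calls$start - 1L)
})
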