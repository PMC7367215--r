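test_that("zscore matches the pooled two-proportion formula", {
  expect_equal(zscore(0.3, 1000, 0.3, 500), 0)
  expect_equal(zscore(0, 1000, 0, 500), 0)   # degenerate pooled proportion
  expect_equal(zscore(1, 1000, 1, 500), 0)

  # independent arithmetic oracle, evaluated step by step
  pbar <- (0.05 * 2000 + 0.025 * 2000) / 4000          # 0.0375
  se <- sqrt(pbar * (1 - pbar) * (1 / 2000 + 1 / 2000)) # 0.006007807...
  expect_equal(zscore(0.05, 2000, 0.025, 2000), (0.05 - 0.025) / se,
               tolerance = 1e-12)
  expect_equal(zscore(0.05, 2000, 0.025, 2000), 4.161252, tolerance = 1e-6)

  expect_error(zscore(0.1, 0, 0.2, 100), "positive")
})

test_that("zscore is antisymmetric and monotone in the local frequency", {
  set.seed(7)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(10:5000, 1); n2 <- sample(10:5000, 1)
    expect_equal(zscore(p1, n1, p2, n2), -zscore(p2, n2, p1, n1),
                 tolerance = 1e-12)
    expect_equal(sign(zscore(p1, n1, p2, n2)), sign(p1 - p2))
  }
  p1 <- seq(0, 1, by = 0.02)
  z <- zscore(p1, 800, 0.4, 3000)
  expect_true(all(diff(z) > 0))
})

test_that("governing z aggregates per-population scores as specified", {
  expect_equal(governing_z(2.5, mode = "strictest_vs_all"), 2.5)
  expect_equal(governing_z(c(5.1, 4.2, 6.0), mode = "strictest_vs_all"), 4.2)
  expect_equal(governing_z(c(3.0, -2.0), mode = "strictest_vs_all"), 0)
  expect_equal(governing_z(c(-3.0, -1.2, -8), mode = "strictest_vs_all"), -1.2)
  expect_true(is.na(governing_z(numeric(0))))
  expect_equal(governing_z(1.7, mode = "global"), 1.7)
})

test_that("z tiers are exhaustive, disjoint and tail-inclusive at the cutpoints", {
  z <- c(-5, -4, -3, -1.96, -1, 0, 1, 1.96, 3, 4, 5, NA)
  expect_equal(z_tier(z),
               c("rare_strong", "rare_strong", "rare", "rare", "neutral",
                 "neutral", "neutral", "common", "common", "common_strong",
                 "common_strong", "unscored"))
  # tier conservation: strong tails are subsets of the nominal tails
  set.seed(3)
  zz <- rnorm(2000, sd = 3)
  t <- z_tier(zz)
  expect_true(all(zz[t == "rare_strong"] <= -1.96))
  expect_true(all(zz[t == "common_strong"] >= 1.96))
  expect_equal(sum(t %in% c("rare_strong", "rare", "neutral", "common",
                            "common_strong")), length(zz))
})

make_annotation_world <- function() {
  # 6 array loci with known frequencies + 1 WGS-only locus
  loci <- toy_loci("1", (1:6) * 100, c("A", "C", "G", "T", "A", "C"),
                   c("G", "T", "A", "C", "C", "A"))
  local <- af_panel(data.table::data.table(
    loci, af = c(0.30, 0.05, 0.60, 0.30, 0.50, 0.02), an = 2000L), "LOCAL")
  ref <- af_panel(data.table::data.table(
    loci, af = c(0.30, 0.30, 0.10, 0.30, 0.50, 0.02), an = 10000L), "REF")
  recs <- data.table::data.table(
    chrom = "1", pos = c((1:6) * 100, 999L),
    ref = c(loci$ref, "A"), alt = c(loci$alt, "T"),
    dosage = c(1L, 2L, 1L, 1L, 2L, 1L, 1L))
  vcf <- write_toy_vcf(recs)
  list(vcf = vcf, local = local, ref = ref, loci = loci)
}

test_that("annotate_vcf joins panels, scores and tiers variants", {
  w <- make_annotation_world()
  out <- tempfile(fileext = ".vcf")
  ann <- annotate_vcf(w$vcf, w$local, list(REF = w$ref), out = out)

  expect_equal(nrow(ann), 7)
  at <- function(p) ann[pos == p]
  expect_equal(at(100)$tier, "neutral")       # p1 == p2 -> z = 0
  expect_equal(at(100)$z_gov, 0)
  expect_equal(at(500)$tier, "neutral")
  expect_equal(at(200)$tier, "rare_strong")   # 5% local vs 30% reference
  expect_equal(at(300)$tier, "common_strong")
  expect_equal(at(999)$tier, "unscored")      # absent from the local panel
  expect_true(is.na(at(999)$z_gov))
  # z agrees with a direct call on the joined frequencies
  expect_equal(at(200)$z_gov, zscore(0.05, 2000, 0.30, 10000))

  # the annotated VCF carries the INFO keys
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_true(any(grepl("TIER=rare_strong", body)))
  expect_true(any(grepl("LOCAL_AF=0.05", body, fixed = TRUE)))
  expect_true(any(grepl("Z_GOV=", body)))
  expect_true(sum(grepl("TIER=unscored", body)) == 1)
})

test_that("priority summary equals a brute-force tally over a toy stream", {
  set.seed(21)
  n <- 20
  ann <- data.table::data.table(
    chrom = "1", pos = 1:n, ref = "A", alt = "G",
    z_gov = c(rnorm(16, sd = 3), NA, NA, 5, -5),
    clinvar_class = sample(c("benign", "non_benign", "pathogenic_or_risk"),
                           n, replace = TRUE),
    sift_deleterious = sample(c(TRUE, FALSE), n, replace = TRUE),
    polyphen_deleterious = sample(c(TRUE, FALSE), n, replace = TRUE),
    protein_altering = sample(c(TRUE, FALSE), n, replace = TRUE))
  s <- summarize_priorities(ann)
  expect_equal(attr(s, "n_unscored"), 2L)

  # independent set-filter oracle
  scored <- ann[!is.na(ann$z_gov)]
  oracle <- function(rows, t) {
    c(all = nrow(rows), rare = sum(rows$z_gov <= -t),
      common = sum(rows$z_gov >= t))
  }
  o <- oracle(scored, 4)
  expect_equal(unlist(s[s$category == "local_af_all",
                        c("n_all", "n_rare", "n_common")], use.names = FALSE),
               unname(o))
  o <- oracle(scored[scored$clinvar_class != "benign", ], 1.96)
  expect_equal(unlist(s[s$category == "clinvar_non_benign",
                        c("n_all", "n_rare", "n_common")], use.names = FALSE),
               unname(o))
  o <- oracle(scored[scored$sift_deleterious | scored$polyphen_deleterious, ],
              1.96)
  expect_equal(unlist(s[s$category == "sift_polyphen_deleterious",
                        c("n_all", "n_rare", "n_common")], use.names = FALSE),
               unname(o))
  # tails are within their all-counts and disjoint
  expect_true(all(s$n_rare + s$n_common <= s$n_all))

  empty <- summarize_priorities(ann[0])
  expect_true(all(empty$n_all == 0))
})

test_that("multiallelic records are skipped with a warning and panels reject key collisions", {
  recs <- data.table::data.table(chrom = "1", pos = c(10L, 20L),
                                 ref = c("A", "C"), alt = c("G,T", "T"),
                                 dosage = c(1L, 1L))
  vcf <- write_toy_vcf(recs)
  loci <- toy_loci("1", 20, "C", "T")
  local <- af_panel(data.table::data.table(loci, af = 0.1, an = 100L), "L")
  ref <- af_panel(data.table::data.table(loci, af = 0.1, an = 100L), "R")
  expect_warning(ann <- annotate_vcf(vcf, local, list(R = ref)),
                 "multiallelic")
  expect_equal(nrow(ann), 1)

  dup <- af_panel(data.table::data.table(rbind(loci, loci),
                                         af = 0.1, an = 100L), "L")
  expect_error(suppressWarnings(annotate_vcf(vcf, dup, list(R = ref))),
               "collision")
})
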