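test_that("cohort simulation is deterministic and respects the model", {
  spec <- cohort_spec(40, 800, n_pops = 3, fst = 0.1, seed = 9)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$truth$pop_af, b$truth$pop_af)

  # Q rows live on the simplex
  expect_true(all(abs(rowSums(a$truth$admixture) - 1) < 1e-9))
  expect_true(all(a$truth$admixture >= 0))

  # K = 1 collapses Q to the single vertex
  one <- simulate_cohort(cohort_spec(10, 50, n_pops = 1, dirichlet_alpha = 2,
                                     seed = 1))
  expect_equal(unname(one$truth$admixture[, 1]), rep(1, 10))

  # Balding-Nichols concentration: population AFs hug the ancestral AF as
  # divergence shrinks
  tight <- simulate_cohort(cohort_spec(5, 400, n_pops = 3, fst = 0.001, seed = 2))
  loose <- simulate_cohort(cohort_spec(5, 400, n_pops = 3, fst = 0.3, seed = 2))
  dev <- function(s) max(abs(sweep(s$truth$pop_af, 2, s$truth$ancestral_af)))
  expect_lt(dev(tight), 0.06)
  expect_gt(dev(loose), dev(tight))

  expect_error(cohort_spec(10, 10, fst = 1.2), "fst")
  expect_error(cohort_spec(10, 10, missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(10, 10, n_pops = 3, dirichlet_alpha = c(1, 1)),
               "dirichlet_alpha")
})

test_that("sample AF deviation from its expectation matches binomial sampling variance", {
  sim <- simulate_cohort(cohort_spec(200, 5000, n_pops = 3, fst = 0.1,
                                     missing_rate = 0, seed = 7))
  g <- sim$genotypes$genotypes
  n <- nrow(g)
  af <- colSums(g) / (2 * n)
  pim <- sim$truth$admixture %*% sim$truth$pop_af   # per-individual AF
  eaf <- colMeans(pim)
  # analytic variance of the sample AF given Q and F
  vaf <- colSums(2 * pim * (1 - pim)) / (2 * n)^2
  ratio <- mean((af - eaf)^2) / mean(vaf)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("emitted sample VCFs mirror the truth and round-trip exactly", {
  sim <- small_cohort(n = 20, m = 400, seed = 5, missing_rate = 0.05)
  path <- tempfile(fileext = ".vcf")

  # no extras: records are exactly the sample's non-hom-ref array loci
  # (array missingness is a chip artifact; the WGS call set does not see it)
  emit_sample_vcf(sim$truth, 3, path, extra_loci = 0)
  v <- read_vcf(path)
  g <- sim$truth$true_genotypes[3, ]
  keep <- g > 0
  expect_equal(nrow(v), sum(keep))
  key_v <- paste(v$chrom, v$pos, v$ref, v$alt)
  key_t <- with(sim$truth$loci[keep], paste(chrom, pos, ref, alt))
  expect_setequal(key_v, key_t)
  expect_equal(v$dosage[match(key_t, key_v)], unname(g[keep]))

  # determinism: identical spec + seed -> byte-identical files
  path2 <- tempfile(fileext = ".vcf")
  emit_sample_vcf(sim$truth, 3, path2, extra_loci = 0)
  expect_identical(readLines(path), readLines(path2))

  # indel fraction among extras is binomial
  emit_sample_vcf(sim$truth, 1, path, extra_loci = 1000, indel_fraction = 0.2)
  v <- read_vcf(path)
  extras <- v[pos > 2e8]
  expect_equal(nrow(extras), 1000)
  n_indel <- sum(classify_variant(extras$ref, extras$alt) != "SNP")
  expect_lt(abs(n_indel - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  expect_error(emit_sample_vcf(sim$truth, 99, path), "sample_index")
})

test_that("reference panels resample the true population AFs", {
  sim <- small_cohort(n = 10, m = 2000, seed = 11)
  dir <- tempfile(); dir.create(dir)

  exact <- emit_reference_panels(sim$truth, pops = "POP1", n_ref = Inf,
                                 out_dir = dir)
  pan <- read_af_panel(exact[["POP1"]], "POP1")
  key <- paste(pan$chrom, pan$pos)
  truth_key <- paste(sim$truth$loci$chrom, sim$truth$loci$pos)
  expect_equal(pan$af[match(truth_key, key)], sim$truth$pop_af[1, ],
               tolerance = 1e-9)

  finite <- emit_reference_panels(sim$truth, pops = c("POP1", "POP2"),
                                  n_ref = 400, out_dir = dir)
  pan <- read_af_panel(finite[["POP2"]], "POP2")
  expect_true(all(pan$af >= 0 & pan$af <= 1))
  expect_true(all(pan$an == 800))
  f <- sim$truth$pop_af[2, match(paste(pan$chrom, pan$pos), truth_key)]
  # half-normal mean of the binomial sampling error
  expected <- mean(sqrt(f * (1 - f) / 800) * sqrt(2 / pi))
  expect_equal(mean(abs(pan$af - f)), expected, tolerance = 0.08)
})

test_that("simulated SV call sets have the stated sensitivity and database structure", {
  perfect <- simulate_sv_callsets(n_true = 60, jitter_sd = 0, sens_a = 1,
                                  sens_b = 1, db_fraction = 0, seed = 4)
  expect_equal(perfect$a[, c("chrom", "start", "end", "type")],
               perfect$truth[, c("chrom", "start", "end", "type")])
  expect_equal(perfect$b$start, perfect$truth$start)
  expect_equal(nrow(perfect$db), 0)

  sets <- simulate_sv_callsets(n_true = 400, jitter_sd = 15, sens_a = 0.9,
                               sens_b = 0.8, db_fraction = 0.5, seed = 8)
  both <- length(intersect(sets$a$truth_id, sets$b$truth_id))
  expect_lt(abs(both - 400 * 0.9 * 0.8), 3 * sqrt(400 * 0.72 * 0.28))
  # true SVs never overlap each other
  tr <- sets$truth[order(start)]
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
})

test_that("pathogenicity tables honor their flag rates", {
  loci <- toy_loci("1", 1:5000, "A", "G")
  zero <- emit_pathogenicity_table(loci, rates = list(), seed = 1)
  expect_true(all(zero$clinvar_class == "benign"))
  expect_false(any(zero$sift_deleterious | zero$polyphen_deleterious |
                     zero$protein_altering))

  all_prot <- emit_pathogenicity_table(loci,
                                       rates = list(protein_altering = 1),
                                       seed = 1)
  expect_true(all(all_prot$protein_altering))

  tab <- emit_pathogenicity_table(loci,
                                  rates = list(clinvar_non_benign = 0.05,
                                               sift_deleterious = 0.1),
                                  seed = 3)
  n <- nrow(tab)
  expect_lt(abs(sum(tab$clinvar_class != "benign") - 0.05 * n),
            3 * sqrt(n * 0.05 * 0.95))
  expect_lt(abs(sum(tab$sift_deleterious) - 0.1 * n),
            3 * sqrt(n * 0.1 * 0.9))
  expect_error(emit_pathogenicity_table(loci, rates = list(sift_deleterious = 2)),
               "probabilities")
})
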