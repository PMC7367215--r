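test_that("PCA separates diverged populations and projection is self-consistent", {
  set.seed(31)
  m <- 800; n <- 60
  p <- runif(m, 0.1, 0.9)
  c0 <- 0.3
  f1 <- rbeta(m, p * (1 - c0) / c0, (1 - p) * (1 - c0) / c0)
  f2 <- rbeta(m, p * (1 - c0) / c0, (1 - p) * (1 - c0) / c0)
  lab <- rep(c("one", "two"), each = n / 2)
  g <- rbind(matrix(rbinom(n / 2 * m, 2, rep(f1, each = n / 2)), n / 2),
             matrix(rbinom(n / 2 * m, 2, rep(f2, each = n / 2)), n / 2))
  gm <- genotype_matrix(g, toy_loci("1", seq_len(m), "A", "G"))
  model <- suppressWarnings(fit_pca(gm, d = 2))

  pc1 <- model$reference_coords[, 1]
  expect_true(max(pc1[lab == "one"]) < min(pc1[lab == "two"]) ||
                max(pc1[lab == "two"]) < min(pc1[lab == "one"]))

  # projecting the reference reproduces its own coordinates
  proj <- project_pca(model, gm$genotypes[, model$kept, drop = FALSE])
  expect_equal(unname(proj), unname(model$reference_coords), tolerance = 1e-8)

  # duplicated sample receives identical coordinates
  expect_equal(project_pca(model, gm$genotypes[3, model$kept]),
               model$reference_coords[3, , drop = FALSE],
               ignore_attr = TRUE)

  # all-missing vector projects to the origin
  expect_equal(unname(project_pca(
    model, rep(NA_integer_, sum(model$kept)))), matrix(0, 1, 2))

  # loadings are orthonormal; retained variance equals the eigenvalues
  expect_equal(crossprod(model$loadings), diag(2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(apply(model$reference_coords, 2, function(x) {
    sum(x^2) / (nrow(g) - 1)
  }), model$eigenvalues, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(suppressWarnings(fit_pca(gm, d = 1e4)), "rank")
})

test_that("supervised admixture EM recovers vertices and never decreases the likelihood", {
  # K = 1: trivial simplex
  one <- supervised_admixture(c(0L, 1L, 2L), matrix(0.5, 1, 3))
  expect_equal(unname(one$Q), 1)

  # separated rows force the vertex
  m <- 500
  F <- rbind(rep(0.999, m), rep(0.001, m))
  fit <- supervised_admixture(rep(2L, m), F)
  expect_gt(fit$Q[1], 0.999)
  expect_lt(fit$Q[2], 0.001)

  # monotone log-likelihood on a messy random problem with missing data
  set.seed(37)
  F3 <- matrix(runif(3 * 400, 0.05, 0.95), 3)
  g <- rbinom(400, 2, as.vector(crossprod(F3, c(0.2, 0.5, 0.3))))
  g[sample(400, 40)] <- NA
  fit3 <- supervised_admixture(g, F3)
  expect_true(all(diff(fit3$loglik_trace) >= -1e-9))
  expect_equal(sum(fit3$Q), 1, tolerance = 1e-9)
  expect_equal(fit3$n_loci_used, 360)

  expect_error(supervised_admixture(rep(NA_integer_, 5), matrix(0.5, 2, 5)),
               "usable")
  expect_error(supervised_admixture(c(1L, 1L), matrix(0.5, 2, 5)), "columns")
})

test_that("representative selection is the centroid argmin with documented tie-breaks", {
  # a sample exactly at the centroid wins with score 0
  coords <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2))
  rownames(coords) <- paste0("s", 1:5)
  Q <- matrix(0.5, 5, 2)
  sel <- select_representatives(coords, Q, rep("g", 5))
  expect_equal(sel$sample_id, "s1")
  expect_equal(sel$centrality, 0)

  # symmetric two-sample group: tie broken by higher dominant ancestry
  coords2 <- rbind(c(-1, 0), c(1, 0))
  rownames(coords2) <- c("a", "b")
  Q2 <- rbind(c(0.6, 0.4), c(0.9, 0.1))
  sel2 <- select_representatives(coords2, Q2, c("g", "g"))
  expect_equal(sel2$sample_id, "b")

  # ... and by lexicographic id when Q ties as well
  sel3 <- select_representatives(coords2, rbind(c(0.7, 0.3), c(0.3, 0.7)),
                                 c("g", "g"))
  expect_equal(sel3$sample_id, "a")

  # exhaustive-search oracle on a synthetic 3-cluster cohort
  set.seed(41)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  grp <- rep(1:3, each = 20)
  pts <- centers[grp, ] + matrix(rnorm(120, sd = 1.2), 60)
  rownames(pts) <- sprintf("x%02d", 1:60)
  Qr <- matrix(runif(120), 60); Qr <- Qr / rowSums(Qr)
  sel <- select_representatives(pts, Qr, as.character(grp))
  for (gname in unique(as.character(grp))) {
    idx <- which(as.character(grp) == gname)
    ctr <- colMeans(pts[idx, ])
    dist <- sqrt(colSums((t(pts[idx, ]) - ctr)^2))
    expect_equal(sel[sel$group == gname, ]$sample_id,
                 rownames(pts)[idx[which.min(dist)]])
  }
})

test_that("IBS distance equals the per-locus allele-sharing tally", {
  g <- rbind(a = c(0L, 1L, 2L, 1L, NA),
             b = c(0L, 1L, 2L, 1L, 0L),
             c = c(2L, 1L, 0L, 1L, 2L),
             d = c(0L, 0L, 2L, 2L, 1L))
  d <- ibs_distance(g)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 0)              # identical where both called
  expect_true(all(d >= 0 & d <= 1))

  # all-0 vs all-2 rows are maximally distant
  e <- ibs_distance(rbind(x = rep(0L, 6), y = rep(2L, 6)))
  expect_equal(e["x", "y"], 1)

  # brute-force per-locus tally oracle
  manual <- function(gi, gj) {
    ok <- !is.na(gi) & !is.na(gj)
    shared <- 0
    for (i in which(ok)) shared <- shared + (2 - abs(gi[i] - gj[i]))
    1 - shared / (2 * sum(ok))
  }
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], manual(g[i, ], g[j, ]))
  }
})

test_that("neighbor joining recovers additive trees and tolerates permutations", {
  # hand-built additive 4-taxon matrix from the quartet ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3          # 1 + 2
  d["a", "c"] <- d["c", "a"] <- 5          # 1 + 1 + 3
  d["a", "d"] <- d["d", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 7
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  dd <- as.matrix(ape::cophenetic.phylo(tr))[letters[1:4], letters[1:4]]
  expect_equal(dd, d, tolerance = 1e-12)

  # ultrametric 3-taxon star resolves with equal limbs
  u <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(u) <- 0
  tru <- neighbor_joining(u)
  expect_equal(sort(tru$edge.length), rep(1, 3))

  # permuting the leaf order yields the same splits and path distances
  perm <- c(3, 1, 4, 2)
  trp <- neighbor_joining(d[perm, perm])
  ddp <- as.matrix(ape::cophenetic.phylo(trp))[letters[1:4], letters[1:4]]
  expect_equal(ddp, d, tolerance = 1e-12)

  # two taxa: a single split edge
  tr2 <- neighbor_joining(matrix(c(0, 4, 4, 0), 2,
                                 dimnames = list(c("p", "q"), c("p", "q"))))
  expect_equal(sum(tr2$edge.length), 4)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("neighbor joining agrees with the reference implementation on noisy matrices", {
  set.seed(43)
  for (i in 1:5) {
    s <- sample(5:9, 1)
    d <- as.matrix(dist(matrix(rnorm(s * 3), s)))
    dimnames(d) <- list(paste0("t", 1:s), paste0("t", 1:s))
    mine <- neighbor_joining(d)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("newick serialization round-trips through the reference parser", {
  d <- as.matrix(dist(matrix(rnorm(18), 6)))
  dimnames(d) <- list(paste0("t", 1:6), paste0("t", 1:6))
  tr <- neighbor_joining(d)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path, digits = 15)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  dd <- as.matrix(ape::cophenetic.phylo(back))[rownames(d), colnames(d)]
  d0 <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
  expect_equal(dd, d0, tolerance = 1e-10)
})
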