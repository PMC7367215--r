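# Population-structure machinery: PCA with projection of new genomes onto
# reference axes, supervised admixture (EM under the binomial mixed-AF
# likelihood with the ancestral frequencies held fixed), centrality-based
# representative selection, and an identity-by-state neighbor-joining tree.

#' Fit a genotype PCA on a reference cohort
#'
#' Each locus is standardized by mean 2p and scale sqrt(2p(1-p)) with p the
#' reference alt-allele frequency; missing genotypes are mean-imputed
#' (standardized 0), keeping projection linear. The top-d right singular
#' vectors of the standardized matrix are the loadings; monomorphic loci
#' (zero scale) are dropped with a warning. Component signs are fixed by
#' making each column's largest-magnitude loading positive.
#'
#' @param reference a [genotype_matrix()] of reference samples.
#' @param d number of components to retain.
#' @return an object of class `pca_model`: `locus_means`, `locus_scales`,
#'   `loadings` (M x d), `reference_coords` (N x d), `eigenvalues`,
#'   `loci`, `kept` (logical over input loci).
#' @export
fit_pca <- function(reference, d = 2L) {
  stopifnot(inherits(reference, "genotype_matrix"))
  geno <- reference$genotypes
  n <- nrow(geno)
  p <- colMeans(geno, na.rm = TRUE) / 2
  scale <- sqrt(2 * p * (1 - p))
  kept <- is.finite(scale) & scale > 0
  if (!all(kept)) {
    warning(sprintf("dropping %d monomorphic/uncallable loci", sum(!kept)))
  }
  if (d > min(n, sum(kept))) stopf("d = %d exceeds matrix rank bound", d)
  x <- sweep(geno[, kept, drop = FALSE], 2L, 2 * p[kept], "-")
  x <- sweep(x, 2L, scale[kept], "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = 0L, nv = d)
  loadings <- sv$v
  flip <- vapply(seq_len(d), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2L, flip, "*")
  coords <- x %*% loadings
  rownames(coords) <- reference$sample_ids
  colnames(coords) <- paste0("PC", seq_len(d))
  structure(list(locus_means = 2 * p[kept], locus_scales = scale[kept],
                 loadings = loadings,
                 reference_coords = coords,
                 eigenvalues = (sv$d[seq_len(d)]^2) / (n - 1),
                 loci = reference$loci[kept], kept = kept),
            class = "pca_model")
}

#' Project genotype vectors onto fitted PCA axes
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param g integer dosage vector over the model's kept loci, or a matrix
#'   (samples x loci). Missing entries contribute 0 after standardization.
#' @return coordinate matrix (samples x d).
#' @export
project_pca <- function(model, g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  if (ncol(g) != length(model$locus_means)) {
    stopf("genotype vector length %d != model loci %d",
          ncol(g), length(model$locus_means))
  }
  x <- sweep(g, 2L, model$locus_means, "-")
  x <- sweep(x, 2L, model$locus_scales, "/")
  x[is.na(x)] <- 0
  x %*% model$loadings
}

#' Supervised admixture proportions by EM
#'
#' Maximum-likelihood admixture vector Q for one genotype vector under
#' g_m ~ Binomial(2, sum_k q_k f_km) with the ancestral frequency matrix F
#' (K x M) held fixed. The EM update is
#' q_k <- (q_k / 2M') * sum_m \[ g_m f_km / p_m + (2 - g_m)(1 - f_km)/(1 - p_m) \]
#' with p_m the current mixed frequency and M' the non-missing locus count.
#' F is clipped to \[1e-6, 1 - 1e-6\]; the log-likelihood is nondecreasing
#' across iterations (a property the tests assert).
#'
#' @param g integer dosage vector (0/1/2/NA) over M loci.
#' @param F K x M matrix of per-population allele frequencies (rows may be
#'   named).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `max_iter` iterations.
#' @return an object of class `admixture_fit`: `Q` (named K-vector on the
#'   simplex), `loglik`, `loglik_trace`, `n_iter`, `n_loci_used`.
#' @export
supervised_admixture <- function(g, F, max_iter = 2000L, tol = 1e-7) {
  F <- as.matrix(F)
  k <- nrow(F)
  if (k < 1L) stopf("F must have at least one population row")
  if (length(g) != ncol(F)) stopf("genotype length %d != F columns %d",
                                  length(g), ncol(F))
  use <- !is.na(g)
  if (!any(use)) stopf("no usable (non-missing) loci")
  g <- as.numeric(g[use])
  F <- pmin(pmax(F[, use, drop = FALSE], 1e-6), 1 - 1e-6)
  m <- length(g)
  pops <- rownames(F) %||% sprintf("POP%d", seq_len(k))
  lchoose2 <- sum(lgamma(3) - lgamma(g + 1) - lgamma(3 - g))
  ll_fun <- function(p) sum(g * log(p) + (2 - g) * log1p(-p)) + lchoose2
  q <- rep(1 / k, k)
  p <- as.vector(crossprod(F, q))
  ll <- ll_fun(p)
  trace <- ll
  iter <- 0L
  if (k > 1L) {
    repeat {
      iter <- iter + 1L
      num <- F %*% (g / p) + (1 - F) %*% ((2 - g) / (1 - p))
      q <- q * as.vector(num) / (2 * m)
      q <- q / sum(q)  # guard against accumulated rounding
      p <- as.vector(crossprod(F, q))
      ll_new <- ll_fun(p)
      trace <- c(trace, ll_new)
      if (iter >= max_iter || ll_new - ll < tol) {
        ll <- ll_new
        break
      }
      ll <- ll_new
    }
  }
  structure(list(Q = stats::setNames(q, pops), loglik = ll,
                 loglik_trace = trace, n_iter = iter, n_loci_used = m),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> %d iterations, loglik %.2f\n  Q: %s\n",
              x$n_iter, x$loglik,
              paste(sprintf("%s=%.3f", names(x$Q), x$Q), collapse = " ")))
  invisible(x)
}

#' Per-population allele frequencies from labeled reference samples
#'
#' The fixed F matrix for supervised admixture: panel AFs per labeled
#' population, clipped away from \{0, 1\}.
#'
#' @param reference a [genotype_matrix()].
#' @param labels population label per reference sample.
#' @param clip clipping bound for the frequencies.
#' @return K x M matrix with population row names.
#' @export
population_frequencies <- function(reference, labels, clip = 1e-6) {
  stopifnot(inherits(reference, "genotype_matrix"),
            length(labels) == nrow(reference$genotypes))
  pops <- sort(unique(as.character(labels)))
  F <- t(vapply(pops, function(pp) {
    colMeans(reference$genotypes[labels == pp, , drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(ncol(reference$genotypes))))
  F[!is.finite(F)] <- 0.5  # all-missing locus in a population: uninformative
  pmin(pmax(F, clip), 1 - clip)
}

#' Select the most central sample of each group in PC space
#'
#' The representative of each group is the sample nearest (Euclidean) to
#' the group centroid in the retained PC plane; ties go to the higher
#' dominant-ancestry proportion, then to the lexicographically smaller id.
#'
#' @param coords samples x D coordinate matrix (rownames are sample ids).
#' @param Q samples x K admixture matrix (rows aligned with `coords`).
#' @param grouping group label per sample.
#' @return data.table with one row per group: group, sample_id, centrality
#'   (distance to centroid), dominant_q, and the sample's Q as list column.
#' @export
select_representatives <- function(coords, Q, grouping) {
  coords <- as.matrix(coords)
  Q <- as.matrix(Q)
  ids <- rownames(coords) %||% paste0("S", seq_len(nrow(coords)))
  stopifnot(nrow(Q) == nrow(coords), length(grouping) == nrow(coords))
  out <- lapply(sort(unique(as.character(grouping))), function(gr) {
    idx <- which(grouping == gr)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    dist <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, ctr)^2))
    dom <- apply(Q[idx, , drop = FALSE], 1L, max)
    ord <- order(dist, -dom, ids[idx])
    pick <- idx[ord[1L]]
    data.table::data.table(group = gr, sample_id = ids[pick],
                           centrality = dist[ord[1L]],
                           dominant_q = max(Q[pick, ]),
                           Q = list(Q[pick, ]))
  })
  data.table::rbindlist(out)
}

#' Identity-by-state distance matrix
#'
#' d(i, j) = 1 - sum_m (2 - |g_im - g_jm|) / (2 M_ij) over the mutually
#' non-missing loci M_ij: the fraction of allele mismatches, in \[0, 1\],
#' zero on the diagonal.
#'
#' @param g a [genotype_matrix()] or integer dosage matrix (samples x loci).
#' @return symmetric S x S matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(g) {
  geno <- if (inherits(g, "genotype_matrix")) g$genotypes else as.matrix(g)
  s <- nrow(geno)
  ids <- rownames(geno) %||% paste0("S", seq_len(s))
  d <- matrix(0, s, s, dimnames = list(ids, ids))
  for (i in seq_len(s)) {
    gi <- geno[i, ]
    for (j in seq_len(s)) {
      if (j <= i) next
      gj <- geno[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      mij <- sum(ok)
      if (mij == 0L) stopf("samples %s and %s share no called loci",
                           ids[i], ids[j])
      shared <- sum(2L - abs(gi[ok] - gj[ok]))
      d[i, j] <- d[j, i] <- 1 - shared / (2 * mij)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion and the standard
#' limb-length formulas, finishing with the three-node resolution. A
#' negative limb is clamped to zero and its deficit moved to the sibling
#' limb (which is itself floored at zero); additive inputs never trigger
#' the clamp. Returns an unrooted `phylo`-compatible tree.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal.
#' @param labels tip labels; defaults to the matrix dimnames.
#' @return an unrooted binary tree of class `phylo` (edge matrix,
#'   edge.length, tip.label, Nnode).
#' @export
neighbor_joining <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  s <- nrow(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(s))
  if (s < 2L) stopf("need at least 2 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(diag(d) != 0) || any(d < 0)) {
    stopf("distance matrix must be symmetric, nonnegative, zero-diagonal")
  }
  if (s == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
                 edge.length = rep(d[1, 2] / 2, 2L),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  n_internal <- s - 2L
  next_node <- s + 1L
  active <- seq_len(s)          # tree-node ids currently joinable
  dd <- d                       # working distances, indexed by active order
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  clamp <- function(la, lb) {
    if (la < 0) { lb <- max(0, lb + la); la <- 0 }
    if (lb < 0) { la <- max(0, la + lb); lb <- 0 }
    c(la, lb)
  }
  while (length(active) > 3L) {
    r <- length(active)
    rowsum <- rowSums(dd)
    qmat <- (r - 2) * dd - outer(rowsum, rowsum, "+")
    diag(qmat) <- Inf
    ij <- which(qmat == min(qmat), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    la <- dd[i, j] / 2 + (rowsum[i] - rowsum[j]) / (2 * (r - 2))
    lb <- dd[i, j] - la
    ll <- clamp(la, lb)
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, ll[1L], ll[2L])
    dnew <- (dd[i, ] + dd[j, ] - dd[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active <- c(active[keep], u)
  }
  # final 3-node star
  u <- next_node
  la <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  lb <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  lc <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  if (la < 0) { la <- 0 }
  if (lb < 0) { lb <- 0 }
  if (lc < 0) { lc <- 0 }
  edges <- rbind(edges, c(u, active[1]), c(u, active[2]), c(u, active[3]))
  lens <- c(lens, la, lb, lc)
  # renumber internal nodes: tips 1..s, root-ish last internal becomes s+1
  internal_ids <- sort(unique(edges[edges > s]))
  remap <- integer(max(internal_ids))
  remap[internal_ids] <- s + rev(seq_along(internal_ids))
  edges2 <- edges
  edges2[edges > s] <- remap[edges[edges > s]]
  tree <- list(edge = edges2[rev(seq_len(nrow(edges2))), , drop = FALSE],
               edge.length = lens[rev(seq_along(lens))],
               tip.label = labels, Nnode = n_internal)
  class(tree) <- "phylo"
  tree
}

#' Serialize a tree to newick
#'
#' @param tree a `phylo` tree (e.g. from [neighbor_joining()]).
#' @param path optional output file.
#' @param digits branch-length precision.
#' @return the newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  s <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rec <- function(node, incoming) {
    lab <- if (node <= s) tree$tip.label[node] else ""
    ch <- kids[[as.character(node)]]
    if (!is.null(ch)) {
      inner <- paste(vapply(ch, function(e) {
        rec(tree$edge[e, 2L], tree$edge.length[e])
      }, character(1)), collapse = ",")
      lab <- paste0("(", inner, ")", lab)
    }
    if (is.na(incoming)) lab else {
      paste0(lab, ":", formatC(incoming, digits = digits, format = "g"))
    }
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  nwk <- paste0(rec(root, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
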