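# End-to-end orchestration: simulate -> cohort AF -> ancestry/selection ->
# per-sample annotation & prioritization -> QC -> concordance -> SV merge,
# from one config, with a manifest of per-stage outputs and hashes.

#' Default demo configuration for the full pipeline
#'
#' Laptop-scale stated world: a 200-sample, 20,000-locus cohort with three
#' ancestral populations at moderate divergence, three finite reference
#' panels, four WGS-only extra-locus blocks per representative, and a
#' 200-call SV scenario. Every stochastic choice derives from `seed`.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
demo_config <- function(out_dir = tempfile("popafkit_run_"), seed = 1L) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    cohort = list(n_samples = 200L, n_loci = 20000L, n_pops = 3L,
                  fst = 0.1, dirichlet_alpha = c(1, 1, 1),
                  missing_rate = 0.02, known_fraction = 0.97),
    local_population = "LOCAL",
    min_call_rate = 0.95,
    ref_pops = c("POP1", "POP2", "POP3"),
    n_ref = 5000L,
    mode = "global",
    pca_d = 2L,
    extra_loci = 2000L,
    indel_fraction = 0.2,
    discordance_rate = 0.002,
    strand_flip_rate = 0.05,
    tree_extras = 20L,
    sv = list(n_true = 200L, genome_len = 1e8, jitter_sd = 20,
              sens_a = 0.9, sens_b = 0.8, db_fraction = 0.865),
    ro_min = 0.5)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror [demo_config()]; missing keys fall back to the demo
#' defaults, file values win over defaults.
#'
#' @param path .yaml/.yml or .json config file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("yaml package required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(unclass(demo_config()), raw)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(seed) || length(seed) != 1L) stopf("seed must be one integer")
    if (min_call_rate < 0 || min_call_rate > 1) stopf("min_call_rate in [0,1]")
    if (ro_min <= 0 || ro_min > 1) stopf("ro_min in (0,1]")
    if (!mode %in% c("global", "strictest_vs_all")) {
      stopf("mode must be global or strictest_vs_all")
    }
  })
  # referenced inputs (none in simulation mode) would be checked here
  invisible(cfg)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[popafkit] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order under `config$out_dir`, aborting
#' with the failing stage's name on error. Re-running with an identical
#' config and seed reproduces byte-identical outputs; the manifest records
#' each artifact's md5 hash for that check.
#'
#' @param config a `run_config` from [demo_config()] or [read_run_config()].
#' @param quiet suppress stage progress messages.
#' @return the run manifest (invisibly also written to
#'   `out_dir/manifest.json`): parameters, per-stage outputs, hashes, and
#'   headline numbers.
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) {
               stopf("stage '%s' failed: %s", name, conditionMessage(e))
             })
  }
  od <- function(...) file.path(config$out_dir, ...)

  stage_log(quiet, "simulate: cohort n=%d, M=%d, K=%d",
            config$cohort$n_samples, config$cohort$n_loci,
            config$cohort$n_pops)
  sim <- stage("simulate", {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    simulate_cohort(spec)
  })
  paths$genotypes <- od("cohort_genotypes.tsv")
  write_genotype_matrix(sim$genotypes, paths$genotypes)

  stage_log(quiet, "cohort-af: local panel at call rate >= %.2f",
            config$min_call_rate)
  local_panel <- stage("cohort_af", {
    build_panel(sim$genotypes, config$local_population,
                min_call_rate = config$min_call_rate)
  })
  paths$local_panel <- od("local_af.tsv")
  write_af_panel(local_panel, paths$local_panel)
  paths$local_sites_vcf <- od("local_af_sites.vcf")
  write_panel_vcf(local_panel, paths$local_sites_vcf)

  stage_log(quiet, "panels: %d reference panels, known sites, pathogenicity",
            length(config$ref_pops))
  ref_paths <- stage("reference_panels", {
    emit_reference_panels(sim$truth, pops = config$ref_pops,
                          n_ref = config$n_ref, out_dir = config$out_dir)
  })
  paths$known_sites <- od("known_sites.tsv")
  write_known_sites(truth_known_sites(sim$truth), paths$known_sites)
  paths$patho <- od("pathogenicity.tsv")
  patho <- stage("pathogenicity", {
    emit_pathogenicity_table(sim$truth$loci, seed = config$seed,
                             path = paths$patho)
  })

  stage_log(quiet, "ancestry: PCA(d=%d), representatives, admixture",
            config$pca_d)
  anc <- stage("ancestry", {
    model <- fit_pca(sim$genotypes, d = config$pca_d)
    grouping <- sprintf("POP%d", max.col(sim$truth$admixture))
    F <- population_frequencies(sim$genotypes, grouping)
    reps <- select_representatives(model$reference_coords,
                                   sim$truth$admixture, grouping)
    fits <- lapply(match(reps$sample_id, sim$truth$sample_ids), function(i) {
      supervised_admixture(sim$genotypes$genotypes[i, ], F)
    })
    names(fits) <- reps$sample_id
    list(model = model, grouping = grouping, F = F, reps = reps, fits = fits)
  })
  paths$coords <- od("pca_coords.tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = rownames(anc$model$reference_coords),
    group = anc$grouping, anc$model$reference_coords),
    paths$coords, sep = "\t", quote = FALSE)
  paths$admixture <- od("representative_admixture.tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = names(anc$fits),
    t(vapply(anc$fits, function(f) f$Q, numeric(nrow(anc$F))))),
    paths$admixture, sep = "\t", quote = FALSE)
  paths$representatives <- od("representatives.json")
  jsonlite::write_json(lapply(seq_len(nrow(anc$reps)), function(i) {
    list(group = anc$reps$group[i], sample_id = anc$reps$sample_id[i],
         centrality = anc$reps$centrality[i],
         Q = as.list(anc$fits[[anc$reps$sample_id[i]]]$Q))
  }), paths$representatives, auto_unbox = TRUE, digits = NA)

  rep_ids <- anc$reps$sample_id
  rep_idx <- match(rep_ids, sim$truth$sample_ids)

  stage_log(quiet, "emit: %d representative VCFs (+%d extra loci each)",
            length(rep_ids), config$extra_loci)
  paths$vcfs <- stats::setNames(od(paste0(rep_ids, ".vcf")), rep_ids)
  stage("emit_vcfs", {
    for (i in seq_along(rep_ids)) {
      emit_sample_vcf(sim$truth, rep_idx[i], paths$vcfs[i],
                      extra_loci = config$extra_loci,
                      indel_fraction = config$indel_fraction,
                      discordance_rate = config$discordance_rate,
                      strand_flip_rate = config$strand_flip_rate)
    }
  })

  stage_log(quiet, "prioritize: annotate vs local + %d reference panels (%s)",
            length(ref_paths), config$mode)
  refs <- lapply(names(ref_paths), function(p) read_af_panel(ref_paths[[p]], p))
  names(refs) <- names(ref_paths)
  known <- read_known_sites(paths$known_sites)
  summaries <- list()
  paths$annotated <- stats::setNames(od(paste0(rep_ids, ".annot.vcf")), rep_ids)
  paths$summaries <- stats::setNames(od(paste0(rep_ids, ".priority.tsv")), rep_ids)
  stage("prioritize", {
    for (sid in rep_ids) {
      ann <- annotate_vcf(paths$vcfs[[sid]], local_panel, refs,
                          patho = patho, known_sites = known,
                          out = paths$annotated[[sid]], mode = config$mode)
      summ <- summarize_priorities(ann)
      write_priority_summary(summ, tsv = paths$summaries[[sid]])
      summaries[[sid]] <- summ
    }
  })

  stage_log(quiet, "qc: per-sample reports and share partition")
  qc_reports <- list()
  paths$qc <- stats::setNames(od(paste0(rep_ids, ".qc.json")), rep_ids)
  stage("qc", {
    for (sid in rep_ids) {
      repq <- sample_qc(paths$vcfs[[sid]], known_sites = known)
      write_qc_report(repq, json = paths$qc[[sid]])
      qc_reports[[sid]] <- repq
    }
  })
  shares <- stage("share_partition", share_partition(unname(paths$vcfs), rep_ids))
  paths$share <- od("share_partition.tsv")
  data.table::fwrite(shares$table, paths$share, sep = "\t", quote = FALSE)

  stage_log(quiet, "concordance: array vs WGS per representative")
  conc <- stage("concordance", {
    lapply(stats::setNames(seq_along(rep_ids), rep_ids), function(i) {
      concordance(sim$genotypes$genotypes[rep_idx[i], ], sim$genotypes$loci,
                  paths$vcfs[[rep_ids[i]]])
    })
  })
  paths$concordance <- od("concordance.tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = rep_ids,
    n_compared = vapply(conc, `[[`, integer(1), "n_compared"),
    n_agree = vapply(conc, `[[`, integer(1), "n_agree"),
    concordance_pct = vapply(conc, `[[`, numeric(1), "concordance_pct"),
    dropped_palindromic = vapply(conc, `[[`, integer(1), "dropped_palindromic"),
    n_strand_flipped = vapply(conc, `[[`, integer(1), "n_strand_flipped")),
    paths$concordance, sep = "\t", quote = FALSE)

  stage_log(quiet, "tree: IBS + neighbor joining over representatives + %d extras",
            config$tree_extras)
  tree <- stage("tree", {
    extra_idx <- with_substream(config$seed, "tree", {
      sample(setdiff(seq_len(config$cohort$n_samples), rep_idx),
             min(config$tree_extras,
                 config$cohort$n_samples - length(rep_idx)))
    })
    sel <- c(rep_idx, sort(extra_idx))
    d <- ibs_distance(sim$genotypes$genotypes[sel, , drop = FALSE])
    neighbor_joining(d)
  })
  paths$newick <- od("ibs_nj.nwk")
  write_newick(tree, paths$newick)

  stage_log(quiet, "svmerge: two-caller intersection + novelty")
  svres <- stage("svmerge", {
    sets <- do.call(simulate_sv_callsets,
                    c(config$sv, list(seed = config$seed)))
    merged <- intersect_callers(sets$a, sets$b, ro_min = config$ro_min)
    classify_novelty(merged, sets$db, ro_min = config$ro_min)
  })
  paths$sv_merged <- od("sv_merged.tsv")
  write_sv_tsv(svres$calls, paths$sv_merged)
  paths$sv_vcf <- od("sv_merged.vcf")
  write_sv_vcf(svres$calls, paths$sv_vcf)
  paths$sv_summary <- od("sv_summary.json")
  jsonlite::write_json(list(tally = svres$tally,
                            novel_fraction = svres$novel_fraction),
                       paths$sv_summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  flat <- unlist(paths, use.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("popafkit")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "out_dir")],
    outputs = as.list(flat),
    hashes = as.list(tools::md5sum(flat)),
    headline = list(
      n_panel_loci = nrow(local_panel),
      representatives = anc$reps$sample_id,
      concordance_pct = vapply(conc, `[[`, numeric(1), "concordance_pct"),
      titv_all = vapply(qc_reports, `[[`, numeric(1), "titv_all"),
      het_hom_ratio = vapply(qc_reports, `[[`, numeric(1), "het_hom_ratio"),
      novel_variant_fraction = vapply(qc_reports, function(q) {
        q$n_novel / q$total_variants
      }, numeric(1)),
      shared_all = shares$shared_all,
      distinct_per_sample = as.list(shares$distinct_per_sample),
      n_merged_sv = nrow(svres$calls),
      sv_novel_fraction = svres$novel_fraction))
  names(manifest$hashes) <- names(flat)
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$paths <- paths
  manifest$summaries <- summaries
  manifest$qc <- qc_reports
  manifest$concordance <- conc
  invisible(manifest)
}
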