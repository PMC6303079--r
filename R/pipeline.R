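#' Default end-to-end run configuration
#'
#' A flat, typed key/value configuration covering every stage of the
#' pipeline. Any subset can be overridden via `...` or loaded from a YAML
#' file with [read_run_config()]; every value is echoed into the run
#' manifest so a run can be reproduced bit-exactly from the manifest alone.
#'
#' Stage toggles: `do_filter`, `do_qc`, `do_prune`, `do_scan`,
#' `do_segregate`. The QC/pruning subset uses its own missingness/MAF
#' thresholds (`prune_max_missing` 0.05, `prune_min_maf` 0.05) distinct
#' from the association filters (`assoc_max_missing` 0.10,
#' `assoc_min_maf` 0.01).
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_prefix = "wgva_run",
    # simulation (see simulation_config for the cohort design rationale)
    n_breeds = 21L, breed_sizes = c(5L, 3L, 2L, rep(5L, 18L)),
    breed_fst = 0.25, n_variants = 20000L, n_chromosomes = 38L,
    variant_spacing = 5000L, case_breeds = 1:3, missing_rate = 0.064,
    n_trios = 6L, genotype_error_rate = 0.115, annotation_fail_rate = 0.02,
    indel_fraction = 0.3, ld_block_size = 10L, ld_rho = 0.9,
    causal_case_freq = 1, causal_control_freq = 0, causal_flank = 10L,
    # stage toggles
    do_filter = TRUE, do_qc = TRUE, do_prune = TRUE, do_scan = TRUE,
    do_segregate = TRUE,
    # hard filters
    qd_min = 2.0, fs_max = 60.0, sor_max = 4.0, readpos_ranksum_min = -8.0,
    dp_max = 3105, mq_min = 40.0, mq_ranksum_min = -12.5,
    inbreeding_coeff_min = -0.8,
    # QC / pruning subset
    prune_max_missing = 0.05, prune_min_maf = 0.05,
    prune_window = 50L, prune_step = 5L, vif_threshold = 2,
    dendro_linkage = "average",
    # association
    assoc_max_missing = 0.10, assoc_min_maf = 0.01, gc_mode = "mean",
    alpha = 0.05,
    # fixation scan
    scan_min_diff = 0.9, scan_max_gap = 1000000L, scan_min_variants = 10L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown run_config keys: ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, overrides), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `"run_config"`.
#' @return `read_run_config()` returns a `"run_config"`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the whole screen end to end
#'
#' Simulates the cohort, writes and hard-filters the VCF, runs cohort QC
#' (IBS distances, dendrogram, VIF pruning, trio Mendelian-error audit),
#' performs the allelic association with genomic control and Bonferroni
#' correction over the pruned haplotype count, scans for nearly fixed
#' candidate regions, and tabulates segregation of the top variant — each
#' stage consuming its predecessor's output. A YAML manifest alongside the
#' outputs records every parameter, per-stage row counts (variant
#' accounting is conserved: tested = input - removed by missingness -
#' removed by MAF), and md5 hashes of every file. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, association object, regions,
#'   pruning/QC summaries, manifest, and output paths.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  prefix <- config$out_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  counts <- list()
  log_stage <- function(...) message(sprintf(...))

  sim_cfg <- simulation_config(
    n_breeds = config$n_breeds, breed_sizes = config$breed_sizes,
    breed_fst = config$breed_fst, n_variants = config$n_variants,
    n_chromosomes = config$n_chromosomes,
    variant_spacing = config$variant_spacing,
    case_breeds = config$case_breeds,
    causal_spec = list(case_freq = config$causal_case_freq,
                       control_freq = config$causal_control_freq,
                       flank = config$causal_flank),
    missing_rate = config$missing_rate, n_trios = config$n_trios,
    genotype_error_rate = config$genotype_error_rate,
    annotation_fail_rate = config$annotation_fail_rate,
    indel_fraction = config$indel_fraction,
    ld_block_size = config$ld_block_size, ld_rho = config$ld_rho,
    seed = config$seed)
  cohort <- simulate_cohort(sim_cfg)
  counts$simulated_variants <- nrow(cohort$genotypes)
  counts$samples <- ncol(cohort$genotypes)
  paths["vcf"] <- paste0(prefix, ".cohort.vcf")
  paths["fam"] <- paste0(prefix, ".cohort.fam")
  write_pedigree(cohort$design, paths["fam"])
  log_stage("simulate: %d variants x %d samples",
            counts$simulated_variants, counts$samples)

  thresholds <- filter_thresholds(
    qd_min = config$qd_min, fs_max = config$fs_max, sor_max = config$sor_max,
    readpos_ranksum_min = config$readpos_ranksum_min, dp_max = config$dp_max,
    mq_min = config$mq_min, mq_ranksum_min = config$mq_ranksum_min,
    inbreeding_coeff_min = config$inbreeding_coeff_min)
  if (config$do_filter) {
    flags <- suppressMessages(apply_hard_filters(cohort$variants, thresholds))
    cohort$variants$filter <- flags$reasons
    keep <- flags$pass & select_biallelic(cohort$variants) &
      drop_unplaced(cohort$variants,
                    paste0("chr", seq_len(config$n_chromosomes)))
    counts$failed_hard_filters <- sum(!flags$pass)
    write_vcf(cohort, paths["vcf"])
    cohort$variants <- recode_indels(cohort$variants[keep, , drop = FALSE])
    cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
    counts$after_site_filters <- nrow(cohort$genotypes)
    log_stage("filter: %d sites failed hard filters; %d retained",
              counts$failed_hard_filters, counts$after_site_filters)
  } else {
    write_vcf(cohort, paths["vcf"])
    counts$after_site_filters <- nrow(cohort$genotypes)
  }

  prune_kept_global <- NULL
  if (config$do_qc) {
    qc_idx <- intersect(
      filter_missingness(cohort$genotypes, config$prune_max_missing),
      filter_maf(cohort$genotypes, config$prune_min_maf))
    counts$qc_subset <- length(qc_idx)
    if (config$do_prune) {
      kept_local <- vif_prune(
        cohort$genotypes[qc_idx, , drop = FALSE],
        chrom = cohort$variants$chrom[qc_idx],
        cfg = prune_config(config$prune_window, config$prune_step,
                           config$vif_threshold))
      prune_kept_global <- qc_idx[kept_local]
      counts$pruned_haplotypes <- length(prune_kept_global)
      paths["prune"] <- paste0(prefix, ".prune.in")
      utils::write.table(
        cohort$variants[prune_kept_global, c("chrom", "pos")],
        paths["prune"], sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
      log_stage("prune: %d of %d QC-subset variants kept at VIF %.1f",
                counts$pruned_haplotypes, counts$qc_subset,
                config$vif_threshold)
    }
    dist_idx <- prune_kept_global %||% qc_idx
    D <- ibs_distance(cohort$genotypes[dist_idx, , drop = FALSE])
    paths["dist"] <- paste0(prefix, ".ibs_dist.tsv")
    utils::write.table(format(D, digits = 10), paths["dist"], sep = "\t",
                       quote = FALSE)
    paths["tree"] <- paste0(prefix, ".ibs_tree.nwk")
    ape::write.tree(ibs_dendrogram(D, config$dendro_linkage), paths["tree"])
    if (nrow(cohort$design$trios) > 0L) {
      me <- mendel_errors(cohort$genotypes[dist_idx, , drop = FALSE],
                          cohort$design$trios)
      counts$mendel_errors <- me$n_errors
      counts$mendel_rate_per_meiosis <- me$rate_per_meiosis
      paths["mendel"] <- paste0(prefix, ".mendel.tsv")
      utils::write.table(me$per_trio, paths["mendel"], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_stage("mendel: %.3f%% errors per meiosis over %d trios",
                100 * me$rate_per_meiosis, nrow(cohort$design$trios))
    }
  }

  keep_miss <- filter_missingness(cohort$genotypes, config$assoc_max_missing)
  counts$removed_missingness <- nrow(cohort$genotypes) - length(keep_miss)
  keep_maf <- intersect(keep_miss,
                        filter_maf(cohort$genotypes, config$assoc_min_maf))
  counts$removed_maf <- length(keep_miss) - length(keep_maf)
  counts$tested <- length(keep_maf)
  log_stage(paste0("assoc filters: %d removed by missingness, ",
                   "%d by MAF, %d tested"),
            counts$removed_missingness, counts$removed_maf, counts$tested)
  n_tests <- if (!is.null(prune_kept_global))
    length(intersect(prune_kept_global, keep_maf)) else counts$tested
  n_tests <- max(n_tests, 1L)
  assoc <- run_association(cohort$genotypes[keep_maf, , drop = FALSE],
                           cohort$variants[keep_maf, , drop = FALSE],
                           cohort$design, gc_mode = config$gc_mode,
                           n_tests = n_tests)
  counts$lambda <- assoc$model$lambda
  counts$n_tests <- n_tests
  counts$significance_threshold <- significance_threshold(
    config$alpha, n_tests, assoc$model)
  paths["assoc"] <- paste0(prefix, ".assoc.tsv")
  write_assoc_tsv(assoc, paths["assoc"])
  log_stage("assoc: lambda = %.4f; raw-p threshold at alpha %.2g = %.3g",
            counts$lambda, config$alpha, counts$significance_threshold)

  regions <- NULL
  if (config$do_scan) {
    passing <- fixation_filter(assoc$result, config$scan_min_diff)
    counts$fixation_passing <- nrow(passing)
    regions <- rank_regions(build_regions(passing, config$scan_max_gap,
                                          config$scan_min_variants))
    counts$candidate_regions <- nrow(regions)
    paths["regions_bed"] <- paste0(prefix, ".regions.bed")
    paths["regions_tsv"] <- paste0(prefix, ".regions.tsv")
    write_regions(regions, paste0(prefix, ".regions"))
    log_stage("scan: %d passing variants in %d candidate regions",
              counts$fixation_passing, counts$candidate_regions)
  }

  segregation <- NULL
  if (config$do_segregate) {
    top <- order(assoc$result$P_GC, -assoc$result$CHISQ)[1L]
    top_id <- paste0(assoc$result$CHR[top], ":", assoc$result$POS[top])
    vi <- match(top_id, paste0(cohort$variants$chrom, ":",
                               cohort$variants$pos))
    gcounts <- suppressWarnings(
      genotype_counts(cohort$genotypes, cohort$design, vi))
    gcounts$alt_freq <- ifelse(
      gcounts$hom_ref + gcounts$het + gcounts$hom_alt > 0,
      (gcounts$het + 2 * gcounts$hom_alt) /
        (2 * pmax(gcounts$hom_ref + gcounts$het + gcounts$hom_alt, 1)), NA)
    status <- cohort$design$samples$status
    g <- cohort$genotypes[vi, match(cohort$design$samples$sample_id,
                                    colnames(cohort$genotypes))]
    gp <- expand.grid(genotype = c("hom_ref", "het", "hom_alt"),
                      stringsAsFactors = FALSE)
    gp$affected <- vapply(0:2, function(d)
      sum(g == d & status == "case", na.rm = TRUE), numeric(1))
    gp$unaffected <- vapply(0:2, function(d)
      sum(g == d & status == "control", na.rm = TRUE), numeric(1))
    seg_p <- suppressWarnings(segregation_test(gp, "recessive"))
    segregation <- list(variant = top_id, genotype_counts = gcounts,
                        gp_table = gp, p_recessive = seg_p)
    counts$segregation_p <- seg_p
    paths["seg"] <- paste0(prefix, ".segregation.tsv")
    utils::write.table(
      cbind(gcounts, variant = top_id, p_recessive = format(seg_p, digits = 6)),
      paths["seg"], sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("segregate: top variant %s, recessive exact p = %.3g",
              top_id, seg_p)
  }

  manifest <- list(parameters = unclass(config),
                   counts = counts,
                   files = as.list(unname(vapply(
                     paths, function(p) unname(tools::md5sum(p)),
                     character(1)))))
  names(manifest$files) <- basename(unname(paths))
  paths["manifest"] <- paste0(prefix, ".manifest.yaml")
  yaml::write_yaml(manifest, paths["manifest"])

  invisible(list(cohort = cohort, assoc = assoc, regions = regions,
                 segregation = segregation, counts = counts,
                 manifest = manifest, paths = paths,
                 prune_kept = prune_kept_global))
}

write_assoc_tsv <- function(assoc, path) {
  out <- assoc$result
  for (col in c("P", "P_GC", "P_BONF"))
    out[[col]] <- format(out[[col]], digits = 6, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
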