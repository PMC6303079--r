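#' Simulation configuration for a breed-structured cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' Defaults describe a screw-tail-style mapping cohort: 21 pure breeds,
#' 100 founder dogs of which the three case breeds contribute 5 + 3 + 2 = 10
#' cases, six parent-parent-offspring trios, strong breed divergence, and a
#' causal recessive deletion fixed in the case breeds and nearly absent
#' elsewhere.
#'
#' @param n_breeds Number of discrete breeds.
#' @param breed_sizes Integer vector of founder counts per breed
#'   (length `n_breeds`, all >= 1).
#' @param breed_fst Balding-Nichols divergence parameter F in `[0, 1)`.
#'   Controls how far per-breed allele frequencies drift from the ancestral
#'   frequency; 0.25 is on the scale observed between dog breeds and
#'   produces the strong genomic-inflation regime the pipeline corrects for.
#' @param n_variants Number of variant sites to simulate.
#' @param n_chromosomes Number of autosomes variants are tiled onto.
#' @param variant_spacing Fixed physical spacing between adjacent variants
#'   on a chromosome, in bp.
#' @param case_breeds Indices of the breeds whose members are cases; must be
#'   a non-empty strict subset of `1:n_breeds`.
#' @param causal_spec List describing the implanted causal variant:
#'   `variant` (index; `NULL` places it mid-chromosome-5), `case_freq`
#'   (alt-allele frequency in case breeds; 1 means every case is homozygous
#'   alt), `control_freq` (alt frequency in control breeds), `flank`
#'   (variants swept on each side of the causal site, emulating the long
#'   fixed haplotype around a breed-defining variant), `flank_case_freq`
#'   and `flank_control_freq` (alt frequencies for the swept flanks,
#'   deliberately weaker than the causal site itself).
#' @param missing_rate Per-cell probability of a missing genotype. The
#'   default 0.064 reproduces a ~93.6% total genotyping rate.
#' @param n_trios Number of trios to append (offspring simulated from two
#'   same-breed founder parents).
#' @param genotype_error_rate Per-cell probability that a trio offspring
#'   genotype is corrupted to a random different dosage. Only about a
#'   third of uniform dosage substitutions violate biparental
#'   transmission per meiosis, so the default 0.115 yields a *detected*
#'   per-meiosis Mendelian error rate of roughly 4%.
#' @param annotation_fail_rate Per-field probability that a site's
#'   annotation is drawn beyond its hard-filter threshold.
#' @param indel_fraction Fraction of sites simulated as 1-bp indels.
#' @param ld_block_size Variants per linkage-disequilibrium block; variants
#'   within a block copy a latent haplotype indicator.
#' @param ld_rho Per-cell probability of copying the block's latent
#'   genotype; pairwise genotype correlation within a block is about
#'   `ld_rho^2`.
#' @param freq_range Range of ancestral allele frequencies (uniform draw).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_breeds = 21,
                              breed_sizes = c(5L, 3L, 2L, rep(5L, 18L)),
                              breed_fst = 0.25,
                              n_variants = 20000,
                              n_chromosomes = 38,
                              variant_spacing = 5000,
                              case_breeds = 1:3,
                              causal_spec = list(),
                              missing_rate = 0.064,
                              n_trios = 6,
                              genotype_error_rate = 0.115,
                              annotation_fail_rate = 0.02,
                              indel_fraction = 0.3,
                              ld_block_size = 10,
                              ld_rho = 0.9,
                              freq_range = c(0.05, 0.95),
                              seed = NULL) {
  causal_default <- list(variant = NULL, case_freq = 1, control_freq = 0,
                         flank = 10, flank_case_freq = 0.95,
                         flank_control_freq = 0.02)
  causal_spec <- utils::modifyList(causal_default, causal_spec)
  cfg <- list(n_breeds = as.integer(n_breeds),
              breed_sizes = as.integer(breed_sizes),
              breed_fst = breed_fst,
              n_variants = as.integer(n_variants),
              n_chromosomes = as.integer(n_chromosomes),
              variant_spacing = as.integer(variant_spacing),
              case_breeds = as.integer(case_breeds),
              causal_spec = causal_spec,
              missing_rate = missing_rate,
              n_trios = as.integer(n_trios),
              genotype_error_rate = genotype_error_rate,
              annotation_fail_rate = annotation_fail_rate,
              indel_fraction = indel_fraction,
              ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho,
              freq_range = freq_range,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$breed_sizes) == cfg$n_breeds,
            all(cfg$breed_sizes >= 1L),
            cfg$breed_fst >= 0, cfg$breed_fst < 1,
            cfg$n_variants >= 1L, cfg$n_chromosomes >= 1L,
            cfg$variant_spacing >= 1L)
  probs <- c(cfg$missing_rate, cfg$genotype_error_rate,
             cfg$annotation_fail_rate, cfg$indel_fraction, cfg$ld_rho,
             cfg$causal_spec$case_freq, cfg$causal_spec$control_freq,
             cfg$causal_spec$flank_case_freq, cfg$causal_spec$flank_control_freq)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (length(cfg$case_breeds) == 0L)
    stop("case_breeds must be non-empty")
  if (!all(cfg$case_breeds %in% seq_len(cfg$n_breeds)) ||
      length(cfg$case_breeds) >= cfg$n_breeds)
    stop("case_breeds must be a strict subset of 1:n_breeds")
  invisible(cfg)
}

#' Per-breed allele frequencies under the Balding-Nichols model
#'
#' Draws one alternate-allele frequency per breed from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, so
#' that across breeds the frequencies have mean `p` and variance
#' `F * p * (1 - p)`. `F = 0` returns the ancestral frequency exactly for
#' every breed; a degenerate ancestral frequency (0 or 1) fixes every breed
#' at that value without sampling.
#'
#' @param ancestral_freq Ancestral alt-allele frequency in `[0, 1]`.
#' @param fst Divergence parameter F in `[0, 1)`.
#' @param n_breeds Number of breeds to draw.
#' @return Numeric vector of length `n_breeds`.
#' @examples
#' set.seed(1)
#' breed_frequencies(0.3, 0.2, 5)
#' breed_frequencies(0.3, 0, 5)  # no divergence: all 0.3
#' @export
breed_frequencies <- function(ancestral_freq, fst, n_breeds) {
  stopifnot(length(ancestral_freq) == 1L, ancestral_freq >= 0,
            ancestral_freq <= 1, fst >= 0, fst < 1, n_breeds >= 1L)
  if (ancestral_freq %in% c(0, 1) || fst == 0)
    return(rep(ancestral_freq, n_breeds))
  shape <- (1 - fst) / fst
  stats::rbeta(n_breeds, ancestral_freq * shape, (1 - ancestral_freq) * shape)
}

# Vectorised Balding-Nichols draw: one row per ancestral frequency,
# one column per breed.
bn_frequency_matrix <- function(p, fst, n_breeds) {
  if (fst == 0)
    return(matrix(rep(p, n_breeds), ncol = n_breeds))
  shape <- (1 - fst) / fst
  out <- matrix(stats::rbeta(length(p) * n_breeds,
                             rep(p, n_breeds) * shape,
                             rep(1 - p, n_breeds) * shape),
                ncol = n_breeds)
  fixed <- p %in% c(0, 1)
  if (any(fixed)) out[fixed, ] <- p[fixed]
  out
}

#' Simulate a breed-structured genotype cohort
#'
#' Generates Hardy-Weinberg genotypes within each breed at Balding-Nichols
#' breed-specific allele frequencies, tiles variants into
#' linkage-disequilibrium blocks, implants a causal recessive variant fixed
#' in the case breeds (optional), appends trio offspring (optional), masks
#' genotypes as missing, and draws GATK-style site annotation fields with a
#' configurable contaminating fraction beyond each hard-filter threshold.
#' Runs are reproducible under a fixed `seed` in the configuration.
#'
#' @param config A [simulation_config()].
#' @param implant Implant the causal variant and its swept flank?
#' @param add_trios Append `config$n_trios` trio offspring?
#' @return A list of class `"wgva_cohort"` with elements:
#'   * `genotypes` — integer matrix (variants x samples) of alt-allele
#'     dosages 0/1/2, `NA` for missing;
#'   * `variants` — data.frame with `chrom`, `pos`, `id`, `ref`, `alt`,
#'     `is_indel`, the eight annotation fields, and `causal`;
#'   * `design` — list with `samples` (data.frame `sample_id`, `breed`,
#'     `status`, `is_offspring`) and `trios` (data.frame `offspring`,
#'     `sire`, `dam`).
#' @examples
#' cfg <- simulation_config(n_breeds = 4, breed_sizes = c(3, 3, 3, 3),
#'                          case_breeds = 1, n_variants = 200, n_trios = 0,
#'                          seed = 1)
#' ch <- simulate_cohort(cfg)
#' dim(ch$genotypes)
#' @export
simulate_cohort <- function(config, implant = TRUE, add_trios = TRUE) {
  validate_simulation_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  nv <- config$n_variants
  nb <- config$n_breeds
  sizes <- config$breed_sizes
  ns <- sum(sizes)

  # physical layout: variants tiled over chromosomes at fixed spacing
  per_chrom <- ceiling(nv / config$n_chromosomes)
  chrom_idx <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(nv)]
  within <- stats::ave(seq_len(nv), chrom_idx, FUN = seq_along)
  chrom <- paste0("chr", chrom_idx)
  pos <- within * config$variant_spacing

  # LD blocks: consecutive variants on a chromosome share a block; all
  # variants of a block share the block's breed frequencies and copy a
  # latent per-sample genotype with probability ld_rho
  block <- paste0(chrom_idx, "_", (within - 1L) %/% config$ld_block_size)
  block_id <- match(block, unique(block))
  n_blocks <- max(block_id)
  p_block <- stats::runif(n_blocks, config$freq_range[1], config$freq_range[2])
  freq_block <- bn_frequency_matrix(p_block, config$breed_fst, nb)

  breed_names <- sprintf("breed%02d", seq_len(nb))
  breed_of_sample <- rep(seq_len(nb), times = sizes)
  sample_ids <- sprintf("%s_s%d", breed_names[breed_of_sample],
                        unlist(lapply(sizes, seq_len)))

  # per-cell success probability: block frequency of the sample's breed
  pmat_block <- freq_block[, breed_of_sample, drop = FALSE]  # blocks x samples
  latent <- matrix(stats::rbinom(n_blocks * ns, 2L, pmat_block),
                   nrow = n_blocks)
  pmat <- pmat_block[block_id, , drop = FALSE]               # variants x samples
  fresh <- matrix(stats::rbinom(nv * ns, 2L, pmat), nrow = nv)
  if (config$ld_rho > 0 && config$ld_block_size > 1L) {
    copy <- matrix(stats::runif(nv * ns) < config$ld_rho, nrow = nv)
    geno <- ifelse(copy, latent[block_id, , drop = FALSE], fresh)
  } else {
    geno <- fresh
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(NULL, sample_ids)

  status <- ifelse(breed_of_sample %in% config$case_breeds, "case", "control")
  design <- list(samples = data.frame(sample_id = sample_ids,
                                      breed = breed_names[breed_of_sample],
                                      status = status,
                                      is_offspring = FALSE,
                                      stringsAsFactors = FALSE),
                 trios = data.frame(offspring = character(),
                                    sire = character(), dam = character(),
                                    stringsAsFactors = FALSE))

  variants <- simulate_site_annotations(chrom, pos, config)
  rownames(geno) <- variants$id

  cohort <- structure(list(genotypes = geno, variants = variants,
                           design = design),
                      class = "wgva_cohort")

  if (implant) {
    v <- config$causal_spec$variant
    if (is.null(v)) {
      on5 <- which(chrom_idx == min(5L, config$n_chromosomes))
      v <- on5[ceiling(length(on5) / 2)]
    }
    cohort <- implant_causal_variant(cohort, utils::modifyList(
      config$causal_spec, list(variant = v)))
    # the causal site is a 1-bp deletion, the variant class of interest;
    # it emulates a real well-supported call, so its annotations sit in
    # the nominal pass region rather than being drawn with the background
    # contamination rate
    cohort$variants$ref[v] <- "AC"
    cohort$variants$alt[v] <- "A"
    cohort$variants$is_indel[v] <- TRUE
    cohort$variants$id[v] <- sprintf("%s:%d_del", chrom[v], pos[v])
    cohort$variants[v, c("QD", "FS", "SOR", "ReadPosRankSum", "DP", "MQ",
                         "MQRankSum", "InbreedingCoeff")] <-
      list(25, 3, 1.2, 0.5, 2500, 55, 0.2, 0.05)
    rownames(cohort$genotypes) <- cohort$variants$id
  }

  # missingness is applied after implanting; the causal site — a genuine,
  # well-covered variant in the population it is fixed in — stays fully
  # genotyped while background sites are masked at the cohort rate
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(nv * ns) < config$missing_rate, nrow = nv)
    if (implant) drop[which(cohort$variants$causal), ] <- FALSE
    cohort$genotypes[drop] <- NA_integer_
  }

  if (add_trios && config$n_trios > 0L)
    cohort <- simulate_trios(cohort, config$n_trios,
                             config$genotype_error_rate,
                             missing_rate = config$missing_rate)
  cohort
}

# GATK-style site annotations: unit-scale distributions centred in the pass
# region, with a contaminating fraction drawn beyond each threshold.
simulate_site_annotations <- function(chrom, pos, config) {
  nv <- length(chrom)
  fail <- function() stats::runif(nv) < config$annotation_fail_rate
  mix <- function(pass, bad) ifelse(fail(), bad, pass)
  is_indel <- stats::runif(nv) < config$indel_fraction
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ins <- stats::runif(nv) < 0.5
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], alt[is_indel & !ins])
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1L, 1L)
  alt[is_indel & ins] <- paste0(ref[is_indel & ins], alt[is_indel & ins])
  data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("%s:%d", chrom, pos),
    ref = ref, alt = alt, is_indel = is_indel,
    QD = mix(stats::runif(nv, 15, 35), stats::runif(nv, 0, 2)),
    FS = mix(stats::runif(nv, 0, 10), stats::runif(nv, 60, 200)),
    SOR = mix(stats::runif(nv, 0.5, 2.5), stats::runif(nv, 4, 9)),
    ReadPosRankSum = mix(stats::runif(nv, -2, 2), stats::runif(nv, -14, -8)),
    DP = mix(round(stats::runif(nv, 1500, 3000)),
             round(stats::runif(nv, 3106, 6000))),
    MQ = mix(stats::runif(nv, 45, 60), stats::runif(nv, 10, 40)),
    MQRankSum = mix(stats::runif(nv, -2, 2), stats::runif(nv, -20, -12.5)),
    InbreedingCoeff = mix(stats::runif(nv, -0.3, 0.6),
                          stats::runif(nv, -1, -0.8)),
    causal = FALSE,
    stringsAsFactors = FALSE)
}

#' Implant a breed-defining causal recessive variant
#'
#' Overwrites one variant so that case-breed samples carry the alternate
#' allele at `case_freq` (1 = every case homozygous alt) while control-breed
#' samples carry it at the low `control_freq`. A configurable flank of
#' surrounding variants is swept to slightly weaker case/control
#' differentiation, emulating the long fixed haplotype that surrounds a
#' breed-defining variant and giving the fixation scan a region to find.
#'
#' @param cohort A `"wgva_cohort"`.
#' @param causal_spec List with `variant` (index), `case_freq`,
#'   `control_freq`, and optionally `flank`, `flank_case_freq`,
#'   `flank_control_freq` (flank defaults to 0 here when unspecified).
#' @return The cohort with genotypes overwritten at the causal site (and
#'   flank) and `variants$causal` flagged.
#' @export
implant_causal_variant <- function(cohort, causal_spec) {
  v <- causal_spec$variant
  nv <- nrow(cohort$genotypes)
  if (is.null(v) || v < 1L || v > nv)
    stop("causal variant index out of range")
  is_case <- cohort$design$samples$status == "case" &
    !cohort$design$samples$is_offspring
  draw <- function(freq, n) {
    if (freq == 1) rep(2L, n)
    else if (freq == 0) rep(0L, n)
    else stats::rbinom(n, 2L, freq)
  }
  set_site <- function(g, i, case_freq, control_freq) {
    g[i, is_case] <- draw(case_freq, sum(is_case))
    g[i, !is_case] <- draw(control_freq, sum(!is_case))
    g
  }
  g <- cohort$genotypes
  if (causal_spec$case_freq == 1) {
    g[v, is_case] <- 2L
    g[v, !is_case] <- draw(causal_spec$control_freq, sum(!is_case))
  } else {
    g <- set_site(g, v, causal_spec$case_freq, causal_spec$control_freq)
  }
  flank <- causal_spec$flank %||% 0L
  if (flank > 0L) {
    same_chrom <- which(cohort$variants$chrom == cohort$variants$chrom[v])
    near <- same_chrom[abs(same_chrom - v) <= flank & same_chrom != v]
    for (i in near)
      g <- set_site(g, i, causal_spec$flank_case_freq,
                    causal_spec$flank_control_freq)
  }
  cohort$genotypes <- g
  cohort$variants$causal[v] <- TRUE
  cohort
}

#' Append simulated trios to a cohort
#'
#' Picks `n_trios` pairs of same-breed founders as sire and dam and forms
#' each offspring genotype by drawing one allele from each parent. Each
#' offspring cell is then independently corrupted with probability
#' `genotype_error_rate` to a random different dosage, and masked missing
#' with probability `missing_rate`. A cell is missing in the offspring
#' wherever a parent is missing.
#'
#' @param cohort A `"wgva_cohort"`.
#' @param n_trios Number of trios to create.
#' @param genotype_error_rate Per-cell corruption probability.
#' @param missing_rate Per-cell missingness probability for offspring.
#' @return The cohort with offspring columns appended and
#'   `design$trios` filled.
#' @export
simulate_trios <- function(cohort, n_trios, genotype_error_rate = 0,
                           missing_rate = 0) {
  samples <- cohort$design$samples[!cohort$design$samples$is_offspring, ]
  eligible <- names(which(table(samples$breed) >= 2))
  if (length(eligible) < 1L || nrow(samples) < 2L * n_trios)
    stop("not enough parent candidates for ", n_trios, " trios")
  breeds <- sample(rep(eligible, length.out = max(n_trios, length(eligible))),
                   n_trios)
  nv <- nrow(cohort$genotypes)
  trios <- data.frame(offspring = character(n_trios), sire = character(n_trios),
                      dam = character(n_trios), stringsAsFactors = FALSE)
  kids <- matrix(NA_integer_, nrow = nv, ncol = n_trios)
  kid_rows <- vector("list", n_trios)
  for (k in seq_len(n_trios)) {
    pair <- sample(samples$sample_id[samples$breed == breeds[k]], 2L)
    gs <- cohort$genotypes[, pair[1]]
    gd <- cohort$genotypes[, pair[2]]
    off <- rbinom_allele(gs) + rbinom_allele(gd)
    if (genotype_error_rate > 0) {
      err <- which(stats::runif(nv) < genotype_error_rate & !is.na(off))
      if (length(err))
        off[err] <- vapply(off[err],
                           function(o) sample(setdiff(0:2, o), 1L),
                           integer(1))
    }
    if (missing_rate > 0)
      off[stats::runif(nv) < missing_rate] <- NA_integer_
    kid_id <- sprintf("%s_trio%d_off", breeds[k], k)
    kids[, k] <- off
    trios[k, ] <- c(kid_id, pair[1], pair[2])
    kid_rows[[k]] <- data.frame(sample_id = kid_id, breed = breeds[k],
                                status = samples$status[
                                  match(pair[1], samples$sample_id)],
                                is_offspring = TRUE, stringsAsFactors = FALSE)
  }
  colnames(kids) <- trios$offspring
  cohort$genotypes <- cbind(cohort$genotypes, kids)
  cohort$design$samples <- rbind(cohort$design$samples,
                                 do.call(rbind, kid_rows))
  cohort$design$trios <- rbind(cohort$design$trios, trios)
  cohort
}

# one transmitted allele per parent genotype (NA propagates)
rbinom_allele <- function(g) {
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  out[ok] <- stats::rbinom(sum(ok), 1L, g[ok] / 2)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wgva_cohort <- function(x, ...) {
  cat(sprintf("wgva_cohort: %d variants x %d samples (%d cases, %d trios)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$design$samples$status == "case" &
                    !x$design$samples$is_offspring),
              nrow(x$design$trios)))
  invisible(x)
}
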