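test_that("missingness filter removes strictly-above-threshold variants", {
  g <- matrix(0L, nrow = 3, ncol = 100)
  g[1, 1:11] <- NA  # 11% missing: removed
  g[2, 1:10] <- NA  # 10% missing: kept
  expect_identical(filter_missingness(g, 0.10), c(2L, 3L))
  expect_identical(filter_missingness(g, 0), 3L)
  expect_identical(filter_missingness(matrix(1L, 2, 4)), c(1L, 2L))
})

test_that("MAF filter keeps variants at or above the threshold", {
  g <- rbind(c(1L, rep(0L, 99)),              # MAF 0.005
             c(1L, 1L, rep(0L, 98)),          # MAF 0.01 exactly
             rep(1L, 100),                    # MAF 0.5
             rep(0L, 100))                    # monomorphic
  expect_identical(filter_maf(g, 0.01), c(2L, 3L))
  expect_identical(filter_maf(g, 0.5), 3L)
})

test_that("IBS distance matches the normalised L1 definition", {
  g <- cbind(a = c(0L, 0L, 0L), b = c(2L, 2L, 2L), c = c(1L, 0L, 0L))
  D <- ibs_distance(g)
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D["a", "b"], 1)            # maximal opposition
  expect_equal(D, t(D))
  expect_equal(ibs_distance(cbind(x = 1L, y = 2L))["x", "y"], 0.5)
  expect_equal(ibs_distance(cbind(x = c(1L, NA), y = c(2L, 0L)))["x", "y"],
               0.5)  # missing site excluded from the denominator
  expect_error(ibs_distance(cbind(x = c(1L, NA), y = c(NA, 0L))),
               "no overlapping")
})

test_that("IBS distance satisfies the triangle inequality without missing data", {
  set.seed(3)
  g <- matrix(sample(0:2, 50 * 6, replace = TRUE), ncol = 6)
  colnames(g) <- letters[1:6]
  D <- ibs_distance(g)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  expect_true(all(D >= 0 & D <= 1))
})

test_that("dendrogram recovers simulated breed structure", {
  cfg <- simulation_config(n_breeds = 3, breed_sizes = c(6, 6, 6),
                           case_breeds = 1, breed_fst = 0.2,
                           n_variants = 2000, n_chromosomes = 4,
                           n_trios = 0, missing_rate = 0, seed = 21)
  ch <- simulate_cohort(cfg, implant = FALSE, add_trios = FALSE)
  D <- ibs_distance(ch$genotypes)
  cl <- cutree(hclust(as.dist(D), method = "average"), k = 3)
  breed <- ch$design$samples$breed
  # the 3-cluster cut recovers the breed partition exactly
  expect_equal(length(unique(paste(cl, breed))), 3L)
  tree <- ibs_dendrogram(D)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, ch$design$samples$sample_id)
})

test_that("two-sample dendrogram is a cherry with half-distance branches", {
  D <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  tree <- ibs_dendrogram(D)
  expect_equal(sort(tree$edge.length), c(0.15, 0.15))
  expect_error(ibs_dendrogram(D[1, 1, drop = FALSE]), "at least 2")
})

test_that("duplicate samples merge first at height zero", {
  set.seed(8)
  g <- matrix(sample(0:2, 40 * 4, replace = TRUE), ncol = 4)
  g[, 4] <- g[, 1]
  colnames(g) <- c("a", "b", "c", "a_dup")
  D <- ibs_distance(g)
  h <- hclust(as.dist(D), method = "average")
  expect_equal(h$height[1], 0)
  expect_setequal(h$labels[-h$merge[1, ]], c("a", "a_dup"))
})

test_that("VIF pruning: uncorrelated variants survive, duplicates lose one copy", {
  set.seed(12)
  g <- matrix(sample(0:2, 20 * 200, replace = TRUE), nrow = 20)
  kept <- vif_prune(g, cfg = prune_config(window_size = 20, step_size = 5))
  expect_identical(kept, 1:20)
  g2 <- rbind(g, g[3, , drop = FALSE])  # exact duplicate of variant 3
  kept2 <- vif_prune(g2, cfg = prune_config(window_size = 21, step_size = 5))
  # tie at infinite VIF removes the larger index, keeping variant 3
  expect_identical(kept2, 1:20)
})

test_that("VIF pruning equals the brute-force least-squares oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 40
    base <- matrix(sample(0:2, 8 * n, replace = TRUE), ncol = 8)
    # induce correlation: some columns copy others with noise
    for (j in sample(8, 3))
      base[, j] <- ifelse(runif(n) < 0.85, base[, sample(8, 1)],
                          sample(0:2, n, replace = TRUE))
    kept <- vif_prune(t(base), cfg = prune_config(8, 8, 2))
    expect_identical(kept, oracle_prune_window(base, 2),
                     label = paste("seed", seed))
  }
})

test_that("VIF pruning is idempotent", {
  cfg <- tiny_config(n_variants = 400, ld_rho = 0.9, missing_rate = 0.05)
  ch <- simulate_cohort(cfg)
  kept <- vif_prune(ch$genotypes, chrom = ch$variants$chrom,
                    cfg = prune_config(20, 5, 2))
  again <- vif_prune(ch$genotypes[kept, , drop = FALSE],
                     chrom = ch$variants$chrom[kept],
                     cfg = prune_config(20, 5, 2))
  expect_identical(again, seq_along(kept))
})

test_that("Mendelian error detection follows biparental transmission rules", {
  g <- cbind(sire = c(0L, 0L, 0L, 2L, 1L, 0L, NA),
             dam  = c(0L, 0L, 2L, 2L, 2L, 1L, 0L),
             kid  = c(0L, 2L, 1L, 1L, 0L, 2L, 2L))
  trios <- data.frame(offspring = "kid", sire = "sire", dam = "dam")
  me <- mendel_errors(g, trios)
  # site 1 ok; 2 error; 3 forced het ok; 4 error; 5 error; 6 error; 7 skipped
  expect_equal(me$n_sites, 6)
  expect_equal(me$n_errors, 4)
  expect_equal(me$rate_per_meiosis, 4 / 12)
})

test_that("detected Mendelian error rate increases with the injected rate", {
  rates <- vapply(c(0.01, 0.05, 0.10), function(e) {
    cfg <- tiny_config(n_variants = 1500, n_trios = 3, missing_rate = 0,
                       genotype_error_rate = e, seed = 99)
    ch <- simulate_cohort(cfg)
    mendel_errors(ch$genotypes, ch$design$trios)$rate_per_meiosis
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates > 0))
})
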