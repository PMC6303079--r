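test_that("allele tables count non-missing alleles per group", {
  g <- rbind(c(rep(2L, 10), rep(0L, 84)))
  colnames(g) <- paste0("s", 1:94)
  design <- list(samples = data.frame(
    sample_id = paste0("s", 1:94),
    status = c(rep("case", 10), rep("control", 84)),
    is_offspring = FALSE, stringsAsFactors = FALSE))
  expect_equal(allele_table(g, design, 1),
               c(case_alt = 20, case_ref = 0, control_alt = 0,
                 control_ref = 168))
  g2 <- g; g2[1, 94] <- NA  # one control missing: denominator drops by 2
  expect_equal(allele_table(g2, design, 1)[["control_ref"]], 166)
  g3 <- g; g3[1, 1:10] <- 1L  # all-het cases
  expect_equal(unname(allele_table(g3, design, 1)[1:2]), c(10, 10))
  g4 <- g; g4[1, 1:10] <- NA
  expect_error(allele_table(g4, design, 1), "missing")
})

test_that("allelic chi-square matches its closed form and the Pearson oracle", {
  # equal frequencies: no signal
  expect_equal(allelic_chisq(5, 5, 20, 20)$chi2, 0)
  expect_equal(allelic_chisq(5, 5, 20, 20)$p_raw, 1)
  # perfect separation: chi2 equals the total allele count
  expect_equal(allelic_chisq(20, 0, 0, 168)$chi2, 188)
  # direct closed-form evaluation
  a <- 20; b <- 0; cc <- 1; d <- 167
  n <- a + b + cc + d
  expect_equal(allelic_chisq(a, b, cc, d)$chi2,
               n * (a * d - b * cc)^2 /
                 ((a + b) * (cc + d) * (a + cc) * (b + d)))
  expect_equal(round(allelic_chisq(a, b, cc, d)$chi2, 2), 177.98)
  # zero marginal: degenerate, uninformative
  expect_equal(allelic_chisq(0, 0, 5, 5)$chi2, 0)
  expect_equal(allelic_chisq(0, 0, 5, 5)$p_raw, 1)
})

test_that("allelic chi-square equals chisq.test on 1,000 random tables", {
  set.seed(17)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 20) + (i %% 3 == 0), 2)
    ours <- allelic_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      expect_equal(ours$chi2, 0)
    } else {
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_lt(abs(ours$chi2 - unname(ref$statistic)),
                1e-10 * max(1, ours$chi2))
      expect_lt(abs(ours$p_raw - ref$p.value), 1e-10)
    }
  }
})

test_that("lambda estimation is calibrated on null draws and scale-equivariant", {
  set.seed(31)
  null_chi2 <- rnorm(100000)^2
  for (mode in c("mean", "median")) {
    lam <- estimate_lambda(null_chi2, mode)$lambda
    expect_gt(lam, 0.95)
    expect_lt(lam, 1.05)
    lam_inflated <- estimate_lambda(null_chi2 * 3.2761, mode)$lambda
    expect_lt(abs(lam_inflated - 3.2761) / 3.2761, 0.05)
  }
  expect_equal(estimate_lambda(rep(2, 10), "mean")$lambda, 2)
  expect_error(estimate_lambda(numeric(0)), "no finite")
})

test_that("genomic control divides statistics and preserves p ordering", {
  model1 <- structure(list(lambda = 1, mode = "mean"), class = "gc_model")
  chi2 <- c(0.5, 2, 10, 93.93)
  gc1 <- gc_correct(chi2, model1)
  expect_equal(gc1$chi2_gc, chi2)
  model <- structure(list(lambda = 3.2761, mode = "mean"), class = "gc_model")
  gc <- gc_correct(chi2, model)
  expect_equal(round(gc$chi2_gc[4], 2), 28.67)
  expect_equal(gc$p_gc[4], pchisq(93.93 / 3.2761, 1, lower.tail = FALSE))
  expect_lt(abs(gc$p_gc[4] - 8.5e-8) / 8.5e-8, 0.02)
  expect_identical(order(gc$p_gc), order(pchisq(chi2, 1, lower.tail = FALSE)))
  # mean of mean-mode-corrected statistics is 1 by construction
  set.seed(4)
  x <- rnorm(500)^2 * 2.5
  m <- estimate_lambda(x, "mean")
  expect_equal(mean(gc_correct(x, m)$chi2_gc), 1)
  # deflation is floored: lambda < 1 leaves statistics unchanged by default
  weak <- structure(list(lambda = 0.8, mode = "mean"), class = "gc_model")
  expect_equal(gc_correct(chi2, weak)$chi2_gc, chi2)
  expect_equal(gc_correct(chi2, weak, floor_lambda = FALSE)$chi2_gc,
               chi2 / 0.8)
})

test_that("Bonferroni correction clamps at 1 and scales linearly", {
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(1e-30, 587159), 5.87159e-25)
  expect_equal(bonferroni(0.03, 1), 0.03)
})

test_that("significance threshold inverts the GC + Bonferroni composition", {
  m1 <- structure(list(lambda = 1, mode = "mean"), class = "gc_model")
  expect_equal(significance_threshold(0.05, 1, m1), 0.05)
  m <- structure(list(lambda = 3.2761, mode = "mean"), class = "gc_model")
  t1 <- significance_threshold(0.05, 587159, m)
  expect_equal(t1, pchisq(3.2761 * qchisq(0.05 / 587159, 1,
                                          lower.tail = FALSE),
                          1, lower.tail = FALSE))
  expect_lt(t1, 1e-20)
  # a variant exactly at the threshold attains p_bonf = alpha
  chi2_at <- qchisq(t1, 1, lower.tail = FALSE)
  p_gc_at <- pchisq(chi2_at / 3.2761, 1, lower.tail = FALSE)
  expect_equal(bonferroni(p_gc_at, 587159), 0.05, tolerance = 1e-6)
  # strictly decreasing in lambda and in the number of tests
  m2 <- structure(list(lambda = 4, mode = "mean"), class = "gc_model")
  expect_lt(significance_threshold(0.05, 587159, m2), t1)
  expect_lt(significance_threshold(0.05, 1e6, m), t1)
})

test_that("run_association ranks an implanted separated variant first", {
  cfg <- tiny_config(missing_rate = 0,
                     causal_spec = list(control_freq = 0, flank = 0))
  ch <- simulate_cohort(cfg, add_trios = FALSE)
  assoc <- run_association(ch$genotypes, ch$variants, ch$design)
  expect_equal(which.min(assoc$result$P_GC),
               which(assoc$result$CAUSAL))
  expect_equal(nrow(assoc$qq), nrow(assoc$result))
  expect_true(all(diff(assoc$qq$expected) <= 0) ||
                all(diff(assoc$qq$expected) >= 0))
})

test_that("an empty case set errors before any statistic is computed", {
  g <- matrix(0L, 2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  design <- list(samples = data.frame(sample_id = paste0("s", 1:4),
                                      status = "control",
                                      is_offspring = FALSE))
  v <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "T")
  expect_error(run_association(g, v, design), "no case samples")
})

test_that("stratification inflates lambda and GC restores calibration", {
  # stratification OFF: lambda near 1
  cfg0 <- simulation_config(n_breeds = 4, breed_sizes = c(5, 5, 45, 45),
                            case_breeds = 1:2, breed_fst = 0,
                            n_variants = 5000, n_chromosomes = 5,
                            n_trios = 0, missing_rate = 0, ld_rho = 0,
                            seed = 61)
  ch0 <- simulate_cohort(cfg0, implant = FALSE, add_trios = FALSE)
  a0 <- run_association(ch0$genotypes, ch0$variants, ch0$design)
  expect_gt(a0$model$lambda, 0.9)
  expect_lt(a0$model$lambda, 1.1)
  # strong stratification ON (trait = breed membership): lambda well above 1
  cfg1 <- simulation_config(n_breeds = 4, breed_sizes = c(5, 5, 45, 45),
                            case_breeds = 1:2, breed_fst = 0.2,
                            n_variants = 5000, n_chromosomes = 5,
                            n_trios = 0, missing_rate = 0, ld_rho = 0,
                            seed = 62)
  ch1 <- simulate_cohort(cfg1, implant = FALSE, add_trios = FALSE)
  a1 <- run_association(ch1$genotypes, ch1$variants, ch1$design)
  expect_gt(a1$model$lambda, 1.5)
})
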