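#' Case/control allele counts for one variant
#'
#' Counts alternate and reference alleles among non-missing cases and
#' controls: `case_alt` is the sum of case dosages, `case_ref` is
#' `2 * n_nonmissing_cases - case_alt`, likewise for controls. Trio
#' offspring are excluded when `exclude_offspring` is set (offspring
#' duplicate parental chromosomes and are dropped from association, as in
#' the source design of 10 cases vs 84 controls).
#'
#' @param geno Dosage matrix (variants x samples).
#' @param design Cohort design list (`samples` with `sample_id`, `status`,
#'   optionally `is_offspring`).
#' @param variant Variant row index.
#' @param exclude_offspring Drop trio offspring before counting?
#' @return Named numeric vector `c(case_alt, case_ref, control_alt,
#'   control_ref)`.
#' @export
allele_table <- function(geno, design, variant, exclude_offspring = TRUE) {
  counts <- allele_count_matrix(geno[variant, , drop = FALSE], design,
                                exclude_offspring)
  if (counts[1, "case_alt"] + counts[1, "case_ref"] == 0 ||
      counts[1, "control_alt"] + counts[1, "control_ref"] == 0)
    stop("variant ", variant, ": all genotypes missing in one group")
  counts[1, ]
}

# vectorised allele counts for all variant rows
allele_count_matrix <- function(geno, design, exclude_offspring = TRUE) {
  s <- design$samples
  use <- if (exclude_offspring && "is_offspring" %in% names(s))
    !s$is_offspring else rep(TRUE, nrow(s))
  is_case <- s$status == "case" & use
  is_control <- s$status == "control" & use
  if (!any(is_case)) stop("no case samples in design")
  if (!any(is_control)) stop("no control samples in design")
  cols <- match(s$sample_id, colnames(geno))
  case_cols <- cols[is_case]
  control_cols <- cols[is_control]
  ga <- geno[, case_cols, drop = FALSE]
  gu <- geno[, control_cols, drop = FALSE]
  case_alt <- rowSums(ga, na.rm = TRUE)
  case_n <- rowSums(!is.na(ga))
  control_alt <- rowSums(gu, na.rm = TRUE)
  control_n <- rowSums(!is.na(gu))
  cbind(case_alt = case_alt, case_ref = 2 * case_n - case_alt,
        control_alt = control_alt, control_ref = 2 * control_n - control_alt)
}

#' Allelic 1-df chi-square test
#'
#' Pearson chi-square on the 2x2 allele table with `a = case_alt`,
#' `b = case_ref`, `c = control_alt`, `d = control_ref`:
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, p from the upper tail
#' of chi-square with 1 df. Any zero marginal gives `chi2 = 0`, `p = 1`
#' (uninformative variant). All arguments vectorise.
#'
#' @param case_alt,case_ref,control_alt,control_ref Allele counts.
#' @return data.frame with `chi2` and `p_raw`.
#' @examples
#' allelic_chisq(20, 0, 0, 168)  # perfect separation: chi2 = N = 188
#' @export
allelic_chisq <- function(case_alt, case_ref, control_alt, control_ref) {
  a <- case_alt; b <- case_ref; c <- control_alt; d <- control_ref
  n <- a + b + c + d
  stopifnot(all(n > 0))
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom == 0, 0, n * (a * d - b * c)^2 / denom)
  data.frame(chi2 = chi2,
             p_raw = ifelse(denom == 0, 1,
                            stats::pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Estimate the genomic inflation factor
#'
#' Under genomic control, association statistics in a stratified cohort are
#' inflated by a factor lambda relative to the null 1-df chi-square.
#' `mode = "mean"` estimates lambda as the mean of the statistics (the
#' assumption being that most variants are null, so the statistics should
#' average 1); `mode = "median"` uses the more outlier-robust
#' `median / 0.4549364` (the null chi-square(1) median).
#'
#' @param chi2 Vector of chi-square statistics (non-finite values dropped).
#' @param mode `"mean"` or `"median"`.
#' @return List of class `"gc_model"` with `lambda` and `mode`.
#' @export
estimate_lambda <- function(chi2, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0L) stop("no finite statistics to estimate lambda")
  lambda <- switch(mode,
                   mean = mean(chi2),
                   median = stats::median(chi2) / CHISQ1_MEDIAN)
  structure(list(lambda = lambda, mode = mode), class = "gc_model")
}

CHISQ1_MEDIAN <- 0.4549364

#' Genomic-control correction of chi-square statistics
#'
#' Divides each statistic by the inflation factor (floored at 1 by default,
#' so deflated cohorts are not inflated) and recomputes p-values from the
#' 1-df chi-square upper tail. The correction is monotone: variant ordering
#' by p-value is preserved.
#'
#' @param chi2 Vector of chi-square statistics.
#' @param model A `"gc_model"` from [estimate_lambda()].
#' @param floor_lambda Floor lambda at 1 before correcting?
#' @return data.frame with `chi2_gc` and `p_gc`.
#' @export
gc_correct <- function(chi2, model, floor_lambda = TRUE) {
  lambda <- if (floor_lambda) max(model$lambda, 1) else model$lambda
  chi2_gc <- chi2 / lambda
  data.frame(chi2_gc = chi2_gc,
             p_gc = stats::pchisq(chi2_gc, df = 1, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' `p_bonf = min(1, p * n_tests)`. `n_tests` is conventionally the size of
#' the LD-pruned variant set (independent haplotypes), overridable to the
#' full tested-variant count.
#'
#' @param p P-values.
#' @param n_tests Number of independent tests (>= 1).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Raw p-value equivalent of a Bonferroni-corrected significance level
#'
#' Inverts the genomic-control + Bonferroni composition: the uncorrected
#' p-value `t` at which a variant attains `p_bonf = alpha` is
#' `t = P(chi2_1 > lambda * Q_chi2_1(1 - alpha / n_tests))`. `t` decreases
#' in both lambda and `n_tests`.
#'
#' @param alpha Target corrected significance level in (0, 1).
#' @param n_tests Number of independent tests.
#' @param model A `"gc_model"` (lambda floored at 1 as in [gc_correct()]).
#' @param floor_lambda Floor lambda at 1?
#' @return The equivalent raw p-value threshold.
#' @export
significance_threshold <- function(alpha, n_tests, model,
                                   floor_lambda = TRUE) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  lambda <- if (floor_lambda) max(model$lambda, 1) else model$lambda
  q <- stats::qchisq(alpha / n_tests, df = 1, lower.tail = FALSE)
  stats::pchisq(lambda * q, df = 1, lower.tail = FALSE)
}

#' Case/control allelic association across all variants
#'
#' Runs the allelic chi-square at every variant, estimates the genomic
#' inflation factor from the genome-wide statistics, applies genomic
#' control and Bonferroni correction, and reports allele frequencies and
#' the case/control allelic difference per variant, plus the QQ table
#' (expected vs observed -log10 p after correction).
#'
#' @param geno Dosage matrix (variants x samples).
#' @param variants Variant data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param design Cohort design list.
#' @param gc_mode Lambda estimator, `"mean"` (default) or `"median"`.
#' @param n_tests Bonferroni denominator; defaults to the number of tested
#'   variants, conventionally overridden with the LD-pruned count.
#' @param exclude_offspring Drop trio offspring before counting alleles?
#' @return List of class `"wgva_assoc"`: `result` (one row per variant,
#'   ordered by chromosome/position: CHR, POS, REF, ALT, A_CASE, U_CASE,
#'   A_CTRL, U_CTRL, F_CASE, F_CTRL, CHISQ, P, CHISQ_GC, P_GC, P_BONF,
#'   ALLELIC_DIFF), `model` (the fitted `gc_model`), `n_tests`, and `qq`
#'   (data.frame `expected`, `observed` in -log10 p units).
#' @export
run_association <- function(geno, variants, design,
                            gc_mode = c("mean", "median"), n_tests = NULL,
                            exclude_offspring = TRUE) {
  gc_mode <- match.arg(gc_mode)
  stopifnot(nrow(geno) == nrow(variants))
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  geno <- geno[ord, , drop = FALSE]
  variants <- variants[ord, , drop = FALSE]
  counts <- allele_count_matrix(geno, design, exclude_offspring)
  ts <- allelic_chisq(counts[, "case_alt"], counts[, "case_ref"],
                      counts[, "control_alt"], counts[, "control_ref"])
  model <- estimate_lambda(ts$chi2, mode = gc_mode)
  gc <- gc_correct(ts$chi2, model)
  if (is.null(n_tests)) n_tests <- nrow(variants)
  f_case <- counts[, "case_alt"] /
    pmax(counts[, "case_alt"] + counts[, "case_ref"], 1)
  f_control <- counts[, "control_alt"] /
    pmax(counts[, "control_alt"] + counts[, "control_ref"], 1)
  result <- data.frame(
    CHR = variants$chrom, POS = variants$pos, REF = variants$ref,
    ALT = variants$alt,
    A_CASE = counts[, "case_alt"], U_CASE = counts[, "case_ref"],
    A_CTRL = counts[, "control_alt"], U_CTRL = counts[, "control_ref"],
    F_CASE = f_case, F_CTRL = f_control,
    CHISQ = ts$chi2, P = ts$p_raw,
    CHISQ_GC = gc$chi2_gc, P_GC = gc$p_gc,
    P_BONF = bonferroni(gc$p_gc, n_tests),
    ALLELIC_DIFF = abs(f_case - f_control),
    stringsAsFactors = FALSE)
  if ("causal" %in% names(variants)) result$CAUSAL <- variants$causal
  p_sorted <- sort(gc$p_gc)
  qq <- data.frame(
    expected = -log10((seq_along(p_sorted) - 0.5) / length(p_sorted)),
    observed = -log10(p_sorted))
  structure(list(result = result, model = model, n_tests = n_tests, qq = qq),
            class = "wgva_assoc")
}

# numeric-aware chromosome ordering: chr1 < chr2 < ... < chr10 < chrX
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  ifelse(is.na(num), 1e6 + as.numeric(factor(chrom)), num)
}

#' @export
print.wgva_assoc <- function(x, ...) {
  cat(sprintf("wgva_assoc: %d variants, lambda = %.4f (%s), n_tests = %d\n",
              nrow(x$result), x$model$lambda, x$model$mode, x$n_tests))
  top <- x$result[order(x$result$P_GC), ][1, ]
  cat(sprintf("top hit: %s:%d  chi2 = %.2f  p_gc = %.3g  p_bonf = %.3g\n",
              top$CHR, top$POS, top$CHISQ, top$P_GC, top$P_BONF))
  invisible(x)
}
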