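#' Per-breed genotype counts at one variant
#'
#' Tallies homozygous-reference, heterozygous and homozygous-alternate
#' samples within each breed at a bi-allelic variant, over non-missing
#' genotypes. Breeds with every sample missing at the variant return a
#' zero row with a warning.
#'
#' @param geno Dosage matrix (variants x samples).
#' @param design Cohort design list (`samples` with `sample_id`, `breed`).
#' @param variant Variant row index.
#' @return data.frame: `breed`, `hom_ref`, `het`, `hom_alt`.
#' @export
genotype_counts <- function(geno, design, variant) {
  s <- design$samples
  g <- geno[variant, match(s$sample_id, colnames(geno))]
  breeds <- unique(s$breed)
  out <- do.call(rbind, lapply(breeds, function(b) {
    gb <- g[s$breed == b]
    data.frame(breed = b,
               hom_ref = sum(gb == 0L, na.rm = TRUE),
               het = sum(gb == 1L, na.rm = TRUE),
               hom_alt = sum(gb == 2L, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  empty <- with(out, hom_ref + het + hom_alt) == 0L
  if (any(empty))
    warning("all genotypes missing at variant ", variant, " for breed(s): ",
            paste(out$breed[empty], collapse = ", "))
  out
}

#' Alternate allele frequency from genotype counts
#'
#' `(het + 2 * hom_alt) / (2 * total)`. Vectorises over rows of counts.
#'
#' @param hom_ref,het,hom_alt Genotype counts.
#' @return Alt-allele frequency in `[0, 1]`.
#' @examples
#' allele_frequency(2, 4, 59)  # 122/130 = 0.9385, reported 0.94
#' @export
allele_frequency <- function(hom_ref, het, hom_alt) {
  total <- hom_ref + het + hom_alt
  if (any(total == 0)) stop("zero genotype total")
  (het + 2 * hom_alt) / (2 * total)
}

#' Penetrance of a phenotype among homozygotes
#'
#' The fraction of genotype-positive individuals expressing the phenotype,
#' as a percentage: `100 * present / (present + absent)`. The full-
#' precision fraction is retained alongside a one-decimal display value
#' (round half up).
#'
#' @param present Count of homozygotes with the phenotype.
#' @param absent Count of homozygotes without it.
#' @return List of class `"penetrance"`: `present`, `absent`, `fraction`,
#'   `penetrance_pct`, `display` (one decimal).
#' @examples
#' penetrance(20, 24)  # 45.45...%, displayed 45.5
#' penetrance(7, 0)    # fully penetrant
#' @export
penetrance <- function(present, absent) {
  total <- present + absent
  if (total <= 0) stop("present + absent must be positive")
  frac <- present / total
  pct <- 100 * frac
  structure(list(present = present, absent = absent, fraction = frac,
                 penetrance_pct = pct,
                 display = floor(pct * 10 + 0.5) / 10),
            class = "penetrance")
}

#' @export
print.penetrance <- function(x, ...) {
  cat(sprintf("penetrance: %d/%d = %.1f%%\n", x$present,
              x$present + x$absent, x$display))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the conventional point-probability
#' two-sided definition: the two-sided p-value sums the probabilities of
#' all tables with the observed margins whose point probability is at most
#' the observed one (comparison tolerance 1e-12 relative). One-sided
#' alternatives sum the upper (`"greater"`, association of `a` with the
#' first margin) or lower (`"less"`) tail.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact(3, 0, 0, 3)               # 0.1
#' fisher_exact(16, 0, 0, 22, "greater")  # 1 / choose(38, 16)
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-12)]),
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]))
  min(p, 1)
}

#' Exact segregation test of genotype against phenotype
#'
#' Tests whether the phenotype segregates with the genotype across breeds.
#' `collapse = "recessive"` (default, matching a recessive inheritance
#' claim) pools homozygous-alternate individuals against all others into a
#' 2x2 table of phenotype presence and applies [fisher_exact()] two-sided.
#' `collapse = "genotypic"` runs the exact conditional test on the full
#' r x 2 genotype-by-phenotype table by complete enumeration of tables
#' with the observed margins (feasible at pedigree-scale counts).
#'
#' @param gp_table data.frame with columns `genotype` (values among
#'   `"hom_ref"`, `"het"`, `"hom_alt"`), `affected`, `unaffected`;
#'   optionally a `breed` column (rows are summed over breeds).
#' @param collapse `"recessive"` or `"genotypic"`.
#' @return The exact p-value (1, with a warning, for an empty margin).
#' @export
segregation_test <- function(gp_table, collapse = c("recessive", "genotypic")) {
  collapse <- match.arg(collapse)
  stopifnot(all(c("genotype", "affected", "unaffected") %in% names(gp_table)))
  aff <- tapply(gp_table$affected, gp_table$genotype, sum)
  una <- tapply(gp_table$unaffected, gp_table$genotype, sum)
  geno_levels <- names(aff)
  if (sum(aff, na.rm = TRUE) == 0 || sum(una, na.rm = TRUE) == 0) {
    warning("empty phenotype margin; segregation test uninformative")
    return(1)
  }
  if (collapse == "recessive") {
    hom <- geno_levels == "hom_alt"
    a <- sum(aff[hom], na.rm = TRUE)
    b <- sum(una[hom], na.rm = TRUE)
    cc <- sum(aff[!hom], na.rm = TRUE)
    d <- sum(una[!hom], na.rm = TRUE)
    return(fisher_exact(a, b, cc, d, alternative = "two.sided"))
  }
  rows <- cbind(affected = as.numeric(aff), unaffected = as.numeric(una))
  rows[is.na(rows)] <- 0
  rows <- rows[rowSums(rows) > 0, , drop = FALSE]
  exact_rx2_test(rows)
}

# exact conditional r x 2 test: enumerate all tables with the observed
# row sums and first-column sum; p = total probability of tables no more
# probable than the observed one (multivariate hypergeometric)
exact_rx2_test <- function(rows) {
  row_sums <- rowSums(rows)
  c1 <- sum(rows[, 1L])
  n <- sum(row_sums)
  log_denom <- lchoose(n, c1)
  table_logp <- function(x) sum(lchoose(row_sums, x)) - log_denom
  p_obs <- exp(table_logp(rows[, 1L]))
  total <- 0
  enumerate <- function(i, remaining, x) {
    if (i > length(row_sums)) {
      if (remaining == 0L) {
        p <- exp(table_logp(x))
        if (p <= p_obs * (1 + 1e-12)) total <<- total + p
      }
      return(invisible())
    }
    lo <- max(0L, remaining - sum(row_sums[-seq_len(i)]))
    hi <- min(row_sums[i], remaining)
    for (xi in lo:hi) enumerate(i + 1L, remaining - xi, c(x, xi))
  }
  enumerate(1L, c1, integer(0))
  min(total, 1)
}
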