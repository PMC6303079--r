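# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Fisher 2x2: full enumeration with log-binomial coefficients (the package
# uses dhyper); two-sided by point-probability ordering.
oracle_fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  switch(alternative,
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-12)]),
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]))
}

# brute-force VIF pruning of a single window using lm() at every
# iteration: remove the max-VIF variant (ties -> larger index) while any
# VIF exceeds the threshold
oracle_prune_window <- function(X, vif_threshold = 2) {
  keep <- seq_len(ncol(X))
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(seq_along(keep), function(k) {
      y <- X[, keep[k]]
      if (stats::sd(y) < 1e-12) return(1)
      others <- X[, keep[-k], drop = FALSE]
      others <- others[, apply(others, 2, stats::sd) >= 1e-12, drop = FALSE]
      if (ncol(others) == 0L) return(1)
      r2 <- suppressWarnings(summary(stats::lm(y ~ others))$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- max(vifs)
    if (!(worst > vif_threshold)) break
    keep <- keep[-max(which(vifs == worst))]
  }
  keep
}

# hand-rolled codon-table translation (package route goes through
# Biostrings); returns residues up to and excluding the first stop, plus
# whether a stop was found
oracle_codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(seq) {
  n_codons <- nchar(seq) %/% 3L
  if (n_codons == 0L) return(list(protein = "", no_stop = TRUE))
  codons <- substring(seq, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aas <- unname(oracle_codon_table[codons])
  stop_at <- which(aas == "*")
  if (length(stop_at) == 0L)
    list(protein = paste(aas, collapse = ""), no_stop = TRUE)
  else
    list(protein = paste(head(aas, stop_at[1L] - 1L), collapse = ""),
         no_stop = FALSE)
}

# random transcript with a valid CDS (ATG ... internal stop-free ... stop)
# plus a random UTR tail
random_transcript <- function(n_codons, utr_len) {
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  utr <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
               collapse = "")
  paste0(cds, utr)
}

# small default cohorts for tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_breeds = 5, breed_sizes = c(4, 3, 3, 5, 5), case_breeds = 1:2,
         n_variants = 500, n_chromosomes = 5, n_trios = 2,
         missing_rate = 0.03, seed = 42),
    list(...))
  do.call(simulation_config, args)
}
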