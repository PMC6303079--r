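#' Variant-level missingness filter
#'
#' Keeps a variant iff the fraction of missing genotype cells across all
#' samples is at most `max_missing`; strictly more than the threshold is
#' removed (so with 100 samples and the default 0.10, eleven missing cells
#' remove a variant but ten keep it).
#'
#' @param geno Dosage matrix (variants x samples), `NA` = missing.
#' @param max_missing Maximum tolerated missing fraction.
#' @return Integer vector of kept variant indices.
#' @export
filter_missingness <- function(geno, max_missing = 0.10) {
  which(rowMeans(is.na(geno)) <= max_missing)
}

#' Minor-allele-frequency filter
#'
#' MAF is computed over non-missing alleles. A variant is kept iff
#' `MAF >= min_maf`; monomorphic variants (MAF 0) are always removed for
#' any positive threshold.
#'
#' @param geno Dosage matrix (variants x samples).
#' @param min_maf Minimum minor allele frequency.
#' @return Integer vector of kept variant indices.
#' @export
filter_maf <- function(geno, min_maf = 0.01) {
  n_called <- rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  f <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(f, 1 - f)
  which(!is.na(maf) & maf >= min_maf)
}

#' Identity-by-state distance matrix
#'
#' Computes the 1-IBS distance between every pair of samples:
#' `d(i, j) = sum |g_i - g_j| / (2 * m)` over the `m` sites non-missing in
#' both, i.e. the normalised L1 distance between dosage vectors. Pairs with
#' no overlapping non-missing site are an error (reported by sample id).
#'
#' @param geno Dosage matrix (variants x samples) with sample column names.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, class `"dist_ibs"`/`"matrix"`.
#' @export
ibs_distance <- function(geno) {
  n <- ncol(geno)
  ids <- colnames(geno) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  obs <- !is.na(geno)
  for (i in seq_len(max(n - 1L, 0L))) {
    gi <- geno[, i]
    oi <- obs[, i]
    for (j in (i + 1L):n) {
      ok <- oi & obs[, j]
      m <- sum(ok)
      if (m == 0L)
        stop("no overlapping non-missing sites for pair ",
             ids[i], " / ", ids[j])
      d <- sum(abs(gi[ok] - geno[ok, j])) / (2 * m)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Hierarchical clustering dendrogram from an IBS distance matrix
#'
#' Agglomerative clustering of the samples (UPGMA by default, the usual
#' choice for breed-relatedness dendrograms) returned as an `ape` `phylo`
#' tree whose leaves are the sample ids and whose branch lengths derive
#' from the merge heights. Use [ape::write.tree()] for Newick output.
#'
#' @param dist_matrix Symmetric distance matrix as from [ibs_distance()].
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An [ape::as.phylo()] tree.
#' @export
ibs_dendrogram <- function(dist_matrix,
                           linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(dist_matrix) < 2L) stop("need at least 2 samples")
  ape::as.phylo(stats::hclust(stats::as.dist(dist_matrix), method = linkage))
}

#' Pruning configuration for VIF-based LD pruning
#'
#' @param window_size Sliding window size in variants (default 50).
#' @param step_size Window step in variants (default 5).
#' @param vif_threshold Variance-inflation-factor threshold (default 2):
#'   variants whose dosage is predicted by the rest of the window with
#'   multiple `R^2 > 1 - 1/threshold` are removed.
#' @return A validated list of class `"prune_config"`.
#' @export
prune_config <- function(window_size = 50L, step_size = 5L,
                         vif_threshold = 2) {
  stopifnot(window_size >= step_size, step_size >= 1L, vif_threshold > 1)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 vif_threshold = vif_threshold),
            class = "prune_config")
}

# VIFs of each column of X given the others: diag of the inverse
# correlation matrix, with a least-squares fallback when that inverse is
# unavailable. Constant columns carry no LD and get VIF 1; R^2 within
# 1e-12 of 1 (perfect collinearity) gives VIF Inf.
window_vifs <- function(X) {
  p <- ncol(X)
  if (p < 2L) return(rep(1, p))
  sds <- apply(X, 2L, stats::sd)
  const <- sds < 1e-12
  vifs <- rep(1, p)
  live <- which(!const)
  if (length(live) < 2L) return(vifs)
  Z <- scale(X[, live, drop = FALSE])
  R <- crossprod(Z) / (nrow(Z) - 1)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  ok <- !is.null(inv) && all(is.finite(diag(inv))) && all(diag(inv) > 0.5)
  if (ok) {
    vifs[live] <- pmax(diag(inv), 1)
    # numerically huge VIF from a near-singular solve is treated as exact
    vifs[live][vifs[live] > 1e10] <- Inf
    return(vifs)
  }
  for (k in seq_along(live)) {
    y <- Z[, k]
    A <- Z[, -k, drop = FALSE]
    fit <- qr(A)
    rss <- sum(qr.resid(fit, y)^2)
    tss <- sum(y^2)
    r2 <- 1 - rss / tss
    vifs[live[k]] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vifs
}

# iteratively remove the max-VIF variant from one window until all
# VIFs <= threshold; ties remove the larger index. Returns local indices
# of removed window members.
prune_window <- function(X, vif_threshold) {
  keep <- seq_len(ncol(X))
  removed <- integer(0)
  repeat {
    if (length(keep) < 2L) break
    vifs <- window_vifs(X[, keep, drop = FALSE])
    worst <- max(vifs)
    if (!(worst > vif_threshold)) break
    out <- max(which(vifs == worst))
    removed <- c(removed, keep[out])
    keep <- keep[-out]
  }
  removed
}

#' Prune variants in linkage disequilibrium by variance inflation factor
#'
#' Slides a window of `window_size` variants (step `step_size`) along each
#' chromosome and, within a window, repeatedly computes for every variant
#' `VIF_j = 1 / (1 - R^2_j)` — `R^2_j` being the squared multiple
#' correlation of variant `j`'s dosage regressed on the other currently
#' kept variants in the window — removing the variant with the largest VIF
#' (ties: larger index) while any VIF exceeds the threshold. Missing
#' dosages are mean-imputed per variant; perfectly collinear variants get
#' infinite VIF and are removed. Whole passes over the chromosome are
#' repeated until no further variant is removed, which makes the operation
#' idempotent: pruning the kept set removes nothing.
#'
#' @param geno Dosage matrix (variants x samples) ordered by chromosome and
#'   position.
#' @param chrom Optional chromosome label per variant; windows never span
#'   chromosomes. Default treats all variants as one chromosome.
#' @param cfg A [prune_config()].
#' @return Sorted integer vector of kept variant indices.
#' @export
vif_prune <- function(geno, chrom = NULL, cfg = prune_config()) {
  nv <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("all", nv)
  stopifnot(length(chrom) == nv)
  X_all <- t(geno)
  # mean-impute missing dosages per variant
  if (anyNA(X_all)) {
    mu <- colMeans(X_all, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(X_all), arr.ind = TRUE)
    X_all[idx] <- mu[idx[, 2L]]
  }
  keep <- rep(TRUE, nv)
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    repeat {
      cur <- on_ch[keep[on_ch]]
      removed_any <- FALSE
      s <- 1L
      while (s <= length(cur)) {
        w <- cur[s:min(s + cfg$window_size - 1L, length(cur))]
        w <- w[keep[w]]
        if (length(w) >= 2L) {
          out <- prune_window(X_all[, w, drop = FALSE], cfg$vif_threshold)
          if (length(out)) {
            keep[w[out]] <- FALSE
            removed_any <- TRUE
          }
        }
        s <- s + cfg$step_size
      }
      if (!removed_any) break
    }
  }
  which(keep)
}

# offspring dosages compatible with each ordered parent-dosage pair:
# a parent transmits 0 from dosage 0, 0 or 1 from dosage 1, 1 from dosage 2
mendel_allowed <- local({
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  arr <- array(FALSE, dim = c(3L, 3L, 3L))
  for (p1 in 0:2) for (p2 in 0:2) {
    kids <- unique(outer(transmit[[p1 + 1L]], transmit[[p2 + 1L]], `+`))
    arr[p1 + 1L, p2 + 1L, kids + 1L] <- TRUE
  }
  arr
})

#' Audit Mendelian errors in trios
#'
#' A trio-site is an error iff the offspring dosage cannot be formed by one
#' allele drawn from each parent (e.g. parents 0 x 0 with offspring 1 or 2;
#' 0 x 2 with offspring 0 or 2; 2 x 2 with offspring 0 or 1). Sites where
#' any trio member is missing are skipped. The per-meiosis rate divides the
#' error count by two meioses per evaluated trio-site.
#'
#' @param geno Dosage matrix (variants x samples).
#' @param trios data.frame with columns `offspring`, `sire`, `dam` holding
#'   sample ids (columns of `geno`).
#' @return A list with `per_trio` (data.frame: offspring, n_sites,
#'   n_errors, rate_per_meiosis), `n_errors`, `n_sites`, and the pooled
#'   `rate_per_meiosis`.
#' @export
mendel_errors <- function(geno, trios) {
  stopifnot(all(unlist(trios[c("offspring", "sire", "dam")]) %in%
                  colnames(geno)))
  per <- lapply(seq_len(nrow(trios)), function(k) {
    o <- geno[, trios$offspring[k]]
    s <- geno[, trios$sire[k]]
    d <- geno[, trios$dam[k]]
    ok <- !(is.na(o) | is.na(s) | is.na(d))
    n <- sum(ok)
    errs <- sum(!mendel_allowed[cbind(s[ok] + 1L, d[ok] + 1L, o[ok] + 1L)])
    data.frame(offspring = trios$offspring[k], n_sites = n, n_errors = errs,
               rate_per_meiosis = if (n > 0) errs / (2 * n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_sites <- sum(per$n_sites)
  n_errors <- sum(per$n_errors)
  list(per_trio = per, n_errors = n_errors, n_sites = n_sites,
       rate_per_meiosis = if (n_sites > 0) n_errors / (2 * n_sites)
       else NA_real_)
}
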