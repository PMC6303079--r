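#' Hard-filter thresholds for site-level variant filtering
#'
#' The GATK-style hard-filter thresholds applied to candidate variants. A
#' site fails when the quoted strict inequality holds (`QD < 2.0`,
#' `FS > 60.0`, `SOR > 4.0`, `ReadPosRankSum < -8.0`, `DP > 3105` for both
#' SNPs and indels; `MQ < 40.0` and `MQRankSum < -12.5` for SNPs only;
#' `InbreedingCoeff < -0.8` for indels only), so a site sitting exactly at
#' a threshold passes that criterion. `DP` is the cohort-wide site depth.
#'
#' @param qd_min,fs_max,sor_max,readpos_ranksum_min,dp_max,mq_min,mq_ranksum_min,inbreeding_coeff_min
#'   Numeric thresholds; defaults as above.
#' @return A named list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(qd_min = 2.0, fs_max = 60.0, sor_max = 4.0,
                              readpos_ranksum_min = -8.0, dp_max = 3105,
                              mq_min = 40.0, mq_ranksum_min = -12.5,
                              inbreeding_coeff_min = -0.8) {
  th <- list(qd_min = qd_min, fs_max = fs_max, sor_max = sor_max,
             readpos_ranksum_min = readpos_ranksum_min, dp_max = dp_max,
             mq_min = mq_min, mq_ranksum_min = mq_ranksum_min,
             inbreeding_coeff_min = inbreeding_coeff_min)
  stopifnot(all(vapply(th, is.finite, logical(1))))
  structure(th, class = "filter_thresholds")
}

#' Apply site-level hard filters
#'
#' Flags each site pass/fail against [filter_thresholds()]. The `MQ` and
#' `MQRankSum` criteria apply to SNPs only and the `InbreedingCoeff`
#' criterion to indels only; all other criteria apply to every site. All
#' inequalities are strict, so values exactly at a threshold pass. A site
#' with a missing annotation field skips that criterion (counted and
#' reported via a message) rather than failing it.
#'
#' @param variants Variant data.frame carrying `is_indel` and the
#'   annotation columns (missing columns are treated as all-`NA`).
#' @param thresholds A [filter_thresholds()].
#' @return A data.frame with logical `pass` and character `reasons`
#'   (semicolon-joined failed-criterion labels, `"PASS"` when clean), one
#'   row per input site.
#' @examples
#' v <- data.frame(is_indel = FALSE, QD = 1.9, FS = 5, SOR = 1,
#'                 ReadPosRankSum = 0, DP = 2000, MQ = 55, MQRankSum = 0,
#'                 InbreedingCoeff = 0.1)
#' apply_hard_filters(v)  # fails with reason "QD<2"
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds()) {
  n <- nrow(variants)
  ann <- function(f) if (f %in% names(variants)) variants[[f]] else
    rep(NA_real_, n)
  snp <- !variants$is_indel
  indel <- variants$is_indel
  criteria <- list(
    list(field = "QD", bad = ann("QD") < thresholds$qd_min,
         label = paste0("QD<", thresholds$qd_min), scope = TRUE),
    list(field = "FS", bad = ann("FS") > thresholds$fs_max,
         label = paste0("FS>", thresholds$fs_max), scope = TRUE),
    list(field = "SOR", bad = ann("SOR") > thresholds$sor_max,
         label = paste0("SOR>", thresholds$sor_max), scope = TRUE),
    list(field = "ReadPosRankSum",
         bad = ann("ReadPosRankSum") < thresholds$readpos_ranksum_min,
         label = paste0("ReadPosRankSum<", thresholds$readpos_ranksum_min),
         scope = TRUE),
    list(field = "DP", bad = ann("DP") > thresholds$dp_max,
         label = paste0("DP>", thresholds$dp_max), scope = TRUE),
    list(field = "MQ", bad = ann("MQ") < thresholds$mq_min,
         label = paste0("MQ<", thresholds$mq_min), scope = snp),
    list(field = "MQRankSum",
         bad = ann("MQRankSum") < thresholds$mq_ranksum_min,
         label = paste0("MQRankSum<", thresholds$mq_ranksum_min),
         scope = snp),
    list(field = "InbreedingCoeff",
         bad = ann("InbreedingCoeff") < thresholds$inbreeding_coeff_min,
         label = paste0("InbreedingCoeff<", thresholds$inbreeding_coeff_min),
         scope = indel))
  reasons <- vector("list", n)
  n_skipped <- 0L
  for (cr in criteria) {
    in_scope <- rep(cr$scope, length.out = n)
    missing_ann <- is.na(cr$bad) & in_scope
    n_skipped <- n_skipped + sum(missing_ann)
    hit <- which(in_scope & !is.na(cr$bad) & cr$bad)
    for (i in hit) reasons[[i]] <- c(reasons[[i]], cr$label)
  }
  if (n_skipped > 0L)
    message(n_skipped, " site-criterion checks skipped for missing annotations")
  pass <- lengths(reasons) == 0L
  data.frame(pass = pass,
             reasons = ifelse(pass, "PASS",
                              vapply(reasons, paste, character(1),
                                     collapse = ";")),
             stringsAsFactors = FALSE)
}

#' Restrict to bi-allelic sites
#'
#' @param variants Variant data.frame with an `alt` column; multiple
#'   alternate alleles are comma-separated.
#' @return Logical vector: `TRUE` for sites with exactly one alt allele.
#' @export
select_biallelic <- function(variants) {
  if (nrow(variants) == 0L) return(logical(0))
  !grepl(",", variants$alt, fixed = TRUE)
}

#' Drop variants on uncharacterized chromosomes
#'
#' @param variants Variant data.frame with a `chrom` column.
#' @param characterized Character vector of chromosome labels to keep;
#'   defaults to 38 autosomes plus X, the characterized canine chromosomes.
#' @return Logical keep vector.
#' @export
drop_unplaced <- function(variants,
                          characterized = c(paste0("chr", 1:38), "chrX")) {
  variants$chrom %in% characterized
}

#' Recode indel alleles to single characters
#'
#' Association tooling built for SNPs needs single-character alleles, so
#' any site where either allele is longer than one base is recoded to
#' `ref = "A"`, `alt = "T"` — a fixed injective assignment that preserves
#' the allelic contrast. The original alleles are kept in `ref_original` /
#' `alt_original` for reporting, positions are unchanged, and the
#' operation is idempotent.
#'
#' @param variants Bi-allelic variant data.frame.
#' @return The data.frame with recoded alleles and sidecar columns.
#' @examples
#' v <- data.frame(ref = c("AC", "G"), alt = c("A", "T"))
#' recode_indels(v)
#' @export
recode_indels <- function(variants) {
  if (!"ref_original" %in% names(variants)) {
    variants$ref_original <- variants$ref
    variants$alt_original <- variants$alt
  }
  multi <- nchar(variants$ref) > 1L | nchar(variants$alt) > 1L
  variants$ref[multi] <- "A"
  variants$alt[multi] <- "T"
  variants
}
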