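#' Write a cohort to VCF 4.2
#'
#' Serialises the genotype matrix and variant table as an uncompressed
#' VCF 4.2 text file: one `GT` entry per sample (missing cells as `./.`)
#' and the eight site annotation fields (`QD`, `FS`, `SOR`,
#' `ReadPosRankSum`, `DP`, `MQ`, `MQRankSum`, `InbreedingCoeff`) in `INFO`,
#' printed with full double precision so reading the file back reproduces
#' the matrix and annotations exactly. A `filter` column in the variant
#' table, when present, is written to `FILTER` (semicolon-joined reasons,
#' `PASS` otherwise).
#'
#' @param cohort A `"wgva_cohort"`, or any list with `genotypes` and
#'   `variants` shaped as by [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_vcf()]
#' @export
write_vcf <- function(cohort, path) {
  geno <- cohort$genotypes
  variants <- cohort$variants
  stopifnot(nrow(geno) == nrow(variants))
  info_fields <- intersect(vcf_info_fields(), names(variants))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wgva",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_fields, vcf_info_descriptions()[info_fields]),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t"))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    vals <- unlist(variants[i, info_fields])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(sprintf("%s=%s", info_fields[keep],
                  sprintf("%.17g", vals[keep])), collapse = ";")
  }, character(1))
  filt <- if ("filter" %in% names(variants)) variants$filter else "."
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt[is.na(geno)] <- "./."
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", filt, info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

vcf_info_fields <- function() {
  c("QD", "FS", "SOR", "ReadPosRankSum", "DP", "MQ", "MQRankSum",
    "InbreedingCoeff")
}

vcf_info_descriptions <- function() {
  c(QD = "Quality by depth",
    FS = "Fisher strand bias",
    SOR = "Strand odds ratio",
    ReadPosRankSum = "Read position rank-sum",
    DP = "Total depth",
    MQ = "RMS mapping quality",
    MQRankSum = "Mapping quality rank-sum",
    InbreedingCoeff = "Inbreeding coefficient")
}

#' Read a VCF into a genotype matrix and variant table
#'
#' Parses a VCF (via `vcfR`) into the alt-allele dosage representation used
#' throughout the package. Genotypes other than `0/0`, `0/1`, `1/0`, `1/1`
#' (and their `|`-phased forms) are treated as missing, as are `./.` cells.
#' The eight standard site annotation fields are pulled from `INFO` where
#' declared.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A list of class `"wgva_cohort"` with `genotypes`, `variants`
#'   (including a `filter` column), and a minimal `design` holding the
#'   sample ids.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  variants$is_indel <- nchar(variants$ref) > 1L |
    vapply(strsplit(variants$alt, ",", fixed = TRUE),
           function(a) any(nchar(a) > 1L), logical(1))
  for (f in vcf_info_fields()) {
    vals <- suppressWarnings(vcfR::extract.info(v, element = f,
                                                as.numeric = TRUE))
    variants[[f]] <- if (is.null(vals)) NA_real_ else vals
  }
  variants$filter <- fix$FILTER
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  rownames(dosage) <- variants$id
  structure(list(genotypes = dosage, variants = variants,
                 design = list(samples = data.frame(
                   sample_id = colnames(dosage),
                   stringsAsFactors = FALSE),
                   trios = data.frame(offspring = character(),
                                      sire = character(), dam = character(),
                                      stringsAsFactors = FALSE))),
            class = "wgva_cohort")
}

#' Write and read pedigree/phenotype files
#'
#' `write_pedigree()` writes a six-column whitespace-delimited pedigree file
#' (family, individual, sire, dam, sex, phenotype; `0` for unknown parent or
#' sex; phenotype `2` = case, `1` = control) with the breed of each sample
#' in a sidecar TSV (`<path minus extension>.breeds.tsv`).
#' `read_pedigree()` reads both back into the `design` structure used by the
#' pipeline, reconstructing the trio list from rows with known parents.
#'
#' @param design A cohort `design` list (`samples` + `trios`).
#' @param path Pedigree file path (conventionally `.fam`).
#' @return `write_pedigree()` returns `path` invisibly; `read_pedigree()`
#'   returns a `design` list.
#' @export
write_pedigree <- function(design, path) {
  s <- design$samples
  sire <- rep("0", nrow(s))
  dam <- rep("0", nrow(s))
  if (nrow(design$trios)) {
    i <- match(design$trios$offspring, s$sample_id)
    sire[i] <- design$trios$sire
    dam[i] <- design$trios$dam
  }
  fam <- data.frame(family = s$breed, id = s$sample_id, sire = sire,
                    dam = dam, sex = 0L,
                    phenotype = ifelse(s$status == "case", 2L, 1L))
  utils::write.table(fam, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".breeds.tsv")
  utils::write.table(s[, c("sample_id", "breed")], side, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "sire", "dam",
                                         "sex", "phenotype"))
  side <- paste0(tools::file_path_sans_ext(path), ".breeds.tsv")
  breeds <- if (file.exists(side))
    utils::read.table(side, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(sample_id = fam$id, breed = fam$family,
                  stringsAsFactors = FALSE)
  has_parents <- fam$sire != "0" & fam$dam != "0"
  list(samples = data.frame(
    sample_id = fam$id,
    breed = breeds$breed[match(fam$id, breeds$sample_id)],
    status = ifelse(fam$phenotype == 2L, "case", "control"),
    is_offspring = has_parents,
    stringsAsFactors = FALSE),
    trios = data.frame(offspring = fam$id[has_parents],
                       sire = fam$sire[has_parents],
                       dam = fam$dam[has_parents],
                       stringsAsFactors = FALSE))
}
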