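#' Select variants nearly fixed between cases and controls
#'
#' A variant passes iff its absolute case/control allelic frequency
#' difference (computed on non-missing alleles) is strictly greater than
#' `min_diff` — the "more than 90% allelic difference" selection used to
#' nominate breed-defining candidates. Symmetric in case/control labels.
#'
#' @param result Association result data.frame (from [run_association()])
#'   with an `ALLELIC_DIFF` column.
#' @param min_diff Strict lower bound on the allelic difference.
#' @return The passing subset of `result`, original row order preserved.
#' @export
fixation_filter <- function(result, min_diff = 0.9) {
  result[result$ALLELIC_DIFF > min_diff, , drop = FALSE]
}

#' Assemble passing variants into candidate regions
#'
#' Consecutive passing variants on one chromosome whose inter-variant gap
#' is at most `max_gap` merge into one region; regions carrying fewer than
#' `min_variants` passing variants are discarded. Each region reports its
#' 1-based inclusive span, member count, mean allelic difference, and the
#' fraction of members with case alt frequency exactly 1.
#'
#' @param passing Output of [fixation_filter()] (needs `CHR`, `POS`,
#'   `ALLELIC_DIFF`, `F_CASE`).
#' @param max_gap Maximum gap between consecutive members, in bp.
#' @param min_variants Minimum members per region.
#' @return data.frame: `chrom`, `start`, `end`, `n_variants`,
#'   `mean_allelic_diff`, `case_fixed_fraction`; disjoint and sorted.
#' @export
build_regions <- function(passing, max_gap = 1e6, min_variants = 10L) {
  if (nrow(passing) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_variants = integer(),
                      mean_allelic_diff = numeric(),
                      case_fixed_fraction = numeric(),
                      stringsAsFactors = FALSE))
  passing <- passing[order(chrom_rank(passing$CHR), passing$POS), ,
                     drop = FALSE]
  new_chrom <- c(TRUE, passing$CHR[-1L] != passing$CHR[-nrow(passing)])
  gap <- c(0, diff(passing$POS))
  chain <- cumsum(new_chrom | gap > max_gap)
  regions <- lapply(split(seq_len(nrow(passing)), chain), function(i) {
    data.frame(chrom = passing$CHR[i[1L]],
               start = min(passing$POS[i]), end = max(passing$POS[i]),
               n_variants = length(i),
               mean_allelic_diff = mean(passing$ALLELIC_DIFF[i]),
               case_fixed_fraction = mean(passing$F_CASE[i] == 1),
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  regions[regions$n_variants >= min_variants, , drop = FALSE]
}

#' Rank candidate regions
#'
#' Orders regions by span length descending — long runs of fixed variants
#' support identity-by-descent inheritance of a selected haplotype — with
#' ties broken by member count, then mean allelic difference.
#'
#' @param regions Output of [build_regions()].
#' @return The reordered data.frame.
#' @export
rank_regions <- function(regions) {
  span <- regions$end - regions$start + 1L
  regions[order(-span, -regions$n_variants, -regions$mean_allelic_diff), ,
          drop = FALSE]
}

#' Write candidate regions as BED and TSV
#'
#' The BED file uses 0-based half-open coordinates (converted from the
#' internal 1-based inclusive spans); the TSV keeps the 1-based inclusive
#' coordinates and all region statistics.
#'
#' @param regions Output of [build_regions()] / [rank_regions()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_regions <- function(regions, prefix) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end)
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
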