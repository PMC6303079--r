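#' Transcript model for consequence calling
#'
#' A single transcript: nucleotide sequence (CDS plus any 3'UTR) with
#' 1-based inclusive CDS bounds. The CDS must be a multiple of 3, begin
#' with ATG and end with a stop codon.
#'
#' @param id Transcript identifier.
#' @param sequence Uppercase A/C/G/T nucleotide string.
#' @param cds_start,cds_end 1-based inclusive CDS positions within
#'   `sequence`.
#' @return A validated list of class `"transcript_model"`.
#' @export
transcript_model <- function(id, sequence, cds_start = 1L,
                             cds_end = nchar(sequence)) {
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGT]+$", sequence),
            cds_start >= 1L, cds_end <= nchar(sequence),
            cds_start < cds_end)
  cds_len <- cds_end - cds_start + 1L
  if (cds_len %% 3L != 0L) stop("CDS length not divisible by 3")
  cds <- substr(sequence, cds_start, cds_end)
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS does not begin with ATG")
  if (!substr(cds, cds_len - 2L, cds_len) %in% c("TAA", "TAG", "TGA"))
    stop("CDS does not end with a stop codon")
  structure(list(id = id, sequence = sequence,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "transcript_model")
}

#' Apply a coding variant to a transcript sequence
#'
#' Replaces the reference allele at CDS coordinate `pos` (c.-numbering:
#' position 1 is the A of the ATG) with the alternate allele, shifting
#' downstream coordinates by `nchar(alt) - nchar(ref)`. The stated
#' reference must match the sequence or an error names the expected and
#' observed bases. A deletion is written with the deleted bases as `ref`
#' and an empty `alt`.
#'
#' @param tx A [transcript_model()].
#' @param pos 1-based c.-coordinate of the first reference base.
#' @param ref,alt Allele strings (`alt` may be `""` for a pure deletion).
#' @return The full mutant nucleotide sequence (CDS plus UTR).
#' @examples
#' tx <- transcript_model("t1", "ATGAAACTGACCGGGTAA")
#' apply_variant(tx, 7, "C", "")  # c.7delC
#' @export
apply_variant <- function(tx, pos, ref, alt) {
  gpos <- tx$cds_start + pos - 1L
  observed <- substr(tx$sequence, gpos, gpos + nchar(ref) - 1L)
  if (nchar(ref) > 0L && observed != ref)
    stop("reference mismatch at c.", pos, ": expected ", ref,
         " but transcript has ", observed)
  paste0(substr(tx$sequence, 1L, gpos - 1L), alt,
         substring(tx$sequence, gpos + nchar(ref)))
}

#' Translate a nucleotide sequence until the first stop codon
#'
#' Standard-genetic-code translation (via Biostrings) of the reading frame
#' starting at base 1, stopping at the first stop codon. A trailing
#' partial codon is ignored. When no stop codon occurs before the end of
#' the sequence the full translation is returned with `no_stop = TRUE`.
#'
#' @param seq Nucleotide string in frame.
#' @return List with `protein` (one-letter amino-acid string, stop
#'   excluded) and `no_stop` flag.
#' @examples
#' translate_cds("ATGAAACTGACCGGGTAA")$protein  # "MKLTG"
#' @export
translate_cds <- function(seq) {
  n <- nchar(seq)
  usable <- (n %/% 3L) * 3L
  if (usable == 0L) return(list(protein = "", no_stop = TRUE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, usable)),
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) list(protein = aa, no_stop = TRUE)
  else list(protein = substr(aa, 1L, stop_at - 1L), no_stop = FALSE)
}

#' Call the protein-level consequence of a coding indel
#'
#' Translates the wild-type CDS and the mutant sequence from the CDS start
#' through the 3'UTR (a frameshifted stop may lie beyond the wild-type
#' stop) and compares residue by residue. For a frameshift (indel length
#' not divisible by 3) the call reports the first affected residue, the
#' number of novel residues before the new stop, and the length change;
#' when the first novel codon is itself a stop the new residue is `"Ter"`
#' with zero novel residues. In-frame indels are reported with
#' `is_frameshift = FALSE` and the residue-level length delta. A mutant
#' reading frame with no downstream stop is flagged and its lengths left
#' undefined.
#'
#' @param tx A [transcript_model()].
#' @param pos,ref,alt Variant in c.-coordinates as for [apply_variant()].
#' @return List of class `"frameshift_call"` with fields `is_frameshift`,
#'   `fs_position`, `wt_residue`, `new_residue`, `n_altered`,
#'   `wt_length`, `mutant_length`, `truncation`
#'   (`wt_length - mutant_length`; negative = extension), `no_stop`,
#'   `notation_hgvs`, `notation_fsx`. When a stop is found,
#'   `mutant_length = fs_position - 1 + n_altered`.
#' @export
call_consequence <- function(tx, pos, ref, alt) {
  cds_len <- tx$cds_end - tx$cds_start + 1L
  if (pos < 1L || pos > cds_len) stop("variant outside CDS (c.", pos, ")")
  indel_shift <- nchar(alt) - nchar(ref)
  wt <- translate_cds(substr(tx$sequence, tx$cds_start, tx$cds_end))
  mutant_seq <- apply_variant(tx, pos, ref, alt)
  mut <- translate_cds(substring(mutant_seq, tx$cds_start))
  wt_len <- nchar(wt$protein)
  call <- list(is_frameshift = indel_shift %% 3L != 0L,
               fs_position = NA_integer_, wt_residue = NA_character_,
               new_residue = NA_character_, n_altered = NA_integer_,
               wt_length = wt_len, mutant_length = NA_integer_,
               truncation = NA_integer_, no_stop = mut$no_stop)
  if (!call$is_frameshift) {
    if (!mut$no_stop) {
      call$mutant_length <- nchar(mut$protein)
      call$truncation <- wt_len - call$mutant_length
    }
    class(call) <- "frameshift_call"
    return(call)
  }
  wt_res <- strsplit(wt$protein, "")[[1]]
  mut_res <- strsplit(mut$protein, "")[[1]]
  shared <- seq_len(min(length(wt_res), length(mut_res)))
  differs <- shared[wt_res[shared] != mut_res[shared]]
  fs_pos <- if (length(differs)) differs[1L]
  else min(length(wt_res), length(mut_res)) + 1L
  call$fs_position <- fs_pos
  call$wt_residue <- if (fs_pos <= length(wt_res)) wt_res[fs_pos] else "Ter"
  if (mut$no_stop) {
    call$new_residue <- if (fs_pos <= length(mut_res)) mut_res[fs_pos]
    else NA_character_
    class(call) <- "frameshift_call"
    call$notation_hgvs <- render_notation(call, "hgvs")
    call$notation_fsx <- render_notation(call, "fsx")
    return(call)
  }
  mut_len <- length(mut_res)
  call$mutant_length <- mut_len
  call$truncation <- wt_len - mut_len
  if (fs_pos > mut_len) {
    # the first divergent codon is the new stop
    call$new_residue <- "Ter"
    call$n_altered <- 0L
  } else {
    call$new_residue <- mut_res[fs_pos]
    call$n_altered <- mut_len - (fs_pos - 1L)
  }
  class(call) <- "frameshift_call"
  call$notation_hgvs <- render_notation(call, "hgvs")
  call$notation_fsx <- render_notation(call, "fsx")
  call
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter", Ter = "Ter")

aa3 <- function(x) unname(AA_THREE[x])

#' Render a frameshift call as protein notation
#'
#' Two conventions are supported. `"hgvs"` renders
#' `p.<Wt><pos><New>fsTer<k>` where `k` counts the new stop with the
#' substituted residue as position 1 (`k = n_altered + 1`). `"fsx"`
#' renders `p.<Wt><pos><New>fsX<n>` where `n = n_altered` counts only the
#' novel residues before the stop — the convention under which a call with
#' 26 altered amino acids reads `fsX26`. A frameshift whose first novel
#' codon is a stop renders `p.(<Wt><pos>Ter)` in both conventions; a call
#' with no downstream stop renders an explicit `no stop found` form.
#'
#' @param call A `"frameshift_call"`.
#' @param convention `"hgvs"` or `"fsx"`.
#' @return The notation string.
#' @export
render_notation <- function(call, convention = c("hgvs", "fsx")) {
  convention <- match.arg(convention)
  if (!isTRUE(call$is_frameshift)) return("p.(=)")
  wt3 <- aa3(call$wt_residue)
  if (isTRUE(call$no_stop))
    return(sprintf("p.%s%d%sfs (no stop found)", wt3, call$fs_position,
                   if (is.na(call$new_residue)) "" else aa3(call$new_residue)))
  if (call$n_altered == 0L)
    return(sprintf("p.(%s%dTer)", wt3, call$fs_position))
  new3 <- aa3(call$new_residue)
  if (convention == "hgvs")
    sprintf("p.%s%d%sfsTer%d", wt3, call$fs_position, new3,
            call$n_altered + 1L)
  else
    sprintf("p.%s%d%sfsX%d", wt3, call$fs_position, new3, call$n_altered)
}

#' @export
print.frameshift_call <- function(x, ...) {
  if (x$is_frameshift)
    cat(sprintf(
      "frameshift at residue %s: %s (%s); %s novel aa, truncation %s\n",
      x$fs_position, x$notation_fsx %||% "", x$notation_hgvs %||% "",
      x$n_altered, x$truncation))
  else
    cat(sprintf("in-frame indel: wt %d aa -> mutant %s aa\n",
                x$wt_length, x$mutant_length))
  invisible(x)
}

#' Batch consequence calls from FASTA and a variant table
#'
#' Reads transcripts from a FASTA file (via Biostrings) and calls the
#' consequence of each tabulated variant on its transcript.
#'
#' @param fasta_path FASTA of transcript sequences.
#' @param variant_table data.frame with `transcript`, `pos` (c.-coordinate),
#'   `ref`, `alt` (empty or `"-"` for deletions).
#' @param cds_start,cds_end CDS bounds applied to every transcript;
#'   `cds_end = NULL` uses each full sequence length.
#' @return data.frame of structured calls, one row per variant, with both
#'   notations.
#' @export
call_consequences_file <- function(fasta_path, variant_table,
                                   cds_start = 1L, cds_end = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- lapply(seq_len(nrow(variant_table)), function(i) {
    vt <- variant_table[i, ]
    seq <- as.character(seqs[[as.character(vt$transcript)]])
    tx <- transcript_model(as.character(vt$transcript), seq, cds_start,
                           cds_end %||% nchar(seq))
    alt <- if (is.na(vt$alt) || vt$alt %in% c("-", "")) "" else
      as.character(vt$alt)
    cl <- call_consequence(tx, vt$pos, as.character(vt$ref), alt)
    data.frame(transcript = tx$id, pos = vt$pos, ref = vt$ref,
               alt = alt, is_frameshift = cl$is_frameshift,
               fs_position = cl$fs_position, wt_residue = cl$wt_residue,
               new_residue = cl$new_residue, n_altered = cl$n_altered,
               wt_length = cl$wt_length, mutant_length = cl$mutant_length,
               truncation = cl$truncation, no_stop = cl$no_stop,
               notation_hgvs = cl$notation_hgvs %||% NA_character_,
               notation_fsx = cl$notation_fsx %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
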