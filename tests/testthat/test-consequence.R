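test_that("transcript validation enforces CDS structure", {
  expect_s3_class(transcript_model("t", "ATGAAACTGACCGGGTAA"),
                  "transcript_model")
  expect_error(transcript_model("t", "ATGAAACTGACCGGGTA"), "divisible")
  expect_error(transcript_model("t", "TTGAAACTGACCGGGTAA"), "ATG")
  expect_error(transcript_model("t", "ATGAAACTGACCGGGAAA"), "stop codon")
})

test_that("apply_variant edits the sequence and guards the reference", {
  tx <- transcript_model("t", "ATGAAACTGACCGGGTAA")
  expect_equal(apply_variant(tx, 7, "C", ""), "ATGAAATGACCGGGTAA")
  expect_equal(apply_variant(tx, 7, "C", "C"), tx$sequence)
  expect_error(apply_variant(tx, 7, "G", ""), "expected G.*has C")
  # insertion shifts downstream bases
  expect_equal(apply_variant(tx, 3, "G", "GTT"), "ATGTTAAACTGACCGGGTAA")
})

test_that("translation stops at the first stop codon and flags its absence", {
  expect_equal(translate_cds("ATGAAACTGACCGGGTAA"),
               list(protein = "MKLTG", no_stop = FALSE))
  expect_equal(translate_cds("ATG"), list(protein = "M", no_stop = TRUE))
  expect_equal(translate_cds(""), list(protein = "", no_stop = TRUE))
  # trailing partial codon ignored
  expect_equal(translate_cds("ATGAA")$protein, "M")
})

test_that("frameshift to an immediate stop: truncation without novel residues", {
  tx <- transcript_model("t", "ATGAAACTGACCGGGTAA")
  cl <- call_consequence(tx, 7, "C", "")
  expect_true(cl$is_frameshift)
  expect_equal(cl$fs_position, 3L)
  expect_equal(cl$wt_residue, "L")
  expect_equal(cl$new_residue, "Ter")
  expect_equal(cl$n_altered, 0L)
  expect_equal(cl$wt_length, 5L)
  expect_equal(cl$mutant_length, 2L)
  expect_equal(cl$truncation, 3L)
  expect_equal(render_notation(cl, "hgvs"), "p.(Leu3Ter)")
  expect_equal(render_notation(cl, "fsx"), "p.(Leu3Ter)")
})

test_that("frameshift running into the UTR can extend the protein", {
  tx <- transcript_model("t", paste0("ATGAAACCAGGAGTTTAA", "GTGAC"),
                         cds_start = 1, cds_end = 18)
  cl <- call_consequence(tx, 7, "C", "")
  expect_true(cl$is_frameshift)
  expect_equal(cl$fs_position, 3L)
  expect_equal(cl$wt_residue, "P")
  expect_equal(cl$new_residue, "Q")
  expect_equal(cl$n_altered, 4L)
  expect_equal(cl$mutant_length, 6L)
  expect_equal(cl$truncation, -1L)  # extension past the wild-type stop
  expect_equal(render_notation(cl, "fsx"), "p.Pro3GlnfsX4")
  expect_equal(render_notation(cl, "hgvs"), "p.Pro3GlnfsTer5")
})

test_that("in-frame deletion of a codon shortens the protein by one residue", {
  tx <- transcript_model("t", "ATGAAACTGACCGGGTAA")
  cl <- call_consequence(tx, 7, "CTG", "")
  expect_false(cl$is_frameshift)
  expect_equal(cl$wt_length - cl$mutant_length, 1L)
  expect_true(is.na(cl$fs_position))
})

test_that("frameshifts with no downstream stop are flagged, not failed", {
  # UTR chosen so the shifted frame never hits a stop
  tx <- transcript_model("t", paste0("ATGAAACCAGGAGTTTAA", "CCCCCC"),
                         cds_start = 1, cds_end = 18)
  cl <- call_consequence(tx, 17, "A", "")
  expect_true(cl$is_frameshift)
  expect_true(cl$no_stop)
  expect_true(is.na(cl$mutant_length))
  expect_match(cl$notation_fsx, "no stop found")
})

test_that("variants outside the CDS are rejected", {
  tx <- transcript_model("t", paste0("ATGAAACCAGGAGTTTAA", "GTGAC"),
                         cds_start = 1, cds_end = 18)
  expect_error(call_consequence(tx, 20, "G", ""), "outside CDS")
})

test_that("structured calls satisfy the length identity of the canonical case", {
  # a call shaped like the canine DVL2 frameshift: first affected residue
  # 684, 26 novel residues, truncation 23
  fs_position <- 684L
  n_altered <- 26L
  truncation <- 23L
  mutant_length <- fs_position - 1L + n_altered
  wt_length <- mutant_length + truncation
  expect_equal(mutant_length, 709L)
  expect_equal(wt_length, 732L)
  call <- structure(list(is_frameshift = TRUE, fs_position = fs_position,
                         wt_residue = "P", new_residue = "L",
                         n_altered = n_altered, wt_length = wt_length,
                         mutant_length = mutant_length,
                         truncation = truncation, no_stop = FALSE),
                    class = "frameshift_call")
  expect_equal(render_notation(call, "fsx"), "p.Pro684LeufsX26")
  expect_equal(render_notation(call, "hgvs"), "p.Pro684LeufsTer27")
})

test_that("random transcript/deletion calls agree with the residue-by-residue oracle", {
  set.seed(77)
  for (i in 1:200) {
    n_codons <- sample(30:120, 1)
    tx_seq <- random_transcript(n_codons, utr_len = sample(30:90, 1))
    cds_len <- n_codons * 3L
    tx <- transcript_model("t", tx_seq, 1, cds_len)
    del_len <- sample(1:2, 1)
    pos <- sample(4:(cds_len - del_len - 3L), 1)  # keep ATG and stop intact
    ref <- substr(tx_seq, pos, pos + del_len - 1L)
    cl <- call_consequence(tx, pos, ref, "")
    # oracle: translate both sequences fully and compare residues
    wt <- oracle_translate(substr(tx_seq, 1, cds_len))
    mut_seq <- paste0(substr(tx_seq, 1, pos - 1L),
                      substring(tx_seq, pos + del_len))
    mut <- oracle_translate(mut_seq)
    expect_true(cl$is_frameshift)
    expect_equal(cl$no_stop, mut$no_stop)
    if (!mut$no_stop) {
      expect_equal(cl$mutant_length, nchar(mut$protein))
      wt_res <- strsplit(wt$protein, "")[[1]]
      mut_res <- strsplit(mut$protein, "")[[1]]
      shared <- seq_len(min(length(wt_res), length(mut_res)))
      diffs <- shared[wt_res[shared] != mut_res[shared]]
      fs_expect <- if (length(diffs)) diffs[1]
      else min(length(wt_res), length(mut_res)) + 1L
      expect_equal(cl$fs_position, fs_expect)
      expect_equal(cl$truncation, nchar(wt$protein) - nchar(mut$protein))
      if (!is.na(cl$n_altered) && cl$n_altered > 0)
        expect_equal(cl$mutant_length, cl$fs_position - 1L + cl$n_altered)
    }
  }
})

test_that("batch FASTA + table interface reproduces single calls", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", "ATGAAACTGACCGGGTAA"), fa)
  vt <- data.frame(transcript = "tx1", pos = 7, ref = "C", alt = "-")
  calls <- call_consequences_file(fa, vt)
  expect_equal(calls$notation_fsx, "p.(Leu3Ter)")
  expect_equal(calls$truncation, 3L)
})
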