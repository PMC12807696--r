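test_that("sequential 5'->3' application with shift tracking edits correctly", {
  expect_equal(apply_variants("ATGAAACCC", tvf(4, "A", "G")), "ATGGAACCC")
  # insertion then SNP: shift tracker moves the second edit
  expect_equal(apply_variants("ATGAAACCC",
                              tvf(c(4, 7), c("A", "C"), c("AG", "T"))),
               "ATGAGAATCC")
  expect_equal(apply_variants("ATGAAACCC", tvf(integer(0), character(0),
                                               character(0))), "ATGAAACCC")
  expect_error(apply_variants("ATGAAACCC", tvf(4, "G", "T")),
               "reference mismatch")
  expect_error(apply_variants("ATGAAACCC",
                              tvf(c(4, 5), c("AA", "A"), c("A", "G"))),
               "overlapping")
})

test_that("shift-tracked application equals descending-coordinate application (property)", {
  withr::with_seed(101, {
    for (i in 1:60) {
      cds <- random_cds(sample(8:25, 1))
      tv <- random_edits(cds)
      edited <- apply_variants(cds, tv)
      expect_identical(edited, oracle_apply_desc(cds, tv))
      # length accounting
      expect_equal(nchar(edited) - nchar(cds),
                   sum(nchar(tv$talt)) - sum(nchar(tv$tref)))
    }
  })
})

test_that("translation implements the terminal/premature stop rules", {
  expect_equal(translate_cds("ATGAAATAA"),
               list(protein = "MK", flags = character(0)))
  expect_equal(translate_cds("ATGTAAAAACCC"),
               list(protein = "M", flags = "truncated_premature_stop"))
  expect_equal(translate_cds("ATGAAACC"),
               list(protein = "MK", flags = "no_stop_reached"))
  # trailing bases short of a codon are ignored
  expect_equal(translate_cds("ATGAAATAAC")$protein, "MK")
})

test_that("frameshift translation continues in the new frame, with optional readthrough", {
  cds <- "ATGAAACCCTAA"
  tv <- tvf(3, "GA", "G")  # 1-bp deletion at tpos 4, VCF-anchored
  pf <- build_proteoform(cds, tv)
  expect_equal(pf$dna, "ATGAACCCTAA")
  expect_equal(pf$protein, "MNP")
  expect_setequal(pf$flags, c("frameshift", "no_stop_reached"))

  # with a downstream 3' sequence, translation extends to the first stop
  pf2 <- build_proteoform(cds, tv, downstream = "TAAATAAATAAA")
  expect_true("extended_readthrough" %in% pf2$flags)
  expect_true("frameshift" %in% pf2$flags)
  expect_false("no_stop_reached" %in% pf2$flags)
  expect_equal(pf2$protein,
               oracle_translate(paste0("ATGAACCCTAA", "TAAATAAATAAA")))

  # net in-frame deletion: no frameshift flag
  pf3 <- build_proteoform("ATGAAACCCTAA", tvf(3, "GAAA", "G"))
  expect_false("frameshift" %in% pf3$flags)
  expect_equal(pf3$protein, "MP")
})

test_that("start-loss rescue finds the next in-frame ATG in the annotated frame", {
  expect_equal(rescue_start("TTGAAAATGGCCTAA"), 6L)
  tr <- translate_cds("TTGAAAATGGCCTAA", offset = 6L)
  expect_equal(tr$protein, "MA")
  expect_identical(rescue_start("TTGAAAA"), NA_integer_)
  # out-of-frame ATG is ignored
  expect_identical(rescue_start("TTATGTTTTTT"), NA_integer_)
  expect_error(rescue_start("ATGAAA"), "intact start")

  # orchestration: rescued and unrescued start-loss
  cds <- "ATGAAAATGGCCTAA"
  pf <- build_proteoform(cds, tvf(2, "T", "C"))
  expect_true("start_rescued" %in% pf$flags)
  expect_equal(pf$protein, "MA")
  cds2 <- "ATGAAAAAATAA"
  pf2 <- build_proteoform(cds2, tvf(2, "T", "C"))
  expect_true("no_start" %in% pf2$flags)
  expect_equal(qc_filter(pf2)$qc$reason, "no_start")
})

test_that("wild-type haplotype reproduces the reference protein with empty flags", {
  withr::with_seed(7, {
    for (i in 1:10) {
      cds <- random_cds(sample(8:30, 1))
      pf <- build_proteoform(cds, tvf(integer(0), character(0), character(0)))
      expect_identical(pf$protein, oracle_translate(cds))
      expect_length(pf$flags, 0L)
    }
  })
})

test_that("consequence classification labels single variants by diffing proteins", {
  cds <- "ATGAAACTGTGCAGATTCTAA"  # M K L C R F *
  expect_equal(classify_consequences(cds, tvf(6, "A", "G")), "synonymous")
  expect_equal(classify_consequences(cds, tvf(4, "A", "G")), "missense")
  expect_equal(classify_consequences(cds, tvf(4, "A", "T")), "stop_gained")
  expect_equal(classify_consequences(cds, tvf(2, "T", "C")), "start_lost")
  expect_equal(classify_consequences(cds, tvf(19, "T", "C")), "stop_lost")
  expect_equal(classify_consequences(cds, tvf(6, "A", "ATTT")),
               "inframe_insertion")
  expect_equal(classify_consequences(cds, tvf(6, "ACTG", "A")),
               "inframe_deletion")
  expect_equal(classify_consequences(cds, tvf(6, "AC", "A")), "frameshift")
  # multiple variants classified independently, order preserved
  expect_equal(classify_consequences(cds, tvf(c(4, 6), c("A", "A"),
                                              c("G", "G"))),
               c("missense", "synonymous"))
})

test_that("classification agrees with a positional-diff oracle on random substitutions", {
  withr::with_seed(55, {
    for (i in 1:40) {
      cds <- random_cds(sample(8:20, 1))
      tv <- random_edits(cds, max_vars = 1L, indels = FALSE)
      if (nrow(tv) == 0L) next
      lab <- classify_consequences(cds, tv)
      wt <- oracle_translate(cds)
      mt <- oracle_translate(oracle_apply_desc(cds, tv))
      if (identical(wt, mt)) {
        expect_equal(lab, "synonymous")
      } else if (nchar(mt) < nchar(wt)) {
        expect_equal(lab, "stop_gained")
      } else if (nchar(mt) == nchar(wt)) {
        expect_equal(lab, "missense")
        expect_equal(sum(strsplit(wt, "")[[1]] != strsplit(mt, "")[[1]]), 1L)
      } else {
        expect_equal(lab, "stop_lost")
      }
    }
  })
})

test_that("protein-length QC excludes 9 and 4001, retains 10, 553 and 4000", {
  expect_equal(qc_filter(pf_of_length(9))$qc,
               list(pass = FALSE, reason = "protein_too_short"))
  expect_equal(qc_filter(pf_of_length(4001))$qc,
               list(pass = FALSE, reason = "protein_too_long"))
  for (n in c(10, 553, 4000))
    expect_true(qc_filter(pf_of_length(n))$qc$pass)
})

test_that("minus-strand pipeline equals the whole-chromosome mutation oracle (property)", {
  withr::with_seed(202, {
    for (i in 1:40) {
      fix <- random_genome_fixture(strand = sample(c("+", "-"), 1))
      tv <- map_variants_to_transcript(fix$variants, fix$model,
                                       fix$reference)
      pf <- build_proteoform(attr(tv, "cds"), tv)
      expect_identical(pf$protein, oracle_genome_protein(fix))
    }
  })
})
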