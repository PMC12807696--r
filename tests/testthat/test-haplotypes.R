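test_that("variant-to-transcript mapping handles both strands and the containment rule", {
  # plus strand: CDS = genome[101..130]; SNP at genomic 104
  chrom <- paste(rep("ACGT", 50), collapse = "")  # 200 bp, pos 104 = T? build explicitly
  chrom <- paste0(strrep("A", 100), "ATGCCCAAATTTGGGCCCAAATTTGGGTAA",
                  strrep("A", 70))
  model <- structure(list(
    transcript_id = "TX", gene_id = "G", gene_symbol = NA, chrom = "c1",
    strand = "+", exons = data.frame(start = 101L, end = 130L),
    cds = data.frame(start = 101L, end = 130L), tsl = NA_integer_),
    class = "transcript_model")
  ref <- c(c1 = chrom)
  v <- data.frame(chrom = "c1", pos = 104L, id = "", ref = "C", alt = "T",
                  stringsAsFactors = FALSE)
  tv <- map_variants_to_transcript(v, model, ref)
  expect_equal(tv$tpos, 4L)
  expect_equal(tv$tref, "C")
  expect_equal(tv$talt, "T")

  # minus strand, single CDS interval genome 100..109, SNP at genomic 103 C>T
  chrom2 <- paste0(strrep("T", 99), "AACCGGTTAA", strrep("T", 20))
  model2 <- model
  model2$chrom <- "c2"; model2$strand <- "-"
  model2$exons <- model2$cds <- data.frame(start = 100L, end = 109L)
  ref2 <- c(c2 = chrom2)
  v2 <- data.frame(chrom = "c2", pos = 103L, id = "", ref = "C", alt = "T",
                   stringsAsFactors = FALSE)
  tv2 <- map_variants_to_transcript(v2, model2, ref2)
  expect_equal(tv2$tpos, 7L)          # 109 - 103 + 1
  expect_equal(tv2$tref, "G")
  expect_equal(tv2$talt, "A")
  # cross-check via whole-chromosome mutation oracle
  mut <- chrom2
  substr(mut, 103, 103) <- "T"
  wt_cds <- rc(substr(chrom2, 100, 109))
  mut_cds <- rc(substr(mut, 100, 109))
  d <- which(strsplit(wt_cds, "")[[1]] != strsplit(mut_cds, "")[[1]])
  expect_equal(d, 7L)
  expect_equal(substr(mut_cds, 7, 7), "A")

  # deletion whose REF span crosses the CDS 3' boundary is excluded
  v3 <- data.frame(chrom = "c1", pos = 128L, id = "", ref = "TAAA",
                   alt = "T", stringsAsFactors = FALSE)
  expect_equal(nrow(map_variants_to_transcript(v3, model, ref)), 0L)

  # reference mismatch names the variant
  v4 <- data.frame(chrom = "c1", pos = 104L, id = "", ref = "G", alt = "A",
                   stringsAsFactors = FALSE)
  expect_error(map_variants_to_transcript(v4, model, ref),
               "reference mismatch")
})

simple_tv <- function(n) {
  data.frame(chrom = "c", pos = 10L * seq_len(n), id = paste0("rs", seq_len(n)),
             ref = "A", alt = "G", tpos = 10L * seq_len(n), tref = "A",
             talt = "G", stringsAsFactors = FALSE)
}

test_that("haplotype enumeration follows phase and the missing-data contract", {
  tv <- simple_tv(2)
  vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]

  # S1 = 0|1 at s1 and 1|0 at s2; S2 homozygous reference
  pg <- make_pg(c("S1", "S2"), vars, a = c(0L, 1L, 0L, 0L),
                b = c(1L, 0L, 0L, 0L))
  hs <- build_haplotypes(tv, pg)
  counts <- setNames(vapply(hs$haplotypes, `[[`, integer(1), "count"),
                     vapply(hs$haplotypes, `[[`, character(1), "key"))
  expect_equal(counts[["WT"]], 2L)
  expect_equal(counts[["10:A>G"]], 1L)
  expect_equal(counts[["20:A>G"]], 1L)
  expect_equal(sum(counts), 4L)

  # all homozygous reference: single WT haplotype, count 2 * n_samples
  pg0 <- make_pg(c("S1", "S2", "S3"), vars, a = 0L, b = 0L)
  hs0 <- build_haplotypes(tv, pg0)
  expect_length(hs0$haplotypes, 1L)
  expect_equal(hs0$haplotypes[[1]]$key, "WT")
  expect_equal(hs0$haplotypes[[1]]$count, 6L)

  # missing genotype excludes both chromosomes of the sample
  pg_na <- make_pg(c("S1", "S2"), vars,
                   a = c(NA, 0L, 0L, 0L), b = c(NA, 0L, 0L, 0L))
  hs_na <- build_haplotypes(tv, pg_na)
  expect_equal(nrow(hs_na$assignments), 2L)
  expect_equal(hs_na$n_excluded, 2L)

  # unphased heterozygote likewise poisons both chromosome copies
  ph <- matrix(TRUE, 2, 2); ph[1, 1] <- FALSE
  pg_up <- make_pg(c("S1", "S2"), vars, a = c(0L, 0L, 0L, 0L),
                   b = c(1L, 0L, 0L, 0L), phased = ph)
  hs_up <- build_haplotypes(tv, pg_up)
  expect_equal(nrow(hs_up$assignments), 2L)

  # wild-type record is always present, even at count zero
  pg1 <- make_pg("S1", vars, a = c(1L, 0L), b = c(1L, 0L))
  keys1 <- vapply(build_haplotypes(tv, pg1)$haplotypes, `[[`,
                  character(1), "key")
  expect_true("WT" %in% keys1)
})

test_that("phase swap of a compound heterozygote changes the haplotype multiset", {
  tv <- simple_tv(2)
  vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]
  cis <- make_pg("S1", vars, a = c(1L, 1L), b = c(0L, 0L))
  trans <- make_pg("S1", vars, a = c(1L, 0L), b = c(0L, 1L))
  keys_cis <- sort(vapply(build_haplotypes(tv, cis)$haplotypes, `[[`,
                          character(1), "key"))
  keys_trans <- sort(vapply(build_haplotypes(tv, trans)$haplotypes, `[[`,
                            character(1), "key"))
  expect_equal(keys_cis, sort(c("WT", "10:A>G;20:A>G")))
  expect_equal(keys_trans, sort(c("WT", "10:A>G", "20:A>G")))
  expect_false(identical(keys_cis, keys_trans))
})

test_that("overlapping variants on one chromosome exclude it with a warning", {
  tv <- data.frame(chrom = "c", pos = c(10L, 11L), id = c("r1", "r2"),
                   ref = c("AT", "T"), alt = c("A", "G"),
                   tpos = c(10L, 11L), tref = c("AT", "T"),
                   talt = c("A", "G"), stringsAsFactors = FALSE)
  vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]
  pg <- make_pg("S1", vars, a = c(1L, 1L), b = c(0L, 0L))
  expect_warning(hs <- build_haplotypes(tv, pg), "overlapping")
  expect_equal(nrow(hs$assignments), 1L)
  expect_equal(hs$n_excluded, 1L)
})

test_that("frequencies divide by included chromosomes, globally and per population", {
  tv <- simple_tv(1)
  vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]
  # 4 samples = 8 chromosomes; 3 carry the variant, all in AFR samples
  a <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  b <- matrix(c(1L, 0L, 0L, 0L), 1, 4)
  pg <- make_pg(paste0("S", 1:4), vars, a, b)
  pm <- structure(setNames(c("AFR", "AFR", "EUR", "EUR"), paste0("S", 1:4)),
                  class = "population_map")
  hs <- compute_frequencies(build_haplotypes(tv, pg), pm)
  f <- haplotype_freqs(hs)
  expect_equal(unname(f["WT"]), 5 / 8)
  expect_equal(unname(f["10:A>G"]), 3 / 8)
  h1 <- hs$haplotypes[[which(names(f) == "10:A>G")]]
  expect_equal(unname(h1$freq_by_pop["AFR"]), 3 / 4)
  expect_equal(unname(h1$freq_by_pop["EUR"]), 0)
  # per-population frequencies sum to one
  for (p in c("AFR", "EUR")) {
    s <- sum(vapply(hs$haplotypes, function(h) h$freq_by_pop[[p]],
                    numeric(1)))
    expect_equal(s, 1, tolerance = 1e-12)
  }

  # single-population cohort: per-pop frequencies equal global
  pm1 <- structure(setNames(rep("EAS", 4), paste0("S", 1:4)),
                   class = "population_map")
  hs1 <- compute_frequencies(build_haplotypes(tv, pg), pm1)
  for (h in hs1$haplotypes)
    expect_equal(unname(h$freq_by_pop[["EAS"]]), h$freq_global)

  # a population with zero included chromosomes gets NA, not zero
  pm2 <- structure(setNames(c(rep("AFR", 4)), paste0("S", 1:4)),
                   class = "population_map")
  pm2 <- structure(c(pm2, SX = "SAS"), class = "population_map")
  hs2 <- compute_frequencies(build_haplotypes(tv, pg), pm2)
  expect_true(all(is.na(vapply(hs2$haplotypes, function(h)
    h$freq_by_pop[["SAS"]], numeric(1)))))
})

test_that("retention filter keeps super-threshold haplotypes plus wild type, order preserved", {
  tv <- simple_tv(2)
  vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]
  pg <- make_pg("S1", vars, a = c(0L, 0L), b = c(0L, 0L))
  hs <- compute_frequencies(build_haplotypes(tv, pg))
  # inject the spec frequencies directly onto a three-haplotype set
  hs$haplotypes <- list(
    list(key = "WT", var_idx = integer(0), count = 1L, freq_global = 0.001,
         count_by_pop = NULL, freq_by_pop = NULL),
    list(key = "10:A>G", var_idx = 1L, count = 6L, freq_global = 0.006,
         count_by_pop = NULL, freq_by_pop = NULL),
    list(key = "20:A>G", var_idx = 2L, count = 4L, freq_global = 0.004,
         count_by_pop = NULL, freq_by_pop = NULL))
  kept <- vapply(filter_haplotypes(hs, 0.005)$haplotypes, `[[`,
                 character(1), "key")
  expect_equal(kept, c("WT", "10:A>G"))
  # threshold zero retains everything; WT-only set is stable
  expect_length(filter_haplotypes(hs, 0)$haplotypes, 3L)
  hs$haplotypes <- hs$haplotypes[1]
  expect_equal(vapply(filter_haplotypes(hs, 0.005)$haplotypes, `[[`,
                      character(1), "key"), "WT")
})

test_that("haplotype counts match brute-force per-chromosome enumeration on random instances", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n_sites <- sample(1:5, 1)
      n_samples <- sample(1:4, 1)
      tv <- simple_tv(n_sites)
      vars <- tv[, c("chrom", "pos", "id", "ref", "alt")]
      a <- matrix(sample(c(0L, 1L, NA), n_sites * n_samples, replace = TRUE,
                         prob = c(.5, .4, .1)), n_sites, n_samples)
      b <- matrix(sample(c(0L, 1L, NA), n_sites * n_samples, replace = TRUE,
                         prob = c(.5, .4, .1)), n_sites, n_samples)
      pg <- make_pg(paste0("S", seq_len(n_samples)), vars, a, b)
      hs <- build_haplotypes(tv, pg)

      # oracle: enumerate chromosome allele strings directly
      strings <- character(0)
      for (s in seq_len(n_samples)) {
        for (al in list(a[, s], b[, s])) {
          if (anyNA(al)) next
          carried <- which(al == 1L)
          strings <- c(strings, if (length(carried))
            paste(sprintf("%d:A>G", tv$tpos[carried]), collapse = ";")
            else "WT")
        }
      }
      oracle <- table(strings)
      got <- setNames(vapply(hs$haplotypes, `[[`, integer(1), "count"),
                      vapply(hs$haplotypes, `[[`, character(1), "key"))
      got <- got[got > 0]
      expect_equal(sort(names(got)), sort(names(oracle)))
      expect_equal(unname(got[sort(names(got))]),
                   unname(as.integer(oracle[sort(names(oracle))])))
    }
  })
})
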