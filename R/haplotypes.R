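#' Enumerate observed haplotypes of one transcript from phased genotypes
#'
#' Each sample contributes two chromosome copies, read off the phased allele
#' pairs (pair order is preserved: the first allele of every site belongs to
#' the same chromosome copy). A chromosome is excluded entirely from
#' counting when any of the transcript's sites is missing or is an unphased
#' heterozygote, and when two carried variants overlap on the CDS
#' (contradictory phasing); exclusions shrink the frequency denominator.
#' The wild-type haplotype (`"WT"`, no alternative alleles) is always
#' present in the result, possibly with count zero.
#'
#' Haplotype keys are canonical: constituent variants sorted by `tpos` and
#' joined as `"tpos:tref>talt"` with semicolons.
#'
#' @param tvariants `transcript_variants` from [map_variants_to_transcript()]
#'   (all of one transcript).
#' @param genotypes `phased_genotypes` covering the source sites.
#' @return Object of class `haplotype_set`: list with `transcript_id`
#'   (attribute may be absent if unknown), `tvariants`, `haplotypes` (list of
#'   records `key`, `var_idx` (row indices into `tvariants`), `count`),
#'   `assignments` (data.frame `sample`, `chromosome`, `key` for every
#'   included chromosome) and `n_excluded`.
#' @export
build_haplotypes <- function(tvariants, genotypes) {
  nv <- nrow(tvariants)
  site_idx <- integer(nv)
  if (nv > 0L) {
    gkey <- paste(genotypes$variants$chrom, genotypes$variants$pos,
                  genotypes$variants$ref, genotypes$variants$alt)
    vkey <- paste(tvariants$chrom, tvariants$pos, tvariants$ref,
                  tvariants$alt)
    site_idx <- match(vkey, gkey)
    if (anyNA(site_idx))
      stopf("genotypes do not cover variant(s): %s",
            paste(vkey[is.na(site_idx)], collapse = "; "))
  }

  key_of <- function(idx) {
    if (!length(idx)) return("WT")
    idx <- idx[order(tvariants$tpos[idx])]
    paste(sprintf("%d:%s>%s", tvariants$tpos[idx], tvariants$tref[idx],
                  tvariants$talt[idx]), collapse = ";")
  }

  counts <- new.env(parent = emptyenv())
  varsets <- new.env(parent = emptyenv())
  asg_sample <- character(0); asg_chr <- integer(0); asg_key <- character(0)
  n_excluded <- 0L

  for (s in seq_along(genotypes$samples)) {
    a <- if (nv) genotypes$hap_a[site_idx, s] else integer(0)
    b <- if (nv) genotypes$hap_b[site_idx, s] else integer(0)
    ph <- if (nv) genotypes$phased[site_idx, s] else logical(0)
    # unphased heterozygotes poison both chromosome copies of the sample
    unph_het <- !ph & !is.na(a) & !is.na(b) & a != b
    for (copy in 1:2) {
      al <- if (copy == 1L) a else b
      if (any(is.na(al)) || any(unph_het)) { n_excluded <- n_excluded + 1L; next }
      carried <- which(al == 1L)
      if (length(carried) > 1L) {
        o <- carried[order(tvariants$tpos[carried])]
        sp_end <- tvariants$tpos[o] + nchar(tvariants$tref[o]) - 1L
        if (any(tvariants$tpos[o][-1] <= sp_end[-length(o)])) {
          warnf("sample %s chromosome %d excluded: overlapping variants on CDS",
                genotypes$samples[s], copy)
          n_excluded <- n_excluded + 1L
          next
        }
      }
      k <- key_of(carried)
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      varsets[[k]] <- carried
      asg_sample <- c(asg_sample, genotypes$samples[s])
      asg_chr <- c(asg_chr, copy)
      asg_key <- c(asg_key, k)
    }
  }
  if (is.null(counts[["WT"]])) { counts[["WT"]] <- 0L; varsets[["WT"]] <- integer(0) }

  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  # deterministic order: WT first, then decreasing count, ties by key
  ord <- order(keys != "WT", -cnt, keys)
  haps <- lapply(ord, function(i) list(
    key = keys[i],
    var_idx = sort(varsets[[keys[i]]]),
    count = unname(cnt[i]),
    freq_global = NA_real_,
    count_by_pop = NULL,
    freq_by_pop = NULL))

  structure(list(
    tvariants = tvariants,
    haplotypes = haps,
    assignments = data.frame(sample = asg_sample, chromosome = asg_chr,
                             key = asg_key, stringsAsFactors = FALSE),
    n_excluded = n_excluded
  ), class = "haplotype_set")
}

#' Compute global and per-population haplotype frequencies
#'
#' `freq_global` is count over all included chromosomes; per-population
#' frequencies restrict both numerator and denominator to chromosomes of
#' samples assigned to that population. A population with zero included
#' chromosomes gets `NA` frequencies (undefined, not zero). Within every
#' population that has at least one included chromosome, frequencies over
#' all haplotypes sum to one.
#'
#' @param hapset `haplotype_set` from [build_haplotypes()].
#' @param popmap `population_map` from [read_population_map()] (or any named
#'   character vector sample -> label); samples absent from the map count
#'   globally but in no population. `NULL` skips per-population frequencies.
#' @return The `haplotype_set` with `freq_global`, `count_by_pop` and
#'   `freq_by_pop` filled on every haplotype record, and `populations`
#'   stored on the set.
#' @export
compute_frequencies <- function(hapset, popmap = NULL) {
  asg <- hapset$assignments
  total <- nrow(asg)
  pops <- if (is.null(popmap)) character(0) else sort(unique(unname(popmap)))
  pop_of <- if (is.null(popmap)) rep(NA_character_, total)
            else unname(popmap[asg$sample])
  pop_totals <- vapply(pops, function(p) sum(pop_of == p, na.rm = TRUE),
                       integer(1))
  hapset$haplotypes <- lapply(hapset$haplotypes, function(h) {
    h$freq_global <- if (total > 0L) h$count / total else NA_real_
    in_hap <- asg$key == h$key
    cbp <- vapply(pops, function(p) sum(in_hap & pop_of == p, na.rm = TRUE),
                  integer(1))
    h$count_by_pop <- setNames(cbp, pops)
    h$freq_by_pop <- setNames(ifelse(pop_totals > 0L, cbp / pop_totals,
                                     NA_real_), pops)
    h
  })
  hapset$populations <- pops
  hapset$pop_totals <- setNames(pop_totals, pops)
  hapset
}

#' Apply the global-frequency retention filter
#'
#' Keeps haplotypes whose global frequency meets the threshold (default
#' 0.5%), always including the wild-type haplotype. Relative order is
#' preserved and frequencies are not renormalised: retained records keep
#' their cohort frequencies.
#'
#' @param hapset `haplotype_set` with frequencies computed.
#' @param min_global_freq Retention threshold on `freq_global`
#'   (default 0.005).
#' @return The filtered `haplotype_set`.
#' @export
filter_haplotypes <- function(hapset, min_global_freq = 0.005) {
  keep <- vapply(hapset$haplotypes, function(h) {
    h$key == "WT" ||
      (!is.na(h$freq_global) && h$freq_global >= min_global_freq)
  }, logical(1))
  hapset$haplotypes <- hapset$haplotypes[keep]
  hapset
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d included chromosomes (%d excluded)\n",
              length(x$haplotypes), nrow(x$assignments), x$n_excluded))
  invisible(x)
}

#' Named global-frequency vector of a haplotype set
#' @param hapset `haplotype_set` with frequencies computed.
#' @return Named numeric vector keyed by haplotype key.
#' @export
haplotype_freqs <- function(hapset) {
  setNames(vapply(hapset$haplotypes, `[[`, numeric(1), "freq_global"),
           vapply(hapset$haplotypes, `[[`, character(1), "key"))
}
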