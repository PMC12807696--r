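# Group-level statistics over score tables: variant-set annotation,
# bootstrap-of-the-median comparison, inter-model correlation.

#' Annotate haplotypes by membership in a variant-identifier set
#'
#' A haplotype is `in_set` when it carries at least one variant whose
#' identifier belongs to `id_set` (e.g. a curated list of GWAS rsIDs); the
#' wild-type haplotype, carrying no variants, is always `out_set`. The two
#' labels partition the haplotypes.
#'
#' @param variant_ids Character vector, one element per haplotype, each a
#'   semicolon-separated list of carried variant identifiers (empty string
#'   for wild type). A list of character vectors is also accepted.
#' @param id_set Character vector of identifiers defining the set.
#' @return Character vector of labels `"in_set"` / `"out_set"`.
#' @export
annotate_by_variant_set <- function(variant_ids, id_set) {
  if (is.character(variant_ids))
    variant_ids <- strsplit(variant_ids, ";", fixed = TRUE)
  vapply(variant_ids, function(ids) {
    ids <- ids[nzchar(ids)]
    if (length(ids) && any(ids %in% id_set)) "in_set" else "out_set"
  }, character(1))
}

#' Bootstrap replicates of the median
#'
#' Draws `n_replicates` same-size resamples with replacement and records the
#' median of each (even-length medians are the mean of the two central order
#' statistics). The RNG is fully determined by `seed`, so results are
#' reproducible across runs and platforms.
#'
#' @param values Non-empty numeric vector.
#' @param n_replicates Number of replicates (default 100).
#' @param seed Integer RNG seed.
#' @return Object of class `bootstrap_result`: list with `n_replicates`,
#'   `statistic = "median"`, `replicate_values`, `seed`.
#' @export
bootstrap_median <- function(values, n_replicates = 100L, seed = 1L) {
  if (length(values) == 0L) stopf("values must be non-empty")
  n <- length(values)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(i)
      median(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  structure(list(n_replicates = as.integer(n_replicates),
                 statistic = "median",
                 replicate_values = reps,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' Bootstrap comparison of two groups' medians
#'
#' Resamples each group independently (`seed` for group a, `seed + 1` for
#' group b) and summarises the replicate distributions: each group's median
#' of replicate medians and the fraction of replicate pairs where a's median
#' is below b's. No formal test statistic is computed; the replicate
#' distributions themselves carry the central tendency and sampling
#' variability.
#'
#' @param a,b Non-empty numeric vectors of scores.
#' @param n_replicates Replicates per group (default 100).
#' @param seed Integer RNG seed.
#' @return List with `bootstrap_a`, `bootstrap_b` (`bootstrap_result`s) and
#'   `summary` (`median_of_medians_a`, `median_of_medians_b`,
#'   `frac_a_lt_b`).
#' @export
compare_groups <- function(a, b, n_replicates = 100L, seed = 1L) {
  if (length(a) == 0L || length(b) == 0L)
    stopf("both groups must be non-empty")
  ba <- bootstrap_median(a, n_replicates, seed)
  bb <- bootstrap_median(b, n_replicates, seed + 1L)
  list(bootstrap_a = ba,
       bootstrap_b = bb,
       summary = list(
         median_of_medians_a = median(ba$replicate_values),
         median_of_medians_b = median(bb$replicate_values),
         frac_a_lt_b = mean(ba$replicate_values < bb$replicate_values)))
}

#' Pearson correlation between two paired score vectors
#'
#' Pairs with a missing value in either vector are dropped listwise; the
#' p-value is the usual two-sided t-transform. Zero variance in either
#' vector yields an undefined-correlation marker (`NA` r and p) rather than
#' an error.
#'
#' @param x,y Numeric vectors of equal length (paired by haplotype).
#' @return List with `r`, `p`, `n` (pairs used).
#' @export
score_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
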