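# Pseudo-log-likelihood scoring: pluggable scorer contract plus the derived
# PLLR_wt / PLLR_mf / PLL_delta metrics and logit-scale aggregation of
# per-variant pathogenicity probabilities.

#' Construct a scorer plugin
#'
#' A scorer maps a protein sequence (character scalar over the 20 standard
#' amino acids) to a real-valued pseudo-log-likelihood: higher means the
#' model considers the sequence more likely. Production protein language
#' models (masked-marginal ESM-2 style, MSA-conditioned autoregressive
#' models with forward/backward averaging, structure-conditioned models)
#' plug in through this same contract; this package ships the deterministic
#' [toy_unigram_scorer()] for testing and demonstration.
#'
#' @param name Scorer name (registry key).
#' @param score Function `character -> numeric(1)`, finite for any sequence
#'   over the 20 standard residues.
#' @param deterministic Logical; `TRUE` when identical sequences always get
#'   identical scores.
#' @return Object of class `scorer_plugin`.
#' @export
new_scorer <- function(name, score, deterministic = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(score))
  structure(list(name = name, score = score, deterministic = deterministic),
            class = "scorer_plugin")
}

#' Unigram pseudo-log-likelihood scorer
#'
#' Scores a protein as the sum over residues of the log of a fixed
#' per-residue probability, matching the additive structure of a
#' pseudo-log-likelihood while staying exactly computable: with the uniform
#' table, `PLL = L * log(1/20)`, strictly decreasing in length. Useful as a
#' deterministic stand-in for protein language models in tests and demos.
#'
#' @param freq_table Named numeric vector of positive probabilities over the
#'   20 standard amino acids, summing to 1 (default: uniform).
#' @param name Registry name (default `"unigram"`).
#' @return A `scorer_plugin`.
#' @export
toy_unigram_scorer <- function(freq_table = NULL, name = "unigram") {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(freq_table)) freq_table <- setNames(rep(1 / 20, 20), aa20)
  if (length(freq_table) == 0L) stopf("empty amino-acid frequency table")
  if (any(freq_table <= 0)) stopf("frequency table entries must be positive")
  if (abs(sum(freq_table) - 1) > 1e-8)
    stopf("frequency table must sum to 1 (got %.6f)", sum(freq_table))
  logp <- log(freq_table)
  score <- function(protein) {
    if (!nzchar(protein)) return(0)
    chars <- strsplit(protein, "", fixed = TRUE)[[1]]
    v <- logp[chars]
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stopf("unknown residue '%s' at position %d", chars[i], i)
    }
    sum(v)
  }
  new_scorer(name, score, deterministic = TRUE)
}

# process-wide scorer registry
.scorer_registry <- new.env(parent = emptyenv())

#' Register a scorer plugin by name
#' @param scorer A `scorer_plugin`.
#' @return The scorer, invisibly.
#' @export
register_scorer <- function(scorer) {
  stopifnot(inherits(scorer, "scorer_plugin"))
  .scorer_registry[[scorer$name]] <- scorer
  invisible(scorer)
}

#' Look up a registered scorer
#' @param name Scorer name.
#' @return The `scorer_plugin`; unknown names are an error listing the
#'   registered scorers.
#' @export
get_scorer <- function(name) {
  s <- .scorer_registry[[name]]
  if (is.null(s))
    stopf("unknown scorer '%s'; registered: %s", name,
          paste(list_scorers(), collapse = ", "))
  s
}

#' Names of all registered scorers
#' @return Character vector.
#' @export
list_scorers <- function() ls(.scorer_registry)

#' Score the proteoforms of one transcript
#'
#' Computes each haplotype's PLL (cached per distinct protein sequence, so
#' identical proteoforms are scored once) and the derived ratios
#' \deqn{PLLR_{wt}(x) = PLL(x) - PLL(x^{wt}), \quad
#'       PLLR_{mf}(x) = PLL(x) - PLL(x^{mf}),}
#' where the wild-type reference is the `"WT"` haplotype and the
#' most-frequent reference is chosen by maximum global frequency with a
#' deterministic tie-break (wild type preferred, then lexicographically
#' smallest key). Lower PLLR means greater predicted impairment.
#'
#' @param proteoforms List of QC-passing `proteoform` objects of one
#'   transcript, wild type included.
#' @param scorer A `scorer_plugin`.
#' @param freqs Named numeric vector of global frequencies keyed by
#'   haplotype key (used to pick the most-frequent reference).
#' @param cache Use the per-sequence cache (default `TRUE`; results are
#'   identical either way).
#' @return data.frame with columns `transcript_id`, `haplotype`, `model`,
#'   `pll`, `pllr_wt`, `pllr_mf`; `NULL` (with a warning) when the scorer
#'   fails on any sequence, leaving other transcripts unaffected.
#' @export
score_haplotypes <- function(proteoforms, scorer, freqs, cache = TRUE) {
  keys <- vapply(proteoforms, `[[`, character(1), "haplotype_key")
  if (!("WT" %in% keys)) stopf("wild-type proteoform absent")
  prots <- vapply(proteoforms, `[[`, character(1), "protein")
  plls <- tryCatch({
    if (cache) {
      uniq <- unique(prots)
      setNames(vapply(uniq, scorer$score, numeric(1)), uniq)[prots]
    } else {
      vapply(prots, scorer$score, numeric(1))
    }
  }, error = function(e) {
    warnf("scorer '%s' failed on transcript %s: %s; transcript left unscored",
          scorer$name, proteoforms[[1]]$transcript_id, conditionMessage(e))
    NULL
  })
  if (is.null(plls)) return(NULL)
  plls <- unname(plls)

  mf_key <- most_frequent_key(freqs[keys])
  pll_wt <- plls[match("WT", keys)]
  pll_mf <- plls[match(mf_key, keys)]
  data.frame(
    transcript_id = vapply(proteoforms, `[[`, character(1), "transcript_id"),
    haplotype = keys,
    model = scorer$name,
    pll = plls,
    pllr_wt = plls - pll_wt,
    pllr_mf = plls - pll_mf,
    stringsAsFactors = FALSE)
}

# deterministic most-frequent selection: max frequency, WT wins ties, then
# lexicographically smallest key
most_frequent_key <- function(freqs) {
  stopifnot(length(freqs) > 0L)
  f <- ifelse(is.na(freqs), -Inf, freqs)
  top <- names(freqs)[f == max(f)]
  if ("WT" %in% top) return("WT")
  sort(top)[1]
}

#' Transcript-level PLL dispersion (max minus min)
#'
#' \deqn{PLL_\Delta(t) = \max_{h \in H_t} PLL(h) - \min_{h \in H_t} PLL(h)}
#' over the transcript's retained haplotypes (wild type included); zero for
#' a single-haplotype transcript. A large value flags transcripts whose
#' common haplotypes span a wide predicted-fitness range.
#'
#' @param records data.frame of score records of one transcript and model
#'   (from [score_haplotypes()]).
#' @return List with `transcript_id`, `model`, `pll_delta` (>= 0) and
#'   `n_haplotypes`.
#' @export
compute_pll_delta <- function(records) {
  stopifnot(nrow(records) >= 1L)
  list(transcript_id = records$transcript_id[1],
       model = records$model[1],
       pll_delta = max(records$pll) - min(records$pll),
       n_haplotypes = nrow(records))
}

#' Logit transform of a pathogenicity probability
#'
#' Reverses the logistic link: `s = ln(p / (1 - p))`, mapping probabilities
#' onto the additive log-odds scale where per-variant scores can be averaged
#' or summed alongside pseudo-log-likelihoods.
#'
#' @param prob Numeric vector of probabilities strictly inside (0, 1);
#'   boundary or out-of-range values are a domain error.
#' @return Numeric vector of logits.
#' @export
am_logit <- function(prob) {
  if (any(!is.finite(prob)) || any(prob <= 0) || any(prob >= 1))
    stopf("probabilities must lie strictly inside (0, 1)")
  log(prob / (1 - prob))
}

#' Aggregate per-variant pathogenicity probabilities for one haplotype
#'
#' Transforms each probability to the logit scale and reports both the mean
#' and the sum as haplotype-level summaries (a single-variant haplotype has
#' mean equal to sum equal to its logit). Order-invariant.
#'
#' @param variant_probs Non-empty numeric vector of probabilities in (0, 1).
#' @param haplotype_key Optional identifier carried into the result.
#' @return List of class `am_record` with `haplotype_key`, `variant_probs`,
#'   `logits`, `logit_mean`, `logit_sum`.
#' @export
aggregate_am <- function(variant_probs, haplotype_key = NA_character_) {
  if (length(variant_probs) == 0L)
    stopf("variant_probs must be non-empty")
  logits <- am_logit(variant_probs)
  structure(list(haplotype_key = haplotype_key,
                 variant_probs = variant_probs,
                 logits = logits,
                 logit_mean = mean(logits),
                 logit_sum = sum(logits)),
            class = "am_record")
}
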