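# End-to-end pipeline: inputs -> haplotype table -> scored table -> group
# statistics. These functions are also the engine behind the command-line
# wrapper shipped in inst/cli/haploscore.R.

#' Build the haplotype/proteoform table from pipeline inputs
#'
#' Runs the full construction pipeline: reads the phased VCF, annotation,
#' reference and population map; maps variants onto each transcript's CDS;
#' enumerates phased haplotypes and computes global plus per-population
#' frequencies; applies the retention filter (wild type always kept);
#' generates each retained haplotype's proteoform under the translation
#' edge rules, classifies per-variant consequences, and applies the
#' protein-length QC. Stage counts are reported as `#STAT` lines on stderr
#' when `verbose = TRUE` and attached as attribute `"stats"`.
#'
#' @param vcf,annotation,fasta,popmap Input file paths (popmap optional,
#'   `NULL` skips per-population frequencies).
#' @param min_global_freq Haplotype retention threshold (default 0.005,
#'   i.e. 0.5%).
#' @param min_len,max_len Protein-length QC bounds in amino acids
#'   (defaults 10 and 4000).
#' @param region Optional region restriction passed to [read_phased_vcf()].
#' @param verbose Emit `#STAT` stage counts on stderr.
#' @return data.frame, one row per (transcript, retained haplotype), with
#'   identifiers, variant lists, consequences, frequencies (global and one
#'   `freq_<POP>` column per population), flags, QC status and the edited
#'   DNA/protein sequences. Proteoform objects are attached as attribute
#'   `"proteoforms"` (a list keyed `transcript_id|haplotype`), the per-set
#'   stage counts as attribute `"stats"`.
#' @export
hap_build <- function(vcf, annotation, fasta, popmap = NULL,
                      min_global_freq = 0.005, min_len = 10L,
                      max_len = 4000L, region = NULL, verbose = FALSE) {
  genotypes <- read_phased_vcf(vcf, region = region)
  models <- read_transcript_models(annotation)
  reference <- read_reference(fasta)
  pm <- if (is.null(popmap)) NULL else read_population_map(popmap)

  stat <- function(name, value)
    if (verbose) message(sprintf("#STAT %s=%s", name, value))
  stat("samples", length(genotypes$samples))
  stat("variants_read", nrow(genotypes$variants))
  stat("transcripts", length(models))

  pops <- if (is.null(pm)) character(0) else sort(unique(unname(pm)))
  rows <- list()
  proteoforms <- list()
  n_observed <- 0L; n_retained <- 0L; n_qc_pass <- 0L
  for (model in models) {
    tv <- map_variants_to_transcript(genotypes$variants, model, reference)
    cds <- attr(tv, "cds")
    downstream <- extract_downstream(model, reference)
    hs <- build_haplotypes(tv, genotypes)
    hs <- compute_frequencies(hs, pm)
    n_observed <- n_observed + length(hs$haplotypes)
    hs <- filter_haplotypes(hs, min_global_freq)
    n_retained <- n_retained + length(hs$haplotypes)

    cons_all <- classify_consequences(cds, tv, downstream = downstream)
    for (h in hs$haplotypes) {
      hv <- tv[h$var_idx, , drop = FALSE]
      pf <- build_proteoform(cds, hv, downstream = downstream,
                             transcript_id = model$transcript_id,
                             haplotype_key = h$key)
      pf$consequences <- cons_all[h$var_idx]
      pf <- qc_filter(pf, min_len = min_len, max_len = max_len)
      if (isTRUE(pf$qc$pass)) n_qc_pass <- n_qc_pass + 1L
      proteoforms[[paste0(model$transcript_id, "|", h$key)]] <- pf
      row <- data.frame(
        gene_id = model$gene_id,
        gene_symbol = model$gene_symbol,
        transcript_id = model$transcript_id,
        haplotype = h$key,
        n_variants = length(h$var_idx),
        variant_ids = paste(hv$id, collapse = ";"),
        nt_changes = paste(sprintf("%s:%d%s>%s", hv$chrom, hv$pos, hv$ref,
                                   hv$alt), collapse = ";"),
        consequences = paste(pf$consequences, collapse = ";"),
        tsl = model$tsl,
        count = h$count,
        freq_global = h$freq_global,
        flags = paste(sort(pf$flags), collapse = ","),
        qc = if (isTRUE(pf$qc$pass)) "pass" else
          paste0("fail:", pf$qc$reason),
        protein_length = nchar(pf$protein),
        dna = pf$dna,
        protein = pf$protein,
        stringsAsFactors = FALSE)
      for (p in pops) row[[paste0("freq_", p)]] <- h$freq_by_pop[[p]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_build_table(pops)
  rownames(out) <- NULL
  out <- out[order(out$transcript_id, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  stat("haplotypes_observed", n_observed)
  stat("haplotypes_retained", n_retained)
  stat("proteoforms_qc_pass", n_qc_pass)
  attr(out, "proteoforms") <- proteoforms
  attr(out, "stats") <- list(samples = length(genotypes$samples),
                             variants_read = nrow(genotypes$variants),
                             transcripts = length(models),
                             haplotypes_observed = n_observed,
                             haplotypes_retained = n_retained,
                             proteoforms_qc_pass = n_qc_pass)
  out
}

empty_build_table <- function(pops = character(0)) {
  out <- data.frame(gene_id = character(0), gene_symbol = character(0),
                    transcript_id = character(0), haplotype = character(0),
                    n_variants = integer(0), variant_ids = character(0),
                    nt_changes = character(0), consequences = character(0),
                    tsl = integer(0), count = integer(0),
                    freq_global = numeric(0), flags = character(0),
                    qc = character(0), protein_length = integer(0),
                    dna = character(0), protein = character(0),
                    stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("freq_", p)]] <- numeric(0)
  out
}

#' Score a built haplotype table with one or more scorer plugins
#'
#' For every transcript, the QC-passing proteoforms (wild type always
#' required) are scored by each plugin; per-model `pll_<name>`,
#' `pllr_wt_<name>` and `pllr_mf_<name>` columns are appended to the table,
#' and a per-transcript PLL_delta summary is returned alongside. Transcripts
#' whose wild type fails QC are left unscored for all models.
#'
#' @param build_table data.frame from [hap_build()] (with its
#'   `"proteoforms"` attribute intact, i.e. not round-tripped through TSV).
#' @param scorers List of `scorer_plugin` objects (default: the uniform
#'   [toy_unigram_scorer()]).
#' @return List with `haplotypes` (the input table plus score columns) and
#'   `transcripts` (data.frame `transcript_id`, `model`, `pll_delta`,
#'   `n_haplotypes`).
#' @export
hap_score <- function(build_table, scorers = list(toy_unigram_scorer())) {
  proteoforms <- attr(build_table, "proteoforms")
  if (is.null(proteoforms))
    stopf("build_table lacks its proteoforms attribute; rerun hap_build()")
  out <- build_table
  deltas <- list()
  for (scorer in scorers) {
    pll <- rep(NA_real_, nrow(out))
    pllr_wt <- rep(NA_real_, nrow(out))
    pllr_mf <- rep(NA_real_, nrow(out))
    for (tx in unique(out$transcript_id)) {
      idx <- which(out$transcript_id == tx & out$qc == "pass")
      if (!length(idx)) next
      pfs <- proteoforms[paste0(tx, "|", out$haplotype[idx])]
      if (!("WT" %in% out$haplotype[idx])) next
      freqs <- setNames(out$freq_global[idx], out$haplotype[idx])
      rec <- score_haplotypes(pfs, scorer, freqs)
      if (is.null(rec)) next
      m <- match(rec$haplotype, out$haplotype[idx])
      pll[idx[m]] <- rec$pll
      pllr_wt[idx[m]] <- rec$pllr_wt
      pllr_mf[idx[m]] <- rec$pllr_mf
      deltas[[length(deltas) + 1L]] <-
        as.data.frame(compute_pll_delta(rec), stringsAsFactors = FALSE)
    }
    out[[paste0("pll_", scorer$name)]] <- pll
    out[[paste0("pllr_wt_", scorer$name)]] <- pllr_wt
    out[[paste0("pllr_mf_", scorer$name)]] <- pllr_mf
  }
  transcripts <- if (length(deltas)) do.call(rbind, deltas) else
    data.frame(transcript_id = character(0), model = character(0),
               pll_delta = numeric(0), n_haplotypes = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "proteoforms") <- proteoforms
  list(haplotypes = out, transcripts = transcripts)
}

#' Group comparison and inter-model correlation over a scored table
#'
#' Annotates each haplotype as `in_set`/`out_set` by membership of any of
#' its variant ids in `id_set`, runs the bootstrap-of-the-median comparison
#' of `pllr_wt` between the two groups for every model, and computes the
#' Pearson correlation of `pllr_wt` (per haplotype) and `pll_delta` (per
#' transcript) between every model pair.
#'
#' @param scored Result of [hap_score()].
#' @param id_set Character vector of variant identifiers (e.g. read from a
#'   one-column file).
#' @param models Character vector of scorer names to analyse (default: all
#'   scored models).
#' @param n_replicates Bootstrap replicates per group (default 100).
#' @param seed Integer RNG seed for the bootstrap.
#' @return List with `groups` (per-haplotype labels), `bootstrap` (one
#'   [compare_groups()] result per model) and `correlations` (data.frame
#'   `model_x`, `model_y`, `metric`, `r`, `p`, `n`).
#' @export
hap_analyze <- function(scored, id_set, models = NULL, n_replicates = 100L,
                        seed = 1L) {
  tab <- scored$haplotypes
  if (is.null(models))
    models <- sub("^pllr_wt_", "",
                  grep("^pllr_wt_", names(tab), value = TRUE))
  labels <- annotate_by_variant_set(tab$variant_ids, id_set)
  boots <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    v <- tab[[paste0("pllr_wt_", m)]]
    a <- v[labels == "in_set" & is.finite(v)]
    b <- v[labels == "out_set" & is.finite(v)]
    if (!length(a) || !length(b))
      stopf("model %s: a group is empty after annotation (in=%d, out=%d)",
            m, length(a), length(b))
    boots[[m]] <- compare_groups(a, b, n_replicates, seed + (i - 1L) * 1000L)
  }
  cors <- list()
  if (length(models) >= 2L) {
    for (i in seq_len(length(models) - 1L)) for (j in (i + 1L):length(models)) {
      mx <- models[i]; my <- models[j]
      cw <- score_correlation(tab[[paste0("pllr_wt_", mx)]],
                              tab[[paste0("pllr_wt_", my)]])
      dx <- scored$transcripts[scored$transcripts$model == mx, ]
      dy <- scored$transcripts[scored$transcripts$model == my, ]
      common <- intersect(dx$transcript_id, dy$transcript_id)
      xv <- dx$pll_delta[match(common, dx$transcript_id)]
      yv <- dy$pll_delta[match(common, dy$transcript_id)]
      cd <- if (length(common) >= 3L)
        score_correlation(xv, yv) else list(r = NA_real_, p = NA_real_,
                                            n = length(common))
      cors[[length(cors) + 1L]] <- data.frame(
        model_x = mx, model_y = my, metric = c("pllr_wt", "pll_delta"),
        r = c(cw$r, cd$r), p = c(cw$p, cd$p), n = c(cw$n, cd$n),
        stringsAsFactors = FALSE)
    }
  }
  list(groups = labels,
       bootstrap = boots,
       correlations = if (length(cors)) do.call(rbind, cors) else
         data.frame(model_x = character(0), model_y = character(0),
                    metric = character(0), r = numeric(0), p = numeric(0),
                    n = integer(0), stringsAsFactors = FALSE))
}
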