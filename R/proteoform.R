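#' Apply a haplotype's variants to the wild-type CDS
#'
#' Edits are applied sequentially in 5'-to-3' order with a cumulative
#' position shift tracker: after each insertion or deletion, the net length
#' change of all preceding edits is added to the next variant's coordinate,
#' so every reference allele lands on the bases it describes. Each edit's
#' reference allele is validated at the shifted position; a mismatch aborts
#' with an error naming the variant.
#'
#' @param cds Wild-type CDS string (5'-to-3').
#' @param tvariants data.frame with `tpos`, `tref`, `talt` (transcript
#'   coordinates/alleles), sorted by `tpos`, non-overlapping.
#' @return The edited CDS string; its length differs from the input by the
#'   summed allele-length differences.
#' @export
apply_variants <- function(cds, tvariants) {
  if (nrow(tvariants) == 0L) return(cds)
  if (is.unsorted(tvariants$tpos, strictly = FALSE))
    stopf("tvariants must be sorted by tpos")
  sp_end <- tvariants$tpos + nchar(tvariants$tref) - 1L
  if (nrow(tvariants) > 1L &&
      any(tvariants$tpos[-1] <= sp_end[-nrow(tvariants)]))
    stopf("overlapping variants on the CDS")
  out <- cds
  shift <- 0L
  for (i in seq_len(nrow(tvariants))) {
    p <- tvariants$tpos[i] + shift
    tref <- tvariants$tref[i]; talt <- tvariants$talt[i]
    seen <- substr(out, p, p + nchar(tref) - 1L)
    if (seen != tref)
      stopf("reference mismatch applying %d:%s>%s (found %s)",
            tvariants$tpos[i], tref, talt, seen)
    out <- paste0(substr(out, 1L, p - 1L), talt,
                  substr(out, p + nchar(tref), nchar(out)))
    shift <- shift + nchar(talt) - nchar(tref)
  }
  out
}

#' Translate an edited CDS under the disruptive-variant rules
#'
#' Codon-by-codon translation with the standard genetic code, starting at
#' `offset` (0-based, default 0). The terminal stop codon is not included in
#' the protein. Rules:
#' \itemize{
#'   \item a stop codon with at least one full codon of CDS remaining after
#'     it truncates the protein and sets flag `truncated_premature_stop`;
#'   \item a stop at the last complete codon is a normal terminus (no flag);
#'   \item when translation reaches the CDS end without a stop (frameshift
#'     or stop-lost) and `downstream` is provided, it continues into the
#'     downstream sequence until the first stop (`extended_readthrough`);
#'   \item with no stop found at all the flag is `no_stop_reached`;
#'   \item trailing bases short of a codon are ignored.
#' }
#' Frameshifts need no special machinery here: after [apply_variants()] the
#' shifted frame is simply what the codon walk reads.
#'
#' @param dna Edited CDS string (non-empty).
#' @param downstream Optional 3' sequence (e.g. the 3'UTR from
#'   [extract_downstream()]) used for readthrough.
#' @param offset 0-based translation start within `dna` (see
#'   [rescue_start()]).
#' @return List with `protein` (amino-acid string, no stop symbol) and
#'   `flags` (character vector).
#' @export
translate_cds <- function(dna, downstream = NULL, offset = 0L) {
  stopifnot(nzchar(dna))
  full <- if (!is.null(downstream) && nzchar(downstream))
    paste0(dna, downstream) else dna
  n_cds <- nchar(dna)
  n_full <- nchar(full)
  starts <- seq.int(offset + 1L, n_full, by = 3L)
  starts <- starts[starts + 2L <= n_full]
  flags <- character(0)
  if (!length(starts))
    return(list(protein = "", flags = "no_stop_reached"))
  codons <- substring(full, starts, starts + 2L)
  aas <- codon_to_aa(codons)
  stop_i <- which(aas == "*")
  if (length(stop_i)) {
    i <- stop_i[1]
    protein <- paste(aas[seq_len(i - 1L)], collapse = "")
    stop_end <- starts[i] + 2L
    if (stop_end > n_cds) {
      flags <- c(flags, "extended_readthrough")
    } else if (n_cds - stop_end >= 3L) {
      flags <- c(flags, "truncated_premature_stop")
    }
  } else {
    protein <- paste(aas, collapse = "")
    flags <- c(flags, "no_stop_reached")
  }
  list(protein = protein, flags = flags)
}

#' Find the rescue start after a start-loss
#'
#' When an edit destroys the annotated ATG, the N-terminus is redefined at
#' the next in-frame ATG of the edited CDS: codon offsets 0, 3, 6, ... are
#' scanned and the first equal to `ATG` is returned. Out-of-frame ATGs are
#' ignored ("next in-frame ATG" is only meaningful relative to the annotated
#' frame).
#'
#' @param dna Edited CDS that does not begin with `ATG` (calling this on an
#'   intact start is an error).
#' @return 0-based offset of the rescue ATG, or `NA_integer_` when no
#'   in-frame ATG exists (flagged `no_start` downstream).
#' @export
rescue_start <- function(dna) {
  if (startsWith(dna, "ATG"))
    stopf("rescue_start called on a CDS with intact start codon")
  n <- nchar(dna)
  if (n < 3L) return(NA_integer_)
  offs <- seq.int(0L, n - 3L, by = 3L)
  hit <- which(substring(dna, offs + 1L, offs + 3L) == "ATG")
  if (!length(hit)) return(NA_integer_)
  offs[hit[1]]
}

#' Build the proteoform of one haplotype
#'
#' Orchestrates the engine: applies the haplotype's variants to the
#' wild-type CDS, handles start-loss rescue, translates under the
#' edge-case rules, and records provenance flags. The wild-type haplotype
#' (no variants) reproduces the reference protein with empty flags.
#'
#' @param cds Wild-type CDS string.
#' @param tvariants data.frame of the haplotype's variants (possibly
#'   zero-row), sorted by `tpos`, non-overlapping.
#' @param downstream Optional 3' readthrough sequence.
#' @param transcript_id,haplotype_key Identifiers carried into the result.
#' @return Object of class `proteoform`: list with `transcript_id`,
#'   `haplotype_key`, `dna` (edited CDS), `protein`, `flags` (subset of
#'   `start_rescued`, `no_start`, `truncated_premature_stop`, `frameshift`,
#'   `extended_readthrough`, `no_stop_reached`), `consequences` (filled by
#'   [classify_consequences()]), and `qc` (set by [qc_filter()], initially
#'   unset).
#' @export
build_proteoform <- function(cds, tvariants, downstream = NULL,
                             transcript_id = NA_character_,
                             haplotype_key = NA_character_) {
  dna <- apply_variants(cds, tvariants)
  flags <- character(0)
  if (nrow(tvariants) > 0L) {
    net <- sum(nchar(tvariants$talt) - nchar(tvariants$tref))
    if (net %% 3L != 0L) flags <- c(flags, "frameshift")
  }
  offset <- 0L
  protein <- ""
  if (!startsWith(dna, "ATG")) {
    off <- rescue_start(dna)
    if (is.na(off)) {
      flags <- c(flags, "no_start")
    } else {
      flags <- c(flags, "start_rescued")
      offset <- off
    }
  }
  if (!("no_start" %in% flags)) {
    tr <- translate_cds(dna, downstream = downstream, offset = offset)
    protein <- tr$protein
    flags <- union(flags, tr$flags)
  }
  structure(list(
    transcript_id = transcript_id,
    haplotype_key = haplotype_key,
    dna = dna,
    protein = protein,
    flags = flags,
    consequences = character(0),
    qc = list(pass = NA, reason = NA_character_)
  ), class = "proteoform")
}

#' Classify the functional consequence of each variant
#'
#' Each variant is applied alone to the wild-type CDS and the resulting
#' proteoform is diffed against the wild type, yielding one Sequence
#' Ontology style label per variant from `start_lost`, `frameshift`,
#' `stop_gained`, `stop_lost`, `inframe_insertion`, `inframe_deletion`,
#' `synonymous`, `missense`. Precedence: start-loss, then frame change,
#' then stop gain/loss, then in-frame length change, then residue identity.
#'
#' @param cds Wild-type CDS string.
#' @param tvariants data.frame of variants (each classified independently).
#' @param downstream Optional 3' readthrough sequence.
#' @return Character vector of labels, one per row of `tvariants`.
#' @export
classify_consequences <- function(cds, tvariants, downstream = NULL) {
  wt <- build_proteoform(cds, tvariants[0, , drop = FALSE],
                         downstream = downstream)
  vapply(seq_len(nrow(tvariants)), function(i) {
    v <- tvariants[i, , drop = FALSE]
    mt <- build_proteoform(cds, v, downstream = downstream)
    dlen <- nchar(v$talt) - nchar(v$tref)
    if (!startsWith(mt$dna, "ATG") && startsWith(cds, "ATG"))
      return("start_lost")
    if (dlen %% 3L != 0L) return("frameshift")
    gained <- "truncated_premature_stop" %in% mt$flags &&
      !("truncated_premature_stop" %in% wt$flags)
    lost <- any(c("no_stop_reached", "extended_readthrough") %in% mt$flags) &&
      !any(c("no_stop_reached", "extended_readthrough") %in% wt$flags)
    if (dlen == 0L) {
      if (gained) return("stop_gained")
      if (lost) return("stop_lost")
      if (identical(mt$protein, wt$protein)) return("synonymous")
      return("missense")
    }
    if (gained) return("stop_gained")
    if (dlen > 0L) "inframe_insertion" else "inframe_deletion"
  }, character(1))
}

#' Apply protein-length and start-codon QC to a proteoform
#'
#' Proteoforms with proteins shorter than `min_len` or longer than `max_len`
#' amino acids fail QC (`protein_too_short` / `protein_too_long`), as does a
#' start-loss with no downstream in-frame ATG (`no_start`). Failing
#' proteoforms are kept, not dropped, so filter effects stay auditable.
#'
#' @param p A `proteoform`.
#' @param min_len,max_len Inclusive protein length bounds (defaults 10 and
#'   4000 amino acids).
#' @return The `proteoform` with `qc` set to
#'   `list(pass = TRUE/FALSE, reason = ...)`.
#' @export
qc_filter <- function(p, min_len = 10L, max_len = 4000L) {
  if ("no_start" %in% p$flags) {
    p$qc <- list(pass = FALSE, reason = "no_start")
  } else if (nchar(p$protein) < min_len) {
    p$qc <- list(pass = FALSE, reason = "protein_too_short")
  } else if (nchar(p$protein) > max_len) {
    p$qc <- list(pass = FALSE, reason = "protein_too_long")
  } else {
    p$qc <- list(pass = TRUE, reason = NA_character_)
  }
  p
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("proteoform %s/%s: %d aa%s\n", x$transcript_id,
              x$haplotype_key, nchar(x$protein),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Write proteoform protein sequences as FASTA
#'
#' One record per proteoform, header `transcript_id|haplotype_key`.
#'
#' @param proteoforms List of `proteoform` objects.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_proteoform_fasta <- function(proteoforms, path) {
  seqs <- vapply(proteoforms, `[[`, character(1), "protein")
  names(seqs) <- vapply(proteoforms, function(p)
    paste0(p$transcript_id, "|", p$haplotype_key), character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
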