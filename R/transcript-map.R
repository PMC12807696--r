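#' Extract the wild-type CDS of a transcript in transcript orientation
#'
#' Concatenates the CDS intervals along the genome and reverse-complements
#' for minus-strand transcripts, yielding the 5'-to-3' coding sequence.
#'
#' @param model A `transcript_model`.
#' @param reference Named sequence map from [read_reference()].
#' @return Character scalar, the wild-type CDS.
#' @export
extract_cds <- function(model, reference) {
  chrom_seq <- reference[[model$chrom]]
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stopf("reference lacks chromosome %s", model$chrom)
  s <- extract_intervals(chrom_seq, model$cds$start, model$cds$end)
  if (model$strand == "-") str_revcomp(s) else s
}

#' Extract the exonic sequence 3' of the CDS (the 3'UTR)
#'
#' Used as the readthrough sequence when frameshift or stop-lost translation
#' runs past the CDS end. Returns the portion of the transcript's exonic
#' sequence downstream of the last CDS base, in transcript orientation
#' (empty string when the CDS reaches the transcript end).
#'
#' @inheritParams extract_cds
#' @return Character scalar (possibly empty).
#' @export
extract_downstream <- function(model, reference) {
  chrom_seq <- reference[[model$chrom]]
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stopf("reference lacks chromosome %s", model$chrom)
  exon_seq <- extract_intervals(chrom_seq, model$exons$start, model$exons$end)
  if (model$strand == "-") exon_seq <- str_revcomp(exon_seq)
  # transcript-orientation exonic offset of the last CDS base
  last_g <- if (model$strand == "+") max(model$cds$end) else min(model$cds$start)
  off0 <- interval_offset0(last_g, model$exons$start, model$exons$end)
  if (is.na(off0)) stopf("CDS end of %s outside exons", model$transcript_id)
  tpos <- if (model$strand == "+") off0 + 1L
          else nchar(exon_seq) - off0
  if (tpos >= nchar(exon_seq)) "" else substr(exon_seq, tpos + 1L,
                                              nchar(exon_seq))
}

#' Map genomic variants onto a transcript's CDS
#'
#' Converts genomic variants to transcript-relative CDS coordinates and
#' transcript-strand alleles. Only variants whose REF span lies entirely
#' within the CDS intervals are returned (a deletion crossing a CDS boundary
#' is excluded). On minus-strand transcripts alleles are reverse-complemented
#' and coordinates flipped so that `tpos` addresses the first affected base
#' in 5'-to-3' transcript orientation. Every converted reference allele is
#' validated against the reference-derived CDS; a mismatch is an error
#' naming the variant.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id` (as produced by [read_phased_vcf()]).
#' @param model A `transcript_model`.
#' @param reference Named sequence map from [read_reference()].
#' @return data.frame of class `transcript_variants` with the input columns
#'   plus `tpos` (1-based CDS coordinate), `tref`, `talt`, sorted by `tpos`.
#'   The wild-type CDS is attached as attribute `"cds"`.
#' @export
map_variants_to_transcript <- function(variants, model, reference) {
  cds_seq <- extract_cds(model, reference)
  L <- nchar(cds_seq)
  starts <- model$cds$start; ends <- model$cds$end
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$chrom != model$chrom) next
    g1 <- v$pos
    g2 <- v$pos + nchar(v$ref) - 1L
    o1 <- interval_offset0(g1, starts, ends)
    o2 <- interval_offset0(g2, starts, ends)
    # contiguous containment: both ends inside and no intronic gap between
    if (is.na(o1) || is.na(o2) || (o2 - o1) != (g2 - g1)) next
    if (model$strand == "+") {
      tpos <- o1 + 1L
      tref <- v$ref; talt <- v$alt
    } else {
      tpos <- L - o2
      tref <- str_revcomp(v$ref); talt <- str_revcomp(v$alt)
    }
    seen <- substr(cds_seq, tpos, tpos + nchar(tref) - 1L)
    if (seen != tref)
      stopf("reference mismatch for variant %s:%d %s>%s (CDS has %s at tpos %d of %s)",
            v$chrom, v$pos, v$ref, v$alt, seen, tpos, model$transcript_id)
    row <- v
    row$id <- if ("id" %in% names(v)) v$id else ""
    row$tpos <- tpos; row$tref <- tref; row$talt <- talt
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), id = character(0),
               ref = character(0), alt = character(0), tpos = integer(0),
               tref = character(0), talt = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$tpos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, cds = cds_seq, class = c("transcript_variants",
                                          "data.frame"))
}
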