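#' Read transcript models from a GTF or GFF3 annotation
#'
#' Parses exon and CDS features into one model per transcript. Transcript
#' identity is taken from the `transcript_id` attribute (GTF) or from
#' `ID`/`Parent` relationships (GFF3). Only transcripts with at least one
#' CDS feature are emitted. Transcripts whose CDS is not fully contained in
#' their exons, or whose exons overlap, are rejected with reason
#' "incomplete CDS annotation" (a warning is raised naming each).
#'
#' @param path Path to a GTF or GFF3 file (format auto-detected by
#'   extension/content via `rtracklayer`).
#' @return A named list of `transcript_model` objects, each a list with
#'   `transcript_id`, `gene_id`, `gene_symbol`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `exons` and `cds` (data.frames of 1-based inclusive
#'   `start`/`end`, sorted by genomic start), and `tsl` (integer 1-5 or
#'   `NA` when unknown).
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  # resolve a transcript id per feature row
  if (!is.null(df$transcript_id)) {
    tx_of <- as.character(df$transcript_id)
  } else if (!is.null(df$Parent)) {
    tx_of <- vapply(df$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else {
    stopf("annotation has neither transcript_id nor Parent attributes")
  }

  feat <- df$type %in% c("exon", "CDS")
  tx_ids <- unique(tx_of[feat & !is.na(tx_of)])

  # transcript-level metadata (gene id / symbol / TSL), best effort per format
  gene_of <- function(tx) {
    rows <- which(tx_of == tx & feat)
    if (!is.null(df$gene_id)) {
      g <- df$gene_id[rows]; g <- g[!is.na(g)]
      if (length(g)) return(as.character(g[1]))
    }
    trow <- which(!is.na(df$ID) & df$ID == tx)
    if (!is.null(df$Parent) && length(trow)) {
      p <- df$Parent[[trow[1]]]
      if (length(p)) return(sub("^gene:", "", as.character(p)[1]))
    }
    NA_character_
  }

  models <- list()
  for (tx in tx_ids) {
    rows <- which(tx_of == tx)
    ex <- df[rows[df$type[rows] == "exon"], , drop = FALSE]
    cd <- df[rows[df$type[rows] == "CDS"], , drop = FALSE]
    if (nrow(cd) == 0L) next
    if (nrow(ex) == 0L) ex <- cd  # annotations carrying only CDS features

    exons <- ex[order(ex$start), c("start", "end")]
    cds <- cd[order(cd$start), c("start", "end")]
    rownames(exons) <- rownames(cds) <- NULL

    ok_contained <- all(vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1)))
    ok_disjoint <- nrow(exons) < 2L ||
      all(exons$start[-1] > exons$end[-nrow(exons)])
    if (!ok_contained || !ok_disjoint) {
      warnf("transcript %s rejected: incomplete CDS annotation", tx)
      next
    }

    tsl <- NA_integer_
    if (!is.null(df$transcript_support_level)) {
      raw <- df$transcript_support_level[rows]
      raw <- raw[!is.na(raw)]
      if (length(raw)) {
        v <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", raw[1])))
        if (!is.na(v) && v >= 1L && v <= 5L) tsl <- v
      }
    }
    sym <- NA_character_
    for (col in c("gene_name", "Name", "gene_symbol")) {
      if (!is.null(df[[col]])) {
        s <- df[[col]][rows]; s <- s[!is.na(s)]
        if (length(s)) { sym <- as.character(s[1]); break }
      }
    }

    models[[tx]] <- structure(list(
      transcript_id = tx,
      gene_id = gene_of(tx),
      gene_symbol = sym,
      chrom = df$seqnames[rows[1]],
      strand = df$strand[rows[1]],
      exons = exons,
      cds = cds,
      tsl = tsl
    ), class = "transcript_model")
  }
  models
}

#' Total CDS length of a transcript model
#' @param model A `transcript_model`.
#' @return Integer number of CDS bases.
#' @export
cds_length <- function(model) {
  sum(model$cds$end - model$cds$start + 1L)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, strand %s): %d exons, CDS %d bp\n",
              x$transcript_id, x$gene_id, x$strand, nrow(x$exons),
              cds_length(x)))
  invisible(x)
}
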