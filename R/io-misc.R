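#' Read a reference FASTA into a named sequence map
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate names are an error; characters outside
#' A/C/G/T/N raise a warning but are retained.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) return(setNames(character(0), character(0)))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stopf("duplicate FASTA record name: %s", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    warnf("FASTA record(s) %s contain non-ACGTN characters (retained)",
          paste(nm[bad], collapse = ", "))
  seqs
}

#' Read a sample-to-population assignment table
#'
#' Expects a two-column TSV (`sample`, `population`), with or without a
#' header line. Duplicate identical rows collapse silently; the same sample
#' mapped to two different populations is an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample name to population label,
#'   with class `population_map`.
#' @export
read_population_map <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) != 2L)
    stopf("population map must have exactly 2 columns, found %d", ncol(dt))
  names(dt) <- c("sample", "population")
  dt <- unique(dt)
  dup <- dt$sample[duplicated(dt$sample)]
  if (length(dup))
    stopf("sample(s) %s assigned to conflicting populations",
          paste(unique(dup), collapse = ", "))
  structure(setNames(dt$population, dt$sample), class = "population_map")
}

#' Write the haplotype/proteoform results table as TSV
#'
#' Rows are ordered deterministically by `transcript_id` then `haplotype`;
#' double-precision columns are rounded to 6 significant digits on output
#' (in-memory objects keep full precision). A path ending `.gz` produces a
#' gzipped file.
#'
#' @param records A data.frame of result rows (e.g. from [hap_build()] or
#'   [hap_score()]).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param columns Optional character vector selecting a column subset;
#'   unknown names are an error listing the valid ones.
#' @return The path, invisibly.
#' @export
write_haplotype_table <- function(records, path, columns = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(columns)) {
    bad <- setdiff(columns, names(records))
    if (length(bad))
      stopf("unknown column(s) %s; valid columns: %s",
            paste(bad, collapse = ", "), paste(names(records), collapse = ", "))
    records <- records[, columns, drop = FALSE]
  }
  ord_cols <- intersect(c("transcript_id", "haplotype"), names(records))
  if (length(ord_cols))
    records <- records[do.call(order, records[ord_cols]), , drop = FALSE]
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], signif, digits = 6)
  data.table::fwrite(records, path, sep = "\t", quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read back a haplotype results TSV
#'
#' Inverse of [write_haplotype_table()].
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return data.frame.
#' @export
read_haplotype_table <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) <= 1L && !nzchar(paste(lines, collapse = "")))
      return(data.frame())
    return(data.table::fread(text = lines, sep = "\t", data.table = FALSE))
  }
  data.table::fread(path, sep = "\t", data.table = FALSE)
}
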