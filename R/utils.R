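# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse complement of plain character DNA (short sequences; IUPAC core only)
str_revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# standard genetic code; unknown codons (e.g. containing N) translate to X
codon_to_aa <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# 0-based offset of genomic position `pos` within the concatenation of the
# 1-based inclusive intervals (starts, ends), sorted by start; NA if outside
interval_offset0 <- function(pos, starts, ends) {
  widths <- ends - starts + 1L
  cum <- cumsum(c(0L, widths))
  vapply(pos, function(p) {
    i <- which(p >= starts & p <= ends)
    if (length(i) != 1L) return(NA_integer_)
    cum[i] + (p - starts[i])
  }, integer(1))
}

# extract and concatenate 1-based inclusive intervals from a sequence string
extract_intervals <- function(seq, starts, ends) {
  paste(substring(seq, starts, ends), collapse = "")
}

is_dna <- function(x) grepl("^[ACGT]+$", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
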