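# Test-owned oracles and fixture builders. These deliberately re-derive
# results by routes independent of the code paths they check.

CODON_TABLE <- Biostrings::GENETIC_CODE

rc <- function(s) {
  if (!nzchar(s)) return(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# descending-coordinate edit application: no shift tracking needed because
# later edits never move earlier coordinates
oracle_apply_desc <- function(cds, tv) {
  out <- cds
  for (i in order(tv$tpos, decreasing = TRUE)) {
    p <- tv$tpos[i]
    stopifnot(substr(out, p, p + nchar(tv$tref[i]) - 1L) == tv$tref[i])
    out <- paste0(substr(out, 1L, p - 1L), tv$talt[i],
                  substr(out, p + nchar(tv$tref[i]), nchar(out)))
  }
  out
}

# plain codon walk to the first stop (or sequence end); start assumed intact
oracle_translate <- function(dna) {
  n <- nchar(dna)
  aa <- character(0)
  i <- 1L
  while (i + 2L <= n) {
    a <- CODON_TABLE[substr(dna, i, i + 2L)]
    if (is.na(a)) a <- "X"
    if (a == "*") break
    aa <- c(aa, a)
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

SAFE_CODONS <- setdiff(names(CODON_TABLE)[CODON_TABLE != "*"], "ATG")

random_cds <- function(n_codons) {
  paste(c("ATG", sample(SAFE_CODONS, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# random non-overlapping transcript-space edits (SNVs and short indels),
# avoiding the start codon; VCF-style anchored indels
random_edits <- function(cds, max_vars = 5L, indels = TRUE) {
  L <- nchar(cds)
  k <- sample(0:max_vars, 1L)
  occupied <- matrix(numeric(0), ncol = 2)
  rows <- list()
  for (i in seq_len(k)) {
    for (try in 1:20) {
      type <- if (indels) sample(c("snv", "ins", "del"), 1L) else "snv"
      p <- sample(4:(L - 4L), 1L)
      if (type == "snv") {
        tref <- substr(cds, p, p)
        talt <- sample(setdiff(c("A", "C", "G", "T"), tref), 1L)
      } else if (type == "ins") {
        tref <- substr(cds, p, p)
        talt <- paste0(tref, paste(sample(c("A", "C", "G", "T"),
                                          sample(1:3, 1L), replace = TRUE),
                                   collapse = ""))
      } else {
        d <- sample(1:3, 1L)
        if (p + d > L) next
        tref <- substr(cds, p, p + d)
        talt <- substr(cds, p, p)
      }
      span <- c(p, p + nchar(tref) - 1L)
      if (nrow(occupied) == 0L ||
          all(span[2] < occupied[, 1] - 1 | span[1] > occupied[, 2] + 1)) {
        occupied <- rbind(occupied, span)
        rows[[length(rows) + 1L]] <- data.frame(
          tpos = p, tref = tref, talt = talt, stringsAsFactors = FALSE)
        break
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tpos = integer(0), tref = character(0),
               talt = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$tpos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random multi-exon transcript on a synthetic chromosome, with genomic
# variants derived from transcript-space edits
random_genome_fixture <- function(strand = "-", max_vars = 4L) {
  C <- sample(10:20, 1L)
  cds <- random_cds(C)
  L <- nchar(cds)
  n_chunks <- sample(1:3, 1L)
  if (n_chunks == 1L) {
    chunk_len <- L
  } else {
    cuts <- sort(sample(seq(6L, L - 6L, by = 1L), n_chunks - 1L))
    while (any(diff(c(0L, cuts, L)) < 6L))
      cuts <- sort(sample(seq(6L, L - 6L, by = 1L), n_chunks - 1L))
    chunk_len <- diff(c(0L, cuts, L))
  }
  cum <- cumsum(c(0L, chunk_len))

  # transcript-space edits whose REF span stays inside one chunk
  tv <- random_edits(cds, max_vars = max_vars)
  keep <- vapply(seq_len(nrow(tv)), function(i) {
    sp <- c(tv$tpos[i], tv$tpos[i] + nchar(tv$tref[i]) - 1L)
    any(sp[1] > cum[-length(cum)] & sp[2] <= cum[-1])
  }, logical(1))
  tv <- tv[keep, , drop = FALSE]

  flank5 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  pieces <- flank5
  starts <- integer(n_chunks); ends <- integer(n_chunks)
  pos <- nchar(flank5)
  for (k in seq_len(n_chunks)) {
    starts[k] <- pos + 1L
    seg <- substr(cds, cum[k] + 1L, cum[k + 1L])
    pieces <- paste0(pieces, seg)
    pos <- pos + nchar(seg)
    ends[k] <- pos
    if (k < n_chunks) {
      intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 10,
                                          replace = TRUE), collapse = ""),
                       "AG")
      pieces <- paste0(pieces, intron)
      pos <- pos + nchar(intron)
    }
  }
  chrom_plus <- paste0(pieces, flank3)

  g_of_t <- function(t) {
    k <- findInterval(t - 1L, cum)
    starts[k] + (t - cum[k] - 1L)
  }
  gpos <- vapply(tv$tpos, g_of_t, integer(1))
  if (strand == "+") {
    chrom <- chrom_plus
    cds_iv <- data.frame(start = starts, end = ends)
    variants <- data.frame(chrom = rep("chrX", length(gpos)), pos = gpos,
                           id = rep("", length(gpos)),
                           ref = tv$tref, alt = tv$talt,
                           stringsAsFactors = FALSE)
  } else {
    Lc <- nchar(chrom_plus)
    chrom <- rc(chrom_plus)
    cds_iv <- data.frame(start = Lc - ends + 1L, end = Lc - starts + 1L)
    cds_iv <- cds_iv[order(cds_iv$start), , drop = FALSE]
    variants <- data.frame(
      chrom = rep("chrX", length(gpos)),
      pos = Lc - (gpos + nchar(tv$tref) - 1L) + 1L,
      id = rep("", length(gpos)),
      ref = vapply(tv$tref, rc, character(1), USE.NAMES = FALSE),
      alt = vapply(tv$talt, rc, character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  }
  rownames(cds_iv) <- NULL
  model <- structure(list(
    transcript_id = "TX", gene_id = "G", gene_symbol = NA_character_,
    chrom = "chrX", strand = strand, exons = cds_iv, cds = cds_iv,
    tsl = NA_integer_), class = "transcript_model")
  list(model = model, reference = c(chrX = chrom), variants = variants,
       cds = cds, n_vars = nrow(tv))
}

# whole-chromosome oracle: apply genomic edits in descending order while
# shifting downstream interval coordinates, re-extract the CDS, reverse
# complement for minus strand, translate by plain codon walk
oracle_genome_protein <- function(fix) {
  seqs <- fix$reference[["chrX"]]
  iv <- fix$model$cds
  v <- fix$variants[order(fix$variants$pos, decreasing = TRUE), ,
                    drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    stopifnot(substr(seqs, p, p + nchar(ref) - 1L) == ref)
    seqs <- paste0(substr(seqs, 1L, p - 1L), alt,
                   substr(seqs, p + nchar(ref), nchar(seqs)))
    d <- nchar(alt) - nchar(ref)
    sel_after <- iv$start > p
    iv$start[sel_after] <- iv$start[sel_after] + d
    iv$end[sel_after] <- iv$end[sel_after] + d
    sel_in <- iv$start <= p & iv$end >= p + nchar(ref) - 1L
    iv$end[sel_in] <- iv$end[sel_in] + d
  }
  cds <- paste(substring(seqs, iv$start, iv$end), collapse = "")
  if (fix$model$strand == "-") cds <- rc(cds)
  oracle_translate(cds)
}

# in-memory phased genotypes (bypasses VCF parsing where tests target the
# haplotype counting itself)
make_pg <- function(samples, variants, a, b, phased = NULL) {
  a <- matrix(a, nrow = nrow(variants), ncol = length(samples))
  b <- matrix(b, nrow = nrow(variants), ncol = length(samples))
  if (is.null(phased)) phased <- matrix(TRUE, nrow(variants), length(samples))
  structure(list(samples = samples, variants = variants, hap_a = a,
                 hap_b = b, phased = phased), class = "phased_genotypes")
}

# minimal transcript-variant frame for engine-level tests
tvf <- function(tpos, tref, talt) {
  data.frame(tpos = as.integer(tpos), tref = tref, talt = talt,
             stringsAsFactors = FALSE)
}

# minimal proteoform for QC tests
pf_of_length <- function(n) {
  structure(list(transcript_id = "T", haplotype_key = "H",
                 dna = "", protein = strrep("K", n), flags = character(0),
                 consequences = character(0),
                 qc = list(pass = NA, reason = NA_character_)),
            class = "proteoform")
}

write_lines_tmp <- function(lines, ext = "") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
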