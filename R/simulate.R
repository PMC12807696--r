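# Synthetic cohort generator: fully self-contained toy cohorts (genome
# FASTA, GTF, phased VCF, population map, pathogenicity table) with exact
# ground truth, so the whole pipeline is testable without any downloads.

#' Specify a synthetic cohort
#'
#' Each transcript gets a designed variant panel spanning the retained
#' consequence classes: a synonymous change, a missense change (placed in
#' the last exon to exercise multi-exon coordinate arithmetic), a stop-gain,
#' a start-loss (with a rescue ATG planted in frame at codon 9), an
#' in-frame single-codon deletion and a 1-bp frameshift insertion. Designed
#' haplotypes combine these panels; chromosomes draw a haplotype i.i.d. from
#' `haplotype_probs`, so designed frequencies are exact sampling targets
#' (per-site linkage is implied by the haplotype draw, not modelled).
#'
#' @param n_samples Named integer vector of samples per population label
#'   (default 20 per 1000 Genomes style super-population).
#' @param transcripts List of transcript layouts, each
#'   `list(n_exons, n_codons, strand)`; `n_codons` counts the terminal stop
#'   codon and must be at least 24.
#' @param haplotype_probs Named numeric vector over designed haplotype
#'   labels (subset of `WT`, `syn`, `mis`, `cis_mis_syn`, `stopgain`,
#'   `startloss`, `del_inframe`, `fs_ins`), summing to 1; applied to every
#'   transcript.
#' @param am_mean Designed mean of the Beta-distributed pathogenicity
#'   probability attached to each missense variant (default 0.8,
#'   concentration 50).
#' @param seed Integer seed; the generated bundle is byte-identical for a
#'   fixed spec and seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = c(AFR = 20L, AMR = 20L, EAS = 20L,
                                      EUR = 20L, SAS = 20L),
                        transcripts = list(
                          list(n_exons = 2L, n_codons = 40L, strand = "+"),
                          list(n_exons = 3L, n_codons = 60L, strand = "-")),
                        haplotype_probs = c(WT = 0.40, syn = 0.15,
                                            mis = 0.15, cis_mis_syn = 0.10,
                                            stopgain = 0.06,
                                            del_inframe = 0.05,
                                            fs_ins = 0.05, startloss = 0.04),
                        am_mean = 0.8,
                        seed = 1L) {
  labels <- c("WT", "syn", "mis", "cis_mis_syn", "stopgain", "startloss",
              "del_inframe", "fs_ins")
  if (is.null(names(haplotype_probs)) ||
      !all(names(haplotype_probs) %in% labels))
    stopf("haplotype_probs names must be a subset of: %s",
          paste(labels, collapse = ", "))
  if (abs(sum(haplotype_probs) - 1) > 1e-9)
    stopf("haplotype_probs must sum to 1")
  for (tr in transcripts) {
    if (tr$n_codons < 24L)
      stopf("n_codons must be >= 24 (got %d)", tr$n_codons)
    if (!tr$strand %in% c("+", "-")) stopf("strand must be + or -")
  }
  structure(list(n_samples = n_samples, transcripts = transcripts,
                 haplotype_probs = haplotype_probs, am_mean = am_mean,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# variant panels per designed haplotype label
.design_sets <- list(
  WT = character(0), syn = "syn", mis = "mis",
  cis_mis_syn = c("syn", "mis"), stopgain = "stopgain",
  startloss = "startloss", del_inframe = "del", fs_ins = "fs")

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# design one transcript: base CDS with forced codons, variant panel, and
# plus-orientation genome layout (flipped later for minus strand)
design_transcript <- function(tx_id, layout) {
  C <- layout$n_codons
  safe <- c("GCT", "GCC", "GCA", "AAA", "CTT", "GAA", "TTT", "CCG", "GGC",
            "TCT", "CAT", "GTT", "TGG", "CAG")  # no stops, no ATG
  codons <- sample(safe, C, replace = TRUE)
  codons[1] <- "ATG"
  codons[3] <- "CTG"   # syn target: CTG -> CTA (Leu)
  codons[9] <- "ATG"   # in-frame rescue start
  codons[15] <- "CAA"  # stop-gain target: CAA -> TAA
  codons[C - 3] <- "GAA"  # missense target: GAA -> CAA (E -> Q), last exon
  codons[C] <- "TAA"
  cds <- paste(codons, collapse = "")

  mis_tpos <- 3L * (C - 4L) + 1L
  variants <- data.frame(
    label = c("syn", "mis", "stopgain", "startloss", "del", "fs"),
    tpos = c(9L, mis_tpos, 43L, 2L, 18L, 31L),
    tref = c("G", "G", "C", "T", substr(cds, 18, 21), substr(cds, 31, 31)),
    talt = c("A", "C", "T", "C", substr(cds, 18, 18),
             paste0(substr(cds, 31, 31), "A")),
    stringsAsFactors = FALSE)
  variants$id <- paste0("rs", sub("^T", "", tx_id), "00", seq_len(6))
  stopifnot(substr(cds, 9, 9) == "G", substr(cds, mis_tpos, mis_tpos) == "G",
            substr(cds, 43, 43) == "C", substr(cds, 2, 2) == "T")

  # CDS chunks across exons: first chunk holds all early designed variants
  n_ex <- layout$n_exons
  total <- 3L * C
  if (n_ex == 1L) {
    chunk_len <- total
  } else {
    rest <- total - 48L
    per <- rest %/% (n_ex - 1L)
    chunk_len <- c(48L, rep(per, n_ex - 1L))
    chunk_len[n_ex] <- chunk_len[n_ex] + (rest - per * (n_ex - 1L))
  }
  if (chunk_len[n_ex] < 12L)
    stopf("last exon too short to host the designed missense variant")

  utr5 <- rand_dna(10L, c("C", "T"))
  utr3 <- strrep("TAAA", 15L)  # stop codons reachable in every frame
  flank5 <- rand_dna(50L); flank3 <- rand_dna(50L)
  introns <- replicate(max(0L, n_ex - 1L),
                       paste0("GT", rand_dna(24L), "AG"))

  pieces <- character(0)
  cds_starts <- integer(n_ex); cds_ends <- integer(n_ex)
  exon_starts <- integer(n_ex); exon_ends <- integer(n_ex)
  pos <- 0L
  add <- function(s) { pieces <<- c(pieces, s); pos <<- pos + nchar(s) }
  add(flank5)
  cum <- 0L
  for (k in seq_len(n_ex)) {
    exon_starts[k] <- pos + 1L
    if (k == 1L) add(utr5)
    cds_starts[k] <- pos + 1L
    add(substr(cds, cum + 1L, cum + chunk_len[k]))
    cds_ends[k] <- pos
    cum <- cum + chunk_len[k]
    if (k == n_ex) add(utr3)
    exon_ends[k] <- pos
    if (k < n_ex) add(introns[k])
  }
  add(flank3)
  chrom_plus <- paste(pieces, collapse = "")

  # genomic (plus-space) position of a CDS coordinate
  cumlen <- cumsum(c(0L, chunk_len))
  g_of_t <- function(t) {
    k <- findInterval(t - 1L, cumlen)  # chunk index, t in (cumlen[k], cumlen[k+1]]
    cds_starts[k] + (t - cumlen[k] - 1L)
  }
  variants$gpos_plus <- vapply(variants$tpos, g_of_t, integer(1))
  # designed ref spans must not cross a chunk boundary
  stopifnot(vapply(seq_len(nrow(variants)), function(i)
    g_of_t(variants$tpos[i] + nchar(variants$tref[i]) - 1L) ==
      variants$gpos_plus[i] + nchar(variants$tref[i]) - 1L, logical(1)))

  list(tx_id = tx_id, layout = layout, cds = cds, utr3 = utr3,
       chrom_plus = chrom_plus, variants = variants,
       exon_starts = exon_starts, exon_ends = exon_ends,
       cds_starts = cds_starts, cds_ends = cds_ends,
       chunk_len = chunk_len)
}

# flip a designed transcript onto the minus strand of its chromosome
finalize_strand <- function(d) {
  if (d$layout$strand == "+") {
    d$chrom <- d$chrom_plus
    d$variants$gpos <- d$variants$gpos_plus
    d$variants$gref <- d$variants$tref
    d$variants$galt <- d$variants$talt
    return(d)
  }
  L <- nchar(d$chrom_plus)
  d$chrom <- str_revcomp(d$chrom_plus)
  flip <- function(s, e) c(L - e + 1L, L - s + 1L)
  ex <- t(mapply(flip, d$exon_starts, d$exon_ends))
  cd <- t(mapply(flip, d$cds_starts, d$cds_ends))
  ord <- order(ex[, 1])
  d$exon_starts <- ex[ord, 1]; d$exon_ends <- ex[ord, 2]
  ord <- order(cd[, 1])
  d$cds_starts <- cd[ord, 1]; d$cds_ends <- cd[ord, 2]
  d$variants$gpos <- L - (d$variants$gpos_plus +
                            nchar(d$variants$tref) - 1L) + 1L
  d$variants$gref <- str_revcomp(d$variants$tref)
  d$variants$galt <- str_revcomp(d$variants$talt)
  d
}

# descending-coordinate edit application: independent of the 5'->3' shift
# tracker in apply_variants, used for ground truth and oracle testing
apply_variants_desc <- function(cds, tvariants) {
  out <- cds
  for (i in order(tvariants$tpos, decreasing = TRUE)) {
    p <- tvariants$tpos[i]
    tref <- tvariants$tref[i]
    stopifnot(substr(out, p, p + nchar(tref) - 1L) == tref)
    out <- paste0(substr(out, 1L, p - 1L), tvariants$talt[i],
                  substr(out, p + nchar(tref), nchar(out)))
  }
  out
}

#' Generate a synthetic cohort bundle with ground truth
#'
#' Writes a genome FASTA, a GTF annotation, a fully phased multi-sample VCF,
#' a sample-to-population map, a pathogenicity probability table for the
#' missense variants and a variant-id set file (the stop-gain and frameshift
#' ids, a stand-in for a curated risk-variant list), all under `dir`. The
#' returned ground truth lists, per transcript, every designed haplotype's
#' exact edited CDS (computed by descending-coordinate application,
#' independent of the pipeline's shift tracker), protein, flags, QC status,
#' designed probability and realized chromosome count.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `truth` (ground-truth
#'   structure) and `spec`.
#' @export
generate_cohort <- function(spec, dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, generate_cohort_impl(spec, dir))
}

generate_cohort_impl <- function(spec, dir) {
  n_total <- sum(spec$n_samples)
  samples <- sprintf("S%03d", seq_len(n_total))
  popmap <- setNames(rep(names(spec$n_samples), spec$n_samples), samples)

  designs <- list()
  for (i in seq_along(spec$transcripts)) {
    d <- design_transcript(sprintf("T%d", i), spec$transcripts[[i]])
    designs[[d$tx_id]] <- finalize_strand(d)
  }

  labels <- names(spec$haplotype_probs)
  # per transcript, per chromosome copy: designed haplotype label
  draws <- lapply(designs, function(d)
    matrix(sample(labels, 2L * n_total, replace = TRUE,
                  prob = spec$haplotype_probs),
           nrow = 2L, ncol = n_total))

  # ---- genome FASTA ----
  fasta <- file.path(dir, "genome.fa")
  lines <- unlist(lapply(designs, function(d)
    c(paste0(">chr", d$tx_id), d$chrom)))
  writeLines(lines, fasta)

  # ---- GTF ----
  gtf <- file.path(dir, "annotation.gtf")
  gtf_lines <- character(0)
  for (d in designs) {
    attrs <- sprintf(paste0('gene_id "G%s"; transcript_id "%s"; ',
                            'gene_name "GENE%s"; transcript_support_level "1";'),
                     d$tx_id, d$tx_id, d$tx_id)
    chrom <- paste0("chr", d$tx_id)
    st <- d$layout$strand
    row <- function(type, s, e, frame = ".")
      paste(chrom, "haploscore", type, s, e, ".", st, frame, attrs,
            sep = "\t")
    gtf_lines <- c(gtf_lines,
                   row("transcript", min(d$exon_starts), max(d$exon_ends)))
    for (k in seq_along(d$exon_starts))
      gtf_lines <- c(gtf_lines, row("exon", d$exon_starts[k], d$exon_ends[k]))
    cum <- cumsum(c(0L, d$chunk_len))
    phases <- (3L - cum[-length(cum)] %% 3L) %% 3L
    if (st == "-") phases <- rev(phases)  # cds rows are genome-sorted
    for (k in seq_along(d$cds_starts))
      gtf_lines <- c(gtf_lines,
                     row("CDS", d$cds_starts[k], d$cds_ends[k], phases[k]))
  }
  writeLines(gtf_lines, gtf)

  # ---- phased VCF ----
  vcf <- file.path(dir, "cohort.vcf")
  vcf_lines <- c("##fileformat=VCFv4.2",
                 vapply(designs, function(d)
                   sprintf("##contig=<ID=chr%s,length=%d>", d$tx_id,
                           nchar(d$chrom)), character(1)),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t"))
  for (d in designs) {
    dr <- draws[[d$tx_id]]
    v <- d$variants[order(d$variants$gpos), , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      lab <- v$label[i]
      carried <- vapply(labels, function(l) lab %in% .design_sets[[l]],
                        logical(1))
      gts <- paste(as.integer(carried[dr[1, ]]),
                   as.integer(carried[dr[2, ]]), sep = "|")
      vcf_lines <- c(vcf_lines,
                     paste(c(paste0("chr", d$tx_id), v$gpos[i], v$id[i],
                             v$gref[i], v$galt[i], ".", "PASS", ".", "GT",
                             gts), collapse = "\t"))
    }
  }
  writeLines(vcf_lines, vcf)

  # ---- population map ----
  popmap_path <- file.path(dir, "popmap.tsv")
  data.table::fwrite(data.frame(sample = samples,
                                population = unname(popmap)),
                     popmap_path, sep = "\t")

  # ---- pathogenicity table for missense variants ----
  am_path <- file.path(dir, "am_table.tsv")
  k <- 50
  am_rows <- do.call(rbind, lapply(designs, function(d) {
    C <- d$layout$n_codons
    data.frame(transcript_id = d$tx_id,
               variant_id = d$variants$id[d$variants$label == "mis"],
               protein_change = sprintf("E%dQ", C - 3L),
               probability = round(rbeta(1, spec$am_mean * k,
                                         (1 - spec$am_mean) * k), 6),
               stringsAsFactors = FALSE)
  }))
  am_rows$class <- ifelse(am_rows$probability < 0.34, "benign",
                          ifelse(am_rows$probability <= 0.564, "ambiguous",
                                 "pathogenic"))
  data.table::fwrite(am_rows, am_path, sep = "\t")

  # ---- variant-id set (designed "impactful" variants) ----
  set_path <- file.path(dir, "variant_set.txt")
  ids <- unlist(lapply(designs, function(d)
    d$variants$id[d$variants$label %in% c("stopgain", "fs")]))
  writeLines(sort(unname(ids)), set_path)

  # ---- ground truth ----
  truth <- list(transcripts = list(), popmap = popmap,
                n_chromosomes = 2L * n_total,
                haplotype_probs = spec$haplotype_probs)
  for (d in designs) {
    dr <- draws[[d$tx_id]]
    haps <- list()
    for (l in labels) {
      vl <- d$variants[match(.design_sets[[l]], d$variants$label), ,
                       drop = FALSE]
      vl <- vl[order(vl$tpos), , drop = FALSE]
      key <- if (nrow(vl) == 0L) "WT" else
        paste(sprintf("%d:%s>%s", vl$tpos, vl$tref, vl$talt), collapse = ";")
      edited <- apply_variants_desc(d$cds, vl)
      pf <- build_proteoform(d$cds, vl, downstream = d$utr3,
                             transcript_id = d$tx_id, haplotype_key = key)
      stopifnot(identical(pf$dna, edited))
      pf <- qc_filter(pf)
      haps[[l]] <- list(label = l, key = key,
                        variant_ids = vl$id,
                        edited_cds = edited, protein = pf$protein,
                        flags = sort(pf$flags),
                        qc_pass = pf$qc$pass,
                        prob = unname(spec$haplotype_probs[l]),
                        realized_count = sum(dr == l))
    }
    truth$transcripts[[d$tx_id]] <- list(
      transcript_id = d$tx_id, strand = d$layout$strand, cds = d$cds,
      downstream = d$utr3, variants = d$variants, haplotypes = haps)
  }

  list(paths = list(fasta = fasta, gtf = gtf, vcf = vcf,
                    popmap = popmap_path, am_table = am_path,
                    variant_set = set_path),
       truth = truth, spec = spec)
}

#' Check pipeline output against a cohort's ground truth
#'
#' Compares haplotype keys, realized counts/frequencies (exactly), designed
#' frequencies (within a binomial tolerance), proteins, flags and QC status
#' of a [hap_build()] table against the generator's ground truth. An empty
#' report means the pipeline reproduced the design.
#'
#' @param bundle Result of [generate_cohort()].
#' @param build_table data.frame from [hap_build()] run on the bundle files.
#' @param min_global_freq Retention threshold used in the build
#'   (default 0.005).
#' @param se_mult Binomial tolerance in standard errors for designed
#'   frequencies (default 3).
#' @return data.frame of mismatches (zero rows = pass) with columns
#'   `transcript_id`, `haplotype`, `field`, `expected`, `observed`.
#' @export
ground_truth_check <- function(bundle, build_table,
                               min_global_freq = 0.005, se_mult = 3) {
  mism <- list()
  note <- function(tx, key, field, exp, obs)
    mism[[length(mism) + 1L]] <<- data.frame(
      transcript_id = tx, haplotype = key, field = field,
      expected = as.character(exp), observed = as.character(obs),
      stringsAsFactors = FALSE)
  n_chrom <- bundle$truth$n_chromosomes
  n_samp <- n_chrom / 2
  for (tx in names(bundle$truth$transcripts)) {
    tt <- bundle$truth$transcripts[[tx]]
    rows <- build_table[build_table$transcript_id == tx, , drop = FALSE]
    for (h in tt$haplotypes) {
      freq <- h$realized_count / n_chrom
      retained <- h$key == "WT" || freq >= min_global_freq
      obs <- rows[rows$haplotype == h$key, , drop = FALSE]
      if (!retained) {
        if (nrow(obs) > 0L) note(tx, h$key, "retained", FALSE, TRUE)
        next
      }
      if (nrow(obs) != 1L) { note(tx, h$key, "present", 1, nrow(obs)); next }
      if (abs(obs$freq_global - freq) > 1e-12)
        note(tx, h$key, "freq_exact", freq, obs$freq_global)
      se <- sqrt(h$prob * (1 - h$prob) / (2 * n_samp))
      if (h$prob > 0 && abs(obs$freq_global - h$prob) > se_mult * se)
        note(tx, h$key, "freq_designed", h$prob, obs$freq_global)
      if (!identical(obs$protein, h$protein))
        note(tx, h$key, "protein", h$protein, obs$protein)
      obs_flags <- sort(strsplit(obs$flags, ",", fixed = TRUE)[[1]])
      if (!identical(obs_flags, h$flags))
        note(tx, h$key, "flags", paste(h$flags, collapse = ","), obs$flags)
      qc_obs <- obs$qc == "pass"
      if (!identical(qc_obs, h$qc_pass))
        note(tx, h$key, "qc", h$qc_pass, qc_obs)
    }
  }
  if (length(mism)) do.call(rbind, mism) else
    data.frame(transcript_id = character(0), haplotype = character(0),
               field = character(0), expected = character(0),
               observed = character(0), stringsAsFactors = FALSE)
}
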