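#' Read phased genotypes from a multi-sample VCF
#'
#' Loads a diploid multi-sample VCF and returns per-site, per-sample allele
#' assignments split by chromosome copy. Multi-allelic records are decomposed
#' into biallelic variants at read time, with allele indices greater than one
#' remapped onto the decomposed records (a `1|2` genotype at an `A>G,T` site
#' becomes allele 1 of `A>G` on the first chromosome copy and allele 1 of
#' `A>T` on the second). Records with symbolic or non-ACGT alleles are
#' dropped with a warning.
#'
#' Unphased or missing genotypes are flagged, not repaired: downstream
#' haplotype counting treats unphased heterozygotes as missing rather than
#' pseudo-phasing them, so frequencies are never corrupted by arbitrary
#' phase assignments.
#'
#' @param path Path to a VCF (optionally gzipped) with a GT field for every
#'   sample.
#' @param region Optional region restriction, either a string
#'   `"chrom:start-end"` or a list with elements `chrom`, `start`, `end`.
#'   Sites whose POS falls outside the region are dropped (equivalent to
#'   reading everything and filtering).
#' @return An object of class `phased_genotypes`: a list with
#'   \describe{
#'     \item{samples}{character vector of sample names;}
#'     \item{variants}{data.frame of decomposed biallelic variants with
#'       columns `chrom`, `pos`, `id`, `ref`, `alt`;}
#'     \item{hap_a, hap_b}{integer matrices (sites x samples) of allele
#'       indices, 0 = reference, 1 = alternative, `NA` = missing;}
#'     \item{phased}{logical matrix, `TRUE` where the genotype was phased.}
#'   }
#' @export
read_phased_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(empty_phased_genotypes(colnames(vcf@gt)[-1] %||% character(0)))
  }
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2L)
    stopf("VCF has no sample genotype columns: %s", path)
  fmt <- gt_mat[, 1L]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt))
    stopf("GT field absent from FORMAT at VCF record %d",
          which(!has_gt)[1])
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  samples <- colnames(gt_mat)[-1L]

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    reg <- parse_region(region)
    pos <- as.integer(fix[, "POS"])
    keep <- fix[, "CHROM"] == reg$chrom & pos >= reg$start & pos <= reg$end
  }

  out_var <- list(); out_a <- list(); out_b <- list(); out_ph <- list()
  for (r in which(keep)) {
    ref <- toupper(fix[r, "REF"])
    alts <- toupper(strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]])
    if (!is_dna(ref) || !all(is_dna(alts))) {
      warnf("dropping record %s:%s with non-ACGT alleles",
            fix[r, "CHROM"], fix[r, "POS"])
      next
    }
    gts <- gt_mat[r, -1L]
    gts <- vapply(strsplit(gts, ":", fixed = TRUE), function(g) {
      if (length(g) >= gt_idx[r]) g[gt_idx[r]] else "."
    }, character(1))
    parsed <- parse_gt(gts)
    for (k in seq_along(alts)) {
      if (alts[k] == ref) next
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        id = ifelse(is.na(fix[r, "ID"]) || fix[r, "ID"] == ".", "",
                    fix[r, "ID"]),
        ref = ref, alt = alts[k], stringsAsFactors = FALSE)
      out_a[[length(out_a) + 1L]] <- as.integer(parsed$a == k)
      out_b[[length(out_b) + 1L]] <- as.integer(parsed$b == k)
      out_ph[[length(out_ph) + 1L]] <- parsed$phased
    }
  }
  if (length(out_var) == 0L) return(empty_phased_genotypes(samples))
  variants <- do.call(rbind, out_var)
  rownames(variants) <- NULL
  structure(list(
    samples = samples,
    variants = variants,
    hap_a = do.call(rbind, out_a),
    hap_b = do.call(rbind, out_b),
    phased = do.call(rbind, out_ph)
  ), class = "phased_genotypes")
}

empty_phased_genotypes <- function(samples) {
  structure(list(
    samples = samples,
    variants = data.frame(chrom = character(0), pos = integer(0),
                          id = character(0), ref = character(0),
                          alt = character(0), stringsAsFactors = FALSE),
    hap_a = matrix(integer(0), 0, length(samples)),
    hap_b = matrix(integer(0), 0, length(samples)),
    phased = matrix(logical(0), 0, length(samples))
  ), class = "phased_genotypes")
}

parse_region <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stopf("malformed region string '%s'", region)
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  } else if (is.list(region)) {
    list(chrom = region$chrom, start = as.integer(region$start),
         end = as.integer(region$end))
  } else stopf("region must be a string or list")
}

# parse GT strings into diploid allele index pairs + phased flag
parse_gt <- function(gts) {
  n <- length(gts)
  a <- rep(NA_integer_, n); b <- rep(NA_integer_, n)
  phased <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- gts[i]
    if (is.na(g) || g == "." || g == "") next
    ph <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L) next  # non-diploid: treated as missing
    phased[i] <- ph
    if (parts[1] != ".") a[i] <- as.integer(parts[1])
    if (parts[2] != ".") b[i] <- as.integer(parts[2])
  }
  list(a = a, b = b, phased = phased)
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d sites x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}
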