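---
title: "Methods: haplotype-resolved proteoforms and fitness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved proteoforms and fitness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscore)
```

## Scope and model

`haploscore` turns phased diploid cohort genotypes into haplotype-resolved
protein sequences and fitness summaries. The underlying model is simple and
deliberately literal: a diploid sample contributes two chromosome copies;
within one transcript, the alternative alleles carried by one copy across
the transcript's coding variant sites form one haplotype; the protein that
haplotype encodes is obtained by editing the wild-type CDS and translating
it under explicit rules for disruptive variants. Everything downstream
(frequencies, retention, scoring, group statistics) is arithmetic over
these reconstructed proteoforms.

The package assumes its inputs are what they claim to be: a VCF whose GT
fields are phased where they matter, an annotation whose CDS intervals are
complete (models failing exon/CDS containment are rejected as incomplete),
and a reference matching both. Every variant's reference allele is
validated twice — once against the reference-derived CDS at mapping time
and once at its shifted position at application time — so coordinate
errors surface as named validation errors rather than silent corruption.

## Coordinate conventions

External formats keep their native conventions (VCF and GTF are 1-based
inclusive); all conversion happens at the I/O boundary, and transcript
coordinates (`tpos`) are 1-based positions in the 5′→3′ CDS. On
minus-strand transcripts, alleles are reverse-complemented and `tpos`
addresses the first affected base in transcript orientation, so a genomic
REF span `[g1, g2]` maps to `tpos = t(g2)`. A variant is mapped only when
its REF span lies entirely within the CDS intervals; a deletion crossing a
CDS/intron boundary is excluded rather than partially applied.

## Haplotype counting decisions

Several choices here were genuinely open and are worth stating:

* **Missing and unphased genotypes.** A chromosome copy with any missing
  allele at the transcript's sites — or belonging to a sample with an
  unphased heterozygote there — is excluded from both numerator and
  denominator. Arbitrarily phasing a `0/1` would fabricate haplotypes;
  excluding only the copy keeps the estimator unbiased for the remaining
  chromosomes. On fully phased cohort releases this choice is inert.
* **Overlapping variants on one chromosome copy** are contradictory
  phasing (two alternative alleles claiming the same CDS bases); the copy
  is excluded with a logged warning rather than resolved by an arbitrary
  application order.
* **Keys** are canonical — variants sorted by `tpos`, joined as
  `"tpos:tref>talt"` with semicolons, `"WT"` for the empty set — which
  guarantees cross-run identity of haplotype identifiers.
* **The retention filter** (global frequency ≥ 0.5%, wild type always
  kept) is applied after frequency computation and frequencies are *not*
  renormalised afterwards: reported values remain cohort frequencies, and
  denominators include chromosomes carrying rare, unretained haplotypes.
* A population with zero included chromosomes gets `NA` frequencies — an
  undefined estimate is not a zero estimate.

## Translation edge rules

Edits are applied 5′→3′ with a cumulative shift tracker (the summed length
difference of preceding edits is added to each coordinate); this is
provably equivalent to descending-coordinate application without tracking,
and the test suite asserts that equivalence on 1000 random fixtures per
run. Translation is a codon walk with the standard genetic code (table 1
only; selenocysteine and other recodings are unsupported):

* a stop codon with at least one full codon of CDS remaining after it is a
  premature stop (`truncated_premature_stop`); a stop in the last complete
  codon is a normal terminus;
* when the annotated ATG is destroyed, the *edited* CDS is scanned at
  offsets 0, 3, 6, … for the next in-frame ATG — out-of-frame ATGs are
  ignored, because "in frame" is only meaningful relative to the annotated
  frame. If none exists the proteoform is emitted with `qc = fail:no_start`
  rather than dropped, so exclusion counts stay auditable;
* frameshifts need no dedicated machinery: after editing, the codon walk
  simply reads the shifted frame. When translation reaches the CDS end
  without a stop — frameshift or stop-loss alike — it continues into a
  caller-supplied 3′ sequence (the pipeline passes the transcript's 3′UTR)
  until the first stop (`extended_readthrough`); with no such sequence the
  walk ends with `no_stop_reached`. Both behaviours are expressible and
  flagged because annotation sources differ in whether UTR sequence is
  available;
* trailing bases short of a codon are ignored.

Consequence labels (`synonymous`, `missense`, `stop_gained`, `stop_lost`,
`start_lost`, `inframe_insertion`, `inframe_deletion`, `frameshift`) are
computed internally by applying each variant alone and diffing against the
wild type, with precedence start-loss → frame change → stop gain/loss →
in-frame length change → residue identity. In-frame indels that also
introduce a premature stop are labelled by their length change; the
haplotype-level flag set still records the truncation.

QC bounds are inclusive: proteins of 10–4000 amino acids pass; 9 and 4001
fail. The lower bound discards fragments too short to score meaningfully;
the upper bound reflects the practical context length of current protein
language models.

## Scoring

A scorer is any function mapping a protein string to a finite real PLL;
the package treats it as a black box behind `new_scorer()`. The shipped
unigram scorer (`PLL = Σ log p(residue)`, uniform by default) is exactly
computable, which is what the identity tests need; it is *not* a fitness
model — under the uniform table PLL is a pure length measure, so
truncating variants score *higher*. Real protein language model adapters
(masked-marginal, autoregressive forward/backward averaging,
structure-conditioned) implement the same contract and are out of the
package's computational scope.

PLL is cached per distinct protein sequence, so haplotypes encoding
identical proteins (e.g. synonymous-only) are scored once; caching is
output-transparent. `PLLR_wt` subtracts the wild-type PLL; `PLLR_mf`
subtracts the most-frequent haplotype's PLL, with a deterministic
tie-break — highest global frequency, then wild type, then
lexicographically smallest key. `PLL_delta` is max − min PLL over the
transcript's retained haplotypes, zero for single-haplotype transcripts.
Scorer failure on any sequence leaves that transcript unscored for that
model and touches nothing else. In-memory scores are full doubles; TSV
output rounds doubles to 6 significant digits.

Pathogenicity probabilities are aggregated per haplotype on the log-odds
scale, `s = ln(s̃ / (1 − s̃))`, as both mean and sum; the domain is the
open interval (0, 1) and boundary values are rejected rather than clamped,
since a probability of exactly 0 or 1 in such tables indicates upstream
rounding that the caller should resolve deliberately.

## Group statistics

The bootstrap of the median uses same-size resampling with replacement,
100 replicates by default, fully determined by an integer seed; the median
of an even-length sample is the mean of the two central order statistics.
Two groups are resampled independently (seeds `seed` and `seed + 1`) and
summarised by each group's median of replicate medians plus the fraction
of replicate pairs where the first group's median is lower. No named test
statistic is computed — the replicate distributions themselves are the
deliverable, and the overlap fraction is a descriptive effect direction,
not a p-value. Pearson correlations (with the usual t-transform p-value)
drop incomplete pairs listwise and return an undefined marker on
zero-variance input.

## The synthetic cohort generator

`generate_cohort()` exists so that every claim the package makes is
checkable without downloads. Each designed transcript carries a fixed
variant panel — synonymous, missense (placed in the last exon to exercise
multi-exon offset arithmetic), stop-gain, start-loss (with a rescue ATG
planted at codon 9), an in-frame single-codon deletion and a 1-bp
frameshift insertion — and designed haplotypes combine these panels.
Chromosome copies draw their haplotype i.i.d. from a categorical
distribution, so designed frequencies are exact sampling targets and the
binomial standard error is the correct recovery tolerance (the default
check is 3 SEs at 500 samples). Ground truth (edited CDS, protein, flags,
QC, realized counts) is computed by descending-coordinate application — a
different code path from the pipeline's shift tracker — at generation
time.

What the generator emulates: phased diploid genotypes over multi-exon
plus- and minus-strand transcripts, canonical GT–AG splice boundaries,
UTRs (the 3′UTR contains stops in all three frames so readthrough always
terminates), population structure as frequency strata, a Beta-distributed
pathogenicity table for the missense variants. What it does not emulate:
linkage from recombination history (haplotypes are drawn, not evolved),
mutation-rate heterogeneity, sex chromosomes and hemizygosity, overlapping
genes, splice-site variants, and real LD between transcripts. Passing
tests therefore demonstrate correctness of the reconstruction arithmetic,
not robustness to annotation pathologies absent from the fixtures; the
GTF convention used by the generator includes the terminal stop codon in
the CDS, and annotations that exclude it (separate `stop_codon` features)
will yield wild types flagged `no_stop_reached`.

## Problem sizes and runtime choices

The test suite runs the oracle-equivalence property on 1000 random edit
fixtures and the whole-chromosome strand oracle on 200 minus-strand
fixtures per run; frequency recovery is checked on a 500-sample,
five-population cohort; the independence bound for Pearson correlation
uses 10 000 simulated pairs; bootstrap convergence uses 10 000 replicates
on a symmetric fixture. These sizes make the probabilistic bounds tight
(3 binomial SEs, |r| < 0.05) while keeping the default suite under a
minute of compute. `scripts/acceptance.R` re-runs the same computations
from scratch at the same sizes with all randomness derived from its
`--seed` flag.

## Known limitations

Ploidy is fixed at two and hemizygous calls are treated as given in the
VCF. Multi-allelic records are decomposed at read time, but indel
normalisation (left-alignment) is assumed done upstream. Splice-site,
UTR-regulatory and NMD effects are out of scope, as are statistical
phasing, LD computation and frequency confidence intervals. The scorer
registry is process-local; deterministic scorers are required for the
package's bit-reproducibility guarantee, and a stochastic plugin forfeits
it for its own columns.
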