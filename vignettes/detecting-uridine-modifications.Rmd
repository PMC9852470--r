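---
title: "Detecting uridine modifications from nanopore direct RNA sequencing"
author: "psiNano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uridine modifications from nanopore direct RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiNano)
```

## The problem and the signal

Pseudouridine (ψ) is the most abundant internal mRNA modification, yet it
is invisible to hybridization (it base-pairs like U) and to mass
spectrometry of digested nucleotides (same mass as U). Nanopore direct
RNA sequencing reads native molecules, and a ψ in the pore perturbs the
current enough that the basecaller systematically miscalls it — most
informatively as a U-to-C mismatch against the reference. psiNano turns
that artifact into a site-level modification caller.

The essential control is an in-vitro-transcribed (IVT) copy of the same
transcriptome. IVT RNA contains only canonical nucleotides, so any
U-to-C mismatch in the IVT library is basecalling or alignment error,
not modification. Everything in the caller reduces to one comparison:
is the U-to-C mismatch in the native (direct) library larger than what
the IVT control predicts for that position?

## The statistical model

Let a uridine site have read depth $N$ in a direct replicate, of which
$N_{mm}$ call C, and let $p_0$ be the expected U-to-C error of the
unmodified site. The per-replicate significance is the binomial upper
tail

$$p(N, N_{mm}, p_0) \;=\; \sum_{k=N_{mm}}^{N} \binom{N}{k}
p_0^{\,k} (1 - p_0)^{\,N-k},$$

computed through the binomial survival function (the regularized
incomplete beta route), which stays accurate at depths of $10^5$ and
beyond — relevant for rRNA-like inputs. Exact enumeration in the test
suite confirms agreement to $10^{-12}$ relative error for all $N \le
200$ over a grid of $p_0$.

### The expected error $p_0$

Basecaller error is strongly sequence dependent, so $p_0$ is conditioned
on the centered 5-mer (the modified U at position 3, read 5'→3' in
transcript orientation; minus-strand sites are reverse complemented).
From the merged IVT replicates the package pools, per 5-mer, the
read-weighted error over every uridine site with at least 7 reads. The
read-weighted (rather than per-site averaged) estimate matches the
binomial model's per-read error interpretation and is stable when many
contributing sites are shallow. A 5-mer with fewer than 10 contributing
sites falls back to the global pooled error.

The site's $p_0$ is then the **maximum** of

* the 5-mer (or global fallback) pooled error,
* the site-specific IVT mismatch, when the merged IVT covers the site
  with at least 7 reads, and
* a floor of $1/(n_{reads}+2)$, an add-one-style guard that keeps the
  test non-degenerate when an estimate is exactly zero.

Taking the maximum makes the test conservative by construction: a site
whose own IVT control misbehaves is tested against its own elevated
error. It also self-suppresses SNPs, which in addition are flagged
explicitly: a site whose merged IVT mismatch is at least 0.20 *and*
whose direct and IVT fractions are statistically indistinguishable
(two-proportion z-test at $\alpha = 0.05$) is reported as SNP-like and
never called. The 0.20/z-test rule is this package's concrete rendering
of the "equivalent mismatch in both libraries" principle; the threshold
is deliberately permissive because the max-rule already disarms such
sites.

### Filters and consensus

Only primary alignments with MAPQ ≥ 20 contribute. Up to 3 aligned
bases adjacent to a soft-clipped read end are masked (clip-adjacent
bases have degraded quality); hard clips trigger the same mask, since
the clipped sequence is equally absent. Deletions at a site count
toward depth but never toward the mismatch — a deleted base is evidence
of sequencing, not of C. Insertions and read-space N calls are ignored.
Base quality is deliberately not used as a per-base filter.

A site is eligible when every direct replicate and the merged IVT reach
7 reads. With $R$ direct replicates, consensus requires $\lceil
\tfrac{2}{3} R \rceil$ replicates at $p \le 0.01$ (2-of-3 for $R = 3$,
2-of-2 for $R = 2$, 1-of-1 for $R = 1$). The significance tier comes
from the $k$-th smallest replicate p-value with $k$ the quorum size, so
`highly_significant` means the same quorum reached $p \le 0.001$; this
makes tiers monotone with the consensus rule, which per-replicate
thresholding alone would not guarantee. Cutoffs are inclusive. No
multiple-testing correction is applied — the manifest records the number
of tested sites so users can correct downstream.

## Hypermodification and transcript anatomy

Synthetic full-length RNA controls carrying a single ψ at natural sites
show that the basecaller *under-calls* the modification: a fully
modified site yields roughly 30–70% U-to-C mismatch depending on
sequence context, not 100%. Mismatch is therefore a semi-quantitative
occupancy proxy, and the package does not attempt absolute occupancy
estimation. Two operational classes follow:

* **Type I**: a called site with merged direct mismatch strictly above
  40% — given under-calling, approximately "half or more copies
  modified".
* **Type II**: a transcript with two or more unique highly significant
  positions.

Called sites are placed on transcript anatomy (5'UTR/CDS/3'UTR, or
`noncoding`) through an Ensembl-dialect GTF. When isoforms overlap, the
site is assigned to the *dominant isoform*: the transcript whose exon
chain is compatible with the most site-covering reads (blocks within
exons, junction gaps matching introns), ties broken by transcript
length then identifier. This is a deliberate, download-free
simplification of full isoform inference; externally computed
read-to-isoform assignments can be substituted by the caller. Splice
distance is measured in spliced transcript coordinates — the natural
scale for comparison with UTR/CDS lengths — as the distance to the
nearest exon–exon junction boundary, and is absent for single-exon
transcripts. 5-mers are tagged with the ψ-synthase motifs UGUAG (PUS7)
and GUUCN (TRUB1), and a position frequency matrix over a ±6 nt window
summarizes sequence context.

## Single-molecule co-modification

For transcripts with several called sites, long reads covering multiple
positions let us ask whether modifications co-occur on the same
molecule. The read-by-site matrix records `C`, `U`, `other` (A/G/
deletion) or `uncovered` per read and site, under the same read filters
as the pileup. The co-modification fraction of a site pair is the
fraction of *co-covering* reads calling C at both positions; marginals
use the same denominator, keeping single-read statistics consistent with
the pileup `mismatch_frac` convention. Sites are numbered 5'-most
first. Across transcripts with exactly two highly significant sites, an
OLS $R^2$ between position-1 and position-2 mismatch quantifies
cross-site dependence; independent errors give $R^2$ near zero.

## What the simulator emulates — and what it does not

The generator produces, deterministically per seed, a reference of
transcripts embedded in synthetic contigs (1–5 exons, introns of
50–200 nt, CDS on 80% of transcripts, both strands), an Ensembl-dialect
GTF, and SAM alignments for any number of direct and IVT replicates.
Reads are 3'-anchored with a configurable fraction truncated at a
uniform 5' point, reproducing the 5'-coverage decay of direct RNA
sequencing; transcript lengths are log-normal with median 670 nt and
sdlog 0.45, which places the N50 near 850 nt, matching typical direct
RNA read-length summaries. Per read and uridine, the call is C with the
5-mer background rate (default 2.64% everywhere, with overrides
CUUUG = 10% and AAUCU = 0.4% reflecting the observed extremes of
k-mer-dependent error); at a truth site of a direct library the
molecule is modified with probability `occupancy` and a modified base
is miscalled C with probability `efficiency` — the measured synthetic
controls ranged from 30% to 70%, and 0.7 is used as the canonical
high-efficiency case in validation. IVT libraries force occupancy 0.
Soft clips of 1–5 nt are injected at read ends with probability 0.2 per
end, and 2% of reads carry MAPQ 10 to exercise the filters. Random
draws use per-replicate substreams, so adding a replicate never
perturbs earlier ones.

Deliberately not modelled: signal-space (squiggle) behaviour,
homopolymer-specific error, quality-score realism, alignment error, and
long-range sequence effects on basecalling. Consequently, passing tests
demonstrate the *statistical machinery* — counting, background
estimation, test calibration, classification, co-modification — under a
faithful basecall-level error model; they cannot certify performance
against idiosyncrasies of a particular basecaller or aligner on real
signal.

## Numerical and design choices

* Coordinates are 0-based half-open internally (BAM arithmetic); TSV
  outputs add a 1-based column matching the usual `chr:pos` site names.
* The binomial tail is computed in log space via the survival function;
  `P[X >= 0]` is exactly 1 and `p0 = 0` yields exactly 0 for any
  positive mismatch count.
* The k-mer table keys are transcript-space 5-mers over {A,C,G,U} with
  U at the center (at most 256 entries); sites within 2 nt of a contig
  end or with an N in the window are skipped.
* Reference lowercase (soft-masked) bases are treated as valid; N bases
  are skipped — soft-masking is annotation, not ambiguity.
* Merging replicates sums counts and recomputes the pooled fraction; a
  pooled fraction, not a mean of per-replicate fractions.
* Degenerate inputs are defined, not fatal: empty site overlap yields an
  empty call set with a valid manifest; a site pair with no co-covering
  reads reports an absent fraction with count 0; fewer than 3 two-site
  transcripts (or zero variance) yields an absent $R^2$.
* Validation problem sizes were chosen to give tight statistical checks
  at desk scale: ~200 IVT sites per k-mer at 50x for background
  recovery (3 binomial SE bounds), >500 eligible null sites for the
  false-positive rate (observed conservative, well under the nominal
  0.01 because of the max-rule $p_0$ and binomial discreteness), 100
  planted sites for power, and 2000 co-covering reads for the
  co-modification check.

## Known limitations

* The method cannot distinguish ψ from other uridine modifications that
  produce U-to-C miscalls (e.g. dihydrouridine); motif enrichment is
  suggestive, not conclusive.
* Mismatch is a lower bound on occupancy; absolute stoichiometry would
  require per-context calibration curves from synthetic controls.
* Isoform assignment uses a majority-compatibility rule, not full
  isoform quantification; shared sites between isoforms of one gene are
  grouped by the dominant isoform.
* The caller consumes alignments as given; systematic misalignment
  (e.g. around splice junctions) propagates into the counts of both
  libraries, and is only partially absorbed by the site-specific IVT
  term.
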