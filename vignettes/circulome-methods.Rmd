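---
title: "Detecting eccDNA from tagmentation sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eccDNA from tagmentation sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circulome)
```

## The problem

Extrachromosomal circular DNA (eccDNA) consists of covalently closed DNA
circles derived from the linear chromosomes. Because a circle's sequence is
(by construction) also present in the linear genome, sequencing reads from
circles are indistinguishable from genomic reads by sequence content alone.
Two experimental handles make them detectable:

1. **Biochemical enrichment.** Exonuclease V degrades linear DNA but spares
   covalently closed circles, so an exoV-treated library is strongly enriched
   for circle-derived molecules relative to an untreated total-genomic
   control from the same specimen.
2. **A structural fingerprint from Tn5 tagmentation.** Every Tn5 insertion
   duplicates 9 bp of target sequence on both sides of the cut. A circle
   that receives *exactly one* insertion linearizes into a fragment whose two
   termini are copies of the same 9-mer; with standard inward-facing
   paired-end chemistry, the first 9 bases of R1 then equal the reverse
   complement of the first 9 bases of R2. Linear molecules never produce this
   configuration except by chance.

`circulome` implements the computational side of this design: a
topology-aware simulator, the 9-bp signature detector, k-mer classification
of reads over unique and repetitive genome space, and a binned enrichment
caller comparing the circle-enriched fraction against its matched control.

## The tagmentation model

Cuts follow a homogeneous Poisson process at rate $\lambda$ per bp (default
$\lambda = 0.004$, a mean fragment length of about 250 bp, typical for
Nextera-style libraries). A cut at position $p$ with duplication length $d$
(default 9) hands bases $[p, p+d)$ to both flanking fragments, so

* consecutive fragments of a linear molecule overlap in exactly $d$ bases,
* the total fragment length is the molecule length plus $d$ times the number
  of cuts, and
* a circle of length $L$ cut once yields one linear molecule of length
  $L + d$ whose first $d$ bases equal its last $d$ bases.

These three conservation laws are the package's tagmentation invariants and
are tested by reassembling fragments after collapsing one duplication copy
per junction. The attenuated reaction (short incubation) is modeled as
"exactly one cut per circle" rather than as a kinetic parameter, because the
signature logic is defined for the single-cut case; the multi-cut regime
remains reachable through $\lambda$ with `attenuated = FALSE`. Insertion-bias
models of Tn5 are deliberately out of scope.

Reads are error-free by default, which keeps the signature analysis
analytic: an exact-match detector has a per-pair chance positive rate of
$4^{-9} \approx 3.8\times10^{-6}$, and perfect sensitivity on singly cut
circles whenever the read length exceeds $d$. A uniform substitution rate
and a `max_mismatch` detector mode exist for error-bearing data, at the cost
of that analytic bound.

## The signature statistics

For a sample of read pairs, `signature_fraction()` reports the percentage of
pairs whose mate starts match as reverse complements over the first 9 bases
— the fraction of captured incidents that are singly tagmented circles. The
fold enrichment of a sample over its matched total-genomic control is the
plain ratio of these fractions (`signature_fold_enrichment()`). We
deliberately compute the ratio of the reported fractions as printed, rather
than reverse-engineering unrounded inputs; with rounded inputs the ratio is
reproducible by inspection. The denominator counts *all* input pairs (no QC
subset is defined).

The comparison orientation (R1 start vs reverse complement of R2 start)
follows from inward-facing paired-end chemistry; a `orientation = "same"`
switch supports nonstandard preps.

## Read classification over repetitive genome space

Reads are placed with a canonical k-mer index (`k = 31` by default — a
standard odd length that excludes reverse-complement palindromes; the
classification result is insensitive to k for error-free reads because
placement is equivalent to exact full-read matching). A placement is
reported wherever every k-mer of the read occurs at the offset-consistent
genomic position, which for exact matching is implemented as: candidate
positions from the read's first k-mer, then full-read verification. The
equivalence of this route with brute-force substring search is a tested
invariant.

The placement set maps to the four field categories:

| category | rule |
|---|---|
| UNIQUE | exactly one placement |
| FOCAL_REPEAT | ≥ 2 placements, one chromosome, span ≤ 300 kb |
| INTRACHROMOSOMAL_REPEAT | ≥ 2 placements, one chromosome, span > 300 kb |
| DISPERSED_REPEAT | placements on ≥ 2 chromosomes |
| UNPLACEABLE | no exact placement |

The 300-kb focal range is the conventional cutoff for "locally repeated"
sequence and is exposed as a parameter; its only monotone effect is that
growing it can reclassify intrachromosomal repeats as focal. Span is
measured between outermost placement start positions (the literal "range of
base pair distance"). For positional tracks, unique reads count at their
placement and focal reads once at their span midpoint — deterministic and
unbiased within the family; intrachromosomal and dispersed repeats have no
single location and are tallied only in the composition. Where mate
categories must be combined, the pair takes the more repetitive mate's
category (a conservative choice). Deduplication of aligned pairs is keyed on
both mates' coordinates *and strands* by default; the strand-blind variant
is available as a switch (`strand_aware = FALSE`) since the original
bookkeeping is described only as "start/stop positional combinations".

## Enrichment calling

Reads are counted in fixed-width bins (1 kb suits worm-scale genomes, 25 kb
human-scale ones). For bin $i$ with sample count $s_i$ (library total $S$)
and control count $c_i$ (total $C$):

* **Point fold**: $((s_i/S))/((c_i/C))$; when $c_i = 0$ a pseudocount of 0.5
  replaces the control count (and is added to $s_i$) so the fold stays
  finite while remaining increasing in $s_i$. Bins empty in both libraries
  are untestable and skipped.
* **Exact two-tailed binomial p**: $P(X = k)$ summed over all $k$ with
  $P(X = k) \le P(X = s_i)$ for $X \sim \mathrm{Bin}(S, c_i/C)$ — the
  minimum-likelihood construction. The implementation locates the opposite
  tail boundary by bisection on the monotone flank of the pmf (so a call is
  $O(\log S)$, with upper tails computed via `lower.tail = FALSE` to avoid
  cancellation); exhaustive enumeration and `stats::binom.test()` serve as
  independent oracles in the tests. The doubled-smaller-tail construction
  was considered and rejected as the default because the minimum-likelihood
  version is the one computed by the field's standard exact test.
* **Robust fold bound**: the fold recomputed from the lower 95% Wilson score
  limit of $s_i/S$ and the upper limit of $c_i/C$ — the smallest fold
  consistent with expected binomial sampling variation in both counts. "A
  greater than fourfold enrichment robust to binomial variation" is read
  strictly: the *bound*, not the point fold, must clear the threshold.

A bin is called when the robust fold bound reaches `min_fold` (default 4)
**and** the p-value clears the correction policy. Two policies are
provided: Bonferroni over the tested bins at family-wise $\alpha = 0.05$
(the default; the procedure described as "two-tailed Bonferroni-corrected
false discovery rate of 0.05" conflates FWER and FDR, and Bonferroni is what
the name denotes), and a per-gene variant with fixed per-test threshold
$0.05/(2 \times n_\text{genes})$, conventionally paired with a twofold
minimum. A "Bayes maximum-likelihood" assessment is sometimes named for
this style of per-bin scan without an accompanying formula; the binomial
test plus robust fold bound is the implementable reading adopted here.

Two whole-track diagnostics accompany the calls: the mitochondrial
chromosome — circular in vivo, hence a built-in positive control — must show
whole-chromosome enrichment in a genuine circular fraction
(`mito_control_enrichment()`), and replicate reproducibility is summarized
as the Pearson correlation of $\log_{10}(\text{count}+1)$ across bins
(`replicate_log_coverage_correlation()`).

## What the simulator emulates — and what it does not

The generator plants focal, dispersed and intrachromosomal repeat families
as *exact* unit copies in random background sequence, plants circles as
genomic intervals carried at a chosen copy number, and models enrichment as
Bernoulli removal of each linear molecule copy with probability
$\varepsilon$ (circles, including the mitochondrial chromosome, always
survive). $\varepsilon = 0$ is the total-genomic control; $\varepsilon$ near
1 approximates the exoV-treated fraction. Because residual linear DNA after
real exoV treatment is not quantified, $\varepsilon$ is a free simulation
parameter, not a calibrated one.

Defaults define the desk-scale study conditions used throughout the test
suite: two 100-kb nuclear chromosomes and a 14-kb circular mitochondrial
chromosome at GC 0.36 (worm-like), read length 50, genome copy number 20,
planted 2-kb circles at tenfold copy number (200), $\varepsilon = 0.999$ for
the enriched fraction, and 1-kb bins. Oracle-equivalence suites run on
ensembles of ~10–20-kb genomes, where classification uses an explicitly
smaller focal range so that all four categories are realizable on a short
chromosome.

Passing tests on these simulations demonstrate the *mechanics* — signature
detection calibrated at its analytic rates, classification identical to
brute-force search, calibrated false-call control, recovery of planted
circles at high enrichment. They do not demonstrate robustness to
sequencing error, Tn5 insertion bias, PCR duplicates and chimeras, nearly
identical (rather than exact) repeat copies, or incomplete linear removal —
all features of real libraries that sit outside the simulator. On real data
the package expects an external aligner's output (SAM/BAM); the built-in
exact mapper exists to make small-genome tests self-contained and supports
no mismatches or gaps.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  conversion happens only at the SAM boundary, and BED stays 0-based.
* Circular molecules store an explicit rotation; rotation-invariant equality
  exists only in test helpers, keeping serialization deterministic.
* `N` bases are legal in references, never emitted by the simulator, and
  k-mers containing `N` are skipped by the index.
* Ties in the binomial tail comparison use the standard relative tolerance
  ($1 + 10^{-7}$) so equal-probability outcomes are not lost to rounding.
* A control fraction of zero makes a signature fold undefined; an `Inf`
  sentinel is returned only on explicit opt-in.
* Every stochastic operation takes an explicit seed; FASTQ output is
  byte-identical under a fixed seed.

## Problem sizes used by the checks

The bundled verification suites use: 10^4 tagmented molecules for the
duplication mechanics; 10^4 singly cut circles and 10^5 random pairs for
detector calibration; 100 seeded two-chromosome genomes (~20 kb) for the
classification oracle; 200 replicates of 1,000 bins × 10^5 reads for the
null calibration of the caller; and the default desk-scale study above for
planted-circle recovery. These sizes were chosen so each property is
measured at, or well beyond, the resolution of its acceptance threshold
while remaining a single-workstation computation.
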