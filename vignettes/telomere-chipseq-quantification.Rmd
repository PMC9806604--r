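---
title: "Quantifying chromatin marks at telomeres from ChIP-seq reads"
author: "telomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin marks at telomeres from ChIP-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomark)
```

## The problem

Plant telomeres are tandem arrays of the 7-bp unit CCCTAAA/TTTAGGG, roughly
3,750 bp per chromosome end in *Arabidopsis thaliana* Col-0. The same unit
also occurs at interstitial telomeric sequences (ITSs) scattered through the
chromosome arms and pericentromeres, so any assay that hybridises to or
aligns against telomeric repeats mixes the terminal and interstitial
compartments. That matters because subtelomeric and pericentromeric regions
are heterochromatic: a telomeric probe contaminated by ITSs inherits their
chromatin signal.

The read-level route around this is to exploit array length. ITSs contain
mostly short perfect stretches of the repeat interrupted by degenerate
copies, whereas terminal arrays are long and essentially perfect. A
sequencing read containing five tandem repeats — the 35-mers `(CCCTAAA)5` or
`(TTTAGGG)5` — therefore almost certainly originates from a telomere.
Counting *overlapping* occurrences (an array of $n$ complete units contains
$n-4$ positions where the 35-mer starts), a census of a repeat-complete
Arabidopsis assembly finds 109 internal occurrences, against an expectation
of about $(3750/7)\times 10 \approx 5{,}350$ at the ten telomeres; only
$109\cdot 100/(109+5350) \approx 2\%$ of five-repeat reads should be of ITS
origin. The two 23-nt motifs Cen1 and Cen2 of the 178-bp centromeric
satellite provide a heterochromatic reference read class by the same logic.

For a mark $m$ with matched input and immunoprecipitated (IP) samples, the
pipeline computes per study

$$f_{\text{class}} = \frac{\#\{\text{mapping reads containing the class motif}\}}
                          {\#\{\text{mapping reads}\}},\qquad
  E_{\text{genome}} = \frac{f^{\mathrm{IP}}_{\text{class}}}{f^{\mathrm{input}}_{\text{class}}},\qquad
  E_{\text{tel/sat}} = \frac{E_{\text{genome}}(\mathrm{TEL})}{E_{\text{genome}}(\mathrm{SAT})},$$

and the fraction of reads mapping to unique sequences,
$\mathrm{RMUS} = \#\{\text{uniquely mapping reads}\}/\#\{\text{mapping
reads}\}$, a proxy for the single-copy versus repetitive origin of each
library. Values are pooled across studies per mark; significance is
normality-gated (below).

## Read classification

`classify_read()` assigns a read to every class whose motif occurs at least
once in the literal read string. Three conventions matter:

* **No reverse-complement expansion.** C-strand-derived and G-strand-derived
  telomeric reads are deliberately separate classes (`TEL_C`, `TEL_G`); the
  strand flip during library construction is what produces both classes from
  both chromosome ends. Collapsing strands would merge the four-class scheme
  into two and hide strand asymmetries.
* **`N` never matches.** An alignment position containing `N` — in the read
  or in the motif — fails. A quality-trimmed telomeric read drops out of the
  numerator symmetrically in input and IP, which leaves ratios unbiased.
* **Multiplicity is ignored.** A read counts once per class however many
  motif copies it contains; multi-class reads count in every class they
  match (co-occurrence is logged, and vanishingly rare in practice).

`count_overlapping()` (every start offset, overlaps allowed) is exposed
separately because genome censuses need occurrence counts, not read counts.
`count_internal_motifs()` restricts a census to occurrences whose *start*
lies outside the masked terminal arrays; `find_telomere_mask()` builds that
mask as the maximal perfect terminal run of any rotation of either repeat
unit, so subtelomeric ITSs beyond the terminal array count as internal.

## The synthetic genome and what it does (and does not) emulate

`build_genome()` assembles chromosomes with the architecture the method is
sensitive to: a C-strand telomeric array on the left end and a G-strand
array on the right (3,750 bp by default, ending exactly at the terminus);
ITSs of perfect stretches (geometric length, mean 1.5 repeats by default)
alternating with degenerate stretches (per-base substitution rate 0.1);
tandem blocks of a fixed 178-bp satellite monomer carrying Cen1 at offset
20 and Cen2 at offset 100, exactly once each; and i.i.d. background at
GC 0.36. Defaults are 2 chromosomes of 200 kb — a desk-scale genome whose
telomere fraction (15 kb / 400 kb) is deliberately much higher than in a
real genome, so that read counts are informative at simulation sizes of
$2\times10^4$–$2\times10^5$ reads per sample.

The stretch-length default of 1.5 repeats reflects real ITSs, whose perfect
runs are mostly one or two units; it keeps perfect runs of five or more
units rare, so that about 2–3% of telomere-classified reads originate
outside the terminal arrays — the contamination regime the classification
scheme is designed for. Raising the mean to 3–5 (as several tests do)
produces ITS-rich genomes for exercising the internal census.

`simulate_sample()` draws read start positions with probability
proportional to the mark weight `λ(label)` of the truth interval containing
the start (uniform for inputs), uniformly within the interval, from either
strand with probability ½, error-free, at constant length (100 nt). The
read name encodes the true origin, so any downstream quantity can be
checked against ground truth. The generator does **not** model
fragment-size distributions, GC bias, PCR duplicates, sequencing errors,
paired ends, or nucleosome-level structure; passing tests therefore
demonstrate the correctness and calibration of the *estimators*, not
robustness to real-library artefacts.

One consequence worth knowing when reading parameter-recovery results: the
recoverable parameter of the generative model is the frequency *ratio*,
whose expectation is not exactly `λ` but approximately
$\lambda/(1+(\lambda-1)p)$ with $p$ the weighted share of the enriched
compartment — enriching a compartment inflates the IP library total that
normalises every frequency. With $p_{\mathrm{tel}}\approx 3.75\%$ this
deflates a 4-fold telomeric enrichment to about 3.5 and inflates a 0.25-fold
depletion to about 0.28 (plus 1–3% from boundary- and ITS-origin reads in
the telomeric classes). The same renormalisation operates in real ChIP-seq;
recovery tests use a ±15% band around `λ` that accommodates it.

## Mapping and RMUS

In synthetic mode, `map_reads_exact()` defines "maps" as exact full-length
occurrence of the read or its reverse complement in the genome and "maps
uniquely" as a total occurrence count of one — no mismatches, indels or
clipping, which makes uniqueness an exactly checkable quantity for the
error-free reads (and makes every simulated read map, since reads are
genome substrings by construction; `count_sample(mapper = "none")` exploits
this to skip mapping when uniqueness is not needed). In real mode,
`ingest_alignments()` summarises SAM/BAM primary records; "maps once" has
no portable encoding across aligners, so the dialect is explicit:
`NH == 1` where NH tags exist, otherwise MAPQ ≥ 10 (with a warning on
fallback). Class counting is restricted to mapping reads by default;
`count_unmapped = TRUE` adds unmapped reads to the tallies for reference
assemblies with incomplete telomeres — with an internal, gap-free genome
the two options coincide.

## Pooled statistics

`pool_and_test()` pools per-study enrichment ratios and tests them against
the null ratio 1. Ratios are multiplicative and right-skewed, so the test
operates on log2 ratios against 0 by default (`scale = "linear"` tests raw
ratios against 1); means and SEMs are reported on the ratio scale for
figure-style output. Test selection is gated by a Shapiro–Wilk test at
α = 0.05 (a conventional gate level): normal → one-sample Student's *t*,
non-normal → Wilcoxon signed-rank (zeros excluded, the signed-rank
convention). Degenerate inputs are handled without crashing: fewer than
three studies → descriptive output only; all values exactly at the null →
p = 1 with no test; identical values off the null → the rank test (the
Shapiro statistic is undefined at zero variance).

`compare_rmus()` compares pooled input and IP RMUS values: both groups
normal → two-sample Student's *t* with pooled variance (the classical
test), otherwise a two-sample Kolmogorov–Smirnov test; with
`paired = TRUE` the gate runs on the paired differences and chooses between
the paired *t* and the Wilcoxon signed-rank test. Group medians and
quartiles are returned for box-plot output. No multiple-testing correction
is applied across marks — each mark is reported with its own p-value, which
is how such per-mark summaries are conventionally read; a
Benjamini–Hochberg adjustment can be applied downstream to the `p_value`
column of the pooled table if desired.

## Numerical and design choices

* Coordinates are 1-based closed inside R (`GRanges`/`IRanges` idiom) and
  0-based half-open on disk (BED, truth JSON, read-name `start0` fields).
* All randomness flows through explicit seeds; `derive_seeds()` expands one
  master seed into per-stage child seeds (all below $2^{31}$), and
  `run_simulate()` records every seed in the cohort manifest together with
  MD5 checksums, making cohorts reproducible byte for byte.
* The 178-bp monomer is one fixed seeded sequence package-wide: only the
  embedded Cen1/Cen2 motifs matter to the pipeline, and a shared monomer
  makes satellite blocks genuinely repetitive genome-wide, which is what
  drives their low RMUS.
* Repeat features are separated from each other and from the telomeres by
  at least 200 bp of background (`min_feature_gap_bp`), keeping terminal
  arrays maximal and feature boundaries unambiguous; packing that does not
  fit the chromosome is an error, not a silent truncation.
* Degenerate ITS bases substitute uniformly among the three alternatives;
  the only property the pipeline needs from degeneracy is that it disrupts
  exact 35-mer matches.
* The length-based telomere-motif expectation deliberately omits the
  per-array edge correction (−4 motifs per array, ~40 genome-wide at
  Arabidopsis scale, under 1% of the estimate); the rounded "about 5,350"
  quotation level absorbs it.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while leaving sampling noise well inside the tolerances they assert:
parameter recovery across the mark-level grid {0.25, 0.5, 1, 2, 4} uses 10
replicate studies of 200,000 reads per sample on the 400-kb default genome
(inputs shared across the grid within a replicate, as real studies reuse
inputs across marks); null-test calibration simulates 200 independent null
studies of 30,000 reads and measures the rejection rate over 2,000
resampled size-10 subsets (the subset count sets the precision of the rate
estimate, about ±0.5 percentage points); the RMUS contrast uses cohorts of
10 studies at 20,000 reads with the exact mapper. `scripts/acceptance.R`
re-runs the same computations from scratch at comparable sizes.

## Known limitations

* The internal mapper is exact-match only; it is an oracle-friendly stand-in
  for alignment at desk scale, not a read aligner, and real data should
  arrive as SAM/BAM.
* Enrichment ratios carry the IP-renormalisation attenuation described
  above; the pipeline reports the ratio the field reports, it does not
  attempt to de-attenuate it.
* Motif matching is exact by design (the five-repeat stringency *is* the
  method); telomere-variant repeats and mismatch-tolerant matching are out
  of scope.
* With very few studies per mark the gated tests are underpowered and the
  Shapiro–Wilk gate is itself noisy; below three studies the pipeline
  refuses to test and reports descriptive statistics only.
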