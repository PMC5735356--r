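---
title: "Methods: small RNA profiling and exact-test differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling and exact-test differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrnade)
```

# The study design this package serves

Insect infection time courses are commonly profiled with one small RNA
library per condition: a control (e.g. Tween-treated) plus several
post-infection time points, sequenced deeply but without biological
replicates. That design rules out dispersion-based methods (DESeq2, edgeR
need replicates to estimate biological variance) and motivates the exact
count-based test between two libraries that this package implements,
together with the surrounding bookkeeping: read filtering with per-category
accounting, tag collapsing, hierarchical annotation, TPM normalization,
novel-miRNA candidate filtering and qPCR concordance.

# Read filtering and accounting

Reads are assigned to exactly one category, in a fixed order, so the
categories partition the high-quality total and the accounting table adds
up exactly:

1. **low-quality** — mean Phred < 20 or any `N` base. Removed before the
   accounting denominator; the remainder is the *high-quality total*.
   Sequencing reports rarely define "low-quality"; this definition is the
   package's contract and the synthetic generator produces exactly this
   kind of read for that fraction.
2. **3′ adapter-null** — no exact match of a 3′-adapter prefix (≥ 6 nt,
   0 mismatches, leftmost hit wins; overlapping seed occurrences are all
   considered). Exact matching is reproducible and sufficient for
   synthetic data; mismatch-tolerant trimming is deliberately out of
   scope.
3. **insert-null** — adapter found at position 1 (empty insert).
4. **5′ adapter contaminant** — the first 8 nt of the trimmed insert occur
   within the 5′ adapter.
5. **shorter than 18 nt** — trimmed insert below the minimum mature-miRNA
   length.
6. **polyA** — insert ≥ 80 % adenine.
7. **clean** — everything else; collapsed to unique tags with counts.

Percentages are `100 · count / high_quality_total`, rounded half-up to two
decimals — the convention under which the published per-library tables
reproduce exactly (verified for all thirty-five cells of the five-library
accounting fixture). The category order follows the published table
top-to-bottom; where a category is named but never defined (insert-null,
polyA), the definitions above are this package's documented choice.

# Annotation

Clean tags are classified by a strict priority rule — structural RNAs
(rRNA, scRNA, snoRNA, snRNA, tRNA, as one group) > known miRNA > repeat >
exon > intron — taking the highest-priority class with a match;
unannotated otherwise. Genome mapping is exact substring match on either
strand; aligner internals (seeds, mismatches, multi-mapping policy) are out
of scope, which keeps the mapped-fraction computation exactly reproducible.
Known-miRNA matching tolerates isomiR length offsets of up to 2 nt (tag
within mature or mature within tag).

Between-library commonality is reported as shared sequence mass. Because a
single "percent in common" between two libraries is ambiguous (one-sided
vs. symmetric, unique tags vs. read mass), the package reports all three
numbers: each library's shared-mass fraction and the combined
`(shared_A + shared_B) / (total_A + total_B)` as the headline.

# Differential expression

Normalized expression is transcripts per million,
`TPM = 10^6 · count / clean_total`. Two presentation rules precede
testing: a TPM of exactly 0 becomes 0.01 (so fold-changes stay
computable), and a miRNA below 1 TPM in *every* library is dropped.
Fold-change is `log2(treatment / control)` on the normalized values.

The p-value is computed from the *raw counts*: with `x` the control count,
`y` the treatment count and `N1`, `N2` the library clean totals,

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}
  \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}$$

evaluated in log-gamma space (exact to x, y in the thousands; the test
suite verifies agreement with direct factorial evaluation to a relative
error below 1e-10 for all x, y ≤ 30, and that the pmf sums to one). The
two tails `C = P(Y ≤ y | x)` and `D = P(Y ≥ y | x)` both include the
observed count; the reported p-value is `min(1, 2·min(C, D))`. Note the
test *conditions on the control count*: the pmf is symmetric
(`p(y|x) = p(x|y)` at equal totals) but the tail p-value is not exactly
symmetric under swapping the libraries — an inherent property of this
family of tests, not a numerical artifact.

Multiple testing is corrected by Bonferroni with `m` = the number of
miRNAs retained in that pairwise comparison; each treatment-vs-control
table is corrected independently. The adjusted column is written as `fdr`
for compatibility with the usual table layout even though the method is
Bonferroni. A miRNA is called significant when the adjusted p-value is
below `alpha` (default 0.05) and `|log2FC| ≥ 1`; both thresholds are
configurable (`de_params()`) since published tables rarely state them.

Calibration, measured by the test suite and `scripts/acceptance.R`: over
10,000 null count pairs (equal Poisson mean 100 — typical of the counts at
which miRNAs are called in deep libraries — and equal totals), the
fraction with p < 0.05 is ≈ 0.046–0.047, within the binomial 3σ band of
the nominal 0.05; the mild conservatism is the usual cost of a discrete
two-tailed test. Planted |log2FC| = 3 effects at control TPM ≥ 50 and
2·10⁶-read depth are detected in effectively 100 % of 200 simulated
experiments, with a null false-call rate around 10⁻³ after Bonferroni and
the fold-change gate.

# Novel miRNA filtering

Candidates carry an externally produced discovery score (hairpin-excision
tools are not re-implemented; their scores are inputs). A candidate is
accepted when **score > 1** and **shuffle-test p < 0.05** and
**MFE < −19 kcal/mol**; the rejection reason names the first failed
criterion in that order.

**Shuffle test.** The sequence is a walk on the graph whose vertices are
bases and whose edges are its overlapping dinucleotides; any Eulerian path
with the same edge multiset is an exact dinucleotide-preserving
permutation fixing the first and last base. The package draws such paths
with Hierholzer's algorithm over randomised adjacency lists
(Altschul–Erickson construction). The empirical p-value uses the add-one
estimator `p = (1 + k)/(1 + n)` (k shuffles folding at least as low),
which cannot return 0; at least 19 shuffles are required for p < 0.05 to
be reachable.

**Folding energy.** The default scorer is a deliberately simple, fully
specified model: pair energies GC −3, AU −2, GU −1 kcal/mol, a −1 bonus
per directly stacked pair, minimum hairpin loop 3, minimised exactly over
nested structures by dynamic programming (`V`/`W` recursions with a
bifurcation term). It is *not* the full nearest-neighbour thermodynamic
model; the scorer is a pluggable argument (`model =`) so a thermodynamic
backend can be substituted, and the −19 kcal/mol threshold is meaningful
only relative to the configured model. The test suite checks the dynamic
program against exhaustive enumeration of *all* nested structures for
hundreds of random sequences up to 14 nt — a regime where enumeration is
tractable and independent of the recursion being tested.

# Target intersection and qPCR

The runnable stand-in predictor emits a (miRNA, transcript) pair when the
reverse complement of miRNA positions 2–8 occurs in the 3′ UTR. Predictor
agreement is evaluated as the seven regions of the three-set Venn diagram
on pair identities (site positions ignored, matching how "common spots"
are counted across predictors); the triple intersection is the set passed
downstream. Hybridization energetics, alignment scores and context scores
of real predictors, and GO/KEGG enrichment, are out of scope.

qPCR relative expression uses 2^−ΔΔCt with replicates averaged on the Ct
scale and the replicate SD of ΔCt propagated as
`sqrt(var(ΔCt_ctl) + var(ΔCt_trt))`. Concordance with sequencing is sign
agreement between log2(2^−ΔΔCt) = −ΔΔCt and the sequencing log2
fold-change; folds are compared on the log2 scale to keep up- and
down-regulation symmetric. Amplification-efficiency correction (Pfaffl) is
not implemented.

# The synthetic study generator

The generator defines the conditions under which the pipeline is tested;
its defaults are fixed once and mirror the five-library design:

- **Libraries**: `TW` control plus `12h`, `18h`, `24h`, `36h`; 20,000
  reads per library by default. The statistical structure, not the raw
  depth, is what downstream tests consume, so desk-scale depth keeps the
  whole suite fast while binomial convergence checks still bind.
- **miRNAs**: 60 mature sequences, lengths 18–24 nt peaked at 22,
  log-normal relative abundances (σ = 1 on the log scale). Precursors are
  built constructively as mature + loop + mismatched reverse complement,
  so they contain the mature arm exactly and fold into a stem-loop.
- **Class mixture**: miRNA 0.30, rRNA 0.08, tRNA 0.05, snRNA 0.02,
  snoRNA 0.02, repeat 0.08, exon 0.10, intron 0.10, unannotated 0.25.
  Non-miRNA inserts are reference fragments with lengths peaked at 28 nt
  (the piRNA-sized class), which gives the characteristic bimodal 22/28
  length histogram.
- **Contamination**: low-quality 1 %, adapter-null 0.3 %, insert-null
  0.1 %, 5′ contaminant 1.7 %, shorter-than-18 5 %, polyA 0.02 % — close
  to the observed proportions in the control library of this design.
- **Counts**: per-miRNA counts are independent Poisson draws with mean
  `abundance · class_fraction · clean_reads`, scaled by
  `2^log2_fold_change` for planted effects — the simplest model consistent
  with the exact test's sampling assumptions. `simulate_mirna_counts()`
  exposes the same count model directly for power and calibration studies
  (10,000 null pairs; 200 replicate experiments with 40 miRNAs at 2·10⁶
  depth are the sizes used by the shipped checks).

Everything is seeded; identical configurations regenerate byte-identical
FASTA/FASTQ/TSV output.

**What passing on synthetic data does and does not show.** The generator
emulates length structure, class mixture, contamination categories and
Poisson counting noise. It does not emulate sequencing substitution
errors, adapter mismatches, isomiR processing heterogeneity,
overdispersion between biological replicates (there are none in this
design), or genome-scale reference complexity. Tests passing here
demonstrate the algorithms are implemented correctly under the stated
model, not that the single-library exact test captures biological
variance — with replicates, a dispersion-based method is the better tool.

# Numerical choices and degenerate inputs

- Percentages are rounded half-up to 2 decimals (with a 1e-9 guard against
  binary representation just below a half), matching the printed tables;
  raw fractions are available upstream of rounding.
- The exact test is evaluated via `lgamma`; the lower tail is a direct sum
  over `0:y` and the upper tail is `1 − C + p(y|x)`, clamped at 0.
- Empty read sets yield an all-zero accounting (not an error); an empty
  tag set is an error for the length distribution ("no clean tags").
- Tag collapsing breaks count ties lexicographically; top-N ranking does
  the same, and restricts to miRNAs non-zero in every library.
- `apply_criteria` is monotone: improving any criterion never flips an
  accepted candidate to rejected.
- Adapter search takes the leftmost verified seed hit; a mature sequence
  whose tail happens to overlap the adapter prefix is still trimmed
  correctly because overlapping seed occurrences are all candidates.
- T→U normalization is applied wherever RNA is expected (folding,
  shuffling, seed matching), so DNA-alphabet inputs are accepted.

# Known limitations

- The exact test is a two-library comparison; no joint modelling across
  time points, and no replicate-aware dispersion.
- Exact-match mapping and annotation do not tolerate sequencing errors or
  near-matches beyond the documented isomiR length offsets.
- The folding model is intentionally simple; energies are not comparable
  with full thermodynamic implementations except through the pluggable
  model interface.
- The published study-level outcomes that depend on unreleased raw
  libraries and external tools (counts of differentially expressed and
  novel miRNAs, predictor intersection sizes, enrichment categories) are
  out of reach by construction; the shipped checks substitute
  property-based verification at desk scale.
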