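---
title: "Methods: TE landscapes, insertion density, and the ORF screen"
author: "retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscapes, insertion density, and the ORF screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscape)
library(dplyr)
```

## What the package computes

retroscape post-processes RepeatMasker-style repeat annotation for
comparative analyses of transposable element (TE) dynamics across species
that differ in lifespan. The chain is:

1. parse `.out` annotation tables and `.align` alignment files;
2. estimate the divergence of every TE copy from its consensus with the
   Kimura 2-parameter (K2P) distance;
3. merge annotation fragments that share a RepeatMasker insertion
   identifier into single insertions;
4. summarise each genome as a divergence landscape (genome percent per
   1%-divergence bin per TE class) and a per-class content table;
5. compute the density of insertion (DI) of *recent* non-LTR
   retrotransposons, pair species by a two-fold lifespan rule, and test the
   paired DI differences with an exact Wilcoxon signed-rank test;
6. relate windowed insertion densities to gene/exon/intron/intergenic
   densities (Spearman), and contrast gene-rich versus gene-poor windows
   (rank-sum);
7. screen annotated LINE loci for open reading frames carrying complete
   reverse-transcriptase (RT) and endonuclease (EN) domains.

A ground-truthed simulator generates genomes, annotation, gene models and
multi-species cohorts so that every stage can be validated at desk scale.

## Divergence model

For an alignment of a TE copy against its consensus, transitions
(`A<->G`, `C<->T`) and transversions are counted over columns free of gaps
and ambiguous bases, giving proportions $P$ and $Q$. The K2P distance is

$$K = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],$$

the expected number of substitutions per site under a two-rate model;
unlike the raw mismatch percent in the `.out` file it corrects for multiple
hits, which matters for the ancient portion of the landscape. `kimura2p()`
refuses inputs outside the model's domain ($1-2P-Q \le 0$ or
$1-2Q \le 0$) rather than returning a saturated value. Divergence used
downstream is computed from `.align` alignment strings whenever the file is
available; the `pct_div` fallback (raw mismatch, not K2P) is accepted with
a warning and flagged on the result, because real-world `.out`-only inputs
must still be analysable.

CpG handling defaults to `include` (plain K2P). The `exclude` switch
removes consensus CpG dinucleotide columns from the usable sites before
counting, mirroring RepeatMasker's CpG-adjusted variant; hypermutable CpG
transitions then no longer inflate the distance. Ambiguity codes other
than N are treated as N — they are rare, and inventing pairing rules for
them would add noise, not information.

Fragments sharing an insertion identifier merge into one insertion whose
divergence is the *length-weighted* mean of fragment values, so a 100 bp
shard cannot dominate a 3 kb body. Class and family come from the longest
fragment (deterministic tie-break). Rows starred as lower-scoring overlaps
are kept by default with a flag (`include_overlaps = FALSE` drops them):
the upstream convention is ambiguous, so the choice is explicit and
reversible rather than silent.

## Landscapes and content tables

Landscapes bin insertions by percent divergence into half-open 1% bins
over [0, 50) plus an overflow bin, accumulating base pairs per TE class;
values are percent of the assembly. The percent denominator is the non-N
assembly length when a genome FASTA is supplied (ambiguous runs cannot be
annotated, so including them deflates percentages); the species table's
assembly size is the fallback. Integer base-pair bookkeeping is exact: the
landscape cells always sum to the merged TE base pairs, which the tests
assert.

Content tables report DNA transposons, Helitrons (rolling-circle elements,
reported separately from cut-and-paste DNA transposons), SINEs, LINEs,
LTRs and Unknown; satellites, simple repeats and other non-TE annotation
fall into `Other`, which is listed but excluded from the total TE percent.
Unrecognised class strings demote to `Other` rather than failing, because
repeat-library labels drift between releases.

## DI, pairing, and the signed-rank test

Recent non-LTR retrotransposons are insertions of class LINE or SINE with
divergence strictly below 3% — a conventional proxy for recent activity;
the comparison is strict (`< 0.03`). The density of insertion is

$$\mathrm{DI} = \frac{\text{number of recent insertions}}{\text{assembly size (Gb)}},$$

with the full assembly size (not non-N length) as denominator, following
the formula's own wording.

Species pairs are every ordered (long-lived, short-lived) combination
whose maximum-lifespan ratio is at least 2, boundary included. With the
bundled 10-species table this yields exactly 25 pairs. The bundled
lifespans mix the five values printed in the study design with five bat
values from the AnAge database (the `lifespan_source` column records
which); body masses are AnAge values and enter no computation.

`wilcoxon_signed_rank()` drops zero differences, assigns average ranks to
tied magnitudes, and computes the exact null distribution of the positive
rank sum by dynamic-programming convolution whenever there are no ties and
$n \le 30$; otherwise it uses the normal approximation with continuity and
tie corrections. For 25 single-sign differences with distinct magnitudes
the exact p-value is $1/2^{25} \approx 2.98\times10^{-8}$ one-sided and
$2/2^{25} \approx 5.96\times10^{-8}$ two-sided — the resolution floor of
the design. Both alternatives are exposed; the package asserts neither as
the "right" one, since a one-tailed protocol and a two-sided-looking
headline value can coexist in published work.

```{r headline}
pairs <- make_pairs(species_profiles(), fold = 2)
nrow(pairs)
tidy(wilcoxon_signed_rank(-(1:25), alternative = "two_sided"))
```

### The independence caveat

Because species recur across the 25 pairs, the paired differences are not
independent, and the signed-rank test's null calibration does not hold for
the *design*: under a null in which every species has the same expected
DI, the test run over the 25 reused pairs rejects well above the nominal
level (a property test in the suite demonstrates the inflation). The test
itself is correctly calibrated on independent differences, which the
acceptance suite verifies by simulation. `pair_test()` therefore
reproduces the published procedure faithfully, and this caveat is the
reason its p-values should be read as descriptive rather than inferential.

## Windows, correlations, and gene-rich/poor contrasts

Chromosomes are tiled with non-overlapping windows (0.5, 1 and 1.5 Mb are
the intended sizes; any positive size is accepted). An insertion or
feature counts in the window containing its start — fractional assignment
of boundary-spanning elements would complicate the bookkeeping for no
statistical gain at these window sizes. Densities are per Mb, so the
trailing partial window is normalised by its true width.

Gene features derive from GFF3 (genes and exons; introns = gene minus
exon, intergenic = chromosome minus gene, all by interval subtraction on
0-based half-open intervals) or BED (gene intervals only). Spearman
correlations use average ranks and the t-approximation for p-values, with
an exact permutation option for $n \le 8$. Gene-poor and gene-rich windows
are those at or below the 0.25 quantile and at or above the 0.75 quantile
of gene density (linear-interpolation quantiles, `stats::quantile` type 7
— a concrete reading of "percentile"); when the two quantiles coincide
the distribution is degenerate and all windows are labelled `neither`
with a warning. The TE-density contrast between the two groups uses the
two-sample rank-sum test.

## ORF screen

LINE loci are extracted (minus-strand loci reverse-complemented), scanned
in all six frames for complete ORFs — ATG to an in-frame stop, stop
required, first ATG per inter-stop region, at least 300 aa (below the
length of a LINE ORF2 product, above random noise) — and each ORF peptide
is aligned locally (Smith-Waterman, BLOSUM62, gap open 10 / extend 0.5)
against bundled RT and EN reference peptides. A domain is "complete" when
the alignment covers at least 90% of the reference and at least half of
the aligned columns score positively; an ORF is intact when *both* domains
pass within that single reading frame, as in LINE ORF2p where EN and RT
reside on one peptide.

The bundled reference peptides are synthetic, fixed-seed stand-ins
(`inst/extdata/synthetic_l1_orf2_domains.faa`): the simulator
back-translates these same peptides into planted loci, making the screen
end-to-end testable, but they carry no information about real L1 ORF2p.
Screening a real genome requires substituting curated RT/EN consensus
peptides via `load_domain_profiles(path = ...)`, and per-species
intactness calls on real assemblies are expressly outside what the tests
demonstrate.

## The simulator: what it emulates, and what it does not

`simulate_genome()` draws random consensus sequences, mutates copies to
target divergences sampled from a two-component mixture — ancient
$\mathcal{N}(25, 3^2)$ percent and recent $\mathcal{N}(1, 0.7^2)$ percent
with per-family weight `w_recent` — places them uniformly without overlap,
and optionally splits copies into fragments (spacered by unannotated
background) that share one insertion identifier. The ancient component
reproduces the ancestral accumulation peak at 20–30% divergence seen in
mammalian repeat landscapes; the recent component feeds the DI analysis.
Substitutions are placed per site with transition:transversion odds
$\kappa:1$ (default 2, a mammalian-like value) at a rate solved
numerically so that the K2P expectation equals the target; the model is
substitution-only, keeping the truth alignment exactly the identity, so
recovered divergences can be compared to truth without alignment
uncertainty. Emitted `.out`/`.align` files parse back bit-exactly.

`make_cohort()` builds multi-species inputs at two fidelities: a fast
count-level mode (Poisson insertion counts per species, enough for DI and
the paired test) and a full-sequence mode. Default rates give short-lived
species twice the recent insertion rate of long-lived ones (9000 vs 4500
per Gb), the direction and order of magnitude of published DI values.

What the simulator does **not** emulate: insertions and deletions within
TE copies, nested insertions, segmental duplication, GC-biased gene
conversion, CpG hypermutation, solo-LTR formation, library
misclassification, or assembly collapse of young repeat copies. Passing
tests therefore demonstrate the correctness of the bookkeeping and the
statistics under a clean generative model — not robustness of biological
conclusions to the messiness of real assemblies.

## Numerical choices and problem sizes

- Exact signed-rank enumeration is limited to $n \le 30$ (the DP is exact
  in double precision there); ties switch to the corrected normal
  approximation rather than an approximate tie-aware enumeration.
- Quantiles are type 7 (linear interpolation), R's default, stated
  explicitly because the classification rule depends on it.
- `kimura2p` errors rather than saturating outside its domain; landscape
  building accumulates divergences ≥ 50% in an overflow bin and logs them.
- Test and vignette simulations use 0.2–1 Mb genomes with tens to hundreds
  of insertions, 5 kb copies for divergence-recovery checks (200
  replicates per target divergence), 500 replicates for null calibration,
  and a 40-locus panel for the ORF screen — sizes at which every
  distributional check has adequate resolution while the whole suite runs
  in minutes on a laptop.

## Known limitations

- The `.align` dialect is a documented simplification of RepeatMasker's
  real (messier) format; the parser is validated against the simulator's
  emitter, not against RepeatMasker output archives.
- The DI analysis inherits the pair-reuse dependence discussed above.
- Domain thresholds (90% coverage, 0.5 positive-column fraction) are
  package defaults chosen to make the planted-panel classification clean;
  they are configurable and should be re-tuned against curated profiles
  for real screening.
- No phylogenetic correction (PGLS, independent contrasts) is applied to
  the cross-species comparisons, by design.
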