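---
title: "Ranking dropout-screen candidates by guide sign concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking dropout-screen candidates by guide sign concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dracoscreen)
```

## The problem

A pooled CRISPR-Cas9 knockout screen infects a cell population with a
genome-wide guide library (here modelled on GeCKOv2-style designs: six
sgRNAs per gene plus non-targeting controls), splits it into a vehicle arm
and one or more drug arms, applies escalating drug pressure, and sequences
the integrated spacers at successive timepoints (T0 before the split,
T1–T3 after). Genes whose knockout sensitizes cells to the drug *drop out*
of the drug arm: their guides' abundance falls relative to the matched
vehicle sample. The analytic difficulty is that the six guides of a gene
behave very differently — editing efficiency is heterogeneous — so a
single extreme guide can masquerade as a gene-level effect. The two
ranking methods implemented here address exactly that.

## The pipeline

**Normalization.** Raw counts are depth-normalized per sample:
\[ N = \frac{\text{count}}{\text{sample total}} \times 10^7 , \]
so every sample column sums to \(10^7\) and abundances are comparable
across sequencing depths (`normalize_counts()`). A guide with zero reads
stays at zero.

**Noise filter.** Guides starting from too few molecules cannot report a
fold change reliably. Any guide whose baseline (T0) count is strictly
below 50 reads — about 10% of the expected per-guide count at the 500×
design coverage — is flagged (`flag_noisy_guides()`) and removed from
*every* downstream arm and timepoint. T0 precedes the arm split, so the
filter is global by construction; with two T0 replicates the default
statistic is their mean (`min` and `all_below` are available). The
10%-of-expected reading is available by passing `threshold = NULL`.

**Fold change.** For each surviving guide, with the vehicle sample of the
same timepoint as control:
\[ L_{FC} = \log_2 \frac{N_{\text{drug}} + 1}{N_{\text{control}} + 1} . \]
The +1 pseudocount keeps the ratio finite when either arm hits zero, and
gives exactly 0 when both do.

**Terrace ranking.** Per gene, `summarize_genes()` computes the mean
\(\mu\) of its guides' \(L_{FC}\) values and the concordance count
\(k\): how many individual guide values share the sign of \(\mu\). The
terrace rank *is* \(k\) (1–6 for a full set); genes on the top terrace
have all guides agreeing in direction. A mean of exactly zero has no sign
to agree with: such genes get rank 0 and are excluded from ranked
selection, and an exactly-zero guide \(L_{FC}\) matches neither sign.
The gene-level reference sign defaults to the mean of the per-guide log
fold changes (`mean_mode = "mean_of_logs"`); the alternative reading that
takes the log of the mean normalized abundances is available as
`mean_mode = "log_of_means"` — the two orderings of mean and log differ
slightly and the per-guide mean is the operational definition used
throughout.

**DRACO selection.** Ranking a gene by its single most efficient guide —
the one with the largest \(|L_{FC}|\) — is attractive because the best
guide carries the cleanest phenotype, but on its own it has no
statistical protection. DRACO therefore applies the *four-of-six* filter
first: a gene is a candidate only if \(k \ge 4\) of its guide values
share the sign of \(\mu\). Only then is its max-\(|L_{FC}|\) guide
reported, at its actual signed value (`draco_select()`). Ties on
\(|L_{FC}|\) resolve to the lexicographically first guide id; genes with
fewer than four usable guides can never pass the literal filter, and a
proportional variant (\(k/n \ge 2/3\), \(n \ge 3\)) is available for
heavily filtered genes.

**Candidate lists.** `select_top()` takes the *n* most dropped-out (or
enriched) genes per method and timepoint — terrace lists are ordered by
rank first and mean \(L_{FC}\) second (a rank-6 gene outranks a deeper
rank-4 gene, which is what the terraces express), DRACO lists by the
selected guide's value — and `merge_candidates()` unions the four
method × timepoint lists while recording provenance, so genes recurring
across groups stand out. Positive-mean genes are excluded from depleted
lists and vice versa.

## Quality control

* `coverage_check()` — reads per guide vs the 500× design target.
* `replicate_correlation()` — Pearson correlation between replicate
  samples, on normalized abundances by default (raw and log1p offered).
* `editing_efficiency_cdf()` — the empirical abundance CDFs of guides
  targeting a designated essential set (typically ribosomal genes)
  versus all other targeting guides, summarized by the maximum vertical
  distance between the curves (the two-sample Kolmogorov–Smirnov
  statistic, computed exactly over the pooled values). Under effective
  editing the gap is near zero at T0 and grows at later timepoints; the
  normalized scale is used because the two guide sets come from the same
  sample and the comparison should not depend on depth.

## Screen comparison

`top_list_overlap()` reports the intersection of two screens' top lists
(count, and fraction relative to the first list). `align_panel()` builds
the two-column gene-panel view — panel genes ordered descending by their
score in screen A with screen B's scores alongside, stable sort on ties,
unmatched genes dropped with a warning — and `panel_correlations()`
attaches Pearson, Kendall and Spearman coefficients. Kendall uses the
tau-b tie correction, the standard choice for tied data.

## Drug-combination efficacy

`compute_viability()` implements the usual MTS-plate arithmetic: subtract
the mean media-only blank, express each well relative to the mean vehicle
signal, clamp negative signals to 0% viability (flagged). Killing is
100 − viability. `assess_combo()` computes the *additive gap* — combo
killing minus the killing of the most potent single agent, in percentage
points — and maps it to an efficacy level:

| level | gap (pp) |
|-------|----------------|
| 1 | < 10 |
| 2 | [10, 20) |
| 3 | [20, 25) |
| 4 | [25, 30) |
| 5 | ≥ 30 |

The two outer boundaries (< 20 ⇒ levels 1–2, ≥ 30 ⇒ level 5) are the
defining ones; the internal 10 and 25 cutoffs are this package's
defaults and are configurable. A combination is *effective* only when
its killing significantly exceeds the best single agent's (two-tailed
t-test on replicate killing values, p < 0.05; Welch by default because
it is the safer choice under unequal variances, with the pooled-variance
Student test as an option). A negative gap is reported as a *rescue*.
With fewer than two replicates, or noiseless replicates, the p-value is
`NA` and the level is still computed.

## The synthetic screen generator

`simulate_library()` / `simulate_screen()` generate screens with known
ground truth so every stage is testable without external data. Guide
abundance evolves multiplicatively,
\[ a_i(t) = a_i(0)\, e^{\,e_i\,(f_g\,t + d_g P(t))}, \]
with \(e_i\) the guide's editing efficiency, \(f_g\) the gene's basal
fitness effect, \(d_g\) its drug-interaction effect and \(P(t)\) the
cumulative drug pressure (zero in the vehicle arm). Counts are drawn
negative-binomially (Gamma–Poisson) around depth-scaled *relative*
abundances, so compositional effects — mass lost by dropouts inflating
every survivor in the drug arm — are reproduced.

Defaults, chosen once to mirror the screen design the analysis assumes:
500× coverage (the design depth), six guides per gene, two T0
replicates, pressure increments (1, 2, 4) over T1–T3 emulating dose
escalation, log-normal baseline with `sdlog = 0.25`, NB size 100 (≈10%
extra coefficient of variation, typical pooled-screen overdispersion),
guide-efficiency mixture of 20% inactive guides plus Beta(2, 2)
efficiencies. Labeled effect classes: *strong_dropout* genes
(`d = -0.5` per pressure unit, efficiencies Beta(5, 1) so at least four
of six guides carry the phenotype), *strong_enrichment* (mirror image),
and *single_efficient_guide* genes — one fully active guide
(`d = -0.75`), five inactive — the false-positive model the four-of-six
filter exists to reject. What the generator does **not** emulate: PCR
amplification bias, infection (MOI) and selection dynamics, copy-number
effects, guide off-targets. Passing tests therefore demonstrate the
correctness and calibration of the ranking logic, not robustness to
those real-data artefacts.

`simulate_plate()` produces absorbance plates with known killing
percentages and multiplicative well noise; `simulate_fastq()` writes a
FASTQ realizing an exact count vector (reads are synthesized so that the
anchor's first occurrence is the true one, which is what makes exact
recovery a valid oracle for `count_spacers()`). Spacer matching is
exact — no mismatch tolerance — with a configurable anchor (default
`CACCG`, the U6 scaffold junction) and an anchor-free substring-scan
mode; exactness is what the published counting approach uses and it
keeps every read auditable (matched + unmapped + anchor-missing = total).

## Numerical and testing choices

* All tie-breaks (guide and gene ids) are lexicographic, making every
  ranking deterministic and testable.
* The KS gap is computed exactly over pooled sorted values; the test
  suite checks it against an independent quadratic-time oracle, and
  terrace/DRACO outputs against brute-force enumeration on over a
  thousand random guide sets.
* Null calibration is checked at the design depth (a 2000-gene screen at
  500×, all drug effects zero): the fraction of genes with \(k \ge 4\)
  is compared with a \(10^5\)-draw Monte-Carlo over six iid
  sign-symmetric values, within a 99% binomial confidence interval.
  Sign concordance of pure noise is common — roughly two thirds of null
  genes reach \(k \ge 4\) — which is why DRACO's filter gates candidacy
  but the *ranking* is driven by effect size.
* Structural recovery is checked in a deliberately near-deterministic
  regime (coverage \(10^5\)×, Poisson counts): with count noise
  suppressed, an inactive guide's fold change collapses to the small
  positive compositional bias of the drug arm, so a gene carried by one
  hyper-efficient guide shows \(k = 1\) and fails the filter *for the
  structural reason the filter encodes*, not by sampling luck, while
  every strong dropout gene lands in the top depleted list. At realistic
  noise levels the five inactive guides' signs are symmetric coin flips
  and such a gene passes \(k \ge 4\) about half the time — the filter is
  a guard against consistent single-guide artefacts, not a noise test.
* Problem sizes in the tests and the acceptance script (2000-gene
  screens, \(10^5\) Monte-Carlo draws, 200-gene correlation panels) were
  chosen as the smallest sizes at which the calibration statements are
  sharp.

## Limitations

No p-values or FDR control are attached to screen hits (MAGeCK-style
count models are out of scope by design); no copy-number correction; no
mismatch-tolerant read assignment; no formal synergy models (Bliss,
Loewe) for the combination assays — the five-level gap ranking is a
screening heuristic, not a synergy claim. Comparisons of real screens
additionally inherit whatever batch structure the screens themselves
carry; nothing here corrects for it.
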