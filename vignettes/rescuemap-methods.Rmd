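---
title: "Models and methods behind rescuemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rescuemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuemap)
```

# The experimental system

rescuemap analyses evolutionary-rescue experiments in which replicate
bacterial populations carry a drug-resistance reporter cassette (a
tetracycline-efflux `tetA-yfp` fusion behind a silent random sequence, plus a
constitutively expressed `cfp` gene) inserted at different chromosomal loci.
Populations are diluted 1:820 daily into geometrically increasing drug, so
unadapted populations decline toward extinction and survival requires
mutations that increase expression of the selected gene. Two-colour
fluorescence separates mutation classes in real time: YFP reports expression
of the selected gene, and because CFP is constitutive and immediately
adjacent, a joint YFP+CFP increase marks tandem amplification of the
cassette, while a YFP-only increase marks other up-mutations (point
mutations, mobile-element insertions, promoter capture by deletion, or
terminator read-through caused by partial-loss-of-function mutations in the
termination factor Rho).

The package has three layers: (i) the trajectory pipeline that turns daily
OD600/YFP/CFP plate-reader series into phenotype calls, (ii) genome-scale
annotation analysis that predicts, per gene, which of these mutation routes
its chromosomal neighborhood makes available (its "adaptive potential"), and
(iii) a stochastic simulator that generates synthetic plates with known
ground truth so every stage is testable without external data.

# Trajectory classification

All thresholds live in `analysis_config()` and follow the source analysis
literally, including the direction of each inequality:

* **OD threshold** `od_threshold = 0.075` (plate-reader units). A population
  is *rescued* iff final-day OD600 strictly exceeds it; normalized
  fluorescence is set to exactly 0 on days where OD600 is strictly below it
  (an OD of exactly 0.075 is normalized, not zeroed). Only the final day
  decides rescue: transient dips do not disqualify.
* **Fold threshold** `fold_threshold = 2.77`, the smallest YFP increase that
  was still sufficient for rescue in the calibration replicate set. A channel
  is *elevated* iff final-day OD-normalized fluorescence divided by the
  ancestral reference strictly exceeds it. Elevated YFP alone prints
  phenotype `"YFP"`; both channels print `"YFP+CFP"` (amplification).
* **Stringent transient criteria** (`stringent_min_days = 2`,
  `stringent_od_min = 0.3`): a transient call requires the fold threshold to
  be beaten on at least 2 days whose OD600 strictly exceeds 0.3. This
  protects extinct wells from spuriously high normalized fluorescence at low
  OD. Wells counted as amplifications *for cost analysis* are extinct wells
  meeting the stringent CFP criteria plus rescued wells that are either
  endpoint-CFP-elevated or meet the stringent criteria (a rescued well whose
  CFP fold fell back below 2.77 by the last day counts here but not in
  endpoint phenotype tallies).
* **Final YFP/CFP ratios** use raw plate-reader units, not OD-normalized
  values — a deliberately different contract from fold classification.
* The ancestral reference is the arithmetic mean OD-normalized fluorescence
  of replicate unselected ancestor wells (95 in the emulated design).

Two qualitative rules from the source analysis needed numeric
formalization; the constants are package conventions, exposed in the config:

* **Amplification timing** (`infer_amplification_timing()`): a YFP/CFP ratio
  trajectory that is *high and flat* (mean above the plate median, relative
  SD below `timing_rel_sd_tol = 0.25`) indicates the amplification expanded
  after the co-occurring mutation; a *sustained mid-experiment step* (best
  early/late split with a late/early mean ratio above
  `timing_step_fold = 2`) indicates the amplification came first. Fewer than
  4 valid days (OD at or above the OD threshold, CFP positive) is
  `indeterminate`.
* **Spot thresholding** for plating experiments: the default rule flags a
  colony spot when its intensity exceeds 6 times the ancestor-spot mean; the
  methods text and the figure legend of the source differ (6 x mean vs
  mean + 6 SD), so both rules are implemented (`rule = "fold"` / `"sd"`)
  with the methods-text rule as default. The discrepancy is documented, not
  resolved.

# Selection design

`compute_mic()` applies the plate-based definition: the MIC is the lowest
tested concentration with OD600 at or below 0.075 in *all* replicates
(non-strict, matching "≤"); no interpolation between the tested
concentrations (the emulated assay steps by 0.125 ug/mL). `make_schedule()`
is anchored so that day 1 is `start_fraction` (default half) of the MIC and
day `D` is `total_fold` (default 10) times day 1, forcing the daily
multiplier `total_fold^(1/(D-1))` — 10 days means 9 multiplicative steps,
multiplier 1.29155. `max_generations()` is `days * log2(dilution)`,
assuming daily regrowth to the same saturation density; 10 days at 1:820
gives 96.8, rounded 97.

# qPCR copy number

`copy_number_ddcq()` implements efficiency-aware relative quantification
against a reference locus and an ancestral calibrator:

$$N = \frac{(1+E_t)^{\,Cq_{t,anc}-Cq_{t,s}}}{(1+E_r)^{\,Cq_{r,anc}-Cq_{r,s}}}$$

with per-assay efficiencies $E \in (0,1]$ supplied as inputs (the emulated
assays all have $E > 0.9$); $E = 1$ recovers the classical $2^{-\Delta\Delta
Cq}$ and the calibrator maps to $N = 1$ identically. Technical triplicates
are aggregated by mean Cq *before* the formula and the SD of $N$ is
propagated by a first-order delta method — the source does not state its
aggregation, so this is declared as a package convention. Which reference
locus ("equidistant from the origin of replication") was used is not
specified in the source; the reference assay is an opaque input here.

# Neighborhood map

## Direct repeats

`find_direct_repeats()` reports maximal same-strand repeat pairs under four
criteria (defaults: length >= 200 bp, Hamming distance <= 8, gap between
copies in [200 bp, 100 kb]). The genome-wide census convention uses these
defaults; scanning a window around a single locus conventionally tightens to
Hamming <= 5. The original analysis used an external repeat finder, so the
algorithm here is a package decision constrained only by the stated
criteria:

* **Seeded scan** (default): exact k-mer seeding with
  $k = \lfloor (L_{min}-m)/(m+1) \rfloor$ capped at 31 (22 for the default
  criteria), then maximal mismatch-bounded extension along each candidate
  diagonal. The pigeonhole bound makes the seed sound: any repeat of length
  200 with at most 8 mismatches contains an exact common run of at least 22
  bases, so seeding misses nothing.
* **Exhaustive scan**: an independent brute-force enumeration over every
  diagonal (start-anchored greedy extension, left-maximality filter), kept
  as the oracle for property tests; quadratic, small genomes only.

Numerical conventions: maximal windows are computed first and the gap
criteria applied afterwards, so a pair whose maximal extension leaves a gap
under the minimum (tight tandems) is excluded rather than trimmed;
overlapping qualifying reports on one diagonal are merged to the longest
extension with leftmost tie-break; reported windows may begin or end on a
mismatched base. Circular sequences are scanned on the doubled string and
rotation-duplicate pairs removed; inter-repeat regions of origin-spanning
pairs keep doubled-string coordinates.

## Property sets and tiers

Three strand-aware sets are built from the annotation (internal coordinates
0-based half-open; GFF3 I/O 1-based closed; BED 0-based half-open;
promoters and terminators are point features, intervals collapsed to
midpoints):

* **Rho set**: genes whose *closest* upstream co-oriented terminator is
  Rho-dependent (annotation mode `rho`; non-intrinsic terminators are
  assumed Rho-dependent upstream). Read-through caused by Rho mutations
  would co-opt the upstream promoter.
* **Deletion set**: genes for which the strand-upstream interval ending at
  the next upstream essential gene (any strand — deleting it is lethal)
  contains a co-oriented *primary* promoter with a co-oriented terminator
  strictly between promoter and gene; promoter confidence scores are
  ignored. The terminator requirement encodes that there is something for a
  deletion to remove.
* **Duplicate set**: genes fully contained in the inter-repeat interval of a
  qualifying repeat pair; boundary-straddling genes are excluded
  (configurable). A `min_region_span` and an explicit exclusion list can
  reproduce the manual curation of genes between closely spaced repeats
  (default: no exclusion).

Upstream scans wrap the circular chromosome by default (whether the original
analysis wrapped is unstated; linear mode is available for contigs).
Overlapping genes and multi-promoter operons are resolved by first-match
semantics. Tiers formalize the qualitative reading of the three-set Venn
diagram: `high` = all three sets; `medium` = at least one promoter
co-option set but not all three; `low` = neither co-option set. The precise
boundary of "medium" is not formalized in the source; this tier map is an
explicit package convention. Reproducing the source's genome-wide census
numbers requires the original genome build, the curated essentiality
database and external transcript-mapping tables, none of which ship with the
package; the test suite instead proves the machinery on constructed toy
genomes where the truth is known exactly.

# Statistics

`fisher_exact_rxc()` enumerates all tables with the observed margins
(depth-first with remainder bounds) and sums the null multivariate
hypergeometric probability of every table whose probability is at most the
observed one, with a relative tolerance of 1e-7 absorbing floating-point
ties — the probability-ordering two-sided criterion used by the analysis
environment the source cites. Above an enumeration budget it falls back to
seeded Monte Carlo over Patefield-sampled tables with an add-one-corrected
p and reported standard error; the 2x4 rescue table enumerates at most 1330
tables, so the published value is always computed exactly.
`odds_ratio_2x2()` is the plain cross-product ratio with no continuity
correction: a zero numerator prints 0 (as the source's table does), a zero
denominator prints `Inf`, both zero prints `NaN`; because the source's table
mixes rescue-odds and extinction-odds orientations for the same reference,
the orientation is an explicit argument, never guessed.
`permutation_test_two_sample()` permutes group labels on the difference in
means, exactly (full enumeration) when `choose(n, nx)` is within budget,
otherwise seeded Monte Carlo with `(b+1)/(reps+1)`; 1e4 replications
two-sided matches the source's setup. `pearson_correlation()` is the
standard r with a two-sided t-based p.

# The simulator: a stated world

`simulate_well()` is a deliberately simple stochastic serial-transfer model
whose purpose is ordering properties and regime shapes, not parameter
inference. Stated design values: 95 wells, 10 days, 1:820 daily dilution,
carrying capacity 2e8 cells, drug following `make_schedule()` from half-MIC
to 5x MIC. Synthetic calibrations (documented defaults in `sim_params()`,
chosen once as field-plausible and not revisited):

* **Growth/drug model**: bacteriostatic threshold — a lineage grows on a day
  iff its expression multiple of the selected gene is at least the day's
  relative drug concentration, else it is static and only diluted. An
  uninhibited lineage below capacity can double up to 24 times a day
  (minimal-medium doubling times of well under an hour), while
  population-level generations stay dilution-limited at log2(820) = 9.7 per
  day; fitness costs scale the exponent, so a lineage outruns dilution only
  while its cost is below `1 - log2(820)/24` (about 0.6).
* **Mutation supply**: Poisson events per ancestral division (point 2e-10,
  mobile-element insertion 2e-10, promoter co-option 1.5e-9 where the preset
  makes it available), with Luria-Delbrück-style jackpot founding sizes
  (`2^U(0, doublings)`). Duplications initiate amplification at 1e-5 per
  division between flanking homology and 1e-9 without.
* **Amplification dynamics**: a biased random walk on copy number `k`
  (step up with probability 0.8 under selection pressure, decay 0.02
  otherwise, never below 1), expression equal to `k`, cost
  `c_amp * (k-1) * amplicon_len_factor` with `c_amp = 0.1` — the preset's
  amplicon length factor is what separates cheap (shortest amplicon, 0.11)
  from costly (post-IS-deletion, 2.0) amplification regimes. Secondary
  expression mutations on amplified backgrounds (2e-9 per division) create
  the cost-limited-escape regime: rescue at modest `k` with elevated
  YFP/CFP.
* **Readout**: OD proportional to total cells (0.9 at capacity, floor 0.02),
  YFP proportional to expression-weighted cells, CFP to copy-weighted cells
  (100 RFU per OD per ancestral unit), multiplicative lognormal noise (sd
  0.1 fluorescence, 0.03 OD) plus a 1-RFU autofluorescence floor.

The per-well truth table records the dominant lineage, its copy number, and
the *noise-free* population-mean fold increases, so end-to-end tests can
separate classification error from genuine ambiguity: accuracy is asserted
only on clear-margin wells (true folds and OD at least 30% away from their
thresholds), where the pipeline is expected to recover at least 95% of
calls.

What the generator does *not* emulate: day-to-day transfer variability,
spatial plate effects, clonal interference beyond discrete lineage
competition, amplification junction structure, and any quantitative fit to
the measured survival curves — a green simulator test establishes internal
consistency of the pipeline and the stated orderings (homology raises
rescue; amplicon cost raises extinction risk among amplified wells and the
final YFP/CFP of rescued ones), never agreement with experimental counts.

# Known limitations

* The repeat finder reports windows, not repeat *families*; three copies of
  one segment appear as three pairs.
* Inter-repeat regions of origin-spanning circular pairs are reported in
  doubled-string coordinates; gene containment for such regions is not
  wrapped.
* The deletion-set rule treats promoters and terminators as points; features
  overlapping the gene body are handled by the strict upstream-distance
  convention rather than by transcript models.
* Monte-Carlo p-values carry sampling error; both Fisher and permutation
  tests report it, and exact paths are forced wherever the published
  comparisons live.
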