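---
title: "Defining eDNA detections under index swapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining eDNA detections under index swapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednadetect)
```

## The detection-definition problem

A multi-species eDNA metabarcoding run pools hundreds of barcoded samples
on one flow cell. Patterned flow cells misassign a small fraction of reads
to the wrong sample barcode ("index swapping" or "index hopping");
published estimates for this class of platform range from 0.2% to 6% of
all reads, with single-i7 swaps — the relevant mode when only the i7 index
is sequenced — near 0.6%. Because swaps are effectively random, they
scatter across the run as *low* read counts of taxa in samples those taxa
were never in. The practical question is where trace eDNA signal ends and
swap artifact begins, and what a manager should do with each.

`ednadetect` answers with a per-run, three-way detection definition fitted
from the run's own tally distribution, plus the decision framework and
reporting surfaces that consume it.

## The threshold model

The unit of analysis is the **tally**: the summed read count of one
sample × primer × taxon combination. Given all tallies of a run with total
reads $T$ and a tail fraction $f$, the cutoff is

$$ c(f) \;=\; \max\{\, v : \textstyle\sum_{t_i \le v} t_i \;\le\; f\,T \,\} $$

with $c(f)=0$ when even the smallest tally value overshoots the budget.
Two cutoffs are fitted: $c(f_\text{drop})$ with $f_\text{drop}=0.006$ and
$c(f_\text{low})$ with $f_\text{low}=0.010$. Classification is then

* `not_detected` — read sum $\le c(f_\text{drop})$;
* `low` — in $(c(f_\text{drop}),\, c(f_\text{low})]$;
* `positive` — above $c(f_\text{low})$.

Assumptions worth making explicit:

* **Swaps are random and individually small.** Aggregated swap reads for
  any one combination stay far below genuine positive counts, so a
  read-mass tail budget separates them. When the swap rate approaches the
  upper end of the published range this assumption degrades — the
  evaluation module quantifies exactly how (false-positive rate among
  swap-only combinations rises with the rate).
* **The budget is measured in reads, not in combinations.** The bottom
  0.6% *of reads* may span the vast majority of combinations (most of a
  run's combinations are one- and two-read artifacts).
* **Cutoffs are value-expressed.** Two tallies with the same read sum
  always share a fate; results cannot depend on sort stability. The
  stored cutoff names the *last dropped* value; the equivalent convention
  naming the first kept value differs only by presentation.
* **One pooled distribution per run.** Lane-level thresholding would be a
  trivial variation (fit per lane), but pooling is the default.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `drop_frac` | 0.006 | fraction of classified reads attributed to swaps and removed; matches the lowest expected single-i7 swap rate |
| `low_frac` | 0.010 | bound of the validation band; chosen over 1.3% because single-indexed designs need not budget for double-index swaps |
| `include_controls` | `FALSE` | whether control tallies enter the fitted distribution |

Both fractions are per-dataset knobs: barcode count, read depth, and run
quality all reshape the tail, so a run with different characteristics may
need different budgets. The package deliberately refuses
`drop_frac > low_frac`.

**Controls and the distribution.** Positive controls carry deliberately
large counts for dozens of taxa; including them inflates $T$ and thereby
every budget. The default therefore fits cutoffs on field-sample tallies
only, while still *classifying* control tallies against the fitted
cutoffs (negative-control QC needs exactly that). This is a genuine design
choice — either convention is defensible — and it is exposed as a flag.

### Degenerate inputs and ties

* All-zero tally sets are an error (no classified reads, nothing to fit).
* A single tally, or any set whose smallest value already exceeds the drop
  budget, yields cutoffs $(0, 0)$: nothing is dropped and every nonzero
  tally is positive. This is the honest reading of the rule at tiny scale,
  and the worked degenerate cases in the tests pin it down.
* `read_sum = 0` is always `not_detected`, for any fitted cutoffs.

## The run simulator

The simulator exists to validate the thresholds against a known truth; its
defaults encode the survey design the package targets: six water bodies
(three rivers, two lakes, one reservoir), ten biweekly events, six 500-mL
replicates per visit, 48-sample plates with one positive and one negative
control, a positive-control mix of 34 taxa.

Generation proceeds in three stages:

1. **Planted occupancy and counts.** Each occupied (site, taxon, primer)
   yields, per replicate sample, a detection with probability `p_detect`
   (default 0.35 — multi-replicate field surveys typically recover a
   species in one to three of six replicates); a detection's read count is
   $\max(1, \mathrm{round}(\mathrm{LogNormal}(\mu, \sigma)))$ with
   defaults $\mu = \log 5000$, $\sigma = 1$. No count distribution is
   canonical for metabarcoding tallies; log-normal reproduces the
   heavy-tailed, log-scale spread real runs show and is a documented
   stand-in, with both parameters exposed.
2. **Controls.** Positive controls draw counts from the same model for
   each expected taxon (probability `p_control`, default 1). Negative
   controls receive nothing here — by construction any read they end up
   with arrives through swapping, which is what they monitor.
3. **Index swapping.** Each read independently moves with probability
   `swap_rate` (default 0.006, admissible range $[0, 0.06]$) to a
   uniformly chosen *different* sample, keeping its primer and taxon —
   the simplest mechanism consistent with single-i7 hopping on a shared
   plate. It is implemented as binomial thinning per source tally with
   the moved reads scattered by multinomial draw, and recorded in a
   ledger at (source, destination, primer, taxon) batch granularity.
   Reads are conserved exactly; the test suite asserts
   post = pre − outgoing + incoming combination by combination.

**Determinism.** One seed drives a single RNG stream consumed in a fixed,
documented order (sites → events → replicates as listed in the manifest,
then controls, then swaps). A (manifest, params, seed) triple always
reproduces a byte-identical tally table. When occupancy is supplied
explicitly, appending new sites leaves existing sites' draws unchanged;
with randomly drawn occupancy, any change to the panel reshuffles draws —
acceptable for a validation tool, and simpler than per-sample sub-streams.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: PCR amplification bias and primer
efficiency differences; chimeras and sequencing error inside the amplicon
(swap artifacts here are always *real* taxa in wrong samples, whereas real
tails mix in misclassified reads); taxon-specific shedding, transport, and
decay of eDNA; correlation of detection across replicates (patchiness);
dual-index swap modes; and the classification step's own errors. The
simulator validates the *thresholding arithmetic and its operating
characteristics under the stated noise model*, not the end-to-end fidelity
of any particular wet-lab pipeline.

### Seasonal scenarios

`seasonal_scenario()` attaches per-event multipliers on `p_detect` per
water-body type, so that scenarios can plant the qualitative pattern real
surveys report — rivers peaking early in the season, reservoirs
mid-season, lakes late — and the cumulative-curve summaries can be checked
against the planted timing. Multipliers are validated non-negative;
effective probabilities are capped at 1.

## The simplified rank assigner

The taxonomic-assignment module preserves one idea: per-rank
percent-identity cutoffs, optimized on positive-control data
(species 97.8, genus 96.2, family 88.3, order 81.21, class 80.91), applied
with **inclusive** boundaries — an identity exactly at a threshold attains
the rank. The printed thresholds read as attained settings, so inclusive
is the natural convention; it is pinned by tests at all five boundaries.

Identity itself is a deliberately small definition: global alignment under
unit match scoring (match 1, mismatch 0, gap column counted as a mismatch
column), maximising matches and, among those optima, minimising alignment
columns; identity is matches over columns. Ties between references at
equal identity break lexicographically by reference id. This is a didactic
stand-in for a k-mer database search with consensus building — those are
explicitly out of scope — but the threshold semantics it feeds are the
real ones. A recursive alignment enumerator serves as the independent
oracle in the tests.

## The management framework

Categories map to actions: `not_detected` stays in routine multi-species
screening; `low` triggers repeat eDNA sampling plus a traditional survey;
`positive` (or escalated/confirmed) adds expanded screening sites, agency
notification, tracking, and containment/eradication planning. Escalation:
any positive, any survey confirmation, or repeated low detections across
distinct events promotes to positive; the repeat count defaults to 2 —
the source framework says "repeated" without a number, so the count is a
documented, configurable choice. A lone low with an all-negative dedicated
follow-up campaign (`followup_negative`) resolves to not-observed; the
follow-up survey itself (e.g. veliger tows) enters only as its boolean
outcome. Escalation is monotone in the history except through that
explicit flag.

## Evaluation conventions

Operating characteristics are **per combination, not per read**: managers
act on detections, not reads. A combination is scored *swap-only* when it
had zero pre-swap reads; everything else is a planted (true) combination —
including planted combinations that also received swapped reads.
Retention is reported two ways: survival past the drop cutoff
(`true_retention`, the quantity that responds to `drop_frac`) and strict
positive-rate (`true_positive_rate`). Sweeps pair seeds across grid cells
(rep *i* uses the same seed everywhere) so monotonicity comparisons ride
on coupled randomness.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise the statistics while
keeping the suite quick to run: 1 000 random tally multisets (up to 10⁴
tallies, mixed artifact/positive scales) against an exhaustive-scan
oracle; twenty replicate 48-field-sample plate simulations (30 taxa, 10
primers, swap rate 0.006, $e^\mu \approx 5000$) for swap-mediation
recovery; a 4 × 3 swap-rate × drop-fraction sweep with three paired
replicates per cell; 200 random detection tables against brute-force
summary oracles; and a nine-event seasonal scenario per water-body
archetype. On these conditions the thresholds remove 100% of swap-only
combinations at the default fractions while retaining ~99% of planted
combinations — figures the acceptance script recomputes from scratch on
every run.

## Known limitations

* The cutoffs inherit the noise model's separation assumption; runs whose
  true trace signals genuinely overlap the swap tail cannot be split by
  any read-mass budget, only flagged `low` for validation.
* Thresholds are fitted per run and are not transferable across runs with
  different barcode counts or depths.
* The rank assigner is not a replacement for a real classifier; it exists
  so the pipeline can be exercised end-to-end from sequences.
* Occupancy-style detection-probability modelling across replicates is
  out of scope (the replicate profiles are its natural input).
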