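---
title: "Methods: window-based peak calling and B-cell progenitor assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based peak calling and B-cell progenitor assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcellkit)
```

bcellkit packages the computational toolbox of a B-lymphoid development
study: a bespoke windowed ChIP-seq peak caller, genomic interval
annotation, a fold-change-plus-Poisson differential-accessibility rule for
ATAC-seq, and the statistics behind the bench assays that accompany such
studies (Ig rearrangement qPCR, comet assays, γH2AX focus scoring, blood
lineage counts). This vignette is the package's account of the models, the
parameters that matter, the numerical decisions taken where the design was
open, and what the synthetic-data tests do and do not demonstrate.

## The windowed Poisson peak caller

### Model

The caller detects binding sites as windows where the immunoprecipitated
(IP) library holds more fragments than a Poisson background calibrated on
the input (control) library. The pipeline, in order:

1. **Duplicate removal.** Reads mapping to the same (chromosome, 5′
   position, strand) are counted once, suppressing clonal PCR
   amplification. The strand-aware key is the standard choice; a
   strand-blind key is available (`dedupe_reads(by_strand = FALSE)`).
2. **Read extension.** Each read is replaced by a 150-bp fragment running
   from its 5′ end in the 3′ direction, approximating the sequenced
   fragment: `+` reads give `[pos, pos + 150)`, `−` reads
   `[pos + length − 150, pos + length)`, clipped at chromosome ends. An
   alternative reading — append 150 bp beyond the read's 3′ end — is kept
   as `extend_reads(mode = "append")`; the fragment interpretation is the
   default because extension-to-fragment-size is the conventional intent
   of fixed-length extension.
3. **Window counts.** The genome is tiled with 50-bp windows; a fragment
   increments every window it overlaps by ≥1 bp (binary overlap, no
   fractional assignment).
4. **Input normalization.** The expected IP count of window *i* is
   λ_i = max(m_i · N_IP / N_input, λ_floor), with m_i the input window
   count and N the post-dedup library totals.
5. **Test.** Each window is scored with the Poisson upper tail
   P(X ≥ k_i | λ_i), k_i the IP window count.
6. **Neighbour rule.** A window is significant when P < 10⁻³ (strict
   inequality; ties at exactly 10⁻³ are not significant). A window
   *qualifies* as peak evidence only when it and both immediate
   neighbours are significant. Terminal windows of a chromosome can be
   significant but never qualify: a missing neighbour counts as
   non-significant.
7. **Peak assembly.** Each maximal run of consecutive significant windows
   containing at least one qualifying window becomes one peak spanning
   the whole run. Runs of length ≤ 2 can contain no qualifying window and
   are discarded. The run — not just its qualifying interior — is
   reported, because the neighbour rule marks run interiors and trimming
   to them would discard the flanking windows the rule itself requires.
   The summit is the midpoint of the run's highest-IP-count window (first
   such window on ties).

### The λ floor

Windows with zero input coverage would give λ = 0 and P = 0 for any stray
IP read, so every isolated read would become "infinitely" significant.
`call_peaks(lam_floor = "auto")` therefore floors λ at the genome-wide mean
normalized input count per window. The floor matters for calibration more
broadly: with it, below-average input windows are tested against the
genome-wide mean rather than their own noisy (low) input count, which is
what keeps the null significant-window fraction well below 5α in the
calibration tests. The floor is configurable (`lam_floor = 0` disables
it) and the effective value is recorded in the `peak_call` object and the
run log.

### Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `window` | 50 | bp | tiling width; last window of a chromosome may be shorter |
| `ext` | 150 | bp | fragment length after extension |
| `alpha` | 1e-3 | — | strict per-window threshold |
| `lam_floor` | `"auto"` | fragments | genome-wide mean normalized input per window |
| `dedup` | `TRUE` | — | strand-aware duplicate key |

### Worked toy example

```{r peaks}
g <- make_toy_genome(1, 100000, 20, seed = 1)
design <- spike_design(g,
  data.frame(chrom = "chr1", start = 40000, end = 40500),
  enrichment = 20, depth = 2e5)
ip <- simulate_chip_library(g, design, seed = 1)
input <- simulate_chip_library(g, design, is_input = TRUE, seed = 2)
pc <- call_peaks(ip, input, g)
pc
```

The single called peak sits inside the spiked region. Note the peak is
somewhat narrower than the 500-bp spike: contained fragments give a
triangular coverage ramp over the outermost ~150 bp of the region, and
ramp windows do not always clear the threshold. Sensitivity (spike
overlapped by a peak) is unaffected.

## Interval annotation

* **TSS distance classes.** A peak's midpoint is compared with the nearest
  TSS: ≤ 5 kb proximal, 5–500 kb distal, otherwise far; both boundaries
  inclusive ("within 5 kb" reads as inclusive). Midpoint-to-TSS is used
  rather than edge-to-TSS for symmetry; both boundaries and the anchor
  are arguments.
* **Peak-to-gene assignment.** A local re-implementation of the GREAT
  basal-plus-extension default: every gene owns a basal domain 5 kb
  upstream / 1 kb downstream of its TSS (strand-aware), extended in each
  direction to the nearer of the neighbouring gene's basal domain or 1 Mb
  from the TSS; extension never shrinks a basal domain, so neighbouring
  regulatory domains may overlap and a peak (assigned by midpoint) can map
  to several genes. This is an association rule only — GREAT's enrichment
  statistics are out of scope.
* **Overlap counting.** The Venn membership of a first-named peak set
  against one or two others, with overlap defined as ≥ 1 shared bp (no
  minimum-fraction option).
* **Metaprofiles.** Mean per-bp signal in equal bins across
  `[center − flank, center + flank)` around anchors (peak summits,
  typically), averaged over anchors; anchors truncated by chromosome ends
  are dropped and counted. Defaults flank = 2000 bp, 100 bins are
  exposed as parameters — they are plotting conventions, not claims.

## Differential accessibility

The decision rule: a region is differentially accessible when one
condition has **at least 4 times more reads** and the test gives
**P ≤ 0.01** — both thresholds inclusive. Around that rule:

* Counting happens on a merged universe of both conditions' peaks
  (`build_universe()`), so every region is scored in both conditions.
* Libraries are scaled to equal totals; replicates are summed within
  condition (condition totals are rescaled to a common replicate number
  first, so a 2-vs-3 design is not biased).
* The test is the Poisson upper tail of the larger normalized condition
  count given the smaller as expectation. The upstream publication
  delegated normalization and testing to MAnorm; its M-A robust
  regression is deliberately not re-implemented here, so results on real
  genome-scale data may differ from MAnorm's even though the stated
  decision rule (≥ 4-fold and P ≤ 0.01) is applied exactly.
* A pseudocount (default 1) is added to both ratio terms and to the
  Poisson expectation, preventing zero-count regions from producing
  infinite ratios and zero P-values. Setting `pseudocount = 0` recovers
  the bare rule: the boundary pair (4, 1) then passes the fold threshold
  at exactly 4 but fails the test (P(X ≥ 4 | 1) ≈ 0.019 > 0.01) and is
  not called.

```{r diffacc}
rc <- simulate_atac_counts(100, 10, fold = 8, base_mean = 200, seed = 5)
dc <- classify_differential(rc)
summary(dc)
table(truth = rc$truth, called = dc$differential)
```

## Bench-assay statistics

* **Ig rearrangement frequency**: 2^ΔCt with ΔCt = Ct_Actb − Ct_Ig; a
  fully rearranged locus amplifying with the reference gives frequency 1.
* **Relative expression**: the ΔCt form 2^(Ct_Actb − Ct_gene); the
  fold-of-control (ΔΔCt) quantity is obtained by composing with
  `normalize_to_control()`, keeping the two normalizations separable.
* **Comet outliers**: a cell is an outlier when |tail moment − median| ≥
  3 · MAD, with the MAD *unscaled* (median of absolute deviations, no
  1.4826 consistency factor) — the literal reading of the rule. When
  MAD = 0 the literal rule would flag every cell; instead only cells with
  nonzero deviation are flagged, preserving the rule's intent of marking
  departures from a tight distribution.
* **γH2AX foci**: positive at ≥ 4 foci, negative at 0–3. Because it is
  unstated whether unscorable cells belong in the denominator, per-sample
  positive fractions are reported both over all cells and over scored
  cells; a warning marks samples under the >50-cells-per-sample
  convention.
* **Lineage counts**: WBC count × lineage fraction from flow cytometry.
* Group summaries report mean ± s.d. (and s.e.m., used by comet-style
  figures) via `group_summary()`.

## The synthetic-data generators

Every stage is testable against generators with known ground truth:

* `simulate_chip_library()` draws a Poisson total around the design depth
  and places background read starts uniformly (homogeneous Poisson per
  bp — the minimal model matching the caller's null). In spiked regions
  the expected read mass is multiplied by the fold enrichment, and the
  extra enriched reads are placed so their 150-bp fragment lies wholly
  inside the region: the region is modelled as the footprint of the bound
  locus. This keeps the mean read-start density across the region at
  enrichment × background while confining coverage enrichment to the
  region, which is what makes base-level precision a meaningful target.
  Read length (50 bp single-end) and fragment footprint are parameters;
  no fragment-size distribution is asserted since none is stated
  upstream.
* `simulate_atac_counts()` draws Poisson counts for 2 replicates per
  condition; truly differential regions have condition-A mean =
  fold × base mean.
* `simulate_ct_table()` inverts the 2^ΔCt model (Ct_Ig = Ct_Actb −
  log2 f + noise), so the noise-free round trip is the identity on
  frequencies.
* `simulate_tail_moments()` draws non-outliers from
  Normal(base, 0.2·base) truncated at 0 — a tight unimodal choice — and
  shifts outliers upward. Under the unscaled-MAD rule a Gaussian base
  yields ≈ 2% tail misclassification regardless of its s.d. (the MAD
  scales with it), so truth agreement plateaus near 98%.
* Truth labels always travel as separate columns or sidecar TSVs, never
  encoded in BED name fields.

**What passing these tests does not show.** The generators emulate none
of: mappability and blacklist artifacts, GC bias, copy-number variation,
overdispersion beyond Poisson (real ATAC replicates are negative
binomial-like), fragment-size mixtures, or chromatin contamination in
inputs. Calibration and recovery results on synthetic data bound what the
algorithms can do under their own assumptions; they are not performance
claims about the deposited genome-scale datasets, whose published peak
and region counts additionally depend on external tools (MACS, MAnorm,
ENCODE pipelines) that this package intentionally does not re-implement.

## Numerical and design notes

* Coordinates are 0-based half-open everywhere internally and in BED
  output; SAM's 1-based positions are converted at the boundary.
* Strict `<` for the peak threshold (as stated upstream), inclusive `≤`
  for the differential thresholds and the TSS-class boundaries (also as
  stated).
* Summit ties break to the leftmost maximal window; peak names are ranks
  by best P-value; BED scores are ⌊min(1000, −10·log₁₀ min P)⌋ with P
  floored at 10⁻³⁰⁰.
* Degenerate inputs: empty IP or input libraries are explicit errors
  naming the library; empty fragment sets count as zero everywhere;
  all-constant comet samples flag nothing; a chromosome without TSSs
  classes its peaks as far with distance `NA`.
* Workflow runs (`run_pipeline()`) write their resolved configuration and
  a log without timestamps, so identical configurations reproduce
  byte-identical outputs.
* Test and acceptance runs use 100-kb single-chromosome genomes at depths
  4×10³–2×10⁵ reads and 10 replicate seeds per property — sizes at which
  the brute-force oracles (direct PMF summation, per-base membership
  arrays) remain exact and the whole suite runs in about a minute.

## Known limitations

* The Poisson surrogate for MAnorm reproduces the published decision rule
  but not MAnorm's normalization; genome-scale region lists will differ.
* Peak calling is single-condition, pooled-replicate (replicates are
  concatenated before dedup), narrow-peak only; no paired-end fragment
  inference.
* The GREAT-like association is the default basal-plus-extension rule
  only, with no curated regulatory domains and no enrichment statistics.
* TSV I/O has no quoting dialect; fields containing tabs are refused
  rather than quoted.
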