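---
title: "Models and methods behind gridedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gridedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridedit)
```

`gridedit` models an arrayed gene-editing screen: guides transcribed in one
pot, transfected cells confined one-per-microfeature on a printed grid,
imaged daily, counted, classified by growth, and genotyped by amplicon
sequencing or gel. This vignette explains each model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and the cut site

All sequence coordinates are 0-based, half-open, reported on the + strand.
Cas9 cuts bluntly between the 3rd and 4th nucleotide upstream of the NGG
PAM; `cut_site` stores the bond as the number of + strand bases to its left
(for a + strand guide this is also the index of the PAM-proximal flanking
base). Cut-site arithmetic then makes paired-guide predictions exact:
`expected_deletion_bp = |cut_b − cut_a|`, and the edited genotyping amplicon
is shorter by exactly that amount.

## One-pot guide design

`find_targets()` enumerates every 23-nt window ending in NGG on either
strand — a complete scan, not a scored ranking; on-target efficiency and
genome-wide off-target search are out of scope. The forward primer
assembled by `assemble_forward_primer()` is `T7min + (G-)spacer + overlap`.
Two defaults substitute for vendor-specific sequences and are configurable:
the minimal T7 promoter `TAATACGACTCACTATAG` (its trailing G is the +1
transcription start; a G is prefixed to spacers that lack one, since T7
initiates poorly otherwise) and a synthetic scaffold template — the
canonical S. pyogenes conserved sgRNA region plus a poly-T terminator —
whose first 15 nt form the primer's annealing overlap.

## The plate and image simulator

`plate_layout()` defaults describe the standard geometry: a 20 × 20 grid of
300 µm circular features per well (400 per well, 2,400 per 6-well plate),
imaged one field per feature at 0.5 px/µm (2 µm pixels, a typical 10×
acquisition after binning); the field covers the feature disk with a 15%
margin (172 px square by default).

Seeding is clonal: founders per feature are Poisson(λ), default λ = 1;
`poisson_seeding()` gives the design numbers, e.g. `P(0 or 1) = 2/e ≈ 0.74`
at λ = 1. Division is a discrete-time branching process evaluated once per
day, matching the daily imaging cadence: each cell survives with
probability `1 − death_prob_per_day`, then divides with probability
`exp(r) − 1`. The expected per-day multiplier is `(1 − d)·e^r`; `r = ln 2`
(the default — a one-day doubling time, typical of pluripotent stem cells)
makes division certain and the colony deterministic. Rates above `ln 2`
are rejected in stochastic mode because a cell divides at most once between
daily images. `stochastic = FALSE` switches to noise-free exponential
colony growth (counts are the rounded sizes `n₀·e^{r·days}`), isolating
imaging noise from division noise — used wherever a test needs growth-rate
populations whose separation is limited only by the measurement chain.

Nuclei are rendered as 2-D Gaussian spots (σ = radius/2) confined to the
feature disk, with centre placement by rejection sampling at a 2.4-radius
exclusion distance (relaxed when crowded), on a flat background with
additive Gaussian read-out noise, quantised to 16-bit. Defaults — 5 px
nucleus radius, peak ≈ 20,000 ± 2,000 counts, background 1,000, noise
σ = 200 — give SNR ≈ 100, comfortably above the SNR ≥ 5 regime the
counting pipeline is specified for. Real micrographs differ in ways the
simulator deliberately omits: textured chromatin, focus drift, debris,
mitotic figures, and colonies that pile up in 3-D. Passing tests therefore
demonstrate correctness of the measurement chain under the stated noise
model, not segmentation performance on arbitrary real data. In particular
the nuclei-counting model assumes colonies remain a near-monolayer of
resolvable nuclei; once a colony overfills its feature (≳ 60–100 nuclei at
the default geometry) counts saturate and under-read, so growth analyses
should use imaging windows that keep colonies within that domain.

## Illumination correction and counting

Shading is modelled as a smooth multiplicative surface. `correct_illumination()`
fits a second-degree polynomial in the pixel coordinates by robust
M-estimation (`MASS::rlm`, Huber weights) to a background band
(pixels ≤ median + 4·MAD, thinned deterministically to ≤ 4,000 for speed),
normalises it to mean one, and divides it out. Robust fitting matters: the
skirts of bright nuclei otherwise bias an ordinary least-squares surface
upward near objects. Flat fields pass through unchanged to ~1e-6 relative,
the operation is idempotent to tolerance, and an all-zero image returns
unchanged with a warning.

`segment_nuclei()` thresholds the corrected image with Otsu's method,
labels connected components, and (by default) declumps touching nuclei by
watershed on the distance transform (tolerance 1, 8-connected seeds).
Because Otsu always bisects a histogram, an empty field would otherwise
segment its noise: a guard requires the absolute threshold to clear the
image median by 5 robust SDs, else zero objects are reported. Components
below `min_area_px` (default 25% of the expected nucleus area, πr²) are
discarded as debris. Counting is invariant to a constant intensity offset.

`process_plate()` maps `well{W}_pos{RRR}x{CCC}_day{D}.tif` filenames to
grid coordinates and produces one count record per image; records persist
in a single keyed CSV store with upsert semantics (re-processing replaces,
with a warning) — a deliberately file-backed stand-in for a database
server, preserving the keyed-join contract without the deployment.

## Growth analysis

`join_timepoints()` joins records on (well, grid_row, grid_col); missing
days stay gaps. Fits are ordinary least squares on `(day, log n)` — slope
= rate, doubling time = `ln 2 / rate`, infinite for non-positive rates.
Zero counts are excluded rather than pseudocounted (a pseudocount would
bias small-colony rates; the exclusion count is recorded), and fewer than
two usable points yields an explicit no-fit row. `r_squared` is reported
only from three points up.

Classification replaces the manual curation such screens often rely on
with explicit thresholds: by default tertiles of the final-day count
(rate is available as an alternative statistic), boundary values going to
the higher class; when a heavily discrete statistic makes the tertiles
tie, the tied value maps to the intermediate class. Group comparison is a
pooled-variance Student two-tailed t test (Welch by flag, Bonferroni by
flag, no correction by default since single comparisons are the norm
here); two constant equal groups return t = 0, p = 1 by convention.

A limitation worth stating plainly: with single-cell founders, the
branching process itself makes growth classes overlap — an
intermediate-rate clone has a non-negligible probability (~5–15% across
reasonable intermediate rates over 6 days) of a count trajectory
indistinguishable from a low- or high-rate clone, so a perfectly diagonal
clone-level confusion matrix is only achievable when division noise is
absent. The acceptance check for three-rate classification therefore runs
the generator in deterministic mode through the full imaging pipeline
(25–49 features per population, 5 days, λ = 0.8 to keep colonies inside
the countable regime), and the stochastic case is tested separately with
an accuracy criterion rather than an exactness one.

## Amplicon read simulation and indel quantification

Simulated reads carry one deletion (default probability 0.85 among edited
reads, the empirically typical NHEJ mixture) or insertion (0.15), with
length uniform on 1–30 nt — chosen for maximum-entropy neutrality since no
canonical length law is agreed; under it exactly 1/3 of indels are
in-frame, the "random chance" baseline
(`expected_inframe_fraction(1:30)`). Indels centre on the cut bond with
signed Gaussian jitter (σ = 1 nt). Sequencing errors are substitutions
only by default so that every called indel is attributable to an edit; an
`error_indels` flag adds rare 1-nt indel errors for robustness testing.
Reads default to spanning the full amplicon (cDNA/amplicon sequencing,
not genome mapping, so there is no BAM stage).

Alignment is optimal semi-global (read global, reference free end gaps)
with affine gaps — match +2, mismatch −4, open −8, extend −1, a length-L
gap costing `open + L·extend` — computed by `Biostrings::pairwiseAlignment`
and verified in the test suite against an independent Gotoh dynamic
program on hundreds of random small instances. Indels left-align within
repeats by the aligner's deterministic tie-breaking.

`call_indels()` reads the "~100-nt window" convention as ±50 nt around the
cut (half-open, configurable): any insertion or deletion intersecting the
window makes the read an indel read; substitutions never do. Frame comes
from the net length (insertions positive, deletions negative) mod 3 — a
read with both an insertion and a deletion counts once, by its net; nets
of zero count as in-frame indels but are excluded from the
deletion:insertion tallies with a note. `per_base_profile()` reports, per
reference position, the fraction of covering reads matching the reference
base, with the PCR-primer flanks flagged masked (reads carry the primer
sequence verbatim there, so those positions are uninformative).

Gel genotyping is a pure band-set rule: WT-length band only → WT; WT plus
a predicted deletion product → monoallelic; deletion product(s) without WT
→ biallelic; anything unexplained → no_call. The default size tolerance is
10% of each predicted size, reflecting how semi-quantitative agarose
sizing is; the rule is exhaustively checked against an enumerated truth
table over all band subsets of a three-guide design.

## Reproducibility and problem sizes

Every generator consumes the session RNG, so `set.seed()` (or the `seed`
in `run_config()`) makes any run bit-reproducible; `run_end_to_end()`
re-emits its resolved config and per-stage record counts. The test suite
sizes its simulations to what the checks need statistically: 10,000 reads
for mixture recovery (binomial 99% intervals), one full 400-feature well
over 4 days for count/doubling-time recovery, 147 features over 5 days
for three-rate classification, 500 random instances for
aligner-vs-oracle equivalence. `scripts/acceptance.R --seed S --out F`
recomputes the deletion:insertion headline from scratch at n = 10,000.
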