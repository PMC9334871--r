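---
title: "Quantitative antibody validation by flow cytometry: models and methods"
author: "flowAbVal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative antibody validation by flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowAbVal)
```

# The problem

Commercial antibodies against alpha-synuclein (aSyn) — and against most
low-abundance intracellular antigens — are frequently used without
application-specific validation. flowAbVal implements a quantitative,
flow-cytometry-based validation workflow as reusable, tested code:

1. **Titration**: find the antibody amount with the best
   signal-to-background separation.
2. **Self-blocking**: pre-incubate the antibody with excess recombinant
   antigen; a specific antibody loses its staining signal.
3. **Cross-reactivity panel**: repeat the blocking with related proteins
   (here beta-/gamma-synuclein and tubulin); residual blocking by a
   non-antigen flags cross-reactivity.
4. **Expression mapping**: compare the stain index across cell types to
   characterize sensitivity.
5. **Physiological contrast**: confirm the antibody resolves a known
   biological difference (gene-dosage or knockdown contrast).

A sequence-level screen (affine-gap pairwise alignment of the antibody
epitopes against candidate cross-reactants) and a Li-threshold image
quantification round out the toolkit.

# Statistics

All cytometry statistics operate on gated live singlet events after
optional spillover compensation ($y = x S^{-1}$ on row vectors, scatter
channels untouched, negative compensated values retained but counted).

* **MFI** — arithmetic mean of a population's intensities on one
  channel. The analysis software behind the original numbers does not
  state mean vs. median; the arithmetic mean is used here, with a median
  option behind a flag for robustness studies.
* **Stain index** $SI = (\mathrm{MFI}_{ab} - \mathrm{MFI}_{iso}) /
  (2\,\mathrm{SD}_{iso})$ — separation of the stained population from
  its isotype control in units of twice the background SD. One figure
  caption paraphrases this as a "ratio"; the difference form above is
  the standard definition, matches the worked numbers, and is the one
  implemented. SI is invariant under affine intensity transforms, which
  the tests exercise directly.
* **Ratio MFI** $= \mathrm{MFI}_{x\,\mu g} / \mathrm{MFI}_{ref}$ — fold
  change against the manufacturer-recommended amount, computed for both
  the antibody and its isotype control.
* **Normalized MFI** — either $\mathrm{MFI}_{ab}/\mathrm{MFI}_{iso}$
  (ratio form) or $\mathrm{MFI}_{ab}-\mathrm{MFI}_{iso}$ (difference
  form). Both conventions appear in practice; callers must choose, and
  the form is recorded in every output.
* **Blocking efficiency** $E = (\mathrm{MFI}_{stained} -
  \mathrm{MFI}_{blocked}) / (\mathrm{MFI}_{stained} -
  \mathrm{MFI}_{nostain})$ — the fraction of specific signal removed by
  pre-incubation. Values outside $[0, 1]$ are flagged, never clipped,
  because "no detectable blocking" is a scientifically distinct outcome
  for low-sensitivity antibodies in low-expressing cells. When
  $\mathrm{MFI}_{stained} \le \mathrm{MFI}_{nostain}$ the statistic is
  undefined and an error with class `undefined_blocking` is raised.
* **Western-blot normalization** — band intensity over beta-actin, then
  over the untreated reference lane; the package consumes quantified
  band intensities only (no densitometry).

# Gating

Two strategies reproduce the standard two-branch hierarchy, and both are
plain geometric gates (no automated clustering): `scatter_only` excludes
debris and dead cells on an FSC-H x FSC-Width rectangle;
`viability_dye` excludes dye-positive dead cells by threshold. Both end
with singlet selection on the pulse area-to-height ratio. Design
choices, all configurable:

* Gate regions are **closed** (boundary events included) so gating is
  deterministic and idempotent; polygons use the even-odd rule.
* The published strategy shows plots, not coordinates, so default
  geometry is chosen for the synthetic data scale
  (`fsc_h_min = 50`, `fsc_w_max = 95`); an optional percentile helper
  (`autoDebrisGate`, trimming the lowest 5% of FSC-H and top 5% of
  FSC-Width) exists but is off by default.
* The singlet band is $[0.8, 1.25]$ on the **median-normalized** A/H
  ratio: dividing by the median centres the singlet mode at 1, so the
  band transfers across instruments; doublets sit near 2 and are
  excluded. Raw-ratio gating is available with `normalize = FALSE`.
* `qcMinEvents` enforces the 20,000-event acquisition floor.

# Epitope similarity screen

The local (Smith–Waterman) and global (Needleman–Wunsch) affine-gap
aligners are original three-state (Gotoh) dynamic programs, with
BLOSUM62 and gap open 10 / extend 0.5 as defaults, matching the common
reference-tool settings. Conventions pinned:

* **Gap cost**: a gap of length $g$ costs
  $\mathrm{open} + g\cdot\mathrm{ext}$ (`open_plus_size`), verified
  against an independent implementation; the alternative
  $\mathrm{open} + (g-1)\cdot\mathrm{ext}$ convention is selectable and
  recorded in the result metadata.
* **Global mode** uses free end gaps (dovetail semantics). When no
  positive-scoring overlap exists the sequences slide past each other
  and the score is 0. End-gap columns count in the alignment length, so
  a short peptide aligned globally to a long protein has low identity
  by construction.
* **Identity denominator** is the full alignment length including gap
  columns; similarity counts columns with positive substitution score.
* **Traceback ties** break deterministically diagonal > up > left, and
  local alignments end at the first-occurring maximal cell; scores are
  unaffected by tie-breaking, identities can differ by one column in
  pathological ties.

Per-epitope identities quoted from full-chain alignments use a
different convention, implemented as `epitopeIdentity()`: restrict the
full antigen-vs-target alignment to the columns covering the epitope
and divide identical residues by the **epitope length**. On the bundled
sequences this reproduces the published figures — 3/8 = 37.5% for the
LB509 epitope (aSyn 115–122) against both pig alpha-tubulin chains,
6/35 ≈ 17% for the 2A7 epitope (aSyn 61–95, the NAC region) against
alpha-1A, and a best local region of full aSyn against human TUBB3 of
33% identity spanning aSyn 114–131, overlapping the LB509/MJFR1
epitopes — the sequence-level rationale for the observed tubulin
cross-reactivity of C-terminal binders.

**Limitation.** The bundled FASTA was transcribed without database
access and is verified against the published alignment statistics of
the aligned regions; residues outside those regions carry transcription
risk. In particular the two pig alpha-tubulin isotype entries are
identical in this copy, so the published 23% figure for the 2A7 epitope
against alpha-1B (vs. 17% for alpha-1A), which depends on true
isotype-specific residues, is **not** reproduced; the corresponding
acceptance assertion is intentionally left failing rather than fitting
residues to the number. Replacing the FASTA with database copies of
SYUA_HUMAN, TBA1A_PIG, TBA1B_PIG, TBB_PIG and TBB3_HUMAN restores the
full check without code changes.

# Li-threshold image quantification

`liThreshold` implements the minimum-cross-entropy threshold via the
standard fixed-point iteration
$t' = (\mu_b(t) - \mu_f(t)) / (\ln\mu_b(t) - \ln\mu_f(t))$ with a
convergence tolerance of 0.5 intensity units. The update has one fixed
point per histogram valley, so the iteration is run from a
deterministic set of quantile starts and the fixed point with the
lowest cross-entropy is returned; tests compare it against an
exhaustive scan of every candidate threshold, treating thresholds in
the same histogram gap as equivalent (they induce the same mask) and
requiring the background/foreground boundary to agree within one
intensity unit. `quantifyICC` masks marker pixels **at or above** the
threshold (inclusive, no morphological cleanup, native bit depth, no
background subtraction) and reports the mean gray value of the target
channel inside the mask. The "constant threshold" batch protocol is
read as: one Li threshold from a designated reference image (or the
pooled histogram) applied batch-wide; a per-image mode exists for
sensitivity analysis.

# Synthetic data: what it emulates, and what it does not

The generator is first-class, tested code; every recovery test reads
its ground truth from the generator's own record.

* **Fluorescence and viability dye**: lognormal, parameterised by
  geometric mean and arithmetic CV (default CV 0.5, a typical width for
  a stained unimodal population). Specs are written in terms of the
  arithmetic mean — the quantity MFI estimates.
* **Scatter**: normal truncated at zero. Defaults: live singlets
  FSC-H 110 ± 12, debris 20 ± 4, dead 30 ± 4 (scatter separation from
  live cells > 6 SD, so scatter gating can succeed), FSC-Width 60 ± 8
  with doublets at 110 ± 10.
* **Composition**: 70% live singlets, 10% each debris / dead /
  doublets, 20,000 events — a clean preparation at the standard
  acquisition scale. Labels are drawn multinomially, so realized counts
  fluctuate binomially.
* **Doublets** are sums of two live-singlet draws on area channels with
  a singlet-like height, giving an area/height ratio near 2.
* **Dead cells** carry a 20-fold elevated dye signal.
* **Titration** follows a saturation-binding model:
  antibody signal $= b + B_{max}\,c/(K_d + c) + s\,c$, isotype signal
  $= b + s\,c$ — specific binding saturates while nonspecific binding
  grows linearly in the amount $c$.
* **Blocking** scales the specific component by $1 - \kappa$, leaving
  background untouched, so the ground-truth efficiency equals $\kappa$
  exactly under the workflow's formula. The excess-fold exponent
  defaults to $h = 0$ (the 300- and 600-fold conditions block equally,
  as observed); it is configurable for sensitivity studies.
* **Determinism**: every output is a pure function of (spec, seed); the
  caller's RNG state is never touched.

Not emulated: spectral spillover realism, autofluorescence spectra,
instrument noise beyond the lognormal/normal families, doublet pulse
shapes, or cell-cycle structure. Passing recovery tests therefore shows
the estimators and decision rules are correct under the stated
statistical model — not that gate geometry or thresholds transfer to
any particular instrument's raw data.

# Decision layer defaults

* **Optimal amount**: smallest tested amount with
  $SI \ge \theta \cdot \max SI$ (default $\theta = 0.75$), optionally
  capped by the isotype ratio MFI. The published choices never state a
  formal rule; this is the simplest policy that reproduces all three
  published titration decisions (2 µg, 1 µg, 0.1 µg) from their printed
  SI tables, and $\theta$ is exposed. At $\theta = 1$ it returns the
  max-SI amount; as $\theta \to 0$ the smallest tested amount.
* **Specificity**: mean self-blocking efficiency ≥ 0.85 ⇒ specific;
  non-self blocker mean ≥ 0.40 ⇒ cross-reactive flag. Both thresholds
  are calibrated to the published verbal classifications and
  configurable. Mixtures containing the antigen and alternative antigen
  species (aggregates) are never counted as cross-reactants.
* **Expression classes**: relative-plus-floor — `not_detected` at
  SI ≤ 0.5 or missing, `marginal` below 1.5, `detected` otherwise, plus
  an SI-descending ordering; published "high/moderate/low" labels come
  from prior literature, not fixed SI cutoffs, so only the ordering and
  a detection floor are formalized.
* **Ranking**: specific first, then fewer cross-reactivity flags, then
  higher self-blocking efficiency; remaining ties keep input order.

# Problem sizes and test design

Unit and property tests run at 2,000–20,000 events per sample; all
recovery claims (MFI within 2%, SI within 10%, blocking efficiency
within ±0.05, ≥99% live-singlet recovery) are checked at the full
20,000-event scale. The alignment DP is verified against exhaustive
enumeration of all alignments for short sequences over a 4-letter
alphabet (all pairs to length 2, seeded random pairs to length 6 —
enumeration grows too fast for the full length-6 cross) and against an
independent library implementation on longer peptides. The end-to-end
ranking simulation uses 100 seeded replicates of a three-antibody
blocking design mirroring the published truth (high-specificity clone
with one weak cross-reactant; specific clone with two cross-reactants;
poorly blockable clone). `scripts/acceptance.R` re-runs all of this
from scratch against the installed package.

# Known limitations

* FCS support covers list-mode FCS 3.0/3.1 with `$DATATYPE` F or I —
  the dialects of current instruments; other datatypes are rejected
  with a clear message. CSV (+ JSON sidecar) is the canonical,
  bit-exact interchange format.
* No spillover matrix accompanies the published workflow, so
  compensation correctness is testable only as a mathematical contract
  (identity, linearity, inversion round trip).
* Real cell-line results (per-cell-type SI values, knockdown and
  gene-dosage contrasts) require the original FCS files and images;
  the package covers them through synthetic analogues whose generating
  truth encodes the same contrasts (e.g. normalized MFI 11.8 vs 8.4;
  3-fold and 1.4-fold contrasts), which the pipeline recovers within
  its stated tolerances.
* The bundled reference sequences carry the transcription caveat
  described above.
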