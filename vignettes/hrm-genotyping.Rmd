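---
title: "Closed-tube melt-curve genotyping of the Manitoba SCID founder mutations"
author: "scidHRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-tube melt-curve genotyping of the Manitoba SCID founder mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scidHRM)
```

## The assay and what this package models

Most severe combined immunodeficiency (SCID) in Manitoba is caused by two
founder mutations that leave circulating T-cell numbers normal and
therefore escape TREC-based newborn screening: an intronic splice-site
substitution in *ZAP70* (c.1624-11G>A, Mennonite) and a single-base
duplication in *IKBKB* (c.1292dupG, Northern Cree). Both can be genotyped
directly from the newborn dried-blood-spot DNA in one closed-tube
reaction: two short amplicons (<100 bp, one per locus) are amplified in a
multiplex with a saturating double-strand-specific dye, and fluorescence
is read while the temperature is ramped from 75 to 95 °C in 0.2 °C steps.
Each amplicon denatures over a narrow temperature interval; the shape and
position of its melt transition encode the genotype. Short amplicons are
used deliberately: the fewer base pairs in the duplex, the larger the
relative effect of a single-base change on its melting temperature.

`scidHRM` implements this assay end to end as testable software: a
thermodynamic simulator that generates realistic plate data for any
genotype combination, and the analysis chain that turns raw plate
fluorescence into per-locus three-state genotype calls
(`wild_type`, `heterozygous`, `homozygous_affected`) with confidence
scores and explicit refusals (`no_call`).

## Duplex thermodynamics and the melt model

Melting temperatures are computed from unified nearest-neighbor
thermodynamics: for a duplex of length $N$,
$\Delta H$ and $\Delta S$ are sums over the $N-1$ dinucleotide stacks plus
duplex-initiation terms for the two ends, and

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+] +
R \ln(C_T/4)} - 273.15 .$$

The parameter table ships as a plain-text file and is swappable. The
default conditions are $C_T = 200$ nM total strand — the assay's
in-reaction IKBKB primer concentration — and an effective monovalent
cation concentration of 110 mM, representing the ionic strength of a
qPCR master mix (monovalent salts, Tris and the Mg²⁺ contribution).
Under these defaults the four published primer melting temperatures are
reproduced to within 0.25 °C, which is why they were frozen as package
defaults; both are exposed in the configuration.

Each amplicon/genotype combination is described as a mixture of duplex
species. A homozygote carries one homoduplex whose $T_m$ is computed by
re-running the nearest-neighbor sums on the wild-type or mutant sequence.
A heterozygote denatures and randomly reanneals in the final PCR step into
four species at mole fraction 0.25 each: both homoduplexes and two
mismatched (ZAP70) or single-base-bulged (IKBKB) heteroduplexes.
Heteroduplex $T_m$s are set to the homoduplex mean plus a destabilization
of −3 °C (single-base mismatch) or −4 °C (single-base bulge), order-of-
magnitude values from melting practice, both configurable. Each species
melts as a two-state logistic in temperature with width 0.35 °C
(configurable), justified for sub-100-bp amplicons.

### Synthetic amplicon fixtures

The true genomic amplicon sequences are not published; the package ships
*synthetic* fixtures that begin and end with the published primers and
have engineered interior filler. Two constraints fixed the filler: the
two wild-type transitions must sit in well-separated domains of the
75–95 °C window with room for the heteroduplex transitions and
normalization cursors (ZAP70 ≈ 81.6 °C, IKBKB ≈ 91.4 °C), and the
mutations must displace $T_m$ by clearly more than the instrument's
thermal calibration error. The ZAP70 fixture is 84 bp with the G>A site
in a C·G·C context (ΔT_m ≈ −0.63 °C). The IKBKB fixture is 68 bp — a
duplicated G always adds exactly one GG stack, and the shorter the
amplicon the larger the resulting shift (ΔT_m ≈ +0.28 °C at 68 bp versus
+0.21 °C at 90 bp); this is the assay's own short-amplicon rationale
applied to the fixture. The fixtures claim no genomic fidelity and are
labelled synthetic.

## The simulator

A raw well signal is

$$s(T) = b_0 + m\,(T - T_0) + \sum_{a} A_a \sum_k f_k\,
\theta(T;\,T_{m,k} + \delta,\;w) + \varepsilon(T)$$

with $\theta$ the logistic helicity falling from 1 to 0. The nuisance
terms emulate what makes real plates hard: per-amplicon amplitudes
$A_a$ (nominal 50 RFU each) carry a lognormal coefficient of variation of
0.15 (amplification-yield differences — the "variable starting intensity"
that normalization exists to remove); the background slope $m$ is drawn
uniformly from −0.2 to −0.05 RFU/°C per well; each well has a thermal
calibration offset $\delta \sim N(0, 0.05\ \mathrm{°C})$ applied to every
species; and $\varepsilon$ is white read noise with s.d. 1% of the
nominal pre-melt amplitude. A single seeded generator drives each plate
and the seed is recorded in the plate metadata, so simulations are
bit-for-bit reproducible.

What the generator does **not** emulate: multi-domain statistical-
mechanical melting (everything is two-state), dye redistribution
chemistry, PCR plateau differences between genotypes, spatial plate
effects, inhibited or partially amplified specimens, and DNA from
genotypes other than the two founder alleles. Passing tests therefore
demonstrate that the analysis chain correctly inverts this generative
model at realistic noise; they cannot certify performance on real
instrument exports, which is what plate-run controls are for.

## The analysis chain

Per plate: build a control-anchored reference, then for every well
smooth → QC → normalize per domain → thermally calibrate → shift →
difference curve → nearest-centroid classification.

**Smoothing and peaks.** Savitzky–Golay filtering (window 7, order 3 —
wide enough to suppress read noise, narrow enough to preserve 0.35 °C
transitions on the 0.2 °C grid). Melt peaks are local maxima of
−d(RFU)/dT with topographic prominence of at least 25% of the global
maximum and an absolute height floor of 8 RFU/°C; the floor suppresses
noise-only "peaks" in template-free wells (true peaks are ~35 RFU/°C at
the simulator scale). A well whose peak count differs from two is flagged
`domain_count_mismatch` but still processed. Wells with a whole-curve
dynamic range under 10 RFU are refused with `low_amplitude`.

**Domains and normalization cursors.** The two analysis domains are fixed
temperature intervals from the configuration, like the manually placed
cursors of melt-analysis software: ZAP70 uses pre-melt
[75.0, 76.8] °C and post-melt [83.2, 86.2] °C; IKBKB uses
[83.2, 86.2] °C and [93.2, 95.0] °C (the inter-domain plateau serves as
ZAP70's post and IKBKB's pre window). Cursor positions were chosen from
the species layout: every window must be at least ~1.3 °C clear of the
nearest transition of *any* genotype, which is also why the fixtures'
wild-type $T_m$s sit where they do. A valley-based domain splitter
(`splitDomains()`) is provided for exploratory use, but the caller does
not depend on valley positions, which are numerically unstable on the
long flat stretch between the domains.

Within each domain the curve is normalized by the standard two-baseline
convention, $\hat s = (s - \ell_{post})/(\ell_{pre} - \ell_{post})$. Two
numerical choices matter here. First, the baselines are fitted on the
*raw* signal and the normalized curve is smoothed afterwards: smoothing
first correlates the window points and destroys the averaging the fit
depends on. Second, the two baselines share one slope; better still, the
pipeline fixes that slope at the plate-wide median of per-well estimates.
A slope fitted inside a 2–3 °C window is several times noisier than the
true well-to-well background variation and, extrapolated to mid-domain,
bows the normalized curve by several percent; a common plate slope makes
whatever error remains common to every well *and* the reference, so it
cancels in the difference curves. The normalization remains exactly
invariant to per-well amplitude scaling and to any linear background
added to a curve (a property the tests verify), at the cost that per-well
slope *differences* from the plate median are left uncorrected — under
the simulator's slope range their effect is below read noise.

**Thermal calibration.** One calibration offset applies to a whole well,
while genotypes displace transitions locus-specifically, so the two must
be separated before curves can be compared. Aligning every curve at a
single helicity crossing (the classical temperature-shift rule) would
erase a homozygote's $T_m$ displacement — its only signal. Instead each
well is registered at three helicity levels (0.25, 0.40, 0.70) per locus;
levels were chosen to avoid a 50/50 heterozygote's half-melted plateau at
0.5 and to include the heteroduplex transition (0.70). Control wells,
whose genotypes are known, provide each genotype's *displacement profile*
across the levels. Every genotype-pair hypothesis then predicts all six
registration points up to one shared offset and is scored by a Gaussian
criterion:

* quadratic misfit of each registration point, weighted by its measured
  precision — read noise divided by the local descent rate of the curve
  at the crossing, plus a systematic term (s.d. 0.08 °C) for
  variant-genotype registrations, whose composite transitions are more
  sensitive to normalization error;
* a Gaussian prior on the shared offset (s.d. 0.06 °C: the instrument
  offset plus the sampling error of the three-control reference) — this
  is what stops a genotype displacement from masquerading as pure
  calibration;
* a rarity penalty of 2.2 log-units per variant locus (variants are rare
  in a screening population).

The winning hypothesis calibrates the well: loci it declares wild type
align by their own measured shift; variant loci borrow the
wild-type-anchored offset, so their genotype displacement is *measured*
by the classifier rather than forced. Two safety valves follow. A
definite alignment must beat, by 3 log-units (20:1 odds), every
alternative hypothesis whose applied shift differs by more than 0.1 °C —
otherwise the affected locus is refused (`no_call`). And hypotheses that
are internally inconsistent (standardized residual above 3.5) or require
an offset beyond 0.35 °C are rejected; a rejected well is left
uncorrected (shift 0) unless its pattern is consistently all-wild-type
beyond the cap, which is pure calibration drift and is applied clipped.
When a plate carries no variant controls the displacement table is empty,
a variant-bearing well cannot be calibrated, and the caller degrades to a
two-way wild-type/not-wild-type decision in which a variant locus is
*never* called homozygous normal.

**Classification.** For each locus the calibrated, shifted curve minus
the reference — restricted to the inter-window melt region, where the
genotype information lives and plateaus contribute only noise — is the
difference curve. Calls are nearest-centroid over the genotype centroids
learned from control wells (the wild-type centroid is the zero curve by
construction), with the `max_abs` metric: genotype signatures are
localized and a maximum statistic preserves them, while the extra
smoothing of the normalized stage (window 9) keeps its noise tails in
check. Confidence is $1 - d_1/(d_1 + d_2)$; a call degrades to `no_call`
below the 0.7 floor (a curve exactly midway between two centroids scores
0.5) or when the nearest distance exceeds the outlier threshold, three
times the maximum within-control distance floored at 0.1. The floor was
derived from the cluster geometry under the default noise model:
within-cluster distances stay below ~0.07 (variant clusters anchored on
single control wells spread more than the wild-type cluster), while the
closest between-cluster separation (wild type vs IKBKB homozygote) is
~0.19. A refusal is always preferred over a guess: in newborn screening a
false negative is the failure mode that matters.

## Tunables

All knobs live in one flat key–value configuration
(`defaultRunConfig()`, `readRunConfig()`); the important ones:

| key | default | meaning |
|---|---|---|
| `thermo.oligo_conc` | 2e-7 M | total strand concentration in the Tm convention |
| `thermo.monovalent` | 0.11 M | effective monovalent cations |
| `sim.rfu_sigma` | 0.01 | read noise, fraction of nominal amplitude |
| `sim.amplitude_cv` | 0.15 | per-amplicon yield variation |
| `sim.temp_offset_sigma` | 0.05 °C | per-well thermal offset |
| `sim.delta_zap70` / `sim.delta_ikbkb` | −3 / −4 °C | heteroduplex destabilization |
| `curve.smooth_window` / `norm_smooth_window` | 7 / 9 pts | Savitzky–Golay windows |
| `curve.calibration_levels` | 0.25, 0.40, 0.70 | registration helicity levels |
| `curve.max_shift` | 0.35 °C | calibration cap |
| `call.confidence_floor` | 0.7 | minimum confidence for a definite call |
| `call.outlier_multiplier` / `outlier_min` | 3 / 0.1 | outlier threshold |

## Problem sizes used in the tests

The shipped test suite and acceptance script run entirely on simulated
data (the clinical dried-blood-spot data are not public). Cohort sizes
mirror the study design: 60 unaffected controls over three seeds, the
46-sample at-risk cohort (3/6/1 ZAP70 and 2/14/20 IKBKB
affected/heterozygous/normal), and a mixed-genotype stress test of five
100-well plates covering all nine genotype pairs. Property checks use
100 random noiseless curves (normalization), 50 random transitions
($T_m$ recovery), 1000 random sequences (duplex symmetry) and a 500-seed
average (simulator unbiasedness).

## Known limitations

* Only the two founder alleles are modelled; any other variant in either
  amplicon would produce an unfamiliar difference curve and, by design,
  a `no_call`, not an identification.
* Genotype calling is control-anchored; a plate without wild-type
  controls cannot be analysed, and without variant controls only
  wild-type calls are issued.
* The two-state logistic melt shape and the synthetic fixtures make the
  simulator a model of the assay, not of any particular instrument;
  absolute thresholds (peak height floor, minimum amplitude) are set for
  the simulator's RFU scale and should be reviewed against real exports.
* The calibration machinery assumes exactly two loci; extending the
  multiplex would generalize the hypothesis space combinatorially.
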