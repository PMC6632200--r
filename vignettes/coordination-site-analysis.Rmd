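---
title: "Quantifying extracellular cation coordination sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extracellular cation coordination sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsite)
```

`ionsite` quantifies transient cation coordination sites on the surface
of membrane transport proteins, with the extracellular P71/D75/D501/K504
pocket of the rice Na⁺/K⁺ symporter *Os*HKT2;2 as the motivating
system. This vignette explains the statistical models behind each
analysis, the parameters that matter and why their defaults were
chosen, what the synthetic generators do and do not emulate, and the
numerical conventions a careful user should know about.

## The contact-frequency model

A residue "is approached" by an ion in a frame when the minimum
distance from the ion to any heavy atom of the residue is at most the
contact cutoff. The defaults encode three deliberate choices:

* **Cutoff 4.0 Å, boundary inclusive.** 4 Å is the conventional
  first-shell criterion for cation–protein contacts; we treat a
  distance of exactly 4.0 Å as a contact (`d <= cutoff`). The boundary
  convention is measurable, so tests probe it with strictly interior
  (3.9 Å) and exterior (4.1 Å) points.
* **Heavy atoms only.** Cations are coordinated through O/N lone
  pairs; hydrogens are both physically irrelevant here and absent from
  most structure templates. `heavy_only = FALSE` is available for
  completeness.
* **Per-(ion, frame) counting.** When two ions sit at a residue in the
  same frame, the default `ion_frame_pairs` convention counts two
  contacts. We chose it because dwell statistics downstream are kept
  per ion, so per-ion bookkeeping is the consistent convention; a
  published table whose relative frequencies can exceed 100% of frames
  is also only explicable under this convention. The alternative
  (`any_ion_per_frame`, counts bounded by the frame total) is a
  parameter, and both are validated against a brute-force recount.

Relative frequencies are `count / n_frames * 100`. Replicate merging
sums counts and frame totals and recomputes the percentages, which is
provably identical to recounting the concatenated trajectory. When
combining species on a table loaded from a publication (where the frame
total is unknown, `n_frames = NA`), the combined percentage falls back
to summing the printed per-species percentages — 2-decimal printed
arithmetic, which is exactly what an internal-consistency check of such
a table should use.

Candidate sites are residues whose combined relative frequency reaches
`rel_threshold` (default 1%), grouped by single linkage on minimum
heavy-atom inter-residue distance with `link_cutoff = 8` Å (inclusive).
The defaults were set from the geometry of the target pocket — residues
a few Å apart across a surface depression must cluster together while
hot spots tens of Å apart must not — and both are exposed as
parameters.

## Approach events and dwell statistics

Site occupancy of one ion is a boolean per frame (minimum distance to
any site member atom ≤ site cutoff). Events are maximal runs of
occupied frames. Two details:

* **Debouncing.** `debounce_gap` (default 0) fuses two runs separated
  by at most that many unoccupied frames, counting the gap toward the
  event duration. The default means a single-frame exit terminates an
  approach; because approach *counts* are sensitive to the frame-saving
  stride of the source trajectory, the parameter exists and is recorded
  in outputs rather than hidden.
* **Dwell percentage conventions.** The per-species dwell percentage is
  by default the mean over that species' ions of each ion's
  occupied-frame fraction; a `union` statistic (fraction of frames with
  ≥ 1 ion of the species in the site) is also provided. Published
  per-simulation totals are ambiguous between the two, so both are
  computable; the mean convention is the default because it matches the
  per-ion Markov ground truth of the generator exactly.

Mean dwell is total occupied frames divided by the number of events; it
is reported as absent when there are no events rather than as 0 or NaN.

## Coordination geometry

While an ion occupies the site, its distances to candidate coordinating
atoms are summarized by the in-site mean, the *population* standard
deviation (divide by `n`; the in-site frames are the entire population
of interest, and the convention is configurable), and the fraction of
in-site frames below a species-specific proximity threshold. An atom is
called coordinating when that fraction reaches `occupancy_fraction`
(default 0.25, inclusive).

The proximity thresholds — Na⁺ 2.6 Å, K⁺ 3.0 Å — are first-shell
cation–oxygen distances. A single threshold will not do: K⁺ coordinates
at systematically longer range (typical in-site K–O means run
2.6–2.9 Å), so a Na⁺-calibrated 2.5 Å criterion would wrongly reject
genuine K⁺ coordination. Calls are withheld below 50 in-site frames
(the statistic is a fraction; 50 Bernoulli observations is a minimal
basis for a 0.25 threshold). Carboxylate oxygen pairs (OD1/OD2,
OE1/OE2) are analyzed as separate atoms, because the two oxygens of an
aspartate genuinely alternate roles. Positively charged atoms (Lys NZ)
are reported but expected to fail the criterion — cation–cation
repulsion is informative output, not an error.

## Salt bridges

For a basic nitrogen against one or two acidic oxygens the package
records per-frame distances, the per-frame minimum, and which oxygen is
currently nearer (the "oriented" oxygen; ties, which have probability
zero on continuous data, go to the lower atom index). Occupancy uses
*strict* thresholds — formed below 3.2 Å, possible below 4.0 Å — in
line with the "closer than" phrasing conventional for these criteria.
Per-oxygen medians are reported both over the full series and
restricted to oriented frames; the restriction is the relevant
statistic when carboxylate oxygens alternate, and the nearest-oxygen
orientation rule is an explicit approximation recorded in the output
metadata. Distributions are exported as five-number summaries with no
outlier trimming (trimming is a plotting nicety, not a statistic).

## Conservation

Conservation is computed on alignment columns mapped from the reference
sequence's ungapped 1-based numbering ("position 75" is the 75th
non-gap character of the reference row). Percentages are over all
sequences with gaps counting as mismatches — the conservative default —
with `ignore_gaps` to switch the denominator. Residue classes (negative
= D/E, positive = K/R/H) are configurable. Phylogenetic rate-based
grades (the 1–9 scales produced by tools like ConSurf) are *not*
recomputed: they are not a function of the column composition alone, so
the package reports raw percentages and passes user-supplied grades
through for display.

The bundled `synthetic_hkt_alignment()` deserves emphasis: it is a
deterministic scaffold, not the real HKT sequences. Only the columns at
the four site positions are meaningful — they carry the reported family
compositions (P71 18/20 with one K and one S; D75 and K504 invariant;
position 501 with 12 D, 3 E, 2 N, 1 P, 1 K, 1 W) — and a 5-column
insertion gapped in the reference exercises the position mapping.
Reproducing the published percentages from the real 20 accessions would
additionally depend on the aligner and its parameters, which are not
part of this package's scope.

## Voltage-clamp analysis

The default protocol steps 1 s pulses from +20 to −160 mV in −15 mV
decrements with 1.5 s rest between pulses; −145 mV is step 12 and
serves as the normalization point (in the Na30K1 solution, 30 mM NaCl +
1 mM KCl). Within a pulse, three statistics are computed as window
means: `I_begin` over `[settle, settle + window]`, `I_end` over the
last `window` seconds, `I_avg` from `settle` to the pulse end. The
windows (settle 25 ms, window 25 ms) skip the capacitive transient and
average out noise; instantaneous samples would be noise-limited. They
are parameters, recorded in output metadata, because published
begin/end measurements rarely state their windows.

Deactivation is `(|I_begin| − |I_end|)/|I_begin| × 100`; magnitudes
make it sign-convention free and invariant to any positive gain. IV
curves default to `I_avg` (the within-pulse statistic behind published
mean IV curves is typically unstated; begin/end are selectable), are
normalized per cell by the magnitude of that cell's current at the
reference point (making curves invariant to per-cell gain and pinning
the reference at magnitude 1), and averaged across cells. Reversal
potentials come from linear interpolation between the two points
bracketing the sign change — exact for piecewise-linear input; multiple
crossings return the least-negative one with a warning. The semilog
concentration fit is ordinary least squares of `V_rev` on `log10(c)`,
reported beside the ideal Nernst slope `(RT/F)·ln 10` at a configured
temperature (default 22 °C, a typical recording-room value; the slope
is 58.6 mV/decade there). Leak subtraction is off by default — wild
type/control comparisons, not subtraction, are the norm for these
recordings — but a control-subtraction option exists.

## What the generators emulate — and what they do not

**Trajectory generator.** Each ion carries an independent two-state
Markov chain: from bulk it enters the site with probability `a` per
frame, in the site it stays with probability `s`. This yields exact
closed forms — stationary occupancy `a/(a+1−s)`, geometric dwell with
mean `1/(1−s)` frames, expected approach count `(n−1)·a·(1−occ) + occ`
— against which recovered statistics can be tested without simulation
error in the reference value. In-site frames are placed in a 2.0–3.5 Å
shell around one of the pocket's five oxygens (inside the 4 Å cutoff);
bulk frames are uniform in the box, rejected within 6 Å of any pocket
atom (outside the cutoff). The chain's mask therefore *equals* the
geometric occupancy mask by construction, making event tests exact. The
defaults — 6 Na⁺ + 6 K⁺ in a 60 Å box, `a = 0.02`, `s = 0.9` — mirror a
dilute two-species ionic pool around one protein and a site occupancy
(16.7%, mean dwell 10 frames) in the regime reported for surface
coordination sites: frequently approached, briefly held.

What this generator does **not** emulate: ions teleport between
placements (no diffusion, no forces, no correlated paths), the protein
scaffold is static, there is no water, and simultaneous ions do not
interact. Passing recovery tests therefore demonstrates the
*statistical machinery* — counting, event extraction, geometry
restricted to in-site frames — not the physics of any real trajectory.
An Ornstein–Uhlenbeck tether (`smooth = TRUE`) smooths within-visit
geometry when that matters, with placements radially clipped so the
occupancy ground truth still holds.

**Voltage-clamp generator.** Sweeps follow a linear chord-conductance
model, `I(t) = g·(V − V_rev)·[f_ss + (1−f_ss)·e^{−t/τ}]`, with
`f_ss = 1 − f` at voltages negative to `V_rev` and 1 otherwise, plus
white Gaussian noise. The default solution set reproduces the wild-type
phenomenology: microampere Na⁺ inward currents that roughly double with
1 mM K⁺, K⁺-only solutions near background, `V_rev` shifting with the
Na⁺ concentration, and deactivating fractions of 0.120, 0.107 and
0.032 at 30 mM Na⁺ with 0, 1 and 30 mM K⁺ — the reported percentage
reductions for those conditions. `analytic_window_mean()` gives the
closed-form value of any window statistic on a noise-free sweep, so
window-current recovery is tested against an integral, not another
simulation. Not emulated: GHK curvature of the IV, seal leak and drift,
series-resistance and capacitance artifacts.

## Numerical conventions and degenerate inputs

* Coordinates in Å, frames 0-based, residue numbers exactly as read
  (author numbering; "P71" is `resid = 71`). Currents in µA, voltages
  in mV, concentrations in mM, log base 10.
* Periodic distances use the orthorhombic minimum image
  (`d − L·round(d/L)` per component); triclinic boxes are rejected with
  a clear error rather than silently mishandled. The property suite
  checks the implementation against a 27-image enumeration.
* PDB I/O is delegated to bio3d (3-decimal coordinate precision bounds
  round-trip accuracy at 10⁻³ Å); CRYST1 is handled alongside because
  bio3d drops it. CHARMM ion residue names (SOD/POT/CLA) map onto
  canonical species labels; the alias table is user-extensible. Only
  single-atom residues can be ions.
* Median: middle value, mean of the two middle values for even counts
  (`stats::median`). Empty statistics (no in-site frames, no events,
  zero `I_begin`) are *withheld* with a warning or reported `NA`, never
  emitted as NaN.
* All generator randomness flows through one integer seed per config;
  identical configs are bit-identical, and the pipeline writes the seed
  and full parameter set into its run manifest.

## Problem sizes used in the validation suite

The test and acceptance suites run entirely on synthetic data sized for
a laptop-class single core: 100 random trajectories of up to 50 atoms ×
200 frames for the brute-force contact oracle; ten 100,000-frame,
12-ion chains for Markov dwell recovery (the pooled 12-ion dwell
estimate is compared within 3 binomial standard errors of the
closed-form 16.67%); 1,000 random masks for the event/RLE equivalence;
10⁴-frame Gaussian series for salt-bridge medians; and noise-free
simulated sweep sets for the voltage-clamp recoveries. These sizes were
chosen so that statistical tolerances (3σ bands, 10% dwell error,
0.5 mV reversal-potential error) are comfortably resolvable, and the
whole suite completes in about two minutes.

## Known limitations

* Contact counting is O(residues × ions × frames) in vectorized R —
  ample for the 10⁴–10⁵-frame analyses here, but a compiled kernel
  would be warranted for multi-microsecond trajectories.
* Binary trajectory formats (DCD/XTC) are out of scope; convert
  upstream, or extend `read_frames()` behind the same contract.
* The nearest-oxygen orientation rule is a proxy for true side-chain
  orientation; frames where both oxygens are nearly equidistant are
  attributed to one of them.
* The candidate-site clustering uses a single reference frame (or mean
  structure) for residue positions; sites that exist only transiently
  in a mobile region may be split or merged.
* Conservation percentages depend on the input alignment; the package
  does not align sequences.
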