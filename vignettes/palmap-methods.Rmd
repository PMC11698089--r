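---
title: "Mapping ligand binding sites by photoaffinity-labeling MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ligand binding sites by photoaffinity-labeling MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmap)
```

## The problem

Photoaffinity labeling (PAL) localizes where a small hydrophobic ligand binds
on a membrane protein when neither structure determination nor direct binding
assays can resolve it. A photoactivatable ligand analog carrying a
trifluoromethyl-diazirine is equilibrated with purified protein and
photolyzed; the short-lived carbene inserts covalently near the binding site,
adding a fixed-mass adduct (216.08 Da here) to whatever residue it touches.
Middle-down LC-MS/MS of a tryptic digest then reveals which peptides — and,
through fragment ions, which residues — carry the adduct. The motivating
application is the propofol-analog labeling of the HCN1
hyperpolarization-activated channel: adducts on the S3 voltage-sensor
segment, the S6 pore helix and the cyclic nucleotide-binding domain, with
competition by excess propofol distinguishing specific sites from incidental
ones. `palmap` implements that analysis as a reusable, fully testable
pipeline, together with the two companion analyses used to interpret the
sites: Boltzmann fitting of conductance-voltage (G-V) curves, and
dual-cutoff ligand-residue contact occupancy on simulation trajectories.

Because no raw runs, trajectories or recordings are deposited alongside the
study, every stage is validated against a synthetic-data module that
generates inputs with known ground truth. The printed peptide table (residue
spans, labeled sites, efficiencies per reagent concentration) is treated as
an input that the generator reproduces, not as a benchmark the pipeline is
tuned toward.

## Digestion, masses and fragment ions

Digestion is fully tryptic: cleavage after K or R, suppressed before P, with
up to five internal missed cleavages by default (the permissive middle-down
search setting). Products carry native protein residue numbers, so a segment
excised from the full-length channel (e.g. S3, residues 220-249) yields
peptides reported in channel numbering.

Masses are monoisotopic: standard residue masses, water 18.010565 Da and
proton 1.007276 Da (the constants are exported as `aa_monoisotopic_masses`,
`water_mass`, `proton_mass`). Fragment ions follow the dominant b/y
convention — b = residue sum + proton, y = residue sum + water + proton at
single charge — which fixes the complementarity identity
`b_i + y_(L-i) = M + 2 * proton` tested across random peptides. The
photo-adduct is stored at the printed two-decimal value 216.08 Da by
default; a full-precision mass can be supplied through
`default_modifications(adduct_delta = ...)` if an elemental composition is
available. N-ethylmaleimide (+125.04768, Cys), a dithiothreitol adduct
(+151.99657, Cys) and methionine oxidation (+15.99491) ship as config
defaults, with masses derived from their elemental compositions.

A labeled y~n~ / unlabeled y~n-1~ pair brackets the adducted residue;
`min_containing_y_index()` gives that first shifted index directly
(`end_residue - residue + 1`). For the S3 peptide 220-241 labeled at Y234
this is y8; for the 53-residue S6 peptide 352-404 at C385, y20; for the
CNBD A-helix peptide 469-490 at M487, y4.

## Site localization and ambiguity

`localize()` enumerates all site combinations of the requested multiplicity
(1 or 2; the doubly labeled species in the reference data carry I227+Y234)
and scores each by its matched *site-determining* ions — ions whose adduct
count differs between at least two candidate combinations. Ions shifted
under every hypothesis carry no positional information and are excluded from
the score; summed matched intensity breaks ties. This mirrors manual
ion-accounting rather than a probabilistic localization score, which would
be an extension, not a reproduction; the count-first/intensity-tiebreak
order is a declared convention. Tied combinations are all reported and
their union forms the ambiguity set: with the single ion separating C385
from Y386 (y19, or equivalently b34) absent from a spectrum, the result is
the two-residue call "C385 or Y386". Neutral losses and internal ions are
ignored (the evidence convention is b/y only). The fragment tolerance
defaults to 20 ppm, with an absolute 0.1 Da alternative for lower-resolution
MS2 acquisition.

## Feature detection and acceptance criteria

MS1 sticks are grouped into chromatographic features by greedy m/z
clustering (gap > tolerance starts a new cluster) split at scan-gap
boundaries, with a minimum of 3 scans per feature by default — enough to
reject one-scan decoy peaks without suppressing genuine low-abundance
species. A labeled candidate must then pass four predetermined criteria:
clearly defined charge states (matched in at least `min_charge_states`
charges; singly charged precursors are not searched, mirroring their
exclusion at acquisition); precursor mass within 20 ppm of theory; apex
retention time strictly later than the unlabeled partner (the hydrophobic
adduct delays elution; the minimum delay defaults to 0 s because the effect
is qualitative); and site-defining fragment ions found within the fragment
tolerance. A candidate without an unlabeled partner has an undetermined
delay and is not accepted. "Clearly defined charge states" is not
operationalized in the source description; the threshold here is explicit
configuration, not an inference of intent.

## Labeling efficiency and competition

Efficiency is quantified from extracted-ion chromatograms: per species the
XIC is summed over the configured charge states and integrated by the
trapezoid rule, and efficiency is the labeled area divided by the total
(unlabeled + singly + doubly) area, times 100. Singly and doubly labeled
species share that common denominator — the parallel singly/doubly columns
of the reference table imply one total per peptide — so the two percentages
sum to at most 100. Summing XICs across charge states identically for all
species cancels charge-state-specific response in the ratio; whether the
original analysis summed across charges is unstated, so this symmetry
convention is declared here. Efficiencies are scale-invariant in the areas.

Competition (prevention of labeling) is tested by one-way ANOVA across
conditions followed by Dunnett many-to-one comparisons against control
(`stats::aov` + `multcomp::glht`); Dunnett is the required adjustment, not
Tukey or Bonferroni. A condition "prevents" labeling when its adjusted p
falls below alpha and its mean efficiency is below control's.

## The synthetic-data generator

`generate_run()` emits, per species (peptide x adduct multiplicity),
Gaussian elution profiles of centroided sticks at the adduct-shifted m/z
for each charge, plus one MS2 spectrum per species holding its full
adduct-shifted b/y series. Design choices that make recovery exactly
checkable:

* peaks are centroided sticks without isotope envelopes — localization and
  efficiency logic do not need isotopes, and matching stays unambiguous;
* the elution profile is a Gaussian density scaled by species abundance, so
  the trapezoidal XIC area equals the abundance analytically (the scan grid
  extends 5 sigma past every apex; with 2-s scans on a 6-s peak the
  quadrature error is below one part in 10^6);
* each adduct adds a fixed retention delay (default 30 s — the magnitude is
  not stated in the source and is a free, realistic parameter);
* noise is seeded and parametric: Gaussian ppm jitter on every stick,
  mean-one lognormal intensity scatter, and Poisson decoy peaks uniform in
  m/z.

`reference_truth()` instantiates the four reference peptides with their
printed per-concentration labeling fractions (rising with reagent
concentration), and condition multipliers for a competition design; the
default scalers (propofol 0.05, cAMP 1.0) emulate near-complete prevention
by excess propofol and no effect of cAMP on the S3 site. The default noise
(5 ppm jitter, 2% intensity CV, 1 decoy/scan) reflects a well-calibrated
Orbitrap-class acquisition. What the generator deliberately does not
emulate: chromatographic tailing, isotope envelopes, chimeric spectra,
dynamic exclusion, charge-state-dependent ionization response, or
incomplete fragmentation — so green tests demonstrate the correctness of
the pipeline's logic under its stated model, not robustness to every
artifact of real acquisitions.

## G-V curves and Boltzmann fits

Tail-current tables are normalized to the maximum peak amplitude and fitted
with the two-parameter Boltzmann `G/Gmax = 1/(1 + exp((V - V0.5)/k))`
(k > 0; conductance rises with hyperpolarization). Optional amplitude or
baseline parameters are off — the reference analysis fits the
two-parameter form. The fit (`minpack.lm::nlsLM`, k bounded positive) is
deterministically initialized: V0.5 by linear interpolation of the 0.5
crossing, k from the 0.25-0.75 span width divided by 2.2 (that width is
2 k ln 3 for an exact Boltzmann). Fits are per replicate, then summarized —
whether the original analysis pooled before fitting is unstated.

One protocol property worth knowing: normalizing to the maximum *observed*
tail current biases fits when the voltage range does not saturate
activation. With steps to -140 mV and a curve shifted to V0.5 = -130 mV,
the maximum observed conductance is well below Gmax and the fitted shift is
compressed (the 40-mV programmed shift in `analysis/04_gv_fit.R` fits as
about -36 mV). This mirrors the real experimental constraint; tests that
assert exact recovery use voltage ranges that saturate.

## Contact occupancy and density grids

`dual_cutoff_occupancy()` implements the hysteretic bound/unbound rule: a
two-state machine starting unbound, binding when the minimum ligand-residue
distance drops below 2.5 Å and releasing only above 3.5 Å, which suppresses
the "rattling in a cage" flicker a single threshold produces. The source
describes transitions but neither initialization nor frame attribution;
here the initial state is unbound and a frame counts as bound if the state
*after* processing it is bound — both declared and tested (the series
[2.0, 3.0, 4.0, 2.0] Å gives occupancy 0.75, the middle 3.0 Å frame held
bound by hysteresis). With equal cutoffs the rule reduces to simple
thresholding. Distances are plain Euclidean by default, with an optional
orthorhombic minimum-image mode for periodic membrane boxes (the synthetic
fixtures are aperiodic). Per-residue occupancy over many ligand copies
takes the maximum across copies, not the sum, so occupancy cannot exceed 1.

Density grids accumulate ligand-atom positions into 1-Å voxels per frame
and divide by frame count; replicate trajectories are averaged, and the
grid total times the frame count equals the number of in-grid observations.
Grids export as OpenDX text. Published per-residue occupancies from the
original trajectories (e.g. V257 47.2%, L237 9%) are context only — they
are not reproducible without those trajectories, and the dwell-model
generator instead provides exact analytic ground truth.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; identical seed and
configuration give byte-identical runs, reports and provenance blocks
(every output bundle embeds the seed, the configuration JSON and its
checksum). The test suite works at deliberately small scale: single-peptide
runs of ~50-140 scans, 20-seed efficiency-recovery ensembles, 100-seed
Boltzmann and competition ensembles, 1000-frame trajectories — sizes at
which the Monte-Carlo tolerances (mean efficiency error under 1 percentage
point; median V0.5 error under 1 mV; competitor detection in at least 95%
of designs) were fixed from pilot runs of the generator itself.

## Known limitations

* The pipeline targets one known protein sequence; it is not an open or
  blind modification search, and semi-tryptic or nonspecific cleavage is
  out of scope.
* Localization considers at most two adducts per peptide, matching the
  reported singly/doubly labeled species.
* Isotope envelopes are not modeled, so the feature detector does not
  deisotope real centroided data beyond m/z clustering.
* The efficiency quantity is relative within a peptide; absolute
  labeling yields and protein-level rollup are out of scope.
* The occupancy module analyzes trajectories; it does not run or validate
  molecular dynamics, docking or pose clustering.
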