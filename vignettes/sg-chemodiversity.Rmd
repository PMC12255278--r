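---
title: "Quantifying steroidal glycoside chemodiversity from untargeted LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying steroidal glycoside chemodiversity from untargeted LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgchem)
```

## The problem

*Solanum* species defend themselves with steroidal glycosides (SGs): a
steroidal aglycone (SA) carrying a chain of sugar residues. Within
*S. dulcamara*, individuals fall into two leaf chemotypes — **S** plants
accumulate saturated aglycones (the m/z 416.3 fragment series) and **U**
plants unsaturated ones (m/z 414.3 without 416.3) — and the glycoside
repertoire varies among organs (roots, leaves, stems) and across ontogeny
(vegetative vs. flowering). Because electrospray ionisation fragments SGs
in-source, a single full-scan chromatographic peak contains the molecular
ion together with a ladder of fragment ions separated by the masses of the
lost residues. `sgchem` turns that in-source structure into a quantitative
chemodiversity analysis: networking, censusing, diversity indices,
variation partitioning, and a matched count-based model for qPCR
expression of the biosynthetic genes.

## Mass arithmetic

Every comparison in the package is an absolute m/z tolerance check,
0.02 Da by default — matching the two-decimal precision at which the
reference ion values are reported; chemotyping uses a coarser 0.05 Da
window around the one-decimal targets 414.3/416.3. Ions are singly
protonated `[M+H]+` (proton mass 1.00728 Da); multiply charged species are
deliberately out of scope, which is why occasional non-integer-spaced ions
(e.g. at half-mass spacings) are ignored rather than annotated.

The residue table ships as a plain-text resource and its masses are
recomputed from elemental compositions at load, so it cannot drift:

```{r}
default_residue_table()
```

`assign_formula()` searches a bounded CHNO space (default C 20–35,
H 10–60, N 0–1, O 0–6, the steroidal aglycone region) for the composition
closest in mass. Two numerical choices matter:

* Candidates are restricted to valid neutral even-electron molecules —
  integer ring-double-bond equivalent (RDBE), i.e. even H+N parity, and
  RDBE ≥ 0. Without this nitrogen-rule filter a chemically impossible
  radical composition can sit closer in mass than the true formula (this
  happens already for the aglycone at m/z 434.36).
* Ties are broken by |RDBE − 7| (SG aglycones cluster at RDBE 5–8), then
  lexicographically — any deterministic rule would do; this one is
  documented and stable.

```{r}
assign_formula(434.36 - proton_mass(), tolerance = 0.005)
```

`predict_fragment_ladder()` and `decompose_glycan()` are mutually inverse
on clean data: decomposing the endpoints of a predicted ladder recovers
the multiset of losses. Note that hexose and deoxyhexose + O have exactly
equal mass; the decomposition avoids the ambiguity by enumerating only
glycosyl residues (plus malonylhexoside and acetyl, at most one each —
observed chains carry at most five sugars, so the per-residue bound of 6
leaves headroom).

## The synthetic data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is validated. Defaults
mirror the experimental design: 3 S and 4 U chemo-genotypes, roots and
leaves of vegetative plants, roots, leaves and stems of flowering plants
(stems cannot be sampled on vegetative plants that are kept for clonal
propagation), retention times inside the 0.75–11 min elution window.

The compound library holds 17 glycosides covering all 12 SA census
species, built around six reference structures: the saturated leaf
tetraoside (aglycone 416.35, Hex₃Pen, molecular ion 1034.55), two
saturated leaf triosides (886.52 and 870.52, differing by a
hexose-for-deoxyhexose substitution), the root-only malonylated
glycoalkaloid (954.51, whose ladder loses two deoxyhexoses and then the
248.05 malonylhexoside), the unsaturated saponin pentoside (1195.5662,
base peak 739.42) and its saturated analogue. The chemotype rule is
structural: U-chemotype leaf compounds carry aglycones 2.016 Da (H₂)
lighter than their S analogues, and roots of both chemotypes share the
unsaturated forms. Analogue pairs co-elute (0.05 min apart) so that the
H₂ biotransformation edge links them in the network; unrelated compounds
are spaced ≥ 0.3 min apart, well beyond the 0.1 min co-elution window.

Remaining generator choices, none of which are stated by the reference
ion tables and all of which are exposed in `sg_design()`:

* **Scan density.** A compound of abundance A emits
  `max(1, round(k·log10(A)))` scans per sample, k = 2. Any monotone
  abundance-to-scans map serves; with the default intensities this yields
  ≈ 3000–3500 SG scans over the 35-sample design, the magnitude observed
  in practice for this kind of census.
* **Intensity noise** is log-normal (σ = 0.3 on the natural-log scale), a
  standard model for LC-MS feature intensities.
* **Decoys**: decoy peaks are drawn uniformly over m/z 100–1300 excluding
  ±0.05 Da around every true library ion, so they cannot silently
  complete a ladder; a fixed artifact feature at m/z 329.32 is always
  present to exercise the TIC_SG exclusion.
* **Ladder intensities**: relative intensities within a ladder are not
  reported for the reference compounds; the default profile (molecular
  ion 0.6, first fragment as base peak, aglycone 0.9) is arbitrary and
  configurable, and nothing downstream depends on it — census rules are
  m/z-based only.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, adducts other than `[M+H]+`, multiply charged ions,
mass-calibration drift, and ionisation suppression. Passing tests
therefore demonstrate the correctness of the analysis logic under the
stated noise model, not robustness to every artifact of real spectra.

The qPCR generator draws true transcript counts from a log-linear Poisson
model (gene × chemotype × organ × ontogeny effects plus genotype and
sample random effects), converts them to quantification cycles via
`Cq = Cq1 − log(count)/log(E)` with gene-specific efficiencies, adds
technical noise in triplicate, and emits a 1–1000× dilution series per
gene. Its default effect table plants the diagnostic patterns: the
saturation-pathway gene silenced in U leaves (near the detection limit),
a leaf-enriched gene with chemotype-dependent fold-changes, a
root-enriched gene, and two condition-stable reference genes.

## Networking, chemotyping, census

`build_mdn()` draws an undirected edge between two features when their
m/z difference matches a residue/biotransformation mass within 0.02 Da
*and* they co-elute within 0.1 min. The window is tight because in-source
fragments of one compound co-elute essentially exactly; the reference
procedure says "retention-time-corrected" without a value, so the window
is a configurable parameter, not a constant. Singletons are pruned;
nodes are annotated with per-group intensity fractions and labelled S/U
when a fraction reaches the association threshold (default 0.75 — node
colouring in the reference figures implies a dominance rule but no
cutoff, so the threshold is exposed). Graphs export to standard GraphML
and round-trip losslessly through igraph.

Chemotype assignment follows the published decision rule verbatim:
presence of 416.3 ⇒ S (it dominates even when 414.3 is present); 414.3
without 416.3 ⇒ U; neither ⇒ undetermined. "Presence" in the original
workflow was a visual judgement of chromatograms; the package substitutes
an explicit rule. The default is *relative*: an EIC peak counts as
present when its maximum reaches 5 % of the larger of the two chemotyping
EIC maxima. An absolute threshold rule (e.g. a multiple of a noise-floor
estimate) fails on clean simulated chromatograms, where every nonzero
trace value is signal and a "5 × median of nonzero values" cutoff ends up
above the maximum itself; a relative rule matches what a human
chromatogram reader actually does. The threshold is exposed for users
with calibrated absolute noise floors.

The census implements the two retention rules:

* **Glycosylation signature** — a scan supports a glycosylated aglycone
  only if some peak connects down to the aglycone peak through ≥ 1
  glycosyl-residue losses (hexose/deoxyhexose/pentose, with
  malonylhexoside permitted as the terminal step). A lone aglycone ion
  never counts.
* **Heaviest fragment** — when several SA species qualify in one scan,
  the whole scan is attributed to the heaviest one. This reading (single
  attribution, not per-species counting with heaviest ladder ions) is a
  deliberate disambiguation of an ambiguous plural: it prevents an
  in-source dehydration artifact of a saturated aglycone from being
  double-counted as its unsaturated analogue.

Counting is per retained scan ("scan mode"), so the grand total equals
the number of qualifying scans, the same bookkeeping that produces a
single integer census total for a whole experiment.

## Diversity indices

Margalef richness `(S − 1)/ln N` and Pielou evenness `J = H′/ln S` use
natural logarithms throughout. Degenerate cases are made explicit rather
than silently propagated: an all-zero sample is undefined (`NA`); N = 1
gives richness 0 by continuity of the numerator; S = 1 leaves evenness
undefined (division by ln 1) and such samples are excluded from
summaries. TIC_SG sums network-node intensities per sample excluding the
m/z 329.32 artifact (a configurable exclusion list — whether that signal
is one ion or a family is not resolvable from the reference material, so
a single value with tolerance is the default). Group summaries are
descriptive means ± sd per chemotype × organ × ontogeny cell; the
mixed-model/EMM layer of the original univariate analysis is out of
scope here.

## GLM-ASCA

Per SA species, counts are modelled by a log-link Poisson GLM on the
design factors. ASCA then needs additive term-wise effect matrices; on
the response scale a GLM is not additive, so the decomposition lives on
the **linear-predictor scale** — each term's effect matrix is its
contribution to the linear predictor, column-centered, and an SVD per
term gives latent variables (sample scores, species loadings, percent
explained variance). Factors are coded with sum-to-zero contrasts, which
has a useful consequence: under the Gaussian family with identity link on
a balanced design, the effect matrices collapse exactly to the classical
ASCA group-mean deviation matrices — the package tests this identity
against hand-computed means on a 2×2 design.

Permutation validation uses the squared Frobenius norm of a term's
centered effect matrix as the statistic. The null is generated by
permuting the rows of that term's design-matrix columns while all other
terms stay fixed, then refitting; for a single-factor model this is an
exact label permutation, and for interaction terms it is a pragmatic
"residualized assignment" scheme whose limitation (main effects held
fixed by construction) is accepted and documented. Type-I error is
verified empirically: 500 null simulations at 499 permutations each
keep the rejection rate at the nominal 5 % (the suite allows ±2
percentage points of Monte-Carlo slack).

The variable screen computes pseudo-R² = 1 − deviance/null deviance per
species and retains species whose observed value exceeds the **median**
pseudo-R² over label-permuted refits. The median is a mild reference: a
structureless species beats it roughly half the time, while any real
effect clears it essentially always — it screens out noise variables on
average without ever discarding signal. An intercept-only alternative
(`null = "intercept"`) is available. Species whose fits sit on the
boundary (a structurally zero factor cell drives fitted means to zero)
are flagged with a message but retained: in this system the
chemotype-defining species are *exactly* the ones with structural zeros
(the saturated 416.35 series is absent from U plants by definition), and
excluding them would remove the chemotype signal the decomposition
exists to display. Only genuinely non-converged fits are excluded, with
a warning.

## Count-based qPCR expression model

Raw Cq values are converted to molecule counts,
`count = round(E^(Cq1 − Cq))`, with efficiencies estimated from dilution
series (`E = 10^(−1/slope)`, slope of Cq on log10 relative template) and
an assumed E = 2 for the reference genes. `Cq1 = 37` is the
single-molecule baseline convention of the count-transform literature;
it is configurable, and because it only shifts all log-counts by a
constant it cancels from every contrast.

The expression model is a hierarchical log-linear Poisson fit estimated
by penalized maximum likelihood: gene intercepts and gene × condition
effects are free; per-sample and per-genotype effects are
ridge-penalized, the exact analogue of Gaussian random effects with
known prior variances (defaults: sd 0.25 for samples, 0.15 for
genotypes). *Soft normalization* adds a tight penalty (prior variance
0.01) on the reference genes' condition effects: rather than dividing by
the references, the model lets them constrain the sample effects, which
are pulled toward values that hold the references flat. The penalty
strength is a tunable, not a constant, because the prior used by the
original Bayesian implementation is internal to that software.
Uncertainty comes from the Laplace approximation (inverse penalized
Fisher information); a random-walk Metropolis refinement with the
conventional long-chain settings is available for users who want
posterior draws, with an autocorrelation-based effective-sample-size
diagnostic. Technical replicates enter as repeated count observations —
no averaging before modelling, in keeping with the count-based
philosophy. Pairwise organ-chemotype contrasts per gene are reported on
the log2 scale with Benjamini–Hochberg adjustment (the conventional
choice where only "FDR-adjusted" is specified).

Interval calibration is checked by simulation: on 200 datasets drawn
from the model itself, 95 % Laplace intervals for the gene × condition
log2 means cover the truth at nominal rate.

## Ordination

Feature tables are sum-normalized, log10-transformed with a pseudo-count
of half the smallest positive normalized value (the transform chain of
the standard metabolomics preprocessing; the pseudo-count rule is not
specified there and is configurable), and mean-centered. PCA is
SVD-based. PCoA double-centers −D²/2 and eigendecomposes; on Euclidean
distances it reproduces PCA scores up to sign, which the suite asserts,
and negative eigenvalues are reported, not corrected. PERMANOVA
partitions squared distances with free, unstratified label permutations
(the default single-factor test); its pseudo-F agrees with
`vegan::adonis2` to machine precision and its type-I error is verified
at 5 % ± 2 over 500 null simulations.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → chemotype → mdn → census → diversity
→ asca → qpcr → ordinate, writing every intermediate artifact and a
manifest carrying the configuration hash, so a rerun with the same
configuration is reproducible. Configuration is a validated list
(unknown keys rejected) readable from YAML; all tolerances and
thresholds above are configuration entries. The package's functions and
this vignette are the intended interface; the pipeline is equally
scriptable from `Rscript` one-liners.

Validation problem sizes were chosen so the full suite exercises every
claim at meaningful resolution while remaining comfortable to run: the
default 35-sample design with ~3000 scans for the end-to-end checks;
500 × 499 permutations for ASCA calibration; 500 × 199 for PERMANOVA;
200 simulated datasets for qPCR interval coverage. The complete test
suite runs in a few minutes on one CPU.

## Known limitations

* Sugar stereochemistry is invisible to mass arithmetic: glucose and
  galactose are indistinguishable, as are all residue isomers.
* Isobaric co-eluting isomers are counted as separate scans only when
  they genuinely produce separate scans; no spectral deconvolution is
  attempted.
* The interaction-term permutation scheme is approximate (see above).
* The census "heaviest fragment" rule is one reading of an ambiguous
  instruction; the alternative (count every qualifying species) would
  inflate counts where saturated and unsaturated ladders co-occur.
* Reported RDBE values for aglycone pairs follow the formula-derived
  assignment; where a printed source lists a pair ordering inconsistent
  with the formulas, the package reports the computed values.
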