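---
title: "Models and methods behind proteasplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proteasplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteasplice)
```

`proteasplice` covers three connected pieces of antigen-processing
informatics: a Bayesian model that ranks antigens by how likely their
physicochemical profile makes them to be represented in HLA-I
immunopeptidomes; exhaustive enumeration and decomposition mapping of
proteasome-generated spliced (PCPS) and non-spliced peptides; and the
quantitative analysis of in vitro proteasome digestions into
site-specific cleavage (SCS-P1) and splicing (PSP-P1) profiles. This
vignette documents the models, the defaults and the numerical choices,
and what the synthetic-data tests do and do not establish.

## The antigen-representation factor model

Each protein is reduced to four intrinsic features: length (residues),
mean Kyte–Doolittle hydropathy (GRAVY, dimensionless), isoelectric
point (pH units; root of the Henderson–Hasselbalch net-charge function
under the EMBOSS pKa set, found by bisection to 10⁻⁶ pH units) and the
Guruprasad dipeptide-weight instability index
II = (10/L)·Σ DIWV(xᵢ, xᵢ₊₁). These are the standard ProtParam
conventions; the model itself is agnostic to the scales chosen, since
all features are z-standardised against the control set before
entering the feature sum *f* = Σ pᵢcᵢ. Without standardisation the
length column (hundreds to thousands) would dominate the bounded
factors pᵢ ∈ [−1, 1] and render the box prior meaningless; the control
set's mean/sd are stored and applied identically to represented and
candidate proteins.

The factors are drawn from a pseudo-posterior
π(p) ∝ exp(β·KS(F₁(p), F₀(p))) on [−1, 1]⁴, where KS is the two-sample
Kolmogorov–Smirnov distance between the represented (F₁) and control
(F₀) feature-sum samples. Sampling uses a Metropolis–Hastings random
walk: Gaussian proposals (sd 0.1) reflected at the box boundary,
burn-in 1,000 iterations, 1,000 retained samples, β = 50. β sets how
sharply the sampler concentrates around factor combinations that
separate the two distributions; 50 gives acceptance rates around 0.5
on realistic inputs while still exploring the ridge of
near-equivalent factor directions. All of these are arguments of
`fit_antigen_factors()`.

Two properties of this objective deserve explicit handling:

* **Sign degeneracy.** KS is invariant under p → −p (both feature-sum
  samples are mirrored, and the ECDF sup-distance is unchanged), so
  the posterior is exactly symmetric and a raw posterior mean would
  collapse toward zero. Retained samples are therefore sign-aligned to
  the convention that *negative factors favor representation*: any
  sample that places the represented set's mean feature sum above the
  control's is flipped. This is a labelling convention, not an extra
  modelling assumption.
* **Conflation of objective and ranking.** The KS distance is used
  only as the MCMC objective. Candidate ranking evaluates, per
  posterior sample, the density difference F_diff = F₁ − F₀ (Gaussian
  KDE, Silverman bandwidth, 512-point grid spanning the pooled range
  ± 3 bandwidths) at the candidate's feature sum, and ranks candidates
  by the median of that per-sample evaluation, with 5–95% intervals
  reported. Reading the procedure as "KS for inference, F_diff for
  ranking" is a deliberate design split. Each KDE is renormalised to
  unit mass over its evaluation grid before differencing, so
  ∫F_diff ≈ 0 holds to 10⁻⁶ rather than only to the ~10⁻³ left in the
  Gaussian tails beyond the grid. Candidate feature sums falling
  outside the grid evaluate to 0 (negligible density) with a warning;
  ranking ties are broken lexicographically by candidate ID and
  flagged as tied.

## Enumeration, decomposition and classification

Coordinates are closed, 1-based intervals in *parental numbering*: a
substrate carries a `numbering_offset` (2 for a polypeptide spanning
KRAS residues 2–35) and every reported position is internal index +
offset − 1, so the G12V mutation is "position 12" everywhere.

`enumerate_nonspliced()` lists every contiguous subsequence in the
length range; `enumerate_cis()` lists every ordered pair of disjoint
intervals with concatenated length in range — normal order (upstream
reactant first) always, reverse order optionally. The minimum
splice-reactant length defaults to 1 (C-terminal splice-reactants down
to very short lengths are observed in digests, and no lower bound is
established). Identical sequences arising from different coordinates
are kept as distinct coordinate entries; filters and exports work at
the unique-sequence level while decomposition multiplicity is
retained.

`map_peptide()` inverts enumeration for an observed peptide: all
single-segment matches, plus all two-segment splits whose parts both
occur in the substrate, categorised as cis-normal (disjoint, in
order), cis-reverse (disjoint, inverted) or trans (overlapping
segments, which requires two substrate molecules; inter-protein trans
is out of scope, and the intervening length is undefined for trans).
Peptides requiring three or more fragments are reported as unmapped —
the two-reactant model is the modelled chemistry. Classification uses
the precedence non-spliced > cis > trans: a peptide is only called
spliced if no hydrolysis-only explanation exists. Correctness of both
directions is established against a naive quadruple-loop oracle over
random substrates in the test suite.

## The candidate cascade

`run_pipeline()` chains enumeration → mutation-coverage filter →
(length filter, implicit in enumeration) → binding filter, and reports
a monotone funnel of per-stage counts. The binding predictor is
pluggable — an imported table of (peptide, IC50 nM) predictions or any
function of peptide sequences — because re-implementing a trained
MHC-binding predictor is neither possible nor desirable offline. The
bundled `toy_anchor_scorer()` scores only P2/C-terminal anchor residues
and is explicitly non-predictive; it exists so the interface can be
exercised in tests. The default cutoff keeps IC50 ≤ 100 nM, boundary
inclusive. `check_uniqueness()` scans a proteome for any other protein
able to yield the peptide by hydrolysis or cis splicing, the criterion
for calling a candidate a unique neoepitope.

Masses for inclusion lists use monoisotopic residue masses, water
18.010565 Da and a proton mass of 1.007276 Da; every m/z is
recomputable from its sequence within 10⁻⁴ Th.

## Digestion analysis

PSM filtering drops hits with ion score < 20 or q > 0.05; when a
spectrum's top hit is spliced, a relative delta score
(top − alternative)/top ≥ 30% is additionally required against both the
best alternative spliced sequence and the best non-spliced hit,
otherwise the spectrum is discarded as ambiguous. The kinetic filters
are qualitative in origin and quantified here as configurable
defaults: a *synthesis artifact* is a t = 0 area above 5% of the series
maximum (a true digestion product cannot pre-exist the reaction); an
*alternating kinetic* is a down-then-up or up-then-down excursion
between consecutive time points with both relative changes above 50%;
peptides must further be quantified in ≥ 2 technical replicates of a
biological replicate and survive in ≥ 2 biological replicates.
Technical replicates are averaged per time point; biological
replicates are analysed separately and then required to agree on
detection.

Absolute quantification inverts a per-peptide ordinary least-squares
titration line (area = slope·pmol + intercept, 0–10 pmol injected),
clipping negative estimates to zero with a warning. Quantification is
accurate only for products whose areas fall inside the calibrated
range; the synthetic generator therefore scales its digestion turnover
so typical products land there.

SCS-P1 sums, per substrate position, the amounts of all products whose
C-terminus sits at that position; PSP-P1 does the same over spliced
products only, at the C-terminus of the N-terminal splice-reactant.
Both are normalised to 100%. When a product's decompositions (within
its classified category) admit k distinct positions, its amount is
split equally, amount/k per position — the equal split conserves total
amount and adds no assumption about which decomposition the proteasome
actually used; whether ambiguous amounts should instead follow one
representative mapping is an open question, and the equal split is this
package's choice. The default time selector is the mean amount over
all time points. An all-zero product table raises an error rather than
silently returning a zero profile.

## Synthetic data: what it emulates, and what it does not

`simulate_proteome()` draws protein lengths from a log-normal
(median 375 residues, sdlog 0.5, floor 50 — the scale of the human
proteome) and per-protein amino-acid compositions as log-normally
perturbed versions of average human-proteome frequencies
(perturbation sd 0.35), which induces realistic spread and correlation
among GRAVY, pI and instability. Represented antigens (20% of 2,000
proteins by default) are sampled with probability ∝
plogis(−f(p*)/T) with T = 0.5 and planted factors
p* = (−1, 0.5, 0.1, 0.4) — long proteins favored, hydrophobic and
unstable ones disfavored, isoelectric point nearly neutral, with
‖p*‖∞ = 1. Recovery tests require cosine similarity ≥ 0.5 between the
posterior-mean factors and p*; observed values are ≈ 0.95.

`simulate_digestion()` plants per-position cleavage and splicing
propensities (gamma-distributed), samples 15 non-spliced and 8
cis-spliced distinct products of the KRAS 2–35 G12V fixture, and
accumulates amounts linearly over 0–4 h at 20 pmol/h total turnover,
so typical products fall inside the 0–10 pmol titration range. Areas
are amounts times a hidden log-normal per-peptide response factor with
5% multiplicative log-normal noise per technical replicate (2
biological × 3 technical replicates); titration tables share the
response factor with 5% noise. Products are drawn only from sequences
whose site attribution is unique within their category, so the
generating coordinates are identifiable and the noiseless limit is
recovered exactly (L1 < 10⁻⁶); ambiguous attribution and the
equal-split rule are exercised directly through the KLVVGAVGV
three-decomposition case instead. With default noise the end-to-end
SCS-P1 recovery error is 1–5 percentage points (L1) across seeds.

The generators do *not* emulate MS physics: no retention times,
fragmentation, missed identifications, saturation or detection-limit
censoring, and trans products are not simulated (they are constructed
directly as tables in tests). Passing the closed-loop tests therefore
shows the estimators are correct under the stated noise model, not
that real digests will be this well-behaved.

The KRAS fixture embeds human KRAS (UniProt P01116) residues 2–35 with
G12V applied at parental position 12; its consistency anchor is that
positions 5–14 of the mutant read KLVVVGAVGV.

## Reproducibility, configuration, sizes

Every stochastic function takes an explicit integer seed and is fully
deterministic given it; simulation outputs are byte-identical across
runs. Configuration is a plain R list (`default_config()`) or a YAML
file; YAML was chosen as the config format supported by the R
toolchain in use. The test suite runs the factor-model recovery at
800–2,000 proteins with 250–300 retained samples after an equal
burn-in, and the digestion loop at 23 products over 5 time points —
sizes at which the full suite completes in a few minutes while leaving
the estimators' behaviour clearly visible.

## Known limitations

* The antigen model uses only intrinsic protein features; expression-
  or abundance-aware presentation models would rank more sharply where
  such data exist.
* Reproducing published candidate counts for specific immunopeptidome
  datasets requires those datasets and an external binding predictor;
  the package ships neither.
* Trans splicing is modelled intra-substrate (two copies of the same
  substrate) only.
* The delta-score and kinetic-filter thresholds are quantified
  interpretations of qualitative filtering descriptions; they are
  configurable and logged per peptide so their effect is auditable.
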