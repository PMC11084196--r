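---
title: "Models and methods behind the HSA ligand screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the HSA ligand screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsascreen)
```

# The problem

Human serum albumin (HSA) is the main transport protein in plasma and a
natural depot for amyloid-beta peptide (A-beta), the aggregating species of
Alzheimer's disease. Small-molecule ligands of HSA can allosterically shift
HSA's affinity for A-beta in either direction, which makes approved drugs
that bind HSA a natural pool for repurposing: a ligand that tightens
HSA--A-beta binding could lower free A-beta, one that loosens it could be a
risk factor. `hsascreen` implements the in-silico arm of such a screen as a
reusable, fully testable pipeline: candidate filtering, binding-site
clustering and ranking, equilibrium occupancy calculations, and two-site
kinetic analysis of surface plasmon resonance (SPR) sensorgrams.

Because the upstream data sources (drug databases, literature counts,
docking poses, raw sensorgrams) are external and partly undisclosed, every
stage is paired with a synthetic-data generator that emulates the *shape*
of those inputs under controlled ground truth. The package's tests
establish that each algorithm does what it claims on data with known
structure; they cannot, and do not, certify the biological conclusions
drawn from the original external data.

# Candidate filtering

`apply_filters()` applies six independent predicates in a fixed order and
reports survivors after each stage:

1. molecular mass strictly between 100 and 900 Da (the "small molecule"
   window);
2. water solubility strictly above 1 µM (experimentally feasible loading
   of HSA; where an experimental solubility exists upstream it takes
   precedence over the predicted one, and the single `solubility` field
   stores the resolved value);
3. predicted blood--brain-barrier penetration strictly above 50%;
4. plasma concentration strictly above 0.5 nM, the approximate total
   plasma concentration of A-beta-40, so the ligand can plausibly compete;
5. at least 2 Alzheimer-literature references (a "more than one" support
   requirement, read inclusively at 2);
6. exclusion of fatty acids, whose effects are already characterised.

All wordings of the form "above"/"less than" are implemented as strict
inequalities, and the boundary behaviour is unit-tested. The survivor *set*
is a conjunction and therefore independent of stage order; the per-stage
*counts* are order-dependent bookkeeping, and the canonical order above is
a convention of this package, not a claim about how any particular panel
was counted. Records with missing attributes raise an error naming the
record and field rather than being dropped silently — a screen whose
headline output is a count should not lose rows quietly.

# Binding-site clustering and ranking

Each predicted binding site is a set of HSA residues (PDB entry 1UOR,
chain A numbering, 1--585). Sites are compared as *number series*: the
sorted residue numbers, aligned with dynamic time warping (DTW). The DTW
implementation is the classic dynamic program with local cost `|x - y|`,
the three symmetric steps (match, insert, delete) each adding one local
cost term, anchored endpoints, no warping window and no path-length
normalisation. The encoding of a site as its ascending residue numbers is
a design choice of this package: it is the simplest encoding under which
the warping distance reflects where a site sits along the chain, and the
tests verify the dynamic program against exhaustive enumeration of all
monotone alignment paths for short series.

Clustering is average-linkage agglomeration on the DTW distance matrix,
cut to `k` clusters (`k = 5` by default: with the screen's site geometry,
finer cuts only fragment the same five regions). Average linkage is chosen
because it behaves well on non-Euclidean precomputed distances; the
linkage is a configurable argument. Cluster ids are relabelled by
decreasing size (ties by smallest member index) so output is deterministic.

Within a cluster of `n` ligands, the frequency `f_aa` of a residue is the
number of member ligands whose site contains it (presence, not
multiplicity), and a ligand's rank is

$$R \;=\; \sum_{r \in \text{site}} \frac{f_{aa}(r)}{n},$$

the sum of within-cluster residue frequencies over the residues of that
ligand's own site — an indicator-weighted sum, so residues absent from the
site contribute zero. (A literal reading of the printed formula would put
the indicator in a denominator, which divides by zero whenever a residue
is absent; the indicator-as-factor reading is the only self-consistent
one and is what this package computes.) A singleton cluster therefore
ranks its ligand at exactly its site cardinality, and a site that is a
superset of another member's site never ranks below it.
`select_representatives()` takes the top-`m` ligands per cluster with ties
broken by ligand id.

# Equilibrium occupancy

Two models are provided, and reports state which was used:

* `occupancy_simple()`: the excess-ligand Langmuir isotherm
  $\theta = K L / (1 + K L)$, valid when total ligand far exceeds total
  binding sites. At the screen's assay concentrations this reproduces the
  reported panel occupancies (e.g. 71% for an association constant of
  $10^3\,\mathrm{M^{-1}}$ at 2.5 mM ligand; 98% for
  $5\times10^4\,\mathrm{M^{-1}}$ at 1 mM).
* `occupancy_depletion()`: the exact single-class mass balance. With total
  sites $S = n_{\text{sites}} \cdot [\mathrm{HSA}]$, $K_d = 1/K$ and total
  ligand $L$, bound ligand is the smaller root
  $b = \tfrac12\big[(S+L+K_d) - \sqrt{(S+L+K_d)^2 - 4SL}\big]$ and
  $\theta = b/S$. This is required when the ligand is solubility-limited —
  15 µM ligand against 40 µM HSA carrying four sites gives
  $\theta \approx 8.8\%$, i.e. 9% after rounding — and reduces to the
  isotherm as $L/S \to \infty$ (asserted numerically in tests).

```{r occupancy}
occupancy_table(representative_ligand_panel())[, c("ligand", "site",
                                                   "percent", "model")]
```

At 2.5 µM HSA the quadratic gives 50% for the solubility-limited ligand;
a published upper bound of 41% for that condition is not reproduced by
this mass-balance model (nor by the isotherm), so the model behind that
particular printed bound evidently differs and is unknown; the package
reports what its stated model computes. Percentages are rounded half away
from zero, and only at the reporting layer.

# Two-site SPR kinetics

Sensorgrams are modelled with the heterogeneous-ligand (two independent
site classes) pseudo-first-order model at constant analyte concentration
$C$. During association each class rises as

$$R_i(t) = R_{\max,i}\,\frac{k_{a,i}C}{k_{a,i}C + k_{d,i}}
  \left(1 - e^{-(k_{a,i}C + k_{d,i})t}\right),$$

and after the phase boundary decays as
$R_i(t_a)\,e^{-k_{d,i}(t-t_a)}$; the observed response is the sum over the
two classes. Mass-transport limitation and conformational-change models
are deliberately out of scope. The closed forms are verified in tests
against an independent numerical integration of the underlying ODEs to
$10^{-6}$ relative tolerance.

`fit_heterogeneous()` fits each sensorgram separately by bounded
Levenberg--Marquardt least squares over
$(k_{a1}, k_{d1}, k_{a2}, k_{d2}, R_{\max,1}, R_{\max,2})$ in
log-parameter space. Biexponential fits are initialisation-sensitive, so
every fit is multi-started from a log-spaced grid
($k_a \in 10^1\ldots10^5\,\mathrm{M^{-1}s^{-1}}$,
$k_d \in 10^{-5}\ldots10^{-1}\,\mathrm{s^{-1}}$, start combinations
restricted to $K_{D1} \le K_{D2}$) and the best-residual solution wins,
stopping early once a start reaches the data to numerical precision.
After each fit, site labels are made canonical ($K_{D1} \le K_{D2}$), so
results are invariant to swapping the site labels in the start. The
per-concentration protocol then averages estimates arithmetically across
analyte concentrations and reports standard deviations; $K_{D,i}$ is
computed per fit as $k_{d,i}/k_{a,i}$ *and then averaged*. An average of
per-concentration ratios is not the ratio of the averaged rates — with
five exact noiseless fits the two can already differ by tens of percent
when the per-curve estimates scatter — so the averaged `KD` columns of a
fit are carried as their own quantities and never recomputed from the
averaged rates. A global fit with shared rates and per-curve
$R_{\max}$ exists (`global = TRUE`) but is explicitly not the averaging
protocol and is labelled as such.

Two identifiability caveats are worth stating because they shape what the
tests can claim. First, a noiseless round trip — simulate from a rate set,
fit, average — recovers the generating rates essentially exactly (to
better than 0.1% relative), so it can only ever return
$K_{D1} = k_{d1}/k_{a1}$ of the generating set; it cannot reconstruct an
averaged-ratio value whose per-concentration inputs were never published.
Second, a dissociation rate is only well determined when its timescale is
visible inside the acquisition window: at
$k_d \approx 2\times10^{-5}\,\mathrm{s^{-1}}$ a 2400 s dissociation phase
decays by only ~5%, and with 1% noise single-curve estimates of that
site's rates scatter by ~10% or worse. The package's noisy
parameter-recovery study therefore uses rates whose dissociation
timescales are resolvable within the window
($k_{a1}=10^4$, $k_{d1}=5\times10^{-4}$, $k_{a2}=10^3$,
$k_{d2}=5\times10^{-3}$), where the median relative error per rate at 1%
plateau noise is under 5% across 20 seeds.

Thermodynamics: `free_energy()` computes
$\Delta G = -RT\,\ln(55.3/K_D)$ with $R = 8.314\times10^{-3}$
kJ mol$^{-1}$ K$^{-1}$, $T = 298.15$ K by default (the assay temperature)
and 55.3 M the molar concentration of water (the unitary standard state);
`delta_delta_g()` gives the ligand-induced shift
$RT\ln(K_D^{\text{lig}}/K_D^{\text{base}})$ per site (negative = the
ligand favors the interaction), and `fold_change()` the
$K_D$ ratio with a direction flag, rounded half-away-from-zero to an
integer only for prose-style reporting.

```{r foldchange}
base <- kinetic_params(1, 0.64e-7, 1, 5.0e-6, relabel = FALSE)
pred <- kinetic_params(1, 0.38e-7, 1, 0.38e-6, relabel = FALSE)
fold_change(pred, base)[, c("site", "factor", "factor_rounded", "direction")]
```

`baseline_correct()` implements plain pointwise blank subtraction (with
optional linear interpolation onto the sample grid); upstream instrument
corrections are vendor-specific and out of scope.

# What the synthetic generators emulate

`generator_config()` fixes the study conditions once:

* **Ligand tables** (`gen_ligand_table()`): 1000 records by default with
  per-filter pass fractions of 0.68, so the expected survivor count of the
  six-stage cascade is about 100 — the size of a realistic screened panel
  emerging from a DrugBank-scale source. Each record flips an independent
  Bernoulli coin per filter and then draws the attribute from a marginal
  conditioned on the pass/fail side of the threshold (mass uniform on
  [50, 1200] Da so both tails of the mass window occur; solubility and
  plasma concentration log-uniform; BBB uniform in percent; reference
  counts shifted-Poisson). Survivor counts are therefore exactly binomial
  and testable analytically. The tables mimic the attribute *set*, not
  real field names, correlations between properties, or real chemistry.
* **Binding sites** (`gen_binding_sites()`): five archetype sites of nine
  residues centred at residues 117, 191, 292, 447 and 525 — one
  representative region per reported cluster, but deliberately chosen at
  least 50 residues apart in sequence so that a planted partition is
  well-posed for a sequence-series distance (the real clusters are
  distinct in 3-D space, not in sequence). Twenty sites per cluster by
  default (a 100-site panel), each perturbed by removing and adding
  `site_jitter = 2` residues near the centre. The hidden `true_cluster`
  label is stored for recovery tests and never read by the clustering.
  Amino-acid identities come from a fixed synthetic residue-number map;
  no real HSA sequence is shipped.
* **Sensorgrams** (`gen_sensorgram()`): the closed-form model plus
  pointwise Gaussian noise (1 RU by default, typical instrument noise),
  at the assay's five analyte concentrations 2.5--40 µM with 300 s
  association and 2400 s dissociation. Zero noise is bit-identical to
  `simulate_sensorgram()`. Drift, spikes, mass transport and regeneration
  artefacts of real instruments are not emulated, so passing fits here
  bound algorithmic error only, not instrument systematics.

All generators take explicit seeds and restore the caller's RNG state;
fixed seed means byte-identical output.

# Numerical and testing choices

* Test problem sizes are chosen for tight feedback: 100-site clustering
  recovery, 2700-point sensorgrams at 2--3 s sampling, 20-seed recovery
  studies, 150 random DTW oracle pairs. Each is large enough to exercise
  the property it tests and small enough to run routinely.
* Comparisons against ~$10^{-7}$-magnitude dissociation constants are
  asserted on the reporting scale (×$10^7$ M) or as ratios to 1, because
  relative-tolerance helpers silently degrade to absolute comparisons at
  magnitudes below the tolerance.
* Degenerate inputs are contracts, not warnings: empty sites, empty
  series, non-square matrices, `k` larger than the item count, negative
  rates and concentrations, mismatched time grids and missing record
  fields all raise errors naming the offending quantity.
* `run_pipeline()` derives every stage seed from the single config seed,
  stamps outputs with the seed and an MD5 hash of the resolved config,
  and re-running from persisted stage artifacts reproduces downstream
  results byte-identically.

# Known limitations

* The clustering operates on sequence-ordered residue series; two sites
  adjacent in 3-D but distant in sequence are far apart under this
  distance. Reproducing the original five clusters' memberships would
  require the undisclosed docking poses and is not attempted.
* The occupancy models are single-class and non-competitive; site classes
  of one ligand are treated independently, and no binding-polynomial
  treatment of competition or cooperativity is included.
* The SPR model excludes mass-transport limitation; rate constants from
  transport-limited data will be biased regardless of fit quality.
* Averaged `KD` values from per-concentration protocols are averages of
  ratios; they are reported as such and cannot be audited beyond
  round-trip self-consistency when raw per-concentration data are not
  available.
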