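---
title: "Modelling stem-cell niche succession in human colonic crypts"
author: "cryptDrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stem-cell niche succession in human colonic crypts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptDrift)
```

## The scientific problem

The human colonic epithelium is maintained by small pools of stem cells
(SCs) at the base of each crypt. Because transgenic lineage tracing is not
possible in humans, age-related somatic mtDNA mutations that abolish
oxidative phosphorylation (OXPHOS) serve as a natural clonal mark: a
mutation that clonally expands within one SC and drifts above a heteroplasmy
threshold renders that SC and its progeny histochemically detectable, and a
transverse section through the crypt reads out the fraction of the
circumference occupied by the marked clone. The frequency and size
distribution of these partially and fully deficient crypts across the adult
life-course constrain three quantities of interest: the effective SC number
$N$, the rate $\lambda$ at which SCs are stochastically lost and replaced by
neighbours, and hence the fraction of SC divisions with an asymmetric fate
outcome.

cryptDrift implements both computational routes to these quantities and the
analyses connecting them to crypt-level data:

1. a **multi-scale stochastic simulator** coupling intracellular mtDNA
   population genetics to SC competition in the niche, and
2. an **analytic one-dimensional neutral-drift model** for marked-clone
   sizes with a time-increasing clone induction rate.

## The multi-scale model

### Intracellular level: mtDNA dynamics

Each SC carries a fixed copy number of $M = 200$ mtDNA molecules. At every
cell division the pool is replicated and randomly segregated:

* **Replication** (default scheme): every molecule is copied exactly once,
  giving a transient pool of $2M$. Each new copy of a wild-type template
  mutates with probability $\mu(t)$ and founds a fresh mutant lineage;
  copies of mutant templates inherit their lineage (no back-mutation). A
  `"resample"` variant draws all $2M$ molecules with replacement from the
  templates, a more aggressive relaxed-replication scheme retained for
  sensitivity analysis; the scheme in force is recorded in every output's
  metadata.
* **Segregation:** a uniformly random partition of the $2M$ pool into two
  daughters of exactly $M$ molecules (multivariate hypergeometric). This
  preserves mean heteroplasmy (a martingale) and produces the canonical
  per-division segregation variance, which is what lets rare lineages drift
  to high heteroplasmy over decades.

The per-replication mutation probability rises exponentially with age from
$10^{-5}$ at birth to $6\times10^{-5}$ at 80 years,
$\mu(t)=\mu_0 (\mu_{80}/\mu_0)^{t/80}$. A cell is OXPHOS-deficient when its
mutant fraction reaches the threshold $\theta = 0.75$ (boundary inclusive:
150 of 200 molecules).

### Niche level: fate outcome and drift

The effective niche is a ring of $N = 5$ SCs dividing synchronously once a
week (4171 divisions in 80 years of 365 days). Per dividing cell,
independently:

* with probability $p_\mathrm{asym}$ (default 0.99) the outcome is
  **asymmetric**: one daughter keeps the ring position, the other leaves the
  niche — the clonal configuration is unchanged;
* otherwise the outcome is **symmetric**: both daughters stay, and one
  uniformly chosen ring neighbour is expunged with all its content. Each
  symmetric event is exactly one loss/replacement event, so a single SC is
  replaced at rate $p_\mathrm{sym}\times 52 \approx 0.52$ per year at
  $p_\mathrm{sym}=0.01$ (`replacementRate()`).

Cells are resolved in uniformly random order within a generation; a cell
expunged before its turn does not divide. Random order was chosen because a
synchronous update has no canonical resolution and a fixed order would
introduce positional artefacts; the residual effect of within-generation
event collisions on the realized replacement rate is below one percent at
the default parameters (and measured explicitly in the test suite). The
coupling of each symmetric duplication to the expulsion of a ring neighbour
conserves the niche size exactly and reduces the label dynamics to the
classical one-dimensional neutral-drift model. A `"global"` neighbourhood
switch (any other SC may be expunged) is provided for sensitivity; the ring
is the default geometry of the annulus model.

### Why a third, "induction" mode exists

`simulateEnsemble(mode = "induction")` replaces the mtDNA machinery with
the analytic model's own assumption — new marked clones arrive as a Poisson
process with rate $R(t)$ and drift under the same fate machinery. It exists
to validate the analytic solver against an exactly matched stochastic
process (a dual-route check); the mtDNA mode is the scientific model, in
which clone induction is emergent rather than prescribed.

## The analytic model

Marked-clone size $n \in \{0,\dots,N\}$ evolves as a continuous-time
birth–death chain, absorbing at 0 (clone loss) and $N$ (niche succession,
irreversible), with rates

$$n \to n+1:\ \lambda\,(1+\delta)/2, \qquad
  n \to n-1:\ \lambda\,(1-\delta)/2,$$

solved by spectral decomposition of the generator (with a dense
`Matrix::expm()` fallback; both to better than $10^{-9}$). Here $\lambda$ is
the *total clone step rate*. One convention deserves care: a contiguous
clone on the ring has two boundary cells, each stepping the clone up and
down at $p_\mathrm{sym}/2$ per division, so the clone chain runs at **twice**
the per-SC replacement rate. `cloneStepRate()` and `replacementRate()` make
the two conversions explicit, and the simulator-versus-chain agreement test
uses the former. $\delta$ is a fate bias of marked cells (default 0,
neutral); the quasi-steady distribution of partial clone sizes under
constant injection at $n=1$ is proportional to $N-n$ for $\delta = 0$ —
linear decay, maximal at one SC's share $1/N$ of the circumference,
independent of $\lambda$ — which is what makes the *shape* of the partial
histogram an estimator of $N$ alone (`quasiSteadyPartialPmf()`,
`scanScNumber()`), while the *abundance* of partials constrains $\lambda$.

Clone induction is empirical and time-increasing, $R(t) = R_0 e^{\eta t}$
per crypt per year, with defaults $\eta = 0.05$ and $R_0/N = 0.01$ (giving
0.14 at age 20 and about 1.7 at age 70). Treating inductions as Poisson and
clones as independent, the class probabilities at age $a$ are

$$P_\mathrm{full}(a) = 1 - e^{-\Lambda_\mathrm{fix}(a)}, \qquad
  P_\mathrm{partial}(a) = e^{-\Lambda_\mathrm{fix}(a)}
  \left(1 - e^{-\Lambda_\mathrm{part}(a)}\right),$$

where $\Lambda_\bullet(a) = \int_0^a R(s)\, P_\bullet(a-s\,|\,n_0{=}1)\,ds$
(Simpson quadrature, 160 panels). The Poisson form matters: at the default
induction parameters the cumulative induction integral reaches tens of
events per crypt by old age, so raw expected clone counts exceed one and are
not probabilities; `expectedClassFractions(mode = "expected")` returns the
raw intensities and warns when that regime is entered. What the Poisson
construction still neglects is *interaction* between co-resident clones
(they cannot overlap in a 5-cell niche, and a new induction can land on an
already-marked cell); the induction-mode simulator measures this
approximation, which stays within Monte-Carlo noise at the rates used in
the consistency tests.

### Fitting

`fitAnalytic()` performs weighted least squares of the model's per-decade
partial/full percentages against a binned summary, weights equal to the
patients per decade — matching how cohorts of 2–44 patients per decade are
pooled. A multi-parameter free set is refused when fewer than three age
bins are available. The fit is a curve fit rather than a likelihood by
design (the decade percentages are ratio summaries over heterogeneous
patients); profile grids over each free parameter are available for
diagnostics. When the per-decade patient ages are supplied, predictions
average over them exactly; otherwise decade midpoints are used.

## Observation model

A crypt with $k$ of $N$ deficient SCs reads out as a contiguous patch of
base fraction $k/N$, jittered by zero-mean Gaussian noise of scale
$\sigma = 0.03$ (lateral dispersion of progeny migrating up the crypt wall)
and clamped to $[0,1]$; $k = 0$ reads exactly 0 and $k = N$ exactly 1.
Fractions at or below the detection floor (0.05, well below $1/N$) are
scored normal — real sections cannot resolve arbitrarily thin patches. The
truncated-Gaussian jitter is the simplest one-parameter dispersion model
consistent with a contiguous patch; a migration random walk could produce
asymmetric dispersion, which is why $\sigma$ is exposed in the
configuration and recorded in outputs rather than hard-coded. Observed
fractions are binned with inclusive upper edges ($(0,0.2] \mapsto 1$ SC for
$N=5$, and exactly 1 always maps to $N$).

## Synthetic cohorts

`generateCohort()` emulates a decade-stratified biopsy study: 148 patients
with composition 2/10/25/44/37/21/9 across the decades 17–20 through 71–80,
ages uniform over each decade's integer years, and a default 1000 crypts
per patient (~148,000 crypts, matching the scale of a study of >150,000).
Patient-to-patient variability in mutation burden — which is why real data
are pooled by decade — is modelled as a mean-1 gamma multiplier (shape 4)
on the induction/mutation rate; the mechanism and shape are a package
choice (only the existence of the variability is established) and are
recorded in the output metadata. Crypt fission and fusion are not
simulated, so collapsing adjacent fully-deficient clusters to single clones
is a no-op by construction.

What the generator does **not** emulate: biopsy sectioning geometry,
fission cluster sizes, staining artefacts, or any real-data values such as
observed regression statistics. Tests passing on these cohorts validate
the package's internal consistency and the recoverability of its
parameters at realistic scale — not the biological estimates themselves.

## Numerical and design choices

* **Skip-ahead sampling.** While a crypt is entirely wild-type, the only
  event that can change its state is a new mutation; the simulator samples
  the arrival generation exactly (time-varying geometric via exponential
  thinning) instead of iterating no-op generations. This is an exact
  acceleration, not an approximation.
* **Lineage identifiers** are minted per mutation event (globally unique
  within a run) purely for clonality audits; dynamics ignore them.
* **Threshold at the boundary** is inclusive ("reaches the threshold"):
  exactly 150/200 mutant molecules is deficient.
* **Deterministic seeding.** All randomness flows through R's RNG; the
  pipeline fans a master seed into per-stage substreams (`deriveSeed()`),
  so identical configurations reproduce outputs byte-for-byte.
* **Problem sizes.** The reference ensemble is 30,000 crypts; the test
  suite and recovery experiments use 2,000–16,000 crypts and the analytic
  refits use the full 148-patient, 1000-crypt-per-patient design, sizes at
  which every recovered parameter sits well inside its tolerance while a
  complete run stays inexpensive on a single core.
* **Degenerate inputs** are first-class: empty histograms, all-zero growth
  curves, decades with zero full crypts, single-bin scans (reported as
  explicit ties), and malformed cohort rows (reported with line numbers)
  all raise informative conditions rather than silent results.

## Known limitations

* The relaxed-replication mechanics are a reconstruction: "replicate each
  molecule once, then partition hypergeometrically" is the minimal scheme
  consistent with random segregation and mean-preserving drift. The
  resampling variant bounds the sensitivity of conclusions to this choice.
* The analytic class-fraction formula ignores clone interaction within a
  crypt; at the default (large) induction rates the Poisson correction
  carries the burden, and the cross-route tests quantify the residual.
* The per-SC versus clone-level factor of two in rate conventions is easy
  to trip over when comparing with other parameterisations of neutral
  drift; use the two conversion helpers rather than raw multiplication.
* Decade summaries pool crypts across patients within a decade (the
  per-patient-average alternative is available through the cohort table
  itself); with strong patient heterogeneity the two differ.

## A worked dual-route check

```{r dual-route, eval = FALSE}
set.seed(1)
cfg <- nicheConfig(lifespanYears = 20)
ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0.99),
                        nRuns = 10000, recordAges = 20, mode = "labelled")
obs <- tabulate(kMatrix(ens)[, 1] + 1L, nbins = 6L) / 10000
lam <- cloneStepRate(0.01, cfg@divisionsPerYear)
cbind(simulated = obs,
      analytic = cloneSizeDistribution(driftParams(lambda = lam), t = 20))
```

The ring simulator and the master-equation solve agree bin by bin within
Monte-Carlo error — the package's two engines are solving the same model.
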