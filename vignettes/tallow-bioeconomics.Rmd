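---
title: "Methods: the tallowsim invasion-bioeconomics model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tallowsim invasion-bioeconomics model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tallowsim` simulates the spread of Chinese tallow (*Triadica sebifera*)
across a lattice of forestland cells and accounts for the discounted
economic consequences — timber damage, search, and control — of
threshold-based management policies. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken where
the problem statement left the design genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The spread model

Each cell is a 4,927 m × 4,927 m (2,428 ha) block of forestland — the FIA
sampling intensity — carrying a percent occupancy $x_i(t) \in [0, K]$ with
carrying capacity $K = 100$ for all cells. The annual update is

$$x_i(t+1) = x_i(t) + \underbrace{r_i\,x_i(t)\left(1 -
\frac{x_i(t)}{K}\right)}_{\text{within-cell growth}} +
\underbrace{\textstyle\sum_{j \ne i} k_{ij}\, e_j(t)}_{\text{dispersal
inflow}}$$

* $r_i$ (per year, ≥ 0) is the cell's maximum spread rate, a habitat-quality
  summary supplied per cell (estimating it from occurrence data is outside
  this package's scope).
* A **mature** source — colonized at least 3 years before the new year,
  since tallow does not bear seed until age 3 — retains a fraction $\ell$
  (`local_fraction`, default 0.9) of its logistic increment and exports
  $e_j = (1-\ell)\, r_j x_j (1 - x_j/K)$. Immature or empty cells export
  nothing but keep their full increment. The 0.9 default reflects the cell
  width (~5 km) relative to typical seed shadows: most recruitment is local.
* $k_{ij}$ is the mass of a radial **lognormal dispersal kernel**,
  $\ln d \sim N(\mu, \sigma^2)$, landing in the recipient's footprint:
  density at distance $d$, spread uniformly over the annulus, integrated
  over the cell area in the standard point approximation
  $f(d)/(2\pi d)\cdot A$. The default median $e^\mu = 1{,}200$ m matches
  the characteristic projected invasion velocity for this species (bird and
  wind dispersal); $\sigma = 1$ gives a moderately fat tail. Masses over a
  global tiling sum to 1 within truncation error (tested against a
  numerical-integration oracle at ±1%).
* **Colonization.** Already-invaded recipients receive inflow
  deterministically. An uninvaded forested recipient is colonized with
  probability $1 - \prod_j (1 - p_{ij})$ over mature sources, where
  $p_{ij} = \min(1, e_j k_{ij})$ is the kernel mass received from source
  $j$ — i.e. colonization pressure is proportional to the recruitment the
  kernel distributes. Two readings of the colonization rule were possible:
  probability equal to the bare kernel volume over the recipient cell, or
  probability equal to the *received* (export-weighted) mass. We implement
  the latter: it makes colonization vanish exactly when nothing is exported,
  which yields the exact dispersal-off reduction to independent logistic
  maps (`local_fraction = 1`, tested exactly) and ties the probabilistic
  channel to the same mass scale as the deterministic one. The consequence
  worth knowing: sources near carrying capacity have a small increment and
  hence exert little colonization pressure; pressure peaks at
  mid-occupancy sources.
* On colonization a cell starts at `x_colonize` (default 0.1% — one
  detectable foothold, ~2.4 ha, in a 2,428-ha cell) and waits out the full
  3-year maturation. Control resets the clock; re-colonization restarts it.
* Non-forested cells absorb dispersal mass but never colonize; the kernel is
  normalized over space, so mass landing on non-forest is simply lost. This
  keeps normalization independent of the forest mosaic.
* The update is synchronous (all increments computed from the year-$t$
  state) and the state is bounded to $[0, K]$ after each step; both are
  property-tested (bounds, no spontaneous generation, determinism under a
  fixed seed).

The dispersal operator is precomputed as a sparse matrix over all cell
pairs within a cutoff radius (default 30 km ≈ 6 cell widths; at the default
kernel the per-cell mass beyond 30 km is below $10^{-4}$ of the total, and
the neighbor index is validated against a brute-force all-pairs oracle).

## 2. The economic model

Costs accrue per cell and year and are discounted at rate $\rho$ (default
0.05; the reporting table spans $\{0.01, 0.03, 0.05, 0.07, 0.09\}$) over a
horizon equal to the 20-year average harvest cycle:

$$\mathrm{ETC} = \sum_i \sum_{t=0}^{T}
\frac{D_i(t) + S_i(t) + C_i(t)}{(1+\rho)^t}.$$

**Damage** is lost timber production on invaded hectares,
$D = (x/100)\,A\,V_i\,P_i$: stand replacement makes losses proportional to
occupied area. $V_i$ comes from a seven-class productivity lookup
(5,536.98 down to 201.75 kg/ha/yr) and $P_i$ defaults to the
harvest-share-weighted stumpage price computed from the embedded five-class
table. That computation gives 0.023338 \$/kg; the source tables print
0.0234, a value not reproducible by exact arithmetic from their own printed
shares and prices (it evidently used unrounded inputs). We embed the honest
computation — the 0.25% difference is immaterial everywhere — and the
corresponding acceptance assertion is deliberately left failing rather than
loosened.

**Search** is the cost of delineating an invasion before treatment. The
anchor is \$48,000 to sweep a full plot (\$19.77/ha, i.e. \$8/acre, times
2,428 ha) when the invasion covers ≤ 1% of the cell; larger invasions are
easier to find, so above the 1% kink the default bill decays inversely,
$S = 48{,}000 / x$. The functional form is a modeling choice, not an
observed quantity, so `search_form` also offers `linear` and `exponential`
decays (both continuous at the kink and matched to the inverse form's
endpoints) plus a configurable floor.

**Control** is charged on treated hectares at an exponential unit price
$a e^{bx}$ \$/ha. The coefficients are not published; they are fit at
startup by log-linear least squares to the four quoted bracket endpoints
(1%, \$111), (25%, \$210), (60%, \$457), (100%, \$1,446), giving
$a \approx 107$, $b \approx 0.0256$ (verified against a closed-form
regression oracle), and can be overridden in the configuration.

**Accounting conventions.** $t = 0$ is the initial year: damage is assessed
on the supplied initial state and the control rule is applied immediately
(undiscounted), which is what "control without delay" means for a
pre-existing invasion. Within each subsequent year the order is
spread → damage accrual (on the post-spread, pre-control occupancy: a cell
treated in year $t$ still lost that year's production) → control decision
with search + control accrual. Ledgers store nominal dollars per cell and
year; discounting is applied on read, so one simulation can be summarized
under all five reporting rates, and the component/total identity is exact
by construction (tested).

## 3. Management policies

A policy is a threshold $\theta$: every cell whose occupancy **strictly
exceeds** $\theta$ ("exceeded" in the policy definitions) is searched,
treated to zero, and its maturation clock reset. Named intensities: NC
(never), LC ($\theta = 60$), MC ($\theta = 25$), HC ($\theta = 0$ —
immediate control of any positive occupancy). Detection and treatment are
assumed perfect. Control is idempotent within a year and monotone in
$\theta$ (both tested). Because this implementation has no exogenous
arrival process (propagules only come from in-grid sources), HC eradicates
the invasion at $t = 0$ and keeps post-control invaded area exactly zero —
a structural difference from systems with continued outside propagule
pressure, where immediate control fights a persistent trickle.

## 4. Monte Carlo engine

Every source of randomness flows from one root seed through a Lehmer-style
mixing function (`derive_seed`): replicate seeds from the root, a per-year
substream within each replicate, and fixed-length vectorized colonization
draws, so results are independent of cell iteration order and reproducible
end-to-end. Threshold sweeps reuse the same replicate seeds across
thresholds (common random numbers), which removes sampling noise from
policy contrasts; the reported optimum breaks ties toward the larger
threshold (less intervention). Summaries are replicate means ± standard
errors; the SE is property-tested for $1/\sqrt{n}$ scaling.

## 5. The synthetic landscape generator

The generator is a first-class, tested module standing in for the
unavailable plot-level inventory data. It emulates the aggregate structure
that the analysis assumes:

* a square lattice (the `paper_like` preset defaults to 118 × 117 ≈ 13.8k
  cells; tests and examples use smaller lattices) with ~90% forested cells;
* a spatially autocorrelated habitat field: white noise smoothed by an
  isotropic Gaussian kernel of range `autocorr_m` (default 15 km), min–max
  rescaled to `r_range` (default [0.2, 0.8], under which favorable cells
  reach ~99% occupancy within ~20 years of colonization and uncontrolled
  landscape-level invaded area expands roughly exponentially, on the order
  of 15× in 20 years — the uncontrolled-scenario pattern);
* a productivity-class mixture over the seven codes (a mid-heavy default);
* an initial invasion confined to a southern "coastal" band (default: the
  bottom 25% of rows), occupying 2.7% of cells with a heavy-tailed
  occupancy mixture — 85% fringe plots ~ Exponential(mean 5%), 15%
  saturated plots ~ Uniform(50, 100) — so some plots start above 95%
  occupancy, as the inventory data describe. All initially invaded cells
  are marked mature. One note on calibration: the target initial state was
  described both as "2.7% of area" and as the analog of ~66k ha on the
  full grid (~0.2% of area); these are inconsistent, and we fixed
  **2.7% of cells**, which with the occupancy mixture yields ~0.4% of area
  — the right order of magnitude for the observed 2003 snapshot. This was
  decided once and not revisited.

What a green test on synthetic data does *not* establish: geographic
realism (coastlines, ownership mosaics), the true joint distribution of
habitat quality and initial occupancy, or the externally estimated
dispersal parameters. Qualitative results (exponential uncontrolled
growth, scenario ordering, an interior cost-minimizing threshold) transfer;
absolute dollar figures do not.

## 6. Numerical choices and degenerate inputs

* Distances are Euclidean on projected planar meters; no geodesy.
* The kernel mass uses the point approximation rather than exact footprint
  integration; the normalization test bounds the induced error (< 1% over a
  fine tiling).
* `occupancy_pct` outside [0, 100], non-positive areas, unknown class
  codes, non-forested cells with positive occupancy, and duplicate cell ids
  are rejected at load with the offending cell named.
* Clamping to $[0, K]$ is the last step of each spread update; colonization
  probabilities are clamped to [0, 1] before combination.
* CSV round-trips write doubles at `%.17g` so landscapes reload
  bit-for-bit.
* Ties in the threshold sweep go to the larger threshold.

## 7. Known limitations

* No exogenous arrival/introduction process (see §3) and no estimation of
  $r_i$, $\mu$, $\sigma$ from data — both belong to the upstream ecology.
* Perfect detection and treatment; no landowner-behavior mosaics.
* Constant prices and cost parameters over the horizon; no nonmarket
  (ecosystem-service) damages — dollar totals are conservative.
* Single kernel family (lognormal); the fat- vs thin-tail sensitivity
  analysis is out of scope.
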