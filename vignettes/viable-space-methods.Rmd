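---
title: "Exploring viable parameter spaces: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring viable parameter spaces: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(viaspace)
```

## The problem

A kinetic model with $d$ uncertain parameters defines a box
$\Theta^d = \Theta_1 \times \cdots \times \Theta_d$ and a cost function
$E(\theta) \ge 0$ measuring how far the model's behavior at $\theta$ is from
a desired behavior; $E = +\infty$ encodes qualitative failure (e.g. no
oscillation at all). The *viable space* is
$\{\theta \in \Theta^d : E(\theta) < E_0\}$ for a threshold $E_0 > 0$. Its
volume and geometry quantify the robustness of the behavior to parameter
change, but in realistic models the viable space is a vanishing fraction of
the box — uniform ("brute force") sampling needs a number of draws growing
exponentially with $d$ — and it may be nonconvex and poorly connected, which
defeats single-Gaussian or single-ellipsoid samplers.

`viaspace` implements a two-stage exploration followed by a union-of-
ellipsoids Monte Carlo volume estimator:

1. **Global stage (`run_oeamc`)** — an out-of-equilibrium adaptive
   Metropolis chain. Proposals are Gaussian with covariance $\Sigma$;
   moves uphill in cost are accepted with probability
   $e^{-\beta \Delta E}$. After every block of $n$ iterations, $\beta$ is
   multiplied by $b$ if the block found no viable point, kept if the
   viable-hit fraction $f_v$ is in $(0, f_0]$, and divided by $b$ if
   $f_v > f_0$; independently $\Sigma$ is scaled by $s$, kept, or scaled by
   $1/s$ according to whether the acceptance fraction $f_a$ is above,
   inside, or below the band $(f_l, f_u]$. The chain is deliberately *not*
   an equilibrium sampler: it keeps viable hits rare but nonzero, which
   lets it cross moderately costly nonviable terrain between poorly
   connected viable regions.
2. **Local stage (`run_mebs`)** — multiple ellipsoid-based sampling. From a
   viable start the viability boundary is bracketed along every coordinate
   axis (doubling steps, then bisection); the $2d$ boundary points seed a
   minimum-volume enclosing ellipsoid (MVEE), and the expansion iterates:
   sample uniformly inside the MVEE scaled by $g_i$, keep viable points,
   refit the MVEE, adapt $g_i$. New expansions start from viable points far
   from the mean of previous starts, so separate lobes of a nonconvex
   region each get covered.
3. **Volume stage (`build_cover` + `estimate_volume`)** — the pooled viable
   points are clustered ($k$-means on whitened coordinates, $k$ chosen over
   $1..k_{\max}$ to minimize the total MVEE volume) and each cluster is
   wrapped in its MVEE. The union $W$ of these ellipsoids is sampled
   stratified-uniformly; an overlap-once integrand credits each point to
   the first ellipsoid (in fixed descending-volume order) containing it, so
   intersections are counted once, and the viable volume is
   $\sum_i \mathrm{Vol}(W_i)\langle f_i \rangle$ with a stratified standard
   error. The points with $f_i = 1$ are a *uniform* sample of the viable
   region inside $W$ — the raw material for downstream robustness analyses.

Both exploration stages stop when the *clustered cover volume* — the same
cluster-and-wrap statistic evaluated on everything found so far — changes
by less than `conv_tol` for `conv_window` consecutive blocks or expansions.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `beta0`, `b` | 1, 2 | initial inverse temperature and its up/down factor |
| `sigma0` | `diag((0.05 (upper-lower))^2)` | initial proposal covariance |
| `s` | 2 | covariance up/down factor |
| `f0` | 0.2 | max tolerated viable-hit frequency |
| `f_l`, `f_u` | 0.2, 0.5 | acceptance-rate band (brackets the classical ~0.23 optimum) |
| `n` | 1000 | Metropolis iterations per adaptation block |
| `g0`, `g1` | 0.9, 1.05 | first two ellipsoid scalings (shrink, then grow) |
| `p` | 0.5 | multiplier on the scaling offset $g-1$ |
| `b_l`, `b_u` | 0.05, 0.5 | viable-yield bounds steering $g$ |
| `n` (MEBS) | `max(100, 20 d)` | samples per expansion iteration |
| `conv_tol`, `conv_window` | 0.01, 3 | stopping rule of both stages |
| `k_max` | 10 | cluster-count scan limit |
| `N` | $10^5$–$10^6$ | volume-stage samples |

The published method fixes the *structure* of all adaptation rules but none
of these numeric values; the defaults above are this package's choices,
made once. Powers of two for `b` and `s` give symmetric up/down moves; the
acceptance band brackets the classical random-walk-Metropolis optimum; the
gentle `g1` avoids flooding high-dimensional ellipsoids with nonviable
volume.

One genuinely ambiguous published detail is the scaling update: the growth
text ("grows by a factor $1/p > 1$") is inconsistent with the shrink branch
staying above 1 under the same reading. The implemented rule,
$g_i = g_{i-1} \pm (g_{i-1}-1)\,p$, multiplies the *offset* $g-1$ by
$(1+p)$ or $(1-p)$; it is self-consistent with the stopping condition
"$g_i$ converges to one" and reproduces the intended qualitative behavior
(`update_scaling` tests pin it down).

## Numerical choices

* **Boundary convention.** The viability test is strict (`E < E0`)
  everywhere. Benchmark problems whose published viability condition is
  `<=` set `E0` to the printed bound times $(1 + 10^{-12})$: a
  measure-zero boundary cannot affect any volume, and a single convention
  avoids edge-case drift between modules.
* **MVEE.** Khachiyan-type barycentric ascent on the lifted determinant
  maximization, with Wolfe–Atwood away/drop steps and an active-set outer
  loop (the optimum touches at most $d(d+3)/2$ points, so the solver works
  on a small core set and re-solves only when an outside point violates
  containment). The returned ellipsoid is rescaled minimally so it contains
  *every* input point exactly. Affinely degenerate inputs (e.g. collinear
  clouds, routine early in an expansion) are solved in their affine span;
  null directions get semi-axis $\varepsilon_{reg} = 10^{-6} \times$ mean
  pairwise distance (floored at $10^{-9}$).
* **Cheap geometry where only guidance is needed.** The MVEE tolerance is
  $10^{-7}$ where the ellipsoid is a *result* (the final cover), but the
  refits inside an expansion only steer the next sampling ellipsoid and the
  stopping statistic only needs a stable *ratio*; both use looser
  tolerances ($3 \times 10^{-3}$ / $10^{-4}$) and deterministically strided
  subsets (800 / 4000 points). The stopping statistic is additionally made a
  deterministic function of the point set (fixed internal k-means seed,
  caller's RNG stream untouched): random restarts would jitter the
  statistic and mask convergence.
* **Stratified allocation.** Volume-stage samples are allocated to
  ellipsoids proportionally to their volumes with largest-remainder
  rounding and a floor of one; the per-ellipsoid variance terms are summed
  in quadrature (independent strata). Any fixed ellipsoid order gives an
  unbiased overlap-once estimator; descending volume lets the largest
  regions claim shared mass.
* **Cover undercoverage.** An MVEE fitted to finitely many sampled points
  sits slightly inside the true region hull, so the estimated volume is a
  (slightly) conservative estimate of the full viable volume — about 1% low
  on the 2-D shell, well under 5% in all benchmark dimensions tested. An
  optional `inflation` factor on the cover counteracts this; the default
  (1.0) never applies it silently.
* **ODE integration.** No ODE solver package is available to depend on, so
  the oscillator ships its own compiled integrators: adaptive
  Dormand–Prince RK5(4) with an automatic switch to an L-stable SDIRK3
  (analytic Jacobian, step-doubling error control) chosen up front when a
  cheap spectral bound on the kinetics says explicit stepping would be
  stability-limited (tiny Michaelis constant `k10` with fast
  dephosphorylation makes the kinetics stiff), and used as a fallback
  otherwise. A point whose integration fails in both is scored $+\infty$
  (nonviable) with an optional warning — the same contract as a
  non-oscillating point.

## The oscillator case study

The bundled 12-parameter model couples a mass-action core (a protein R
produced at constant rate, phosphorylated to Rp, and degraded) with three
Michaelis–Menten phosphorylation cycles. Rp activates Z, whose active form
Zp feeds back *positively* on the phosphorylation of R
($p = \tilde k_2 + \tilde k_{11} [Z_p]$); Rp also activates the X → Y
cascade whose output Yp feeds back *negatively* by accelerating Rp
degradation ($n = \tilde k_3 + \tilde k_{12} [Y_p]$). Parameters are
explored as $k_i = \log_{10} \tilde k_i$ over $[-4, 2]$ (rates) and
$[-7, 2]$ (feedback strengths). The cost is
$((T - 1)/0.1)^2$ for an oscillating trajectory with period $T$ of Rp, and
$+\infty$ otherwise, so viability means a period in $[0.9, 1.1]$.

Choices the published description leaves open, decided once here:

* **Initial state** all concentrations zero — R is produced at rate
  $\tilde k_1$, so the system self-starts from a state that favors no
  particular attractor.
* **Analysis window** $t \in [0, 100]$ (about 50 target periods), first
  half discarded as transient, with solver tolerances $10^{-6}$/$10^{-8}$.
  An earlier design used $[0, 200]$ at $10^{-8}$/$10^{-10}$; halving the
  window and relaxing the tolerance cuts the per-evaluation cost about
  threefold while leaving period detection accurate to well under 0.1% —
  far inside the 1% regularity gate — so the longer, tighter setting
  bought nothing but wall time.
* **"Oscillates"** means: at least 4 interior peaks in the analysis
  window, peak-to-trough amplitude above $10^{-4}$, and inter-peak
  intervals with coefficient of variation below 1% (sustained, regular
  oscillation — damped or drifting dynamics fail).
* **Start point.** A known oscillating parameter point is required to seed
  exploration, and none is published in the sources available to this
  package; `osc_reference_params()` is a synthetic reference found by
  random search for sustained oscillations followed by *exact* rescaling
  of the rate constants to unit period (multiplying all rates except the
  Michaelis constant `k10` by $T$ rescales time by exactly $1/T$).
* **Loop substitution.** "Replacing a loop by a constant rate" is
  operationalized as freezing $p(\cdot)$ (resp. $n(\cdot)$) at its time
  average over one period of the unperturbed trajectory — by construction
  at least the loop-free base rate. A loop is *dispensable* if removal
  (`k11` or `k12` set to 0) or substitution leaves the model viable;
  essentiality labels follow. A fourth label, `neither-essential`, is kept
  for logical completeness, reported separately, and excluded from the
  three-class shares.
* **Random walks** use per-coordinate Gaussian steps with $\sigma = 0.01$
  in log-parameter space, 10 walks per point; leaving the box counts as
  nonviable (the escape event of interest is "loses the behavior", and a
  parameter outside its allowed range has lost it by definition).
* **Connectivity** uses straight segments in log-parameter space divided
  into 4 equal parts (5–8 supported); an edge requires every interior
  point viable. The default graph size is 100 uniformly sampled viable
  points.

## What the synthetic benchmarks do and do not establish

The spherical-shell problems (one shell, or two externally tangent shells,
$r_e = 0.5$, $r_i = 0.3$, box $[-10, 10]^d$) have analytically known viable
volumes $n\,C_d (r_e^d - r_i^d)$, are nonconvex, and — in the tangent
configuration — are connected only through a single tangency point, which
is exactly the failure mode that defeats purely local exploration in high
dimension. A green benchmark suite establishes that the pipeline recovers
known volumes to a few percent up to $d = 15$, that the global stage finds
poorly connected regions where the local stage alone often cannot, and
that cost grows sub-exponentially with dimension. It does *not* establish
anything about cost landscapes with plateaus of $+\infty$ (the oscillator's
regime), about viable regions below the sampler's resolution, or about
regions disconnected from every seed — the last is a stated limitation of
the method itself, not of this implementation.

The reduced-budget oscillator runs used in the test suite scale the block
sizes and sample counts down so an ODE-costed exploration finishes in CI
time; they reproduce the case study's headline structure (dominant
negative-essential class, largely connected viable space, integration
domain orders of magnitude below the box) with proportionally wider
uncertainties than a full-size run.

## Known limitations

* The volume estimate is conditional on the cover: viable territory never
  visited by either exploration stage is invisible to the estimator. The
  reported `stderr` quantifies Monte Carlo noise, not coverage error.
* Explicit-solver stiffness is handled by the SDIRK fallback, but a
  parameter point whose dynamics defeat both integrators is scored
  nonviable; in stiff corners of the box (very small `k10` together with
  near-maximal turnover rates) this can shave genuinely viable volume.
* The evaluation counter, not wall time, is the efficiency currency;
  per-evaluation cost varies strongly across the box for ODE-based
  problems.
* Box-bounded domains only; no constrained or manifold parameter spaces.
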