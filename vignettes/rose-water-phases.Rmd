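---
title: "Mapping the phase diagram of a 2D hydrogen-bonding water model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the phase diagram of a 2D hydrogen-bonding water model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosewater)
```

## The model

`rosewater` implements a two-dimensional water model in which molecules are
Lennard-Jones discs carrying three hydrogen-bonding "arms" 120 degrees
apart. The pair energy is

$$U_{ij} = U_{\mathrm{LJ}}(r_{ij}) +
  \tfrac{\epsilon_{\mathrm{HB}}}{2}\,
  \left[\rho(\theta_{ij}) + \rho(\theta_{ji})\right] s(r_{ij}),$$

where $r_{ij}$ is the center-center distance, $\theta_{ij}$ is the angle of
the connecting vector in molecule $i$'s body frame, and

* $U_{\mathrm{LJ}}$ is the 12-6 potential, truncated by cut-and-shift at
  $4\sigma_{\mathrm{LJ}}$ (the shift, about $10^{-4}\epsilon_{\mathrm{LJ}}$,
  keeps the potential continuous so microcanonical energy conservation is a
  meaningful test);
* $\rho(\theta) = \left[a_1\cos 3\theta + a_2\cos 6\theta\right]/a_{\max}$
  is the normalized 3-petal rose orientational term. $a_{\max}$ is the
  maximum magnitude of the unnormalized term over one period, so the global
  minimum of $\rho$ is exactly $-1$, attained when an arm points along the
  connecting line. For both shipped coefficient sets
  ($a_1 = 0.6$, $a_2 = -0.4$) the minimum value $a_2 - a_1 = -1$ needs no
  rescaling at all - the coefficients were evidently chosen for that;
* $s(r)$ is a double-sided cubic switching window: two mirrored smoothstep
  cubics $1 - 3u^2 + 2u^3$, $u = |r - r_{\mathrm{HB}}|/r_{\mathrm{fwhm}}$,
  equal to 1 at the hydrogen-bond distance, 0 outside
  $[r_{\mathrm{HB}} - r_{\mathrm{fwhm}}, r_{\mathrm{HB}} + r_{\mathrm{fwhm}}]$,
  passing 0.5 at the half-window (so $r_{\mathrm{fwhm}}$ is the full width
  at half maximum), and continuously differentiable everywhere - required
  for forces.

Each molecule contributes at most $-\epsilon_{\mathrm{HB}}/2$
independently of its partner, so a "half bond" (one molecule aligned, the
other not) is worth half a full bond; an ideally aligned pair at
$r_{\mathrm{HB}}$ has hydrogen-bond energy exactly
$-\epsilon_{\mathrm{HB}}$. Two parametrizations are shipped
(`rose_params("mb")` and `rose_params("real")`); the MB one has distinct LJ
and hydrogen-bond distances (0.7 vs 1.0) and hence the richer phase
behavior.

Reduced units are used throughout: energies in $\epsilon_{\mathrm{HB}}$,
lengths in $r_{\mathrm{HB}}$, $k_B = 1$, $m = 1$,
$T^* = k_B T/\epsilon_{\mathrm{HB}}$,
$p^* = p\,r_{\mathrm{HB}}^2/\epsilon_{\mathrm{HB}}$.

```{r params}
p <- rose_params("mb")
p
rose_orientational(arm_angles(p), p)   # exactly -1 along each arm
```

## Choices the model statement leaves open

Several quantities are not fixed by the model itself; the package makes
these choices once and exposes them as arguments:

* **Moment of inertia** $I = m r_{\mathrm{HB}}^2/4 = 0.25$. It only sets
  the rotational timescale; equilibrium averages are independent of it.
* **Degrees of freedom**: the thermostat acts on all $3N - 2$ degrees of
  freedom (translations minus the frozen center of mass, plus rotations).
  Velocity initialization is rescaled to exact equipartition between the
  translational and rotational pools, because a global rescaling thermostat
  preserves whatever split it is handed - in weakly coupled systems an
  unlucky initial split would persist.
* **Virial pressure** uses only the distance derivative of the pair
  potential, $pA = K_{\mathrm{trans}} + \tfrac12\sum_{ij} (-U'(r_{ij})\,
  r_{ij})$; the angular gradients are perpendicular to the connecting
  vector and do no virial work. The analytic forces are validated against
  central finite differences at $10^{-6}$.
* **Body-frame arm directions** are at 60, 180 and 300 degrees (the minima
  of the rose term); lattice generators place orientations so that every
  arm points exactly at a neighbor, with the two honeycomb sublattices
  rotated 60 degrees from each other.

## Simulation engines

**NPT molecular dynamics** (`run_npt`) uses velocity Verlet at
$\Delta t = 0.001$. Equilibration runs under exact velocity rescaling and
the Berendsen barostat; sampling under stochastic velocity rescaling
(canonical kinetic-energy resampling with coupling $\tau_T = 0.01$) and a
stochastic cell rescale barostat ($\tau_P = 0.1$). The barostat integrates
the overdamped Langevin equation for $\ln A$,

$$d\ln A = -\frac{\kappa}{\tau_P}(p_0 - p_{\mathrm{inst}})\,dt +
  \sqrt{\frac{2 k_B T \kappa}{A \tau_P}}\,dW,$$

whose stationary law is the NPT area distribution
$P(A) \propto A^N e^{-\beta p_0 A}$ (the $N$ vs $N{+}1$ measure term
cancels against the spurious-drift correction exactly when
$p_{\mathrm{inst}}$ carries the instantaneous kinetic part). $\kappa$ is a
dimensionless effective compressibility, default 1. The engine is checked
against the 2D ideal-gas equation of state
($\langle A\rangle \approx N k_B T/p$), energy conservation
($|\Delta E|/|E| < 10^{-4}$ over $10^4$ steps), and the second-order
convergence of the integrator.

**Constant-pressure nested sampling** (`ns_sample`) compresses a live set
of $K$ configurations through decreasing enthalpy levels
$H_i = U + pV$; the enclosed configuration-space volume shrinks by
$K/(K{+}1)$ per level. Volumes are sampled in an isotropically rescalable
square cell bounded by $V_0 = 100\,N r_{\mathrm{HB}}^2$ (so
$k_B T \ll p V_0$ for all $T^* \le 1$) under the $V^N\,dV$ measure;
replacement walkers take $L \times N$ single-particle moves plus one
volume attempt per $N$ sub-steps, with move sizes auto-tuned toward 50%
acceptance. A fully deformable (shear-flexible) cell is not implemented;
the isotropic simplification may shift solid-solid transition estimates.
`partition_thermo` turns one run into $\langle H\rangle(T)$, $C_p(T)$
(level-weighted enthalpy variance over $T^2$ plus the $3N/2$ kinetic
term), and - because the per-level volume is recorded - $\kappa_T(T)$ and
$\alpha_P(T)$ from the volume fluctuations, at any temperature without
re-sampling. The kinetic prefactor of the partition function contributes
only a smooth additive constant to $\log\Delta$ and cancels in every
response function. `ns_thermo_se` estimates errors by resampling the
Beta$(K,1)$-distributed compression ratios. Extrema of the response
curves (`find_extrema`) mark candidate phase transitions. The sampler is
validated against the analytic single-particle ideal gas and an
independent NPT Metropolis Monte Carlo oracle for the LJ dimer.

## Observables and descriptors

Per phase point, the package computes angular distribution functions
(ADFs) and a 15-quantity property vector. The ADF histograms, for ordered
pairs in a thin radial shell, the angle between molecule $i$'s nearest arm
and the connecting line, folded into $[-60^\circ, 60^\circ)$ by the
3-fold arm symmetry. On the ideal honeycomb lattice the ADF at $r = 1.0$
is a single peak at $0^\circ$ (the direct bond) and at $r = 1.73 \approx
\sqrt3$ two peaks at $\pm 30^\circ$ (two molecules bonded to a shared
neighbor). Five shells are used (0.7, 1.0, 1.73, 2.0, 3.0 - the peaks of
$g(r)$). Definitions the model statement leaves open are fixed as
follows, each behind an argument: shell half-width $0.05\,r_{\mathrm{HB}}$;
diffusion from the Einstein MSD slope (middle 10-50% of the lag window,
divided by 4) on unwrapped coordinates; a pair is hydrogen-bonded when its
HB energy is below $-0.5\,\epsilon_{\mathrm{HB}}$ (an energetic criterion,
because the model defines the bond energetically); the "radial structure
factor" is the height of the first $g(r)$ peak beyond
$0.5\,\sigma_{\mathrm{LJ}}$; the orientational cosine is
$\langle\cos 3\theta\rangle$ (the plain cosine is not invariant under the
arm relabeling $\theta \to \theta + 120^\circ$); $\psi_3$ and $\psi_6$
bond-orientational order uses neighbors within the first $g(r)$ minimum,
falling back to $1.35\,r_{\mathrm{HB}}$.

The ADF machine-learning descriptor keeps every third bin of each of the
five ADFs and concatenates them. A 3-degree grid over the 120-degree
window would give 41 points per distance and 205 in total, which cannot
reproduce the 125-dimensional descriptor this pipeline is defined around;
125 is taken as authoritative, so the native ADF binning is 75 bins of
1.6 degrees and stride 3 gives exactly 25 points per distance. The ADF
descriptor is left unstandardized (all ADFs share one scale); the
15-quantity property table is standardized column-wise to mean 0,
variance 1, with constant columns mapped to all-zero rather than NaN.

## The unsupervised phase-diagram pipelines

`reduce` projects a feature table to 3 components by metric MDS, Isomap
(default 100 neighbors), Laplacian-eigenmap spectral embedding, or exact
t-SNE (perplexity 20, early exaggeration 12, learning rate 100, up to
3000 iterations); `cluster` applies k-means, Ward (on standardized
Euclidean distances) or DBSCAN. t-SNE, DBSCAN, spectral embedding and the
Hungarian label assignment are implemented in the package and are checked
in the test suite against constructed fixtures and an exhaustive
assignment oracle. All stochastic stages take an explicit seed and the
full provenance (methods, hyperparameters, seed, package version) travels
with every label grid, so any result can be re-executed bit-identically.

Two pipelines mirror the two descriptor sets:

* `adf_phase_pipeline`: reduce the 125-dim ADF table, then cluster into
  $k$ phases.
* `intelligent_phase_pipeline`: first separate the states of matter from
  the diffusion coefficient alone by sequential DBSCAN peeling
  (`sequential_diffusion_dbscan`): the diffusion values are standardized,
  and each round chooses $\varepsilon$ from the k-distance elbow and peels
  the points that fall outside the dense cluster - gas first (large,
  scattered diffusion), then two liquid bands; three rounds leave gas,
  liquid-a, liquid-b, solid, labeled by descending mean diffusion. The
  solid points are then re-standardized on the remaining 14 features
  (diffusion is spent), reduced to 3D and clustered into solid sub-phases.

For the elbow, the maximum second difference of the sorted k-distance
curve was tried first and proved fragile: on ragged curves it locks onto
local spikes inside the high-diffusion segment and the peeling stalls.
The package instead uses the standard knee criterion - the point of
maximum deviation below the chord joining the ends of the lightly
smoothed, descending curve - which is deterministic and lands where the
curve "falls toward zero and flattens". On a 1D grid of equally spaced
points it recovers the spacing within a factor of two.

`fraction_of_agreement` scores a predicted label grid against a reference:
predicted clusters are matched one-to-one to reference phases by the
Hungarian assignment that maximizes total matches (majority mapping can
double-count and was rejected), a merge map can declare label groups
equivalent (e.g. two parts of one liquid), and noise points count as
disagreement by default (conservative; a flag excludes them from the
denominator instead).

## Desk-scale study conditions and what the tests show

The production protocol of record is 200 molecules, $10^5$ equilibration
steps and 20 series of $10^5$ steps per phase point, with nested sampling
at $N = 32$, $K = 500$, $L = 5000$ and $5\times10^5$ iterations. The test
suite runs the same code at desk scale: a $5 \times 8$ (T*, p*) grid with
64 molecules and $1{,}500 + 4\times1{,}500$ steps per point, nested
sampling with $K \le 200$ and a few thousand levels, and planted-partition
fixtures for the ML stages. At low temperature the grid runner can seed
phase points with candidate lattices (honeycomb below $p^* \approx 4$,
triangular above; `init = "auto"`) - legitimate and common practice that
shortens equilibration enormously at desk scale, at the price of biasing
glassy points toward the seeded crystal.

On these conditions the diffusion peeling separates gas, liquid and solid
cleanly (the gas corner $T^*{=}0.30$, $p^*{=}0.01$ is the most mobile
group and the whole $T^*{=}0.05$ row is solid), and Isomap + Ward with
$k = 7$ on the ADF descriptor resolves the cold row into exactly 4
distinct clusters - the model's 4 solid phases (low-pressure honeycomb,
two intermediate disordered solids, high-pressure close packing). This
was verified under two independent MD seeds before the tests were frozen.

What passing does **not** show: 6,000-step runs are far from equilibrated
for glassy high-pressure points (their structures are lattice-seeded or
quenched, not annealed); the two liquid sub-bands found by peeling are a
property of the diffusion distribution, not two thermodynamic phases; and
the planted ML fixtures demonstrate algorithmic correctness, not that real
descriptor noise is as benign as the fixtures'. Published agreement
fractions against a manually drawn reference diagram are not reproducible
here, because that reference exists only as a figure; the
planted-partition recovery properties stand in for them.

## Numerical notes

* Degenerate inputs: a constant feature column standardizes to zeros; a
  frozen trajectory has $D = 0$; a monotone response curve has no extrema;
  DBSCAN with $\varepsilon$ below the minimum pairwise distance returns
  all noise; identical diffusion values end peeling with one group and a
  warning.
* Ties in `count_adf_peaks` are broken toward the left bin edge and the
  $\pm 60^\circ$ seam is periodic.
* The LJ cut-and-shift displaces the stated zero crossing at
  $\sigma_{\mathrm{LJ}}$ and the $-\epsilon_{\mathrm{LJ}}$ minimum by
  about $10^{-3}$ relative; tests assert at that tolerance.
* The minimum-energy pair separation sits a hair below
  $r_{\mathrm{HB}}$ (LJ slope against switching penalty), so "minimum
  pair energy = LJ at the optimum minus $\epsilon_{\mathrm{HB}}$" holds to
  about $10^{-3}$, not exactly.
* Angles are radians internally; degrees appear only at I/O boundaries
  (ADF grids, CSV files).

## Reproducing a small end-to-end run

```{r pipeline, eval = FALSE}
spec <- grid_spec(
  temperatures = c(0.05, 0.10, 0.175, 0.25, 0.30),
  pressures = c(0.01, 0.1, 1, 2, 5, 8, 12, 20),
  protocol = md_protocol(n = 64, n_equil = 1500, n_series = 4,
                         series_len = 1500, frame_interval = 100,
                         init = "auto", density_guess = 0.3, seed = 100),
  params_preset = "mb")
res <- run_grid(spec, "both", cache_dir = "grid_cache")

states <- intelligent_phase_pipeline(
  res$property_table,
  params = list(min_pts_peel = 6, n_rounds = 3, min_pts = 6), seed = 3)
table(attr(states, "stage1")$label)

phases <- adf_phase_pipeline(res$adf_table, "isomap", "ward",
                             n_clusters = 7, seed = 1,
                             reduce_hyperparams = list(n_neighbors = 39))
```
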