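---
title: "Methods: a 3D vertex model of the stratifying epidermis"
author: "epivertex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3D vertex model of the stratifying epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`epivertex` simulates a stratified epithelium — basement membrane, a
one-cell-thick basal stem-cell layer, and suprabasal differentiated layers —
as a three-dimensional vertex model.  Cells are space-filling polyhedra; the
shared vertices are the dynamical degrees of freedom.  The tissue energy is

$$E \;=\; \sum_c K_V \,(V_c - V_{0,c})^2 \;+\; \sum_c K_S\,(S_c - S_{0,c})^2
\;+\; \sum_{\langle ij\rangle} \sigma_{t_i t_j}\, A_{ij},$$

where $V_c, S_c$ are the volume and surface area of cell $c$, $V_0, S_0$
their homeostatic targets, and the last sum runs once over every shared
interface between cells of different types with interfacial tension
$\sigma$.  The volume term penalises volumetric perturbation; the surface
term captures the competition between actomyosin contractility and
cadherin-mediated adhesion; the heterotypic term encodes the
basal–suprabasal tension and the integrin-mediated wetting of the basal
layer on the basement membrane.  After nondimensionalization ($V_0 = 1$,
$K_V = K_S = 1$) the remaining shape parameter is the target shape index
$s_0 = S_0 V_0^{-2/3}$, which controls tissue rigidity: low $s_0$ is
solid-like, high $s_0$ fluid-like, with the 3D rigidity transition near
$s_0 \approx 5.4$.

Vertices follow overdamped Langevin dynamics,

$$\partial_t \mathbf r_i = -\mu \nabla_i E + \sqrt{2 D_t}\,\boldsymbol\eta_i(t),$$

integrated by Euler–Maruyama with step $\delta t = 0.01\,\tau$.  The white
noise of strength $D_t$ is a memoryless stand-in for active cell-generated
forces.

Ghost cells cap the apical surface: they retain full topology (faces,
edges, vertices) but contribute neither energy nor force.  They absorb the
upward flux of stratifying material so that the simulated slab keeps a
quasi-steady height.

## Developmental stages

Stage-specific mechanics enter through the triplet
$(\sigma_a, \sigma_b, \Delta s)$ — basal–suprabasal heterotypic tension,
basal–basement wetting tension, and basal stiffness shift.  The shipped
presets are E14 $= (0.044,\, 0.062,\, 0)$ and E16 $= (0.116,\, 0.067,\,
0.14)$.  $\Delta s$ is applied as a downward shift of the basal target shape
index from the reference $s_{0,\mathrm{ref}} = 5.40$: the model family
controls rigidity through $s_0$, so "stiffer" means a lower basal target
shape index.  E15 sits near a droplet-forming instability and is not
treated.

# Numerical scheme

## Tessellation and topology maintenance

The tissue is built and maintained as the periodic Voronoi diagram of one
seed per cell (periodic in $x$–$y$; the rheometer geometry is periodic in
$z$ as well).  Each Voronoi cell is carved from an initial prism by
bisector half-space clipping against neighbouring seeds (including periodic
images), with a security-radius stop.  The per-cell polyhedra are merged
into a shared-vertex complex; every internal face is stored once, labelled
with its unordered cell pair and periodic image, wound outward from the
lower-id ("owner") cell.

The reference implementation of this model family performs explicit
reconnection (T1) moves.  This package instead refreshes the entire
topology by full re-tessellation from current cell centroids (i) at every
division, and (ii) at a configurable cadence `t_retess` (default $1\,\tau$),
followed by a brief energy relaxation.  The cadence-based rebuild realises
T1-equivalent neighbour exchanges without a hand-coded move catalogue; its
cadence is a numerical parameter, and the exact reconnection thresholds of
the reference code are not reproduced.  Consequences of this choice are
flagged below where they matter (droplet rheology, caging statistics).

Degenerate inputs are handled conservatively: duplicate seeds raise an
error (builders perturb and retry); on exact lattices, bisector planes
tangent at edges produce no face, so jitter-free builds yield exact prisms;
coincident Voronoi vertices are merged within a tolerance of $10^{-6}$ of a
cell length.

## Forces, integration, minimization

Volume, area and interfacial gradients are analytic; the test suite holds
them to central finite differences at $10^{-5}$ relative on jittered
tissues.  Cell volumes use signed tetrahedra fanned from face centroids;
areas use the centroid-fan triangulation.  Energy minimization (after
divisions, identity switches and topology rebuilds) uses FIRE — inertial
descent with adaptive time step and a displacement cap of $0.2$ cell
lengths per iteration — with force-residual tolerance `tol` (default
$10^{-3}$).  A single Langevin step that would move a vertex further than
one cell length aborts the run with a diagnostic, as that always indicates
a too-large time step or force.

Pinned degrees of freedom: the basement-membrane floor vertices and the
ghost-ceiling vertices are immobile.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `K_V`, `K_S` | 1 | nondimensional | model-family convention |
| `mu` | 1 | inverse drag | sets the time unit |
| `D_t` | 0.02 | length$^2$/$\tau$ | basal layer quiescent but not frozen; unconstrained by the main text |
| `dt` | 0.01 | $\tau$ | stated simulation step |
| `s0_ref` | 5.40 | — | near the 3D rigidity transition |
| `s0` (basement) | 5.30 | — | stiff support layer |
| `s0` (suprabasal) | 5.50 | — | softer differentiated compartment |
| `s0` (droplet) | 5.80 | — | fluid regime, no shear-modulus contribution |
| `t_div` | 200 | $\tau$ | division interval; studied range 50–800 |
| `alpha` | 1/200 | $V_0$/$\tau$ | target-volume growth rate: roughly doubles $V_0$ within one default division interval |
| `ell_sep` | $0.3 V_0^{1/3}$ | length | daughter-seed separation, small vs. cell size |
| `t_pop` | `t_div`/2 | $\tau$ | homeostasis checked at least as often as divisions |
| `t_retess` | 1 | $\tau$ | topology refresh cadence (T1 stand-in) |

Units policy: times are reported in $\tau$ with $\tau = 0.1$ min, so one
estimated day is $14400\,\tau$; division rates are reported as
$\lambda = 14400/(N_\mathrm{basal}\, t_\mathrm{div})$ divisions per basal
cell per estimated day.  The Kupffer's-vesicle cross-check
(`speed_conversions()`): $0.55\,\mu$m/min at cell size $10\,\mu$m is $0.055\,
l$/min $= 0.0055\,l/\tau$.

# Division and stratification protocols

A division replaces the parent's Voronoi seed by two daughter seeds at
$\pm(\ell_\mathrm{sep}/2)\,\hat n$, with mitotic axis $\hat n = (\cos\theta
\cos\phi, \cos\theta \sin\phi, \sin\theta)$; $\theta = 0$ is an in-plane
(symmetric) division, $\theta = \pi/2$ perpendicular (asymmetric), and
$\phi = 0$ without loss of generality.  The full tessellation is then
recomputed, daughters split the parent's target volume equally and inherit
basal identity, and the energy is re-minimized before dynamics resume.
Divisions fire on the `t_div` timer regardless of the growing cell's
instantaneous volume (an optional volume-threshold mode exists but is off
by default); exactly one basal cell carries a nonzero growth coefficient at
any time, re-drawn uniformly whenever the growing cell divides or
stratifies.

Stratification bookkeeping follows two channels.  *Homotypic* events: a
basal cell whose centroid lies above the basal–suprabasal interface (mean
height of shared-face centroids between the two layers) **and** which no
longer touches the basement membrane instantaneously switches to suprabasal
mechanical identity ($N_\mathrm{homo}$).  *Fate* events (homeostatic
protocol only): at every multiple of `t_pop`, if the basal count exceeds its
initial reference by more than two, one uniformly random basal cell
switches identity ($N_\mathrm{fate}$).  Every stratification event converts
the top-most suprabasal cell (largest centroid $z$; ties by cell id) into a
ghost, so the non-ghost suprabasal count is conserved.  Under the
densifying protocol the fate channel is disabled and the basal layer
crowds.  At steady state under homeostasis
$N_\mathrm{homo} + N_\mathrm{fate} \approx N_\mathrm{div}$, so yields are
reported normalized by $N_\mathrm{div}$.

Homotypic detection runs at every topology rebuild (contact queries need
fresh adjacency).  The +2 threshold is compared against the initial
reference $N_\mathrm{basal}(0)$ throughout a run, not against a running
reference updated after conversions.

# The droplet rheometer

A contiguous blob of `n_droplet_cells` (17 at full scale) is re-typed to
droplet identity with $s_\mathrm{droplet} = 5.8$ (fluid, no shear-modulus
contribution) and droplet–tissue interfacial tension $\sigma$.  During
actuation every droplet vertex receives the zero-net-force dipole

$$F_i = f\,(x_i - x_\mathrm{cm})\,\hat x,$$

and the droplet elongates along $\hat x$; after release it rounds up again.
Strain is measured from the gyration tensor of the droplet vertex cloud as
$\varepsilon = \ell_\parallel/\ell_\perp - 1$ (elongation along the force
axis over the mean transverse extent).  The printed definition
$\varepsilon = (b - a)/a$ with $a$ the major axis would be non-positive
under stretch; this package uses the positive-under-stretch convention
matching the published strain traces.

Two numerical points discovered while implementing the protocol:

* The dipole must be included in the brief relaxation that follows each
  topology rebuild during actuated phases; otherwise every rebuild relaxes
  the droplet onto the *unloaded* equilibrium and no deformation
  accumulates.
* In this package's normalization the dipole force grows linearly with
  elongation while the interfacial restoring force does not, so there is a
  critical forcing above which the droplet stretches without bound.  At
  desk-scale droplets the published $f = 0.5$ is super-critical; scaled
  runs use $f \approx 0.015$–$0.02$, which saturates near $\varepsilon
  \approx 0.2$, comparable to the published strain amplitudes.  The
  normalization of $f$ (per vertex vs. per cell) is not fixed by the main
  text.

Scaled rheometer runs are executed with $D_t = 0$: the strain noise floor
of a 17-cell droplet at $D_t = 0.02$ is $|\varepsilon| \sim 0.1$, which
would swamp the recovery criterion $|\varepsilon| < 0.02$; the deterministic
response is the meaningful scaled measurement.  Recovery traces are fitted
by nonlinear least squares to
$\varepsilon(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ on the force-off
branch only, with multi-start initialization, amplitudes bounded by twice
the observed range and $\tau_2$ bounded by three times the branch length
(the bounds keep the two-exponential model identifiable on noisy traces).
$\tau_1 < \tau_2$ by convention.

**Known limitation.** At desk scale the slow-mode amplitude is small and
the fitted $\tau_2$ has large estimator variance; moreover the slow
timescale is partly set by droplet rounding (hence by $\sigma$) and by the
re-tessellation cadence rather than by tissue viscoelasticity alone.  The
full-size insensitivity of $\tau_2$ to $s_0$ and $\sigma$ is therefore not
reproduced at desk scale — the corresponding acceptance check is expected
to fail honestly there, and full-size runs are cluster-scale.

# Analysis layer

*Orientation distributions.*  Long-axis angles (gyration-tensor fit;
degenerate fits with equal leading axes are excluded) are measured on
$[0, \pi/2]$, histogrammed, mirrored about $\pi/2$, normalized, and divided
by the 3D isotropic reference $P_\mathrm{iso}(\theta) = \sin(\theta)/2$ —
the uniform orientation measure on the sphere, the natural reading of
"isotropic reference".  Metrics on the $P/P_\mathrm{iso}$ curve: peak,
anisotropy ratio (max/min), and FWHM by linear interpolation between bin
midpoints around the global peak.

*Division-angle weights.*  Published fractions for planar
$[0, \pi/6]$, oblique $(\pi/6, \pi/3]$, perpendicular $(\pi/3, \pi/2]$
divisions — E14: (0.20, 0.25, 0.55), E16: (0.60, 0.25, 0.15) — are
normalized to weights $W_i = f_i / \sum f_i$ and used for
orientation-weighted averages $\langle X\rangle = \sum_\theta W(\theta)
X(\theta)$.  The reported spread is the unweighted standard error of the
mean over the orientation angles (the literal published convention).

*Daughter separation.*  For each division at $t_0$,
$\mathbf s(t) = \mathbf r_{d1}(t) - \mathbf r_{d2}(t)$ (minimal image,
unwrapped along the trajectory), $\Delta\mathbf s = \mathbf s(t) -
\mathbf s(t_0)$, and $\Delta d^2(t) = \lVert\Delta\mathbf s\rVert^2$
ensemble-averaged over events, indexed by time since division with no time
averaging; pairs are censored once either daughter leaves the basal layer.
Binned curves carry subgroup errors: events split into $n$ subgroups
(default 5, e.g. 40 events into 5×8), error = sd(subgroup means)$/\sqrt n$.
The diffusion coefficient is the raw slope of $\Delta d^2$ vs $t$ on the
late-time window (default the late 40% of the trace; no $1/(2d)$ factor,
matching the $\Delta d^2 \sim D t$ convention), with uncertainty from
per-subgroup slopes.  `msd_exponent()` classifies the log–log slope
(subdiffusive below 0.8).

# Synthetic data

`generate_fixture()` builds the deterministic test inputs: tiny layered
lattices (all geometry invariants hold by construction), independent
3D Brownian daughter pairs with known diffusivity $D_0$ (closed form
$\Delta d^2 = 12 D_0 t$), and two-exponential strain traces with specified
$(A_1, \tau_1, A_2, \tau_2)$ and multiplicative noise.  These fixtures
emulate the *statistical structure* of simulator output (trajectory and
trace tables), not epidermal biology: a green parameter-recovery test
establishes that the estimators are correct, not that the tissue model
produces those parameter values.

# The scaled-down world

Full-size studies of this system — 150-cell basal layers run for
thousands of $\tau$, 2115-cell droplet tissues, 40–50 independent runs per
condition — are cluster-scale.  The default test and acceptance runs here
use 9–36 basal cells, 17-cell droplets in ~180–300-cell boxes, 2–3 seeds
per condition and runs of order $10^2\,\tau$, chosen to fit a single-CPU
budget.  Consequences:

* Stratification trends ($N_\mathrm{homo}/N_\mathrm{div}$ monotone in
  $\theta$; E14 above E16; homeostatic bookkeeping closing) reproduce at
  desk scale.
* Division rates cannot be matched in physical units at small
  $N_\mathrm{basal}$ (matching $\lambda = 1.95$/day at $N = 16$ would need
  $t_\mathrm{div} \approx 900\,\tau$ per event); rate trends are asserted
  between fast and slow scaled rates instead, and the published point
  values (e.g. orientation-metric numbers 4.10/6.71, 10.35/25.32,
  58.1°/46.4°) are cluster-scale checks.
* The caging statistics are sensitive to the re-tessellation stand-in for
  T1 moves and to censoring bias at perpendicular angles (the surviving
  basal daughter pairs after near-vertical divisions are atypical); the
  per-angle ordering of $D$ and the late-time scaling regimes at desk scale
  can deviate from the full-scale behaviour, and the corresponding
  trend tests document their own outcome rather than being relaxed.
* Of the three orientation-order metrics, the peak and the FWHM are stable
  at desk-scale sample sizes ($\sim$90 division events per stage), while
  the anisotropy ratio — a max/min statistic — is dominated by
  near-empty bins at planar angles and does not reproduce the full-scale
  stage ordering.

# Open design choices made here

* Daughter target volumes split 50/50 (volume conservation does not fix the
  split; the symmetric default is used).
* Divisions fire on the timer, not on a volume threshold (literal reading;
  threshold mode available).
* $P_\mathrm{iso} = \sin\theta/2$; FWHM via linear interpolation.
* `t_pop = t_div/2`; top-most ghost conversion ties broken by id.
* The Maxwell fit uses the unloading (recovery) branch only, with no offset
  term.
* The ellipsoid fit is the unweighted vertex gyration tensor
  (parameter-free; "ellipsoidal fitting" is not further specified).
* A single seeded RNG stream drives all stochastic choices (noise, cell
  selection, fate conversion), so runs replay bit-for-bit at fixed
  dependency versions; noise-free runs are deterministic given the
  configuration.
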