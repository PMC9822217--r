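---
title: "Mapping CT Hounsfield units to finite-element bone materials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CT Hounsfield units to finite-element bone materials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemapr)
```

## The model

Bone is mechanically heterogeneous: a dense cortical shell carries most of
the load around a porous trabecular interior. Calibrated CT measures this
heterogeneity — the Hounsfield unit (HU) of a voxel is an affine rescaling
of X-ray attenuation (water ≈ 0, dense cortical bone > 1000) and, through
a scanner calibration line, a proxy for volumetric mineral density.
`bonemapr` turns a CT volume plus a tet4 mesh into a material-annotated FE
model in three stages, each treated as an explicit, configurable model
component:

1. a **representative HU per element**, by one of three averaging
   strategies;
2. a **law chain** HU → density → Young's modulus;
3. **binning** of elements into material sets with a modulus /
   volume-fraction distribution.

The package treats the bone as locally isotropic and linear-elastic, the
standard simplification in this class of models: anisotropy measurements
on trabecular bone report modest directional differences, and virtually
all published density–modulus laws are scalar.

## The HU field and its interpolation

The voxel value is taken to sit at the voxel center; world coordinates are
`origin + orientation %*% (spacing * index)` with 0-based indices,
everything in mm. Between voxel centers the field is evaluated by
**trilinear interpolation** (`hu_at()`). Trilinear is the convention of
the established mapping tools; it is exact for fields affine in space,
which gives every averaging strategy a closed-form oracle, and it never
overshoots the local 8-voxel stencil.

Points outside the voxel-center hull are **clamped** to the hull by
default and counted, with a strict `oob = "error"` mode available. Meshes
routinely overhang the scanned volume by fractions of a voxel, so a hard
error by default would reject legitimate inputs; silently extrapolating
would be worse, hence the per-element `clamped_fraction` and the run
report's list of fully-clamped elements.

## Law chains

A `law_chain` is: one calibration line `rho = slope * HU + intercept`
(g/cm³ per HU), zero or more linear density conversions (between
calibrated ρ_CT, ash density ρ_ash, and apparent density ρ_app), and a
piecewise modulus law whose segments are `E = a * rho^b` (MPa) or
constants over half-open intervals `(lo, hi]`. Units are fixed package-wide
(g/cm³, MPa, mm); no unit inference is attempted.

Four published chains ship with their coefficients verbatim
(`builtin_chain()`):

| chain | calibration | conversions | modulus law |
|---|---|---|---|
| `pelvis_uniform_eq1_2` | ρ_ash = 0.00063·HU − 0.0067 | — | E = 10500·ρ_ash^2.29 |
| `cortical_apparent_eq3_5` | ρ_CT = 0.0008·HU (package default, see below) | ρ_ash = 0.877·ρ_CT + 0.079; ρ_app = ρ_ash/0.6 | E = 6850·ρ_app^1.49 |
| `piecewise_eq6_10` | ρ_CT = 0.0008·HU | ρ_ash = 0.877·1.15·ρ_CT + 0.08 | E = 33900·ρ_ash^2.2 (ρ_ash ≤ 0.3); E = 2398 (0.3 < ρ_ash ≤ 0.486); E = 10200·ρ_ash^2.01 (ρ_ash > 0.486) |
| `bonemat_test_eq11_13` | ρ_CT = 0.00079·HU − 0.0039 | ρ_ash = 0.877·ρ_CT + 0.079 | E = 14664·ρ_ash^1.49 |

Decisions worth knowing:

* **Regime boundaries are taken literally** from the printed inequalities:
  ρ_ash = 0.486 falls in the constant 2398 MPa segment, ρ_ash = 0.3 in the
  low-density power law. Segment coverage of `(rho_floor, ∞)` without gaps
  or overlap is enforced at construction, so a misconfigured user chain
  fails at load time with the offending interval named.
* The apparent-density chain's source literature prints **no HU
  calibration** for that law family (its relations start from ρ_CT). The
  chain ships with the same ρ_CT = 0.0008·HU line as the piecewise chain
  so that it is runnable out of the box, but that line is a package
  default, not a published companion: replace it with your scanner's
  calibration for any real use. Calibration coefficients are always
  configuration inputs; the package never estimates them.
* **Floors.** Calibration lines go negative for air and soft tissue, and a
  zero or negative modulus breaks any downstream solve. Densities are
  floored at `rho_floor` (default 1e-3 g/cm³) and moduli at `e_floor`
  (default 0.01 MPa); both are configurable and every flooring event is
  counted in the run report. The floors are numerical guards, not tissue
  models.
* **Averaging order.** By default the element's mean HU is converted once
  to a density and then a modulus. Because the power laws are convex,
  converting each sample and averaging the moduli gives systematically
  higher values; the alternative is exposed as `average = "modulus"`
  rather than silently chosen, since the two orders are a known source of
  discrepancy between mapping implementations.

```{r}
density_to_modulus(builtin_chain("piecewise_eq6_10"), 0.4)
```

## Element averaging strategies

* `node_average` — mean of `hu_at()` at the 4 (transformed) element
  nodes. Cheap; degrades when elements are much larger than voxels.
* `voxel_average` — mean raw HU over voxels whose centers fall inside the
  element. Degrades in the opposite regime: once the element shrinks below
  the voxel size it may contain no center at all, in which case the
  element falls back to volume integration (logged per element) or errors,
  per `voxel_fallback`.
* `volume_integration` (default) — `(1/V)∫ HU dV` by recursive 8-way
  subdivision of the tet into congruent sub-tets, sampling the interpolated
  field at each sub-tet centroid with equal weights.

The integration rule is deliberately low-order. The integrand is only
piecewise-trilinear — it has kinks at every voxel boundary — so
fixed-order polynomial quadrature has no accuracy advantage; what matters
is dense, evenly weighted coverage. The congruent-subdivision point set
has two useful exact properties: its equal-weight centroid coincides with
the element centroid (volume ratios are affine invariants), so the rule is
exact for affine fields at *every* refinement level, and refinement
multiplies the sample count by 8. The default `refinement = 2` (64
samples/element) is validated in the tests by convergence against a
refinement-6 reference on smooth nonlinear fields.

The mesh-to-CT alignment is a user-supplied rigid transform (identity by
default); no automatic registration is attempted, matching the manual
positioning step of the established workflow. Mapping is deterministic —
two runs on identical inputs are bitwise identical — and frame-invariant
under a simultaneous rigid motion of mesh and volume.

## Binning and the distribution

Equal-width intervals in modulus space (default) or HU space, between the
observed minimum and maximum; the highest value belongs to the last bin
and the minimum is closed into the first, so the intervals `(lo, hi]`
partition the elements exactly. Empty bins are dropped with indices
preserved. The default `n_bins = 50` is a presentation choice (tens of
sets resolve the distribution without starving bins); the bin count is
configuration and is echoed in the run report. The representative modulus
per bin defaults to the **volume-weighted mean** of its members, which
preserves the mesh's volume-averaged stiffness better than the interval
midpoint; both statistics are available. Volume fractions must sum to 1
within 1e-12 on every run — this is asserted, not assumed.

## The verification solver

`solve_static()` is a constant-strain tet4 implementation of small-strain
isotropic elasticity with a direct sparse solve. It exists to answer one
question — *does a mapped material field behave physically?* — via three
checks: the constant-strain patch test (exact to ~1e-10 relative in
double precision across the full mapped modulus range 0.01–20000 MPa),
the two-layer laminate under axial traction against the series (Reuss)
compliance closed form, and qualitative load transfer through a stiff
shell (von Mises medians). It is verification-scale by design (direct
solve, no contact, no nonlinearity, meshes of order 10⁴ elements).

The bone Poisson ratio is a single global configuration value, default
0.3 — the conventional choice for bone FE, not a patient-specific or
literature-fitted value — and is echoed in every solution object. In the
laminate verification case the package's tests use ν = 0, because only
then is the 1D series-spring solution exact in 3D (with ν > 0 the layers'
lateral-contraction mismatch perturbs the stress field near the
interface).

## Phantoms: what they do and do not show

The phantom generator produces volumes whose field value is known in
closed form at any world point: constants, globally affine ramps, a
two-valued checkerboard, and a shell body (high-HU cortex around a low-HU
interior) in either spherical (`norm = "l2"`) or cubic (`norm = "linf"`)
geometry. Optional Gaussian HU noise is off by default and requires an
explicit seed; volumes are bitwise reproducible.

One geometric subtlety motivated the cubic option. The strict
element-wise contrast check — *every* element whose centroid lies in the
cortical shell stiffer than *every* interior element — is only well-posed
when no element straddles the material interface: an element crossing the
boundary with its centroid just inside the shell can carry as little as
~42% shell volume (a plane through a tet centroid can leave either side
with ~42–58% of the volume), while an interior-centroid neighbour carries
up to ~58%, so the class extremes overlap regardless of element size. On
a curved interface a structured box mesh always straddles; with the cubic
shell the interfaces are axis-aligned planes that the mesh conforms to
exactly, and the strict check passes with a wide margin for all three
strategies. The spherical shell remains the default and is used for the
trend-level checks (median cortical vs interior modulus and von Mises).

Passing tests on phantoms shows the *mapping machinery* is correct. It
does not validate the empirical law chains against any patient, does not
exercise partial-volume effects at real cortical thickness (~1–3 mm), CT
noise texture, beam hardening, or segmentation error, and box meshes do
not probe the element-quality range of anatomical meshes.

## Numerical choices and problem sizes

* Degenerate elements: volume < 1e-12 mm³ is an error naming the element.
* Element orientation is fixed up at construction (nodes 3/4 swapped where
  the signed volume is negative).
* Point-in-tet membership uses barycentric coordinates with a caller
  tolerance (boundary-inclusive at 1e-9 in the mapping path).
* Out-of-hull detection tolerates 1e-9 voxel units of round-off.
* All file outputs are written atomically (temp file + rename), so a
  failed run leaves no partial artifacts; numeric text output uses 17
  significant digits so re-reads are lossless.
* The test suite runs on meshes of 1–24k elements and volumes up to
  ~2M voxels, sizes chosen so the full suite completes in well under two
  minutes while still exercising every code path at non-trivial scale.

## Known limitations

* tet4 only; quadratic tets are rejected loudly rather than linearized.
* Isotropic laws only; no site-specific or anisotropic mapping.
* DICOM support is restricted to uncompressed explicit-VR little-endian
  single-frame series — the form calibrated clinical CT is normally
  exported in; anything else errors with the reason.
* The solver does not model contact, pretension or gait loading; it is a
  verification instrument, not an analysis engine.
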