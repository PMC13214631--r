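---
title: "Binocular Listing kinematics with misaligned eye optics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular Listing kinematics with misaligned eye optics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listingr)
library(dplyr)
```

This vignette is the package's own account of the model it implements: the
geometry, the algebra, the tunable parameters, the numerical choices, and
what the tests do and do not establish.

## 1. The asymmetric reduced eye and its resting posture

The eye model keeps two anatomical misalignments of the human eye: the fovea
is displaced from the posterior pole (horizontal angle `alpha_deg`, vertical
`gamma_deg`, measured at the eye's rotation center) and the crystalline lens
is tilted away from the eye's optical axis (horizontal `beta_deg`, vertical
`epsilon_deg`). Typical population values — the package defaults — are
α = 5.2°, β = 3.3°, γ = −2°, ε = −1°. β is physiologically meaningful over
roughly −0.4° to 4.7°; the constructors accept ±15° for sensitivity work.

In the binocular **resting posture** (ERP) both lenses' equatorial planes and
both image planes are coplanar with the head's frontal plane `y = 0`. This
posture corresponds to the eye muscles' natural tonus and to binocular
fixation at the abathic distance (about 1 m for the defaults); it replaces
the classical primary position, and the frontal plane replaces the Listing
plane. The resting fixation `fa_cm` (default `(0, 99.56, 1.72)` cm) is a
**configuration input**, not derived: its closed form in terms of the
misalignment angles belongs to the horopter geometry, which is outside this
package's scope.

`build_erp()` constructs, per eye (right at `C = (a, 0, 0)` with
`a_cm = 3.25`, left mirrored through `x = 0`):

* the optical-axis direction `û = Rx(ε)·Rz(−β)·ĵ` — the sign convention,
  exposed as `tilt_sign`, tilts the right eye's axis temporally (+x) for
  β > 0. The calibration anchor for this choice is the pair of reference checks the
  construction must reproduce: the optical center lands at
  `Or = (3.3044, 0, −0.0209)`, which yields the 89.53°/89.37° bisector
  alignment angles to two decimals, and the resting gaze deviates from the
  image-plane normal by 2.12°. The opposite vertical sign moves the
  alignment angle to 89.55° — a small but diagnostic difference.
* the nodal point `N = C + nodal_cm·û` (`nodal_cm = 0.6`), its perpendicular
  projection onto the image plane (the lens-axis foot), and the optical
  center `O` as the intersection of the visual axis (through `N` and `Fa`)
  with the image plane.

With the full 3D defaults the optical center sits 0.0225 cm from the
lens-axis foot. The horizontal-only configuration (γ = ε = 0,
`fa_cm = (0, 99.61, 0)`) gives 0.0199 cm; the figure of "0.02 cm" usually
quoted for this offset is the two-decimal print of either value. Our tests
assert the printed precision (±0.005), not a tighter band the 3D geometry
cannot meet.

Because `O ≠ C`, a symmetric eye (all angles zero) fixating a *midline*
point still converges and keeps `O ≠ C`; the textbook collapse
`O = foot = C` requires the resting gaze along the eye's own optical axis.
The symmetric-limit tests therefore use an on-axis resting fixation (or a
cyclopean eye with `a → 0`).

## 2. Rotation algebra

Rotation vectors `r = tan(φ/2)·n` compose by the Rodrigues rule; the
implementation rejects composites within tolerance of a half-turn (the
representation diverges there) rather than saturating — the model's validity
envelope (< 60° of gaze rotation) never approaches 180°, so the error path
is genuinely exceptional. Angles are degrees at every public interface and
radians internally. Unit and orthogonality checks use an absolute tolerance
of 1e-9 — double precision with a safety margin for the ~10 chained
operations a typical pipeline performs. Euler parameters
(`ρ = cos(φ/2)`, `e = sin(φ/2)n`) are provided alongside; they do represent
half-turns and compose by the classical product rules, and the tests check
both representations against an independently coded quaternion oracle.

## 3. Gaze conventions and the torsion they carry

Sending a gaze axis to a new target fixes two rotational degrees of freedom;
a full rigid posture needs a convention for the third (torsion about the
line of sight). Four are implemented:

| tag | construction |
|---|---|
| `fixation_geodesic` | single rotation about `(Va × V1)/‖·‖` at the rotation center (the closed-form construction) |
| `visual_geodesic` | same, anchored at the optical center |
| `gimbal_vertical_first` | head-vertical (z) rotation first, then horizontal (x) |
| `gimbal_horizontal_first` | the reverse nesting |

The geodesics carry almost no torsion (< 1° for the reference targets); the
gimbals carry "false torsion" of the order of degrees, as any construction
that realizes a gaze change by successive azimuth/elevation rotations does.
The reference simulation values this package is checked against (τ of 3.15°
and 4.14° at the first tertiary target) clearly come from a
torsion-carrying construction: `calibrate_convention()` ranks the four
conventions by summed torsion residual and selects `gimbal_vertical_first`
(residuals 0.38°, 0.64°, 0.16°, 0.25° across the four reference torsions).
Three of the four land within 0.5°; the left-eye torsion at the first
target does not (0.64°), under any convention in the enum — the reference
construction is not fully specified by its source, and the validator
*reports* this residual rather than hiding it. All quantities that do not
depend on the convention (resting geometry, reference-input compositions,
alignment angles, tilt-angle coefficients) reproduce at their stated
tolerances.

`refine_for_O_translation` iterates the visual geodesic so the rotated
visual axis passes through the target to 1e-6 cm despite the optical
center's own displacement; it defaults to off because rotated *angles* are
unaffected by that sub-0.03 cm translation, and on only where overlay
checks need the translated center. Targets are accepted up to 90° of
rotation with a warning beyond the 60° validity envelope; targets on the
eye's resting fixation axis give the identity for the fixation-based
conventions (tie-break: zero rotation), and the gimbals return pure
single-axis rotations for targets reachable by one.

## 4. Torsion decomposition

`decompose_posture()` computes `r = geodesic(j → b)` (its axis is exactly
in-plane: the cross product of `j` with anything has zero y-component),
rotates the posture frame back by `−r`, and reads the signed torsion τ from
`k` to the primed `c'` about `+j` (positive = counterclockwise seen from in
front of the head; the reference values are unsigned frame angles, so
`tau_unsigned_deg` is reported alongside). The reconstruction
`r ∘ q = full rotation` is an algebraic identity, tested to 1e-10 over 1000
random postures.

For transfers, the torsional part is `q12 = tan((τ2 − τ1)/2)·j`. The
half-angle matters: the superficially plausible `tan(τ2 − τ1)·j` is not a
valid rotation vector, and only the half-angle form satisfies `q12 ∘ q1 = q2`
(rotations about a common axis add their angles, and the rotation-vector
magnitude is the tangent of *half* the angle). The tests assert that
identity directly.

## 5. Half-angle rule, displacement planes, and the TAC

For a move away from a tertiary fixation F1, the displacement plane is
perpendicular to the bisector `e = normalize(ĵ + unit(F1 − O*))`. The
alignment angle between the transfer vector and `e` measures the rule
(90° = exact); the overlay check instead rotates F1 by `r12` about the
translated optical center and measures the angular miss from the end
posture's visual axis (< 0.1° for the reference scenario, asserted < 0.5°).
`O*` defaults to the translated optical center for eccentricity and overlay
(the drawn constructions use the rotated eye) and to the resting one for
the bisector; both are flags, and the difference is below 0.01° in the
reported angles.

The tilt-angle coefficient construction selects equidistant points `H1` (on
the normal line) and `I1` (on the visual axis) and a point `J1` on the chord
between them. A drawn-figure recipe for `J1` — drop a perpendicular from the
tip of the displayed `r12` arrow to the chord — depends on the arrow's
display scale and has *no* solution for this geometry: the arrow tip sits at
height `≈ −0.014·s` while the chord spans heights `[0.90d, d]` for every
plausible scale. The package instead takes `J1` as the intersection of the
chord with the plane through `O*` perpendicular to `r12` — the plane in
which points actually move under the transfer rotation. This solve is
parameter-free (the chord parameter `t = −(ĵ·r̂12)/((v̂−ĵ)·r̂12)` contains
neither the chord distance `d` nor any display scale), degrades gracefully
(`r12` in the resting plane ⇒ ν = 0 ⇒ TAC = 0), and reproduces the
reference coefficients to ±0.02 (0.46/0.47/0.46/0.46 against
0.48/0.45/0.46/0.46). ν carries the sign of the tilt toward the visual
axis. In the symmetric-eye limit the alignment angle is 90° exactly — the
suite verifies the closed-form identity
`tan(φ/2)(1 + cos φ) = sin φ` numerically to 0.01° over random in-plane
rotation pairs up to 25°.

## 6. Configuration space

Posture changes are pairs `σ = (r, q)` composing componentwise, right to
left, with labelled endpoints guarding against composing non-adjacent legs.
Componentwise composition is the *defined* operation; it is **not** the
torsion decomposition of the composed physical rotation — composing two
in-plane-axis rotations generically leaves the plane, which is the
noncommutativity underlying the half-angle rule. `sigma_coupling_gap()`
exposes both quantities and their discrepancy instead of guessing which one
a caller means. Because every fixation is referenced to the resting posture,
chains telescope: `path_reduce()` over any fixation sequence returns a net
change identical (to 1e-10) to the direct transfer between the endpoints,
and closed loops return the identity.

## 7. Synthetic targets, problem sizes, and what the tests show

`generate_target_grid()` draws targets uniformly in azimuth/elevation/
distance (defaults ±40°, ±20°, 25–100 cm — inside the 60° envelope, spanning
near to the abathic distance) under a fixed seed, leaving the global RNG
untouched, and appends the two named tertiary fixtures. The property suite
runs 1000 random composition pairs and 1000 random posture decompositions,
100 transfer-antisymmetry pairs, 100 five-leg telescoping paths, and 50
symmetric-limit alignment checks; the whole suite completes in ~20 s on one
CPU. These sizes are chosen so that each property is exercised across the
full representable angle range while the suite stays interactive.

What passing does **not** show: the model idealizes the eye as a rigid body
with a single fixed rotation center, takes the resting fixation as given
rather than deriving it from the optics, and treats gaze changes as static
posture-to-posture maps — no trajectories, no velocity-domain axes, no
motor-plant (pulley) mechanics, and no retinal correspondence/horopter
geometry. The torsion a *real* eye carries is convention-free
physiology; here it is convention-dependent except for its decomposition
algebra, and one reference torsion is reproduced only to 0.64°. Comparisons
with clinical torsion data (the shipped `literature_table()` fixtures) are
side-by-side displays, not fits.

## 8. Degenerate inputs and tie-breaks

Rejected with explicit errors: 180° rotations anywhere in the algebra
(composition denominators within 1e-9 of zero, matrices with trace within
1e-9 of −1), antiparallel geodesic endpoints, fixations at the anchor point
of an axis, targets at or behind the eye (≥ 90° rotation), postures whose
frame normal is antiparallel to the resting normal, configurations whose
visual axis is parallel to the image plane, and non-chainable
configuration-space labels. Ties: a target already on the gaze axis gives
the zero rotation; the torsion sign at exactly τ = ±180° cannot occur
within the envelope.
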