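# tapekin

Kinematics of tape-like unstable training surfaces from angles measured
near the anchor points.

## The problem

Balance and coordination training on unstable bases of support —
slacklines, or the two tapes of a Sensopro Luna — benefits from live
performance feedback: step counts and rhythm from vertical tape
displacement, foot positioning from the longitudinal position of the
loaded point, lateral displacement as a proxy for center-of-pressure
movement, and the roll of the tape under the foot as a posture cue.
Instrumenting the foot or the middle of the tape is impractical; sensors
near the anchors are not.

A tensioned tape carries only longitudinal force, so each unloaded
stretch is a straight segment between anchor and load point (an ideal
rope). The position of the loaded point therefore follows in closed form
from the orientation of the tape sections adjacent to the two anchors.
With normalized pitch angles α (back) and β (front), both positive for
downward displacement, on a span of rest length L:

    t  = cos α + sin α · cos β / sin β
    Z  = −sin(α) · L / t            (vertical displacement, ≤ 0)
    XZ =  cos(α) · L / t            (distance from the back anchor)

and identically in the horizontal plane for yaw → (XY, Y). A flat foot
segment of length LF makes the point-mass model overestimate depth by
the intercept-theorem factor dR/dM = 1 − LF/L (≈ 0.85 for LF = 260 mm on
L = 1726 mm), applied as the `segment_ratio` correction. Four roll
predictors (RM, RS, RWS, RA) extrapolate the measured end-section rolls
to the foot, with a calibratable spring twist-rate coefficient.

The package is for movement scientists and feedback-system developers:
it implements the inverse model, a forward geometric simulator
(ground-truth shapes, marker clouds, sensor noise, one-sided IMU pitch
drift) that doubles as the test oracle, the offline conditioning
pipeline (zero-phase Butterworth filtering, resampling onto a common
grid, exclusion rules, pitch-drift adjustments), rigid-body section
reconstruction from motion-capture markers (Kabsch alignment, Tait-Bryan
XYZ-intrinsic angles), least-squares parameter calibration, and an
accuracy-evaluation toolkit (per-trial RMSE, percentile box statistics,
position-conditioned error profiles).

## Worked example

```r
library(tapekin)

geom <- luna_geometry()                       # 1726 mm span, 200 mm springs
pars <- model_params(segment_ratio = 0.85,    # flat-foot correction (dR/dM)
                     spring_coeff = 2)        # spring twist-rate multiple

# one frame of normalized anchor angles (degrees)
ang <- data.frame(pitch_back_deg = 12.4, pitch_front_deg = 7.9,
                  yaw_back_deg = 1.6, yaw_front_deg = 1.1,
                  roll_back_deg = 3.2, roll_front_deg = 1.4)
est <- estimate_tape(ang, geom, pars)
round(est[, c("xz_mm","z_mm","zr_mm","xy_mm","y_mm",
              "roll_rs_deg","roll_rws_deg","roll_ra_deg")], 1)
#>    xz_mm   z_mm  zr_mm  xy_mm y_mm roll_rs_deg roll_rws_deg roll_ra_deg
#> 1 -195.2 -146.8 -124.8 -159.9 19.6         5.7            6         4.6
```

Reading the output: the foot is about 195 mm behind mid-span (pitch
model), the tape center is 147 mm below rest — 125 mm after the
flat-foot correction — the yaw model agrees on the position to ~35 mm
and sees a 20 mm leftward displacement, and the spring-corrected roll
predictors put the foot-segment roll near 6°.

The forward simulator serves as the oracle for all of this. For example,
the flat-foot correction ratio emerges from simulated geometry rather
than being assumed:

```r
s <- simulate_static(foot_load(x_mm = 0, depth_mm = 100, flat_mm = 260), geom)
inv <- estimate_sagittal(s$angles$pitch_back_deg, s$angles$pitch_front_deg,
                         geom, pars)
100 / (-inv$z_mm)     # true depth / model depth
#> 0.8494
```

## Command line

An executable wrapper is installed as `exec/tapekin` inside the package
library; it wraps `tapekin_cli()`:

```sh
tapekin simulate  --scenario scenario.json --out bundle/
tapekin estimate  --bundle bundle/ --out est.csv --source imu [--no-clamp] [--detrend]
tapekin evaluate  --estimates est.csv --bundle bundle/ --out summary.json
tapekin calibrate --bundle bundle/ --target spring_coeff --out params.json
```

Exit codes: 0 success, 2 usage error, 3 data error. A ready-made
scenario and device configuration ship in `inst/extdata/`.

## Scope

Offline analysis only; no sensor-fusion algorithm for raw IMU data, no
center-of-pressure inference, no slackline/trampoline-specific
parameterizations, and no reproduction of human-subject accuracy tables
(the underlying recordings are not public). See the methods vignette
(`vignettes/tape-kinematics-methods.Rmd`) for the model assumptions,
parameter defaults, and the design decisions taken where the source
material leaves the construction open.
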