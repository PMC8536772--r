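# gaitmms

Digital gait analysis from wearable-sensor kinematics: standardized
micro-movement spikes (MMS), a single-internal-delay Granger-causality model
of information flow between body nodes, and stochastic signatures that
stratify subjects into self-emerging clusters.

## The problem and who this is for

Wearable sensor grids record angular speeds, accelerations and positions from
15–23 body nodes while a person walks for a few minutes. Conventional gait
summaries (mean cadence, stride time) throw away the moment-to-moment
fluctuations that carry information about how the nervous system coordinates
the body. `gaitmms` is for movement-science and digital-biomarker researchers
who want to work with those fluctuations directly:

- **MMS standardization.** Each local peak of a kinematic series is
  normalized by its flanking minima, `v = p / (p + (m_before + m_after)/2)`,
  a unitless amplitude in (0, 1] that cancels anatomical scale, so subjects
  of different sizes and sensors of different gains become comparable.
- **Causal networks with internal timings.** For every directed pair of node
  series the package fits a non-causal and a causal autoregressive model with
  one internal delay `l`:

  ```
  x_n = a1 x_(n-l) + w1          (non-causal)
  x_n = a2 x_(n-l) + b y_(n-l) + w2   (causal)
  GC(l) = log(sigma1^2 / sigma2^2)
  ```

  solved in closed form from the sample moments R_xx(0), R_xx(l), R_yy(0),
  R_xy(0), R_xy(l). The delay maximizing GC is the *optimal lag* (an internal
  motor timing); `force = max GC / optimal lag` proxies the speed of
  information transfer; significant causality in both directions of a pair is
  a *feedback loop*. Surrogate (circular-shift) testing supplies
  significance; out-degree, asymmetry and feedback maps summarise the
  directed network.
- **Stochastic signatures and stratification.** MMS amplitudes are
  characterised by an MLE gamma fit (the scale is the noise-to-signal ratio),
  skewness, the Hartigan dip test of unimodality, and an exponential +
  Gaussian mode decomposition; together with the stride proxy
  (mean COM speed / mean frequency, in meters) these features place every
  subject in low-dimensional spaces where k-means finds subgroups.
- **Synthetic ground truth.** A seeded generator produces quasi-periodic
  multi-node walks with known cadence, gamma or two-mode amplitude
  distributions, directed spike-level couplings and optional tremor bands, so
  every stage of the pipeline can be validated against planted truth.

## A worked example

```r
library(gaitmms)

# a synthetic subject: 3-minute walk, left foot drives the right with
# gain 0.4 at a delay of 3 strides
truth <- gait_truth(couplings = data.frame(
  source = "foot_left", target = "foot_right", gain = 0.4, lag = 3))
sim <- simulate_subject(truth, duration_s = 180, rate_hz = 100, seed = 1)

# micro-movement spikes of the right foot
mms <- mms_extract(sim$recording$foot_right, rate_hz = 100, center = TRUE,
                   source_unit = "rad/s")
mms
#> <mms_series> 179 spikes (gamma-centered) [source: rad/s]

# directed causality: does the left foot predict the right?
src <- mms_extract(sim$recording$foot_left, 100, center = TRUE)
sweep <- lag_sweep(mms$value_centered, src$value_centered, lags = 1:10,
                   mode = "ols")
sweep
#> <lag_sweep> optimal lag 3, max GC 0.09618, force 0.03206 (ols/strict)
glance(sweep)

# is it significant, and is there feedback?
gc_significance(mms$value_centered, src$value_centered, 1:10, "ols",
                "strict", n_surrogates = 199, seed = 2)$p_value
#> [1] 0.005
```

The optimal lag of 3 recovers the planted 3-stride delay; the force is the
maximal causality divided by that lag; the p-value of 0.005 (199 surrogates)
says no circular-shift surrogate reached the observed causality.

Cohort-level analysis chains the same pieces:

```r
cohort <- simulate_cohort(list(control = gait_truth(),
                               affected = gait_truth(
                                 mode_mixture = list(weight1 = 0.5, rate1 = 25,
                                                     mean2 = 0.72, sd2 = 0.05))),
                          n_per_group = 4, seed = 3)
res <- run_pipeline(cohort)
res$centroids[, c("group_label", "mode1_pct", "dip", "nsr")]
```

A command-line front end (`inst/cli/gaitmms.R`) exposes the stages as
subcommands (`simulate`, `mms`, `gc`, `network`, `coherence`, `signatures`,
`strata`, `all`) for shell pipelines.

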