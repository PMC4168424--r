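# gaitmode

Locomotion-intent prediction from wearable gait sensors: recognize the
current locomotion mode of a walking person in real time and detect
transitions between modes *before* they complete — the information a
powered lower-limb prosthesis controller needs to switch control modes
safely.

The package is built around recordings from a practical wearable suite
sampled at 100 Hz: two plantar-pressure insoles (four force sensors each,
under the big toe, 1st metatarsal, 4th metatarsal and heel of both feet)
and three inertial measurement units on the thigh, shank and foot of one
"measured" leg (pitch, roll and two acceleration axes each) — 20 channels
in all. Six locomotion modes are recognized: standing (S, including
dynamic standing while turning), level walking (W), stair ascent (SA),
stair descent (SD), ramp ascent (RA) and ramp descent (RD), together with
the ten transitions between them.

## The model

Recognition is two-level:

1. **Gait-phase segmentation.** Foot contact is detected from each
   insole's 4-sensor sum by hysteresis thresholding with a refractory
   debounce. A state machine anchored on the measured leg converts the
   two contact series into the four adjacent gait phases — measured
   foot-contact starts initial double stance (DS1), contralateral
   foot-off starts single stance (SS), contralateral foot-contact starts
   terminal double stance (DS2), measured foot-off starts swing (SW).
   Standing holds the current double-stance state.

2. **Phase-gated classification.** Overlapping 150 ms analysis windows
   advance every 10 ms. Each window is summarized by six time-domain
   features per channel — maximum, minimum, mean, waveform length
   `WL = sum(|x[k+1] - x[k]|)`, population standard deviation, and RMS —
   giving a 120-dimensional feature vector. One linear discriminant
   classifier per gait phase (class means, pooled shrunken covariance
   `(1-lambda) * Sigma_hat + lambda * (tr(Sigma_hat)/d) * I`, empirical
   priors) produces a mode decision `R_i` and its posterior `p_i` via a
   softmax over the discriminant scores.

3. **Posterior-weighted majority voting.** Each decision votes with
   weight `W_i = (p_i - p0)/(1 - p0)` if `p_i >= p0`, else 0. Over the
   last `N = 5` decisions the voting value of mode j is
   `V_j = sum_i W_i * [R_i = M_j]`, and the smoothed output changes to
   the top mode only when `V_max > gamma * N` (defaults `p0 = 0.5`,
   `gamma = 0.75`); otherwise the previous decision is held. An
   unweighted plurality over 15 decisions is included as the classical
   baseline.

4. **Transition scoring.** Each trial is split into steady periods and
   transition periods. A transition is detected when more than 30
   consecutive smoothed decisions equal the new mode, starting inside
   the transition period, with no contrary decision afterwards within
   the period. Prediction time is `T_pre = t_c - t_pre`, measured
   against the critical moment `t_c` (the measured foot's contact, or
   the final contact before standing); the adjusted prediction time
   `APD = sum(T_pre) - 2000 ms * N_miss` summarizes a trial.

Because the reference dataset for this kind of system is not publicly
available, the package ships a synthetic gait generator
(`generate_trial()`, `generate_cohort()`) that emulates the standard
protocol trial — stand, walk, stair ascent, walk, ramp descent, walk,
stand/turn, walk, ramp ascent, walk, stair descent, walk, stand/turn —
with exact ground truth (mode segments, per-foot contact events), Set-A
and Set-B leading-leg variants, per-subject and per-trial template
variability, sensor noise, motion artifacts, and controllable inter-mode
separability.

## Worked example

```r
library(gaitmode)

cohort <- generate_cohort(n_subjects = 2, n_pairs_per_subject = 3,
                          sim_config(seed = 42))
trials <- cohort_trials(cohort)

# train a bank on subject 1's first two experiment pairs (Set-A + Set-B)
fit <- gaitlda(trials$trial[trials$subject == 1 & trials$pair <= 2])
fit
#> Phase-gated LDA locomotion-mode classifier (150 ms windows, lambda = 0.001)
#> Training windows per phase: DS1=3170, SS=5544, DS2=2398, SW=5544

# causal replay of a held-out trial and full scoring
test_trial <- trials$trial[[which(trials$subject == 1 & trials$pair == 3 &
                                  trials$variant == "A")]]
res <- evaluate_trial(fit, test_trial)
sprintf("steady CA: %.2f%%  APD: %.0f ms  missed: %d/12",
        res$CA, 1000 * res$APD, res$n_miss)
#> "steady CA: 99.23%  APD: 2602 ms  missed: 0/12"

head(res$outcomes[, c("from", "to", "lead", "detected", "T_pre")], 4)
#>   from to lead detected T_pre
#> 1    S  W    M     TRUE 0.188
#> 2    W SA    M     TRUE 0.108
#> 3   SA  W    M     TRUE 0.118
#> 4    W RD    M     TRUE 0.118

# leave-one-pair-out cross-validation of the whole cohort
loocv_evaluate(cohort)
#> Pipeline evaluation (6 folds, modified post-processing)
#>   steady-period CA: 98.91% +/- 0.32% (SEM across subjects)
#>   APD: 3243 ms +/- 113 ms; missed detections: 0 / 144
#>   mean T_pre: measured-led 137 ms, unmeasured-led 404 ms
```

The per-trial numbers read as follows: 99.23% of the smoothed decisions
during steady locomotion match the ground-truth mode; all 12 transitions
of the protocol trial were detected, most of them 100-400 ms before the
critical foot contact (positive `T_pre`, in seconds); transitions led by
the unmeasured leg are predicted earlier than measured-leg-led ones
because the contralateral insole reports the new terrain half a gait
cycle before the instrumented leg moves.

## Trial files and command line

Trials are stored as one CSV per trial (a `time` column plus the 20
canonical channels) with a JSON ground-truth sidecar (`<stem>.gt.json`)
holding the mode segments, per-foot contact/off events and the Set-A/B
variant; `write_recording()` / `read_recording()` round-trip them
losslessly. A thin command-line front end with verbs `simulate`,
`train`, `predict`, `evaluate` and `sweep` lives at
`inst/cli/gaitmode.R`:

```sh
Rscript inst/cli/gaitmode.R simulate --subjects 7 --pairs 6 --seed 42 --out trials/
Rscript inst/cli/gaitmode.R train --in trials/ --out model.bank
Rscript inst/cli/gaitmode.R predict --model model.bank --trial trials/S01_P06_A.csv --out stream.csv
```

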