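# betatrack

Synthetic bimanual tracking and movement-related beta desynchronization
(MRBD) analysis.

## What this is for

Attenuation of sensorimotor beta-band (13–30 Hz) EEG power during
movement planning and execution — MRBD — is a hallmark of motor
control, changes with age, and relates to bimanual performance. Testing
an MRBD analysis pipeline is hard precisely because the interesting
quantities (stage-, region- and hemisphere-specific power changes in
dB) are buried in noisy spectral estimates, and public data for the
classic design (a bimanual tracking task performed by younger and older
adults during EEG) do not exist.

betatrack solves this by pairing the full analysis pipeline with
generators whose ground truth is known:

* a **bimanual tracking task simulator** — 4-block sessions with
  transition-balanced pseudo-random condition order (inter-hand speed
  ratios 1:1, 1:3, 3:1), constant-speed target on an inclined line,
  dial-rotation traces from a noisy delayed controller, and the
  tracking-error score (mean of cursor–dot distance plus orthogonal
  cursor–line distance over the 5 s execution stage);
* a **synthetic EEG generator** — epoched six-channel recordings
  (F3/F4, C3/C4, P3/P4; −3 to 3.5 s around execution onset) containing
  a band-limited beta rhythm over 1/f noise, whose amplitude envelope
  implements configurable stage-specific desynchronization depths in dB
  (elevated resting beta in older adults; central-dominant,
  left-lateralized planning and right-lateralized execution MRBD);
* the **analysis**: complex Morlet time-frequency decomposition, dB
  normalization against the frequency-specific condition-average
  baseline (−2.5 to −2.2 s), a condition/group-blind grand-average
  significance mask (per-cell t-tests at the Bonferroni-corrected
  threshold α/(n_freqs × n_times)), masked MRBD extraction per
  participant × electrode × condition × stage, and the inferential
  layer: an inverse-Gaussian identity-link GLMM for tracking error,
  Gaussian LMMs for MRBD with backward stepwise reduction,
  BH-FDR-corrected pairwise contrasts, an MRBD–behavior association
  model, and Spearman correlations.

Every stage is deterministic per seed, so injected effects can be
recovered end to end: that recovery is the package's acceptance
standard. The audience is anyone building or sanity-checking
ERD/ERS-style EEG pipelines, or teaching them.

## The core quantities

For a trial with cursor c(t) and target dot d(t) on a target line with
unit direction u:

    tracking error = mean_t [ ‖c(t) − d(t)‖ + dist⊥(c(t), line) ]

For EEG, power P(f, t) from unit-energy complex Morlet wavelets is
baselined as

    dB(f, t) = 10 · log10( P(f, t) / B(f) ),

B(f) the baseline-window mean of the across-condition average power.
A grand-average time-frequency matrix (all participants, electrodes,
conditions) feeds the mask: a beta-band cell enters when its value is
inconsistent with the rest-stage (−3 to −2 s) distribution at that
frequency,

    t = (x − mean_rest) / (s_rest · sqrt(1 + 1/n)),   p < α / (n_f · n_t),

and MRBD is the mean dB over masked cells. See the methods vignette
(`vignettes/betatrack-methods.Rmd`) for the full account.

## Worked example

```r
library(betatrack)

report <- run_study(study_config(master_seed = 1))

report$masks$planning$included_fraction   # 57.9 (% of beta cells)
report$masks$execution$included_fraction  # 100

aggregate(tracking_error ~ condition, report$behavior, mean)
#>   condition tracking_error
#> 1   ONE_ONE      0.1037709
#> 2 ONE_THREE      0.1413293
#> 3 THREE_ONE      0.1447640

aggregate(tracking_error ~ group, report$behavior, mean)
#>     group tracking_error
#> 1   OLDER     0.16351108
#> 2 YOUNGER    0.09639842

report$recovery
#>       stage injected_mean_db extracted_mean_db    error_db
#> 1  planning        -1.282002         -1.372683 -0.09068083
#> 2 execution        -3.306488         -3.323317 -0.01682960

report$correlations
#>     group        rho         p  n
#> 1   OLDER  0.6000000 0.0666880 10
#> 2 YOUNGER -0.1030303 0.7769985 10
```

Reading the output: the iso-frequency condition is tracked best and
older adults track worse (in normalized line units, lower = better);
the execution-stage mask covers the whole candidate beta plane while
the planning mask covers about 58% of it; the pipeline recovers the
injected cohort-mean desynchronization depths to better than 0.1 dB;
and right-central planning MRBD correlates positively with tracking
error in the older group (less desynchronization, worse performance) —
the association the generator encodes via its participant-level skill
latent. The association model's retained coefficient on that predictor
(`report$association`) is ≈ 0.034 tracking-error units per dB.

The numbered scripts under `analysis/` run the same study as a
stepwise narrative (simulate → behavioral GLMM → EEG/TFR/mask/MRBD →
factor and association models), writing tables under `results/`.

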