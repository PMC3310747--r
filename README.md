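# etdprep

Pre-processing and precursor charge determination for electron transfer
dissociation (ETD) tandem mass spectra.

ETD dissociates multiply protonated peptides into c and z&#775; (and often y)
fragment ions, but a large share of the precursor population survives as
intense *charge-reduced precursor* (CP) ions: a parent ion of neutral mass
M and charge n leaves peaks at

    MH(z+) = (M + zH) / z,   z = 1 .. n

together with neutral-loss (NL) satellites of ammonia (−17 Da), water
(−18 Da), CO (−28 Da) and the guanidino group (−43 Da), each offset by
loss/z on the m/z axis. These peaks are noise for a sequence-library
search engine — but for spectra from low-resolution ion traps, where the
precursor charge is not measured, their *pattern* is the best available
evidence of what n is. `etdprep` implements both sides of that trade:

* **Precursor filter** — removes each charge-reduced species with an
  asymmetric window: mass-proportional upstream extent `M/(W·z)`
  (default W = 500) to cover the widening isotopic envelope, and
  downstream extent `N1/z` (60 Da, z ≤ 2) or `N2/z` (18 Da, z ≥ 3) to
  cover the neutral losses. A fixed ±3.1 Da comparison filter and a
  passthrough are included.
* **Noise filter** — deisotoping (peaks 1–2 Da above a more intense peak
  are dropped) followed by retention of the top `h1` peaks per ±27 Da
  sliding window (1+ products) and top `h2` per ±14 Da (2+ products);
  `h` should equal the number of ion series searched (3 for c, z&#775;, y).
* **Charge determination** — per candidate charge c ∈ {3..7}, the
  TIC-normalised intensity captured by that hypothesis's CP windows
  (`MH(z+) − tolp/z` to `MH(z+) + M/(W·z) + tolp/z`) and NL windows
  (`MH(z+) − N2/z ± tol/z`) feed a linear discriminant classifier whose
  posteriors drive three assignment strategies: **Top 1** (always the best
  charge), **Top 1/Top 2** (best if p ≥ t1, else top two) and **1/2/All**
  (best if p > t1, top two if t2 ≤ p ≤ t1, the whole range otherwise),
  with t1 = 0.99 and t2 = 0.9. NL features matter because charge
  *multiples* (3+ vs 6+) share CP bins but not loss positions.
* **Synthetic data** — a seedable generator of annotated ETD spectra
  (CP ladders with 1/z-spaced isotopes, NL satellites, c/z&#775;/y
  ladders, chemical noise) for validating the filters and classifier.
* **MGF I/O and pipeline** — `read_mgf()`/`write_mgf()` (multi-candidate
  `CHARGE=3+ and 4+` dialect), an end-to-end `run_pipeline()`, and a CLI
  script at `inst/cli/etdprep-cli.R` with `simulate`/`train`/`predict`/
  `filter`/`run`/`evaluate` subcommands.

## Worked example

The charge-reduced series of a precursor observed at 492.2 m/z with
charge 3+:

```r
library(etdprep)
reduced_precursor_series(492.2, 3)
#>   z        mz
#> 1 1 1474.5854
#> 2 2  737.7964
#> 3 3  492.2000
```

The MH(1+) and MH(2+) species sit at 1474.6 and 737.8 m/z; under a 4+
hypothesis they would instead sit at 1965.8, 983.4 and 655.9 m/z —
non-overlapping bins, which is what makes the pattern informative.
Filtering a small spectrum containing the series and two water losses:

```r
sp <- etd_spectrum(
  mz        = c(250.1, 474.6, 492.2, 581.0, 719.8, 737.8, 900.4, 1456.6, 1474.6),
  intensity = c(40, 15, 950, 120, 25, 820, 35, 90, 760),
  precursor_mz = 492.2, precursor_charge = 3, scan_id = "demo")
peaks(apply_precursor_filter(sp))
#>      mz intensity
#> 1 250.1        40
#> 2 474.6        15
#> 3 581.0       120
#> 4 900.4        35
```

The three CP peaks (492.2, 737.8, 1474.6) and their water losses (719.8,
1456.6) are gone; the fragment-region peaks survive. Training the charge
classifier on 428 synthetic spectra and applying the 1/2/All strategy to
500 held-out spectra:

```r
train <- generate_dataset(428, seed = 20)
fp    <- charge_feature_params()
model <- fit_charge_lda(extract_feature_matrix(train$spectra, fp),
                        train$truth$charge, feature_params = fp)
test  <- generate_dataset(500, seed = 21)
post  <- posterior_charge(model, extract_feature_matrix(test$spectra, fp))
asg   <- assign_charges(post, "all", scan_id = test$truth$scan_id)
evaluate_assignments(asg, test$truth)
#> Charge evaluation on 500 spectra
#>   misclassification (true charge outside assigned set): 0.00%
#>   best-charge error: 0.00%
```

The misclassification rate counts spectra whose true charge is not in the
assigned candidate set; under 1/2/All, uncertain spectra fall back to the
full 3+–7+ range rather than being guessed.

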