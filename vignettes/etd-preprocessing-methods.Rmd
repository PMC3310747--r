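---
title: "ETD spectral pre-processing and charge determination: methods and design"
author: "etdprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ETD spectral pre-processing and charge determination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdprep)
```

## The problem

Electron transfer dissociation fragments multiply protonated peptides by
transferring an electron from a reagent anion to the precursor cation.
Two consequences shape the spectra this package processes. First, a large
fraction of precursors capture electrons without dissociating, leaving a
ladder of intense charge-reduced species at `MH(z+) = (M + zH)/z` for
`z = 1..n`, each trailed by neutral losses of ammonia, water, and
sometimes CO or the guanidino group, offset by `loss/z` on the m/z axis.
These peaks depress sequence-search scores and should be removed before
searching. Second, on low-resolution ion traps the precursor charge `n`
is not measured, forcing search engines into slow, false-positive-prone
range searches — yet the CP/NL pattern itself encodes `n`, because a
charge-n parent distributes its reduced series over n characteristic,
non-overlapping bins.

`etdprep` treats the same raw spectrum twice, for two different purposes:
feature extraction for charge determination reads the CP/NL regions, and
the filters then delete those same regions for the benefit of the search
engine. The pipeline order is therefore fixed: predict charge first, then
filter.

## Precursor filter

For each charge-reduced species z of a precursor of neutral mass M, the
filter removes peaks strictly inside

* `(MH(z+) − N1/z, MH(z+) + M/(W·z))` for z = 1, 2, and
* `(MH(z+) − N2/z, MH(z+) + M/(W·z))` for z = 3..n,

with defaults `W = 500` (dimensionless), `N1 = 60` Da and `N2 = 18` Da.
The upstream extent is proportional to mass because the isotopic envelope
of a peptide widens with mass: a fixed window either clips fragment
signal from small 3+ peptides or leaves envelope tails of large 7+ ones.
The broad `N1` blanket below the 1+ and 2+ species covers all common
losses (−17 to −43 Da); at higher z the losses compress as `loss/z` and
the narrower water-scaled `N2` suffices. A fixed ±3.1 Da variant (with
its own `(MH(z+) − N1/z, MH(z+))` loss window) is provided for
comparison, and `variant = "none"` is a passthrough.

Two contract details are deliberate. The window inequalities are strict,
exactly as written above, so a peak *on* a boundary survives; floating
point makes the case rare, but the behaviour must be fixed and testable.
And when charge determination returns a candidate *set*, filtering uses
the largest candidate: its windows cover the shared species of the
smaller hypotheses at every common position, and conservative removal is
the filter's purpose.

## Noise filter

Stage one removes isotope satellites: visiting peaks in descending
intensity order, each surviving peak discards strictly less intense peaks
lying 1 ± 0.2 or 2 ± 0.2 Da *above* it. Isotopes sit above their
monoisotopic peak, and processing by descending intensity means a removed
satellite can never shield anything — removal always acts relative to a
retained peak, and the most intense peak of a cluster is always kept.
Charge-dependent 1/z spacings are intentionally not handled here: this
stage models singly-charged product envelopes, and the high-z precursor
envelopes are the precursor filter's job.

Stage two keeps, for every peak, only those ranking in the top `h` by
intensity within the window centred on that peak: ±27 Da with `h1` for
the 1+ product search, ±14 Da with `h2` for the 2+ search. The window is
peak-centred rather than a fixed grid so retention cannot depend on bin
phase. `h` is the number of ion series expected per region — one forward
(c) and one reverse (z-dot) series gives the classical `h = 2`; adding y
ions, as ETD search practice recommends, gives `h = 3`, which is the
recommended setting here (`noise_filter_params(h1 = 3, h2 = 3)`).
Intensity ties are broken toward the lower-m/z peak for determinism.
Retained sets grow monotonically with `h`, which the tests assert as a
property.

## Charge determination

For each candidate charge `c` (default 3..7), the hypothesis implies a
neutral mass `M_c = c·(precursor_mz − H)`, a CP window per z = 1..c,

    (MH(z+) − tolp/z,  MH(z+) + M_c/(W·z) + tolp/z),    tolp = 2 Da,

and an NL window per z,

    MH(z+) − N2/z ± tol/z,    N2 = 18 Da, tol = 4 Da,

whose z = 1 instance spans −22..−14 Da and therefore catches both water
and ammonia losses. The feature vector is one CP intensity sum and one NL
intensity sum per candidate charge, each normalised by the spectrum's
total ion current — 10 features for the default range. A finer layout
(one feature per z) is conceivable, but the per-hypothesis sums encode
the discriminating pattern while keeping the pooled covariance
well-conditioned at a few hundred training spectra.

The classifier is linear discriminant analysis with charge states as
classes: per-class means, empirical priors, and a pooled within-class
covariance divided by (N − K) and ridged by `1e-6·trace(Σ)/p` so that
nearly collinear features (a charge and its multiple share CP bins on
part of the data) never make the fit singular. Posteriors are a
numerically stable softmax over the linear discriminants. The
implementation is self-contained and is cross-checked in the test suite
against an independent LDA implementation and against a hand-computed
Gaussian Bayes rule on small fixtures.

Assignment uses the best posterior p under three strategies: Top 1
(always one charge), Top 1/Top 2 (one charge if p ≥ t1, else two), and
1/2/All (one if p > t1, two if t2 ≤ p ≤ t1, the whole range otherwise),
with t1 = 0.99, t2 = 0.9. Boundary semantics follow the rule text
exactly: "greater than t1" is strict, the middle band is inclusive. The
candidate sets are nested across strategies for every spectrum, so the
misclassification rate (true charge outside the assigned set) is
monotone: Top 1 ≥ Top 1/Top 2 ≥ 1/2/All — a structural fact the tests
assert, not an empirical one. Posterior ties prefer the lower charge.

Why neutral losses matter: charge multiples share CP bins. A 2+ precursor
at 300 m/z (proton rounded to 1 Da) puts MH(1+) at 599; a 4+ precursor at
the same 300 m/z puts MH(2+) at the same 599. But the water loss below
the 599 bin sits at 581 under the 2+ reading (−18/1) and at 590 under the
4+ reading (−18/2). The NL features separate what the CP features cannot.

## The synthetic-spectrum generator

`generator_params()` encodes the study conditions the package is
validated under:

* charges 3+..7+ with probabilities 0.201, 0.514, 0.194, 0.077, 0.014 —
  the charge-state breakdown of a large ion-trap ETD phosphopeptide
  training set;
* neutral mass uniform between 300·n and 850·n Da (clipped to
  1000–6000 Da), reflecting that higher charges come from longer
  peptides and keeping precursor m/z in a common 300–850 band across
  charges so no trivial m/z shortcut exists;
* CP ladders with lognormal intensities a factor `cp_intensity_scale`
  (default 10) above fragments, carrying 1 to 4 isotope satellites
  spaced 1/z Da (more for heavier peptides); NL species carry the same
  envelope, since they are the same peptide ion minus a small neutral;
* each reduced species below the parent charge is observed with
  probability `cp_coverage = 0.8`, emulating variable electron-transfer
  efficiency — this incompleteness is precisely what makes charge
  multiples ambiguous on CP evidence alone and gives the NL feature its
  role;
* c/z-dot/y fragment ladders from a random residue-mass walk (rescaled
  to sum to the peptide mass, optionally carrying one +79.966 Da
  phospho group), each ion observed with probability 0.7 and lognormal
  intensity; fragment charge is 1+ only;
* 60 uniform noise peaks with exponential intensities (mean 15 on the
  scale where the median fragment is 100), and Gaussian m/z jitter of
  0.1 Da on every peak.

What the generator does *not* model — ETD fragmentation propensities,
hydrogen-transfer z/z+1 mixtures, chimeric spectra, charge-state-
dependent fragment charges, detector saturation — bounds what passing
tests show: they validate the window arithmetic, the classifier
machinery and the assignment logic under realistic peak geometry, not
performance on real instrument data, for which the external-label hook
(`fit_charge_lda` on user-supplied confident identifications) exists.

Two boundary subtleties surface in testing and are worth recording. The
removal window for z ≥ 3 reaches exactly `N2/z = 18/z` Da below the
species, i.e. to the nominal water-loss position itself; the monoisotopic
water-loss peak therefore sits on an open boundary and only its isotope
envelope lies strictly inside. The filter-efficiency property (≥ 95 % of
CP+NL intensity removed, ≤ 5 % of fragment intensity) consequently holds
as a mean over spectra, not per spectrum. Similarly, CP-peak containment
in the feature windows is guaranteed only when the m/z jitter is small
against `tolp/z` at the largest z (0.29 Da at z = 7); the containment
property is tested at jitter 0.02 Da where it is effectively sure, while
the default 0.1 Da leaves a few-sigma margin.

## Problem sizes and numerical choices

The validation suite trains on 428 spectra and evaluates on 2000 (the
classifier recovery check), compares the filters against brute-force
per-peak oracles on 1000 random spectra, checks the multiples property
on a 300/400 train/test split restricted to charges {3, 6}, and verifies
the generator's charge marginal on 10 000 draws within ±1.5 percentage
points per class. All randomness flows through explicit seeds; the
generator is byte-for-byte reproducible for a fixed seed. Peak lists are
deduplicated on construction (identical m/z merged by intensity
summation) so window membership is a set operation. Model persistence
uses a plain-text key-value format at full double precision
(`%.17g`), and a written model reproduces posteriors exactly.

## Known limitations

* Deisotoping assumes 1–2 Da spacings and will not collapse multiply
  charged product envelopes.
* The filters target low-resolution data; no profile-mode or
  high-resolution (sub-ppm) handling is attempted.
* The LDA features assume the CP/NL pattern is present; spectra whose
  precursor region was swept out upstream (e.g. already-filtered MGFs)
  will fall back to range search under the 1/2/All strategy.
* MGF is the only input format; mzML/mzXML readers would slot in at
  `read_mgf()`'s contract (one `etd_spectrum` per scan) but are not
  implemented.
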