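---
title: "Natural isotope correction with isofine: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural isotope correction with isofine: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofine)
```

## The problem

In a metabolic stable-isotope labelling experiment, cells are switched to a
medium containing a labelled precursor (for instance uniformly
\eqn{^{13}}C-labelled glucose) and the appearance of labelled species —
isotopologues — is followed over time by high-resolution MS. For histone
acetylation, \eqn{^{13}}C-glucose is converted to \eqn{^{13}}C-acetyl-CoA,
whose acetyl group carries two \eqn{^{13}}C atoms, so a peptide with two
acetylatable lysines appears as three labelling states: M+0 (no labelled
acetyl), M+2 (one) and M+4 (both).

The measured intensities are contaminated by *natural* heavy isotopes:
carbon is already 1.07% \eqn{^{13}}C, so a large peptide has a substantial
probability of carrying two natural heavy atoms and being detected at the
M+2 position even when it carries no labelled acetyl group at all. For a
C~46~ peptide roughly 45% of the molecules carry at least one natural heavy
isotope. Removing this contamination — isotopologue correction — is
essential before any dynamics are estimated.

## The correction model

### Fine structure

For a molecular formula, every combination of natural heavy isotopes is a
*fine-structure species* with an exact mass shift (e.g. \eqn{^{13}}C~2~ =
+2.00671 Da, \eqn{^{18}}O = +2.00425 Da, \eqn{^{15}}N~2~ = +1.99407 Da) and
a probability given per element by the multinomial distribution

$$P = \prod_e \binom{n_e}{k_1, k_2, \dots} a_0^{n_e - \sum_i k_i}
      \prod_i a_i^{k_i},$$

where \eqn{n_e} is the number of atoms of element \eqn{e}, \eqn{a_0} the
principal-isotope abundance and \eqn{a_i, k_i} the abundance and count of
its \eqn{i}-th heavy isotope. `fine_structure()` enumerates these species
per element up to the requested mass shift and convolves across elements,
keeping exact (never nominal) shifts; `species_probability()` evaluates a
single species in closed form.

### Resolution-dependent merging

Whether \eqn{^{13}}C~2~ and \eqn{^{18}}O are distinct peaks or one merged
peak depends on the resolving power \eqn{R = m/z / \mathrm{FWHM}}. On
Orbitrap analyzers \eqn{R} falls off as the inverse square root of m/z from
its value at a calibration point (here \eqn{R} = 60,000 at m/z 200 by
default). Two species are called unresolved when their neutral-mass
difference is below

$$\Delta m_{\min} = s \cdot \frac{m/z}{R(m/z)} \cdot z,$$

with separation factor \eqn{s = 1.66}, the classical criterion for baseline
separation of two equal-height Gaussian peaks. At \eqn{R} = 60,000 (m/z
200) a 2+ peptide ion at m/z 536.8 has an effective \eqn{R \approx} 36,600
and \eqn{\Delta m_{\min} \approx} 0.049 Da: every nominal-mass-2 species
(\eqn{^{13}}C~2~, \eqn{^{13}}C\eqn{^{15}}N, \eqn{^{18}}O, \eqn{^{15}}N~2~,
\eqn{^{13}}C\eqn{^{2}}H, …) merges into the M+2 peak, while \eqn{^{13}}C
vs \eqn{^{15}}N (6.3 mDa apart) would separate for a small 1+ ion at m/z
200. The window is evaluated once per run at the unlabelled compound's
monoisotopic m/z; across a label series it varies by well under 1% of its
value, so a single representative window keeps the matrix construction
simple and symmetric.

### The skewed matrix

Over the measured labelling states \eqn{j} (ascending exact label shift),
the correction matrix has entries

$$T_{ij} = \sum_{\sigma:\;|\Delta m_\sigma - (s_i - s_j)| < \Delta m_{\min}}
           P_\sigma(\text{residual formula of } j),$$

the probability that a molecule truly in state \eqn{j} is detected at the
peak of state \eqn{i}. The crucial point — the *skewed* aspect — is that
the fine structure is computed from the **residual** formula of column
\eqn{j}: the atoms carrying the tracer are removed, because an atom that is
already heavy cannot also be naturally heavy. A fully labelled species
therefore has zero probability of appearing at any heavier peak. The
*classical* alternative (`method = "classical"`) reuses the full formula's
fine structure for every column; it is provided for comparison and
reproduces the well-known bias towards heavy isotopologues.

Measured values are interpreted as the intensity of each labelling state's
lowest-mass (monoisotopic) peak. Correction solves \eqn{\mathrm{obs} = T c}
by forward substitution down the triangle,

$$c_j = \frac{\mathrm{obs}_j - \sum_{k<j} T_{jk} c_k}{T_{jj}},$$

so unmeasured intermediate states simply contribute and receive nothing —
the method needs only the isotopologues of interest, which is what makes it
usable for peptides where the full isotopologue list is enormous.
`missing_intermediates()` flags plausible unmeasured states (e.g. a
sizeable natural M+1 cluster between measured M+0 and M+2) as a warning,
never an error. The division by the diagonal rescales the monoisotopic-peak
intensity to whole-envelope species abundance and makes
`correct_isotopologues()` the exact inverse of `forward_observe()`.

Negative solutions, which arise from measurement noise when a peak is
smaller than the predicted natural contamination, are clipped to zero after
substitution and logged with their magnitude. A constrained least-squares
refit was considered and rejected: clipping is simple, reproducible, and on
the reference histone data yields the expected exactly-zero label signal at
the pre-label time point. Relative fractions are computed per sample after
clipping; per-replicate correction comes first, summary statistics
afterwards.

## Dynamics

Label incorporation is summarised by the initial slope of relative
abundance against time. `fit_slope()` is ordinary least squares
(`stats::lm`) through all points pooled across replicates, with the
analytic slope standard error; `fit_slopes()` applies it per isotopologue
and optionally per replicate (averaging replicate slopes, with the SEM
across replicates). Pooled OLS over all supplied points is the default
because the time window that defines "initial" is a user decision, not a
property of the data; pass a subset of time points to restrict it.
`slope_change()` reports the relative slope change
\eqn{(c - u)/|u|} between uncorrected and corrected estimates. On the
packaged histone example this is 0.54 using the unrounded two-point slopes
(1.26 to 1.94 %/h); quoting the same quantity from slopes first rounded to
one decimal (1.3 to 1.9) gives 0.46 — the package always reports the
unrounded ratio.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `resolution` | 60,000 | Resolving power (FWHM) at `mz_ref` |
| `mz_ref` | 200 Da | Calibration m/z of the resolving power |
| `scaling` | `"orbitrap"` | \eqn{R \propto 1/\sqrt{m/z}}; `"constant"` for FT-free analyzers |
| `separation` | 1.66 | FWHM multiple required to call two species resolved |
| `charge` | 1 | Ion charge; converts the m/z window to neutral mass |
| `prune` | 1e-10 | Absolute probability below which fine-structure species are dropped |

The isotope abundance table (packaged CSV: \eqn{^{13}}C 0.0107, \eqn{^{2}}H
0.000115, \eqn{^{15}}N 0.00364, \eqn{^{17}}O 0.00038, \eqn{^{18}}O 0.00205,
\eqn{^{33}}S 0.0075, \eqn{^{34}}S 0.0425, \eqn{^{36}}S 0.0001) is
user-overridable via `isotope_table(path)`; note that plausible alternative
\eqn{^{13}}C abundances (0.0107 vs 0.0111) move corrected values in the
third decimal. Tracer atoms are treated as isotopically pure — no
tracer-purity correction is applied — and protonation is the only adduct
modelled. Isotope-labelled modifications (e.g. a \eqn{^{13}}C~2~-acetyl
group) are expressed as the plain modification plus a tracer label
(`"2C13"`), keeping elemental composition and isotope labelling orthogonal.

## Numerical choices

Fine-structure enumeration prunes species below an absolute probability of
1e-10 (pruning partial cross-element products is safe because every
remaining factor is at most 1) and bounds the enumeration at the largest
required shift plus half a dalton, so a nominal cluster is never truncated
mid-cluster. Species are ordered by ascending exact shift with ties broken
by the heavy-count signature, making all outputs deterministic.
Probabilities are accumulated in log space (`lgamma`) to keep 83-atom
multinomials accurate. In the degenerate limit of a zero-heavy-abundance
table the matrix is exactly the identity; with `model = NULL` the merging
window is half a dalton (the nominal, low-resolution limit).

## The synthetic generator

`simulate_timecourse()` emulates a media-switch experiment: each of the
\eqn{n} labellable sites is replaced with first-order kinetics
\eqn{f(t) = 1 - e^{-kt}}, giving binomial state fractions
\eqn{\binom{n}{i} f^i (1-f)^{n-i}} (for two acetylation sites:
\eqn{(1-f)^2, 2f(1-f), f^2}, which reproduces the qualitative M+0/M+2/M+4
shapes of a histone labelling time course). True fractions are pushed
through the forward model and multiplicative Gaussian noise (truncated at
zero) is applied per peak; the default CV of 2% and 3 replicates reflect
routine targeted LC-MS precision. The generator does **not** simulate
chromatography, ionisation efficiency, detector saturation, tracer
impurity, or inter-replicate biological variation, so passing tests
demonstrate correctness of the correction arithmetic under the stated noise
model, not robustness to every real-data pathology.

The validation suite runs the recovery study at 100 simulated experiments
of 5 time points x 3 replicates, and checks convergence of corrected
fractions at 1000 replicates of a single time point — sizes at which
Monte-Carlo error is comfortably below the asserted tolerances.

## Known limitations

* Only protonated ions; no adducts, no charge-state deconvolution.
* No tracer-purity correction.
* The resolving window uses one representative m/z per run rather than each
  isotopologue's own m/z (a sub-1% effect on the window).
* Elements whose principal isotope is not the lightest (Se, and metals
  generally) are not in the packaged table; the enumeration assumes
  non-negative natural shifts.
* Correction assumes the measured peaks are correctly integrated upstream;
  no peak picking or spectral processing is attempted.

## Worked example

```{r example}
f <- peptide_formula("KQLATKAAR", c("acetyl", "acetyl"))
monoisotopic_mz(f, charge = 2)
cm <- correction_matrix(f, c("No label", "2C13", "4C13"),
                        resolution_model(60000, 200), charge = 2)
round(cm$T, 4)
path <- system.file("extdata", "h3_acetylation_timecourse.tsv",
                    package = "isofine")
res <- correct_isotopologues(read_measurements(path), cm)
round(res$fractions[c("No label", "2C13", "4C13")] * 100, 1)
fit_slopes(within(res$fractions, {
  `4C13` <- `4C13` * 100; `2C13` <- `2C13` * 100
  `No label` <- `No label` * 100
}))
```
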