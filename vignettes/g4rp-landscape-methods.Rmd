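---
title: "Profiling transient RNA G-quadruplex landscapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transient RNA G-quadruplex landscapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4rpseq)
```

## The experiment this package models

Guanine-rich RNA can fold into four-stranded G-quadruplexes (G4-RNAs).
In living cells these structures appear to be transient: they form and are
rapidly resolved, so endpoint structure-probing methods tend to see them
unfolded. G4RP-seq takes the complementary snapshot view: cells are
chemically crosslinked, G4-folded transcripts are captured with a
biotinylated G4-specific probe on streptavidin beads, and the captured
pool is sequenced next to a matched *input* library taken before capture.
Because G4-stabilizing ligands change gene expression, each treatment
condition (untreated, or treated with a G4 ligand such as BRACO-19 or
RHPS4) carries its own input control.

Two ratio statistics summarize the landscape:

* the **Enrichment Score**, per gene,
  $$\mathrm{ES}_i \;=\; \frac{\overline{\text{pulldown}}_i + \varepsilon}
  {\overline{\text{input}}_i + \varepsilon},$$
  computed on normalized mean counts within one condition. ES ranks
  transcripts by their relative propensity to be captured in a folded
  state; it is not an absolute measure of G4 formation.
* the **Enrichment Score Change**,
  $\Delta\mathrm{ES}_i = \mathrm{ES}_i^{\text{treated}} /
  \mathrm{ES}_i^{\text{untreated}}$, the ligand-induced fold change in
  enrichment.

Genes pass an expression filter (mean normalized read count strictly
greater than 50), a high-confidence abundance filter (mean at least 500),
and an induction filter ($\Delta\mathrm{ES} > 1.75$, i.e. 0.8 on the log2
scale). Downstream landscape analyses regress ES and
$\Delta\mathrm{ES}$ on sequence features (G/C content, gene length,
predicted-G4 density), compare the top and bottom 100 ranked transcripts,
and intersect the two ligands' induced target lists.

## pG4 motif scanning

A predicted G4 (pG4) is four runs of at least $g$ consecutive guanines
separated by three loops of bounded length. The package ships the three
standard stringencies — `G3L1-7` (mid; $g=3$, loops 1–7 nt), `G3L1-5`
(high), and `G2L1-10` (low) — plus custom presets.

Published motif counts are only reproducible if the overlap policy is
fixed, and quadparser-family tools differ in unstated ways. `scan_pg4()`
therefore commits to a single, documented policy: **leftmost, lazy
(shortest) matching with resumption after the match end**, exactly the
match a PCRE lazy pattern `G{3,}?(?:N{1,7}?G{3,}?){3}` returns. Matching
is case-insensitive, `T` and `U` are equivalent, `N` never counts as G but
may sit in loops, and loops may themselves contain G runs when the lazy
decomposition allows it. Hits from one scan never overlap. Reported
coordinates are 0-based half-open (BED convention); tract start positions
and loop lengths are retained per hit. Transcript-space scans cover the
given (sense) strand; scanning the reverse complement is a separate,
explicit call by the user, since for RNA the antisense sequence is a
different molecule.

The implementation is a backtracking matcher over the G-run structure of
the sequence with failure memoisation, which keeps adversarial inputs
(e.g. long poly-G tracts) linear in practice. The test suite holds it
equal to two independent oracles: the PCRE engine itself, iterated with
the same resumption rule, and an exhaustive interval-enumeration check on
short sequences.

## The synthetic study design

Real G4RP-seq data tie the analysis to a specific cell line, depth and
annotation, so the package validates itself on a generator that emulates
the experimental design with known ground truth. The generator is
first-class, deterministic given its seed, and its defaults *are* the
study conditions used by the acceptance checks.

**Sequences.** Each transcript draws a length (uniform 500–4000 nt), a
G/C target (0.35–0.65) and a planted `G3L1-7` motif count (Poisson, mean
2, capped at 10). Background sequence is sampled from a G-depleted base
distribution and any residual run of three or more G is broken by a
G-to-C substitution (preserving G/C exactly); exact
`GGG–loop–GGG–loop–GGG–loop–GGG` cassettes with 1–7 nt G-free loops are
then spliced between background segments of at least 8 nt, so no loop can
bridge cassettes and the scanner recovers the planted count exactly — a
property the tests assert for every generated transcript. Residual G/C
error is repaired by flipping non-cassette A/T↔C positions, leaving
realized G/C within rounding of target. Because pG4-dense transcripts are
G/C-rich in real transcriptomes (the landscape correlations with G/C and
with pG4 density are two views of the same structure), the G/C target is
coupled to planted density through a Gaussian copula with correlation 0.5
(`gc_pg4_correlation`; 0 disables the coupling).

**Latent folding and capture.** Baseline folding propensity follows a
logistic link on pG4 density per kb, $f_i = \mathrm{plogis}(-2 + 1.0
\cdot d_i)$, an assumption of the generator (folding rates are not
quantified by the assay itself). Capture is
$r_i = b + c\,f_i$ with background capture $b = 0.01$ and gain
$c = 0.6$: a transcript that never folds is still captured at a low
nonspecific rate. Under each ligand, 10% of transcripts ("responders")
have $f_i$ multiplied by 3 (clamped at 1). Responders are drawn
preferentially from low-pG4 transcripts (sampling weight
$((n-\mathrm{rank})/n)^4$), reflecting the interpretation that
pG4-dense transcripts are already folded at baseline and ligands mainly
stabilize G4s that were unfolded — which is what produces the negative
$\Delta\mathrm{ES}$–G/C relationship on this design.

**Counts.** The default design is 3 conditions × (1 input + 2 pulldown
replicates), one input per condition as in the assay protocol
(replicated inputs are a configuration option). Input counts are
negative binomial with mean $s_j \lambda_i$ and variance
$\mu + \alpha\mu^2$ ($\alpha = 0.05$, the conventional RNA-seq
mean–dispersion form); pulldown counts use mean $s_j \lambda_i r_i$.
Expression $\lambda_i$ is lognormal (meanlog 5, sdlog 1.2) and $s_j$
scales each library to an expected 3 million reads. An optional
`rrna_spike` mode marks the most abundant transcripts as residual rRNA
with capture below background, mimicking ribodepletion leftovers that
appear strongly depleted in pulldown libraries; it is off by default.
A single RNG stream per stage is used: sequences derive from `seed`,
counts from `seed + 1`, and the seed is recorded in the output.

**What the generator does not emulate.** Positional coverage within
transcripts, isoforms, alignment/counting artifacts, crosslinking
chemistry, probe topology preferences, and expression changes induced by
ligands beyond the capture model. Passing recovery tests on this design
therefore demonstrates that the *statistics* behave as intended, not that
any particular biological conclusion transfers to real data.

## Normalization and scoring choices

* **Median-of-ratios size factors.** Libraries are made comparable by the
  median-of-ratios estimator: per sample, the median over genes of the
  count divided by that gene's geometric mean across samples, excluding
  genes with any zero; factors are rescaled to geometric mean 1 so
  normalized counts stay on the raw-count scale. When no gene is positive
  everywhere the estimator is undefined and the function stops, pointing
  to `pseudo_reference = TRUE` (geometric means over positive entries
  only). One test pins the estimator to DESeq2's implementation of the
  same statistic.
* **Ratio statistics, not GLM inference.** The landscape quantities are
  ratio thresholds and ranks. The package deliberately computes ES and
  $\Delta\mathrm{ES}$ as ratio statistics on normalized means rather than
  fitting a negative-binomial GLM with Wald tests: the downstream rules
  (strictly greater than 50; at least 500; $\Delta\mathrm{ES} > 1.75$)
  operate on these ratios directly, and no p-values are attached to
  per-gene enrichment. This is the package's one deliberate
  methodological substitution relative to running a full
  differential-expression engine underneath.
* **Pseudocount** $\varepsilon = 0.5$ is added to both numerator and
  denominator means, keeping ES finite at zero input with bias well below
  0.1% at the abundance filter; it is a parameter everywhere.
* **Input handling.** Each condition's ES uses that condition's own
  input (`pool_inputs = FALSE` by default), matching the design in which
  every treatment carries an internal input control.
* **$\Delta\mathrm{ES}$ definition.** The default is the ratio of the two
  conditions' ES values, so treatment-induced expression changes are
  divided out through the inputs. The input-unadjusted variant
  (`des_mode = "pulldown_ratio"`, the ratio of pulldown means only) is
  offered because with a single input library per condition the input
  noise dominates the variance of the ES-ratio form: on the default
  design the null spread of $\log\Delta\mathrm{ES}$ is roughly
  $\sqrt{\alpha(\tfrac12+1+\tfrac12+1)} \approx 0.39$, of which two
  thirds is input noise. The pulldown-ratio variant roughly halves that
  spread and sharpens the $\Delta\mathrm{ES} > 1.75$ rule considerably,
  at the price of conflating expression changes with folding changes.
  See "Known limitations" below.
* **Boundaries.** The expression filter is strict (`> 50`); the abundance
  filter defaults to `>= 500` with a `strict_abundance` switch, because
  the two conventions (at-least versus strictly-greater) both appear in
  practice and differ only at the exact boundary. The induction filter is
  strict (`> 1.75`), so $\Delta\mathrm{ES}$ exactly 1.75 is not induced.
* **Ranking.** Descending ES (or $\Delta\mathrm{ES}$) among expressed
  genes, ties broken by gene id for stable output; filtered-out genes
  carry `NA` ranks and never enter top/bottom lists. Landscape
  regressions default to the abundant subset, where gene-level ratios are
  quantitatively trustworthy at moderate depth.

## Statistics conventions

Feature regressions are ordinary least squares with the Pearson
correlation, $R^2 = r^2$, and the two-sided t-test for non-zero slope
(identical to the correlation t-test in simple regression); the
implementation is held to a closed-form oracle at $10^{-10}$. Top-vs-
bottom comparisons use the two-tailed Student's t-test, equal-variance by
default with a Welch flag, recorded in the output. Landscape regressions
are reported unadjusted; the Bonferroni correction is available in the
ANOVA utility (`anova_table()`), which wraps `stats::aov()` for the
plate-assay analyses where multiple-comparison correction is
conventional.

## Assay computations

* **FRET melting.** Curves are min-max normalized to $[0,1]$ on their own
  extrema (plate-wide normalization would couple unrelated wells);
  $T_{1/2}$ is the temperature of the *first upward* crossing of 0.5,
  linearly interpolated between the bracketing readings of the stepwise
  ramp (25 °C start, 65 cycles of +1 °C to 90 °C, `melt_ramp()`). On a
  logistic melt sampled at this 1 °C resolution the midpoint is recovered
  within 0.25 °C. $\Delta T_{1/2}$ pairs replicate curves with and
  without ligand, subtracts per pair, then averages — subtraction before
  averaging keeps paired plate effects out of the spread.
* **Capture efficiency** is the mean signal of probe-containing wells
  over the mean of no-probe control wells (controls normalized to 1); it
  is invariant under common rescaling of all wells.
* **G4RP-qPCR** uses the delta-delta-Ct method: technical triplicates are
  averaged on the Ct scale (the conventional order), each condition's
  pulldown Ct is normalized to its input control, and the fold change is
  `efficiency^(dCt_untreated - dCt_treated)` with efficiency 2 (perfect
  doubling) by default.
* **Dose–response LDx.** Confluency curves are normalized with the
  maximum and minimum achievable values; the LDx dose solves
  normalized response $= 1 - x/100$ by linear interpolation on
  log10(dose), the natural scale for serial dilutions. Extrapolation
  beyond the measured range is refused rather than guessed.

## Numerical and degenerate-input behavior

Illegal sequence characters error with their position; empty sequences
scan to empty hit lists but error in `gc_content()` (a 0/0). Zero-length
transcripts are rejected by `pg4_density()`. Flat emission or response
curves cannot be normalized and say so. Curves that never cross 0.5
upward error; multiple crossings warn and use the first. The
infeasibility check in the generator (planted motifs that cannot fit the
requested length) names the offending transcript. All file writers emit
floating point at 6 significant digits; identifiers and integers
round-trip exactly, and the pipeline manifest records version, seed,
thresholds and input checksums so reruns are verifiable.

## Problem sizes used in validation

The shipped checks run the generator at its default 2,000 transcripts for
recovery properties, 1,000 transcripts for the no-enrichment null
calibration (median ES within $[0.9, 1.1]$), 1,000 random sequences plus
adversarial poly-G cases for scanner/oracle equivalence, and 25 logistic
melt curves for $T_{1/2}$ recovery — sizes at which the Monte-Carlo error
of each property is comfortably below its test margin.

## Known limitations

* With one input library per condition, the ES-ratio
  $\Delta\mathrm{ES}$ is noisy: at dispersion 0.05 the null spread of
  $\log \Delta\mathrm{ES}$ (~0.39) is commensurate with the
  $\log 1.75 \approx 0.56$ threshold, so on the default design the
  $\Delta\mathrm{ES} > 1.75$ rule attains high sensitivity (~0.85–0.9)
  but a false-discovery proportion around 0.4 among abundant genes.
  This is a property of the design, not of the implementation: it can be
  mitigated by replicated inputs (`n_input_reps`), lower dispersion,
  or the `pulldown_ratio` variant (false-discovery proportion ~0.06 on
  the same design), each with its own trade-off.
* ES ranks relative folding propensity; transcripts differing in probe
  accessibility or topology preference are not distinguishable.
* In the generator, folding couples to motif *density* (count/length),
  which induces a negative ES–length correlation absent from real data
  where length and enrichment are essentially uncorrelated; generator
  regressions on length should be read with that in mind.
* The scanner predicts intramolecular pG4 motifs only; intermolecular
  G4s and thermodynamic stability scoring are out of scope.
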