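---
title: "Occupancy analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidychip)
```

`tidychip` analyses where a chromatin-associated protein sits in a compact
genome, how its occupancy relates to RNA polymerase II loading and to mRNA
output, and whether the genes it occupies are the ones whose expression
changes when it is removed. This vignette is the package's own account of
the models behind each stage, the parameters that matter, and the places
where the design was genuinely open.

## Coordinate contract

Every function uses 0-based, half-open `[start, end)` coordinates on the
forward genomic axis. GFF3 (1-based, inclusive) is converted only at the
I/O boundary, and the conversion is its own inverse. The TSS of a gene is
`start` on the plus strand and `end - 1` on the minus strand; the TES is
the opposite end. Tiling-array probes are located by the lowest-coordinate
base of their 25-bp footprint regardless of probe strand; all strand-aware
arithmetic (offsets in transcription direction) lives in the metagene
functions, so the file formats stay unambiguous.

## Tiling-array signals

Affymetrix-style arrays pair each 25-mer perfect-match (PM) probe with a
mismatch (MM) probe whose central base is flipped; the MM intensity
estimates cross-hybridization background. Per probe pair we form an ideal
mismatch `IM = min(MM, PM/2)` — the background estimate, capped at half
the PM so the contrast `PM - IM` never vanishes and the summary is
monotone in PM — and a probe value `log2(PM - IM)` floored at `2^-20`.
The gene signal is `2^T` with `T` the one-step Tukey biweight location of
the probe values (tuning constant `c = 5`, unscaled MAD plus a small
epsilon as scale), which downweights outlying probes the way the classic
MAS5 signal does. The full Affymetrix specific-background chain is
deliberately not reproduced: the capped-minimum rule preserves the
behaviour that matters downstream (positive contrasts, monotonicity,
robustness) in one testable expression.

Control arrays come in pairs. Each pair is scaled to a common median (the
arithmetic mean of the two medians), averaged per gene, and the IP signal
of each gene is divided by its control signal. Genes whose control signal
is non-positive are excluded rather than patched, and the exclusion count
is reported.

For probe-resolution work, each array's PM/MM ratio is normalized by the
mean ratio of the control arrays, and replicate IP arrays are averaged per
probe.

## Enriched-gene calling

The caller is a simplified sliding-window scheme that preserves the
decision rules applied downstream of a model-based tiling-array analysis
(probe-level significance cutoff, region merging, the "50% of the gene"
rule, and region-mean enrichment scores) without the probe-sequence
affinity model, which would require sequences the synthetic arrays do not
carry:

1. probe score = `log(normalized value)`, standardized genome-wide by a
   robust z (median and MAD with the 1.4826 consistency constant; the SD
   is used if the MAD is zero; if both are zero the input is degenerate
   and the caller stops);
2. window statistic = 10%-trimmed mean of scores within ±150 bp
   (`window_bp = 300`), scaled by the square root of the number of probes
   kept after trimming, with a one-sided normal P-value;
3. probes with `P < p_cutoff` (default `1e-3`; `1e-4` as the stringent
   alternative) merge into regions when separated by at most
   `maxgap_bp = 300`, each region extended by the probe footprint;
4. a gene is enriched iff merged regions cover at least half of its
   length **in base pairs** (the fraction could equally be defined over
   probe counts; base pairs were chosen because they are invariant to
   probe spacing, and the choice is exposed, not hidden);
5. the enrichment score is the mean normalized value of probes inside the
   region span(s) overlapping the gene.

Robust (median/MAD) rather than moment standardization matters because
enriched probes would inflate a plain SD and cost sensitivity exactly
where the signal is. Because lowering `p_cutoff` only removes significant
probes, calls at `1e-4` are always a subset of calls at `1e-3`.

The caller assumes enrichment is a minority phenomenon: if most of the
genome is enriched, the genome-wide median itself shifts into the
enriched mass and sensitivity degrades by construction. Benchmarks
therefore plant binding in 30% of genes (in the real assay the strongly
bound set was well under 10% of the annotation).

## ChIP-seq coverage

Coverage is the number of read intervals containing each base (so total
coverage equals total read-bases, a conservation law the tests assert).
Depth normalization divides by the total aligned reads; input
normalization is the base-wise IP/input ratio. Where the input is zero the
ratio is undefined: the default policy masks those bases (`NA`) rather
than inventing signal with a pseudocount (available as
`policy = "pseudocount"`), and masked bases are excluded — never
zero-filled — from every downstream mean. Replicate averaging propagates
missingness (a base is missing in the mean iff missing in any input). No
smoothing is applied at any point.

## Metagene profiles

Two axes are supported. The **percent-position** profile (arrays) maps
each in-range probe to `100 * u / (L - 25)` where `u` is the offset of
the probe's 5'-most base from the TSS in transcription direction; 0% is
the TSS and 100% is 24 bp upstream of the TES, the last position where the
footprint fits. Values are pooled over all genes into 1000 half-open 0.1%
bins, with 100% assigned to the last bin (a deterministic tie-break).

The **flank/body** profile (coverage) averages 1 kb upstream of the TSS
per base pair, the gene body scaled into 1000 equal fractional windows
(window value = coverage mean weighted by base-overlap fraction; each
contributing gene has equal weight in a bin), and 1 kb downstream of the
TES per base pair. `body_bins = 1000` matches the array profile's
resolution. Flanks clipped at chromosome edges contribute nothing, genes
shorter than `body_bins/10` bp are excluded, and genes overlapping other
genes still contribute (exclusion would silently change the gene universe
between datasets). Both builders are verified against naive per-probe and
per-base loops.

## Association statistics

Expression is summarized as the mean FPKM over replicates, transformed as
`log(mean FPKM + 1)` (natural log). The Spearman correlation takes an
optional top-expressed filter: with fraction `f`, genes below the `1 - f`
quantile of the **expression** variable are dropped before ranking — the
filter is deliberately one-sided because it models the practice of
trusting only genes the RNA-seq assay quantifies reliably. Ties take
average ranks and the two-sided P uses the t approximation.

Ratio classification labels genes by `d = log2(upf1) - log2(polII)`
against thresholds (default ±1, i.e. two-fold either way, exposed as
configuration): `high_ratio`, `low_ratio`, or `similar`; genes with both
signals below `min_signal` are set aside as `unclassified`.

Gene-set overlap is tested twice. The permutation route draws `|A|` genes
from universe A and `|B|` from universe B independently (the two
universes model different platforms — a 7054-gene annotation versus a
5280-gene expression array — without assuming how they nest), records the
intersection size, and reports `(r + 1)/(reps + 1)` where `r` counts draws
at least as extreme as the observed overlap; the add-one estimator never
reports zero, which a finite Monte-Carlo experiment cannot support. The
analytic route is the one-sided hypergeometric upper tail with
`N = |universe A|` by default; with identical universes the permutation
P converges to it, a cross-check the tests run at 10^4 replicates.

## qPCR quantities

Relative expression is `2^-(Ct_target - Ct_reference)` with the reference
target supplied per row, never hard-coded. Percent-of-input adjusts the
input Ct for its dilution (`Ct_input - log2(1/fraction)`; the fraction is
a required input with no default, because it is a property of the
experiment) and is invariant to re-expressing the same dilution. Signal
ratios propagate SEM to first order (`ratio * sqrt(cv_n^2 + cv_d^2)`),
accurate to within 10% of a parametric bootstrap at the coefficient of
variation of typical triplicate qPCR. Decay profiles divide by the
time-zero value and fit `ln(relative) ~ time` by least squares;
`t_half = ln 2 / |slope|`, infinite (and flagged) for non-decaying
series. The two-sample t-test is the pooled-variance Student form, as is
conventional for triplicate qPCR comparisons, with Welch available by
flag; zero-variance groups return 0.5 (equal means) or a flagged 0/1.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes and
records everything it plants:

- **Annotation**: non-overlapping genes, log-normal lengths (median
  1500 bp, clamped to 300–8000 bp — fission-yeast-like gene sizes),
  intergenic gaps of at least 200 bp with an exponential tail,
  Bernoulli(0.5) strands.
- **Occupancy**: a latent transcription rate `tau ~ logNormal(0, 1)` per
  gene; Pol II occupancy equals `tau`. A bound subset (default 50% of
  genes) is drawn with probability proportional to `tau`: chromatin
  association of an RNA-binding factor tracks active transcription, so
  binding is planted preferentially at transcribed genes — a uniform draw
  would plant "bound but silent" genes whose occupancy sits at background
  and whose label no assay could recover. Bound genes get
  `upf1 = tau * exp(sigma * eps)`; unbound genes sit strictly below a
  recorded background level (0.05). `sigma` is solved by bisection so the
  realized all-gene Spearman correlation matches `rho_target` (default
  0.56); because unbound genes pin a rank block, the attainable
  correlation is capped by the bound fraction (about 0.68 at 50% bound),
  which is why the default bound fraction is 0.5 and not lower. The
  solved `sigma` and realized correlation are recorded as attributes.
  Noisy measured signal columns (log-normal, sd 0.1) model assay-level
  error on top of the latent occupancies.
- **Probe arrays**: probes every 20 bp genome-wide;
  `PM = B * exp(eta) * (1 + g * occ)`, `MM = B * kappa * exp(eta')` with
  background `B = 100`, cross-hybridization `kappa = 0.5`, gain `g = 5`
  and log-normal noise sd 0.3. The multiplicative link keeps log-scale
  noise homoscedastic and makes PM/MM ratios directly interpretable.
  Occupancy is smoothed by a 500-bp moving average across gene
  boundaries, emulating the spread of ~500 bp chromatin fragments beyond
  a probe's footprint. The paired control array zeroes the occupancy
  term.
- **Reads**: fragment midpoints proportional to occupancy plus a uniform
  floor (IP) or uniform (input); fragment lengths Normal(500, 100)
  truncated at the read length; one 50-bp read from the fragment 5' end
  on a random strand.
- **Expression / DE labels**: replicate FPKM = true FPKM × log-normal
  noise; exactly `n_de` genes labelled differentially expressed with an
  exactly planted overlap with the bound set.

One root seed derives fixed-offset child seeds per component, recorded in
the pipeline manifest, so a single component can be re-run without
disturbing the others and identical inputs give byte-identical outputs.

No assay in the source system comes with stated noise magnitudes; the
defaults above are configuration chosen for testability, not claims about
the instruments. The generator also idealizes in ways real data do not:
no probe-sequence affinity differences, no mappability or repeat
artifacts (real tiling arrays show hybridization artifacts at
retrotransposon families), no PCR duplicates, no batch effects, and
independence between the array and sequencing error processes. Passing
recovery tests on these inputs therefore demonstrates that the
*computations* are correct and well-calibrated, not that the pipeline
would be robust to every pathology of real arrays.

## Problem sizes and numerical choices

The bundled checks run at sizes chosen to make sampling error small
relative to the tolerances tested: 500 genes (about 54,000 probes) for
caller recovery, 5000 genes for correlation and classification recovery,
10^4 replicates for the permutation/hypergeometric cross-check, and
15–20-gene instances for brute-force comparisons. Equality between the
vectorized and naive metagene implementations is asserted at 10^-12
relative tolerance (different summation orders), the hypergeometric tail
against choose-product enumeration likewise at 10^-12. Degenerate inputs
fail loudly by policy: zero-MAD-and-zero-SD probe scores, empty probe
sets, non-positive control signals, infeasible planted overlaps and
unfittable gene placements are all errors, not warnings.

## Known limitations

- The enriched-gene caller is a stand-in for model-based tiling-array
  analysis; its probe P-values are calibrated against a normal reference
  under the synthetic noise model and should be treated as rankings, not
  literal error rates, on real arrays.
- Fragment-size extension of reads, duplicate marking and mappability
  correction are out of scope for the coverage module.
- The hypergeometric universe for the headline overlap P defaults to the
  annotation universe; with two genuinely different platform universes no
  single `N` is canonical, and the permutation route is the more faithful
  model of that design.
- Array metagenes cover 0–100% of the gene body only; flanked array
  profiles were never part of the published analysis and are not
  implemented.
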