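---
title: "Methods: measuring ex situ representation of wild allelic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring ex situ representation of wild allelic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exsitu)
```

## The measures and their assumptions

The package treats a dataset as an individuals × loci table of diploid
co-dominant calls (`genotype_matrix`), split by a `sample_partition` into
garden (ex situ) and wild (in situ) individuals, with optional wild
population labels and an exclusion list applied before any analysis.
Two conventions are enforced at construction and matter everywhere
downstream:

* **All-or-nothing cells.** A genotype is either fully typed (two allele
  codes) or missing; half-calls are collapsed to missing. Presence
  filters, frequency denominators and capture counts all assume per-cell
  presence is binary.
* **Labels are recomputed, never stored.** The allele set of a locus is
  always re-derived from the current calls, so subsetting or filtering
  can never leave phantom alleles behind.

### Representation by frequency category

Wild allele frequencies use wild, non-excluded samples only, with
*locus-specific* denominators (copies actually typed at that locus).
Under no missing-data filter (R0) per-locus typing varies enormously,
and a global-N denominator would systematically misclassify alleles at
poorly typed loci — this is why the denominators are per locus.

An allele is *captured* if it appears in at least one non-missing garden
call. Alleles are binned by wild frequency `p` into the field's
overlapping classes: very common (`p > 0.10`), common (`p > 0.05`), low
frequency (`0.01 ≤ p ≤ 0.10`), rare (`p < 0.01`), total (`p > 0`). The
overlap is deliberate (an allele at 8% is both common and low-frequency);
published category tables are only reproducible with it. The verbal
definitions leave the boundary points 1% and 10% ambiguous; this package
assigns **both boundary values to the low-frequency class** (closed
interval), a convention that is configurable via
`frequency_categories()` and echoed in every report header so results
are auditable. Garden-only alleles (absent from the wild sample) are
counted and reported but never enter a percentage; empty categories
report an undefined percentage rather than 0 or 100.

### Minimum sample size by resampling

For each replicate, one uniform permutation of the `N` wild individuals
is drawn and prefixes of length `n = 2 … N` serve as the subsamples
(*nested* design). Capture at `n` is the percentage of the total wild
allele set seen in the subsample. Nesting makes capture non-decreasing
within a replicate, so the per-replicate "smallest `n` reaching
`100·threshold` percent" is well defined and always reached at `N`.
An independent-draw-per-size mode (`nested = FALSE`) exists for
sensitivity analysis; the mode used is recorded in output metadata.
The headline estimate is the mean and the `n−1`-denominator standard
deviation of per-replicate minima over `n_replicates` (default 5000,
the field's convention; tests use 100–5000 depending on problem size,
with tolerances widened accordingly). With a single replicate the SD is
reported as `NA`, not zero. The threshold applies to the *total*
category only. A subtlety: because sizes start at 2, the per-replicate
minimum is floored at 2 even when a single individual would suffice;
the order-statistic test in the suite accounts for this floor.

Two numerical details: the threshold comparison subtracts `1e-9` from
`100·threshold` to guard against decimal percentages that are not
exactly representable in binary floating point, and the whole engine is
driven by one `set.seed(seed)` call per invocation (the caller's RNG
state is saved and restored), which makes runs bit-reproducible; no
parallel execution is used, so no per-replicate stream derivation is
needed.

The Monte-Carlo engine has an exact oracle, `analytic_expected_capture`:
under without-replacement sampling of `n` of `N` individuals, an allele
with `c` carriers is missed with hypergeometric probability
`C(N−c, n)/C(N, n)`; the expected capture is the mean over alleles of
one minus that. The test suite verifies (i) that this closed form equals
the brute-force all-subsets average exactly on small fixtures and
(ii) that the Monte-Carlo mean agrees with it within three standard
errors.

### Population-genetic summaries

* **He** is uncorrected gene diversity `1 − Σ p²` averaged over loci
  with data; the `2n/(2n−1)` small-sample correction is opt-in
  (`unbiased = TRUE`) because published values mix both conventions, and
  the variant in use is therefore a flag rather than a silent default.
* **Allelic richness** is hypergeometric rarefaction to `g` gene copies;
  `g` defaults to the smallest per-locus typed copy count across the
  compared groups (rarefy-to-smallest). Loci too sparse for `g` are
  skipped with a message.
* **FST** is the Nei Gst-style pairwise estimator on wild populations:
  per locus, `Hs` is the mean of the two within-population gene
  diversities and `Ht` the gene diversity of the unweighted mean of the
  two frequency vectors; the ratio `(H̄t − H̄s)/H̄t` is taken on locus
  *averages*, not averaged over per-locus ratios (short, noisy loci would
  otherwise dominate). Slightly negative estimates are reported as
  computed. A `corrected` flag applies the `2n/(2n−1)` diversity
  correction. The estimator name and variant are printed with every
  result because absolute FST values are estimator-dependent.

A caveat established during development and recorded in the test suite:
for two populations simulated under the Balding–Nichols model with
parameter `F`, the *expectation* of this pairwise estimator is
`F/(2−F)` — generally `F(1−1/k)/(1−F/k)` for `k` demes — because the
pooled `Ht` is computed from the two sampled demes rather than the
(unobservable) ancestral pool. The property test therefore targets
`F/(2−F)`; an estimator that returned `F` itself here would be a
different estimator (e.g. Hudson-style, using between-population
heterozygosity), not the one this package implements.

## What the generator emulates, and what it does not

`sim_config()` + `simulate_dataset()` produce a stated world:

* **Structure**: `n_populations` demes whose per-locus frequencies are
  Dirichlet(`p·(1−F)/F`) around ancestral frequencies — the
  Balding–Nichols model, chosen over coalescent/forward simulation
  because it gives direct, testable control of the only structure
  parameter the analyses consume. Genotypes are Hardy–Weinberg draws
  within demes. Defaults: 4 populations × 50 diploids, `F = 0.10` —
  a mid-range differentiation typical of regionally structured trees.
* **Marker regimes**: `multiallelic` (default 20 loci × 8 alleles,
  symmetric Dirichlet α = 0.5 so spectra are skewed and rare alleles
  occur) emulates microsatellite panels; `biallelic` (default 3000 loci,
  minor allele frequency ~ Beta(0.3, 3), placing appreciable mass below
  1%) emulates RADseq SNP panels. `min_base_freq` optionally rejects
  draws below a floor — used to build the "every allele ≥ 5%" benchmark
  population (there with α = 1, the uninformative symmetric choice,
  where rejection costs ~½ of draws).
* **Gardens**: accessions are clonal copies of wild founders sampled
  without replacement (`random`, `stratified`, or `skewed` by
  population weights). No meiosis is simulated: representation depends
  only on which alleles enter the collection, and most accessions in
  real assessments are wild-collected individuals. A one-generation
  open-pollination mode would be the natural extension point.
* **Missingness**: per-sample rates from a Beta with mean `rate` and
  concentration `missing_heterogeneity` (default 20), cells dropped
  independently — variable "sequencing depth" across samples.
* **Artifacts**, two mechanisms:
  * `inject_error_alleles` replaces single allele copies with codes
    unique to the event — sample-private singletons that, in any
    reasonably sized sample, land in the rare class (frequency
    `1/(2·N_typed) < 1%`).
  * `inject_artifact_loci` appends *spurious loci* typed only in the
    sample that generated them (homozygous private allele, missing
    everywhere else). This is the de novo assembly failure mode that a
    presence filter actually removes: such loci have presence `1/N`, so
    R80 prunes them while R0 keeps them. Copy-replacement errors inside
    real loci are *not* preferentially removed by a locus-presence
    filter — they occur in kept and dropped loci alike — which is why
    the filter-contrast experiments in the acceptance suite use the
    artifact-locus mechanism. Artifact rates are free parameters with
    no empirical anchor; defaults are 0 and the contrast experiments
    set them to values (0.5–1% per sample-locus) chosen once to make
    the artifact load a visible minority of loci, as in real de novo
    panels where unfiltered locus counts exceed filtered ones many-fold.

A green test on this world establishes that the *pipeline* behaves as
claimed under its stated assumptions — independent loci, equal-sized
demes, clonal gardens, missingness independent of genotype. It does not
establish anything about linkage, inbreeding, null alleles,
genotyping-error structure beyond the two mechanisms above, or
collection histories with maternal-line structure; none of those are
modelled.

## Filters

`apply_missing_filter(gm, r)` drops loci typed in strictly fewer than
`r·N` individuals (so `r = 0` is the identity and `r = 0.8` is the
conventional R80); the keep rule is `≥`, matching "present in less than
80% … are dropped" semantics. The filter is idempotent, and the R0
allele universe is a superset of the R80 universe — both are asserted
as properties. `first_variant_per_group` keeps the first locus per
source group (e.g. RAD locus), the standard guard against intra-locus
linkage. Deliberately absent, and documented as such: Hardy–Weinberg
filtering and minor-allele-frequency filtering — a MAF filter deletes
exactly the rare-allele class whose representation is being measured,
inflating it toward 100%.

## Degenerate inputs and tie-breaks

* Loci with zero typed wild individuals have no defined frequency; they
  are excluded from the wild allele universe and listed in an attribute.
* Population pairs sharing no typed locus yield an undefined (NA) FST
  entry; the mean is taken over defined pairs.
* Unknown IDs in exclusion lists warn and are ignored (collection
  records are messy; hard failure would block batch runs).
* Sample-ID matching across marker datasets trims whitespace and folds
  case; anything fancier must be supplied by the caller as an explicit
  mapping.
* Genepop digit width (2 vs 3) is auto-detected from the first genotype
  token; mixed widths are an error naming the offending locus, never a
  guess.

## Known limitations

* The resampling engine holds the full first-capture matrix
  (alleles × replicates) in memory; at 5000 replicates this is fine for
  up to ~10⁴ alleles but would need chunking for unfiltered de novo
  panels with 10⁵⁺ alleles.
* Nei pairwise FST carries the finite-deme bias discussed above; users
  wanting an estimator whose expectation is the simulation parameter
  should not read the pairwise values as estimates of `F`.
* VCF input is GT-only and diploid-only by design; dosage fields,
  ploidy mixtures and imputation are out of scope, as are read-level QC
  and SNP calling upstream of the genotype matrix.
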