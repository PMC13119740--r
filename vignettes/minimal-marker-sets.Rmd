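---
title: "Minimal marker sets for genebank fingerprinting: models and methods"
author: "minmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal marker sets for genebank fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minmark)
```

## The problem

Genebanks conserve millions of seed accessions that must be regenerated
periodically, and every regeneration cycle risks mislabelling, seed mix-ups
and admixture. Full-genome or saturated-array genotyping can detect such
errors but is too expensive and too analysis-heavy for routine operations. A
*minimal marker set* (MMS) is the opposite design point: the fewest biallelic
SNP assays (typically run as KASP reactions) whose joint genotype calls still
give every accession in a collection a unique multilocus fingerprint. With a
couple of dozen markers, a technician can verify that a regenerated seed lot
matches its originator stock, recover the identity of a mislabelled sample by
searching the fingerprint registry, and flag likely duplicate accessions.

`minmark` implements that workflow end to end: genotype I/O, the quality
filters applied before selection, the greedy selection algorithm itself,
fingerprinting and registry matching, per-marker informativeness statistics,
and a Monte-Carlo assessment of how gracefully a panel degrades when assays
fail.

## Data model

A biallelic SNP call has four canonical states — homozygous reference,
heterozygous, homozygous alternate, missing — stored internally as the
alternate-allele dosage (0/1/2, `NA`). Input dialects (`A/B/H` letters,
`AA/AB/BB` pairs, nucleotide pairs like `G/T`, or dosage digits) are mapped
onto this coding at read time; for nucleotide dialects the reference allele
is the alphabetically first allele observed unless marker metadata says
otherwise. Orientation (accessions in rows vs markers in rows) must be
declared: silent auto-transposition is a worse failure mode than an explicit
error. A no-call carries no evidence about the genotype, so a missing call
never *separates* two accessions anywhere in the package.

## Quality filters

Markers are kept when call rate is **strictly above** 0.95 and minor allele
frequency **strictly above** 0.05; accessions when call rate is strictly
above 0.995 and the heterozygous fraction strictly below 0.001. The strict
inequalities are deliberate (the conventional screens are phrased as ">95%",
">5%", ">99.5%", "<0.1%"), and the boundary behaviour is pinned by tests.
Two consequences worth knowing:

* the heterozygosity denominator is the number of *non-missing* calls — a
  missing call is not evidence of homozygosity;
* each removed item gets exactly one primary reason code, the first failing
  test in the order call rate → MAF (markers) or call rate → heterozygosity
  (accessions). Monomorphic markers are removed by a separate pass
  (`drop_monomorphic()`), where "monomorphic" means a single homozygous state
  among the non-missing calls; an all-missing marker is classed monomorphic
  too, keeping the reason enumeration closed.

The minor allele frequency is computed from the minor-allele *count*
(`min(n_ref, n_alt) / 2n`) rather than `min(p, 1 - p)`, so that a marker
with exactly 10 minor alleles in 200 is compared against 0.05 without
floating-point perturbation.

## Marker informativeness

For reference-allele frequency $p$ (allele-based: a heterozygote contributes
one copy of each allele) and $q = 1 - p$:

$$\mathrm{He} = 1 - (p^2 + q^2), \qquad
  \mathrm{PIC} = 1 - (p^2 + q^2) - 2p^2q^2,$$

with observed heterozygosity the fraction of heterozygous calls and
$\mathrm{MAF} = \min(p, q)$. For a biallelic marker PIC is bounded by He,
symmetric in $p \leftrightarrow q$, strictly increasing in MAF, and maximal
at $p = 0.5$ where $\mathrm{He} = 0.5$ and $\mathrm{PIC} = 0.375$. Linkage
disequilibrium between markers is the squared Pearson correlation $r^2$ of
their dosage codings over pairwise-complete accessions (listwise deletion
would discard too much of a sparse panel); pairs undefined because a marker
is constant within the shared complete cases are reported as `NA`, not
silently zeroed.

## The greedy selection algorithm

Discrimination is defined pairwise. Under the default `strict` policy only
opposite homozygotes distinguish two accessions — the conservative choice for
KASP data, whose heterozygote cluster is the least reliable, and a natural
one for collections filtered to highly homozygous inbred lines. The
`genotypic` policy, in which any two distinct non-missing states distinguish,
is available for workflows that trust the three-cluster readout. Under both,
a missing call never distinguishes.

Selection proceeds as follows:

1. **Forced markers** (already-validated assays) are seeded into the panel in
   the given order, consuming the pairs they resolve.
2. If no pair has been resolved yet, the **first free pick** is the
   highest-MAF marker among those that resolve at least one pair (ties broken
   by input order). With fully homozygous data and all pairs open this
   coincides with the most-resolving marker; the restriction to markers with
   positive yield keeps the termination rule uniform.
3. Every **subsequent pick** maximises *incremental discrimination*: the
   number of still-unresolved pairs the candidate newly distinguishes.
4. Selection stops when no pair remains, when no candidate adds a pair, or
   when `max_markers` is reached.

Markers in complete LD with a selected marker have zero incremental value
and are never picked — redundancy control falls out of the objective, with
no explicit LD filter. Ties anywhere are broken by marker input order, the
only reproducible data-independent rule, making selection fully
deterministic.

Internally the unresolved set is kept as an explicit pair index vector rather
than as fingerprint pools. The reason is a subtlety of the `strict` policy:
"cannot distinguish" is not transitive (a heterozygous call bridges the two
homozygote classes), so pool refinement would miscount resolved pairs. The
pair bookkeeping identity
$\sum_s \text{newly\_resolved}_s + \text{unresolved} = n(n-1)/2$
holds exactly and is asserted in tests. The cost is $O(\text{markers} \times
\text{open pairs})$ per step with vectorised scans, comfortable for
populations of several hundred accessions; the published workflows selected
panels from training populations of 345–500 accessions, the scale the
implementation is tuned for.

Greedy set cover is not guaranteed minimal. On randomly generated instances
small enough for exhaustive search (≤ 15 markers, ≤ 12 accessions) the test
suite verifies that the greedy panel always resolves everything the full
marker set can and is rarely more than one marker above the true optimum; a
log₂ lower bound (a panel of $k$ binary markers yields at most $2^k$
distinct homozygous fingerprints) is also asserted.

`augment_panel()` re-runs selection with an existing panel forced, which is
how a panel trained on one collection is extended after disappointing
resolution on another — the route by which a 12-marker starting panel grows
into a ~25-marker production panel.

## Fingerprinting and matching

Two accessions share a fingerprint group iff *no* panel marker resolves
them. Because missing calls never separate, the relation can be
non-transitive in pathological missing patterns; groups are its connected
components, and components that would split without their missing-heavy
members (≥ 50% missing over the panel) are flagged for curator attention.
When the call matrix is unambiguous (no missing calls; no heterozygotes
under `strict`) grouping reduces to exact row equality and is computed by
hashing, which is what makes the robustness simulation fast.

The **discrimination rate** is the percentage of accessions in singleton
groups, reported to two decimals with half-up rounding (the convention of
the published summary tables: 90 unique of 96 prints as 93.75, 616 of 668
as 92.22). Per-group summaries recompute the rate *within* each group, and
any merged row is recomputed over the union, never averaged.

`match_fingerprint()` performs regeneration QC: a query call vector is
compared to its registered originator row, counting only positions where
both calls are non-missing. The default tolerance is 0 mismatches — any
discrepancy is a failure triggering a re-test in genebank practice — and a
verdict based on fewer than `min_informative` comparisons is `AMBIGUOUS`
rather than a false reassurance. The best-matching registry entries are
reported alongside, supporting identity recovery when a mix-up has simply
swapped two plots.

## Robustness under marker failure

KASP assays fail marker-wise, so panel value depends on graceful
degradation. `marker_failure_simulation()` removes, for each level $k$ from
1 to panel size − 1, a uniform random $k$-subset of the panel, recomputes
the discrimination rate, and repeats (200 replicates per level by default,
the convention for this analysis). Means and sample standard deviations
($n-1$ denominator) are reported; the $k = 0$ row is exact with zero spread.
A single root seed spawns one substream per (level, replicate), so results
are independent of iteration order and bit-reproducible. Removal can only
merge fingerprint groups, so every replicate's rate is bounded by the full
panel's rate — a deterministic dominance the tests assert replicate by
replicate, not just in expectation.

## The synthetic genotype generator

The published selections used real genebank genotype resources that are not
redistributable; the generator provides panels with the same *structure* and
known ground truth, which is what the correctness of the algorithms — not
distributional fidelity to barley — requires. The model:

* Ancestral minor allele frequencies uniform on \[0.05, 0.5\] (the
  post-filter MAF range), randomly assigned to reference or alternate.
* Subpopulation frequencies from a Balding–Nichols draw,
  $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, the
  simplest standard model with a single Fst-like divergence knob $F$
  (default 0.15, a typical differentiation level among domesticated cereal
  subpopulations; the default of three subpopulations mirrors the K = 3
  structure typical of such collections).
* Inbred accessions draw one allele per marker from their subpopulation
  frequency and are homozygous for it — marginally equivalent to repeated
  selfing and matching the "highly homozygous lines" filter — then flip to
  heterozygous at rate 0.001 (the residual level the accession filter
  tolerates).
* Pedigree groups share a drawn parent genotype and re-segregate only at a
  fixed random subset of markers, emulating related breeder lines.
* Duplicates are exact copies planted before missingness.
* Missing calls are uniform at rate 0.028 by default (a realistic KASP
  non-call rate); a whole-marker dropout mode exists because real assay
  failures are marker-wise.

`simulate_wild_populations()` emulates the wild-relative sampling design:
strongly diverged populations (default $F = 0.35$, 16 populations) each
contributing 4–10 progeny; a founder genotype per population with each
progeny re-drawing alleles at a `within_pop_diversity` fraction of markers.
At zero within-population diversity all progeny coincide — the definitional
limit in which within-population discrimination is 0%.

What the generator does **not** emulate: linkage and recombination maps,
ascertainment bias of array SNPs, geographically structured missingness, and
mutation. Tests passing on synthetic data therefore certify the algorithms
and their bookkeeping, not wet-lab performance on any particular crop.

## Numerical and degenerate-input choices

* Percentages are rounded half-up to 2 decimals only at the reporting
  surface; all internal comparisons use full precision.
* Statistics of an all-missing marker are `NA`, never silently 0; requesting
  allele frequencies of an all-missing vector is an error.
* An empty matrix filters to an empty matrix with a warning; an empty panel
  has resolved fraction 0; a single-marker panel admits only the $k = 0$
  robustness row.
* Classed conditions distinguish identity errors (duplicate or unknown
  identifiers), coding errors (unresolvable tokens, naming the accession,
  marker and token), and configuration errors.

## Problem sizes in the shipped tests

The test suite exercises: oracle equivalence (exhaustive minimal-set search
and brute-force grouping closure) on 200 random instances of up to 12
accessions × 15 markers; duplicate/pedigree recovery on a 120-accession,
300-marker panel; and robustness invariants at 200 replicates per level on a
500-accession, 200-marker panel — sizes chosen to match the published
workflows' populations while keeping a full test run around a quarter of a
minute.

## Limitations

Greedy panels are near-minimal, not certified minimal. The strict policy
discards heterozygote information by design; collections with meaningful
heterozygosity should use `genotypic` and accept the KASP cluster-calling
risk. Fingerprint identity is always "indistinguishable at this panel's
resolution": lines from a shared pedigree, mutants, and progeny of one wild
population routinely collide, which is a property of the resolution, not a
bug — `duplicate_report()` deliberately juxtaposes passport metadata instead
of inferring duplication. Match probabilities given allele frequencies
(forensic-style likelihoods) are out of scope.
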