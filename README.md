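# minmark

Minimal SNP marker sets (MMS) for molecular barcoding of genebank
accessions.

Genebanks periodically regenerate conserved seed lots, and every cycle risks
mislabelling, mix-ups and admixture. High-density genotyping detects such
errors but is too expensive and analysis-heavy for routine use. `minmark`
takes the opposite approach: given a genotype matrix for a collection, it
selects the **fewest biallelic SNP markers** (deployable as cheap KASP
assays) whose joint calls give each accession a unique multilocus
fingerprint, then supports the operations a genebank runs with that panel —
fingerprinting, duplicate-group review, regeneration quality control by
registry matching, and quantification of how gracefully the panel degrades
when assays fail.

## What is implemented

* **Genotype I/O** — delimited matrices in `A/B/H`, `AA/AB/BB`, nucleotide
  (`G/T`), and 0/1/2 dosage dialects; VCF import; panel and fingerprint
  registry files. All codings normalise to one four-state representation
  (HOM_REF / HET / HOM_ALT / MISSING).
* **QC filters** — markers kept at call rate > 0.95 and MAF > 0.05;
  accessions at call rate > 0.995 and heterozygosity < 0.001 (strict
  inequalities); monomorphic-marker removal; reason-coded reports.
* **Marker statistics** — allele frequencies, MAF, expected/observed
  heterozygosity, polymorphic information content, and pairwise LD:

  He = 1 − (p² + q²),  PIC = 1 − (p² + q²) − 2p²q²,  r² = cor(dosage)²

* **Greedy minimal selection** — `select_minimal_markers()` seeds any forced
  markers, starts from the highest-MAF marker, and then repeatedly picks the
  marker with the greatest *incremental discrimination* (unresolved
  accession pairs newly distinguished) until the collection is resolved.
  Forced/excluded lists, panel augmentation for new populations, and panel
  validation are included.
* **Fingerprinting** — duplicate-group partitions (a missing call never
  separates two accessions), discrimination rates, per-group summaries, and
  mismatch-tolerant registry matching with identity recovery.
* **Robustness** — Monte-Carlo marker-failure simulation (default 200
  replicates per removal level) with exact k = 0 baseline and
  seed-reproducible substreams.
* **Synthetic data** — a Balding–Nichols-style generator emulating genebank
  structure: diverged subpopulations of inbred lines, planted duplicates,
  pedigree-related breeder lines, wild populations with sampled progeny,
  residual heterozygosity and missing calls, with full ground truth.

## Worked example

```r
library(minmark)

# a synthetic genebank panel: 150 accessions from 3 subpopulations,
# 300 SNPs, two planted duplicate pairs, 1% missing calls
sim <- simulate_panel(n_markers = 300, n_accessions = 150, n_subpops = 3,
                      n_duplicate_pairs = 2, missing_rate = 0.01, seed = 2024)
gm  <- sim$matrix

fm <- filter_markers(gm)
fm$report
#> filter_report (markers): 300 in, 275 kept, 25 removed
#>   LOW_MAF: 25

panel <- select_minimal_markers(fm$matrix)
summary(panel)
#> Minimal marker panel: 10 markers
#>  rank marker newly_resolved cumulative_resolved_fraction
#>     1 M00006           5329                    0.4768680
#>     2 M00236           2959                    0.7416555
#>     3 M00136           1464                    0.8726622
#>     4 M00141            733                    0.9382550
#>     5 M00180            359                    0.9703803
#>     6 M00123            177                    0.9862192
#>     7 M00121             86                    0.9939150
#>     8 M00065             39                    0.9974049
#>     9 M00149             19                    0.9991051
#>    10 M00169              8                    0.9998210
#> unresolved pairs remaining: 2 (resolved fraction 0.9998)
#> training-population discrimination rate: 97.33%
```

Ten markers resolve 11,173 of the 11,175 accession pairs; the two remaining
pairs are exactly the planted duplicates, which no marker can split:

```r
ft <- predict(panel)          # fingerprint the training population
duplicate_report(ft)
#>   group group_size   accession meta.group flagged
#> 1    10          2     ACC0010    subpop1   FALSE
#> 2    10          2 ACC0010_DUP    subpop1   FALSE
#> 3    67          2     ACC0067    subpop1   FALSE
#> 4    67          2 ACC0067_DUP    subpop1   FALSE
```

The discrimination rate of 97.33% is the percentage of accessions with a
unique fingerprint (146 of 150; the four duplicate members share theirs).
Simulated marker failure shows how the panel degrades as assays drop out:

```r
rob <- simulate(panel, nsim = 200, seed = 7)
robustness_plot_table(rob)
#>    k     mean        sd
#> 1  0 97.33000 0.0000000
#> 2  1 78.86880 4.0790808
#> 3  2 52.25295 5.5807000
#> 4  3 26.02330 3.8700180
#> 5  4  8.11665 1.9901600
#> ...
plot(rob)
```

Regeneration QC against the fingerprint registry:

```r
query <- calls(gm)["ACC0042", panel$markers]
match_fingerprint(query, ft, expected = "ACC0042")
#> match_verdict: MATCH (expected 'ACC0042'; 0/10 mismatches, tolerance 0)
```

## Learning more

The methods vignette (`vignettes/minimal-marker-sets.Rmd`) documents the
statistical model, the selection algorithm and its tie-breaking, the
missing-call semantics, the synthetic generator's assumptions, and known
limitations.
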