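# The generator: seed determinism, planted structure, frequency model.

test_that("identical config and seed give a bit-identical matrix", {
  cfg <- list(n_markers = 80, n_accessions = 40, n_duplicate_pairs = 2,
              pedigree_groups = list(c(4, 10)), seed = 5)
  a <- do.call(simulate_panel, cfg)
  b <- do.call(simulate_panel, cfg)
  expect_identical(calls(a$matrix), calls(b$matrix))
  expect_identical(a$truth, b$truth)
  cfg$seed <- 6
  expect_false(identical(calls(do.call(simulate_panel, cfg)$matrix),
                         calls(a$matrix)))
})

test_that("planted duplicates are exact copies recovered by full-set grouping", {
  sim <- simulate_panel(n_markers = 120, n_accessions = 30,
                        n_duplicate_pairs = 3, missing_rate = 0,
                        residual_het_rate = 0, seed = 11)
  gm <- sim$matrix
  for (r in seq_len(nrow(sim$truth$duplicate_pairs))) {
    o <- sim$truth$duplicate_pairs$original[r]
    cp <- sim$truth$duplicate_pairs$copy[r]
    expect_identical(calls(gm)[o, ], calls(gm)[cp, ])
  }
  ft <- fingerprint_table(gm, markers(gm))
  dup <- duplicate_report(ft)
  planted <- sort(c(sim$truth$duplicate_pairs$original,
                    sim$truth$duplicate_pairs$copy))
  expect_identical(sort(dup$accession), planted)
})

test_that("pedigree lines share the parent genotype off the segregating markers", {
  sim <- simulate_panel(n_markers = 100, n_accessions = 30,
                        pedigree_groups = list(c(5, 8)), missing_rate = 0,
                        residual_het_rate = 0, seed = 12)
  acc <- sim$truth$accessions
  lines <- acc$id[!is.na(acc$pedigree_group)]
  expect_length(lines, 5)
  m <- calls(sim$matrix)[lines, ]
  differing <- which(apply(m, 2, function(v) length(unique(v)) > 1))
  expect_lte(length(differing), 8)
})

test_that("realised rates match their nominal binomial levels", {
  sim <- simulate_panel(n_markers = 100, n_accessions = 100,
                        missing_rate = 0.05, residual_het_rate = 0.01,
                        seed = 13)
  m <- calls(sim$matrix)
  frac_missing <- mean(is.na(m))
  sd_miss <- sqrt(0.05 * 0.95 / length(m))
  expect_lt(abs(frac_missing - 0.05), 3 * sd_miss)
  frac_het <- mean(m == 1L, na.rm = TRUE)
  expect_lt(abs(frac_het - 0.01), 4 * sqrt(0.01 * 0.99 / length(m)))
  # whole-marker dropout kills entire columns
  sim2 <- simulate_panel(n_markers = 200, n_accessions = 20,
                         missing_rate = 0, marker_dropout = 0.1, seed = 14)
  col_na <- colMeans(is.na(calls(sim2$matrix)))
  expect_true(all(col_na %in% c(0, 1)))
  expect_gt(sum(col_na == 1), 0)
})

test_that("zero divergence keeps subpopulation frequencies at the ancestral values", {
  sim <- simulate_panel(n_markers = 300, n_accessions = 10, n_subpops = 4,
                        divergence = 0, seed = 15)
  for (s in seq_len(4)) {
    expect_equal(sim$truth$subpop_freq[, s], sim$truth$ancestral_freq)
  }
  # and higher divergence spreads them further from the ancestral values
  spread <- function(d) {
    s <- simulate_panel(n_markers = 400, n_accessions = 10, n_subpops = 2,
                        divergence = d, seed = 16)
    mean(abs(s$truth$subpop_freq - s$truth$ancestral_freq))
  }
  expect_gt(spread(0.4), spread(0.02))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_panel(n_markers = 10, n_accessions = 5,
                              n_duplicate_pairs = 4, seed = 1),
               class = "minmark_config_error")
  expect_error(simulate_panel(n_markers = 10, n_accessions = 8,
                              pedigree_groups = list(c(10, 2)), seed = 1),
               class = "minmark_config_error")
})

test_that("wild populations: zero within-population diversity collapses progeny", {
  sim <- simulate_wild_populations(n_populations = 5, within_pop_diversity = 0,
                                   n_markers = 60, seed = 21)
  ft <- fingerprint_table(sim$matrix, markers(sim$matrix))
  bg <- summarize_by_group(ft, "group")
  expect_true(all(bg$discrimination_pct == 0))
  # population labels partition the accessions
  expect_identical(sum(table(sim$truth$accessions$population)),
                   nrow(sim$matrix))
})

test_that("diverged wild populations are distinguishable between populations", {
  sim <- simulate_wild_populations(n_populations = 16,
                                   progeny_per_population = 1,
                                   within_pop_diversity = 0,
                                   divergence = 0.5, n_markers = 150, seed = 22)
  ft <- fingerprint_table(sim$matrix, markers(sim$matrix))
  expect_equal(discrimination_rate(ft), 100)
})

test_that("resolution ordering matches genebank expectations", {
  # distinct cultivars/landraces resolve more easily than pedigree siblings,
  # which resolve more easily than progeny of a low-diversity wild population
  sim <- simulate_panel(n_markers = 250, n_accessions = 60, n_subpops = 3,
                        pedigree_groups = list(c(6, 6), c(6, 6)),
                        missing_rate = 0, residual_het_rate = 0, seed = 23)
  gm <- sim$matrix
  panel <- select_minimal_markers(gm, max_markers = 12)
  ft <- fingerprint_table(gm, panel)
  acc <- sim$truth$accessions
  is_ped <- !is.na(acc$pedigree_group)
  rate_of <- function(ids) {
    sub <- fingerprint_table(gm[ids, ], panel)
    discrimination_rate(sub)
  }
  strata_rate <- rate_of(acc$id[!is_ped])
  ped_rate <- rate_of(acc$id[is_ped])
  wild <- simulate_wild_populations(n_populations = 4,
                                    progeny_per_population = c(6, 6),
                                    within_pop_diversity = 0.05,
                                    n_markers = 250, seed = 24)
  wgm <- wild$matrix
  wild_rate <- mean(summarize_by_group(
    fingerprint_table(wgm, markers(wgm)[seq_len(12)]), "group")$discrimination_pct)
  expect_gte(strata_rate, ped_rate)
  expect_gte(ped_rate, wild_rate)
})
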