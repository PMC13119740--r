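# Greedy selection: the discrimination predicate, incremental scoring,
# panel construction, forced/excluded handling, and oracle comparisons.

test_that("pair_resolved implements both policies with missing never splitting", {
  expect_true(pair_resolved(0L, 2L, "strict"))
  expect_true(pair_resolved(2L, 0L, "strict"))
  expect_false(pair_resolved(0L, 1L, "strict"))
  expect_true(pair_resolved(0L, 1L, "genotypic"))
  expect_true(pair_resolved(1L, 2L, "genotypic"))
  expect_false(pair_resolved(0L, 0L, "genotypic"))
  expect_false(pair_resolved(0L, NA, "genotypic"))
  expect_false(pair_resolved(NA, NA, "strict"))
  # vectorised
  expect_identical(pair_resolved(c(0L, 0L, 1L), c(2L, 1L, 1L), "strict"),
                   c(TRUE, FALSE, FALSE))
})

test_that("incremental discrimination counts newly split pairs", {
  g <- cbind(m1 = c(0L, 0L, 2L, 2L),
             m2 = c(0L, 2L, 0L, 2L),
             m3 = c(0L, 0L, 2L, 2L),
             mono = rep(0L, 4))
  gm <- genotype_matrix(g, accession_ids = paste0("A", 1:4))
  all_pairs <- t(utils::combn(4, 2))
  expect_identical(incremental_discrimination(gm, "m1", all_pairs, "strict"), 4L)
  expect_identical(incremental_discrimination(gm, "mono", all_pairs, "strict"), 0L)
  # after selecting m1 only pairs (1,2) and (3,4) remain
  rest <- rbind(c(1, 2), c(3, 4))
  expect_identical(incremental_discrimination(gm, "m3", rest, "strict"), 0L)
  expect_identical(incremental_discrimination(gm, "m2", rest, "strict"), 2L)
  # accession ids accepted too
  expect_identical(
    incremental_discrimination(gm, "m2", cbind(c("A1", "A3"), c("A2", "A4"))), 2L)
  expect_error(incremental_discrimination(gm, "nope", all_pairs),
               class = "minmark_identity_error")
})

test_that("greedy selection finds the textbook two-marker panel, skipping duplicates", {
  g <- cbind(m1 = c(0L, 0L, 2L, 2L),
             m2 = c(0L, 2L, 0L, 2L),
             m3 = c(0L, 0L, 2L, 2L))  # duplicate of m1
  gm <- genotype_matrix(g)
  panel <- select_minimal_markers(gm)
  expect_identical(panel$markers, c("m1", "m2"))
  expect_identical(unname(panel$newly_resolved), c(4L, 2L))
  expect_identical(panel$unresolved_pairs_remaining, 0L)
  expect_equal(panel$resolved_fraction, 1)
  # brute force confirms 2 is the optimum
  expect_identical(oracle_min_set_size(g, "strict"), 2L)
})

test_that("identical accessions stay unresolved and terminate the loop", {
  g <- cbind(m1 = c(0L, 0L, 2L), m2 = c(2L, 2L, 0L))
  gm <- genotype_matrix(g, accession_ids = c("A", "Acopy", "B"))
  panel <- select_minimal_markers(gm)
  expect_identical(panel$unresolved_pairs_remaining, 1L)
  expect_identical(panel$unresolved_pairs$accession_a, "A")
  expect_identical(panel$unresolved_pairs$accession_b, "Acopy")
  expect_identical(sum(panel$newly_resolved) + panel$unresolved_pairs_remaining, 3L)
})

test_that("forced markers head the panel and consume pairs before greedy scoring", {
  set.seed(31)
  gm <- rand_gm(12, 10)
  panel <- select_minimal_markers(gm, forced = c("m007", "m002"))
  expect_identical(panel$markers[1:2], c("m007", "m002"))
  # augmenting with a base panel is the same as forcing it
  aug <- augment_panel(gm, c("m007", "m002"))
  expect_identical(aug$markers, panel$markers)
  # a base panel that already resolves everything is returned as-is
  full <- select_minimal_markers(gm)
  if (full$unresolved_pairs_remaining == 0L) {
    again <- augment_panel(gm, full)
    expect_identical(again$markers, full$markers)
  }
  # empty base = plain selection
  expect_identical(augment_panel(gm, character(0))$markers,
                   select_minimal_markers(gm)$markers)
})

test_that("augmentation resolves a population the base panel cannot", {
  # 8 distinct lines need at least ceil(log2(8)) = 3 binary markers
  g <- sapply(1:5, function(k) as.integer(intToBits(0:7))[seq(k, 32 * 8, by = 32)])
  g <- matrix(2L * as.integer(g >= 1), 8, 5)
  g <- cbind(g[, 1:3], extra1 = g[, 1], extra2 = g[, 2])
  colnames(g) <- paste0("b", 1:5)
  gm <- genotype_matrix(g)
  base <- c("b4", "b5")  # redundant pair: b4 = b1, b5 = b2
  aug <- augment_panel(gm, base)
  expect_identical(aug$unresolved_pairs_remaining, 0L)
  expect_gte(length(aug$markers), 3L)
  expect_identical(aug$markers[1:2], base)
})

test_that("configuration violations raise classed errors", {
  gm <- rand_gm(5, 4)
  expect_error(select_minimal_markers(gm, excluded = markers(gm)),
               class = "minmark_config_error")
  expect_error(select_minimal_markers(gm, forced = "m001", excluded = "m001"),
               class = "minmark_config_error")
  expect_error(select_minimal_markers(gm, forced = "nope"),
               class = "minmark_identity_error")
})

test_that("the first free pick is the highest-MAF marker that splits pairs", {
  # under the strict policy HETs dilute splitting power without lowering MAF:
  # m_hi has maf 0.5 but splits only one pair; m_lo has maf 1/3 and splits 8
  g <- cbind(m_lo = c(0L, 0L, 2L, 2L, 2L, 2L),
             m_hi = c(1L, 1L, 1L, 1L, 0L, 2L))
  gm <- genotype_matrix(g)
  st <- marker_summary(gm)
  expect_gt(st["m_hi", "maf"], st["m_lo", "maf"])
  all_pairs <- t(utils::combn(6, 2))
  expect_gt(incremental_discrimination(gm, "m_lo", all_pairs),
            incremental_discrimination(gm, "m_hi", all_pairs))
  # highest-MAF rule governs only the first pick
  expect_identical(select_minimal_markers(gm)$markers[1], "m_hi")
  # when a forced marker has already resolved pairs, greedy proceeds directly
  # on incremental discrimination and picks m_lo
  g2 <- cbind(f = c(0L, 2L, 2L, 2L, 2L, 2L), g)
  panel2 <- select_minimal_markers(genotype_matrix(g2), forced = "f")
  expect_identical(panel2$markers[2], "m_lo")
})

test_that("selection is deterministic and ties break by input order", {
  set.seed(33)
  gm <- rand_gm(10, 12)
  p1 <- select_minimal_markers(gm)
  p2 <- select_minimal_markers(gm)
  expect_identical(p1$markers, p2$markers)
  expect_identical(p1$newly_resolved, p2$newly_resolved)
  # two identical columns: the first one in input order is picked
  g <- cbind(ma = c(0L, 0L, 2L, 2L), mb = c(0L, 0L, 2L, 2L))
  expect_identical(select_minimal_markers(genotype_matrix(g))$markers[1], "ma")
})

test_that("greedy panels are valid discriminating sets on random instances", {
  set.seed(34)
  for (rep in 1:25) {
    n_acc <- sample(4:12, 1)
    n_mk <- sample(3:15, 1)
    gm <- rand_gm(n_acc, n_mk, p_het = 0.05, p_missing = 0.05)
    policy <- sample(c("strict", "genotypic"), 1)
    panel <- select_minimal_markers(gm, policy = policy)
    m <- calls(gm)
    # completeness: every pair resolvable by the full set is resolved
    resolvable <- oracle_resolvable_pairs(m, policy)
    sel_cols <- match(panel$markers, markers(gm))
    for (r in seq_len(nrow(resolvable))) {
      expect_true(oracle_pair_split(m, resolvable[r, 1], resolvable[r, 2],
                                    sel_cols, policy))
    }
    # pair accounting
    expect_identical(sum(panel$newly_resolved) + panel$unresolved_pairs_remaining,
                     as.integer(n_acc * (n_acc - 1) / 2))
    # validate_panel agrees with the selection bookkeeping
    val <- validate_panel(gm, panel, policy = policy)
    expect_equal(val$resolved_fraction, panel$resolved_fraction)
    expect_identical(val$per_marker$newly_resolved,
                     unname(as.integer(panel$newly_resolved)))
  }
})

test_that("a candidate perfectly correlated with a selected marker adds nothing", {
  set.seed(35)
  gm <- rand_gm(15, 8)
  g <- calls(gm)
  g <- cbind(g, twin = g[, 1])            # r2 = 1 with column 1
  g <- cbind(g, anti = 2L - g[, 1])       # label swap, also r2 = 1
  gm2 <- genotype_matrix(g)
  expect_equal(pairwise_r2(gm2)[ "m001", "twin"], 1)
  expect_equal(pairwise_r2(gm2)[ "m001", "anti"], 1)
  panel <- select_minimal_markers(gm2, forced = "m001")
  unres <- as.matrix(validate_panel(gm2, "m001")$unresolved_pairs)
  expect_identical(incremental_discrimination(gm2, "twin", unres), 0L)
  expect_identical(incremental_discrimination(gm2, "anti", unres), 0L)
  expect_false(any(c("twin", "anti") %in% panel$markers))
})

test_that("validate_panel reports what the panel leaves unresolved", {
  set.seed(36)
  gm <- rand_gm(20, 30)
  panel <- select_minimal_markers(gm)
  val <- validate_panel(gm, panel)
  # unresolved pairs are exactly those identical across ALL markers
  m <- calls(gm)
  oracle_unres <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    if (!oracle_pair_split(m, i, j, seq_len(ncol(m)), "strict")) {
      oracle_unres <- rbind(oracle_unres, c(i, j))
    }
  }
  n_o <- if (is.null(oracle_unres)) 0L else nrow(oracle_unres)
  expect_identical(nrow(val$unresolved_pairs), n_o)
  # empty panel resolves nothing; full panel achieves the maximum
  expect_equal(validate_panel(gm, character(0))$resolved_fraction, 0)
  full <- validate_panel(gm, markers(gm))
  expect_equal(full$resolved_fraction, 1 - n_o / choose(20, 2))
  expect_error(validate_panel(gm, "absent"), class = "minmark_identity_error")
})

test_that("max_markers caps the panel size", {
  set.seed(37)
  gm <- rand_gm(20, 25)
  panel <- select_minimal_markers(gm, max_markers = 2)
  expect_lte(length(panel$markers), 2L)
})
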