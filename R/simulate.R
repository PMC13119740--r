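# Seed-reproducible synthetic genotype panels with known ground truth,
# emulating the structure of genebank collections of largely homozygous
# inbred lines: diverged subpopulations, planted duplicates, pedigree-related
# breeder lines, residual heterozygosity and missing calls.

#' Simulate a genebank-like genotype panel
#'
#' Ancestral minor allele frequencies are drawn uniformly in
#' `ancestral_maf_range` (the minor allele is assigned to reference or
#' alternate at random); subpopulation frequencies derive from a
#' Balding–Nichols draw, `Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F =
#' divergence` (at `divergence = 0` subpopulation frequencies equal the
#' ancestral ones). Each inbred accession draws one allele per marker from
#' its subpopulation frequency and is homozygous for it, then flips to HET
#' at `residual_het_rate`. Pedigree groups share a common parent genotype and
#' segregate (independent redraws per line) only at a fixed random set of
#' markers. Duplicates are exact copies of distinct base accessions, made
#' before missingness. Missing calls are applied uniformly at `missing_rate`
#' after everything else. Identical config + seed gives a bit-identical
#' matrix.
#'
#' @param n_markers,n_accessions panel dimensions. `n_accessions` counts all
#'   rows: base accessions + pedigree lines + duplicate copies.
#' @param n_subpops number of diverged subpopulations (default 3).
#' @param divergence Fst-like parameter in \[0, 1).
#' @param ancestral_maf_range range for ancestral minor allele frequencies.
#' @param residual_het_rate per-call probability of a residual heterozygous
#'   call (default 0.001, the level typical of highly homozygous genebank
#'   lines).
#' @param missing_rate per-call no-call probability (default 0.028, a
#'   realistic KASP wet-lab non-call rate).
#' @param n_duplicate_pairs number of planted exact-duplicate pairs.
#' @param pedigree_groups list of `c(n_lines, n_segregating_markers)` pairs;
#'   each group emulates related breeder lines differing only at the group's
#'   segregating markers.
#' @param marker_dropout optional fraction of markers failing wholesale
#'   (entire column set missing), emulating assay-level failure; default 0.
#' @param seed integer seed.
#' @return A list with `matrix` (a [genotype_matrix()] carrying a `group`
#'   accession-metadata column) and `truth` (list: `accessions` data.frame
#'   with `subpop`, `duplicate_of`, `pedigree_group`; `duplicate_pairs`
#'   data.frame; `ancestral_freq`; `subpop_freq` markers x subpops matrix of
#'   reference-allele frequencies).
#' @export
#' @examples
#' sim <- simulate_panel(n_markers = 50, n_accessions = 20,
#'                       n_duplicate_pairs = 2, missing_rate = 0, seed = 1)
#' sim$truth$duplicate_pairs
simulate_panel <- function(n_markers = 500, n_accessions = 200, n_subpops = 3,
                           divergence = 0.15,
                           ancestral_maf_range = c(0.05, 0.5),
                           residual_het_rate = 0.001, missing_rate = 0.028,
                           n_duplicate_pairs = 0, pedigree_groups = NULL,
                           marker_dropout = 0, seed = NULL) {
  stopifnot(n_markers >= 1, n_accessions >= 1, n_subpops >= 1,
            divergence >= 0, divergence < 1,
            residual_het_rate >= 0, residual_het_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            marker_dropout >= 0, marker_dropout <= 1)
  ped_lines <- if (length(pedigree_groups)) {
    vapply(pedigree_groups, function(g) as.integer(g[[1L]]), 1L)
  } else integer(0)
  n_base <- n_accessions - n_duplicate_pairs - sum(ped_lines)
  if (n_base < max(1L, n_duplicate_pairs)) {
    stop_config("infeasible config: duplicates + pedigree lines leave %d base accessions",
                n_base)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  maf <- stats::runif(n_markers, ancestral_maf_range[1L], ancestral_maf_range[2L])
  minor_is_ref <- stats::runif(n_markers) < 0.5
  p_anc <- ifelse(minor_is_ref, maf, 1 - maf)  # reference-allele frequency

  p_sub <- matrix(NA_real_, n_markers, n_subpops,
                  dimnames = list(NULL, paste0("subpop", seq_len(n_subpops))))
  for (s in seq_len(n_subpops)) {
    p_sub[, s] <- if (divergence == 0) p_anc else {
      stats::rbeta(n_markers,
                   p_anc * (1 - divergence) / divergence,
                   (1 - p_anc) * (1 - divergence) / divergence)
    }
  }

  draw_inbred <- function(subpop, n) {
    # one allele per marker, homozygous for it
    g <- matrix(0L, n, n_markers)
    u <- matrix(stats::runif(n * n_markers), n, n_markers)
    g[u >= matrix(p_sub[, subpop], n, n_markers, byrow = TRUE)] <- 2L
    g
  }

  subpop_of_base <- rep_len(seq_len(n_subpops), n_base)
  base <- matrix(0L, n_base, n_markers)
  for (s in seq_len(n_subpops)) {
    rows <- which(subpop_of_base == s)
    if (length(rows)) base[rows, ] <- draw_inbred(s, length(rows))
  }
  ids <- sprintf("ACC%04d", seq_len(n_base))
  subpop <- paste0("subpop", subpop_of_base)
  ped_id <- rep(NA_character_, n_base)

  g_all <- base
  if (length(pedigree_groups)) {
    for (gi in seq_along(pedigree_groups)) {
      spec <- pedigree_groups[[gi]]
      n_lines <- as.integer(spec[[1L]]); n_seg <- as.integer(spec[[2L]])
      if (n_seg > n_markers) stop_config("pedigree group %d segregates at more markers than exist", gi)
      s <- sample.int(n_subpops, 1L)
      parent <- draw_inbred(s, 1L)
      seg <- sample.int(n_markers, n_seg)
      lines <- matrix(rep(parent, n_lines), n_lines, n_markers, byrow = TRUE)
      if (n_seg > 0L) lines[, seg] <- draw_inbred(s, n_lines)[, seg, drop = FALSE]
      g_all <- rbind(g_all, lines)
      ids <- c(ids, sprintf("PED%02d_%02d", gi, seq_len(n_lines)))
      subpop <- c(subpop, rep(paste0("subpop", s), n_lines))
      ped_id <- c(ped_id, rep(sprintf("PED%02d", gi), n_lines))
    }
  }

  duplicate_of <- rep(NA_character_, nrow(g_all))
  dup_pairs <- data.frame(original = character(0), copy = character(0),
                          stringsAsFactors = FALSE)
  if (n_duplicate_pairs > 0L) {
    src <- sample.int(n_base, n_duplicate_pairs)
    copies <- g_all[src, , drop = FALSE]
    copy_ids <- paste0(ids[src], "_DUP")
    dup_pairs <- data.frame(original = ids[src], copy = copy_ids,
                            stringsAsFactors = FALSE)
    g_all <- rbind(g_all, copies)
    duplicate_of <- c(duplicate_of, ids[src])
    ids <- c(ids, copy_ids)
    subpop <- c(subpop, subpop[src])
    ped_id <- c(ped_id, ped_id[src])
  }

  # residual heterozygosity, then whole-marker dropout, then random missing
  if (residual_het_rate > 0) {
    flip <- matrix(stats::runif(length(g_all)) < residual_het_rate, nrow(g_all))
    g_all[flip] <- 1L
  }
  if (marker_dropout > 0) {
    dead <- stats::runif(n_markers) < marker_dropout
    g_all[, dead] <- NA_integer_
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(g_all)) < missing_rate, nrow(g_all))
    g_all[miss] <- NA_integer_
  }

  group <- ifelse(is.na(ped_id), subpop, ped_id)
  gm <- genotype_matrix(g_all, accession_ids = ids,
                        marker_ids = sprintf("M%05d", seq_len(n_markers)),
                        accession_meta = data.frame(group = group,
                                                    stringsAsFactors = FALSE))
  truth <- list(
    accessions = data.frame(id = ids, subpop = subpop,
                            duplicate_of = duplicate_of,
                            pedigree_group = ped_id, stringsAsFactors = FALSE),
    duplicate_pairs = dup_pairs,
    ancestral_freq = p_anc,
    subpop_freq = p_sub
  )
  list(matrix = gm, truth = truth)
}

#' Simulate wild populations with sampled progeny
#'
#' Emulates the sampling design for crop wild relatives: a handful of
#' strongly diverged wild populations, each represented by several progeny
#' plants. Each population has Balding–Nichols frequencies at divergence
#' `divergence` (typically higher than among domesticated subpopulations)
#' and a founder genotype; each progeny copies the founder but, per marker
#' with probability `within_pop_diversity`, redraws its allele from the
#' population frequency. At `within_pop_diversity = 0` all progeny of a
#' population are identical.
#'
#' @param n_populations number of wild populations (default 16).
#' @param progeny_per_population integer range `c(min, max)`; the number of
#'   progeny per population is drawn uniformly from it (default 4–10).
#' @param within_pop_diversity per-marker probability a progeny segregates
#'   from the founder.
#' @param divergence Fst-like differentiation among populations.
#' @param n_markers markers simulated.
#' @param ancestral_maf_range,missing_rate as in [simulate_panel()]
#'   (`missing_rate` defaults to 0 here).
#' @param seed integer seed.
#' @return A list with `matrix` (a [genotype_matrix()] with a `group`
#'   metadata column = population) and `truth` (`accessions` data.frame with
#'   `population`; `pop_freq`; `founders` matrix).
#' @export
simulate_wild_populations <- function(n_populations = 16,
                                      progeny_per_population = c(4, 10),
                                      within_pop_diversity = 0.3,
                                      divergence = 0.35, n_markers = 200,
                                      ancestral_maf_range = c(0.05, 0.5),
                                      missing_rate = 0, seed = NULL) {
  stopifnot(n_populations >= 1, within_pop_diversity >= 0,
            within_pop_diversity <= 1, divergence >= 0, divergence < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  progeny_per_population <- as.integer(progeny_per_population)
  if (length(progeny_per_population) == 1L) {
    progeny_per_population <- rep(progeny_per_population, 2L)
  }
  maf <- stats::runif(n_markers, ancestral_maf_range[1L], ancestral_maf_range[2L])
  p_anc <- ifelse(stats::runif(n_markers) < 0.5, maf, 1 - maf)
  p_pop <- matrix(NA_real_, n_markers, n_populations,
                  dimnames = list(NULL, sprintf("POP%02d", seq_len(n_populations))))
  for (s in seq_len(n_populations)) {
    p_pop[, s] <- if (divergence == 0) p_anc else {
      stats::rbeta(n_markers,
                   p_anc * (1 - divergence) / divergence,
                   (1 - p_anc) * (1 - divergence) / divergence)
    }
  }
  n_prog <- sample(seq(progeny_per_population[1L], progeny_per_population[2L]),
                   n_populations, replace = TRUE)
  founders <- matrix(0L, n_populations, n_markers)
  rows <- list(); ids <- character(0); pop_lab <- character(0)
  for (s in seq_len(n_populations)) {
    founder <- ifelse(stats::runif(n_markers) < p_pop[, s], 0L, 2L)
    founders[s, ] <- founder
    for (pl in seq_len(n_prog[s])) {
      seg <- stats::runif(n_markers) < within_pop_diversity
      g <- founder
      if (any(seg)) {
        g[seg] <- ifelse(stats::runif(sum(seg)) < p_pop[seg, s], 0L, 2L)
      }
      rows[[length(rows) + 1L]] <- g
      ids <- c(ids, sprintf("POP%02d_P%02d", s, pl))
      pop_lab <- c(pop_lab, sprintf("POP%02d", s))
    }
  }
  g_all <- do.call(rbind, rows)
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(g_all)) < missing_rate, nrow(g_all))
    g_all[miss] <- NA_integer_
  }
  gm <- genotype_matrix(g_all, accession_ids = ids,
                        marker_ids = sprintf("M%05d", seq_len(n_markers)),
                        accession_meta = data.frame(group = pop_lab,
                                                    stringsAsFactors = FALSE))
  list(matrix = gm,
       truth = list(accessions = data.frame(id = ids, population = pop_lab,
                                            stringsAsFactors = FALSE),
                    pop_freq = p_pop,
                    founders = founders))
}
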