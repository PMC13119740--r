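# Minimal marker selection: greedy maximisation of incremental pair
# discrimination, seeded by forced markers and (for the first free pick) by
# the highest-MAF marker.

#' Can one marker's calls tell two accessions apart?
#'
#' The atomic discrimination predicate. Under the `strict` policy only
#' opposite homozygotes discriminate (the conservative choice for KASP data,
#' where the heterozygote cluster is the least reliable); under `genotypic`
#' any two distinct non-missing states discriminate. A comparison involving a
#' missing call never discriminates under either policy.
#'
#' @param call_a,call_b canonical genotype codes (0/1/2/NA) or state names;
#'   vectors are compared elementwise (recycled).
#' @param policy `"strict"` or `"genotypic"`.
#' @return Logical vector.
#' @export
#' @examples
#' pair_resolved(0L, 2L, "strict")            # TRUE
#' pair_resolved(0L, 1L, "strict")            # FALSE: HET never splits
#' pair_resolved(0L, 1L, "genotypic")         # TRUE
#' pair_resolved(0L, NA, "genotypic")         # FALSE: missing never splits
pair_resolved <- function(call_a, call_b, policy = c("strict", "genotypic")) {
  policy <- match.arg(policy)
  a <- as_calls(call_a)
  b <- as_calls(call_b)
  ok <- !is.na(a) & !is.na(b)
  if (policy == "strict") {
    ok & ((a == 0L & b == 2L) | (a == 2L & b == 0L))
  } else {
    ok & a != b
  }
}

# vectorised over a pair index set; x is one marker's call vector
.resolves_pairs <- function(x, ii, jj, policy) {
  a <- x[ii]; b <- x[jj]
  if (policy == "strict") {
    r <- (a == 0L & b == 2L) | (a == 2L & b == 0L)
  } else {
    r <- a != b
  }
  r & !is.na(r)
}

#' Incremental discrimination of a candidate marker
#'
#' The number of currently unresolved accession pairs that a candidate marker
#' would newly distinguish — the greedy selection score. A candidate
#' identical (or perfectly correlated) to an already-selected marker scores
#' zero, which is how linkage-disequilibrium redundancy is handled without an
#' explicit LD filter.
#'
#' @param gm a [genotype_matrix()].
#' @param candidate_marker marker id.
#' @param unresolved two-column matrix or data.frame of accession pairs
#'   (ids or row indices) still unresolved.
#' @param policy discrimination policy, see [pair_resolved()].
#' @return Integer count.
#' @export
incremental_discrimination <- function(gm, candidate_marker, unresolved,
                                       policy = c("strict", "genotypic")) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(gm))
  if (!candidate_marker %in% markers(gm)) {
    stop_identity("unknown marker '%s'", candidate_marker)
  }
  unresolved <- as.matrix(unresolved)
  if (nrow(unresolved) == 0L) return(0L)
  idx <- function(v) {
    if (is.character(v)) {
      i <- match(v, accessions(gm))
      if (anyNA(i)) stop_identity("unresolved pairs reference unknown accession(s)")
      i
    } else as.integer(v)
  }
  ii <- idx(unresolved[, 1L]); jj <- idx(unresolved[, 2L])
  if (any(ii < 1L | ii > nrow(gm)) || any(jj < 1L | jj > nrow(gm))) {
    stop_identity("unresolved pairs reference invalid accession indices")
  }
  x <- calls(gm)[, candidate_marker]
  sum(.resolves_pairs(x, ii, jj, policy))
}

new_marker_panel <- function(markers, newly_resolved = integer(0),
                             unresolved_remaining = NA_integer_,
                             n_accessions = NA_integer_,
                             policy = NA_character_, forced = character(0),
                             unresolved_pairs = NULL, data = NULL) {
  structure(list(markers = as.character(markers),
                 newly_resolved = stats::setNames(as.integer(newly_resolved),
                                                  if (length(newly_resolved)) markers),
                 unresolved_pairs_remaining = unresolved_remaining,
                 resolved_fraction = NA_real_,
                 n_accessions = n_accessions,
                 policy = policy,
                 forced = forced,
                 unresolved_pairs = unresolved_pairs,
                 data = data),
            class = "marker_panel")
}

panel_markers <- function(panel) {
  if (inherits(panel, "marker_panel")) panel$markers else as.character(panel)
}

#' Select a minimal discriminating marker set
#'
#' Greedy selection of the fewest SNP markers whose joint fingerprints
#' distinguish the accessions of a genotype matrix. Forced markers are seeded
#' into the panel first, in the given order, consuming the pairs they
#' resolve. If no pair has been resolved when greedy scoring starts, the
#' first free pick is the eligible marker with the highest minor allele
#' frequency (among those that resolve at least one pair); every subsequent
#' pick maximises incremental discrimination — the number of still-unresolved
#' accession pairs the marker newly distinguishes. Selection stops when all
#' pairs are resolved, when no candidate resolves any further pair, or when
#' `max_markers` is reached. Ties (on MAF or on incremental counts) are
#' broken by marker input order, the only reproducible data-independent rule.
#'
#' @param gm a [genotype_matrix()].
#' @param forced character vector of marker ids that must head the panel.
#' @param excluded character vector of marker ids never considered.
#' @param max_markers optional cap on total panel size (forced included).
#' @param policy discrimination policy, see [pair_resolved()]. Default
#'   `"strict"`.
#' @return An object of class `marker_panel`: the ordered selected markers
#'   with per-step `newly_resolved` pair counts, the remaining unresolved
#'   pair count and pair list, and the resolved fraction. The training matrix
#'   is kept in `$data` so that [predict.marker_panel()],
#'   [simulate.marker_panel()] and [plot.marker_panel()] work without
#'   re-supplying it. The bookkeeping identity
#'   `sum(newly_resolved) + unresolved_pairs_remaining == n(n-1)/2` always
#'   holds.
#' @seealso [augment_panel()], [validate_panel()], [fingerprint_table()]
#' @export
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L,
#'                                0L, 2L, 0L, 2L,
#'                                0L, 0L, 2L, 2L), 4, 3,
#'                       dimnames = list(paste0("ACC", 1:4), c("m1", "m2", "m3"))))
#' select_minimal_markers(gm)  # picks m1, m2; m3 is redundant with m1
select_minimal_markers <- function(gm, forced = character(0),
                                   excluded = character(0),
                                   max_markers = NULL,
                                   policy = c("strict", "genotypic")) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(gm))
  if (nrow(gm) == 0L || ncol(gm) == 0L) stop_config("empty genotype matrix")
  mk <- markers(gm)
  forced <- as.character(forced); excluded <- as.character(excluded)
  unknown <- setdiff(c(forced, excluded), mk)
  if (length(unknown)) {
    stop_identity("unknown marker(s) in configuration: %s",
                  paste(unknown, collapse = ", "))
  }
  if (length(intersect(forced, excluded))) {
    stop_config("forced and excluded marker sets overlap: %s",
                paste(intersect(forced, excluded), collapse = ", "))
  }
  candidates <- setdiff(mk, excluded)
  if (length(candidates) == 0L) stop_config("all markers excluded")

  m <- calls(gm)
  n <- nrow(m)
  pr <- pair_indices(n)
  ii <- pr$i; jj <- pr$j
  n_pairs <- length(ii)
  unres <- rep(TRUE, n_pairs)
  sel <- character(0)
  newly <- integer(0)

  consume <- function(marker) {
    r <- .resolves_pairs(m[, marker], ii[unres], jj[unres], policy)
    k <- sum(r)
    unres[which(unres)[r]] <<- FALSE
    k
  }

  for (f in forced) {
    newly <- c(newly, consume(f))
    sel <- c(sel, f)
  }
  maf_first <- sum(newly) == 0L  # no forced marker resolved anything
  maf <- marker_summary(gm)$maf

  repeat {
    if (!any(unres)) break
    if (!is.null(max_markers) && length(sel) >= max_markers) break
    cand <- setdiff(candidates, sel)
    if (length(cand) == 0L) break
    ui <- ii[unres]; uj <- jj[unres]
    counts <- vapply(cand, function(mc) sum(.resolves_pairs(m[, mc], ui, uj, policy)),
                     integer(1))
    if (max(counts) == 0L) break
    if (maf_first) {
      eligible <- cand[counts > 0L]
      pick <- eligible[which.max(maf[match(eligible, mk)])]
      maf_first <- FALSE
    } else {
      pick <- cand[which.max(counts)]
    }
    newly <- c(newly, consume(pick))
    sel <- c(sel, pick)
  }

  remaining <- which(unres)
  panel <- new_marker_panel(sel, newly,
                            unresolved_remaining = length(remaining),
                            n_accessions = n, policy = policy, forced = forced,
                            unresolved_pairs = if (length(remaining)) {
                              data.frame(accession_a = accessions(gm)[ii[remaining]],
                                         accession_b = accessions(gm)[jj[remaining]],
                                         stringsAsFactors = FALSE)
                            } else {
                              data.frame(accession_a = character(0),
                                         accession_b = character(0))
                            },
                            data = gm)
  panel$resolved_fraction <-
    if (n_pairs > 0) (n_pairs - length(remaining)) / n_pairs else 1
  panel
}

#' Extend an existing panel to a new population
#'
#' Equivalent to [select_minimal_markers()] with the base panel's markers
#' forced: the established (already-validated) assays are kept, and greedy
#' selection appends the markers needed to resolve whatever the base panel
#' leaves unresolved in the new population. This is how a panel trained on
#' one collection is refined after disappointing wet-lab resolution on
#' another.
#'
#' @param gm_new a [genotype_matrix()] for the new population; must contain
#'   the base panel's markers.
#' @param base_panel a `marker_panel` or character vector of marker ids.
#' @param excluded,max_markers,policy as in [select_minimal_markers()].
#' @return A `marker_panel` whose markers start with the base panel.
#' @export
augment_panel <- function(gm_new, base_panel, excluded = character(0),
                          max_markers = NULL,
                          policy = c("strict", "genotypic")) {
  select_minimal_markers(gm_new, forced = panel_markers(base_panel),
                         excluded = excluded, max_markers = max_markers,
                         policy = policy)
}

#' Validate a panel against a population
#'
#' Deterministically recomputes the panel bookkeeping on any genotype matrix:
#' sequential per-marker contributions (in panel order), the resolved pair
#' fraction, and the list of accession pairs the panel leaves unresolved.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `marker_panel` or character vector of marker ids.
#' @param policy discrimination policy, see [pair_resolved()].
#' @return A list of class `panel_validation`: `resolved_fraction`,
#'   `unresolved_pairs` (data.frame), `per_marker` (data.frame of sequential
#'   `newly_resolved` counts), `n_accessions`.
#' @export
validate_panel <- function(gm, panel, policy = c("strict", "genotypic")) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(gm))
  ids <- panel_markers(panel)
  unknown <- setdiff(ids, markers(gm))
  if (length(unknown)) {
    stop_identity("panel marker(s) absent from matrix: %s",
                  paste(unknown, collapse = ", "))
  }
  m <- calls(gm)
  n <- nrow(m)
  pr <- pair_indices(n)
  ii <- pr$i; jj <- pr$j
  unres <- rep(TRUE, length(ii))
  newly <- integer(length(ids))
  for (s in seq_along(ids)) {
    r <- .resolves_pairs(m[, ids[s]], ii[unres], jj[unres], policy)
    newly[s] <- sum(r)
    unres[which(unres)[r]] <- FALSE
  }
  remaining <- which(unres)
  structure(list(
    resolved_fraction = if (length(ii)) (length(ii) - length(remaining)) / length(ii) else 1,
    unresolved_pairs = data.frame(accession_a = accessions(gm)[ii[remaining]],
                                  accession_b = accessions(gm)[jj[remaining]],
                                  stringsAsFactors = FALSE),
    per_marker = data.frame(marker = ids, rank = seq_along(ids),
                            newly_resolved = newly, stringsAsFactors = FALSE),
    n_accessions = n,
    policy = policy
  ), class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("panel_validation: %d markers on %d accessions (%s policy)\n",
              nrow(x$per_marker), x$n_accessions, x$policy))
  cat(sprintf("  resolved pair fraction: %.4f; unresolved pairs: %d\n",
              x$resolved_fraction, nrow(x$unresolved_pairs)))
  invisible(x)
}

# ---- marker_panel methods ---------------------------------------------------

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d markers", length(x$markers)))
  if (length(x$forced)) cat(sprintf(" (%d forced)", length(x$forced)))
  if (!is.na(x$n_accessions)) {
    cat(sprintf(", selected on %d accessions (%s policy)", x$n_accessions, x$policy))
  }
  cat("\n")
  if (length(x$markers)) {
    cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  }
  if (!is.na(x$unresolved_pairs_remaining)) {
    cat(sprintf("  resolved fraction: %.4f; unresolved pairs remaining: %d\n",
                x$resolved_fraction, x$unresolved_pairs_remaining))
  }
  invisible(x)
}

#' Summarise a marker panel
#'
#' Per-step table: marker, newly resolved pairs, and cumulative resolved
#' fraction; plus the discrimination rate on the training population when it
#' is available.
#'
#' @param object a `marker_panel`.
#' @param ... unused.
#' @return A list of class `summary.marker_panel`.
#' @export
summary.marker_panel <- function(object, ...) {
  steps <- data.frame(rank = seq_along(object$markers),
                      marker = object$markers,
                      newly_resolved = as.integer(object$newly_resolved),
                      stringsAsFactors = FALSE)
  total <- if (!is.na(object$n_accessions) && object$n_accessions > 1) {
    object$n_accessions * (object$n_accessions - 1) / 2
  } else NA_real_
  steps$cumulative_resolved_fraction <-
    if (!is.na(total) && total > 0) cumsum(steps$newly_resolved) / total else NA_real_
  disc <- if (!is.null(object$data)) {
    discrimination_rate(fingerprint_table(object$data, object,
                                          policy = object$policy))
  } else NA_real_
  structure(list(steps = steps, panel_size = length(object$markers),
                 unresolved = object$unresolved_pairs_remaining,
                 resolved_fraction = object$resolved_fraction,
                 training_discrimination_rate = disc),
            class = "summary.marker_panel")
}

#' @export
print.summary.marker_panel <- function(x, ...) {
  cat(sprintf("Minimal marker panel: %d markers\n", x$panel_size))
  print(x$steps, row.names = FALSE)
  cat(sprintf("unresolved pairs remaining: %d (resolved fraction %.4f)\n",
              x$unresolved, x$resolved_fraction))
  if (!is.na(x$training_discrimination_rate)) {
    cat(sprintf("training-population discrimination rate: %.2f%%\n",
                x$training_discrimination_rate))
  }
  invisible(x)
}

#' Plot the selection trajectory of a panel
#'
#' Cumulative fraction of accession pairs resolved after each selected
#' marker.
#'
#' @param x a `marker_panel`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.marker_panel <- function(x, ...) {
  s <- summary(x)$steps
  if (nrow(s) == 0L) stop_config("empty panel: nothing to plot")
  graphics::plot(c(0, s$rank), c(0, s$cumulative_resolved_fraction),
                 type = "s", xlab = "markers selected",
                 ylab = "fraction of accession pairs resolved",
                 ylim = c(0, 1), ...)
  graphics::points(s$rank, s$cumulative_resolved_fraction, pch = 16)
  invisible(x)
}

#' Fingerprint accessions with a fitted panel
#'
#' Applies the panel to a (possibly new) genotype matrix, returning the
#' multilocus fingerprints and duplicate-group partition.
#'
#' @param object a `marker_panel`.
#' @param newdata a [genotype_matrix()]; defaults to the training matrix.
#' @param policy discrimination policy; defaults to the panel's.
#' @param ... unused.
#' @return A [fingerprint_table()].
#' @export
predict.marker_panel <- function(object, newdata = NULL, policy = NULL, ...) {
  gm <- if (is.null(newdata)) object$data else newdata
  if (is.null(gm)) stop_config("no genotype matrix available; supply newdata")
  if (is.null(policy)) policy <- if (!is.na(object$policy)) object$policy else "strict"
  fingerprint_table(gm, object, policy = policy)
}

#' Simulate marker failure for a fitted panel
#'
#' Convenience wrapper around [marker_failure_simulation()] using the panel's
#' training matrix.
#'
#' @param object a `marker_panel`.
#' @param nsim replicates per removal level (default 200).
#' @param seed integer seed for reproducibility.
#' @param gm genotype matrix to evaluate on; defaults to the training matrix.
#' @param ... passed to [marker_failure_simulation()].
#' @return A `robustness_result`.
#' @export
simulate.marker_panel <- function(object, nsim = 200, seed = NULL,
                                  gm = NULL, ...) {
  if (is.null(gm)) gm <- object$data
  if (is.null(gm)) stop_config("no genotype matrix available; supply gm")
  marker_failure_simulation(gm, object, reps = nsim, seed = seed, ...)
}
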