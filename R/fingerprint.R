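# Multilocus fingerprints, duplicate grouping, discrimination rate and
# registry matching for regeneration QC/QA.

# Group accessions by the cannot-resolve relation over a call matrix.
# Two accessions fall in one group iff NO marker resolves them; since a
# missing (and, under the strict policy, a heterozygous) call never
# separates, the relation need not be transitive, and groups are its
# connected components. A fast path handles the unambiguous case (no missing
# calls, and no HETs under strict) where grouping reduces to row equality.
group_calls <- function(m, policy) {
  n <- nrow(m)
  if (n == 0L) return(integer(0))
  has_na <- anyNA(m)
  has_het <- any(m == 1L, na.rm = TRUE)
  if (!has_na && (policy == "genotypic" || !has_het)) {
    key <- if (ncol(m) == 0L) rep("", n)
           else do.call(paste, c(asplit(m, 2), sep = "\r"))
    return(match(key, unique(key)))
  }
  pr <- pair_indices(n)
  unres <- rep(TRUE, length(pr$i))
  for (k in seq_len(ncol(m))) {
    if (!any(unres)) break
    r <- .resolves_pairs(m[, k], pr$i[unres], pr$j[unres], policy)
    unres[which(unres)[r]] <- FALSE
  }
  edge <- which(unres)
  if (length(edge) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(pr$i[edge], pr$j[edge]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  # stable relabelling by first occurrence
  match(comp, unique(comp))
}

#' Multilocus fingerprints over a panel
#'
#' Extracts each accession's call vector over the panel markers (in panel
#' order) and partitions the accessions into identical-fingerprint groups:
#' two accessions share a group iff no panel marker resolves them (see
#' [pair_resolved()]). A missing call never separates two accessions —
#' conservative, since a no-call carries no evidence of difference — so in
#' pathological missing patterns "same group" is non-transitive and groups
#' are connected components of the cannot-resolve relation; groups held
#' together only via missing-heavy members are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `marker_panel` or character vector of marker ids; must be a
#'   subset of the matrix markers.
#' @param policy discrimination policy, see [pair_resolved()].
#' @return An object of class `fingerprint_table`: `panel` (marker ids),
#'   `calls` (accessions x panel matrix), `groups` (named integer vector of
#'   group ids, numbered by first occurrence), `flagged_groups` (ids of
#'   groups whose cohesion depends on members missing half or more of the
#'   panel), and `policy`.
#' @export
fingerprint_table <- function(gm, panel, policy = c("strict", "genotypic")) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(gm))
  ids <- panel_markers(panel)
  unknown <- setdiff(ids, markers(gm))
  if (length(unknown)) {
    stop_identity("panel marker(s) absent from matrix: %s",
                  paste(unknown, collapse = ", "))
  }
  m <- calls(gm)[, ids, drop = FALSE]
  groups <- group_calls(m, policy)
  names(groups) <- rownames(m)
  # flag groups that would fall apart without their missing-heavy members
  flagged <- integer(0)
  if (length(ids) > 0L && anyNA(m)) {
    miss_heavy <- rowMeans(is.na(m)) >= 0.5
    for (grp in unique(groups[tabulate(groups)[groups] > 1L])) {
      members <- which(groups == grp)
      solid <- members[!miss_heavy[members]]
      if (length(solid) < length(members)) {
        sub <- group_calls(m[solid, , drop = FALSE], policy)
        if (length(solid) < 2L || length(unique(sub)) > 1L) {
          flagged <- c(flagged, grp)
        }
      }
    }
  }
  structure(list(panel = ids, calls = m, groups = groups,
                 flagged_groups = flagged, policy = policy,
                 accession_meta = accession_meta(gm)),
            class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("fingerprint_table: %d accessions over %d markers (%s policy)\n",
              length(x$groups), length(x$panel), x$policy))
  cat(sprintf("  %d fingerprint groups; %d unique accessions; discrimination rate %.2f%%\n",
              length(tab), sum(tab == 1), discrimination_rate(x)))
  if (length(x$flagged_groups)) {
    cat(sprintf("  %d group(s) held together only via missing-heavy members\n",
                length(x$flagged_groups)))
  }
  invisible(x)
}

#' Discrimination rate of a fingerprint table
#'
#' The percentage of accessions whose multilocus fingerprint is unique in the
#' population (singleton groups), reported to two decimals, rounded half-up.
#'
#' @param ft a [fingerprint_table()].
#' @return Percentage in \[0, 100\] with two decimals.
#' @export
#' @examples
#' # 96 accessions of which 90 unique -> 93.75%
discrimination_rate <- function(ft) {
  stopifnot(inherits(ft, "fingerprint_table"))
  n <- length(ft$groups)
  if (n < 1L) stop_config("discrimination rate needs at least one accession")
  tab <- tabulate(ft$groups)
  round_half_up(100 * sum(tab == 1L) / n, 2)
}

#' Duplicate groups for curator review
#'
#' Lists every non-singleton fingerprint group with its members' metadata
#' (pedigree, source, ...) side by side. No inference is made: accessions
#' sharing a fingerprint may be true duplicates, related lines below the
#' panel's resolution, or distinct lines colliding by chance.
#'
#' @param ft a [fingerprint_table()].
#' @param accession_meta optional data.frame keyed by accession id; defaults
#'   to the metadata carried by the fingerprinted matrix.
#' @return A data.frame with columns `group`, `group_size`, `accession`, any
#'   metadata columns, and `flagged` (group cohesion depends on
#'   missing-heavy members). One row per member of each non-singleton group.
#' @export
duplicate_report <- function(ft, accession_meta = NULL) {
  stopifnot(inherits(ft, "fingerprint_table"))
  if (is.null(accession_meta)) accession_meta <- ft$accession_meta
  tab <- tabulate(ft$groups)
  dup_groups <- which(tab > 1L)
  rows <- lapply(dup_groups, function(grp) {
    members <- names(ft$groups)[ft$groups == grp]
    df <- data.frame(group = grp, group_size = length(members),
                     accession = members, stringsAsFactors = FALSE)
    if (!is.null(accession_meta)) {
      meta <- accession_meta[members, , drop = FALSE]
      clash <- names(meta) %in% names(df)
      names(meta)[clash] <- paste0("meta.", names(meta)[clash])
      df <- cbind(df, meta)
    }
    df$flagged <- grp %in% ft$flagged_groups
    df
  })
  if (length(rows) == 0L) {
    out <- data.frame(group = integer(0), group_size = integer(0),
                      accession = character(0), flagged = logical(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match a query fingerprint against a registry
#'
#' The regeneration QC / distribution QA primitive: a freshly genotyped
#' sample is compared with the registered fingerprint of the stock it is
#' supposed to be. Comparisons are counted only where both calls are
#' non-missing; with fewer than `min_informative` comparisons the verdict is
#' `AMBIGUOUS`, otherwise `MATCH` if the mismatch count is within
#' `tolerance` (default 0: any discrepancy fails) and `MISMATCH` otherwise.
#' The registry entries with the fewest mismatches are reported as best
#' alternative hits, supporting identity recovery after a detected mix-up.
#'
#' @param query named call vector over the registry panel (names = marker
#'   ids), or unnamed in panel order.
#' @param registry a [fingerprint_table()] acting as the reference store.
#' @param expected accession id of the registered stock the query is checked
#'   against; if `NULL`, the verdict is computed against the best hit.
#' @param tolerance maximum mismatches still counted as a match (default 0).
#' @param min_informative minimum non-missing comparisons for a confident
#'   verdict (default 1).
#' @return An object of class `match_verdict`: `status` (`"MATCH"`,
#'   `"MISMATCH"` or `"AMBIGUOUS"`), `expected`, `n_compared`, `n_mismatch`,
#'   `mismatching_markers`, and `best_hits` (data.frame of registry
#'   accessions ranked by mismatch count).
#' @export
match_fingerprint <- function(query, registry, expected = NULL, tolerance = 0,
                              min_informative = 1) {
  stopifnot(inherits(registry, "fingerprint_table"))
  n_acc <- nrow(registry$calls)
  if (n_acc == 0L) stop_config("empty registry")
  q <- as_calls(if (!is.null(names(query))) {
    unknown <- setdiff(names(query), registry$panel)
    if (length(unknown)) {
      stop_identity("query marker(s) not in registry panel: %s",
                    paste(unknown, collapse = ", "))
    }
    unname(query[match(registry$panel, names(query))])
  } else {
    if (length(query) != length(registry$panel)) {
      stop_config("unnamed query length %d does not match panel size %d",
                  length(query), length(registry$panel))
    }
    query
  })
  Q <- matrix(q, nrow = n_acc, ncol = length(q), byrow = TRUE)
  both <- !is.na(Q) & !is.na(registry$calls)
  mism <- both & Q != registry$calls
  hits <- data.frame(accession = rownames(registry$calls),
                     n_compared = as.integer(rowSums(both)),
                     n_mismatch = as.integer(rowSums(mism)),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$n_mismatch, -hits$n_compared), ]
  rownames(hits) <- NULL
  target <- if (is.null(expected)) hits$accession[1L] else expected
  if (!target %in% rownames(registry$calls)) {
    stop_identity("expected accession '%s' not in registry", target)
  }
  ti <- match(target, rownames(registry$calls))
  n_compared <- as.integer(sum(both[ti, ]))
  n_mismatch <- as.integer(sum(mism[ti, ]))
  status <- if (n_compared < min_informative) "AMBIGUOUS"
            else if (n_mismatch > tolerance) "MISMATCH" else "MATCH"
  structure(list(status = status,
                 expected = target,
                 n_compared = n_compared,
                 n_mismatch = n_mismatch,
                 mismatching_markers = registry$panel[mism[ti, ]],
                 tolerance = tolerance,
                 min_informative = min_informative,
                 best_hits = utils::head(hits, 5L)),
            class = "match_verdict")
}

#' @export
print.match_verdict <- function(x, ...) {
  cat(sprintf("match_verdict: %s (expected '%s'; %d/%d mismatches, tolerance %d)\n",
              x$status, x$expected, x$n_mismatch, x$n_compared, x$tolerance))
  if (length(x$mismatching_markers)) {
    cat("  mismatching markers:", paste(x$mismatching_markers, collapse = ", "), "\n")
  }
  if (x$status != "MATCH") {
    cat("  best registry hits:\n")
    print(x$best_hits, row.names = FALSE)
  }
  invisible(x)
}

#' Per-group discrimination summary
#'
#' Recomputes the discrimination rate independently within each group of
#' accessions (e.g. landraces vs cultivars vs wild populations): group
#' members are re-partitioned among themselves, so an accession unique
#' within its group counts as unique even if it collides with a member of
#' another group. An optional overall row recomputes over the union, not the
#' mean of group rates.
#'
#' @param ft a [fingerprint_table()].
#' @param groups character/factor vector of group labels, one per accession
#'   (or the name of a column in the fingerprinted matrix's accession
#'   metadata). `NA` labels are collected under `"ungrouped"`.
#' @param include_overall add a final `ALL` row recomputed over all
#'   accessions.
#' @return Data.frame with columns `group`, `n`, `n_unique`,
#'   `discrimination_pct` (two decimals).
#' @export
summarize_by_group <- function(ft, groups, include_overall = FALSE) {
  stopifnot(inherits(ft, "fingerprint_table"))
  if (length(groups) == 1L && is.character(groups) &&
      !is.null(ft$accession_meta) && groups %in% names(ft$accession_meta)) {
    groups <- ft$accession_meta[names(ft$groups), groups]
  }
  if (length(groups) != length(ft$groups)) {
    stop_config("group labels (%d) do not match accessions (%d)",
                length(groups), length(ft$groups))
  }
  groups <- as.character(groups)
  groups[is.na(groups)] <- "ungrouped"
  one <- function(idx, label) {
    sub <- group_calls(ft$calls[idx, , drop = FALSE], ft$policy)
    tab <- tabulate(sub)
    data.frame(group = label, n = length(idx), n_unique = sum(tab == 1L),
               discrimination_pct = round_half_up(100 * sum(tab == 1L) / length(idx), 2),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    one(which(groups == g), g)
  }))
  if (include_overall) {
    out <- rbind(out, one(seq_along(groups), "ALL"))
  }
  rownames(out) <- NULL
  out
}
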