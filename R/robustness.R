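# Monte-Carlo marker-failure simulation: how much discrimination survives
# when random markers drop out of a panel (assay failures are marker-wise in
# KASP practice).

#' Simulate marker failure for a panel
#'
#' For each removal level `k`, draws `reps` uniform without-replacement
#' subsets of `k` markers to delete from the panel and recomputes the
#' discrimination rate on the reduced panel; the mean and sample standard
#' deviation (n-1 denominator) per level are recorded. The `k = 0` level is
#' always included and is exact (sd 0). A single root seed spawns one
#' substream per (level, replicate), so results do not depend on iteration
#' order and are bit-reproducible.
#'
#' @param gm a [genotype_matrix()] of the accessions to discriminate.
#' @param panel a `marker_panel` or character vector of marker ids (all
#'   present in `gm`).
#' @param reps replicates per removal level, default 200.
#' @param seed integer root seed; `NULL` leaves the RNG state alone (results
#'   then irreproducible).
#' @param k_values removal levels; default `1:(panel size - 1)`. Values must
#'   be below the panel size.
#' @param policy discrimination policy, see [pair_resolved()].
#' @param keep_replicates keep the full replicate x level rate matrix.
#' @return An object of class `robustness_result`: `table` (data.frame `k`,
#'   `mean`, `sd`, `reps`), `replicates` (matrix of per-replicate rates, or
#'   `NULL`), `seed`, `panel`, `full_rate`.
#' @export
marker_failure_simulation <- function(gm, panel, reps = 200, seed = NULL,
                                      k_values = NULL,
                                      policy = c("strict", "genotypic"),
                                      keep_replicates = TRUE) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(gm), reps >= 1)
  ids <- panel_markers(panel)
  if (length(ids) == 0L) stop_config("empty panel")
  unknown <- setdiff(ids, markers(gm))
  if (length(unknown)) {
    stop_identity("panel marker(s) absent from matrix: %s",
                  paste(unknown, collapse = ", "))
  }
  p <- length(ids)
  if (is.null(k_values)) k_values <- seq_len(max(0L, p - 1L))
  k_values <- as.integer(k_values)
  if (any(k_values < 0L) || any(k_values >= p)) {
    stop_config("k values must lie in [0, panel size - 1]")
  }
  ks <- sort(unique(c(0L, k_values)))
  m <- calls(gm)[, ids, drop = FALSE]
  n <- nrow(m)
  rate_of <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    tab <- tabulate(group_calls(sub, policy))
    round_half_up(100 * sum(tab == 1L) / n, 2)
  }
  full_rate <- rate_of(seq_len(p))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, reps * length(ks)),
                      nrow = reps, ncol = length(ks))
  rates <- matrix(NA_real_, nrow = reps, ncol = length(ks),
                  dimnames = list(NULL, paste0("k", ks)))
  for (c_idx in seq_along(ks)) {
    k <- ks[c_idx]
    if (k == 0L) {
      rates[, c_idx] <- full_rate
      next
    }
    for (r in seq_len(reps)) {
      set.seed(sub_seeds[r, c_idx])
      removed <- sample.int(p, k)
      rates[r, c_idx] <- rate_of(setdiff(seq_len(p), removed))
    }
  }
  tab <- data.frame(k = ks,
                    mean = colMeans(rates),
                    sd = apply(rates, 2L, stats::sd),
                    reps = reps)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 replicates = if (keep_replicates) rates else NULL,
                 seed = seed,
                 panel = ids,
                 full_rate = full_rate),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness_result: %d-marker panel, %d replicates per level%s\n",
              length(x$panel), x$table$reps[1L],
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Long-format robustness table
#'
#' Direct serialisation of a robustness result for plotting or export; no
#' recomputation.
#'
#' @param result a `robustness_result`.
#' @return Data.frame with columns `k`, `mean`, `sd`.
#' @export
robustness_plot_table <- function(result) {
  stopifnot(inherits(result, "robustness_result"))
  result$table[, c("k", "mean", "sd")]
}

#' Rebuild a robustness result from its table
#'
#' Inverse of [robustness_plot_table()] (up to the replicate matrix, which a
#' summary table cannot carry).
#'
#' @param table data.frame with columns `k`, `mean`, `sd` (optionally
#'   `reps`).
#' @param panel,seed optional provenance to reattach.
#' @return A `robustness_result`.
#' @export
as_robustness_result <- function(table, panel = character(0), seed = NULL) {
  stopifnot(all(c("k", "mean", "sd") %in% names(table)))
  if (is.null(table$reps)) table$reps <- NA_integer_
  structure(list(table = as.data.frame(table)[, c("k", "mean", "sd", "reps")],
                 replicates = NULL, seed = seed, panel = panel,
                 full_rate = table$mean[table$k == 0][1L]),
            class = "robustness_result")
}

#' Plot a robustness curve
#'
#' Mean discrimination rate (points) with one-standard-deviation error bars
#' against the number of removed markers.
#'
#' @param x a `robustness_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.robustness_result <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$k, tab$mean, pch = 16,
                 ylim = c(max(0, min(tab$mean - tab$sd, na.rm = TRUE)), 100),
                 xlab = "markers removed", ylab = "discrimination rate (%)", ...)
  has_sd <- !is.na(tab$sd) & tab$sd > 0
  if (any(has_sd)) {
    graphics::arrows(tab$k[has_sd], tab$mean[has_sd] - tab$sd[has_sd],
                     tab$k[has_sd], tab$mean[has_sd] + tab$sd[has_sd],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}
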