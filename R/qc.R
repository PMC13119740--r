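# Quality filters applied ahead of marker selection. All thresholds are
# strict inequalities: a marker is kept only if call rate > min_call_rate AND
# maf > min_maf, an accession only if call rate > min_call_rate and
# heterozygous fraction < max_het. Boundary items (exactly at a threshold)
# are removed.

new_filter_report <- function(what, kept, removed_ids, reasons) {
  structure(list(
    what = what,
    n_in = length(kept) + length(removed_ids),
    n_out = length(kept),
    removed = data.frame(id = removed_ids, reason = reasons,
                         stringsAsFactors = FALSE)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report (%s): %d in, %d kept, %d removed\n",
              x$what, x$n_in, x$n_out, nrow(x$removed)))
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) x$removed

#' Filter markers on call rate and minor allele frequency
#'
#' Retains markers with call rate strictly above `min_call_rate` and minor
#' allele frequency strictly above `min_maf` (the defaults reproduce the
#' ">95% call rate, >5% MAF" screening customary for genebank genotype
#' panels). Each removed marker carries one primary reason code, the first
#' failing test in the order call rate, then MAF.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate fraction in \[0,1\]; keep markers with call rate
#'   strictly greater.
#' @param min_maf fraction in \[0,1\]; keep markers with MAF strictly
#'   greater. MAF of an all-missing marker is undefined; such markers fail
#'   the call-rate test first.
#' @return A list with elements `matrix` (the filtered [genotype_matrix()],
#'   column order preserved) and `report` (a `filter_report` with reason
#'   codes `LOW_CALL_RATE`, `LOW_MAF`).
#' @export
filter_markers <- function(gm, min_call_rate = 0.95, min_maf = 0.05) {
  stopifnot(is_genotype_matrix(gm),
            min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  m <- calls(gm)
  if (ncol(m) == 0L || nrow(m) == 0L) {
    warning("empty genotype matrix; nothing to filter")
    return(list(matrix = gm, report = new_filter_report("markers", markers(gm),
                                                        character(0), character(0))))
  }
  st <- marker_summary(gm)
  low_cr <- !(st$call_rate > min_call_rate)
  low_maf <- !low_cr & !(st$maf > min_maf)
  low_maf[is.na(low_maf)] <- FALSE  # undefined maf already caught by call rate
  keep <- !(low_cr | low_maf)
  reason <- ifelse(low_cr, "LOW_CALL_RATE", "LOW_MAF")[!keep]
  list(matrix = gm[, keep],
       report = new_filter_report("markers", markers(gm)[keep],
                                  markers(gm)[!keep], reason))
}

#' Filter accessions on call rate and heterozygosity
#'
#' Retains accessions with call rate strictly above `min_call_rate` and a
#' heterozygous-call fraction strictly below `max_het` (defaults reproduce
#' the ">99.5% call rate, <0.1% heterozygosity" screen for highly homozygous
#' inbred lines). The heterozygosity denominator is the number of non-missing
#' calls. Reason order: call rate, then heterozygosity.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate keep accessions with call rate strictly greater.
#' @param max_het keep accessions with het fraction strictly smaller.
#' @return A list `matrix` + `report` (reason codes `LOW_CALL_RATE`,
#'   `HIGH_HET`), as in [filter_markers()].
#' @export
filter_accessions <- function(gm, min_call_rate = 0.995, max_het = 0.001) {
  stopifnot(is_genotype_matrix(gm),
            min_call_rate >= 0, min_call_rate <= 1, max_het >= 0, max_het <= 1)
  m <- calls(gm)
  if (ncol(m) == 0L || nrow(m) == 0L) {
    warning("empty genotype matrix; nothing to filter")
    return(list(matrix = gm, report = new_filter_report("accessions", accessions(gm),
                                                        character(0), character(0))))
  }
  n_called <- rowSums(!is.na(m))
  cr <- n_called / ncol(m)
  het <- ifelse(n_called > 0, rowSums(m == 1L, na.rm = TRUE) / n_called, NA_real_)
  low_cr <- !(cr > min_call_rate)
  high_het <- !low_cr & !(het < max_het)
  high_het[is.na(high_het)] <- FALSE
  keep <- !(low_cr | high_het)
  reason <- ifelse(low_cr, "LOW_CALL_RATE", "HIGH_HET")[!keep]
  list(matrix = gm[keep, ],
       report = new_filter_report("accessions", accessions(gm)[keep],
                                  accessions(gm)[!keep], reason))
}

#' Drop monomorphic markers
#'
#' Removes markers whose non-missing calls are a single homozygous state —
#' such markers carry no discriminating information. Markers with at least
#' one heterozygous call are polymorphic and retained. All-missing markers
#' are classed `MONOMORPHIC` too (degenerate case; the reason enumeration is
#' kept closed).
#'
#' @param gm a [genotype_matrix()].
#' @return A list `matrix` + `report` (reason code `MONOMORPHIC`), as in
#'   [filter_markers()].
#' @export
drop_monomorphic <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  m <- calls(gm)
  n_hom_ref <- colSums(m == 0L, na.rm = TRUE)
  n_het <- colSums(m == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(m == 2L, na.rm = TRUE)
  n_states <- (n_hom_ref > 0) + (n_het > 0) + (n_hom_alt > 0)
  mono <- n_states == 0L | (n_states == 1L & n_het == 0L)
  if (nrow(m) == 0L) mono <- rep(TRUE, ncol(m))
  list(matrix = gm[, !mono],
       report = new_filter_report("markers", markers(gm)[!mono],
                                  markers(gm)[mono],
                                  rep("MONOMORPHIC", sum(mono))))
}
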