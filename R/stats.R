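#' Allele frequencies of one marker
#'
#' Frequencies are allele-based: a heterozygote contributes one copy of each
#' allele, so for a marker with `n0` HOM_REF, `n1` HET calls among `n`
#' non-missing calls, `p = (2 n0 + n1) / (2 n)`.
#'
#' @param x integer vector of canonical genotype codes (0/1/2/NA) or a
#'   character vector of state names.
#' @return Named numeric vector `c(p = ..., q = ...)` where `p` is the
#'   reference-allele frequency.
#' @export
#' @examples
#' allele_frequencies(c(0L, 1L, 2L, NA))  # p = 3/6
allele_frequencies <- function(x) {
  x <- as_calls(x)
  n <- sum(!is.na(x))
  if (n == 0L) stop_config("allele frequencies undefined: all calls missing")
  p <- (2 * sum(x == 0L, na.rm = TRUE) + sum(x == 1L, na.rm = TRUE)) / (2 * n)
  c(p = p, q = 1 - p)
}

as_calls <- function(x) {
  if (is.character(x)) {
    codes <- genotype_codes()
    y <- unname(codes[x])
    if (any(!is.na(x) & is.na(y))) stop_coding("unknown genotype state name")
    return(y)
  }
  as.integer(x)
}

#' Per-marker informativeness statistics
#'
#' For each marker, the reference-allele frequency `p`, minor allele
#' frequency `maf = min(p, q)`, expected heterozygosity
#' `He = 1 - (p^2 + q^2)`, observed heterozygosity `Ho` (proportion of
#' heterozygous calls among non-missing calls), polymorphic information
#' content `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` (the biallelic form, maximal
#' at 0.375 when p = 0.5), and the call rate. Statistics of an all-missing
#' marker are `NA`, not zero.
#'
#' @param gm a [genotype_matrix()].
#' @return A data.frame with one row per marker and columns `marker`, `p`,
#'   `q`, `maf`, `he`, `ho`, `pic`, `call_rate`. Values are full precision;
#'   round for presentation (conventionally 3 decimals).
#' @export
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1,
#'                              dimnames = list(NULL, "m1")))
#' marker_summary(gm)  # p = 0.5: He = 0.5, PIC = 0.375
marker_summary <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  m <- calls(gm)
  n_total <- nrow(m)
  n0 <- colSums(m == 0L, na.rm = TRUE)
  n1 <- colSums(m == 1L, na.rm = TRUE)
  n2 <- colSums(m == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  n_ref <- 2 * n0 + n1
  n_alt <- 2 * n2 + n1
  p <- ifelse(n > 0, n_ref / (2 * n), NA_real_)
  q <- 1 - p
  he <- 1 - (p^2 + q^2)
  pic <- he - 2 * p^2 * q^2
  # maf from the minor-allele count directly, so exact threshold comparisons
  # (e.g. maf > 0.05 at 10 of 200 alleles) are not perturbed by 1 - p rounding
  maf <- ifelse(n > 0, pmin(n_ref, n_alt) / (2 * n), NA_real_)
  data.frame(marker = colnames(m),
             p = p, q = q,
             maf = maf,
             he = he,
             ho = ifelse(n > 0, n1 / n, NA_real_),
             pic = pic,
             call_rate = if (n_total > 0) n / n_total else NA_real_,
             row.names = colnames(m),
             stringsAsFactors = FALSE)
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' LD between two markers is the squared Pearson correlation of their
#' alternate-allele dosages (0/1/2) over pairwise-complete accessions.
#' Markers in complete LD (r² = 1) are mutually redundant for accession
#' discrimination. Pairs where either marker is constant within the shared
#' complete cases (or with fewer than two complete cases) are undefined and
#' returned as `NA`; the diagonal is 1.
#'
#' @param gm a [genotype_matrix()].
#' @param marker_subset optional character vector restricting the computation.
#' @return Symmetric numeric matrix of r² values in \[0,1\].
#' @export
pairwise_r2 <- function(gm, marker_subset = NULL) {
  stopifnot(is_genotype_matrix(gm))
  m <- calls(gm)
  if (!is.null(marker_subset)) {
    unknown <- setdiff(marker_subset, colnames(m))
    if (length(unknown)) {
      stop_identity("unknown marker(s): %s", paste(unknown, collapse = ", "))
    }
    m <- m[, marker_subset, drop = FALSE]
  }
  if (ncol(m) < 2L) stop_config("pairwise_r2 needs at least two markers")
  storage.mode(m) <- "double"
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  r2
}
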