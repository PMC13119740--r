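#' Canonical genotype codes
#'
#' All input dialects are normalised to a single four-state representation of
#' a biallelic SNP call: homozygous reference, heterozygous, homozygous
#' alternate, and missing. Internally calls are stored as the alternate-allele
#' dosage (`0`, `1`, `2`) with `NA` for missing, so a genotype matrix is an
#' ordinary integer matrix and base-R arithmetic applies directly.
#'
#' @return Named integer vector `c(HOM_REF = 0, HET = 1, HOM_ALT = 2)`.
#' @export
#' @examples
#' genotype_codes()
genotype_codes <- function() {
  c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)
}

#' Construct a genotype matrix
#'
#' The central data container: an accessions x markers integer matrix of
#' canonical genotype codes (see [genotype_codes()]) with optional per-marker
#' and per-accession metadata. Row names are accession identifiers, column
#' names are marker identifiers; both must be unique.
#'
#' @param calls integer or character matrix. Integer entries must be 0/1/2/NA
#'   (alternate-allele dosage); character entries must be the state names
#'   `"HOM_REF"`, `"HET"`, `"HOM_ALT"` or NA.
#' @param accession_ids,marker_ids identifiers; default to the dimnames of
#'   `calls`.
#' @param marker_meta optional data.frame of per-marker metadata (e.g.
#'   `chromosome`, `position_bp`, `allele_ref`, `allele_alt`), one row per
#'   marker.
#' @param accession_meta optional data.frame of per-accession metadata (e.g.
#'   `group`, `origin`), one row per accession.
#' @return An object of class `genotype_matrix` (an integer matrix with
#'   metadata attributes).
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 2L, 0L, 2L, 1L, NA), nrow = 2,
#'          dimnames = list(c("ACC1", "ACC2"), c("m1", "m2", "m3")))
#' )
#' gm
genotype_matrix <- function(calls, accession_ids = rownames(calls),
                            marker_ids = colnames(calls),
                            marker_meta = NULL, accession_meta = NULL) {
  if (is.character(calls)) {
    codes <- genotype_codes()
    m <- matrix(unname(codes[calls]), nrow = nrow(calls))
    bad <- !is.na(calls) & is.na(m)
    if (any(bad)) {
      stop_coding("unknown genotype state(s): %s",
                  paste(unique(calls[bad]), collapse = ", "))
    }
    calls <- m
  }
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(accession_ids)) accession_ids <- sprintf("ACC%d", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%d", seq_len(ncol(calls)))
  accession_ids <- as.character(accession_ids)
  marker_ids <- as.character(marker_ids)
  if (length(accession_ids) != nrow(calls) || length(marker_ids) != ncol(calls)) {
    stop_identity("identifier lists do not match call grid dimensions (%d x %d)",
                  nrow(calls), ncol(calls))
  }
  if (anyDuplicated(accession_ids)) {
    stop_identity("duplicate accession identifier(s): %s",
                  paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  }
  if (anyDuplicated(marker_ids)) {
    stop_identity("duplicate marker identifier(s): %s",
                  paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  }
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop_coding("genotype codes must be 0, 1, 2 or NA")
  dimnames(calls) <- list(accession_ids, marker_ids)
  if (!is.null(marker_meta)) {
    marker_meta <- as.data.frame(marker_meta)
    if (nrow(marker_meta) != length(marker_ids)) {
      stop_identity("marker_meta has %d rows for %d markers",
                    nrow(marker_meta), length(marker_ids))
    }
    rownames(marker_meta) <- marker_ids
    if (!is.null(marker_meta$position_bp) &&
        any(marker_meta$position_bp < 0, na.rm = TRUE)) {
      stop_config("marker positions must be non-negative")
    }
  }
  if (!is.null(accession_meta)) {
    accession_meta <- as.data.frame(accession_meta)
    if (nrow(accession_meta) != length(accession_ids)) {
      stop_identity("accession_meta has %d rows for %d accessions",
                    nrow(accession_meta), length(accession_ids))
    }
    rownames(accession_meta) <- accession_ids
  }
  structure(calls,
            marker_meta = marker_meta,
            accession_meta = accession_meta,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' Extract the raw call matrix
#'
#' @param gm a `genotype_matrix`.
#' @return Plain integer matrix of canonical codes (0/1/2/NA).
#' @export
calls <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  m <- unclass(gm)
  attr(m, "marker_meta") <- NULL
  attr(m, "accession_meta") <- NULL
  m
}

#' @rdname calls
#' @export
accessions <- function(gm) rownames(gm)

#' @rdname calls
#' @export
markers <- function(gm) colnames(gm)

#' @rdname calls
#' @export
marker_meta <- function(gm) attr(gm, "marker_meta")

#' @rdname calls
#' @export
accession_meta <- function(gm) attr(gm, "accession_meta")

#' Subset a genotype matrix
#'
#' Subsetting keeps the class and carries marker/accession metadata along.
#' `drop` defaults to `FALSE`: a single accession or marker remains a matrix.
#'
#' @param x a `genotype_matrix`.
#' @param i,j accession / marker indices (numeric, logical or names).
#' @param ... unused.
#' @param drop if `TRUE`, return a plain vector when one dimension has length 1.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- calls(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  sub <- m[i, j, drop = FALSE]
  if (drop && (nrow(sub) == 1L || ncol(sub) == 1L)) {
    return(m[i, j, drop = TRUE])
  }
  mm <- attr(x, "marker_meta")
  am <- attr(x, "accession_meta")
  genotype_matrix(sub,
                  marker_meta = if (!is.null(mm)) mm[j, , drop = FALSE],
                  accession_meta = if (!is.null(am)) am[i, , drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  m <- calls(x)
  cat(sprintf("genotype_matrix: %d accessions x %d markers\n", nrow(m), ncol(m)))
  nm <- sum(is.na(m))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              if (length(m)) 100 * nm / length(m) else 0))
  if (!is.null(attr(x, "marker_meta"))) {
    cat("  marker_meta: ", paste(names(attr(x, "marker_meta")), collapse = ", "), "\n")
  }
  if (!is.null(attr(x, "accession_meta"))) {
    cat("  accession_meta: ", paste(names(attr(x, "accession_meta")), collapse = ", "), "\n")
  }
  nr <- min(5L, nrow(m)); nc <- min(8L, ncol(m))
  if (nr && nc) {
    cat("  top-left corner (0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = missing):\n")
    print(m[seq_len(nr), seq_len(nc), drop = FALSE])
  }
  invisible(x)
}
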