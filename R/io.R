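#' Describe a genotype file dialect
#'
#' KASP, array and GBS exports encode biallelic SNP calls in several common
#' ways. A dialect spec states, up front, how a delimited genotype file is to
#' be interpreted; no guessing is attempted (silent transposition or token
#' misreads are worse failure modes than an explicit error).
#'
#' Supported codings:
#' \describe{
#'   \item{AB}{single letters `A` (HOM_REF), `B` (HOM_ALT), `H` (HET).}
#'   \item{PAIR}{allele pairs `AA`, `BB`, `AB`/`BA`.}
#'   \item{NUCLEOTIDE}{nucleotide pairs such as `G/G`, `G/T`. The reference
#'     allele of each marker is the alphabetically first allele observed,
#'     unless marker metadata supplies `allele_ref`/`allele_alt`.}
#'   \item{DOSAGE}{alternate-allele dosage `0`, `1`, `2`.}
#' }
#'
#' @param coding one of `"AB"`, `"PAIR"`, `"NUCLEOTIDE"`, `"DOSAGE"`.
#' @param delimiter field separator, default tab.
#' @param missing_tokens character vector of tokens read as missing. The
#'   default is a superset covering common KASP/array exports; the first
#'   element is the token written for missing calls.
#' @param orientation `"accessions_in_rows"` (default) or `"markers_in_rows"`.
#' @return A list of class `genotype_dialect`.
#' @export
#' @examples
#' genotype_dialect("AB", delimiter = ",")
genotype_dialect <- function(coding = c("AB", "PAIR", "NUCLEOTIDE", "DOSAGE"),
                             delimiter = "\t",
                             missing_tokens = c("NA", "N", "-", "./.", ".", ""),
                             orientation = c("accessions_in_rows", "markers_in_rows")) {
  structure(list(coding = match.arg(coding),
                 delimiter = delimiter,
                 missing_tokens = as.character(missing_tokens),
                 orientation = match.arg(orientation)),
            class = "genotype_dialect")
}

#' @export
print.genotype_dialect <- function(x, ...) {
  cat(sprintf("genotype_dialect: coding=%s, delimiter=%s, orientation=%s\n",
              x$coding, deparse(x$delimiter), x$orientation))
  cat("  missing tokens:", paste(deparse(x$missing_tokens), collapse = ""), "\n")
  invisible(x)
}

# token maps for the fixed-token codings
.token_map <- function(coding) {
  switch(coding,
         AB = c(A = 0L, H = 1L, B = 2L),
         PAIR = c(AA = 0L, AB = 1L, BA = 1L, BB = 2L),
         DOSAGE = c(`0` = 0L, `1` = 1L, `2` = 2L),
         NULL)
}

#' Read a genotype matrix from delimited text
#'
#' Reads an accession x marker call table and normalises it to the canonical
#' four-state coding. The first column (or row, for `markers_in_rows`
#' orientation) carries identifiers; the header carries the other dimension's
#' identifiers.
#'
#' @param path file to read.
#' @param dialect a [genotype_dialect()].
#' @param marker_meta optional data.frame of per-marker metadata; for the
#'   NUCLEOTIDE coding a column `allele_ref` overrides the
#'   alphabetically-first-allele rule.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = genotype_dialect(),
                                 marker_meta = NULL) {
  stopifnot(inherits(dialect, "genotype_dialect"))
  if (!file.exists(path)) stop_config("file not found: %s", path)
  raw <- utils::read.table(path, sep = dialect$delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           na.strings = character(0),  # tokens stay literal
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  tokens <- as.matrix(raw[, -1L, drop = FALSE])
  other_ids <- colnames(raw)[-1L]
  if (dialect$orientation == "markers_in_rows") {
    tokens <- t(tokens)
    acc_ids <- other_ids
    mk_ids <- ids
  } else {
    acc_ids <- ids
    mk_ids <- other_ids
  }
  dimnames(tokens) <- NULL
  if (anyDuplicated(acc_ids)) {
    stop_identity("duplicate accession identifier(s) in %s: %s", path,
                  paste(unique(acc_ids[duplicated(acc_ids)]), collapse = ", "))
  }
  if (anyDuplicated(mk_ids)) {
    stop_identity("duplicate marker identifier(s) in %s: %s", path,
                  paste(unique(mk_ids[duplicated(mk_ids)]), collapse = ", "))
  }
  tokens[] <- trimws(tokens)
  miss <- matrix(tokens %in% dialect$missing_tokens, nrow = nrow(tokens))
  codes <- matrix(NA_integer_, nrow(tokens), ncol(tokens))

  if (dialect$coding == "NUCLEOTIDE") {
    alle_ref <- character(ncol(tokens))
    alle_alt <- character(ncol(tokens))
    forced_ref <- if (!is.null(marker_meta) && !is.null(marker_meta$allele_ref)) {
      as.character(marker_meta$allele_ref)
    }
    for (k in seq_len(ncol(tokens))) {
      tk <- tokens[, k]
      ok <- !miss[, k]
      parts <- strsplit(tk[ok], "/", fixed = TRUE)
      bad <- vapply(parts, length, 1L) != 2L
      if (any(bad)) {
        r <- which(ok)[which(bad)[1L]]
        stop_coding("unresolvable token '%s' at accession '%s', marker '%s'",
                    tk[r], acc_ids[r], mk_ids[k])
      }
      a1 <- vapply(parts, `[`, "", 1L)
      a2 <- vapply(parts, `[`, "", 2L)
      alleles <- sort(unique(c(a1, a2)))
      if (length(alleles) > 2L) {
        stop_coding("marker '%s' has >2 alleles (%s); only biallelic SNPs supported",
                    mk_ids[k], paste(alleles, collapse = ","))
      }
      ref <- if (!is.null(forced_ref) && !is.na(forced_ref[k])) forced_ref[k]
             else alleles[1L]
      alt <- setdiff(alleles, ref)
      if (length(alt) == 0L) alt <- ref  # monomorphic column
      alle_ref[k] <- ref; alle_alt[k] <- alt
      dose <- (a1 != ref) + (a2 != ref)
      unknown <- !(a1 %in% c(ref, alt)) | !(a2 %in% c(ref, alt))
      if (any(unknown)) {
        r <- which(ok)[which(unknown)[1L]]
        stop_coding("unresolvable token '%s' at accession '%s', marker '%s'",
                    tk[r], acc_ids[r], mk_ids[k])
      }
      codes[which(ok), k] <- as.integer(dose)
    }
    mm <- data.frame(allele_ref = alle_ref, allele_alt = alle_alt,
                     stringsAsFactors = FALSE)
    if (!is.null(marker_meta)) {
      keep <- setdiff(names(marker_meta), c("allele_ref", "allele_alt"))
      mm <- cbind(mm, as.data.frame(marker_meta)[, keep, drop = FALSE])
    }
    marker_meta <- mm
  } else {
    map <- .token_map(dialect$coding)
    idx <- match(tokens, names(map))
    bad <- which(is.na(idx) & !miss)
    if (length(bad)) {
      b <- bad[1L]
      r <- (b - 1L) %% nrow(tokens) + 1L
      k <- (b - 1L) %/% nrow(tokens) + 1L
      stop_coding("unresolvable token '%s' at accession '%s', marker '%s' under %s coding",
                  tokens[b], acc_ids[r], mk_ids[k], dialect$coding)
    }
    codes[] <- unname(map[idx])
    codes[miss] <- NA_integer_
  }
  genotype_matrix(codes, accession_ids = acc_ids, marker_ids = mk_ids,
                  marker_meta = marker_meta)
}

#' Write a genotype matrix to delimited text
#'
#' The file round-trips under [read_genotype_matrix()] with the same dialect.
#' Missing calls are written as the first entry of the dialect's
#' `missing_tokens`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param dialect a [genotype_dialect()]. For NUCLEOTIDE coding the matrix
#'   must carry `allele_ref`/`allele_alt` marker metadata.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path, dialect = genotype_dialect()) {
  stopifnot(is_genotype_matrix(gm), inherits(dialect, "genotype_dialect"))
  m <- calls(gm)
  miss_tok <- dialect$missing_tokens[1L]
  if (dialect$coding == "NUCLEOTIDE") {
    mm <- marker_meta(gm)
    if (is.null(mm) || is.null(mm$allele_ref) || is.null(mm$allele_alt)) {
      stop_coding("NUCLEOTIDE coding needs allele_ref/allele_alt marker metadata to write")
    }
    out <- matrix(miss_tok, nrow(m), ncol(m))
    for (k in seq_len(ncol(m))) {
      ref <- mm$allele_ref[k]; alt <- mm$allele_alt[k]
      tok <- c(paste0(ref, "/", ref), paste0(ref, "/", alt), paste0(alt, "/", alt))
      ok <- !is.na(m[, k])
      out[ok, k] <- tok[m[ok, k] + 1L]
    }
  } else {
    map <- .token_map(dialect$coding)
    rev_map <- names(map)[match(0:2, map)]  # first token for each state
    out <- matrix(miss_tok, nrow(m), ncol(m))
    ok <- !is.na(m)
    out[ok] <- rev_map[m[ok] + 1L]
  }
  dimnames(out) <- dimnames(m)
  if (dialect$orientation == "markers_in_rows") {
    body <- cbind(marker = colnames(m), t(out))
  } else {
    body <- cbind(accession = rownames(m), out)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(body), collapse = dialect$delimiter), con)
  if (nrow(body) > 0L) {
    utils::write.table(body, con, sep = dialect$delimiter, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Import biallelic SNP calls from a VCF file
#'
#' Convenience bridge from the standard variant format. Only biallelic SNP
#' records are used; other records are skipped with a message reporting the
#' count. GT fields `0/0`, `0/1` (or `1/0`, phased variants), `1/1` and `./.`
#' map to HOM_REF, HET, HOM_ALT and MISSING.
#'
#' @param path VCF file (plain or bgzipped).
#' @param verbose print the skip count, default `TRUE`.
#' @return A [genotype_matrix()] (accessions = VCF samples) with chromosome,
#'   position and allele marker metadata.
#' @export
import_vcf <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (verbose && n_skipped > 0) {
    message(sprintf("import_vcf: skipped %d non-biallelic-SNP record(s)", n_skipped))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  map <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  codes <- matrix(unname(map[gt_clean]), nrow = nrow(gt))
  bad <- !is.na(gt_clean) & is.na(codes) & !grepl("^\\.", gt_clean)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop_coding("unresolvable GT '%s' at record %d, sample '%s'",
                gt[w[1L], w[2L]], w[1L], colnames(gt)[w[2L]])
  }
  mm <- data.frame(chromosome = fix[, "CHROM"],
                   position_bp = as.integer(fix[, "POS"]),
                   allele_ref = fix[, "REF"], allele_alt = fix[, "ALT"],
                   stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(codes), accession_ids = colnames(gt),
                        marker_ids = ids, marker_meta = mm)
  attr(gm, "n_skipped_records") <- n_skipped
  gm
}

#' Read / write marker panel files
#'
#' Panels are stored as plain text, one marker per line, or as TSV with
#' `marker`, `rank` and `newly_resolved_pairs` columns when per-step
#' bookkeeping is available. Markers referencing unknown identifiers are not
#' checked here; they are flagged when the panel is used against a matrix.
#'
#' @param path panel file.
#' @return `read_panel()` returns a `marker_panel` (see
#'   [select_minimal_markers()]); an empty file gives an empty panel.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_marker_panel(character(0), integer(0)))
  }
  if (grepl("\t", lines[[1L]])) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df$marker)
    newly <- if (!is.null(df$newly_resolved_pairs)) {
      as.integer(df$newly_resolved_pairs)
    } else {
      rep(NA_integer_, length(ids))
    }
  } else {
    ids <- trimws(lines)
    newly <- rep(NA_integer_, length(ids))
  }
  if (anyDuplicated(ids)) {
    stop_identity("duplicate marker identifier(s) in panel %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  new_marker_panel(ids, newly)
}

#' @rdname read_panel
#' @param panel a `marker_panel` or character vector of marker ids.
#' @return `write_panel()` returns `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  ids <- panel_markers(panel)
  newly <- if (inherits(panel, "marker_panel")) panel$newly_resolved else NULL
  if (!is.null(newly) && length(newly) == length(ids) && !all(is.na(newly))) {
    df <- data.frame(marker = ids, rank = seq_along(ids),
                     newly_resolved_pairs = as.integer(newly))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(ids, path)
  }
  invisible(path)
}

#' Write a fingerprint registry
#'
#' A registry is a TSV with one row per accession and one column per panel
#' marker, in canonical dosage coding, suitable as the reference store for
#' regeneration QC ([match_fingerprint()]).
#'
#' @param ft a `fingerprint_table` (see [fingerprint_table()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(ft, path) {
  stopifnot(inherits(ft, "fingerprint_table"))
  df <- data.frame(accession = rownames(ft$calls), ft$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
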