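# Independent brute-force oracles, deliberately written without reusing the
# package's vectorised internals: plain per-element loops over explicit pair
# enumerations.

# does one marker's pair of calls tell two accessions apart?
oracle_resolves <- function(a, b, policy) {
  if (is.na(a) || is.na(b)) return(FALSE)
  if (policy == "strict") (a == 0 && b == 2) || (a == 2 && b == 0) else a != b
}

# TRUE iff some marker in `cols` resolves accessions i and j
oracle_pair_split <- function(m, i, j, cols, policy) {
  for (k in cols) {
    if (oracle_resolves(m[i, k], m[j, k], policy)) return(TRUE)
  }
  FALSE
}

# grouping = transitive closure of the all-pairs cannot-resolve relation
oracle_groups <- function(m, policy, cols = seq_len(ncol(m))) {
  n <- nrow(m)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!oracle_pair_split(m, i, j, cols, policy) && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# pairs (as i < j index matrix) resolvable by at least one marker in cols
oracle_resolvable_pairs <- function(m, policy, cols = seq_len(ncol(m))) {
  n <- nrow(m)
  out <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (oracle_pair_split(m, i, j, cols, policy)) out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# size of the smallest marker subset resolving every pair the full set
# resolves, by exhaustive enumeration over subset sizes
oracle_min_set_size <- function(m, policy) {
  target <- oracle_resolvable_pairs(m, policy)
  if (nrow(target) == 0) return(0L)
  nm <- ncol(m)
  # per-marker resolution profile over the target pairs
  prof <- sapply(seq_len(nm), function(k) {
    apply(target, 1, function(pr) oracle_resolves(m[pr[1], k], m[pr[2], k], policy))
  })
  prof <- matrix(prof, nrow = nrow(target))
  for (s in 1:nm) {
    hit <- utils::combn(nm, s, FUN = function(ix) {
      all(rowSums(prof[, ix, drop = FALSE]) > 0)
    })
    if (any(hit)) return(s)
  }
  nm
}

# counting-based per-marker statistics from first principles
oracle_stats <- function(x) {
  x <- x[!is.na(x)]
  n_ref <- 2 * sum(x == 0) + sum(x == 1)
  p <- n_ref / (2 * length(x))
  q <- 1 - p
  list(p = p, maf = min(p, q), he = 1 - (p^2 + q^2),
       ho = mean(x == 1), pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2)
}

round_half_up_oracle <- function(x) floor(x * 100 + 0.5) / 100

# a matrix of n pairwise-distinct homozygous fingerprints (binary encoding
# over ceiling(log2(n)) markers, coded 0/2)
diag_gm <- function(n) {
  n_bits <- max(1L, ceiling(log2(n)))
  g <- sapply(seq_len(n_bits), function(b) {
    2L * ((seq_len(n) - 1L) %/% 2L^(b - 1L)) %% 2L
  })
  g <- matrix(as.integer(g), n, n_bits)
  colnames(g) <- sprintf("bit%02d", seq_len(n_bits))
  genotype_matrix(g, accession_ids = sprintf("D%04d", seq_len(n)))
}

# random genotype matrix generator for property tests
rand_gm <- function(n_acc, n_mk, p_het = 0, p_missing = 0) {
  g <- matrix(sample(c(0L, 2L), n_acc * n_mk, replace = TRUE), n_acc, n_mk)
  if (p_het > 0) g[matrix(runif(length(g)) < p_het, n_acc)] <- 1L
  if (p_missing > 0) g[matrix(runif(length(g)) < p_missing, n_acc)] <- NA_integer_
  genotype_matrix(g, accession_ids = sprintf("A%03d", seq_len(n_acc)),
                  marker_ids = sprintf("m%03d", seq_len(n_mk)))
}
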