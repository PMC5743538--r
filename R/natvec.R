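#' Occurrence positions of each canonical symbol
#'
#' Splits a sequence into per-symbol position sets: for every canonical
#' symbol of the record's alphabet, the strictly increasing 1-based
#' positions at which it occurs.  Non-canonical characters occupy positions
#' (they count toward \eqn{N}) but appear in no set.
#'
#' @param rec An [nv_record()].
#' @return Named list of integer vectors, one per canonical symbol (possibly
#'   empty), with attribute `N` = sequence length.
#' @examples
#' ps <- position_sets(nv_record("ex", "ACACACGTGT", "DNA"))
#' ps$A  # 1 3 5
#' @export
position_sets <- function(rec) {
  stopifnot(inherits(rec, "nv_record"))
  syms <- nv_alphabet(rec$alphabet)
  chars <- strsplit(rec$residues, "", fixed = TRUE)[[1L]]
  sets <- lapply(syms, function(s) which(chars == s))
  names(sets) <- syms
  attr(sets, "N") <- rec$N
  sets
}

#' Mean position of a symbol
#'
#' \eqn{\mu_k = T_k / n_k} where \eqn{T_k} is the sum of the occurrence
#' positions and \eqn{n_k} their count; 0 for an absent symbol (the fixed
#' zero-count convention used throughout the vector).
#'
#' @param positions Integer vector of occurrence positions (possibly empty).
#' @return The mean position, a dimensionless index.
#' @examples
#' nv_mean_position(c(1, 3, 5))  # 3
#' @export
nv_mean_position <- function(positions) {
  if (length(positions) == 0L) return(0)
  mean(positions)
}

#' Normalized central moment of a symbol's positions
#'
#' \deqn{D_j^k = \sum_i (i - \mu_k)^j w_k(s_i) \, / \, (n_k^{j-1} N^{j-1})}
#' The first moment is identically zero; the second (`j = 2`) is the moment
#' used in the 12/60-dimensional vectors.  Zero-count symbols return 0.
#'
#' @param positions Integer vector of occurrence positions.
#' @param N Parent sequence length.
#' @param j Moment order (>= 1), default 2.
#' @return The normalized moment \eqn{D_j^k}.
#' @examples
#' nv_central_moment(c(1, 3, 5), N = 10)  # 8/30
#' @export
nv_central_moment <- function(positions, N, j = 2L) {
  stopifnot(j >= 1, N >= 1)
  n <- length(positions)
  if (n == 0L) return(0)
  mu <- mean(positions)
  sum((positions - mu)^j) / (n^(j - 1) * N^(j - 1))
}

#' Rank-paired positional covariance, brute-force subset enumeration
#'
#' Reference implementation of the covariance feature between two symbols'
#' position sets.  For equal counts the sorted lists are paired by rank and
#' the sample covariance (divided by the count, then by \eqn{N}) is
#' returned.  For unequal counts every same-size increasing subset of the
#' larger set is enumerated, paired by rank with the smaller set, its
#' covariance computed with the subset's own mean, and the
#' \eqn{C(n,m)} results averaged.  Intended as a test oracle: the number of
#' subsets must not exceed `cap`.
#'
#' @param a,b Integer vectors of occurrence positions (strictly increasing).
#' @param N Parent sequence length.
#' @param cap Maximum number of subsets to enumerate (default 1e5).
#' @return Cov(a, b)/N; 0 if either set is empty.
#' @examples
#' nv_covariance_brute(c(1, 3, 5), c(2, 4, 6), N = 10)  # 4/15
#' @export
nv_covariance_brute <- function(a, b, N, cap = 1e5) {
  stopifnot(N >= 1)
  if (length(a) == 0L || length(b) == 0L) return(0)
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a); m <- length(b)
  if (n == m) {
    return(sum((a - mean(a)) * (b - mean(b))) / m / N)
  }
  n_subsets <- choose(n, m)
  if (n_subsets > cap) {
    stop("C(", n, ",", m, ") = ", n_subsets, " subsets exceeds cap ", cap,
         "; use nv_covariance_closed()")
  }
  mu_b <- mean(b)
  idx <- utils::combn(n, m)
  total <- 0
  for (col in seq_len(ncol(idx))) {
    sub <- a[idx[, col]]
    total <- total + sum((sub - mean(sub)) * (b - mu_b)) / m
  }
  total / n_subsets / N
}

# Normalized subset-pairing weights: w[i, j] = C(j-1, i-1) C(n-j, m-i) / C(n, m)
# is the probability that the i-th order statistic of a uniform size-m subset
# of {1..n} equals j.  Rows sum to one; computed in log space for stability.
pairing_weights <- function(n, m) {
  i <- seq_len(m); j <- seq_len(n)
  lw <- outer(i, j, function(ii, jj) {
    lchoose(jj - 1, ii - 1) + lchoose(n - jj, m - ii)
  }) - lchoose(n, m)
  exp(lw)
}

#' Rank-paired positional covariance, closed form
#'
#' Production implementation of the covariance feature.  The average over
#' all \eqn{C(n,m)} subsets collapses to a weighted bilinear form
#' \eqn{I = \frac{1}{m\,C(n,m)} B D A^T - \mu_A \mu_B}, where
#' \eqn{D_{ij}} counts the subsets in which the larger set's \eqn{j}-th
#' element is paired with rank \eqn{i}.  The normalized weights
#' \eqn{D_{ij}/C(n,m)} are hypergeometric-style probabilities computed via
#' `lchoose`, so \eqn{C(n,m)} is never materialized and the computation is
#' \eqn{O(nm)}.  Equal counts reduce to the direct rank-paired formula.
#'
#' @inheritParams nv_covariance_brute
#' @return Cov(a, b)/N; 0 if either set is empty.  Agrees with
#'   [nv_covariance_brute()] to 1e-9 wherever the latter is computable.
#' @examples
#' nv_covariance_closed(c(1, 3, 5), c(7, 9), N = 10)  # 2/15
#' @export
nv_covariance_closed <- function(a, b, N) {
  stopifnot(N >= 1)
  if (length(a) == 0L || length(b) == 0L) return(0)
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a); m <- length(b)
  if (n == m) {
    return(sum((a - mean(a)) * (b - mean(b))) / m / N)
  }
  W <- pairing_weights(n, m)
  I <- drop(b %*% W %*% a) / m - mean(a) * mean(b)
  if (!is.finite(I)) stop("non-finite covariance weights for n=", n, " m=", m)
  I / N
}

#' Natural vector of a sequence
#'
#' The basic natural vector concatenates, in alphabet order, the per-symbol
#' counts \eqn{n_k}, mean positions \eqn{\mu_k}, and normalized second
#' moments \eqn{D_2^k} (12 components for DNA, 60 for protein).  The
#' extended vector appends the positional covariance Cov(X,Y)/N for every
#' unordered symbol pair in lexicographic alphabet order (6 more for DNA,
#' 190 for protein: 18 / 250 total).  Zero-count symbols contribute 0 to
#' their mean, moment, and every covariance involving them, keeping the
#' dimension fixed across sequences.
#'
#' @param rec An [nv_record()].
#' @param extended Append pair covariances (default `TRUE`).
#' @return Named numeric vector (`n_A`, ..., `mu_A`, ..., `D2_A`, ...,
#'   `cov_A_C`, ...) with attribute `alphabet`.
#' @examples
#' v <- natural_vector(nv_record("ex", "ACACACGTGT", "DNA"))
#' length(v)        # 18
#' v[["cov_A_C"]]   # 4/15
#' @export
natural_vector <- function(rec, extended = TRUE) {
  ps <- position_sets(rec)
  syms <- nv_alphabet(rec$alphabet)
  N <- attr(ps, "N")
  counts <- lengths(ps)
  means <- vapply(ps, nv_mean_position, numeric(1L))
  d2 <- vapply(ps, nv_central_moment, numeric(1L), N = N, j = 2L)
  out <- c(counts, means, d2)
  names(out) <- c(paste0("n_", syms), paste0("mu_", syms), paste0("D2_", syms))
  if (extended) {
    pairs <- utils::combn(syms, 2L)
    covs <- apply(pairs, 2L, function(p) {
      nv_covariance_closed(ps[[p[1L]]], ps[[p[2L]]], N)
    })
    names(covs) <- paste0("cov_", pairs[1L, ], "_", pairs[2L, ])
    out <- c(out, covs)
  }
  attr(out, "alphabet") <- rec$alphabet
  out
}

#' Natural-vector matrix for a set of records
#'
#' @param records List of [nv_record()] (or an [nv_profile()]).
#' @param extended Passed to [natural_vector()].
#' @return Numeric matrix, one row per sequence (rownames = record ids),
#'   with attribute `alphabet`.
#' @export
nv_matrix <- function(records, extended = TRUE) {
  if (inherits(records, "nv_profile")) records <- records$records
  stopifnot(length(records) >= 1L)
  rows <- lapply(records, natural_vector, extended = extended)
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(records, `[[`, character(1L), "id")
  attr(out, "alphabet") <- records[[1L]]$alphabet
  out
}

#' Write a natural-vector matrix as TSV
#'
#' Tab-delimited with a header row; first column `id` holds the sequence
#' ids, remaining columns are the named vector components.
#'
#' @param mat Matrix from [nv_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nv_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
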