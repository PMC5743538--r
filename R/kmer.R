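#' k-mer composition of a sequence
#'
#' Counts words of length `k` over the canonical alphabet with a sliding
#' window of stride 1; windows containing any non-canonical character are
#' skipped.  Frequency mode divides by the number of valid windows (an
#' all-zero vector is returned, with a warning, when no window is valid).
#'
#' @param rec An [nv_record()].
#' @param k Word length, `1 <= k <= N`.
#' @param normalization `"frequency"` (default) or `"count"`.
#' @return Named numeric vector over the observed canonical words, with
#'   attributes `k`, `alphabet`, `n_windows` (valid window count), and
#'   `normalization`.
#' @examples
#' kmer_vector(nv_record("x", "ACG", "DNA"), k = 2, "count")  # AC=1 CG=1
#' @export
kmer_vector <- function(rec, k = 3L, normalization = c("frequency", "count")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(rec, "nv_record"))
  if (k < 1L || k > rec$N) stop("need 1 <= k <= N (N=", rec$N, ", k=", k, ")")
  syms <- nv_alphabet(rec$alphabet)
  n_win <- rec$N - k + 1L
  words <- substring(rec$residues, seq_len(n_win), seq_len(n_win) + k - 1L)
  valid <- !grepl(paste0("[^", paste(syms, collapse = ""), "]"), words)
  words <- words[valid]
  counts <- c(table(words))
  if (length(counts) > 0L) {
    counts <- counts[order(names(counts), method = "radix")]
  }
  out <- as.numeric(counts)
  names(out) <- names(counts)
  if (normalization == "frequency") {
    if (length(words) == 0L) {
      warning("record '", rec$id, "': no valid ", k, "-mer windows")
    } else {
      out <- out / length(words)
    }
  }
  structure(out, k = k, alphabet = rec$alphabet, n_windows = length(words),
            normalization = normalization)
}

# Pool k-mer counts over all sequences of a profile, then normalize to a
# frequency vector (sparse, named by word).
pooled_kmer_freq <- function(profile, k) {
  total <- numeric(0)
  for (rec in profile$records) {
    v <- kmer_vector(rec, k, "count")
    all_words <- union(names(total), names(v))
    new <- stats::setNames(numeric(length(all_words)), all_words)
    new[names(total)] <- total
    new[names(v)] <- new[names(v)] + v
    total <- new
  }
  s <- sum(total)
  if (s == 0) stop("profile '", profile$label, "': no valid ", k, "-mer windows")
  total[order(names(total), method = "radix")] / s
}

# Distance between two sparse named frequency vectors over the implicit
# full word space (absent words are zero on both sides, so the union view
# is exact for any Minkowski metric).
sparse_vec_dist <- function(u, v, base_metric) {
  words <- union(names(u), names(v))
  du <- stats::setNames(numeric(length(words)), words)
  dv <- du
  du[names(u)] <- u
  dv[names(v)] <- v
  point_distance(du, dv, base_metric)
}

#' k-mer composition distance between two taxon profiles
#'
#' Each taxon is summarized as one pooled composition vector: k-mer counts
#' are summed over all of its sequences and normalized to frequencies, and
#' the base metric is taken between the two vectors over the full canonical
#' word space.
#'
#' @param p1,p2 [nv_profile()] objects over the same alphabet.
#' @param k Word length (default 3, the amino-acid composition baseline).
#' @inheritParams point_distance
#' @return Non-negative scalar.
#' @export
kmer_profile_distance <- function(p1, p2, k = 3L,
                                  base_metric = c("euclidean", "manhattan")) {
  base_metric <- match.arg(base_metric)
  if (p1$alphabet != p2$alphabet) stop("profiles mix alphabets")
  sparse_vec_dist(pooled_kmer_freq(p1, k), pooled_kmer_freq(p2, k),
                  base_metric)
}

#' Pairwise k-mer composition distance matrix
#'
#' The k-mer baseline counterpart of [pairwise_matrix()].  By default each
#' taxon is one pooled frequency vector (`pool = "pooled"`);
#' `pool = "hausdorff"` instead keeps one k-mer frequency vector per
#' sequence and compares taxa with the Hausdorff distance.
#'
#' @param profiles List of [nv_profile()] (>= 2, one alphabet).
#' @param k Word length (default 3).
#' @inheritParams point_distance
#' @param pool `"pooled"` or `"hausdorff"`.
#' @return An `nv_distmat` (set_metric `"kmer-pooled"` or
#'   `"kmer-hausdorff"`), directly usable by [single_linkage()].
#' @export
kmer_pairwise_matrix <- function(profiles, k = 3L,
                                 base_metric = c("euclidean", "manhattan"),
                                 pool = c("pooled", "hausdorff")) {
  base_metric <- match.arg(base_metric)
  pool <- match.arg(pool)
  labels <- check_profiles(profiles)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  n <- length(profiles)
  values <- matrix(0, n, n)
  if (pool == "pooled") {
    freqs <- lapply(profiles, pooled_kmer_freq, k = k)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        d <- sparse_vec_dist(freqs[[i]], freqs[[j]], base_metric)
        values[i, j] <- d; values[j, i] <- d
      }
    }
  } else {
    # dense per-sequence frequency matrices over the union word space
    per_seq <- lapply(profiles, function(p) {
      lapply(p$records, function(r) {
        v <- kmer_vector(r, k, "frequency")
        if (attr(v, "n_windows") == 0L) {
          stop("record '", r$id, "': no valid ", k, "-mer windows")
        }
        v
      })
    })
    words <- sort(unique(unlist(lapply(per_seq, function(l)
      unlist(lapply(l, names))))), method = "radix")
    mats <- lapply(per_seq, function(l) {
      m <- matrix(0, length(l), length(words),
                  dimnames = list(NULL, words))
      for (i in seq_along(l)) m[i, names(l[[i]])] <- l[[i]]
      m
    })
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        d <- hausdorff(mats[[i]], mats[[j]], base_metric)
        values[i, j] <- d; values[j, i] <- d
      }
    }
  }
  new_distmat(values, labels, base_metric, paste0("kmer-", pool))
}
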