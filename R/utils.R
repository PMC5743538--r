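# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# All-pairs distances between the rows of two matrices.
cross_dist <- function(A, B, base_metric = c("euclidean", "manhattan")) {
  base_metric <- match.arg(base_metric)
  A <- rbind(A); B <- rbind(B)
  if (ncol(A) != ncol(B)) {
    stop("dimension mismatch: ", ncol(A), " vs ", ncol(B))
  }
  # direct differences, not the |a|^2+|b|^2-2ab expansion: the latter
  # loses ~8 digits to cancellation and breaks exact self-distances
  tB <- t(B)
  out <- matrix(0, nrow(A), nrow(B))
  if (base_metric == "euclidean") {
    for (i in seq_len(nrow(A))) {
      out[i, ] <- sqrt(colSums((tB - A[i, ])^2))
    }
  } else {
    for (i in seq_len(nrow(A))) {
      out[i, ] <- colSums(abs(tB - A[i, ]))
    }
  }
  out
}
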