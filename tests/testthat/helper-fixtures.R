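# Shared fixture builders; everything is generated in code.

rec <- function(residues, id = "seq", alphabet = "DNA") {
  nv_record(id, residues, alphabet)
}

# Random strictly increasing position sets: m <= n positions each, drawn
# without replacement from 1..N.
random_posets <- function(n, m, N = 40L) {
  a <- sort(sample.int(N, n))
  b <- sort(sample.int(N, m))
  list(a = a, b = b, N = N)
}

# Random DNA profile: n_seq sequences of length len around one ancestor.
random_profile <- function(label, n_seq = 3L, len = 60L, alphabet = "DNA") {
  syms <- nv_alphabet(alphabet)
  anc <- sample(syms, len, replace = TRUE)
  recs <- lapply(seq_len(n_seq), function(i) {
    chars <- anc
    hit <- sample.int(len, max(1L, round(len * 0.05)))
    chars[hit] <- sample(syms, length(hit), replace = TRUE)
    nv_record(sprintf("%s_%d", label, i), paste(chars, collapse = ""), syms)
  })
  nv_profile(label, recs)
}

# Random symmetric zero-diagonal distance matrix with distinct entries.
random_distmat <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  ut <- upper.tri(v)
  v[ut] <- sample(seq_len(sum(ut))) + stats::runif(sum(ut))
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  v
}

# Independent MST oracle (Prim's algorithm) for the single-linkage
# equivalence check: sorted MST edge weights == sorted merge heights.
prim_mst_weights <- function(v) {
  n <- nrow(v)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- v[1L, ]
  weights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    weights[step] <- best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, v[nxt, ])
  }
  sort(weights)
}

write_tmp_fasta <- function(dir, stem, seqs, ids = NULL, wrap = NULL) {
  if (is.null(ids)) ids <- sprintf("%s_%d", stem, seq_along(seqs))
  lines <- character(0)
  for (i in seq_along(seqs)) {
    body <- seqs[i]
    if (!is.null(wrap)) {
      starts <- seq(1L, nchar(body), by = wrap)
      body <- substring(body, starts, pmin(starts + wrap - 1L, nchar(body)))
    }
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  path <- file.path(dir, paste0(stem, ".fasta"))
  writeLines(lines, path)
  path
}
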