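# Frozen worked-example values: positions A={1,3,5}, C={2,4,6}, G={7,9},
# T={8,10} in ACACACGTGT (N=10), mu_A=3, mu_C=4, mu_G=8, Cov(A,C)/N=4/15,
# Cov(A,G)/N=2/15.

test_that("position_sets splits sequences by symbol with 1-based indices", {
  ps <- position_sets(rec("ACACACGTGT"))
  expect_equal(ps, list(A = c(1L, 3L, 5L), C = c(2L, 4L, 6L),
                        G = c(7L, 9L), T = c(8L, 10L)),
               ignore_attr = TRUE)
  expect_equal(attr(ps, "N"), 10L)

  ps <- position_sets(rec("AAAA"))
  expect_equal(ps$A, 1:4)
  expect_equal(lengths(ps[c("C", "G", "T")]), c(C = 0L, G = 0L, T = 0L))

  # non-canonical characters occupy positions but join no class
  ps <- position_sets(rec("AXA"))
  expect_equal(ps$A, c(1L, 3L))
  expect_equal(attr(ps, "N"), 3L)
  expect_equal(sum(lengths(ps)), 2L)
})

test_that("mean positions match the worked example", {
  ps <- position_sets(rec("ACACACGTGT"))
  expect_equal(nv_mean_position(ps$A), 3)
  expect_equal(nv_mean_position(ps$C), 4)
  expect_equal(nv_mean_position(ps$G), 8)
  expect_equal(nv_mean_position(integer(0)), 0)
})

test_that("central moments follow the normalized formula", {
  # D2 for A={1,3,5}, N=10: ((1-3)^2 + 0 + (5-3)^2) / (3 * 10)
  expect_equal(nv_central_moment(c(1, 3, 5), N = 10, j = 2), 8 / 30)
  expect_equal(nv_central_moment(c(5), N = 10, j = 2), 0)  # singleton
  expect_equal(nv_central_moment(integer(0), N = 10, j = 2), 0)
  # first moment vanishes identically (property over random sets)
  withr::local_seed(42)
  for (i in 1:50) {
    ps <- random_posets(sample(1:10, 1), 1)
    expect_equal(nv_central_moment(ps$a, N = ps$N, j = 1), 0)
  }
  # higher orders accepted: direct check of j=3 against the formula
  a <- c(2, 3, 9)
  expect_equal(nv_central_moment(a, N = 12, j = 3),
               sum((a - mean(a))^3) / (3^2 * 12^2))
})

test_that("both covariance paths reproduce the worked example exactly", {
  A <- c(1, 3, 5); C <- c(2, 4, 6); G <- c(7, 9)
  for (f in list(nv_covariance_brute, nv_covariance_closed)) {
    expect_equal(f(A, C, 10), 4 / 15, tolerance = 1e-14)
    expect_equal(f(A, G, 10), 2 / 15, tolerance = 1e-14)
    expect_equal(f(A, integer(0), 10), 0)
    # identical equal-count sets give the positive spread value
    expect_equal(f(c(2, 4, 6), c(2, 4, 6), 10), 4 / 15, tolerance = 1e-14)
  }
})

test_that("closed form agrees with the brute-force oracle for all m <= n <= 8", {
  withr::local_seed(1)
  checked <- 0L
  for (n in 1:8) for (m in 1:n) for (i in 1:3) {
    ps <- random_posets(n, m)
    expect_equal(nv_covariance_closed(ps$a, ps$b, ps$N),
                 nv_covariance_brute(ps$a, ps$b, ps$N),
                 tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})

test_that("covariance is symmetric and reversal-invariant", {
  withr::local_seed(2)
  for (i in 1:20) {
    ps <- random_posets(sample(2:9, 1), sample(1:6, 1))
    expect_equal(nv_covariance_closed(ps$a, ps$b, ps$N),
                 nv_covariance_closed(ps$b, ps$a, ps$N))
    if (choose(max(length(ps$a), length(ps$b)),
               min(length(ps$a), length(ps$b))) <= 1e5) {
      expect_equal(nv_covariance_brute(ps$a, ps$b, ps$N),
                   nv_covariance_brute(ps$b, ps$a, ps$N))
    }
  }
  # reversing the sequence leaves the equal-count covariance unchanged
  for (i in 1:20) {
    ps <- random_posets(5, 5)
    rev_a <- sort(ps$N + 1 - ps$a)
    rev_b <- sort(ps$N + 1 - ps$b)
    expect_equal(nv_covariance_closed(rev_a, rev_b, ps$N),
                 nv_covariance_closed(ps$a, ps$b, ps$N))
  }
})

test_that("pairing weights form row-stochastic matrices", {
  for (nm in list(c(3, 2), c(8, 3), c(20, 7), c(100, 40), c(1000, 250))) {
    W <- nvphylo:::pairing_weights(nm[1], nm[2])
    expect_equal(rowSums(W), rep(1, nm[2]), tolerance = 1e-12)
    expect_true(all(W >= 0))
  }
})

test_that("brute force enforces its enumeration cap", {
  a <- seq(1, 60, by = 2)  # n = 30
  b <- seq(2, 30, by = 2)  # m = 15, C(30,15) ~ 1.55e8
  expect_error(nv_covariance_brute(a, b, 60), "cap")
  expect_silent(nv_covariance_closed(a, b, 60))
})

test_that("natural_vector honors the dimensional contract and ordering", {
  v <- natural_vector(rec("ACACACGTGT"))
  expect_length(v, 18L)
  expect_equal(sum(startsWith(names(v), "cov_")), 6L)
  expect_equal(names(v)[1:4], c("n_A", "n_C", "n_G", "n_T"))
  expect_equal(v[["cov_A_C"]], 4 / 15, tolerance = 1e-14)
  expect_equal(v[["cov_A_G"]], 2 / 15, tolerance = 1e-14)
  expect_equal(v[["mu_G"]], 8)

  p <- natural_vector(rec("MKVL", alphabet = "PROTEIN"))
  expect_length(p, 250L)
  expect_equal(sum(startsWith(names(p), "cov_")), 190L)
  expect_length(natural_vector(rec("MKVL", alphabet = "PROTEIN"),
                               extended = FALSE), 60L)

  # basic DNA vector of AAAA, by direct formula evaluation
  b <- natural_vector(rec("AAAA"), extended = FALSE)
  expect_equal(as.vector(b), c(4, 0, 0, 0, 2.5, 0, 0, 0, 0.3125, 0, 0, 0))

  # counts sum to N minus non-canonical positions
  v <- natural_vector(rec("AXGTN"))
  expect_equal(sum(v[startsWith(names(v), "n_")]), 3)
  expect_true(all(is.finite(v)))
})

test_that("distinct short sequences map to distinct basic vectors", {
  withr::local_seed(99)
  n <- 10000L
  seqs <- unique(vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, character(1)))
  keys <- vapply(seqs, function(s) {
    paste(format(natural_vector(rec(s), extended = FALSE), digits = 15),
          collapse = "|")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("nv_matrix and TSV export keep ids and column names", {
  withr::local_seed(5)
  prof <- random_profile("m", n_seq = 4L, len = 50L)
  mat <- nv_matrix(prof)
  expect_equal(dim(mat), c(4L, 18L))
  expect_equal(rownames(mat), paste0("m_", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nv_tsv(mat, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$id, rownames(mat))
  expect_equal(as.matrix(back[, -1]), mat, ignore_attr = TRUE)
})
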