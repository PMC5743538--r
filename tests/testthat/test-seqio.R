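test_that("read_fasta applies ingest rules per policy", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "dna", "ACGT", ids = "x")
  r <- read_fasta(file.path(dir, "dna.fasta"), "DNA")
  expect_length(r, 1L)
  expect_equal(r[[1]]$id, "x")
  expect_equal(r[[1]]$N, 4L)
  expect_equal(r[[1]]$n_noncanonical, 0L)

  # trailing stop stripped, non-canonical retained under skip
  write_tmp_fasta(dir, "prot", "MKX*", ids = "y")
  r <- read_fasta(file.path(dir, "prot.fasta"), "PROTEIN", "skip")
  expect_equal(r[[1]]$residues, "MKX")
  expect_equal(r[[1]]$N, 3L)
  expect_equal(r[[1]]$n_noncanonical, 1L)

  # strict mode names the record, character, and position
  expect_error(read_fasta(file.path(dir, "prot.fasta"), "PROTEIN", "strict"),
               "'y'.*'X'.*position 3")

  # lower case is upper-cased; internal '*' is non-canonical
  write_tmp_fasta(dir, "lc", "mk*av", ids = "z")
  r <- read_fasta(file.path(dir, "lc.fasta"), "PROTEIN")[[1]]
  expect_equal(r$residues, "MK*AV")
  expect_equal(r$n_noncanonical, 1L)

  # wrapped and unwrapped entries parse identically
  long <- paste(rep("ACGT", 30), collapse = "")
  write_tmp_fasta(dir, "wrapped", long, ids = "w", wrap = 17L)
  write_tmp_fasta(dir, "flat", long, ids = "w")
  expect_equal(read_fasta(file.path(dir, "wrapped.fasta"), "DNA"),
               read_fasta(file.path(dir, "flat.fasta"), "DNA"))
})

test_that("read_fasta rejects empty files and empty entries", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fasta")
  file.create(empty)
  expect_error(read_fasta(empty, "DNA"))
  bad <- file.path(dir, "bad.fasta")
  writeLines(c(">a", "ACGT", ">b", ""), bad)
  expect_error(read_fasta(bad, "DNA"), "empty sequence")
  expect_error(read_fasta(file.path(dir, "nope.fasta"), "DNA"), "no such file")
})

test_that("FASTA round-trip preserves ids and residues", {
  withr::local_seed(7)
  dir <- withr::local_tempdir()
  recs <- random_profile("rt", n_seq = 5L, len = 133L)$records
  path <- file.path(dir, "rt.fasta")
  write_fasta(recs, path, width = 60L)
  back <- read_fasta(path, "DNA")
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(recs, `[[`, character(1), "id"))
  expect_equal(vapply(back, `[[`, character(1), "residues"),
               vapply(recs, `[[`, character(1), "residues"))
})

test_that("load_profiles orders labels, rejects duplicates and empty dirs", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "b", c("ACGT", "GGCC", "ATAT"))
  write_tmp_fasta(dir, "a", c("ACGT", "TTTT"))
  profs <- load_profiles(dir, "DNA")
  expect_equal(vapply(profs, `[[`, character(1), "label"), c("a", "b"))
  expect_equal(lengths(lapply(profs, `[[`, "records")), c(2L, 3L))

  writeLines(c(">x", "ACGT"), file.path(dir, "a.fa"))
  expect_error(load_profiles(dir, "DNA"), "duplicate taxon labels")

  expect_error(load_profiles(withr::local_tempdir(), "DNA"), "no FASTA files")
  expect_error(load_profiles(file.path(dir, "missing"), "DNA"),
               "no such directory")
})

test_that("simulate_strains honors its structural contract", {
  sim <- simulate_strains(2, 2, 10, 300, 0.3, 0.02, "PROTEIN", seed = 1)
  expect_length(sim$profiles, 4L)
  expect_true(all(lengths(lapply(sim$profiles, `[[`, "records")) == 10L))
  expect_equal(sim$clades,
               list(c("c01_s01", "c01_s02"), c("c02_s01", "c02_s02")))
  expect_equal(unname(sim$partition),
               rep(c("clade01", "clade02"), each = 2L))
  # determinism: same seed, byte-identical residues
  sim2 <- simulate_strains(2, 2, 10, 300, 0.3, 0.02, "PROTEIN", seed = 1)
  expect_identical(sim, sim2)
  sim3 <- simulate_strains(2, 2, 10, 300, 0.3, 0.02, "PROTEIN", seed = 2)
  expect_false(identical(sim$profiles, sim3$profiles))
  # parameter validation
  expect_error(simulate_strains(2, 2, 2, 5, 0.3, 0.02, "DNA", 1), "seq_len")
  expect_error(simulate_strains(2, 2, 2, 50, 0.02, 0.3, "DNA", 1),
               "within_divergence")
  expect_error(simulate_strains(0, 2, 2, 50, 0.3, 0.02, "DNA", 1))
})

test_that("within_divergence = 0 collapses clades to identical strains", {
  sim <- simulate_strains(2, 3, 4, 80, 0.4, 0, "DNA", seed = 11)
  seqs_of <- function(p) sort(vapply(p$records, `[[`, character(1), "residues"))
  expect_identical(seqs_of(sim$profiles[[1]]), seqs_of(sim$profiles[[2]]))
  expect_identical(seqs_of(sim$profiles[[1]]), seqs_of(sim$profiles[[3]]))
  # downstream: zero within-clade Hausdorff distance
  dm <- pairwise_matrix(sim$profiles)
  v <- as.matrix(dm)
  expect_equal(v["c01_s01", "c01_s02"], 0)
  expect_equal(v["c02_s01", "c02_s03"], 0)
  expect_gt(v["c01_s01", "c02_s01"], 0)
})

test_that("write_strains round-trips through load_profiles with sidecar", {
  dir <- file.path(withr::local_tempdir(), "sim")
  sim <- simulate_strains(2, 2, 3, 50, 0.3, 0.05, "DNA", seed = 3)
  write_strains(sim, dir)
  profs <- load_profiles(dir, "DNA")
  expect_equal(vapply(profs, `[[`, character(1), "label"),
               vapply(sim$profiles, `[[`, character(1), "label"))
  expect_equal(lapply(profs, function(p)
                 vapply(p$records, `[[`, character(1), "residues")),
               lapply(sim$profiles, function(p)
                 vapply(p$records, `[[`, character(1), "residues")),
               ignore_attr = TRUE)
  side <- utils::read.delim(file.path(dir, "planted_partition.tsv"))
  expect_equal(side$taxon, names(sim$partition))
  expect_equal(side$clade, unname(sim$partition))
})
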