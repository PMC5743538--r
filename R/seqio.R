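#' Read a FASTA file into sequence records
#'
#' Parses a (multi-)FASTA file, wrapped or unwrapped, and applies the
#' package's ingest rules: residues are upper-cased, one trailing `*` is
#' stripped, and non-canonical characters are either retained as positional
#' placeholders (`policy = "skip"`, the default) or rejected
#' (`policy = "strict"`, reporting the record id and offending position).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param policy `"skip"` (keep non-canonical characters out of every symbol
#'   class but inside the sequence) or `"strict"` (error on any of them).
#' @return List of [nv_record()] in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ACGT"), tf)
#' read_fasta(tf, "DNA")
#' @export
read_fasta <- function(path, alphabet, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("no such file: ", path)
  syms <- nv_alphabet(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(as.character(set))
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    if (!nzchar(ids[i])) stop("entry ", i, " in ", path, " has an empty id")
    rec <- nv_record(ids[i], seqs[i], syms)
    if (policy == "strict" && rec$n_noncanonical > 0L) {
      chars <- strsplit(rec$residues, "", fixed = TRUE)[[1L]]
      bad <- which(!(chars %in% syms))[1L]
      stop("record '", rec$id, "': non-canonical character '",
           chars[bad], "' at position ", bad)
    }
    records[[i]] <- rec
  }
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [nv_record()].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- vapply(records, `[[`, character(1L), "residues")
  ids <- vapply(records, `[[`, character(1L), "id")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

FASTA_EXTENSIONS <- c("fasta", "fa", "faa", "fna", "ffn", "frn", "fas")

#' Load one taxon profile per FASTA file in a directory
#'
#' Each FASTA file becomes one taxon; the taxon label is the file stem.
#' Profiles are returned in lexicographic label order (C locale) so that
#' downstream matrices and trees are deterministic.
#'
#' @inheritParams read_fasta
#' @param directory Directory holding one FASTA file per taxon (extensions
#'   .fasta .fa .faa .fna .ffn .frn .fas, case-insensitive).
#' @return List of [nv_profile()] sorted by label.
#' @export
load_profiles <- function(directory, alphabet, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  pattern <- paste0("\\.(", paste(FASTA_EXTENSIONS, collapse = "|"), ")$")
  files <- list.files(directory, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", directory)
  stems <- sub("\\.[^.]*$", "", basename(files))
  if (anyDuplicated(stems)) {
    stop("duplicate taxon labels from file stems: ",
         paste(unique(stems[duplicated(stems)]), collapse = ", "))
  }
  ord <- order(stems, method = "radix")
  files <- files[ord]
  stems <- stems[ord]
  profiles <- vector("list", length(files))
  for (i in seq_along(files)) {
    recs <- read_fasta(files[i], alphabet, policy)
    profiles[[i]] <- nv_profile(stems[i], recs)
  }
  check_profiles(profiles)
  profiles
}

# Substitute each position independently with probability `rate`; a
# substituted position receives a uniformly random *different* symbol.
mutate_chars <- function(chars, rate, syms) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0L) return(chars)
  k <- length(syms)
  # index among the k-1 symbols that differ from the current one
  shift <- sample.int(k - 1L, length(hit), replace = TRUE)
  cur <- match(chars[hit], syms)
  repl <- shift + (shift >= cur)
  chars[hit] <- syms[repl]
  chars
}

#' Simulate planted-clade strain collections
#'
#' Generates a hierarchical collection of taxa for offline validation of the
#' whole pipeline.  A single random root sequence is mutated independently
#' at rate `between_divergence` to give one ancestral sequence per clade;
#' every sequence of every strain in that clade is then an independent
#' mutant of the clade ancestor at rate `within_divergence`.  Mutation is
#' i.i.d. per position: with the given probability the position is replaced
#' by a uniformly chosen different symbol.  Because strains within a clade
#' are exchangeable draws around one ancestor, the planted signal lives at
#' the clade level; `within_divergence = 0` makes all strains of a clade
#' byte-identical.
#'
#' @param n_clades,strains_per_clade,seqs_per_strain Positive counts.
#' @param seq_len Sequence length (>= 10).
#' @param between_divergence,within_divergence Substitution probabilities
#'   with `0 <= within < between <= 1`.
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return List with components `profiles` (list of [nv_profile()], labels
#'   `c<clade>_s<strain>`), `partition` (named character vector
#'   label -> clade id), and `clades` (list of label vectors, one per
#'   planted clade).
#' @examples
#' sim <- simulate_strains(2, 2, 3, 60, 0.3, 0.02, "DNA", seed = 1)
#' sim$clades
#' @export
simulate_strains <- function(n_clades, strains_per_clade, seqs_per_strain,
                             seq_len, between_divergence, within_divergence,
                             alphabet, seed) {
  stopifnot(n_clades >= 1, strains_per_clade >= 1, seqs_per_strain >= 1)
  if (seq_len < 10) stop("seq_len must be >= 10")
  if (!(within_divergence >= 0 && within_divergence < between_divergence &&
        between_divergence <= 1)) {
    stop("need 0 <= within_divergence < between_divergence <= 1")
  }
  syms <- nv_alphabet(alphabet)
  with_seed(seed, {
    root <- sample(syms, seq_len, replace = TRUE)
    profiles <- list()
    partition <- character(0)
    clades <- vector("list", n_clades)
    for (ci in seq_len(n_clades)) {
      anc <- mutate_chars(root, between_divergence, syms)
      labels_ci <- character(strains_per_clade)
      for (si in seq_len(strains_per_clade)) {
        label <- sprintf("c%02d_s%02d", ci, si)
        recs <- lapply(seq_len(seqs_per_strain), function(qi) {
          chars <- mutate_chars(anc, within_divergence, syms)
          nv_record(sprintf("%s_seq%03d", label, qi),
                    paste(chars, collapse = ""), syms)
        })
        profiles[[length(profiles) + 1L]] <- nv_profile(label, recs)
        partition[label] <- sprintf("clade%02d", ci)
        labels_ci[si] <- label
      }
      clades[[ci]] <- labels_ci
    }
    list(profiles = profiles, partition = partition, clades = clades)
  })
}

#' Write a simulated strain collection to disk
#'
#' One FASTA file per strain (readable back with [load_profiles()]) plus a
#' plain-text sidecar `planted_partition.tsv` recording the planted clade of
#' each strain.
#'
#' @param sim Result of [simulate_strains()].
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_strains <- function(sim, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (p in sim$profiles) {
    write_fasta(p$records, file.path(directory, paste0(p$label, ".fasta")))
  }
  side <- file.path(directory, "planted_partition.tsv")
  utils::write.table(
    data.frame(taxon = names(sim$partition), clade = unname(sim$partition)),
    side, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(directory)
}
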