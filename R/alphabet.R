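#' Canonical alphabets
#'
#' Fixed, ordered symbol sets over which all natural vectors are built.
#' The component order of every vector produced by the package follows
#' these orders, so they must never be permuted.
#'
#' @format Character vectors: the 4 DNA bases and the 20 proteinogenic
#'   amino acids in their canonical one-letter order.
#' @name alphabets
NULL

DNA_SYMBOLS <- c("A", "C", "G", "T")

PROTEIN_SYMBOLS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Look up a canonical alphabet
#'
#' @param alphabet `"DNA"` or `"PROTEIN"` (case-insensitive), or a character
#'   vector of symbols already in canonical order (passed through after
#'   validation).
#' @return A character vector of canonical symbols with a `"name"` attribute.
#' @examples
#' nv_alphabet("DNA")
#' @export
nv_alphabet <- function(alphabet) {
  if (is.character(alphabet) && length(alphabet) == 1L) {
    name <- toupper(alphabet)
    syms <- switch(name,
      DNA = DNA_SYMBOLS,
      PROTEIN = PROTEIN_SYMBOLS,
      stop("unknown alphabet: ", alphabet, " (use 'DNA' or 'PROTEIN')")
    )
    return(structure(syms, name = name))
  }
  bare <- as.character(alphabet)
  attributes(bare) <- NULL
  if (identical(bare, DNA_SYMBOLS)) {
    return(structure(DNA_SYMBOLS, name = "DNA"))
  }
  if (identical(bare, PROTEIN_SYMBOLS)) {
    return(structure(PROTEIN_SYMBOLS, name = "PROTEIN"))
  }
  stop("alphabet must be 'DNA', 'PROTEIN', or one of the canonical symbol vectors")
}

alphabet_name <- function(alphabet) {
  attr(nv_alphabet(alphabet), "name")
}

#' Construct a sequence record
#'
#' A record stores the residues of one identified sequence together with its
#' declared alphabet.  Residues are upper-cased; exactly one trailing stop
#' character `*` is stripped before the length \eqn{N} is computed.
#' Characters outside the canonical alphabet (ambiguity codes, `X`, gaps,
#' internal `*`, ...) are retained: they occupy positions and count toward
#' \eqn{N} but belong to no symbol class.
#'
#' @param id Record identifier (non-empty string).
#' @param residues Character string of residues, length >= 1 after the
#'   trailing-stop strip.
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @return An object of class `nv_record` with fields `id`, `alphabet`,
#'   `residues`, `N`, and `n_noncanonical`.
#' @examples
#' r <- nv_record("x", "mkx*", "PROTEIN")
#' r$N               # 3: '*' stripped, 'X' kept
#' r$n_noncanonical  # 1
#' @export
nv_record <- function(id, residues, alphabet) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  syms <- nv_alphabet(alphabet)
  residues <- toupper(residues)
  residues <- sub("\\*$", "", residues)
  if (!nzchar(residues)) {
    stop("record '", id, "': empty sequence")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  noncanon <- !(chars %in% syms)
  structure(
    list(
      id = id,
      alphabet = attr(syms, "name"),
      residues = residues,
      N = length(chars),
      n_noncanonical = sum(noncanon)
    ),
    class = "nv_record"
  )
}

#' @export
print.nv_record <- function(x, ...) {
  cat(sprintf("<nv_record> %s [%s] N=%d (non-canonical: %d)\n",
              x$id, x$alphabet, x$N, x$n_noncanonical))
  invisible(x)
}

#' Construct a taxon profile
#'
#' A labeled, non-empty set of sequence records that together represent one
#' organism or strain (for example its full set of ribosomal proteins).
#'
#' @param label Taxon label (non-empty string).
#' @param records Non-empty list of [nv_record()] objects sharing one
#'   alphabet.
#' @return An object of class `nv_profile` with fields `label`, `alphabet`,
#'   and `records`.
#' @export
nv_profile <- function(label, records) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.list(records) || length(records) == 0L) {
    stop("profile '", label, "': needs at least one record")
  }
  ok <- vapply(records, inherits, logical(1L), what = "nv_record")
  if (!all(ok)) stop("records must all be nv_record objects")
  alpha <- unique(vapply(records, `[[`, character(1L), "alphabet"))
  if (length(alpha) != 1L) {
    stop("profile '", label, "': records mix alphabets ",
         paste(alpha, collapse = ", "))
  }
  structure(
    list(label = label, alphabet = alpha, records = records),
    class = "nv_profile"
  )
}

#' @export
print.nv_profile <- function(x, ...) {
  cat(sprintf("<nv_profile> %s [%s]: %d sequence(s)\n",
              x$label, x$alphabet, length(x$records)))
  invisible(x)
}

check_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    stop("profiles must be a non-empty list of nv_profile objects")
  }
  ok <- vapply(profiles, inherits, logical(1L), what = "nv_profile")
  if (!all(ok)) stop("profiles must all be nv_profile objects")
  labels <- vapply(profiles, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  alpha <- unique(vapply(profiles, `[[`, character(1L), "alphabet"))
  if (length(alpha) != 1L) {
    stop("profiles mix alphabets: ", paste(alpha, collapse = ", "))
  }
  invisible(labels)
}
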