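# Flatten profiles into one vector matrix with taxon labels per row.
vectorize_profiles <- function(profiles, extended = TRUE) {
  labels <- check_profiles(profiles)
  mats <- lapply(profiles, nv_matrix, extended = extended)
  vectors <- do.call(rbind, mats)
  taxa <- rep(labels, vapply(mats, nrow, integer(1L)))
  list(vectors = vectors, taxa = taxa, labels = labels)
}

#' Nearest-taxon classification of one query vector
#'
#' Assigns the query to the taxon whose vector set contains the nearest
#' vector by Euclidean distance (the minimum over that taxon's sequences,
#' \eqn{D(X, S_k) = \min_{X \ne X_{k\xi}} d_E(X, X_{k\xi})}).  Distance
#' ties between taxa are broken by the lexicographically smallest label.
#' `exclude` removes the query's own row (instance-level exclusion: other
#' identical vectors, even in the same taxon, remain candidates).
#'
#' @param x Query natural vector.
#' @param db List from `vectorize_profiles()`, or a list with `vectors`
#'   (matrix) and `taxa` (row labels).
#' @param exclude Optional row index of the query instance itself.
#' @return The predicted taxon label.
#' @export
classify_query <- function(x, db, exclude = NULL) {
  vectors <- db$vectors
  taxa <- db$taxa
  if (length(x) != ncol(vectors)) {
    stop("dimension mismatch: ", length(x), " vs ", ncol(vectors))
  }
  d <- drop(cross_dist(rbind(x), vectors, "euclidean"))
  if (!is.null(exclude)) d[exclude] <- Inf
  if (all(is.infinite(d))) stop("no candidate vectors after exclusion")
  per_taxon <- tapply(d, taxa, min)
  labs <- sort(names(per_taxon), method = "radix")
  per_taxon <- per_taxon[labs]
  labs[which.min(per_taxon)]  # which.min takes the first = smallest label
}

#' Leave-one-out nearest-neighbor evaluation of a taxon collection
#'
#' Every sequence is queried once against the full collection with its own
#' instance excluded, and the predictions are tallied into per-taxon
#' accuracies, a confusion table, and the "most wrong strain" statistics.
#'
#' @param profiles List of [nv_profile()] (>= 2 taxa).
#' @param extended Use covariance-extended vectors (default `TRUE`).
#' @return An `nv_classification`: list with `per_taxon_accuracy` (named),
#'   `total_accuracy`, `confusion` (true x predicted count matrix),
#'   `taxon_sizes`, `most_wrong` (data frame: taxon, most_wrong,
#'   most_error_rate), and `predictions` (data frame: id, taxon,
#'   predicted).
#' @export
evaluate_all <- function(profiles, extended = TRUE) {
  if (length(profiles) < 2L) stop("need at least 2 taxa")
  db <- vectorize_profiles(profiles, extended = extended)
  labs <- sort(db$labels, method = "radix")
  nseq <- nrow(db$vectors)
  if (nseq < 2L) stop("need at least 2 sequences overall")
  pred <- character(nseq)
  for (i in seq_len(nseq)) {
    pred[i] <- classify_query(db$vectors[i, ], db, exclude = i)
  }
  confusion <- table(factor(db$taxa, levels = labs),
                     factor(pred, levels = labs))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  sizes <- rowSums(confusion)
  per_taxon <- diag(confusion) / sizes
  structure(
    list(
      per_taxon_accuracy = per_taxon,
      total_accuracy = sum(diag(confusion)) / sum(confusion),
      confusion = confusion,
      taxon_sizes = sizes,
      most_wrong = most_error_stats(confusion, sizes),
      predictions = data.frame(id = rownames(db$vectors), taxon = db$taxa,
                               predicted = pred)
    ),
    class = "nv_classification"
  )
}

#' @export
print.nv_classification <- function(x, ...) {
  cat("<nv_classification>\n")
  df <- data.frame(taxon = names(x$per_taxon_accuracy),
                   accuracy = round(x$per_taxon_accuracy, 4))
  print(df, row.names = FALSE)
  cat(sprintf("Total accuracy: %.4f\n", x$total_accuracy))
  invisible(x)
}

#' Most-wrong-strain statistics from a confusion table
#'
#' For each true taxon, the foreign taxon receiving the largest number of
#' its misclassified sequences ("most wrong strain") and that count divided
#' by the taxon's sequence total ("most error rate").  Count ties go to the
#' lexicographically smallest label; a taxon with zero errors reports `NA`
#' and rate 0.
#'
#' @param confusion Square count matrix, rows = true taxa, columns =
#'   predicted taxa, identical dimnames.
#' @param taxon_sizes Named row totals (defaults to `rowSums(confusion)`).
#' @return Data frame with columns `taxon`, `most_wrong`,
#'   `most_error_rate` (a fraction in `[0, 1]`).
#' @examples
#' conf <- matrix(c(112, 0, 6, 0), 2,
#'                dimnames = list(c("MED4", "AS9601"), c("MED4", "AS9601")))
#' most_error_stats(conf)  # MED4 -> AS9601, 6/118
#' @export
most_error_stats <- function(confusion, taxon_sizes = rowSums(confusion)) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  labs <- rownames(confusion)
  ord <- order(colnames(confusion), method = "radix")
  out <- data.frame(taxon = labs, most_wrong = NA_character_,
                    most_error_rate = 0)
  for (i in seq_along(labs)) {
    wrong <- confusion[i, ord]
    wrong <- wrong[names(wrong) != labs[i]]
    if (any(wrong > 0)) {
      j <- which.max(wrong)  # first max = lexicographically smallest label
      out$most_wrong[i] <- names(wrong)[j]
      out$most_error_rate[i] <- wrong[[j]] / taxon_sizes[[labs[i]]]
    }
  }
  out
}

#' Write a classification report as TSV files
#'
#' `<stem>_accuracy.tsv` mirrors a per-strain accuracy table with a final
#' `Total` row; `<stem>_most_wrong.tsv` lists each taxon's most wrong
#' strain and most error rate (percent).
#'
#' @param report An `nv_classification` from [evaluate_all()].
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_classification <- function(report, stem) {
  acc_path <- paste0(stem, "_accuracy.tsv")
  mw_path <- paste0(stem, "_most_wrong.tsv")
  acc <- data.frame(
    taxon = c(names(report$per_taxon_accuracy), "Total"),
    accuracy = sprintf("%.4f", c(report$per_taxon_accuracy,
                                 report$total_accuracy))
  )
  utils::write.table(acc, acc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mw <- report$most_wrong
  mw$most_error_rate <- sprintf("%.2f", 100 * mw$most_error_rate)
  names(mw)[3L] <- "most_error_rate_pct"
  utils::write.table(mw, mw_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(acc_path, mw_path))
}
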