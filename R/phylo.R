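#' Single-linkage agglomerative clustering of a distance matrix
#'
#' Repeatedly merges the two clusters with the smallest single-linkage
#' distance (the minimum over cross-cluster pairs); the merge height is
#' that minimum.  Ties are broken deterministically: among tied pairs the
#' one whose lexicographically smallest member label is smallest wins, then
#' the other cluster's smallest label.  Heights are non-decreasing, the
#' classical single-linkage property (they are the MST edge weights of the
#' distance graph in ascending order).
#'
#' @param dm An `nv_distmat` (or a plain symmetric matrix with dimnames).
#' @return An `nv_dendrogram`: list with `leaves` (labels in input order)
#'   and `merges`, an ordered list of merges, each a list with sorted
#'   member vectors `a`, `b` and the merge `height`.
#' @examples
#' m <- matrix(c(0, 1, 5, 1, 0, 4, 5, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' single_linkage(m)
#' @export
single_linkage <- function(dm) {
  values <- if (inherits(dm, "nv_distmat")) dm$values else as.matrix(dm)
  labels <- rownames(values)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa")
  if (!all(is.finite(values))) stop("non-finite distances")
  # clusters as sorted label vectors; cluster-level distance matrix updated
  # by the single-linkage (minimum) rule
  clusters <- as.list(labels)
  D <- values
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        d <- D[i, j]
        key <- sort(c(clusters[[i]][1L], clusters[[j]][1L]), method = "radix")
        if (d < best_d ||
            (d == best_d && (key[1L] < best_key[1L] ||
                             (key[1L] == best_key[1L] && key[2L] < best_key[2L])))) {
          best_d <- d; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    a <- clusters[[i]]; b <- clusters[[j]]
    if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
    merges[[step]] <- list(a = a, b = b, height = best_d)
    merged <- sort(c(a, b), method = "radix")
    # Lance-Williams single-linkage update: d(new, x) = min(d(a,x), d(b,x))
    newd <- pmin(D[i, ], D[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    clusters <- c(clusters[keep], list(merged))
  }
  structure(list(leaves = labels, merges = merges), class = "nv_dendrogram")
}

#' @export
print.nv_dendrogram <- function(x, ...) {
  cat(sprintf("<nv_dendrogram> %d leaves, %d merges\n",
              length(x$leaves), length(x$merges)))
  for (m in x$merges) {
    cat(sprintf("  {%s} + {%s} @ %.6g\n",
                paste(m$a, collapse = ","), paste(m$b, collapse = ","),
                m$height))
  }
  invisible(x)
}

#' Internal clades of a dendrogram
#'
#' One entry per merge whose leaf set is a proper subset of all leaves
#' (i.e. the root clade is excluded).
#'
#' @param tree An `nv_dendrogram`.
#' @return Named list of sorted leaf-label vectors; names are the labels
#'   joined with `"|"`, values carry a `height` attribute.
#' @export
clades <- function(tree) {
  stopifnot(inherits(tree, "nv_dendrogram"))
  n <- length(tree$leaves)
  out <- list()
  for (m in tree$merges) {
    members <- sort(c(m$a, m$b), method = "radix")
    if (length(members) < n) {
      out[[paste(members, collapse = "|")]] <-
        structure(members, height = m$height)
    }
  }
  out
}

quote_newick <- function(label) {
  if (grepl("[][ ,():;']", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' Serialize a dendrogram to Newick
#'
#' Ultrametric output: each branch length is the parent merge height minus
#' the child's own height (leaves sit at height 0).  Labels containing
#' Newick-unsafe characters are single-quoted.  When `support` is given
#' (named by the `"|"`-joined clade key, as returned by
#' [bootstrap_support()]), support values are written as internal node
#' labels.
#'
#' @param tree An `nv_dendrogram`.
#' @param support Optional named numeric vector of clade support fractions.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by `";"`.
#' @examples
#' m <- matrix(c(0, 1, 5, 1, 0, 4, 5, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(single_linkage(m))  # "((A:1,B:1):3,C:4);"
#' @export
to_newick <- function(tree, support = NULL, digits = 10L) {
  stopifnot(inherits(tree, "nv_dendrogram"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  # grow subtree strings bottom-up, keyed by "|"-joined sorted members
  node_str <- as.list(vapply(tree$leaves, quote_newick, character(1L)))
  names(node_str) <- tree$leaves
  node_h <- stats::setNames(rep(0, length(tree$leaves)), tree$leaves)
  n_all <- length(tree$leaves)
  for (m in tree$merges) {
    ka <- paste(m$a, collapse = "|"); kb <- paste(m$b, collapse = "|")
    members <- sort(c(m$a, m$b), method = "radix")
    key <- paste(members, collapse = "|")
    lab <- ""
    if (!is.null(support) && length(members) < n_all && key %in% names(support)) {
      lab <- fmt(support[[key]])
    }
    node_str[[key]] <- paste0(
      "(", node_str[[ka]], ":", fmt(m$height - node_h[[ka]]),
      ",", node_str[[kb]], ":", fmt(m$height - node_h[[kb]]), ")", lab)
    node_h[[key]] <- m$height
  }
  root_key <- paste(sort(tree$leaves, method = "radix"), collapse = "|")
  paste0(node_str[[root_key]], ";")
}

#' Bootstrap support for the clades of the single-linkage tree
#'
#' Builds the tree from the full data, then resamples, independently within
#' each taxon, its sequences with replacement to the original per-taxon
#' count; each replicate's natural vectors feed the same distance-matrix /
#' single-linkage pipeline.  The support of an original internal clade is
#' the fraction of replicate trees containing an internal clade with the
#' identical leaf set.  Since a sequence's natural vector does not depend
#' on the rest of the data, the per-sequence vectors are computed once and
#' replicates resample rows.
#'
#' @inheritParams pairwise_matrix
#' @param n_replicates Number of bootstrap replicates (>= 1, default 100).
#' @param seed Integer seed (required; resampling is the only randomness).
#' @return An `nv_supported_tree`: list with `dendrogram`, `support` (named
#'   numeric, one entry per internal clade of the original tree),
#'   `n_replicates`.
#' @export
bootstrap_support <- function(profiles, n_replicates = 100L,
                              base_metric = c("euclidean", "manhattan"),
                              set_metric = c("hausdorff", "direct"),
                              extended = TRUE, seed) {
  base_metric <- match.arg(base_metric)
  set_metric <- match.arg(set_metric)
  if (missing(seed)) stop("seed is required for bootstrap_support()")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  labels <- check_profiles(profiles)
  mats <- lapply(profiles, nv_matrix, extended = extended)
  tree <- single_linkage(vecset_matrix(mats, labels, base_metric, set_metric))
  orig <- clades(tree)
  hits <- stats::setNames(numeric(length(orig)), names(orig))
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      rmats <- lapply(mats, function(m) {
        m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE]
      })
      rtree <- single_linkage(
        vecset_matrix(rmats, labels, base_metric, set_metric))
      rkeys <- names(clades(rtree))
      hit <- names(hits) %in% rkeys
      hits[hit] <- hits[hit] + 1
    }
  })
  structure(
    list(dendrogram = tree, support = hits / n_replicates,
         n_replicates = n_replicates),
    class = "nv_supported_tree"
  )
}

#' @export
print.nv_supported_tree <- function(x, ...) {
  cat(sprintf("<nv_supported_tree> %d replicates\n", x$n_replicates))
  for (key in names(x$support)) {
    cat(sprintf("  %-40s %.2f\n", key, x$support[[key]]))
  }
  invisible(x)
}
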