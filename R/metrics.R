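#' Distance between two natural vectors
#'
#' @param u,v Numeric vectors of identical length.
#' @param base_metric `"euclidean"` (default) or `"manhattan"`.
#' @return Non-negative scalar.
#' @export
point_distance <- function(u, v, base_metric = c("euclidean", "manhattan")) {
  base_metric <- match.arg(base_metric)
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  }
  if (base_metric == "euclidean") sqrt(sum((u - v)^2)) else sum(abs(u - v))
}

#' Hausdorff distance between two finite vector sets
#'
#' \deqn{H(X,Y) = \max\{\max_{x \in X} \min_{y \in Y} d(x,y),\;
#'                      \max_{y \in Y} \min_{x \in X} d(x,y)\}}
#' with `d` the chosen base metric.  A true metric on non-empty finite
#' sets: symmetric, zero iff the sets coincide, and satisfying the triangle
#' inequality.
#'
#' @param X,Y Numeric matrices, one point per row (a plain vector is taken
#'   as a single point); both non-empty with equal column count.
#' @inheritParams point_distance
#' @return Non-negative scalar.
#' @examples
#' hausdorff(rbind(0, 3), rbind(1))  # 2
#' @export
hausdorff <- function(X, Y, base_metric = c("euclidean", "manhattan")) {
  base_metric <- match.arg(base_metric)
  X <- rbind(X); Y <- rbind(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("Hausdorff distance needs non-empty sets")
  D <- cross_dist(X, Y, base_metric)
  max(max(apply(D, 1L, min)), max(apply(D, 2L, min)))
}

new_distmat <- function(values, labels, base_metric, set_metric) {
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values,
         base_metric = base_metric, set_metric = set_metric),
    class = "nv_distmat"
  )
}

#' @export
print.nv_distmat <- function(x, ...) {
  cat(sprintf("<nv_distmat> %d taxa; base=%s set=%s\n",
              length(x$labels), x$base_metric, x$set_metric))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.nv_distmat <- function(x, ...) x$values

#' Pairwise distance matrix between taxon profiles
#'
#' Represents every sequence by its natural vector, then compares taxa
#' either as vector *sets* via the Hausdorff distance
#' (`set_metric = "hausdorff"`, the proteome mode) or directly by the base
#' metric between single vectors (`set_metric = "direct"`, the
#' one-sequence-per-taxon rRNA mode).
#'
#' @param profiles List of [nv_profile()] (>= 2, one alphabet).
#' @inheritParams point_distance
#' @param set_metric `"hausdorff"` or `"direct"` (direct requires exactly
#'   one sequence per taxon).
#' @param extended Use the covariance-extended vectors (default `TRUE`).
#' @return An `nv_distmat`: symmetric, zero-diagonal, finite.
#' @export
pairwise_matrix <- function(profiles,
                            base_metric = c("euclidean", "manhattan"),
                            set_metric = c("hausdorff", "direct"),
                            extended = TRUE) {
  base_metric <- match.arg(base_metric)
  set_metric <- match.arg(set_metric)
  labels <- check_profiles(profiles)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  mats <- lapply(profiles, nv_matrix, extended = extended)
  if (set_metric == "direct") {
    nseq <- vapply(mats, nrow, integer(1L))
    if (any(nseq != 1L)) {
      stop("set_metric='direct' requires exactly one sequence per taxon; ",
           "offending taxa: ", paste(labels[nseq != 1L], collapse = ", "))
    }
  }
  vecset_matrix(mats, labels, base_metric, set_metric)
}

# Shared core: Hausdorff (or direct) distances between per-taxon row sets.
vecset_matrix <- function(mats, labels, base_metric, set_metric) {
  n <- length(mats)
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- if (set_metric == "direct") {
        point_distance(mats[[i]][1L, ], mats[[j]][1L, ], base_metric)
      } else {
        hausdorff(mats[[i]], mats[[j]], base_metric)
      }
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  new_distmat(values, labels, base_metric, set_metric)
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm An `nv_distmat`.
#' @param path Output path.
#' @param format `"tsv"` (labeled, header row + `taxon` column) or
#'   `"phylip"` (square PHYLIP).
#' @return `path`, invisibly.
#' @export
write_distmat <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon = dm$labels, dm$values, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$labels)), con)
    for (i in seq_along(dm$labels)) {
      writeLines(paste(c(sprintf("%-10s", dm$labels[i]),
                         format(dm$values[i, ], digits = 10)),
                       collapse = "  "), con)
    }
  }
  invisible(path)
}

#' Read a labeled TSV distance matrix
#'
#' Inverse of [write_distmat()]'s TSV format; used for tree-only runs.
#'
#' @param path TSV path with a `taxon` column and one column per taxon.
#' @param base_metric,set_metric Metadata to attach (defaults `"euclidean"`,
#'   `"hausdorff"`); the values themselves come from the file.
#' @return An `nv_distmat`.
#' @export
read_distmat <- function(path, base_metric = "euclidean",
                         set_metric = "hausdorff") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(values), labels)) {
    stop("distance matrix columns do not match the taxon column")
  }
  rownames(values) <- labels
  if (!isTRUE(all.equal(unname(values), unname(t(values))))) {
    stop("matrix is not symmetric")
  }
  new_distmat(values, labels, base_metric, set_metric)
}
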