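#' Indices of the top-percentile modulus peaks of one instance
#'
#' Computes the \code{p}-quantile of an instance's own modulus distribution
#' (linear interpolation between order statistics, the R default type 7;
#' configurable) and returns the indices of samples strictly above it - the
#' "top 5 percent" intensity peaks when \code{p = 0.95}. If strict selection
#' is empty (a constant series), the indices of the maximal values are
#' returned instead, so the selection is never empty.
#'
#' @param moduli numeric vector, one instance's modulus series.
#' @param p quantile level in (0, 1); default 0.95.
#' @param type quantile convention, passed to [stats::quantile()].
#' @return Integer vector of indices into \code{moduli}.
#' @export
top_percentile_indices <- function(moduli, p = 0.95, type = 7) {
  if (!is.numeric(moduli) || length(moduli) == 0 || !all(is.finite(moduli)))
    stop("'moduli' must be a non-empty finite numeric vector")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("'p' must lie strictly between 0 and 1")
  q <- stats::quantile(moduli, probs = p, type = type, names = FALSE)
  idx <- which(moduli > q)
  if (length(idx) == 0) idx <- which(moduli == max(moduli))
  idx
}

#' Dominant cluster of a recording instance
#'
#' The instance-level prediction: the cluster label occurring most often among
#' the instance's top-percentile samples. Ties break to the lowest cluster
#' label.
#'
#' @param assignments per-sample cluster labels of the instance.
#' @param top_indices indices selected by [top_percentile_indices()].
#' @param p the percentile level used (recorded in the result).
#' @return A list of class \code{"dominant_cluster"}: \code{dominant_cluster},
#'   \code{n_top}, \code{top_fraction}.
#' @export
dominant_cluster <- function(assignments, top_indices, p = 0.95) {
  if (length(top_indices) == 0) stop("'top_indices' must be non-empty")
  if (any(top_indices < 1) || any(top_indices > length(assignments)))
    stop("'top_indices' out of range")
  top <- assignments[top_indices]
  counts <- table(top)
  lab <- names(counts)[counts == max(counts)]
  # lowest label on ties; labels may be numeric-like or arbitrary
  num <- suppressWarnings(as.numeric(lab))
  dom <- if (!anyNA(num)) lab[which.min(num)] else sort(lab)[1]
  dom <- if (is.numeric(assignments)) as.numeric(dom) else dom
  structure(list(dominant_cluster = dom, n_top = length(top_indices),
                 top_fraction = p),
            class = "dominant_cluster")
}

.permutations <- function(v) {
  n <- length(v)
  if (n <= 1) return(list(v))
  out <- list()
  for (i in seq_len(n))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Accuracy-maximising mapping of cluster labels to clinical scores
#'
#' Unsupervised clusters carry arbitrary labels; this searches all one-to-one
#' assignments of the observed cluster labels onto the observed true scores
#' and keeps the one with the highest accuracy (exhaustive permutation
#' mapping; the label counts here make k! enumeration trivial). Ties break to
#' the lexicographically smallest mapped-score sequence over the sorted
#' cluster labels, so the result is deterministic.
#'
#' @param predicted per-instance dominant cluster labels.
#' @param truth per-instance true scores, same length.
#' @return A list of class \code{"label_mapping"}: \code{clusters} (sorted
#'   distinct cluster labels), \code{permutation} (named vector, cluster ->
#'   score), \code{mapped} (per-instance mapped scores) and
#'   \code{mapped_accuracy}.
#' @export
map_labels_by_permutation <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length")
  if (length(predicted) == 0) stop("empty input")
  clusters <- sort(unique(predicted))
  scores <- sort(unique(truth))
  if (length(clusters) > length(scores))
    stop("more distinct clusters (", length(clusters),
         ") than distinct true scores (", length(scores), ")")
  k <- length(clusters)
  best <- NULL
  for (perm in .permutations(scores)) {
    map <- perm[seq_len(k)]
    key <- paste(map, collapse = ",")
    if (!is.null(best) && key %in% best$seen) next
    mapped <- map[match(predicted, clusters)]
    acc <- mean(mapped == truth)
    if (is.null(best)) {
      best <- list(map = map, acc = acc, seen = key)
    } else {
      best$seen <- c(best$seen, key)
      # strict improvement only: enumeration order is lexicographic, so the
      # first optimum encountered is the lexicographically smallest
      if (acc > best$acc) {
        best$map <- map
        best$acc <- acc
      }
    }
  }
  mapped <- best$map[match(predicted, clusters)]
  structure(list(clusters = clusters,
                 permutation = stats::setNames(best$map, clusters),
                 mapped = mapped,
                 mapped_accuracy = best$acc),
            class = "label_mapping")
}

#' @export
print.label_mapping <- function(x, ...) {
  cat("Cluster-to-score permutation mapping (accuracy-maximising)\n")
  for (i in seq_along(x$clusters))
    cat("  cluster ", x$clusters[i], " -> score ", x$permutation[i], "\n",
        sep = "")
  cat("Mapped accuracy: ", sprintf("%.3f", x$mapped_accuracy), "\n", sep = "")
  invisible(x)
}
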