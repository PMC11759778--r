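#' @export
print.kmeans1d <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("1-D k-means fit (", if (x$init == "dp") "dynamic-programming optimum"
      else paste0(x$init, " init, ", x$n_restarts, " restart",
                  if (x$n_restarts > 1) "s"), ")\n", sep = "")
  cat("k = ", x$k, ", n = ", length(x$x), ", SSE = ",
      format(x$sse, digits = digits), "\n", sep = "")
  cat("Centroids (ascending):\n")
  print(signif(x$centroids, digits))
  cat("Cluster sizes: ", paste(x$size, collapse = ", "), "\n", sep = "")
  if (!x$converged) cat("Warning: fit did not converge\n")
  invisible(x)
}

#' @export
summary.kmeans1d <- function(object, ...) {
  within_sse <- vapply(seq_len(object$k), function(u) {
    sum((object$x[object$cluster == u] - object$centroids[u])^2)
  }, numeric(1))
  out <- list(
    k = object$k,
    n = length(object$x),
    centroids = object$centroids,
    size = object$size,
    within_sse = within_sse,
    sse = object$sse,
    total_ss = sum((object$x - mean(object$x))^2),
    n_iter = object$n_iter,
    converged = object$converged
  )
  class(out) <- "summary.kmeans1d"
  out
}

#' @export
print.summary.kmeans1d <- function(x, digits = 4, ...) {
  cat("1-D k-means: k =", x$k, " n =", x$n, "\n")
  tab <- data.frame(
    cluster = seq_len(x$k),
    centroid = signif(x$centroids, digits),
    size = x$size,
    within_sse = signif(x$within_sse, digits)
  )
  print(tab, row.names = FALSE)
  cat("Total SSE:", format(x$sse, digits = digits),
      " (between-SS fraction:",
      format(1 - x$sse / x$total_ss, digits = digits), ")\n")
  invisible(x)
}

#' Model coefficients of a 1-D k-means fit
#'
#' @param object a \code{"kmeans1d"} fit.
#' @param ... unused.
#' @return Named numeric vector of cluster centroids in ascending order.
#' @export
coef.kmeans1d <- function(object, ...) {
  stats::setNames(object$centroids, paste0("cluster", seq_len(object$k)))
}

#' Assign new values to the nearest fitted cluster
#'
#' @param object a \code{"kmeans1d"} fit.
#' @param newdata numeric vector; defaults to the training data.
#' @param ... unused.
#' @return Integer cluster indices in \code{1:k}; nearest-centroid ties break
#'   to the lowest index.
#' @export
predict.kmeans1d <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cluster)
  if (!is.numeric(newdata) || !all(is.finite(newdata)))
    stop("'newdata' must be numeric and finite")
  .assign_nearest(as.numeric(newdata), object$centroids)
}

#' @export
fitted.kmeans1d <- function(object, ...) {
  object$centroids[object$cluster]
}

#' @export
residuals.kmeans1d <- function(object, ...) {
  object$x - fitted(object)
}

#' Histogram of the clustered data with centroid positions
#'
#' @param x a \code{"kmeans1d"} fit.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments to [graphics::hist()].
#' @export
plot.kmeans1d <- function(x, breaks = 50, ...) {
  graphics::hist(x$x, breaks = breaks, main = "1-D k-means fit",
                 xlab = "value", ...)
  graphics::abline(v = x$centroids, col = seq_len(x$k) + 1, lwd = 2)
  graphics::legend("topright", legend = paste0("cluster ", seq_len(x$k)),
                   col = seq_len(x$k) + 1, lwd = 2, bty = "n")
  invisible(x)
}
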