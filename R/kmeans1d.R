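#' One-dimensional k-means clustering of movement-intensity moduli
#'
#' Fits the k-means model to a one-dimensional dataset with k-means++ (or
#' random) initialisation and multiple restarts, keeping the solution with the
#' lowest within-cluster sum of squared distances (SSE). Each restart runs the
#' two-phase scheme of the standard implementations: batch Lloyd iterations to
#' convergence, then an online phase of single-point reassignments using exact
#' size-weighted SSE deltas until no move improves the objective. On scalar
#' data the Euclidean distance reduces to the absolute difference; squared
#' differences are used throughout so the objective matches the SSE exactly.
#'
#' Clusters in the returned object are relabelled so that cluster 1 has the
#' smallest centroid; with modulus data cluster 1 is therefore always the
#' lowest-intensity group. Nearest-centroid ties during assignment break to the
#' lowest cluster index, and a cluster emptied during an update is re-seeded
#' with the data point currently farthest from its assigned centroid, so the
#' requested \code{k} is always realised.
#'
#' @param x numeric vector of finite values (e.g. pooled moduli, in g).
#' @param k number of clusters; must not exceed the number of distinct values.
#' @param init initialisation: \code{"kpp"} (k-means++, the default) or
#'   \code{"random"} (k distinct data points drawn uniformly).
#' @param n_restarts number of independent initialisations; the best fit by SSE
#'   is returned.
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param max_iter iteration cap per restart; if no restart converges the best
#'   result is returned with \code{converged = FALSE} and a warning.
#' @param seed optional integer; when given, the fit is reproducible and the
#'   caller's RNG state is left untouched.
#'
#' @return An object of class \code{"kmeans1d"}: a list with components
#'   \code{centroids} (ascending), \code{cluster} (integer assignments in
#'   \code{1:k} aligned to \code{x}), \code{k}, \code{sse}, \code{size}
#'   (cluster sizes), \code{n_iter}, \code{converged}, and \code{x} (the data,
#'   retained for the methods).
#'
#' @seealso [kmeans1d_dp()] for the globally optimal solution, and the
#'   [predict.kmeans1d()], [coef.kmeans1d()], [fitted.kmeans1d()],
#'   [residuals.kmeans1d()] and [plot.kmeans1d()] methods.
#' @examples
#' fit <- kmeans1d(c(rnorm(50, 0), rnorm(50, 10)), k = 2, seed = 1)
#' coef(fit)
#' predict(fit, c(-1, 11))
#' @export
kmeans1d <- function(x, k, init = c("kpp", "random"), n_restarts = 10,
                     tol = 1e-8, max_iter = 300, seed = NULL) {
  init <- match.arg(init)
  if (!is.numeric(x) || length(x) == 0 || !all(is.finite(x)))
    stop("'x' must be a non-empty numeric vector of finite values")
  x <- as.numeric(x)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  k <- as.integer(k)
  n_distinct <- length(unique(x))
  if (k > n_distinct)
    stop("'k' (", k, ") exceeds the number of distinct values (", n_distinct, ")")
  if (n_restarts < 1) stop("'n_restarts' must be >= 1")

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- if (init == "kpp") .init_kpp(x, k) else .init_random(x, k)
    run <- .lloyd(x, centers, tol = tol, max_iter = max_iter)
    run <- .online_phase(x, run)
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  if (!best$converged)
    warning("k-means did not converge in ", max_iter, " iterations on any restart")

  # canonical labels: ascending centroid order
  ord <- order(best$centers)
  centroids <- best$centers[ord]
  cluster <- match(best$cluster, ord)

  structure(list(
    centroids = centroids,
    cluster = cluster,
    k = k,
    sse = best$sse,
    size = tabulate(cluster, nbins = k),
    n_iter = best$n_iter,
    converged = best$converged,
    init = init,
    n_restarts = n_restarts,
    x = x
  ), class = "kmeans1d")
}

# nearest-centroid assignment; ties go to the lowest cluster index
.assign_nearest <- function(x, centers) {
  d2 <- vapply(centers, function(m) (x - m)^2, numeric(length(x)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = length(x))
  max.col(-d2, ties.method = "first")
}

# greedy k-means++: each new centre is the best (by resulting potential) of
# several D^2-weighted candidate draws, as in mainstream implementations
.init_kpp <- function(x, k) {
  n <- length(x)
  n_cand <- 2L + as.integer(ceiling(log(max(k, 2))))
  centers <- numeric(k)
  centers[1] <- x[sample.int(n, 1L)]
  if (k > 1) {
    d2 <- (x - centers[1])^2
    for (u in 2:k) {
      # all-zero weights impossible while k <= number of distinct values
      cand <- x[sample.int(n, n_cand, replace = TRUE, prob = d2)]
      pot <- vapply(cand, function(cc) sum(pmin(d2, (x - cc)^2)), numeric(1))
      centers[u] <- cand[which.min(pot)]
      d2 <- pmin(d2, (x - centers[u])^2)
    }
  }
  centers
}

.init_random <- function(x, k) {
  ux <- unique(x)
  ux[sample.int(length(ux), k)]
}

# Lloyd iterations; SSE is checked to be non-increasing at every step
.lloyd <- function(x, centers, tol, max_iter) {
  k <- length(centers)
  cl <- .assign_nearest(x, centers)
  sse <- sum((x - centers[cl])^2)
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    new_centers <- vapply(seq_len(k), function(u) {
      if (any(cl == u)) mean(x[cl == u]) else NA_real_
    }, numeric(1))
    empty <- which(is.na(new_centers))
    if (length(empty)) {
      # re-seed each empty cluster with the point farthest from its centroid
      d2 <- (x - new_centers[cl])^2
      for (u in empty) {
        far <- which.max(d2)
        new_centers[u] <- x[far]
        d2[far] <- -Inf
      }
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    new_cl <- .assign_nearest(x, centers)
    new_sse <- sum((x - centers[new_cl])^2)
    if (new_sse > sse + 1e-8 * (1 + sse))
      stop("internal error: SSE increased during Lloyd iteration")
    unchanged <- all(new_cl == cl)
    cl <- new_cl
    sse <- new_sse
    if (unchanged || shift < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  list(centers = centers, cluster = cl, sse = sse, n_iter = it,
       converged = converged)
}

# online refinement phase, as in the two-phase batch+online scheme of the
# standard implementations (MATLAB's kmeans, Hartigan-Wong): single-point
# reassignments that strictly decrease the total SSE, using the exact
# size-weighted deltas, until no improving move remains
.online_phase <- function(x, run, max_moves = NULL) {
  k <- length(run$centers)
  if (k == 1) return(run)
  cl <- run$cluster
  size <- tabulate(cl, nbins = k)
  centers <- run$centers
  sse <- run$sse
  if (is.null(max_moves)) max_moves <- 100L * k
  for (mv in seq_len(max_moves)) {
    # removal gain of each point from its own cluster (size-weighted)
    na <- size[cl]
    gain <- ifelse(na > 1, na / (na - 1) * (x - centers[cl])^2, -Inf)
    # insertion cost into every other cluster; best net improvement per point
    best_delta <- rep(Inf, length(x))
    best_to <- integer(length(x))
    for (b in seq_len(k)) {
      cost_b <- size[b] / (size[b] + 1) * (x - centers[b])^2
      delta <- cost_b - gain
      delta[cl == b] <- Inf
      upd <- delta < best_delta
      best_delta[upd] <- delta[upd]
      best_to[upd] <- b
    }
    i <- which.min(best_delta)
    if (best_delta[i] >= -1e-12 * (1 + sse)) break
    a <- cl[i]; b <- best_to[i]
    centers[a] <- (centers[a] * size[a] - x[i]) / (size[a] - 1)
    centers[b] <- (centers[b] * size[b] + x[i]) / (size[b] + 1)
    size[a] <- size[a] - 1L
    size[b] <- size[b] + 1L
    cl[i] <- b
    sse <- sse + best_delta[i]
  }
  # recompute exactly to shed accumulated float error
  centers <- vapply(seq_len(k), function(u) mean(x[cl == u]), numeric(1))
  list(centers = centers, cluster = cl,
       sse = sum((x - centers[cl])^2),
       n_iter = run$n_iter, converged = run$converged)
}

#' Globally optimal 1-D k-means by dynamic programming
#'
#' Computes the clustering that minimises the within-cluster SSE exactly,
#' exploiting the fact that optimal one-dimensional k-means clusters are
#' contiguous intervals in sorted order. Dynamic programming over the sorted
#' breakpoints runs in O(k n^2) time, which is ample at the problem sizes this
#' package works at. Intended as the exact reference against which the
#' heuristic [kmeans1d()] fit is judged.
#'
#' @inheritParams kmeans1d
#' @return A \code{"kmeans1d"} object (see [kmeans1d()]); \code{n_iter} is
#'   \code{NA} and \code{converged} is \code{TRUE}. Clusters are labelled in
#'   ascending centroid order.
#' @examples
#' kmeans1d_dp(c(1, 2, 100), k = 2)$centroids
#' @export
kmeans1d_dp <- function(x, k) {
  if (!is.numeric(x) || length(x) == 0 || !all(is.finite(x)))
    stop("'x' must be a non-empty numeric vector of finite values")
  x <- as.numeric(x)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  k <- as.integer(k)
  n <- length(x)
  if (k > length(unique(x)))
    stop("'k' (", k, ") exceeds the number of distinct values (",
         length(unique(x)), ")")

  ord <- order(x)
  xs <- x[ord]
  s1 <- c(0, cumsum(xs))
  s2 <- c(0, cumsum(xs^2))
  # SSE of the sorted segment (i..j), 1-based inclusive
  seg_cost <- function(i, j) {
    s <- s1[j + 1] - s1[i]
    q <- s2[j + 1] - s2[i]
    max(0, q - s^2 / (j - i + 1))
  }

  cost <- matrix(Inf, nrow = k, ncol = n)
  from <- matrix(NA_integer_, nrow = k, ncol = n)
  for (j in seq_len(n)) cost[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (u in 2:k) {
      for (j in u:n) {
        # last cluster is (i..j); previous u-1 clusters cover (1..i-1)
        cand <- vapply(u:j, function(i) cost[u - 1, i - 1] + seg_cost(i, j),
                       numeric(1))
        b <- which.min(cand)
        cost[u, j] <- cand[b]
        from[u, j] <- (u:j)[b]
      }
    }
  }

  # backtrack cluster boundaries in sorted order
  cl_sorted <- integer(n)
  j <- n
  for (u in k:1) {
    i <- if (u == 1) 1L else from[u, j]
    cl_sorted[i:j] <- u
    j <- i - 1L
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centroids <- vapply(seq_len(k), function(u) mean(x[cluster == u]), numeric(1))

  structure(list(
    centroids = centroids,
    cluster = cluster,
    k = k,
    sse = cost[k, n],
    size = tabulate(cluster, nbins = k),
    n_iter = NA_integer_,
    converged = TRUE,
    init = "dp",
    n_restarts = 1L,
    x = x
  ), class = "kmeans1d")
}

#' Pool recording instances into a single clustering dataset
#'
#' Concatenates the modulus series of all recording instances into one long
#' vector while keeping per-sample provenance, the form the clustering stage
#' consumes.
#'
#' @param instances list of [recording_instance()] objects.
#' @return A data frame with columns \code{instance_id}, \code{j} (sample index
#'   within the instance) and \code{modulus}.
#' @export
pool_instances <- function(instances) {
  if (!is.list(instances) || length(instances) == 0)
    stop("'instances' must be a non-empty list of recording instances")
  ok <- vapply(instances, inherits, logical(1), what = "recording_instance")
  if (!all(ok)) stop("all elements must be 'recording_instance' objects")
  ids <- vapply(instances, function(z) z$instance_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate instance ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  n <- vapply(instances, function(z) length(z$moduli), integer(1))
  data.frame(
    instance_id = rep(ids, n),
    j = unlist(lapply(n, seq_len), use.names = FALSE),
    modulus = unlist(lapply(instances, function(z) z$moduli), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
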