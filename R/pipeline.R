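#' Specification of a classification task
#'
#' The three evaluation tasks the pipeline supports:
#' \itemize{
#'   \item Task 1 - tremor vs non-tremor: all instances (PD and HC), k = 2,
#'     true scores binarised to tremor (>0) vs none.
#'   \item Task 2 - multiclass severity: PD instances only, k = number of
#'     distinct observed severity scores, scores kept as-is.
#'   \item Task 3 - moderate vs milder tremor: PD instances only, k = 2,
#'     scores binarised (1 and 2 together vs 3).
#' }
#'
#' @param task integer 1, 2 or 3.
#' @return List with \code{task}, \code{groups}, \code{k} (NA for task 2,
#'   resolved at fit time), \code{positive} (positive class for the binary
#'   tasks) and \code{transform} (label transform function).
#' @export
task_spec <- function(task) {
  if (!task %in% 1:3) stop("'task' must be 1, 2 or 3")
  switch(as.character(task),
    "1" = list(task = 1L, groups = c("PD", "HC"), k = 2L, positive = 1,
               transform = function(s) as.integer(s > 0)),
    "2" = list(task = 2L, groups = "PD", k = NA_integer_, positive = NA,
               transform = identity),
    "3" = list(task = 3L, groups = "PD", k = 2L, positive = 2,
               transform = function(s) ifelse(s >= 3, 2L, 1L)))
}

#' Run one unsupervised classification task end-to-end
#'
#' Executes the full pipeline on preprocessed recording instances: pool all
#' moduli, fit the 1-D k-means model, reduce each instance to the dominant
#' cluster of its top-percentile intensity peaks, map cluster labels onto the
#' clinical scores by exhaustive permutation, and evaluate against the true
#' labels. Fully reproducible under a fixed \code{seed}.
#'
#' @param instances list of [recording_instance()] objects (e.g. from
#'   [preprocess_cohort()]).
#' @param task task number, see [task_spec()].
#' @param p top-percentile level for the instance-level reduction.
#' @param seed seed for the k-means restarts.
#' @param exclude_hc_from_fit task 1 only: fit the clustering on PD moduli and
#'   assign HC samples to the fitted centroids afterwards, instead of pooling
#'   both groups into the fit (the default).
#' @param ... further arguments passed to [kmeans1d()] (\code{init},
#'   \code{n_restarts}, \code{tol}, \code{max_iter}).
#' @return An object of class \code{"tremor_task"}: the task spec, the
#'   \code{"kmeans1d"} fit, per-instance dominant clusters, the
#'   \code{"label_mapping"}, the \code{"tremor_eval"} report, and - for the
#'   binary tasks - \code{binary} metrics for the task's positive class.
#' @export
run_task <- function(instances, task = 1, p = 0.95, seed = 1L,
                     exclude_hc_from_fit = FALSE, ...) {
  spec <- task_spec(task)
  ok <- vapply(instances, inherits, logical(1), "recording_instance")
  if (!all(ok)) stop("'instances' must be recording_instance objects")
  groups <- vapply(instances, function(z) z$group, character(1))
  use <- instances[groups %in% spec$groups]
  if (length(use) == 0)
    stop("no instances in group(s): ", paste(spec$groups, collapse = ", "))
  scores <- vapply(use, function(z) z$true_score, integer(1))
  labels <- spec$transform(scores)
  k <- if (is.na(spec$k)) length(unique(labels)) else spec$k
  if (length(use) < k)
    stop("configuration error: ", length(use), " instances but k = ", k)

  pooled <- pool_instances(use)
  if (spec$task == 1L && exclude_hc_from_fit) {
    pd_ids <- vapply(use[vapply(use, function(z) z$group, character(1)) == "PD"],
                     function(z) z$instance_id, character(1))
    fit <- kmeans1d(pooled$modulus[pooled$instance_id %in% pd_ids], k,
                    seed = seed, ...)
    assignments <- predict(fit, pooled$modulus)
  } else {
    fit <- kmeans1d(pooled$modulus, k, seed = seed, ...)
    assignments <- fit$cluster
  }

  ids <- vapply(use, function(z) z$instance_id, character(1))
  dom <- integer(length(use))
  n_top <- integer(length(use))
  offset <- 0L
  for (i in seq_along(use)) {
    m <- use[[i]]$moduli
    top <- top_percentile_indices(m, p = p)
    dc <- dominant_cluster(assignments[offset + seq_along(m)], top, p = p)
    dom[i] <- dc$dominant_cluster
    n_top[i] <- dc$n_top
    offset <- offset + length(m)
  }

  mapping <- map_labels_by_permutation(dom, labels)
  classes <- sort(unique(labels))
  conf <- confusion_matrix(labels, mapping$mapped, classes)
  report <- multiclass_metrics(conf, task = spec$task)
  binary <- if (!is.na(spec$positive) && length(classes) == 2)
    binary_metrics(conf, positive = spec$positive) else NULL

  structure(list(
    task = spec$task,
    spec = spec,
    k = k,
    fit = fit,
    instances = data.frame(instance_id = ids,
                           group = vapply(use, function(z) z$group, character(1)),
                           true_score = scores,
                           label = labels,
                           dominant_cluster = dom,
                           mapped = mapping$mapped,
                           n_top = n_top,
                           stringsAsFactors = FALSE),
    mapping = mapping,
    report = report,
    binary = binary,
    params = list(p = p, seed = seed,
                  exclude_hc_from_fit = exclude_hc_from_fit)
  ), class = "tremor_task")
}

#' @export
print.tremor_task <- function(x, digits = 2, ...) {
  cat("Unsupervised tremor classification - task ", x$task, "\n", sep = "")
  cat(nrow(x$instances), " instances, k = ", x$k, ", SSE = ",
      format(x$fit$sse, digits = 4), "\n", sep = "")
  print(x$report, digits = digits)
  if (!is.null(x$binary))
    cat("Positive class ", x$spec$positive, ": precision ",
        sprintf("%.*f", digits, x$binary$precision), ", recall ",
        sprintf("%.*f", digits, x$binary$recall), ", F1 ",
        sprintf("%.*f", digits, x$binary$f1), "\n", sep = "")
  invisible(x)
}

#' Evaluate the packaged per-instance reference tables
#'
#' Re-derives every published performance number from the packaged
#' per-instance tables (see [load_fixture()]): for each task it applies the
#' exhaustive permutation mapping to the table's predominant-cluster column
#' against its true scores, builds the confusion matrix and computes accuracy,
#' precision, recall and F1 (macro-averaged for the multiclass task). The
#' result is a compact per-task summary of the kind usually reported for
#' these three tasks.
#'
#' @return An object of class \code{"reference_evaluation"}: per-task
#'   \code{"tremor_eval"} reports (with binary metrics where applicable), the
#'   label mappings, and a \code{summary} data frame with one row per task.
#' @export
reference_evaluation <- function() {
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")

  m1 <- map_labels_by_permutation(t2$predominant_cluster, t2$true_score)
  c1 <- confusion_matrix(t2$true_score, m1$mapped, classes = c(0, 1))
  r1 <- multiclass_metrics(c1, task = 1)
  b1 <- binary_metrics(c1, positive = 1)

  m2 <- map_labels_by_permutation(t3$predominant_cluster, t3$true_score)
  c2 <- confusion_matrix(t3$true_score, m2$mapped, classes = 1:3)
  r2 <- multiclass_metrics(c2, task = 2)

  m3 <- map_labels_by_permutation(t4$predominant_cluster, t4$true_score)
  c3 <- confusion_matrix(t4$true_score, m3$mapped, classes = 1:2)
  r3 <- multiclass_metrics(c3, task = 3)
  b3 <- binary_metrics(c3, positive = 2)

  summary <- data.frame(
    task = 1:3,
    accuracy = c(r1$accuracy, r2$accuracy, r3$accuracy),
    precision = c(b1$precision, r2$macro[["precision"]], b3$precision),
    recall = c(b1$recall, r2$macro[["recall"]], b3$recall),
    f1 = c(b1$f1, r2$macro[["f1"]], b3$f1))

  structure(list(
    task1 = list(report = r1, binary = b1, mapping = m1),
    task2 = list(report = r2, mapping = m2),
    task3 = list(report = r3, binary = b3, mapping = m3),
    summary = summary
  ), class = "reference_evaluation")
}

#' @export
print.reference_evaluation <- function(x, digits = 2, ...) {
  cat("Performance across tasks (from the packaged reference tables)\n")
  s <- x$summary
  s[-1] <- round(s[-1], digits)
  names(s) <- c("Task", "Accuracy", "Precision", "Recall", "F1")
  print(s, row.names = FALSE)
  cat("(Task 1: tremor vs non-tremor, 25 instances; Task 2: multiclass",
      "severity,\n 14 PD instances, macro-averaged; Task 3: moderate vs",
      "milder tremor.)\n")
  invisible(x)
}
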