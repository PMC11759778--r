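#' Extract and concatenate rest-period samples from a recording
#'
#' Selects the samples whose timestamps fall inside any annotation interval
#' carrying a rest label and concatenates them in temporal order into a single
#' stream (the "recording instance"). Intervals are treated as half-open
#' \code{[start, end)} so adjacent intervals never double-count a sample, and
#' annotation intervals are non-overlapping by construction.
#'
#' @param recording a [triaxial_recording()].
#' @param annotations data frame with columns \code{label}, \code{start},
#'   \code{end} (see [read_annotations()]).
#' @param rest_labels character vector of labels that constitute a resting
#'   state; which labels these are is cohort-specific configuration.
#' @return Data frame of the selected samples (columns \code{t}, \code{x},
#'   \code{y}, \code{z}).
#' @section Errors: if no rest-labelled interval overlaps the recording the
#'   instance is unusable and an error of class
#'   \code{"tremorclust_empty_instance"} is signalled, mirroring how such
#'   subjects must be excluded from a cohort.
#' @export
extract_rest_segments <- function(recording, annotations, rest_labels) {
  stopifnot(inherits(recording, "triaxial_recording"))
  validate_annotations(annotations)
  if (!is.character(rest_labels) || length(rest_labels) == 0)
    stop("'rest_labels' must be a non-empty character vector")
  rest <- annotations[annotations$label %in% rest_labels, , drop = FALSE]
  t <- recording$data$t
  keep <- rep(FALSE, length(t))
  if (nrow(rest)) {
    rest <- rest[order(rest$start), , drop = FALSE]
    for (i in seq_len(nrow(rest)))
      keep <- keep | (t >= rest$start[i] & t < rest$end[i])
  }
  if (!any(keep)) {
    cond <- structure(
      class = c("tremorclust_empty_instance", "error", "condition"),
      list(message = paste0("no rest-labelled samples in instance '",
                            recording$instance_id,
                            "'; the instance must be excluded"),
           call = sys.call(-1)))
    stop(cond)
  }
  recording$data[keep, , drop = FALSE]
}

#' Mean-center triaxial samples
#'
#' Subtracts the per-axis arithmetic mean computed over the whole sample
#' sequence, moving the origin of the coordinate frame to the average point.
#' This removes the constant gravity/orientation component and any constant
#' sensor bias, leaving only the dynamic movement.
#'
#' @param samples data frame with numeric columns \code{x}, \code{y}, \code{z}
#'   (a column \code{t}, if present, is carried through unchanged).
#' @return The same data frame with centered axes; the per-axis means that
#'   were removed are attached as attribute \code{"axis_means"}.
#' @export
mean_center <- function(samples) {
  if (!is.data.frame(samples) || !all(c("x", "y", "z") %in% names(samples)))
    stop("'samples' must be a data frame with columns x, y, z")
  if (nrow(samples) == 0) stop("cannot center an empty sample sequence")
  mu <- c(x = mean(samples$x), y = mean(samples$y), z = mean(samples$z))
  samples$x <- samples$x - mu[["x"]]
  samples$y <- samples$y - mu[["y"]]
  samples$z <- samples$z - mu[["z"]]
  attr(samples, "axis_means") <- mu
  samples
}

#' Movement-intensity modulus (signal vector magnitude)
#'
#' Reduces each centered triaxial sample to its Euclidean norm
#' \eqn{\sqrt{x^2 + y^2 + z^2}}, a scalar, orientation-invariant measure of
#' movement intensity.
#'
#' @param segment data frame of (centered) samples with columns \code{x},
#'   \code{y}, \code{z}.
#' @return Non-negative numeric vector, one modulus per sample.
#' @export
modulus <- function(segment) {
  if (!is.data.frame(segment) || !all(c("x", "y", "z") %in% names(segment)))
    stop("'segment' must be a data frame with columns x, y, z")
  sqrt(segment$x^2 + segment$y^2 + segment$z^2)
}

#' Full preprocessing of one recording into a recording instance
#'
#' Composes rest-segment extraction, mean-centering and the modulus reduction.
#' Centering is computed over the concatenated rest samples of the instance,
#' not per segment, so a single constant offset is removed per instance.
#'
#' @inheritParams extract_rest_segments
#' @param group,true_score instance metadata (see [recording_instance()]).
#' @return A [recording_instance()].
#' @export
preprocess_recording <- function(recording, annotations, rest_labels,
                                 group, true_score) {
  seg <- extract_rest_segments(recording, annotations, rest_labels)
  recording_instance(recording$instance_id, group, true_score,
                     modulus(mean_center(seg)))
}
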