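#' Triaxial accelerometer recording
#'
#' Constructs and validates a triaxial recording: a uniformly sampled stream of
#' acceleration samples (in g) with timestamps in seconds from recording start.
#'
#' @param instance_id character scalar identifying the recording instance.
#' @param data data frame with numeric columns \code{t}, \code{x}, \code{y},
#'   \code{z}; timestamps must be strictly increasing and uniformly spaced
#'   within 1% of the nominal sampling interval.
#' @param sampling_rate sampling frequency in Hz; if \code{NULL} it is inferred
#'   from the median inter-sample spacing.
#' @return An object of class \code{"triaxial_recording"}.
#' @export
triaxial_recording <- function(instance_id, data, sampling_rate = NULL) {
  if (!is.character(instance_id) || length(instance_id) != 1 || is.na(instance_id))
    stop("'instance_id' must be a single character string")
  req <- c("t", "x", "y", "z")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("'data' must be a data frame with columns t, x, y, z")
  data <- data[req]
  for (cn in req) {
    if (!is.numeric(data[[cn]]))
      stop("column '", cn, "' is not numeric")
    bad <- which(!is.finite(data[[cn]]))
    if (length(bad))
      stop("non-finite value in column '", cn, "' at row ", bad[1])
  }
  if (nrow(data) < 2) stop("a recording needs at least 2 samples")
  dt <- diff(data$t)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("timestamps not strictly increasing at row ", bad[1] + 1)
  med_dt <- stats::median(dt)
  if (is.null(sampling_rate)) sampling_rate <- 1 / med_dt
  nominal <- 1 / sampling_rate
  off <- which(abs(dt - nominal) > 0.01 * nominal)
  if (length(off))
    stop("non-uniform sampling at row ", off[1] + 1,
         " (interval ", signif(dt[off[1]], 6), " s, nominal ",
         signif(nominal, 6), " s)")
  structure(list(instance_id = instance_id,
                 sampling_rate = sampling_rate,
                 data = data),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat("Triaxial recording '", x$instance_id, "': ", nrow(x$data),
      " samples @ ", signif(x$sampling_rate, 6), " Hz (",
      signif(max(x$data$t) - min(x$data$t), 4), " s)\n", sep = "")
  invisible(x)
}

#' Recording instance: concatenated rest-period moduli of one subject-limb
#'
#' @param instance_id character scalar.
#' @param group \code{"PD"} or \code{"HC"}; healthy controls must carry a true
#'   score of 0.
#' @param true_score clinician-assigned MDS-UPDRS 3.17 rest-tremor score, 0-4.
#' @param moduli non-empty numeric vector of non-negative movement-intensity
#'   moduli (g).
#' @return An object of class \code{"recording_instance"}.
#' @export
recording_instance <- function(instance_id, group, true_score, moduli) {
  if (!is.character(instance_id) || length(instance_id) != 1)
    stop("'instance_id' must be a single character string")
  if (!group %in% c("PD", "HC")) stop("'group' must be 'PD' or 'HC'")
  if (!is.numeric(true_score) || length(true_score) != 1 ||
      !true_score %in% 0:4)
    stop("'true_score' must be an integer in 0..4")
  if (group == "HC" && true_score != 0)
    stop("healthy controls must have true_score 0")
  if (!is.numeric(moduli) || length(moduli) == 0 || !all(is.finite(moduli)))
    stop("'moduli' must be a non-empty finite numeric vector")
  if (any(moduli < 0)) stop("moduli must be non-negative")
  structure(list(instance_id = instance_id, group = group,
                 true_score = as.integer(true_score),
                 moduli = as.numeric(moduli)),
            class = "recording_instance")
}

#' @export
print.recording_instance <- function(x, ...) {
  cat("Recording instance '", x$instance_id, "' (", x$group,
      ", score ", x$true_score, "): n_i = ", length(x$moduli),
      ", peak modulus ", signif(max(x$moduli), 4), " g\n", sep = "")
  invisible(x)
}

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " '", path, "' lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read an accelerometer CSV into a triaxial recording
#'
#' Expects columns \code{t_s}, \code{ax_g}, \code{ay_g}, \code{az_g} (seconds
#' and g). The sampling rate is inferred from the median inter-sample spacing.
#'
#' @param path path to the CSV file.
#' @param instance_id identifier for the recording; defaults to the file name
#'   without extension.
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, instance_id = NULL) {
  df <- .read_csv_checked(path, c("t_s", "ax_g", "ay_g", "az_g"),
                          "accelerometer CSV")
  for (cn in c("t_s", "ax_g", "ay_g", "az_g")) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))
      stop("non-numeric cell in column '", cn, "' of '", path,
           "' at data row ", if (length(bad)) bad[1] else NA)
    }
  }
  if (is.null(instance_id))
    instance_id <- sub("\\.[^.]*$", "", basename(path))
  triaxial_recording(instance_id,
                     data.frame(t = df$t_s, x = df$ax_g, y = df$ay_g,
                                z = df$az_g))
}

#' Write a triaxial recording to CSV
#'
#' @param recording a [triaxial_recording()].
#' @param path output path; columns are \code{t_s}, \code{ax_g}, \code{ay_g},
#'   \code{az_g}.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "triaxial_recording"))
  utils::write.csv(data.frame(t_s = recording$data$t,
                              ax_g = recording$data$x,
                              ay_g = recording$data$y,
                              az_g = recording$data$z),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read clinical task annotations
#'
#' Annotation files give the start and end timestamps (seconds) of the tasks
#' performed during the clinical assessment; rest-period extraction keys on
#' their labels.
#'
#' @param path CSV with columns \code{label}, \code{start_s}, \code{end_s}.
#' @return Data frame with columns \code{label}, \code{start}, \code{end};
#'   intervals are validated to have \code{start < end} and to be mutually
#'   non-overlapping.
#' @export
read_annotations <- function(path) {
  df <- .read_csv_checked(path, c("label", "start_s", "end_s"), "annotation CSV")
  ann <- data.frame(label = as.character(df$label),
                    start = as.numeric(df$start_s),
                    end = as.numeric(df$end_s),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param annotations data frame with columns \code{label}, \code{start},
#'   \code{end}.
#' @export
validate_annotations <- function(annotations) {
  req <- c("label", "start", "end")
  if (!is.data.frame(annotations) || !all(req %in% names(annotations)))
    stop("annotations must have columns label, start, end")
  bad <- which(!(annotations$start < annotations$end))
  if (length(bad))
    stop("annotation interval ", bad[1], " has start >= end")
  o <- order(annotations$start)
  s <- annotations$start[o]; e <- annotations$end[o]
  if (length(s) > 1 && any(s[-1] < e[-length(e)]))
    stop("annotation intervals overlap")
  annotations
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  utils::write.csv(data.frame(label = annotations$label,
                              start_s = annotations$start,
                              end_s = annotations$end),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort ground-truth table
#'
#' @param path CSV with columns \code{instance_id}, \code{group},
#'   \code{updrs_3_17}.
#' @return Data frame with those columns; HC rows must score 0.
#' @export
read_ground_truth <- function(path) {
  df <- .read_csv_checked(path, c("instance_id", "group", "updrs_3_17"),
                          "ground-truth CSV")
  if (!all(df$group %in% c("PD", "HC")))
    stop("'group' must be PD or HC")
  if (!all(df$updrs_3_17 %in% 0:4))
    stop("'updrs_3_17' must be integer scores 0..4")
  if (any(df$group == "HC" & df$updrs_3_17 != 0))
    stop("HC rows must have updrs_3_17 = 0")
  df
}

#' @rdname read_ground_truth
#' @param truth ground-truth data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[c("instance_id", "group", "updrs_3_17")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Load a packaged per-instance reference table
#'
#' The package ships the three per-instance clustering tables published for
#' the 25-instance clinic cohort this pipeline re-implements: \code{"table2"}
#' (tremor vs non-tremor, 25 instances), \code{"table3"} (multiclass severity
#' among the 14 PD instances, including the published mapped scores) and
#' \code{"table4"} (binarised severity, 14 PD instances). They drive the
#' regression tests and [reference_evaluation()].
#'
#' @param name one of \code{"table2"}, \code{"table3"}, \code{"table4"}.
#' @return Data frame; all tables have columns \code{instance_id},
#'   \code{true_score}, \code{predominant_cluster} and
#'   \code{correctly_classified}; \code{"table3"} adds \code{mapped_score}.
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("table2", "table3", "table4"))
    stop("unknown fixture name; use 'table2', 'table3' or 'table4'")
  path <- system.file("extdata", paste0(name, ".csv"), package = "tremorclust",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_expect <- if (name == "table2") 25L else 14L
  if (nrow(df) != n_expect)
    stop("fixture '", name, "' has ", nrow(df), " rows, expected ", n_expect)
  df
}
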