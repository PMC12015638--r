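#' The seven canonical cortical networks
#'
#' Label set used to aggregate ROI-level measures: somatomotor cortex (SMC),
#' visual cortex (VIS), salience network (SAN), dorsal attention network
#' (DAN), (para)limbic system (LIM), cognitive control network (CCN), and
#' default mode network (DMN), ordered along the unimodal-to-transmodal axis.
#'
#' @return Character vector of the 7 network labels.
#' @export
yeo7_networks <- function() {
  c("SMC", "VIS", "SAN", "DAN", "LIM", "CCN", "DMN")
}

#' Construct a parcellation table
#'
#' A parcellation maps each region of interest (ROI) to one of the seven
#' canonical networks and records its size in voxels, which later weights
#' network-level aggregation.
#'
#' @param roi_id Character vector of unique ROI identifiers.
#' @param network Character vector of network labels, one of
#'   [yeo7_networks()] per ROI.
#' @param voxel_count Positive integer vector, voxels per ROI.
#' @return A tibble of class `fcg_parcellation` with columns `roi_id`,
#'   `network`, `voxel_count`, preserving input row order.
#' @export
parcellation <- function(roi_id, network, voxel_count) {
  roi_id <- as.character(roi_id)
  network <- as.character(network)
  voxel_count <- as.integer(voxel_count)
  n <- length(roi_id)
  if (length(network) != n || length(voxel_count) != n) {
    stop("roi_id, network and voxel_count must have the same length", call. = FALSE)
  }
  if (anyDuplicated(roi_id)) {
    stop("roi_id values must be unique", call. = FALSE)
  }
  bad <- which(!network %in% yeo7_networks())
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown network label '%s' at row %d (allowed: %s)",
      network[bad[1]], bad[1], paste(yeo7_networks(), collapse = ", ")
    ), call. = FALSE)
  }
  bad_vc <- which(is.na(voxel_count) | voxel_count <= 0)
  if (length(bad_vc) > 0) {
    stop(sprintf("non-positive voxel_count at row %d", bad_vc[1]), call. = FALSE)
  }
  out <- tibble::tibble(roi_id = roi_id, network = network, voxel_count = voxel_count)
  class(out) <- c("fcg_parcellation", class(out))
  out
}

#' Read a parcellation from a tab-delimited file
#'
#' Expects a header with columns `roi_id`, `network`, `voxel_count`.
#' File row order is preserved.
#'
#' @param path Path to a TSV file.
#' @return An `fcg_parcellation` tibble.
#' @export
read_parcellation <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("roi_id", "network", "voxel_count")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("parcellation file missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  parcellation(tbl$roi_id, tbl$network, tbl$voxel_count)
}

#' Write a parcellation to a tab-delimited file
#'
#' @param p An `fcg_parcellation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "fcg_parcellation"))
  readr::write_tsv(tibble::as_tibble(unclass_parcellation(p)), path, progress = FALSE)
  invisible(path)
}

unclass_parcellation <- function(p) {
  class(p) <- setdiff(class(p), "fcg_parcellation")
  p
}

#' Construct an ROI time-series object
#'
#' @param subject_id Subject identifier.
#' @param data Numeric matrix, ROIs in rows, time points in columns, rows
#'   ordered as the parcellation.
#' @param sampling_interval_s Sampling interval in seconds (default 1).
#' @param roi_ids Optional ROI identifiers used as row names.
#' @return An object of class `fcg_timeseries`.
#' @export
roi_timeseries <- function(subject_id, data, sampling_interval_s = 1, roi_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) {
    stop("time-series data must be numeric with no missing values", call. = FALSE)
  }
  if (!is.numeric(sampling_interval_s) || sampling_interval_s <= 0) {
    stop("sampling_interval_s must be a positive number", call. = FALSE)
  }
  if (!is.null(roi_ids)) {
    if (length(roi_ids) != nrow(data)) {
      stop("roi_ids length does not match number of rows", call. = FALSE)
    }
    rownames(data) <- as.character(roi_ids)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      sampling_interval_s = sampling_interval_s
    ),
    class = "fcg_timeseries"
  )
}

#' @export
print.fcg_timeseries <- function(x, ...) {
  cat(sprintf(
    "<fcg_timeseries> subject %s: %d ROIs x %d samples @ %g s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$sampling_interval_s
  ))
  invisible(x)
}

#' Read an ROI-by-time matrix from a tab-delimited file
#'
#' Two layouts are accepted: a headerless numeric matrix in parcellation
#' order (`orientation` giving whether ROIs are in rows or columns), or a
#' headered table whose first column is `roi_id`, in which case rows are
#' reordered to the parcellation regardless of file order.
#'
#' @param path Path to a TSV file.
#' @param parcellation An `fcg_parcellation` defining ROI count and order.
#' @param subject_id Subject identifier to attach (default: file base name).
#' @param sampling_interval_s Sampling interval in seconds; plain matrices
#'   carry no time metadata, so this is supplied, not inferred.
#' @param orientation `"rois-in-rows"` (default) or `"rois-in-cols"` for
#'   headerless matrices.
#' @return An `fcg_timeseries` aligned to the parcellation ROI order.
#' @export
read_timeseries <- function(path, parcellation, subject_id = NULL,
                            sampling_interval_s = 1,
                            orientation = c("rois-in-rows", "rois-in-cols")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readr::read_lines(path, n_max = 1)
  has_ids <- grepl("^roi_id\\t", first)
  if (has_ids) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(parcellation$roi_id, tbl$roi_id)
    if (length(miss) > 0) {
      stop("time-series file missing ROIs: ", paste(utils::head(miss, 3), collapse = ", "),
        call. = FALSE
      )
    }
    tbl <- tbl[match(parcellation$roi_id, tbl$roi_id), ]
    mat <- as.matrix(tbl[, -1, drop = FALSE])
    check_numeric_cells(mat, offset = 1)
  } else {
    tbl <- suppressWarnings(
      readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
    )
    mat <- as.matrix(tbl)
    check_numeric_cells(mat, offset = 0)
    storage.mode(mat) <- "double"
    if (orientation == "rois-in-cols") mat <- t(mat)
    if (nrow(mat) != nrow(parcellation)) {
      stop(sprintf(
        "dimension mismatch: file has %d x %d values (%s) but parcellation has %d ROIs",
        nrow(mat), ncol(mat), orientation, nrow(parcellation)
      ), call. = FALSE)
    }
    rownames(mat) <- parcellation$roi_id
  }
  if (nrow(mat) != nrow(parcellation)) {
    stop(sprintf(
      "dimension mismatch: %d ROI rows in file vs %d in parcellation",
      nrow(mat), nrow(parcellation)
    ), call. = FALSE)
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- parcellation$roi_id
  roi_timeseries(subject_id, mat, sampling_interval_s)
}

check_numeric_cells <- function(mat, offset = 0) {
  if (is.numeric(mat) && !anyNA(mat)) {
    return(invisible(TRUE))
  }
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric or missing value at row %d, column %d",
      bad[1, 1], bad[1, 2] + offset
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an ROI time series as TSV (roi_id column + one column per sample)
#'
#' @param ts An `fcg_timeseries`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "fcg_timeseries"))
  tbl <- tibble::as_tibble(ts$data, .name_repair = ~ paste0("t", seq_along(.x)))
  tbl <- dplyr::bind_cols(tibble::tibble(roi_id = rownames(ts$data)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a subject table
#'
#' Expects tab-delimited text with header columns `subject_id`, `group`
#' and any numeric covariate columns (e.g. `age`, `sex` coded 0/1,
#' `education`, `moca`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with unique `subject_id`.
#' @export
read_subjects <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("subject table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$subject_id)) {
    stop("subject_id values must be unique", call. = FALSE)
  }
  tbl$subject_id <- as.character(tbl$subject_id)
  tbl
}

#' Read per-ROI values (betas, reference gradient) aligned to a parcellation
#'
#' Expects columns `roi_id` and `value`; rows are reordered to the
#' parcellation order.
#'
#' @param path Path to a TSV file.
#' @param parcellation An `fcg_parcellation`.
#' @return Named numeric vector in parcellation ROI order.
#' @export
read_roi_values <- function(path, parcellation) {
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("roi_id", "value"), names(tbl))
  if (length(miss) > 0) {
    stop("ROI value file missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(parcellation$roi_id, tbl$roi_id)
  if (anyNA(idx)) {
    stop("ROI value file missing ROIs from the parcellation", call. = FALSE)
  }
  stats::setNames(as.numeric(tbl$value[idx]), parcellation$roi_id)
}

#' Write per-ROI values as TSV
#'
#' @param values Named numeric vector (names = roi_id).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_values <- function(values, path) {
  readr::write_tsv(
    tibble::tibble(roi_id = names(values), value = unname(values)),
    path,
    progress = FALSE
  )
  invisible(path)
}
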