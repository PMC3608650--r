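## Plain-text (CSV/TSV/JSON) and PNG/NIfTI serialization of the package's
## containers.

#' Write / read a prototype set as CSV
#'
#' One row per category, one column per voxel, categories in the first
#' column.
#'
#' @param prototypes A `prototype_set`.
#' @param path CSV file path.
#' @return `read_prototypes()` returns a `prototype_set`.
#' @export
write_prototypes <- function(prototypes, path) {
  stopifnot(inherits(prototypes, "prototype_set"))
  df <- data.frame(category = prototypes$category_names,
                   prototypes$prototypes, check.names = FALSE)
  colnames(df) <- c("category", sprintf("v%d", seq_len(prototypes$n_voxels)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  proto <- as.matrix(df[, -1, drop = FALSE])
  rownames(proto) <- df$category
  structure(
    list(category_names = df$category, prototypes = unname(proto),
         n_voxels = ncol(proto), separation = NA_real_),
    class = "prototype_set"
  )
}

#' Write / read a rating table as CSV
#'
#' @param ratings Rating table data.frame.
#' @param path CSV file path.
#' @return `read_rating_table()` returns the data.frame.
#' @export
write_rating_table <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rating_table
#' @export
read_rating_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$is_check <- as.logical(df$is_check)
  df
}

#' Serialize a scan run to disk
#'
#' Writes the voxel x time data, a BIDS-style events table (onset, duration,
#' trial_type) and a JSON metadata sidecar under a common path prefix.
#' `format = "csv"` stores the data matrix as plain CSV; `format = "nifti"`
#' stores it as a 4-D NIfTI volume (V x 1 x 1 x T, TR in the header) and
#' requires the RNifti package.
#'
#' @param run A `scan_run`.
#' @param prefix Path prefix (files `<prefix>_bold.csv` or
#'   `<prefix>_bold.nii.gz`, `<prefix>_events.tsv`, `<prefix>_meta.json`).
#' @param format `"csv"` or `"nifti"`.
#' @return `read_scan_run()` returns the `scan_run`.
#' @export
write_scan_run <- function(run, prefix, format = c("csv", "nifti")) {
  stopifnot(inherits(run, "scan_run"))
  format <- match.arg(format)
  events <- data.frame(onset = run$onsets, duration = run$durations,
                       trial_type = run$labels)
  write.table(events, paste0(prefix, "_events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(TR = run$TR, condition = run$condition, run_id = run$run_id,
               design_type = run$design_type, format = format,
               n_volumes = nrow(run$data), n_voxels = ncol(run$data))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  if (format == "csv") {
    write.csv(as.data.frame(run$data), paste0(prefix, "_bold.csv"),
              row.names = FALSE)
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("the RNifti package is required for format = 'nifti'", call. = FALSE)
    }
    vol <- array(t(run$data), dim = c(ncol(run$data), 1L, 1L, nrow(run$data)))
    img <- RNifti::asNifti(vol, pixdim = c(1, 1, 1, run$TR))
    RNifti::writeNifti(img, paste0(prefix, "_bold.nii.gz"))
  }
  invisible(prefix)
}

#' @rdname write_scan_run
#' @export
read_scan_run <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  events <- read.delim(paste0(prefix, "_events.tsv"), stringsAsFactors = FALSE)
  if (identical(meta$format, "nifti")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("the RNifti package is required to read NIfTI runs", call. = FALSE)
    }
    vol <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
    data <- t(matrix(vol, nrow = dim(vol)[1]))
  } else {
    data <- as.matrix(read.csv(paste0(prefix, "_bold.csv")))
    dimnames(data) <- NULL
  }
  make_scan_run(data, meta$TR, events$onset, events$duration,
                events$trial_type, meta$condition, meta$run_id,
                meta$design_type)
}

#' Write an image set as 8-bit RGB PNG files
#'
#' @param images List of H x W x 3 arrays in \[0, 1\].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return `read_image_set()` returns the list of arrays.
#' @export
write_image_set <- function(images, dir, prefix = "img") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- sprintf("%s/%s_%03d.png", dir, prefix, seq_along(images))
  for (i in seq_along(images)) png::writePNG(images[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(dir, prefix = "img") {
  paths <- sort(list.files(dir, pattern = paste0("^", prefix, ".*\\.png$"),
                           full.names = TRUE))
  lapply(paths, png::readPNG)
}

#' Write a feature matrix as CSV (image id + 64 feature columns)
#'
#' @param features n x 64 feature matrix.
#' @param path CSV file path.
#' @param image_ids Optional ids; defaults to row numbers.
#' @export
write_feature_matrix <- function(features, path, image_ids = NULL) {
  if (is.null(image_ids)) image_ids <- seq_len(nrow(features))
  df <- data.frame(image_id = image_ids, unclass(features),
                   check.names = FALSE)
  colnames(df) <- c("image_id", sprintf("f%02d", seq_len(ncol(features))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
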