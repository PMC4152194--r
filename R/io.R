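#' Read / write ROI time series as TSV
#'
#' Canonical interchange format: tab-separated, header row of ROI labels,
#' rows = timepoints.
#'
#' @param ts A [roi_timeseries()].
#' @param path File path.
#' @return `write_timeseries_tsv` invisibly returns `path`;
#'   `read_timeseries_tsv` returns a [roi_timeseries()].
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param subject_id Subject id for the read object (default: file name
#'   without the `_timeseries.tsv` suffix).
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL) {
  x <- utils::read.delim(path, check.names = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("_timeseries\\.tsv$", "", basename(path))
  roi_timeseries(as.matrix(x), colnames(x), subject_id)
}

#' Read / write FC matrices as TSV
#'
#' Square matrix with ROI labels as both header row and first column.
#'
#' @param fc An [fc_matrix()] (or plain matrix for `write_fc_tsv`).
#' @param path File path.
#' @export
write_fc_tsv <- function(fc, path) {
  m <- if (inherits(fc, "fc_matrix")) fc$z else fc
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_fc_tsv
#' @param n_subjects_averaged Stored on the object read back (default 1).
#' @export
read_fc_tsv <- function(path, n_subjects_averaged = 1L) {
  x <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  m <- (m + t(m)) / 2
  fc_matrix(m, rownames(m), n_subjects_averaged = n_subjects_averaged)
}

#' Read / write a partition with its modularity scores as JSON
#'
#' The affiliation vector is keyed by ROI label.
#'
#' @param result A `"modularity_result"` from [maximize_modularity()].
#' @param roi_labels ROI labels keying the affiliation vector.
#' @param path File path.
#' @export
write_partition_json <- function(result, roi_labels, path) {
  stopifnot(inherits(result, "modularity_result"))
  aff <- as.list(stats::setNames(unclass(result$partition), roi_labels))
  jsonlite::write_json(list(affiliation = aff,
                            q_star = result$q_star,
                            q_pos = result$q_pos,
                            q_neg = result$q_neg,
                            n_restarts = result$n_restarts,
                            seed = result$seed),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$partition <- as_partition(unlist(x$affiliation))
  x
}

#' Write a reproducibility report as JSON
#' @param report A `"reproducibility_report"`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "reproducibility_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Extract ROI-mean time series from a 4D volume and a label atlas
#'
#' For every labelled region, averages the functional signal over all
#' voxels carrying that label, at each timepoint. Inputs must already be
#' co-registered on the same voxel grid; label 0 is background.
#'
#' @param image4d 4D numeric array (x, y, z, t) or a NIfTI file path /
#'   `RNifti` image.
#' @param atlas 3D integer array of region labels, or NIfTI path / image,
#'   on the same grid as `image4d`.
#' @param labels Optional named table: integer labels -> ROI names
#'   (a named integer vector, names = ROI names). Defaults to
#'   `ROI<label>` for every nonzero label present.
#' @param subject_id Subject id for the result.
#' @return A [roi_timeseries()] with one column per label, in label-table
#'   order.
#' @export
extract_roi_timeseries <- function(image4d, atlas, labels = NULL,
                                   subject_id = "subject") {
  if (is.character(image4d)) image4d <- RNifti::readNifti(image4d)
  if (is.character(atlas)) atlas <- RNifti::readNifti(atlas)
  img <- as.array(image4d)
  atl <- as.array(atlas)
  if (length(dim(img)) != 4L)
    stop("functional image must be 4D (x, y, z, t)", call. = FALSE)
  if (!identical(dim(img)[1:3], dim(atl)[1:3]))
    stop("functional image and atlas voxel grids do not match", call. = FALSE)
  if (is.null(labels)) {
    ids <- sort(unique(as.integer(atl[atl > 0])))
    labels <- stats::setNames(ids, paste0("ROI", ids))
  }
  if (anyDuplicated(names(labels)))
    stop("ROI names must be unique", call. = FALSE)
  nt <- dim(img)[4]
  flat <- matrix(img, ncol = nt)        # voxels x time
  atl_vec <- as.integer(atl)
  values <- vapply(seq_along(labels), function(k) {
    vox <- which(atl_vec == labels[k])
    if (length(vox) == 0L)
      stop("ROI '", names(labels)[k], "' has no voxels in the atlas",
           call. = FALSE)
    colMeans(flat[vox, , drop = FALSE])
  }, numeric(nt))
  roi_timeseries(values, names(labels), subject_id)
}
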