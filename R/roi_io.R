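#' ROI time course container
#'
#' One run's ROI-mean signal for one participant.
#'
#' @param values numeric signal, one value per TR (length >= 2, finite).
#' @param tr repetition time in seconds.
#' @param run_id,participant_id identifiers.
#' @param zscored logical; if TRUE the values must have mean 0 and SD 1
#'   (within 1e-6).
#' @return object of class `roi_tc`.
#' @export
roi_tc <- function(values, tr, run_id = "run1", participant_id = "p001",
                   zscored = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a time course needs at least 2 samples")
  if (!all(is.finite(values))) stop("time course contains non-finite values")
  stopifnot_scalar(tr, "tr", positive = TRUE)
  if (zscored &&
      (abs(mean(values)) > 1e-6 || abs(stats::sd(values) - 1) > 1e-6))
    stop("zscored = TRUE but values are not standardized")
  structure(list(values = values, tr = tr, run_id = run_id,
                 participant_id = participant_id, zscored = zscored),
            class = "roi_tc")
}

#' @export
#' @method print roi_tc
print.roi_tc <- function(x, ...) {
  cat(sprintf("<roi_tc> %s/%s: %d TRs @ %.3g s%s\n", x$participant_id,
              x$run_id, length(x$values), x$tr,
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Extract an ROI-mean time course from a 4D volume
#'
#' @param volume_4d 4D array, `RNifti` image, or path to a NIfTI file
#'   (x, y, z, time).
#' @param mask 3D logical/integer array, `RNifti` image or NIfTI path on the
#'   same grid; nonzero voxels define the ROI.
#' @param tr repetition time in seconds; taken from the NIfTI header when
#'   available and not supplied.
#' @param ... passed to [roi_tc()].
#' @return an [roi_tc()] with the per-TR mean over mask voxels.
#' @export
extract_roi <- function(volume_4d, mask, tr = NULL, ...) {
  if (is.character(volume_4d)) volume_4d <- RNifti::readNifti(volume_4d)
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  if (is.null(tr) && inherits(volume_4d, "niftiImage")) {
    pd <- RNifti::pixdim(volume_4d)
    if (length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
  }
  vol <- unclass(as.array(volume_4d))
  msk <- unclass(as.array(mask)) != 0
  if (length(dim(vol)) != 4L) stop("volume must be 4D (x, y, z, time)")
  if (!identical(dim(vol)[1:3], dim(msk)))
    stop("mask grid does not match the volume grid")
  if (!any(msk)) stop("mask is empty")
  if (is.null(tr)) stop("'tr' is required when the header carries no timing")
  n_tr <- dim(vol)[4]
  vmat <- matrix(vol, ncol = n_tr)
  roi_tc(colMeans(vmat[as.vector(msk), , drop = FALSE]), tr = tr, ...)
}

#' Z-score a time course over its full length
#'
#' @param tc an [roi_tc()].
#' @return the z-scored [roi_tc()] (errors on a constant series).
#' @export
zscore_tc <- function(tc) {
  stopifnot(inherits(tc, "roi_tc"))
  roi_tc(zscore_vec(tc$values), tr = tc$tr, run_id = tc$run_id,
         participant_id = tc$participant_id, zscored = TRUE)
}

#' Z-score each participant's time course, then average across participants
#'
#' Each input series is standardized over its full length first; the group
#' series is the element-wise mean of the standardized series (the mean of
#' z-scores is not itself unit variance, so the result is not flagged as
#' z-scored). Hemisphere pairs are averaged the same way: pass both series.
#'
#' @param tcs list of [roi_tc()] objects of equal length and TR.
#' @return an [roi_tc()] with `participant_id = "group"`.
#' @export
zscore_and_average <- function(tcs) {
  stopifnot(length(tcs) >= 1L)
  lens <- vapply(tcs, function(t) length(t$values), integer(1))
  if (length(unique(lens)) != 1L) stop("time courses differ in length")
  trs <- vapply(tcs, `[[`, numeric(1), "tr")
  if (length(unique(trs)) != 1L) stop("time courses differ in TR")
  Z <- vapply(tcs, function(t) zscore_vec(t$values), numeric(lens[1]))
  roi_tc(rowMeans(matrix(Z, nrow = lens[1])), tr = trs[1],
         run_id = tcs[[1]]$run_id, participant_id = "group")
}

#' Read / write a plain-text (TSV) time course
#'
#' Single column `value`, one row per TR; TR and ids passed alongside.
#'
#' @param path file path.
#' @param tr repetition time in seconds.
#' @param ... passed to [roi_tc()].
#' @export
read_tc <- function(path, tr, ...) {
  df <- utils::read.delim(path)
  roi_tc(df$value, tr = tr, ...)
}

#' @rdname read_tc
#' @param tc an [roi_tc()] to write.
#' @export
write_tc <- function(tc, path) {
  utils::write.table(data.frame(value = tc$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
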