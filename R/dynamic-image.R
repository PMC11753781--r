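#' Dynamic PET image
#'
#' A 4D activity volume (x, y, z, frame) in kBq/ml together with its voxel
#' spacing in millimetres and its [frame_schedule()]. Voxel indices are
#' 1-based in R code; files written by this package store the array verbatim.
#'
#' @param values 4D numeric array, frame as the fourth axis.
#' @param voxel_spacing_mm numeric length-3, all positive.
#' @param schedule a [frame_schedule()]; its length must match `dim(values)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, voxel_spacing_mm, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.array(values)
  if (length(dim(values)) != 4L)
    stop("values must be a 4D array (x, y, z, frame)")
  if (dim(values)[4] != length(schedule))
    stop("frame axis has ", dim(values)[4], " frames but schedule has ",
         length(schedule))
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive lengths")
  if (any(!is.finite(values)))
    stop("image values must be finite")
  structure(list(values = values,
                 voxel_spacing_mm = voxel_spacing_mm,
                 schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dynamic image: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel spacing: %g x %g x %g mm; %g s total\n",
              x$voxel_spacing_mm[1], x$voxel_spacing_mm[2],
              x$voxel_spacing_mm[3], max(x$schedule$end_s)))
  invisible(x)
}

#' Read and write dynamic images as NIfTI + schedule sidecar
#'
#' The volume goes to a single NIfTI file with a float32 payload; the frame
#' schedule goes to a CSV sidecar (`<stem>_frames.csv` by default, columns
#' `frame,start_s,duration_s`). Reading validates that the number of volume
#' frames matches the sidecar.
#'
#' @param image a [dynamic_image()].
#' @param path path of the NIfTI file (`.nii` or `.nii.gz`).
#' @param schedule_path path of the schedule CSV; defaults to the image path
#'   with the extension replaced by `_frames.csv`.
#' @return `read_dynamic_image` returns a `dynamic_image`;
#'   `write_dynamic_image` returns `path` invisibly.
#' @export
write_dynamic_image <- function(image, path, schedule_path = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  if (is.null(schedule_path)) schedule_path <- sidecar_path(path)
  vals <- image$values
  attr(vals, "pixdim") <- c(image$voxel_spacing_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "float"), path)
  write_frame_schedule(image$schedule, schedule_path)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path, schedule_path = NULL) {
  if (is.null(schedule_path)) schedule_path <- sidecar_path(path)
  if (!file.exists(path)) stop("no such image file: ", path)
  if (!file.exists(schedule_path))
    stop("no schedule sidecar found at ", schedule_path)
  nii <- RNifti::readNifti(path)
  sched <- read_frame_schedule(schedule_path)
  vals <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(vals)) == 3L) vals <- array(vals, dim = c(dim(vals), 1L))
  if (dim(vals)[4] != length(sched))
    stop("image has ", dim(vals)[4], " frames but schedule lists ",
         length(sched))
  spacing <- RNifti::pixdim(nii)[1:3]
  dynamic_image(vals, spacing, sched)
}

sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, "_frames.csv")
}

#' Write / read a 3D parameter or p-value map as NIfTI
#'
#' Single-volume float32 NIfTI, readable by common viewers. Non-finite
#' values abort the write unless `fill` supplies an explicit replacement
#' (typical for undefined voxels outside a mask).
#'
#' @param volume 3D numeric array.
#' @param voxel_spacing_mm numeric length-3, positive.
#' @param path output path.
#' @param fill optional scalar written in place of non-finite values.
#' @return `write_map` returns `path` invisibly; `read_map` returns a list
#'   with `values` (3D array) and `voxel_spacing_mm`.
#' @export
write_map <- function(volume, voxel_spacing_mm, path, fill = NULL) {
  volume <- as.array(volume)
  if (length(volume) == 0L) stop("cannot write an empty volume")
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (any(!is.finite(volume))) {
    if (is.null(fill))
      stop("volume contains non-finite values; supply fill= to write them")
    volume[!is.finite(volume)] <- fill
  }
  attr(volume, "pixdim") <- as.numeric(voxel_spacing_mm)
  RNifti::writeNifti(RNifti::asNifti(volume, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  nii <- RNifti::readNifti(path)
  list(values = array(as.numeric(nii), dim = dim(nii)[1:3]),
       voxel_spacing_mm = RNifti::pixdim(nii)[1:3])
}

#' Write / read time--activity-curve tables
#'
#' Delimited text with one row per frame and columns
#' `frame_index, mid_time_s, <one column per series>`. Mid time is
#' `start + duration/2`.
#'
#' @param tacs numeric matrix (frames x series) or vector; column names are
#'   preserved.
#' @param schedule a [frame_schedule()] matching `nrow(tacs)`.
#' @param path file path.
#' @return `write_tac_table` returns `path` invisibly; `read_tac_table`
#'   returns a list with `schedule_mid_s` and `tacs` (matrix).
#' @export
write_tac_table <- function(tacs, schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  tacs <- as.matrix(tacs)
  if (nrow(tacs) != length(schedule))
    stop("tac table has ", nrow(tacs), " rows but schedule has ",
         length(schedule), " frames")
  if (is.null(colnames(tacs)))
    colnames(tacs) <- paste0("tac", seq_len(ncol(tacs)))
  out <- data.frame(frame_index = seq_len(nrow(tacs)),
                    mid_time_s = schedule$mid_s)
  out <- cbind(out, as.data.frame(tacs))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_table
#' @export
read_tac_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("frame_index", "mid_time_s") %in% names(tab)))
    stop("TAC table must have frame_index and mid_time_s columns")
  if (any(!is.finite(as.matrix(tab))))
    stop("TAC table contains missing or ragged entries")
  series <- setdiff(names(tab), c("frame_index", "mid_time_s"))
  list(schedule_mid_s = tab$mid_time_s,
       tacs = as.matrix(tab[, series, drop = FALSE]))
}
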