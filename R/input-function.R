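#' Plasma input function
#'
#' An arterial (or image-derived) plasma activity curve: sample times in
#' seconds and activity values in kBq/ml. The interpolation contract used by
#' every consumer in this package is piecewise-linear between samples, zero
#' before the first sample, and flat continuation after the last.
#'
#' @param times_s strictly increasing sample times in seconds.
#' @param values_kbq_ml finite activity values, same length as `times_s`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(times_s, values_kbq_ml) {
  times_s <- as.numeric(times_s)
  values_kbq_ml <- as.numeric(values_kbq_ml)
  if (length(times_s) != length(values_kbq_ml) || length(times_s) < 1L)
    stop("times and values must be non-empty and of equal length")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values_kbq_ml))) stop("values must be finite")
  structure(list(times_s = times_s, values = values_kbq_ml),
            class = "input_function")
}

#' Evaluate an input function at arbitrary times
#'
#' Applies the interpolation contract: linear between samples, 0 before the
#' first sample, constant at the last value afterwards.
#'
#' @param fn an [input_function()].
#' @param t_s times in seconds.
#' @return numeric vector of plasma activities.
#' @export
evaluate_input_function <- function(fn, t_s) {
  stopifnot(inherits(fn, "input_function"))
  out <- stats::approx(fn$times_s, fn$values, xout = t_s, method = "linear",
                       yleft = 0, rule = c(1, 2))$y
  out[t_s < fn$times_s[1]] <- 0
  out
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function: %d samples over [%g, %g] s, peak %.3g kBq/ml\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              max(x$values)))
  invisible(x)
}

#' @export
plot.input_function <- function(x, ...) {
  plot(x$times_s / 60, x$values, type = "l", xlab = "time (min)",
       ylab = "plasma activity (kBq/ml)", ...)
}

#' Volume of interest
#'
#' A labelled set of voxel indices, stored as an integer matrix with one row
#' per voxel and columns `x, y, z` (1-based).
#'
#' @param voxel_indices integer matrix (n x 3) of voxel coordinates.
#' @param label character label.
#' @return An object of class `voi`.
#' @export
voi <- function(voxel_indices, label = "voi") {
  voxel_indices <- as.matrix(voxel_indices)
  if (nrow(voxel_indices) == 0L) stop("a VOI must contain at least one voxel")
  if (ncol(voxel_indices) != 3L) stop("voxel_indices must have 3 columns")
  storage.mode(voxel_indices) <- "integer"
  dimnames(voxel_indices) <- list(NULL, c("x", "y", "z"))
  structure(list(label = label, voxel_indices = voxel_indices), class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("VOI '%s': %d voxels\n", x$label, nrow(x$voxel_indices)))
  invisible(x)
}

#' Read / write VOI voxel lists
#'
#' Delimited text with columns `label, x, y, z` (1-based voxel indices).
#' A file may hold several VOIs distinguished by label.
#'
#' @param vois a `voi` or list of `voi` objects.
#' @param path file path.
#' @return `read_voi_table` returns a named list of `voi` objects.
#' @export
write_voi_table <- function(vois, path) {
  if (inherits(vois, "voi")) vois <- list(vois)
  rows <- do.call(rbind, lapply(vois, function(v)
    data.frame(label = v$label, v$voxel_indices)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voi_table
#' @export
read_voi_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("label", "x", "y", "z") %in% names(tab)))
    stop("VOI table must have columns label, x, y, z")
  out <- lapply(split(tab, tab$label), function(d)
    voi(as.matrix(d[, c("x", "y", "z")]), label = d$label[1]))
  out[unique(tab$label)]
}

check_voi_in_grid <- function(v, grid_dim) {
  idx <- v$voxel_indices
  if (any(idx < 1L) ||
      any(idx[, 1] > grid_dim[1]) || any(idx[, 2] > grid_dim[2]) ||
      any(idx[, 3] > grid_dim[3]))
    stop("VOI '", v$label, "' contains voxel indices outside the image grid")
  invisible(TRUE)
}

voi_linear_index <- function(v, grid_dim) {
  idx <- v$voxel_indices
  as.integer(idx[, 1] + grid_dim[1] * (idx[, 2] - 1L) +
               grid_dim[1] * grid_dim[2] * (idx[, 3] - 1L))
}

#' Extract a VOI time--activity curve as an input function
#'
#' Per-frame unweighted mean over the VOI voxels, timestamped at the frame
#' mid-times. Used to obtain the image-derived input function from a blood
#' (aorta) VOI identified on an early frame, and for any regional TAC.
#'
#' @param image a [dynamic_image()].
#' @param v a [voi()] inside the image grid.
#' @return An [input_function()] sampled at the frame mid-times.
#' @export
extract_voi_tac <- function(image, v) {
  stopifnot(inherits(image, "dynamic_image"), inherits(v, "voi"))
  d <- dim(image$values)
  check_voi_in_grid(v, d[1:3])
  flat <- matrix(image$values, nrow = prod(d[1:3]), ncol = d[4])
  lin <- voi_linear_index(v, d[1:3])
  means <- colMeans(flat[lin, , drop = FALSE])
  input_function(image$schedule$mid_s, means)
}

#' Partial-volume correction of an input function
#'
#' Small blood pools such as the mouse aorta recover only a fraction of the
#' true activity at PET resolution. The correction divides the whole curve
#' by a standardized volume fraction (default 0.6), a pure spill-out model
#' with no spill-in term.
#'
#' @param fn an [input_function()].
#' @param volume_fraction recovered fraction, in (0, 1]; default 0.6.
#' @return The corrected [input_function()]; times unchanged.
#' @examples
#' fn <- input_function(c(0, 60), c(0.6, 0.6))
#' pve_correct(fn)$values    # 1.0 1.0
#' @export
pve_correct <- function(fn, volume_fraction = 0.6) {
  stopifnot(inherits(fn, "input_function"))
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be a single number in (0, 1]")
  input_function(fn$times_s, fn$values / volume_fraction)
}
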