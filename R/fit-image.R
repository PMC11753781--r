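#' Voxel-wise parametric mapping
#'
#' Applies [fit_tac()] independently to every voxel of a dynamic image
#' (optionally restricted to a mask VOI) and assembles parametric maps of
#' K1, k2, k3, k4 and the glucose-transport ratio CE/CP, plus a convergence
#' mask. Voxels outside the mask are marked non-converged and carry `NA`
#' parameters; they are excluded from downstream statistics.
#'
#' The result is deterministic given the image, input function and settings:
#' no randomness is used and voxel order does not influence any voxel's fit.
#'
#' @param image a [dynamic_image()].
#' @param input_fn an [input_function()] (partial-volume corrected if
#'   image-derived); must cover the schedule.
#' @param mask optional [voi()]; default fits every voxel.
#' @param ... further arguments passed to [fit_tac()] (e.g. `pin_k4`,
#'   `lumped_factor`, bounds).
#' @return An object of class `parametric_map`: 3D arrays `K1`, `k2`, `k3`,
#'   `k4`, `CEoverCP`, `fit_rss`, logical array `converged`, plus
#'   `voxel_spacing_mm`.
#' @export
fit_image <- function(image, input_fn, mask = NULL, ...) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$values)
  grid_dim <- d[1:3]
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voi"))
    check_voi_in_grid(mask, grid_dim)
    lin <- voi_linear_index(mask, grid_dim)
    if (length(lin) == 0L) stop("mask VOI is empty")
  } else {
    lin <- seq_len(prod(grid_dim))
  }
  ctx <- tcm_context(input_fn, image$schedule)
  flat <- matrix(image$values, nrow = prod(grid_dim), ncol = d[4])

  blank <- array(NA_real_, dim = grid_dim)
  out <- list(K1 = blank, k2 = blank, k3 = blank, k4 = blank,
              CEoverCP = blank, fit_rss = blank,
              converged = array(FALSE, dim = grid_dim),
              voxel_spacing_mm = image$voxel_spacing_mm)
  for (v in lin) {
    fit <- fit_tac(flat[v, ], input_fn, image$schedule, context = ctx, ...)
    p <- unclass(fit$params)
    out$K1[v] <- p[["K1"]]; out$k2[v] <- p[["k2"]]
    out$k3[v] <- p[["k3"]]; out$k4[v] <- p[["k4"]]
    out$CEoverCP[v] <- fit$cecp
    out$fit_rss[v] <- fit$rss
    out$converged[v] <- fit$converged
  }
  class(out) <- "parametric_map"
  out
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$K1)
  n_fit <- sum(!is.na(x$K1))
  cat(sprintf("Parametric map: %d x %d x %d voxels, %d fitted, %d converged\n",
              d[1], d[2], d[3], n_fit, sum(x$converged)))
  if (any(x$converged))
    cat(sprintf("  median CE/CP over converged voxels: %.3g\n",
                stats::median(x$CEoverCP[x$converged])))
  invisible(x)
}

#' Tabulate a parametric map
#'
#' One row per fitted voxel with columns `voxel_x, voxel_y, voxel_z, K1, k2,
#' k3, k4, CEoverCP, fit_rss, converged` (1-based indices).
#'
#' @param x a `parametric_map`.
#' @param row.names,optional,... standard [as.data.frame()] arguments, unused.
#' @export
as.data.frame.parametric_map <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  keep <- which(!is.na(x$K1))
  idx <- arrayInd(keep, dim(x$K1))
  data.frame(voxel_x = idx[, 1], voxel_y = idx[, 2], voxel_z = idx[, 3],
             K1 = x$K1[keep], k2 = x$k2[keep], k3 = x$k3[keep],
             k4 = x$k4[keep], CEoverCP = x$CEoverCP[keep],
             fit_rss = x$fit_rss[keep], converged = x$converged[keep])
}

#' Write a parametric map to disk
#'
#' One NIfTI volume per parameter (`<stem>_K1.nii.gz`, ... `_CEoverCP.nii.gz`,
#' `_converged.nii.gz`) plus the voxel table as `<stem>_params.csv`.
#' Unfitted voxels are written as 0 in the volumes and omitted from the
#' table.
#'
#' @param pmap a `parametric_map`.
#' @param stem output path stem.
#' @return The paths written, invisibly.
#' @export
write_parametric_map <- function(pmap, stem) {
  stopifnot(inherits(pmap, "parametric_map"))
  paths <- character(0)
  for (nm in c("K1", "k2", "k3", "k4", "CEoverCP", "fit_rss")) {
    p <- paste0(stem, "_", nm, ".nii.gz")
    write_map(pmap[[nm]], pmap$voxel_spacing_mm, p, fill = 0)
    paths <- c(paths, p)
  }
  p <- paste0(stem, "_converged.nii.gz")
  write_map(array(as.numeric(pmap$converged), dim = dim(pmap$converged)),
            pmap$voxel_spacing_mm, p)
  tab <- paste0(stem, "_params.csv")
  utils::write.csv(as.data.frame(pmap), tab, row.names = FALSE)
  invisible(c(paths, p, tab))
}

#' Extract one parameter volume from parametric maps
#'
#' @param maps a list of `parametric_map` objects (e.g. one per animal).
#' @param param parameter name, default `"CEoverCP"`.
#' @return A list of 3D arrays.
#' @export
map_volumes <- function(maps, param = "CEoverCP") {
  lapply(maps, function(m) {
    stopifnot(inherits(m, "parametric_map"))
    m[[param]]
  })
}
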