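#' Voxel-wise two-sample t-test between groups of parameter maps
#'
#' Unpaired two-tailed Student's t with pooled variance, computed per masked
#' voxel on the per-animal parameter values; p-values from the t
#' distribution with `n_A + n_B - 2` degrees of freedom. The sign of t
#' encodes group A minus group B.
#'
#' Degenerate voxels (zero pooled variance) yield `t = 0, p = 1` when the
#' group means agree and `p = 0` with a raised `degenerate` flag when they
#' differ.
#'
#' @param maps_a,maps_b lists of 3D arrays (one per animal), all of
#'   identical shape; at least two per group. Use [map_volumes()] to pull a
#'   parameter out of fitted `parametric_map`s.
#' @param mask optional logical 3D array or [voi()]; default: voxels where
#'   every animal is finite.
#' @param voxel_spacing_mm spacing carried to the output.
#' @return An object of class `pvalue_map`: arrays `t`, `p` (NA outside the
#'   mask), `mask`, `df`, `degenerate`, `voxel_spacing_mm`.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask = NULL,
                            voxel_spacing_mm = c(0.4, 0.4, 0.8)) {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least two maps per group")
  dims <- dim(maps_a[[1]])
  for (m in c(maps_a, maps_b))
    if (!identical(dim(m), dims))
      stop("all maps must share the same shape")
  na <- length(maps_a); nb <- length(maps_b)
  A <- vapply(maps_a, as.numeric, numeric(prod(dims)))
  B <- vapply(maps_b, as.numeric, numeric(prod(dims)))
  if (is.null(mask)) {
    keep <- rowSums(!is.finite(A)) == 0 & rowSums(!is.finite(B)) == 0
  } else {
    if (inherits(mask, "voi")) {
      check_voi_in_grid(mask, dims)
      keep <- logical(prod(dims))
      keep[voi_linear_index(mask, dims)] <- TRUE
    } else keep <- as.logical(mask)
    keep <- keep & rowSums(!is.finite(A)) == 0 & rowSums(!is.finite(B)) == 0
  }
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  tv <- (ma - mb) / se
  pv <- 2 * stats::pt(-abs(tv), df)
  degen <- is.finite(se) & se == 0
  i0 <- which(degen & ma == mb)
  tv[i0] <- 0; pv[i0] <- 1
  i1 <- which(degen & ma != mb)
  tv[i1] <- sign(ma - mb)[i1] * Inf; pv[i1] <- 0
  tv[!keep] <- NA_real_; pv[!keep] <- NA_real_
  structure(list(t = array(tv, dims), p = array(pv, dims),
                 mask = array(keep, dims), df = df,
                 degenerate = array(degen & keep, dims),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("p-value map: %s voxels tested, df = %d\n",
              format(n, big.mark = ","), x$df))
  if (n > 0)
    cat(sprintf("  %d voxels with p < 0.05 (%.1f%%)\n",
                sum(x$p < 0.05, na.rm = TRUE),
                100 * sum(x$p < 0.05, na.rm = TRUE) / n))
  invisible(x)
}

# Trilinear interpolation of a 3D volume onto per-axis target coordinates
# given in source voxel units (0-based continuous index). NA nodes
# propagate: any output sample whose 8-node neighborhood touches an NA is NA.
trilinear_resample <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-6, round(v), v)
  clamp <- function(v, n) pmin(pmax(snap(v), 0), n - 1)
  xi <- clamp(xi, d[1]); yi <- clamp(yi, d[2]); zi <- clamp(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 2 + (d[1] == 1)); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 2 + (d[2] == 1)); fy <- yi - y0
  z0 <- pmin(floor(zi), d[3] - 2 + (d[3] == 1)); fz <- zi - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, dim = c(nx, ny, nz))
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(x0 + dx, d[1] - 1) + 1
    iy <- pmin(y0 + dy, d[2] - 1) + 1
    iz <- pmin(z0 + dz, d[3] - 1) + 1
    node <- array(vol[ix, iy, iz, drop = FALSE], c(nx, ny, nz))
    w <- (if (dx) FX else 1 - FX) * (if (dy) FY else 1 - FY) *
      (if (dz) FZ else 1 - FZ)
    term <- w * node
    term[w == 0] <- 0       # zero-weight nodes never poison a sample with NA
    out <- out + term
  }
  out
}

#' Re-grid a p-value map by trilinear interpolation
#'
#' Recalculates the p volume on a finer grid (default 0.1 mm isotropic) for
#' presentation. Values at the original voxel centers are preserved exactly;
#' interpolated values are bounded by the surrounding nodes. Interpolation
#' never crosses the mask boundary: any target sample whose enclosing nodes
#' include an undefined voxel is undefined (`NA`).
#'
#' @param pmap a `pvalue_map`.
#' @param target_spacing_mm numeric length-3, each `<=` the source spacing.
#' @return A `pvalue_map` on the fine grid (t is interpolated the same way,
#'   for convenience; the p volume is interpolated directly, not re-derived
#'   from t).
#' @export
upsample_pmap <- function(pmap, target_spacing_mm = c(0.1, 0.1, 0.1)) {
  stopifnot(inherits(pmap, "pvalue_map"))
  src <- pmap$voxel_spacing_mm
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (any(target_spacing_mm > src + 1e-9))
    stop("target spacing must be <= source spacing on every axis")
  d <- dim(pmap$p)
  coords <- lapply(1:3, function(ax) {
    extent <- (d[ax] - 1) * src[ax]
    seq(0, extent, by = target_spacing_mm[ax]) / src[ax]  # 0-based voxel units
  })
  pw <- pmap$p; pw[!pmap$mask] <- NA_real_
  tw <- pmap$t; tw[!pmap$mask] <- NA_real_
  p_up <- trilinear_resample(pw, coords[[1]], coords[[2]], coords[[3]])
  t_up <- trilinear_resample(tw, coords[[1]], coords[[2]], coords[[3]])
  structure(list(t = t_up, p = p_up, mask = is.finite(p_up), df = pmap$df,
                 degenerate = NULL, voxel_spacing_mm = target_spacing_mm),
            class = "pvalue_map")
}

#' Define VOIs from a significance map
#'
#' Thresholds the p map at `alpha`, labels connected components of the
#' significant voxels (26-neighborhood: voxels sharing a face, edge or
#' corner), discards components smaller than `min_cluster`, and returns the
#' surviving clusters as VOIs sorted by size (largest first, ties broken by
#' the smallest linear voxel index in the component).
#'
#' @param pmap a `pvalue_map`.
#' @param alpha significance level in (0, 1).
#' @param min_cluster minimum cluster size in voxels.
#' @return A list of [voi()] objects (possibly empty), labelled
#'   `cluster1`, `cluster2`, ...
#' @export
define_vois <- function(pmap, alpha = 0.05, min_cluster = 5) {
  stopifnot(inherits(pmap, "pvalue_map"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  d <- dim(pmap$p)
  sig <- which(pmap$p < alpha & pmap$mask)
  if (length(sig) == 0L) return(list())
  in_sig <- logical(prod(d)); in_sig[sig] <- TRUE
  labels <- integer(prod(d))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  comp <- 0L
  comps <- list()
  for (s in sig) {
    if (labels[s]) next
    comp <- comp + 1L
    queue <- s; labels[s] <- comp
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      ijk <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nl <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- nl[in_sig[nl] & labels[nl] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
    comps[[comp]] <- sort(members)
  }
  comps <- Filter(function(m) length(m) >= min_cluster, comps)
  if (length(comps) == 0L) return(list())
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, min, integer(1)))
  comps <- comps[ord]
  lapply(seq_along(comps), function(i)
    voi(arrayInd(comps[[i]], d), label = paste0("cluster", i)))
}

#' VOI-level group test
#'
#' For each animal, the unweighted mean of its parameter map over the VOI;
#' then an unpaired two-tailed Student's t-test (pooled variance) between
#' the two groups of per-animal means.
#'
#' @param maps_a,maps_b lists of 3D arrays, one per animal.
#' @param v a [voi()].
#' @return A list with `t`, `p`, `df`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `n_voxels` and the per-animal means `values_a`, `values_b`.
#' @export
voi_test <- function(maps_a, maps_b, v) {
  stopifnot(inherits(v, "voi"))
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least two maps per group")
  dims <- dim(maps_a[[1]])
  check_voi_in_grid(v, dims)
  lin <- voi_linear_index(v, dims)
  mean_voi <- function(m) mean(m[lin])
  xa <- vapply(maps_a, mean_voi, numeric(1))
  xb <- vapply(maps_b, mean_voi, numeric(1))
  na <- length(xa); nb <- length(xb)
  sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- if (se == 0) { if (mean(xa) == mean(xb)) 0 else
    sign(mean(xa) - mean(xb)) * Inf } else (mean(xa) - mean(xb)) / se
  pv <- if (is.infinite(tv)) 0 else 2 * stats::pt(-abs(tv), na + nb - 2)
  list(t = tv, p = pv, df = na + nb - 2,
       mean_a = mean(xa), sem_a = stats::sd(xa) / sqrt(na),
       mean_b = mean(xb), sem_b = stats::sd(xb) / sqrt(nb),
       n_voxels = length(lin), values_a = xa, values_b = xb)
}

#' Seeded power simulation for the VOI test
#'
#' Repeats the full analysis chain -- simulate a two-group phantom study,
#' extract and partial-volume-correct the image-derived input function per
#' animal, fit the affected region's voxels, and run [voi_test()] on the
#' per-animal regional CE/CP means -- and returns the p-value of each
#' repeat. Repeat seeds are `seed + 1000 * repeat index`.
#'
#' @param spec a [phantom_spec()] whose `group_effects` name the affected
#'   region; the VOI tested is that region.
#' @param n_per_group animals per group.
#' @param n_repeats number of seeded repeats.
#' @param seed base seed.
#' @param param parameter tested, default CE/CP.
#' @return numeric vector of p-values, one per repeat.
#' @export
voi_power_simulation <- function(spec, n_per_group = 8, n_repeats = 100,
                                 seed = 1L, param = "CEoverCP") {
  region <- names(spec$group_effects)[1]
  target <- spec$regions[[region]]$voi
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  vapply(seq_len(n_repeats), function(r) {
    st <- generate_group_study(spec, cp, n_per_group = n_per_group,
                               seed = seed + 1000L * r, schedule = sched)
    fit_one <- function(img) {
      idif <- pve_correct(extract_voi_tac(img, spec$blood_region))
      fit_image(img, idif, mask = target)[[param]]
    }
    maps_a <- lapply(st$group_a, fit_one)
    maps_b <- lapply(st$group_b, fit_one)
    voi_test(maps_a, maps_b, target)$p
  }, numeric(1))
}

#' Tabulate VOI tests over a list of VOIs
#'
#' @inheritParams voi_test
#' @param vois list of [voi()] objects.
#' @return A data frame with one row per VOI: `label, n_voxels, mean_a,
#'   sem_a, mean_b, sem_b, t, p`.
#' @export
voi_test_table <- function(maps_a, maps_b, vois) {
  do.call(rbind, lapply(vois, function(v) {
    r <- voi_test(maps_a, maps_b, v)
    data.frame(label = v$label, n_voxels = r$n_voxels,
               mean_a = r$mean_a, sem_a = r$sem_a,
               mean_b = r$mean_b, sem_b = r$sem_b, t = r$t, p = r$p)
  }))
}
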