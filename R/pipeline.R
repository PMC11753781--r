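# Orchestration: a shared config, seeded deterministic runs of the
# simulate / fit / stats / calcium / behavior stages, and a manifest of
# written artifacts with content checksums. The exported functions are the
# package-level interface; inst/cli/fdgmap.R is a thin shell wrapper.

KNOWN_CONFIG_KEYS <- c("seed", "out_dir", "simulate", "fit", "stats",
                       "calcium", "behavior")

#' Load and validate a run configuration
#'
#' Configurations are nested key--value YAML. Unknown top-level keys are
#' rejected; stage blocks carry stage-specific settings (see the demo config
#' in `system.file("demo", "demo-config.yml", package = "fdgmap")`).
#' Model constants are range-checked: `volume_fraction` in (0, 1],
#' `lumped_factor` > 0, `alpha` in (0, 1).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a file path or a named list")
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("config field 'out_dir' is required")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  vf <- cfg$fit$volume_fraction %||% 0.6
  if (vf <= 0 || vf > 1) stop("fit.volume_fraction must be in (0, 1]")
  lf <- cfg$fit$lumped_factor %||% 0.26
  if (lf <= 0) stop("fit.lumped_factor must be > 0")
  al <- cfg$stats$alpha %||% 0.05
  if (al <= 0 || al >= 1) stop("stats.alpha must be in (0, 1)")
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

update_manifest <- function(out_dir, paths) {
  mf <- file.path(out_dir, "manifest.csv")
  old <- if (file.exists(mf)) utils::read.csv(mf) else
    data.frame(path = character(0), md5 = character(0))
  rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
             normalizePath(paths))
  new <- data.frame(path = rel, md5 = unname(tools::md5sum(paths)))
  keep <- old[!old$path %in% new$path, , drop = FALSE]
  all <- rbind(keep, new)
  all <- all[order(all$path), , drop = FALSE]
  utils::write.csv(all, mf, row.names = FALSE)
  invisible(mf)
}

#' Run one pipeline stage
#'
#' Dispatches on subcommand: `"simulate"` writes a synthetic two-group
#' phantom study (dynamic images, truth tables, region VOIs, study
#' metadata); `"fit"` extracts the image-derived input function from the
#' blood VOI, applies the partial-volume correction and fits every masked
#' voxel of every animal; `"stats"` runs the voxel-wise t-test on the fitted
#' parameter maps, defines VOIs from the significant clusters and tests
#' them; `"calcium"` classifies responder traces; `"behavior"` computes the
#' behavioral metrics. Every stage appends the files it writes to
#' `<out_dir>/manifest.csv` with their MD5 checksums; identical config and
#' seed reproduce identical artifacts.
#'
#' @param subcommand one of `"simulate"`, `"fit"`, `"stats"`, `"calcium"`,
#'   `"behavior"`.
#' @param config a path or list accepted by [read_run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, the character vector of files written.
#' @export
fdg_run <- function(subcommand, config, quiet = FALSE) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  written <- switch(match.arg(subcommand, c("simulate", "fit", "stats",
                                            "calcium", "behavior")),
                    simulate = run_simulate(cfg, say),
                    fit = run_fit(cfg, say),
                    stats = run_stats(cfg, say),
                    calcium = run_calcium(cfg, say),
                    behavior = run_behavior(cfg, say))
  update_manifest(cfg$out_dir, written)
  invisible(written)
}

run_simulate <- function(cfg, say) {
  sc <- cfg$simulate %||% list()
  n <- sc$n_per_group %||% 8
  spec <- default_phantom_spec(
    seed = cfg$seed,
    noise_cv = sc$noise_cv %||% 0.05,
    group_effects = unlist(sc$group_effects %||% list(striatum = 1.15)))
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  study <- generate_group_study(spec, cp, n_per_group = n, seed = cfg$seed)
  img_dir <- file.path(cfg$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  paths <- character(0)
  for (g in c("a", "b")) {
    imgs <- study[[paste0("group_", g)]]
    for (i in seq_along(imgs)) {
      p <- file.path(img_dir, sprintf("group%s_%02d.nii", toupper(g), i))
      write_dynamic_image(imgs[[i]], p)
      paths <- c(paths, p, sidecar_path(p))
    }
  }
  vpath <- file.path(cfg$out_dir, "regions.csv")
  vois <- c(lapply(names(spec$regions), function(nm) {
    v <- spec$regions[[nm]]$voi; v$label <- nm; v
  }), list({ b <- spec$blood_region; b$label <- "blood"; b }))
  write_voi_table(vois, vpath)
  tpath <- file.path(cfg$out_dir, "truth_params.csv")
  utils::write.csv(as.data.frame(study$truth_a), tpath, row.names = FALSE)
  meta <- file.path(cfg$out_dir, "study.yml")
  yaml::write_yaml(list(grid_shape = spec$grid_shape,
                        voxel_spacing_mm = spec$voxel_spacing_mm,
                        n_per_group = n, seed = cfg$seed), meta)
  say("simulate: wrote ", 2 * n, " dynamic images to ", img_dir)
  c(paths, vpath, tpath, meta)
}

run_fit <- function(cfg, say) {
  fc <- cfg$fit %||% list()
  meta <- yaml::read_yaml(file.path(cfg$out_dir, "study.yml"))
  vois <- read_voi_table(file.path(cfg$out_dir, "regions.csv"))
  blood <- vois[["blood"]]
  mask_mode <- fc$mask %||% "regions"
  mask <- if (identical(mask_mode, "regions")) {
    idx <- do.call(rbind, lapply(vois[setdiff(names(vois), "blood")],
                                 function(v) v$voxel_indices))
    voi(idx, "tissue")
  } else if (identical(mask_mode, "all")) NULL else
    read_voi_table(mask_mode)[[1]]
  img_dir <- file.path(cfg$out_dir, "images")
  map_dir <- file.path(cfg$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  paths <- character(0)
  for (f in sort(list.files(img_dir, pattern = "\\.nii$",
                            full.names = TRUE))) {
    img <- read_dynamic_image(f)
    idif <- pve_correct(extract_voi_tac(img, blood),
                        fc$volume_fraction %||% 0.6)
    pmap <- fit_image(img, idif, mask = mask,
                      pin_k4 = isTRUE(fc$pin_k4),
                      lumped_factor = fc$lumped_factor %||% 0.26)
    stem <- file.path(map_dir, sub("\\.nii$", "", basename(f)))
    p <- paste0(stem, "_params.csv")
    utils::write.csv(as.data.frame(pmap), p, row.names = FALSE)
    n_conv <- sum(pmap$converged)
    say("fit: ", basename(f), " -> ", n_conv, " converged voxels")
    paths <- c(paths, p)
  }
  paths
}

read_param_maps <- function(map_dir, pattern, grid_shape, param) {
  files <- sort(list.files(map_dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no parameter tables matching ", pattern,
                                " in ", map_dir)
  lapply(files, function(f) {
    tab <- utils::read.csv(f)
    vol <- array(NA_real_, dim = grid_shape)
    lin <- tab$voxel_x + grid_shape[1] * (tab$voxel_y - 1L) +
      grid_shape[1] * grid_shape[2] * (tab$voxel_z - 1L)
    vol[lin] <- tab[[param]]
    vol
  })
}

run_stats <- function(cfg, say) {
  sc <- cfg$stats %||% list()
  meta <- yaml::read_yaml(file.path(cfg$out_dir, "study.yml"))
  gs <- as.integer(unlist(meta$grid_shape))
  param <- sc$param %||% "CEoverCP"
  map_dir <- file.path(cfg$out_dir, "maps")
  maps_a <- read_param_maps(map_dir, "^groupA.*_params\\.csv$", gs, param)
  maps_b <- read_param_maps(map_dir, "^groupB.*_params\\.csv$", gs, param)
  pmap <- voxelwise_ttest(maps_a, maps_b,
                          voxel_spacing_mm = unlist(meta$voxel_spacing_mm))
  st_dir <- file.path(cfg$out_dir, "stats")
  dir.create(st_dir, showWarnings = FALSE)
  tp <- file.path(st_dir, "t_map.nii"); pp <- file.path(st_dir, "p_map.nii")
  write_map(pmap$t, pmap$voxel_spacing_mm, tp, fill = 0)
  write_map(pmap$p, pmap$voxel_spacing_mm, pp, fill = 1)
  paths <- c(tp, pp)
  if (isTRUE(sc$upsample)) {
    up <- upsample_pmap(pmap)
    pu <- file.path(st_dir, "p_map_0.1mm.nii")
    write_map(up$p, up$voxel_spacing_mm, pu, fill = 1)
    paths <- c(paths, pu)
  }
  vois <- define_vois(pmap, alpha = sc$alpha %||% 0.05,
                      min_cluster = sc$min_cluster %||% 5)
  vt <- file.path(st_dir, "voi_tests.csv")
  tab <- if (length(vois)) voi_test_table(maps_a, maps_b, vois) else
    data.frame(label = character(0), n_voxels = integer(0),
               mean_a = numeric(0), sem_a = numeric(0), mean_b = numeric(0),
               sem_b = numeric(0), t = numeric(0), p = numeric(0))
  utils::write.csv(tab, vt, row.names = FALSE)
  say("stats: ", sum(pmap$p < sc$alpha %||% 0.05, na.rm = TRUE),
      " significant voxels, ", length(vois), " VOIs")
  c(paths, vt)
}

run_calcium <- function(cfg, say) {
  cc <- cfg$calcium %||% list()
  if (is.null(cc$traces) || is.null(cc$windows))
    stop("calcium stage needs 'traces' and 'windows' file paths")
  traces <- read_trace_table(cc$traces, cc$windows)
  calls <- do.call(rbind, lapply(names(traces), function(nm) {
    tr0 <- traces[[nm]]
    # fit the bleach trend on the whole agonist-free head of the recording
    tr <- correct_bleaching(tr0, c(tr0$times_s[1], tr0$windows$baseline[2]))
    q <- quantify_response(tr)
    call <- classify_responder(q$response, q$sigma,
                               cc$threshold_multiple %||% 3)
    hk <- quantify_response(tr, "baseline", "highK")
    pct <- if (hk$response > 0)
      normalize_to_highK(q$response, hk$response) else NA_real_
    data.frame(trace = nm, response = q$response, sigma = q$sigma,
               z_score = call$z_score, responder = call$responder,
               pct_highK = pct)
  }))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(cfg$out_dir, "calcium_calls.csv")
  utils::write.csv(calls, p, row.names = FALSE)
  say("calcium: ", sum(calls$responder), "/", nrow(calls), " responders")
  p
}

run_behavior <- function(cfg, say) {
  bc <- cfg$behavior %||% list()
  paths <- character(0)
  if (!is.null(bc$cpp)) {
    tab <- cpp_score_table(utils::read.csv(bc$cpp))
    p <- file.path(cfg$out_dir, "cpp_scores.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bc$bottles)) {
    bt <- utils::read.csv(bc$bottles)
    per_animal <- vapply(split(bt, bt$animal), function(d)
      preference_percentage(sum(d$solution_g), sum(d$water_g)), numeric(1))
    test <- preference_test(per_animal)
    p <- file.path(cfg$out_dir, "preference.csv")
    utils::write.csv(data.frame(animal = names(per_animal),
                                preference_pct = per_animal,
                                group_mean = test$mean, group_p = test$p),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bc$activity)) {
    at <- utils::read.csv(bc$activity)
    inj <- at$injection_min[1]
    pre_w <- unlist(bc$window_pre %||% c(inj - 40, inj - 10))
    post_w <- unlist(bc$window_post %||% c(inj + 5, inj + 35))
    p <- file.path(cfg$out_dir, "locomotor_auc.csv")
    utils::write.csv(data.frame(
      window = c("pre", "post"),
      start_min = c(pre_w[1], post_w[1]), end_min = c(pre_w[2], post_w[2]),
      auc = c(locomotor_auc(at$bin_min, at$counts, pre_w),
              locomotor_auc(at$bin_min, at$counts, post_w))),
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(paths) == 0L) stop("behavior stage got no input tables")
  paths
}

#' Read traces and window annotations from CSV
#'
#' `traces_path` holds columns `trace, time_s, value` (long format);
#' `windows_path` holds `label, start_s, end_s` applied to every trace.
#'
#' @param traces_path,windows_path file paths.
#' @return A named list of [trace()] objects.
#' @export
read_trace_table <- function(traces_path, windows_path) {
  tt <- utils::read.csv(traces_path)
  if (!all(c("trace", "time_s", "value") %in% names(tt)))
    stop("trace table needs columns trace, time_s, value")
  wt <- utils::read.csv(windows_path)
  if (!all(c("label", "start_s", "end_s") %in% names(wt)))
    stop("window table needs columns label, start_s, end_s")
  windows <- lapply(seq_len(nrow(wt)), function(i)
    c(wt$start_s[i], wt$end_s[i]))
  names(windows) <- wt$label
  out <- lapply(split(tt, tt$trace), function(d)
    trace(d$time_s, d$value, windows))
  out[unique(tt$trace)]
}

#' Write traces and their windows to CSV
#'
#' Inverse of [read_trace_table()]; all traces must share the same windows.
#'
#' @param traces named list of [trace()] objects.
#' @param traces_path,windows_path output paths.
#' @export
write_trace_table <- function(traces, traces_path, windows_path) {
  if (is.null(names(traces)))
    names(traces) <- sprintf("trace%03d", seq_along(traces))
  long <- do.call(rbind, lapply(names(traces), function(nm)
    data.frame(trace = nm, time_s = traces[[nm]]$times_s,
               value = traces[[nm]]$values)))
  utils::write.csv(long, traces_path, row.names = FALSE)
  w <- traces[[1]]$windows
  utils::write.csv(data.frame(label = names(w),
                              start_s = vapply(w, `[`, numeric(1), 1),
                              end_s = vapply(w, `[`, numeric(1), 2)),
                   windows_path, row.names = FALSE)
  invisible(c(traces_path, windows_path))
}
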