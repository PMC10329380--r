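# Config-driven orchestration: simulate (or read) -> detect/track ->
# kymograph -> dwell/SCI/coloc, with a reproducible run manifest.

#' Compare dwell-time groups
#'
#' Two-sample t test on uncensored dwell times. Welch's test is the default
#' (no variance-homogeneity assumption); the classical equal-variance
#' Student's flavor is available for comparability with reports that use it.
#' Censored values (NA) are rejected, not silently dropped: filter them
#' first, deliberately.
#'
#' @param dwells_a,dwells_b numeric vectors of uncensored dwell times,
#'   seconds; each of length >= 2.
#' @param flavor `"welch"` (default) or `"student"`.
#' @return list of class `GroupComparison`: per-group `n, mean, sd`,
#'   `t_stat`, `df`, `p_value`, `flavor`.
#' @examples
#' compare_groups(c(3.1, 3.9, 4.2, 3.6), c(2.2, 2.9, 2.4, 2.8))
#' @export
compare_groups <- function(dwells_a, dwells_b,
                           flavor = c("welch", "student")) {
  flavor <- match.arg(flavor)
  if (anyNA(dwells_a) || anyNA(dwells_b)) {
    stop("censored (NA) dwell values present: filter them out explicitly ",
         "before group comparison")
  }
  if (length(dwells_a) < 2L || length(dwells_b) < 2L) {
    stop("each group needs at least 2 uncensored dwell values")
  }
  tt <- stats::t.test(dwells_a, dwells_b, var.equal = (flavor == "student"))
  structure(list(
    n = c(a = length(dwells_a), b = length(dwells_b)),
    mean = c(a = mean(dwells_a), b = mean(dwells_b)),
    sd = c(a = stats::sd(dwells_a), b = stats::sd(dwells_b)),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, flavor = flavor
  ), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "Group A: n=%d, %.2f +/- %.2f s | Group B: n=%d, %.2f +/- %.2f s\n%s t = %.3f (df %.1f), p = %.3g\n",
    x$n["a"], x$mean["a"], x$sd["a"], x$n["b"], x$mean["b"], x$sd["b"],
    if (x$flavor == "welch") "Welch" else "Student", x$t_stat, x$df,
    x$p_value))
  invisible(x)
}

# Auto scan-line placement: one horizontal line of length 2*ceil(3 sigma)+1
# through each trajectory's time-median position, clamped so the widthwise
# band stays inside the image; trajectories too close to the border for the
# band are skipped.
auto_scan_lines <- function(trajs, dims, psf_sigma_px, linewidth = 11L,
                            min_locs = 3L) {
  ts <- trajectory_summary(trajs)
  ts <- ts[ts$n_locs >= min_locs, , drop = FALSE]
  half <- ceiling(3 * psf_sigma_px)
  margin_y <- (linewidth - 1) / 2
  lines <- list()
  for (i in seq_len(nrow(ts))) {
    cx <- round(ts$x_med[i]); cy <- round(ts$y_med[i])
    if (cx - half < 0 || cx + half > dims[2] - 1 ||
        cy - margin_y < 0 || cy + margin_y > dims[1] - 1) next
    ln <- scan_line(cx - half, cy, cx + half, cy, linewidth)
    lines[[length(lines) + 1L]] <- list(line = ln, traj_id = ts$traj_id[i])
  }
  lines
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the package end to end from a single config: simulate a
#' movie (or read TIFF stacks), detect and link particles, place scan lines
#' (auto or from CSV), extract kymographs, detect/validate dwell segments,
#' compute the SCI, and — for two-channel runs — register channel B and
#' quantify colocalization. All randomness derives from `config$seed`; the
#' same config and seed reproduce byte-identical CSV outputs.
#'
#' Config keys (all optional unless noted): `seed`; `outdir` (required);
#' either `simulate` (a [sim_params()]-style list), `simulate_two_channel`
#' (a [two_channel_params()]-style list) or `inputs` (list with `path`(s),
#' `frame_interval_s`, `pixel_size_um`); `detect` (`psf_sigma_px`,
#' `threshold_k`, `first_n_frames`); `link` (`max_disp_px`, `max_gap`);
#' `kymo` (`linewidth`, `reduction`, `threshold_k`, `max_gap_frames`,
#' `scan_lines` = `"auto"` or a CSV path, `match_radius_px`); `coloc`
#' (`dist_thresh_px`, `min_frames`); `write_images` (logical).
#'
#' @param config named list or path to a YAML config file.
#' @return invisibly, a list with the dwell table, trajectories, SCI,
#'   colocalization result (or NULL), per-stage counts, and the manifest;
#'   the same tables are written as CSV under `config$outdir` together with
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$outdir)) stop("config$outdir is required")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  counts <- list()

  # --- acquire -------------------------------------------------------------
  two_channel <- !is.null(config$simulate_two_channel)
  truth <- NULL; stack_b <- NULL
  if (two_channel) {
    tc <- config$simulate_two_channel
    prm <- run_stage("simulate", {
      ba <- do.call(sim_params, tc$base_a %||% list())
      ba$seed <- seed
      bb <- if (is.null(tc$base_b)) NULL else do.call(sim_params, tc$base_b)
      two_channel_params(ba, bb, tc$coloc_fraction %||% 0.5,
                         tc$channel_shift_px %||% c(0, 0))
    })
    sim <- run_stage("simulate", simulate_two_channel(prm))
    stack <- sim$stack_a; stack_b <- sim$stack_b; truth <- sim$truth
  } else if (!is.null(config$simulate)) {
    args <- config$simulate; args$seed <- seed
    prm <- run_stage("simulate", do.call(sim_params, args))
    sim <- run_stage("simulate", simulate_movie(prm))
    stack <- sim$stack; truth <- sim$truth
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    stack <- run_stage("image_io", read_stack(inp$path, inp$frame_interval_s,
                                              inp$pixel_size_um))
    if (!is.null(inp$path_b)) {
      stack_b <- run_stage("image_io", read_stack(inp$path_b,
                                                  inp$frame_interval_s,
                                                  inp$pixel_size_um))
      two_channel <- TRUE
    }
  } else {
    stop("config must provide 'simulate', 'simulate_two_channel' or 'inputs'")
  }
  if (!is.null(truth)) {
    run_stage("simulate", write_ground_truth(
      truth, file.path(config$outdir, "truth_particles.csv"),
      file.path(config$outdir, "truth_positions.csv")))
  }

  # --- detect & track ------------------------------------------------------
  det <- config$detect %||% list()
  psf_sigma <- det$psf_sigma_px %||% 1.0
  locs <- run_stage("detect", detect_movie(stack, psf_sigma,
                                           det$threshold_k %||% 3,
                                           det$first_n_frames))
  lnk <- config$link %||% list()
  trajs <- run_stage("track", link_trajectories(locs,
                                                lnk$max_disp_px %||% 3,
                                                lnk$max_gap %||% 1L))
  counts$n_localizations <- nrow(locs)
  counts$n_trajectories <- length(unique(trajs$traj_id))
  write_trajectories(trajs, file.path(config$outdir, "trajectories.csv"))

  # --- kymographs & dwell --------------------------------------------------
  kcfg <- config$kymo %||% list()
  linewidth <- kcfg$linewidth %||% 11L
  reduction <- kcfg$reduction %||% "max"
  scan_src <- kcfg$scan_lines %||% "auto"
  lines <- run_stage("kymograph", {
    if (identical(scan_src, "auto")) {
      auto_scan_lines(trajs, dim(stack$pixels), psf_sigma, linewidth,
                      kcfg$min_locs %||% 3L)
    } else {
      lapply(read_scan_lines(scan_src, linewidth),
             function(ln) list(line = ln, traj_id = NA_integer_))
    }
  })
  counts$n_scan_lines <- length(lines)
  dwell_rows <- list()
  for (li in seq_along(lines)) {
    entry <- lines[[li]]
    seg <- run_stage("kymograph", {
      kymo <- extract_kymograph(stack, entry$line, reduction)
      segs <- detect_segments(kymo, threshold_k = kcfg$threshold_k %||% 3,
                              max_gap_frames = kcfg$max_gap_frames %||% 1L,
                              min_area_px = kcfg$min_area_px %||% 3L)
      segs <- validate_segments(segs, kymo, trajs,
                                match_radius_px = kcfg$match_radius_px %||% 3,
                                min_support_frames = kcfg$min_support_frames %||% 2L)
      if (isTRUE(config$write_images) && nrow(segs) > 0L) {
        render_views(kymo, NULL,
                     file.path(config$outdir, sprintf("line%03d", li)))
      }
      segs
    })
    if (nrow(seg) > 0L) {
      seg <- cbind(line_id = li, line_traj = entry$traj_id, seg)
      dwell_rows[[length(dwell_rows) + 1L]] <- seg
    }
  }
  dwell <- if (length(dwell_rows) > 0L) {
    do.call(rbind, dwell_rows)
  } else {
    data.frame(line_id = integer(), line_traj = integer(),
               start_frame = integer(), end_frame = integer(),
               j_min = integer(), j_max = integer(),
               censored_left = logical(), censored_right = logical(),
               dwell_s = numeric(), status = character(),
               reason = character(), support_traj = integer())
  }
  counts$n_segments <- nrow(dwell)
  counts$n_validated <- sum(dwell$status == "validated")
  counts$n_rejected_censored <- sum(dwell$reason %in% "censored")
  counts$n_rejected_merged <- sum(dwell$reason %in% "merged")
  counts$n_rejected_unsupported <- sum(dwell$reason %in% "unsupported")
  utils::write.csv(dwell, file.path(config$outdir, "dwell.csv"),
                   row.names = FALSE)

  # --- SCI -----------------------------------------------------------------
  sci <- run_stage("sci", compute_sci(stack))
  sci_tab <- data.frame(channel = "A", frame = seq_along(sci$per_frame) - 1L,
                        sci = sci$per_frame)
  coloc <- NULL
  if (two_channel) {
    run_stage("coloc", {
      sci_b <- compute_sci(stack_b)
      sci_tab <- rbind(sci_tab,
                        data.frame(channel = "B",
                                   frame = seq_along(sci_b$per_frame) - 1L,
                                   sci = sci_b$per_frame))
      mean_a <- apply(stack$pixels, c(1, 2), mean)
      mean_b <- apply(stack_b$pixels, c(1, 2), mean)
      reg <- estimate_registration(mean_a, mean_b)
      locs_b <- detect_movie(stack_b, psf_sigma, det$threshold_k %||% 3,
                             det$first_n_frames)
      trajs_b <- link_trajectories(locs_b, lnk$max_disp_px %||% 3,
                                   lnk$max_gap %||% 1L)
      trajs_b <- register_trajectories(trajs_b, reg)
      ccfg <- config$coloc %||% list()
      coloc <- colocalize_trajectories(trajs, trajs_b,
                                        ccfg$dist_thresh_px %||% 2,
                                        ccfg$min_frames %||% 3L)
      utils::write.csv(coloc$per_traj, file.path(config$outdir, "coloc.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(dx = reg$dx, dy = reg$dy, score = reg$score,
                   low_confidence = reg$low_confidence,
                   coloc_fraction = coloc$summary,
                   ci_lo = coloc$ci[1], ci_hi = coloc$ci[2]),
        file.path(config$outdir, "coloc_summary.csv"), row.names = FALSE)
    })
  }
  utils::write.csv(sci_tab, file.path(config$outdir, "sci.csv"),
                   row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(package = "smkymo",
                   version = as.character(utils::packageVersion("smkymo")),
                   seed = seed, config = config, counts = counts)
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  message(sprintf(
    "pipeline: %d localizations, %d trajectories, %d scan lines, %d segments (%d validated, %d censored, %d merged, %d unsupported)",
    counts$n_localizations, counts$n_trajectories, counts$n_scan_lines,
    counts$n_segments, counts$n_validated, counts$n_rejected_censored,
    counts$n_rejected_merged, counts$n_rejected_unsupported))
  invisible(list(dwell = dwell, trajectories = trajs, sci = sci,
                 coloc = coloc, counts = counts, manifest = manifest,
                 truth = truth))
}
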