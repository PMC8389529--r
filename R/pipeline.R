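## End-to-end orchestration: path-find -> resample -> path CVs ->
## WT-MetaD -> F(S,Z) -> x* -> standard binding free energy, with every
## intermediate persisted when an output directory is given.

#' Pipeline configuration
#'
#' Validates and freezes all settings of a [run_pipeline()] invocation.
#' Either a toy `system` is supplied (the engine stage runs), or
#' `skip_engine = TRUE` with paths to precomputed HILLS/COLVAR files (the
#' analysis stages run on them). Referenced files are checked for
#' existence up front, before any computation.
#'
#' @param system A `"toy_system"` (e.g. [toy_funnel()]); `NULL` when
#'   `skip_engine`.
#' @param cloud A [points_cloud()] of sampled configurations.
#' @param endpoints 2 x d matrix: bound and fully unbound configurations.
#' @param n_waypoints Number of principal-path waypoints.
#' @param smoothness Smoothness `s`, or a grid (the elbow pick of
#'   [select_smoothness()] is used).
#' @param threshold Equidistance RMSD threshold in nm (default 0.1).
#' @param lambda `"AUTO"` (heuristic from the resampled spacing) or a
#'   value in nm^-2.
#' @param metad_params A [wtmetad_params()].
#' @param n_steps,dt,friction Engine settings.
#' @param seed Integer seed controlling every stochastic stage.
#' @param n_s,n_z FES grid resolution (default 200 x 50).
#' @param v_bulk Sampled unbound volume in A^3 (default the standard
#'   volume, i.e. no correction), or an [atom_spheres()] set measured
#'   with [ses_volume()].
#' @param skip_engine If `TRUE`, read `hills_file`/`colvar_file` instead
#'   of running the engine; `rescale_p` must then give the path length P.
#' @param hills_file,colvar_file Precomputed ledgers (HILLS dialect).
#' @param rescale_p Number of path frames for raw-to-rescaled S mapping
#'   when `skip_engine`.
#' @param pad_frames Number of extrapolated frames added at each path end
#'   before building the CVs (default 2; see [pad_path_refs()]).
#' @param n_dg_checkpoints Number of time checkpoints for the
#'   time-average of the binding free energy (default 10).
#' @param out_dir Directory for intermediates and the final report
#'   (`NULL` = keep everything in memory).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(system = NULL, cloud = NULL, endpoints = NULL,
                            n_waypoints = 12, smoothness = 1,
                            threshold = 0.1, lambda = "AUTO",
                            metad_params = wtmetad_params(),
                            n_steps = 1.5e8, dt = 0.002, friction = 10,
                            seed = 1, n_s = 200, n_z = 50,
                            v_bulk = standard_volume(FALSE),
                            skip_engine = FALSE, hills_file = NULL,
                            colvar_file = NULL, rescale_p = NULL,
                            pad_frames = 2, n_dg_checkpoints = 10,
                            out_dir = NULL) {
  if (skip_engine) {
    for (f in c(hills_file, colvar_file)) {
      if (is.null(f) || !file.exists(f))
        stop("missing input file: ", f %||% "(hills/colvar not given)")
    }
    if (is.null(rescale_p))
      stop("rescale_p (path length P) is required with skip_engine")
  } else {
    stopifnot(inherits(system, "toy_system"),
              inherits(cloud, "points_cloud"), !is.null(endpoints))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full workflow
#'
#' Executes, in order: principal-path extraction and snapping to samples;
#' equidistant resampling with the geometric propagator; path-CV
#' construction with the automatic lambda; WT-MetaD on the toy system
#' (skipped when precomputed ledgers are given); FES reconstruction;
#' the dG-versus-divider curve and x* identification; bound/unbound
#' integration, standard-volume correction and time-average statistics
#' over the converged window. Every intermediate is returned (and written
#' under `out_dir` when given) so the run can be resumed from any stage.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"binding_result"` with fields `dg_b`, `dg_v`,
#'   `dg_standard`, `stderr`, `v_bulk`, `x_star`, `converged_window`, and
#'   a `stages` list holding every intermediate (path model, snapped
#'   ids, resampled points, PCV definition, run, fes, pmf, curve).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stages <- list()
  persist <- !is.null(cfg$out_dir)
  if (persist) dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(name, note) {
    message(sprintf("[pipeline] %-12s %s", name, note))
  }

  if (!cfg$skip_engine) {
    set.seed(cfg$seed)
    ## 1. principal path
    s_use <- if (length(cfg$smoothness) > 1) {
      pick <- select_smoothness(cfg$cloud, cfg$endpoints, cfg$n_waypoints,
                                cfg$smoothness)
      stages$smoothness_scan <- pick
      pick$s
    } else cfg$smoothness
    fit <- fit_principal_path(cfg$cloud, cfg$endpoints, cfg$n_waypoints,
                              s = s_use)
    snapped <- snap_to_samples(fit, cfg$cloud)
    stages$path_model <- fit
    stages$snapped_ids <- snapped
    log_stage("path-find", sprintf("%d waypoints -> %d snapped frames (s = %g)",
                                   cfg$n_waypoints, length(snapped), s_use))

    ## 2. equidistant resampling (toy points as single-atom conformations);
    ## snapped frames closer than the threshold to the previous kept frame
    ## are pruned first, so insertion yields near-uniform spacing
    idx <- match(snapped, cfg$cloud$frame_ids)
    pts <- cfg$cloud$samples[idx, , drop = FALSE]
    pts <- rbind(cfg$endpoints[1, ], pts, cfg$endpoints[2, ])
    pts <- pts[!duplicated(pts), , drop = FALSE]
    confs <- lapply(seq_len(nrow(pts)), function(i)
      conformation(c(pts[i, ], rep(0, 3 - ncol(pts))), frame_id = i))
    confs <- prune_close_frames(confs, min_gap = cfg$threshold)
    rs <- equidistant_resample(confs, threshold = cfg$threshold)
    stages$resample_report <- rs$report
    refs <- t(vapply(rs$path, function(f) f$coords[1, seq_len(ncol(pts))],
                     numeric(ncol(pts))))
    stages$refs <- refs
    log_stage("resample", sprintf("%d -> %d frames, max gap %.3g nm",
                                  nrow(pts), nrow(refs), max(rs$report$final_gaps)))

    ## 3. path CVs (ends padded so no sampled basin sits on a path end)
    refs <- pad_path_refs(refs, cfg$pad_frames)
    stages$refs_padded <- refs
    defn <- pcv_definition(refs, lambda = cfg$lambda, rescaled = TRUE)
    stages$pcv <- defn
    log_stage("pcv", sprintf("P = %d, lambda = %.4g nm^-2", defn$P, defn$lambda))

    ## 4. WT-MetaD
    run <- run_wtmetad(cfg$system, defn, cfg$metad_params, cfg$n_steps,
                       dt = cfg$dt, friction = cfg$friction, seed = cfg$seed)
    hills <- run$hills
    colvar <- run$colvar
    stages$run <- run
    P <- defn$P
    log_stage("metad", sprintf("%d hills, final height %.3g kcal/mol",
                               nrow(hills), utils::tail(hills$height, 1)))
    if (persist) {
      write_hills(hills, file.path(cfg$out_dir, "HILLS"))
      write_colvar(colvar, file.path(cfg$out_dir, "COLVAR"))
      utils::write.csv(as.data.frame(refs),
                       file.path(cfg$out_dir, "path_refs.csv"),
                       row.names = FALSE)
    }
  } else {
    hills <- read_hills(cfg$hills_file)
    colvar <- read_colvar(cfg$colvar_file)
    P <- cfg$rescale_p
    log_stage("metad", sprintf("skipped; read %d hills from %s",
                               nrow(hills), cfg$hills_file))
  }

  ## 5. FES and profile
  fes <- fes_from_hills(hills, n_s = cfg$n_s, n_z = cfg$n_z, rescale_p = P)
  pmf <- pmf_along_s(fes, z_max = cfg$metad_params$wall_z)
  stages$fes <- fes
  stages$pmf <- pmf

  ## 6. divider; the search stays inside the physical (unpadded) span of
  ## the path -- the padded ends are deliberately unsampled
  pad <- if (cfg$skip_engine) 0L else cfg$pad_frames
  s_lo <- pad / (P - 1) + 0.02
  s_hi <- (P - 1 - pad) / (P - 1) - 0.02
  s_cand <- fes$s[fes$s > s_lo & fes$s < s_hi]
  curve <- dg_vs_divider_curve(fes, s_values = s_cand,
                               z_max = cfg$metad_params$wall_z)
  xstar <- find_x_star(curve, pmf[pmf$s > s_lo & pmf$s < s_hi, ])
  stages$curve <- curve
  log_stage("xstar", sprintf("s* = %.3f (%s)", xstar$s_star, xstar$method))

  ## 7. free energies with convergence window and time statistics
  v_bulk <- if (inherits(cfg$v_bulk, "atom_spheres"))
    as.numeric(ses_volume(cfg$v_bulk)) else cfg$v_bulk
  dg_v <- volume_correction(v_bulk)
  colvar_resc <- dplyr::mutate(colvar, s = (.data$s - 1) / (P - 1))
  win <- convergence_window(hills, colvar_resc,
                            height0 = cfg$metad_params$height)
  if (win$converged) {
    ts <- seq(win$t_start, win$t_end, length.out = cfg$n_dg_checkpoints)
    dg_series <- vapply(ts, function(tmax) {
      f <- fes_from_hills(hills[hills$time <= tmax, ],
                          n_s = cfg$n_s, n_z = cfg$n_z, rescale_p = P)
      dg_bound_unbound(f, xstar, z_max = cfg$metad_params$wall_z) + dg_v
    }, numeric(1))
    st <- dg_time_stats(dg_series)
    dg_std <- st$mean
    stderr <- st$stderr
    dg_b <- dg_std - dg_v
  } else {
    warning("run not converged: reporting the final-time estimate with NA stderr")
    dg_b <- dg_bound_unbound(fes, xstar, z_max = cfg$metad_params$wall_z)
    dg_std <- dg_b + dg_v
    stderr <- NA_real_
  }
  log_stage("dg", sprintf("dG_b = %.2f, dG_V = %.2f, dG_std = %.2f +/- %.2f",
                          dg_b, dg_v, dg_std, stderr))

  result <- structure(
    list(dg_b = dg_b, dg_v = dg_v, dg_standard = dg_std, stderr = stderr,
         v_bulk = v_bulk, x_star = xstar, converged_window = win,
         temperature = 300, stages = stages, config = cfg),
    class = "binding_result")
  if (persist) {
    report <- tidy(result)
    utils::write.csv(curve, file.path(cfg$out_dir, "dg_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(dg_b = dg_b, dg_v = dg_v, dg_standard = dg_std, stderr = stderr,
           v_bulk = v_bulk, v_standard = standard_volume(FALSE),
           s_star = xstar$s_star, x_star_method = xstar$method,
           converged = win$converged, t_start = win$t_start,
           t_end = win$t_end, seed = cfg$seed,
           lambda = if (!cfg$skip_engine) stages$pcv$lambda else NA),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

## drop frames closer than min_gap (RMSD) to the previously kept frame;
## both endpoints always survive, a too-close penultimate frame is dropped
prune_close_frames <- function(path, min_gap, align = NULL, measure = NULL) {
  n <- length(path)
  keep <- 1L
  for (i in seq(2L, n)) {
    last <- path[[keep[length(keep)]]]
    if (conf_rmsd(path[[i]], last, align, measure) >= min_gap || i == n)
      keep <- c(keep, i)
  }
  if (length(keep) > 2L) {
    tail_gap <- conf_rmsd(path[[keep[length(keep)]]],
                          path[[keep[length(keep) - 1L]]], align, measure)
    if (tail_gap < min_gap / 2) keep <- keep[-(length(keep) - 1L)]
  }
  path[keep]
}

#' @export
print.binding_result <- function(x, ...) {
  cat("<binding_result>\n")
  cat(sprintf("  dG_b      %8.2f kcal/mol\n", x$dg_b))
  cat(sprintf("  dG_V      %8.2f kcal/mol  (V_bulk %.0f A^3)\n",
              x$dg_v, x$v_bulk))
  cat(sprintf("  dG_b(std) %8.2f +/- %.2f kcal/mol\n", x$dg_standard,
              x$stderr))
  cat(sprintf("  x*        s = %.3f (%s); converged window %s\n",
              x$x_star$s_star, x$x_star$method,
              if (x$converged_window$converged)
                sprintf("[%.0f, %.0f] ps", x$converged_window$t_start,
                        x$converged_window$t_end) else "none"))
  invisible(x)
}

#' Tidy a binding result into one row per free energy term
#'
#' @param x A `"binding_result"`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `stderr`, `units`.
#' @rdname tidy
#' @export
tidy.binding_result <- function(x, ...) {
  tibble::tibble(
    term = c("dg_b", "dg_v", "dg_standard"),
    estimate = c(x$dg_b, x$dg_v, x$dg_standard),
    stderr = c(NA_real_, NA_real_, x$stderr),
    units = "kcal/mol")
}

#' One-row summary of a binding result
#'
#' @param x A `"binding_result"`.
#' @param ... Unused.
#' @return One-row tibble.
#' @rdname glance
#' @export
glance.binding_result <- function(x, ...) {
  tibble::tibble(
    dg_standard = x$dg_standard, stderr = x$stderr, s_star = x$x_star$s_star,
    x_star_method = x$x_star$method,
    converged = x$converged_window$converged, v_bulk = x$v_bulk)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
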