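#' Build and validate a pipeline run configuration
#'
#' A run configuration collects everything a reproducible analysis needs:
#' the stages to execute, the drusen condition, calibration, seeds, and
#' per-stage options. Unknown stages and inconsistent fields fail validation
#' before any computation.
#'
#' @param stages Character vector from `c("simulate", "thickness",
#'   "morphometrics", "swelling", "indent", "tfm")`.
#' @param condition `"medium-drusen"` or `"large-drusen"`.
#' @param seed Base integer seed; replicate r uses `seed + r - 1`.
#' @param n_replicates Number of synthetic replicates for the thickness and
#'   morphometrics stages.
#' @param center_xy Optional drusen center (um); defaults to the preset's.
#' @param exclusions Optional character vector of measurement/cell ids to
#'   exclude, recorded in the log (explicit manual-outlier policy).
#' @param options Named list of per-stage overrides (passed to the
#'   generators and analyses).
#' @return A validated `run_config`.
#' @export
run_config <- function(stages = c("simulate", "thickness"),
                       condition = "medium-drusen",
                       seed = 1L,
                       n_replicates = 3L,
                       center_xy = NULL,
                       exclusions = character(),
                       options = list()) {
  known <- c("simulate", "thickness", "morphometrics", "swelling", "indent",
             "tfm")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop_invalid("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  if (!condition %in% c("medium-drusen", "large-drusen")) {
    stop_invalid("`condition` must be 'medium-drusen' or 'large-drusen'")
  }
  check_positive(n_replicates, "n_replicates")
  if (!is.null(center_xy) && (!is.numeric(center_xy) || length(center_xy) != 2L)) {
    stop_invalid("`center_xy` must be two coordinates (um); field: center_xy")
  }
  structure(list(stages = stages, condition = condition,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 center_xy = center_xy, exclusions = exclusions,
                 options = options),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic preset
#' data (or user-supplied inputs via `config$options`), writing tidy CSVs
#' and a JSON summary into `out_dir`. Every output records the config hash
#' and base seed, so a rerun with an identical config is bit-identical for
#' the deterministic stages.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of per-stage results plus `summary` and `log`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("drusenmorph_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("drusenmorph run | config %s | base seed %d",
                         hash, config$seed),
                 sprintf("condition: %s | stages: %s", config$condition,
                         paste(config$stages, collapse = ", ")))
  if (length(config$exclusions)) {
    log_lines <- c(log_lines, paste("manual exclusions:",
                                    paste(config$exclusions, collapse = ", ")))
  }
  res <- list()
  summary <- list(config_hash = hash, seed = config$seed,
                  condition = config$condition)

  if (any(c("simulate", "thickness") %in% config$stages)) {
    meas <- list()
    for (r in seq_len(config$n_replicates)) {
      pre <- drusen_preset(config$condition, seed = config$seed + r - 1L)
      if (!is.null(config$center_xy)) {
        pre$geometry$center_xy <- config$center_xy
      }
      gen <- generate_monolayer_stack(pre$params, pre$geometry)
      if ("thickness" %in% config$stages) {
        m <- measure_monolayer(gen$stack, pre$geometry,
                               replicate_id = sprintf("rep%02d", r))
        log_lines <- c(log_lines,
                       sprintf("thickness rep%02d: %d measurements, %d dropped",
                               r, nrow(m), attr(m, "n_dropped")))
        meas[[r]] <- m
      }
      res$geometry <- pre$geometry
    }
    if ("thickness" %in% config$stages) {
      all_m <- normalize_heights(do.call(rbind, meas))
      if (length(config$exclusions)) {
        keep <- !paste(all_m$replicate_id, all_m$row, all_m$col,
                       sep = ":") %in% config$exclusions
        all_m <- all_m[keep, ]
      }
      utils::write.csv(cbind(all_m, config_hash = hash),
                       file.path(out_dir, "thickness_measurements.csv"),
                       row.names = FALSE)
      summary$thickness <- region_height_summary(all_m)
      res$thickness <- all_m
    }
  }

  if ("morphometrics" %in% config$stages) {
    recs <- list()
    for (r in seq_len(config$n_replicates)) {
      pre <- drusen_preset(config$condition, seed = config$seed + r - 1L)
      mp_over <- config$options$mosaic %||% list()
      mp <- do.call(mosaic_params, utils::modifyList(
        list(seed = config$seed + 100L + r), mp_over))
      geom <- drusen_geometry(rep(mp$frame_size / 2, 2),
                              pre$geometry$illumination_diameter,
                              pre$geometry$condition_label)
      mos <- generate_cell_mosaic(mp, geom)
      rc <- measure_cells(mos$mask, geom)
      rc$replicate_id <- sprintf("rep%02d", r)
      recs[[r]] <- rc
      log_lines <- c(log_lines,
                     sprintf("morphometrics rep%02d: %d cells, %d skipped",
                             r, nrow(rc), attr(rc, "n_skipped")))
    }
    cells <- normalize_areas(do.call(rbind, recs))
    utils::write.csv(cbind(cells, config_hash = hash),
                     file.path(out_dir, "cell_records.csv"),
                     row.names = FALSE)
    keep <- !cells$border
    summary$morphometrics <- lapply(
      split(cells[keep, ], cells$region[keep]),
      function(d) list(n = nrow(d),
                      mean_area = mean(d$area),
                      mean_shape_factor = mean(d$shape_factor),
                      mean_angle_to_origin = mean(d$angle_to_origin,
                                                  na.rm = TRUE)))
    res$morphometrics <- cells
  }

  if ("swelling" %in% config$stages) {
    sw_over <- config$options$swelling %||% list()
    sw <- do.call(generate_swelling_series, utils::modifyList(
      list(plateau = 20, tau_h = 2,
           sample_times = c(0, 0.5, 1, 2, 4, 8, 24),
           noise_sd = 0.3, seed = config$seed), sw_over))
    ser <- normalize_series(sw$time_h, sw$height_um)
    utils::write.csv(ser, file.path(out_dir, "swelling_series.csv"),
                     row.names = FALSE)
    t90 <- ser$time_h[which(ser$height_norm >= 0.9)[1]]
    summary$swelling <- list(plateau_um = max(sw$height_um),
                             time_to_90pct_h = t90)
    res$swelling <- ser
  }

  if ("indent" %in% config$stages) {
    in_over <- config$options$indent %||% list()
    cur <- do.call(generate_indentation_curve, utils::modifyList(
      list(E_eff = 4000, R_tip = 10, depth_max = 3.5,
           seed = config$seed), in_over))
    fit <- fit_hertz(cur)
    utils::write.csv(cur, file.path(out_dir, "indentation_curve.csv"),
                     row.names = FALSE)
    summary$indent <- list(E_eff_kPa = fit$E_eff_kPa,
                           r_squared = fit$r_squared,
                           accepted = fit$accepted)
    res$indent <- fit
  }

  if ("tfm" %in% config$stages) {
    tf_over <- config$options$tfm %||% list()
    E <- tf_over$E %||% 4000
    nu <- tf_over$nu %||% 0.5
    lam <- tf_over$lambda %||% 5e-3
    tf <- synthetic_traction_field(n = 64, spacing = 4,
                                   seed = config$seed + 500L)
    bp <- generate_bead_pair(tf, E = E, nu = nu, seed = config$seed + 501L)
    pv <- piv_displacement(bp$reference, bp$deformed, pixel_pitch = 1,
                           window = 32, overlap = 0.75)
    tr <- fttc_traction(pv, E = E, nu = nu, lambda = lam)
    geom <- drusen_geometry(rep(max(tr$x) / 2, 2), 100)
    ts <- region_traction_summary(tr, geom)
    utils::write.csv(
      data.frame(x = rep(tr$x, each = length(tr$y)),
                 y = rep(tr$y, length(tr$x)),
                 tx = as.vector(tr$tx), ty = as.vector(tr$ty),
                 magnitude = as.vector(tr$magnitude)),
      file.path(out_dir, "traction_field.csv"), row.names = FALSE)
    summary$tfm <- ts
    summary$tfm_lambda <- lam
    res$tfm <- tr
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  res$summary <- summary
  res$log <- log_lines
  res$out_dir <- out_dir
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay the preset effect-size recovery
#'
#' Generates `n_replicates` synthetic stacks per drusen condition, runs the
#' thickness pipeline, and tabulates the recovered Top/Edge percentage
#' deltas (relative to Outside) against the preset ground-truth deltas.
#'
#' @param n_replicates Replicates per condition (>= 1).
#' @param seed Base seed; replicate r of each condition uses `seed + r - 1`.
#' @return Data frame: `condition, region, preset_delta_pct,
#'   recovered_delta_pct, sem_pct, n_measurements`.
#' @export
replay_report <- function(n_replicates = 5L, seed = 1L) {
  if (n_replicates < 1L) stop_invalid("n_replicates must be >= 1")
  out <- list()
  for (cond in c("medium-drusen", "large-drusen")) {
    meas <- lapply(seq_len(n_replicates), function(r) {
      pre <- drusen_preset(cond, seed = seed + r - 1L)
      gen <- generate_monolayer_stack(pre$params, pre$geometry)
      measure_monolayer(gen$stack, pre$geometry,
                        replicate_id = sprintf("%s_rep%02d", cond, r))
    })
    m <- normalize_heights(do.call(rbind, meas))
    s <- region_height_summary(m)
    mods <- drusen_preset(cond, seed = seed)$params$thickness_modifiers
    for (reg in c("Top", "Edge")) {
      row <- s[s$region == reg, ]
      # SEM of the delta across replicates
      per_rep <- vapply(split(m, m$replicate_id), function(d) {
        mu_o <- mean(d$height_norm[d$region == "Outside"])
        100 * (mean(d$height_norm[d$region == reg]) - mu_o) / mu_o
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, region = reg,
        preset_delta_pct = 100 * (mods[[reg]] - 1),
        recovered_delta_pct = row$delta_pct,
        sem_pct = stats::sd(per_rep) / sqrt(length(per_rep)),
        n_measurements = row$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
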