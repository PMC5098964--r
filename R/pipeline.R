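#' Pipeline configuration
#'
#' Validates the full configuration of the synthetic end-to-end pipeline
#' (simulate -> segment -> classify -> register -> ROI -> COP -> compare ->
#' summarize) before any stage runs. Unknown keys are rejected.
#'
#' @param out_dir Output directory for artifacts, or `NULL` to keep results
#'   in memory only.
#' @param seed Master seed; per-stage child seeds are derived by stable
#'   hashing of the stage names, so stages are reproducible in isolation.
#' @param n_subjects,trials_per_subject Synthetic cohort size.
#' @param noise_sd_kpa Sensor noise level passed to the generator.
#' @param stance_s Stance duration per footstep passed to the generator.
#' @param segmentation A [segmentation_config()].
#' @param registration_mode `"auto"` (optimizer) or `"none"` (identity
#'   transforms, for noise-free diagnostics).
#' @param roi_mode `"auto"` (template digitization) or `"manual"` with
#'   `roi_points` (named list per foot label).
#' @param roi_points Manual ROI points (see [digitize_rois()]).
#' @param n_points Time-normalization length for COP trajectories.
#' @param pairs Comparison pairs (see [compare_feet()]); `NULL` = all.
#' @param threshold_kpa COP activation threshold.
#' @param exclude Optional predicate `function(step_summary_row) TRUE/FALSE`
#'   flagging trials/steps to exclude (e.g. unsteady walking); exclusions are
#'   logged. Default: none.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, n_subjects = 5L,
                            trials_per_subject = 2L, noise_sd_kpa = 1,
                            stance_s = 1.2,
                            segmentation = segmentation_config(),
                            registration_mode = c("auto", "none"),
                            roi_mode = c("auto", "manual"), roi_points = NULL,
                            n_points = 101L, pairs = NULL, threshold_kpa = 5,
                            exclude = NULL) {
  registration_mode <- match.arg(registration_mode)
  roi_mode <- match.arg(roi_mode)
  if (n_subjects < 1L || trials_per_subject < 1L) {
    stop("cohort size must be positive", call. = FALSE)
  }
  if (roi_mode == "manual" && is.null(roi_points)) {
    stop("manual ROI mode needs `roi_points`", call. = FALSE)
  }
  if (!is.null(exclude) && !is.function(exclude)) {
    stop("`exclude` must be a predicate function or NULL", call. = FALSE)
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed),
      n_subjects = as.integer(n_subjects),
      trials_per_subject = as.integer(trials_per_subject),
      noise_sd_kpa = noise_sd_kpa, stance_s = stance_s,
      segmentation = segmentation,
      registration_mode = registration_mode, roi_mode = roi_mode,
      roi_points = roi_points, n_points = as.integer(n_points),
      pairs = pairs, threshold_kpa = threshold_kpa, exclude = exclude
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param x A list of configuration fields (e.g. parsed from JSON/YAML).
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, x)
}

# deterministic 32-bit string hash (djb2 modulo a prime), for child seeds
stage_seed <- function(seed, stage) {
  h <- 5381
  for (ch in utf8ToInt(stage)) h <- (h * 33 + ch) %% 2147483647
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' Run the synthetic analysis pipeline end-to-end
#'
#' Simulates a cohort of walkway trials, isolates and labels footsteps,
#' registers each foot's prints to a per-subject template, extracts the ROI
#' sensitivity tables, computes mean COP trajectories per foot, compares
#' feet pairwise, and summarizes the cohort. With `out_dir` set, all result
#' tables plus a manifest (configuration echo, hash, seed, package version)
#' are written as plain CSV/JSON; rerunning with the same configuration and
#' seed reproduces every output byte-identically.
#'
#' @param config A [pipeline_config()] (or plain list convertible via
#'   [as_pipeline_config()]).
#' @return Invisibly, a result bundle: `steps_summary`, `roi_table`,
#'   `roi_means`, `cop_trajs`, `mean_trajs`, `comparisons`,
#'   `subject_summary`, `cohort_summary`, `truths`, `excluded`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- as_pipeline_config(config)
  spec <- plate_spec()
  sim_seed <- stage_seed(config$seed, "simulate")

  steps_rows <- list()
  roi_rows <- list()
  cop_trajs <- list()
  truths <- list()
  excluded <- list()

  # per subject: simulate trials, segment, register within foot, measure
  for (si in seq_len(config$n_subjects)) {
    subject <- sprintf("S%d", si)
    set.seed(stage_seed(sim_seed, subject))
    amp_scale <- exp(stats::rnorm(1, 0, 0.06))
    size_scale <- exp(stats::rnorm(1, 0, 0.04))
    models <- default_foot_models(size_scale = size_scale, amp_scale = amp_scale)

    subj_steps <- list() # per foot label: list of (trial, step, series)
    for (ti in seq_len(config$trials_per_subject)) {
      trial_seed <- stage_seed(sim_seed, sprintf("%s-trial%d", subject, ti))
      set.seed(trial_seed)
      steps <- default_step_sequence()
      steps$x_m <- steps$x_m + stats::rnorm(nrow(steps), 0, 0.01)
      steps$y_m <- steps$y_m + stats::rnorm(nrow(steps), 0, 0.02)
      steps$heading_deg <- stats::rnorm(nrow(steps), 0, 3)
      plan <- gait_plan(steps, stance_s = config$stance_s,
                        noise_sd_kpa = config$noise_sd_kpa, seed = trial_seed)
      trial <- generate_trial(models, plan, spec)
      truths[[sprintf("%s_t%d", subject, ti)]] <- trial$truth

      segs <- segment_steps(trial$record, config$segmentation)
      for (k in seq_along(segs)) {
        fl <- assess_completeness(segs[[k]], trial$record, config$segmentation)
        segs[[k]]$complete_spatial <- fl[["complete_spatial"]]
        segs[[k]]$complete_temporal <- fl[["complete_temporal"]]
      }
      segs <- suppressMessages(classify_feet(segs))
      for (k in seq_along(segs)) {
        s <- segs[[k]]
        row <- tibble::tibble(
          subject = subject, trial = ti, step = k,
          foot = s$foot_label,
          onset_s = (s$t_range[1] - 1) / spec$freq_hz,
          duration_s = diff(s$t_range) / spec$freq_hz,
          n_voxels = nrow(s$voxels),
          complete_spatial = s$complete_spatial,
          complete_temporal = s$complete_temporal
        )
        if (!is.null(config$exclude) && isTRUE(config$exclude(row))) {
          excluded[[length(excluded) + 1L]] <- row
          message(sprintf("excluded %s trial %d step %d (%s)", subject, ti, k,
                          s$foot_label))
          next
        }
        steps_rows[[length(steps_rows) + 1L]] <- row
        if (s$foot_label != "unknown" && s$complete_spatial && s$complete_temporal) {
          subj_steps[[s$foot_label]] <- c(
            subj_steps[[s$foot_label]],
            list(list(trial = ti, step = k, series = s))
          )
        }
      }
    }

    # registration + ROI + COP per foot
    for (foot in names(subj_steps)) {
      entries <- subj_steps[[foot]]
      images <- lapply(entries, function(e) {
        img <- peak_pressure_image(e$series)
        img$foot_label <- foot
        img
      })
      flags <- lapply(entries, function(e) {
        c(complete_spatial = e$series$complete_spatial,
          complete_temporal = e$series$complete_temporal)
      })
      tpl <- tryCatch(select_template(images, flags),
                      error = function(e) NULL)
      if (is.null(tpl)) {
        message(sprintf("no template for %s %s; foot skipped", subject, foot))
        next
      }
      reg_images <- vector("list", length(entries))
      for (k in seq_along(entries)) {
        if (k == tpl$source_index || config$registration_mode == "none") {
          reg_images[[k]] <- images[[k]]
          reg_series <- entries[[k]]$series
        } else {
          tf <- register_to_template(images[[k]], tpl)
          reg_images[[k]] <- apply_transform(images[[k]], tf)
          reg_series <- apply_transform_to_series(entries[[k]]$series, tf)
        }
        tr <- tryCatch(
          time_normalize(cop_trajectory(reg_series, config$threshold_kpa),
                         config$n_points),
          error = function(e) NULL
        )
        if (!is.null(tr)) {
          cop_trajs[[sprintf("%s_t%d_s%d_%s", subject, entries[[k]]$trial,
                             entries[[k]]$step, foot)]] <-
            list(subject = subject, foot = foot, traj = tr)
        }
      }
      mimg <- mean_image(reg_images)
      mtpl <- tpl
      mtpl$values <- mimg$values
      mtpl$mask <- mimg$values >= tpl$iso_threshold_kpa
      rois <- tryCatch(
        if (config$roi_mode == "manual") {
          digitize_rois(mtpl, "manual", points = config$roi_points[[foot]])
        } else {
          digitize_rois(mtpl, "auto")
        },
        error = function(e) {
          message(sprintf("ROI digitization failed for %s %s: %s",
                          subject, foot, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(rois)) next
      for (k in seq_along(entries)) {
        st <- sensitivity_table(reg_images[[k]], rois)
        st$subject <- subject
        st$trial <- entries[[k]]$trial
        st$step <- entries[[k]]$step
        roi_rows[[length(roi_rows) + 1L]] <- st
      }
    }
  }

  steps_summary <- dplyr::bind_rows(steps_rows)
  roi_table <- dplyr::bind_rows(roi_rows)
  if (nrow(roi_table)) {
    roi_table <- roi_table[, c("subject", "trial", "step", "foot", "roi",
                               "position", "is_primary", "row", "col",
                               "peak_pressure_kpa")]
  }

  # 5-position mean per (subject, trial, step, foot, roi): the value used
  # for further processing
  roi_means <- if (nrow(roi_table)) {
    summarize_pressures(roi_table, c("subject", "trial", "step", "foot", "roi")) |>
      dplyr::rename(peak_pressure_kpa = mean) |>
      dplyr::select(-se, -n)
  } else {
    tibble::tibble()
  }

  # mean COP per foot: centred, pooled across subjects
  mean_trajs <- list()
  foot_order <- c("FL", "FR", "HL", "HR")
  for (foot in foot_order) {
    tl <- Filter(function(e) e$foot == foot, cop_trajs)
    if (length(tl)) {
      mean_trajs[[foot]] <- mean_trajectory(
        lapply(tl, function(e) center_trajectory(e$traj))
      )
    }
  }
  comparisons <- if (length(mean_trajs) >= 2L) {
    compare_feet(mean_trajs, pairs = config$pairs)
  } else {
    tibble::tibble()
  }

  subject_summary <- if (nrow(roi_means)) {
    summarize_pressures(roi_means, c("subject", "foot"))
  } else {
    tibble::tibble()
  }
  cohort_summary <- if (nrow(roi_means)) {
    fh <- roi_means |>
      dplyr::mutate(limb = ifelse(substr(.data$foot, 1, 1) == "F", "fore", "hind")) |>
      summarize_pressures("limb")
    pick <- function(col, limb) {
      v <- fh[[col]][fh$limb == limb]
      if (length(v)) v else NA_real_
    }
    fore <- pick("mean", "fore")
    hind <- pick("mean", "hind")
    tibble::tibble(
      grand_mean_kpa = mean(roi_means$peak_pressure_kpa),
      fore_mean_kpa = fore, fore_se_kpa = pick("se", "fore"),
      hind_mean_kpa = hind, hind_se_kpa = pick("se", "hind"),
      fore_hind_contrast_pct = if (is.na(fore) || is.na(hind)) NA_real_ else
        fore_hind_contrast(fore, hind),
      n_rows = nrow(roi_means)
    )
  } else {
    tibble::tibble()
  }

  bundle <- list(
    steps_summary = steps_summary, roi_table = roi_table,
    roi_means = roi_means, cop_trajs = cop_trajs, mean_trajs = mean_trajs,
    comparisons = comparisons, subject_summary = subject_summary,
    cohort_summary = cohort_summary, truths = truths,
    excluded = dplyr::bind_rows(excluded), config = config
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(bundle, config)
  invisible(bundle)
}

write_pipeline_artifacts <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  data.table::fwrite(bundle$steps_summary, out("steps_summary.csv"))
  data.table::fwrite(bundle$roi_table, out("roi_table.csv"))
  data.table::fwrite(bundle$roi_means, out("roi_means.csv"))
  data.table::fwrite(bundle$comparisons, out("comparisons.csv"))
  data.table::fwrite(bundle$subject_summary, out("subject_summary.csv"))
  data.table::fwrite(bundle$cohort_summary, out("cohort_summary.csv"))
  if (length(bundle$mean_trajs)) {
    write_cop_table(bundle$mean_trajs, out("mean_cop.csv"))
  }
  cfg <- unclass(config)
  cfg$exclude <- if (is.null(cfg$exclude)) NULL else "<predicate>"
  cfg <- lapply(cfg[setdiff(names(cfg), "out_dir")],
                function(x) if (is.object(x)) unclass(x) else x)
  manifest <- list(
    package = "pedopress",
    version = as.character(utils::packageVersion("pedopress")),
    seed = config$seed,
    config = cfg,
    config_hash = rlang::hash(cfg),
    n_subjects = config$n_subjects,
    trials_per_subject = config$trials_per_subject,
    outputs = c("steps_summary.csv", "roi_table.csv", "roi_means.csv",
                "comparisons.csv", "subject_summary.csv", "cohort_summary.csv")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(NULL)
}
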