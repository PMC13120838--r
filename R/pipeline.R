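# FNV-1a hash of a serialized R object, reported as 8 hex digits; used to
# fingerprint configurations in run manifests.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Simulate a dataset to disk
#'
#' Builds a schedule and synthesizes a recording for every participant,
#' writing per participant `p<id>_recording.bin/.json`, `p<id>_events.tsv`
#' and `p<id>_ground_truth.json`, plus a `dataset.json` manifest (config
#' echo, seeds, durations).
#'
#' @param config a `synth_config`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-participant seeds are derived from it.
#' @param quiet suppress the dataset summary message?
#' @return invisibly, the manifest list.
#' @export
simulate_dataset <- function(config, out_dir, seed = config$seed,
                             quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_config("simulate_dataset: cannot create '%s'", out_dir)
  participants <- list()
  for (p in seq_len(config$n_participants)) {
    sched <- build_schedule(config, child_seed(seed, p))
    sched$participant <- p
    synth <- synthesize_participant(config, sched, child_seed(seed, 1000L + p))
    stem <- file.path(out_dir, sprintf("p%02d", p))
    write_recording(synth$recording, paste0(stem, "_recording"))
    write_events_tsv(sched, paste0(stem, "_events.tsv"))
    write_ground_truth(synth$ground_truth, paste0(stem, "_ground_truth.json"))
    participants[[p]] <- list(
      id = p, duration_s = attr(sched, "total_duration"),
      n_trials = max(sched$trial), schedule_seed = child_seed(seed, p),
      signal_seed = child_seed(seed, 1000L + p)
    )
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("wmpulse")),
    seed = seed, config_hash = config_hash(config),
    n_participants = config$n_participants, fs = config$fs,
    n_channels = config$n_channels, participants = participants
  )
  jsonlite::write_json(manifest, file.path(out_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    message(sprintf(
      "simulated %d participants (%d trials each, %d ch @ %g Hz) -> %s",
      config$n_participants, participants[[1]]$n_trials, config$n_channels,
      config$fs, out_dir))
  }
  invisible(manifest)
}

# crop a trial_series (or epoch_set time axis) to a window
crop_series <- function(ts, window) {
  idx <- ts$time >= window[1] & ts$time <= window[2]
  if (!any(idx)) stop_config("crop_series: empty window")
  ts$data <- if (length(dim(ts$data)) == 3L) ts$data[, , idx, drop = FALSE] else
    ts$data[, idx, drop = FALSE]
  ts$time <- ts$time[idx]
  ts
}

# shared per-participant preprocessing for the pulse-locked analyses
preprocess_participant <- function(rec, events, epoch_window, decode_fs,
                                   filter_band, notch) {
  events <- add_dummy_events(events)
  ep <- epoch_around(rec, events,
                     c("sptms_d12", "dummy_sptms_d12"), epoch_window)
  if (decode_fs < ep$fs) ep <- resample_epochs(ep, decode_fs)
  # widen the fit context at low sampling rates so a cubic stays determined
  ep <- interpolate_pulse_gap(ep, context = max(0.005, 4.5 / ep$fs))
  if (!is.null(filter_band) && filter_band[2] < ep$fs / 2) {
    ep <- filter_band_notch(ep, band = filter_band,
                            notch = if (notch < ep$fs / 2 - 2) notch else NULL)
  }
  ep
}

#' Run the analysis pipeline over a simulated (or imported) dataset
#'
#' Per participant: dummy-event tagging, epoching around the Delay 1.2 pulse
#' (real or dummy), resampling, artifact-gap interpolation and filtering;
#' then the requested stages: "decode" (time-frequency features and
#' cross-validated AUC per category/timepoint/spTMS condition, with a group
#' cluster test against chance), "phase" (band-filtered Hilbert phase,
#' adaptive window selection on spTMS-present trials, the three phase
#' measures normalized against spTMS-absent trials, paired permutation and
#' time-resolved consistency), and "power" (pre/post relative band power with
#' permutation tests). Result tables are written as TSV plus a run manifest.
#'
#' @param data_dir directory written by [simulate_dataset()].
#' @param out_dir output directory for result tables.
#' @param stages subset of c("decode", "phase", "power").
#' @param epoch_window epoch limits around the pulse, seconds.
#' @param decode_fs sampling rate for the decoding path, Hz.
#' @param phase_fs sampling rate for the phase/power path, Hz.
#' @param filter_band broadband filter edges, Hz (NULL to skip).
#' @param notch notch center, Hz.
#' @param n_perm permutation iterations for the inferential stages.
#' @param seed integer seed.
#' @param quiet suppress stage progress messages?
#' @return invisibly, a list with the in-memory results.
#' @export
analyze_dataset <- function(data_dir, out_dir,
                            stages = c("decode", "phase", "power"),
                            epoch_window = c(-4.5, 4.5),
                            decode_fs = 500, phase_fs = 100,
                            filter_band = c(1, 100), notch = 60,
                            n_perm = 1000, seed = 1L, quiet = FALSE) {
  manifest <- jsonlite::read_json(file.path(data_dir, "dataset.json"),
                                  simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  np <- manifest$n_participants
  if ("phase" %in% stages && np < 2) {
    stop_config("analyze_dataset: the phase stage needs >= 2 participants (got %d)", np)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  bands <- default_band_defs("bands")
  auc_rows <- NULL
  phase_present <- list(); phase_absent <- list()
  power_rows <- NULL
  series_present <- list(); series_absent <- list()
  for (p in seq_len(np)) {
    stem <- file.path(data_dir, sprintf("p%02d", p))
    rec <- read_recording(paste0(stem, "_recording"))
    pinfo <- manifest$participants
    dur <- if (is.data.frame(pinfo)) pinfo$duration_s[p] else pinfo[[p]]$duration_s
    events <- read_events_tsv(paste0(stem, "_events.tsv"),
                              total_duration = dur)
    say("participant %d/%d: preprocessing", p, np)
    ep <- preprocess_participant(rec, events, epoch_window, decode_fs,
                                 filter_band, notch)
    present <- !startsWith(ep$trial_meta$event_label, "dummy")
    if ("decode" %in% stages) {
      tf <- spectral_transform(ep)
      tf <- log_and_smooth(tf)
      btf <- band_average(tf, default_band_defs("broadband"))
      for (sp in c(TRUE, FALSE)) {
        sel <- which(present == sp)
        if (length(sel) < 8L) next
        btf_c <- lapply(btf, function(x) {
          x$power <- x$power[sel, , , , drop = FALSE]
          x$trial_meta <- x$trial_meta[sel, ]
          x
        })
        for (cat_ in c("face", "word", "motion")) {
          for (tp in btf_c[[1]]$times) {
            res <- tryCatch({
              fs_ <- assemble_features(btf_c, tp, cat_)
              fit_eval_auc(fs_, seed = child_seed(seed, p * 131L + round(tp * 10)))
            }, error = function(e) NULL) # condition too small at this timepoint
            if (is.null(res)) next
            auc_rows <- rbind(auc_rows, data.frame(
              participant = p, sptms = sp, category = cat_,
              timepoint_s = tp, auc = res$auc,
              n_effective = res$n_effective_samples))
          }
        }
      }
    }
    if (any(c("phase", "power") %in% stages)) {
      epp <- baseline_correct(ep, c(min(ep$time), min(ep$time) + 1))
      epp <- resample_epochs(epp, phase_fs)
      ts <- average_channels(epp)
      ts4 <- crop_series(ts, c(-2, 2))
      split_ts <- function(keep) {
        out <- ts4
        out$data <- out$data[keep, , drop = FALSE]
        out$trial_meta <- out$trial_meta[keep, ]
        out
      }
      series_present[[p]] <- split_ts(present)
      series_absent[[p]] <- split_ts(!present)
    }
  }
  results <- list(manifest = manifest)
  if ("decode" %in% stages && !is.null(auc_rows)) {
    write_tsv(auc_rows, file.path(out_dir, "decode_auc.tsv"))
    cl_rows <- NULL
    for (sp in unique(auc_rows$sptms)) {
      sub <- auc_rows[auc_rows$sptms == sp, ]
      tps <- sort(unique(sub$timepoint_s))
      cats <- sort(unique(sub$category))
      arr <- array(NA_real_, dim = c(np, length(cats), length(tps)))
      for (i in seq_len(nrow(sub))) {
        arr[sub$participant[i], match(sub$category[i], cats),
            match(sub$timepoint_s[i], tps)] <- sub$auc[i]
      }
      if (anyNA(arr)) next
      dr <- aggregate_group(arr)
      ct <- cluster_perm_vs_chance(dr$participant, n_perm = max(n_perm, 100),
                                   seed = child_seed(seed, 7L + sp),
                                   times = tps)
      for (cl in ct$clusters) {
        cl_rows <- rbind(cl_rows, data.frame(
          sptms = sp, span_start_s = cl$start_s, span_end_s = cl$end_s,
          mass = cl$mass, p = cl$p))
      }
      results$decode[[if (sp) "present" else "absent"]] <-
        list(group = dr, clusters = ct, times = tps)
    }
    if (!is.null(cl_rows)) write_tsv(cl_rows, file.path(out_dir, "clusters.tsv"))
  }
  if ("phase" %in% stages && length(series_present) >= 2L) {
    say("phase stage")
    ph_rows <- NULL; win_rows <- NULL; grp_rows <- NULL
    for (b in names(bands)) {
      psp <- lapply(series_present, instantaneous_phase, band = bands[[b]])
      psa <- lapply(series_absent, instantaneous_phase, band = bands[[b]])
      w <- select_window(psp, bands[[b]], "sptms")
      win_rows <- rbind(win_rows, data.frame(
        band = b, event_class = "sptms", n_cycles = w$n_cycles,
        onset_s = w$onset, length_s = w$length, selection_t = w$selection_t))
      mp <- compute_phase_measures(psp, w, seed = child_seed(seed, 21L))
      ma <- compute_phase_measures(psa, w, seed = child_seed(seed, 22L))
      mn <- normalize_vs_absent(mp, ma)
      pt <- paired_permutation(mp$wp_plv_change, ma$wp_plv_change,
                               n_iter = max(n_perm, 100),
                               seed = child_seed(seed, 23L))
      trc <- time_resolved_consistency(psp, psa, n_iter = max(n_perm, 100),
                                       seed = child_seed(seed, 24L))
      ph_rows <- rbind(ph_rows, data.frame(
        participant = seq_along(psp), band = b, event = "sptms_d12",
        wp_plv_change = mn$wp_plv_change,
        mean_shift_deg = mn$mean_shift * 180 / pi,
        confidence_r = mn$confidence_r))
      grp_rows <- rbind(grp_rows, data.frame(
        band = b, event = "sptms_d12", contrast = "present_vs_absent",
        p_perm = pt$p, intersubject_r = mn$intersubject$r,
        r_se = mn$intersubject$se))
      results$phase[[b]] <- list(window = w, present = mp, absent = ma,
                                 normalized = mn, perm = pt,
                                 time_resolved = trc)
    }
    grp_rows$p_fdr <- fdr_bh(grp_rows$p_perm)
    write_tsv(ph_rows, file.path(out_dir, "phase_measures.tsv"))
    write_tsv(win_rows, file.path(out_dir, "windows.tsv"))
    write_tsv(grp_rows, file.path(out_dir, "group_phase.tsv"))
  }
  if ("power" %in% stages && length(series_present) >= 1L) {
    say("power stage")
    for (p in seq_along(series_present)) {
      for (b in names(bands)) {
        for (cond in c("present", "absent")) {
          ts_ <- if (cond == "present") series_present[[p]] else series_absent[[p]]
          pre <- relative_band_power(ts_, "pre", bands[[b]])
          post <- relative_band_power(ts_, "post", bands[[b]])
          tst <- pre_post_power_test(pre, post, n_iter = max(n_perm, 100),
                                     seed = child_seed(seed, 31L + p))
          power_rows <- rbind(power_rows, data.frame(
            participant = p, band = b, condition = cond,
            rel_power_pre = mean(pre), rel_power_post = mean(post),
            p_pre_post = tst$p))
        }
      }
    }
    write_tsv(power_rows, file.path(out_dir, "power_measures.tsv"))
    results$power <- power_rows
  }
  run_manifest <- list(
    package_version = as.character(utils::packageVersion("wmpulse")),
    stages = stages, seed = seed, n_perm = n_perm,
    config_hash = manifest$config_hash,
    analysis_hash = config_hash(list(stages, epoch_window, decode_fs,
                                     phase_fs, filter_band, notch, n_perm,
                                     seed))
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Render a plain-text report over analysis results
#'
#' Summarizes the result tables written by [analyze_dataset()] into a
#' markdown report (selected analysis windows, group AUC summary, phase and
#' power tables, permutation counts and seeds). Sections whose tables are
#' absent are marked as such rather than failing.
#'
#' @param results_dir directory written by [analyze_dataset()].
#' @param path output report path.
#' @return the report path, invisibly.
#' @export
report_dataset <- function(results_dir, path = file.path(results_dir, "report.md")) {
  lines <- c("# wmpulse analysis report", "")
  rm_path <- file.path(results_dir, "run_manifest.json")
  if (file.exists(rm_path)) {
    rm <- jsonlite::read_json(rm_path, simplifyVector = TRUE)
    lines <- c(lines, sprintf("- package version: %s", rm$package_version),
               sprintf("- stages: %s", paste(rm$stages, collapse = ", ")),
               sprintf("- seed: %s; permutation iterations: %s", rm$seed, rm$n_perm),
               sprintf("- config hash: %s", rm$config_hash), "")
  }
  section <- function(title, file, fmt) {
    fp <- file.path(results_dir, file)
    if (!file.exists(fp)) {
      return(c(sprintf("## %s", title), "", "_absent_", ""))
    }
    df <- utils::read.table(fp, sep = "\t", header = TRUE)
    c(sprintf("## %s", title), "", fmt(df), "")
  }
  lines <- c(lines, section("Selected analysis windows", "windows.tsv", function(df) {
    sprintf("- %s: %d cycles, onset %.0f ms, length %.0f ms (t = %.2f)",
            df$band, df$n_cycles, 1000 * df$onset_s, 1000 * df$length_s,
            df$selection_t)
  }))
  lines <- c(lines, section("Group decoding AUC", "decode_auc.tsv", function(df) {
    agg <- stats::aggregate(auc ~ timepoint_s + sptms, data = df, FUN = mean)
    sprintf("- t = %+.1f s, spTMS %s: mean AUC = %.3f",
            agg$timepoint_s, ifelse(agg$sptms, "present", "absent"), agg$auc)
  }))
  lines <- c(lines, section("Significant AUC clusters", "clusters.tsv", function(df) {
    sprintf("- spTMS %s: [%.1f, %.1f] s, mass %.1f, p = %.4f",
            ifelse(df$sptms, "present", "absent"), df$span_start_s,
            df$span_end_s, df$mass, df$p)
  }))
  lines <- c(lines, section("Phase contrasts (present vs absent)",
                            "group_phase.tsv", function(df) {
    sprintf("- %s: p_perm = %.4f (FDR %.4f), intersubject r = %.3f (SE %.3f)",
            df$band, df$p_perm, df$p_fdr, df$intersubject_r, df$r_se)
  }))
  lines <- c(lines, section("Relative band power", "power_measures.tsv",
                            function(df) {
    agg <- stats::aggregate(cbind(rel_power_pre, rel_power_post) ~ band + condition,
                            data = df, FUN = mean)
    sprintf("- %s (%s): pre %.3f -> post %.3f", agg$band, agg$condition,
            agg$rel_power_pre, agg$rel_power_post)
  }))
  writeLines(lines, path)
  invisible(path)
}
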