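# Assign n trials to k cells as evenly as possible; when n %% k != 0 the
# remainder is spread over randomly chosen cells (closest integer split).
balanced_cells <- function(n, k) {
  base <- rep(n %/% k, k)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- sample.int(k, rem)
    base[idx] <- base[idx] + 1
  }
  sample(rep(seq_len(k), times = base))
}

trial_category_plan <- function(n) {
  cats <- c("face", "word", "motion")
  pairs <- utils::combn(cats, 2) # 3 unordered memory arrays
  combos <- do.call(rbind, lapply(1:3, function(j) {
    rbind(c(pairs[1, j], pairs[2, j]), c(pairs[2, j], pairs[1, j]))
  })) # 6 (cued, uncued) combinations
  idx <- balanced_cells(n, nrow(combos))
  data.frame(category_cued = combos[idx, 1], category_uncued = combos[idx, 2],
             stringsAsFactors = FALSE)
}

#' Build a trial/event schedule for one simulated participant
#'
#' Lays out every block and trial of the DSR/SR experiment on a continuous
#' timeline: blocks alternate task (order flipping across sessions), memory
#' arrays and cue targets are counterbalanced within block, spTMS is assigned
#' to each eligible delay with an exact split when the block's trial count
#' divides evenly (independently for the two DSR delays, so under the 50%
#' default a quarter of DSR trials carry two pulses), and pulse lags are drawn
#' uniformly from the 50 ms grid. The result is a long-format events table with
#' one row per event.
#'
#' @param config a `synth_config`.
#' @param seed integer seed; the schedule is deterministic given (config, seed).
#' @return data.frame of class `event_schedule` with columns participant,
#'   block, trial, task, event_label, latency_s, duration_s, epoch,
#'   sptms_present, lag_s, category_cued, category_uncued, priority_status.
#'   The total recording duration is attached as attribute `total_duration`.
#' @export
build_schedule <- function(config, seed = config$seed) {
  validate_synth_config(config)
  tm <- config$timing
  block_gap <- 5 # seconds of rest between blocks
  with_local_seed(seed, {
    rows <- vector("list", 2048L); nr <- 0L
    push <- function(df) { nr <<- nr + 1L; rows[[nr]] <<- df }
    t_now <- block_gap
    trial_id <- 0L
    n_blocks_total <- config$n_sessions * config$n_blocks
    for (s in seq_len(config$n_sessions)) {
      first_task <- if (s %% 2 == 1) "DSR" else "SR"
      for (b in seq_len(config$n_blocks)) {
        task <- if (b %% 2 == 1) first_task else setdiff(c("DSR", "SR"), first_task)
        n <- config$n_trials_per_block
        block_idx <- (s - 1L) * config$n_blocks + b
        cats <- trial_category_plan(n)
        # spTMS assignment: exact split per delay when possible
        if (task == "DSR") {
          cell <- balanced_cells(n, 4L) # (d12, d2) in {TT, TF, FT, FF}
          tms12 <- cell %in% c(1L, 2L)
          tms2 <- cell %in% c(1L, 3L)
          if (config$sptms_prob != 0.5) {
            tms12 <- stats::runif(n) < config$sptms_prob
            tms2 <- stats::runif(n) < config$sptms_prob
          }
          stay <- balanced_cells(n, 2L) == 1L
        } else {
          tms12 <- if (config$sptms_prob == 0.5) {
            balanced_cells(n, 2L) == 1L
          } else stats::runif(n) < config$sptms_prob
          tms2 <- rep(NA, n)
          stay <- rep(NA, n)
        }
        for (i in seq_len(n)) {
          trial_id <- trial_id + 1L
          t0 <- t_now
          cued1 <- cats$category_cued[i]; unc1 <- cats$category_uncued[i]
          prio1 <- if (task == "DSR") "UMI" else "IMI"
          ev <- function(label, lat, dur, epoch = NA_character_,
                         sp = NA, lag = NA_real_, cc = cued1, cu = unc1,
                         prio = prio1) {
            data.frame(block = block_idx, trial = trial_id, task = task,
                       event_label = label, latency_s = lat, duration_s = dur,
                       epoch = epoch, sptms_present = sp, lag_s = lag,
                       category_cued = cc, category_uncued = cu,
                       priority_status = prio, stringsAsFactors = FALSE)
          }
          push(ev("sample", t0, tm$sample))
          push(ev("delay_d11", t0 + tm$sample, tm$delay11))
          t_cue1 <- t0 + tm$sample + tm$delay11
          push(ev("cue1", t_cue1, tm$cue))
          t_d12 <- t_cue1 + tm$cue
          lag1 <- if (isTRUE(tms12[i])) sample(config$sptms_lag_grid, 1L) else NA_real_
          push(ev("delay_d12", t_d12, tm$delay12, epoch = "d12",
                  sp = isTRUE(tms12[i]), lag = lag1))
          if (isTRUE(tms12[i])) {
            push(ev("sptms_d12", t_d12 + lag1, 0, epoch = "d12",
                    sp = TRUE, lag = lag1))
          }
          t_probe1 <- t_d12 + tm$delay12
          push(ev("probe1", t_probe1, tm$probe))
          t_resp_end <- t_probe1 + tm$response
          if (task == "DSR") {
            cued2 <- if (stay[i]) cued1 else unc1
            unc2 <- if (stay[i]) unc1 else cued1
            t_cue2 <- t_resp_end
            push(ev("cue2", t_cue2, tm$cue, cc = cued2, cu = unc2, prio = "IMI"))
            t_d2 <- t_cue2 + tm$cue
            lag2 <- if (isTRUE(tms2[i])) sample(config$sptms_lag_grid, 1L) else NA_real_
            push(ev("delay_d2", t_d2, tm$delay12, epoch = "d2",
                    sp = isTRUE(tms2[i]), lag = lag2, cc = cued2, cu = unc2,
                    prio = "IMI"))
            if (isTRUE(tms2[i])) {
              push(ev("sptms_d2", t_d2 + lag2, 0, epoch = "d2", sp = TRUE,
                      lag = lag2, cc = cued2, cu = unc2, prio = "IMI"))
            }
            t_probe2 <- t_d2 + tm$delay12
            push(ev("probe2", t_probe2, tm$probe, cc = cued2, cu = unc2,
                    prio = "IMI"))
            t_end <- t_probe2 + tm$response
          } else {
            t_end <- t_resp_end
          }
          iti <- stats::runif(1, tm$iti_range[1], tm$iti_range[2])
          t_now <- t_end + iti
        }
        t_now <- t_now + block_gap
      }
    }
    sched <- do.call(rbind, rows[seq_len(nr)])
    sched <- cbind(participant = 1L, sched)
    sched <- sched[order(sched$latency_s), ]
    rownames(sched) <- NULL
    attr(sched, "total_duration") <- t_now
    attr(sched, "n_blocks") <- n_blocks_total
    class(sched) <- c("event_schedule", "data.frame")
    sched
  })
}

# Per-trial summary of a long-format schedule (one row per trial).
schedule_trials <- function(schedule) {
  d12 <- schedule[schedule$event_label == "delay_d12", ]
  d2 <- schedule[schedule$event_label == "delay_d2", ]
  out <- d12[, c("participant", "block", "trial", "task", "sptms_present",
                 "lag_s", "category_cued", "category_uncued")]
  names(out)[names(out) == "sptms_present"] <- "sptms_d12"
  names(out)[names(out) == "lag_s"] <- "lag_d12"
  out$sptms_d2 <- NA
  out$lag_d2 <- NA_real_
  m <- match(out$trial, d2$trial)
  out$sptms_d2[!is.na(m)] <- d2$sptms_present[m[!is.na(m)]]
  out$lag_d2[!is.na(m)] <- d2$lag_s[m[!is.na(m)]]
  out
}
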