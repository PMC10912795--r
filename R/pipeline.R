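# End-to-end orchestration: synthesize -> closed-loop detect/stimulate ->
# clean -> segment -> band power / coherence / coupling -> group statistics.

#' Simulate a closed-loop stimulation session on synthetic data
#'
#' Generates the recording from `spec`, runs the online detector causally,
#' triggers a stimulation episode at each accepted detection (the trigger
#' is the decision time, i.e. the end of the qualifying run), excludes every
#' scheduled episode from further detection (artifacts would retrigger the
#' detector), injects the stimulation artifact waveform into the stimulated
#' channel and removes it again by blanking for analysis.
#'
#' The intervention effect on seizures is explicit bookkeeping, not
#' biophysics: ground-truth seizures overlapping a stimulation episode have
#' their duration multiplied by `shortening_factor`.
#'
#' @param spec a [synth_spec()].
#' @param detector a [detector_config()].
#' @param protocol a [stim_protocol()].
#' @param shortening_factor factor in `(0, 1]` applied to the duration of
#'   stimulated seizures; default 1 (no effect).
#' @param stim_channel stimulated channel; defaults to the detector channel.
#' @param blank_s artifact blanking window per pulse (s); default 0.01.
#' @return list with `recording` (artifact-bearing), `cleaned` (after
#'   artifact removal), `detections`, `pulses` (stim log data.frame),
#'   `episodes` (list of `stim_episode`), `events` (post-intervention
#'   seizure table), `truth` (pre-intervention table).
#' @export
run_closed_loop <- function(spec, detector = detector_config(),
                            protocol = stim_protocol(),
                            shortening_factor = 1,
                            stim_channel = detector$channel,
                            blank_s = 0.01) {
  check_scalar_num(shortening_factor, "shortening_factor", lo = 0, hi = 1,
                   open_lo = TRUE)
  out <- assemble_recording(spec)
  rec <- out$recording
  dur <- rec_duration(rec)

  episodes <- list()
  accepted_t <- numeric(); accepted_b <- numeric()
  exclusions <- matrix(numeric(0), ncol = 2L)
  t_free <- -Inf
  repeat {
    d <- detect_onsets(rec, detector, exclusions)
    d <- d[d$t_detect_s >= t_free, , drop = FALSE]
    if (!nrow(d)) break
    t_det <- d$t_detect_s[1L]
    accepted_t <- c(accepted_t, t_det)
    accepted_b <- c(accepted_b, d$baseline_power[1L])
    t_trig <- t_det + detector$n_consecutive * detector$epoch_s
    ep <- schedule_episode(t_trig, protocol)
    ep$pulses <- ep$pulses[ep$pulses$time_s < dur - 1 / rec$fs, , drop = FALSE]
    episodes[[length(episodes) + 1L]] <- ep
    exclusions <- rbind(exclusions, c(t_trig, min(ep$t_end_s, dur) + blank_s))
    t_free <- min(ep$t_end_s, dur)
  }
  detections <- data.frame(t_detect_s = accepted_t,
                           baseline_power = accepted_b)
  class(detections) <- c("detections", "data.frame")

  pulses <- if (length(episodes))
    do.call(rbind, lapply(episodes, `[[`, "pulses"))
  else data.frame(time_s = numeric(), package_idx = integer(),
                  width_s = numeric(), amplitude = numeric())

  stim_rec <- rec
  if (nrow(pulses) && spec$artifact$a0 != 0)
    stim_rec <- inject_artifacts(rec, pulses, spec$artifact,
                                 channel = stim_channel)
  cleaned <- remove_artifacts(stim_rec, pulses, blank_s = blank_s,
                              channel = stim_channel)

  events <- out$events
  if (nrow(events) && length(episodes)) {
    stim_iv <- do.call(rbind, lapply(episodes, function(e)
      c(e$t_trigger_s, e$t_end_s)))
    for (k in seq_len(nrow(events))) {
      hit <- any(events$onset_s[k] < stim_iv[, 2L] &
                 events$termination_s[k] > stim_iv[, 1L])
      if (hit) {
        d0 <- events$termination_s[k] - events$onset_s[k]
        events$termination_s[k] <- events$onset_s[k] + d0 * shortening_factor
      }
    }
  }
  list(recording = stim_rec, cleaned = cleaned, detections = detections,
       pulses = pulses, episodes = episodes, events = events,
       truth = out$events)
}

#' Seizure accounting per experimental period
#'
#' Per-period seizure count and mean durations, mirroring the
#' before / during / after summary of a stimulation-week design.
#'
#' @param events data.frame with `onset_s`, `termination_s`, a `period`
#'   column with values among `periods`, and optionally
#'   `behavior_duration_s`.
#' @param periods allowed period labels, in display order.
#' @return data.frame with columns `period`, `n_seizures`,
#'   `mean_discharge_duration_s`, `mean_behavior_duration_s` (NA when the
#'   period is empty or behavioral durations are absent).
#' @export
seizure_accounting <- function(events,
                               periods = c("before", "during", "after")) {
  if (nrow(events) && !all(events$period %in% periods))
    stop_lfpdbs(sprintf("unknown period tag(s): %s",
                        paste(setdiff(unique(events$period), periods),
                              collapse = ", ")),
                "lfpdbs_validation_error")
  out <- do.call(rbind, lapply(periods, function(p) {
    e <- events[nrow(events) > 0 & events$period == p, , drop = FALSE]
    data.frame(
      period = p,
      n_seizures = nrow(e),
      mean_discharge_duration_s =
        if (nrow(e)) mean(e$termination_s - e$onset_s) else NA_real_,
      mean_behavior_duration_s =
        if (nrow(e) && "behavior_duration_s" %in% names(e))
          mean(e$behavior_duration_s) else NA_real_)
  }))
  out$period <- factor(out$period, levels = periods)
  out
}

#' Per-seizure peri-ictal metric table
#'
#' For every seizure with valid pre/ictal/post windows, computes per
#' channel and band: Welch band power; inter-channel band coherence; and
#' band-level modulation index in both directions (channel-1 phase with
#' channel-2 amplitude and the reverse) plus within-channel coupling.
#' Seizures whose windows extend past the recording are skipped with a
#' warning. Coherence and MI need several analysis windows/cycles, so both
#' are computed on the pre and post windows only when those are long enough;
#' the 5 s ictal window gets band power always and coherence/MI when
#' feasible.
#'
#' @param rec an [recording()] (artifact-cleaned).
#' @param events a [seizure_events()] table.
#' @param bands named list of [band_def()]; default [default_bands()].
#' @param seg_cfg a [segmentation_config()].
#' @param wcfg a [welch_config()].
#' @param mi_phase_band,mi_amp_band bands for the band-level MI; default
#'   theta phase and gamma amplitude from `bands`.
#' @param mi_edge_trim_s edge trim for phase/amplitude extraction (s).
#' @return tidy data.frame: `seizure_id`, `period`, `metric`
#'   (`"power"`, `"coherence"`, `"mi"`), `channel` (label, pair, or
#'   `"<phase>->amp:<amp>"`), `band`, `value`.
#' @export
compute_seizure_metrics <- function(rec, events, bands = default_bands(),
                                    seg_cfg = segmentation_config(),
                                    wcfg = welch_config(),
                                    mi_phase_band = bands$theta,
                                    mi_amp_band = bands$gamma,
                                    mi_edge_trim_s = 1) {
  rows <- list()
  add <- function(sid, period, metric, channel, band, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      seizure_id = sid, period = period, metric = metric,
      channel = channel, band = band, value = value)

  for (sid in seq_len(nrow(events))) {
    segs <- tryCatch(segment_around_seizure(rec, events[sid, ], seg_cfg),
                     lfpdbs_boundary_error = function(e) NULL)
    if (is.null(segs)) {
      warning(sprintf("seizure %d skipped: windows outside recording", sid))
      next
    }
    for (period in names(segs)) {
      seg <- segs[[period]]
      psd <- welch_psd(seg, wcfg)
      for (ch in seg$channels) for (b in bands)
        add(sid, period, "power", ch, b$name, band_power(psd, b, ch))

      if (length(seg$channels) >= 2L) {
        cs <- tryCatch(msc(seg$samples[, 1L], seg$samples[, 2L], seg$fs, wcfg),
                       lfpdbs_validation_error = function(e) NULL)
        if (!is.null(cs)) {
          pair <- paste(seg$channels[1:2], collapse = "-")
          for (b in bands)
            add(sid, period, "coherence", pair, b$name, band_coherence(cs, b))
        }
      }

      trim <- min(mi_edge_trim_s, rec_duration(seg) / 4)
      mi_ok <- rec_duration(seg) - 2 * trim >=
        3 / mi_phase_band$f_lo  # need a few slow cycles after trimming
      if (mi_ok) {
        chs <- seg$channels
        combos <- list(c(1L, 1L))
        if (length(chs) >= 2L)
          combos <- c(combos, list(c(2L, 2L), c(1L, 2L), c(2L, 1L)))
        for (cb in combos) {
          v <- tryCatch(band_mi(seg$samples[, cb[1L]], seg$samples[, cb[2L]],
                                seg$fs, mi_phase_band, mi_amp_band,
                                edge_trim_s = trim),
                        lfpdbs_error = function(e) NA_real_)
          if (!is.na(v))
            add(sid, period, "mi",
                sprintf("%s->amp:%s", chs[cb[1L]], chs[cb[2L]]),
                sprintf("%s-%s", mi_phase_band$name, mi_amp_band$name), v)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(seizure_id = integer(), period = character(),
                      metric = character(), channel = character(),
                      band = character(), value = numeric()))
  do.call(rbind, rows)
}

#' Group statistics over per-seizure metric tables
#'
#' For every (metric, period, channel, band) cell present in all groups,
#' runs the KS normality screen per group, a one-way ANOVA across groups
#' and Tukey's HSD post-hoc test.
#'
#' @param metrics_by_group named list (one element per experimental group)
#'   of [compute_seizure_metrics()] tables.
#' @return list of data.frames: `anova` (one row per cell), `tukey` (one
#'   row per cell x pair), `ks` (one row per cell x group).
#' @export
group_metric_stats <- function(metrics_by_group) {
  if (length(metrics_by_group) < 2L)
    stop_lfpdbs("need at least 2 groups", "lfpdbs_validation_error")
  key_cols <- c("metric", "period", "channel", "band")
  keys <- unique(do.call(rbind,
    lapply(metrics_by_group, function(d) d[key_cols])))
  anova_rows <- list(); tukey_rows <- list(); ks_rows <- list()
  for (r in seq_len(nrow(keys))) {
    k <- keys[r, ]
    vals <- lapply(metrics_by_group, function(d) {
      sel <- d$metric == k$metric & d$period == k$period &
        d$channel == k$channel & d$band == k$band
      d$value[sel]
    })
    if (any(vapply(vals, length, integer(1)) < 2L)) next
    a <- one_way_anova(vals)
    anova_rows[[length(anova_rows) + 1L]] <-
      cbind(k, data.frame(F = a$F, df_between = a$df_between,
                          df_within = a$df_within, p = a$p))
    tk <- tukey_hsd(vals)
    tukey_rows[[length(tukey_rows) + 1L]] <- cbind(k[rep(1L, nrow(tk)), ], tk)
    for (g in names(vals)) {
      ks <- tryCatch(ks_normality(vals[[g]]), lfpdbs_error = function(e)
        list(statistic = NA_real_, p = NA_real_))
      ks_rows[[length(ks_rows) + 1L]] <-
        cbind(k, data.frame(group = g, D = ks$statistic, p = ks$p))
    }
  }
  list(anova = do.call(rbind, anova_rows),
       tukey = do.call(rbind, tukey_rows),
       ks = do.call(rbind, ks_rows))
}

#' Run the full analysis stage and write tidy outputs
#'
#' Removes stimulation artifacts when a pulse log is supplied, computes the
#' per-seizure metric table and post/pre ratios, and optionally writes the
#' tables plus a JSON manifest (configuration and seed) to `out_dir`. Rerun
#' with the same inputs, the outputs are bit-identical.
#'
#' @param rec an [recording()].
#' @param events a [seizure_events()] table.
#' @param pulses optional stimulation log (data.frame with `time_s`).
#' @param bands,seg_cfg,wcfg as in [compute_seizure_metrics()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param manifest optional named list stored in the JSON manifest.
#' @return list with `metrics`, `ratios` and (if written) `files`.
#' @export
run_analysis <- function(rec, events, pulses = NULL,
                         bands = default_bands(),
                         seg_cfg = segmentation_config(),
                         wcfg = welch_config(),
                         out_dir = NULL, manifest = list()) {
  if (!is.null(pulses) && nrow(pulses))
    rec <- remove_artifacts(rec, pulses)
  metrics <- compute_seizure_metrics(rec, events, bands, seg_cfg, wcfg)
  if (!nrow(metrics)) {
    warning("no analyzable seizures")
    return(list(metrics = metrics, ratios = NULL))
  }
  rt <- metrics[metrics$period %in% c("pre", "post"), ]
  names(rt)[names(rt) == "value"] <- "value"
  ratios <- post_pre_ratio(data.frame(seizure_id = rt$seizure_id,
                                      period = rt$period, channel = rt$channel,
                                      band = rt$band, metric = rt$metric,
                                      value = rt$value))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(metrics = file.path(out_dir, "metrics.csv"),
               ratios = file.path(out_dir, "post_pre_ratios.csv"),
               manifest = file.path(out_dir, "manifest.json"))
    utils::write.csv(metrics, files[["metrics"]], row.names = FALSE)
    utils::write.csv(ratios, files[["ratios"]], row.names = FALSE)
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, ratios = ratios, files = files)
}
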