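#' Call cell-cycle phases from FUCCI reporter tracks
#'
#' Thresholds the red (G1) and green (S/G2) channels with hysteresis: a
#' channel switches on only above `threshold * (1 + hysteresis_fraction)` and
#' off only below `threshold * (1 - hysteresis_fraction)`, which suppresses
#' flicker from frame-to-frame noise. Green-only frames are S/G2, red-only
#' frames G1, both-high frames "transition"; frames where neither channel is
#' on keep the previous call. A set dead flag overrides everything.
#'
#' @param tracks a `track_table`.
#' @param thresholds named numeric `c(red_on = ..., green_on = ...)`.
#' @param hysteresis_fraction relative hysteresis band width (default 0.2).
#' @return a `phase_series` data.frame: cell_id, time_h, phase with phase in
#'   `{"G1", "S/G2", "transition", "dead"}`.
#' @export
call_phases <- function(tracks, thresholds = c(red_on = 300, green_on = 300),
                        hysteresis_fraction = 0.2) {
  tracks <- as_track_table(tracks)
  red_on <- thresholds[["red_on"]]
  green_on <- thresholds[["green_on"]]
  if (red_on <= 0 || green_on <= 0) stop("thresholds must be positive")
  f <- hysteresis_fraction
  out <- vector("list", length(unique(tracks$cell_id)))
  i <- 0L
  for (cid in unique(tracks$cell_id)) {
    sub <- tracks[tracks$cell_id == cid, ]
    red_state <- sub$red[1L] > red_on
    green_state <- sub$green[1L] > green_on
    phase <- character(nrow(sub))
    prev <- "transition"
    for (t in seq_len(nrow(sub))) {
      if (t > 1L) {
        red_state <- if (red_state) sub$red[t] >= red_on * (1 - f) else sub$red[t] > red_on * (1 + f)
        green_state <- if (green_state) sub$green[t] >= green_on * (1 - f) else sub$green[t] > green_on * (1 + f)
      }
      phase[t] <- if (sub$dead[t] == 1) {
        "dead"
      } else if (green_state && !red_state) {
        "S/G2"
      } else if (red_state && !green_state) {
        "G1"
      } else if (red_state && green_state) {
        "transition"
      } else {
        prev
      }
      if (phase[t] != "dead") prev <- phase[t]
    }
    i <- i + 1L
    out[[i]] <- data.frame(cell_id = cid, time_h = sub$time_h, phase = phase,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("phase_series", "data.frame")
  res
}

#' Population-level cell-cycle dynamics
#'
#' Counts alive cells per phase at every observed timepoint and expresses
#' them as percentages. By default percentages are relative to the number of
#' cells alive at `baseline_time` (so the total curve can fall below 100% as
#' cells die or leave observation); `normalize = "per_time"` uses each
#' timepoint's own alive total instead.
#'
#' @param phases a `phase_series` from [call_phases()].
#' @param baseline_time timepoint defining the 100% reference (default 0).
#' @param normalize `"baseline"` (default) or `"per_time"`.
#' @return data.frame time_h, n_total, n_G1, n_SG2, n_transition,
#'   pct_total, pct_G1, pct_SG2.
#' @export
population_curve <- function(phases, baseline_time = 0,
                             normalize = c("baseline", "per_time")) {
  normalize <- match.arg(normalize)
  times <- sort(unique(phases$time_h))
  alive <- phases$phase != "dead"
  n_total <- vapply(times, function(t) sum(alive & phases$time_h == t), numeric(1))
  n_g1 <- vapply(times, function(t) sum(phases$phase == "G1" & phases$time_h == t), numeric(1))
  n_sg2 <- vapply(times, function(t) sum(phases$phase == "S/G2" & phases$time_h == t), numeric(1))
  n_tr <- vapply(times, function(t) sum(phases$phase == "transition" & phases$time_h == t), numeric(1))
  base <- if (normalize == "baseline") {
    idx <- which(times == baseline_time)
    if (length(idx) == 0L || n_total[idx] == 0L) {
      stop("baseline timepoint has no alive cell")
    }
    rep(n_total[idx], length(times))
  } else {
    pmax(n_total, 1)
  }
  data.frame(
    time_h = times, n_total = n_total, n_G1 = n_g1, n_SG2 = n_sg2,
    n_transition = n_tr,
    pct_total = 100 * n_total / base,
    pct_G1 = 100 * n_g1 / base,
    pct_SG2 = 100 * n_sg2 / base
  )
}

#' Classify per-cell fate after S/G2 entry
#'
#' For every cell with an S/G2 entry in its phase series: mitosis if a
#' division event follows entry; death if the cell dies before any division;
#' endoreplication if the phase returns to G1 after S/G2 with neither
#' division nor death (mitotic slippage); otherwise the cell is censored
#' (still in S/G2 at track end) and excluded from fate percentages but
#' reported.
#'
#' @param phases a `phase_series` from [call_phases()].
#' @param tracks the matching `track_table` (source of the division and
#'   death flags).
#' @return a `fate_record` data.frame: cell_id, t_SG2_entry, fate (one of
#'   mitosis / endoreplication / death / censored), t_event, g1_duration_h
#'   (pre-entry dwell), sg2_duration_h (entry to event).
#' @export
classify_fate <- function(phases, tracks) {
  tracks <- as_track_table(tracks)
  rows <- list()
  for (cid in unique(phases$cell_id)) {
    ph <- phases[phases$cell_id == cid, ]
    tr <- tracks[tracks$cell_id == cid, ]
    if (nrow(tr) == 0L) next
    if (any(tr$divided == 1 & tr$dead == 1)) {
      stop(sprintf("cell '%s' is flagged divided and dead at the same timepoint", cid))
    }
    entry_idx <- which(ph$phase == "S/G2")[1L]
    if (is.na(entry_idx)) next
    t_entry <- ph$time_h[entry_idx]
    t_div <- tr$time_h[tr$divided == 1 & tr$time_h >= t_entry][1L]
    t_dead <- tr$time_h[tr$dead == 1][1L]
    after <- ph[ph$time_h > t_entry, ]
    t_g1_return <- after$time_h[after$phase == "G1"][1L]

    if (!is.na(t_div) && (is.na(t_dead) || t_div < t_dead)) {
      fate <- "mitosis"; t_event <- t_div
    } else if (!is.na(t_dead) && t_dead >= t_entry) {
      fate <- "death"; t_event <- t_dead
    } else if (!is.na(t_g1_return)) {
      fate <- "endoreplication"; t_event <- t_g1_return
    } else {
      fate <- "censored"; t_event <- NA_real_
    }
    rows[[cid]] <- data.frame(
      cell_id = cid, t_SG2_entry = t_entry, fate = fate, t_event = t_event,
      g1_duration_h = t_entry - ph$time_h[1L],
      sg2_duration_h = if (is.na(t_event)) NA_real_ else t_event - t_entry,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(cell_id = character(), t_SG2_entry = numeric(),
                      fate = character(), t_event = numeric(),
                      g1_duration_h = numeric(), sg2_duration_h = numeric(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("fate_record", "data.frame")
  out
}

#' Summarize cell fates per condition
#'
#' Percentages of mitosis, endoreplication and death over uncensored cells
#' (summing to 100 within rounding), plus mean and SEM of the pre-entry G1
#' and post-entry S/G2 dwell times.
#'
#' @param records a `fate_record` (or rbind of several).
#' @param conditions optional named vector mapping cell_id to condition;
#'   default treats all records as one condition.
#' @return data.frame per condition: n_tracked, n_censored, pct_mitosis,
#'   pct_endoreplication, pct_death, mean/SEM durations.
#' @export
fate_summary <- function(records, conditions = NULL) {
  if (nrow(records) == 0L) stop("no fate records supplied")
  cond <- if (is.null(conditions)) {
    rep("all", nrow(records))
  } else {
    unname(conditions[records$cell_id])
  }
  out <- lapply(sort(unique(cond)), function(cc) {
    sub <- records[cond == cc, ]
    unc <- sub[sub$fate != "censored", ]
    if (nrow(unc) == 0L) stop(sprintf("condition '%s' has no uncensored record", cc))
    n <- nrow(unc)
    sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(
      condition = cc, n_tracked = nrow(sub), n_censored = nrow(sub) - n,
      pct_mitosis = 100 * sum(unc$fate == "mitosis") / n,
      pct_endoreplication = 100 * sum(unc$fate == "endoreplication") / n,
      pct_death = 100 * sum(unc$fate == "death") / n,
      mean_g1_h = mean(unc$g1_duration_h), sem_g1_h = sem(unc$g1_duration_h),
      mean_sg2_h = mean(unc$sg2_duration_h), sem_sg2_h = sem(unc$sg2_duration_h),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
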