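# Tumor-volume response: caliper ellipsoid volumes, percent volume change,
# best response, and mRECIST classification of PARP-inhibitor antitumor
# activity in xenografts.

#' Caliper ellipsoid tumor volume
#'
#' \eqn{V = (\pi/6) L l^2}, the standard scalene-ellipsoid caliper formula
#' with L the largest and l the smallest diameter in mm. Percent volume
#' change is ratio-based, so the leading constant never affects response
#' classification.
#'
#' @param L largest diameter (mm).
#' @param l smallest diameter (mm).
#' @return volume in mm^3 (vectorized).
#' @export
ellipsoid_volume <- function(L, l) {
  if (any(l <= 0) || any(L < l))
    abort("need L >= l > 0")
  (pi / 6) * L * l^2
}

#' Construct/validate a tumor-volume series
#'
#' @param df data.frame with columns `day` and `volume_mm3`, or `day`,
#'   `L_mm`, `l_mm` (volumes derived via [ellipsoid_volume()]). Days must be
#'   strictly increasing and include day 1 (first treatment day).
#' @return the validated data.frame, ordered by day.
#' @export
volume_series <- function(df) {
  if (!"volume_mm3" %in% names(df)) {
    if (!all(c("L_mm", "l_mm") %in% names(df)))
      abort("need volume_mm3 or L_mm + l_mm columns")
    df$volume_mm3 <- ellipsoid_volume(df$L_mm, df$l_mm)
  }
  df <- df[order(df$day), , drop = FALSE]
  if (anyDuplicated(df$day)) abort("duplicate measurement days")
  if (!1 %in% df$day) abort("series must contain day 1")
  if (any(df$volume_mm3 <= 0)) abort("volumes must be positive")
  df
}

# Nearest measurement to `day` within +/- window; earlier wins ties.
nearest_day <- function(days, day, window = 3) {
  d <- abs(days - day)
  if (min(d) > window)
    abort(sprintf("no measurement within %d days of day %d", window, day))
  cand <- which(d == min(d))
  days[cand[1]]  # days sorted ascending, so ties resolve to the earlier day
}

#' Percent tumor-volume change relative to day 1
#'
#' \eqn{100 (V_{day} - V_1)/V_1}, using the measurement nearest to the
#' requested day within a +/- `window`-day tolerance (earlier wins ties).
#'
#' @param series a [volume_series()] data.frame.
#' @param day target day (default 21).
#' @param window matching window in days (default 3; caliper measurements
#'   are bi-weekly).
#' @return percent change.
#' @export
percent_volume_change <- function(series, day = 21, window = 3) {
  series <- volume_series(series)
  v1 <- series$volume_mm3[series$day == 1]
  d <- nearest_day(series$day, day, window)
  100 * (series$volume_mm3[series$day == d] - v1) / v1
}

#' Best response of a volume series
#'
#' The minimum percent volume change observed at least 10 days after
#' treatment start (day >= 11) — a sustained response, not a transient dip.
#' Option `rule = "window"` instead requires the value to be maintained over
#' a 10-day window: it returns the minimum over timepoints t of the maximum
#' change within \[t, t+10\] days, evaluated where such a window exists.
#'
#' @param series a [volume_series()] data.frame.
#' @param rule `"from_day10"` (default) or `"window"`.
#' @return best response in percent.
#' @export
best_response <- function(series, rule = c("from_day10", "window")) {
  rule <- match.arg(rule)
  series <- volume_series(series)
  if (max(series$day) - min(series$day) < 10)
    abort("series must span at least 10 days")
  chg <- vapply(series$day, function(d)
    percent_volume_change(series, d, window = 0), numeric(1))
  if (rule == "from_day10") {
    min(chg[series$day >= 11])
  } else {
    anchors <- series$day[series$day + 10 <= max(series$day)]
    min(vapply(anchors, function(t) {
      max(chg[series$day >= t & series$day <= t + 10])
    }, numeric(1)))
  }
}

#' Classify a volume series by mRECIST
#'
#' Progressive disease (PD) iff the day-21 change exceeds +20 percent;
#' otherwise the best response is classed CR (<= -95), PR (-95 < x <= -30)
#' or SD (-30 < x <= +20), boundaries inclusive as written.
#'
#' @param series a [volume_series()] data.frame.
#' @param day21_window matching window for the day-21 measurement.
#' @param rule best-response rule, see [best_response()].
#' @return list(`mrecist`, `best_response`, `pct_change_day21`).
#' @export
classify_mrecist <- function(series, day21_window = 3,
                             rule = "from_day10") {
  d21 <- percent_volume_change(series, 21, day21_window)
  br <- best_response(series, rule)
  cls <- if (d21 > 20) "PD"
         else if (br <= -95) "CR"
         else if (br <= -30) "PR"
         else "SD"
  list(mrecist = cls, best_response = br, pct_change_day21 = d21)
}

# Classification from a precomputed percent-change trajectory (model-level
# mean curves); same thresholds as classify_mrecist.
classify_mrecist_changes <- function(days, changes, day21_window = 3) {
  d <- abs(days - 21)
  if (min(d) > day21_window) abort("no measurement near day 21")
  d21 <- changes[which(d == min(d))[1]]
  if (max(days) - min(days) < 10) abort("trajectory must span >= 10 days")
  br <- min(changes[days >= 11])
  cls <- if (d21 > 20) "PD"
         else if (br <= -95) "CR"
         else if (br <= -30) "PR"
         else "SD"
  list(mrecist = cls, best_response = br, pct_change_day21 = d21)
}

#' Classify every model in a volume table
#'
#' Animals are aggregated per model and arm by the mean percent change per
#' measurement day (each animal normalized to its own day-1 volume), then
#' the mean trajectory is classified; `aggregate = "animal"` instead
#' classifies each animal and reports the modal class.
#'
#' @param volumes data.frame: `model_id`, `animal_id`, `arm`, `day`, and
#'   `volume_mm3` (or `L_mm` + `l_mm`).
#' @param aggregate `"model"` (default) or `"animal"`.
#' @return data.frame: `model_id`, `arm`, `pct_change_day21`,
#'   `best_response`, `mrecist`.
#' @export
classify_models <- function(volumes, aggregate = c("model", "animal")) {
  aggregate <- match.arg(aggregate)
  res <- lapply(split(volumes, volumes[c("model_id", "arm")], drop = TRUE),
                function(g) {
    per_animal <- lapply(split(g, g$animal_id), function(a) {
      a <- volume_series(a)
      data.frame(day = a$day,
                 change = vapply(a$day, function(d)
                   percent_volume_change(a, d, 0), numeric(1)))
    })
    if (aggregate == "animal") {
      calls <- vapply(per_animal, function(tr)
        classify_mrecist_changes(tr$day, tr$change)$mrecist, character(1))
      cl <- names(sort(table(calls), decreasing = TRUE))[1]
      mean_tr <- do.call(rbind, per_animal)
      m <- stats::aggregate(change ~ day, mean_tr, mean)
      cc <- classify_mrecist_changes(m$day, m$change)
      cc$mrecist <- cl
    } else {
      all_tr <- do.call(rbind, per_animal)
      m <- stats::aggregate(change ~ day, all_tr, mean)
      cc <- classify_mrecist_changes(m$day, m$change)
    }
    data.frame(model_id = g$model_id[1], arm = g$arm[1],
               pct_change_day21 = cc$pct_change_day21,
               best_response = cc$best_response, mrecist = cc$mrecist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$model_id, out$arm), , drop = FALSE]
}
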