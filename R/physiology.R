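# Organism-level quantification: embryonic-heart function from axis/area
# traces, cardinal-vein erythrocyte velocity, larval locomotor summaries,
# inverted-screen scoring, and six-minute-walk reference distances.
#
# A ventricle trace is a list with:
#   $frames  data.frame(a, b, area)  - long axis, short axis, area per frame
#   $fps     frame rate (default 150)
#   $diastole, $systole  frame indices of end-diastole / end-systole per beat

#' Heart rate from annotated beats
#'
#' The inter-beat interval is measured over consecutive triplets of beats
#' (time across three beats / 3); the rate is the mean of the per-triplicate
#' rates.
#'
#' @param trace ventricle trace (needs `$diastole` and `$fps`).
#' @return heart rate in beats per minute.
#' @export
heart_rate <- function(trace) {
  d <- trace$diastole
  if (length(d) < 4) stop("need >= 3 annotated beats (4 diastole marks)")
  times <- (d - d[1]) / trace$fps
  ibi <- diff(times)
  n_tri <- length(ibi) %/% 3
  tri_rate <- vapply(seq_len(n_tri), function(k)
    60 / mean(ibi[(3 * k - 2):(3 * k)]), numeric(1))
  mean(tri_rate)
}

#' Prolate-spheroid ventricular volume
#'
#' `V = (4/3) * pi * a * b^2`, applied verbatim to the supplied long-axis
#' `a` and short-axis `b` values. Whether `a`, `b` are full lengths or
#' semi-axes changes only a constant factor that cancels in SF, FAC, EF and
#' any between-group ratio; `semi = TRUE` applies the semi-axis form
#' `pi * a * b^2 / 6`.
#'
#' @param a,b long and short axis (same length units).
#' @param semi interpret `a`, `b` as full lengths and halve them.
#' @return volume in units^3.
#' @export
spheroid_volume <- function(a, b, semi = FALSE) {
  stopifnot(all(a > 0), all(b > 0))
  if (semi) pi * a * b^2 / 6 else 4 / 3 * pi * a * b^2
}

#' Cardiac function metrics from a ventricle trace
#'
#' End-diastolic and end-systolic volumes come from [spheroid_volume()] at
#' the annotated frames, averaged over the first three beats (triplicate).
#' SV = EDV - ESV; CO = HR x SV;
#' SF = (Ld - Ls)/Ld x 100; FAC = (Ad - As)/Ad x 100; EF = (EDV - ESV)/EDV x 100.
#'
#' @param trace ventricle trace.
#' @param n_beats beats averaged (default 3).
#' @param semi passed to [spheroid_volume()].
#' @return list `HR`, `EDV`, `ESV`, `SV`, `CO`, `SF`, `FAC`, `EF`, plus
#'   per-beat values; traces where ESV > EDV in more than half the beats are
#'   flagged invalid.
#' @export
cardiac_metrics <- function(trace, n_beats = 3L, semi = FALSE) {
  nd <- min(length(trace$diastole), length(trace$systole), n_beats)
  if (nd < 1) stop("need annotated diastole/systole frames")
  di <- trace$diastole[seq_len(nd)]
  si <- trace$systole[seq_len(nd)]
  f <- trace$frames
  edv <- spheroid_volume(f$a[di], f$b[di], semi = semi)
  esv <- spheroid_volume(f$a[si], f$b[si], semi = semi)
  if (mean(esv > edv) > 0.5) stop("trace invalid: ESV > EDV in most beats")
  hr <- heart_rate(trace)
  EDV <- mean(edv); ESV <- mean(esv)
  Ld <- mean(f$a[di]); Ls <- mean(f$a[si])
  Ad <- mean(f$area[di]); As <- mean(f$area[si])
  SV <- EDV - ESV
  list(HR = hr, EDV = EDV, ESV = ESV, SV = SV, CO = hr * SV,
       SF = (Ld - Ls) / Ld * 100,
       FAC = (Ad - As) / Ad * 100,
       EF = (EDV - ESV) / EDV * 100,
       per_beat = data.frame(EDV = edv, ESV = esv))
}

#' Mean erythrocyte velocity from frame-by-frame tracks
#'
#' Each cell is tracked over a fixed window of consecutive frames (default
#' 10); its velocity is the mean frame-to-frame displacement times the frame
#' rate. The per-fish value is the mean over the tracked cells (default 3).
#'
#' @param tracks list of per-cell data.frames with `x`, `y` (mm) per frame.
#' @param fps frame rate (default 150).
#' @param n_frames frames per tracking window (default 10).
#' @return list `per_cell` (mm/s) and `velocity` (per-fish mean, mm/s).
#' @export
rbc_velocity <- function(tracks, fps = 150, n_frames = 10L) {
  per_cell <- vapply(tracks, function(tr) {
    if (nrow(tr) < n_frames) stop("track shorter than the tracking window")
    tr <- tr[seq_len(n_frames), , drop = FALSE]
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    mean(step) * fps
  }, numeric(1))
  list(per_cell = per_cell, velocity = mean(per_cell))
}

#' Locomotor summary of a larval swim track
#'
#' Frame speeds below the record threshold (default 2 mm/s) count as
#' inactivity and contribute no distance; active movement is classified
#' small (< 10 mm/s) or high-speed (>= `high_speed`). Distances and moving
#' times are aggregated per integration bin (default 30 s) and totalled.
#'
#' @param x,y positions in mm per frame.
#' @param t timestamps in s (strictly increasing).
#' @param bin_s integration period (default 30).
#' @param record_mm_s inactivity threshold (default 2).
#' @param small_mm_s upper bound of "small" movements (default 10).
#' @param high_speed lower bound of high-speed movements in mm/s; this
#'   threshold is a package default (20), not a measured constant.
#' @return list `bins` (per-bin distance, moving time, small/high-speed
#'   durations), `total_distance`, `total_moving_time`, `small_time`,
#'   `high_speed_time`.
#' @export
locomotor_summary <- function(x, y, t, bin_s = 30, record_mm_s = 2,
                              small_mm_s = 10, high_speed = 20) {
  stopifnot(length(x) == length(y), length(x) == length(t))
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (bin_s > (t[length(t)] - t[1])) stop("bin longer than recording")
  dt <- diff(t)
  step <- sqrt(diff(x)^2 + diff(y)^2)
  speed <- step / dt
  active <- speed >= record_mm_s
  small <- active & speed < small_mm_s
  high <- speed >= high_speed
  mid <- t[-length(t)] - t[1]
  bin <- floor(mid / bin_s) + 1L
  agg <- function(v) as.numeric(tapply(v, bin, sum))
  bins <- data.frame(
    bin = sort(unique(bin)),
    distance = agg(step * active),
    moving_time = agg(dt * active),
    small_time = agg(dt * small),
    high_speed_time = agg(dt * high)
  )
  list(bins = bins,
       total_distance = sum(bins$distance),
       total_moving_time = sum(bins$moving_time),
       small_time = sum(bins$small_time),
       high_speed_time = sum(bins$high_speed_time))
}

#' Inverted-screen trial scoring
#'
#' Each hang time is capped at `cap` seconds (a mouse still hanging at the
#' cap is removed and assigned the cap); the cumulative score is the sum of
#' capped times across the trials (default 6).
#'
#' @param times raw hang times in s.
#' @param n_trials expected trial count (default 6; mismatch warns).
#' @param cap per-trial maximum (default 180 s).
#' @return list `capped`, `cumulative`.
#' @export
inverted_screen_score <- function(times, n_trials = 6L, cap = 180) {
  stopifnot(all(times >= 0))
  if (length(times) != n_trials)
    warning(sprintf("expected %d trials, got %d", n_trials, length(times)))
  capped <- pmin(times, cap)
  list(capped = capped, cumulative = sum(capped))
}

#' Reference six-minute-walk distance (adults)
#'
#' Enright-Sherrill reference equations, with the published coefficients:
#' men `6MWD = 7.57 h - 5.02 age - 1.76 w - 309`,
#' women `6MWD = 2.11 h - 2.29 w - 5.78 age + 667` (h in cm, w in kg,
#' age in years, result in meters).
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm,age_y,weight_kg adult anthropometrics (> 0).
#' @return predicted distance in meters.
#' @export
reference_6mwd <- function(sex = c("male", "female"), height_cm, age_y, weight_kg) {
  sex <- match.arg(sex)
  stopifnot(height_cm > 0, age_y > 0, weight_kg > 0)
  if (sex == "male")
    7.57 * height_cm - 5.02 * age_y - 1.76 * weight_kg - 309
  else
    2.11 * height_cm - 2.29 * weight_kg - 5.78 * age_y + 667
}
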