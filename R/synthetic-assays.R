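# Seeded assay simulators. Noiseless output lies exactly on the closed-form
# models the analysis fits, so round-trip recovery can be asserted to
# numerical precision; noise models are multiplicative log-normal jitter on
# counts and additive Gaussian error on currents.

#' Simulate a rubidium-efflux experiment
#'
#' Released counts per collection interval are proportional to the increments
#' of the cumulative efflux `1 - exp(-(k1 + k2) t)`; the lysate carries the
#' remainder. `noise_cv = 0` gives exact model counts.
#'
#' @param k1 background (channel-independent) rate, per minute.
#' @param k2 K(ATP)-dependent rate, per minute (0 for GFP-only wells).
#' @param timepoints collection times in minutes.
#' @param n_wells replicate wells.
#' @param total_counts loaded counts per well.
#' @param noise_cv coefficient of variation of the multiplicative count
#'   noise.
#' @param seed integer.
#' @return list of class `efflux_sim`: `wells` (list of
#'   `data.frame(time, released)` plus `lysate`), `timepoints`, `truth`.
#' @export
simulate_efflux <- function(k1, k2 = 0,
                            timepoints = c(2.5, 5, 12.5, 22.5, 37.5),
                            n_wells = 6L, total_counts = 2e4,
                            noise_cv = 0.05, seed = 1L) {
  if (k1 < 0 || k2 < 0) stop("rates must be >= 0")
  stopifnot(all(diff(timepoints) > 0), noise_cv >= 0)
  local_seed(seed, {
    frac <- 1 - exp(-(k1 + k2) * timepoints)
    inc <- diff(c(0, frac))
    wells <- lapply(seq_len(n_wells), function(w) {
      jit <- if (noise_cv > 0)
        exp(stats::rnorm(length(inc) + 1L, -noise_cv^2 / 2, noise_cv))
      else rep(1, length(inc) + 1L)
      released <- total_counts * inc * jit[-length(jit)]
      lysate <- total_counts * (1 - frac[length(frac)]) * jit[length(jit)]
      list(data = data.frame(time = timepoints, released = released),
           lysate = lysate)
    })
    structure(list(wells = wells, timepoints = timepoints,
                   truth = list(k1 = k1, k2 = k2, noise_cv = noise_cv,
                                seed = seed)),
              class = "efflux_sim")
  })
}

#' Pool simulated efflux wells into fit-ready vectors
#'
#' @param sim an `efflux_sim`.
#' @return data.frame `time`, `fraction` with all wells concatenated.
#' @export
pool_efflux <- function(sim) {
  do.call(rbind, lapply(sim$wells, function(w) {
    data.frame(time = w$data$time,
               fraction = cumulative_efflux(w$data$released, w$lysate))
  }))
}

#' Simulate an ATP dose-response experiment
#'
#' Noiseless currents lie exactly on
#' `basal * (Imin + (1 - Imin) / (1 + (x / IC50)^H))`.
#'
#' @param ic50 half-maximal inhibitory concentration.
#' @param h Hill coefficient (> 0).
#' @param imin normalized residual current in \[0, 1\] (default 0.1).
#' @param concentrations tested concentrations (> 0).
#' @param n_rep replicates per concentration.
#' @param basal basal (inhibitor-free) current the normalization divides by.
#' @param noise_sd additive noise on the normalized scale.
#' @param seed integer.
#' @return list of class `dose_sim`: `data` (`concentration`, `current`),
#'   `basal`, `truth`.
#' @export
simulate_dose_response <- function(ic50 = 100, h = 1, imin = 0.1,
                                   concentrations = c(1, 3, 10, 30, 100, 300,
                                                      1000, 3000, 10000),
                                   n_rep = 5L, basal = 500,
                                   noise_sd = 0.015, seed = 1L) {
  stopifnot(ic50 > 0, h > 0, imin >= 0, imin <= 1, all(concentrations > 0),
            basal > 0, noise_sd >= 0)
  local_seed(seed, {
    x <- rep(concentrations, each = n_rep)
    y <- hill_current(x, ic50, h, imin) + stats::rnorm(length(x), 0, noise_sd)
    structure(list(data = data.frame(concentration = x, current = y * basal),
                   basal = basal,
                   truth = list(ic50 = ic50, h = h, imin = imin,
                                noise_sd = noise_sd, seed = seed)),
              class = "dose_sim")
  })
}

#' Simulate a ventricle axis/area trace
#'
#' Long and short axes oscillate sinusoidally between their end-diastolic and
#' end-systolic values at the given beat rate; the per-frame area is the
#' ellipse area `pi * a * b / 4`. End-diastole and end-systole frames are
#' annotated at the phase extrema. Noiseless traces reproduce the planted
#' volumes exactly.
#'
#' @param ed_long,es_long end-diastolic / end-systolic long axis.
#' @param ed_short,es_short end-diastolic / end-systolic short axis.
#' @param rate_bpm beat rate (default 150, ~a 5-dpf embryonic heart).
#' @param fps frame rate (default 150).
#' @param duration_s recording length (default 10 s, ~30 cycles).
#' @param noise_sd additive axis noise (same units as the axes).
#' @param seed integer.
#' @return ventricle trace list (`frames`, `fps`, `diastole`, `systole`,
#'   `truth`).
#' @export
simulate_ventricle_trace <- function(ed_long = 10, es_long = 8,
                                     ed_short = 6, es_short = 4.5,
                                     rate_bpm = 150, fps = 150,
                                     duration_s = 10, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(ed_long >= es_long, ed_short >= es_short, es_long > 0,
            es_short > 0, fps > 0, rate_bpm > 0)
  local_seed(seed, {
    n <- floor(duration_s * fps)
    # beat period quantized to an even number of frames, so end-diastole and
    # end-systole fall exactly on annotated frames; the realized rate is
    # reported in the truth ledger
    pf <- max(2L, 2L * round(fps * 30 / rate_bpm))
    hr <- 60 * fps / pf
    k <- seq_len(n) - 1L
    phase <- cos(2 * pi * k / pf)                 # +1 diastole, -1 systole
    a <- (ed_long + es_long) / 2 + (ed_long - es_long) / 2 * phase
    b <- (ed_short + es_short) / 2 + (ed_short - es_short) / 2 * phase
    if (noise_sd > 0) {
      a <- a + stats::rnorm(n, 0, noise_sd)
      b <- b + stats::rnorm(n, 0, noise_sd)
    }
    area <- pi * a * b / 4
    n_beats <- n %/% pf
    diastole <- 1L + (seq_len(n_beats) - 1L) * pf
    systole <- diastole + pf %/% 2L
    systole <- systole[systole <= n]
    list(frames = data.frame(a = a, b = b, area = area), fps = fps,
         diastole = diastole, systole = systole,
         truth = list(EDV = spheroid_volume(ed_long, ed_short),
                      ESV = spheroid_volume(es_long, es_short),
                      HR = hr,
                      SF = (ed_long - es_long) / ed_long * 100,
                      FAC = (ed_long * ed_short - es_long * es_short) /
                        (ed_long * ed_short) * 100,
                      seed = seed))
  })
}

#' Simulate a larval swim track
#'
#' Per-frame speeds follow a three-state Markov mixture (inactive, small,
#' high-speed); headings follow a random walk. Speeds within each state are
#' uniform over the state's band.
#'
#' @param duration_s recording length (default 300 s).
#' @param fps frame rate.
#' @param p_state stationary probabilities `c(inactive, small, high)`.
#' @param persist per-frame probability of staying in the current state.
#' @param bands speed bands (mm/s) as a list of `c(lo, hi)` per state.
#' @param seed integer.
#' @return list `track` (`t`, `x`, `y`), `speeds`, `states`, `truth`.
#' @export
simulate_track <- function(duration_s = 300, fps = 25,
                           p_state = c(0.4, 0.4, 0.2), persist = 0.9,
                           bands = list(c(0, 1.5), c(2.5, 9.5), c(20, 35)),
                           seed = 1L) {
  stopifnot(length(p_state) == 3, abs(sum(p_state) - 1) < 1e-8, fps > 0)
  local_seed(seed, {
    n <- floor(duration_s * fps)
    states <- integer(n)
    states[1] <- sample(1:3, 1, prob = p_state)
    for (i in 2:n) {
      states[i] <- if (stats::runif(1) < persist) states[i - 1]
                   else sample(1:3, 1, prob = p_state)
    }
    lo <- vapply(bands, `[`, numeric(1), 1)
    hi <- vapply(bands, `[`, numeric(1), 2)
    speeds <- stats::runif(n, lo[states], hi[states])
    heading <- cumsum(stats::rnorm(n, 0, 0.4))
    step <- speeds / fps
    x <- cumsum(c(0, (step * cos(heading))[-n]))
    y <- cumsum(c(0, (step * sin(heading))[-n]))
    tt <- (seq_len(n) - 1) / fps
    list(track = data.frame(t = tt, x = x, y = y),
         speeds = speeds, states = states,
         truth = list(p_state = p_state, bands = bands, seed = seed))
  })
}
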