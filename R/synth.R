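#' Synthetic-recording generator configuration
#'
#' Parameters of the seeded generator that emulates the amplitude taxonomy
#' of abdominal accelerometry: fetal-movement bursts with peak amplitude in
#' (0.015, 0.06) g, maternal body-movement artifacts above 0.1 g, maternal
#' breathing below 0.015 g, and white sensor noise. Event rates are per
#' minute (FM perception counts of roughly 7-12 per hour correspond to
#' `fm_rate_per_min` near 0.15).
#'
#' @param duration_s recording length in seconds (default 3600).
#' @param sample_rate samples/second (default 100).
#' @param fm_rate_per_min expected FM events per minute (default 0.15).
#' @param fm_amp_range FM burst peak amplitude range in g (default
#'   0.015-0.06, the candidate band).
#' @param artifact_amp_range artifact peak amplitude range in g (default
#'   0.1-0.3).
#' @param artifact_rate_per_min expected artifacts per minute (default 0.3).
#' @param breathing_amp breathing sinusoid amplitude in g (default 0.01,
#'   below the 0.015 g candidate bound).
#' @param breathing_freq breathing frequency in Hz (default 0.3).
#' @param background_amp_range amplitude band of "other background noise"
#'   segments used for non-FM training windows, in g (default 0.06-0.1).
#' @param noise_sigma white sensor-noise standard deviation in g
#'   (default 0.003).
#' @param dc_offset_range per-channel constant offset range in g
#'   (default -0.05 to 0.05).
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 3600, sample_rate = 100,
                         fm_rate_per_min = 0.15,
                         fm_amp_range = c(0.015, 0.06),
                         artifact_amp_range = c(0.1, 0.3),
                         artifact_rate_per_min = 0.3,
                         breathing_amp = 0.01, breathing_freq = 0.3,
                         background_amp_range = c(0.06, 0.1),
                         noise_sigma = 0.003,
                         dc_offset_range = c(-0.05, 0.05),
                         seed = 1L) {
  window_seconds <- 2.56
  if (duration_s < window_seconds)
    stop("duration_s must cover at least one ", window_seconds, " s window")
  th <- gate_thresholds()
  if (fm_amp_range[1] < th$a1 - 1e-12 || fm_amp_range[2] > th$a2 + 1e-12)
    stop("fm_amp_range must lie within the candidate band (A1, A2)")
  if (artifact_amp_range[1] < th$a3 - 1e-12)
    stop("artifact_amp_range must start at or above A3")
  if (breathing_amp > th$a1)
    stop("breathing_amp must stay below A1")
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 fm_rate_per_min = fm_rate_per_min,
                 fm_amp_range = fm_amp_range,
                 artifact_amp_range = artifact_amp_range,
                 artifact_rate_per_min = artifact_rate_per_min,
                 breathing_amp = breathing_amp,
                 breathing_freq = breathing_freq,
                 background_amp_range = background_amp_range,
                 noise_sigma = noise_sigma,
                 dc_offset_range = dc_offset_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw one synthetic fetal-movement burst
#'
#' A fetal movement presents at the abdominal wall as a single- or
#' double-crested transient spanning one 2.56 s analysis window. The burst
#' is modelled as one or two (equal probability) Gaussian-windowed
#' oscillation packets with a common 2-10 Hz carrier, scaled so the peak
#' absolute amplitude equals a draw from `fm_amp_range` and therefore lies
#' strictly inside the (A1, A2) candidate band.
#'
#' @param cfg [synth_config()] object.
#' @param seed optional seed; if `NULL` the burst is drawn from the current
#'   RNG stream (as [make_recording()] does internally).
#' @param center_s optional crest-centre position in seconds within the
#'   2.56 s support (default: drawn near the middle). Training-corpus
#'   construction varies this across the window so learned atoms cover
#'   every position the tiling grid can cut an event at.
#' @return list with `samples` (length `round(2.56 * sample_rate)`), `peak`
#'   (g), `crests` (1 or 2), `freq_hz`, `center_s`.
#' @export
make_fm_burst <- function(cfg = synth_config(), seed = NULL, center_s = NULL) {
  with_seed(seed, {
    fs <- cfg$sample_rate
    n <- as.integer(round(2.56 * fs))
    t <- (seq_len(n) - 1L) / fs
    crests <- 1L + stats::rbinom(1L, 1L, 0.5)
    f <- stats::runif(1L, 2, 10)
    # envelope width tied to the carrier period so every crest is a
    # coherent multi-cycle packet (a kick rings at its characteristic
    # frequency) and stays temporally localized
    sigma <- stats::runif(1L, 0.6, 1.2) / f
    if (is.null(center_s)) center_s <- 1.28 + stats::runif(1L, -0.35, 0.35)
    centers <- if (crests == 1L) {
      center_s
    } else {
      sep <- stats::runif(1L, 0.5, 0.9)
      center_s + c(-sep, sep) / 2
    }
    centers <- pmin(pmax(centers, 0.05), 2.51)
    wave <- numeric(n)
    for (ci in centers) {
      phi <- stats::runif(1L, 0, 2 * pi)
      wave <- wave + exp(-(t - ci)^2 / (2 * sigma^2)) * sin(2 * pi * f * (t - ci) + phi)
    }
    peak <- stats::runif(1L, cfg$fm_amp_range[1], cfg$fm_amp_range[2])
    wave <- wave * (peak / max(abs(wave)))
    list(samples = wave, peak = peak, crests = crests, freq_hz = f)
  })
}

# maternal body-movement artifact: a longer, larger transient mixing a
# low-frequency sway with incoherent broadband rumble (posture shifts are
# impulsive wideband events, unlike the coherent narrowband ring of a
# fetal kick)
make_artifact <- function(cfg) {
  fs <- cfg$sample_rate
  dur <- stats::runif(1L, 1, 2)
  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1L) / fs
  f <- stats::runif(1L, 0.5, 1.5)
  env <- exp(-(t - dur / 2)^2 / (2 * (dur / 4)^2))
  sm <- as.numeric(stats::filter(stats::rnorm(n), rep(1 / 4, 4), sides = 2L))
  lo <- as.numeric(stats::filter(sm, rep(1 / 16, 16), sides = 2L))
  rumble <- sm - lo
  rumble[is.na(rumble)] <- 0
  rumble <- rumble / max(stats::sd(rumble), 1e-12)
  # rumble concentrated at the movement's peak (env^2): onsets and offsets
  # are smooth sway ramps, as in a real posture shift
  wave <- env * sin(2 * pi * f * t + stats::runif(1L, 0, 2 * pi)) +
    0.8 * env^2 * rumble
  peak <- stats::runif(1L, cfg$artifact_amp_range[1], cfg$artifact_amp_range[2])
  list(samples = wave * (peak / max(abs(wave))), peak = peak, duration_s = dur)
}

# draw non-overlapping event start times; redraw on collision, skip after 100
place_events <- function(n_events, len_s, dur_s, occupied) {
  starts <- numeric(0)
  for (i in seq_len(n_events)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      s <- stats::runif(1L, 0, dur_s - len_s)
      if (nrow(occupied) == 0L ||
          !any(intervals_overlap(s, s + len_s, occupied$start, occupied$end))) {
        ok <- TRUE
        break
      }
    }
    if (ok) {
      starts <- c(starts, s)
      occupied <- rbind(occupied, data.frame(start = s, end = s + len_s))
    }
  }
  list(starts = starts, occupied = occupied)
}

#' Generate a synthetic dual-accelerometer recording
#'
#' Builds six channels as per-channel DC offset + white sensor noise +
#' common-phase breathing sinusoid (per-channel gain), injects
#' Poisson-placed FM bursts (each on a dominant axis at full amplitude and
#' on each other axis independently with probability 1/2 at attenuation
#' 0.3-0.9), and occasional whole-body artifacts on all six axes
#' simultaneously. Every injected FM event is annotated as a ground-truth
#' interval; artifacts are recorded in the `artifact_intervals` attribute
#' (not as FM). Overlapping placements are redrawn up to 100 times, then
#' skipped. A fixed seed yields a bit-identical recording.
#'
#' @param cfg [synth_config()] object.
#' @return [fm_recording()] with annotations; attribute
#'   `artifact_intervals` holds the injected artifact intervals.
#' @export
make_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    n <- as.integer(round(cfg$duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    wlen_s <- 2.56

    ch <- matrix(stats::rnorm(n * 6L, 0, cfg$noise_sigma), n, 6L)
    dc <- stats::runif(6L, cfg$dc_offset_range[1], cfg$dc_offset_range[2])
    ph <- stats::runif(1L, 0, 2 * pi)
    bg <- stats::runif(6L, 0.5, 1)
    breath <- sin(2 * pi * cfg$breathing_freq * t + ph)
    for (a in seq_len(6L))
      ch[, a] <- ch[, a] + dc[a] + cfg$breathing_amp * bg[a] * breath

    occupied <- data.frame(start = numeric(0), end = numeric(0))
    mins <- cfg$duration_s / 60

    n_art <- stats::rpois(1L, cfg$artifact_rate_per_min * mins)
    art_iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (i in seq_len(n_art)) {
      art <- make_artifact(cfg)
      len_s <- length(art$samples) / fs
      pl <- place_events(1L, len_s, cfg$duration_s, occupied)
      occupied <- pl$occupied
      if (length(pl$starts) == 0L) next
      i0 <- as.integer(round(pl$starts * fs)) + 1L
      idx <- i0:(i0 + length(art$samples) - 1L)
      for (a in seq_len(6L)) ch[idx, a] <- ch[idx, a] + art$samples
      art_iv <- rbind(art_iv,
                      data.frame(start_s = pl$starts, end_s = pl$starts + len_s))
    }

    n_fm <- stats::rpois(1L, cfg$fm_rate_per_min * mins)
    ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0))
    for (i in seq_len(n_fm)) {
      burst <- make_fm_burst(cfg)
      len_s <- length(burst$samples) / fs
      pl <- place_events(1L, len_s, cfg$duration_s, occupied)
      occupied <- pl$occupied
      if (length(pl$starts) == 0L) next
      i0 <- as.integer(round(pl$starts * fs)) + 1L
      idx <- i0:(i0 + length(burst$samples) - 1L)
      dominant <- sample.int(6L, 1L)
      gains <- ifelse(stats::runif(6L) < 0.5, stats::runif(6L, 0.3, 0.9), 0)
      gains[dominant] <- 1
      for (a in seq_len(6L))
        if (gains[a] > 0) ch[idx, a] <- ch[idx, a] + gains[a] * burst$samples
      ann <- rbind(ann, data.frame(start_s = pl$starts,
                                   end_s = pl$starts + len_s,
                                   label = "FM_perceived"))
    }
    ann <- ann[order(ann$start_s), , drop = FALSE]
    rownames(ann) <- NULL

    rec <- fm_recording(ch, sample_rate = fs, annotations = ann)
    attr(rec, "artifact_intervals") <- art_iv
    rec
  })
}

# one training window of breathing + sensor noise (+ optional extra signal),
# rescaled so the composite peak equals `peak`; bg_gain attenuates the
# breathing/noise background relative to its nominal level. The background
# variance at the final scale is attached so the window can be Kalman-
# preprocessed exactly as the detection path would.
compose_window <- function(cfg, extra = 0, peak, bg_gain = 1) {
  fs <- cfg$sample_rate
  n <- as.integer(round(2.56 * fs))
  t <- (seq_len(n) - 1L) / fs
  bg <- bg_gain * (stats::rnorm(n, 0, cfg$noise_sigma) +
    cfg$breathing_amp * stats::runif(1L, 0.5, 1) *
      sin(2 * pi * cfg$breathing_freq * t + stats::runif(1L, 0, 2 * pi)))
  w <- bg + extra
  w <- w - mean(w)
  s <- peak / max(abs(w))
  structure(w * s, bg = bg * s)
}

# background + extra signal at natural (unscaled) amplitude
compose_window_raw <- function(cfg, extra = 0) {
  fs <- cfg$sample_rate
  n <- as.integer(round(2.56 * fs))
  t <- (seq_len(n) - 1L) / fs
  bg <- stats::rnorm(n, 0, cfg$noise_sigma) +
    cfg$breathing_amp * stats::runif(1L, 0.5, 1) *
      sin(2 * pi * cfg$breathing_freq * t + stats::runif(1L, 0, 2 * pi))
  w <- bg + extra
  w - mean(w)
}

# slow baseline wander (body sway / posture drift): AR(1) colored noise,
# spectrum concentrated below ~2 Hz
make_wander <- function(n) {
  as.numeric(stats::filter(stats::rnorm(n), 0.95, method = "recursive"))
}

#' Build FM and non-FM training sets
#'
#' The FM set contains windows holding a synthetic burst (crest position
#' varied across the window, as the tiling grid cuts events at arbitrary
#' offsets) over an attenuated breathing + noise background (high-SNR training exemplars, so
#' the learned atoms capture burst morphology rather than the background
#' shared with the non-FM class), composite peak rescaled to a draw from
#' the (A1, A2) candidate band. The non-FM set mixes, in equal parts, the two
#' regimes the gate can pass to the fuser but the detector must reject or
#' that surround candidates: sub-candidate breathing/noise windows (peak
#' below A1) and "other background noise" windows (slow baseline wander,
#' peak inside (A2, A3)). Every window is preprocessed the way the
#' detection path preprocesses it (mean removal + Kalman smoothing at
#' `kalman_q`, with the measurement-noise variance taken from the window's
#' own background level) and then scaled to unit l2 norm (the dictionary
#' convention); peaks quoted above refer to the pre-normalization
#' composite.
#'
#' @param cfg [synth_config()] object (`cfg$seed` drives all draws).
#' @param n_per_class number of windows per class (complete-dictionary
#'   training needs at least the atom count, 256 by default).
#' @param kalman_q Kalman process-noise variance used for the
#'   training-window preprocessing (default 5e-5, the pipeline default).
#' @param kalman_q_classify process-noise variance of the heavier
#'   classifier-stage smoothing pass (default 1e-7, the pipeline default).
#' @return list with elements `fm` and `nonfm`, each an `fm_training_set`:
#'   list with `Y` (`256 x n_per_class` matrix), `class_label`, and
#'   `peaks` (pre-normalization composite peaks).
#' @export
make_training_sets <- function(cfg = synth_config(), n_per_class = 1000L,
                               kalman_q = 5e-5, kalman_q_classify = 1e-7) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    n <- as.integer(round(2.56 * fs))
    th <- gate_thresholds()
    # identical preprocessing to the detection path: baseline detrend +
    # gate-stage Kalman + heavier classifier-stage Kalman. R is the nominal
    # detrended background variance (sensor-noise floor), the same quantity
    # the pipeline estimates from a recording's first window — training
    # exemplars must be smoothed exactly as candidates will be.
    prep <- function(w) {
      R <- max(cfg$noise_sigma^2, 1e-12)
      x <- kalman_filter(detrend_poly(as.numeric(w)), kalman_params(Q = kalman_q, R = R))
      x <- kalman_filter(as.numeric(x), kalman_params(Q = kalman_q_classify, R = R))
      normalize_window(as.numeric(x))
    }

    fm_peaks <- numeric(n_per_class)
    Yfm <- matrix(0, n, n_per_class)
    for (l in seq_len(n_per_class)) {
      # crest position varied across the whole window, edges included:
      # the tiling grid cuts events at arbitrary offsets, so atoms must
      # cover every position a crest (or its truncated half) can occupy
      burst <- make_fm_burst(cfg, center_s = stats::runif(1L, 0.05, 2.51))
      # high-SNR training exemplars: the burst dominates an attenuated
      # background, so the learned atoms capture burst morphology rather
      # than the breathing/noise floor shared with the non-FM class
      w <- compose_window(cfg, extra = burst$samples, peak = burst$peak,
                          bg_gain = stats::runif(1L, 0.15, 0.5))
      fm_peaks[l] <- burst$peak
      Yfm[, l] <- prep(w)
    }

    nf_peaks <- numeric(n_per_class)
    Ynf <- matrix(0, n, n_per_class)
    for (l in seq_len(n_per_class)) {
      reg <- c("remnant", "sub", "remnant", "wander",
               "remnant", "sub", "remnant", "remnant")[l %% 8L + 1L]
      if (reg == "wander") {
        # background-noise regime: slow wander with peak in (A2, A3)
        extra <- make_wander(n)
        peak <- stats::runif(1L, cfg$background_amp_range[1] + 5e-4,
                             cfg$background_amp_range[2] - 5e-4)
        extra <- extra * (peak / max(abs(extra)))
      } else if (reg == "remnant") {
        # maternal-artifact remnant: a grid-cut window overlapping an
        # artifact's edge at its natural amplitude -- exactly the windows
        # the per-window veto cannot catch (their own peak stays below A3)
        # but the gate can pass to the detector, which must reject them
        w <- NULL
        for (try in seq_len(50L)) {
          art <- make_artifact(cfg)$samples
          pad <- c(numeric(n), art, numeric(n))
          o <- sample.int(length(pad) - n, 1L)
          cand <- compose_window_raw(cfg, extra = pad[o:(o + n - 1L)])
          p <- max(abs(detrend_poly(cand)))
          if (p > th$a1 && p < th$a3) { w <- cand; peak <- p; break }
        }
        if (is.null(w)) { w <- compose_window(cfg, extra = 0, peak = 0.01); peak <- 0.01 }
        nf_peaks[l] <- peak
        Ynf[, l] <- prep(w)
        next
      } else {
        # sub-candidate regime, peak below A1
        extra <- 0
        peak <- stats::runif(1L, 0.004, th$a1 - 5e-4)
      }
      w <- compose_window(cfg, extra = extra, peak = peak)
      nf_peaks[l] <- peak
      Ynf[, l] <- prep(w)
    }

    list(fm = structure(list(Y = Yfm, class_label = "FM", peaks = fm_peaks),
                        class = "fm_training_set"),
         nonfm = structure(list(Y = Ynf, class_label = "NON_FM",
                                peaks = nf_peaks),
                           class = "fm_training_set"))
  })
}

#' @export
print.fm_training_set <- function(x, ...) {
  cat(sprintf("fm_training_set (%s): %d x %d window matrix\n",
              x$class_label, nrow(x$Y), ncol(x$Y)))
  invisible(x)
}
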