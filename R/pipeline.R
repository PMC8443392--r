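#' Detection pipeline configuration
#'
#' Collects the knobs of the full detection flow: windowing, gate
#' thresholds, Kalman preprocessing, detector choice and parameters.
#'
#' @param window_seconds analysis window length (default 2.56 s).
#' @param sample_rate samples/second (default 100).
#' @param gate [gate_thresholds()] object.
#' @param kalman_q Kalman process-noise variance in g^2 of the gate-stage
#'   smoothing (default 5e-5; light, to preserve the amplitude calibration
#'   the thresholds assume).
#' @param kalman_q_classify process-noise variance of the additional,
#'   heavier smoothing pass applied to candidate windows before
#'   classification (default 1e-7); the matched-filter comparison is
#'   shape-based, so stronger denoising sharpens the class margin without
#'   affecting the gate.
#' @param kalman_r optional fixed measurement-noise variance; if `NULL`,
#'   estimated per axis from the recording's first window.
#' @param dc_method DC/baseline correction before Kalman smoothing:
#'   `"detrend"` (default; per-window polynomial baseline removal, cancels
#'   DC and the breathing trend while preserving transient amplitudes),
#'   `"demean"` (mean only) or `"diff"` (first differences).
#' @param method detector: `"omp"` (dual-dictionary OMP residual, default)
#'   or `"lms"` (adaptive-filter matching).
#' @param omp_t0 OMP sparsity (default 3, the operating optimum).
#' @param lms [lms_params()] object for the LMS detector.
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_seconds = 2.56, sample_rate = 100,
                            gate = gate_thresholds(),
                            kalman_q = 5e-5, kalman_q_classify = 1e-7,
                            kalman_r = NULL,
                            dc_method = c("detrend", "demean", "diff"),
                            method = c("omp", "lms"),
                            omp_t0 = 3L, lms = lms_params(), seed = 1L) {
  structure(list(window_seconds = window_seconds, sample_rate = sample_rate,
                 gate = gate, kalman_q = kalman_q,
                 kalman_q_classify = kalman_q_classify, kalman_r = kalman_r,
                 dc_method = match.arg(dc_method), method = match.arg(method),
                 omp_t0 = as.integer(omp_t0), lms = lms,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train the FM / non-FM dictionary pair
#'
#' Convenience wrapper: draws seeded training sets with
#' [make_training_sets()] and fits a complete K-SVD dictionary per class.
#'
#' @param cfg [synth_config()] describing the training corpus.
#' @param n_per_class training windows per class (default 1000).
#' @param n_atoms atoms per dictionary (default 256, complete).
#' @param T0 training sparsity (default 3).
#' @param n_iter K-SVD iterations (default 30, with early stop).
#' @param seed initialization seed (default: `cfg$seed`).
#' @return list with fitted [ksvd()] objects `D1` (FM) and `D2` (non-FM).
#' @export
train_dictionaries <- function(cfg = synth_config(), n_per_class = 1000L,
                               n_atoms = 256L, T0 = 3L, n_iter = 30L,
                               seed = cfg$seed) {
  ts <- make_training_sets(cfg, n_per_class)
  list(D1 = ksvd(ts$fm, n_atoms = n_atoms, T0 = T0, n_iter = n_iter, seed = seed),
       D2 = ksvd(ts$nonfm, n_atoms = n_atoms, T0 = T0, n_iter = n_iter, seed = seed))
}

#' Run the full FM detection flow over a recording
#'
#' Stages, in fixed order per window: segmentation into non-overlapping
#' windows, DC correction + Kalman smoothing, amplitude gating (an artifact
#' veto short-circuits classification for the whole window), per-axis
#' dual-dictionary classification of candidate axes, and six-axis mask
#' fusion. If the recording carries annotations, event-level TDR/PPV
#' metrics are computed against them.
#'
#' @param rec [fm_recording()] object.
#' @param cfg [pipeline_config()] object.
#' @param D1 FM feature dictionary ([ksvd()] object or matrix).
#' @param D2 non-FM feature dictionary.
#' @param verbose emit a per-recording summary message (default `FALSE`).
#' @return an object of class `fm_detection`: list with `decisions` (data
#'   frame: `window_index` 0-based, `start_s`, `gate_flag`, `mask_bits`,
#'   `fused_label`, `n_candidates`), `events` (detected intervals),
#'   `metrics` (`fm_metrics` or `NULL`), `axis_errors` (per-window list of
#'   candidate-axis decisions), `n_windows`, `config`.
#' @export
run_detection <- function(rec, cfg = pipeline_config(), D1, D2,
                          verbose = FALSE) {
  stopifnot(inherits(rec, "fm_recording"), inherits(cfg, "pipeline_config"))
  seg <- segment_windows(rec, cfg$window_seconds)
  m1 <- nrow(dict_matrix(D1))
  if (m1 != seg$window_samples || nrow(dict_matrix(D2)) != seg$window_samples)
    stop("configuration error: dictionary atom length (", m1,
         ") does not match the window length (", seg$window_samples, ")")
  pre <- preprocess_windows(seg, Q = cfg$kalman_q, R = cfg$kalman_r,
                            dc_method = cfg$dc_method)
  K <- pre$n_windows
  gate_flag <- character(K)
  fused <- character(K)
  mask_bits <- character(K)
  n_cand <- integer(K)
  axis_errors <- vector("list", K)
  for (k in seq_len(K)) {
    peaks <- vapply(seq_len(6L), function(a) peak_amplitude(pre$windows[, k, a]),
                    numeric(1))
    g <- gate_window(peaks, cfg$gate, window_index = k - 1L)
    decs <- vector("list", 6L)
    if (g$window_flag == "PASS") {
      for (a in which(g$per_axis == "CANDIDATE")) {
        # heavier classifier-stage denoising of the candidate window
        w <- as.numeric(kalman_filter(
          pre$windows[, k, a],
          kalman_params(Q = cfg$kalman_q_classify, R = pre$kalman_R[a])))
        decs[[a]] <- if (cfg$method == "omp")
          omp_classify(w, D1, D2, T0 = cfg$omp_t0, axis_index = a - 1L)
        else
          lms_classify(w, D1, D2, p = cfg$lms, axis_index = a - 1L)
      }
    }
    wd <- fuse_masks(decs, g)
    gate_flag[k] <- wd$gate_flag
    fused[k] <- wd$fused_label
    mask_bits[k] <- paste(wd$mask, collapse = "")
    n_cand[k] <- sum(g$per_axis == "CANDIDATE")
    axis_errors[[k]] <- Filter(Negate(is.null), decs)
  }
  decisions <- data.frame(window_index = seq_len(K) - 1L,
                          start_s = pre$start_s, gate_flag = gate_flag,
                          mask_bits = mask_bits, fused_label = fused,
                          n_candidates = n_cand,
                          stringsAsFactors = FALSE)
  events <- decisions_to_events(decisions, cfg$window_seconds)
  metrics <- NULL
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0L)
    metrics <- compute_metrics(events, rec$annotations)
  if (verbose)
    message(sprintf(
      "run_detection [%s]: %d windows (%d artifact, %d candidate-bearing), %d event(s) detected",
      toupper(cfg$method), K, sum(gate_flag == "ARTIFACT"),
      sum(n_cand > 0L), nrow(events)))
  structure(list(decisions = decisions, events = events, metrics = metrics,
                 axis_errors = axis_errors, n_windows = K, config = cfg),
            class = "fm_detection")
}

#' @export
print.fm_detection <- function(x, ...) {
  cat(sprintf("fm_detection [%s]: %d windows, %d detected FM event(s)\n",
              toupper(x$config$method), x$n_windows, nrow(x$events)))
  cat(sprintf("  gate: %d ARTIFACT window(s), %d window(s) with candidates\n",
              sum(x$decisions$gate_flag == "ARTIFACT"),
              sum(x$decisions$n_candidates > 0L)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @export
summary.fm_detection <- function(object, ...) {
  d <- object$decisions
  cat(sprintf("Windows: %d; FM-labelled: %d; artifact-vetoed: %d\n",
              nrow(d), sum(d$fused_label == "FM"),
              sum(d$gate_flag == "ARTIFACT")))
  cat(sprintf("Detected events: %d\n", nrow(object$events)))
  if (!is.null(object$metrics)) print(object$metrics)
  invisible(object)
}

#' Sparsity sweep of the OMP detector
#'
#' Re-runs [run_detection()] with the OMP detector at each sparsity in
#' `t0_values` over an annotated recording and tabulates the event-level
#' metrics, reproducing the TDR/PPV-versus-sparsity experiment.
#'
#' @param rec annotated [fm_recording()].
#' @param cfg [pipeline_config()] (its `method` is forced to `"omp"`).
#' @param D1,D2 feature dictionaries.
#' @param t0_values integer vector of sparsities to evaluate (non-empty).
#' @return data frame with columns `T0, TMF, DME, FD, TDR, PPV`.
#' @export
sweep_sparsity <- function(rec, cfg = pipeline_config(), D1, D2, t0_values) {
  if (length(t0_values) == 0L)
    stop("parameter error: t0_values must be non-empty")
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0L)
    stop("sweep requires an annotated recording")
  rows <- lapply(t0_values, function(t0) {
    cfg$method <- "omp"
    cfg$omp_t0 <- as.integer(t0)
    m <- run_detection(rec, cfg, D1, D2)$metrics
    data.frame(T0 = as.integer(t0), TMF = m$TMF, DME = m$DME, FD = m$FD,
               TDR = m$TDR, PPV = m$PPV)
  })
  do.call(rbind, rows)
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Documented keys:
#' `window_seconds`, `sample_rate`, `gate.a1_g`, `gate.a2_g`, `gate.a3_g`,
#' `kalman.q`, `kalman.r`, `preproc.dc`, `detector.method`, `omp.t0`,
#' `lms.order`, `lms.mu`, `lms.max_epochs`, `lms.tol`, `seed`.
#'
#' @param path config file path.
#' @return named list of values (read); `path` invisibly (write).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' @rdname read_config
#' @param config named list as returned by `read_config`.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k)
    paste(k, "=", format(config[[k]], scientific = FALSE)), character(1)), path)
  invisible(path)
}

#' Build a [pipeline_config()] from a flat key-value list
#'
#' Unknown keys are ignored; missing keys keep their defaults.
#'
#' @param kv named list, e.g. from [read_config()].
#' @return [pipeline_config()] object.
#' @export
config_from_keys <- function(kv) {
  g <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  pipeline_config(
    window_seconds = g("window_seconds", 2.56),
    sample_rate = g("sample_rate", 100),
    gate = gate_thresholds(g("gate.a1_g", 0.015), g("gate.a2_g", 0.06),
                           g("gate.a3_g", 0.1)),
    kalman_q = g("kalman.q", 5e-5),
    kalman_r = kv[["kalman.r"]],
    dc_method = g("preproc.dc", "detrend"),
    method = g("detector.method", "omp"),
    omp_t0 = g("omp.t0", 3L),
    lms = lms_params(M = g("lms.order", 8L), mu = g("lms.mu", 0.05),
                     max_epochs = g("lms.max_epochs", 100L),
                     tol = g("lms.tol", 1e-8)),
    seed = g("seed", 1L))
}
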