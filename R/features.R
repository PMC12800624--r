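#' Frame and analysis settings for feature extraction
#'
#' @param frame_length_samples Analysis frame length (samples).
#' @param hop_fraction Hop as a fraction of the frame length.
#' @param f0_search_hz Two-element search interval for the fundamental (Hz).
#' @param voicing_threshold Normalised-autocorrelation peak required to call
#'   a frame voiced, in `(0, 1)`.
#' @param lpc_order Linear-prediction order for formant estimation; default
#'   `effective_rate / 1000 + 8`, resolved per waveform after decimation to
#'   the formant band (a strongly harmonic source needs several poles beyond
#'   the classical speech rule of thumb before root bandwidths tighten).
#' @param max_formant_bandwidth_hz Roots broader than this are not counted
#'   as formants.
#' @param max_formant_hz Formant search ceiling; signals sampled well above
#'   `2 * max_formant_hz` are decimated to that band before linear
#'   prediction so the model order is spent where the formants are.
#' @return A `frame_settings` list.
#' @export
frame_settings <- function(frame_length_samples = 1024,
                           hop_fraction = 0.5,
                           f0_search_hz = c(40, 1200),
                           voicing_threshold = 0.45,
                           lpc_order = NULL,
                           max_formant_bandwidth_hz = 400,
                           max_formant_hz = 5000) {
  stopifnot(frame_length_samples >= 64, hop_fraction > 0, hop_fraction <= 1,
            length(f0_search_hz) == 2, f0_search_hz[1] > 0,
            f0_search_hz[2] > f0_search_hz[1],
            voicing_threshold > 0, voicing_threshold < 1)
  structure(list(frame_length_samples = as.integer(frame_length_samples),
                 hop_fraction = hop_fraction,
                 f0_search_hz = f0_search_hz,
                 voicing_threshold = voicing_threshold,
                 lpc_order = lpc_order,
                 max_formant_bandwidth_hz = max_formant_bandwidth_hz,
                 max_formant_hz = max_formant_hz),
            class = "frame_settings")
}

settings_hash <- function(s) {
  paste(vapply(s, function(v) paste(format(v, digits = 10), collapse = ","),
               character(1)), collapse = ";")
}

# Split a signal into windowed frames (columns). Signals shorter than one
# frame are zero-padded (the stated padding policy).
frame_signal <- function(x, frame, hop) {
  if (length(x) < frame) x <- c(x, numeric(frame - length(x)))
  starts <- seq(1, length(x) - frame + 1, by = hop)
  sapply(starts, function(i) x[i:(i + frame - 1)])
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Track the fundamental frequency
#'
#' Per frame, f0 is the inverse of the lag maximising the normalised
#' autocorrelation within the search band (with parabolic refinement of the
#' peak). A frame is voiced iff that peak reaches `voicing_threshold`.
#'
#' @param w A [waveform].
#' @param s A [frame_settings].
#' @return Data frame with one row per frame: `time_s`, `f0_hz`, `voiced`,
#'   `peak` (normalised autocorrelation at the chosen lag).
#' @export
track_f0 <- function(w, s = frame_settings()) {
  sr <- w$sample_rate_hz
  if (s$f0_search_hz[2] >= sr / 2)
    stop_invalid("f0 search interval must lie below Nyquist")
  frame <- s$frame_length_samples
  hop <- max(1L, round(frame * s$hop_fraction))
  fr <- frame_signal(w$samples, frame, hop)
  win <- hann_window(frame)
  lag_min <- max(2L, floor(sr / s$f0_search_hz[2]))
  lag_max <- min(frame - 2L, ceiling(sr / s$f0_search_hz[1]))
  nfft <- 2 ^ ceiling(log2(2 * frame))
  res <- apply(fr, 2, function(x) {
    x <- (x - mean(x)) * win
    sp <- fft(c(x, numeric(nfft - frame)))
    ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[1:frame] / nfft
    if (ac[1] <= 0) return(c(NA_real_, 0))
    r <- ac / ac[1]
    band <- r[(lag_min + 1):(lag_max + 1)]
    i <- which.max(band)
    lag <- lag_min + i - 1L
    peak <- band[i]
    # parabolic interpolation around the integer-lag peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- r[lag]; y2 <- r[lag + 1]; y3 <- r[lag + 2]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    c(sr / lag, peak)
  })
  n_frames <- ncol(fr)
  starts <- seq(1, by = hop, length.out = n_frames)
  out <- data.frame(
    time_s = (starts - 1 + frame / 2) / sr,
    f0_hz = res[1, ],
    peak = res[2, ]
  )
  out$voiced <- !is.na(out$f0_hz) & out$peak >= s$voicing_threshold
  out$f0_hz[!out$voiced] <- NA_real_
  out
}

#' Estimate formant frequencies by linear prediction
#'
#' For each voiced frame, linear-prediction coefficients of order
#' `lpc_order` are fitted by the autocorrelation (Yule-Walker) method after
#' pre-emphasis; complex roots with bandwidth below
#' `max_formant_bandwidth_hz` are converted to frequencies and the lowest
#' four ascending are taken as F1-F4. Frames yielding fewer than four
#' admissible roots are skipped.
#'
#' @param w A [waveform].
#' @param s A [frame_settings].
#' @return List with `per_frame` (matrix, frames x F1..F4, skipped frames
#'   `NA`), `medians` (length-4 vector) and `admissible_frac`, the fraction
#'   of voiced frames that yielded four formants (a low value flags an
#'   unreliable, e.g. unfiltered or tonal, input).
#' @export
estimate_formants <- function(w, s = frame_settings()) {
  sr <- w$sample_rate_hz
  f0t <- track_f0(w, s)
  x <- w$samples
  # decimate to ~2 x max_formant so the LPC order is spent on the band of
  # interest (moving-average anti-alias filter, then subsample)
  q <- max(1L, floor(sr / (2 * (s$max_formant_hz %||% 5000))))
  if (q > 1L) {
    x <- as.numeric(stats::filter(x, rep(1 / q, q), sides = 2))
    x[is.na(x)] <- 0
    x <- x[seq(1, length(x), by = q)]
    sr <- sr / q
  }
  frame <- max(64L, round(s$frame_length_samples / q))
  hop <- max(1L, round(frame * s$hop_fraction))
  p <- s$lpc_order %||% (round(sr / 1000) + 8)
  # pre-emphasis: y_t = x_t - 0.97 x_{t-1}
  x <- x - 0.97 * c(0, x[-length(x)])
  fr <- frame_signal(x, frame, hop)
  win <- hann_window(frame)
  nyq <- sr / 2
  per_frame <- matrix(NA_real_, nrow = ncol(fr), ncol = 4,
                      dimnames = list(NULL, paste0("F", 1:4)))
  voiced_idx <- which(f0t$voiced[seq_len(ncol(fr))])
  for (i in voiced_idx) {
    xf <- fr[, i] * win
    if (sd(xf) < 1e-10) next
    fit <- tryCatch(
      stats::ar(xf, aic = FALSE, order.max = p, method = "yule-walker",
                demean = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) < 1) next
    roots <- polyroot(c(1, -fit$ar))      # roots in z^{-1}
    z <- 1 / roots
    freq <- abs(Arg(z)) * sr / (2 * pi)
    bw <- -(sr / pi) * log(pmin(Mod(z), 1 - 1e-12))
    keep <- Im(z) > 0 & freq > 90 & freq < nyq - 50 &
      bw < s$max_formant_bandwidth_hz
    ff <- sort(freq[keep])
    # merge near-coincident poles (< 200 Hz apart): a single spectral line
    # fitted by several narrow roots is one candidate, not several formants
    if (length(ff) > 1) {
      grp <- cumsum(c(1, diff(ff) >= 200))
      ff <- as.numeric(tapply(ff, grp, mean))
    }
    if (length(ff) >= 4) per_frame[i, ] <- ff[1:4]
  }
  ok <- stats::complete.cases(per_frame)
  medians <- if (any(ok)) apply(per_frame[ok, , drop = FALSE], 2, median)
             else rep(NA_real_, 4)
  names(medians) <- paste0("F", 1:4)
  list(per_frame = per_frame, medians = medians,
       admissible_frac = if (length(voiced_idx)) sum(ok) / length(voiced_idx) else 0)
}

spectral_moments <- function(freqs, power) {
  p <- power / sum(power)
  mu <- sum(freqs * p)
  v <- sum((freqs - mu)^2 * p)
  sdv <- sqrt(v)
  skew <- if (sdv > 0) sum((freqs - mu)^3 * p) / sdv^3 else 0
  kurt <- if (sdv > 0) sum((freqs - mu)^4 * p) / sdv^4 else 0
  cdf <- cumsum(p)
  qf <- function(q) {
    i <- which(cdf >= q)[1]
    if (i == 1) return(freqs[1])
    # linear interpolation on the cumulative power
    f0 <- freqs[i - 1]; f1 <- freqs[i]
    c0 <- cdf[i - 1]; c1 <- cdf[i]
    f0 + (q - c0) / (c1 - c0) * (f1 - f0)
  }
  ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  flat <- exp(mean(log(p + 1e-300))) / mean(p)
  list(centroid = mu, sd = sdv, skew = skew, kurt = kurt,
       q25 = qf(0.25), q50 = qf(0.5), q75 = qf(0.75),
       entropy = ent, flatness = flat)
}

#' Extract the acoustic feature panel for one call
#'
#' Computes a ~32-feature panel covering the temporal, intensity, source
#' (f0) and filter (formant) families: duration; per-frame RMS level
#' statistics (dB re full scale); spectral moments, quantiles, entropy and
#' flatness of the Welch average periodogram; dominant-frequency statistics;
#' f0 statistics, slope and voiced fraction; and median F1-F4 with formant
#' dispersion.
#'
#' @param w A [waveform].
#' @param s A [frame_settings].
#' @return One-row data frame (a feature vector) with identifying columns
#'   `call_id`, `caller_id`, `context` followed by the named features.
#' @export
extract_features <- function(w, s = frame_settings()) {
  sr <- w$sample_rate_hz
  frame <- s$frame_length_samples
  hop <- max(1L, round(frame * s$hop_fraction))
  x <- w$samples
  fr <- frame_signal(x, frame, hop)
  win <- hann_window(frame)
  nfft <- frame
  nb <- nfft %/% 2 + 1
  freqs <- (seq_len(nb) - 1) * sr / nfft

  # per-frame RMS in dB re full scale
  rms <- sqrt(colMeans(fr^2))
  rms_db <- 20 * log10(rms + 1e-12)

  # Welch average periodogram + per-frame dominant frequency
  spec <- apply(fr, 2, function(col) {
    X <- fft(col * win)
    (Mod(X[1:nb])^2) / sum(win^2)
  })
  spec <- matrix(spec, nrow = nb)
  avg <- rowMeans(spec)
  mom <- spectral_moments(freqs, avg)
  dom <- freqs[apply(spec[-1, , drop = FALSE], 2, which.max) + 1L]

  f0t <- track_f0(w, s)
  v <- f0t$f0_hz[f0t$voiced]
  if (length(v) > 0) {
    f0_stats <- c(mean(v), median(v), if (length(v) > 1) sd(v) else 0,
                  min(v), max(v), max(v) - min(v))
    f0_slope <- if (sum(f0t$voiced) >= 3) {
      unname(coef(lm(f0_hz ~ time_s, data = f0t[f0t$voiced, ]))[2])
    } else NA_real_
  } else {
    f0_stats <- rep(NA_real_, 6)
    f0_slope <- NA_real_
  }

  fm <- estimate_formants(w, s)

  out <- data.frame(
    call_id = w$call_id, caller_id = w$caller_id, context = w$context,
    dur_s = length(x) / sr,
    rms_db_mean = mean(rms_db), rms_db_median = median(rms_db),
    rms_db_sd = if (length(rms_db) > 1) sd(rms_db) else 0,
    rms_db_max = max(rms_db),
    spec_centroid_hz = mom$centroid, spec_sd_hz = mom$sd,
    spec_skew = mom$skew, spec_kurt = mom$kurt,
    spec_q25_hz = mom$q25, spec_q50_hz = mom$q50, spec_q75_hz = mom$q75,
    spec_iqr_hz = mom$q75 - mom$q25,
    spec_entropy = mom$entropy, spec_flatness = mom$flatness,
    domfreq_mean_hz = mean(dom), domfreq_median_hz = median(dom),
    domfreq_sd_hz = if (length(dom) > 1) sd(dom) else 0,
    f0_mean_hz = f0_stats[1], f0_median_hz = f0_stats[2],
    f0_sd_hz = f0_stats[3], f0_min_hz = f0_stats[4],
    f0_max_hz = f0_stats[5], f0_range_hz = f0_stats[6],
    f0_slope_hz_per_s = f0_slope,
    voiced_frac = mean(f0t$voiced),
    f1_median_hz = fm$medians[1], f2_median_hz = fm$medians[2],
    f3_median_hz = fm$medians[3], f4_median_hz = fm$medians[4],
    formant_dispersion_hz = (fm$medians[4] - fm$medians[1]) / 3,
    formant_admissible_frac = fm$admissible_frac,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract a feature table from a call pool
#'
#' Runs [extract_features] over a list of waveforms, or over a manifest data
#' frame whose `file` column points at WAV files, and assembles the rows
#' into the pipeline's central exchange object. Partial failures abort the
#' job unless `skip_bad = TRUE`, in which case failing calls are dropped
#' with a warning.
#'
#' @param calls Named list of [waveform]s, or a manifest data frame with
#'   columns `call_id`, `caller_id`, `context`, `file`.
#' @param s A [frame_settings].
#' @param skip_bad Drop unreadable/failing calls instead of erroring.
#' @return Data frame of class `feature_table`, one row per call, with a
#'   `settings` attribute carrying the settings hash.
#' @export
extract_table <- function(calls, s = frame_settings(), skip_bad = FALSE) {
  get_wave <- function(i) {
    if (is.data.frame(calls)) {
      read_wav(calls$file[i], call_id = calls$call_id[i],
               caller_id = calls$caller_id[i], context = calls$context[i])
    } else calls[[i]]
  }
  n <- if (is.data.frame(calls)) nrow(calls) else length(calls)
  rows <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    row <- tryCatch(extract_features(get_wave(i), s), error = function(e) e)
    if (inherits(row, "error")) {
      id <- if (is.data.frame(calls)) calls$call_id[i] else names(calls)[i]
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(row)))
    } else rows[[i]] <- row
  }
  if (length(failures) > 0) {
    if (!skip_bad)
      stop(sprintf("feature extraction failed for %d call(s): %s",
                   length(failures), paste(failures, collapse = "; ")))
    warning(sprintf("skipped %d call(s): %s", length(failures),
                    paste(failures, collapse = "; ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (anyDuplicated(out$call_id)) stop("duplicate call_id in feature table")
  attr(out, "settings") <- settings_hash(s)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the numeric features in a feature table
#'
#' @param table A `feature_table`.
#' @return Character vector of feature column names (identifying and
#'   diagnostic columns excluded).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("call_id", "caller_id", "context",
                          "formant_admissible_frac"))
}
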