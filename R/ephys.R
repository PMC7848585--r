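#' Classifier thresholds for unit identification
#'
#' The waveform and firing-rate criteria separating putative fast-spiking
#' interneurons (FSIs) from medium spiny neurons (MSNs): FSIs have a
#' peak-to-trough duration below the amplifier-dependent cutoff and a
#' baseline rate above 2 Hz; MSNs a duration above the cutoff and a baseline
#' rate below 10 Hz. The cutoff depends on the amplifier profile because
#' spike shape depends strongly on the amplifier's filter settings, so the
#' profile is a required input and never guessed from the data.
#'
#' @param amplifier `"long"` (800 us cutoff) or `"short"` (480 us cutoff).
#' @param fsi_min_rate,msn_max_rate Rate criteria in Hz.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(amplifier = c("long", "short"),
                                  fsi_min_rate = 2, msn_max_rate = 10) {
  amplifier <- match.arg(amplifier)
  cutoff <- c(long = 800, short = 480)[[amplifier]]
  stopifnot(cutoff > 0, fsi_min_rate > 0, msn_max_rate > 0)
  structure(list(amplifier = amplifier, duration_cutoff = cutoff,
                 fsi_min_rate = fsi_min_rate, msn_max_rate = msn_max_rate),
            class = "classifier_thresholds")
}

#' Median spike waveform
#'
#' Aligns a set of single-spike voltage traces on their peaks and takes the
#' pointwise median, the robust template used for duration measurement. Peak
#' alignment shifts each trace so its global maximum falls at the median peak
#' index; samples shifted outside the window are dropped from the median at
#' that position.
#'
#' @param traces Matrix of voltage traces (one row per spike) or a list of
#'   equal-length numeric vectors.
#' @return Numeric vector: the aligned pointwise median trace.
#' @export
median_waveform <- function(traces) {
  if (is.list(traces)) {
    len <- unique(lengths(traces))
    if (length(len) != 1) stop("traces must have equal lengths", call. = FALSE)
    traces <- do.call(rbind, traces)
  }
  if (!is.matrix(traces) || nrow(traces) == 0) {
    stop("need at least one trace", call. = FALSE)
  }
  peaks <- apply(traces, 1, which.max)
  target <- stats::median(peaks)
  nc <- ncol(traces)
  aligned <- matrix(NA_real_, nrow(traces), nc)
  for (i in seq_len(nrow(traces))) {
    shift <- round(target - peaks[i])
    src <- seq_len(nc) - shift
    ok <- src >= 1 & src <= nc
    aligned[i, ok] <- traces[i, src[ok]]
  }
  apply(aligned, 2, stats::median, na.rm = TRUE)
}

#' Peak-to-trough duration of a spike waveform
#'
#' Interpolates the trace with a cubic spline onto a finer grid and measures
#' the time from the global peak to the subsequent trough (the global minimum
#' after the peak).
#'
#' @param trace Numeric voltage trace.
#' @param sampling_interval_us Sampling interval of `trace` in microseconds.
#' @param upsample Spline upsampling factor (>= 1); default 10.
#' @return Duration in microseconds (positive).
#' @export
peak_trough_duration <- function(trace, sampling_interval_us, upsample = 10) {
  if (length(trace) < 3 || diff(range(trace)) == 0) {
    stop("trace has no peak/trough pair", call. = FALSE)
  }
  t_raw <- (seq_along(trace) - 1) * sampling_interval_us
  sp <- stats::spline(t_raw, trace, n = (length(trace) - 1) * upsample + 1)
  ipk <- which.max(sp$y)
  if (ipk >= length(sp$y)) stop("no trough after the peak", call. = FALSE)
  post <- sp$y[(ipk + 1):length(sp$y)]
  itr <- ipk + which.min(post)
  if (sp$y[itr] >= sp$y[ipk]) stop("no trough after the peak", call. = FALSE)
  sp$x[itr] - sp$x[ipk]
}

#' Baseline firing rate
#'
#' Mean firing rate in the 250 ms windows preceding each scene onset: total
#' spike count over all windows divided by the total window time. Windows
#' must be disjoint.
#'
#' @param spike_times Spike times in seconds.
#' @param scene_onsets Scene-onset times in seconds (>= 1).
#' @param window Window length in seconds before each onset; default 0.25.
#' @return Rate in Hz.
#' @export
baseline_rate <- function(spike_times, scene_onsets, window = 0.25) {
  if (length(scene_onsets) < 1) stop("need at least one scene onset", call. = FALSE)
  ons <- sort(scene_onsets)
  if (length(ons) > 1 && any(diff(ons) < window)) {
    stop("baseline windows overlap (onsets closer than the window length)",
         call. = FALSE)
  }
  count <- sum(vapply(ons, function(o) {
    sum(spike_times >= o - window & spike_times < o)
  }, numeric(1)))
  count / (length(ons) * window)
}

#' Classify a unit as FSI, MSN or neither
#'
#' Applies the duration/rate criteria of [classifier_thresholds()]. The
#' inequalities are strict on both sides, so measurements falling exactly on
#' a threshold satisfy neither rule and come back `"unclassified"` with
#' `boundary = TRUE`. Tonically active neurons are excluded by annotation
#' (`tan_flag`), not detected.
#'
#' @param duration_us Measured peak-to-trough duration (microseconds).
#' @param baseline_hz Measured baseline rate (Hz).
#' @param thresholds A [classifier_thresholds()].
#' @param tan_flag The unit is a tonically active neuron (external label).
#' @return A list of class `unit_class` with `label` (one of `"FSI"`,
#'   `"MSN"`, `"TAN_excluded"`, `"unclassified"`), the measurements, and a
#'   `boundary` flag.
#' @examples
#' classify_unit(500, 15)$label    # FSI
#' classify_unit(1200, 1)$label    # MSN
#' classify_unit(500, 1)$label     # unclassified
#' @export
classify_unit <- function(duration_us, baseline_hz,
                          thresholds = classifier_thresholds("long"),
                          tan_flag = FALSE) {
  stopifnot(is.finite(duration_us), is.finite(baseline_hz))
  th <- thresholds
  boundary <- duration_us == th$duration_cutoff ||
    baseline_hz == th$fsi_min_rate || baseline_hz == th$msn_max_rate
  label <- if (tan_flag) {
    "TAN_excluded"
  } else if (duration_us < th$duration_cutoff && baseline_hz > th$fsi_min_rate) {
    "FSI"
  } else if (duration_us > th$duration_cutoff && baseline_hz < th$msn_max_rate) {
    "MSN"
  } else {
    "unclassified"
  }
  structure(list(label = label, duration_us = duration_us,
                 baseline_hz = baseline_hz, thresholds = th,
                 boundary = boundary),
            class = "unit_class")
}

#' @export
print.unit_class <- function(x, ...) {
  cat(sprintf("%s (duration %.0f us, baseline %.2f Hz%s)\n", x$label,
              x$duration_us, x$baseline_hz,
              if (x$boundary) ", on a classification boundary" else ""))
  invisible(x)
}

#' Classify a recorded or synthetic unit record
#'
#' Convenience wrapper measuring duration ([peak_trough_duration()]) and
#' baseline rate ([baseline_rate()]) from an `sg_unit` and applying
#' [classify_unit()].
#'
#' @param unit An `sg_unit` from [synthetic_unit()].
#' @param thresholds A [classifier_thresholds()].
#' @return A `unit_class`.
#' @export
classify_unit_record <- function(unit, thresholds = classifier_thresholds("long")) {
  dur <- peak_trough_duration(unit$waveform, unit$sampling_interval_us)
  rate <- baseline_rate(unit$spike_times, unit$scene_onsets)
  classify_unit(dur, rate, thresholds, tan_flag = isTRUE(unit$tan))
}

#' Stimulus responsiveness with Bonferroni correction
#'
#' Two-sided paired comparison of per-trial firing rates in the post-onset
#' response window (50--400 ms) against the pre-onset baseline window
#' (250 ms), one test per stimulus, flagged significant at
#' `p < alpha / n_comparisons`. Counts are converted to rates before the
#' comparison because the two windows differ in length. The default test is
#' the paired t test; `method = "permutation"` runs an exact sign-flip
#' permutation of the paired rate differences for small trial counts.
#'
#' @param post_counts,pre_counts Numeric vectors (or single-column matrices)
#'   of per-trial spike counts for one stimulus, or matrices with one column
#'   per stimulus.
#' @param post_window,pre_window Window lengths in seconds (defaults 0.35 and
#'   0.25).
#' @param n_comparisons Number of stimuli tested together (Bonferroni
#'   divisor); default the number of columns.
#' @param alpha Family-wise level; default 0.05.
#' @param method `"t"` or `"permutation"`.
#' @return Data frame with one row per stimulus: `statistic`, `p_value`,
#'   `threshold`, `significant`.
#' @export
response_significance <- function(post_counts, pre_counts,
                                  post_window = 0.35, pre_window = 0.25,
                                  n_comparisons = NULL, alpha = 0.05,
                                  method = c("t", "permutation")) {
  method <- match.arg(method)
  post <- as.matrix(post_counts)
  pre <- as.matrix(pre_counts)
  if (!all(dim(post) == dim(pre))) {
    stop("post and pre counts must be paired (same dimensions)", call. = FALSE)
  }
  if (nrow(post) < 2) stop("need at least 2 paired trials", call. = FALSE)
  if (is.null(n_comparisons)) n_comparisons <- ncol(post)
  threshold <- alpha / n_comparisons
  res <- lapply(seq_len(ncol(post)), function(j) {
    d <- post[, j] / post_window - pre[, j] / pre_window
    if (stats::sd(d) == 0) {
      return(data.frame(statistic = 0, p_value = 1))
    }
    if (method == "t") {
      tt <- stats::t.test(d)
      data.frame(statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      obs <- mean(d)
      n <- length(d)
      if (n <= 14) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
        perm <- abs(signs %*% d) / n
        p <- mean(perm >= abs(obs) - 1e-12)
      } else {
        signs <- matrix(sample(c(-1, 1), 2000 * n, replace = TRUE), ncol = n)
        perm <- abs(signs %*% d) / n
        p <- (sum(perm >= abs(obs) - 1e-12) + 1) / (2000 + 1)
      }
      data.frame(statistic = obs, p_value = p)
    }
  })
  out <- do.call(rbind, res)
  out$threshold <- threshold
  out$significant <- out$p_value < threshold
  rownames(out) <- colnames(post)
  out
}

#' Gaussian-kernel spike density
#'
#' Peristimulus spike-density estimate: each spike contributes a unit-mass
#' Gaussian (sigma = 15 ms by default); the sum is divided by the trial count
#' so the curve is in Hz (spikes per second per trial).
#'
#' @param spike_times Spike times in seconds (pooled over trials, relative to
#'   the alignment event).
#' @param times Evaluation grid in seconds; its spacing should not exceed
#'   `sigma / 3`.
#' @param sigma Kernel width in seconds; default 0.015.
#' @param n_trials Number of trials pooled into `spike_times`; default 1.
#' @return Numeric vector of rates (Hz) over `times`.
#' @examples
#' tt <- seq(-0.1, 0.1, by = 0.001)
#' max(spike_density(0, tt))  # 1 / (0.015 * sqrt(2*pi)) = 26.6 Hz
#' @export
spike_density <- function(spike_times, times, sigma = 0.015, n_trials = 1) {
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (length(times) > 1 && max(diff(times)) > sigma / 3 + 1e-12) {
    stop("time grid resolution must be <= sigma / 3", call. = FALSE)
  }
  if (length(spike_times) == 0) return(numeric(length(times)))
  dens <- vapply(times, function(t0) {
    sum(stats::dnorm(t0, mean = spike_times, sd = sigma))
  }, numeric(1))
  dens / n_trials
}
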