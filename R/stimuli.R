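#' Per-channel current traces
#'
#' Container for the injection currents that drive the A population: a
#' channels x samples matrix with the pulse amplitude normalized to 1.
#'
#' @param values Numeric matrix, channels x samples.
#' @param dt Sample step (ms).
#' @param pulse_ms Nominal pulse duration (ms), kept as metadata.
#' @return An object of class \code{"current_traces"}.
#' @export
current_traces <- function(values, dt, pulse_ms = 5.5) {
  values <- as.matrix(values)
  stopifnot(dt > 0, pulse_ms > 0)
  structure(list(values = values, dt = dt, pulse_ms = pulse_ms),
            class = "current_traces")
}

#' @export
print.current_traces <- function(x, ...) {
  cat(sprintf("Current traces: %d channels x %d samples (dt = %g ms, %g ms)\n",
              nrow(x$values), ncol(x$values), x$dt,
              ncol(x$values) * x$dt))
  invisible(x)
}

#' FM-sweep injection currents
#'
#' A linear frequency-modulated sweep encoded as a unit current pulse of
#' \code{pulse_ms} delivered to each channel in turn: channel k (counting
#' from the low edge for an up sweep, from the high edge for a down sweep)
#' receives its pulse starting at \eqn{(k-1) \cdot} \code{onset_step_ms}.
#' The sweep rate is \code{1/onset_step_ms} channels/ms.
#'
#' @param n_channels Number of channels.
#' @param onset_step_ms Interval between successive channel onsets (ms), > 0.
#' @param direction \code{"up"} or \code{"down"}.
#' @param pulse_ms Pulse duration (ms), default 5.5.
#' @param dt Sample step (ms).
#' @param amplitude Pulse amplitude (default 1, the normalization unit).
#' @return A \code{\link{current_traces}} object of duration
#'   \code{(n_channels - 1) * onset_step_ms + pulse_ms}.
#' @export
#' @examples
#' tr <- fm_sweep_current(8, onset_step_ms = 5.5)
fm_sweep_current <- function(n_channels, onset_step_ms,
                             direction = c("up", "down"), pulse_ms = 5.5,
                             dt = 0.1, amplitude = 1) {
  direction <- match.arg(direction)
  stopifnot(onset_step_ms > 0, n_channels >= 1, pulse_ms > 0, dt > 0)
  duration <- (n_channels - 1) * onset_step_ms + pulse_ms
  n_samp <- as.integer(round(duration / dt))
  vals <- matrix(0, n_channels, n_samp)
  for (k in seq_len(n_channels)) {
    t0 <- (k - 1) * onset_step_ms
    i0 <- as.integer(round(t0 / dt)) + 1L
    i1 <- min(n_samp, as.integer(round((t0 + pulse_ms) / dt)))
    ch <- if (direction == "up") k else n_channels - k + 1L
    vals[ch, i0:i1] <- amplitude
  }
  current_traces(vals, dt = dt, pulse_ms = pulse_ms)
}

#' Ornstein-Uhlenbeck noise specification
#'
#' The noise level sigma is defined as the ratio between the stationary
#' standard deviation of the zero-mean OU process and the amplitude of the
#' noise-free current pulse.  The mean-reversion time constant defaults to
#' 5 ms, comparable to the pulse duration, so the noise is neither white nor
#' quasi-DC on the time scale of the stimulus.
#'
#' @param sigma Noise level (>= 0).
#' @param theta_ou Mean-reversion rate (1/ms), default 0.2 (5 ms time
#'   constant).
#' @param dt Sample step (ms).
#' @param seed Integer seed.
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(sigma, theta_ou = 0.2, dt = 0.1, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(theta_ou > 0, theta_ou * dt < 1, dt > 0)
  structure(list(sigma = sigma, theta_ou = theta_ou, dt = dt,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate an Ornstein-Uhlenbeck noise path
#'
#' Forward-Euler simulation of a zero-mean OU process,
#' \eqn{x_{n+1} = x_n (1 - \theta \Delta t) + \sigma_w \sqrt{\Delta t}\,
#' \xi_n}.  The diffusion amplitude is calibrated to the exact stationary
#' standard deviation of this discrete recursion, so the sample s.d. of a
#' long path matches \code{sigma} times the (unit) pulse amplitude.  Paths
#' start from a stationary draw.
#'
#' @param n_samples Path length (> 0); or, for \code{ou_noise_matrix}, the
#'   number of samples per channel.
#' @param spec A \code{\link{noise_spec}}.
#' @param n_channels Number of independent channels (matrix variant).
#' @param pulse_amplitude Amplitude the sigma ratio refers to (default 1).
#' @return \code{ou_noise}: a numeric vector; \code{ou_noise_matrix}: an
#'   n_channels x n_samples matrix of independent paths.
#' @export
#' @examples
#' x <- ou_noise(1e4, noise_spec(sigma = 0.45, seed = 7))
#' sd(x)
ou_noise <- function(n_samples, spec, pulse_amplitude = 1) {
  stopifnot(n_samples > 0)
  drop(ou_noise_matrix(n_samples, spec, n_channels = 1L,
                       pulse_amplitude = pulse_amplitude))
}

#' @rdname ou_noise
#' @export
ou_noise_matrix <- function(n_samples, spec, n_channels,
                            pulse_amplitude = 1) {
  stopifnot(inherits(spec, "noise_spec"), n_samples > 0, n_channels >= 1)
  if (spec$sigma == 0)
    return(matrix(0, n_channels, n_samples))
  a <- 1 - spec$theta_ou * spec$dt
  sd_stat <- spec$sigma * pulse_amplitude
  sig_w_sqdt <- sd_stat * sqrt(1 - a^2)
  set.seed(spec$seed)
  x0 <- stats::rnorm(n_channels, 0, sd_stat)
  innov <- matrix(stats::rnorm(n_channels * n_samples, 0, sig_w_sqdt),
                  nrow = n_samples, ncol = n_channels)
  paths <- stats::filter(innov, filter = a, method = "recursive",
                         init = matrix(x0, nrow = 1))
  t(matrix(as.numeric(paths), nrow = n_samples))
}

#' Add OU noise to current traces
#'
#' Adds an independent OU noise path to every channel, spanning the whole
#' stimulus period.  Purely additive: subtracting the same noise recovers
#' the clean traces exactly.
#'
#' @param traces A \code{\link{current_traces}} object.
#' @param spec A \code{\link{noise_spec}} with matching \code{dt}.
#' @return A \code{\link{current_traces}} object with noise added.
#' @export
add_noise <- function(traces, spec) {
  stopifnot(inherits(traces, "current_traces"), inherits(spec, "noise_spec"))
  if (abs(traces$dt - spec$dt) > 1e-12)
    stop("noise dt does not match trace dt", call. = FALSE)
  nz <- ou_noise_matrix(ncol(traces$values), spec,
                        n_channels = nrow(traces$values))
  traces$values <- traces$values + nz
  traces
}

#' Encode current traces into an A-population spike raster
#'
#' Off-line preparation of input spike patterns: each channel's current
#' trace (optionally with OU noise spanning the whole stimulus period) is
#' injected into an independent LIF neuron with parameters \code{neuron},
#' and the resulting spikes form the A raster.  The integration is the same
#' update used inside the network simulator.
#'
#' @param drive A \code{\link{current_traces}} object.
#' @param noise Optional \code{\link{noise_spec}}; \code{NULL} or sigma 0
#'   leaves the drive clean.
#' @param neuron A \code{\link{neuron_params}} object.
#' @return A \code{\link{spike_raster}} with population \code{"A"}.
#' @export
encode_to_spikes <- function(drive, noise = NULL, neuron = neuron_params()) {
  stopifnot(inherits(drive, "current_traces"))
  if (!is.null(noise)) drive <- add_noise(drive, noise)
  n_ch <- nrow(drive$values)
  # run the network core with all synaptic weights silenced; keep A spikes
  p <- network_params(n_channels = max(2L, n_ch), fan_out = 1L,
                      w_a_b1 = 0, w_a_b2 = 0, w_inh = 0,
                      w_plastic_max = 0, dt = drive$dt)
  vals <- drive$values
  if (nrow(vals) < p$n_channels)
    vals <- rbind(vals, matrix(0, p$n_channels - nrow(vals), ncol(vals)))
  net <- build_network(p, neuron)
  sim <- simulate_network(net, drive = current_traces(vals, drive$dt,
                                                      drive$pulse_ms))
  r <- sim$raster
  r <- r[r$population == "A" & r$channel <= n_ch, , drop = FALSE]
  spike_raster(r$time_ms, r$population, r$channel,
               duration = attr(sim$raster, "duration"))
}

#' Binary spectro-temporal stimulus pattern
#'
#' A channels x time-bins 0/1 matrix with a bin width; the representation
#' used for formant-track word stimuli (default 32 channels x 25 bins of
#' 10 ms, i.e. a 250 ms word).
#'
#' @param grid Matrix with entries in \{0, 1\}.
#' @param bin_ms Bin width (ms).
#' @param label Class label.
#' @return An object of class \code{"stimulus_pattern"}.
#' @export
stimulus_pattern <- function(grid, bin_ms = 10, label = "") {
  grid <- as.matrix(grid)
  if (!all(grid %in% c(0, 1)))
    stop("pattern grid must be binary", call. = FALSE)
  stopifnot(bin_ms > 0)
  structure(list(grid = grid, bin_ms = bin_ms, label = label),
            class = "stimulus_pattern")
}

#' @export
print.stimulus_pattern <- function(x, ...) {
  cat(sprintf("Stimulus pattern '%s': %d channels x %d bins (%g ms bins)\n",
              x$label, nrow(x$grid), ncol(x$grid), x$bin_ms))
  invisible(x)
}

# smooth formant channel trajectories defining each synthetic class;
# t in [0, 1], returns channels on a continuous scale in [1, n].  Classes
# mimic vowel-like stimuli: each occupies a distinct region of the
# (channel, separation) plane -- as vowels do in formant space -- while the
# pair exhibits a distinct dynamic shape (rising, falling, converging,
# diverging, steady close/wide, rise-fall)
formant_class_shapes <- function(n_channels) {
  s <- (n_channels - 1) / 31        # scale relative to the 32-channel grid
  ch <- function(k) 1 + (k - 1) * s
  list(
    rising   = function(t) cbind(ch(4 + 4 * t), ch(12 + 6 * t)),
    falling  = function(t) cbind(ch(24 - 4 * t), ch(31 - 6 * t)),
    converge = function(t) cbind(ch(10 + 3 * t), ch(22 - 6 * t)),
    diverge  = function(t) cbind(ch(16 - 4 * t), ch(18 + 5 * t)),
    steady_close = function(t) cbind(rep(ch(7), length(t)),
                                     rep(ch(12), length(t))),
    steady_wide  = function(t) cbind(rep(ch(17), length(t)),
                                     rep(ch(26), length(t))),
    rise_fall = function(t) cbind(ch(14 + 3 * sin(pi * t)),
                                  ch(24 + 3 * sin(pi * t)))
  )
}

#' Synthetic formant-track pattern set
#'
#' Generates a stand-in for a speech-derived stimulus vocabulary: each class
#' is defined by two smooth "formant" channel trajectories with a distinct
#' spectro-temporal shape (rising, falling, converging, diverging, steady
#' and rise-fall pairs), rendered onto a binary channels x bins grid with at
#' most two active channels per time bin.  Exemplars within a class are
#' channel-jittered copies: each exemplar's formants are shifted by a random
#' offset and tilt with standard deviation \code{jitter} channels, emulating
#' the within-class variability of repeated utterances.
#'
#' @param n_classes Number of classes (default 7, at most 7).
#' @param n_exemplars Exemplars per class (default 3).
#' @param n_channels,n_bins Grid size (default 32 x 25).
#' @param bin_ms Bin width (ms, default 10).
#' @param jitter Channel s.d. of the exemplar jitter (default 0.75; 0 gives
#'   identical exemplars).
#' @param seed Integer seed; the same seed reproduces the same set.
#' @return A list of \code{\link{stimulus_pattern}} objects of length
#'   \code{n_classes * n_exemplars}, with labels \code{"class1"} ...;
#'   attribute \code{"classes"} holds the class labels.
#' @export
#' @examples
#' pats <- synth_formant_patterns(seed = 42)
#' length(pats)
synth_formant_patterns <- function(n_classes = 7, n_exemplars = 3,
                                   n_channels = 32, n_bins = 25,
                                   bin_ms = 10, jitter = 0.75, seed = 1L) {
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  shapes <- formant_class_shapes(n_channels)
  if (n_classes > length(shapes))
    stop("at most ", length(shapes), " classes are available", call. = FALSE)
  set.seed(seed)
  tt <- (seq_len(n_bins) - 0.5) / n_bins
  out <- vector("list", n_classes * n_exemplars)
  k <- 0L
  for (ci in seq_len(n_classes)) {
    base <- shapes[[ci]](tt)          # n_bins x 2 continuous channels
    for (ei in seq_len(n_exemplars)) {
      offs <- stats::rnorm(2, 0, jitter)    # per-formant offset
      tilt <- stats::rnorm(2, 0, jitter)    # per-formant slope perturbation
      grid <- matrix(0, n_channels, n_bins)
      for (f in 1:2) {
        ch <- round(base[, f] + offs[f] + tilt[f] * (tt - 0.5))
        ch <- pmin(n_channels, pmax(1, ch))
        grid[cbind(ch, seq_len(n_bins))] <- 1
      }
      k <- k + 1L
      out[[k]] <- stimulus_pattern(grid, bin_ms = bin_ms,
                                   label = paste0("class", ci))
    }
  }
  attr(out, "classes") <- paste0("class", seq_len(n_classes))
  out
}

# nearest-neighbour time-warp of a pattern grid to n_bins_out columns,
# center-aligned round-half-up mapping
warp_grid <- function(grid, n_bins_out) {
  n_bins <- ncol(grid)
  idx <- floor((seq_len(n_bins_out) - 0.5) * n_bins / n_bins_out + 0.5)
  idx <- pmin(n_bins, pmax(1L, as.integer(idx)))
  grid[, idx, drop = FALSE]
}

#' Concatenate patterns into a gapless "sentence"
#'
#' Builds a probe/exposure sequence by concatenating words drawn from the
#' pattern set in seeded random order with equal counts per class, without
#' silent gaps.  Presentation rate is varied by time-warping every word to
#' \code{T' = max(1, floor(T * 100 / rate_percent + 0.5))} bins by
#' nearest-neighbour column resampling (round-half-up), which preserves
#' binarity; at the normal rate (100\%) a 25-bin word lasts 250 ms, i.e.
#' 4 words per second.
#'
#' @param patterns Pattern set from \code{\link{synth_formant_patterns}} (or
#'   any list of \code{\link{stimulus_pattern}}s sharing \code{bin_ms}).
#' @param n_reps_per_class Occurrences of each class in the sentence.
#' @param rate_percent Presentation rate as a percentage of normal (60, 100,
#'   150, 200 are the standard grid); any positive value is accepted.
#' @param seed Integer seed controlling word order and exemplar choice.
#' @return An object of class \code{"sentence"}: \code{pattern} (the
#'   concatenated \code{\link{stimulus_pattern}}), \code{label_track}
#'   (per-bin class label), \code{words} (data frame with \code{label},
#'   \code{exemplar}, \code{start_bin}, \code{end_bin}), and
#'   \code{rate_percent}.
#' @export
build_sentence <- function(patterns, n_reps_per_class = 1,
                           rate_percent = 100, seed = 1L) {
  if (rate_percent <= 0) stop("rate_percent must be > 0", call. = FALSE)
  stopifnot(n_reps_per_class >= 1)
  labels <- vapply(patterns, function(p) p$label, character(1))
  classes <- attr(patterns, "classes")
  if (is.null(classes)) classes <- unique(labels)
  bin_ms <- patterns[[1]]$bin_ms
  set.seed(seed)
  # draw: one exemplar index per occurrence, equal class counts, shuffled
  occ <- do.call(rbind, lapply(classes, function(cl) {
    ex <- which(labels == cl)
    data.frame(class = cl,
               idx = ex[sample.int(length(ex), n_reps_per_class,
                                   replace = TRUE)])
  }))
  occ <- occ[sample.int(nrow(occ)), , drop = FALSE]

  grids <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    g <- patterns[[occ$idx[i]]]$grid
    t_out <- max(1L, as.integer(floor(ncol(g) * 100 / rate_percent + 0.5)))
    grids[[i]] <- warp_grid(g, t_out)
  }
  lens <- vapply(grids, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  pattern <- stimulus_pattern(do.call(cbind, grids), bin_ms = bin_ms,
                              label = "sentence")
  structure(list(pattern = pattern,
                 label_track = rep(occ$class, lens),
                 words = data.frame(label = occ$class,
                                    exemplar = occ$idx,
                                    start_bin = starts, end_bin = ends),
                 rate_percent = rate_percent),
            class = "sentence")
}

#' @export
print.sentence <- function(x, ...) {
  cat(sprintf("Sentence: %d words, %d bins (%g ms), rate %g%%\n",
              nrow(x$words), ncol(x$pattern$grid),
              ncol(x$pattern$grid) * x$pattern$bin_ms, x$rate_percent))
  cat("  ", paste(x$words$label, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Convert a binary pattern to injection currents
#'
#' Every active bin becomes a unit current pulse in its channel lasting
#' one bin width; inactive bins contribute zero current.
#'
#' @param p A \code{\link{stimulus_pattern}} (or a \code{"sentence"}, whose
#'   concatenated pattern is used).
#' @param dt Sample step (ms).
#' @param amplitude Current amplitude for active bins (default 1).
#' @return A \code{\link{current_traces}} object.
#' @export
pattern_to_current <- function(p, dt = 0.1, amplitude = 1) {
  if (inherits(p, "sentence")) p <- p$pattern
  stopifnot(inherits(p, "stimulus_pattern"), dt > 0)
  spb <- as.integer(round(p$bin_ms / dt))
  if (spb < 1) stop("bin_ms must be at least dt", call. = FALSE)
  vals <- amplitude * p$grid[, rep(seq_len(ncol(p$grid)), each = spb),
                             drop = FALSE]
  current_traces(vals, dt = dt, pulse_ms = p$bin_ms)
}
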