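#' Configuration of a two-phase exposure/probe trial
#'
#' Bundles everything one trial needs: the exposure stimulus, the probe set,
#' repetition counts, noise level, presentation rate and seeds.  Two
#' stimulus families are supported:
#' \itemize{
#'   \item \strong{traces}: \code{exposure} is a
#'     \code{\link{current_traces}} object (e.g. an FM sweep) and
#'     \code{probe_set} a named list of such objects; probes are presented
#'     individually with \code{gap_ms} of silence and fresh membrane state.
#'   \item \strong{patterns}: \code{exposure} is a class label into
#'     \code{patterns} (a set from \code{\link{synth_formant_patterns}});
#'     exposure and probe are gapless random "sentences" built from the set.
#' }
#' Learning is always on during exposure and off during probe.  Probe-phase
#' stimuli carry the OU noise at level \code{sigma}; the exposure stimulus
#' is the clean formative pattern.
#'
#' @param exposure \code{\link{current_traces}} or a class label.
#' @param probe_set Named list of \code{\link{current_traces}} (traces
#'   family; default: the exposure alone).
#' @param patterns Pattern set (patterns family).
#' @param n_exposure_reps Exposure presentations (30 for FM sweeps, 20 for
#'   formant words are the reference designs).
#' @param n_probe_reps Probe presentations per stimulus (100 FM / 50
#'   formant in the reference designs).
#' @param sigma Probe noise level (OU stationary s.d. over pulse amplitude).
#' @param rate_percent Presentation rate for the patterns family.
#' @param probe_order_seed Seed for the randomized probe order (and exemplar
#'   draws in the patterns family).
#' @param exposure_seed Seed for exposure-sentence word order.
#' @param noise_seed Base seed for probe noise; presentation k uses
#'   \code{noise_seed + k}.
#' @param gap_ms Silent gap between traces-family presentations (ms).
#' @param settle_ms Quiescent drift period applied to the efficacies after
#'   exposure, driving them to their bistable endpoints (ms).
#' @return An object of class \code{"trial_config"}.
#' @export
trial_config <- function(exposure, probe_set = NULL, patterns = NULL,
                         n_exposure_reps = 30, n_probe_reps = 100,
                         sigma = 0, rate_percent = 100,
                         probe_order_seed = 1L, exposure_seed = 1L,
                         noise_seed = 1L, gap_ms = 50, settle_ms = 2500) {
  stopifnot(n_exposure_reps >= 1, n_probe_reps >= 1, sigma >= 0,
            rate_percent > 0, gap_ms >= 0, settle_ms > 0)
  if (inherits(exposure, "current_traces")) {
    family <- "traces"
    if (is.null(probe_set)) probe_set <- list(exposure = exposure)
    if (is.null(names(probe_set)) || any(names(probe_set) == ""))
      stop("probe_set must be a named list", call. = FALSE)
    if (!all(vapply(probe_set, inherits, logical(1), "current_traces")))
      stop("traces-family probe_set entries must be current_traces",
           call. = FALSE)
  } else if (is.character(exposure) && length(exposure) == 1) {
    family <- "patterns"
    if (is.null(patterns))
      stop("patterns family needs a `patterns` set", call. = FALSE)
    labels <- vapply(patterns, function(p) p$label, character(1))
    if (!exposure %in% labels)
      stop("exposure class '", exposure, "' not found in patterns",
           call. = FALSE)
  } else {
    stop("exposure must be current_traces or a class label", call. = FALSE)
  }
  structure(list(family = family, exposure = exposure,
                 probe_set = probe_set, patterns = patterns,
                 n_exposure_reps = n_exposure_reps,
                 n_probe_reps = n_probe_reps, sigma = sigma,
                 rate_percent = rate_percent,
                 probe_order_seed = as.integer(probe_order_seed),
                 exposure_seed = as.integer(exposure_seed),
                 noise_seed = as.integer(noise_seed),
                 gap_ms = gap_ms, settle_ms = settle_ms),
            class = "trial_config")
}

# concatenate one presentation's traces n times with silent gaps
rep_with_gaps <- function(traces, n_reps, gap_ms) {
  v <- traces$values
  gap <- matrix(0, nrow(v), as.integer(round(gap_ms / traces$dt)))
  block <- cbind(v, gap)
  current_traces(block[, rep(seq_len(ncol(block)), n_reps), drop = FALSE],
                 dt = traces$dt, pulse_ms = traces$pulse_ms)
}

# exposure sentence: n_reps occurrences of one class, gapless
exposure_sentence <- function(cfg) {
  labels <- vapply(cfg$patterns, function(p) p$label, character(1))
  sub <- cfg$patterns[labels == cfg$exposure]
  attr(sub, "classes") <- cfg$exposure
  build_sentence(sub, n_reps_per_class = cfg$n_exposure_reps,
                 rate_percent = cfg$rate_percent, seed = cfg$exposure_seed)
}

#' Run the exposure phase
#'
#' Resets the network (plastic efficacies to their "low" state of zero) and
#' presents the exposure stimulus \code{n_exposure_reps} times with the
#' learning rule on, then lets the efficacies drift quiescently for
#' \code{settle_ms} so each one reaches its bistable endpoint.
#'
#' @param net A \code{"tononet"} object.
#' @param cfg A \code{\link{trial_config}}.
#' @return The trained network.
#' @export
run_exposure <- function(net, cfg) {
  stopifnot(inherits(net, "tononet"), inherits(cfg, "trial_config"))
  net <- reset_network(net, weights_low = TRUE)
  if (cfg$family == "traces") {
    drive <- rep_with_gaps(resample_traces(cfg$exposure, net$params$dt),
                           cfg$n_exposure_reps, cfg$gap_ms)
  } else {
    sen <- exposure_sentence(cfg)
    drive <- pattern_to_current(sen, dt = net$params$dt)
  }
  sim <- simulate_network(net, drive = drive, learning = TRUE,
                          record_a = FALSE)
  net <- sim$net
  net$synapses$w <- drift_efficacy(net$synapses$w, cfg$settle_ms,
                                   net$plasticity)
  net
}

# match a current_traces object to the network dt (nearest-sample resample)
resample_traces <- function(traces, dt) {
  if (abs(traces$dt - dt) < 1e-12) return(traces)
  n_out <- as.integer(round(ncol(traces$values) * traces$dt / dt))
  idx <- pmin(ncol(traces$values),
              pmax(1L, ceiling(seq_len(n_out) * ncol(traces$values) / n_out)))
  current_traces(traces$values[, idx, drop = FALSE], dt, traces$pulse_ms)
}

#' Run the probe phase
#'
#' Presents the probe stimuli with the learning rule off and records the
#' total B2 spike count for every presentation.  In the traces family each
#' presentation is simulated separately from resting state with its own
#' fresh OU noise path; in the patterns family a single gapless probe
#' sentence containing \code{n_probe_reps} occurrences of every class in
#' randomized order is simulated continuously (membrane state persists
#' across words) and spikes are attributed to the word whose bins span
#' their time.
#'
#' @param net A trained \code{"tononet"}.
#' @param cfg A \code{\link{trial_config}}.
#' @return A response table: data frame with columns \code{class},
#'   \code{rep}, \code{count}, \code{sigma}, \code{rate_percent}.
#' @export
run_probe <- function(net, cfg) {
  stopifnot(inherits(net, "tononet"), inherits(cfg, "trial_config"))
  dt <- net$params$dt
  if (cfg$family == "traces") {
    stims <- names(cfg$probe_set)
    plan <- data.frame(
      class = rep(stims, each = cfg$n_probe_reps),
      rep = rep(seq_len(cfg$n_probe_reps), times = length(stims)))
    set.seed(cfg$probe_order_seed)
    plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
    counts <- integer(nrow(plan))
    for (k in seq_len(nrow(plan))) {
      drive <- resample_traces(cfg$probe_set[[plan$class[k]]], dt)
      if (cfg$sigma > 0)
        drive <- add_noise(drive, noise_spec(cfg$sigma, dt = dt,
                                             seed = cfg$noise_seed + k))
      sim <- simulate_network(net, drive = drive, learning = FALSE,
                              record_a = FALSE)
      counts[k] <- count_spikes(sim$raster, "B2")
    }
    plan$count <- counts
  } else {
    sen <- build_sentence(cfg$patterns,
                          n_reps_per_class = cfg$n_probe_reps,
                          rate_percent = cfg$rate_percent,
                          seed = cfg$probe_order_seed)
    drive <- pattern_to_current(sen, dt = dt)
    if (cfg$sigma > 0)
      drive <- add_noise(drive, noise_spec(cfg$sigma, dt = dt,
                                           seed = cfg$noise_seed))
    sim <- simulate_network(net, drive = drive, learning = FALSE,
                            record_a = FALSE)
    b2 <- sim$raster[sim$raster$population == "B2", , drop = FALSE]
    bin_ms <- sen$pattern$bin_ms
    w <- sen$words
    from <- (w$start_bin - 1) * bin_ms
    to <- w$end_bin * bin_ms
    counts <- vapply(seq_len(nrow(w)), function(i)
      sum(b2$time_ms >= from[i] & b2$time_ms < to[i]), integer(1))
    plan <- data.frame(class = w$label,
                       rep = stats::ave(seq_len(nrow(w)), w$label,
                                        FUN = seq_along),
                       count = counts)
  }
  plan$sigma <- cfg$sigma
  plan$rate_percent <- cfg$rate_percent
  rownames(plan) <- NULL
  plan[order(plan$class, plan$rep), ]
}
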