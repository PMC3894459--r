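#' Lateral propagation delay between two channels
#'
#' The distance-dependent part of the lateral transmission delay,
#' \eqn{\Delta t = |x - y| \nu}, where \eqn{\nu} is the time taken for
#' activity to propagate between adjacent channels.
#'
#' @param x,y Channel indices (vectorized).
#' @param nu Propagation time per channel separation (ms/channel), >= 0.
#' @return Delay in ms.
#' @export
#' @examples
#' delta_t(5, 9, nu = 2)  # 8
delta_t <- function(x, y, nu) {
  if (any(nu < 0)) stop("nu must be >= 0", call. = FALSE)
  abs(x - y) * nu
}

#' Prediction parameters for the connectivity operator
#'
#' @param nu Propagation time per channel separation (ms/channel).
#' @param epsilon Pre/post coincidence half-window of the plasticity rule
#'   (ms), > 0.
#' @param d0 Fixed propagation offset (ms).  Default 0, reproducing the bare
#'   correlation operator; set it to the network's offset when comparing
#'   with simulated learning.
#' @param clip_negative Clip negative predicted strengths to 0 (efficacies
#'   are bounded below by 0); default \code{TRUE}.  Signed values are kept
#'   when \code{FALSE}.
#' @return An object of class \code{"prediction_params"}.
#' @export
prediction_params <- function(nu, epsilon, d0 = 0, clip_negative = TRUE) {
  stopifnot(nu >= 0, epsilon > 0, d0 >= 0)
  structure(list(nu = nu, epsilon = epsilon, d0 = d0,
                 clip_negative = clip_negative),
            class = "prediction_params")
}

#' Activity matrix for connectivity prediction
#'
#' @param a Channels x time matrix, non-negative (binary or graded).
#' @param dt_ms Time width of one column (ms).
#' @return An object of class \code{"activity_matrix"}.
#' @export
activity_matrix <- function(a, dt_ms = 1) {
  a <- as.matrix(a)
  if (any(a < 0)) stop("activity must be non-negative", call. = FALSE)
  stopifnot(dt_ms > 0)
  structure(list(a = a, dt_ms = dt_ms), class = "activity_matrix")
}

#' Predict post-exposure connectivity from stimulus correlations
#'
#' Analytical prediction of what the network would learn if exposed to an
#' arbitrary stimulus: the strength of connectivity between channels x
#' (source) and y (target) is the lag-specific spectro-temporal correlation
#' \deqn{C(x,y) = \sum_t \left[ A_{x,t} A_{y,\,t+\Delta t+\epsilon}
#'   - A_{x,t} A_{y,\,t+\Delta t-\epsilon} \right]}
#' with \eqn{\Delta t = d_0 + |x-y| \nu}.  The positive term rewards
#' activity in y arriving when the delayed activity from x does; the
#' negative term penalizes activity in y that precedes it, mirroring the
#' depression branch of the plasticity rule.  Time offsets are rounded to
#' the nearest column; out-of-range time indices contribute zero.  The
#' diagonal is zero (no self-channel plastic synapses).
#'
#' @param act An \code{\link{activity_matrix}} (or a bare matrix, taken at
#'   1 ms per column).
#' @param params A \code{\link{prediction_params}} object.
#' @return A channels x channels matrix \code{C[x, y]}, clipped at zero
#'   unless \code{params$clip_negative} is \code{FALSE}.
#' @export
#' @examples
#' a <- matrix(0, 12, 30); a[5, 4] <- 1; a[9, 13] <- 1
#' p <- prediction_params(nu = 2, epsilon = 1)
#' which(predict_connectivity(a, p) > 0, arr.ind = TRUE)  # (5, 9)
predict_connectivity <- function(act, params) {
  if (!inherits(act, "activity_matrix")) act <- activity_matrix(act)
  stopifnot(inherits(params, "prediction_params"))
  a <- act$a
  n <- nrow(a)
  tn <- ncol(a)
  cmat <- matrix(0, n, n)
  # all (x, y) pairs with the same |x - y| share the two lags; accumulate
  # the lagged cross-products distance by distance
  for (m in seq_len(n - 1)) {
    dtm <- params$d0 + m * params$nu
    for (sgn in c(1, -1)) {
      lag <- as.integer(round((dtm + sgn * params$epsilon) / act$dt_ms))
      s <- lagged_crossprod(a, lag)   # s[x, y] = sum_t a[x,t] a[y,t+lag]
      for (x in seq_len(n)) {
        for (y in c(x - m, x + m)) {
          if (y >= 1 && y <= n) cmat[x, y] <- cmat[x, y] + sgn * s[x, y]
        }
      }
    }
  }
  diag(cmat) <- 0
  if (params$clip_negative) cmat[cmat < 0] <- 0
  cmat
}

# sum_t a[x, t] * a[y, t + lag] for all pairs (x, y); zero outside range
lagged_crossprod <- function(a, lag) {
  tn <- ncol(a)
  if (lag >= tn || lag <= -tn) return(matrix(0, nrow(a), nrow(a)))
  if (lag >= 0) {
    t1 <- seq_len(tn - lag)
    tcrossprod(a[, t1, drop = FALSE], a[, t1 + lag, drop = FALSE])
  } else {
    t1 <- seq_len(tn + lag) - lag
    tcrossprod(a[, t1, drop = FALSE], a[, t1 + lag, drop = FALSE])
  }
}

#' Sweep the propagation time of the connectivity prediction
#'
#' One prediction per value of \eqn{\nu}, sharing \eqn{\epsilon} and
#' \eqn{d_0}: small \eqn{\nu} picks out fast (within-event) correlations,
#' large \eqn{\nu} picks out correlations at progressively longer time
#' scales such as those between successive calls.
#'
#' @param act An \code{\link{activity_matrix}} (or bare matrix).
#' @param nu_list Non-empty numeric vector of \eqn{\nu} values.
#' @param params A \code{\link{prediction_params}} whose \code{nu} is
#'   ignored in favour of each \code{nu_list} entry.
#' @return Named list of connectivity matrices (names = nu values).
#' @export
sweep_nu <- function(act, nu_list, params) {
  stopifnot(length(nu_list) > 0)
  out <- lapply(nu_list, function(nu) {
    p <- params; p$nu <- nu
    predict_connectivity(act, p)
  })
  names(out) <- as.character(nu_list)
  out
}

#' Summed connectivity mass above and below the diagonal
#'
#' In the source-by-target matrix \code{C[x, y]} the lower triangle
#' (y < x) collects downward-sweep correlations (high channels leading) and
#' the upper triangle upward ones; comparing the two masses identifies the
#' apparent sweep direction a given \eqn{\nu} would learn.
#'
#' @param cmat Connectivity matrix.
#' @return Named numeric vector with elements \code{below} and \code{above}.
#' @export
diagonal_mass <- function(cmat) {
  c(below = sum(cmat[lower.tri(cmat)]), above = sum(cmat[upper.tri(cmat)]))
}
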