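#' Deterministic stimulus fixtures
#'
#' Generates the small canonical stimuli used throughout the examples and
#' tests:
#' \describe{
#'   \item{\code{"two-dot"}}{Two unit impulses: channel 5 at an early time
#'     and channel 9 one lag later -- the minimal correlated pair.  The
#'     synapse 5 -> 9 is the one a matched propagation speed potentiates.}
#'   \item{\code{"double-sweep"}}{Two rising tones with different slopes
#'     and starting times; its predicted connectivity shows one band per
#'     sweep velocity parallel to the diagonal.}
#'   \item{\code{"chirp-train"}}{A train of identical descending chirps
#'     (channel strictly decreasing within each chirp).  At small
#'     propagation times the prediction is dominated by the within-chirp
#'     down-sweep (below-diagonal); at the inter-chirp-matched propagation
#'     time by the apparent up-sweep between the end of one chirp and the
#'     next (above-diagonal).}
#'   \item{\code{"formant-set"}}{The synthetic 7-class x 3-exemplar
#'     formant-track vocabulary (see
#'     \code{\link{synth_formant_patterns}}).}
#' }
#'
#' @param kind Fixture name.
#' @param seed Integer seed (only \code{"formant-set"} is stochastic).
#' @return \code{"formant-set"}: a pattern list; otherwise a
#'   \code{\link{stimulus_pattern}}.  Chirp-train metadata (chirp length and
#'   period in bins) is attached as attributes.
#' @export
#' @examples
#' td <- make_fixture("two-dot")
#' which(td$grid == 1, arr.ind = TRUE)
make_fixture <- function(kind = c("two-dot", "double-sweep", "chirp-train",
                                  "formant-set"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "two-dot" = {
      grid <- matrix(0, 12, 30)
      grid[5, 4] <- 1
      grid[9, 13] <- 1
      p <- stimulus_pattern(grid, bin_ms = 1, label = "two-dot")
      attr(p, "dots") <- data.frame(channel = c(5, 9), bin = c(4, 13))
      p
    },
    "double-sweep" = {
      n <- 16; tn <- 40
      grid <- matrix(0, n, tn)
      for (tcol in 1:tn) {            # slope 1 ch / 3 bins, from channel 2
        ch <- 2 + (tcol - 1) %/% 3
        if (ch <= n) grid[ch, tcol] <- 1
      }
      for (tcol in 8:tn) {            # slope 1 ch / 4 bins, starts later
        ch <- 1 + (tcol - 8) %/% 4
        if (ch <= n) grid[ch, tcol] <- 1
      }
      stimulus_pattern(grid, bin_ms = 1, label = "double-sweep")
    },
    "chirp-train" = {
      n <- 8L; chirp_len <- 8L; period <- 16L; n_chirps <- 5L
      grid <- matrix(0, n, period * n_chirps)
      for (ci in seq_len(n_chirps)) {
        t0 <- (ci - 1L) * period
        for (j in seq_len(chirp_len))     # channel 8 down to 1
          grid[n - j + 1L, t0 + j] <- 1
      }
      p <- stimulus_pattern(grid, bin_ms = 1, label = "chirp-train")
      attr(p, "chirp_len") <- chirp_len
      attr(p, "period") <- period
      p
    },
    "formant-set" = synth_formant_patterns(seed = seed)
  )
}

#' Write fixture files
#'
#' Writes the named fixture(s) as pattern files under \code{dir}.
#'
#' @param kind Fixture name, as \code{\link{make_fixture}}.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Paths written, invisibly.
#' @export
write_fixture <- function(kind, dir = ".", seed = 1L) {
  fx <- make_fixture(kind, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "formant-set") {
    paths <- character(length(fx))
    for (i in seq_along(fx)) {
      paths[i] <- file.path(dir, sprintf("formant_%s_ex%d.txt",
                                         fx[[i]]$label,
                                         (i - 1) %% 3 + 1))
      write_pattern(fx[[i]], paths[i])
    }
  } else {
    paths <- file.path(dir, paste0(kind, ".txt"))
    write_pattern(fx, paths)
  }
  invisible(paths)
}
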