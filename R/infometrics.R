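#' Empirical response distributions from a response table
#'
#' Estimates the joint structure needed by the information metrics from
#' labeled spike counts: the conditional distributions p(r | class) over the
#' observed integer-count support, a uniform class prior (the experimental
#' designs present every class equally often), the response marginal p(r),
#' and the posterior p(class | r) by Bayes' rule.  Counts are binned at
#' their raw integer values; an optional Laplace pseudo-count can regularize
#' the conditionals.
#'
#' @param tab A response table: data frame with columns \code{class} and
#'   \code{count} (non-negative integers), as produced by
#'   \code{\link{run_probe}}.
#' @param classes Class labels to use (default: sorted unique labels in
#'   \code{tab}).  Every class must have at least one row; labels in
#'   \code{tab} outside \code{classes} are an error.
#' @param pseudo Laplace pseudo-count added to every (class, response) cell
#'   (default 0, the plain empirical estimator).
#' @return An object of class \code{"response_distribution"}: list with
#'   \code{classes}, \code{support} (observed response values),
#'   \code{prior}, \code{cond} (classes x support matrix p(r | class)),
#'   \code{marginal}, \code{posterior} (classes x support, p(class | r)).
#' @export
#' @examples
#' tab <- data.frame(class = rep(c("A", "B"), each = 3),
#'                   count = c(1, 1, 2, 2, 2, 2))
#' d <- estimate_distributions(tab)
#' d$cond["A", "2"]       # 1/3
#' d$posterior["A", "2"]  # 1/4
estimate_distributions <- function(tab, classes = NULL, pseudo = 0) {
  stopifnot(is.data.frame(tab), all(c("class", "count") %in% names(tab)),
            pseudo >= 0)
  tab$class <- as.character(tab$class)
  if (is.null(classes)) classes <- sort(unique(tab$class))
  if (!all(tab$class %in% classes))
    stop("response table contains labels outside `classes`: ",
         paste(setdiff(tab$class, classes), collapse = ", "), call. = FALSE)
  if (!all(classes %in% tab$class))
    stop("every class needs at least one observation", call. = FALSE)
  support <- sort(unique(tab$count))
  counts <- table(factor(tab$class, levels = classes),
                  factor(tab$count, levels = support))
  counts <- matrix(as.numeric(counts), nrow = length(classes),
                   dimnames = list(classes, as.character(support)))
  counts <- counts + pseudo
  cond <- counts / rowSums(counts)
  prior <- rep(1 / length(classes), length(classes))
  names(prior) <- classes
  marginal <- as.numeric(prior %*% cond)
  names(marginal) <- colnames(cond)
  posterior <- (prior * cond) / rep(marginal, each = length(classes))
  structure(list(classes = classes, support = support, prior = prior,
                 cond = cond, marginal = marginal, posterior = posterior),
            class = "response_distribution")
}

#' @export
print.response_distribution <- function(x, ...) {
  cat(sprintf("Response distribution: %d classes, %d response values\n",
              length(x$classes), length(x$support)))
  invisible(x)
}

# entropy helper with the 0 log 0 = 0 convention
plogp <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

#' Specific information of a response
#'
#' The reduction in uncertainty about the stimulus class gained by observing
#' the response value r:
#' \deqn{i_{sp}(r) = -\sum_\Theta p(\Theta)\log_2 p(\Theta)
#'   + \sum_\Theta p(\Theta|r)\log_2 p(\Theta|r)}
#' High for unambiguous responses (posterior concentrated on few classes),
#' zero when the posterior equals the prior.  For K equiprobable classes it
#' is bounded by \eqn{\log_2 K}.
#'
#' @param d A \code{\link{estimate_distributions}} result.
#' @param r A response value in the support (vectorized).
#' @return Specific information in bits.
#' @export
specific_information <- function(d, r) {
  stopifnot(inherits(d, "response_distribution"))
  j <- match(r, d$support)
  if (anyNA(j))
    stop("response value not in the observed support: ",
         paste(r[is.na(j)], collapse = ", "), call. = FALSE)
  h_prior <- -sum(plogp(d$prior))
  vapply(j, function(jj) h_prior + sum(plogp(d$posterior[, jj])),
         numeric(1))
}

#' Stimulus-specific information
#'
#' The average specific information of the responses that occur when a
#' particular stimulus class is presented:
#' \deqn{i_{SSI}(\Theta) = \sum_r p(r|\Theta)\, i_{sp}(r)}
#' A classifier-free acuity measure: it is maximal (\eqn{\log_2 K} for K
#' equiprobable classes) when responses are perfectly diagnostic, and zero
#' when responses carry no class information.
#'
#' @param d A \code{\link{estimate_distributions}} result.
#' @param theta Class label(s); default all classes.
#' @return Named vector of SSI values in bits.
#' @export
#' @examples
#' tab <- data.frame(class = rep(c("a", "b"), each = 5),
#'                   count = rep(c(3, 7), each = 5))
#' ssi(estimate_distributions(tab))  # 1 bit each: perfectly diagnostic
ssi <- function(d, theta = d$classes) {
  stopifnot(inherits(d, "response_distribution"))
  if (!all(theta %in% d$classes))
    stop("unknown class label", call. = FALSE)
  isp <- specific_information(d, d$support)
  out <- vapply(theta, function(th) sum(d$cond[th, ] * isp), numeric(1))
  names(out) <- theta
  out
}

#' ROC curve and AUC from spike counts
#'
#' Treats the network output as a binary detector for the exposure-stimulus
#' class: a presentation is called a target when its spike count is at or
#' above a detection threshold (higher count = more target-like).  Sweeping
#' the threshold over all values traces the ROC curve, the false positive
#' rate FPR = FP/(FP+TN) against the true positive rate TPR = TP/(TP+FN);
#' the area under it (trapezoid summation) summarizes discriminability:
#' 0.5 is chance, 1.0 a perfect classifier at all thresholds.
#'
#' @param target_counts Spike counts of target-class presentations.
#' @param nontarget_counts Spike counts of all other presentations.
#' @return An object of class \code{"roc_curve"}: data frame \code{points}
#'   with columns \code{threshold}, \code{fpr}, \code{tpr} (from (0,0) to
#'   (1,1)), and scalar \code{auc}.
#' @export
#' @examples
#' roc(c(2, 3), c(1, 2))$auc  # 0.875
roc <- function(target_counts, nontarget_counts) {
  stopifnot(length(target_counts) > 0, length(nontarget_counts) > 0)
  thr <- sort(unique(c(target_counts, nontarget_counts)))
  # threshold above every count first (0,0), then descending to (1,1)
  thr <- c(Inf, rev(thr))
  tpr <- vapply(thr, function(h) mean(target_counts >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(nontarget_counts >= h), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' AUC of the exposure class against all others in a response table
#'
#' Convenience wrapper around \code{\link{roc}} for the keyword-spotting
#' reading of a probe: counts of the exposure class are targets, counts of
#' every other class are non-targets.
#'
#' @param tab Response table (columns \code{class}, \code{count}).
#' @param target Exposure-class label.
#' @return The scalar AUC.
#' @export
auc_target_vs_rest <- function(tab, target) {
  stopifnot(target %in% tab$class)
  roc(tab$count[tab$class == target],
      tab$count[tab$class != target])$auc
}
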