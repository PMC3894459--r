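test_that("distribution estimation performs textbook Bayes on counts", {
  tab <- data.frame(class = rep(c("A", "B"), each = 3),
                    count = c(1, 1, 2, 2, 2, 2))
  d <- estimate_distributions(tab)
  expect_equal(unname(d$cond["A", "2"]), 1 / 3)
  expect_equal(unname(d$posterior["A", "2"]), 1 / 4)
  expect_equal(unname(colSums(d$posterior)), rep(1, 2))
  expect_equal(sum(d$marginal), 1)
  # identical responses: posterior equals prior
  same <- data.frame(class = c("A", "B"), count = c(4, 4))
  ds <- estimate_distributions(same)
  expect_equal(unname(ds$posterior[, "4"]), unname(ds$prior))
  # disjoint responses: point-mass posteriors
  dd <- estimate_distributions(data.frame(class = c("A", "B"),
                                          count = c(3, 7)))
  expect_equal(unname(dd$posterior[, "3"]), c(1, 0))
  expect_error(estimate_distributions(tab, classes = "A"), "outside")
})

test_that("specific information matches direct evaluation of the two sums", {
  # posterior (2/3, 1/3) over two equiprobable classes: p(r=2|A) = 2/3,
  # p(r=2|B) = 1/3
  tab <- data.frame(class = rep(c("A", "B"), each = 3),
                    count = c(2, 2, 1, 2, 1, 1))
  d <- estimate_distributions(tab)
  expect_equal(unname(d$posterior[, "2"]), c(2 / 3, 1 / 3))
  expect_equal(specific_information(d, 2),
               1 + (2 / 3) * log2(2 / 3) + (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)
  expect_equal(specific_information(d, 2), 0.0817, tolerance = 1e-3)
  # point-mass posterior over 10 equiprobable classes gives log2(10)
  tab10 <- data.frame(class = paste0("c", 1:10), count = 1:10)
  d10 <- estimate_distributions(tab10)
  expect_equal(specific_information(d10, 5), log2(10), tolerance = 1e-12)
  # posterior equal to prior gives zero bits
  ds <- estimate_distributions(data.frame(class = c("A", "B"),
                                          count = c(4, 4)))
  expect_equal(specific_information(ds, 4), 0)
  expect_error(specific_information(d, 99), "support")
})

test_that("SSI averages specific information under p(r|class)", {
  # class1 always 1; class2 responds 1 or 2 equally
  tab <- data.frame(class = c("c1", "c1", "c2", "c2"),
                    count = c(1, 1, 1, 2))
  d <- estimate_distributions(tab)
  isp1 <- 1 + (2 / 3) * log2(2 / 3) + (1 / 3) * log2(1 / 3)
  expect_equal(unname(ssi(d, "c2")), 0.5 * isp1 + 0.5 * 1, tolerance = 1e-12)
  expect_equal(unname(ssi(d, "c2")), 0.541, tolerance = 1e-3)
  # class-independent responses carry zero bits
  flat <- data.frame(class = rep(c("a", "b", "c"), each = 4),
                     count = rep(c(1, 5, 9, 11), times = 3))
  expect_equal(unname(ssi(estimate_distributions(flat))), rep(0, 3))
})

test_that("SSI and specific information agree with an independent hand oracle", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    nr <- sample(2:6, 1)
    # random integer count table (each class observed at least once)
    m <- matrix(sample(0:9, k * nr, replace = TRUE), k)
    m[, 1] <- m[, 1] + 1L
    tab <- data.frame(
      class = rep(rep(paste0("c", seq_len(k)), times = nr), times = as.vector(m)),
      count = rep(rep(seq_len(nr), each = k), times = as.vector(m)))
    d <- estimate_distributions(tab)
    oracle <- hand_info(d$cond)
    expect_equal(unname(specific_information(d, d$support)), oracle$isp,
                 tolerance = 1e-12)
    expect_equal(unname(ssi(d)), oracle$ssi, tolerance = 1e-12)
    # non-negativity and the log2(K) bound
    expect_true(all(oracle$ssi >= -1e-12))
    expect_true(all(specific_information(d, d$support) >= -1e-12))
    expect_true(all(ssi(d) <= log2(k) + 1e-12))
  }
})

test_that("SSI is invariant to relabeling response values", {
  tab <- data.frame(class = rep(c("a", "b"), each = 6),
                    count = c(0, 0, 1, 1, 2, 2, 1, 2, 2, 3, 3, 3))
  d1 <- estimate_distributions(tab)
  tab2 <- tab
  tab2$count <- match(tab$count, sort(unique(tab$count))) * 100
  d2 <- estimate_distributions(tab2)
  expect_equal(unname(ssi(d1)), unname(ssi(d2)))
})

test_that("ROC endpoints, monotonicity and canonical AUC values", {
  r <- roc(c(2, 3), c(1, 2))
  expect_equal(r$auc, 0.875)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # identical distributions are chance; disjoint supports are perfect
  expect_equal(roc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(roc(c(5, 6, 9), c(1, 2, 4))$auc, 1.0)
})

test_that("trapezoid AUC equals the Mann-Whitney statistic with tie credit", {
  set.seed(7)
  for (i in 1:200) {
    t <- sample(0:12, sample(3:25, 1), replace = TRUE)
    n <- sample(0:12, sample(3:25, 1), replace = TRUE)
    expect_equal(roc(t, n)$auc, mw_auc(t, n))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    t <- sample(0:15, 30, replace = TRUE) + sample(0:3, 30, replace = TRUE)
    n <- sample(0:15, 30, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(length(t), length(n))),
      predictor = c(t, n), quiet = TRUE, direction = "<")))
    expect_equal(roc(t, n)$auc, ref)
  }
})
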