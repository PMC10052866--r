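test_that("signal series join indices with future abruptness", {
  # constant community: all labels negative, join covers the overlap days
  tab <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = rep(1:30, 2),
    taxon = rep(c("A", "B"), each = 30), abundance = rep(c(2, 1), each = 30)))
  ab <- abruptness_series(tab, p = 7)
  idx <- tibble::tibble(treatment = "t", replicate = "R1", day = 1:30,
                        gap = runif(30))
  ss <- build_signal_series(idx, ab, p = 7)
  expect_true(all(!ss$is_abrupt))
  expect_equal(sort(ss$day), sort(intersect(1:30, ab$t)))
  # QC-excluded days are dropped from the pairing
  ss2 <- build_signal_series(idx, ab, p = 7,
                             qc_exclude = tibble::tibble(
                               treatment = "t", replicate = "R1", day = 10))
  expect_false(10 %in% ss2$day)
  expect_error(build_signal_series(idx[0, ], ab, p = 7), "overlap|index")
})

test_that("per-replicate regressions with BH control behave as expected", {
  set.seed(19)
  mk <- function(rep_id, value, abrupt) tibble::tibble(
    treatment = "t", replicate = rep_id, day = seq_along(value),
    index = "gap", value = value, abruptness = abrupt,
    is_abrupt = abrupt > 0.5)
  v <- runif(30)
  series <- dplyr::bind_rows(
    mk("R1", v, v),                      # index equals abruptness exactly
    mk("R2", runif(30), runif(30)),      # unrelated
    mk("R3", rep(1, 30), runif(30)))     # zero-variance index
  res <- regress_signal(series)
  r1 <- res[res$replicate == "R1", ]
  expect_equal(r1$slope, 1, tolerance = 1e-8)
  expect_lt(r1$p_value, 1e-10)
  expect_true(r1$significant)
  expect_true(is.na(res$slope[res$replicate == "R3"]))
  # all p-values 1: nothing significant after adjustment
  flat <- dplyr::bind_rows(lapply(1:4, function(i)
    mk(paste0("F", i), c(1, 2, 3), c(0.2, 0.2, 0.2))))
  resf <- regress_signal(flat)
  expect_true(all(!resf$significant | is.na(resf$significant)))
})

test_that("ROC analysis equals the pairwise-comparison statistic", {
  # perfect separation: AUC exactly 1, threshold in the separating gap
  rc <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_identical(rc$auc, 1)
  expect_equal(rc$youden_threshold, 6.5)
  expect_equal(rc$youden_j, 1)
  # label-independent scores: AUC near one half
  set.seed(20)
  rc2 <- roc_analysis(rnorm(2000), runif(2000) < 0.5)
  expect_lt(abs(rc2$auc - 0.5), 0.05)
  # exhaustive pairwise oracle on random instances, with ties
  for (i in 1:40) {
    n <- sample(6:200, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    rc3 <- roc_analysis(scores, labels)
    pos <- scores[labels]
    neg <- scores[!labels]
    u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(rc3$auc, u, tolerance = 1e-12)
  }
})

test_that("ROC is invariant to monotone transforms and flips with labels", {
  set.seed(21)
  scores <- rnorm(100)
  labels <- runif(100) < 0.3 + 0.4 * (scores > 0)
  if (!any(labels)) labels[1] <- TRUE
  a0 <- roc_analysis(scores, labels)$auc
  expect_equal(roc_analysis(exp(scores), labels)$auc, a0)
  expect_equal(roc_analysis(qnorm(pnorm(scores)), labels)$auc, a0,
               tolerance = 1e-10)
  expect_equal(roc_analysis(scores, !labels)$auc, 1 - a0)
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(150)
  labels <- runif(150) < plogis(scores)
  a <- roc_analysis(scores, labels)$auc
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the Youden threshold beats every alternative cutoff", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), 1)
    labels <- runif(n) < plogis(2 * scores)
    if (!any(labels) || all(labels)) next
    rc <- roc_analysis(scores, labels)
    thr <- youden_threshold(rc)
    jfun <- function(th) {
      sens <- sum(scores >= th & labels) / sum(labels)
      spec <- sum(scores < th & !labels) / sum(!labels)
      sens + spec - 1
    }
    cands <- c(sort(unique(scores)), sort(unique(scores)) - 0.05,
               max(scores) + 1)
    expect_true(all(jfun(thr) >= vapply(cands, jfun, numeric(1)) - 1e-12))
  }
})

test_that("single-class labels are rejected with class counts", {
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "0 negative")
  expect_error(roc_analysis(1:5, rep(FALSE, 5)), "0 positive")
})

test_that("pooling treatments reproduces and interpolates thresholds", {
  set.seed(24)
  mk <- function(trt, n) {
    sc <- c(rnorm(n, 0), rnorm(n, 2))
    tibble::tibble(treatment = trt, replicate = "R1", day = seq_len(2 * n),
                   index = "sse", value = sc,
                   abruptness = rep(c(0.2, 0.8), each = n),
                   is_abrupt = rep(c(FALSE, TRUE), each = n))
  }
  a <- mk("A", 150)
  b <- mk("B", 150)
  both <- dplyr::bind_rows(a, b)
  pa <- pooled_threshold(a, "sse")
  pb <- pooled_threshold(b, "sse")
  pab <- pooled_threshold(both, "sse")
  # identically distributed treatments give a similar pooled threshold
  expect_lt(abs(pab$threshold - pa$threshold), 0.5)
  # pooled AUC lies between (or at) the per-treatment AUCs
  expect_gte(pab$auc, min(pa$auc, pb$auc) - 0.02)
  expect_lte(pab$auc, max(pa$auc, pb$auc) + 0.02)
  # the pooled threshold applied back matches the pooled ROC point
  th <- pab$threshold
  sens <- sum(both$value >= th & both$is_abrupt) / sum(both$is_abrupt)
  k <- which(pab$curve$thresholds == th)
  expect_equal(pab$curve$sensitivity[k], sens)
})
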