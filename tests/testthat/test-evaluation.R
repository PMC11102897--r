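test_that("classification metrics reproduce the constant-classifier results", {
  truth <- rep(lesion_classes(), table1_test_counts())
  constant_nv <- rep("NV", length(truth))
  m <- classification_metrics(constant_nv, truth)
  expect_equal(m$accuracy, 908 / 1511)
  expect_equal(round_half_up(100 * m$accuracy, 1), 60.1)
  expect_equal(m$balanced_accuracy, 1 / 7)
  expect_equal(unname(m$per_class_sensitivity["NV"]), 1)
  expect_equal(sum(m$per_class_sensitivity == 0), 6L)

  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(unname(perfect$per_class_sensitivity), rep(1, 7))

  expect_error(classification_metrics(character(0), character(0)), "empty")
  expect_warning(classification_metrics(c("NV", "MEL"), c("NV", "MEL")),
                 "absent")
})

test_that("constant-classifier accuracy equals its class prevalence", {
  set.seed(3)
  for (rep in 1:4) {
    counts <- stats::rmultinom(1, 300, stats::rgamma(7, 2))[, 1] + 1L
    truth <- rep(lesion_classes(), counts)
    cls <- sample(lesion_classes(), 1)
    m <- suppressWarnings(classification_metrics(rep(cls, length(truth)),
                                                 truth))
    expect_equal(m$accuracy, counts[match(cls, lesion_classes())] / sum(counts))
    expect_equal(m$balanced_accuracy, 1 / 7)
  }
})

test_that("roc_auc_binary is the tie-corrected pairwise statistic", {
  expect_equal(roc_auc_binary(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc_binary(rep(1.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(roc_auc_binary(1:3, c(TRUE, TRUE, TRUE)), "undefined")

  # exhaustive pairwise oracle on random instances with ties
  set.seed(19)
  for (rep in 1:10) {
    n <- 20
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    pairs <- expand.grid(p = which(labels), n = which(!labels))
    oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                          ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
    expect_equal(roc_auc_binary(scores, labels), oracle)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(23)
  scores <- stats::rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, TRUE)
  base <- roc_auc_binary(scores, labels)
  expect_equal(roc_auc_binary(exp(scores), labels), base)
  expect_equal(roc_auc_binary(3 * scores - 10, labels), base)
})

test_that("roc_metrics composes one-vs-rest AUCs and the malignant sum", {
  classes <- lesion_classes()
  set.seed(29)
  n <- 30
  truth <- sample(classes, n, TRUE)
  while (length(unique(truth)) < 7) truth <- sample(classes, n, TRUE)

  # perfect one-hot scores
  S1 <- matrix(0, n, 7); S1[cbind(seq_len(n), match(truth, classes))] <- 1
  r1 <- roc_metrics(S1, truth)
  expect_equal(r1$mean_roc_auc, 1.0)
  expect_equal(r1$malignant_roc_auc, 1.0)

  # identical score vectors: everything 0.5
  S2 <- matrix(rep(stats::rnorm(7), each = n), n, 7)
  r2 <- roc_metrics(S2, truth)
  expect_equal(r2$mean_roc_auc, 0.5)
  expect_equal(r2$malignant_roc_auc, 0.5)

  # compositional oracle: each one-vs-rest AUC equals roc_auc_binary by hand
  S3 <- matrix(stats::rnorm(n * 7), n, 7)
  r3 <- roc_metrics(S3, truth)
  per <- vapply(1:7, function(k)
    roc_auc_binary(S3[, k], truth == classes[k]), numeric(1))
  expect_equal(unname(r3$per_class_auc), per)
  expect_equal(r3$mean_roc_auc, mean(per))
  w_cancer <- rowSums(S3[, match(malignant_classes(), classes)])
  expect_equal(r3$malignant_roc_auc,
               roc_auc_binary(w_cancer, truth %in% malignant_classes()))
  expect_equal(r3$nonmalignant_score_sum,
               rowSums(S3[, -match(malignant_classes(), classes)]))
})

test_that("disagreement rate is a pseudo-metric with exact counting", {
  a <- rep("NV", 50)
  expect_equal(disagreement_rate(a, a), 0)
  b <- a; b[c(3, 17, 42)] <- "MEL"
  expect_equal(disagreement_rate(a, b), 0.06)
  expect_error(disagreement_rate(a, b[-1]), "misaligned")

  set.seed(37)
  algs <- lapply(1:3, function(i) sample(lesion_classes(), 40, TRUE))
  names(algs) <- c("x", "y", "z")
  m <- disagreement_matrix(algs)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m, t(m))
  # triangle inequality
  expect_lte(m["x", "z"], m["x", "y"] + m["y", "z"])
  expect_lte(m["x", "y"], m["x", "z"] + m["z", "y"])
})

test_that("bootstrap_ci_difference behaves on degenerate and aligned input", {
  set.seed(41)
  truth <- sample(lesion_classes(), 120, TRUE,
                  prob = c(1, 1.5, 2, 1, 2, 5, 1))
  while (length(unique(truth)) < 7) truth <- sample(lesion_classes(), 120, TRUE)
  dec <- ifelse(stats::runif(120) < 0.7, truth,
                sample(lesion_classes(), 120, TRUE))
  oc <- list(decisions = dec, truths = truth)

  # identical algorithms: difference 0, CI [0, 0]
  r <- bootstrap_ci_difference(oc, oc, "accuracy", n_boot = 200, seed = 2)
  expect_equal(r$difference, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(0, 0))

  # deterministic given seed
  oc2 <- list(decisions = sample(dec), truths = truth)
  r1 <- bootstrap_ci_difference(oc, oc2, "balanced_accuracy", n_boot = 300,
                                seed = 7)
  r2 <- bootstrap_ci_difference(oc, oc2, "balanced_accuracy", n_boot = 300,
                                seed = 7)
  expect_equal(r1$ci_low, r2$ci_low)
  expect_equal(r1$ci_high, r2$ci_high)

  expect_error(bootstrap_ci_difference(
    oc, list(decisions = dec, truths = rev(truth)), "accuracy",
    n_boot = 100), "misaligned")
})

test_that("bootstrap endpoints stabilize as n_boot grows", {
  set.seed(43)
  n <- 200
  truth <- sample(lesion_classes(), n, TRUE)
  mk <- function(p) list(
    decisions = ifelse(stats::runif(n) < p, truth,
                       sample(lesion_classes(), n, TRUE)),
    truths = truth)
  a <- mk(0.8); b <- mk(0.7)
  ends <- function(n_boot, seeds) vapply(seeds, function(s) {
    r <- bootstrap_ci_difference(a, b, "accuracy", n_boot = n_boot, seed = s)
    r$ci_high
  }, numeric(1))
  spread_small <- stats::sd(ends(100, 1:6))
  spread_large <- stats::sd(ends(4000, 1:6))
  expect_lt(spread_large, spread_small)
})

test_that("crowd_size_curve is exhaustive at full size and calibrated at n=1", {
  set.seed(47)
  classes <- lesion_classes()
  a <- 0.65
  ids <- sprintf("p%d", 1:30)
  pr <- manual_profiles(stats::setNames(rep(a, 30), ids))
  n_img <- 120
  rows <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    truth <- sample(classes, 1)
    k <- 10
    who <- sample(ids, k)
    resp <- ifelse(stats::runif(k) < a, truth, sample(setdiff(classes, truth), k, TRUE))
    data.frame(participant_id = who, image_id = sprintf("img%03d", i),
               split = "test", true_label = truth, response = resp,
               response_time_s = 5, day = 1L)
  }))
  tab <- decision_table(rows)
  cfg <- aggregation_config("SV", tie_break = "lexicographic")
  curve <- crowd_size_curve(tab, list(1, "ALL"), cfg, pr, reps = 20, seed = 9)

  # full crowd: zero sampling variance and equal to the direct aggregate
  full <- curve[curve$size == "ALL" & curve$metric == "accuracy", ]
  sw <- run_switchboard(tab, list(cfg), pr)
  direct <- mean(sw$decisions$decision == sw$decisions$true_label)
  expect_equal(full$mean, direct)
  expect_true(is.na(full$sd) || full$sd == 0)

  # n = 1 on a homogeneous crowd with accuracy a: mean accuracy ~ a
  one <- curve[curve$size == "1" & curve$metric == "accuracy", ]
  mc_se <- stats::sd(c(one$ci_low, one$ci_high)) # crude scale guard
  se <- sqrt(a * (1 - a) / n_img) / sqrt(20) + 1e-9
  expect_lt(abs(one$mean - a), max(2 * sqrt(a * (1 - a) / n_img), 4 * se))
})
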