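#' Accuracy, per-class sensitivity and balanced accuracy
#'
#' Accuracy is the fraction of images the crowd labels correctly. Sensitivity
#' for class T is TP_T / (TP_T + FN_T); balanced accuracy is the unweighted
#' mean of the sensitivities over the classes present in the truth (absent
#' classes are excluded with a warning).
#'
#' @param decisions per-image crowd decisions (class labels).
#' @param truths per-image true labels, aligned with `decisions`.
#' @return list with `accuracy`, `balanced_accuracy`, `per_class_sensitivity`
#'   (named 7-vector, NA for absent classes), `n_images`.
#' @export
classification_metrics <- function(decisions, truths) {
  n <- length(truths)
  if (n == 0) stop("empty input: no images to score", call. = FALSE)
  stopifnot(length(decisions) == n)
  classes <- lesion_classes()
  tr <- factor(truths, levels = classes)
  correct <- as.character(decisions) == as.character(truths)
  per_class <- as.numeric(tapply(correct, tr, mean))
  names(per_class) <- classes
  absent <- classes[is.na(per_class)]
  if (length(absent) > 0) {
    warning("class(es) absent from truth excluded from balanced accuracy: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  list(accuracy = mean(correct),
       balanced_accuracy = mean(per_class, na.rm = TRUE),
       per_class_sensitivity = per_class,
       n_images = n)
}

#' Binary ROC-AUC as the tie-corrected rank statistic
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg), computed via
#' mid-ranks (the Mann-Whitney statistic).
#'
#' @param scores per-image real-valued scores.
#' @param labels logical (TRUE = positive) or two-level vector aligned with
#'   `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc_binary <- function(scores, labels) {
  pos <- as.logical(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined AUC: need at least one positive and one negative label",
         call. = FALSE)
  }
  r <- data.table::frank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# internal, no checks: used inside bootstrap loops
auc_fast <- function(scores, pos, n_pos, n_neg) {
  r <- data.table::frank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# weighted AUC on a pre-sorted score column: a bootstrap resample enters as
# per-item multiplicities, so each resampled AUC costs two cumsums instead of
# a fresh ranking. Identical to the mid-rank AUC of the resampled multiset.
presort_scores <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  ends <- which(c(xs[-1] != xs[-n], TRUE))  # last index of each tie group
  list(ord = ord, ends = ends)
}

weighted_auc <- function(pre, w_pos, w_neg) {
  cp <- cumsum(w_pos[pre$ord])[pre$ends]
  cn <- cumsum(w_neg[pre$ord])[pre$ends]
  g <- length(pre$ends)
  gp <- cp - c(0, cp[-g])
  gn <- cn - c(0, cn[-g])
  below <- c(0, cn[-g])
  total_p <- cp[g]
  total_n <- cn[g]
  sum(gp * (below + 0.5 * gn)) / (total_p * total_n)
}

#' Mean one-vs-rest ROC-AUC and malignant ROC-AUC from class scores
#'
#' The mean ROC-AUC is the unweighted mean of the seven one-vs-rest AUCs,
#' each using the class score w_T as the ranking score. The malignant ROC-AUC
#' scores each image by the literal sum w_AKIEC + w_BCC + w_MEL against
#' truth-malignancy; `use_posterior = TRUE` substitutes the softmax-posterior
#' sum P(AKIEC) + P(BCC) + P(MEL) (log-probability scale only).
#'
#' @param score_matrix images x 7 matrix of class scores (columns in
#'   [lesion_classes()] order).
#' @param truths per-image true labels.
#' @param use_posterior convert log-probability scores to posteriors first.
#' @return list with `mean_roc_auc`, `malignant_roc_auc`,
#'   `nonmalignant_score_sum` (the complementary w_non-cancer sums),
#'   `per_class_auc`.
#' @export
roc_metrics <- function(score_matrix, truths, use_posterior = FALSE) {
  classes <- lesion_classes()
  stopifnot(ncol(score_matrix) == 7, nrow(score_matrix) == length(truths))
  S <- score_matrix
  if (use_posterior) S <- posterior_probabilities(score_matrix)
  truths <- as.character(truths)
  per_class <- rep(NA_real_, 7)
  names(per_class) <- classes
  for (k in seq_len(7)) {
    pos <- truths == classes[k]
    if (any(pos) && any(!pos)) {
      per_class[k] <- roc_auc_binary(S[, k], pos)
    }
  }
  if (anyNA(per_class)) {
    warning("class(es) absent from truth skipped in mean ROC-AUC: ",
            paste(classes[is.na(per_class)], collapse = ", "), call. = FALSE)
  }
  mal_cols <- match(malignant_classes(), classes)
  w_cancer <- rowSums(S[, mal_cols, drop = FALSE])
  w_noncancer <- rowSums(S[, -mal_cols, drop = FALSE])
  is_mal <- truths %in% malignant_classes()
  malignant_auc <- if (any(is_mal) && any(!is_mal)) {
    roc_auc_binary(w_cancer, is_mal)
  } else NA_real_
  list(mean_roc_auc = mean(per_class, na.rm = TRUE),
       malignant_roc_auc = malignant_auc,
       nonmalignant_score_sum = w_noncancer,
       per_class_auc = per_class)
}

#' Full four-metric report for one set of crowd decisions
#'
#' @param decisions per-image crowd decisions.
#' @param truths aligned true labels.
#' @param scores optional images x 7 score matrix; the two ROC metrics are NA
#'   without it.
#' @param use_posterior passed to [roc_metrics()].
#' @return A `metric_report` list: accuracy, balanced_accuracy,
#'   per_class_sensitivity, mean_roc_auc, malignant_roc_auc, n_images.
#' @export
metric_report <- function(decisions, truths, scores = NULL,
                          use_posterior = FALSE) {
  cm <- classification_metrics(decisions, truths)
  if (!is.null(scores)) {
    rm_ <- roc_metrics(scores, truths, use_posterior = use_posterior)
    cm$mean_roc_auc <- rm_$mean_roc_auc
    cm$malignant_roc_auc <- rm_$malignant_roc_auc
  } else {
    cm$mean_roc_auc <- NA_real_
    cm$malignant_roc_auc <- NA_real_
  }
  class(cm) <- "metric_report"
  cm
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metrics on %d images: accuracy %.1f%%, balanced accuracy %.1f%%, mean ROC-AUC %s, malignant ROC-AUC %s\n",
    x$n_images, 100 * x$accuracy, 100 * x$balanced_accuracy,
    ifelse(is.na(x$mean_roc_auc), "NA", sprintf("%.3f", x$mean_roc_auc)),
    ifelse(is.na(x$malignant_roc_auc), "NA",
           sprintf("%.3f", x$malignant_roc_auc))))
  invisible(x)
}

#' Inter-algorithm disagreement rate
#'
#' Fraction of images on which two label assignments differ. Inputs must be
#' aligned; if both carry names, alignment is checked on them.
#'
#' @param decisions_a,decisions_b per-image labels from two algorithms.
#' @return proportion in \[0, 1\].
#' @export
disagreement_rate <- function(decisions_a, decisions_b) {
  if (length(decisions_a) != length(decisions_b)) {
    stop("misaligned image sets: lengths differ", call. = FALSE)
  }
  na <- names(decisions_a); nb <- names(decisions_b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    if (!setequal(na, nb)) stop("misaligned image sets: names differ",
                                call. = FALSE)
    decisions_b <- decisions_b[na]
  }
  mean(as.character(decisions_a) != as.character(decisions_b))
}

#' Pairwise disagreement matrix over several algorithms
#'
#' @param decision_list named list of aligned per-image label vectors.
#' @return symmetric matrix of disagreement rates with zero diagonal.
#' @export
disagreement_matrix <- function(decision_list) {
  stopifnot(length(decision_list) >= 2)
  k <- length(decision_list)
  m <- matrix(0, k, k, dimnames = list(names(decision_list),
                                       names(decision_list)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- disagreement_rate(decision_list[[i]],
                                              decision_list[[j]])
    }
  }
  m
}

metric_value <- function(metric, decisions, truths, scores) {
  switch(metric,
    accuracy = mean(as.character(decisions) == as.character(truths)),
    balanced_accuracy =
      classification_metrics(decisions, truths)$balanced_accuracy,
    mean_roc_auc = roc_metrics(scores, truths)$mean_roc_auc,
    malignant_roc_auc = roc_metrics(scores, truths)$malignant_roc_auc,
    stop("unknown metric: ", metric, call. = FALSE))
}

resample_defined <- function(metric, truths_r) {
  if (metric == "accuracy") return(TRUE)
  if (metric == "malignant_roc_auc") {
    is_mal <- truths_r %in% malignant_classes()
    return(any(is_mal) && any(!is_mal))
  }
  # balanced accuracy / mean ROC-AUC need every class present
  all(lesion_classes() %in% truths_r)
}

#' Bootstrap confidence interval for the difference between two algorithms
#'
#' Resamples image ids with replacement, recomputes the metric for both
#' algorithms on each resample, and reports percentile 2.5/97.5 bounds of the
#' difference (a - b). Resamples on which the metric is undefined (a class
#' missing from the resampled truth) are redrawn, with the redraw count
#' logged. Deterministic given `seed`.
#'
#' @param outcomes_a,outcomes_b per-image outcomes for the two algorithms:
#'   lists with `decisions`, `truths`, and (for the ROC metrics) `scores`
#'   (images x 7 matrix), aligned on the same image set.
#' @param metric one of "accuracy", "balanced_accuracy", "mean_roc_auc",
#'   "malignant_roc_auc".
#' @param n_boot number of bootstrap resamples (>= 100; default 10,000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return A `comparison_result`: metric, point difference (a - b), ci_low,
#'   ci_high, n_boot, n_redrawn, seed.
#' @export
bootstrap_ci_difference <- function(outcomes_a, outcomes_b, metric,
                                    n_boot = 10000, seed = 1L, level = 0.95) {
  stopifnot(n_boot >= 100)
  truths <- as.character(outcomes_a$truths)
  if (!identical(truths, as.character(outcomes_b$truths))) {
    stop("misaligned image sets: the two algorithms must share truths",
         call. = FALSE)
  }
  n <- length(truths)
  da <- as.character(outcomes_a$decisions)
  db <- as.character(outcomes_b$decisions)
  sa <- outcomes_a$scores; sb <- outcomes_b$scores
  needs_scores <- metric %in% c("mean_roc_auc", "malignant_roc_auc")
  if (needs_scores && (is.null(sa) || is.null(sb))) {
    stop("metric ", metric, " needs per-image score matrices", call. = FALSE)
  }
  point <- metric_value(metric, da, truths, sa) -
    metric_value(metric, db, truths, sb)

  # precomputed fast paths: the generic metric_value() is far too slow to
  # call 2 x n_boot times at n_boot = 10,000
  classes <- lesion_classes()
  ti <- match(truths, classes)
  mal_flag <- classes %in% malignant_classes()
  ca <- da == truths
  cb <- db == truths
  present <- sort(unique(ti))
  if (metric == "malignant_roc_auc") {
    mal_cols <- which(mal_flag)
    pre_a <- list(presort_scores(rowSums(sa[, mal_cols, drop = FALSE])))
    pre_b <- list(presort_scores(rowSums(sb[, mal_cols, drop = FALSE])))
    pos_mal <- mal_flag[ti]
  } else if (metric == "mean_roc_auc") {
    pre_a <- lapply(present, function(k) presort_scores(sa[, k]))
    pre_b <- lapply(present, function(k) presort_scores(sb[, k]))
    pos_class <- lapply(present, function(k) ti == k)
  }
  boot_stat <- function(idx) {
    tidx <- ti[idx]
    switch(metric,
      accuracy = mean(ca[idx]) - mean(cb[idx]),
      balanced_accuracy = {
        tot <- tabulate(tidx, 7)[present]
        mean(tabulate(tidx[ca[idx]], 7)[present] / tot) -
          mean(tabulate(tidx[cb[idx]], 7)[present] / tot)
      },
      mean_roc_auc = {
        w <- tabulate(idx, n)
        aa <- ab <- numeric(length(present))
        for (m_ in seq_along(present)) {
          wp <- w * pos_class[[m_]]
          wn <- w - wp
          aa[m_] <- weighted_auc(pre_a[[m_]], wp, wn)
          ab[m_] <- weighted_auc(pre_b[[m_]], wp, wn)
        }
        mean(aa) - mean(ab)
      },
      malignant_roc_auc = {
        w <- tabulate(idx, n)
        wp <- w * pos_mal
        wn <- w - wp
        weighted_auc(pre_a[[1]], wp, wn) - weighted_auc(pre_b[[1]], wp, wn)
      })
  }
  resample_ok <- function(tidx) {
    if (metric == "accuracy") return(TRUE)
    if (metric == "malignant_roc_auc") {
      p <- mal_flag[tidx]
      return(any(p) && !all(p))
    }
    # balanced accuracy / mean ROC-AUC: every truth-present class must survive
    all(tabulate(tidx, 7)[present] > 0)
  }
  set.seed(seed)
  diffs <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (resample_ok(ti[idx])) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) {
        stop("metric ", metric, " undefined on nearly all resamples",
             call. = FALSE)
      }
    }
    diffs[b] <- boot_stat(idx)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  structure(list(metric = metric, difference = point,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, n_redrawn = redrawn, seed = seed,
                 level = level),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s difference %.4f, %d%% CI [%.4f, %.4f] (n_boot = %d%s)\n",
              x$metric, x$difference, round(100 * x$level), x$ci_low,
              x$ci_high, x$n_boot,
              if (x$n_redrawn > 0) paste0(", ", x$n_redrawn, " redrawn")
              else ""))
  invisible(x)
}

#' Crowd-size curve: metrics as a function of decisions per image
#'
#' For each size n, repeatedly subsamples n decisions per test image without
#' replacement (images with fewer than n decisions keep them all), aggregates
#' under `config`, and computes the four metrics; reports the mean and a
#' percentile band across repetitions. `n = "ALL"` uses every decision (one
#' repetition, zero sampling variance).
#'
#' @param table a `decision_table`.
#' @param sizes numeric vector of crowd sizes, optionally including "ALL".
#' @param config an [aggregation_config()].
#' @param profiles an `annotator_profiles` object.
#' @param group a `group_profile`; defaults to `profiles$group`.
#' @param reps repetitions per size (default 25).
#' @param seed master seed.
#' @return data.frame with columns n, metric, mean, ci_low, ci_high, sd.
#' @export
crowd_size_curve <- function(table, sizes, config, profiles,
                             group = profiles$group, reps = 25, seed = 1L) {
  test <- as.data.frame(table[table$split == "test", , drop = FALSE])
  stopifnot(nrow(test) > 0)
  img <- factor(test$image_id)
  idx_by_img <- split(seq_len(nrow(test)), img)
  out <- list()
  for (s in sizes) {
    all_crowd <- identical(s, "ALL")
    nrep <- if (all_crowd) 1L else reps
    vals <- matrix(NA_real_, nrep, 4)
    colnames(vals) <- c("accuracy", "balanced_accuracy", "mean_roc_auc",
                        "malignant_roc_auc")
    for (r in seq_len(nrep)) {
      if (all_crowd) {
        sub <- test
      } else {
        set.seed(seed + 7919L * r + 104729L * as.integer(s))
        take <- unlist(lapply(idx_by_img, function(ii) {
          if (length(ii) <= s) ii else ii[sample.int(length(ii), s)]
        }), use.names = FALSE)
        sub <- test[take, , drop = FALSE]
      }
      class(sub) <- c("decision_table", "data.frame")
      res <- aggregate_split(sub, config, profiles, group)
      rep_ <- metric_report(res$decision, res$truth, scores = res$scores)
      vals[r, ] <- c(rep_$accuracy, rep_$balanced_accuracy,
                     rep_$mean_roc_auc, rep_$malignant_roc_auc)
    }
    for (m in colnames(vals)) {
      v <- vals[, m]
      out[[length(out) + 1L]] <- data.frame(
        n = if (all_crowd) NA_integer_ else as.integer(s),
        size = if (all_crowd) "ALL" else as.character(s),
        metric = m, mean = mean(v),
        ci_low = unname(stats::quantile(v, 0.025)),
        ci_high = unname(stats::quantile(v, 0.975)),
        sd = stats::sd(v))
    }
  }
  do.call(rbind, out)
}
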