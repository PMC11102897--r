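#' Default class-similarity kernel for simulated confusions
#'
#' Relative off-diagonal affinities (rows = true class, cols = response):
#' errors concentrate on visually confusable pairs, e.g. true NV drawn to MEL
#' about 3.5x as strongly as to AKIEC. Values are relative weights, not
#' probabilities; each annotator's off-diagonal row mass is distributed
#' proportionally to its kernel row.
#'
#' @return 7x7 matrix with zero diagonal.
#' @export
default_confusion_kernel <- function() {
  classes <- lesion_classes()
  k <- matrix(c(
    #        AKIEC  BCC  BKL   DF  MEL   NV VASC
    0.0, 2.5, 3.0, 0.5, 1.5, 1.0, 0.3,   # AKIEC
    2.0, 0.0, 1.5, 0.5, 1.5, 1.5, 0.5,   # BCC
    1.5, 1.0, 0.0, 0.8, 2.0, 2.5, 0.3,   # BKL
    0.5, 0.8, 1.5, 0.0, 0.8, 2.5, 0.8,   # DF
    0.8, 1.0, 1.8, 0.4, 0.0, 3.5, 0.3,   # MEL
    0.55, 0.7, 1.6, 0.7, 1.95, 0.0, 0.6, # NV
    0.5, 1.0, 0.8, 1.0, 0.8, 2.0, 0.0    # VASC
  ), 7, 7, byrow = TRUE, dimnames = list(true = classes, response = classes))
  k
}

#' Simulation configuration for a synthetic annotator crowd
#'
#' Defaults state the study's observed world: ~300 annotators with
#' heavy-tailed participation (log-normal total decision counts, median ~135,
#' a rare individual above 10,000), latent skill correlated 0.67 with log
#' participation, a logistic skill-to-accuracy link calibrated so individual
#' mean training accuracy is ~0.42 with IQR ~0.28-0.57, class-difficulty
#' offsets (VASC easy, AKIEC hard), class-similarity-structured confusion,
#' counterbalanced training presentation vs the skewed test prevalence
#' (43, 93, 217, 44, 171, 908, 35 over 1511 images), 21-25 decisions per test
#' image, a 75/25 train/test exposure, and log-normal response times with
#' median 8.5 s so that ~0.8% of decisions exceed the 20 s cleaning cutoff.
#'
#' @param n_annotators number of annotators.
#' @param n_train_images,n_test_images image counts per split.
#' @param train_prevalence 7-vector of train-pool class proportions (sums
#'   to 1). The train image pool is skewed like the test pool; only the
#'   *presentation* of train images to annotators is counterbalanced.
#' @param test_prevalence 7-vector of test-class proportions (sums to 1).
#' @param decisions_per_test_image integer range (lo, hi) of decisions each
#'   test image receives.
#' @param participation list(meanlog, sdlog) for per-annotator total counts.
#' @param skill list(mean, sd) of latent skill on the logit scale.
#' @param skill_effort_correlation target correlation between latent skill and
#'   log decision count, in (-1, 1).
#' @param class_difficulty named 7-vector of logit offsets per true class.
#' @param confusion_kernel 7x7 relative off-diagonal affinity matrix.
#' @param dirichlet_concentration per-annotator row noise (larger = rows
#'   closer to their expected value; Inf disables noise).
#' @param train_fraction fraction of each annotator's decisions on the train
#'   split.
#' @param rt list(meanlog, sdlog, invalid_rate) for response times.
#' @param n_days number of study days over which decisions are spread.
#' @param seed integer master seed.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_annotators = 300,
                              n_train_images = 10015,
                              n_test_images = 1511,
                              train_prevalence = c(327, 514, 1099, 115, 1113, 6705, 142) / 10015,
                              test_prevalence = c(43, 93, 217, 44, 171, 908, 35) / 1511,
                              decisions_per_test_image = c(21, 25),
                              participation = list(meanlog = log(135), sdlog = 1.6),
                              skill = list(mean = -1.028, sd = 1.381),
                              skill_effort_correlation = 0.67,
                              class_difficulty = c(AKIEC = -1.1, BCC = 0.0,
                                                   BKL = -0.2, DF = 0.1,
                                                   MEL = -0.5, NV = 0.4,
                                                   VASC = 1.4),
                              confusion_kernel = default_confusion_kernel(),
                              dirichlet_concentration = 60,
                              train_fraction = 0.75,
                              rt = list(meanlog = log(8.5), sdlog = 0.355,
                                        invalid_rate = 0.002),
                              n_days = 14,
                              seed = 1L) {
  stopifnot(n_annotators >= 1, n_train_images >= 7, n_test_images >= 1,
            length(train_prevalence) == 7,
            abs(sum(train_prevalence) - 1) < 1e-8,
            length(test_prevalence) == 7,
            abs(sum(test_prevalence) - 1) < 1e-8,
            length(decisions_per_test_image) == 2,
            decisions_per_test_image[1] <= decisions_per_test_image[2],
            train_fraction > 0, train_fraction < 1,
            dirichlet_concentration > 0)
  rho <- skill_effort_correlation
  if (!(rho > -1 && rho < 1)) {
    stop("infeasible config: skill_effort_correlation must lie in (-1, 1)",
         call. = FALSE)
  }
  if (skill$sd < 0 || participation$sdlog < 0) {
    stop("infeasible config: negative dispersion", call. = FALSE)
  }
  structure(list(
    n_annotators = as.integer(n_annotators),
    n_train_images = as.integer(n_train_images),
    n_test_images = as.integer(n_test_images),
    train_prevalence = stats::setNames(train_prevalence, lesion_classes()),
    test_prevalence = stats::setNames(test_prevalence, lesion_classes()),
    decisions_per_test_image = as.integer(decisions_per_test_image),
    participation = participation, skill = skill,
    skill_effort_correlation = rho,
    class_difficulty = class_difficulty,
    confusion_kernel = confusion_kernel,
    dirichlet_concentration = dirichlet_concentration,
    train_fraction = train_fraction, rt = rt,
    n_days = as.integer(n_days), seed = as.integer(seed)
  ), class = "simulation_config")
}

rdirichlet_rows <- function(base, conc) {
  # one Dirichlet draw per row of `base` with concentration conc * base
  if (!is.finite(conc)) return(base)
  out <- base
  for (i in seq_len(nrow(base))) {
    g <- stats::rgamma(ncol(base), shape = conc * base[i, ])
    out[i, ] <- g / sum(g)
  }
  out
}

#' Sample the annotator block of a simulation's ground truth
#'
#' Draws (latent skill, log participation) from a bivariate normal with the
#' configured correlation; maps skill plus a class-difficulty offset through a
#' logistic link (floored at chance, 1/7) to the diagonal of each annotator's
#' true confusion matrix; distributes off-diagonal mass proportionally to the
#' class-similarity kernel rows; and perturbs each row with Dirichlet noise.
#'
#' @param config a [simulation_config()].
#' @return A `crowd_truth` annotator block: list with `participants`
#'   (data.frame: participant_id, latent_skill, n_total, expected_accuracy)
#'   and `confusion` (7 x 7 x n array of true annotator matrices).
#' @export
sample_annotators <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "annotators"))
  n <- config$n_annotators
  rho <- config$skill_effort_correlation
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  latent <- config$skill$mean + config$skill$sd * z1
  n_total <- pmax(1L, as.integer(round(exp(
    config$participation$meanlog + config$participation$sdlog * z2))))
  classes <- lesion_classes()
  kern <- config$confusion_kernel
  conf <- array(NA_real_, c(7, 7, n),
                dimnames = list(true = classes, response = classes,
                                participant = NULL))
  diag_acc <- matrix(NA_real_, n, 7)
  for (j in seq_len(n)) {
    p_diag <- 1 / 7 + (6 / 7) * stats::plogis(latent[j] + config$class_difficulty)
    base <- matrix(0, 7, 7)
    for (t in seq_len(7)) {
      off <- kern[t, ] / sum(kern[t, ])
      base[t, ] <- (1 - p_diag[t]) * off
      base[t, t] <- p_diag[t]
    }
    conf[, , j] <- rdirichlet_rows(base, config$dirichlet_concentration)
    diag_acc[j, ] <- diag(conf[, , j])
  }
  ids <- sprintf("P%04d", seq_len(n))
  dimnames(conf)[[3]] <- ids
  participants <- data.frame(
    participant_id = ids,
    latent_skill = latent,
    n_total = n_total,
    expected_accuracy = rowMeans(diag_acc)  # balanced train presentation
  )
  structure(list(participants = participants, confusion = conf,
                 config = config),
            class = "crowd_truth")
}

#' Simulate a decision table from a crowd ground truth
#'
#' Generates image labels (counterbalanced train split; test split drawn from
#' the configured prevalence), assigns each annotator
#' `round(train_fraction * n_total)` training decisions on class-balanced
#' train images, staffs every test image with a target of
#' `decisions_per_test_image` distinct annotators sampled with probability
#' proportional to participation, draws each response from the annotator's
#' true confusion row for the image's class, and attaches log-normal response
#' times (a small fraction invalid/NA) and day indices. Fully reproducible
#' from the config seed.
#'
#' @param ground_truth a `crowd_truth` from [sample_annotators()].
#' @param config a [simulation_config()]; defaults to the one stored in
#'   `ground_truth`.
#' @return A `decision_table`. The complete ground truth (annotator block plus
#'   `images`, a data.frame of true image labels) is attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_decisions <- function(ground_truth, config = ground_truth$config) {
  stopifnot(inherits(ground_truth, "crowd_truth"))
  classes <- lesion_classes()
  lo <- config$decisions_per_test_image[1]
  hi <- config$decisions_per_test_image[2]
  if (config$n_annotators < hi) {
    stop("config error: each test image needs up to ", hi,
         " distinct annotators but only ", config$n_annotators,
         " are available; required minimum n_annotators = ", hi,
         call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "decisions"))
  part <- ground_truth$participants
  n_ann <- nrow(part)

  # image labels: both pools are prevalence-skewed (presentation of train
  # images is counterbalanced below, the pool itself is not); every class
  # gets at least one train image so balanced presentation stays feasible
  tr_counts <- pmax(1L, round(config$train_prevalence * config$n_train_images))
  big <- which.max(tr_counts)
  tr_counts[big] <- tr_counts[big] + config$n_train_images - sum(tr_counts)
  train_labels <- sample(rep(classes, tr_counts))
  test_labels <- sample(classes, config$n_test_images, replace = TRUE,
                        prob = config$test_prevalence)
  train_ids <- sprintf("train_%05d", seq_len(config$n_train_images))
  test_ids <- sprintf("test_%05d", seq_len(config$n_test_images))
  images <- data.frame(
    image_id = c(train_ids, test_ids),
    split = rep(c("train", "test"),
                c(config$n_train_images, config$n_test_images)),
    true_label = c(train_labels, test_labels)
  )
  train_by_class <- split(seq_len(config$n_train_images), train_labels)

  # training decisions: class-balanced presentation per annotator
  n_train_j <- pmax(0L, as.integer(round(config$train_fraction * part$n_total)))
  tr_ann <- rep(seq_len(n_ann), n_train_j)
  n_tr <- length(tr_ann)
  tr_class <- sample.int(7, n_tr, replace = TRUE)
  tr_img <- integer(n_tr)
  for (t in seq_len(7)) {
    m <- tr_class == t
    pool <- train_by_class[[classes[t]]]
    tr_img[m] <- pool[sample.int(length(pool), sum(m), replace = TRUE)]
  }

  # test decisions: each image staffed by distinct annotators, participation-
  # weighted, so each ends with its full per-image quota
  quota <- sample(lo:hi, config$n_test_images, replace = TRUE)
  wt <- part$n_total
  te_ann <- integer(sum(quota))
  te_img <- rep(seq_len(config$n_test_images), quota)
  pos <- 1L
  for (i in seq_len(config$n_test_images)) {
    te_ann[pos:(pos + quota[i] - 1L)] <-
      sample.int(n_ann, quota[i], replace = FALSE, prob = wt)
    pos <- pos + quota[i]
  }

  ann <- c(tr_ann, te_ann)
  img_id <- c(train_ids[tr_img], test_ids[te_img])
  split <- rep(c("train", "test"), c(n_tr, length(te_ann)))
  truth <- c(train_labels[tr_img], test_labels[te_img])
  n_dec <- length(ann)

  # responses from each annotator's confusion row of the true class,
  # grouped by (annotator, true class) for one multinomial draw per group
  truth_idx <- match(truth, classes)
  response <- character(n_dec)
  grp <- split(seq_len(n_dec), (ann - 1L) * 7L + truth_idx)
  for (key in names(grp)) {
    ii <- grp[[key]]
    kk <- as.integer(key) - 1L
    j <- kk %/% 7L + 1L
    t <- kk %% 7L + 1L
    response[ii] <- sample(classes, length(ii), replace = TRUE,
                           prob = ground_truth$confusion[t, , j])
  }

  rt <- stats::rlnorm(n_dec, config$rt$meanlog, config$rt$sdlog)
  invalid <- stats::runif(n_dec) < config$rt$invalid_rate
  rt[invalid] <- NA_real_

  # day structure: a per-annotator partition only (no learning dynamics)
  n_days_j <- pmin(config$n_days, 1L + stats::rgeom(n_ann, prob = 0.4))
  day <- as.integer(ceiling(stats::runif(n_dec) * n_days_j[ann]))

  tab <- decision_table(data.frame(
    participant_id = part$participant_id[ann],
    image_id = img_id,
    split = split,
    true_label = truth,
    response = response,
    response_time_s = rt,
    day = day
  ), provenance = sprintf("simulated crowd (seed %d)", config$seed))
  gt <- ground_truth
  gt$images <- images
  attr(tab, "ground_truth") <- gt
  tab
}

#' Simulate a full synthetic crowd
#'
#' Convenience wrapper: [sample_annotators()] then [simulate_decisions()].
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a `decision_table`) and `truth` (the
#'   `crowd_truth`, including image labels).
#' @export
simulate_crowd <- function(config = simulation_config()) {
  gt <- sample_annotators(config)
  tab <- simulate_decisions(gt, config)
  list(table = tab, truth = attr(tab, "ground_truth"))
}

#' Parameter-recovery report: estimated vs true annotator parameters
#'
#' Compares profile estimates against the generative ground truth:
#' per-annotator absolute accuracy error with its binomial standard error,
#' mean absolute confusion-entry error for annotators profiled individually,
#' and whether errors shrink with the number of training decisions.
#'
#' @param table the simulated `decision_table` used to build `profiles`.
#' @param ground_truth the `crowd_truth`.
#' @param profiles the `annotator_profiles` built from `table`.
#' @param strata n_train cut points for the shrinkage summary.
#' @return A `recovery_report`: list with `per_annotator` (data.frame) and
#'   `by_stratum` (data.frame of mean errors per n_train stratum).
#' @export
recovery_report <- function(table, ground_truth, profiles,
                            strata = c(0, 50, 500, 5000, Inf)) {
  stopifnot(inherits(profiles, "annotator_profiles"),
            inherits(ground_truth, "crowd_truth"))
  gt_part <- ground_truth$participants
  k <- match(gt_part$participant_id, profiles$participant_id)
  present <- !is.na(k)
  n_train <- ifelse(present, profiles$n_train[k], 0L)
  est_acc <- ifelse(present, profiles$train_accuracy[k], NA_real_)
  true_acc <- gt_part$expected_accuracy
  excluded <- n_train == 0
  se <- sqrt(true_acc * (1 - true_acc) / pmax(n_train, 1))
  conf_err <- rep(NA_real_, nrow(gt_part))
  for (i in which(present)) {
    if (!profiles$used_fallback[k[i]]) {
      est_m <- profiles$confusion[, , k[i]]
      true_m <- ground_truth$confusion[, , i]
      conf_err[i] <- mean(abs(est_m - true_m))
    }
  }
  per <- data.frame(
    participant_id = gt_part$participant_id,
    n_train = n_train,
    true_accuracy = true_acc,
    estimated_accuracy = est_acc,
    abs_error = abs(est_acc - true_acc),
    binomial_se = se,
    within_3se = abs(est_acc - true_acc) <= 3 * se,
    confusion_mae = conf_err,
    excluded = excluded
  )
  bin <- cut(per$n_train, breaks = strata, right = FALSE)
  ok <- !per$excluded
  by_stratum <- do.call(rbind, lapply(levels(bin), function(b) {
    m <- ok & !is.na(bin) & bin == b
    data.frame(stratum = b, n = sum(m),
               mean_abs_error = if (any(m)) mean(per$abs_error[m]) else NA_real_,
               mean_confusion_mae = if (any(m & !is.na(per$confusion_mae)))
                 mean(per$confusion_mae[m], na.rm = TRUE) else NA_real_)
  }))
  structure(list(per_annotator = per, by_stratum = by_stratum),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  ok <- !x$per_annotator$excluded
  cat(sprintf(
    "recovery: %d annotators (%d excluded, n_train = 0); %.1f%% within 3 binomial SE; mean |acc error| %.4f\n",
    nrow(x$per_annotator), sum(x$per_annotator$excluded),
    100 * mean(x$per_annotator$within_3se[ok], na.rm = TRUE),
    mean(x$per_annotator$abs_error[ok], na.rm = TRUE)))
  invisible(x)
}
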