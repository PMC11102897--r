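test_that("select_top_r ranks by training accuracy with deterministic ties", {
  pr <- manual_profiles(c(p1 = 0.9, p2 = 0.7, p3 = 0.5))
  crowd <- one_image_crowd(c("p3", "p1", "p2"), c("NV", "MEL", "BKL"))
  top2 <- select_top_r(crowd, pr, 2)
  expect_equal(top2$participant_id, c("p1", "p2"))

  # r = ALL is the identity
  expect_equal(as.data.frame(select_top_r(crowd, pr, "ALL")),
               as.data.frame(crowd))

  # r beyond the crowd size keeps everyone
  expect_equal(nrow(select_top_r(crowd, pr, 10)), 3L)

  # accuracy tie at r = 1: lexicographically smaller id wins
  pr_tie <- manual_profiles(c(pa = 0.8, pz = 0.8, pm = 0.5))
  crowd_tie <- one_image_crowd(c("pz", "pa", "pm"), c("NV", "MEL", "BKL"))
  expect_equal(select_top_r(crowd_tie, pr_tie, 1)$participant_id, "pa")
})

test_that("decision_weights implements every scheme's printed form", {
  tau <- 0.02
  pr <- manual_profiles(c(p1 = 0.9))
  prof <- get_profile(pr, "p1")
  classes <- lesion_classes()

  sv <- decision_weights("NV", "SV", prof, tau)
  expect_equal(unname(sv), c(0, 0, 0, 0, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(attr(sv, "scale"), "count")

  saw <- decision_weights("MEL", "SAW", prof, tau)
  expect_equal(unname(saw[classes == "MEL"]), 0.9)
  expect_equal(sum(saw != 0), 1L)

  le <- decision_weights("MEL", "LAW_E", prof, tau)
  expect_equal(unname(le[classes == "MEL"]), log(0.9))
  expect_equal(unname(le[classes != "MEL"]), rep(log(0.1 / 6), 6))
  expect_equal(attr(le, "scale"), "log_probability")

  # perfect accuracy is clamped to 1 - tau before the log
  pr1 <- manual_profiles(c(p1 = 1.0))
  le1 <- decision_weights("MEL", "LAW_E", get_profile(pr1, "p1"), tau)
  expect_equal(unname(le1[classes == "MEL"]), log(0.98))
  expect_true(all(is.finite(le1)))

  # confusion weighting reads the response column across true classes
  cm <- matrix(0.05, 7, 7); diag(cm) <- 0.7
  dimnames(cm) <- list(true = classes, response = classes)
  cm["NV", "MEL"] <- 0.25
  pri <- manual_profiles(c(p1 = 0.7), conf_list = list(cm))
  ci <- decision_weights("MEL", "LAW_CI", get_profile(pri, "p1"), tau)
  expect_equal(unname(ci[classes == "NV"]), log(0.25))
  expect_equal(unname(ci[classes == "MEL"]), log(0.7))

  ca <- decision_weights("MEL", "LAW_CA", prof, tau, group = pri$group)
  expect_equal(unname(ca), rep(log(1 / 7), 7), ignore_attr = TRUE)
  expect_error(decision_weights("MEL", "LAW_CA", prof, tau), "group")
})

test_that("aggregate_image implements plurality and tie rules", {
  pr <- manual_profiles(c(p1 = 0.6, p2 = 0.6, p3 = 0.6))
  crowd <- one_image_crowd(c("p1", "p2", "p3"), c("NV", "NV", "MEL"))
  res <- aggregate_image(crowd, aggregation_config("SV"), pr)
  expect_equal(res$decision, "NV")
  expect_equal(unname(res$scores), c(0, 0, 0, 0, 1, 2, 0),
               ignore_attr = TRUE)

  # all-tied scores: tie-break rules resolve deterministically
  pru <- manual_profiles(c(p1 = 0.5),
                         priors = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.4, 0.1))
  one <- one_image_crowd("p1", "BKL")
  tie_ci <- aggregate_image(one, aggregation_config("LAW_CI"), pru)
  expect_equal(unname(tie_ci$scores), rep(log(1 / 7), 7), ignore_attr = TRUE)
  expect_equal(tie_ci$decision, "NV")  # prior_frequency: most prevalent class
  lex <- aggregate_image(one, aggregation_config("LAW_CI",
                                                 tie_break = "lexicographic"),
                         pru)
  expect_equal(lex$decision, "AKIEC")

  expect_error(aggregate_image(crowd[0, ], aggregation_config("SV"), pr),
               "empty")
  expect_error(aggregation_config("SV", use_priors = TRUE), "priors")
  expect_error(aggregation_config("SAW", use_priors = TRUE), "priors")
})

test_that("LAW scores equal the brute-force Bayes oracle (<= 5 annotators)", {
  tau <- 0.02
  classes <- lesion_classes()
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    acc <- stats::runif(n, 0.2, 0.98)
    confs <- lapply(seq_len(n), function(j) {
      m <- matrix(stats::rgamma(49, 1.2), 7, 7)
      m <- m / rowSums(m)
      dimnames(m) <- list(true = classes, response = classes)
      m
    })
    priors <- as.numeric(stats::rgamma(7, 2)); priors <- priors / sum(priors)
    pr <- manual_profiles(stats::setNames(acc, sprintf("p%d", 1:n)),
                          conf_list = confs, tau = tau, priors = priors)
    responses <- sample(classes, n, TRUE)
    crowd <- one_image_crowd(sprintf("p%d", 1:n), responses)

    # LAW_E: P(d | T) = a if d == T else (1-a)/6, with clamped a
    for (use_p in c(FALSE, TRUE)) {
      lp <- if (use_p) log(priors) else rep(0, 7)
      oracle_e <- oracle_log_scores(responses, function(j, d, t) {
        a <- min(max(acc[j], tau), 1 - tau)
        if (d == t) a else (1 - a) / 6
      }, lp)
      got <- aggregate_image(crowd,
                             aggregation_config("LAW_E", use_priors = use_p,
                                                tau = tau), pr)
      expect_equal(unname(got$scores), oracle_e, tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(got$decision, classes[which.max(oracle_e)])

      # LAW_CI: P(d | T) = individual confusion entry
      oracle_ci <- oracle_log_scores(responses, function(j, d, t) {
        min(max(confs[[j]][t, d], tau), 1 - tau)
      }, lp)
      got_ci <- aggregate_image(crowd,
                                aggregation_config("LAW_CI", use_priors = use_p,
                                                   tau = tau), pr)
      expect_equal(unname(got_ci$scores), oracle_ci, tolerance = 1e-9,
                   ignore_attr = TRUE)

      # LAW_CA: group confusion (uniform here) for every annotator
      oracle_ca <- oracle_log_scores(responses, function(j, d, t) 1 / 7, lp)
      got_ca <- aggregate_image(crowd,
                                aggregation_config("LAW_CA", use_priors = use_p,
                                                   tau = tau), pr)
      expect_equal(unname(got_ca$scores), oracle_ca, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }

    # posterior matches the enumerated posterior entrywise
    oracle_e0 <- oracle_log_scores(responses, function(j, d, t) {
      a <- min(max(acc[j], tau), 1 - tau)
      if (d == t) a else (1 - a) / 6
    })
    post_oracle <- exp(oracle_e0) / sum(exp(oracle_e0))
    got0 <- aggregate_image(crowd, aggregation_config("LAW_E", tau = tau), pr)
    expect_equal(unname(posterior_probabilities(got0$scores)), post_oracle,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("posterior_probabilities normalizes stably and checks its contract", {
  z <- rep(0, 7)
  attr(z, "scale") <- "log_probability"
  expect_equal(unname(posterior_probabilities(z)), rep(1 / 7, 7),
               ignore_attr = TRUE)

  # invariance to additive constants, near -Inf floors tolerated
  for (const in c(0, -500, 731)) {
    s <- c(log(0.7), log(0.3), rep(-745, 5)) + const
    attr(s, "scale") <- "log_probability"
    p <- posterior_probabilities(s)
    expect_equal(p[1:2], c(0.7, 0.3), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }

  counts <- c(1, 0, 0, 0, 0, 2, 0)
  attr(counts, "scale") <- "count"
  expect_error(posterior_probabilities(counts), "log_probability")
})

test_that("aggregation invariants hold on random crowds", {
  set.seed(77)
  classes <- lesion_classes()
  pr <- manual_profiles(stats::setNames(stats::runif(9, 0.3, 0.95),
                                        sprintf("p%d", 1:9)))
  for (rep in 1:6) {
    k <- sample(3:9, 1)
    ids <- sample(sprintf("p%d", 1:9), k)
    crowd <- one_image_crowd(ids, sample(classes, k, TRUE))
    for (scheme in c("SV", "SAW", "LAW_E")) {
      cfg <- aggregation_config(scheme, tie_break = "lexicographic")
      base <- aggregate_image(crowd, cfg, pr)
      # permutation invariance
      shuf <- crowd[sample.int(k), , drop = FALSE]
      class(shuf) <- c("decision_table", "data.frame")
      again <- aggregate_image(shuf, cfg, pr)
      expect_equal(again$scores, base$scores)
      expect_equal(again$decision, base$decision)
      # additive-constant safety of the argmax
      shifted <- matrix(base$scores + 12.34, nrow = 1)
      expect_equal(
        crowdlaw:::argmax_label(shifted, "lexicographic"),
        base$decision)
    }
  }
})

test_that("homogeneous-accuracy crowds reduce LAW_E and SAW to SV", {
  set.seed(13)
  classes <- lesion_classes()
  a <- 0.6  # shared accuracy > 1/7
  pr <- manual_profiles(stats::setNames(rep(a, 12), sprintf("p%d", 1:12)))
  tab <- do.call(rbind, lapply(1:25, function(i) {
    k <- sample(5:12, 1)
    data.frame(participant_id = sample(sprintf("p%d", 1:12), k),
               image_id = sprintf("img%02d", i), split = "test",
               true_label = sample(classes, 1),
               response = sample(classes, k, TRUE),
               response_time_s = 5, day = 1L)
  }))
  tab <- decision_table(tab)
  grid <- list(aggregation_config("SV", tie_break = "lexicographic"),
               aggregation_config("SAW", tie_break = "lexicographic"),
               aggregation_config("LAW_E", tie_break = "lexicographic"))
  sw <- run_switchboard(tab, grid, pr)
  d <- split(sw$decisions, sw$decisions$config_id)

  # the reduction holds exactly on images without plurality ties (tied score
  # vectors are broken by floating-point summation order, not the algebra)
  untied <- vapply(d$SV_rALL$image_id, function(img) {
    v <- table(tab$response[tab$image_id == img])
    sum(v == max(v)) == 1
  }, logical(1))
  expect_gt(sum(untied), 10)
  expect_equal(d$SAW_rALL$decision[untied], d$SV_rALL$decision[untied])
  expect_equal(d$LAW_E_rALL$decision[untied], d$SV_rALL$decision[untied])
})

test_that("run_switchboard composes aggregate_image and keeps shapes", {
  set.seed(21)
  classes <- lesion_classes()
  pr <- manual_profiles(stats::setNames(stats::runif(8, 0.3, 0.9),
                                        sprintf("p%d", 1:8)))
  tab <- do.call(rbind, lapply(1:5, function(i) {
    k <- 6
    data.frame(participant_id = sample(sprintf("p%d", 1:8), k),
               image_id = sprintf("img%d", i), split = "test",
               true_label = sample(classes, 1),
               response = sample(classes, k, TRUE),
               response_time_s = 5, day = 1L)
  }))
  tab <- decision_table(tab)

  # 2-config grid on a 5-image toy table: 2 x 4 metric rows
  grid <- list(aggregation_config("SV", selection_r = 1),
               aggregation_config("SV", selection_r = "ALL"))
  sw <- suppressWarnings(run_switchboard(tab, grid, pr))
  expect_equal(nrow(sw$metrics), 8L)
  expect_equal(nrow(sw$decisions), 10L)

  # single config == aggregate_image mapped over images
  cfg <- aggregation_config("LAW_E", selection_r = 3)
  sw1 <- suppressWarnings(run_switchboard(tab, list(cfg), pr))
  for (img in unique(tab$image_id)) {
    crowd <- tab[tab$image_id == img, , drop = FALSE]
    class(crowd) <- c("decision_table", "data.frame")
    ai <- aggregate_image(crowd, cfg, pr)
    row <- sw1$decisions[sw1$decisions$image_id == img, ]
    expect_equal(row$decision, ai$decision)
    expect_equal(unname(sw1$scores[[1]][img, ]), unname(ai$scores),
                 ignore_attr = TRUE)
  }

  # SV with r = ALL maximizes the response count on every image
  swv <- suppressWarnings(run_switchboard(tab, list(aggregation_config(
    "SV", tie_break = "lexicographic")), pr))
  for (img in unique(tab$image_id)) {
    votes <- table(factor(tab$response[tab$image_id == img],
                          levels = classes))
    dec <- swv$decisions$decision[swv$decisions$image_id == img]
    expect_equal(unname(votes[dec]), max(votes))
  }
})
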