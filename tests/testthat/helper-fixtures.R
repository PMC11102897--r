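# fixtures are built in code at test time; nothing is read from disk

# hand-sized decision table with known structure
toy_table <- function() {
  decision_table(data.frame(
    participant_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    image_id = c("t1", "t2", "t3", "t1", "t4", "t1"),
    split = "train",
    true_label = c("NV", "NV", "MEL", "NV", "BKL", "NV"),
    response = c("NV", "MEL", "MEL", "NV", "BKL", "MEL"),
    response_time_s = c(5, 8, 12, 3, 6, 9),
    day = 1L
  ), provenance = "toy")
}

# one-decision-per-image test table with a given class composition
composition_table <- function(counts, split = "test",
                              responder = function(truth) truth) {
  classes <- lesion_classes()
  truth <- rep(classes, counts)
  n <- length(truth)
  decision_table(data.frame(
    participant_id = "p1",
    image_id = sprintf("%s_%05d", split, seq_len(n)),
    split = split,
    true_label = truth,
    response = vapply(truth, responder, character(1)),
    response_time_s = 5,
    day = 1L
  ))
}

# the published test-split composition (counts per class, canonical order)
table1_test_counts <- function() c(43, 93, 217, 44, 171, 908, 35)
table1_train_counts <- function() c(327, 514, 1099, 115, 1113, 6705, 142)

# small, fast simulation for structural tests
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_annotators = 40,
    n_train_images = 350,
    n_test_images = 60,
    decisions_per_test_image = c(21, 25),
    participation = list(meanlog = log(120), sdlog = 0.9),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# crowd truth with hand-chosen confusion matrices (bypasses sample_annotators)
manual_truth <- function(conf_list, n_total = 400, seed = 1) {
  n <- length(conf_list)
  classes <- lesion_classes()
  conf <- array(NA_real_, c(7, 7, n),
                dimnames = list(true = classes, response = classes,
                                participant = sprintf("P%04d", seq_len(n))))
  for (j in seq_len(n)) conf[, , j] <- conf_list[[j]]
  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    latent_skill = 0,
    n_total = rep_len(n_total, n),
    expected_accuracy = vapply(conf_list, function(m) mean(diag(m)), numeric(1))
  )
  structure(list(participants = participants, confusion = conf,
                 config = small_sim_config(seed = seed, n_annotators = n)),
            class = "crowd_truth")
}

# profiles object with prescribed accuracies/confusions, for oracle tests
manual_profiles <- function(acc, conf_list = NULL, tau = 0.02,
                            priors = rep(1 / 7, 7)) {
  n <- length(acc)
  ids <- names(acc)
  if (is.null(ids)) ids <- sprintf("p%d", seq_len(n))
  classes <- lesion_classes()
  conf <- array(1 / 7, c(7, 7, n),
                dimnames = list(true = classes, response = classes,
                                participant = ids))
  if (!is.null(conf_list)) {
    for (j in seq_len(n)) conf[, , j] <- conf_list[[j]]
  }
  group <- structure(list(
    confusion = matrix(1 / 7, 7, 7, dimnames = list(true = classes,
                                                    response = classes)),
    priors = stats::setNames(priors, classes),
    accuracy = mean(acc),
    tau = tau
  ), class = "group_profile")
  structure(list(
    participant_id = ids, n_train = rep(1000L, n),
    train_accuracy = unname(acc),
    used_fallback = rep(FALSE, n),
    confusion = conf, group = group,
    min_individual_n = 100, tau = tau
  ), class = "annotator_profiles")
}

# a one-image crowd as a decision_table
one_image_crowd <- function(participants, responses, truth = "NV",
                            image = "img1", split = "test") {
  decision_table(data.frame(
    participant_id = participants,
    image_id = image,
    split = split,
    true_label = truth,
    response = responses,
    response_time_s = 5,
    day = 1L
  ))
}

# brute-force Bayes oracle: enumerate the 7 hypotheses and multiply raw
# (clamped) response probabilities; completely independent of the scoring path
oracle_log_scores <- function(responses, prob_fun, log_prior = rep(0, 7)) {
  classes <- lesion_classes()
  vapply(seq_len(7), function(t) {
    p <- vapply(seq_along(responses), function(j) {
      prob_fun(j, responses[j], classes[t])
    }, numeric(1))
    log(prod(p)) + log_prior[t]
  }, numeric(1))
}
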