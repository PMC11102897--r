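#' Training accuracy of one participant
#'
#' Fraction of a participant's training-split decisions that match the true
#' label.
#'
#' @param table a `decision_table`.
#' @param participant participant identifier.
#' @return proportion in \[0, 1\].
#' @export
training_accuracy <- function(table, participant) {
  stopifnot(inherits(table, "decision_table"))
  sub <- table[table$split == "train" &
                 table$participant_id == participant, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("undefined profile: participant '", participant,
         "' has no training decisions; use the group fallback", call. = FALSE)
  }
  mean(sub$response == sub$true_label)
}

#' Estimate a 7x7 confusion matrix from training decisions
#'
#' Entry (T, d) is the empirical probability that the response is class d when
#' the true class is T. Rows with zero observations are set to the uniform row
#' (1/7) and flagged. Every entry is then clamped into \[tau, 1 - tau\] so
#' later logarithms stay finite. Clamped rows are not renormalized by default,
#' matching a hard-boundary reading of the clamp; `renormalize = TRUE` is
#' available for sensitivity analysis.
#'
#' @param decisions data.frame with columns true_label and response (training
#'   decisions).
#' @param tau clamp threshold in (0, 0.5); default 0.02.
#' @param clamp apply the tau clamp (default TRUE).
#' @param renormalize re-scale rows to sum to one after clamping.
#' @return 7x7 matrix (rows = true class, cols = response) with attributes
#'   `raw` (pre-clamp proportions), `counts`, and `zero_rows`.
#' @export
estimate_confusion <- function(decisions, tau = 0.02, clamp = TRUE,
                               renormalize = FALSE) {
  stopifnot(nrow(decisions) > 0, tau > 0, tau < 0.5)
  classes <- lesion_classes()
  counts <- table(factor(decisions$true_label, levels = classes),
                  factor(decisions$response, levels = classes))
  counts <- matrix(as.numeric(counts), 7, 7,
                   dimnames = list(true = classes, response = classes))
  rs <- rowSums(counts)
  zero_rows <- rs == 0
  raw <- counts / ifelse(rs == 0, 1, rs)
  raw[zero_rows, ] <- 1 / 7
  out <- raw
  if (clamp) out <- clamp_unit(out, tau)
  if (renormalize) out <- out / rowSums(out)
  attr(out, "raw") <- raw
  attr(out, "counts") <- counts
  attr(out, "zero_rows") <- classes[zero_rows]
  out
}

#' Estimate class prevalence priors from the training image composition
#'
#' pi_T is the fraction of distinct training images whose true class is T.
#' Image counts (not decision counts) are used because training presentation
#' is counterbalanced across classes, so decision counts would distort
#' prevalence. Classes absent from the training split get a tau floor followed
#' by renormalization, and are flagged.
#'
#' @param table a `decision_table` with a non-empty train split.
#' @param tau floor for absent classes.
#' @return named 7-vector summing to 1, with attribute `floored` naming any
#'   absent classes.
#' @export
estimate_priors <- function(table, tau = 0.02) {
  stopifnot(inherits(table, "decision_table"))
  train <- table[table$split == "train", , drop = FALSE]
  if (nrow(train) == 0) stop("no training decisions: priors underivable",
                             call. = FALSE)
  classes <- lesion_classes()
  img <- unique(train[, c("image_id", "true_label")])
  n <- table(factor(img$true_label, levels = classes))
  pi <- as.numeric(n) / sum(n)
  floored <- classes[pi == 0]
  if (length(floored) > 0) {
    pi[pi == 0] <- tau
    pi <- pi / sum(pi)
  }
  names(pi) <- classes
  attr(pi, "floored") <- floored
  pi
}

#' Build annotator profiles and the group profile from a decision table
#'
#' Individual training accuracy is used whenever a participant has at least
#' one training decision. An individual confusion matrix is used only for
#' participants with `min_individual_n` or more training decisions (default
#' 100); everyone else falls back to the group-level confusion matrix with
#' `used_fallback = TRUE`. Participants present only in the test split get a
#' full group fallback (group accuracy and group confusion).
#'
#' @param table a `decision_table` (typically already cleaned).
#' @param min_individual_n minimum training decisions for an individual
#'   confusion matrix; the study's default is 100 (sensitivity value 500).
#' @param tau clamp threshold passed to [estimate_confusion()].
#' @param renormalize passed to [estimate_confusion()].
#' @return An `annotator_profiles` object: list with vectors `participant_id`,
#'   `n_train`, `train_accuracy`, `used_fallback`, a 7 x 7 x n array
#'   `confusion`, and the `group` profile (list with `confusion`, `priors`,
#'   `accuracy`, `tau`).
#' @export
build_profiles <- function(table, min_individual_n = 100, tau = 0.02,
                           renormalize = FALSE) {
  stopifnot(inherits(table, "decision_table"), min_individual_n >= 1,
            tau > 0, tau < 0.5)
  train <- table[table$split == "train", , drop = FALSE]
  if (nrow(train) == 0) {
    stop("empty train split: no profiles derivable", call. = FALSE)
  }
  classes <- lesion_classes()
  group_conf <- estimate_confusion(train, tau = tau, renormalize = renormalize)
  group <- list(
    confusion = group_conf,
    priors = estimate_priors(table, tau = tau),
    accuracy = mean(train$response == train$true_label),
    tau = tau
  )
  class(group) <- "group_profile"

  ids <- sort(unique(table$participant_id))
  n <- length(ids)
  pid_train <- factor(train$participant_id, levels = ids)
  n_train <- as.integer(table(pid_train))
  correct_full <- integer(n)
  seen <- levels(droplevels(pid_train))
  correct_full[match(seen, ids)] <- as.integer(
    rowsum(as.numeric(train$response == train$true_label), droplevels(pid_train)))
  acc <- ifelse(n_train > 0, correct_full / pmax(n_train, 1), group$accuracy)
  used_fallback <- n_train < min_individual_n

  conf <- array(rep(group_conf, n), dim = c(7, 7, n),
                dimnames = list(true = classes, response = classes,
                                participant = ids))
  own <- which(!used_fallback)
  for (k in own) {
    sub <- train[train$participant_id == ids[k], , drop = FALSE]
    conf[, , k] <- estimate_confusion(sub, tau = tau,
                                      renormalize = renormalize)
  }
  structure(list(
    participant_id = ids,
    n_train = n_train,
    train_accuracy = as.numeric(acc),
    used_fallback = used_fallback,
    confusion = conf,
    group = group,
    min_individual_n = min_individual_n,
    tau = tau
  ), class = "annotator_profiles")
}

#' Extract one annotator's profile
#' @param profiles an `annotator_profiles` object.
#' @param participant participant identifier.
#' @return An `annotator_profile` list: participant_id, n_train,
#'   train_accuracy, confusion (7x7), used_fallback.
#' @export
get_profile <- function(profiles, participant) {
  stopifnot(inherits(profiles, "annotator_profiles"))
  k <- match(participant, profiles$participant_id)
  if (is.na(k)) stop("no profile for participant '", participant, "'",
                     call. = FALSE)
  structure(list(
    participant_id = participant,
    n_train = profiles$n_train[k],
    train_accuracy = profiles$train_accuracy[k],
    confusion = profiles$confusion[, , k],
    used_fallback = profiles$used_fallback[k]
  ), class = "annotator_profile")
}

#' @export
print.annotator_profiles <- function(x, ...) {
  cat(sprintf(
    "annotator profiles: %d participants (%d with individual confusion, tau = %g)\n",
    length(x$participant_id), sum(!x$used_fallback), x$tau))
  invisible(x)
}

#' Serialize profiles to long CSV-ready tables
#' @param profiles an `annotator_profiles` object.
#' @return list of two data.frames: `summary` (one row per participant) and
#'   `confusion` (one row per participant x true class x response class).
#' @export
profiles_long <- function(profiles) {
  stopifnot(inherits(profiles, "annotator_profiles"))
  classes <- lesion_classes()
  summary <- data.frame(
    participant_id = profiles$participant_id,
    n_train = profiles$n_train,
    train_accuracy = profiles$train_accuracy,
    used_fallback = profiles$used_fallback
  )
  n <- length(profiles$participant_id)
  confusion <- data.frame(
    participant_id = rep(profiles$participant_id, each = 49),
    true_class = rep(rep(classes, times = 7), times = n),
    response_class = rep(rep(classes, each = 7), times = n),
    probability = as.vector(profiles$confusion)
  )
  list(summary = summary, confusion = confusion)
}
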