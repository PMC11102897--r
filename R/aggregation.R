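#' Aggregation configuration (one switchboard cell)
#'
#' Bundles one combination of weighting scheme, top-r selection size, prior
#' use, clamp threshold, and tie-break rules.
#'
#' Schemes: `"SV"` simple (plurality) voting; `"SAW"` simple accuracy
#' weighting (each vote counts its annotator's training accuracy a_j);
#' `"LAW_E"` log accuracy weighting with equal off-diagonal mass
#' (log a_j on the response, log((1 - a_j)/6) elsewhere); `"LAW_CA"` log
#' weighting by the group confusion matrix; `"LAW_CI"` log weighting by
#' individual confusion matrices with group fallback. Priors (`use_priors`)
#' add log pi_T once per image and are defined only in the log-probability
#' framework, so they are rejected for SV and SAW.
#'
#' @param scheme one of SV, SAW, LAW_E, LAW_CA, LAW_CI.
#' @param selection_r positive integer, or "ALL" to keep the full crowd.
#' @param use_priors add the log-prevalence prior (LAW schemes only).
#' @param tau clamp threshold for probabilities entering logarithms.
#' @param tie_break argmax tie rule: `"prior_frequency"` (highest training
#'   prevalence among tied classes, the default), `"lexicographic"` (class
#'   code order), or `"seeded_random"`.
#' @param selection_tie_break rank-tie rule when accuracies are equal:
#'   `"lexicographic"` (participant id, the default) or `"seeded_random"`.
#' @param seed integer seed used by the seeded_random rules.
#' @return An `aggregation_config`.
#' @export
aggregation_config <- function(scheme = c("SV", "SAW", "LAW_E", "LAW_CA", "LAW_CI"),
                               selection_r = "ALL",
                               use_priors = FALSE,
                               tau = 0.02,
                               tie_break = c("prior_frequency", "lexicographic",
                                             "seeded_random"),
                               selection_tie_break = c("lexicographic",
                                                       "seeded_random"),
                               seed = 1L) {
  scheme <- match.arg(scheme)
  tie_break <- match.arg(tie_break)
  selection_tie_break <- match.arg(selection_tie_break)
  if (!identical(selection_r, "ALL")) {
    selection_r <- as.integer(selection_r)
    stopifnot(length(selection_r) == 1, selection_r >= 1)
  }
  if (use_priors && scheme %in% c("SV", "SAW")) {
    stop("use_priors is defined only in the log-probability framework; ",
         "scheme ", scheme, " does not admit priors", call. = FALSE)
  }
  stopifnot(tau > 0, tau < 0.5)
  structure(list(scheme = scheme, selection_r = selection_r,
                 use_priors = use_priors, tau = tau, tie_break = tie_break,
                 selection_tie_break = selection_tie_break,
                 seed = as.integer(seed)),
            class = "aggregation_config")
}

#' @keywords internal
config_id <- function(config) {
  paste0(config$scheme,
         if (config$use_priors) "_P" else "",
         "_r", if (identical(config$selection_r, "ALL")) "ALL"
               else config$selection_r)
}

score_scale <- function(scheme) {
  switch(scheme, SV = "count", SAW = "accuracy", "log_probability")
}

#' Select the top-r decisions on one image by training accuracy
#'
#' Returns the `min(r, |crowd|)` decisions made by the annotators with the
#' highest training accuracy (an image with fewer decisions than r keeps them
#' all). Rank ties are broken lexicographically on participant id by default,
#' or by a seeded random shuffle. `r = "ALL"` returns the crowd unchanged.
#'
#' @param crowd `decision_table` rows for a single image.
#' @param profiles an `annotator_profiles` object covering every participant.
#' @param r positive integer or "ALL".
#' @param tie_break "lexicographic" or "seeded_random".
#' @param seed seed for the random rule.
#' @return the selected subset of `crowd` (rows in rank order).
#' @export
select_top_r <- function(crowd, profiles, r, tie_break = "lexicographic",
                         seed = 1L) {
  if (identical(r, "ALL")) return(crowd)
  r <- as.integer(r)
  stopifnot(r >= 1)
  k <- match(crowd$participant_id, profiles$participant_id)
  if (anyNA(k)) stop("decision from participant without a profile",
                     call. = FALSE)
  acc <- profiles$train_accuracy[k]
  ord <- if (tie_break == "lexicographic") {
    order(-acc, crowd$participant_id)
  } else {
    set.seed(seed)
    order(-acc, sample.int(nrow(crowd)))
  }
  crowd[ord[seq_len(min(r, nrow(crowd)))], , drop = FALSE]
}

#' Per-class weight contribution of one decision
#'
#' The weight function w_T(d) of a single decision under each scheme:
#' SV gives a one-hot vote; SAW puts the training accuracy a_j on the response
#' and 0 elsewhere; LAW_E puts log(a_j) on the response and
#' log((1 - a_j)/6) on the other six classes; LAW_CA and LAW_CI read
#' log(c\[d | T\]) off the group or individual confusion matrix column for the
#' observed response d. Probabilities are clamped into \[tau, 1 - tau\] before
#' any logarithm.
#'
#' @param response the decided class (one of [lesion_classes()]).
#' @param scheme weighting scheme.
#' @param profile an `annotator_profile` (from [get_profile()]).
#' @param tau clamp threshold.
#' @param group the `group_profile`; required for LAW_CA.
#' @return named 7-vector with attribute `scale`.
#' @export
decision_weights <- function(response, scheme, profile, tau = 0.02,
                             group = NULL) {
  classes <- lesion_classes()
  stopifnot(response %in% classes)
  d <- match(response, classes)
  w <- numeric(7)
  names(w) <- classes
  if (scheme == "SV") {
    w[d] <- 1
  } else if (scheme == "SAW") {
    w[d] <- profile$train_accuracy
  } else if (scheme == "LAW_E") {
    a <- clamp_unit(profile$train_accuracy, tau)
    w[] <- log((1 - a) / 6)
    w[d] <- log(a)
  } else if (scheme == "LAW_CA") {
    if (is.null(group)) stop("LAW_CA requires the group profile",
                             call. = FALSE)
    w[] <- log(clamp_unit(group$confusion[, d], tau))
  } else if (scheme == "LAW_CI") {
    w[] <- log(clamp_unit(profile$confusion[, d], tau))
  } else {
    stop("unknown scheme: ", scheme, call. = FALSE)
  }
  if (any(!is.finite(w))) {
    stop("internal error: non-finite decision weight despite clamping",
         call. = FALSE)
  }
  attr(w, "scale") <- score_scale(scheme)
  w
}

argmax_label <- function(scores, tie_break, priors = NULL, seed = 1L) {
  classes <- lesion_classes()
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  dec <- switch(tie_break,
    lexicographic = max.col(scores, ties.method = "first"),
    seeded_random = {
      set.seed(seed)
      max.col(scores, ties.method = "random")
    },
    prior_frequency = {
      if (is.null(priors)) stop("prior_frequency tie-break needs priors",
                                call. = FALSE)
      perm <- order(-priors)
      j <- max.col(scores[, perm, drop = FALSE], ties.method = "first")
      perm[j]
    },
    stop("unknown tie_break: ", tie_break, call. = FALSE))
  classes[dec]
}

#' Aggregate one image's crowd into a score vector and decision
#'
#' Applies top-r selection, sums the per-decision weights w_T(d) over the
#' surviving decisions, adds log pi_T once per class if `use_priors`, and
#' returns the full score vector together with the argmax decision D_i under
#' the configured tie-break.
#'
#' @param crowd `decision_table` rows for one image (non-empty).
#' @param config an [aggregation_config()].
#' @param profiles an `annotator_profiles` object.
#' @param group a `group_profile`; defaults to `profiles$group`.
#' @return list with `scores` (named 7-vector, attribute `scale`) and
#'   `decision` (class label).
#' @export
aggregate_image <- function(crowd, config, profiles, group = profiles$group) {
  if (nrow(crowd) == 0) stop("empty crowd: nothing to aggregate",
                             call. = FALSE)
  sel <- select_top_r(crowd, profiles, config$selection_r,
                      tie_break = config$selection_tie_break,
                      seed = config$seed)
  contrib <- lapply(seq_len(nrow(sel)), function(i) {
    decision_weights(sel$response[i], config$scheme,
                     get_profile(profiles, sel$participant_id[i]),
                     tau = config$tau, group = group)
  })
  scores <- Reduce(`+`, contrib)
  if (config$use_priors) scores <- scores + log(group$priors)
  attr(scores, "scale") <- score_scale(config$scheme)
  decision <- argmax_label(matrix(scores, nrow = 1), config$tie_break,
                           priors = group$priors, seed = config$seed)
  list(scores = scores, decision = decision)
}

#' Convert a log-probability score vector to posterior class probabilities
#'
#' Exponentiate-and-normalize with max subtraction for numerical stability.
#' Only defined for score vectors on the log-probability scale (the LAW
#' family); other scales are a contract error.
#'
#' @param scores named 7-vector (or matrix with 7 columns) with attribute
#'   `scale = "log_probability"`.
#' @return vector (or matrix) of probabilities summing to 1 per image.
#' @export
posterior_probabilities <- function(scores) {
  scale <- attr(scores, "scale")
  if (is.null(scale) || scale != "log_probability") {
    stop("posterior_probabilities requires scale = 'log_probability', got: ",
         if (is.null(scale)) "<missing>" else scale, call. = FALSE)
  }
  if (is.null(dim(scores))) {
    z <- exp(scores - max(scores))
    return(z / sum(z))
  }
  m <- apply(scores, 1, max)
  z <- exp(scores - m)
  z / rowSums(z)
}

# ---- vectorized fast path over a whole test split -------------------------

# per-decision selection rank within each image (1 = highest accuracy);
# computed once per (tie_break, seed) and reused across the grid.
selection_ranks <- function(df, profiles, tie_break = "lexicographic",
                            seed = 1L) {
  k <- match(df$participant_id, profiles$participant_id)
  if (anyNA(k)) stop("decision from participant without a profile",
                     call. = FALSE)
  acc <- profiles$train_accuracy[k]
  ord <- if (tie_break == "lexicographic") {
    order(df$image_id, -acc, df$participant_id)
  } else {
    set.seed(seed)
    order(df$image_id, -acc, sample.int(nrow(df)))
  }
  rank <- integer(nrow(df))
  img_sorted <- df$image_id[ord]
  rank[ord] <- stats::ave(seq_along(ord), img_sorted,
                          FUN = seq_along)
  rank
}

# weight matrix (n decisions x 7 classes) for a scheme
weight_matrix <- function(df, scheme, profiles, tau, group) {
  n <- nrow(df)
  resp <- match(df$response, lesion_classes())
  k <- match(df$participant_id, profiles$participant_id)
  if (scheme == "SV") {
    W <- matrix(0, n, 7)
    W[cbind(seq_len(n), resp)] <- 1
  } else if (scheme == "SAW") {
    W <- matrix(0, n, 7)
    W[cbind(seq_len(n), resp)] <- profiles$train_accuracy[k]
  } else if (scheme == "LAW_E") {
    a <- clamp_unit(profiles$train_accuracy[k], tau)
    W <- matrix(log((1 - a) / 6), n, 7)
    W[cbind(seq_len(n), resp)] <- log(a)
  } else if (scheme == "LAW_CA") {
    LG <- log(clamp_unit(group$confusion, tau))
    W <- t(LG[, resp, drop = FALSE])
  } else if (scheme == "LAW_CI") {
    la <- log(clamp_unit(profiles$confusion, tau))
    base <- (k - 1L) * 49L + (resp - 1L) * 7L
    idx <- outer(1:7, base, `+`)      # 7 x n
    W <- matrix(la[as.vector(idx)], n, 7, byrow = TRUE)
  } else {
    stop("unknown scheme: ", scheme, call. = FALSE)
  }
  W
}

# aggregate every image of the test split under one config; returns
# image-level scores, decisions, truths.
aggregate_split <- function(df, config, profiles, group,
                            ranks = NULL) {
  stopifnot(nrow(df) > 0)
  if (!identical(config$selection_r, "ALL")) {
    if (is.null(ranks)) {
      ranks <- selection_ranks(df, profiles, config$selection_tie_break,
                               config$seed)
    }
    df <- df[ranks <= config$selection_r, , drop = FALSE]
  }
  W <- weight_matrix(df, config$scheme, profiles, config$tau, group)
  img <- factor(df$image_id)
  S <- rowsum(W, img)
  colnames(S) <- lesion_classes()
  if (config$use_priors) {
    S <- S + matrix(log(group$priors), nrow(S), 7, byrow = TRUE)
  }
  truth <- df$true_label[!duplicated(df$image_id)]
  names(truth) <- df$image_id[!duplicated(df$image_id)]
  truth <- truth[rownames(S)]
  decision <- argmax_label(S, config$tie_break, priors = group$priors,
                           seed = config$seed)
  attr(S, "scale") <- score_scale(config$scheme)
  list(image_id = rownames(S), scores = S, decision = decision,
       truth = unname(truth))
}

#' The default switchboard grid
#'
#' Selection size r in 1..20 and ALL, crossed with the five weighting schemes,
#' crossed with prior use where permitted (LAW schemes only).
#'
#' @param r_values selection sizes (default `c(1:20, "ALL")`).
#' @param schemes weighting schemes to include.
#' @param priors logical values to cross with the LAW schemes.
#' @param tau,tie_break,selection_tie_break,seed passed to every cell.
#' @return list of [aggregation_config()] objects.
#' @export
default_grid <- function(r_values = c(as.list(1:20), list("ALL")),
                         schemes = c("SV", "SAW", "LAW_E", "LAW_CA", "LAW_CI"),
                         priors = c(FALSE, TRUE),
                         tau = 0.02, tie_break = "prior_frequency",
                         selection_tie_break = "lexicographic", seed = 1L) {
  if (!is.list(r_values)) r_values <- as.list(r_values)
  grid <- list()
  for (scheme in schemes) {
    pset <- if (scheme %in% c("SV", "SAW")) FALSE else priors
    for (p in pset) {
      for (r in r_values) {
        grid[[length(grid) + 1L]] <- aggregation_config(
          scheme = scheme, selection_r = r, use_priors = p, tau = tau,
          tie_break = tie_break, selection_tie_break = selection_tie_break,
          seed = seed)
      }
    }
  }
  grid
}

#' Run a switchboard of aggregation configurations over the test split
#'
#' Evaluates every configuration in `grid` on the test-split decisions of
#' `table`, retaining per-image decisions and score matrices for downstream
#' disagreement and bootstrap analysis, and computing the four study metrics
#' per configuration. Deterministic given the configs' seeds.
#'
#' @param table a `decision_table`; only `split == "test"` rows are
#'   aggregated.
#' @param grid list of [aggregation_config()] objects (see [default_grid()]).
#' @param profiles an `annotator_profiles` object.
#' @param group a `group_profile`; defaults to `profiles$group`.
#' @param keep_scores retain per-config score matrices (default TRUE).
#' @return A `switchboard_result`: list with `metrics` (long data.frame:
#'   config_id, scheme, selection_r, use_priors, metric, value), `decisions`
#'   (data.frame config_id x image_id with decision and truth), `scores`
#'   (named list of image x class matrices), and `configs`.
#' @export
run_switchboard <- function(table, grid, profiles, group = profiles$group,
                            keep_scores = TRUE) {
  stopifnot(inherits(table, "decision_table"), length(grid) > 0)
  test <- as.data.frame(table[table$split == "test", , drop = FALSE])
  if (nrow(test) == 0) stop("no test-split decisions to aggregate",
                            call. = FALSE)
  # selection ranks are scheme-independent; compute once per tie rule/seed
  rank_cache <- new.env(parent = emptyenv())
  get_ranks <- function(cfg) {
    key <- paste(cfg$selection_tie_break, cfg$seed)
    if (is.null(rank_cache[[key]])) {
      rank_cache[[key]] <- selection_ranks(test, profiles,
                                           cfg$selection_tie_break, cfg$seed)
    }
    rank_cache[[key]]
  }
  metrics <- vector("list", length(grid))
  decisions <- vector("list", length(grid))
  scores <- if (keep_scores) vector("list", length(grid)) else NULL
  ids <- character(length(grid))
  for (g in seq_along(grid)) {
    cfg <- grid[[g]]
    res <- aggregate_split(test, cfg, profiles, group, ranks = get_ranks(cfg))
    rep_ <- metric_report(res$decision, res$truth, scores = res$scores)
    cid <- config_id(cfg)
    ids[g] <- cid
    metrics[[g]] <- data.frame(
      config_id = cid, scheme = cfg$scheme,
      selection_r = if (identical(cfg$selection_r, "ALL")) NA_integer_
                    else cfg$selection_r,
      use_priors = cfg$use_priors,
      metric = c("accuracy", "balanced_accuracy", "mean_roc_auc",
                 "malignant_roc_auc"),
      value = c(rep_$accuracy, rep_$balanced_accuracy, rep_$mean_roc_auc,
                rep_$malignant_roc_auc)
    )
    decisions[[g]] <- data.frame(
      config_id = cid, image_id = res$image_id,
      decision = res$decision, true_label = res$truth
    )
    if (keep_scores) scores[[g]] <- res$scores
  }
  if (keep_scores) names(scores) <- ids
  structure(list(
    metrics = do.call(rbind, metrics),
    decisions = do.call(rbind, decisions),
    scores = scores,
    configs = stats::setNames(grid, ids)
  ), class = "switchboard_result")
}

#' @export
print.switchboard_result <- function(x, ...) {
  cat(sprintf("switchboard result: %d configurations x 4 metrics on %d images\n",
              length(x$configs),
              length(unique(x$decisions$image_id))))
  invisible(x)
}
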