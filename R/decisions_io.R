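#' Construct a decision table
#'
#' A decision table is the universal exchange format between pipeline stages:
#' one row per individual crowd decision, with columns `participant_id`,
#' `image_id`, `split` ("train"/"test"), `true_label`, `response` (both drawn
#' from [lesion_classes()]), `response_time_s` (seconds, NA allowed) and `day`
#' (integer index >= 1, NA allowed).
#'
#' @param df data.frame holding at least participant_id, image_id, split,
#'   true_label and response. Labels are normalized via [normalize_labels()].
#' @param provenance free-text note on where the records came from.
#' @return A `decision_table` (a validated data.frame).
#' @export
decision_table <- function(df, provenance = "unspecified") {
  required <- c("participant_id", "image_id", "split", "true_label", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("decision table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    participant_id = as.character(df$participant_id),
    image_id = as.character(df$image_id),
    split = tolower(trimws(as.character(df$split))),
    true_label = as.character(df$true_label),
    response = as.character(df$response),
    response_time_s = if ("response_time_s" %in% names(df))
      as.numeric(df$response_time_s) else NA_real_,
    day = if ("day" %in% names(df)) as.integer(df$day) else NA_integer_,
    stringsAsFactors = FALSE
  )

  bad_split <- which(!out$split %in% c("train", "test"))
  if (length(bad_split) > 0) {
    stop("decision table parse error: unknown split value(s) at row(s) ",
         paste(utils::head(bad_split, 5), collapse = ", "),
         ": ", paste(unique(df$split[utils::head(bad_split, 5)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("true_label", "response")) {
    norm <- normalize_labels(out[[col]])
    bad <- which(is.na(norm))
    if (length(bad) > 0) {
      stop("decision table parse error: unknown ", col, " value(s) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": ", paste(unique(out[[col]][utils::head(bad, 5)]), collapse = ", "),
           call. = FALSE)
    }
    out[[col]] <- norm
  }
  neg <- which(!is.na(out$response_time_s) & out$response_time_s < 0)
  # negative RTs are representable (they count as invalid for cleaning)
  bad_day <- which(!is.na(out$day) & out$day < 1L)
  if (length(bad_day) > 0) {
    stop("decision table parse error: day index < 1 at row(s) ",
         paste(utils::head(bad_day, 5), collapse = ", "), call. = FALSE)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("decision_table", "data.frame")
  out
}

#' Read a decision table from CSV/TSV
#'
#' @param path file path; delimiter is inferred from the extension
#'   (".tsv"/".tab" -> tab, otherwise comma) unless `delim` is given.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(participant_id = "user", response = "label")`.
#' @param delim optional single-character field delimiter.
#' @return A `decision_table`.
#' @export
read_decision_table <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("decision table format error: dialect column '", src,
             "' (for ", canon, ") not present in file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  decision_table(raw, provenance = path)
}

#' Write a decision table to CSV/TSV
#'
#' @param table a `decision_table`.
#' @param path output path; extension selects the delimiter as in
#'   [read_decision_table()].
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(table, path) {
  stopifnot(inherits(table, "decision_table"))
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard decisions with long or invalid response times
#'
#' Applies the study's cleaning rule: responses with response times strictly
#' longer than `max_rt` seconds (default 20), or with missing or negative
#' response times, are discarded. A response time of exactly `max_rt` is kept.
#'
#' @param table a `decision_table`.
#' @param max_rt positive cutoff in seconds.
#' @return list with elements `table` (the cleaned `decision_table`) and
#'   `report` (a `cleaning_report` with counts and the fraction dropped).
#' @export
clean_decisions <- function(table, max_rt = 20) {
  stopifnot(inherits(table, "decision_table"), max_rt > 0)
  rt <- table$response_time_s
  missing <- is.na(rt)
  negative <- !missing & rt < 0
  too_long <- !missing & !negative & rt > max_rt
  keep <- !(missing | negative | too_long)
  n <- nrow(table)
  report <- structure(list(
    n_input = n,
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    n_over_max = sum(too_long),
    n_missing = sum(missing),
    n_negative = sum(negative),
    max_rt = max_rt,
    fraction_dropped = if (n == 0) 0 else sum(!keep) / n
  ), class = "cleaning_report")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("decision_table", "data.frame")
  list(table = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "cleaning report: %d of %d decisions dropped (%.2f%%): %d RT > %gs, %d missing, %d negative\n",
    x$n_dropped, x$n_input, 100 * x$fraction_dropped,
    x$n_over_max, x$max_rt, x$n_missing, x$n_negative))
  invisible(x)
}

#' Serialize a cleaning report to a long data.frame
#' @param report a `cleaning_report`.
#' @return data.frame with columns statistic, value.
#' @export
cleaning_report_long <- function(report) {
  stopifnot(inherits(report, "cleaning_report"))
  data.frame(statistic = names(unlist(report)),
             value = unname(unlist(report)))
}

#' Summarize a decision table
#'
#' Computes the dataset descriptives used throughout the study: per-split
#' image composition (counts and percentages per class, to one decimal,
#' half-up), per-participant decision counts and train/test accuracies,
#' per-image decision-count distributions, and participation strata by number
#' of training decisions.
#'
#' @param table a `decision_table`.
#' @param strata_breaks left-closed break points for the training-decision
#'   strata (defaults to the study's 0-100, 100-500, ..., 10000+ bins).
#' @return A `dataset_summary` list with components `composition`,
#'   `participants`, `image_counts`, and `strata`.
#' @export
summarize_table <- function(table,
                            strata_breaks = c(0, 100, 500, 1000, 3000, 5000,
                                              10000, 1e6)) {
  stopifnot(inherits(table, "decision_table"))
  df <- as.data.frame(table)
  classes <- lesion_classes()

  composition <- do.call(rbind, lapply(c("train", "test"), function(s) {
    sub <- df[df$split == s, , drop = FALSE]
    img_class <- unique(sub[, c("image_id", "true_label")])
    n <- table(factor(img_class$true_label, levels = classes))
    total <- sum(n)
    data.frame(split = s, class = classes, n_images = as.integer(n),
               percent = if (total == 0) rep(NA_real_, length(classes))
                         else round_half_up(100 * as.integer(n) / total, 1))
  }))

  correct <- df$response == df$true_label
  is_train <- df$split == "train"
  pid <- df$participant_id
  ids <- sort(unique(pid))
  agg <- function(mask) {
    cnt <- tapply(rep(1L, sum(mask)), pid[mask], sum)
    cor <- tapply(correct[mask], pid[mask], sum)
    list(n = cnt, correct = cor)
  }
  tr <- agg(is_train); te <- agg(!is_train)
  get0i <- function(v, ids) {
    out <- v[ids]; out[is.na(out)] <- 0; as.integer(out)
  }
  n_train <- get0i(tr$n, ids); n_test <- get0i(te$n, ids)
  c_train <- get0i(tr$correct, ids); c_test <- get0i(te$correct, ids)
  participants <- data.frame(
    participant_id = ids,
    n_train = n_train, n_test = n_test, n_total = n_train + n_test,
    train_accuracy = ifelse(n_train > 0, c_train / n_train, NA_real_),
    test_accuracy = ifelse(n_test > 0, c_test / n_test, NA_real_)
  )

  image_counts <- do.call(rbind, lapply(c("train", "test"), function(s) {
    sub <- df[df$split == s, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(split = s, n_images = 0L, min = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        max = NA_real_, mean = NA_real_))
    }
    cnt <- as.integer(table(sub$image_id))
    q <- stats::quantile(cnt, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(split = s, n_images = length(cnt), min = min(cnt), q1 = q[1],
               median = q[2], q3 = q[3], max = max(cnt), mean = mean(cnt))
  }))

  br <- strata_breaks
  lab <- paste0(utils::head(br, -1), "-", utils::tail(br, -1))
  bin <- cut(participants$n_train, breaks = br, labels = lab, right = FALSE,
             include.lowest = TRUE)
  total_dec <- nrow(df)
  strata <- do.call(rbind, lapply(levels(bin), function(b) {
    m <- !is.na(bin) & bin == b
    nd <- sum(participants$n_total[m])
    data.frame(
      stratum = b,
      n_individuals = sum(m),
      pct_individuals = round_half_up(100 * sum(m) / nrow(participants), 2),
      pct_decisions = round_half_up(100 * nd / max(total_dec, 1), 2),
      mean_train_accuracy = if (any(m & participants$n_train > 0))
        mean(participants$train_accuracy[m], na.rm = TRUE) else NA_real_,
      mean_test_accuracy = if (any(m & participants$n_test > 0))
        mean(participants$test_accuracy[m], na.rm = TRUE) else NA_real_
    )
  }))

  structure(list(composition = composition, participants = participants,
                 image_counts = image_counts, strata = strata),
            class = "dataset_summary")
}

#' Flatten a dataset summary to one long CSV-ready table
#' @param summary a `dataset_summary` from [summarize_table()].
#' @return data.frame with columns section, stratum, statistic, value.
#' @export
summary_long <- function(summary) {
  stopifnot(inherits(summary, "dataset_summary"))
  pieces <- lapply(names(summary), function(nm) {
    d <- summary[[nm]]
    key_cols <- intersect(c("split", "class", "participant_id", "stratum"),
                          names(d))
    stat_cols <- setdiff(names(d), key_cols)
    key <- do.call(paste, c(d[key_cols], sep = "/"))
    do.call(rbind, lapply(stat_cols, function(sc) {
      data.frame(section = nm, stratum = key, statistic = sc,
                 value = as.numeric(d[[sc]]))
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
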