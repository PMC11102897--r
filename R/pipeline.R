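#' Derive a stage seed from a master seed
#'
#' One master seed spawns per-stage seeds by a fixed affine scheme (kept below
#' 2^31), so stages can be rerun independently yet reproducibly.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stages <- c(annotators = 1L, decisions = 2L, profiles = 3L,
              switchboard = 4L, bootstrap = 5L, crowd_size = 6L,
              selection = 7L, misc = 8L)
  idx <- unname(stages[stage])
  if (is.na(idx)) idx <- 99L
  as.integer((as.numeric(master) * 48271 + 1009 * idx) %% 2147483629)
}

#' Assemble or load a pipeline run configuration
#'
#' Exactly one of `input` (path to a decision-table CSV/TSV) or `simulation`
#' (a list of [simulation_config()] arguments, or TRUE for defaults) must be
#' given. Remaining fields control cleaning, profiling, the switchboard grid
#' and evaluation; any omitted seed is derived from `seed` via
#' [derive_seed()].
#'
#' @param input optional path to a decision table.
#' @param simulation optional simulation block (list of overrides or TRUE).
#' @param max_rt cleaning cutoff in seconds.
#' @param min_individual_n,tau profiling parameters.
#' @param grid list: `r_values`, `schemes`, `priors` for [default_grid()];
#'   NULL uses the full default grid.
#' @param n_boot bootstrap resamples for headline comparisons.
#' @param sizes crowd-size curve sizes.
#' @param reps crowd-size curve repetitions.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL, max_rt = 20,
                       min_individual_n = 100, tau = 0.02, grid = NULL,
                       n_boot = 10000, sizes = c(1, 2, 4, 8, 16, "ALL"),
                       reps = 25, seed = 1L) {
  if (is.null(input) == is.null(simulation)) {
    stop("run config error: exactly one of `input` or `simulation` must be set",
         call. = FALSE)
  }
  structure(list(input = input, simulation = simulation, max_rt = max_rt,
                 min_individual_n = min_individual_n, tau = tau, grid = grid,
                 n_boot = n_boot, sizes = sizes, reps = reps,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file with the [run_config()] fields (nested `simulation`
#'   section allowed).
#' @param seed optional master-seed override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(seed)) raw$seed <- seed
  if (is.null(raw$seed)) {
    raw$seed <- 1L
    message("no seed in config; master seed 1 derived and logged")
  }
  do.call(run_config, raw)
}

build_sim_config <- function(config) {
  args <- config$simulation
  if (isTRUE(args)) args <- list()
  if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "annotators")
  do.call(simulation_config, args)
}

resolve_table <- function(config) {
  if (!is.null(config$input)) {
    list(table = read_decision_table(config$input), truth = NULL)
  } else {
    simulate_crowd(build_sim_config(config))
  }
}

#' Simulate a crowd and write its artifacts
#'
#' Writes `decisions.csv` (the decision table), `truth_annotators.csv` and
#' `truth_confusion.csv` (ground-truth sidecars), `truth_images.csv`, and a
#' `manifest.json` recording the configuration. Byte-identical across reruns
#' with the same seed.
#'
#' @param config a `run_config` with a simulation block.
#' @param outdir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
cmd_simulate <- function(config, outdir) {
  if (is.null(config$simulation)) {
    stop("cmd_simulate requires a simulation block", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_crowd(build_sim_config(config))
  paths <- list(
    decisions = file.path(outdir, "decisions.csv"),
    annotators = file.path(outdir, "truth_annotators.csv"),
    confusion = file.path(outdir, "truth_confusion.csv"),
    images = file.path(outdir, "truth_images.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_decision_table(sim$table, paths$decisions)
  utils::write.csv(sim$truth$participants, paths$annotators, row.names = FALSE)
  classes <- lesion_classes()
  n <- dim(sim$truth$confusion)[3]
  conf_long <- data.frame(
    participant_id = rep(sim$truth$participants$participant_id, each = 49),
    true_class = rep(rep(classes, times = 7), times = n),
    response_class = rep(rep(classes, each = 7), times = n),
    probability = as.vector(sim$truth$confusion)
  )
  utils::write.csv(conf_long, paths$confusion, row.names = FALSE)
  utils::write.csv(sim$truth$images, paths$images, row.names = FALSE)
  manifest <- list(stage = "simulate", seed = config$seed,
                   simulation = config$simulation,
                   n_decisions = nrow(sim$table))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}

#' Run the full aggregation pipeline and write result artifacts
#'
#' Stages: load or simulate the decision table; clean (RT filter); build
#' profiles; run the switchboard grid; bootstrap each r = ALL weighting
#' algorithm against simple voting on all four metrics; compute the pairwise
#' disagreement matrix of the r = ALL algorithms; compute the crowd-size
#' curve (SV) and the selection curve (SV across r). Artifacts are long-format
#' CSVs plus a `manifest.json`; all stages are seeded from the master seed.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory stage results.
#' @export
cmd_run <- function(config, outdir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  src <- resolve_table(config)
  say("stage input: %d decisions", nrow(src$table))
  cleaned <- clean_decisions(src$table, max_rt = config$max_rt)
  say("stage clean: dropped %d (%.2f%%)", cleaned$report$n_dropped,
      100 * cleaned$report$fraction_dropped)
  tab <- cleaned$table

  profiles <- build_profiles(tab, min_individual_n = config$min_individual_n,
                             tau = config$tau)
  say("stage profile: %d participants, %d individual confusion matrices",
      length(profiles$participant_id), sum(!profiles$used_fallback))

  grid <- if (is.null(config$grid)) {
    default_grid(tau = config$tau, seed = derive_seed(config$seed, "switchboard"))
  } else {
    do.call(default_grid, c(config$grid,
                            list(tau = config$tau,
                                 seed = derive_seed(config$seed, "switchboard"))))
  }
  sw <- run_switchboard(tab, grid, profiles)
  say("stage switchboard: %d configurations", length(sw$configs))

  # headline comparisons: each r = ALL weighting algorithm vs SV
  all_ids <- names(sw$configs)[vapply(sw$configs, function(cfg)
    identical(cfg$selection_r, "ALL"), logical(1))]
  sv_id <- "SV_rALL"
  comparisons <- list()
  if (sv_id %in% all_ids && length(all_ids) > 1) {
    outcome <- function(cid) {
      d <- sw$decisions[sw$decisions$config_id == cid, ]
      list(decisions = d$decision, truths = d$true_label,
           scores = sw$scores[[cid]])
    }
    base <- outcome(sv_id)
    for (cid in setdiff(all_ids, sv_id)) {
      oc <- outcome(cid)
      for (m in c("accuracy", "balanced_accuracy", "mean_roc_auc",
                  "malignant_roc_auc")) {
        cr <- bootstrap_ci_difference(oc, base, m, n_boot = config$n_boot,
                                      seed = derive_seed(config$seed,
                                                         "bootstrap"))
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          config_id = cid, reference = sv_id, metric = m,
          difference = cr$difference, ci_low = cr$ci_low,
          ci_high = cr$ci_high, n_boot = cr$n_boot)
      }
    }
    say("stage bootstrap: %d comparisons vs %s", length(comparisons), sv_id)
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL

  dis <- NULL
  if (length(all_ids) >= 2) {
    dl <- lapply(all_ids, function(cid) {
      d <- sw$decisions[sw$decisions$config_id == cid, ]
      stats::setNames(d$decision, d$image_id)
    })
    names(dl) <- all_ids
    dis <- disagreement_matrix(dl)
  }

  sv_cfg <- aggregation_config("SV", seed = derive_seed(config$seed,
                                                        "crowd_size"))
  curve <- crowd_size_curve(tab, config$sizes, sv_cfg, profiles,
                            reps = config$reps,
                            seed = derive_seed(config$seed, "crowd_size"))
  say("stage crowd-size curve: %d sizes", length(config$sizes))

  selection <- sw$metrics[sw$metrics$scheme == "SV", ]

  utils::write.csv(sw$metrics, file.path(outdir, "switchboard_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(sw$decisions, file.path(outdir, "per_image_decisions.csv"),
                   row.names = FALSE)
  if (!is.null(comparisons)) {
    utils::write.csv(comparisons, file.path(outdir, "bootstrap_vs_sv.csv"),
                     row.names = FALSE)
  }
  if (!is.null(dis)) {
    utils::write.csv(data.frame(algorithm = rownames(dis), dis,
                                check.names = FALSE),
                     file.path(outdir, "disagreement_matrix.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(curve, file.path(outdir, "crowd_size_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(selection, file.path(outdir, "selection_curve.csv"),
                   row.names = FALSE)
  manifest <- list(
    stage = "run", seed = config$seed, max_rt = config$max_rt,
    min_individual_n = config$min_individual_n, tau = config$tau,
    n_boot = config$n_boot, n_configs = length(sw$configs),
    n_decisions_in = cleaned$report$n_input,
    n_decisions_kept = cleaned$report$n_kept,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = c("switchboard_metrics.csv", "per_image_decisions.csv",
                  "bootstrap_vs_sv.csv", "disagreement_matrix.csv",
                  "crowd_size_curve.csv", "selection_curve.csv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(table = tab, cleaning = cleaned$report, profiles = profiles,
                 switchboard = sw, comparisons = comparisons,
                 disagreement = dis, crowd_size = curve,
                 selection = selection))
}

#' Per-decision, per-image and dataset labeling costs
#'
#' Per-decision cost is the total payout divided by the number of decisions,
#' reported to 4 decimals; per-image and dataset costs are derived from it.
#' A single-reader time estimate (images x seconds per decision) is reported
#' alongside.
#'
#' @param n_decisions total number of decisions collected (> 0).
#' @param total_payout total payout in currency units (>= 0).
#' @param per_image decisions collected per image.
#' @param n_images number of images in the dataset.
#' @param seconds_per_decision single-reader seconds per decision (default
#'   8.5).
#' @return A `cost_report` list.
#' @export
cmd_cost_summary <- function(n_decisions, total_payout, per_image, n_images,
                             seconds_per_decision = 8.5) {
  if (n_decisions <= 0) stop("zero decisions: cost undefined", call. = FALSE)
  stopifnot(total_payout >= 0, per_image > 0, n_images > 0)
  per_decision <- round(total_payout / n_decisions, 4)
  per_image_cost <- per_decision * per_image
  dataset_cost <- per_image_cost * n_images
  structure(list(
    n_decisions = n_decisions, total_payout = total_payout,
    per_decision_cost = per_decision,
    per_image_cost = per_image_cost,
    dataset_cost = dataset_cost,
    single_reader_hours = n_images * seconds_per_decision / 3600
  ), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(
    "cost: %.4f per decision; %.4f per image; %.2f for the dataset; single reader ~%.1f h\n",
    x$per_decision_cost, x$per_image_cost, x$dataset_cost,
    x$single_reader_hours))
  invisible(x)
}

parse_cli_flags <- function(args) {
  flags <- list()
  pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        flags[[kv[1]]] <- kv[2]
      } else {
        flags[[key]] <- if (i < length(args) && !startsWith(args[i + 1L], "--")) {
          i <- i + 1L
          args[i]
        } else TRUE
      }
    } else {
      pos <- c(pos, a)
    }
    i <- i + 1L
  }
  list(flags = flags, positional = pos)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `clean`, `profile`, `aggregate`, `evaluate`,
#' `switchboard`, `cost`, `run`. Common flags: `--config <json>`,
#' `--seed <int>`, `--outdir <dir>`, `--input <csv>`, `--log-level quiet`.
#' Designed to be called from an Rscript wrapper, e.g.
#' `Rscript -e 'crowdlaw::crowd_cli()' run --config cfg.json --outdir out`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return exit status, invisibly (0 on success).
#' @export
crowd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: crowdlaw <simulate|clean|profile|aggregate|evaluate|switchboard|cost|run> [--config f.json] [--seed n] [--outdir d] [--input f.csv]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  p <- parse_cli_flags(args[-1])
  fl <- p$flags
  quiet <- identical(fl[["log-level"]], "quiet")
  outdir <- if (!is.null(fl$outdir)) fl$outdir else "."
  seed <- if (!is.null(fl$seed)) as.integer(fl$seed) else NULL
  get_config <- function(need_sim = FALSE) {
    if (!is.null(fl$config)) {
      read_run_config(fl$config, seed = seed)
    } else if (!is.null(fl$input)) {
      run_config(input = fl$input, seed = if (is.null(seed)) 1L else seed)
    } else if (need_sim || is.null(fl$input)) {
      if (is.null(seed)) {
        seed <- 1L
        message("no seed given; master seed 1 derived and logged")
      }
      run_config(simulation = TRUE, seed = seed)
    }
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cmd_simulate(get_config(need_sim = TRUE), outdir)
        0L
      },
      clean = {
        cfg <- get_config()
        src <- resolve_table(cfg)
        cl <- clean_decisions(src$table, max_rt = cfg$max_rt)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        write_decision_table(cl$table, file.path(outdir, "decisions_clean.csv"))
        utils::write.csv(cleaning_report_long(cl$report),
                         file.path(outdir, "cleaning_report.csv"),
                         row.names = FALSE)
        if (!quiet) print(cl$report)
        0L
      },
      profile = {
        cfg <- get_config()
        src <- resolve_table(cfg)
        tab <- clean_decisions(src$table, max_rt = cfg$max_rt)$table
        pr <- build_profiles(tab, min_individual_n = cfg$min_individual_n,
                             tau = cfg$tau)
        long <- profiles_long(pr)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(long$summary,
                         file.path(outdir, "profiles_summary.csv"),
                         row.names = FALSE)
        utils::write.csv(long$confusion,
                         file.path(outdir, "profiles_confusion.csv"),
                         row.names = FALSE)
        0L
      },
      aggregate = ,
      switchboard = {
        cfg <- get_config()
        src <- resolve_table(cfg)
        tab <- clean_decisions(src$table, max_rt = cfg$max_rt)$table
        pr <- build_profiles(tab, min_individual_n = cfg$min_individual_n,
                             tau = cfg$tau)
        grid <- if (cmd == "aggregate") {
          list(aggregation_config(
            scheme = if (!is.null(fl$scheme)) fl$scheme else "SV",
            selection_r = if (!is.null(fl$r)) fl$r else "ALL",
            use_priors = isTRUE(as.logical(fl$priors)),
            tau = cfg$tau))
        } else if (is.null(cfg$grid)) {
          default_grid(tau = cfg$tau)
        } else {
          do.call(default_grid, c(cfg$grid, list(tau = cfg$tau)))
        }
        sw <- run_switchboard(tab, grid, pr)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(sw$metrics,
                         file.path(outdir, "switchboard_metrics.csv"),
                         row.names = FALSE)
        utils::write.csv(sw$decisions,
                         file.path(outdir, "per_image_decisions.csv"),
                         row.names = FALSE)
        0L
      },
      evaluate = {
        if (is.null(fl$decisions)) {
          stop("evaluate needs --decisions <per_image_decisions.csv>",
               call. = FALSE)
        }
        d <- utils::read.csv(fl$decisions, stringsAsFactors = FALSE)
        rows <- lapply(split(d, d$config_id), function(dd) {
          mr <- metric_report(dd$decision, dd$true_label)
          data.frame(config_id = dd$config_id[1],
                     metric = c("accuracy", "balanced_accuracy"),
                     value = c(mr$accuracy, mr$balanced_accuracy))
        })
        res <- do.call(rbind, rows)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(res, file.path(outdir, "evaluation_metrics.csv"),
                         row.names = FALSE)
        0L
      },
      cost = {
        rep_ <- cmd_cost_summary(
          n_decisions = as.numeric(fl$decisions),
          total_payout = as.numeric(fl$payout),
          per_image = if (!is.null(fl[["per-image"]]))
            as.numeric(fl[["per-image"]]) else 8,
          n_images = if (!is.null(fl$images)) as.numeric(fl$images) else 1511)
        print(rep_)
        0L
      },
      run = {
        cmd_run(get_config(), outdir, quiet = quiet)
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        1L
      })
  }, error = function(e) {
    message("stage '", cmd, "' failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
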