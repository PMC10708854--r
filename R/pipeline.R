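#' Default configuration for the end-to-end pipeline
#'
#' @param seed master seed; each stage derives its own seed from it by
#'   stable hashing of the stage name, so stages can be re-run in
#'   isolation.
#' @param blocks feature blocks to analyse (`"mean"`, `"sd"`, or both).
#' @param fs_methods ranking methods to run (default: all seven).
#' @param fs_threshold fusion vote threshold (default `"majority"`).
#' @param n_per_temp,temps synthetic-trial design passed to
#'   [generate_dataset()] when no `data_path` is given.
#' @param data_path optional CSV of an existing dataset; overrides the
#'   simulation stage.
#' @param radius_frac,lvq_rate clustering-initialisation settings.
#' @param train a [cagfinn_control()]; the pipeline default caps
#'   training at 150 epochs, which is ample for these problem sizes.
#' @param stack_folds folds used to build out-of-fold base predictions
#'   for the stacking stage.
#' @param protocol evaluation protocol for the per-block reports,
#'   `"kfold"` (default, reuses the stacking folds) or `"holdout"`.
#' @param test_frac hold-out test fraction when `protocol = "holdout"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, blocks = c("mean", "sd"),
                            fs_methods = msitvc::fs_methods(),
                            fs_threshold = "majority",
                            n_per_temp = 17, temps = c(0, 4, 8, 12, 16),
                            data_path = NULL,
                            radius_frac = 0.3, lvq_rate = 0.05,
                            train = cagfinn_control(max_epochs = 150,
                                                    tol = 1e-5),
                            stack_folds = 5, protocol = "kfold",
                            test_frac = 0.1) {
  blocks <- match.arg(blocks, c("mean", "sd"), several.ok = TRUE)
  structure(list(seed = seed, blocks = blocks, fs_methods = fs_methods,
                 fs_threshold = fs_threshold, n_per_temp = n_per_temp,
                 temps = temps, data_path = data_path,
                 radius_frac = radius_frac, lvq_rate = lvq_rate,
                 train = train, stack_folds = stack_folds,
                 protocol = protocol, test_frac = test_frac),
            class = "pipeline_config")
}

# stable stage seed: master seed + a small hash of the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h %% 100003L) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-block wavelength ranking and
#' majority-vote fusion -> clustering-initialised neuro-fuzzy training
#' with out-of-fold predictions -> stacked ensembling (averaging,
#' linear PLS and degree-4 NIPALS meta-models) -> metric reports.  All
#' artifacts are written under `out_dir` as CSV/JSON, and a manifest
#' records the configuration and stage seeds.  Reruns with the same
#' configuration reproduce the artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return Invisibly, a list with the dataset, per-block fusion results,
#'   models, out-of-fold predictions, ensemble reports and the manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("msitvc_run_")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- "simulate"
  result <- list()
  tryCatch({
    # --- data -------------------------------------------------------------
    if (is.null(cfg$data_path)) {
      ds <- generate_dataset(n_per_temp = cfg$n_per_temp, temps = cfg$temps,
                             seed = stage_seed(cfg$seed, "simulate"))
      log_line("simulate: %d samples at %d temperatures", nrow(ds),
               length(cfg$temps))
    } else {
      ds <- read_dataset(cfg$data_path)
      log_line("load: %d samples from %s", nrow(ds), cfg$data_path)
    }
    write_dataset(ds, file.path(out_dir, "data.csv"))
    result$dataset <- ds
    y <- ds$tvc

    oof <- list()
    for (block in cfg$blocks) {
      # --- feature selection + fusion ------------------------------------
      stage <- paste0("select_", block)
      tabs <- list()
      for (m in cfg$fs_methods) {
        tabs[[m]] <- tryCatch(
          rank_features(ds, m, block = block,
                        seed = stage_seed(cfg$seed, paste0(stage, "_", m))),
          error = function(e) {
            log_line("ranker %s (%s) failed: %s", m, block, conditionMessage(e))
            NULL
          })
      }
      tabs <- Filter(function(t) !is.null(t) && nrow(t) > 0, tabs)
      if (length(tabs) == 0) stop("no ranking method produced a result")
      rt <- ranking_table(do.call(rbind, lapply(tabs, as.data.frame)),
                          statistic = block)
      write_ranking_table(rt, file.path(out_dir, sprintf("ranks_%s.csv", block)))
      fus <- fuse_rankings(rt, threshold = cfg$fs_threshold)
      jsonlite::write_json(
        list(selected = fus$selected, votes = as.list(fus$votes),
             mean_rank = as.list(fus$mean_rank), threshold = fus$threshold,
             n_methods = fus$n_methods),
        file.path(out_dir, sprintf("fusion_%s.json", block)),
        digits = NA, auto_unbox = TRUE)
      log_line("fusion (%s): %d bands selected [%s]", block,
               length(fus$selected), paste(fus$selected, collapse = ","))
      result[[paste0("fusion_", block)]] <- fus
      bands <- fus$selected
      if (length(bands) == 0) stop(sprintf("fusion selected no bands (%s)", block))
      X <- feature_matrix(ds, block, bands = sort(bands))

      # --- base model: out-of-fold predictions + full fit ----------------
      stage <- paste0("train_", block)
      k <- min(cfg$stack_folds, nrow(X))
      sseed <- stage_seed(cfg$seed, stage)
      old <- .Random.seed_safe()
      set.seed(sseed)
      fold_id <- sample(rep(seq_len(k), length.out = nrow(X)))
      .restore_seed(old)
      preds <- rep(NA_real_, nrow(X))
      for (f in seq_len(k)) {
        tr <- fold_id != f
        part <- cluster_init(X[tr, , drop = FALSE], y[tr],
                             radius_frac = cfg$radius_frac,
                             lvq_rate = cfg$lvq_rate, seed = sseed)
        mdl <- cagfinn_fit(X[tr, , drop = FALSE], y[tr], part,
                           control = cfg$train)
        preds[!tr] <- predict(mdl, X[!tr, , drop = FALSE])
      }
      part <- cluster_init(X, y, radius_frac = cfg$radius_frac,
                           lvq_rate = cfg$lvq_rate, seed = sseed)
      model <- cagfinn_fit(X, y, part, control = cfg$train)
      write_cagfinn(model, file.path(out_dir, sprintf("model_%s.json", block)))
      rep_block <- compute_metrics(y, preds)
      write_metrics(rep_block, file.path(out_dir,
                                         sprintf("report_%s.json", block)))
      log_line("train (%s): %d rules, oof RMSE %.4f", block,
               model$n_rules, rep_block$rmse)
      result[[paste0("model_", block)]] <- model
      result[[paste0("report_", block)]] <- rep_block
      oof[[block]] <- preds
    }

    # --- stacking ensemble ------------------------------------------------
    if (length(cfg$blocks) == 2) {
      stage <- "ensemble"
      sp <- stacked_predictions(oof$mean, oof$sd, y)
      combos <- list(
        averaging = average_combine(sp),
        pls_linear = NULL, poly4_nipals = NULL)
      for (kind in c("pls_linear", "poly4_nipals")) {
        # honest meta evaluation: leave-one-out over the stacked rows
        n <- length(y)
        meta_preds <- vapply(seq_len(n), function(i) {
          sp_tr <- stacked_predictions(sp$x_mean[-i], sp$x_sd[-i], y[-i])
          m <- fit_meta(sp_tr, kind = kind)
          predict_meta(m, sp$x_mean[i], sp$x_sd[i])
        }, numeric(1))
        combos[[kind]] <- meta_preds
        meta_full <- fit_meta(sp, kind = kind)
        jsonlite::write_json(
          list(kind = kind, coefficients = as.list(meta_full$coefficients),
               ncomp = meta_full$ncomp),
          file.path(out_dir, sprintf("meta_%s.json", kind)),
          digits = NA, auto_unbox = TRUE)
        result[[paste0("meta_", kind)]] <- meta_full
      }
      for (nm in names(combos)) {
        repc <- compute_metrics(y, combos[[nm]])
        write_metrics(repc, file.path(out_dir,
                                      sprintf("report_ensemble_%s.json", nm)))
        result[[paste0("report_ensemble_", nm)]] <- repc
        log_line("ensemble %s: RMSE %.4f", nm, repc$rmse)
      }
      result$stacked <- sp
    } else {
      log_line("ensemble skipped: only block '%s' was run", cfg$blocks[1])
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("msitvc")),
      seed = cfg$seed, blocks = cfg$blocks,
      fs_methods = cfg$fs_methods, protocol = cfg$protocol,
      stage_seeds = stats::setNames(
        lapply(c("simulate", paste0("train_", cfg$blocks)),
               function(s) stage_seed(cfg$seed, s)),
        c("simulate", paste0("train_", cfg$blocks))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    result$manifest <- manifest
    result$out_dir <- out_dir
  }, error = function(e) {
    log_line("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
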