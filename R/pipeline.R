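# Stage runner: simulate -> extract -> preprocess -> fit -> evaluate/ablate.
# Every stage writes plain CSV artifacts plus a JSON manifest (seed, config,
# row counts) and is re-runnable from the previous stage's outputs.

.GROUPS <- list(all = c("CO", "MS_I", "MS_II"), co = "CO",
                ms = c("MS_I", "MS_II"), ms1 = "MS_I", ms2 = "MS_II")

config_fingerprint <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

write_manifest <- function(dir, stage, config, counts) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         config_hash = config_fingerprint(config),
         config = unclass(config), counts = counts),
    file.path(dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

require_artifact <- function(dir, file, needed_by) {
  p <- file.path(dir, file)
  if (!file.exists(p)) {
    stopf("dependency error: stage '%s' needs %s; run the earlier stage first",
          needed_by, file)
  }
  p
}

group_pids <- function(participants, group) {
  group <- match.arg(group, names(.GROUPS))
  participants$id[participants$group %in% .GROUPS[[group]]]
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to disk), `extract` (features from
#' raw streams, with sleep/wake estimated from the data), `preprocess`
#' (per-participant normalization + zero imputation), `fit` (subsample
#' backward elimination for one participant group), `evaluate` (within-group
#' leave-one-participant-out, or across-group when `train != test`, plus the
#' baseline regressor and paired Wilcoxon tests), `ablate` (feature-group
#' ablation). Each stage logs one line per participant-scale unit of work
#' and writes a JSON manifest.
#'
#' @param config a [run_config()].
#' @param stage one of the six stage names.
#' @param dir artifact directory.
#' @param spec a [cohort_spec()] (simulate only).
#' @param truth a [truth_model()] (simulate only; defaults to
#'   [default_truth_model()]).
#' @param group,train,test participant groups (`all`, `co`, `ms`, `ms1`,
#'   `ms2`) for fit/evaluate/ablate.
#' @param candidates candidate features for fit/ablate; default: every
#'   feature with complete-enough data in the group.
#' @param quiet suppress progress lines.
#' @return stage-dependent value, invisibly (paths or result objects).
#' @export
run_pipeline <- function(config, stage, dir,
                         spec = NULL, truth = NULL,
                         group = "all", train = group, test = group,
                         candidates = NULL, quiet = FALSE) {
  stage <- match.arg(stage, c("simulate", "extract", "preprocess", "fit",
                              "evaluate", "ablate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  if (stage == "simulate") {
    if (is.null(spec)) stopf("simulate requires a cohort_spec")
    if (is.null(truth)) truth <- default_truth_model(spec$noise_sd)
    log_line("[simulate] generating cohort (seed %d)", spec$seed)
    cohort <- generate_cohort(spec, truth, config)
    for (pid in names(cohort$bundles)) {
      write_sensor_bundle(cohort$bundles[[pid]], file.path(dir, "raw", pid))
      log_line("[simulate] wrote raw streams for %s", pid)
    }
    utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$weather, file.path(dir, "weather.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$ratings[, c("rating_id", "participant_id",
                                        "time", "vas")],
                     file.path(dir, "ratings.csv"), row.names = FALSE)
    jsonlite::write_json(cohort$truth["tabulated"],
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(dir, "simulate", config,
                   list(participants = nrow(cohort$participants),
                        ratings = nrow(cohort$ratings)))
    return(invisible(cohort))
  }

  if (stage == "extract") {
    require_artifact(dir, "ratings.csv", "extract")
    require_artifact(dir, "participants.csv", "extract")
    ratings <- utils::read.csv(file.path(dir, "ratings.csv"),
                               stringsAsFactors = FALSE)
    weather <- utils::read.csv(file.path(dir, "weather.csv"),
                               stringsAsFactors = FALSE)
    pids <- unique(ratings$participant_id)
    tables <- list()
    for (pid in pids) {
      bundle <- load_sensor_bundle(require_artifact(dir, file.path("raw", pid),
                                                    "extract"))
      sched <- estimate_sleep_wake(bundle$acc, bundle$hr)
      r_p <- ratings[ratings$participant_id == pid, , drop = FALSE]
      tables[[pid]] <- assemble_features(bundle, r_p, sched, weather, config)
      log_line("[extract] %s: %d ratings, %d rest windows", pid, nrow(tables[[pid]]),
               nrow(attr(tables[[pid]], "rest_windows")))
    }
    ft <- bind_feature_tables(tables)
    write_feature_table(ft, file.path(dir, "features.csv"))
    write_manifest(dir, "extract", config,
                   list(rows = nrow(ft), features = length(feature_names(ft))))
    return(invisible(ft))
  }

  if (stage == "preprocess") {
    ft <- read_feature_table(require_artifact(dir, "features.csv", "preprocess"))
    norm <- normalize_per_participant(ft)
    imp <- impute_zero(norm$table)
    write_feature_table(imp$table, file.path(dir, "normalized.csv"))
    utils::write.csv(norm$stats, file.path(dir, "norm_stats.csv"),
                     row.names = FALSE)
    n_inc <- sum(rowSums(imp$mask) > 0L)
    log_line("[preprocess] %d rows, %d incomplete (%.1f%%)", nrow(ft), n_inc,
             100 * n_inc / max(nrow(ft), 1))
    write_manifest(dir, "preprocess", config,
                   list(rows = nrow(ft), incomplete = n_inc))
    return(invisible(list(table = imp$table, mask = imp$mask,
                          stats = norm$stats)))
  }

  # downstream stages share these artifacts
  table <- read_feature_table(require_artifact(dir, "normalized.csv", stage))
  participants <- utils::read.csv(require_artifact(dir, "participants.csv", stage),
                                  stringsAsFactors = FALSE)
  fn <- feature_names(table)
  mask <- as.matrix(as.data.frame(table)[paste0("miss_", fn)])
  colnames(mask) <- fn

  subset_group <- function(g) {
    pid <- group_pids(participants, g)
    keep <- as.data.frame(table)$participant_id %in% pid
    list(table = feature_table(as.data.frame(table)[keep, , drop = FALSE],
                               feature_names = fn),
         mask = mask[keep, , drop = FALSE])
  }
  usable_candidates <- function(tab, msk) {
    if (!is.null(candidates)) return(candidates)
    ok <- colSums(!msk) >= 0.5 * nrow(msk) &
      apply(as.data.frame(tab)[, fn, drop = FALSE], 2,
            function(v) length(unique(v[!is.na(v)])) >= 10L)
    fn[ok]
  }

  if (stage == "fit") {
    gd <- subset_group(group)
    cand <- usable_candidates(gd$table, gd$mask)
    cc <- complete_cases(gd$table, gd$mask, features = cand)
    log_line("[fit] group %s: %d complete rows, %d candidates", group,
             nrow(cc), length(cand))
    sel <- backward_eliminate(as.data.frame(cc), cand, config,
                              seed = child_seed(config$seed, paste0("fit-", group)))
    jsonlite::write_json(
      list(group = group, selected = sel$selected,
           trace = sel$trace, candidates = cand),
      file.path(dir, paste0("model_", group, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_manifest(dir, paste0("fit_", group), config,
                   list(candidates = length(cand),
                        selected = length(sel$selected)))
    return(invisible(sel))
  }

  if (stage == "evaluate") {
    model <- jsonlite::read_json(
      require_artifact(dir, paste0("model_", train, ".json"), "evaluate"),
      simplifyVector = TRUE)
    terms <- model$selected
    if (!length(terms)) stopf("model for group %s selected no terms", train)
    te <- subset_group(test)
    base <- baseline_evaluate(te$table)
    if (identical(train, test)) {
      res <- lopo_evaluate(te$table, te$mask, terms, config)
    } else {
      tr <- subset_group(train)
      res <- across_group_evaluate(tr$table, tr$mask, te$table, te$mask,
                                   terms, config)
    }
    p_cc <- p_imp <- NA_real_
    if (res$n_participants >= 5L) {
      b <- base$per_participant$complete
      m <- merge(res$per_participant$complete, b, by = "participant_id")
      p_cc <- compare_wilcoxon(m$r2.x, m$r2.y)
      m2 <- merge(res$per_participant$imputed, base$per_participant$imputed,
                  by = "participant_id")
      p_imp <- compare_wilcoxon(m2$r2.x, m2$r2.y)
    }
    out <- data.frame(
      train = train, test = test, n_participants = res$n_participants,
      n_rows = res$n_rows,
      r2_complete = res$means$complete["r2"], mae_complete = res$means$complete["mae"],
      rmse_complete = res$means$complete["rmse"],
      r2_imputed = res$means$imputed["r2"], mae_imputed = res$means$imputed["mae"],
      rmse_imputed = res$means$imputed["rmse"],
      r2_baseline = base$means$complete["r2"],
      mae_baseline = base$means$complete["mae"],
      rmse_baseline = base$means$complete["rmse"],
      p_vs_baseline = p_cc, p_vs_baseline_imputed = p_imp)
    rownames(out) <- NULL
    f <- file.path(dir, "evaluation.csv")
    if (file.exists(f)) {
      prev <- utils::read.csv(f, stringsAsFactors = FALSE)
      prev <- prev[!(prev$train == train & prev$test == test), , drop = FALSE]
      out <- rbind(prev, out)
    }
    utils::write.csv(out, f, row.names = FALSE)
    log_line("[evaluate] %s -> %s: R2 %.1f%% (complete), baseline 0", train,
             test, out$r2_complete[nrow(out)])
    write_manifest(dir, paste0("evaluate_", train, "_", test), config,
                   list(participants = res$n_participants))
    return(invisible(res))
  }

  # ablate
  gd <- subset_group(group)
  cand <- usable_candidates(gd$table, gd$mask)
  log_line("[ablate] group %s: %d candidates, %d perturbations", group,
           length(cand), config$n_perturbations)
  abl <- ablation_study(gd$table, gd$mask, cand, config,
                        seed = child_seed(config$seed, paste0("abl-", group)))
  utils::write.csv(as.data.frame(abl), file.path(dir, "ablation.csv"),
                   row.names = FALSE)
  write_manifest(dir, paste0("ablate_", group), config,
                 list(configurations = nrow(abl)))
  invisible(abl)
}
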