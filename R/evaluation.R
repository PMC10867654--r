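# Within-group (leave-one-participant-out) and across-group evaluation,
# baseline regressor, paired Wilcoxon comparisons, feature-group ablation,
# and the descriptive VAS~FSMC correlation.

#' Per-participant prediction metrics
#'
#' On the per-participant normalized scale the total sum of squares is taken
#' about zero (the participant's own normalized mean), so the
#' participant-mean baseline regressor scores exactly R2 = 0 on any data:
#' `r2 = 100 * (1 - sum((y - yhat)^2) / sum(y^2))` (percent, may be
#' negative), plus MAE and RMSE.
#'
#' @param y normalized ratings.
#' @param yhat predictions.
#' @return list `r2` (percent), `mae`, `rmse`.
#' @export
participant_metrics <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    stopf("y and yhat must be non-empty and aligned")
  }
  sse <- sum((y - yhat)^2)
  sst <- sum(y^2)
  r2 <- if (sst == 0) {
    if (sse == 0) 100 else NA_real_
  } else 100 * (1 - sse / sst)
  list(r2 = r2, mae = mean(abs(y - yhat)), rmse = sqrt(mean((y - yhat)^2)))
}

metrics_by_participant <- function(df, yhat, pids = unique(df$participant_id)) {
  out <- lapply(pids, function(p) {
    i <- df$participant_id == p
    if (!any(i)) return(NULL)
    m <- participant_metrics(df$vas[i], yhat[i])
    data.frame(participant_id = p, n = sum(i), r2 = m$r2, mae = m$mae,
               rmse = m$rmse)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

eval_result <- function(train, test, per_cc, per_imp, n_rows) {
  res <- list(train = train, test = test,
              per_participant = list(complete = per_cc, imputed = per_imp),
              n_participants = nrow(per_cc), n_rows = n_rows,
              means = list(
                complete = colMeans(per_cc[, c("r2", "mae", "rmse")], na.rm = TRUE),
                imputed = if (!is.null(per_imp))
                  colMeans(per_imp[, c("r2", "mae", "rmse")], na.rm = TRUE)))
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval %s -> %s: n=%d participants, R2 %.1f%% (complete)",
              x$train, x$test, x$n_participants, x$means$complete["r2"]))
  if (!is.null(x$means$imputed)) {
    cat(sprintf(", %.1f%% (imputed)", x$means$imputed["r2"]))
  }
  cat("\n")
  invisible(x)
}

#' Leave-one-participant-out evaluation
#'
#' Each participant is held out once; the model (the given smooth terms) is
#' trained on the complete cases of the remaining participants and evaluated
#' on the held-out participant twice: on their complete cases only, and on
#' all of their rows with zero (mean) imputation. Group means are unweighted
#' means of the per-participant metrics.
#'
#' @param table imputed, normalized [feature_table()].
#' @param mask imputation mask from [impute_zero()].
#' @param terms selected feature names.
#' @param config a [run_config()].
#' @return an `eval_result` (train = test = `"group"`).
#' @export
lopo_evaluate <- function(table, mask, terms, config = run_config()) {
  df <- as.data.frame(table)
  pids <- unique(df$participant_id)
  if (length(pids) < 3L) stopf("need at least 3 participants for LOPO")
  cc_keep <- rowSums(mask[, terms, drop = FALSE]) == 0L
  rows_cc <- rows_imp <- list()
  for (p in pids) {
    test_i <- df$participant_id == p
    train <- df[!test_i & cc_keep, , drop = FALSE]
    if (sum(test_i) == 0L) {
      warnf("participant %s has no test rows; skipped", p)
      next
    }
    fit <- fit_gam(train, "vas", terms, config)
    te_all <- df[test_i, , drop = FALSE]
    yhat_all <- predict(fit, te_all)
    rows_imp[[p]] <- metrics_by_participant(te_all, yhat_all, p)
    te_cc <- df[test_i & cc_keep, , drop = FALSE]
    if (nrow(te_cc)) {
      rows_cc[[p]] <- metrics_by_participant(te_cc, predict(fit, te_cc), p)
    }
  }
  eval_result("group", "group", do.call(rbind, rows_cc),
              do.call(rbind, rows_imp), nrow(df))
}

#' Across-group evaluation
#'
#' One model is fitted on all complete cases of the training group and
#' evaluated on each participant of the (disjoint) test group separately.
#'
#' @param train_table,train_mask training group (imputed table + mask).
#' @param test_table,test_mask test group.
#' @param terms selected feature names (normally the training group's
#'   selection).
#' @param config a [run_config()].
#' @return an `eval_result`.
#' @export
across_group_evaluate <- function(train_table, train_mask, test_table,
                                  test_mask, terms, config = run_config()) {
  tr <- as.data.frame(train_table)
  te <- as.data.frame(test_table)
  if (length(intersect(unique(tr$participant_id), unique(te$participant_id)))) {
    stopf("train and test groups share participants")
  }
  cc_tr <- rowSums(train_mask[, terms, drop = FALSE]) == 0L
  fit <- fit_gam(tr[cc_tr, , drop = FALSE], "vas", terms, config)
  cc_te <- rowSums(test_mask[, terms, drop = FALSE]) == 0L
  per_imp <- metrics_by_participant(te, predict(fit, te))
  te_cc <- te[cc_te, , drop = FALSE]
  per_cc <- metrics_by_participant(te_cc, predict(fit, te_cc))
  eval_result("train", "test", per_cc, per_imp, nrow(te))
}

#' Baseline regressor evaluation
#'
#' Predicts each participant's own average rating, i.e. 0 on the normalized
#' scale; its per-participant R2 is exactly 0 by construction.
#'
#' @param table normalized [feature_table()].
#' @return an `eval_result` (identical complete/imputed parts).
#' @export
baseline_evaluate <- function(table) {
  df <- as.data.frame(table)
  per <- metrics_by_participant(df, rep(0, nrow(df)))
  eval_result("baseline", "baseline", per, per, nrow(df))
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided; exact for n <= 25 pairs (zero differences dropped, mid-ranks
#' for ties, null distribution built by convolution so ties are handled
#' exactly — `stats::wilcox.test` refuses exact p-values under ties), normal
#' approximation with continuity correction otherwise. All-zero differences
#' return p = 1 by convention.
#'
#' @param a,b paired per-participant metric vectors.
#' @return p-value.
#' @export
compare_wilcoxon <- function(a, b) {
  if (length(a) != length(b) || length(a) < 5L) {
    stopf("need at least 5 pairs of equal length")
  }
  d <- (a - b)[a != b]
  if (length(d) == 0L) return(1.0)
  if (length(d) <= 25L) {
    r2 <- round(rank(abs(d)) * 2)  # doubled mid-ranks are integers
    v <- sum(r2[d > 0])
    tot <- sum(r2)
    probs <- c(1, numeric(tot))  # P(V2 = 0..tot), V2 on the doubled scale
    for (w in r2) {
      half <- probs / 2
      probs <- half
      probs[(w + 1L):(tot + 1L)] <- probs[(w + 1L):(tot + 1L)] +
        half[1:(tot + 1L - w)]
    }
    return(min(1, 2 * min(sum(probs[1:(v + 1L)]),
                          sum(probs[(v + 1L):(tot + 1L)]))))
  }
  res <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
  unname(res$p.value)
}

#' Feature-group ablation study
#'
#' Ten configurations over the four wearable/weather feature groups (CAR,
#' EDA, ACC, WEA): all four, minus each one, only each one, and none;
#' daily-routine features are always included. Each configuration runs the
#' full selection loop and leave-one-participant-out evaluation; its gain
#' over the routine-only baseline is tested with paired Wilcoxon signed-rank
#' tests across `config$n_perturbations` perturbations, each refitting with
#' two random participants excluded and scoring them out of sample (the
#' exclusion draws are shared across configurations for pairing).
#'
#' @param table imputed, normalized [feature_table()].
#' @param mask imputation mask.
#' @param candidates candidate feature names (the routine candidates among
#'   them are always kept in every configuration).
#' @param config a [run_config()].
#' @param seed integer seed.
#' @return data.frame of class `ablation_result`: configuration, features
#'   used, selected terms, group-mean R2 (complete cases), p-value vs the
#'   routine-only configuration.
#' @export
ablation_study <- function(table, mask, candidates, config = run_config(),
                           seed = config$seed) {
  groups <- feature_groups(candidates)
  four <- c("CAR", "EDA", "ACC", "WEA")
  present <- intersect(four, unique(groups))
  routine <- candidates[groups == "ROUTINE"]
  if (!length(routine)) stopf("candidates must include ROUTINE features")
  configs <- list(all = present)
  for (g in present) configs[[paste0("minus_", g)]] <- setdiff(present, g)
  for (g in present) configs[[paste0("only_", g)]] <- g
  configs$routine_only <- character(0)
  df <- as.data.frame(table)
  pids <- unique(df$participant_id)
  draws <- with_seed(child_seed(seed, "ablation-draws"), {
    lapply(seq_len(config$n_perturbations), function(i) sample(pids, 2L))
  })
  perturb_scores <- function(terms) {
    cc <- rowSums(mask[, terms, drop = FALSE]) == 0L
    vapply(draws, function(out2) {
      tr <- df[!df$participant_id %in% out2 & cc, , drop = FALSE]
      te <- df[df$participant_id %in% out2 & cc, , drop = FALSE]
      if (nrow(te) == 0L) return(NA_real_)
      fit <- try(fit_gam(tr, "vas", terms, config), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      mean(metrics_by_participant(te, predict(fit, te))$r2)
    }, numeric(1))
  }
  rows <- list(); scores <- list(); selections <- list()
  for (nm in names(configs)) {
    cand <- c(routine, candidates[groups %in% configs[[nm]]])
    if (length(cand) == 0L) {
      warnf("configuration %s has no candidates; skipped", nm)
      next
    }
    sel <- backward_eliminate(df[rowSums(mask[, cand, drop = FALSE]) == 0L, ,
                                 drop = FALSE],
                              cand, config, seed = child_seed(seed, nm))
    terms <- sel$selected
    if (!length(terms)) terms <- routine[1]  # fall back to a routine anchor
    lopo <- lopo_evaluate(table, mask, terms, config)
    selections[[nm]] <- terms
    scores[[nm]] <- perturb_scores(terms)
    rows[[nm]] <- data.frame(
      configuration = nm, n_features = length(cand),
      n_selected = length(terms),
      selected = paste(terms, collapse = ";"),
      r2_complete = unname(lopo$means$complete["r2"]),
      r2_imputed = unname(lopo$means$imputed["r2"]))
  }
  out <- do.call(rbind, rows)
  base <- scores[["routine_only"]]
  out$p_vs_routine <- vapply(out$configuration, function(nm) {
    if (nm == "routine_only" || is.null(base)) return(NA_real_)
    s <- scores[[nm]]
    ok <- stats::complete.cases(cbind(s, base))
    if (sum(ok) < 5L) return(NA_real_)
    compare_wilcoxon(s[ok], base[ok])
  }, numeric(1))
  rownames(out) <- NULL
  attr(out, "perturbation_scores") <- scores
  attr(out, "selections") <- selections
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Spearman correlation of mean VAS rating with FSMC score
#'
#' Mid-rank ties, p-value from the t approximation.
#'
#' @param participants data.frame with `mean_vas` and `fsmc` columns.
#' @return list `rho`, `p`, `n`.
#' @export
correlate_mean_vas_fsmc <- function(participants) {
  ok <- stats::complete.cases(participants[, c("mean_vas", "fsmc")])
  if (sum(ok) < 3L) stopf("need at least 3 participants with both values")
  ct <- suppressWarnings(
    stats::cor.test(participants$mean_vas[ok], participants$fsmc[ok],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
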