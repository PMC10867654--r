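# Per-participant normalization, zero imputation, complete-case splitting.

#' Normalize features and ratings per participant
#'
#' For every participant, each feature column and the VAS rating are centred
#' by the participant's mean and scaled by the participant's population SD,
#' computed over the full study ignoring missing values. Columns with fewer
#' than two non-missing values or zero variance for a participant are masked
#' (set missing) with a warning instead of being divided by zero.
#'
#' @param table a [feature_table()] (raw scale).
#' @return list with `table` (normalized [feature_table()]) and `stats`
#'   (data.frame `participant_id`, `feature`, `mean`, `sd`; the VAS stats are
#'   stored under feature `"vas"`).
#' @export
normalize_per_participant <- function(table) {
  fn <- feature_names(table)
  df <- as.data.frame(table)
  stats_rows <- list()
  zero_masked <- character(0)
  for (pid in unique(df$participant_id)) {
    ridx <- which(df$participant_id == pid)
    for (f in c(fn, "vas")) {
      v <- df[[f]][ridx]
      ok <- !is.na(v)
      m <- if (any(ok)) mean(v[ok]) else NA_real_
      s <- if (sum(ok) >= 2L) pop_sd(v[ok]) else NA_real_
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(participant_id = pid, feature = f, mean = m, sd = s)
      if (is.na(s) || s == 0) {
        df[[f]][ridx] <- NA_real_
        if (f != "vas") df[[paste0("miss_", f)]][ridx] <- TRUE
        zero_masked <- c(zero_masked, paste0(pid, ":", f))
      } else {
        df[[f]][ridx] <- (v - m) / s
      }
    }
  }
  if (length(zero_masked)) {
    warnf("masked %d degenerate participant/column pairs (zero variance or < 2 values), e.g. %s",
          length(zero_masked), zero_masked[1])
  }
  list(table = feature_table(df, feature_names = fn),
       stats = do.call(rbind, stats_rows))
}

#' Denormalize a normalized table using stored stats
#'
#' Inverse of [normalize_per_participant()] on non-missing cells.
#'
#' @param table normalized [feature_table()].
#' @param stats the `stats` component returned by the normalizer.
#' @return raw-scale [feature_table()].
#' @export
denormalize <- function(table, stats) {
  fn <- feature_names(table)
  df <- as.data.frame(table)
  for (pid in unique(df$participant_id)) {
    ridx <- which(df$participant_id == pid)
    for (f in c(fn, "vas")) {
      st <- stats[stats$participant_id == pid & stats$feature == f, ]
      if (nrow(st) == 0L || is.na(st$sd)) next
      df[[f]][ridx] <- df[[f]][ridx] * st$sd + st$mean
    }
  }
  feature_table(df, feature_names = fn)
}

#' Impute missing normalized values with zero
#'
#' On the per-participant normalized scale, zero is the participant's mean,
#' so zero imputation is mean imputation. Never touches non-missing cells.
#'
#' @param table normalized [feature_table()].
#' @return list with `table` (no missing feature cells remain) and `mask`
#'   (logical matrix, TRUE where a cell was imputed).
#' @export
impute_zero <- function(table) {
  fn <- feature_names(table)
  df <- as.data.frame(table)
  mask <- matrix(FALSE, nrow(df), length(fn), dimnames = list(NULL, fn))
  for (f in fn) {
    na <- is.na(df[[f]])
    mask[, f] <- na
    df[[f]][na] <- 0
  }
  list(table = feature_table(df, feature_names = fn), mask = mask)
}

#' Rows without any imputed cell
#'
#' @param table an imputed [feature_table()].
#' @param mask the imputation mask from [impute_zero()].
#' @param features optionally restrict the completeness requirement to these
#'   features (used when a model only consumes a subset).
#' @return the complete-case subset, a [feature_table()].
#' @export
complete_cases <- function(table, mask, features = NULL) {
  fn <- feature_names(table)
  if (is.null(features)) features <- fn
  if (nrow(mask) != nrow(table)) stopf("mask is not aligned with the table")
  keep <- rowSums(mask[, features, drop = FALSE]) == 0L
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  feature_table(out, feature_names = fn)
}
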