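# Shrinkage smoothing-spline additive model and the subsample
# backward-elimination loop. Smooths are penalized regression splines whose
# null space is also penalized (shrinkage bases "cs"/"ts", or the explicit
# double penalty via select = TRUE for "tp"/"cr"), so terms with no
# explanatory power can be shrunk to exactly nothing; smoothness is selected
# numerically by the configured criterion (GCV by default).

#' Build a 1-D smooth basis with its two penalty matrices
#'
#' Thin-plate regression spline basis of dimension `k` for one covariate,
#' together with the wiggliness penalty (rank `k - 2`: it annihilates the
#' constant+linear null space) and the null-space shrinkage penalty (rank 2,
#' positive definite on that null space). If `x` has fewer than `k` distinct
#' values, `k` is reduced with a warning.
#'
#' @param x covariate values (not constant).
#' @param k basis dimension (>= 3).
#' @return list with `X` (basis, n x k), `S_wiggle`, `S_null` (k x k
#'   penalties) and `k`.
#' @export
build_smooth_basis <- function(x, k = 10L) {
  if (k < 3L) stopf("basis dimension k must be at least 3")
  nd <- length(unique(x))
  if (nd < 2L) stopf("constant covariate: cannot build a smooth basis")
  if (nd < k) {
    warnf("only %d distinct values: reducing basis dimension from %d", nd, k)
    k <- nd
  }
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "tp"),
                        data = data.frame(x = x), absorb.cons = FALSE)[[1]]
  S <- sm$S[[1]]
  ev <- eigen(S, symmetric = TRUE)
  null_dim <- sum(ev$values < max(ev$values) * 1e-10)
  U0 <- ev$vectors[, (ncol(S) - null_dim + 1L):ncol(S), drop = FALSE]
  list(X = sm$X, S_wiggle = S, S_null = U0 %*% t(U0), k = k)
}

#' Fit a shrinkage additive model
#'
#' Gaussian additive model `y ~ sum_j f_j(x_j)` with every effect a
#' penalized regression spline carrying both a wiggliness and a null-space
#' shrinkage penalty, so effects with no explanatory power vanish; penalty
#' weights are chosen by numerical optimization of the configured criterion
#' (GCV by default). Deterministic given inputs and config.
#'
#' @param data data.frame containing the term columns and the response.
#' @param response name of the response column (normalized VAS).
#' @param terms character vector of feature names to include as smooths.
#' @param config a [run_config()] (supplies the basis dimension `k`).
#' @param sp optional fixed smoothing-parameter vector (bypasses GCV); use
#'   `rep(0, ...)` for an unpenalized fit.
#' @param select force the explicit extra null-space penalty; by default it
#'   is added only for the non-shrinkage bases (`"tp"`, `"cr"`), since the
#'   shrinkage bases (`"cs"`, `"ts"`) already penalize their null space.
#' @return object of class `fatigue_gam`: list with the `mgcv` fit (`gam`),
#'   `terms`, `response`.
#' @export
fit_gam <- function(data, response = "vas", terms, config = run_config(),
                    sp = NULL, select = NULL) {
  if (is.null(select)) select <- config$basis %in% c("tp", "cr")
  if (!length(terms)) stopf("no terms to fit")
  miss <- terms[!terms %in% names(data)]
  if (length(miss)) stopf("terms absent from data: %s", paste(miss, collapse = ", "))
  if (anyNA(data[, c(response, terms)])) {
    stopf("fit_gam requires complete data (impute or drop incomplete rows first)")
  }
  if (nrow(data) < 10L * length(terms)) {
    stopf("insufficient data: %d rows for %d terms (need >= 10 per term)",
          nrow(data), length(terms))
  }
  ks <- vapply(terms, function(tm) {
    nd <- length(unique(data[[tm]]))
    if (nd < 3L) stopf("term %s is (near-)constant; mask it upstream", tm)
    min(config$k, nd)
  }, integer(1))
  if (any(ks < config$k)) {
    warnf("reduced basis dimension for %s",
          paste(terms[ks < config$k], collapse = ", "))
  }
  rhs <- paste(sprintf("s(%s, k = %d, bs = \"%s\")", terms, ks, config$basis),
               collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- mgcv::gam(form, data = data, method = config$method,
                   select = select, sp = sp)
  if (fit$rank < length(fit$coefficients)) {
    warnf("rank-deficient design (%d < %d coefficients)", fit$rank,
          length(fit$coefficients))
  }
  structure(list(gam = fit, terms = terms, response = response,
                 config = config),
            class = "fatigue_gam")
}

#' @export
print.fatigue_gam <- function(x, ...) {
  cat(sprintf("fatigue_gam: %d smooth terms, n = %d, total EDF %.2f\n",
              length(x$terms), length(x$gam$y), sum(x$gam$edf)))
  invisible(x)
}

#' @export
predict.fatigue_gam <- function(object, newdata, ...) {
  as.numeric(mgcv::predict.gam(object$gam, newdata = newdata, ...))
}

term_index <- function(fit, name) {
  labs <- vapply(fit$gam$smooth, function(s) s$term, character(1))
  i <- match(name, labs)
  if (is.na(i)) stopf("unknown term '%s'", name)
  i
}

#' Per-term effective degrees of freedom and approximate p-value
#'
#' EDF is the trace of the term's block of the influence matrix; the p-value
#' is the Wald-type test of the term's coefficients against zero using the
#' penalized covariance (as reported by `summary.gam`).
#'
#' @param fit a [fit_gam()] result.
#' @param name term (feature) name.
#' @return a single numeric value.
#' @export
term_edf <- function(fit, name) {
  i <- term_index(fit, name)
  sm <- fit$gam$smooth[[i]]
  sum(fit$gam$edf[sm$first.para:sm$last.para])
}

#' @rdname term_edf
#' @export
term_pvalue <- function(fit, name) {
  i <- term_index(fit, name)
  s <- summary(fit$gam)$s.table
  unname(s[i, "p-value"])
}

# ---- backward elimination ---------------------------------------------------

#' Subsample backward elimination of smooth terms
#'
#' The variable-selection loop: at each iteration the model is fitted on
#' `config$n_subsamples` subsamples of the data, each randomly excluding all
#' rows of two participants; per candidate the EDF and p-value are averaged
#' across subsamples. All candidates whose mean EDF falls below
#' `config$edf_threshold` are purged at once; otherwise, if any candidate's
#' mean p-value exceeds `config$p_threshold`, the single candidate with the
#' highest mean p is removed (ties broken by removing the lexicographically
#' last name). The loop stops when neither rule applies; the model is then
#' refitted on all participants and both rules are re-applied until stable.
#'
#' @param data complete-case data.frame with `participant_id`, the response
#'   and candidate columns.
#' @param candidates character vector of candidate feature names.
#' @param config a [run_config()].
#' @param seed integer seed (subsample draws are deterministic under it).
#' @param response response column name.
#' @return list with `selected` (character vector) and `trace` (data.frame of
#'   class `elimination_trace`: iteration, candidate, mean EDF, mean p,
#'   action).
#' @export
backward_eliminate <- function(data, candidates, config = run_config(),
                               seed = config$seed, response = "vas") {
  pids <- unique(data$participant_id)
  if (length(pids) < 4L) stopf("need at least 4 participants for subsampling")
  current <- sort(candidates)
  trace <- list()
  it <- 0L
  with_seed(child_seed(seed, "elim"), {
    while (length(current) > 0L) {
      it <- it + 1L
      stats <- subsample_term_stats(data, current, config, response)
      action <- rep("keep", length(current))
      low_edf <- stats$edf < config$edf_threshold
      if (any(low_edf)) {
        action[low_edf] <- "edf_purge"
        nxt <- current[!low_edf]
      } else if (any(stats$p > config$p_threshold)) {
        worst <- max(stats$p)
        cand <- current[stats$p == worst]
        drop <- cand[length(cand)]  # lexicographically last (current sorted)
        action[current == drop] <- "p_removal"
        nxt <- setdiff(current, drop)
      } else {
        action[] <- "stop"
        nxt <- current
      }
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it, candidate = current, mean_edf = stats$edf,
        mean_p = stats$p, action = action, phase = "subsample")
      if (identical(nxt, current)) break
      current <- nxt
    }
    # final refit on all participants, re-applying both rules until stable
    repeat {
      if (!length(current)) break
      fit <- fit_gam(data, response, current, config)
      edf <- vapply(current, term_edf, 0, fit = fit)
      p <- vapply(current, term_pvalue, 0, fit = fit)
      action <- rep("keep", length(current))
      low_edf <- edf < config$edf_threshold
      if (any(low_edf)) {
        action[low_edf] <- "edf_purge"
        nxt <- current[!low_edf]
      } else if (any(p > config$p_threshold)) {
        worst <- max(p)
        cand <- current[p == worst]
        drop <- cand[length(cand)]
        action[current == drop] <- "p_removal"
        nxt <- setdiff(current, drop)
      } else {
        action[] <- "stop"
        nxt <- current
      }
      it <- it + 1L
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it, candidate = current, mean_edf = edf,
        mean_p = p, action = action, phase = "full")
      if (identical(nxt, current)) break
      current <- nxt
    }
  })
  tr <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(0), candidate = character(0),
               mean_edf = numeric(0), mean_p = numeric(0),
               action = character(0), phase = character(0))
  class(tr) <- c("elimination_trace", "data.frame")
  list(selected = current, trace = tr)
}

# mean EDF / p per candidate over subsamples, each excluding 2 participants
subsample_term_stats <- function(data, terms, config, response) {
  pids <- unique(data$participant_id)
  edf_acc <- p_acc <- stats::setNames(numeric(length(terms)), terms)
  n_ok <- 0L
  first_err <- NULL
  for (b in seq_len(config$n_subsamples)) {
    out2 <- sample(pids, 2L)
    sub <- data[!data$participant_id %in% out2, , drop = FALSE]
    fit <- try(fit_gam(sub, response, terms, config), silent = TRUE)
    if (inherits(fit, "try-error")) {
      if (is.null(first_err)) first_err <- attr(fit, "condition")$message
      next
    }
    edf_acc <- edf_acc + vapply(terms, term_edf, 0, fit = fit)
    p_acc <- p_acc + vapply(terms, term_pvalue, 0, fit = fit)
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stopf("every subsample fit failed (first error: %s)", first_err)
  list(edf = edf_acc / n_ok, p = p_acc / n_ok)
}

# ---- partial effects --------------------------------------------------------

#' Partial effect of one selected term
#'
#' Evaluates the fitted smooth on a grid of normalized feature values (all
#' other terms held at 0) and labels its shape.
#'
#' @param fit a [fit_gam()] result.
#' @param name selected term name.
#' @param grid grid of covariate values (default 41 points over the observed
#'   range).
#' @return list of class `effect_curve`: `feature`, `grid`, `effect`,
#'   `shape`.
#' @export
partial_effect <- function(fit, name, grid = NULL) {
  i <- term_index(fit, name)
  if (is.null(grid)) {
    x <- fit$gam$model[[name]]
    grid <- seq(min(x), max(x), length.out = 41L)
  }
  nd <- as.data.frame(stats::setNames(
    lapply(fit$terms, function(tm) if (tm == name) grid else rep(0, length(grid))),
    fit$terms))
  pt <- mgcv::predict.gam(fit$gam, newdata = nd, type = "terms")
  col <- grep(paste0("s\\(", name, "\\)"), colnames(pt))
  eff <- as.numeric(pt[, col[1]])
  structure(list(feature = name, grid = grid, effect = eff,
                 shape = classify_shape(eff)),
            class = "effect_curve")
}

#' Label the shape of a partial-effect curve
#'
#' `"inc"` for a monotone rise (first differences >= -tol with total rise
#' above `tol`), `"dec"` mirrored, `"concave"` for rise-then-fall,
#' `"convex"` for fall-then-rise, `"flat"` otherwise. These correspond to
#' the up/down/cap/cup/tilde glyphs used to summarize partial-dependence
#' shapes.
#'
#' @param curve numeric vector of effect values on an ordered grid (or an
#'   `effect_curve`).
#' @param tol both the flatness tolerance on total variation and the slack
#'   allowed on individual first differences.
#' @return one of `"inc"`, `"dec"`, `"concave"`, `"convex"`, `"flat"`.
#' @export
classify_shape <- function(curve, tol = 0.05) {
  if (inherits(curve, "effect_curve")) curve <- curve$effect
  d <- diff(curve)
  rise <- curve[length(curve)] - curve[1]
  amp <- max(curve) - min(curve)
  if (amp <= tol) return("flat")
  slack <- tol * amp
  if (all(d >= -slack) && rise > tol) return("inc")
  if (all(d <= slack) && rise < -tol) return("dec")
  peak <- which.max(curve)
  trough <- which.min(curve)
  n <- length(curve)
  if (peak > 1 && peak < n &&
      all(d[seq_len(peak - 1)] >= -slack) && all(d[peak:(n - 1)] <= slack)) {
    return("concave")
  }
  if (trough > 1 && trough < n &&
      all(d[seq_len(trough - 1)] <= slack) && all(d[trough:(n - 1)] >= -slack)) {
    return("convex")
  }
  "flat"
}
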