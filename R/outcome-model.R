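#' Trapezoidal AUC of a biomarker trajectory
#'
#' Time-integral of a sparsely sampled biomarker over a window, by the
#' trapezoidal rule on the observed points. The trajectory is clipped to
#' the window: values at the window edges are linearly interpolated from
#' the bracketing observations, but the integral is never extrapolated
#' beyond the first or last observation. Observation times inside the
#' window are used as-is.
#'
#' @param time_h Observation times, hours, strictly increasing.
#' @param value Biomarker values at those times.
#' @param window `c(t0, t1)` integration window in hours (default
#'   `c(0, 6)`, the early-NMP window used for outcome prediction).
#' @param average If `TRUE`, divide by the integrated duration
#'   (time-averaged value instead of raw value-hours). Default `FALSE`.
#' @return The integral in value-hours (`NA` if fewer than two
#'   observations overlap the window).
#' @export
#' @examples
#' time_auc(c(0, 1, 6), c(0.8, 0.8, 0.8))        # 4.8
#' time_auc(c(0, 6), c(0, 6))                    # 18
time_auc <- function(time_h, value, window = c(0, 6), average = FALSE) {
  stopifnot(length(time_h) == length(value), length(window) == 2,
            window[1] < window[2])
  ok <- !is.na(time_h) & !is.na(value)
  time_h <- time_h[ok]
  value <- value[ok]
  if (length(time_h) >= 2 && any(diff(time_h) <= 0)) {
    stop("observation times must be strictly increasing")
  }
  t0 <- max(window[1], min(time_h))
  t1 <- min(window[2], max(time_h))
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) return(NA_real_)
  inside <- time_h > t0 & time_h < t1
  if (sum(time_h >= t0 & time_h <= t1) < 2 && !any(inside)) {
    # need at least a bracketing pair to form one trapezoid
    if (length(time_h) < 2) return(NA_real_)
  }
  tt <- c(t0, time_h[inside], t1)
  vv <- c(stats::approx(time_h, value, xout = t0)$y,
          value[inside],
          stats::approx(time_h, value, xout = t1)$y)
  auc <- sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  if (average) auc / (t1 - t0) else auc
}

#' Assemble a regression design from a cohort table
#'
#' Builds the modelling table: outcome plus requested main-effect columns
#' and pairwise interaction columns (elementwise products of their parent
#' AUC columns), restricted to complete cases. The number of dropped rows
#' is recorded in the `n_dropped` attribute and messaged.
#'
#' @param cohort Tibble keyed by `liver_id` with AUC biomarker columns and
#'   the outcome column.
#' @param outcome Name of the outcome column (e.g. `"lgraft"`).
#' @param predictors Character vector of main-effect column names.
#' @param interactions List of character pairs, each a pairwise
#'   interaction, e.g. `list(c("auc_cytc", "auc_leak"))`.
#' @return Tibble with `liver_id`, the outcome, main effects and
#'   interaction columns named `"a:b"`.
#' @export
assemble_design <- function(cohort, outcome, predictors,
                            interactions = list()) {
  missing_cols <- setdiff(c(outcome, predictors, unlist(interactions)),
                          names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- cohort[, c("liver_id", outcome, predictors)]
  for (pair in interactions) {
    stopifnot(length(pair) == 2)
    out[[paste(pair, collapse = ":")]] <- cohort[[pair[1]]] * cohort[[pair[2]]]
  }
  cc <- stats::complete.cases(out)
  dropped <- sum(!cc)
  if (dropped > 0) {
    message(dropped, " row(s) dropped for missing values")
  }
  out <- out[cc, ]
  num <- setdiff(names(out), c("liver_id", outcome))
  for (v in num) {
    if (stats::sd(out[[v]]) == 0) stop("zero-variance predictor: ", v)
  }
  attr(out, "n_dropped") <- dropped
  out
}

interaction_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
is_interaction <- function(term) grepl(":", term, fixed = TRUE)

# RSS of a least-squares fit of y on an intercept plus the named columns
rss_fit <- function(data, outcome, terms) {
  y <- data[[outcome]]
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  for (tm in terms) X <- cbind(X, data[[tm]])
  q <- qr(X)
  if (q$rank < ncol(X)) return(list(rss = NA_real_, rank = q$rank, p = ncol(X)))
  res <- qr.resid(q, y)
  list(rss = sum(res^2), rank = q$rank, p = ncol(X))
}

step_aic_value <- function(n, rss, n_par) n * log(rss / n) + 2 * n_par

#' Bidirectional stepwise model selection by AIC
#'
#' Starts from the intercept-only model and repeatedly takes the single
#' addition or deletion with the lowest AIC over the candidate scope,
#' stopping when no move improves on the current model. Marginality
#' (hierarchy) is enforced: an interaction `"a:b"` may enter only while
#' both parents are in the model, and a main effect may not leave while
#' one of its interactions remains. AIC uses the regression convention
#' `n * log(RSS/n) + 2 * k`. Ties are broken by lexicographic term order,
#' making the selection deterministic.
#'
#' @param data Design tibble from [assemble_design()].
#' @param outcome Outcome column name.
#' @param scope Character vector of candidate terms (main effects and
#'   `"a:b"` interactions, parents included in scope).
#' @return List: `terms` (selected, in scope order), `aic`, and `path`
#'   (tibble logging each move).
#' @export
stepwise_aic <- function(data, outcome, scope) {
  n <- nrow(data)
  if (n <= length(scope) + 1) {
    stop("need more observations than candidate terms plus intercept")
  }
  full <- rss_fit(data, outcome, scope)
  if (is.na(full$rss)) stop("degenerate (collinear) design over the full scope")
  scope <- sort(scope)

  current <- character()
  cur_fit <- rss_fit(data, outcome, current)
  cur_aic <- step_aic_value(n, cur_fit$rss, 1L)
  path <- list(tibble::tibble(move = "start", term = NA_character_,
                              aic = cur_aic))

  repeat {
    adds <- setdiff(scope, current)
    adds <- adds[vapply(adds, function(tm) {
      !is_interaction(tm) || all(interaction_parents(tm) %in% current)
    }, logical(1))]
    drops <- current[vapply(current, function(tm) {
      if (is_interaction(tm)) return(TRUE)
      !any(vapply(current[is_interaction(current)], function(it) {
        tm %in% interaction_parents(it)
      }, logical(1)))
    }, logical(1))]

    cand <- rbind(
      if (length(adds)) data.frame(move = "add", term = adds),
      if (length(drops)) data.frame(move = "drop", term = drops)
    )
    if (is.null(cand) || nrow(cand) == 0) break

    cand$aic <- vapply(seq_len(nrow(cand)), function(i) {
      terms <- if (cand$move[i] == "add") {
        union(current, cand$term[i])
      } else {
        setdiff(current, cand$term[i])
      }
      f <- rss_fit(data, outcome, terms)
      if (is.na(f$rss)) return(Inf)
      step_aic_value(n, f$rss, length(terms) + 1L)
    }, numeric(1))

    cand <- cand[order(cand$aic, cand$move, cand$term), ]
    if (cand$aic[1] >= cur_aic - 1e-10) break
    if (cand$move[1] == "add") {
      current <- union(current, cand$term[1])
    } else {
      current <- setdiff(current, cand$term[1])
    }
    cur_aic <- cand$aic[1]
    path[[length(path) + 1]] <- tibble::tibble(
      move = cand$move[1], term = cand$term[1], aic = cur_aic
    )
  }

  list(terms = intersect(scope, current), aic = cur_aic,
       path = dplyr::bind_rows(path))
}

#' Fit the outcome model with Type II ANOVA
#'
#' Ordinary least squares of the outcome on the given terms, with the
#' summaries the clinical model table reports: raw coefficients with 95%
#' confidence intervals, standardized coefficients
#' (`beta = b * sd(x)/sd(y)`), per-term Type II tests, and overall fit.
#' Type II sums of squares respect marginality: each term's SS is the RSS
#' increase from removing it from the largest model that contains no
#' interaction involving it (for a main effect, its interactions are
#' excluded from both models); F uses the full-model residual mean square.
#'
#' @param data Design tibble from [assemble_design()].
#' @param outcome Outcome column name.
#' @param terms Character vector of terms to fit.
#' @return An `outcome_model_fit`: list with `model` (the `lm` object on
#'   the constructed columns), `coef_table` (term, b, conf.low, conf.high,
#'   beta, ss, df, statistic, p), `r2`, `adj_r2`, `f_statistic`,
#'   `df`, `n`, `sigma`.
#' @export
fit_and_anova <- function(data, outcome, terms) {
  n <- nrow(data)
  p <- length(terms) + 1L
  if (n - p < 1) stop("residual degrees of freedom below 1")
  df_model <- data[, c(outcome, terms)]
  names(df_model) <- c(".y", if (length(terms) > 0) {
    paste0(".x", seq_along(terms))
  })
  fml <- stats::as.formula(paste(".y ~", if (length(terms) == 0) "1" else
    paste(names(df_model)[-1], collapse = " + ")))
  fit <- stats::lm(fml, data = df_model)
  if (any(is.na(stats::coef(fit)))) stop("singular design matrix")

  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- n - p
  y <- data[[outcome]]
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss_full / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  f_overall <- if (length(terms) > 0) {
    ((tss - rss_full) / length(terms)) / (rss_full / df_res)
  } else {
    NA_real_
  }

  cf <- stats::coef(fit)[-1]
  ci <- if (length(terms) > 0) stats::confint(fit)[-1, , drop = FALSE] else
    matrix(numeric(0), 0, 2)
  sdy <- stats::sd(y)

  rows <- lapply(seq_along(terms), function(i) {
    tm <- terms[i]
    # marginality: drop every term containing tm as a component
    contains_tm <- vapply(terms, function(o) {
      tm %in% interaction_parents(o) || o == tm
    }, logical(1))
    base_terms <- terms[!contains_tm]
    rss_with <- rss_fit(data, outcome, c(base_terms, tm))$rss
    rss_without <- rss_fit(data, outcome, base_terms)$rss
    ss <- rss_without - rss_with
    fstat <- (ss / 1) / (rss_full / df_res)
    tibble::tibble(
      term = tm,
      b = unname(cf[i]),
      conf.low = ci[i, 1], conf.high = ci[i, 2],
      beta = unname(cf[i]) * stats::sd(data[[tm]]) / sdy,
      ss = ss, df = 1L, statistic = fstat,
      p = stats::pf(fstat, 1, df_res, lower.tail = FALSE)
    )
  })

  structure(
    list(
      model = fit, terms = terms, outcome = outcome, data = data,
      coef_table = dplyr::bind_rows(rows),
      r2 = r2, adj_r2 = adj_r2,
      f_statistic = f_overall, df = c(length(terms), df_res),
      n = n, sigma = sqrt(rss_full / df_res), rss = rss_full
    ),
    class = "outcome_model_fit"
  )
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat("<outcome_model_fit> n =", x$n, "\n")
  if (nrow(x$coef_table) > 0) {
    print(as.data.frame(x$coef_table[, c("term", "b", "beta", "statistic", "p")]),
          digits = 3, row.names = FALSE)
  }
  cat(sprintf("r2 = %.3f, adj r2 = %.3f, F(%d, %d) = %.3f\n",
              x$r2, x$adj_r2, x$df[1], x$df[2], x$f_statistic))
  invisible(x)
}

#' Partial residuals for one model term
#'
#' Component-plus-residual values `resid + b_term * x_term`, the quantity
#' plotted when showing how one biomarker relates to the outcome with the
#' other model terms held fixed. Regressing the returned values on
#' `x_term` recovers exactly `b_term`.
#'
#' @param fit An `outcome_model_fit`.
#' @param term Term name present in the fit.
#' @return Tibble with `liver_id` (if present), `x` (the term values) and
#'   `partial_residual`.
#' @export
partial_residuals <- function(fit, term) {
  stopifnot(inherits(fit, "outcome_model_fit"))
  if (length(fit$terms) > 0 && !term %in% fit$terms) {
    stop("unknown term: ", term)
  }
  res <- stats::residuals(fit$model)
  if (length(fit$terms) == 0) {
    # intercept-only: partial residuals are ordinary residuals
    out <- tibble::tibble(x = NA_real_, partial_residual = unname(res))
  } else {
    b <- fit$coef_table$b[fit$coef_table$term == term]
    x <- fit$data[[term]]
    out <- tibble::tibble(x = x, partial_residual = unname(res) + b * x)
  }
  if ("liver_id" %in% names(fit$data)) {
    out <- dplyr::bind_cols(
      tibble::tibble(liver_id = fit$data$liver_id), out
    )
  }
  out
}
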