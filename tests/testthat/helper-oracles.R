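# Independent oracles and fixture builders shared across tests.

# Canonical succinate coupling-control truth used throughout: the published
# cohort means at the end of static cold storage.
suit02_truth <- c(LEAK = 8.21, OXPHOS = 40.49, OXPHOS_cytc = 43.48,
                  CCCP1 = 65, CCCP2 = 70.33, CCCP3 = 68)

suit02_table <- function(fluxes = suit02_truth, liver_id = "L001",
                         timepoint = "pre") {
  tibble::tibble(
    liver_id = liver_id, timepoint = timepoint, protocol_id = "SUIT02",
    step = names(fluxes), flux = unname(fluxes),
    t_start = NA_real_, t_end = NA_real_, cv = 0, qc = "ok"
  )
}

# Exhaustive AIC minimization over all hierarchy-respecting term subsets;
# brute-force counterpart of the greedy stepwise search.
enum_best_aic <- function(d, outcome, scope) {
  mains <- scope[!grepl(":", scope)]
  ints <- scope[grepl(":", scope)]
  best <- NULL
  best_aic <- Inf
  n <- nrow(d)
  msets <- unlist(lapply(0:length(mains), function(k) {
    utils::combn(mains, k, simplify = FALSE)
  }), recursive = FALSE)
  for (ms in msets) {
    oks <- if (length(ints)) {
      ints[vapply(ints, function(it) {
        all(strsplit(it, ":")[[1]] %in% ms)
      }, logical(1))]
    } else {
      character(0)
    }
    isets <- unlist(lapply(0:length(oks), function(k) {
      utils::combn(oks, k, simplify = FALSE)
    }), recursive = FALSE)
    for (is in isets) {
      terms <- c(ms, unlist(is))
      X <- as.matrix(cbind(1, d[, terms, drop = FALSE]))
      r <- qr.resid(qr(X), d[[outcome]])
      aic <- n * log(sum(r^2) / n) + 2 * (length(terms) + 1)
      if (aic < best_aic - 1e-10) {
        best_aic <- aic
        best <- sort(terms)
      }
    }
  }
  best
}

# RSS by direct QR algebra, bypassing lm(): used to recompute Type II SS.
qr_rss <- function(d, outcome, terms) {
  X <- as.matrix(cbind(1, d[, terms, drop = FALSE]))
  sum(qr.resid(qr(X), d[[outcome]])^2)
}

# Dense-grid trapezoid: integrate the piecewise-linear interpolant of
# (time, value) over [t0, t1] on a fine uniform grid.
fine_grid_auc <- function(time_h, value, window, n_grid = 50001) {
  t0 <- max(window[1], min(time_h))
  t1 <- min(window[2], max(time_h))
  # include the observation knots so the piecewise-linear integrand is
  # integrated exactly
  g <- sort(unique(c(seq(t0, t1, length.out = n_grid),
                     time_h[time_h > t0 & time_h < t1])))
  v <- stats::approx(time_h, value, xout = g)$y
  sum(diff(g) * (head(v, -1) + tail(v, -1)) / 2)
}

# Random design with an interaction column, used by model-fitting tests.
random_design <- function(n, seed, with_interaction = TRUE) {
  set.seed(seed)
  d <- tibble::tibble(
    liver_id = seq_len(n),
    a = stats::rnorm(n), b = stats::rnorm(n), c = stats::rnorm(n)
  )
  if (with_interaction) d$`a:b` <- d$a * d$b
  d$y <- 0.8 * d$a - 0.4 * d$b +
    (if (with_interaction) -0.5 * d$`a:b` else 0) + stats::rnorm(n)
  d
}

# Perfusate series builder with all three criteria controllable.
make_perfusate <- function(lactate_ok = TRUE, ph_ok = TRUE,
                           enzymes_ok = TRUE) {
  tibble::tibble(
    time_h = c(0.25, 1, 6, 12),
    lactate = if (lactate_ok) c(6.4, 1.6, 0.9, 0.6) else c(6.4, 4.1, 3.2, 2.9),
    ph = if (ph_ok) rep(7.38, 4) else c(7.38, 7.21, 7.38, 7.38),
    ast = if (enzymes_ok) c(1200, 1500, 1800, 2500) else c(1200, 1500, 25000, 26000),
    alt = c(800, 1000, 1300, 1800),
    ldh = c(2000, 2600, 3100, 4300),
    il6 = c(4000, 5000, 6000, 7000),
    bicarbonate_given = FALSE
  )
}
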