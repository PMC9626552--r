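# AUC, design assembly, stepwise selection, Type II ANOVA, partial residuals.

test_that("trapezoidal AUC matches rectangle and triangle closed forms", {
  expect_equal(time_auc(c(0, 1, 6), c(0.8, 0.8, 0.8)), 4.8)
  expect_equal(time_auc(c(0, 6), c(0, 6)), 18)
  # time-averaged variant
  expect_equal(time_auc(c(0, 6), c(0, 6), average = TRUE), 3)
})

test_that("AUC clips to the window by interpolation, never extrapolates", {
  # observation past the window: interpolate at t = 6
  expect_equal(time_auc(c(0, 1, 7.5), c(1, 1, 1), window = c(0, 6)), 6)
  # observations start inside the window: integrate only observed span
  expect_equal(time_auc(c(2, 6), c(1, 1), window = c(0, 6)), 4)
  # fewer than two observations in the window: missing
  expect_true(is.na(time_auc(c(0), c(1))))
  expect_true(is.na(time_auc(c(10, 12), c(1, 1), window = c(0, 6))))
  expect_error(time_auc(c(0, 0, 6), c(1, 1, 1)), "strictly increasing")
})

test_that("AUC equals a fine-grid trapezoid oracle on irregular grids", {
  set.seed(31)
  for (i in 1:20) {
    t <- sort(stats::runif(stats::rpois(1, 6) + 2, 0, 10))
    t <- t[c(TRUE, diff(t) > 1e-3)]
    v <- stats::rnorm(length(t))
    w <- sort(stats::runif(2, 0, 10))
    if (diff(w) < 0.1) next
    got <- time_auc(t, v, window = w)
    want <- fine_grid_auc(t, v, w)
    if (is.na(got)) next
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("AUC is linear in the trajectory on a fixed grid", {
  t <- c(0, 1, 3, 6)
  f <- c(2, 5, 4, 1)
  a <- 2.5
  cst <- 1.3
  expect_equal(time_auc(t, a * f + cst),
               a * time_auc(t, f) + cst * 6, tolerance = 1e-12)
})

test_that("design assembly builds interactions as products on complete cases", {
  co <- tibble::tibble(liver_id = sprintf("L%02d", 1:22),
                       x1 = stats::rnorm(22), x2 = stats::rnorm(22),
                       y = stats::rnorm(22))
  co$x1[21:22] <- NA
  d <- suppressMessages(
    assemble_design(co, "y", c("x1", "x2"), list(c("x1", "x2")))
  )
  expect_equal(nrow(d), 20)
  expect_equal(attr(d, "n_dropped"), 2)
  expect_equal(d$`x1:x2`, d$x1 * d$x2)
  expect_named(d, c("liver_id", "y", "x1", "x2", "x1:x2"))

  # residual df 15 with 4 terms and n = 20 complete cases
  co20 <- co[1:20, ]
  co20$x3 <- stats::rnorm(20)
  d20 <- assemble_design(co20, "y", c("x1", "x2", "x3"), list(c("x1", "x2")))
  f <- fit_and_anova(d20, "y", c("x1", "x2", "x3", "x1:x2"))
  expect_equal(f$df[2], 15)

  co$flat <- 1
  expect_error(assemble_design(co, "y", c("x1", "flat")), "flat")
  expect_error(assemble_design(co, "y", "nope"), "nope")
})

test_that("stepwise recovers a noiseless planted model exactly", {
  set.seed(41)
  n <- 40
  d <- tibble::tibble(liver_id = 1:n, a = stats::rnorm(n),
                      b = stats::rnorm(n), c = stats::rnorm(n))
  d$`a:b` <- d$a * d$b
  d$y <- 2 + 1.5 * d$a - 0.8 * d$b + 0.6 * d$`a:b`
  sw <- stepwise_aic(d, "y", c("a", "b", "c", "a:b"))
  expect_setequal(sw$terms, c("a", "b", "a:b"))
})

test_that("stepwise equals exhaustive hierarchical enumeration on random data", {
  for (s in 1:10) {
    d <- random_design(100, seed = s)
    scope <- c("a", "b", "c", "a:b")
    expect_identical(sort(stepwise_aic(d, "y", scope)$terms),
                     sort(enum_best_aic(d, "y", scope)))
  }
})

test_that("stepwise agrees with stats::step on the same scope", {
  skip_if_not_installed("MASS")
  for (s in c(3, 14, 27)) {
    d <- random_design(60, seed = s)
    sw <- stepwise_aic(d, "y", c("a", "b", "c", "a:b"))
    df <- data.frame(y = d$y, a = d$a, b = d$b, c = d$c)
    st <- stats::step(stats::lm(y ~ 1, data = df),
                      scope = y ~ a + b + c + a:b,
                      direction = "both", trace = 0)
    st_terms <- attr(stats::terms(st), "term.labels")
    # normalize interaction label order before comparing
    norm <- function(x) sort(vapply(strsplit(x, ":"), function(p) {
      paste(sort(p), collapse = ":")
    }, character(1)))
    expect_identical(norm(sw$terms), norm(st_terms))
  }
})

test_that("pure-noise predictors select intercept-only in the majority of seeds", {
  picks <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    n <- 200
    d <- tibble::tibble(liver_id = 1:n, a = stats::rnorm(n),
                        b = stats::rnorm(n), c = stats::rnorm(n),
                        y = stats::rnorm(n))
    length(stepwise_aic(d, "y", c("a", "b", "c"))$terms) == 0
  }, logical(1))
  expect_gt(mean(picks), 0.5)
})

test_that("hierarchy is enforced: interactions only with both parents in", {
  set.seed(53)
  n <- 60
  d <- tibble::tibble(liver_id = 1:n, a = stats::rnorm(n),
                      b = stats::rnorm(n))
  d$`a:b` <- d$a * d$b
  d$y <- 3 * d$a + stats::rnorm(n)
  sw <- stepwise_aic(d, "y", c("a", "b", "a:b"))
  if ("a:b" %in% sw$terms) {
    expect_true(all(c("a", "b") %in% sw$terms))
  }
  expect_error(stepwise_aic(d[1:3, ], "y", c("a", "b", "a:b")),
               "more observations")
})

test_that("Type II SS equals nested-refit RSS differences computed by QR", {
  for (s in 1:10) {
    d <- random_design(35, seed = 100 + s)
    terms <- c("a", "b", "c", "a:b")
    f <- fit_and_anova(d, "y", terms)
    for (tm in terms) {
      keep <- terms[!vapply(terms, function(o) {
        o == tm || tm %in% strsplit(o, ":")[[1]]
      }, logical(1))]
      ss_oracle <- qr_rss(d, "y", keep) - qr_rss(d, "y", c(keep, tm))
      expect_equal(f$coef_table$ss[f$coef_table$term == tm], ss_oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("on orthogonal designs Type II SS equals sequential (Type I) SS", {
  # balanced +/-1 factors are exactly orthogonal
  d <- tibble::tibble(liver_id = 1:8,
                      a = rep(c(-1, 1), each = 4),
                      b = rep(c(-1, 1, -1, 1), each = 2))
  set.seed(61)
  d$y <- 1 + 0.5 * d$a - 0.25 * d$b + stats::rnorm(8, 0, 0.3)
  f <- fit_and_anova(d, "y", c("a", "b"))
  a1 <- stats::anova(stats::lm(y ~ a + b, data = d))
  expect_equal(f$coef_table$ss, a1$`Sum Sq`[1:2], tolerance = 1e-10)
})

test_that("overall F reproduces the r-squared closed form; df are consistent", {
  d <- random_design(20, seed = 77)
  f <- fit_and_anova(d, "y", c("a", "b", "c", "a:b"))
  expect_equal(f$f_statistic,
               (f$r2 / 4) / ((1 - f$r2) / 15), tolerance = 1e-12)
  expect_equal(f$df, c(4, 15))
  expect_lte(f$adj_r2, f$r2)
  # a 4-term model with r2 = 0.40 at n = 20 implies F ~ 2.5
  expect_equal((0.40 / 4) / ((1 - 0.40) / 15), 2.5)
  # standardized beta definition
  expect_equal(f$coef_table$beta,
               unname(f$coef_table$b * vapply(f$coef_table$term, function(tm) {
                 stats::sd(d[[tm]])
               }, numeric(1)) / stats::sd(d$y)))
  # confidence intervals match lm's
  ci <- stats::confint(f$model)[-1, ]
  expect_equal(unname(f$coef_table$conf.low), unname(ci[, 1]))
  expect_error(fit_and_anova(d[1:5, ], "y", c("a", "b", "c", "a:b")),
               "residual degrees")
})

test_that("partial residuals regress back onto their term with slope b", {
  d <- random_design(30, seed = 88)
  f <- fit_and_anova(d, "y", c("a", "b", "a:b"))
  for (tm in c("a", "b", "a:b")) {
    pr <- partial_residuals(f, tm)
    slope <- stats::coef(stats::lm(pr$partial_residual ~ pr$x))[2]
    expect_equal(unname(slope),
                 f$coef_table$b[f$coef_table$term == tm], tolerance = 1e-9)
    # direct definition from the design matrix
    direct <- stats::residuals(f$model) +
      f$coef_table$b[f$coef_table$term == tm] * d[[tm]]
    expect_equal(pr$partial_residual, unname(direct), tolerance = 1e-12)
  }
  expect_error(partial_residuals(f, "zzz"), "unknown term")

  f0 <- fit_and_anova(d, "y", character(0))
  pr0 <- partial_residuals(f0, "any")
  expect_equal(pr0$partial_residual, unname(stats::residuals(f0$model)))
})
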