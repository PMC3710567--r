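test_that("build_design produces the stated response and columns", {
  df <- toy_panel_df(n_states = 3, years = 1999:2007)
  p <- ltss_panel(df)
  d <- build_design(p, frontier_spec(base_year = 2007))
  expect_equal(sum(grepl("^yr", colnames(d$X))), 8)  # 8 year dummies
  expect_equal(d$y, log(df[order(df$state, df$year), "total_cost"]))

  one <- ltss_panel(toy_panel_df(n_states = 3, years = 2005))
  d1 <- build_design(one, frontier_spec(base_year = 2005))
  expect_equal(sum(grepl("^yr", colnames(d1$X))), 0)

  rec <- toy_panel_df(n_states = 2, years = 2007)
  rec$total_cost[1] <- 1000; rec$q_hcbs[1] <- 10; rec$q_inst[1] <- 5
  dr <- build_design(ltss_panel(rec), frontier_spec(base_year = 2007))
  i <- which(dr$state == rec$state[1])
  expect_equal(dr$y[i], log(1000))
  expect_equal(unname(dr$X[i, 1:3]), c(1, log(10), log(5)))

  # squares-and-interaction form adds exactly three columns
  d2 <- build_design(p, frontier_spec(output_terms = "with_squares_and_interaction",
                                      base_year = 2007))
  expect_equal(ncol(d2$X), ncol(d$X) + 3)
})

test_that("zero counts are a domain error unless an offset is given", {
  df <- toy_panel_df(n_states = 2, years = 2006:2007)
  df$q_hcbs[2] <- 0
  p <- suppressMessages(ltss_panel(df))
  expect_error(build_design(p, frontier_spec()), "domain error")
  d <- build_design(p, frontier_spec(), offset = 1)
  expect_true(all(is.finite(d$X)))
})

test_that("decay factor has its anchor, null, and evaluated cases", {
  expect_equal(decay_factor(2007, 2007, 0.3), 1)
  expect_equal(decay_factor(1999:2007, 2007, 0), rep(1, 9))
  expect_equal(decay_factor(1999, 2007, 0.011), 1.0919889, tolerance = 1e-6)
  expect_error(decay_factor(2008, 2007, 0.1))
})

test_that("closed-form log-likelihood agrees with the quadrature oracle", {
  set.seed(42)
  for (rep in 1:20) {
    df <- toy_panel_df(n_states = sample(2:4, 1),
                       years = 2000 + seq_len(sample(2:4, 1)), seed = rep)
    des <- build_design(ltss_panel(df), frontier_spec(base_year = 2004))
    p <- random_frontier_params(ncol(des$X))
    p$beta[1] <- 13  # keep residuals in a numerically honest range
    spec <- frontier_spec()
    expect_lt(abs(frontier_loglik(p, des, spec) - quad_loglik(p, des, spec)),
              1e-8)
  }
})

test_that("half-normal path equals truncated-normal with mu = 0, and nesting holds", {
  df <- toy_panel_df(n_states = 4, years = 2001:2004, seed = 7)
  des <- build_design(ltss_panel(df), frontier_spec(base_year = 2004))
  p <- random_frontier_params(ncol(des$X))
  p$mu <- 0
  expect_identical(frontier_loglik(p, des, frontier_spec("hnormal")),
                   frontier_loglik(p, des, frontier_spec("tnormal")))
})

test_that("gamma -> 0 limit collapses to the Gaussian log-likelihood", {
  df <- toy_panel_df(n_states = 3, years = 2001:2003, seed = 3)
  des <- build_design(ltss_panel(df), frontier_spec(base_year = 2003))
  beta <- qr.coef(qr(des$X), des$y)
  eps <- des$y - drop(des$X %*% beta)
  p <- frontier_params(beta, sigma_sq = 0.5, gamma = 1e-12, mu = 0, eta = 0)
  expect_equal(frontier_loglik(p, des, frontier_spec()),
               sum(dnorm(eps, 0, sqrt(0.5), log = TRUE)), tolerance = 1e-5)
})

test_that("log-likelihood is invariant to state order and year relabeling", {
  df <- toy_panel_df(n_states = 4, years = 2001:2004, seed = 13)
  spec <- frontier_spec(base_year = 2004)
  des <- build_design(ltss_panel(df), spec)
  p <- random_frontier_params(ncol(des$X))
  ll <- frontier_loglik(p, des, spec)
  # permute states
  df2 <- df[order(df$state, decreasing = TRUE), ]
  des2 <- build_design(ltss_panel(df2), spec)
  expect_equal(frontier_loglik(p, des2, spec), ll, tolerance = 1e-10)
  # shift all years by +10 (t - T preserved; year dummies follow the shift)
  df3 <- df; df3$year <- df3$year + 10
  des3 <- build_design(ltss_panel(df3, year_range = c(1999, 2020)),
                       frontier_spec(base_year = 2014))
  expect_equal(frontier_loglik(p, des3, spec), ll, tolerance = 1e-10)
})

test_that("analytic score matches the numerical gradient", {
  set.seed(8)
  df <- toy_panel_df(n_states = 4, years = 2001:2004, seed = 8)
  des <- build_design(ltss_panel(df), frontier_spec(base_year = 2004))
  k <- ncol(des$X)
  for (spec in list(frontier_spec("tnormal"), frontier_spec("hnormal"),
                    frontier_spec("exponential", time_varying = FALSE))) {
    p <- random_frontier_params(k)
    p$beta[1] <- 13
    if (spec$distribution == "hnormal") p$mu <- 0
    sc <- ltssfa:::frontier_score(p, des, spec)
    nat <- c(p$beta, p$sigma_sq, p$gamma)
    if (spec$distribution == "tnormal") nat <- c(nat, p$mu)
    if (spec$time_varying) nat <- c(nat, p$eta)
    num <- numDeriv::grad(function(v) {
      pp <- list(beta = v[seq_len(k)], sigma_sq = v[k + 1], gamma = v[k + 2],
                 mu = 0, eta = 0)
      j <- k + 3
      if (spec$distribution == "tnormal") { pp$mu <- v[j]; j <- j + 1 }
      if (spec$time_varying) pp$eta <- v[j]
      frontier_loglik(pp, des, spec)
    }, nat)
    expect_lt(max(abs(sc - num)), 1e-5 * max(1, max(abs(num))))
  }
})

test_that("exponential path matches numerical convolution", {
  df <- toy_panel_df(n_states = 3, years = 2001:2003, seed = 5)
  spec <- frontier_spec("exponential", time_varying = FALSE,
                        base_year = 2003)
  des <- build_design(ltss_panel(df), spec)
  beta <- qr.coef(qr(des$X), des$y)
  p <- frontier_params(beta, sigma_sq = 0.4, gamma = 0.5)
  sv <- sqrt(0.2); su <- sqrt(0.2)
  eps <- des$y - drop(des$X %*% beta)
  ll_num <- sum(vapply(eps, function(e)
    log(integrate(function(u) dnorm(e - u, 0, sv) * dexp(u, 1 / su),
                  0, Inf, rel.tol = 1e-12)$value), 0))
  expect_equal(frontier_loglik(p, des, spec), ll_num, tolerance = 1e-8)
  # exponential + time-varying is rejected by the spec constructor
  expect_error(frontier_spec("exponential", time_varying = TRUE))
})

test_that("fit collapses to OLS when the generating sigma_u is zero", {
  cfg <- synthetic_config(n_states = 20, years = 2001:2006, seed = 31,
                          frontier = frontier_truth(sigma_u = 0, mu = 0,
                                                    eta = 0, sigma_v = 0.15))
  gen <- suppressMessages(generate_panel(cfg))
  # half-normal, time-invariant: with no true inefficiency, gamma is
  # identified by skewness and collapses toward its boundary. (Under
  # tnormal + decay the mean-inefficiency path is collinear with the year
  # dummies, so gamma/mu sit on a likelihood ridge there - see vignette.)
  fit <- fit_frontier(gen$panel,
                      frontier_spec("hnormal", time_varying = FALSE,
                                    base_year = 2006),
                      options = list(n_starts = 3))
  des <- fit$design
  ols <- qr.coef(qr(des$X), des$y)
  s <- summary(stats::lm(des$y ~ des$X - 1))$coefficients[, "Std. Error"]
  expect_lt(fit$params$gamma, 0.3)
  expect_true(all(abs(fit$params$beta - ols) < 2 * s))
})

test_that("refitting identical data is deterministic", {
  gen <- suppressMessages(
    generate_panel(synthetic_config(n_states = 10, years = 2002:2006,
                                    seed = 77)))
  f1 <- fit_frontier(gen$panel, frontier_spec(base_year = 2006))
  f2 <- fit_frontier(gen$panel, frontier_spec(base_year = 2006))
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("score prediction matches posterior-mean quadrature and its contracts", {
  df <- toy_panel_df(n_states = 1, years = 2006:2007, seed = 19)
  p_panel <- ltss_panel(df)
  spec <- frontier_spec(base_year = 2007)
  des <- build_design(p_panel, spec)
  pars <- frontier_params(beta = c(13, 0.2, 0.2, 0),
                          sigma_sq = 0.3, gamma = 0.6, mu = 0.2, eta = 0.05)
  fit <- structure(list(spec = spec, params = pars, design = des),
                   class = "frontier_fit")
  sc <- predict_scores(fit)
  e_u <- quad_posterior_mean(pars, des, spec, df$state[1])
  h <- exp(-pars$eta * des$t_rel)
  expect_equal(sc$u_hat, h * e_u, tolerance = 1e-8)
  expect_equal(sc$ce, exp(-sc$score / 100), tolerance = 1e-12)
  expect_true(all(sc$score >= 0 & sc$ce > 0 & sc$ce <= 1))
  # states not in the fit are an index error
  other <- ltss_panel(toy_panel_df(n_states = 3, years = 2006:2007, seed = 20))
  expect_error(predict_scores(fit, other), "index error")
})

test_that("fitted decay produces within-state monotone scores", {
  gen <- suppressMessages(
    generate_panel(synthetic_config(n_states = 15, seed = 41,
                                    frontier = frontier_truth(eta = 0.03))))
  fit <- fit_frontier(gen$panel, frontier_spec(), options = list(n_starts = 3))
  expect_gt(fit$params$eta, 0)
  sc <- predict_scores(fit)
  for (s in unique(sc$state)) {
    u <- sc$score[sc$state == s][order(sc$year[sc$state == s])]
    expect_true(all(diff(u) < 0))
  }
  # fitted hnormal is nested in tnormal: loglik ordering
  fit_h <- fit_frontier(gen$panel, frontier_spec("hnormal"),
                        options = list(n_starts = 3))
  expect_lte(fit_h$loglik, fit$loglik + 1e-6)
})
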