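# Independent oracles and fixture builders. Everything here stays
# deliberately independent of the package's closed-form code paths: the
# likelihood oracle integrates numerically, the LSDV oracle calls lm()
# with explicit dummies, the sandwich oracle loops over clusters.

# small valid panel data.frame, built directly
toy_panel_df <- function(n_states = 3, years = 2001:2003, seed = 1,
                         cost_fun = NULL) {
  set.seed(seed)
  states <- state_codes()[seq_len(n_states)]
  df <- expand.grid(state = states, year = years, stringsAsFactors = FALSE)
  n <- nrow(df)
  df$q_inst <- round(runif(n, 500, 5000))
  df$q_hcbs <- round(runif(n, 500, 8000))
  df$total_cost <- if (is.null(cost_fun))
    exp(13 + 0.2 * log(df$q_hcbs) + 0.2 * log(df$q_inst) + rnorm(n, 0, 0.2))
  else cost_fun(df)
  df$hcbs_share <- runif(n, 20, 90)
  df$waiver_share <- runif(n, 10, 90)
  df$icfmr_share <- runif(n, 0, 15)
  df$managed_care <- rbinom(n, 1, 0.4)
  df$con <- rbinom(n, 1, 0.7)
  df$population <- runif(n, 5e5, 3e7)
  df$pc_income <- runif(n, 25000, 45000)
  df$unemployment <- runif(n, 3, 8)
  df[, c("state", "year", "total_cost", "q_inst", "q_hcbs", "hcbs_share",
         "waiver_share", "icfmr_share", "managed_care", "con", "population",
         "pc_income", "unemployment")]
}

# a complete 51-jurisdiction x 9-year grid with valid values
full_grid_df <- function() {
  df <- expand.grid(state = state_codes(), year = 1999:2007,
                    stringsAsFactors = FALSE)
  n <- nrow(df)
  df$total_cost <- 1e9
  df$q_inst <- 1000
  df$q_hcbs <- 1500
  df$hcbs_share <- 54
  df$waiver_share <- 52
  df$icfmr_share <- 6
  df$managed_care <- 0
  df$con <- 1
  df$population <- 5e6
  df$pc_income <- 33000
  df$unemployment <- 4.7
  df
}

# marginal log-likelihood by scaled adaptive 1-D quadrature, state by state
quad_loglik <- function(params, design, spec) {
  sv <- sqrt((1 - params$gamma) * params$sigma_sq)
  su <- sqrt(params$gamma * params$sigma_sq)
  mu <- if (spec$distribution == "hnormal") 0 else params$mu
  eta <- if (spec$time_varying) params$eta else 0
  eps <- design$y - drop(design$X %*% params$beta)
  total <- 0
  for (s in unique(design$state)) {
    i <- design$state == s
    h <- exp(-eta * design$t_rel[i])
    e <- eps[i]
    lf <- function(u) sum(dnorm((e - u * h) / sv, log = TRUE) - log(sv)) +
      dnorm((u - mu) / su, log = TRUE) - log(su) -
      pnorm(mu / su, log.p = TRUE)
    M <- optimize(lf, c(0, 50), maximum = TRUE)$objective
    f <- function(u) vapply(u, function(uu) exp(lf(uu) - M), 0)
    total <- total + M +
      log(integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
  }
  total
}

# E[u_i | data] by quadrature for one state
quad_posterior_mean <- function(params, design, spec, state) {
  sv <- sqrt((1 - params$gamma) * params$sigma_sq)
  su <- sqrt(params$gamma * params$sigma_sq)
  mu <- if (spec$distribution == "hnormal") 0 else params$mu
  eta <- if (spec$time_varying) params$eta else 0
  eps <- design$y - drop(design$X %*% params$beta)
  i <- design$state == state
  h <- exp(-eta * design$t_rel[i])
  e <- eps[i]
  lf <- function(u) sum(dnorm((e - u * h) / sv, log = TRUE)) +
    dnorm((u - mu) / su, log = TRUE)
  M <- optimize(lf, c(0, 50), maximum = TRUE)$objective
  f0 <- function(u) vapply(u, function(uu) exp(lf(uu) - M), 0)
  f1 <- function(u) u * f0(u)
  integrate(f1, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value /
    integrate(f0, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# random frontier parameters in a plausible region
random_frontier_params <- function(k) {
  frontier_params(beta = c(runif(1, 5, 15), runif(k - 1, -0.3, 0.5)),
                  sigma_sq = runif(1, 0.05, 1.5),
                  gamma = runif(1, 0.1, 0.9),
                  mu = runif(1, -0.8, 0.8),
                  eta = runif(1, -0.1, 0.15))
}

# second-stage regression table built directly (bypasses the frontier)
toy_ss_table <- function(n_states = 4, n_years = 3, seed = 1, k = 2,
                         beta = NULL, state_effect_sd = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- seq_len(k)
  st <- sprintf("S%02d", seq_len(n_states))
  tab <- expand.grid(state = st, year = seq_len(n_years) + 2000,
                     stringsAsFactors = FALSE)
  n <- nrow(tab)
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  alpha <- rnorm(n_states, 0, state_effect_sd)
  names(alpha) <- st
  tab$log_score <- drop(X %*% beta) + alpha[tab$state] + rnorm(n, 0, 0.5)
  cbind(tab, as.data.frame(X))
}

# LSDV oracle: lm with explicit state dummies
lsdv_oracle <- function(table, covariates) {
  f <- stats::as.formula(paste("log_score ~ 0 + factor(state) +",
                               paste(covariates, collapse = " + ")))
  coef(stats::lm(f, data = table))[covariates]
}

# CR1 sandwich by explicit cluster loop on the demeaned regression
sandwich_oracle <- function(fit) {
  X <- fit$model_matrix
  e <- fit$residuals
  g <- as.character(fit$group)
  k <- ncol(X)
  meat <- matrix(0, k, k)
  for (cl in unique(g)) {
    idx <- g == cl
    s <- t(X[idx, , drop = FALSE]) %*% e[idx]
    meat <- meat + s %*% t(s)
  }
  bread <- solve(t(X) %*% X)
  G <- length(unique(g))
  n <- nrow(X)
  cf <- G / (G - 1) * (n - 1) / (n - k)
  sqrt(diag(cf * bread %*% meat %*% bread))
}

score_panel_from <- function(state, year, u_hat) {
  structure(data.frame(state = state, year = year, u_hat = u_hat,
                       score = 100 * u_hat, ce = exp(-u_hat),
                       stringsAsFactors = FALSE),
            class = c("score_panel", "data.frame"))
}
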