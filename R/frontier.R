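# Panel stochastic cost frontier with time-varying-decay inefficiency.
#
# Model: log(cost_it) = x_it' beta + eps_it,  eps_it = v_it + u_it (cost
# orientation: inefficiency raises cost), v_it ~ N(0, sigma_v^2) iid, and
# u_it = u_i * h_it with h_it = exp(-eta * (t - T_i)) and u_i drawn from
# N(mu, sigma_u^2) truncated at zero (truncated-normal; mu = 0 gives the
# half-normal). The state-level u_i is integrated out analytically: the
# integrand is Gaussian in u_i, so each state's contribution reduces to a
# ratio of normal cdfs (the Battese-Coelli panel likelihood). Variance is
# parameterized as sigma_sq = sigma_v^2 + sigma_u^2, gamma = sigma_u^2 /
# sigma_sq in (0, 1).

#' Frontier model specification
#'
#' @param distribution inefficiency distribution. `"tnormal"` (default,
#'   reported model), `"hnormal"` (mu pinned to 0), or `"exponential"`
#'   (robustness check; pooled observation-level convolution, so
#'   `time_varying` must be `FALSE` — the time-decay panel form has no
#'   closed likelihood for exponential u).
#' @param time_varying decay-form time-varying inefficiency?
#' @param output_terms `"linear_logs"` (default, matches the reported
#'   frontier) or `"with_squares_and_interaction"` (two-output form with
#'   squared log outputs and their interaction).
#' @param base_year omitted year dummy (default 2007).
#' @return list of class `frontier_spec`.
#' @export
frontier_spec <- function(distribution = c("tnormal", "hnormal", "exponential"),
                          time_varying = TRUE,
                          output_terms = c("linear_logs",
                                           "with_squares_and_interaction"),
                          base_year = 2007L) {
  distribution <- match.arg(distribution)
  output_terms <- match.arg(output_terms)
  if (distribution == "exponential" && time_varying)
    stop("exponential inefficiency is supported only with time_varying = FALSE",
         call. = FALSE)
  structure(list(distribution = distribution, time_varying = time_varying,
                 output_terms = output_terms,
                 base_year = as.integer(base_year)),
            class = "frontier_spec")
}

#' Frontier parameters on the natural scale
#'
#' @param beta coefficient vector matching the design columns.
#' @param sigma_sq total variance sigma_v^2 + sigma_u^2 (> 0).
#' @param gamma inefficiency variance share sigma_u^2 / sigma_sq, in (0, 1).
#' @param mu truncated-normal location (0 for half-normal).
#' @param eta time-decay rate.
#' @return list of class `frontier_params`.
#' @export
frontier_params <- function(beta, sigma_sq, gamma, mu = 0, eta = 0) {
  stopifnot(sigma_sq > 0, gamma > 0, gamma < 1)
  structure(list(beta = beta, sigma_sq = sigma_sq, gamma = gamma,
                 mu = mu, eta = eta),
            class = "frontier_params")
}

#' Time-decay factor of inefficiency
#'
#' `exp(-eta * (t - T))`: 1 in the anchor year `T` (a state's last observed
#' year), above 1 in earlier years when `eta > 0` (inefficiency shrinking
#' toward `T`).
#'
#' @param t year (<= `T`).
#' @param T anchor year.
#' @param eta decay rate.
#' @return positive numeric.
#' @export
decay_factor <- function(t, T, eta) {
  stopifnot(all(t <= T))
  exp(-eta * (t - T))
}

#' Build the frontier design from a panel
#'
#' Response is `log(total_cost)` (costs should already be deflated).
#' Regressors: intercept, `log(q_hcbs)`, `log(q_inst)`, year dummies for
#' every panel year except `base_year`, and optionally squared log outputs
#' plus their interaction. Zero participant counts are a domain error
#' naming the offending record unless a positive `offset` is supplied
#' (added to the counts before logging; off by default because silent
#' offsets distort elasticities).
#'
#' @param data an `ltss_panel`.
#' @param spec a [frontier_spec()].
#' @param offset optional constant added to `q_hcbs` and `q_inst`.
#' @return list with `y`, `X`, `state`, `year`, `t_rel` (year minus the
#'   state's last observed year), and bookkeeping fields.
#' @export
build_design <- function(data, spec = frontier_spec(), offset = NULL) {
  stopifnot(inherits(data, "ltss_panel"), inherits(spec, "frontier_spec"))
  df <- data$records
  qh <- df$q_hcbs
  qi <- df$q_inst
  if (!is.null(offset)) {
    stopifnot(offset > 0)
    qh <- qh + offset
    qi <- qi + offset
  }
  zero <- qh <= 0 | qi <= 0
  if (any(zero)) {
    bad <- df[zero, c("state", "year")]
    stop("domain error: zero participant count, log undefined: ",
         paste(sprintf("%s %d", bad$state, bad$year), collapse = "; "),
         " (use offset= to add a constant)", call. = FALSE)
  }
  y <- log(df$total_cost)
  lh <- log(qh)
  li <- log(qi)
  X <- cbind(`(Intercept)` = 1, log_q_hcbs = lh, log_q_inst = li)
  if (spec$output_terms == "with_squares_and_interaction") {
    X <- cbind(X, log_q_hcbs_sq = lh^2, log_q_inst_sq = li^2,
               log_q_hcbs_x_inst = lh * li)
  }
  yrs <- sort(unique(df$year))
  for (yy in setdiff(yrs, spec$base_year)) {
    X <- cbind(X, as.numeric(df$year == yy))
    colnames(X)[ncol(X)] <- paste0("yr", yy)
  }
  Tmax <- tapply(df$year, df$state, max)
  list(y = y, X = X, state = df$state, year = df$year,
       t_rel = df$year - as.numeric(Tmax[df$state]),
       group = factor(df$state, levels = unique(df$state)),
       n_obs = nrow(df), n_states = length(Tmax), base_year = spec$base_year)
}

# inverse Mills ratio phi(z)/Phi(z), stable for very negative z
mills <- function(z) exp(stats::dnorm(z, log = TRUE) -
                           stats::pnorm(z, log.p = TRUE))

# Per-state sufficient pieces of the integrated likelihood: given residuals
# eps and decay weights h, the posterior of u_i given the state's data is
# N(mu_star, sd_star^2) truncated at 0 with
#   sd_star^2 = sigma_v^2 sigma_u^2 / (sigma_v^2 + sigma_u^2 sum h^2)
#   mu_star   = (mu sigma_v^2 + sigma_u^2 sum h eps) / (sigma_v^2 + sigma_u^2 sum h^2)
bc_state_posterior <- function(sum_h2, sum_he, sigma_v2, sigma_u2, mu) {
  denom <- sigma_v2 + sigma_u2 * sum_h2
  list(mu_star = (mu * sigma_v2 + sigma_u2 * sum_he) / denom,
       sd_star = sqrt(sigma_v2 * sigma_u2 / denom))
}

#' Frontier marginal log-likelihood (closed form)
#'
#' Integrates the state-level truncated-normal inefficiency out of the
#' product of Gaussian noise densities analytically. The half-normal path
#' is the truncated-normal path with `mu = 0`; the exponential path is the
#' pooled observation-level normal-exponential convolution.
#'
#' @param params a [frontier_params()] (or plain list with the same
#'   fields).
#' @param design output of [build_design()].
#' @param spec a [frontier_spec()].
#' @return scalar log-likelihood.
#' @export
frontier_loglik <- function(params, design, spec = frontier_spec()) {
  beta <- params$beta
  sigma_sq <- params$sigma_sq
  gamma <- params$gamma
  if (!is.finite(sigma_sq) || sigma_sq <= 0 || gamma <= 0 || gamma >= 1)
    return(-Inf)
  mu <- if (spec$distribution == "hnormal") 0 else params$mu
  eta <- if (spec$time_varying) params$eta else 0
  eps <- design$y - drop(design$X %*% beta)
  if (any(!is.finite(eps))) stop("numeric error: non-finite residuals",
                                 call. = FALSE)
  sigma_u2 <- gamma * sigma_sq
  sigma_v2 <- (1 - gamma) * sigma_sq

  if (spec$distribution == "exponential") {
    # eps = v + u, u ~ Exp(mean sigma_u), pointwise closed form
    sigma_u <- sqrt(sigma_u2)
    sigma_v <- sqrt(sigma_v2)
    ll <- -log(sigma_u) + sigma_v2 / (2 * sigma_u2) - eps / sigma_u +
      stats::pnorm(eps / sigma_v - sigma_v / sigma_u, log.p = TRUE)
    return(sum(ll))
  }

  if (max(abs(eta * design$t_rel)) > 125) return(-Inf)  # h^2 would overflow
  h <- exp(-eta * design$t_rel)
  g <- design$group %||%
    factor(design$state, levels = unique(design$state))
  gi <- as.integer(g)
  sum_h2 <- rowsum(h^2, g)[, 1]
  sum_he <- rowsum(h * eps, g)[, 1]
  T_i <- tabulate(g)

  post <- bc_state_posterior(sum_h2, sum_he, sigma_v2, sigma_u2, mu)
  z_star <- post$mu_star / post$sd_star
  sigma_u <- sqrt(sigma_u2)
  a <- mu / sigma_u
  D <- sigma_v2 + sigma_u2 * sum_h2
  head_i <- -(T_i / 2) * log(2 * pi * sigma_v2) + 0.5 * log(sigma_v2 / D)

  # The naive per-state term logPhi(z) - logPhi(a)
  # - (sum_e2/sv2 + a^2 - z^2)/2 suffers catastrophic cancellation between
  # ~1e100-magnitude pieces in the deep-tail regions the optimizer probes
  # (it fabricates spuriously high likelihoods there). Each case below
  # performs the dominant cancellation symbolically. L(x) = logPhi(x)
  # + x^2/2, asymptotic in the far left tail.
  L_deep <- function(x) -log(-x) - 0.5 * log(2 * pi) +
    log1p(-1 / x^2 + 3 / x^4 - 15 / x^6)
  ll_i <- numeric(length(z_star))
  zs <- z_star > -30
  if (any(zs)) {
    # quadratic as an explicit sum of squares; logPhi(z) direct
    sum_e2 <- rowsum((eps - post$mu_star[gi] * h)^2, g)[, 1]
    quad <- sum_e2[zs] / sigma_v2
    lz <- stats::pnorm(z_star[zs], log.p = TRUE)
    if (a > -30) {
      ll_i[zs] <- head_i[zs] + lz -
        0.5 * (quad + (post$mu_star[zs] - mu)^2 / sigma_u2) -
        stats::pnorm(a, log.p = TRUE)
    } else {
      # fold logPhi(a)'s -a^2/2 into the quadratic:
      # a^2/2 - (mu_star - mu)^2/(2 su2) = mu_star (2 mu - mu_star)/(2 su2)
      ms <- post$mu_star[zs]
      ll_i[zs] <- head_i[zs] + lz - 0.5 * quad +
        ms * (2 * mu - ms) / (2 * sigma_u2) - L_deep(a)
    }
  }
  if (any(!zs)) {
    # posterior mass deep below zero: likelihood is dominated by the raw
    # Gaussian term; L(z) and L(a) are both moderate
    raw_e2 <- rowsum(eps^2, g)[, 1]
    La <- if (a > -30) stats::pnorm(a, log.p = TRUE) + a^2 / 2 else L_deep(a)
    ll_i[!zs] <- head_i[!zs] - 0.5 * raw_e2[!zs] / sigma_v2 +
      L_deep(z_star[!zs]) - La
  }
  sum(ll_i)
}

# Analytic score of the marginal log-likelihood on the natural scale
# (beta, sigma_sq, gamma, mu, eta), obtained by chaining through the
# per-state sufficient statistics (sum h^2, sum h*eps, sum eps^2) and the
# posterior moments (mu_star, sd_star). Verified against numDeriv in the
# test suite; used for BFGS, Newton polishing and the observed
# information.
frontier_score <- function(params, design, spec) {
  beta <- params$beta
  sigma_sq <- params$sigma_sq
  gamma <- params$gamma
  mu <- if (spec$distribution == "hnormal") 0 else params$mu
  eta <- if (spec$time_varying) params$eta else 0
  eps <- design$y - drop(design$X %*% beta)
  sigma_u2 <- gamma * sigma_sq
  sigma_v2 <- (1 - gamma) * sigma_sq

  if (spec$distribution == "exponential") {
    sigma_u <- sqrt(sigma_u2)
    sigma_v <- sqrt(sigma_v2)
    w <- eps / sigma_v - sigma_v / sigma_u
    lw <- mills(w)
    g_beta <- drop(crossprod(design$X, 1 / sigma_u - lw / sigma_v))
    d_sv <- sum(sigma_v / sigma_u2 + lw * (-eps / sigma_v^2 - 1 / sigma_u))
    d_su <- sum(-1 / sigma_u - sigma_v2 / sigma_u^3 + eps / sigma_u2 +
                  lw * sigma_v / sigma_u2)
    d_sv2 <- d_sv / (2 * sigma_v)
    d_su2 <- d_su / (2 * sigma_u)
    out <- c(g_beta,
             sigma_sq = (1 - gamma) * d_sv2 + gamma * d_su2,
             gamma = sigma_sq * (d_su2 - d_sv2))
    return(out)
  }

  h <- exp(-eta * design$t_rel)
  g <- design$group %||% factor(design$state, levels = unique(design$state))
  sum_h2 <- rowsum(h^2, g)[, 1]
  sum_he <- rowsum(h * eps, g)[, 1]
  sum_e2 <- rowsum(eps^2, g)[, 1]
  T_i <- tabulate(g)

  D <- sigma_v2 + sigma_u2 * sum_h2
  mu_star <- (mu * sigma_v2 + sigma_u2 * sum_he) / D
  s_star2 <- sigma_v2 * sigma_u2 / D
  s_star <- sqrt(s_star2)
  z <- mu_star / s_star
  lz <- mills(z)
  # d ll / d mu_star and d ll / d s_star2 per state
  Gmu <- (z + lz) / s_star
  Gs2 <- 1 / (2 * s_star2) - (z + lz) * mu_star / (2 * s_star2 * s_star)

  # beta: d ll = eps/sigma_v2 - c_i * h, c_i = Gmu * sigma_u2 / D
  c_i <- Gmu * sigma_u2 / D
  w_obs <- eps / sigma_v2 - c_i[as.integer(g)] * h
  g_beta <- drop(crossprod(design$X, w_obs))

  a <- mu / sqrt(sigma_u2)
  la <- mills(a)
  n_i <- length(T_i)
  d_mu <- sum(-la / sqrt(sigma_u2) - mu / sigma_u2 + Gmu * sigma_v2 / D)
  d_sv2 <- sum(-T_i / (2 * sigma_v2) + sum_e2 / (2 * sigma_v2^2) +
                 Gmu * (mu - mu_star) / D + Gs2 * (sigma_u2 - s_star2) / D)
  d_su2 <- sum(rep(-1 / (2 * sigma_u2) + la * mu / (2 * sigma_u2^1.5) +
                     mu^2 / (2 * sigma_u2^2), n_i) +
                 Gmu * (sum_he - mu_star * sum_h2) / D +
                 Gs2 * (sigma_v2 - s_star2 * sum_h2) / D)
  # eta through h: dSh2/deta = -2 sum t h^2, dShe/deta = -sum t h eps
  P2 <- -(Gmu * mu_star + Gs2 * s_star2) * sigma_u2 / D
  sum_th2 <- rowsum(design$t_rel * h^2, g)[, 1]
  sum_the <- rowsum(design$t_rel * h * eps, g)[, 1]
  d_eta <- sum(c_i * (-sum_the) + P2 * (-2 * sum_th2))

  out <- c(g_beta,
           sigma_sq = (1 - gamma) * d_sv2 + gamma * d_su2,
           gamma = sigma_sq * (d_su2 - d_sv2))
  if (spec$distribution == "tnormal") out <- c(out, mu = d_mu)
  if (spec$time_varying) out <- c(out, eta = d_eta)
  out
}

# ---- internal <-> natural parameter mapping -------------------------------

# theta = (beta, log sigma_sq, qlogis(gamma)[, mu][, eta]); mu present for
# tnormal only, eta present when time_varying
theta_layout <- function(k, spec) {
  nm <- c(paste0("b", seq_len(k)), "log_sigma_sq", "logit_gamma")
  if (spec$distribution == "tnormal") nm <- c(nm, "mu")
  if (spec$time_varying) nm <- c(nm, "eta")
  nm
}

theta_to_params <- function(theta, k, spec) {
  p <- list(beta = theta[seq_len(k)],
            sigma_sq = exp(theta[k + 1]),
            gamma = stats::plogis(theta[k + 2]),
            mu = 0, eta = 0)
  j <- k + 3
  if (spec$distribution == "tnormal") { p$mu <- theta[j]; j <- j + 1 }
  if (spec$time_varying) p$eta <- theta[j]
  p
}

params_to_theta <- function(params, spec) {
  th <- c(params$beta, log(params$sigma_sq), stats::qlogis(params$gamma))
  if (spec$distribution == "tnormal") th <- c(th, params$mu)
  if (spec$time_varying) th <- c(th, params$eta)
  th
}

#' Fit the stochastic cost frontier by maximum likelihood
#'
#' Maximizes the marginal likelihood over an unconstrained internal
#' parameterization (`log sigma_sq`, `logit gamma`, `mu`, `eta` free) with
#' BFGS multi-starts from OLS-based initial values across a gamma grid
#' \{0.1, 0.3, 0.5, 0.7, 0.9\}, then Newton-polishes the best point until
#' the internal gradient norm drops below `grad_tol`. Standard errors come
#' from the inverse observed information on the natural scale.
#' Non-convergence is reported in the `convergence` block, never silently.
#'
#' @param data an `ltss_panel` (costs deflated).
#' @param spec a [frontier_spec()].
#' @param options list: `n_starts` (default 5), `maxit` (500), `grad_tol`
#'   (1e-6), `offset` (see [build_design()]).
#' @return object of class `frontier_fit`: `spec`, `params` (natural
#'   scale), `se`, `loglik`, `convergence` (flag, iterations, gradient
#'   norm), `n_obs`, `n_states`, and the design for score prediction.
#' @export
fit_frontier <- function(data, spec = frontier_spec(), options = list()) {
  opt <- utils::modifyList(list(n_starts = 5, maxit = 500, grad_tol = 1e-6,
                                offset = NULL), options)
  design <- build_design(data, spec, offset = opt$offset)
  if (design$n_states < 2) stop("need at least 2 states", call. = FALSE)
  if (spec$time_varying && max(table(design$state)) < 2)
    stop("time_varying needs at least 2 years for some state", call. = FALSE)
  k <- ncol(design$X)
  qr_x <- qr(design$X)
  if (qr_x$rank < k)
    stop("design not full rank; drop collinear columns", call. = FALSE)

  ols <- qr.coef(qr_x, design$y)
  res <- design$y - drop(design$X %*% ols)
  s2 <- sum(res^2) / (design$n_obs - k)

  negll <- function(theta) {
    p <- theta_to_params(theta, k, spec)
    ll <- tryCatch(frontier_loglik(p, design, spec), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # analytic gradient of negll on the internal scale (chain rule through
  # exp / plogis for the variance parameters)
  negll_grad <- function(theta) {
    p <- theta_to_params(theta, k, spec)
    sc <- tryCatch(frontier_score(p, design, spec), error = function(e) NULL)
    if (is.null(sc) || any(!is.finite(sc))) return(rep(0, length(theta)))
    jac <- rep(1, length(sc))
    jac[k + 1] <- p$sigma_sq
    jac[k + 2] <- p$gamma * (1 - p$gamma)
    -sc * jac
  }

  gammas <- seq(0.1, 0.9, length.out = opt$n_starts)
  best <- NULL
  for (g0 in gammas) {
    p0 <- list(beta = ols, sigma_sq = s2 / (1 - g0 / 2), gamma = g0,
               mu = 0, eta = 0)
    th0 <- params_to_theta(p0, spec)
    fit <- tryCatch(
      stats::optim(th0, negll, gr = negll_grad, method = "BFGS",
                   control = list(maxit = opt$maxit, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)

  # Newton polish toward grad norm < grad_tol, with Levenberg damping: the
  # observed information can be indefinite near the gamma boundary or
  # where mu is weakly identified
  theta <- best$par
  iters <- best$counts[["function"]]
  damp <- 1e-6
  for (it in seq_len(60)) {
    gr <- negll_grad(theta)
    g0 <- sqrt(sum(gr^2))
    if (g0 < opt$grad_tol) break
    H <- numDeriv::jacobian(negll_grad, theta)
    H <- (H + t(H)) / 2
    f0 <- negll(theta)
    improved <- FALSE
    for (trial in seq_len(12)) {
      step <- tryCatch(solve(H + diag(damp, nrow(H)), gr),
                       error = function(e) NULL)
      if (!is.null(step)) {
        lam <- 1
        for (ls in seq_len(10)) {
          cand <- theta - lam * step
          # near the optimum the objective decrease drops below float
          # noise while the gradient is still informative: accept on
          # gradient-norm decrease there, on objective decrease otherwise
          ok <- if (g0 < 1e-2)
            sqrt(sum(negll_grad(cand)^2)) < g0 && negll(cand) <= f0 + 1e-8
          else negll(cand) < f0
          if (ok) {
            theta <- cand
            improved <- TRUE
            break
          }
          lam <- lam / 4
        }
      }
      if (improved) {
        damp <- max(damp / 10, 1e-10)
        break
      }
      damp <- damp * 10
    }
    if (!improved) break
    iters <- iters + 1
  }
  gnorm <- sqrt(sum(negll_grad(theta)^2))
  converged <- is.finite(gnorm) && gnorm < opt$grad_tol

  pars <- theta_to_params(theta, k, spec)
  names(pars$beta) <- colnames(design$X)
  loglik <- frontier_loglik(pars, design, spec)

  # observed information on the natural scale
  nat <- c(pars$beta, sigma_sq = pars$sigma_sq, gamma = pars$gamma)
  if (spec$distribution == "tnormal") nat <- c(nat, mu = pars$mu)
  if (spec$time_varying) nat <- c(nat, eta = pars$eta)
  score_nat <- function(v) {
    # finite differencing can step over the variance boundaries
    if (v[[k + 1]] <= 0 || v[[k + 2]] <= 0 || v[[k + 2]] >= 1)
      return(rep(NaN, length(v)))
    p <- list(beta = v[seq_len(k)], sigma_sq = v[[k + 1]], gamma = v[[k + 2]],
              mu = 0, eta = 0)
    j <- k + 3
    if (spec$distribution == "tnormal") { p$mu <- v[[j]]; j <- j + 1 }
    if (spec$time_varying) p$eta <- v[[j]]
    -frontier_score(p, design, spec)
  }
  se <- rep(NA_real_, length(nat))
  vc <- tryCatch(suppressWarnings({
    H <- numDeriv::jacobian(score_nat, nat)
    solve((H + t(H)) / 2)
  }), error = function(e) NULL)
  if (!is.null(vc)) {
    d <- diag(vc)
    ok <- is.finite(d) & d > 0
    se[ok] <- sqrt(d[ok])
  }
  names(se) <- names(nat)

  structure(
    list(spec = spec, params = frontier_params(pars$beta, pars$sigma_sq,
                                               pars$gamma, pars$mu, pars$eta),
         se = se, loglik = loglik,
         convergence = list(converged = converged, iterations = iters,
                            grad_norm = gnorm),
         n_obs = design$n_obs, n_states = design$n_states, design = design),
    class = "frontier_fit")
}

#' @export
print.frontier_fit <- function(x, ...) {
  cat(sprintf("Stochastic cost frontier (%s%s), %d obs / %d states\n",
              x$spec$distribution,
              if (x$spec$time_varying) ", time-varying decay" else "",
              x$n_obs, x$n_states))
  tab <- cbind(estimate = c(x$params$beta,
                            sigma_sq = x$params$sigma_sq,
                            gamma = x$params$gamma,
                            mu = x$params$mu, eta = x$params$eta))
  print(round(tab, 4))
  cat(sprintf("log-likelihood %.3f; converged: %s (|grad| = %.2e)\n",
              x$loglik, x$convergence$converged, x$convergence$grad_norm))
  invisible(x)
}

#' Predict state-year efficiency scores
#'
#' Computes `u_hat_it = E[u_it | eps_i1..iT]` under the fitted model: for
#' the panel truncated-normal model the posterior of `u_i` is truncated
#' normal, so `u_hat_it = h_it * (mu_star + sd_star *
#' mills(mu_star/sd_star))`; for the pooled exponential model the
#' observation-level posterior mean is used. The score is `100 * u_hat`
#' (so national-average magnitudes are comparable to published state
#' score tables) and `ce = exp(-u_hat)`, with `ce = exp(-score/100)`
#' holding exactly.
#'
#' @param fit a converged [fit_frontier()] result.
#' @param data optional `ltss_panel`; defaults to the fitted panel. Every
#'   requested state must appear in the fit (posterior conditioning is by
#'   state), else an index error is raised.
#' @return data.frame of class `score_panel`: `state, year, u_hat, score,
#'   ce`.
#' @export
predict_scores <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "frontier_fit"))
  design <- if (is.null(data)) fit$design else {
    extra <- setdiff(data$records$state, fit$design$state)
    if (length(extra) > 0)
      stop("index error: state(s) absent from the fit: ",
           paste(extra, collapse = ", "), call. = FALSE)
    build_design(data, fit$spec)
  }
  p <- fit$params
  spec <- fit$spec
  eps <- design$y - drop(design$X %*% p$beta)
  sigma_u2 <- p$gamma * p$sigma_sq
  sigma_v2 <- (1 - p$gamma) * p$sigma_sq

  if (spec$distribution == "exponential") {
    sigma_u <- sqrt(sigma_u2)
    sigma_v <- sqrt(sigma_v2)
    m <- eps - sigma_v2 / sigma_u
    u_hat <- m + sigma_v * mills(m / sigma_v)
  } else {
    mu <- if (spec$distribution == "hnormal") 0 else p$mu
    h <- exp(-p$eta * design$t_rel)
    g <- factor(design$state, levels = unique(design$state))
    sum_h2 <- rowsum(h^2, g)[, 1]
    sum_he <- rowsum(h * eps, g)[, 1]
    post <- bc_state_posterior(sum_h2, sum_he, sigma_v2, sigma_u2, mu)
    e_u <- post$mu_star + post$sd_star * mills(post$mu_star / post$sd_star)
    names(e_u) <- levels(g)
    u_hat <- h * e_u[design$state]
  }
  u_hat <- pmax(as.numeric(u_hat), 0)
  structure(data.frame(state = design$state, year = design$year,
                       u_hat = u_hat, score = 100 * u_hat,
                       ce = exp(-u_hat), stringsAsFactors = FALSE),
            class = c("score_panel", "data.frame"))
}
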