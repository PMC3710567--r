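# Second estimation step: regress log efficiency scores on HCBS and policy
# covariates with state fixed effects, cluster-robust inference, and a
# Hausman fixed-vs-random-effects specification test. All estimators are
# implemented directly (within transform, CR1 sandwich, Swamy-Arora GLS);
# the LSDV and brute-force-sandwich oracles live in the test suite.

DEFAULT_COVARIATES <- c("hcbs_share", "waiver_share", "icfmr_share",
                        "managed_care", "con", "log_population",
                        "log_pc_income", "unemployment")

#' Second-stage regression specification
#'
#' @param covariates ordered covariate names; `log_population` and
#'   `log_pc_income` are computed from the panel's `population` and
#'   `pc_income`, other names are taken as-is.
#' @param estimator `"fe"` (within), `"re"` (Swamy-Arora GLS), or
#'   `"pooled"` (OLS; the between dimension is the only place a
#'   state-level inefficiency predictor can carry covariate signal, see
#'   the vignette on end-to-end recovery).
#' @param cluster grouping key for robust inference (default `"state"`).
#' @param critical_value CI critical value; 1.96 (normal) by default, set
#'   `t_df_cluster = TRUE` to use t with G-1 degrees of freedom.
#' @param t_df_cluster use t(G-1) critical values instead of 1.96.
#' @return list of class `second_stage_spec`.
#' @export
second_stage_spec <- function(covariates = DEFAULT_COVARIATES,
                              estimator = c("fe", "re", "pooled"),
                              cluster = "state",
                              critical_value = 1.96,
                              t_df_cluster = FALSE) {
  structure(list(covariates = covariates, estimator = match.arg(estimator),
                 cluster = cluster, critical_value = critical_value,
                 t_df_cluster = t_df_cluster),
            class = "second_stage_spec")
}

#' Join scores and panel into the second-stage regression table
#'
#' Dependent variable is `log(score)`. Scores must be positive (log is
#' undefined at 0: a `gamma` near its boundary can produce numerically
#' zero scores, which is a domain error here, not silently dropped).
#' Score rows with no matching panel record are dropped with a warning;
#' zero overlap is a join error. Complete cases only; the dropped count is
#' logged.
#'
#' @param scores a `score_panel` from [predict_scores()].
#' @param data the `ltss_panel` holding the covariates.
#' @param spec a [second_stage_spec()].
#' @return data.frame: `state`, `year`, `log_score`, covariate columns.
#' @export
build_second_stage <- function(scores, data, spec = second_stage_spec()) {
  stopifnot(inherits(scores, "score_panel"), inherits(data, "ltss_panel"))
  if (any(scores$score <= 0))
    stop("domain error: nonpositive score, log undefined (state ",
         paste(unique(scores$state[scores$score <= 0]), collapse = ", "), ")",
         call. = FALSE)
  df <- data$records
  df$log_population <- log(df$population)
  df$log_pc_income <- log(df$pc_income)
  miss_cov <- setdiff(spec$covariates, names(df))
  if (length(miss_cov) > 0)
    stop("covariate(s) not in panel: ", paste(miss_cov, collapse = ", "),
         call. = FALSE)
  tab <- merge(scores[, c("state", "year", "score")],
               df[, c("state", "year", spec$covariates)],
               by = c("state", "year"))
  if (nrow(tab) == 0) stop("join error: no (state, year) overlap", call. = FALSE)
  n_drop <- nrow(scores) - nrow(tab)
  if (n_drop > 0)
    warning(n_drop, " score row(s) without matching panel record dropped",
            call. = FALSE)
  tab$log_score <- log(tab$score)
  cc <- stats::complete.cases(tab)
  if (any(!cc)) message(sum(!cc), " incomplete row(s) dropped")
  tab <- tab[cc, c("state", "year", "log_score", spec$covariates)]
  tab[order(tab$state, tab$year), , drop = FALSE]
}

# shared: response vector, covariate matrix, group factor from a table
ss_matrices <- function(table, spec) {
  y <- table$log_score
  X <- as.matrix(table[, spec$covariates, drop = FALSE])
  g <- factor(table[[spec$cluster]])
  list(y = y, X = X, g = g)
}

#' Fixed-effects (within) estimator
#'
#' Demeans the dependent and every covariate by state and runs least
#' squares; coefficients are identical to least-squares-with-dummies
#' (LSDV). Covariates with no within-state variation are dropped with a
#' warning. Within R-squared is `1 - SSR/SST` on the demeaned data.
#'
#' @param table output of [build_second_stage()].
#' @param spec a [second_stage_spec()].
#' @return object of class `second_stage_fit` with `coefficients`,
#'   classical `vcov`, `within_r2`, `n_obs`, `n_clusters`, residuals and
#'   demeaned design (for the sandwich), estimator tag `"fe"`.
#' @export
fit_within <- function(table, spec = second_stage_spec()) {
  m <- ss_matrices(table, spec)
  demean <- function(v) v - ave(v, m$g)
  yd <- demean(m$y)
  Xd <- apply(m$X, 2, demean)
  keep <- apply(Xd, 2, function(col) max(abs(col)) > 1e-10)
  if (any(!keep))
    warning("dropped covariate(s) with no within-", spec$cluster,
            " variation: ", paste(colnames(Xd)[!keep], collapse = ", "),
            call. = FALSE)
  Xd <- Xd[, keep, drop = FALSE]
  if (ncol(Xd) == 0) stop("no covariates with within variation", call. = FALSE)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd))
    stop("singularity error: collinear demeaned column(s): ",
         paste(colnames(Xd)[-seq_len(qx$rank)], collapse = ", "),
         call. = FALSE)
  b <- qr.coef(qx, yd)
  e <- yd - drop(Xd %*% b)
  n <- length(yd)
  G <- nlevels(m$g)
  k <- ncol(Xd)
  df_resid <- n - G - k  # LSDV degrees of freedom
  sst <- sum(yd^2)
  ssr <- sum(e^2)
  sigma2 <- ssr / df_resid
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xd), colnames(Xd))
  structure(
    list(coefficients = b, vcov = sigma2 * xtx_inv,
         within_r2 = 1 - ssr / sst, residuals = e, model_matrix = Xd,
         group = m$g, n_obs = n, n_clusters = G, df_resid = df_resid,
         estimator = "fe", spec = spec),
    class = "second_stage_fit")
}

#' Cluster-robust (CR1) standard errors and confidence intervals
#'
#' Sandwich estimator with cluster-summed score outer products and the
#' small-sample factor `G/(G-1) * (N-1)/(N-K)`, `K` = number of slope
#' coefficients in the (transformed) regression. With every cluster a
#' singleton this reduces exactly to heteroskedasticity-robust HC1. CIs
#' use `estimate +/- crit * SE` with `crit` from the spec (1.96 default).
#'
#' @param fit a `second_stage_fit`.
#' @return list: `se`, `ci_low`, `ci_high`, `vcov`, `crit`.
#' @export
cluster_robust_se <- function(fit) {
  stopifnot(inherits(fit, "second_stage_fit"))
  X <- fit$model_matrix
  e <- fit$residuals
  g <- fit$group
  G <- nlevels(droplevels(g))
  if (G < 2) stop("cluster-robust inference needs >= 2 clusters", call. = FALSE)
  n <- nrow(X)
  k <- ncol(X)
  Xe <- X * e
  S <- rowsum(Xe, g)              # G x k matrix of cluster score sums
  meat <- crossprod(S)
  bread <- solve(crossprod(X))
  c_factor <- G / (G - 1) * (n - 1) / (n - k)
  V <- c_factor * bread %*% meat %*% bread
  se <- sqrt(diag(V))
  crit <- if (isTRUE(fit$spec$t_df_cluster)) stats::qt(0.975, G - 1)
          else fit$spec$critical_value
  b <- fit$coefficients
  list(se = se, ci_low = b - crit * se, ci_high = b + crit * se,
       vcov = V, crit = crit)
}

#' Random-effects (Swamy-Arora) estimator
#'
#' Estimates the idiosyncratic variance from the within residuals and the
#' state-effect variance from the between regression, truncating a
#' negative component at zero with a warning, then runs feasible GLS by
#' quasi-demeaning with a per-state theta
#' `1 - sqrt(sigma_e^2 / (T_g * sigma_a^2 + sigma_e^2))`. With
#' `sigma_a^2 = 0` this is pooled OLS exactly; as theta approaches 1 it
#' approaches the within estimator.
#'
#' @param table output of [build_second_stage()].
#' @param spec a [second_stage_spec()].
#' @return `second_stage_fit` with estimator tag `"re"` (includes an
#'   `(Intercept)` coefficient).
#' @export
fit_re <- function(table, spec = second_stage_spec()) {
  m <- ss_matrices(table, spec)
  n <- length(m$y)
  G <- nlevels(m$g)
  Tg <- as.numeric(table(m$g))
  k <- ncol(m$X)

  # within step for sigma_e^2
  demean <- function(v) v - ave(v, m$g)
  yd <- demean(m$y)
  Xd <- apply(m$X, 2, demean)
  keepw <- apply(Xd, 2, function(col) max(abs(col)) > 1e-10)
  bw <- qr.coef(qr(Xd[, keepw, drop = FALSE]), yd)
  ew <- yd - drop(Xd[, keepw, drop = FALSE] %*% bw)
  sigma_e2 <- sum(ew^2) / (n - G - sum(keepw))

  # between step for sigma_a^2
  ym <- tapply(m$y, m$g, mean)
  Xm <- apply(m$X, 2, function(v) tapply(v, m$g, mean))
  Xb <- cbind(`(Intercept)` = 1, Xm)
  qb <- qr(Xb)
  kb <- qb$rank
  eb <- ym - drop(Xb %*% qr.coef(qb, ym))
  Tbar <- n / G
  sigma_b2 <- sum(eb^2) / max(G - kb, 1)
  sigma_a2 <- sigma_b2 - sigma_e2 / Tbar
  if (sigma_a2 < 0) {
    warning("negative state variance component truncated at 0", call. = FALSE)
    sigma_a2 <- 0
  }
  theta_g <- 1 - sqrt(sigma_e2 / (Tg * sigma_a2 + sigma_e2))
  theta_i <- theta_g[as.integer(m$g)]

  quasi <- function(v) v - theta_i * ave(v, m$g)
  ys <- quasi(m$y)
  Xs <- cbind(`(Intercept)` = 1 - theta_i, apply(m$X, 2, quasi))
  qs <- qr(Xs)
  if (qs$rank < ncol(Xs))
    stop("singularity error in GLS design", call. = FALSE)
  b <- qr.coef(qs, ys)
  es <- ys - drop(Xs %*% b)
  xtx_inv <- chol2inv(qr.R(qs))
  dimnames(xtx_inv) <- list(colnames(Xs), colnames(Xs))
  sst <- sum((ys - mean(ys))^2)
  structure(
    list(coefficients = b, vcov = sigma_e2 * xtx_inv,
         within_r2 = 1 - sum(es^2) / sst, residuals = es, model_matrix = Xs,
         group = m$g, n_obs = n, n_clusters = G,
         df_resid = n - ncol(Xs), estimator = "re",
         variance_components = c(sigma_e2 = sigma_e2, sigma_a2 = sigma_a2),
         theta = theta_g, spec = spec),
    class = "second_stage_fit")
}

#' Pooled OLS estimator
#'
#' Plain least squares with an intercept, no state effects. Because the
#' frontier's inefficiency predictor is a state-level posterior mean
#' scaled by a common decay factor, within-state log-score variation is a
#' deterministic trend shared by all states; covariate signal survives
#' only in the between-state dimension, which pooled OLS (and the between
#' regression) retain. Cluster-robust inference by state still applies.
#'
#' @param table output of [build_second_stage()].
#' @param spec a [second_stage_spec()].
#' @return `second_stage_fit` with estimator tag `"pooled"`.
#' @export
fit_pooled <- function(table, spec = second_stage_spec()) {
  m <- ss_matrices(table, spec)
  X <- cbind(`(Intercept)` = 1, m$X)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singularity error: collinear column(s)", call. = FALSE)
  b <- qr.coef(qx, m$y)
  e <- m$y - drop(X %*% b)
  n <- length(m$y)
  k <- ncol(X)
  sigma2 <- sum(e^2) / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  sst <- sum((m$y - mean(m$y))^2)
  structure(
    list(coefficients = b, vcov = sigma2 * xtx_inv,
         within_r2 = 1 - sum(e^2) / sst, residuals = e, model_matrix = X,
         group = m$g, n_obs = n, n_clusters = nlevels(m$g),
         df_resid = n - k, estimator = "pooled", spec = spec),
    class = "second_stage_fit")
}

#' @export
print.second_stage_fit <- function(x, ...) {
  cat(sprintf("Second-stage %s fit: %d obs, %d clusters, within R2 = %.3f\n",
              toupper(x$estimator), x$n_obs, x$n_clusters, x$within_r2))
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Hausman specification test (fixed vs random effects)
#'
#' `H = d' (V_FE - V_RE)^+ d` on the covariates common to both fits
#' (slopes only), chi-square with rank degrees of freedom. Classical
#' covariances are used, as in the standard test; a pseudo-inverse is used
#' (and flagged) when the covariance difference is not positive definite.
#'
#' @param fe a `second_stage_fit` with estimator `"fe"`.
#' @param re a `second_stage_fit` with estimator `"re"`.
#' @return list of class `hausman_result`: `statistic`, `df`, `p_value`,
#'   `recommendation`, `pseudo_inverse` flag.
#' @export
hausman <- function(fe, re) {
  common <- intersect(names(fe$coefficients),
                      setdiff(names(re$coefficients), "(Intercept)"))
  if (length(common) == 0) stop("no common covariates", call. = FALSE)
  d <- fe$coefficients[common] - re$coefficients[common]
  Vd <- fe$vcov[common, common, drop = FALSE] -
    re$vcov[common, common, drop = FALSE]
  ev <- eigen((Vd + t(Vd)) / 2, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-10
  pos <- ev$values > tol
  used_pinv <- any(ev$values < -tol) || sum(pos) < length(d)
  inv_vals <- ifelse(pos, 1 / ev$values, 0)
  Vinv <- ev$vectors %*% (inv_vals * t(ev$vectors))
  H <- max(0, drop(t(d) %*% Vinv %*% d))
  df <- sum(pos)
  p <- if (df == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  structure(list(statistic = H, df = df, p_value = p,
                 recommendation = if (p < 0.05) "fe" else "re",
                 pseudo_inverse = used_pinv),
            class = "hausman_result")
}

#' Multiplicative effect summary of a log-score coefficient
#'
#' A coefficient `b` on the log-score scale multiplies the score by
#' `exp(b)` per unit of the covariate; for `b < 0` the proportional score
#' decrease is `1 - exp(b)`. Presentation values are truncated (not
#' rounded) to two decimals, matching the convention of the published
#' interpretation (e.g. `1 - exp(-0.37)` presented as 0.30 and `exp(0.77)`
#' presented as 2.15).
#'
#' @param b finite coefficient.
#' @return list: `multiplier`, `decrease`, `presented_multiplier`,
#'   `presented_decrease`.
#' @export
effect_transform <- function(b) {
  stopifnot(is.finite(b))
  trunc2 <- function(x) trunc(x * 100) / 100
  mult <- exp(b)
  dec <- 1 - exp(b)
  list(multiplier = mult, decrease = dec,
       presented_multiplier = trunc2(mult), presented_decrease = trunc2(dec))
}
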