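# Rankings, quartile trends, national averages, and the Spearman
# rank-correlation diagnostic.

#' Rank states by efficiency score
#'
#' Rank 1 = most efficient = lowest score. Ranking is by the mean score
#' across years (`by = "mean"`, the default) or by a single year's score.
#' Ties are broken alphabetically by state code and logged. Efficiency
#' tiers split the ranking into four quartile groups (`high`, `moderate`,
#' `low`, `very_low`), assigned once from the ranking value.
#'
#' @param scores a `score_panel`.
#' @param by `"mean"` or a year present in the scores.
#' @return data.frame of class `ranking_table`: `state`, `value` (the
#'   ranking score), `rank`, `tier`; per-year scores in wide form as
#'   attribute `"per_year"`.
#' @export
rank_states <- function(scores, by = "mean") {
  stopifnot(inherits(scores, "score_panel"), nrow(scores) > 0)
  if (identical(by, "mean")) {
    val <- tapply(scores$score, scores$state, mean)
  } else {
    yr <- as.integer(by)
    if (!yr %in% scores$year)
      stop("requested year ", yr, " absent from scores", call. = FALSE)
    sub <- scores[scores$year == yr, ]
    val <- stats::setNames(sub$score, sub$state)
  }
  st <- names(val)
  ord <- order(val, st)
  if (anyDuplicated(val[ord]) > 0)
    message("ties in ranking broken alphabetically by state code")
  n <- length(val)
  tiers <- c("high", "moderate", "low", "very_low")
  out <- data.frame(state = st[ord], value = as.numeric(val[ord]),
                    rank = seq_len(n),
                    tier = tiers[ceiling(4 * seq_len(n) / n)],
                    stringsAsFactors = FALSE)
  per_year <- stats::reshape(scores[, c("state", "year", "score")],
                             idvar = "state", timevar = "year",
                             direction = "wide")
  names(per_year) <- sub("^score\\.", "", names(per_year))
  attr(out, "per_year") <- per_year
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Per-quartile score trends
#'
#' States are grouped once into quartiles by their mean score across all
#' years; within each quartile the per-year unweighted mean score is
#' reported, together with the absolute first-to-last-year improvement
#' (first-year mean minus last-year mean; positive = scores fell =
#' efficiency improved).
#'
#' @param scores a `score_panel` with at least 4 states.
#' @return list: `trends` (data.frame `tier`, `year`, `mean_score`),
#'   `improvement` (named vector by tier).
#' @export
quartile_trends <- function(scores) {
  stopifnot(inherits(scores, "score_panel"))
  if (length(unique(scores$state)) < 4)
    stop("quartile trends need at least 4 states", call. = FALSE)
  ranking <- rank_states(scores, by = "mean")
  tier_of <- stats::setNames(ranking$tier, ranking$state)
  df <- scores
  df$tier <- factor(tier_of[df$state],
                    levels = c("high", "moderate", "low", "very_low"))
  agg <- stats::aggregate(score ~ tier + year, data = df, FUN = mean)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg <- agg[order(agg$tier, agg$year), ]
  rownames(agg) <- NULL
  first_yr <- min(df$year)
  last_yr <- max(df$year)
  imp <- sapply(levels(df$tier), function(tt) {
    mean(df$score[df$tier == tt & df$year == first_yr]) -
      mean(df$score[df$tier == tt & df$year == last_yr])
  })
  list(trends = agg, improvement = imp)
}

#' National average score per year
#'
#' Unweighted mean of state scores per year (each state is one unit of
#' analysis); a population-weighted mean is available via `weights`.
#' Unbalanced years are averaged over the available states, with the count
#' logged.
#'
#' @param scores a `score_panel`.
#' @param weights optional named vector of state weights (e.g.
#'   populations).
#' @return data.frame: `year`, `mean_score`, `n_states`.
#' @export
national_average <- function(scores, weights = NULL) {
  stopifnot(inherits(scores, "score_panel"), nrow(scores) > 0)
  yrs <- sort(unique(scores$year))
  n_states_total <- length(unique(scores$state))
  out <- do.call(rbind, lapply(yrs, function(yy) {
    sub <- scores[scores$year == yy, ]
    m <- if (is.null(weights)) mean(sub$score)
         else stats::weighted.mean(sub$score, weights[sub$state])
    data.frame(year = yy, mean_score = m, n_states = nrow(sub))
  }))
  if (any(out$n_states < n_states_total))
    message("unbalanced years averaged over available states: ",
            paste(sprintf("%d (n=%d)", out$year[out$n_states < n_states_total],
                          out$n_states[out$n_states < n_states_total]),
                  collapse = ", "))
  out
}

# all permutations of 1..n (n! rows); used for the exact Spearman p-value
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of average (mid-) ranks. The two-sided
#' p-value uses the full permutation distribution for `n <= 8` and the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y paired numeric vectors (scores, ranks, or any monotone
#'   relabeling thereof), length >= 3.
#' @return list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}
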