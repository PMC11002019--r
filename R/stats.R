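# Outcome statistics: exact contingency tests, rank tests, correlation,
# survival comparison and ROC evaluation.
#
# The exact tests are implemented here by enumeration (the 2x2 test by
# hypergeometric summation with the probability-ordering two-sided rule, the
# r x c Freeman-Halton generalization by depth-first enumeration over
# margin-consistent tables with a seeded Monte-Carlo fallback). Kaplan-Meier
# and the log-rank test delegate to the survival package; Kruskal-Wallis
# delegates to stats::kruskal.test.

# relative tolerance when comparing table probabilities, so enumeration is
# robust to floating-point ties
PROB_TIE_TOL <- 1e-7

#' Fisher's exact test (two-sided) for r x c contingency tables
#'
#' 2x2 tables: sum of hypergeometric probabilities of all margin-consistent
#' tables whose probability does not exceed the observed one (relative
#' tolerance 1e-7). Larger tables: Freeman-Halton generalization by full
#' enumeration, falling back to seeded Monte-Carlo sampling of
#' margin-consistent tables when enumeration would exceed `max_tables`
#' (the method used is recorded in the `method` attribute).
#'
#' A table with an all-zero row or column margin returns P = 1 with a
#' warning.
#'
#' @param table non-negative integer matrix, at least 2x2.
#' @param max_tables enumeration budget before the Monte-Carlo fallback.
#' @param mc_reps Monte-Carlo tables to sample in the fallback.
#' @param mc_seed seed for the fallback.
#' @return Two-sided P with a `method` attribute.
#' @export
fisher_exact <- function(table, max_tables = 2e6, mc_reps = 1e6,
                         mc_seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("contingency table must hold non-negative integers")
  if (sum(table) < 1) stop("grand total must be >= 1")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero row/column margin: P = 1 by convention")
    return(structure(1, method = "degenerate"))
  }
  if (nrow(table) == 2 && ncol(table) == 2) {
    x <- table[1, 1]
    m <- rs[1]; n <- rs[2]; k <- cs[1]
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(x, m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + PROB_TIE_TOL)])
    return(structure(min(1, p), method = "hypergeometric"))
  }
  freeman_halton(table, max_tables = max_tables, mc_reps = mc_reps,
                 mc_seed = mc_seed)
}

# log null probability of a table with fixed margins
log_table_prob <- function(tab, rs, cs, n) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

#' Freeman-Halton exact test for r x c tables
#'
#' Depth-first enumeration over all tables with the observed margins; the
#' two-sided P is the total null probability of tables no more probable than
#' the observed one (relative tolerance 1e-7). When the number of visited
#' tables would exceed `max_tables`, a seeded Monte-Carlo estimate over
#' `mc_reps` tables drawn from the null (Patefield sampling via
#' [stats::r2dtable()]) is returned instead.
#'
#' @inheritParams fisher_exact
#' @return Two-sided P with a `method` attribute ("enumeration" or
#'   "monte-carlo").
#' @export
freeman_halton <- function(table, max_tables = 2e6, mc_reps = 1e6,
                           mc_seed = 1L) {
  table <- as.matrix(table)
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  r <- nrow(table); cc <- ncol(table)
  log_cut <- log_table_prob(table, rs, cs, n) + log1p(PROB_TIE_TOL)

  p_sum <- 0
  visited <- 0L
  overflow <- FALSE
  tab <- matrix(0L, r, cc)
  col_left <- cs

  fill_row <- function(i, j, row_left) {
    # fill cell (i, j); last column and last row are forced by the margins
    if (overflow) return()
    if (j == cc) {
      v <- row_left
      if (v > col_left[j]) return()
      tab[i, j] <<- v; col_left[j] <<- col_left[j] - v
      next_row(i)
      col_left[j] <<- col_left[j] + v
      return()
    }
    lo <- max(0L, row_left - sum(col_left[(j + 1):cc]))
    hi <- min(row_left, col_left[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      tab[i, j] <<- v; col_left[j] <<- col_left[j] - v
      fill_row(i, j + 1L, row_left - v)
      col_left[j] <<- col_left[j] + v
      if (overflow) return()
    }
  }
  next_row <- function(i) {
    if (i == r - 1L) {
      # last row forced
      tab[r, ] <<- col_left
      visited <<- visited + 1L
      if (visited > max_tables) { overflow <<- TRUE; return() }
      lp <- log_table_prob(tab, rs, cs, n)
      if (lp <= log_cut) p_sum <<- p_sum + exp(lp)
    } else {
      fill_row(i + 1L, 1L, rs[i + 1L])
    }
  }
  fill_row(1L, 1L, rs[1L])

  if (!overflow)
    return(structure(min(1, p_sum), method = "enumeration"))

  set.seed(mc_seed)
  sims <- stats::r2dtable(mc_reps, rs, cs)
  lp_obs <- log_table_prob(table, rs, cs, n)
  lp_sim <- vapply(sims, log_table_prob, numeric(1), rs = rs, cs = cs, n = n)
  p <- (sum(lp_sim <= lp_obs + log1p(PROB_TIE_TOL)) + 1) / (mc_reps + 1)
  structure(min(1, p), method = "monte-carlo")
}

#' Pearson chi-square test for contingency tables
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction,
#' the conventional test for tables with more than two rows or columns.
#'
#' @param table contingency matrix.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chisq_contingency <- function(table) {
  ct <- suppressWarnings(stats::chisq.test(as.matrix(table), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs with x > y (+ 0.5 per tie). Small samples (both groups
#' <= `exact_max`) use exact enumeration of the permutation distribution of
#' U over all group assignments (tie-aware); larger samples use the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param x,y nonempty numeric vectors.
#' @param exact_max per-group size bound for the exact branch.
#' @return List: `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps)))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Kruskal-Wallis test with tie correction
#'
#' Delegates to [stats::kruskal.test()]; the degenerate all-equal case (tie
#' correction 0/0) is returned as H = 0, P = 1 by convention.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return List: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("groups must be nonempty")
  values <- unlist(groups)
  if (length(unique(values)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Spearman rank correlation with t-approximation P
#'
#' rho is the Pearson correlation of tie-averaged ranks; the two-sided P
#' uses t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom. Zero
#' variance in either variable yields an undefined (flagged) result.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return List: `rho`, `p_value`, `undefined`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, undefined = TRUE))
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p_value = p, undefined = FALSE)
}

#' Kaplan-Meier comparison of two groups with the log-rank test
#'
#' Product-limit curves with right censoring via [survival::survfit()];
#' group medians use the first time S(t) <= 0.5 (NA when never reached);
#' Mantel-Cox log-rank chi-square with 1 df via [survival::survdiff()].
#'
#' @param samples data.frame with columns `time` (> 0), `event` (0/1),
#'   `group`.
#' @param group_a,group_b the two group labels to compare (defaults: the two
#'   groups present).
#' @return List: `fit` (survfit), `medians` (named), `chisq`, `p_value`.
#' @export
survival_compare <- function(samples, group_a = NULL, group_b = NULL) {
  stopifnot(all(c("time", "event", "group") %in% names(samples)))
  if (any(samples$time <= 0)) stop("times must be positive")
  if (!all(samples$event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(group_a) || is.null(group_b)) {
    gl <- unique(samples$group)
    if (length(gl) != 2)
      stop("specify group_a and group_b when more than two groups are present")
    group_a <- gl[1]; group_b <- gl[2]
  }
  d <- samples[samples$group %in% c(group_a, group_b), , drop = FALSE]
  if (!sum(d$group == group_a) || !sum(d$group == group_b))
    stop("each group must be nonempty")
  d$group <- factor(d$group, levels = c(group_a, group_b))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  # median convention: first time with S(t) <= 0.5, NA when never reached
  strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  medians <- vapply(c(group_a, group_b), function(g) {
    s <- fit$surv[strata == g]; tt <- fit$time[strata == g]
    hit <- which(s <= 0.5)
    if (length(hit)) tt[hit[1]] else NA_real_
  }, numeric(1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- unname(sd$chisq)
  list(fit = fit, medians = medians, chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier median for a single group
#'
#' First time with S(t) <= 0.5; NA when the curve never reaches 0.5.
#' @param time positive times.
#' @param event 0/1 event indicators.
#' @return Median time (possibly NA).
#' @export
km_median <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  hit <- which(fit$surv <= 0.5)
  if (length(hit)) fit$time[hit[1]] else NA_real_
}

#' Area under the empirical ROC curve
#'
#' AUC = (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg), computed via
#' the rank-sum identity; equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param score numeric scores (higher = more positive-like).
#' @param label binary outcome (logical or 0/1); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  if (length(score) != length(label)) stop("score and label lengths differ")
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for an ROC curve")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
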