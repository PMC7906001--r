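# The statistical battery mirrors the study's analysis plan: for each skill
# group and each eye-hand metric pair, Shapiro-Wilk normality on both
# variables gates the choice between Pearson's r and Spearman's rho; the
# coefficient is labeled with Cohen's strength bands; group differences in
# observer scores use a Mann-Whitney U with mid-ranks and a tie-corrected
# normal approximation (exact permutation p for small samples).

METRIC_PAIRS <- data.frame(
  pair = c("FD-SSD", "FN-SSN", "SN-SSM"),
  eye = c("FD", "FN", "SN"),
  hand = c("SSD", "SSN", "SSM"),
  stringsAsFactors = FALSE
)

#' Choose the correlation method by normality gating
#'
#' Pearson iff the Shapiro-Wilk p-value exceeds `alpha` for *both* vectors;
#' otherwise Spearman. A constant vector (Shapiro-Wilk undefined) selects
#' Spearman with a warning.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param alpha gate level (0.05 in the emulated analysis).
#' @return `"pearson"` or `"spearman"`, with attributes `normality_p_x`,
#'   `normality_p_y` (NA for a constant vector).
#' @export
choose_method <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 4L || length(y) < 4L) {
    stop("need at least 4 observations per vector for the normality gate")
  }
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0 || !is.finite(stats::sd(v))) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- shapiro_p(x)
  py <- shapiro_p(y)
  if (is.na(px) || is.na(py)) {
    warning("constant vector: Shapiro-Wilk undefined, falling back to spearman")
    method <- "spearman"
  } else {
    method <- if (px > alpha && py > alpha) "pearson" else "spearman"
  }
  structure(method, normality_p_x = px, normality_p_y = py)
}

#' Correlate one eye-hand metric pair
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param method `"pearson"` or `"spearman"` (mid-ranks for ties), typically
#'   from [choose_method()].
#' @param pair,group,n_label optional labels carried into the result.
#' @return An object of class `correlation_result`: list with `pair`,
#'   `group`, `method`, `coefficient`, `p`, `strength`, `sign`,
#'   `normality_p_x`, `normality_p_y`, `n`.
#' @export
correlate_pair <- function(x, y, method = c("pearson", "spearman"),
                           pair = NA_character_, group = NA_character_,
                           n_label = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (method == "pearson") stop("zero variance: Pearson correlation undefined")
    warning("zero variance: Spearman coefficient undefined, reported as NA")
    return(structure(list(pair = pair, group = group, method = method,
                          coefficient = NA_real_, p = NA_real_,
                          strength = NA_character_, sign = NA_character_,
                          normality_p_x = NA_real_, normality_p_y = NA_real_,
                          n = length(x)),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE,
                    alternative = "two.sided"))
  r <- unname(ct$estimate)
  structure(list(pair = pair, group = group, method = method,
                 coefficient = r, p = ct$p.value,
                 strength = classify_strength(r),
                 sign = if (r < 0) "-" else "+",
                 normality_p_x = NA_real_, normality_p_y = NA_real_,
                 n = length(x)),
            class = "correlation_result")
}

#' Cohen strength band of a correlation coefficient
#'
#' `|r| < 0.3` small, `0.3 <= |r| < 0.5` moderate, `|r| >= 0.5` strong. The
#' bands are the ones used to label the study's correlation tables; the lower
#' edge subsumes coefficients below 0.1 into "small" so the labeling is total.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return character vector of `"small"`, `"moderate"`, `"strong"`.
#' @export
classify_strength <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("|r| must be finite and at most 1")
  }
  out <- character(length(r))
  a <- abs(r)
  out[a < 0.3] <- "small"
  out[a >= 0.3 & a < 0.5] <- "moderate"
  out[a >= 0.5] <- "strong"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s %s: %s r = %.3f (%s%s), p = %.4g, n = %d\n",
              x$group, x$pair, x$method, x$coefficient, x$strength, x$sign,
              x$p, x$n))
  invisible(x)
}

#' Mann-Whitney U comparison of two groups
#'
#' Mid-ranks for ties; `U = min(U1, U2)`; z from the tie-corrected normal
#' approximation (no continuity correction). The two-sided p-value comes from
#' the exact permutation distribution of U when `exact` allows it and the
#' pooled sample is small, otherwise from the normal approximation. With all
#' observations tied the dispersion is zero and `z = 0`, `p = 1`.
#'
#' @param a,b numeric score vectors of the two groups, each non-empty.
#' @param exact `"auto"` (exact when `n1 + n2 <= 12`), `"always"`, `"never"`.
#' @return An object of class `mw_result`: list with `U`, `z`, `p`,
#'   `mean_rank_1`, `mean_rank_2`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b, exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)                      # mid-ranks for ties
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
    p_norm <- 1
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p_norm <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  do_exact <- switch(exact, always = TRUE, never = FALSE, auto = n <= 12L)
  if (do_exact) {
    p <- mw_exact_p(pooled, n1, u)
    method <- "exact permutation"
  } else {
    p <- p_norm
    method <- "normal approximation, tie-corrected"
  }
  structure(list(U = u, z = z, p = p,
                 mean_rank_1 = r1 / n1,
                 mean_rank_2 = (sum(rk) - r1) / n2,
                 n1 = n1, n2 = n2, method = method),
            class = "mw_result")
}

# exact two-sided permutation p: share of group assignments whose min-U is at
# most the observed one
mw_exact_p <- function(pooled, n1, u_obs) {
  n <- length(pooled)
  rk <- rank(pooled)
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) {
    u1 <- sum(rk[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * (n - n1) - u1)
  })
  mean(us <= u_obs + 1e-9)
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf(
    "<mw_result> U = %g, z = %.3f, p = %.4g (%s); mean ranks %.2f vs %.2f (n = %d, %d)\n",
    x$U, x$z, x$p, x$method, x$mean_rank_1, x$mean_rank_2, x$n1, x$n2))
  invisible(x)
}

#' Run the full eye-hand correlation battery
#'
#' For each group and each of the three metric pairs (FD-SSD, FN-SSN,
#' SN-SSM): normality-gate the method, correlate, label the strength. The
#' correlation unit is either the participant-task record (the default, one
#' observation per task) or the participant (task-averaged values).
#'
#' @param records per-task metric records with a `group` column (or `groups`
#'   lookup as in [summarize_metrics()]).
#' @param unit `"task"` or `"participant"`.
#' @param alpha normality-gate level.
#' @param groups optional `participant, group` lookup.
#' @return data.frame with one row per group x pair: `group, pair, method,
#'   coefficient, p, strength, sign, normality_p_x, normality_p_y, n`.
#' @export
run_correlation_battery <- function(records, unit = c("task", "participant"),
                                    alpha = 0.05, groups = NULL) {
  unit <- match.arg(unit)
  records <- as.data.frame(records)
  if (is.null(records$group)) {
    if (is.null(groups)) stop("records carry no group column and no groups lookup given")
    records$group <- groups$group[match(records$participant, groups$participant)]
  }
  data_unit <- if (unit == "participant") participant_means(records) else records
  out <- list()
  for (g in unique(records$group)) {
    sub <- data_unit[data_unit$group == g, , drop = FALSE]
    for (i in seq_len(nrow(METRIC_PAIRS))) {
      x <- sub[[METRIC_PAIRS$eye[i]]]
      y <- sub[[METRIC_PAIRS$hand[i]]]
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]; y <- y[keep]
      if (length(x) < 4L) {
        stop("fewer than 4 complete observations for group ", g,
             " pair ", METRIC_PAIRS$pair[i])
      }
      method <- choose_method(x, y, alpha = alpha)
      res <- correlate_pair(x, y, method = as.character(method),
                            pair = METRIC_PAIRS$pair[i], group = g)
      out[[length(out) + 1L]] <- data.frame(
        group = g, pair = METRIC_PAIRS$pair[i],
        method = res$method, coefficient = res$coefficient, p = res$p,
        strength = res$strength, sign = res$sign,
        normality_p_x = attr(method, "normality_p_x"),
        normality_p_y = attr(method, "normality_p_y"),
        n = res$n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag extreme standardized values without removing them
#'
#' The study screened for outliers by inspection and removed none; this
#' helper reports `|z| > threshold` observations for the same purpose.
#'
#' @param x numeric vector.
#' @param threshold z-score magnitude above which a value is flagged.
#' @return integer indices of flagged values.
#' @export
flag_outliers <- function(x, threshold = 3) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) return(integer())
  which(abs((x - mean(x)) / stats::sd(x)) > threshold)
}
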