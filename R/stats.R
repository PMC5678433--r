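# Cohort statistics: case-control matching, ANCOVA, regression, exact
# tests, repeatability.

#' Apply recruitment exclusions to a cohort table
#'
#' Drops subjects whose exclusion-reason column is non-empty and attaches
#' an accounting summary (recruited, excluded per reason, retained), so
#' that cohort sizes entering the analysis are auditable rather than
#' silently filtered.
#'
#' @param table cohort data frame.
#' @param reason_col name of the exclusion-reason column; `NA` or `""`
#'   means the subject is retained.
#' @return The retained rows, with attribute `"accounting"`: a list with
#'   `recruited`, `excluded` (named count per reason) and `retained`.
#' @export
apply_exclusions <- function(table, reason_col = "exclude_reason") {
  if (!reason_col %in% names(table)) {
    stop("no column '", reason_col, "' in table")
  }
  reasons <- table[[reason_col]]
  excluded <- !is.na(reasons) & reasons != ""
  out <- table[!excluded, ]
  acc <- list(recruited = nrow(table),
              excluded = if (any(excluded)) {
                tab <- table(reasons[excluded])
                stats::setNames(as.integer(tab), names(tab))
              } else {
                integer(0)
              },
              retained = nrow(out))
  attr(out, "accounting") <- acc
  out
}

#' Optimal case-control matching on GA and PMA
#'
#' Solves the one-to-one assignment of each case to a distinct control that
#' minimises the total Euclidean distance in (gestational age,
#' postmenstrual age) space, as a linear assignment problem (globally
#' optimal, not greedy). Ties are broken deterministically by subject_id
#' order.
#'
#' @param cases data frame with `subject_id`, `ga_wk`, `pma_wk`.
#' @param pool data frame of candidate controls, same columns; must have at
#'   least as many rows as `cases`.
#' @return A data frame with `case_id`, `control_id`, `distance`, and the
#'   total distance as attribute `"total_distance"`.
#' @export
match_controls <- function(cases, pool) {
  need <- c("subject_id", "ga_wk", "pma_wk")
  if (!all(need %in% names(cases)) || !all(need %in% names(pool))) {
    stop("cases and pool must have columns ", paste(need, collapse = ", "))
  }
  if (anyNA(cases[need]) || anyNA(pool[need])) {
    stop("GA and PMA must be present for all cases and pool members")
  }
  if (nrow(pool) < nrow(cases)) {
    stop("control pool (", nrow(pool), ") smaller than case list (",
         nrow(cases), ")")
  }
  cases <- cases[order(cases$subject_id), ]
  pool <- pool[order(pool$subject_id), ]
  cost <- outer(seq_len(nrow(cases)), seq_len(nrow(pool)),
                function(i, j) {
                  sqrt((cases$ga_wk[i] - pool$ga_wk[j])^2 +
                       (cases$pma_wk[i] - pool$pma_wk[j])^2)
                })
  assign <- solve_lap(cost)
  out <- data.frame(case_id = cases$subject_id,
                    control_id = pool$subject_id[assign],
                    distance = cost[cbind(seq_len(nrow(cases)), assign)],
                    stringsAsFactors = FALSE)
  attr(out, "total_distance") <- sum(out$distance)
  out
}

# Jonker-Volgenant-style shortest augmenting path solver for the
# rectangular linear assignment problem (n rows <= m columns). Returns the
# column assigned to each row. O(n^2 m).
solve_lap <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1] > 0) assign[p[j + 1]] <- j
  }
  assign
}

#' ANCOVA group effect
#'
#' Fits the ordinary least-squares model
#' \code{outcome ~ group + covariates} and reports the group-indicator
#' coefficient (CHD minus control; group coded control = 0, CHD = 1) with
#' its two-sided t-test p-value and 95 percent confidence interval. Rows
#' with missing values in any model column are dropped listwise and the
#' count reported.
#'
#' @param table cohort data frame with a `group` column holding `control`
#'   and `CHD`.
#' @param outcome name of the outcome column.
#' @param covariates covariate column names (default `pma_wk`).
#' @param extra_covariates optional additional covariate columns (e.g.
#'   ventilation days) appended to the model.
#' @return A list of class \code{ancova_result}: `outcome`,
#'   `group_effect`, `group_p`, `ci95`, `covariates`, `n_per_group`,
#'   `n_dropped`.
#' @export
ancova_group_effect <- function(table, outcome, covariates = "pma_wk",
                                extra_covariates = NULL) {
  covs <- c(covariates, extra_covariates)
  cols <- c(outcome, "group", covs)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  d <- table[cols]
  complete <- stats::complete.cases(d)
  n_dropped <- sum(!complete)
  d <- d[complete, ]
  d$group <- factor(d$group, levels = c("control", "CHD"))
  n_per <- table(d$group)
  if (any(n_per < 3)) {
    stop("need at least 3 subjects per group with complete data; got ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  }
  fml <- stats::reformulate(c("group", covs), response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["groupCHD", ]
  structure(list(outcome = outcome,
                 group_effect = unname(sm["groupCHD", "Estimate"]),
                 group_p = unname(sm["groupCHD", "Pr(>|t|)"]),
                 ci95 = unname(ci),
                 covariates = covs,
                 n_per_group = c(control = unname(n_per["control"]),
                                 CHD = unname(n_per["CHD"])),
                 n_dropped = n_dropped),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA %s ~ group + %s: CHD - control = %.4g (95%% CI %.4g to %.4g), p = %.4g\n",
              x$outcome, paste(x$covariates, collapse = " + "),
              x$group_effect, x$ci95[1], x$ci95[2], x$group_p))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with slope, intercept, R-squared
#' and the two-sided slope p-value. Rows with missing values in either
#' column are dropped.
#'
#' @param table data frame.
#' @param x,y column names.
#' @return A list of class \code{regression_result}: `x`, `y`, `slope`,
#'   `intercept`, `r_squared`, `p`, `n`.
#' @export
linreg <- function(table, x, y) {
  if (!all(c(x, y) %in% names(table))) {
    stop("columns not in table: ",
         paste(setdiff(c(x, y), names(table)), collapse = ", "))
  }
  d <- table[stats::complete.cases(table[c(x, y)]), c(x, y)]
  if (nrow(d) < 3) stop("need at least 3 complete (x, y) pairs")
  if (stats::var(d[[x]]) == 0) stop("zero variance in ", x)
  fit <- stats::lm(d[[y]] ~ d[[x]])
  sm <- summary(fit)
  structure(list(x = x, y = y,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = unname(sm$coefficients[2, "Pr(>|t|)"]),
                 n = nrow(d)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.4g, R^2 = %.3f, p = %.4g (n = %d)\n",
              x$y, x$x, x$slope, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons in the family (>= 1).
#' @return `alpha / m` (e.g. 0.05 over the four lobes gives 0.0125).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.finite(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  alpha / m
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (product of sizes at most
#' `exact_limit`) the p-value is exact, computed from the full permutation
#' distribution of the rank sum by dynamic programming over midranks, so
#' ties are handled exactly; larger samples use the normal approximation
#' with tie correction and continuity correction. The two-sided exact p is
#' twice the smaller tail, capped at 1.
#'
#' @param xs,ys numeric samples (non-empty).
#' @param exact_limit switch point on `length(xs) * length(ys)`
#'   (default 400).
#' @return A list of class \code{mw_test}: `p`, `u`, `method`
#'   (`"exact"`/`"normal"`), `all_tied` flag.
#' @export
mann_whitney <- function(xs, ys, exact_limit = 400) {
  if (length(xs) == 0 || length(ys) == 0) stop("both samples must be non-empty")
  if (anyNA(xs) || anyNA(ys)) stop("samples must not contain NA")
  nx <- length(xs)
  ny <- length(ys)
  all_v <- c(xs, ys)
  if (length(unique(all_v)) == 1) {
    out <- list(p = 1, u = nx * ny / 2, method = "degenerate", all_tied = TRUE)
    class(out) <- "mw_test"
    warning("all values tied across both samples; p = 1")
    return(out)
  }
  r <- rank(all_v)   # midranks
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  if (nx * ny <= exact_limit) {
    # exact permutation distribution of the (doubled, integer) rank sum,
    # computed over the smaller group; the two-sided p is the same either
    # way because the two groups' rank sums are complementary
    if (nx <= ny) {
      ns <- nx
      ws <- w
    } else {
      ns <- ny
      ws <- sum(r[nx + seq_len(ny)])
    }
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # dp[c+1, s+1]: number of size-c subsets with doubled rank sum s
    dp <- matrix(0, nrow = ns + 1, ncol = total + 1)
    dp[1, 1] <- 1
    for (item in r2) {
      for (cc in rev(seq_len(ns))) {
        nzero <- which(dp[cc, ] > 0)
        if (length(nzero)) {
          tgt <- nzero + item
          dp[cc + 1, tgt] <- dp[cc + 1, tgt] + dp[cc, nzero]
        }
      }
    }
    dist <- dp[ns + 1, ]
    ntot <- sum(dist)   # == choose(nx + ny, ns)
    w2 <- as.integer(round(2 * ws))
    p_lo <- sum(dist[seq_len(w2 + 1)]) / ntot
    p_hi <- sum(dist[(w2 + 1):(total + 1)]) / ntot
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    nn <- nx + ny
    mu <- nx * ny / 2
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- nx * ny / 12 * ((nn + 1) - tie_term)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(p = p, u = u, method = method, all_tied = FALSE),
            class = "mw_test")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables no more probable than the observed one (the rule used by
#' \code{stats::fisher.test}, which performs the computation).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   \code{matrix(c(a, c, b, d), 2, 2)} has rows (a, b) and (c, d).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
      (a + c) == 0 || (b + d) == 0) {
    stop("all row and column margins must be positive")
  }
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Repeatability of paired repeated measurements
#'
#' Pearson correlation between first and second readings, reported with
#' its square (the linear R-squared used to summarise agreement between
#' consecutive NIRS readings).
#'
#' @param first,second paired numeric readings (n >= 3, NA pairs dropped).
#' @return A list of class \code{regression_result} (slope/intercept of
#'   second on first, `r_squared = cor^2`, two-sided p, n).
#' @export
repeatability <- function(first, second) {
  if (length(first) != length(second)) stop("readings must be paired")
  ok <- stats::complete.cases(first, second)
  first <- first[ok]
  second <- second[ok]
  if (length(first) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(first) == 0 || stats::sd(second) == 0) {
    stop("zero variance in one of the reading series")
  }
  linreg(data.frame(first = first, second = second), "first", "second")
}
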