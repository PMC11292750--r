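# Rank-based statistics used by the comparative-validity battery. These are
# implemented in-package (rather than wrapping cor.test/wilcox.test) because
# the battery needs the midrank U statistic itself, exact enumeration in the
# presence of ties for small groups, and the AUC = U/(n1*n2) identity; base
# R and pROC serve as independent cross-checks in the test suite.

complete_pairs <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

# all permutations of seq_len(n), one per row; n is kept small by callers
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with pairwise deletion
#'
#' Computes rho as the Pearson correlation of midranks (average ranks for
#' ties), after dropping pairs where either value is missing (pairwise
#' deletion). The two-sided p-value uses the t approximation with n - 2
#' degrees of freedom; for n <= 8 an exact permutation p-value is computed
#' by full enumeration instead (valid with ties).
#'
#' @param x,y numeric/ordinal vectors of equal length; `NA`s allowed.
#' @return list with `rho`, `p`, and `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cp <- complete_pairs(x, y)
  if (cp$n < 3L) stop("fewer than 3 complete pairs after pairwise deletion")
  if (length(unique(cp$x)) < 2L || length(unique(cp$y)) < 2L) {
    stop("degenerate input: a variable is constant; rho undefined")
  }
  rx <- rank(cp$x); ry <- rank(cp$y)
  rho <- stats::cor(rx, ry)
  n <- cp$n
  if (n <= 8L) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# midrank U statistic for group 1 vs group 2 (number of pairs where a
# group-1 value exceeds a group-2 value, ties counting 1/2)
mann_whitney_u <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann--Whitney test with midrank ties
#'
#' U counts pairs in which a value from the first group exceeds one from the
#' second, ties counting one half. Missing values are dropped pairwise (a
#' record missing either the value or the group label is excluded). For
#' groups both of size <= 8 the two-sided p-value is exact, by enumeration
#' of all group assignments of the observed ranks (valid under ties);
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param values numeric vector.
#' @param group logical (or two-level) vector; `TRUE`/first level is group 1.
#' @return list with `U` (for group 1), `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(values, group) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  if (!is.logical(group)) {
    lev <- sort(unique(group))
    if (length(lev) > 2L) stop("group must be binary")
    group <- group == lev[length(lev)]
  }
  x1 <- values[group]; x2 <- values[!group]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0L || n2 == 0L) stop("degenerate input: a group is empty")
  U <- mann_whitney_u(x1, x2)
  N <- n1 + n2
  if (n1 <= 8L && n2 <= 8L) {
    r <- rank(c(x1, x2))
    idx <- utils::combn(N, n1)
    u_all <- apply(idx, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    r <- rank(c(x1, x2))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p, n1 = n1, n2 = n2)
}

#' Dichotomize a modified Rankin Scale score
#'
#' Good outcome is `mrs <= k`. The four cutpoints of interest are k = 0
#' (no symptoms vs any), k = 1, k = 2 (functional independence vs
#' dependence/death) and k = 3.
#'
#' @param mrs integer scores 0--6 (`NA` passed through).
#' @param k threshold in 0--3.
#' @return logical vector, `TRUE` = good outcome.
#' @export
dichotomize_mrs <- function(mrs, k) {
  if (!k %in% 0:3) stop("k must be one of 0, 1, 2, 3")
  if (any(!is.na(mrs) & (mrs < 0 | mrs > 6))) stop("mRS outside 0-6")
  mrs <= k
}

#' ROC discrimination of a score against a binary outcome
#'
#' AUC is the probability that a randomly chosen good-outcome patient has a
#' higher score than a bad-outcome one, with ties counting one half --
#' identically U / (n_pos * n_neg) for the Mann--Whitney U of scores by
#' class. The 95% CI uses DeLong's placement-value variance. Orientation is
#' fixed: higher score predicts the good outcome.
#'
#' @param score numeric (e.g. DAOH values).
#' @param good logical outcome labels (e.g. from [dichotomize_mrs()]);
#'   pairs with missing score or label are dropped.
#' @param conf_level confidence level for the CI, default 0.95.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`, and
#'   `curve` (data frame of `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(score, good, conf_level = 0.95) {
  cp <- complete_pairs(score, good)
  score <- cp$x; good <- as.logical(cp$y)
  n_pos <- sum(good); n_neg <- sum(!good)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate input: need both outcome classes")
  }
  xs <- score[good]; ys <- score[!good]
  auc <- mann_whitney_u(xs, ys) / (n_pos * n_neg)

  # DeLong placements: v10[i] = P-hat(score_i > neg), v01[j] = P-hat(pos > score_j)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- max(0, auc - zq * se)
  ci_high <- min(1, auc + zq * se)

  # ROC curve: sweep thresholds from high to low
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(xs >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ys >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  rownames(curve) <- NULL
  list(auc = auc, ci_low = ci_low, ci_high = ci_high,
       n_pos = n_pos, n_neg = n_neg, curve = curve)
}

#' Multivariable binary logistic model with c-statistic
#'
#' Fits a maximum-likelihood logistic regression (iteratively reweighted
#' least squares via [stats::glm()], log-likelihood tolerance 1e-8, up to
#' 100 iterations) after listwise deletion over the outcome and predictor
#' columns. The c-statistic is the in-sample AUC of the fitted
#' probabilities against the outcome. Complete or quasi-complete separation
#' (fitted probabilities pinned at 0/1, diverging coefficients) is detected
#' and reported as a warning, not silently.
#'
#' @param data data frame containing all columns.
#' @param outcome name of a logical/0-1 outcome column.
#' @param predictors character vector of predictor column names.
#' @return list with `coefficients` (data frame: term, estimate, se),
#'   `c_statistic`, `n_used`, `outcome`, `converged`.
#' @export
fit_logistic <- function(data, outcome, predictors) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  cols <- c(outcome, predictors)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  n_used <- nrow(d)
  if (n_used < 10L) stop("fewer than 10 complete rows for the model")
  y <- d[[outcome]]
  if (length(unique(y)) < 2L) stop("degenerate input: constant outcome")
  const <- predictors[vapply(predictors,
                             function(p) length(unique(d[[p]])) < 2L,
                             logical(1))]
  if (length(const) > 0L) {
    stop("constant predictor(s): ", paste(const, collapse = ", "))
  }
  fml <- stats::reformulate(if (length(predictors) > 0L) predictors else "1",
                            response = outcome)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("logistic model did not converge in 100 iterations; deviance trace: ",
         paste(signif(fit$deviance, 6), collapse = " -> "))
  }
  if (separation || any(abs(stats::coef(fit)[-1]) > 15)) {
    warning("possible complete separation: fitted probabilities at 0/1 or ",
            "diverging coefficients")
  }
  sm <- summary(fit)$coefficients
  cstat <- roc_auc(stats::fitted(fit), as.logical(y))$auc
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, "Estimate"],
                                 se = sm[, "Std. Error"],
                                 row.names = NULL),
       c_statistic = cstat, n_used = n_used, outcome = outcome,
       converged = fit$converged)
}

#' Summary of a modified Rankin Scale distribution
#'
#' Counts per category 0--6, percentages of non-missing values, and the
#' functional-independence tally (mRS 0--2).
#'
#' @param mrs integer vector of scores 0--6, `NA` allowed.
#' @return list with `counts` (named integer, "0".."6"), `percent`, `n`
#'   (non-missing), `n_missing`, `fi_count`, `fi_percent`.
#' @export
mrs_distribution_summary <- function(mrs) {
  if (any(!is.na(mrs) & (mrs < 0 | mrs > 6))) stop("mRS value outside 0-6")
  v <- mrs[!is.na(mrs)]
  counts <- vapply(0:6, function(k) sum(v == k), integer(1))
  names(counts) <- as.character(0:6)
  n <- length(v)
  fi <- sum(v <= 2)
  list(counts = counts,
       percent = if (n > 0) 100 * counts / n else counts * NA_real_,
       n = n, n_missing = sum(is.na(mrs)),
       fi_count = fi,
       fi_percent = if (n > 0) 100 * fi / n else NA_real_)
}

#' Subgroup validity table (median DAOH and mRS by prognostic factor)
#'
#' For each prognostic factor, splits the cohort into a present and an
#' absent level -- directly for binary flags, at the cohort median for
#' continuous variables (value >= median counts as present) -- and reports
#' the median DAOH and median mRS per level, the present-minus-absent
#' differences, Mann--Whitney p-values for both outcomes, and the Spearman
#' correlation between DAOH and mRS within each level. Records missing the
#' factor are excluded for that row only (pairwise deletion).
#'
#' @param data data frame with columns `daoh`, `mrs90`, and the factor
#'   columns.
#' @param factors named character vector: names are the factor column
#'   names, values are `"flag"` (logical/0-1) or `"continuous"`.
#' @return data frame with one row per factor; columns `factor`, `split`,
#'   `n_present`, `n_absent`, `daoh_present`, `daoh_absent`,
#'   `daoh_difference`, `daoh_p`, `mrs_present`, `mrs_absent`,
#'   `mrs_difference`, `mrs_p`, `rho_present`, `rho_present_p`,
#'   `rho_absent`, `rho_absent_p`. Factors with a single observed level
#'   yield a row with `NA` differences.
#' @export
subgroup_table <- function(data, factors) {
  stopifnot(all(c("daoh", "mrs90") %in% names(data)))
  rows <- lapply(names(factors), function(f) {
    type <- factors[[f]]
    v <- data[[f]]
    if (is.null(v)) stop("unknown factor column: ", f)
    if (type == "continuous") {
      med <- stats::median(v, na.rm = TRUE)
      present <- v >= med
      split_lab <- sprintf(">=%g", med)
    } else {
      present <- as.logical(v)
      split_lab <- "flag"
    }
    keep <- !is.na(present)
    d <- data[keep, , drop = FALSE]
    present <- present[keep]
    safe <- function(expr) tryCatch(expr, error = function(e) NULL)
    med_or_na <- function(x) if (length(x) == 0L) NA_real_ else
      stats::median(x, na.rm = TRUE)
    dp <- med_or_na(d$daoh[present]); da <- med_or_na(d$daoh[!present])
    mp <- med_or_na(d$mrs90[present]); ma <- med_or_na(d$mrs90[!present])
    one_level <- !any(present) || all(present)
    mw_d <- if (one_level) NULL else safe(mann_whitney(d$daoh, present))
    mw_m <- if (one_level) NULL else safe(mann_whitney(d$mrs90, present))
    sp_p <- safe(spearman_cor(d$daoh[present], d$mrs90[present]))
    sp_a <- safe(spearman_cor(d$daoh[!present], d$mrs90[!present]))
    data.frame(
      factor = f, split = split_lab,
      n_present = sum(present), n_absent = sum(!present),
      daoh_present = dp, daoh_absent = da,
      daoh_difference = if (one_level) NA_real_ else dp - da,
      daoh_p = if (is.null(mw_d)) NA_real_ else mw_d$p,
      mrs_present = mp, mrs_absent = ma,
      mrs_difference = if (one_level) NA_real_ else mp - ma,
      mrs_p = if (is.null(mw_m)) NA_real_ else mw_m$p,
      rho_present = if (is.null(sp_p)) NA_real_ else sp_p$rho,
      rho_present_p = if (is.null(sp_p)) NA_real_ else sp_p$p,
      rho_absent = if (is.null(sp_a)) NA_real_ else sp_a$rho,
      rho_absent_p = if (is.null(sp_a)) NA_real_ else sp_a$p,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
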