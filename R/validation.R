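# The validation pipeline applied to cohort tables: descriptives,
# zero-order Pearson correlations, simultaneous-entry (ENTER) multiple
# regression on z-scores with collinearity and normality checks, a paired
# comparison of the two lostness measures, and the one-sided outlier
# screen. p-values are two-sided throughout; no multiple-testing
# correction is applied by default.

#' Means and standard deviations
#'
#' @param table Data frame.
#' @param variables Character vector of numeric column names; defaults to
#'   all numeric columns.
#' @return Data frame with columns `variable`, `n`, `mean`, `sd`.
#' @export
describe <- function(table, variables = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 2L)
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  for (v in variables) {
    if (!v %in% names(table)) stop("no column named `", v, "`")
    if (!is.numeric(table[[v]])) stop("column `", v, "` is not numeric")
  }
  out <- data.frame(
    variable = variables,
    n = vapply(variables, function(v) sum(!is.na(table[[v]])), 0L),
    mean = vapply(variables, function(v) mean(table[[v]], na.rm = TRUE), 0),
    sd = vapply(variables, function(v) sd(table[[v]], na.rm = TRUE), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Zero-order correlation matrix
#'
#' Pairwise-complete Pearson correlations with two-sided p-values.
#' Zero-variance variables get `NA` coefficients and are listed in
#' `$flags`.
#'
#' @param table Data frame with at least 3 complete rows on the requested
#'   variables.
#' @param variables Character vector of column names.
#' @return List of class `lost_cormat` with matrices `r`, `p`, `n` and a
#'   character vector `flags` naming undefined-correlation variables.
#' @export
correlation_matrix <- function(table, variables) {
  stopifnot(is.data.frame(table), length(variables) >= 2L)
  dat <- table[, variables, drop = FALSE]
  if (sum(complete.cases(dat)) < 3L) {
    stop("need at least 3 complete rows for correlations")
  }
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  diag(p) <- 0
  flags <- character(0)
  zerovar <- vapply(variables, function(v) {
    s <- sd(dat[[v]], na.rm = TRUE)
    is.na(s) || s == 0
  }, TRUE)
  flags <- variables[zerovar]
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(dat[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- complete.cases(dat[[i]], dat[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (zerovar[i] || zerovar[j] || sum(ok) < 3L) next
      ct <- cor.test(dat[[i]][ok], dat[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, flags = flags), class = "lost_cormat")
}

#' @export
print.lost_cormat <- function(x, digits = 3, ...) {
  cat("Zero-order correlations (Pearson, two-sided p):\n")
  print(round(x$r, digits))
  if (length(x$flags)) {
    cat("undefined for zero-variance variable(s):",
        paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standardized multiple regression (simultaneous entry)
#'
#' Ordinary least squares on z-scored criterion and predictors with every
#' predictor entered at once (the ENTER method): standardized betas with
#' two-sided p-values, variance inflation factors, the multiple
#' correlation, and the overall F test. Rows with missing values are
#' dropped listwise.
#'
#' @param table Data frame.
#' @param criterion Name of the criterion column.
#' @param predictors Character vector of predictor column names.
#' @return List of class `lost_regression` with elements `coefficients`
#'   (data frame `term`, `beta`, `se`, `t`, `p`, `vif`), `multiple_r`,
#'   `r_squared`, `f`, `df1`, `df2`, `p_overall`, `n`.
#' @export
standardized_regression <- function(table, criterion, predictors) {
  stopifnot(is.data.frame(table), length(predictors) >= 1L)
  vars <- c(criterion, predictors)
  for (v in vars) {
    if (!v %in% names(table)) stop("no column named `", v, "`")
  }
  dat <- table[, vars, drop = FALSE]
  keep <- complete.cases(dat)
  if (sum(!keep)) {
    message("dropping ", sum(!keep), " incomplete row(s) (listwise deletion)")
  }
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1L) {
    stop("insufficient data: need more rows than predictors + 1")
  }
  for (v in vars) {
    s <- sd(dat[[v]])
    if (is.na(s) || s == 0) stop("zero-variance variable `", v, "`")
    dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
  }
  fml <- stats::as.formula(paste(
    sprintf("`%s`", criterion), "~",
    paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  if (any(sm$aliased)) {
    stop("exact collinearity among predictors: ",
         paste(names(sm$aliased)[sm$aliased], collapse = ", "))
  }
  ct <- sm$coefficients[-1L, , drop = FALSE]
  vif <- if (length(predictors) >= 2L) {
    unname(car::vif(fit))[seq_along(predictors)]
  } else 1
  fstat <- sm$fstatistic
  res <- list(
    coefficients = data.frame(
      term = predictors,
      beta = unname(ct[, 1L]), se = unname(ct[, 2L]),
      t = unname(ct[, 3L]), p = unname(ct[, 4L]),
      vif = vif, stringsAsFactors = FALSE),
    multiple_r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    f = unname(fstat[1L]), df1 = unname(fstat[2L]), df2 = unname(fstat[3L]),
    p_overall = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
    n = nrow(dat), criterion = criterion)
  class(res) <- "lost_regression"
  res
}

#' @export
print.lost_regression <- function(x, digits = 3, ...) {
  cat("Standardized regression of", x$criterion, "(n =", x$n, ")\n")
  co <- x$coefficients
  co[, c("beta", "se", "t", "p", "vif")] <-
    round(co[, c("beta", "se", "t", "p", "vif")], digits)
  print(co, row.names = FALSE)
  cat(sprintf("Multiple R = %.3f, F(%d, %d) = %.3f, p = %.4f\n",
              x$multiple_r, x$df1, x$df2, x$f, x$p_overall))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Advisory only: regression is reported regardless of the outcome, as is
#' conventional for small behavioral samples.
#'
#' @param values Numeric vector with 3 to 5000 non-missing values.
#' @return List with elements `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires between 3 and 5000 values")
  }
  if (sd(values) == 0) stop("degenerate input: all values identical")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired comparison of two measures
#'
#' Paired t test (df = n - 1, two-sided) of per-player differences, e.g.
#' global vs local lostness for the same players.
#'
#' @param a,b Numeric vectors of equal length, paired by player.
#' @return List of class `lost_paired` with `mean_diff`, `t`, `df`, `p`,
#'   `degenerate` (zero-variance differences).
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("pairing error: unequal lengths")
  ok <- complete.cases(a, b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  # essentially-constant differences (up to floating-point noise)
  if (s == 0 || s < 1e-10 * abs(m)) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(structure(list(mean_diff = m, t = t, df = n - 1L,
                          p = if (m == 0) 1 else 0, degenerate = TRUE),
                     class = "lost_paired"))
  }
  t <- m / (s / sqrt(n))
  structure(list(mean_diff = m, t = t, df = n - 1L,
                 p = 2 * pt(-abs(t), n - 1L), degenerate = FALSE),
            class = "lost_paired")
}

#' @export
print.lost_paired <- function(x, ...) {
  cat(sprintf("Paired comparison: mean diff = %.3f, t(%d) = %.3f, p = %.4f%s\n",
              x$mean_diff, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Screen for high outliers
#'
#' Marks values more than `k` standard deviations *above* the mean for
#' exclusion (the one-sided rule used to screen disoriented participants
#' on local lostness); values far below the mean are retained. Mean and SD
#' are computed on the full sample.
#'
#' @param values Numeric vector (at least 3 values).
#' @param k Number of standard deviations (default 2).
#' @param side `"above"` (default) or `"both"`.
#' @return Logical inclusion mask: `TRUE` = keep.
#' @export
exclude_outliers <- function(values, k = 2, side = c("above", "both")) {
  side <- match.arg(side)
  if (sum(!is.na(values)) < 3L) stop("need at least 3 values")
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning("zero variance: no exclusions")
    return(rep(TRUE, length(values)))
  }
  keep <- !(values > m + k * s)
  if (side == "both") keep <- keep & !(values < m - k * s)
  keep[is.na(values)] <- TRUE
  keep
}

#' Run the full validation pipeline on a cohort table
#'
#' Applies the outlier screen (on local lostness), descriptives, the
#' zero-order correlation matrix, the paired comparison of the two
#' lostness measures, normality checks, and the two standardized
#' regressions (overall and spatial knowledge on both lostness measures
#' and the three experience scales).
#'
#' @param cohort Data frame with columns `global_lostness`,
#'   `local_lostness`, `knowledge_overall`, `knowledge_spatial`,
#'   `presence`, `engagement`, `cognitive_interest`.
#' @param screen_outliers Apply the one-sided 2-SD screen on local
#'   lostness first (default `TRUE`).
#' @return List of class `cohort_validation` with elements `descriptives`,
#'   `correlations`, `paired`, `normality`, `regression_overall`,
#'   `regression_spatial`, `excluded` (player ids or row numbers), `n`.
#' @export
validate_cohort <- function(cohort, screen_outliers = TRUE) {
  needed <- c("global_lostness", "local_lostness", "knowledge_overall",
              "knowledge_spatial", "presence", "engagement",
              "cognitive_interest")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  excluded <- character(0)
  if (screen_outliers) {
    keep <- exclude_outliers(cohort$local_lostness, k = 2, side = "above")
    excluded <- if (!is.null(cohort$player)) {
      cohort$player[!keep]
    } else as.character(which(!keep))
    cohort <- cohort[keep, , drop = FALSE]
  }
  predictors <- c("global_lostness", "local_lostness", "presence",
                  "engagement", "cognitive_interest")
  norm <- lapply(stats::setNames(needed, needed), function(v) {
    tryCatch(normality_check(cohort[[v]]), error = function(e) NULL)
  })
  structure(list(
    descriptives = describe(cohort, needed),
    correlations = correlation_matrix(cohort, needed),
    paired = paired_comparison(cohort$global_lostness, cohort$local_lostness),
    normality = norm,
    regression_overall = standardized_regression(cohort, "knowledge_overall",
                                                 predictors),
    regression_spatial = standardized_regression(cohort, "knowledge_spatial",
                                                 predictors),
    excluded = excluded, n = nrow(cohort)), class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation report (n =", x$n, ")\n")
  if (length(x$excluded)) {
    cat("excluded as high outliers on local lostness:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  cat("\nDescriptives:\n")
  print(x$descriptives, row.names = FALSE)
  cat("\n")
  print(x$paired)
  cat("\n")
  print(x$correlations)
  cat("\n")
  print(x$regression_overall)
  cat("\n")
  print(x$regression_spatial)
  invisible(x)
}
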