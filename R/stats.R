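#' Ordinary least squares fit with collinearity diagnostics
#'
#' Classical OLS of `dependent` on `terms`: unstandardized coefficients B
#' with classical SEs and p-values, standardized betas
#' `B_k * SD(x_k) / SD(y)`, per-term tolerance and VIF, and the adjusted
#' `R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1)`.
#'
#' @param records data.frame of case records (no missing values in fitted
#'   columns).
#' @param dependent response column name.
#' @param terms predictor column names.
#' @return a `regression_result`: `coefficients` data.frame (term, b, se,
#'   beta, p, tolerance, vif), `intercept` (b, se, p), `r2`, `adj_r2`, `n`,
#'   plus the underlying `lm` fit.
#' @export
ols_fit <- function(records, dependent, terms) {
  if (!length(terms)) stop("at least one term required")
  df <- records[, c(dependent, terms), drop = FALSE]
  if (any(!complete.cases(df))) stop("missing values in fitted columns")
  n <- nrow(df)
  if (n <= length(terms) + 1) stop("need n > number of terms + 1")
  X <- as.matrix(df[, terms, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(terms) + 1) {
    stop("design matrix rank deficient; collinear terms among: ",
         paste(terms, collapse = ", "))
  }
  fml <- stats::as.formula(paste(dependent, "~",
                                 paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- lm(fml, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  sy <- sd(df[[dependent]])
  tv <- vif_tolerance(records, terms)
  coefs <- data.frame(term = terms,
                      b = co[terms, 1], se = co[terms, 2],
                      beta = co[terms, 1] * vapply(terms, function(t) sd(df[[t]]),
                                                   0) / sy,
                      p = co[terms, 4],
                      tolerance = tv$tolerance[match(terms, tv$term)],
                      vif = tv$vif[match(terms, tv$term)],
                      row.names = NULL, stringsAsFactors = FALSE)
  k <- length(terms)
  r2 <- sm$r.squared
  structure(list(coefficients = coefs,
                 intercept = list(b = co[1, 1], se = co[1, 2], p = co[1, 4]),
                 r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
                 n = n, dependent = dependent, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s (n = %d)\n", x$dependent,
              paste(x$coefficients$term, collapse = " + "), x$n))
  print(transform(x$coefficients, b = signif(b, 6), se = signif(se, 4),
                  beta = signif(beta, 3), p = signif(p, 3),
                  tolerance = signif(tolerance, 3), vif = signif(vif, 4)),
        row.names = FALSE)
  cat(sprintf("Intercept %.2f (SE %.2f); R2 %.4f, adjusted R2 %.4f\n",
              x$intercept$b, x$intercept$se, x$r2, x$adj_r2))
  invisible(x)
}

#' Tolerance and variance inflation factors
#'
#' For each term, `VIF = 1 / (1 - R^2_k)` from regressing it on the other
#' terms, and `tolerance = 1 / VIF`. Perfect collinearity yields infinite
#' VIF. A single term has VIF 1 by convention.
#'
#' @inheritParams ols_fit
#' @export
vif_tolerance <- function(records, terms) {
  if (length(terms) < 2)
    return(data.frame(term = terms, tolerance = rep(1, length(terms)),
                      vif = rep(1, length(terms)), stringsAsFactors = FALSE))
  out <- lapply(terms, function(t) {
    others <- setdiff(terms, t)
    fml <- stats::as.formula(paste(sprintf("`%s`", t), "~",
                                   paste(sprintf("`%s`", others), collapse = " + ")))
    r2k <- summary(lm(fml, data = records))$r.squared
    tol <- 1 - r2k
    data.frame(term = t, tolerance = tol,
               vif = if (tol <= .Machine$double.eps) Inf else 1 / tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stepwise multiple linear regression
#'
#' SPSS-style stepwise selection: repeatedly add the excluded candidate with
#' the smallest entry p-value if it is at most `p_enter`, then remove any
#' included term whose p-value is at least `p_remove`, until a fixed point.
#' Deterministic given the data.
#'
#' @inheritParams ols_fit
#' @param candidates candidate predictor column names.
#' @param p_enter entry threshold on the candidate's p-value.
#' @param p_remove removal threshold on an included term's p-value.
#' @return a `regression_result` with an `inclusion_order` field; an
#'   intercept-only result (with a warning) if no candidate enters.
#' @export
stepwise_mlr <- function(records, dependent, candidates,
                         p_enter = 0.05, p_remove = 0.10) {
  included <- character(0)
  order_in <- character(0)
  repeat {
    changed <- FALSE
    excl <- setdiff(candidates, included)
    if (length(excl)) {
      entry_p <- vapply(excl, function(cand) {
        f <- ols_fit(records, dependent, c(included, cand))
        f$coefficients$p[f$coefficients$term == cand]
      }, 0)
      best <- which.min(entry_p)
      if (entry_p[best] <= p_enter) {
        included <- c(included, excl[best])
        order_in <- c(order_in, excl[best])
        changed <- TRUE
      }
    }
    if (length(included)) {
      f <- ols_fit(records, dependent, included)
      worst <- which.max(f$coefficients$p)
      if (f$coefficients$p[worst] >= p_remove) {
        included <- setdiff(included, f$coefficients$term[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(included)) {
    warning("no candidate entered the model; returning intercept-only result")
    df <- records[, dependent, drop = FALSE]
    fit <- lm(stats::as.formula(paste(dependent, "~ 1")), data = df)
    co <- summary(fit)$coefficients
    return(structure(list(coefficients = data.frame(
      term = character(0), b = numeric(0), se = numeric(0), beta = numeric(0),
      p = numeric(0), tolerance = numeric(0), vif = numeric(0)),
      intercept = list(b = co[1, 1], se = co[1, 2], p = co[1, 4]),
      r2 = 0, adj_r2 = 0, n = nrow(df), dependent = dependent, fit = fit,
      inclusion_order = character(0)),
      class = "regression_result"))
  }
  out <- ols_fit(records, dependent, included)
  out$inclusion_order <- order_in[order_in %in% included]
  out
}

#' One-way ANOVA by group
#'
#' Classical one-way F test (`MS_between / MS_within`, `(k-1, N-k)` degrees
#' of freedom) with per-group n, mean and SD.
#'
#' @param records data.frame.
#' @param group grouping column name (e.g. lung lobe).
#' @param variable numeric column to compare.
#' @export
oneway_anova <- function(records, group, variable) {
  g <- factor(records[[group]])
  v <- records[[variable]]
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2)) stop("every group needs n >= 2")
  fit <- lm(v ~ g)
  an <- anova(fit)
  groups <- data.frame(group = levels(g), n = as.integer(ns),
                       mean = as.numeric(tapply(v, g, mean)),
                       sd = as.numeric(tapply(v, g, sd)),
                       stringsAsFactors = FALSE)
  structure(list(groups = groups, f = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df_between = an$Df[1], df_within = an$Df[2],
                 variable = variable),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$variable, x$df_between, x$df_within, x$f, x$p))
  print(transform(x$groups, mean = signif(mean, 6), sd = signif(sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Filter the high-ΔHI subgroup
#'
#' Keeps records whose ΔHI (default; set `variable = "hi_del"` for absolute
#' delivered HI) is at most the threshold; the count of excluded records is
#' attached as attribute `n_excluded`.
#'
#' @param records case table.
#' @param max_delta_hi threshold.
#' @param variable column the threshold applies to.
#' @export
filter_subgroup <- function(records, max_delta_hi = 17, variable = "dHI") {
  keep <- records[[variable]] <= max_delta_hi
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Flag regression outliers
#'
#' Records with absolute studentized residual above `threshold` are flagged;
#' the full residual-vs-predicted table is returned alongside.
#'
#' @param fit a `regression_result`.
#' @param records the records the model was fitted on.
#' @param threshold studentized-residual cutoff in SD units.
#' @return list with `flagged` (row indices), `table` (predicted, residual,
#'   studentized, flagged).
#' @export
flag_outliers <- function(fit, records, threshold = 3) {
  stopifnot(inherits(fit, "regression_result"))
  rs <- rstudent(fit$fit)
  tab <- data.frame(predicted = stats::fitted(fit$fit),
                    residual = residuals(fit$fit),
                    studentized = rs,
                    flagged = abs(rs) > threshold)
  list(flagged = which(tab$flagged), table = tab)
}

#' Cohort-weighted overall mean
#'
#' `sum(n_i m_i) / sum(n_i)`; reproduces a total row from per-group
#' summaries.
#'
#' @param group_ns group sizes (> 0).
#' @param group_means group means.
#' @export
weighted_total_mean <- function(group_ns, group_means) {
  if (length(group_ns) != length(group_means)) stop("length mismatch")
  if (any(group_ns <= 0)) stop("group sizes must be > 0")
  sum(group_ns * group_means) / sum(group_ns)
}
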