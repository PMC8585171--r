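#' Three-factor fixed-effects ANOVA with partial eta-squared
#'
#' The regional design crosses region (SA/SP/IA/IP), side (left/right) and
#' vertebral level (C2-C7). This fits the full factorial fixed-effects model
#' for one response, reports per-term F, p and partial eta-squared
#' (`SS_effect / (SS_effect + SS_error)`, shown also as the percentage
#' "Eta%"), runs Bartlett's homogeneity-of-variance test over the design
#' cells first, and flags terms at the chosen alpha. Type III sums of
#' squares (with sum-to-zero contrasts) are the default, matching common
#' statistical-package output for unbalanced data; designs with empty cells
#' fall back to Type II with a warning.
#'
#' @param data A data frame in long format.
#' @param response Response column (unquoted).
#' @param factors Character vector of factor column names (2 or 3 of them).
#' @param ss_type `"III"` (default) or `"II"`.
#' @param alpha Significance level for flagging (default 0.05).
#' @return An object of class `trab_anova`; use [tidy()] for the term table
#'   and [glance()] for the model-level summary.
#' @examples
#' d <- generate_paired_dataset(paired_spec(seed = 2))
#' fit <- factorial_anova(d, y, factors = c("region", "side", "level"))
#' tidy(fit)
#' @export
factorial_anova <- function(data, response, factors = c("region", "side", "level"),
                            ss_type = c("III", "II"), alpha = 0.05) {
  ss_type <- match.arg(ss_type)
  rsym <- rlang::ensym(response)
  rname <- rlang::as_string(rsym)
  if (!rname %in% names(data)) abort(sprintf("no column `%s`.", rname))
  if (!all(factors %in% names(data))) abort("missing factor column(s).")
  if (length(factors) < 2L) abort("need at least two factors.")
  df <- as.data.frame(data[c(rname, factors)])
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) {
      abort(sprintf("factor `%s` has fewer than 2 levels.", f))
    }
  }
  cells <- table(df[factors])
  if (any(cells == 0) && ss_type == "III") {
    empty <- which(cells == 0, arr.ind = TRUE)
    nm <- apply(empty, 1, function(i) {
      paste(mapply(function(f, k) dimnames(cells)[[f]][k],
                   seq_along(factors), i), collapse = ":")
    })
    warn(sprintf(paste0("empty design cell(s) %s; falling back to Type II ",
                        "sums of squares."),
                 paste(utils::head(nm, 5L), collapse = ", ")))
    ss_type <- "II"
  }
  cell_id <- interaction(df[factors], drop = TRUE)
  bartlett <- if (min(table(cell_id)) >= 2L && nlevels(cell_id) >= 2L) {
    bartlett.test(df[[rname]], cell_id)
  } else {
    NULL
  }
  fml <- stats::as.formula(paste(rname, "~", paste(factors, collapse = "*")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  mod <- lm(fml, data = df, contrasts = contr)
  if (stats::df.residual(mod) <= 0) {
    abort(paste0("residual df = 0: the full factorial model needs ",
                 "replication within cells (more observations or fewer ",
                 "factors)."))
  }
  if (stats::var(df[[rname]]) == 0) {
    # a constant response carries no variance at all: every effect is null
    terms_ <- attr(stats::terms(fml), "term.labels")
    res <- tibble::tibble(term = terms_, df = NA_real_, sumsq = 0,
                          statistic = 0, p.value = 1, partial_eta_sq = 0,
                          eta_pct = 0, significant = FALSE)
    return(structure(list(table = res, ss_error = 0,
                          df_error = stats::df.residual(mod),
                          bartlett = NULL, alpha = alpha, ss_type = ss_type,
                          model = mod, response = rname, factors = factors,
                          n = nrow(df)),
                     class = "trab_anova"))
  }
  atab <- car::Anova(mod, type = ss_type)
  tab <- as.data.frame(atab)
  term <- rownames(tab)
  keep <- !term %in% c("(Intercept)", "Residuals")
  ss_err <- tab["Residuals", "Sum Sq"]
  ss <- tab[keep, "Sum Sq"]
  eta <- ss / (ss + ss_err)
  fval <- tab[keep, "F value"]
  pval <- tab[keep, "Pr(>F)"]
  # a response constant within every cell carries no variance at all:
  # report null effects rather than 0/0
  degen <- !is.finite(fval) & ss < .Machine$double.eps * abs(ss_err + 1)
  fval[degen] <- 0; pval[degen] <- 1; eta[degen] <- 0
  res <- tibble::tibble(
    term = term[keep],
    df = tab[keep, "Df"],
    sumsq = ss,
    statistic = fval,
    p.value = pval,
    partial_eta_sq = eta,
    eta_pct = 100 * eta,
    significant = pval < alpha)
  structure(list(table = res, ss_error = ss_err,
                 df_error = tab["Residuals", "Df"],
                 bartlett = bartlett, alpha = alpha, ss_type = ss_type,
                 model = mod, response = rname, factors = factors,
                 n = nrow(df)),
            class = "trab_anova")
}

#' @export
print.trab_anova <- function(x, ...) {
  cat(sprintf("Factorial ANOVA (Type %s SS) of %s over %s; n = %d\n",
              x$ss_type, x$response, paste(x$factors, collapse = " x "), x$n))
  if (!is.null(x$bartlett)) {
    cat(sprintf("Bartlett homogeneity: K2 = %.3f, p = %.4g\n",
                unname(x$bartlett$statistic), x$bartlett$p.value))
  }
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.trab_anova <- function(x, ...) x$table

#' @export
glance.trab_anova <- function(x, ...) {
  tibble::tibble(
    n = x$n, ss_type = x$ss_type, alpha = x$alpha,
    ss_error = x$ss_error, df_error = x$df_error,
    bartlett_statistic = if (is.null(x$bartlett)) NA_real_ else
      unname(x$bartlett$statistic),
    bartlett_p = if (is.null(x$bartlett)) NA_real_ else x$bartlett$p.value,
    r_squared = summary(x$model)$r.squared)
}

#' Simple-effects analysis
#'
#' Fixes one factor at each of its levels in turn and tests the other
#' factor's effect inside that stratum: a one-way decomposition whose F uses
#' either the pooled error of the full two-factor model (default, more
#' powerful) or the stratum's own error. Raw p-values are reported alongside
#' a Bonferroni adjustment over the strata family. Strata in which the test
#' factor has fewer than two observed levels are skipped with a note.
#'
#' @param data A data frame in long format.
#' @param response Response column (unquoted).
#' @param fix_factor Factor fixed at each level (character).
#' @param test_factor Factor tested within each stratum (character).
#' @param pooled_error Use the full-model error term?
#' @param alpha Significance level.
#' @return A tibble, one row per stratum: `df1`, `df2`, `statistic`,
#'   `p.value`, `p.adjusted`, `significant`, `note`.
#' @export
simple_effects <- function(data, response, fix_factor, test_factor,
                           pooled_error = TRUE, alpha = 0.05) {
  rname <- rlang::as_string(rlang::ensym(response))
  df <- as.data.frame(data[c(rname, fix_factor, test_factor)])
  df[[fix_factor]] <- factor(df[[fix_factor]])
  df[[test_factor]] <- factor(df[[test_factor]])
  full <- lm(stats::as.formula(
    paste(rname, "~", fix_factor, "*", test_factor)), data = df)
  mse_full <- sum(full$residuals^2) / full$df.residual
  out <- purrr::map_dfr(levels(df[[fix_factor]]), function(lv) {
    sub <- df[df[[fix_factor]] == lv, ]
    present <- droplevels(sub[[test_factor]])
    if (nlevels(present) < 2L) {
      return(tibble::tibble(!!fix_factor := lv, df1 = NA_real_,
                            df2 = NA_real_, statistic = NA_real_,
                            p.value = NA_real_,
                            note = "skipped: <2 levels represented"))
    }
    sub[[test_factor]] <- present
    m <- lm(stats::as.formula(paste(rname, "~", test_factor)), data = sub)
    a <- anova(m)
    ss <- a[test_factor, "Sum Sq"]
    df1 <- a[test_factor, "Df"]
    if (pooled_error) {
      f <- (ss / df1) / mse_full
      df2 <- full$df.residual
    } else {
      f <- a[test_factor, "F value"]
      df2 <- a["Residuals", "Df"]
    }
    tibble::tibble(!!fix_factor := lv, df1 = df1, df2 = df2,
                   statistic = f, p.value = pf(f, df1, df2, lower.tail = FALSE),
                   note = NA_character_)
  })
  out$p.adjusted <- p.adjust(out$p.value, "bonferroni")
  out$significant <- !is.na(out$p.adjusted) & out$p.adjusted < alpha
  out
}

#' Microstructure-mechanics linear regression
#'
#' Ordinary least squares of one mechanical property on one microstructure
#' parameter, reported the way structure-mechanics tables are printed:
#' slope, intercept, adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)`, and
#' the two-sided Pearson correlation p-value.
#'
#' @param data A data frame.
#' @param x,y Predictor and response columns (unquoted).
#' @return An object of class `trab_regression`; [tidy()] gives the
#'   coefficient table, [glance()] the fit summary including the printed
#'   equation.
#' @examples
#' d <- generate_paired_dataset(paired_spec(noise_sd = 0))
#' glance(regress(d, x, y))
#' @export
regress <- function(data, x, y) {
  xname <- rlang::as_string(rlang::ensym(x))
  yname <- rlang::as_string(rlang::ensym(y))
  xv <- data[[xname]]; yv <- data[[yname]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) abort("need at least 3 complete observations.")
  if (sd(xv) == 0) abort(sprintf("`%s` is constant: slope undefined.", xname))
  mod <- lm(yv ~ xv)
  r2 <- summary(mod)$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p <- if (sd(yv) == 0) NA_real_ else cor.test(xv, yv)$p.value
  structure(list(slope = unname(coef(mod)[2]),
                 intercept = unname(coef(mod)[1]),
                 r_squared = r2, adj_r_squared = adj, p_value = p, n = n,
                 x = xname, y = yname, model = mod),
            class = "trab_regression")
}

#' @export
print.trab_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s: y = %.4gx %s %.4g (adj R2 = %.4f, p = %.3g, n = %d)\n",
              x$y, x$x, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept), x$adj_r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.trab_regression <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = c("(Intercept)", x$x),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.trab_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 p.value = x$p_value, n = x$n,
                 equation = sprintf("y = %.6gx %s %.6g", x$slope,
                                    if (x$intercept < 0) "-" else "+",
                                    abs(x$intercept)))
}

#' Ridge regression on standardized predictors
#'
#' Solves `(Z'Z + lambda I) beta = Z'y` with `Z` the column-standardized
#' predictors (sd with `n - 1` denominator), screening which microstructure
#' parameters relate most strongly to bone strength when predictors are
#' collinear. `lambda = 0` reduces exactly to OLS; coefficients shrink
#' monotonically in L2 norm as `lambda` grows.
#'
#' @param data A data frame.
#' @param y Response column (unquoted).
#' @param predictors Character vector of predictor column names; default all
#'   numeric columns except the response.
#' @param lambda Non-negative penalty (scalar or vector).
#' @return A tibble with one row per predictor and lambda:
#'   `lambda`, `term`, `estimate_std` (standardized scale), `estimate`
#'   (original scale), plus `(Intercept)` rows on the original scale.
#' @export
ridge_regress <- function(data, y, predictors = NULL, lambda = 0) {
  yname <- rlang::as_string(rlang::ensym(y))
  if (any(lambda < 0)) abort("`lambda` must be non-negative.")
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          yname)
  }
  X <- as.matrix(data[predictors])
  yv <- data[[yname]]
  ok <- stats::complete.cases(X, yv)
  X <- X[ok, , drop = FALSE]; yv <- yv[ok]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) abort("constant predictor column(s).")
  mus <- colMeans(X)
  Z <- scale(X, center = mus, scale = sds)
  yc <- yv - mean(yv)
  G <- crossprod(Z)
  zy <- crossprod(Z, yc)
  purrr::map_dfr(lambda, function(l) {
    beta_std <- solve(G + diag(l, ncol(Z)), zy)[, 1]
    beta <- beta_std / sds
    icpt <- mean(yv) - sum(beta * mus)
    tibble::tibble(lambda = l,
                   term = c("(Intercept)", predictors),
                   estimate_std = c(NA_real_, unname(beta_std)),
                   estimate = c(icpt, unname(beta)))
  })
}
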