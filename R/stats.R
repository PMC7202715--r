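# Association battery: composite neuropsychological scoring, correlations
# with Fisher z and its (N-3)^(-1/2) standard error, age-partialed
# correlations, paired tests, and Baron-Kenny mediation with the Sobel test.

#' Composite cognitive domain scores
#'
#' Standardizes every test across subjects, orients it so positive always
#' means better than average (timed tests get orientation -1), and averages
#' the oriented z-scores within each domain (equal weights). Tests with zero
#' variance are excluded with a warning.
#'
#' @param tests Data frame of raw scores, one row per subject.
#' @param domains Named character vector: test column -> domain label.
#' @param orientation Named numeric vector of +1/-1 per test column
#'   (default +1 for every test).
#' @return Data frame with one column per domain.
#' @export
composite_scores <- function(tests, domains,
                             orientation = stats::setNames(rep(1, length(domains)),
                                                           names(domains))) {
  stopifnot(all(names(domains) %in% names(tests)))
  z <- list()
  for (tn in names(domains)) {
    v <- tests[[tn]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("test '", tn, "' has zero variance; excluded")
      next
    }
    o <- if (tn %in% names(orientation)) orientation[[tn]] else 1
    z[[tn]] <- o * (v - mean(v)) / s
  }
  doms <- unique(domains[names(z)])
  out <- as.data.frame(lapply(doms, function(d) {
    cols <- names(z)[domains[names(z)] == d]
    rowMeans(do.call(cbind, z[cols]))
  }))
  names(out) <- doms
  out
}

#' Pearson correlation with Fisher z and its standard error
#'
#' Returns r, Fisher `z = atanh(r)`, the standard error `(n - 3)^(-1/2)`,
#' and a two-sided p-value from the t distribution with n - 2 df. `|r| = 1`
#' yields an infinite z flagged rather than an error.
#'
#' @param x,y Numeric vectors (>= 4 finite pairs, both non-constant).
#' @return List of class `eac_assoc`: `r`, `n`, `z`, `se_z`, `p`,
#'   `df`, `degenerate_z`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  df <- n - 2
  .assoc(r, n, df)
}

# shared assembly: Fisher z with the (n-3)^(-1/2) SE; |r| at 1 (to numerical
# precision) yields a flagged infinite z rather than an error
.assoc <- function(r, n, df) {
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(r = r, n = n,
                 z = if (degenerate) sign(r) * Inf else atanh(r),
                 se_z = 1 / sqrt(n - 3), p = p, df = df,
                 degenerate_z = degenerate),
            class = "eac_assoc")
}

#' @export
print.eac_assoc <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, z = %.3f (SE %.3f), p = %.4g\n",
              x$df, x$r, x$z, x$se_z, x$p))
  invisible(x)
}

#' Partial correlation controlling for one covariate
#'
#' Residualizes both variables on the covariate (with intercept) by least
#' squares and correlates the residuals; the p-value loses one further
#' degree of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector (non-constant).
#' @return `eac_assoc` (with `df = n - 3`).
#' @export
partial_correlate <- function(x, y, covariate) {
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 5) stop("need >= 5 finite triples")
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  rx <- stats::residuals(stats::lm(x ~ covariate))
  ry <- stats::residuals(stats::lm(y ~ covariate))
  if (stats::sd(rx) < 1e-12 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-12 * max(stats::sd(y), 1)) {
    stop("undefined correlation: variable collinear with covariate")
  }
  r <- stats::cor(rx, ry)
  .assoc(r, n, n - 3)
}

#' Paired t test on two measurement vectors
#'
#' Standard paired t on the differences (df = n - 1); zero-variance
#' differences raise a degenerate-test error.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return List: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need >= 2 pairs")
  if (stats::sd(d) == 0) stop("degenerate test: zero-variance differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Baron-Kenny mediation with the Sobel test
#'
#' Three-step procedure on (by default) standardized variables:
#' (1) total effect `c` from `y ~ x`; (2) path `a` from `m ~ x` -- if either
#' is non-significant at `alpha` mediation is not assessable; (3) `y ~ x + m`
#' gives the direct effect `b1` and the mediator effect `b2`. Classified
#' "full" when the direct effect loses significance while the mediator
#' remains significant; "partial" when the direct effect stays significant
#' but attenuated (`|b1| < |c|`) with a significant Sobel statistic; "none"
#' otherwise. Sobel statistic: `a*b2 / sqrt(b2^2 se_a^2 + a^2 se_b2^2)`.
#'
#' @param x Independent variable (e.g. age).
#' @param m Proposed mediator.
#' @param y Dependent variable.
#' @param alpha Significance level (default 0.05, two-sided).
#' @param standardize Standardize x, m, y first (default TRUE; the reported
#'   coefficients are then betas).
#' @return List of class `eac_mediation`: paths `c`, `a`, `b1`, `b2` with
#'   SEs and p-values, `sobel` (statistic, `p_z`, `p_t`), `classification`.
#' @export
mediate <- function(x, m, y, alpha = 0.05, standardize = TRUE) {
  ok <- is.finite(x) & is.finite(m) & is.finite(y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need >= 10 complete cases")
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m)); y <- as.numeric(scale(y))
  }
  if (abs(stats::cor(x, m)) > 1 - 1e-10) stop("singular regression: x and m collinear")

  coef2 <- function(fit, term) {
    s <- summary(fit)$coefficients
    c(est = s[term, 1], se = s[term, 2], p = s[term, 4])
  }
  step1 <- coef2(stats::lm(y ~ x), "x")     # total effect c
  step2 <- coef2(stats::lm(m ~ x), "x")     # path a
  fit3 <- stats::lm(y ~ x + m)
  b1 <- coef2(fit3, "x")                    # direct effect
  b2 <- coef2(fit3, "m")                    # mediator effect

  a <- step2["est"]; b <- b2["est"]
  sobel <- a * b / sqrt(b^2 * step2["se"]^2 + a^2 * b2["se"]^2)
  sobel_p_z <- 2 * stats::pnorm(-abs(sobel))
  sobel_p_t <- 2 * stats::pt(-abs(sobel), df = n - 3)

  classification <- if (step1["p"] >= alpha || step2["p"] >= alpha) {
    "not-assessable"
  } else if (b1["p"] >= alpha && b2["p"] < alpha) {
    "full"
  } else if (b1["p"] < alpha && abs(b1["est"]) < abs(step1["est"]) &&
             sobel_p_z < alpha) {
    "partial"
  } else {
    "none"
  }
  structure(list(
    n = n, alpha = alpha, standardized = standardize,
    c_total = step1, a_path = step2, b1_direct = b1, b2_mediator = b2,
    sobel = c(statistic = unname(sobel), p_z = unname(sobel_p_z),
              p_t = unname(sobel_p_t)),
    classification = classification
  ), class = "eac_mediation")
}

#' @export
print.eac_mediation <- function(x, ...) {
  cat(sprintf("mediation (n = %d): %s\n", x$n, x$classification))
  cat(sprintf("  c = %.3f (p %.3g), a = %.3f (p %.3g), b1 = %.3f (p %.3g), b2 = %.3f (p %.3g)\n",
              x$c_total["est"], x$c_total["p"], x$a_path["est"], x$a_path["p"],
              x$b1_direct["est"], x$b1_direct["p"],
              x$b2_mediator["est"], x$b2_mediator["p"]))
  cat(sprintf("  Sobel = %.3f (p_z %.3g)\n", x$sobel["statistic"], x$sobel["p_z"]))
  invisible(x)
}

#' Correlation table of covariates against the EAC components
#'
#' For every covariate column: Pearson r with EAC1, EAC2 and age, plus the
#' age-partialed correlations with EAC1 and EAC2; significance tiers at
#' p < 0.05 and p < 0.10 are flagged. No multiple-comparison correction is
#' applied.
#'
#' @param cohort Data frame with columns `EAC1`, `EAC2`, `age` and the
#'   covariates.
#' @param covariates Character vector of covariate column names (default:
#'   every other numeric column).
#' @return Data frame: one row per covariate with `r_eac1`, `r_eac2`,
#'   `r_age`, `r_eac1_age_partialed`, `r_eac2_age_partialed` and matching
#'   p-values and significance tiers.
#' @export
association_battery <- function(cohort, covariates = NULL) {
  needed <- c("EAC1", "EAC2", "age")
  stopifnot(all(needed %in% names(cohort)))
  if (is.null(covariates)) {
    num <- vapply(cohort, is.numeric, TRUE)
    covariates <- setdiff(names(cohort)[num], c(needed, "id"))
  }
  tier <- function(p) ifelse(is.na(p), "", ifelse(p < 0.05, "p<0.05",
                                                  ifelse(p < 0.10, "p<0.10", "")))
  safe <- function(expr) tryCatch(expr, error = function(e) list(r = NA_real_, p = NA_real_))
  rows <- lapply(covariates, function(cn) {
    v <- cohort[[cn]]
    r1 <- safe(correlate(v, cohort$EAC1))
    r2 <- safe(correlate(v, cohort$EAC2))
    ra <- if (cn == "age") list(r = 1, p = 0) else safe(correlate(v, cohort$age))
    p1 <- if (cn == "age") NULL else safe(partial_correlate(v, cohort$EAC1, cohort$age))
    p2 <- if (cn == "age") NULL else safe(partial_correlate(v, cohort$EAC2, cohort$age))
    data.frame(
      variable = cn,
      r_eac1 = r1$r, p_eac1 = r1$p, tier_eac1 = tier(r1$p),
      r_eac2 = r2$r, p_eac2 = r2$p, tier_eac2 = tier(r2$p),
      r_age = ra$r, p_age = ra$p,
      r_eac1_age_partialed = if (is.null(p1)) NA_real_ else p1$r,
      p_eac1_age_partialed = if (is.null(p1)) NA_real_ else p1$p,
      r_eac2_age_partialed = if (is.null(p2)) NA_real_ else p2$r,
      p_eac2_age_partialed = if (is.null(p2)) NA_real_ else p2$p
    )
  })
  do.call(rbind, rows)
}
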