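#' Fit a standard-addition / calibration line
#'
#' Ordinary least-squares fit of response against concentration, carrying
#' the summary statistics the extrapolation uncertainty needs: slope,
#' intercept, residual standard deviation `s_yx`, `Sxx`, the response mean,
#' and R². When any concentration level is replicated a lack-of-fit test is
#' run (F test of the straight line against the per-level means model, pure
#' error from the replicates) and its p-value stored; linearity of the
#' calibration is judged against it at the chosen alpha.
#'
#' @param x concentrations (or a two-column data frame/matrix of `(x, y)`).
#' @param y responses.
#' @return an object of class `sa_fit` with components `slope`, `intercept`,
#'   `n`, `s_yx`, `x_mean`, `Sxx`, `y_mean`, `r2`, `lof_pvalue` (NA when no
#'   level is replicated), `fitted`, `residuals`, `x`, `y`.
#' @seealso [qsa_concentration()] for the x-intercept extrapolation,
#'   [qec_concentration()] for inverse prediction.
#' @examples
#' f <- fit_line(c(0, 5, 10), c(2, 4, 6))
#' coef(f)            # intercept 2, slope 0.4
#' qsa_concentration(f)$conc  # 5
#' @export
fit_line <- function(x, y = NULL) {
  if (is.null(y)) {
    pts <- as.data.frame(x)
    if (ncol(pts) < 2) stop("need (x, y) points", call. = FALSE)
    y <- pts[[2]]; x <- pts[[1]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2) {
    stop("singular design: need >= 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  s_yx <- if (n > 2) sqrt(ss_res / (n - 2)) else 0
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else 0
  r2 <- min(max(r2, 0), 1)

  lof_p <- NA_real_
  xf <- factor(x)
  m <- nlevels(xf)
  if (m >= 3 && n > m && any(table(xf) >= 2)) {
    full <- stats::lm(y ~ xf)
    a <- stats::anova(fit, full)
    p <- a[["Pr(>F)"]][2]
    lof_p <- if (is.finite(p)) p else NA_real_
  }

  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]), n = n,
         s_yx = s_yx, x_mean = mean(x), Sxx = sum((x - mean(x))^2),
         y_mean = mean(y), r2 = r2, lof_pvalue = lof_p,
         fitted = unname(stats::fitted(fit)), residuals = unname(res),
         x = x, y = y),
    class = "sa_fit"
  )
}

#' @export
print.sa_fit <- function(x, ...) {
  cat(sprintf("Calibration line: y = %.6g + %.6g x  (n = %d, R2 = %.4f)\n",
              x$intercept, x$slope, x$n, x$r2))
  if (!is.na(x$lof_pvalue)) {
    cat(sprintf("  lack-of-fit p = %.4g\n", x$lof_pvalue))
  }
  invisible(x)
}

#' @export
coef.sa_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.sa_fit <- function(object, ...) object$residuals

#' @export
fitted.sa_fit <- function(object, ...) object$fitted

#' @export
predict.sa_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' @export
summary.sa_fit <- function(object, ...) {
  se_b <- if (object$Sxx > 0) object$s_yx / sqrt(object$Sxx) else NA_real_
  se_a <- object$s_yx * sqrt(1 / object$n +
                               object$x_mean^2 / object$Sxx)
  out <- list(fit = object, se_slope = se_b, se_intercept = se_a,
              extrapolation = qsa_concentration(object))
  class(out) <- "summary.sa_fit"
  out
}

#' @export
print.summary.sa_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  s_yx = %.6g; se(slope) = %.4g; se(intercept) = %.4g\n",
              x$fit$s_yx, x$se_slope, x$se_intercept))
  e <- x$extrapolation
  cat(sprintf("  x-intercept extrapolation: %.6g +- %.4g [%s]\n",
              e$conc, e$sd, e$flag))
  invisible(x)
}

#' Detected concentration by standard-addition extrapolation
#'
#' The detected concentration is the magnitude of the calibration line's
#' negative x-intercept, `a / b`. Its standard deviation propagates the
#' uncertainty of both slope and intercept:
#' \deqn{s_C = \frac{s_{y/x}}{b}\sqrt{\frac{1}{n} +
#'   \frac{\bar y^2}{b^2 S_{xx}}}}
#' A nonpositive slope makes the curve non-quantifiable (flag, not error);
#' a negative intercept is flagged as a negative concentration.
#'
#' @param fit an [fit_line()] object.
#' @return list with `conc`, `sd`, and `flag` (`"ok"`, `"neg_slope"`,
#'   `"neg_conc"`).
#' @export
qsa_concentration <- function(fit) {
  stopifnot(inherits(fit, "sa_fit"))
  b <- fit$slope; a <- fit$intercept
  if (!is.finite(b) || b <= 0) {
    return(list(conc = NA_real_, sd = NA_real_, flag = "neg_slope"))
  }
  conc <- a / b
  sd <- (fit$s_yx / b) * sqrt(1 / fit$n + fit$y_mean^2 / (b^2 * fit$Sxx))
  list(conc = conc, sd = sd, flag = if (a < 0) "neg_conc" else "ok")
}

#' One-point internal-standard concentration
#'
#' Detected concentration from the analyte / internal-standard signal ratio
#' at a constant IS concentration. Because analyte and labeled IS are
#' ionized from the same pixel, suppression cancels in the ratio.
#'
#' @param analyte_signal analyte response(s).
#' @param is_signal internal-standard response(s).
#' @param is_conc internal-standard concentration in the solvent.
#' @return list with `conc` (NA where the IS signal is nonpositive) and
#'   `flag` (`"ok"` / `"non_quantifiable"`), vectorized over inputs.
#' @export
qis_concentration <- function(analyte_signal, is_signal, is_conc) {
  bad <- !is.finite(is_signal) | is_signal <= 0
  conc <- ifelse(bad, NA_real_, analyte_signal / is_signal * is_conc)
  list(conc = conc,
       flag = ifelse(bad, "non_quantifiable", "ok"))
}

#' External-calibration concentration (inverse prediction)
#'
#' Inverts a solvent-only calibration line at an observed tissue response:
#' `C = (response - a) / b`. External calibration cannot see the pixel's
#' matrix, so under ion suppression the result is biased low; negative
#' concentrations are returned flagged rather than censored.
#'
#' @param response observed response(s).
#' @param ec_fit calibration [fit_line()] from standards measured off
#'   tissue.
#' @return list with `conc` and `flag` (`"ok"`, `"neg_conc"`,
#'   `"non_quantifiable"`), vectorized over `response`.
#' @export
qec_concentration <- function(response, ec_fit) {
  stopifnot(inherits(ec_fit, "sa_fit"))
  b <- ec_fit$slope
  if (!is.finite(b) || b <= 0) {
    return(list(conc = rep(NA_real_, length(response)),
                flag = rep("non_quantifiable", length(response))))
  }
  conc <- (response - ec_fit$intercept) / b
  list(conc = conc, flag = ifelse(conc < 0, "neg_conc", "ok"))
}
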