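## The composite-index statistics stage: pairwise Pearson correlations with
## Shapiro-Wilk normality screening, the multilinear model
## Y = beta0 + beta1*DA + beta2*EF per micromechanical outcome, aggregation
## of the slope ratios beta2/beta1 into gamma, and the DAEF index
## DAEF = DA + gamma*EF.

#' Published reference coefficients for the DAEF index
#'
#' Multilinear coefficients `Y = beta0 + beta1*DA + beta2*EF` reported for
#' the original cohort of 29 human femoral-head allograft cores, one row per
#' micromechanical outcome (axial strain in %, axial and von Mises stress in
#' MPa, strain energy density in MPa).  These printed values are the
#' reference inputs for the gamma aggregation behind the canonical
#' `DAEF = DA + 1.69 * EF`.
#'
#' @return data.frame with columns `outcome`, `beta0`, `beta1`, `beta2`
#' @export
daef_reference_coefficients <- function() {
  data.frame(
    outcome = c("eps_z", "sigma_z", "sigma_vm", "W_e"),
    beta0 = c(-0.016, -1.3, 4.3, 0.0009),
    beta1 = c(-0.067, -10.6, 9.4, 0.0054),
    beta2 = c(-0.117, -17.3, 14.0, 0.0120))
}

#' Pairwise Pearson correlation screen
#'
#' Pairwise Pearson r-squared and two-tailed p-values between all numeric
#' columns, with a per-column Shapiro-Wilk normality p-value.  Normality is
#' advisory: a warning is raised for columns with Shapiro-Wilk p < 0.05, but
#' correlations are always computed.  Significance threshold: raw p < 0.05
#' (no multiplicity correction).
#'
#' @param table data.frame of numeric columns, one row per sample (>= 3).
#' @return object of class `correlation_screen`: `r2` and `p` matrices,
#'   `shapiro_p`, logical `significant` (p < 0.05), logical `constant`
#'   column flags
#' @export
correlation_matrix <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[num]
  n <- nrow(table)
  if (n < 3) stop("at least 3 samples required")
  p <- ncol(table)
  nm <- colnames(table)
  constant <- vapply(table, function(x) var(x) == 0, logical(1))
  r2 <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  pv <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p)) {
    r2[i, i] <- 1
    pv[i, i] <- 0
    if (i == p) next
    for (j in seq((i + 1), p)) {
      if (constant[i] || constant[j]) next
      ct <- stats::cor.test(table[[i]], table[[j]], method = "pearson")
      r2[i, j] <- r2[j, i] <- unname(ct$estimate)^2
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  sw <- vapply(seq_len(p), function(i) {
    if (constant[i] || n < 3 || n > 5000) return(NA_real_)
    shapiro.test(table[[i]])$p.value
  }, numeric(1))
  names(sw) <- nm
  if (any(!is.na(sw) & sw < 0.05))
    warning("non-normal column(s) by Shapiro-Wilk (p < 0.05): ",
            paste(nm[!is.na(sw) & sw < 0.05], collapse = ", "),
            " - Pearson correlations reported anyway")
  if (any(constant))
    warning("constant column(s), correlations undefined: ",
            paste(nm[constant], collapse = ", "))
  structure(list(r2 = r2, p = pv, shapiro_p = sw,
                 significant = pv < 0.05, constant = constant, n = n),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("<correlation_screen> n =", x$n, "samples; pairwise Pearson R^2:\n")
  print(round(x$r2, 2))
  invisible(x)
}

#' Multilinear fit of one outcome on DA and EF
#'
#' Ordinary least squares for `Y = beta0 + beta1*DA + beta2*EF`, the
#' per-outcome building block of the DAEF index.  The slope ratio
#' `beta2/beta1` is NA when beta1 is (numerically) zero.
#'
#' @param Y numeric outcome vector.
#' @param DA,EF numeric predictors (same length as Y, >= 4 samples).
#' @param outcome_name label stored with the fit.
#' @return object of class `daef_fit_one`: `beta0`, `beta1`, `beta2`, `r2`,
#'   `ratio`, `outcome_name`, and the underlying `lm`
#' @export
multilinear_fit <- function(Y, DA, EF, outcome_name = "Y") {
  if (length(Y) < 4) stop("at least 4 samples required")
  if (length(DA) != length(Y) || length(EF) != length(Y))
    stop("Y, DA, EF must have equal length")
  qrX <- qr(cbind(1, DA, EF))
  if (qrX$rank < 3) stop("rank-deficient design: DA and EF are collinear")
  fit <- lm(Y ~ DA + EF)
  b <- unname(coef(fit))
  # beta1 counts as zero at the numerical noise floor of this fit
  scl <- max(1, abs(b), mean(abs(Y)))
  ratio <- if (abs(b[2]) > 1e-10 * scl) b[3] / b[2] else NA_real_
  ss_tot <- sum((Y - mean(Y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  structure(list(beta0 = b[1], beta1 = b[2], beta2 = b[3], r2 = r2,
                 ratio = ratio, outcome_name = outcome_name, lm = fit),
            class = "daef_fit_one")
}

#' @export
print.daef_fit_one <- function(x, ...) {
  cat(sprintf("%s = %.4g %+.4g*DA %+.4g*EF   (R^2 = %.3f, beta2/beta1 = %.3g)\n",
              x$outcome_name, x$beta0, x$beta1, x$beta2, x$r2, x$ratio))
  invisible(x)
}

#' Aggregate the slope ratios into gamma
#'
#' Pools the per-outcome ratios `beta2/beta1` into a single gamma for the
#' DAEF index.  The default is the median (for the published reference
#' coefficients it reproduces the canonical 1.69 at two decimals, which the
#' arithmetic mean of the printed ratios does not); the mean is also
#' available.  Aggregation ignores undefined ratios and is invariant to fit
#' ordering.
#'
#' @param fits list of [multilinear_fit()] results (or a numeric vector of
#'   ratios).
#' @param method "median" or "mean".
#' @return gamma (numeric scalar)
#' @export
aggregate_gamma <- function(fits, method = c("median", "mean")) {
  method <- match.arg(method)
  ratios <- if (is.numeric(fits)) fits
            else vapply(fits, function(f) f$ratio, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop("no defined beta2/beta1 ratios to aggregate")
  if (method == "median") median(ratios) else mean(ratios)
}

#' DAEF composite index
#'
#' `DAEF = DA + gamma * EF`.  With the canonical gamma = 1.69 this is the
#' published composite index combining fabric anisotropy and plate/rod
#' character into a single predictor of microscopic mechanical loading.
#'
#' @param DA degree of anisotropy in \[0, 1\].
#' @param EF ellipsoid factor in \[-1, 1\].
#' @param gamma aggregation coefficient (default 1.69).
#' @return numeric DAEF values
#' @export
daef_index <- function(DA, EF, gamma = 1.69) {
  if (any(DA < 0 | DA > 1, na.rm = TRUE)) stop("DA must lie in [0, 1]")
  if (any(EF < -1 | EF > 1, na.rm = TRUE)) stop("EF must lie in [-1, 1]")
  DA + gamma * EF
}

#' Fit the DAEF composite-index model
#'
#' The statistics stage in one call: per-outcome multilinear fits
#' `Y = beta0 + beta1*DA + beta2*EF`, aggregation of the slope ratios into
#' gamma, per-sample DAEF values, and per-outcome R-squared of each outcome
#' against EF alone, DA alone and DAEF (reported, not ranked).
#'
#' @param data data.frame with columns `DA`, `EF` and the outcome columns.
#' @param outcomes character vector of outcome column names; defaults to the
#'   four micromechanical parameters `eps_z`, `sigma_z`, `sigma_vm`, `W_e`
#'   (those present in `data`).
#' @param gamma_method "median" (default) or "mean", see [aggregate_gamma()].
#' @param gamma override gamma instead of aggregating from the fits.
#' @return object of class `daef`: `fits` (per outcome), `gamma`,
#'   `gamma_method`, `ratios`, `daef` (per-sample index), `r2_table`
#'   (outcomes x \{EF, DA, DAEF\}), `data`
#' @examples
#' d <- make_regression_dataset(-1.3, -10.6, -17.3, noise_sd = 0, n = 29)
#' names(d)[3] <- "sigma_z"
#' fit <- daef_fit(d, outcomes = "sigma_z")
#' coef(fit)
#' @export
daef_fit <- function(data, outcomes = NULL, gamma_method = c("median", "mean"),
                     gamma = NULL) {
  gamma_method <- match.arg(gamma_method)
  data <- as.data.frame(data)
  if (!all(c("DA", "EF") %in% names(data)))
    stop("`data` needs DA and EF columns")
  if (is.null(outcomes)) {
    outcomes <- intersect(c("eps_z", "sigma_z", "sigma_vm", "W_e"), names(data))
    if (!length(outcomes)) stop("no outcome columns found")
  }
  miss <- setdiff(outcomes, names(data))
  if (length(miss)) stop("missing outcome column(s): ", paste(miss, collapse = ", "))
  keep <- complete.cases(data[c("DA", "EF", outcomes)])
  data <- data[keep, , drop = FALSE]
  fits <- lapply(outcomes, function(o)
    multilinear_fit(data[[o]], data$DA, data$EF, outcome_name = o))
  names(fits) <- outcomes
  ratios <- vapply(fits, function(f) f$ratio, numeric(1))
  g <- if (is.null(gamma)) aggregate_gamma(fits, gamma_method) else gamma
  idx <- daef_index(data$DA, data$EF, g)
  r2_of <- function(y, x) {
    if (var(y) == 0 || var(x) == 0) return(NA_real_)
    cor(y, x)^2
  }
  r2_table <- t(vapply(outcomes, function(o)
    c(EF = r2_of(data[[o]], data$EF),
      DA = r2_of(data[[o]], data$DA),
      DAEF = r2_of(data[[o]], idx)), numeric(3)))
  structure(list(fits = fits, gamma = g, gamma_method = gamma_method,
                 ratios = ratios, daef = idx, r2_table = r2_table,
                 data = data, outcomes = outcomes, n = nrow(data)),
            class = "daef")
}

#' Evaluate the DAEF model on a joined sample table
#'
#' Alias of [daef_fit()] matching the pipeline vocabulary.
#' @inheritParams daef_fit
#' @return a `daef` object
#' @export
evaluate_daef <- function(data, outcomes = NULL,
                          gamma_method = c("median", "mean"), gamma = NULL) {
  daef_fit(data, outcomes, gamma_method, gamma)
}

#' @export
print.daef <- function(x, ...) {
  cat(sprintf("DAEF composite-index model (n = %d samples)\n", x$n))
  cat(sprintf("  gamma = %.4g (%s of beta2/beta1 ratios: %s)\n", x$gamma,
              x$gamma_method,
              paste(sprintf("%.3g", x$ratios), collapse = ", ")))
  cat("  DAEF = DA +", sprintf("%.4g", x$gamma), "* EF\n")
  invisible(x)
}

#' @export
summary.daef <- function(object, ...) {
  structure(list(model = object), class = "summary.daef")
}

#' @export
print.summary.daef <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-outcome multilinear fits Y = beta0 + beta1*DA + beta2*EF:\n")
  for (f in m$fits) print(f)
  cat("\nLinear R^2 of each outcome against EF, DA and DAEF:\n")
  print(round(m$r2_table, 3))
  invisible(x)
}

#' @export
coef.daef <- function(object, ...) {
  out <- t(vapply(object$fits, function(f)
    c(beta0 = f$beta0, beta1 = f$beta1, beta2 = f$beta2,
      ratio = f$ratio, r2 = f$r2), numeric(5)))
  out
}

#' Predict micromechanical outcomes or the index itself
#'
#' With `type = "index"` returns the DAEF values for new DA/EF; with
#' `type = "outcome"` returns the multilinear prediction of one outcome.
#'
#' @param object a `daef` model.
#' @param newdata data.frame with `DA` and `EF` columns (the training data
#'   when omitted).
#' @param type "index" or "outcome".
#' @param outcome outcome name for `type = "outcome"`.
#' @param ... unused.
#' @return numeric vector
#' @export
predict.daef <- function(object, newdata = NULL, type = c("index", "outcome"),
                         outcome = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (type == "index") return(daef_index(newdata$DA, newdata$EF, object$gamma))
  if (is.null(outcome)) outcome <- object$outcomes[1]
  f <- object$fits[[outcome]]
  if (is.null(f)) stop("unknown outcome: ", outcome)
  f$beta0 + f$beta1 * newdata$DA + f$beta2 * newdata$EF
}

#' Residuals of the per-outcome multilinear fits
#' @param object a `daef` model
#' @param outcome outcome name (first outcome when omitted)
#' @param ... unused
#' @return numeric vector
#' @export
residuals.daef <- function(object, outcome = NULL, ...) {
  if (is.null(outcome)) outcome <- object$outcomes[1]
  stats::residuals(object$fits[[outcome]]$lm)
}

#' Scatter plots of outcomes against EF, DA and DAEF
#'
#' One row per outcome, three panels (EF, DA, DAEF) with the least-squares
#' line and R-squared annotated — the numeric counterpart of the classic
#' composite-index regression figure.
#'
#' @param x a `daef` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.daef <- function(x, ...) {
  preds <- list(EF = x$data$EF, DA = x$data$DA, DAEF = x$daef)
  old <- graphics::par(mfrow = c(length(x$outcomes), 3),
                       mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (o in x$outcomes) {
    for (pn in names(preds)) {
      xx <- preds[[pn]]
      yy <- x$data[[o]]
      graphics::plot(xx, yy, xlab = pn, ylab = o, pch = 19, ...)
      if (var(xx) > 0 && var(yy) > 0) {
        fit <- lm(yy ~ xx)
        graphics::abline(fit, col = "red3")
        graphics::mtext(sprintf("R2 = %.2f", cor(xx, yy)^2), side = 3,
                        line = 0.2, cex = 0.7)
      }
    }
  }
  invisible(x)
}
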