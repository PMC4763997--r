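# Age-reference centile curves by the LMS (lambda-mu-sigma) method.
#
# A positive measurement y at age t is modeled through a Box-Cox transform
#   z = ((y/M(t))^L(t) - 1) / (L(t) S(t))     (L != 0)
#   z = log(y/M(t)) / S(t)                    (L  = 0)
# with z standard normal: L(t) is the age-varying Box-Cox power (skewness),
# M(t) the median and S(t) the coefficient of variation. The three curves
# are smooth functions of transformed age t = log(age + offset), fitted
# jointly by maximum likelihood over natural-spline bases of modest
# degrees of freedom.

lms_basis <- function(t, df) {
  if (df <= 1) return(list(ns = NULL, df = 1L))
  list(ns = splines::ns(t, df = df - 1L), df = as.integer(df))
}

lms_design <- function(basis, t) {
  if (is.null(basis$ns)) return(matrix(1, length(t), 1))
  cbind(1, unclass(stats::predict(basis$ns, t)))
}

#' Fit LMS reference curves
#'
#' Joint maximum-likelihood fit of the Box-Cox power `L`, median `M` and
#' coefficient of variation `S` as smooth natural-spline functions of
#' transformed age `t = log(age + age_offset)`. The log transform of the
#' age axis concentrates resolution in infancy, where the peritoneal
#' measures change steepest; `M` and `S` are kept positive by modeling
#' them on the log scale.
#'
#' @param values Positive measurements.
#' @param ages Ages in years, same length.
#' @param df Equivalent degrees of freedom (including intercept) for the
#'   `L`, `M` and `S` curves (defaults 2, 4, 3).
#' @param age_offset Offset (years) inside the log-age transform
#'   (default 0.25).
#' @param maxit Maximum optimizer iterations.
#' @return An object of class `lms_model` with [print()], [summary()],
#'   [coef()], [predict()], [plot()], [simulate()], [residuals()] and
#'   [fitted()] methods.
#' @export
#' @examples
#' set.seed(1)
#' age <- runif(120, 0, 20)
#' y <- 100 * exp(0.1 * rnorm(120))   # lognormal, constant M = 100
#' m <- fit_lms(y, age)
#' predict(m, newages = c(1, 5, 10))  # fitted medians
fit_lms <- function(values, ages, df = c(L = 2, M = 4, S = 3),
                    age_offset = 0.25, maxit = 1000) {
  y <- as.numeric(values); age <- as.numeric(ages)
  if (length(y) != length(age)) stop("values and ages differ in length")
  ok <- is.finite(y) & is.finite(age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 30) stop("at least 30 (value, age) pairs are required")
  if (any(y <= 0)) stop("LMS requires strictly positive values")
  if (stats::sd(y) == 0) stop("degenerate constant data: zero variance")
  t <- log(age + age_offset)
  df <- c(L = df[[1]], M = df[[2]], S = df[[3]])

  bL <- lms_basis(t, df["L"]); bM <- lms_basis(t, df["M"])
  bS <- lms_basis(t, df["S"])
  BL <- lms_design(bL, t); BM <- lms_design(bM, t); BS <- lms_design(bS, t)
  iL <- seq_len(ncol(BL))
  iM <- max(iL) + seq_len(ncol(BM))
  iS <- max(iM) + seq_len(ncol(BS))

  logy <- log(y)
  nll <- function(par) {
    L <- drop(BL %*% par[iL])
    lm_ <- pmin(pmax(drop(BM %*% par[iM]), -40), 40)
    ls_ <- pmin(pmax(drop(BS %*% par[iS]), -20), 10)
    lr <- logy - lm_                       # log(y/M)
    S <- exp(ls_)
    z <- ifelse(abs(L) < 1e-7, lr / S, (exp(L * lr) - 1) / (L * S))
    v <- 0.5 * z^2 + ls_ - L * lr
    if (any(!is.finite(v))) return(1e10)
    sum(v)
  }

  cM <- stats::coef(stats::lm.fit(BM, logy))
  res <- logy - drop(BM %*% cM)
  par0 <- numeric(max(iS))
  par0[iL[1]] <- 1
  par0[iM] <- cM
  par0[iS[1]] <- log(max(stats::sd(res), 1e-4))
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 5000))
    if (opt2$value < opt$value) opt <- opt2
  }
  if (opt$convergence != 0)
    warning("LMS fit did not fully converge (optim code ",
            opt$convergence, ", nll ", signif(opt$value, 8), ")")

  ll <- -opt$value - sum(logy) - length(y) * 0.5 * log(2 * pi)
  m <- structure(list(
    par = opt$par, idx = list(L = iL, M = iM, S = iS),
    bases = list(L = bL, M = bM, S = bS), df = df,
    age_offset = age_offset, age_range = range(age),
    n = length(y), logLik = ll, convergence = opt$convergence,
    data = list(values = y, ages = age)), class = "lms_model")
  m
}

# Evaluate L(t), M(t), S(t) at given ages.
lms_eval <- function(model, ages) {
  t <- log(ages + model$age_offset)
  L <- drop(lms_design(model$bases$L, t) %*% model$par[model$idx$L])
  M <- exp(drop(lms_design(model$bases$M, t) %*% model$par[model$idx$M]))
  S <- exp(drop(lms_design(model$bases$S, t) %*% model$par[model$idx$S]))
  list(L = L, M = M, S = S)
}

#' LMS z-score
#'
#' Transforms a measurement at a given age to its standard-normal z-score
#' under the fitted reference model; continuous in `L` at `L = 0`.
#'
#' @param model An [fit_lms()] model.
#' @param age Age(s) in years.
#' @param value Positive measurement(s).
#' @return z-score(s).
#' @export
lms_zscore <- function(model, age, value) {
  if (any(value <= 0)) stop("values must be > 0")
  if (any(age < model$age_range[1] - 1e-9 |
          age > model$age_range[2] + 1e-9))
    warning("age outside the fitted range: extrapolating reference curves")
  p <- lms_eval(model, age)
  lr <- log(value / p$M)
  ifelse(abs(p$L) < 1e-7, lr / p$S,
         (exp(p$L * lr) - 1) / (p$L * p$S))
}

#' LMS centile value
#'
#' Inverse transform: the measurement value at a given age whose
#' cumulative reference probability is `alpha`. `alpha = 0.5` returns the
#' median curve `M(t)` exactly.
#'
#' @param model An [fit_lms()] model.
#' @param age Age(s) in years.
#' @param alpha Probability in (0, 1).
#' @return Measurement value(s) on the original scale.
#' @export
lms_percentile <- function(model, age, alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  p <- lms_eval(model, age)
  z <- stats::qnorm(alpha)
  arg <- 1 + p$L * p$S * z
  ifelse(abs(p$L) < 1e-7, p$M * exp(p$S * z),
         p$M * pmax(arg, 1e-12)^(1 / ifelse(p$L == 0, 1, p$L)))
}

#' @export
print.lms_model <- function(x, ...) {
  cat(sprintf("LMS reference model: n = %d, ages %.2g-%.3g y\n",
              x$n, x$age_range[1], x$age_range[2]))
  cat(sprintf("  df (L, M, S) = (%d, %d, %d), log-likelihood %.2f\n",
              x$df["L"], x$df["M"], x$df["S"], x$logLik))
  p <- lms_eval(x, x$age_range)
  cat(sprintf("  M: %.4g -> %.4g   S: %.3g -> %.3g   L: %.3g -> %.3g\n",
              p$M[1], p$M[2], p$S[1], p$S[2], p$L[1], p$L[2]))
  invisible(x)
}

#' @export
summary.lms_model <- function(object, ages = NULL, ...) {
  if (is.null(ages))
    ages <- seq(object$age_range[1], object$age_range[2], length.out = 7)
  p <- lms_eval(object, ages)
  z <- residuals(object)
  structure(list(model = object,
                 table = data.frame(age = ages, L = p$L, M = p$M, S = p$S),
                 z_mean = mean(z), z_sd = stats::sd(z)),
            class = "summary.lms_model")
}

#' @export
print.summary.lms_model <- function(x, ...) {
  print(x$model)
  cat("\nCurve values:\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("\nTraining z-scores: mean %.3f, sd %.3f\n", x$z_mean, x$z_sd))
  invisible(x)
}

#' @export
coef.lms_model <- function(object, ...) {
  list(L = object$par[object$idx$L], M = object$par[object$idx$M],
       S = object$par[object$idx$S])
}

#' Predict from an LMS model
#'
#' @param object An `lms_model`.
#' @param newages Ages in years (defaults to the training ages).
#' @param type `"median"` (the M curve), `"centile"` (value at probability
#'   `alpha`) or `"zscore"` (requires `values`).
#' @param alpha Centile probability for `type = "centile"`.
#' @param values Measurements for `type = "zscore"`.
#' @param ... Unused.
#' @export
predict.lms_model <- function(object, newages = NULL,
                              type = c("median", "centile", "zscore"),
                              alpha = 0.5, values = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newages)) newages <- object$data$ages
  switch(type,
         median = lms_eval(object, newages)$M,
         centile = lms_percentile(object, newages, alpha),
         zscore = {
           if (is.null(values)) stop("type = 'zscore' needs values")
           lms_zscore(object, newages, values)
         })
}

#' @export
fitted.lms_model <- function(object, ...)
  lms_eval(object, object$data$ages)$M

#' @export
residuals.lms_model <- function(object, ...)
  lms_zscore(object, object$data$ages, object$data$values)

#' @export
simulate.lms_model <- function(object, nsim = 1, seed = NULL,
                               ages = NULL, ...) {
  if (is.null(ages)) ages <- object$data$ages
  with_seed(seed, {
    out <- as.data.frame(lapply(seq_len(nsim), function(i) {
      z <- stats::rnorm(length(ages))
      p <- lms_eval(object, ages)
      arg <- pmax(1 + p$L * p$S * z, 1e-12)
      ifelse(abs(p$L) < 1e-7, p$M * exp(p$S * z), p$M * arg^(1 / p$L))
    }))
    names(out) <- paste0("sim_", seq_len(nsim))
    attr(out, "ages") <- ages
    out
  })
}

#' Centile fan plot of an LMS model
#'
#' @param x An `lms_model`.
#' @param alphas Centiles to draw.
#' @param n_grid Age grid resolution.
#' @param points Overlay the training data.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lms_model <- function(x, alphas = c(.03, .10, .25, .50, .75, .90, .97),
                           n_grid = 200, points = TRUE, ...) {
  ages <- seq(x$age_range[1], x$age_range[2], length.out = n_grid)
  cent <- sapply(alphas, function(a) lms_percentile(x, ages, a))
  graphics::matplot(ages, cent, type = "l", lty = 1,
                    col = grDevices::grey(abs(alphas - 0.5) + 0.2),
                    xlab = "age (years)", ylab = "value", ...)
  if (points)
    graphics::points(x$data$ages, x$data$values, pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("steelblue", 0.5))
  graphics::mtext(sprintf("centiles: %s",
                          paste(round(100 * alphas), collapse = "/")),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Centile table over an age grid
#'
#' @param model An `lms_model`.
#' @param ages Age grid (years).
#' @param alphas Centile probabilities.
#' @return Data frame: age plus one column per centile (`p3`, `p10`, ...).
#' @export
centile_table <- function(model, ages = NULL,
                          alphas = c(.03, .10, .25, .50, .75, .90, .97)) {
  if (is.null(ages))
    ages <- seq(model$age_range[1], model$age_range[2], length.out = 61)
  out <- data.frame(age = ages)
  for (a in alphas)
    out[[sprintf("p%g", 100 * a)]] <- lms_percentile(model, ages, a)
  out
}
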