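# Equilibrium 2AP titration: control subtraction and hyperbolic K_d fits.

#' Construct a titration dataset
#'
#' @param points data frame with columns \code{conc} (polymerase
#'   concentration, nM, strictly increasing, ≥ 0) and \code{fluor}
#'   (fluorescence, a.u.).
#' @param control optional matched control series (same concentrations) from
#'   the non-fluorescent probe experiment.
#' @param probe_conc probe (2AP primer/template) concentration in nM.
#' @return object of class \code{titration_dataset}.
#' @export
titration_dataset <- function(points, control = NULL, probe_conc = NA_real_) {
  points <- as.data.frame(points)[, c("conc", "fluor")]
  if (any(points$conc < 0)) stop("concentrations must be >= 0")
  if (is.unsorted(points$conc, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (!is.null(control)) {
    control <- as.data.frame(control)[, c("conc", "fluor")]
    if (nrow(control) != nrow(points) ||
        any(abs(control$conc - points$conc) > 1e-9))
      stop("alignment error: control concentrations do not match the data")
  }
  structure(list(points = points, control = control, probe_conc = probe_conc),
            class = "titration_dataset")
}

#' Subtract the matched control series
#'
#' Pointwise fluorescence minus control fluorescence (protein background);
#' concentrations unchanged.
#'
#' @param data a \code{\link{titration_dataset}} with a control.
#' @return data frame \code{conc}, \code{fluor} of corrected points.
#' @export
correct_fluorescence <- function(data) {
  if (is.null(data$control))
    stop("alignment error: dataset has no control series")
  data.frame(conc = data$points$conc,
             fluor = data$points$fluor - data$control$fluor)
}

# shared machinery for the two hyperbolic fits: y = ymax * x / (K + x)
.fit_hyperbola <- function(x, y, pname = c("Kd", "Fmax")) {
  ok <- x > 0
  if (length(unique(x[ok])) < 3L)
    stop("need at least 3 distinct positive concentrations")
  if (all(abs(y) < .Machine$double.eps * 100))
    stop("degenerate data: signal is identically zero")
  # direction: binding may raise or quench the signal; fit on the dominant sign
  sgn <- if (sum(y * x) >= 0) 1 else -1
  ys <- sgn * y
  ymax0 <- max(ys)
  k0 <- x[which.min(abs(ys - ymax0 / 2))]
  if (k0 <= 0) k0 <- median(x[ok])
  df <- data.frame(x = x, ys = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ ymax * x / (k + x), data = df,
                      start = list(ymax = ymax0, k = k0),
                      lower = c(-Inf, .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-13,
                                                           ptol = 1e-13)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(k = NA_real_, ymax = NA_real_, se = c(NA_real_, NA_real_),
                rss = NA_real_, converged = FALSE, sgn = sgn, fit = NULL,
                diagnostics = conditionMessage(fit), data = df))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  list(k = unname(cf["k"]), ymax = unname(cf["ymax"]),
       se = c(k = unname(se["k"]), ymax = unname(se["ymax"])),
       rss = sum(residuals(fit)^2), converged = fit$convInfo$isConv,
       sgn = sgn, fit = fit, diagnostics = NULL, data = df)
}

#' Fit an equilibrium dissociation constant
#'
#' Unweighted nonlinear least squares of the binding hyperbola
#' \deqn{F = F_{max} [pol] / (K_d + [pol])}
#' to control-corrected fluorescence. Replicate measurements at the same
#' concentration are averaged before fitting; the concentration entering the
#' model is total added polymerase (no ligand-depletion correction), matching
#' the standard reporting convention for these titrations. A
#' depletion-corrected quadratic model is available via
#' \code{model = "quadratic"} (requires \code{probe_conc}).
#'
#' @param data a \code{\link{titration_dataset}} (control subtracted
#'   automatically when present) or a data frame with \code{conc} (nM) and
#'   \code{fluor}.
#' @param model \code{"hyperbola"} (default) or \code{"quadratic"}.
#' @param probe_conc probe concentration (nM) for the quadratic model;
#'   taken from the dataset when available.
#' @return object of class \code{kd_fit}: \code{kd}, \code{fmax} (signed as
#'   the data: negative for quenching), standard errors, residual sum of
#'   squares, convergence flag, and the underlying \code{nls} fit.
#' @export
fit_kd <- function(data, model = c("hyperbola", "quadratic"),
                   probe_conc = NULL) {
  model <- match.arg(model)
  if (inherits(data, "titration_dataset")) {
    probe_conc <- probe_conc %||% data$probe_conc
    df <- if (!is.null(data$control)) correct_fluorescence(data) else data$points
  } else df <- as.data.frame(data)[, c("conc", "fluor")]
  # replicate averaging before fitting
  df <- aggregate(fluor ~ conc, data = df, FUN = mean)
  df <- df[order(df$conc), ]
  if (model == "quadratic") {
    if (is.null(probe_conc) || !is.finite(probe_conc))
      stop("quadratic (depletion-corrected) model needs probe_conc")
    return(.fit_kd_quadratic(df, probe_conc))
  }
  h <- .fit_hyperbola(df$conc, df$fluor)
  structure(list(kd = h$k, fmax = h$sgn * h$ymax,
                 se = c(kd = unname(h$se["k"]), fmax = unname(h$se["ymax"])),
                 rss = h$rss, converged = h$converged, direction = h$sgn,
                 model = "hyperbola", fit = h$fit,
                 diagnostics = h$diagnostics,
                 data = data.frame(conc = df$conc, fluor = df$fluor)),
            class = "kd_fit")
}

.fit_kd_quadratic <- function(df, probe) {
  sgn <- if (sum(df$fluor * df$conc) >= 0) 1 else -1
  ys <- sgn * df$fluor
  frac <- function(conc, kd) {
    b <- conc + probe + kd
    (b - sqrt(b^2 - 4 * conc * probe)) / (2 * probe)
  }
  fit <- minpack.lm::nlsLM(ys ~ ymax * frac(conc, kd),
                           data = cbind(df, ys = ys),
                           start = list(ymax = max(ys),
                                        kd = max(df$conc[which.min(abs(ys - max(ys) / 2))],
                                                 1e-6)),
                           lower = c(-Inf, .Machine$double.eps))
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  structure(list(kd = unname(cf["kd"]), fmax = sgn * unname(cf["ymax"]),
                 se = c(kd = unname(se["kd"]), fmax = unname(se["ymax"])),
                 rss = sum(residuals(fit)^2),
                 converged = fit$convInfo$isConv, direction = sgn,
                 model = "quadratic", fit = fit, diagnostics = NULL,
                 data = df),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("kd_fit: NOT CONVERGED —", x$diagnostics %||% "see $fit", "\n")
    return(invisible(x))
  }
  cat(sprintf("kd_fit (%s): K_d = %.3g +/- %.2g nM, F_max = %.4g +/- %.2g\n",
              x$model, x$kd, x$se["kd"], x$fmax, x$se["fmax"]))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd, fmax = object$fmax)

#' @export
summary.kd_fit <- function(object, ...) {
  tab <- data.frame(estimate = c(object$kd, object$fmax),
                    std_error = unname(object$se),
                    row.names = c("K_d (nM)", "F_max"))
  structure(list(coefficients = tab, rss = object$rss,
                 converged = object$converged, model = object$model,
                 n = nrow(object$data)),
            class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic titration fit (%s model), %d points\n", x$model, x$n))
  print(x$coefficients)
  cat(sprintf("RSS %.4g; converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$fmax * conc / (object$kd + conc)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$fluor - predict(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  plot(x$data$conc, x$data$fluor, xlab = "[pol] (nM)",
       ylab = "corrected fluorescence (a.u.)",
       main = sprintf("K_d = %.3g nM", x$kd), ...)
  cs <- seq(0, max(x$data$conc), length.out = 200)
  lines(cs, predict(x, data.frame(conc = cs)))
  abline(v = x$kd, lty = 3)
  invisible(x)
}

#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sdres <- sd(residuals(object))
  with_seed(seed, replicate(nsim, simplify = FALSE, {
    data.frame(conc = object$data$conc,
               fluor = predict(object) + rnorm(nrow(object$data), 0, sdres))
  }))
}
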