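# Single-nucleotide insertion Michaelis-Menten kinetics and derived ratios.

#' Construct a velocity dataset
#'
#' @param points data frame with columns \code{conc} (dNTP, µM) and \code{v}
#'   (rate, nM/min), optionally \code{replicate}.
#' @param variant,template_base,dntp metadata: variant label, template base
#'   (\code{"G"} or \code{"8-oxoG"}), nucleotide (\code{"dCTP"} or
#'   \code{"dATP"}).
#' @return object of class \code{velocity_dataset}.
#' @export
velocity_dataset <- function(points, variant = NA_character_,
                             template_base = NA_character_,
                             dntp = NA_character_) {
  points <- as.data.frame(points)
  if (!"replicate" %in% names(points)) points$replicate <- 1L
  points <- points[, c("conc", "v", "replicate")]
  if (any(points$conc < 0)) stop("concentrations must be >= 0")
  if (any(points$v < 0)) stop("rates must be >= 0")
  for (r in split(points$conc, points$replicate))
    if (is.unsorted(r, strictly = TRUE))
      stop("concentrations must be strictly increasing within a replicate")
  structure(list(points = points,
                 metadata = list(variant = variant,
                                 template_base = template_base, dntp = dntp)),
            class = "velocity_dataset")
}

#' Fit Michaelis–Menten insertion kinetics
#'
#' Unweighted nonlinear least squares of
#' \deqn{v = V_{max} [dNTP] / (K_m + [dNTP])}
#' to replicate-averaged rates. Parameter uncertainties are reported as the
#' standard errors from the fit covariance (the table convention
#' "mean ± standard deviation" of the fitted parameter).
#'
#' @param data a \code{\link{velocity_dataset}} or data frame with
#'   \code{conc} (µM) and \code{v} (nM/min); duplicates at the same
#'   concentration are averaged before fitting.
#' @return object of class \code{mm_fit}: \code{km} (µM), \code{vmax}
#'   (nM/min), their uncertainties, \code{efficiency}
#'   (\eqn{V_{max}/K_m} with \eqn{K_m} in mM), metadata, convergence flag
#'   and the underlying \code{nls} fit. Non-convergence or a non-positive
#'   fitted parameter yields a flagged (unconverged) fit, never a silent
#'   fallback.
#' @export
fit_michaelis_menten <- function(data) {
  meta <- list(variant = NA_character_, template_base = NA_character_,
               dntp = NA_character_)
  if (inherits(data, "velocity_dataset")) {
    meta <- data$metadata
    df <- data$points
  } else df <- as.data.frame(data)
  df <- aggregate(v ~ conc, data = df[, c("conc", "v")], FUN = mean)
  df <- df[order(df$conc), ]
  if (diff(range(df$v[df$conc > 0])) < 1e-12 * max(abs(df$v), 1))
    return(.mm_flagged(meta, "K_m unidentifiable: rates do not vary with [dNTP]"))
  h <- tryCatch(.fit_hyperbola(df$conc, df$v), error = function(e) e)
  if (inherits(h, "error")) return(.mm_flagged(meta, conditionMessage(h)))
  if (!isTRUE(h$converged) || is.na(h$k))
    return(.mm_flagged(meta, h$diagnostics %||% "solver did not converge"))
  if (h$k <= 0 || h$sgn * h$ymax <= 0)
    return(.mm_flagged(meta, sprintf(
      "non-positive fitted parameter (K_m = %.3g, V_max = %.3g)",
      h$k, h$sgn * h$ymax)))
  structure(list(km = h$k, vmax = h$ymax,
                 sd = c(km = unname(h$se["k"]), vmax = unname(h$se["ymax"])),
                 efficiency = h$ymax / (h$k / 1000),
                 metadata = meta, rss = h$rss, converged = TRUE,
                 fit = h$fit, diagnostics = NULL,
                 data = data.frame(conc = df$conc, v = df$v)),
            class = "mm_fit")
}

.mm_flagged <- function(meta, msg) {
  structure(list(km = NA_real_, vmax = NA_real_,
                 sd = c(km = NA_real_, vmax = NA_real_),
                 efficiency = NA_real_, metadata = meta, rss = NA_real_,
                 converged = FALSE, fit = NULL, diagnostics = msg,
                 data = NULL),
            class = "mm_fit")
}

#' Michaelis–Menten parameters taken from a published table
#'
#' Wraps printed \eqn{K_m}/\eqn{V_{max}} values in the same class as
#' \code{\link{fit_michaelis_menten}} output so the derived-quantity
#' functions (\code{\link{catalytic_efficiency}}, \code{\link{fold_change}},
#' \code{\link{misinsertion_ratio}}) apply to either.
#'
#' @param km,vmax parameters (µM, nM/min).
#' @param km_sd,vmax_sd reported uncertainties.
#' @param variant,template_base,dntp metadata.
#' @return object of class \code{c("mm_params", "mm_fit")}.
#' @export
mm_params <- function(km, vmax, km_sd = NA_real_, vmax_sd = NA_real_,
                      variant = NA_character_, template_base = NA_character_,
                      dntp = NA_character_) {
  stopifnot(km > 0, vmax > 0)
  structure(list(km = km, vmax = vmax, sd = c(km = km_sd, vmax = vmax_sd),
                 efficiency = vmax / (km / 1000),
                 metadata = list(variant = variant,
                                 template_base = template_base, dntp = dntp),
                 rss = NA_real_, converged = TRUE, fit = NULL,
                 diagnostics = NULL, data = NULL),
            class = c("mm_params", "mm_fit"))
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("mm_fit: FLAGGED —", x$diagnostics, "\n")
    return(invisible(x))
  }
  with(x$metadata, cat(sprintf(
    "mm_fit%s: K_m = %.3g +/- %.2g uM, V_max = %.3g +/- %.2g nM/min, V_max/K_m = %.3g\n",
    if (is.na(variant)) "" else sprintf(" [%s %s/%s]", variant, template_base, dntp),
    x$km, x$sd["km"], x$vmax, x$sd["vmax"], x$efficiency)))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(km = object$km, vmax = object$vmax)

#' @export
summary.mm_fit <- function(object, ...) {
  tab <- data.frame(estimate = c(object$km, object$vmax),
                    std_error = unname(object$sd),
                    row.names = c("K_m (uM)", "V_max (nM/min)"))
  structure(list(coefficients = tab, efficiency = object$efficiency,
                 metadata = object$metadata, rss = object$rss,
                 converged = object$converged,
                 n = if (is.null(object$data)) 0L else nrow(object$data)),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit, %d averaged points\n", x$n))
  print(x$coefficients)
  cat(sprintf("V_max/K_m (K_m in mM): %.4g; converged: %s\n",
              x$efficiency, x$converged))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$vmax * conc / (object$km + conc)
}

#' @export
residuals.mm_fit <- function(object, ...) object$data$v - predict(object)

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$data$conc, x$data$v, xlab = "[dNTP] (uM)", ylab = "v (nM/min)",
       main = sprintf("K_m = %.3g uM, V_max = %.3g nM/min", x$km, x$vmax), ...)
  cs <- seq(0, max(x$data$conc), length.out = 200)
  lines(cs, predict(x, data.frame(conc = cs)))
  invisible(x)
}

#' Catalytic efficiency in table units
#'
#' \eqn{V_{max}} (nM/min) divided by \eqn{K_m} expressed in mM — the only
#' convention consistent with the published efficiency column (e.g.
#' 1.0 nM/min at \eqn{K_m} 88.2 µM gives 11). Full precision by default;
#' pass \code{digits} for 2-significant-figure table display.
#'
#' @param fit an \code{mm_fit}/\code{mm_params} (or a \eqn{K_m} in µM when
#'   \code{vmax} is given).
#' @param vmax optional \eqn{V_{max}} when \code{fit} is numeric.
#' @param digits optional significant digits for display rounding.
#' @return efficiency in nM·min⁻¹·mM⁻¹.
#' @export
catalytic_efficiency <- function(fit, vmax = NULL, digits = NULL) {
  eff <- if (inherits(fit, "mm_fit")) {
    if (!isTRUE(fit$converged)) stop("cannot derive efficiency from a flagged fit")
    fit$efficiency
  } else {
    stopifnot(is.numeric(fit), !is.null(vmax), fit > 0, vmax > 0)
    vmax / (fit / 1000)
  }
  if (!is.null(digits)) signif(eff, digits) else eff
}

.meta_matches <- function(a, b) {
  identical(a$metadata$template_base, b$metadata$template_base) &&
    identical(a$metadata$dntp, b$metadata$dntp)
}

#' Fold change of a kinetic quantity between two variants
#'
#' @param a,b \code{mm_fit}/\code{mm_params} objects for the same
#'   (template base, dNTP) condition (enforced unless \code{override}).
#' @param quantity \code{"vmax"}, \code{"km"} or \code{"efficiency"}.
#' @param override skip the metadata-match check.
#' @return ratio quantity(a) / quantity(b).
#' @export
fold_change <- function(a, b, quantity = c("vmax", "km", "efficiency"),
                        override = FALSE) {
  quantity <- match.arg(quantity)
  if (!override && !.meta_matches(a, b))
    stop("comparison error: (template base, dNTP) metadata differ; ",
         "use override = TRUE to compare anyway")
  get <- function(f) switch(quantity, vmax = f$vmax, km = f$km,
                            efficiency = f$efficiency)
  get(a) / get(b)
}

#' Misinsertion fidelity ratio
#'
#' Efficiency of incorrect insertion over efficiency of correct (dCTP)
#' insertion opposite the same template base.
#'
#' @param correct \code{mm_fit} for the correct (dCTP) insertion.
#' @param incorrect \code{mm_fit} for the incorrect insertion.
#' @return dimensionless fidelity ratio (0 when the incorrect efficiency
#'   is 0).
#' @export
misinsertion_ratio <- function(correct, incorrect) {
  if (!identical(correct$metadata$template_base,
                 incorrect$metadata$template_base))
    stop("comparison error: template bases differ")
  if (!is.na(correct$metadata$dntp) && correct$metadata$dntp != "dCTP")
    stop("comparison error: 'correct' fit must be the dCTP insertion")
  if (identical(incorrect$efficiency, 0)) return(0)
  incorrect$efficiency / correct$efficiency
}
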