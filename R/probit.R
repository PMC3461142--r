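#' Abbott control-mortality correction
#'
#' Rescales an observed mortality proportion for background mortality in the
#' controls: `p' = (p_obs - p_c) / (1 - p_c)`, clipped to `[0, 1]`.
#'
#' @param p_obs observed mortality proportion(s) in a treated group.
#' @param p_c control mortality proportion (must be < 1).
#' @return corrected mortality proportion(s).
#' @examples
#' abbott_correct(0.40, 0.20)  # 0.25
#' @export
abbott_correct <- function(p_obs, p_c) {
  if (any(p_c < 0) || any(p_c >= 1))
    stop("control mortality must be in [0, 1); p_c = 1 leaves no signal")
  if (any(p_obs < 0) || any(p_obs > 1))
    stop("observed mortality must be in [0, 1]")
  pmin(1, pmax(0, (p_obs - p_c) / (1 - p_c)))
}

#' Fit a probit dose-mortality curve
#'
#' Maximum-likelihood probit regression of mortality on log10 concentration
#' for one species at one census day:
#' `Phi^-1(mortality) = a + b * log10(dose)`.
#'
#' Replicates are pooled within each dose level (replicate is not a fitted
#' effect in an LC analysis); control mortality is averaged over the water
#' and vehicle controls for that species and day and removed with
#' [abbott_correct()] before fitting, and the controls themselves never
#' enter the regression. Fitting is iteratively reweighted least squares
#' (the probit-link GLM). Overdispersion relative to the binomial is
#' absorbed Finney-style: when the Pearson chi-square of the fit is
#' significant at 0.05 (`heterogeneity = "significant"`, the classical
#' convention and the default), the factor `h = max(1, X^2 / (k - 2))`
#' inflates the coefficient covariance and the confidence limits later
#' switch from normal to t critical values with `k - 2` degrees of
#' freedom; `"always"` inflates whenever `h > 1`, `"never"` disables the
#' factor.
#'
#' @param table an exposure table (see [read_exposure_table()]).
#' @param species species label to fit (may be omitted if the table holds a
#'   single species).
#' @param day census day whose cumulative mortality is modelled.
#' @param correct_controls apply the Abbott correction (default) or fit raw
#'   mortalities.
#' @param dose_scale use the `dose_measured` column when present
#'   (`"measured"`, default) or the nominal `dose` column (`"nominal"`).
#' @param heterogeneity when to apply the heterogeneity factor:
#'   `"significant"` (Pearson chi-square P < 0.05), `"always"`, or
#'   `"never"`.
#' @return an object of class `"probit_lc"` with components `coefficients`
#'   (`a`, `b`), `vcov` (heterogeneity-inflated), `h`, `k`, `N`, `df`,
#'   `control_mortality`, `converged`, `species`, `day`.
#' @seealso [lc()] for LC estimates with Fieller limits, [predict.probit_lc()]
#'   for the fitted curve.
#' @examples
#' cfg <- sim_config(seed = 1)
#' tab <- simulate_dose_response(cfg)
#' fit <- probit_lc(tab, day = 4)
#' coef(fit)
#' lc(fit, p = 0.5)
#' @export
probit_lc <- function(table, species = NULL, day = 4,
                      correct_controls = TRUE,
                      dose_scale = c("measured", "nominal"),
                      heterogeneity = c("significant", "always", "never")) {
  dose_scale <- match.arg(dose_scale)
  heterogeneity <- match.arg(heterogeneity)
  table <- validate_exposure_table(table)
  if (is.null(species)) {
    species <- unique(table$species)
    if (length(species) != 1L)
      stop("table holds several species; name one")
  }
  rows <- table$species == species & table$day == day
  if (!any(rows)) stop("no rows for species '", species, "' at day ", day)
  tab <- table[rows, , drop = FALSE]

  dose <- if (dose_scale == "measured" && "dose_measured" %in% names(tab))
    tab$dose_measured else tab$dose

  ctrl <- tab$control_kind != "none"
  p_c <- 0
  if (correct_controls) {
    if (!any(ctrl)) stop("no control rows to estimate background mortality")
    p_c <- 1 - sum(tab$alive[ctrl]) / sum(tab$total[ctrl])
    if (p_c >= 1) stop("degenerate controls: 100% control mortality")
  }

  # pool replicates within dose level
  d <- dose[!ctrl]
  dead <- tapply(tab$total[!ctrl] - tab$alive[!ctrl], d, sum)
  tot <- tapply(tab$total[!ctrl], d, sum)
  lev <- as.numeric(names(tot))
  if (any(lev <= 0)) stop("non-control rows must have positive dose")
  p_corr <- abbott_correct(dead / tot, p_c)

  k <- length(lev)
  if (k < 2L) stop("insufficient data: need >= 2 nonzero dose levels")
  if (all(p_corr %in% c(0, 1)))
    stop("non-estimable: every dose level shows 0% or 100% corrected ",
         "mortality (complete separation)")

  x <- log10(lev)
  fit <- stats::glm(p_corr ~ x, family = stats::quasibinomial("probit"),
                    weights = tot)
  s <- summary(fit)
  X2 <- sum(stats::residuals(fit, type = "pearson")^2)
  overdispersed <- switch(heterogeneity,
    never = FALSE,
    always = k > 2L && X2 / (k - 2L) > 1,
    significant = k > 2L &&
      stats::pchisq(X2, df = k - 2L, lower.tail = FALSE) < 0.05)
  h <- if (overdispersed) max(1, X2 / (k - 2L)) else 1
  V <- s$cov.unscaled * h
  dimnames(V) <- list(c("a", "b"), c("a", "b"))

  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("a", "b")),
                 vcov = V, h = h, k = k, N = sum(tot),
                 df = max(k - 2L, 1L),
                 control_mortality = p_c,
                 converged = isTRUE(fit$converged),
                 species = species, day = day,
                 dose = lev, mortality = as.numeric(p_corr)),
            class = "probit_lc")
}

#' @export
print.probit_lc <- function(x, ...) {
  cat("Probit dose-mortality fit:", x$species,
      sprintf("(day %d)\n", x$day))
  cat(sprintf("  probit(mortality) = %.4f + %.4f log10(dose ppb)\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  %d dose levels, %d animals; control mortality %.3f\n",
              x$k, x$N, x$control_mortality))
  if (x$h > 1)
    cat(sprintf("  heterogeneity factor %.2f (limits use t, %d df)\n",
                x$h, x$df))
  invisible(x)
}

#' @export
coef.probit_lc <- function(object, ...) object$coefficients

#' @export
vcov.probit_lc <- function(object, ...) object$vcov

#' Predicted mortality at a concentration
#'
#' Evaluates the fitted curve `Phi(a + b log10(dose))`. At `dose = LC50`
#' the prediction is 0.5 by construction.
#'
#' @param object a [probit_lc()] fit.
#' @param dose concentration(s), ppb, strictly positive.
#' @param ... unused.
#' @return predicted mortality proportion(s).
#' @export
predict.probit_lc <- function(object, dose, ...) {
  if (any(dose <= 0)) stop("dose must be positive")
  ab <- object$coefficients
  stats::pnorm(ab[[1]] + ab[[2]] * log10(dose))
}
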