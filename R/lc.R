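#' LC estimate with Fieller confidence limits
#'
#' Inverts a probit fit at mortality level `p`: the point estimate is
#' `10^m` with `m = (Phi^-1(p) - a) / b`, and the confidence limits come
#' from Fieller's theorem for the ratio `(Phi^-1(p) - a) / b` using the
#' heterogeneity-inflated covariance of `(a, b)`, back-transformed through
#' `10^m`. The default 84% level is the one whose interval-overlap rule
#' approximates a 0.05 pairwise test; its normal critical value is
#' `qnorm(0.92) ~ 1.4051`. When the fit is overdispersed (`h > 1`) a t
#' critical value with `k - 2` degrees of freedom replaces the normal one.
#'
#' If the Fieller condition fails (`g >= 1`, a slope indistinguishable from
#' zero at this confidence) the interval is unbounded: limits are returned
#' as `NA` and the estimate is flagged, never truncated.
#'
#' @param fit a [probit_lc()] fit.
#' @param p mortality level in (0, 1): 0.5 for the LC50.
#' @param conf confidence level of the limits.
#' @return an object of class `"lc_estimate"`: `p`, `point`, `ci_low`,
#'   `ci_high`, `conf`, `duration_days`, `species`, `adjusted`, `unbounded`,
#'   `g`.
#' @export
lc <- function(fit, p = 0.5, conf = 0.84) {
  stopifnot(inherits(fit, "probit_lc"))
  if (!fit$converged) stop("probit fit did not converge")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  V <- fit$vcov
  xi <- stats::qnorm(p)
  crit <- if (fit$h > 1) stats::qt(1 - (1 - conf) / 2, df = fit$df)
          else stats::qnorm(1 - (1 - conf) / 2)

  # Fieller for rho = num/den with num = xi - a, den = b:
  # roots of (num - rho den)^2 = crit^2 Var(num - rho den)
  num <- xi - a; den <- b
  v_num <- V[1, 1]          # Var(xi - a) = Var(a)
  v_den <- V[2, 2]
  c_nd <- -V[1, 2]          # Cov(xi - a, b)
  g <- crit^2 * v_den / den^2
  m <- num / den
  A <- den^2 - crit^2 * v_den
  B <- -2 * (num * den - crit^2 * c_nd)
  C <- num^2 - crit^2 * v_num
  disc <- B^2 - 4 * A * C
  if (g < 1 && disc >= 0) {
    roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    ci <- 10^roots
    unbounded <- FALSE
  } else {
    ci <- c(NA_real_, NA_real_)
    unbounded <- TRUE
  }
  structure(list(p = p, point = 10^m, ci_low = ci[1], ci_high = ci[2],
                 conf = conf, duration_days = fit$day,
                 species = fit$species, adjusted = FALSE,
                 unbounded = unbounded, g = g),
            class = "lc_estimate")
}

#' Construct an LC estimate from published numbers
#'
#' Wraps a point estimate and confidence limits (e.g. a row of
#' [species_lc_table()]) in the `"lc_estimate"` class so the downstream
#' overlap tests treat packaged and freshly fitted estimates alike.
#'
#' @param point point estimate (ppb).
#' @param ci_low,ci_high confidence limits (ppb).
#' @param p mortality level in (0, 1).
#' @param conf confidence level of the limits.
#' @param duration_days exposure duration the estimate refers to.
#' @param species optional species label.
#' @return an `"lc_estimate"` object.
#' @export
lc_estimate <- function(point, ci_low, ci_high, p = 0.5, conf = 0.84,
                        duration_days = NA_integer_, species = NA_character_) {
  if (is.na(ci_low) || is.na(ci_high)) {
    unbounded <- TRUE
  } else {
    if (!(ci_low <= point && point <= ci_high))
      stop("limits must bracket the point estimate")
    unbounded <- FALSE
  }
  structure(list(p = p, point = point, ci_low = ci_low, ci_high = ci_high,
                 conf = conf, duration_days = duration_days,
                 species = species, adjusted = FALSE, unbounded = unbounded,
                 g = NA_real_),
            class = "lc_estimate")
}

#' @export
print.lc_estimate <- function(x, ...) {
  lab <- sprintf("LC%g", 100 * x$p)
  dur <- if (is.na(x$duration_days)) "" else sprintf(" %d-d", x$duration_days)
  sp <- if (is.na(x$species)) "" else paste0(x$species, " ")
  if (x$unbounded)
    cat(sprintf("%s%s%s = %.3g ppb (interval unbounded, g >= 1)\n",
                sp, lab, dur, x$point))
  else
    cat(sprintf("%s%s%s = %.3g ppb (%d%% CI %.3g, %.3g)%s\n",
                sp, lab, dur, x$point, round(100 * x$conf), x$ci_low,
                x$ci_high, if (x$adjusted) " [adjusted]" else ""))
  invisible(x)
}

#' Enforce non-decreasing mortality between census days
#'
#' Post-exposure mortality cannot fall, so an 8-day LC estimate above its
#' 4-day counterpart is an artefact of control-mortality differences. If
#' `lc8` exceeds `lc4`, the 4-day estimate is returned in its place with
#' `adjusted = TRUE`; otherwise `lc8` is returned unchanged.
#'
#' @param lc4,lc8 `"lc_estimate"` objects at the same level `p` for the
#'   same species.
#' @return an `"lc_estimate"`.
#' @export
enforce_monotone_lag <- function(lc4, lc8) {
  stopifnot(inherits(lc4, "lc_estimate"), inherits(lc8, "lc_estimate"))
  if (!isTRUE(all.equal(lc4$p, lc8$p)))
    stop("estimates are at different mortality levels")
  if (!is.na(lc4$species) && !is.na(lc8$species) &&
      lc4$species != lc8$species)
    stop("estimates are for different species")
  if (lc8$point <= lc4$point) return(lc8)
  out <- lc4
  out$duration_days <- lc8$duration_days
  out$adjusted <- TRUE
  out
}

#' LC summary table for one fitted curve
#'
#' @param fit a [probit_lc()] fit.
#' @param levels LC levels as percentages.
#' @param conf confidence level.
#' @return a data frame mirroring the packaged fixture layout: `species`,
#'   `level`, `duration_days`, `estimate`, `ci_low`, `ci_high`, `adjusted`.
#' @export
lc_summary <- function(fit, levels = c(10, 50, 90), conf = 0.84) {
  rows <- lapply(levels, function(l) {
    e <- lc(fit, p = l / 100, conf = conf)
    data.frame(species = e$species, level = l,
               duration_days = e$duration_days, estimate = e$point,
               ci_low = e$ci_low, ci_high = e$ci_high,
               adjusted = e$adjusted)
  })
  do.call(rbind, rows)
}
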