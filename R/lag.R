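#' Confidence-interval overlap test for two LC estimates
#'
#' Declares two estimates significantly different exactly when their
#' confidence intervals are strictly disjoint; touching endpoints count as
#' overlap (not significant). With 84% intervals and comparable standard
#' errors this rule approximates a pairwise test at alpha = 0.05 (see
#' [overlap_alpha_calibration()]).
#'
#' @param e1,e2 `"lc_estimate"` objects at the same level and confidence.
#' @return `1L` if the intervals are disjoint, else `0L`.
#' @examples
#' a <- lc_estimate(2.8, 2.3, 3.4)
#' b <- lc_estimate(1.9, 1.7, 2.1)
#' ci_overlap_test(a, b)  # 1: disjoint
#' @export
ci_overlap_test <- function(e1, e2) {
  stopifnot(inherits(e1, "lc_estimate"), inherits(e2, "lc_estimate"))
  if (!isTRUE(all.equal(e1$conf, e2$conf)))
    stop("estimates carry different confidence levels")
  if (!isTRUE(all.equal(e1$p, e2$p)))
    stop("estimates are at different mortality levels")
  if (e1$unbounded || e2$unbounded) return(0L)
  as.integer(max(e1$ci_low, e2$ci_low) > min(e1$ci_high, e2$ci_high))
}

#' Code the mortality time lag as a binary character
#'
#' Applies [ci_overlap_test()] to the 4-day and 8-day LC50 of every species
#' in an LC table: state 1 marks a significant time lag (the 8-day interval
#' disjoint from, and below, no overlap with the 4-day one), state 0 marks
#' none.
#'
#' @param lc_table a table in the layout of [species_lc_table()], holding
#'   LC50 rows with confidence limits at both durations for every species.
#' @param conf confidence level the table's limits were computed at.
#' @return a named integer vector of 0/1 states keyed by species.
#' @examples
#' sum(lag_character(species_lc_table()))  # 7 of 15 species lag
#' @export
lag_character <- function(lc_table, conf = 0.84) {
  lc50 <- lc_table[lc_table$level == 50, , drop = FALSE]
  sp <- unique(lc50$species)
  states <- vapply(sp, function(s) {
    r4 <- lc50[lc50$species == s & lc50$duration_days == 4, , drop = FALSE]
    r8 <- lc50[lc50$species == s & lc50$duration_days == 8, , drop = FALSE]
    if (nrow(r4) != 1L || nrow(r8) != 1L)
      stop("species '", s, "' lacks an LC50 row at one duration")
    e4 <- lc_estimate(r4$estimate, r4$ci_low, r4$ci_high, conf = conf,
                      duration_days = 4L, species = s)
    e8 <- lc_estimate(r8$estimate, r8$ci_low, r8$ci_high, conf = conf,
                      duration_days = 8L, species = s)
    ci_overlap_test(e4, e8)
  }, integer(1))
  states
}

#' Type-I error of the interval-overlap rule
#'
#' Simulates pairs of independent, normally distributed point estimates
#' with equal true means, builds symmetric confidence intervals at the
#' given level, and returns the fraction of pairs judged different by the
#' disjoint-interval rule. At 84% confidence and equal standard errors the
#' exact rate is `2 * Phi(-2 * qnorm(0.92) / sqrt(2)) ~ 0.047`, close to a
#' nominal 0.05.
#'
#' @param n_sims number of simulated pairs (>= 1000).
#' @param se_ratio ratio of the second estimate's standard error to the
#'   first's.
#' @param confidence confidence level of the intervals.
#' @param seed integer seed.
#' @return the simulated rejection rate.
#' @export
overlap_alpha_calibration <- function(n_sims = 1e5, se_ratio = 1,
                                      confidence = 0.84, seed = 1L) {
  if (n_sims < 1000) stop("n_sims must be >= 1000")
  if (se_ratio <= 0) stop("se_ratio must be positive")
  set.seed(seed)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  x1 <- stats::rnorm(n_sims)
  x2 <- stats::rnorm(n_sims, sd = se_ratio)
  # disjoint iff |x1 - x2| > z * (se1 + se2)
  mean(abs(x1 - x2) > z * (1 + se_ratio))
}
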