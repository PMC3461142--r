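#' Lowest observable effect concentration
#'
#' Finds the smallest tested concentration whose survival is significantly
#' lower than the water control by one-tailed Dunnett many-to-one
#' comparisons on per-replicate survival proportions. Familywise error is
#' held at `alpha` using the multivariate-t critical values computed (by
#' Monte Carlo, seed-controlled) in \pkg{multcomp}.
#'
#' Vehicle-control rows are excluded: the comparison is each dose against
#' the water control only.
#'
#' @param table an exposure table (see [read_exposure_table()]).
#' @param species species label (optional for single-species tables).
#' @param day census day.
#' @param alpha familywise error rate.
#' @param seed integer seed for the multivariate-t quantile computation.
#' @return the LOEC as a numeric dose (ppb), or `NA_real_` when no dose
#'   differs significantly from the control. The per-dose adjusted p-values
#'   are attached as `attr(, "p_values")`.
#' @export
loec <- function(table, species = NULL, day = 4, alpha = 0.05, seed = 1L) {
  table <- validate_exposure_table(table)
  if (is.null(species)) {
    species <- unique(table$species)
    if (length(species) != 1L) stop("table holds several species; name one")
  }
  tab <- table[table$species == species & table$day == day, , drop = FALSE]
  tab <- tab[tab$control_kind != "vehicle", , drop = FALSE]
  if (!any(tab$control_kind == "water"))
    stop("no water-control rows for species '", species, "'")
  if (!any(tab$control_kind == "none"))
    stop("no dose groups to compare")

  tab$surv <- tab$alive / tab$total
  # control first so Dunnett contrasts are dose - control
  tab$grp <- factor(tab$dose, levels = sort(unique(tab$dose)))
  if (stats::var(tab$surv) == 0) {
    out <- NA_real_
    attr(out, "p_values") <- stats::setNames(
      rep(1, nlevels(tab$grp) - 1L), levels(tab$grp)[-1L])
    return(out)
  }
  fit <- stats::aov(surv ~ grp, data = tab)
  set.seed(seed)
  cmp <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"),
                        alternative = "less")
  pv <- summary(cmp)$test$pvalues
  doses <- as.numeric(levels(tab$grp))[-1L]
  names(pv) <- doses
  sig <- doses[pv < alpha]
  out <- if (length(sig)) min(sig) else NA_real_
  attr(out, "p_values") <- pv
  out
}
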