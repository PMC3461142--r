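#' Packaged LC tables for 15 tadpole species
#'
#' Point estimates and 84% confidence limits of the endosulfan LC10, LC50 and
#' LC90 (ppb) for 15 species of North American tadpoles, after a 4-day
#' exposure and after a further 4 days in clean water (8-day values). Seven
#' species show a significant mortality time lag (disjoint 84% intervals of
#' the 4- and 8-day LC50); seven of the fifteen are estimates previously
#' published with the same assay design.
#'
#' @return a data frame with one row per species x level x duration:
#'   `species`, `level` (10/50/90), `duration_days` (4/8), `estimate`,
#'   `ci_low`, `ci_high` (all ppb), `lag_significant` (0/1, LC50 rows carry
#'   the published time-lag coding), `previously_published` (0/1).
#' @examples
#' lc <- species_lc_table()
#' subset(lc, species == "Rana_catesbeiana" & level == 50)
#' @export
species_lc_table <- function() {
  read_lc_fixture("table1_species_lc.csv")
}

#' Packaged LC table for six Rana sylvatica populations
#'
#' Endosulfan LC10/LC50/LC90 (ppb) with 84% confidence limits after a 2-day
#' exposure, for six wood-frog populations sampled at least 20 km apart.
#'
#' @return a data frame with columns `population`, `level`, `duration_days`,
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
population_lc_table <- function() {
  read_lc_fixture("table2_population_lc.csv")
}

read_lc_fixture <- function(name) {
  path <- system.file("extdata", name, package = "phylotox", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- tab$ci_low > tab$estimate | tab$estimate > tab$ci_high
  if (any(bad)) stop("corrupt fixture: CI does not bracket estimate")
  tab
}

#' Reference 15-species topologies
#'
#' Returns the packaged 15-taxon tree used by the comparative analyses. The
#' topology follows family-level anuran systematics (Bufonidae sister to the
#' hylids, ranids outside; *Hyla* sister to *Pseudacris* with *P. crucifer*
#' diverging first; ranids split into a western *R. boylii*/*R. aurora*/
#' *R. cascadae* clade and an eastern clade). Tip labels match
#' [species_lc_table()].
#'
#' * `"equal_length"` - the speciational tree: every branch length 1.
#' * `"mtdna_topology"` - the same topology standing in for the
#'   mitochondrial-DNA tree. The original maximum-likelihood branch lengths
#'   derive from GenBank sequence data and are not packaged, so unit lengths
#'   are used and the returned tree carries
#'   `attr(tree, "lengths_unavailable") = TRUE`; treat results on this tree
#'   as topology-only.
#'
#' The within-ranid placement of *R. sylvatica* (sister to the whole eastern
#' clade vs. sister to the *R. catesbeiana*/*R. clamitans* pair) is not
#' resolvable from the source figure; `alt = TRUE` returns the second
#' reading.
#'
#' @param kind which reference tree.
#' @param alt use the alternative within-ranid resolution.
#' @return a validated `"phylo"` object with 15 tips and 28 unit-length
#'   edges.
#' @examples
#' tr <- reference_tree()
#' ape::Ntip(tr)
#' @export
reference_tree <- function(kind = c("equal_length", "mtdna_topology"),
                           alt = FALSE) {
  kind <- match.arg(kind)
  file <- if (alt) "tree_equal_alt.nwk" else
    switch(kind, equal_length = "tree_equal.nwk",
           mtdna_topology = "tree_mtdna_topology.nwk")
  path <- system.file("extdata", file, package = "phylotox", mustWork = TRUE)
  tree <- read_tree(path)
  if (kind == "mtdna_topology") attr(tree, "lengths_unavailable") <- TRUE
  tree
}

#' Extract a per-species LC trait vector from an LC table
#'
#' @param lc_table a table in the layout of [species_lc_table()].
#' @param level LC level (10, 50 or 90).
#' @param duration_days exposure duration (4 or 8).
#' @param log10 return log10-transformed concentrations.
#' @return a named numeric vector (ppb) keyed by species.
#' @export
lc_trait <- function(lc_table, level = 50, duration_days = 4, log10 = FALSE) {
  rows <- lc_table$level == level & lc_table$duration_days == duration_days
  if (!any(rows)) stop("no rows at level ", level, ", duration ",
                       duration_days, " days")
  key <- if ("species" %in% names(lc_table)) "species" else "population"
  x <- stats::setNames(lc_table$estimate[rows], lc_table[[key]][rows])
  if (anyDuplicated(names(x))) stop("duplicate entries in LC table")
  if (log10) log10(x) else x
}
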