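#' Configuration for the synthetic mortality generator
#'
#' Bundles the experimental design and the generating truth for
#' [simulate_dose_response()]. The defaults mirror a standard acute
#' tadpole assay: six concentrations plus a water and a vehicle control,
#' two blocks with two replicate containers each, ten animals per
#' container, and nominal concentrations of 1-500 ppb. The default probit
#' truth `a = -3, b = 2` puts the 4-day LC50 at `10^1.5 ~ 31.6` ppb, in
#' the middle of the dose range.
#'
#' The time-lag mechanism is phenomenological: each 4-day survivor in a
#' treated unit dies before day 8 with the per-dose probability
#' `delayed_death` (recycled across doses). With all-zero `delayed_death`
#' day-8 mortality equals day-4 mortality in every unit.
#'
#' @param seed integer seed used by the generator.
#' @param doses nominal concentrations (ppb).
#' @param reps replicate containers per block.
#' @param blocks number of blocks.
#' @param animals_per_unit animals per container.
#' @param a,b probit intercept and slope (per log10 ppb).
#' @param control_mortality background mortality probability over 4 days.
#' @param delayed_death per-dose probability that a 4-day survivor dies
#'   during the clean-water phase.
#' @param species label written to the table.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, doses = c(1, 5, 10, 50, 100, 500),
                       reps = 2L, blocks = 2L, animals_per_unit = 10L,
                       a = -3, b = 2, control_mortality = 0.02,
                       delayed_death = 0, species = "synthetic_sp") {
  stopifnot(length(doses) >= 1, all(doses > 0),
            reps >= 1, blocks >= 1, animals_per_unit >= 1,
            control_mortality >= 0, control_mortality < 1,
            all(delayed_death >= 0), all(delayed_death <= 1))
  delayed_death <- rep_len(delayed_death, length(doses))
  structure(list(seed = as.integer(seed), doses = doses,
                 reps = as.integer(reps), blocks = as.integer(blocks),
                 animals_per_unit = as.integer(animals_per_unit),
                 a = a, b = b, control_mortality = control_mortality,
                 delayed_death = delayed_death, species = species),
            class = "sim_config")
}

#' Simulate a grouped binomial mortality experiment
#'
#' Draws an exposure table with the structure the probit pipeline assumes.
#' For each treated unit, 4-day deaths are binomial with mortality
#' `p_c + (1 - p_c) * Phi(a + b log10(dose))` (background and dose-driven
#' mortality act independently, so the Abbott correction is exact in
#' expectation); controls draw from the background rate alone. Day-8
#' deaths add a binomial draw among the 4-day survivors at the configured
#' per-dose delayed-death probability (controls use probability 0). The
#' output has one row per unit per census day (4 and 8).
#'
#' @param cfg a [sim_config()].
#' @return a validated exposure table (see [read_exposure_table()]).
#' @export
simulate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  units <- expand.grid(block = seq_len(cfg$blocks),
                       replicate = seq_len(cfg$reps),
                       dose_i = c(-2L, -1L, seq_along(cfg$doses)),
                       KEEP.OUT.ATTRS = FALSE)
  n_units <- nrow(units)
  rows <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    di <- units$dose_i[i]
    is_ctrl <- di < 0L
    dose <- if (is_ctrl) 0 else cfg$doses[di]
    kind <- if (di == -2L) "water" else if (di == -1L) "vehicle" else "none"
    p4 <- if (is_ctrl) cfg$control_mortality else
      cfg$control_mortality + (1 - cfg$control_mortality) *
        stats::pnorm(cfg$a + cfg$b * log10(dose))
    dead4 <- stats::rbinom(1, cfg$animals_per_unit, p4)
    alive4 <- cfg$animals_per_unit - dead4
    p_lag <- if (is_ctrl) 0 else cfg$delayed_death[di]
    alive8 <- alive4 - stats::rbinom(1, alive4, p_lag)
    rows[[i]] <- data.frame(
      species = cfg$species, population = "",
      dose = dose, control_kind = kind,
      replicate = units$replicate[i], block = units$block[i],
      day = c(4L, 8L), alive = c(alive4, alive8),
      total = cfg$animals_per_unit)
  }
  validate_exposure_table(do.call(rbind, rows))
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Gaussian increments along every branch with variance
#' `sigma2 * branch length`, accumulated from the root value.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root = 0, seed = 1L) {
  validate_tree(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  set.seed(seed)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  val <- numeric(nn)
  val[n + 1L] <- root
  for (e in rev(ape::postorder(tree)))   # preorder: parents first
    val[tree$edge[e, 2]] <- val[tree$edge[e, 1]] +
      stats::rnorm(1, 0, sqrt(sigma2 * tree$edge.length[e]))
  stats::setNames(val[seq_len(n)], tree$tip.label)
}

#' Simulate a binary character under the equal-rates Mk model
#'
#' Root state drawn from the stationary (1/2, 1/2); along each branch of
#' length t the state flips with probability `(1 - exp(-2qt))/2`.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param q transition rate (>= 0).
#' @param seed integer seed.
#' @return named integer vector of 0/1 tip states.
#' @export
simulate_mk_character <- function(tree, q = 0.2, seed = 1L) {
  validate_tree(tree)
  if (q < 0) stop("q must be >= 0")
  set.seed(seed)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  state <- integer(nn)
  state[n + 1L] <- stats::rbinom(1, 1, 0.5)
  for (e in rev(ape::postorder(tree))) {
    flip <- (1 - exp(-2 * q * tree$edge.length[e])) / 2
    parent <- state[tree$edge[e, 1]]
    state[tree$edge[e, 2]] <- if (stats::runif(1) < flip) 1L - parent
                              else parent
  }
  stats::setNames(state[seq_len(n)], tree$tip.label)
}
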