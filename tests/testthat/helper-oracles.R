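# Independent oracles used across the suite. Each reimplements a quantity by
# a different route than the package (enumeration, closed form, generic GLS)
# so agreement is evidence, not tautology.

# Mk likelihood by brute-force enumeration over all internal-node labelings.
brute_mk_loglik <- function(tree, char, q) {
  n <- ape::Ntip(tree)
  n_int <- tree$Nnode
  x <- as.integer(char[tree$tip.label])
  edges <- tree$edge
  lens <- tree$edge.length
  p_same <- (1 + exp(-2 * q * lens)) / 2
  total <- 0
  for (mask in 0:(2^n_int - 1)) {
    states <- c(x, as.integer(intToBits(mask))[seq_len(n_int)])
    pr <- 0.5  # root prior
    for (e in seq_len(nrow(edges))) {
      same <- states[edges[e, 1]] == states[edges[e, 2]]
      pr <- pr * if (same) p_same[e] else 1 - p_same[e]
    }
    total <- total + pr
  }
  log(total)
}

# Minimum number of changes by enumeration (oracle for Fitch).
brute_parsimony <- function(tree, char) {
  n <- ape::Ntip(tree)
  n_int <- tree$Nnode
  x <- as.integer(char[tree$tip.label])
  edges <- tree$edge
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    states <- c(x, as.integer(intToBits(mask))[seq_len(n_int)])
    best <- min(best, sum(states[edges[, 1]] != states[edges[, 2]]))
  }
  best
}

# Pooled-binomial probit log-likelihood on Abbott-corrected proportions;
# grid argmax is the fitting oracle.
probit_grid_fit <- function(dose, p_corr, total,
                            a_grid = seq(-6, 0, by = 0.02),
                            b_grid = seq(0.5, 4, by = 0.02)) {
  x <- log10(dose)
  ll_fun <- function(a, b) {
    mu <- pmin(pmax(pnorm(a + b * x), 1e-12), 1 - 1e-12)
    sum(total * (p_corr * log(mu) + (1 - p_corr) * log(1 - mu)))
  }
  best <- c(a = NA, b = NA); best_ll <- -Inf
  for (a in a_grid) for (b in b_grid) {
    ll <- ll_fun(a, b)
    if (ll > best_ll) { best_ll <- ll; best <- c(a = a, b = b) }
  }
  best
}

# Exact two-sample permutation test on unit survival (oracle for the LOEC
# Dunnett machinery on a single contrast).
perm_test_less <- function(treated, control, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- mean(treated) - mean(control)
  pooled <- c(treated, control)
  k <- length(treated)
  stat <- replicate(n_perm, {
    idx <- sample(length(pooled), k)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(stat <= obs)
}

# A reproducible random bifurcating tree with unit-ish branch lengths.
random_tree <- function(n, seed, lengths = c("runif", "one")) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- switch(match.arg(lengths),
                           runif = runif(nrow(tr$edge), 0.2, 2),
                           one = rep(1, nrow(tr$edge)))
  tr
}

random_binary_char <- function(tree, seed) {
  set.seed(seed)
  repeat {
    x <- stats::setNames(sample(0:1, ape::Ntip(tree), replace = TRUE),
                         tree$tip.label)
    if (length(unique(x)) == 2) return(x)
  }
}
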