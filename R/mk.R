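# Two-state equal-rates Markov (Mk) machinery for a binary character on a
# rooted bifurcating tree. Transition probability over a branch of length t:
# P(same) = (1 + exp(-2qt))/2, P(different) = (1 - exp(-2qt))/2; root prior
# is the stationary (1/2, 1/2).

MK_Q_MIN <- 1e-8
MK_Q_MAX <- 1e3

validate_binary_character <- function(tree, char) {
  x <- match_trait(tree, char, what = "character")
  if (!all(x %in% c(0, 1))) stop("character states must be 0 or 1")
  as.integer(x)
}

# Precomputed traversal structure, built once per tree and reused across
# likelihood evaluations (the permutation test performs tens of thousands).
mk_prep <- function(tree) {
  n <- ape::Ntip(tree)
  po <- ape::postorder(tree)
  list(n = n, nn = n + tree$Nnode,
       parent = tree$edge[, 1], kid = tree$edge[, 2],
       len = tree$edge.length, po = po, pre = rev(po))
}

mk_down <- function(x, q, pp) {
  down <- matrix(1, pp$nn, 2)
  down[cbind(seq_len(pp$n), 2L - x)] <- 0   # tip i certain in state x[i]
  w <- exp(-2 * q * pp$len)
  same <- (1 + w) / 2
  diff <- (1 - w) / 2
  for (e in pp$po) {
    p <- pp$parent[e]; k <- pp$kid[e]
    down[p, ] <- down[p, ] *
      c(same[e] * down[k, 1] + diff[e] * down[k, 2],
        diff[e] * down[k, 1] + same[e] * down[k, 2])
  }
  down
}

mk_ll <- function(x, q, pp) {
  log(sum(0.5 * mk_down(x, q, pp)[pp$n + 1L, ]))
}

# maximize over log q: the likelihood is flat in large q for saturated
# data, and a linear-scale golden search can stall on that plateau
mk_optimize <- function(x, pp) {
  opt <- stats::optimize(function(lq) mk_ll(x, exp(lq), pp),
                         c(log(MK_Q_MIN), log(MK_Q_MAX)),
                         maximum = TRUE, tol = 1e-10)
  list(q = exp(opt$maximum), loglik = opt$objective)
}

mk_marginal <- function(x, q, pp) {
  down <- mk_down(x, q, pp)
  w <- exp(-2 * q * pp$len)
  same <- (1 + w) / 2
  diff <- (1 - w) / 2
  # partial messages down each edge: P(branch) %*% down[kid]
  msg0 <- same * down[pp$kid, 1] + diff * down[pp$kid, 2]
  msg1 <- diff * down[pp$kid, 1] + same * down[pp$kid, 2]
  up <- matrix(1, pp$nn, 2)
  up[pp$n + 1L, ] <- 0.5
  sib <- match(pp$parent, pp$parent) # first edge index with same parent
  for (e in pp$pre) {
    p <- pp$parent[e]; k <- pp$kid[e]
    # sibling edge: the bifurcating tree has exactly one
    s <- if (sib[e] == e) which(pp$parent == p)[2L] else sib[e]
    m <- up[p, ] * c(msg0[s], msg1[s])
    up[k, ] <- c(same[e] * m[1] + diff[e] * m[2],
                 diff[e] * m[1] + same[e] * m[2])
  }
  marg <- down * up
  marg / rowSums(marg)
}

#' Log-likelihood of a binary character under the equal-rates Mk model
#'
#' Felsenstein pruning with stationary root prior (1/2, 1/2).
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param char named 0/1 vector covering every tip.
#' @param q transition rate per unit branch length (> 0).
#' @return the log-likelihood (always <= 0).
#' @export
mk_loglik <- function(tree, char, q) {
  validate_tree(tree)
  if (q <= 0) stop("q must be positive")
  x <- validate_binary_character(tree, char)
  mk_ll(x, q, mk_prep(tree))
}

#' Maximum-likelihood fit of the Mk rate
#'
#' One-dimensional optimization of [mk_loglik()] over `q` in
#' `[1e-8, 1e3]`, carried out on the log-rate scale. A constant character
#' is a boundary case: no change is ever implied, the rate estimate
#' collapses to the lower bracket and the fit is flagged.
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param char named 0/1 vector covering every tip.
#' @return an object of class `"mk_fit"`: `q`, `loglik`, `converged`,
#'   `boundary`.
#' @export
mk_fit <- function(tree, char) {
  validate_tree(tree)
  x <- validate_binary_character(tree, char)
  pp <- mk_prep(tree)
  if (length(unique(x)) == 1L) {
    return(structure(list(q = MK_Q_MIN, loglik = mk_ll(x, MK_Q_MIN, pp),
                          converged = TRUE, boundary = TRUE),
                     class = "mk_fit"))
  }
  opt <- mk_optimize(x, pp)
  structure(list(q = opt$q, loglik = opt$loglik,
                 converged = is.finite(opt$loglik),
                 boundary = opt$q <= MK_Q_MIN * (1 + 1e-6) ||
                   opt$q >= MK_Q_MAX * (1 - 1e-6)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Equal-rates Mk fit: q = %.5g, log-likelihood = %.4f%s\n",
              x$q, x$loglik,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

mk_recon_build <- function(tree, x, q, pp) {
  marg <- mk_marginal(x, q, pp)
  internal <- (pp$n + 1L):pp$nn
  marg <- marg[internal, , drop = FALSE]
  rownames(marg) <- internal
  colnames(marg) <- c("0", "1")
  tie <- abs(marg[, 1] - marg[, 2]) < 1e-9
  ml_state <- ifelse(marg[, 2] > marg[, 1], 1L, 0L)
  ml_state[tie] <- NA_integer_
  structure(list(tree = tree,
                 tip_states = stats::setNames(x, tree$tip.label),
                 marginal = marg, ml_state = ml_state, tie = tie, q = q),
            class = "mk_recon")
}

#' Marginal ancestral reconstruction of a binary character
#'
#' Computes, at the fitted rate, the marginal posterior probability of
#' states 0 and 1 at every internal node by the standard two-pass
#' (rerooting) algorithm, and assigns each node the state with the higher
#' marginal likelihood. Nodes whose marginals are equal within 1e-9 are
#' flagged as ties; [count_steps()] resolves them.
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param char named 0/1 vector covering every tip.
#' @param fit an [mk_fit()] result; fitted afresh when omitted.
#' @return an object of class `"mk_recon"`: `tree`, `tip_states`,
#'   `marginal` (Nnode x 2 matrix of posteriors), `ml_state` (per internal
#'   node; `NA` marks a tie), `tie`, `q`.
#' @export
marginal_reconstruct <- function(tree, char, fit = NULL) {
  validate_tree(tree)
  x <- validate_binary_character(tree, char)
  if (is.null(fit)) fit <- mk_fit(tree, char)
  stopifnot(inherits(fit, "mk_fit"))
  mk_recon_build(tree, x, fit$q, mk_prep(tree))
}

#' @export
print.mk_recon <- function(x, ...) {
  cat(sprintf("Marginal Mk reconstruction (q = %.5g): %d internal nodes",
              x$q, nrow(x$marginal)))
  if (any(x$tie)) cat(sprintf(", %d tied", sum(x$tie)))
  cat(sprintf("; %d transitions\n", count_steps(x)))
  invisible(x)
}

#' Count evolutionary transitions in a reconstruction
#'
#' Counts the branches on which the most likely state differs between the
#' ancestral and descendant node, or between an ancestral node and the
#' observed state of a tip. Tied nodes are resolved conservatively: a tie
#' takes its parent's (already resolved) state, and a tie at the root takes
#' the majority tip state (state 0 on an even split).
#'
#' @param recon an [marginal_reconstruct()] result.
#' @return integer transition count, between the Fitch parsimony score and
#'   the number of edges.
#' @export
count_steps <- function(recon) {
  stopifnot(inherits(recon, "mk_recon"))
  tree <- recon$tree
  n <- ape::Ntip(tree)
  state <- c(recon$tip_states, recon$ml_state)
  root <- n + 1L
  if (is.na(state[root]))
    state[root] <- as.integer(mean(recon$tip_states) > 0.5)
  for (e in rev(ape::postorder(tree))) {   # preorder: parents first
    kid <- tree$edge[e, 2]
    if (kid > n && is.na(state[kid])) state[kid] <- state[tree$edge[e, 1]]
  }
  sum(state[tree$edge[, 1]] != state[tree$edge[, 2]])
}

#' Fitch parsimony score of a binary character
#'
#' Minimum number of state changes required on the tree, by the Fitch
#' small-parsimony downpass. A lower bound for [count_steps()].
#'
#' @param tree a bifurcating `"phylo"`.
#' @param char named 0/1 vector covering every tip.
#' @return integer parsimony score.
#' @export
parsimony_score <- function(tree, char) {
  validate_tree(tree, require_lengths = FALSE)
  x <- validate_binary_character(tree, char)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  set <- integer(nn)                  # bitmask: 1 = {0}, 2 = {1}, 3 = both
  set[seq_len(n)] <- x + 1L
  score <- 0L
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
    if (set[parent] == 0L) {
      set[parent] <- set[kid]
    } else {
      s <- bitwAnd(set[parent], set[kid])
      if (s == 0L) {
        s <- bitwOr(set[parent], set[kid])
        score <- score + 1L
      }
      set[parent] <- s
    }
  }
  score
}

#' Tip-shuffle permutation test for the transition count
#'
#' Tests whether a binary character shows fewer evolutionary transitions on
#' the tree than expected if its states were independent of phylogeny. The
#' observed count comes from [count_steps()] on the marginal Mk
#' reconstruction; the null distribution reassigns the observed states to
#' tips without replacement `n_perm` times, refitting the rate and
#' reconstructing each time (set `refit_q = FALSE` to keep the observed
#' rate). Following the usual convention for this randomization the
#' p-value is the plain fraction of shuffles with as few or fewer steps,
#' without the add-one correction.
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param char named 0/1 vector covering every tip.
#' @param n_perm number of shuffles (>= 99).
#' @param seed integer seed.
#' @param refit_q refit the Mk rate on every shuffle (default), or reuse
#'   the rate fitted to the observed character.
#' @return an object of class `"step_null"`: `observed`, `null_mean`,
#'   `null_sd`, `null` (all counts), `p_value`, `n_perm`, `seed`.
#' @examples
#' tr <- reference_tree()
#' ch <- lag_character(species_lc_table())
#' steps_permutation_test(tr, ch, n_perm = 199, seed = 1)
#' @export
steps_permutation_test <- function(tree, char, n_perm = 1000, seed = 1L,
                                   refit_q = TRUE) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  validate_tree(tree)
  x <- validate_binary_character(tree, char)
  pp <- mk_prep(tree)
  fit <- mk_fit(tree, stats::setNames(x, tree$tip.label))
  count_one <- function(xs, q) {
    rec <- mk_recon_build(tree, xs, q, pp)
    count_steps(rec)
  }
  observed <- count_one(x, fit$q)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    xs <- sample(x)
    q <- if (!refit_q || length(unique(xs)) == 1L) fit$q
         else mk_optimize(xs, pp)$q
    count_one(xs, q)
  }, integer(1))
  structure(list(observed = observed, null_mean = mean(null),
                 null_sd = stats::sd(null), null = null,
                 p_value = mean(null <= observed),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "step_null")
}

#' @export
print.step_null <- function(x, ...) {
  cat("Transition-count permutation test\n")
  cat(sprintf("  observed %d steps; null %.2f (sd %.2f) over %d shuffles\n",
              x$observed, x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  P(null <= observed) = %.4g  (seed %d)\n",
              x$p_value, x$seed))
  invisible(x)
}
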