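#' Phylogenetic covariance matrix
#'
#' The Brownian-motion covariance implied by a rooted tree with branch
#' lengths: `V[i, j]` is the depth (distance from the root) of the most
#' recent common ancestor of tips i and j, and `V[i, i]` the root-to-tip
#' distance of i.
#'
#' @param tree a validated `"phylo"` object with branch lengths.
#' @return an n x n symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts: proceeding from the tips, each internal node
#' contributes `(x1 - x2) / sqrt(v1 + v2)` where `x1, x2` are the (possibly
#' already-combined) values of its two daughters and `v1, v2` their branch
#' lengths after the standard extension `v_parent + v1 v2 / (v1 + v2)`.
#' Under Brownian evolution the n - 1 contrasts are i.i.d. normal, so their
#' variance estimates the Brownian rate.
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param trait named numeric vector covering every tip.
#' @return numeric vector of n - 1 standardized contrasts, in postorder,
#'   named by internal node number.
#' @export
pic_contrasts <- function(tree, trait) {
  validate_tree(tree)
  x <- match_trait(tree, trait)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  val <- c(as.numeric(x), rep(NA_real_, tree$Nnode))
  # branch length subtending each node, extended as nodes are pruned
  blen <- numeric(nn)
  blen[tree$edge[, 2]] <- tree$edge.length
  contrasts <- stats::setNames(rep(NA_real_, tree$Nnode),
                               as.character((n + 1):nn))
  child <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (e in ape::postorder(tree)) {
    node <- tree$edge[e, 1]
    if (!is.na(val[node])) next
    kids <- tree$edge[child[[as.character(node)]], 2]
    v <- blen[kids]
    if (sum(v) <= 0)
      stop("degenerate node ", node,
           ": sibling branches of total length zero")
    contrasts[as.character(node)] <- (val[kids[1]] - val[kids[2]]) /
      sqrt(sum(v))
    val[node] <- (v[2] * val[kids[1]] + v[1] * val[kids[2]]) / sum(v)
    blen[node] <- blen[node] + prod(v) / sum(v)
  }
  contrasts
}

#' Blomberg's K
#'
#' The ratio of the observed phylogenetic dependence of a continuous trait
#' to the dependence expected under Brownian motion on the same tree.
#' With `V` the phylogenetic covariance, `z` the trait and
#' `a = (1'V^-1 z)/(1'V^-1 1)` the GLS root state,
#' \deqn{K = \frac{(z-a)'(z-a) / (z-a)'V^{-1}(z-a)}
#'             {(\mathrm{tr}(V) - n/1'V^{-1}1)/(n-1)}.}
#' `K = 1` is the Brownian expectation; values toward 0 indicate
#' phylogenetic independence, values above 1 stronger clustering of similar
#' values among relatives than Brownian motion predicts.
#'
#' K is invariant to affine transformation of the trait and to uniform
#' rescaling of all branch lengths.
#'
#' @param tree a `"phylo"` with branch lengths, n >= 4 tips.
#' @param trait named numeric vector covering every tip; must not be
#'   constant.
#' @return the scalar K.
#' @examples
#' k <- blomberg_k(reference_tree(), lc_trait(species_lc_table(), 50, 4))
#' @export
blomberg_k <- function(tree, trait) {
  validate_tree(tree)
  z <- match_trait(tree, trait)
  n <- length(z)
  if (n < 4) stop("need at least 4 tips")
  if (stats::var(z) == 0) stop("K is undefined for a constant trait")
  V <- phylo_covariance(tree)
  if (max(abs(V - t(V))) > 1e-10) stop("phylogenetic covariance not symmetric")
  Vi_z <- tryCatch(solve(V, z), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e),
         call. = FALSE))
  Vi_1 <- solve(V, rep(1, n))
  a <- sum(Vi_z) / sum(Vi_1)
  r <- z - a
  mse0 <- sum(r^2)
  mse <- sum(r * solve(V, r))
  expected <- (sum(diag(V)) - n / sum(Vi_1)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test of phylogenetic signal
#'
#' Compares the variance of the phylogenetically independent contrasts of
#' the observed trait with the variances obtained when trait values are
#' shuffled across the tips (each label used exactly once per shuffle). A
#' trait with phylogenetic signal yields a smaller contrast variance than
#' its shuffles; the p-value is one-tailed low with the add-one correction
#' `(1 + #\{null <= observed\}) / (n_perm + 1)`. Blomberg's K is reported
#' alongside.
#'
#' @param tree a bifurcating `"phylo"` with branch lengths.
#' @param trait named numeric vector covering every tip.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; results are reproducible given the seed.
#' @param variance `"sample"` (divisor n - 2 over the n - 1 contrasts) or
#'   `"mean_square"` (mean squared contrast, the GLS Brownian rate).
#' @return an object of class `"signal_result"`: `K`, `p_value`, `n_perm`,
#'   `observed_pic_variance`, `null_mean`, `null_sd`, `seed`.
#' @examples
#' tr <- reference_tree()
#' res <- signal_permutation_test(tr, lc_trait(species_lc_table(), 50, 4),
#'                                n_perm = 999, seed = 1)
#' res
#' @export
signal_permutation_test <- function(tree, trait, n_perm = 10000, seed = 1L,
                                    variance = c("sample", "mean_square")) {
  variance <- match.arg(variance)
  if (n_perm < 99) stop("n_perm must be >= 99")
  x <- match_trait(tree, trait)
  vfun <- if (variance == "sample") stats::var else function(u) mean(u^2)
  K <- blomberg_k(tree, x)
  obs <- vfun(pic_contrasts(tree, x))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    vfun(pic_contrasts(tree, stats::setNames(sample(x), names(x))))
  }, numeric(1))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  structure(list(K = K, p_value = p, n_perm = as.integer(n_perm),
                 observed_pic_variance = obs,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 seed = as.integer(seed)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Phylogenetic signal (PIC-variance permutation test)\n")
  cat(sprintf("  Blomberg's K = %.3f,  P = %.4g  (%d permutations, seed %d)\n",
              x$K, x$p_value, x$n_perm, x$seed))
  cat(sprintf("  contrast variance: observed %.4g, null %.4g (sd %.4g)\n",
              x$observed_pic_variance, x$null_mean, x$null_sd))
  invisible(x)
}
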