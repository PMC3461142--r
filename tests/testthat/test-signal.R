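test_that("phylogenetic covariance records shared path lengths", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)
  star <- read_tree(text = "(A:3,B:3,C:3,D:3);", resolve = TRUE)
  expect_equal(unname(phylo_covariance(star)),
               unname(3 * diag(4)), tolerance = 1e-12)
  # equal-depth fixture is ultrametric
  expect_equal(var(diag(phylo_covariance(
    ape::compute.brlen(reference_tree())))), 0, tolerance = 1e-12)
})

test_that("contrasts follow the two-taxon closed form and vanish for a
           constant trait", {
  tr <- read_tree(text = "(A:1,B:1);")
  expect_equal(unname(pic_contrasts(tr, c(A = 3, B = 1))), sqrt(2))
  tr8 <- random_tree(8, seed = 2)
  const <- setNames(rep(4.2, 8), tr8$tip.label)
  expect_equal(unname(pic_contrasts(tr8, const)), rep(0, 7))
  zero <- read_tree(text = "((A:0,B:0):1,C:1);")
  expect_error(pic_contrasts(zero, c(A = 1, B = 2, C = 3)), "degenerate")
})

test_that("contrasts agree with ape and satisfy the GLS rate identity", {
  for (seed in 1:5) {
    tr <- random_tree(8, seed = seed)
    set.seed(seed + 100)
    x <- setNames(rnorm(8, sd = 3), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x, tr)
    expect_equal(unname(sort(abs(mine))), unname(sort(abs(ref))),
                 tolerance = 1e-10)
    # mean squared contrast = GLS Brownian rate estimate from V
    V <- phylo_covariance(tr)
    a <- sum(solve(V, x)) / sum(solve(V, rep(1, 8)))
    rate <- c((x - a) %*% solve(V, x - a)) / 7
    expect_equal(mean(mine^2), rate, tolerance = 1e-10)
  }
})

test_that("K matches the independent picante implementation", {
  skip_if_not_installed("picante")
  for (seed in 1:4) {
    tr <- random_tree(10, seed = seed)
    set.seed(seed + 50)
    x <- setNames(rnorm(10), tr$tip.label)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant to affine trait maps and branch rescaling", {
  tr <- random_tree(12, seed = 9)
  set.seed(60)
  x <- setNames(rnorm(12), tr$tip.label)
  k <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 3.7 * x - 11), k, tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 42
  expect_equal(blomberg_k(tr2, x), k, tolerance = 1e-10)
  expect_error(blomberg_k(tr, setNames(rep(1, 12), tr$tip.label)),
               "constant")
})

test_that("anti-clumped traits on a balanced tree give K below 1", {
  tr <- read_tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  # alternate extreme values within every cherry: maximal disparity
  # between closest relatives
  x <- setNames(rep(c(0, 10), 4), tr$tip.label)
  expect_lt(blomberg_k(tr, x), 1)
})

test_that("the permutation test is seed-deterministic and detects signal", {
  tr <- reference_tree()
  x <- simulate_bm_trait(tr, sigma2 = 1, seed = 8)
  r1 <- signal_permutation_test(tr, x, n_perm = 199, seed = 4)
  r2 <- signal_permutation_test(tr, x, n_perm = 199, seed = 4)
  expect_identical(r1, r2)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_error(signal_permutation_test(tr, x, n_perm = 50), "99")
})

test_that("BM traits usually reject, i.i.d. traits reject at the nominal
           rate", {
  tr <- reference_tree()
  # power under strong signal
  rej <- vapply(1:50, function(i) {
    x <- simulate_bm_trait(tr, sigma2 = 1, seed = 1000 + i)
    signal_permutation_test(tr, x, n_perm = 99, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.6)
  # size under the null of no signal
  set.seed(77)
  rej0 <- vapply(1:500, function(i) {
    x <- setNames(rnorm(15), tr$tip.label)
    signal_permutation_test(tr, x, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej0), 0.02)
  expect_lte(mean(rej0), 0.08)
})
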