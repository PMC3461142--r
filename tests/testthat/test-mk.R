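test_that("Mk likelihood reaches its no-change and saturation limits", {
  cherry <- read_tree(text = "(A:1,B:1);")
  # identical tips, vanishing rate: only the root prior remains
  expect_equal(mk_loglik(cherry, c(A = 1, B = 1), 1e-9), log(0.5),
               tolerance = 1e-6)
  # huge rate: tips become independent fair coins
  tr <- random_tree(6, seed = 3)
  x <- random_binary_char(tr, seed = 4)
  expect_equal(mk_loglik(tr, x, 500), 6 * log(0.5), tolerance = 1e-6)
  expect_error(mk_loglik(tr, x, 0), "positive")
})

test_that("pruning equals brute-force enumeration on small trees", {
  for (n in 4:7) {
    for (seed in 1:3) {
      tr <- random_tree(n, seed = 10 * n + seed)
      x <- random_binary_char(tr, seed = 20 * n + seed)
      for (q in c(0.05, 0.3, 1.5)) {
        expect_equal(mk_loglik(tr, x, q), brute_mk_loglik(tr, x, q),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("rate fitting is deterministic, bounded and boundary-flagged", {
  tr <- reference_tree()
  x <- lag_character(species_lc_table())
  f1 <- mk_fit(tr, x)
  f2 <- mk_fit(tr, x)
  expect_identical(f1, f2)
  expect_true(f1$converged && !f1$boundary)
  expect_gt(f1$q, 1e-8); expect_lt(f1$q, 1e3)
  # the fitted rate beats nearby rates
  expect_gte(f1$loglik, mk_loglik(tr, x, f1$q * 1.2))
  expect_gte(f1$loglik, mk_loglik(tr, x, f1$q / 1.2))
  const <- setNames(rep(1L, 15), tr$tip.label)
  fc <- mk_fit(tr, const)
  expect_true(fc$boundary)
  expect_equal(fc$q, 1e-8)
})

test_that("simulated rates are recovered to single-character precision", {
  tr <- reference_tree()
  qs <- vapply(1:200, function(i) {
    x <- simulate_mk_character(tr, q = 0.2, seed = 3000 + i)
    if (length(unique(x)) == 1) return(NA_real_)
    mk_fit(tr, x)$q
  }, numeric(1))
  expect_true(median(qs, na.rm = TRUE) > 0.1 &&
              median(qs, na.rm = TRUE) < 0.4)
})

test_that("marginal posteriors are proper and reconstruction is sensible", {
  tr <- random_tree(10, seed = 31)
  x <- random_binary_char(tr, seed = 32)
  rec <- marginal_reconstruct(tr, x)
  expect_equal(unname(rowSums(rec$marginal)), rep(1, 9), tolerance = 1e-12)
  # uniform character: every node reconstructs to it, zero steps
  all0 <- setNames(rep(0L, 10), tr$tip.label)
  rec0 <- marginal_reconstruct(tr, all0)
  expect_true(all(rec0$ml_state == 0, na.rm = TRUE))
  expect_equal(count_steps(rec0), 0)
})

test_that("marginals match the independent ape implementation", {
  tr <- reference_tree()
  x <- lag_character(species_lc_table())
  rec <- marginal_reconstruct(tr, x)
  # ape's flag naming is historical: marginal = FALSE is the standard
  # rerooting marginal reconstruction
  ref <- ape::ace(x[tr$tip.label], tr, type = "discrete", model = "ER",
                  marginal = FALSE)
  expect_equal(rec$q, unname(ref$rates), tolerance = 1e-4)
  expect_equal(unname(rec$marginal), unname(ref$lik.anc), tolerance = 1e-4)
})

test_that("a lone deviant cherry costs exactly one step", {
  # cherry (I,J) with states {0,1} hanging off an all-0 clade
  tr <- read_tree(text = paste0("(((((A:1,B:1):1,(C:1,D:1):1):1,",
                                "((E:1,F:1):1,(G:1,H:1):1):1):1,",
                                "(I:1,J:1):1):1,K:1);"))
  x <- setNames(rep(0L, 11), tr$tip.label)
  x["I"] <- 1L
  rec <- marginal_reconstruct(tr, x)
  expect_true(all(rec$ml_state == 0, na.rm = TRUE))
  expect_equal(count_steps(rec), 1)
  expect_equal(count_steps(rec), brute_parsimony(tr, x))
})

test_that("Fitch parsimony equals the enumeration minimum", {
  expect_equal(parsimony_score(read_tree(text = "(A:1,B:1);"),
                               c(A = 0, B = 1)), 1)
  tr <- random_tree(7, seed = 41)
  expect_equal(parsimony_score(tr, setNames(rep(1L, 7), tr$tip.label)), 0)
  for (seed in 1:10) {
    x <- random_binary_char(tr, seed = 50 + seed)
    expect_equal(parsimony_score(tr, x), brute_parsimony(tr, x))
  }
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    trn <- random_tree(12, seed = 60 + seed)
    x <- random_binary_char(trn, seed = 70 + seed)
    pd <- phangorn::phyDat(matrix(as.character(x[trn$tip.label]), ncol = 1,
                                  dimnames = list(trn$tip.label, NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(parsimony_score(trn, x),
                 as.integer(phangorn::parsimony(trn, pd)))
  }
})

test_that("ML step counts never beat parsimony and fit within the tree", {
  for (seed in 1:25) {
    tr <- random_tree(sample(6:14, 1), seed = 500 + seed)
    x <- random_binary_char(tr, seed = 600 + seed)
    s <- count_steps(marginal_reconstruct(tr, x))
    expect_gte(s, parsimony_score(tr, x))
    expect_lte(s, nrow(tr$edge))
  }
})

test_that("the step permutation test is deterministic and degenerates
           correctly", {
  tr <- reference_tree()
  x <- lag_character(species_lc_table())
  r1 <- steps_permutation_test(tr, x, n_perm = 199, seed = 11)
  r2 <- steps_permutation_test(tr, x, n_perm = 199, seed = 11)
  expect_identical(r1, r2)
  const <- setNames(rep(1L, 15), tr$tip.label)
  rc <- steps_permutation_test(tr, const, n_perm = 99, seed = 1)
  expect_equal(rc$observed, 0)
  expect_equal(rc$p_value, 1)   # shuffles of a constant are constant
})

test_that("the fixture null mean is stable across seeds", {
  tr <- reference_tree()
  x <- lag_character(species_lc_table())
  means <- vapply(1:3, function(s)
    steps_permutation_test(tr, x, n_perm = 500, seed = s)$null_mean,
    numeric(1))
  expect_lt(max(means) - min(means), 0.5)
})

test_that("the step test holds its size under phylogeny-free characters", {
  tr <- reference_tree()
  set.seed(123)
  rej <- vapply(1:300, function(i) {
    x <- setNames(sample(c(rep(0L, 8), rep(1L, 7))), tr$tip.label)
    steps_permutation_test(tr, x, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})
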