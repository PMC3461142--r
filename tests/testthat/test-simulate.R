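test_that("generators are deterministic given a seed", {
  cfg <- sim_config(seed = 9)
  expect_identical(simulate_dose_response(cfg), simulate_dose_response(cfg))
  tr <- reference_tree()
  expect_identical(simulate_bm_trait(tr, seed = 5),
                   simulate_bm_trait(tr, seed = 5))
  expect_identical(simulate_mk_character(tr, q = 0.3, seed = 5),
                   simulate_mk_character(tr, q = 0.3, seed = 5))
})

test_that("no delayed death means identical day-4 and day-8 counts", {
  tab <- simulate_dose_response(sim_config(seed = 2, delayed_death = 0))
  a4 <- tab$alive[tab$day == 4]
  a8 <- tab$alive[tab$day == 8]
  expect_identical(a4, a8)
  tab2 <- simulate_dose_response(sim_config(seed = 2, delayed_death = 0.5))
  expect_true(any(tab2$alive[tab2$day == 8 & tab2$control_kind == "none"] <
                  tab2$alive[tab2$day == 4 & tab2$control_kind == "none"]))
})

test_that("marginal day-4 mortality tracks the configured probit curve", {
  truth <- sim_config(seed = 4, a = -3, b = 2, control_mortality = 0,
                      animals_per_unit = 2500L, reps = 2L, blocks = 2L)
  tab <- simulate_dose_response(truth)
  d4 <- tab[tab$day == 4 & tab$control_kind == "none", ]
  mort <- 1 - tapply(d4$alive, d4$dose, sum) / tapply(d4$total, d4$dose, sum)
  doses <- as.numeric(names(mort))
  expected <- pnorm(-3 + 2 * log10(doses))
  # 10^4 animals per dose: binomial error ~ 3 * sqrt(p(1-p)/1e4)
  tol <- 3 * sqrt(expected * (1 - expected) / 1e4) + 1e-6
  expect_true(all(abs(mort - expected) < tol))
  # at the true LC50 mortality is one half
  lc50 <- 10^1.5
  cfg50 <- sim_config(seed = 6, doses = lc50, animals_per_unit = 5000L)
  t50 <- simulate_dose_response(cfg50)
  m50 <- 1 - sum(t50$alive[t50$day == 4 & t50$dose > 0]) /
    sum(t50$total[t50$day == 4 & t50$dose > 0])
  expect_equal(m50, 0.5 + 0.02 * 0.5, tolerance = 0.05)  # incl. background
})

test_that("BM traits have the tree-implied covariance", {
  tr <- read_tree(text = "((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  V <- phylo_covariance(tr)
  sims <- vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = 2, root = 1, seed = i), numeric(4))
  expect_equal(unname(rowMeans(sims)), rep(1, 4), tolerance = 0.15)
  emp <- cov(t(sims))
  expect_equal(unname(emp), unname(2 * V), tolerance = 0.15 * 2 * max(V))
  expect_equal(unname(simulate_bm_trait(tr, sigma2 = 0, root = 7, seed = 1)),
               rep(7, 4))
})

test_that("Mk characters respect the per-branch flip probability", {
  tr <- read_tree(text = "(A:0.5,B:2);")
  q <- 0.4
  sims <- vapply(1:4000, function(i)
    simulate_mk_character(tr, q = q, seed = i), integer(2))
  # tips disagree when exactly one branch flips:
  # P(A != B) = p_a (1-p_b) + p_b (1-p_a), p_t = (1-exp(-2qt))/2
  p <- function(t) (1 - exp(-2 * q * t)) / 2
  expect_equal(mean(sims[1, ] != sims[2, ]),
               p(0.5) * (1 - p(2)) + p(2) * (1 - p(0.5)), tolerance = 0.03)
  # q = 0 freezes the root state everywhere
  frozen <- simulate_mk_character(reference_tree(), q = 0, seed = 12)
  expect_length(unique(frozen), 1)
  # saturation: state frequencies approach one half
  tr_long <- read_tree(text = "(A:50,B:50);")
  manyy <- vapply(1:2500, function(i)
    simulate_mk_character(tr_long, q = 1, seed = i), integer(2))
  expect_equal(mean(manyy), 0.5, tolerance = 0.04)
})

test_that("a two-fold true LC50 drop is usually caught by the overlap rule", {
  # delayed death of 0.35 at every dose halves the true 8-day LC50
  hits <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 7000 + i, delayed_death = 0.35)
    tab <- simulate_dose_response(cfg)
    f4 <- try(probit_lc(tab, day = 4), silent = TRUE)
    f8 <- try(probit_lc(tab, day = 8), silent = TRUE)
    if (inherits(f4, "try-error") || inherits(f8, "try-error"))
      return(NA)
    e4 <- lc(f4, 0.5); e8 <- lc(f8, 0.5)
    if (e4$unbounded || e8$unbounded) return(NA)
    ci_overlap_test(e4, e8) == 1L
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})
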