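test_that("phylo_cov reads MRCA depths off the tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_cov(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
  st <- star_tree(5, branch = 3)
  expect_equal(unname(phylo_cov(st)), diag(3, 5))
  expect_error(phylo_cov(ape::read.tree(text = "(A:1,B:1);")), "at least 3")
})

test_that("phylo_cov matches a brute-force per-pair MRCA-depth oracle", {
  tr <- simulate_yule_tree(16, 1, seed = 51)
  C <- phylo_cov(tr)
  for (a in tr$tip.label[1:8]) {
    for (b in setdiff(tr$tip.label, a)[1:8]) {
      expect_equal(C[a, b], mrca_depth_oracle(tr, a, b), tolerance = 1e-9)
    }
  }
})

test_that("Blomberg's K is exactly 1 on star trees", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(8:24, 1)
    st <- star_tree(n, branch = runif(1, 0.5, 3))
    x <- stats::setNames(rnorm(n), st$tip.label)
    expect_lt(abs(blomberg_k(st, x) - 1), 1e-10)
  }
})

test_that("K is invariant under affine trait transforms", {
  tr <- simulate_yule_tree(20, 1, seed = 71)
  x <- simulate_bm(tr, 1, seed = 72)
  k0 <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 2.5 * x - 7), k0, tolerance = 1e-10)
  expect_equal(blomberg_k(tr, -x), k0, tolerance = 1e-10)
  expect_error(blomberg_k(tr, x * 0), "zero variance")
})

test_that("K agrees with independent reference implementations", {
  skip_if_not_installed("picante")
  skip_if_not_installed("phytools")
  for (seed in c(1, 2, 3)) {
    tr <- simulate_yule_tree(24, 1, seed = 80 + seed)
    x <- simulate_bm(tr, 2, seed = 90 + seed)
    k <- blomberg_k(tr, x)
    expect_equal(k, as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
    expect_equal(k, as.numeric(phytools::phylosig(tr, x, method = "K")),
                 tolerance = 1e-8)
  }
})

test_that("the K permutation test is reproducible and add-one bounded", {
  tr <- simulate_yule_tree(16, 1, seed = 5)
  x <- simulate_bm(tr, 1, seed = 6)
  r1 <- blomberg_k_test(tr, x, n_permutations = 199, seed = 7)
  r2 <- blomberg_k_test(tr, x, n_permutations = 199, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 200)
  expect_equal(r1$p_value,
               (1 + sum(r1$K_permuted >= r1$K)) / (1 + r1$n_permutations))
  expect_error(blomberg_k_test(tr, x, n_permutations = 10), "n_permutations")
})

test_that("strong Brownian signal is detected with small p", {
  detected <- 0
  for (seed in 1:20) {
    tr <- simulate_yule_tree(32, 1, seed = 100 + seed)
    x <- simulate_bm(tr, 4, seed = 200 + seed)
    p <- blomberg_k_test(tr, x, n_permutations = 199, seed = 300 + seed)$p_value
    detected <- detected + (p <= 0.01)
  }
  expect_gte(detected / 20, 0.9)
})

test_that("proximity weights are inverse patristic distances", {
  st <- star_tree(3, branch = 2)
  W <- proximity_weights(st, row_normalize = TRUE)
  expect_equal(unname(W[1, 2:3]), c(0.5, 0.5))
  tr <- simulate_yule_tree(10, 1, seed = 31)
  Wraw <- proximity_weights(tr, row_normalize = FALSE)
  expect_equal(Wraw, t(Wraw))
  expect_equal(unname(diag(Wraw)), rep(0, 10))
  for (a in tr$tip.label[1:4]) {
    for (b in setdiff(tr$tip.label[1:5], a)) {
      expect_equal(Wraw[a, b], 1 / patristic_oracle(tr, a, b),
                   tolerance = 1e-9)
    }
  }
  Wn <- proximity_weights(tr, row_normalize = TRUE)
  expect_equal(unname(rowSums(Wn)), rep(1, 10), tolerance = 1e-12)
})

test_that("Moran's I identities hold", {
  # complete-graph weights: I = -1/(n-1) for any non-constant trait
  set.seed(41)
  for (n in c(4, 7, 12)) {
    W <- matrix(1, n, n); diag(W) <- 0
    x <- rnorm(n)
    expect_equal(moran_i(x, W), -1 / (n - 1), tolerance = 1e-12)
  }
  # two-block weights with block-constant trait: positive autocorrelation
  Wb <- matrix(0, 6, 6)
  Wb[1:3, 1:3] <- 1; Wb[4:6, 4:6] <- 1; diag(Wb) <- 0
  xb <- c(5, 5, 5, -5, -5, -5) + rnorm(6, 0, 0.01)
  expect_gt(moran_i(xb, Wb), 0)
  expect_error(moran_i(rep(1, 6), Wb), "zero variance")
})

test_that("permutation mean of Moran's I is about -1/(n-1)", {
  tr <- simulate_yule_tree(20, 1, seed = 55)
  W <- proximity_weights(tr)
  x <- simulate_bm(tr, 1, seed = 56)
  set.seed(57)
  perms <- replicate(3000, moran_i(stats::setNames(sample(unname(x)), names(x)), W))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / 19)), 3 * se)
})

test_that("the correlogram flags near-distance BM autocorrelation only", {
  hits <- 0
  for (seed in 1:10) {
    tr <- simulate_yule_tree(48, 1, seed = 400 + seed)
    x <- simulate_bm(tr, 4, seed = 500 + seed)
    cg <- suppressWarnings(correlogram(tr, x, n_classes = 5,
                                       n_permutations = 199, seed = 600 + seed))
    first <- which(!is.na(cg$classes$I))[1]
    hits <- hits + (cg$classes$significant[first] &&
                      cg$classes$I[first] > 0)
  }
  expect_gte(hits / 10, 0.9)
  # identical seed gives identical envelope
  tr <- simulate_yule_tree(24, 1, seed = 42)
  x <- simulate_bm(tr, 1, seed = 43)
  c1 <- suppressWarnings(correlogram(tr, x, seed = 9))
  c2 <- suppressWarnings(correlogram(tr, x, seed = 9))
  expect_identical(c1, c2)
  expect_true(all(c1$classes$lower <= c1$classes$upper, na.rm = TRUE))
})

test_that("shuffled traits are mostly nonsignificant in the correlogram", {
  signif <- 0; classes <- 0
  for (seed in 1:15) {
    tr <- simulate_yule_tree(32, 1, seed = 700 + seed)
    x <- simulate_white_noise(tr, seed = 800 + seed)
    cg <- suppressWarnings(correlogram(tr, x, n_classes = 4,
                                       n_permutations = 199, seed = 900 + seed))
    ok <- !is.na(cg$classes$I)
    signif <- signif + sum(cg$classes$significant[ok])
    classes <- classes + sum(ok)
  }
  # two-sided envelope at alpha = 0.05: expect roughly 5% significant
  expect_lt(signif / classes, 0.15)
})

test_that("LIPA local values sum to n times global I and are reproducible", {
  tr <- simulate_yule_tree(18, 1, seed = 21)
  x <- simulate_bm(tr, 1, seed = 22)
  lp <- lipa(tr, x, n_permutations = 99, seed = 23)
  W <- proximity_weights(tr, row_normalize = TRUE)
  expect_equal(sum(lp$local_I), length(x) * moran_i(x, W), tolerance = 1e-9)
  lp2 <- lipa(tr, x, n_permutations = 99, seed = 23)
  expect_identical(lp, lp2)
  expect_error(lipa(tr, x * 0 + 2, n_permutations = 99), "zero variance")
})

test_that("LIPA flags a planted elevated clade", {
  tr <- simulate_yule_tree(64, 1, seed = 61)
  sim <- simulate_clade_trait(tr, seed = 62)
  lp <- lipa(tr, sim$trait, n_permutations = 499, seed = 63, alpha = 0.01)
  expect_gte(mean(sim$clade_tips %in% lp$flagged_tips), 0.5)
})
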