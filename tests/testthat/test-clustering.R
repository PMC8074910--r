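block_matrix <- function() {
  # two well-separated blocks of identical rows
  counts <- rbind(matrix(0L, 3, 4), matrix(10L, 3, 4))
  dimnames(counts) <- list(sprintf("s%d", 1:6), sprintf("F%d", 1:4))
  class(counts) <- c("trait_matrix", "matrix", "array")
  counts
}

test_that("hierarchical_partition separates obvious blocks and handles k=1", {
  m <- block_matrix()
  p <- hierarchical_partition(m, k = 2)
  expect_equal(unname(p$assignments), c(1L, 1L, 1L, 2L, 2L, 2L))
  p1 <- hierarchical_partition(m, k = 1)
  expect_equal(unname(p1$assignments), rep(1L, 6))
  expect_error(hierarchical_partition(m, k = 7), "exceeds")
  # degenerate: all rows identical
  same <- m; same[] <- 1L
  expect_error(hierarchical_partition(same, k = 2), "degenerate")
})

test_that("partition labels are canonical and permutation-equivariant", {
  d <- simulate_diet_dataset(sim_config(n_strains = 20, n_families = 15,
                                        n_groups = 4, prevalence_tiers = NULL,
                                        seed = 21))
  m <- suppressMessages(build_matrix(d$annotations, d$metadata))
  p <- hierarchical_partition(m, k = 4)
  # canonical labels: first strain in row order gets label 1, etc.
  first_seen <- !duplicated(p$assignments)
  expect_equal(unname(p$assignments[first_seen]),
               seq_len(max(p$assignments)))
  # permuting rows permutes assignments identically
  perm <- sample(nrow(m))
  mp <- unclass(m)[perm, , drop = FALSE]
  class(mp) <- class(m)
  pp <- hierarchical_partition(mp, k = 4)
  expect_equal(adjusted_rand(p, pp), 1, tolerance = 1e-12)
})

test_that("adjusted_rand matches hand cases and the pair-counting oracle", {
  a <- stats::setNames(c(1, 1, 2, 2), c("A", "B", "C", "D"))
  expect_equal(adjusted_rand(a, a), 1)
  b <- stats::setNames(c(1, 2, 1, 2), c("A", "B", "C", "D"))
  expect_equal(adjusted_rand(a, b), -0.5, tolerance = 1e-12)
  expect_error(adjusted_rand(a, b[1:3]), "different strain sets")
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    p <- random_partition(n)
    q <- stats::setNames(sample.int(4, n, replace = TRUE), names(p))
    expect_equal(adjusted_rand(p, q), ari_oracle(p, q), tolerance = 1e-12)
    expect_equal(adjusted_rand(p, q), adjusted_rand(q, p), tolerance = 1e-12)
  }
})

test_that("select_stable_set applies the plateau rule", {
  # all sets yield identical partitions -> first usable set selected
  m <- block_matrix()
  sets <- structure(lapply(1:21, function(i) {
    structure(list(set_index = i, threshold_percent = c(100, seq(95, 0, -5))[i],
                   family_ids = c("F1", "F2", "F3", "F4")),
              class = "family_set")
  }), class = c("family_set_list", "list"))
  res <- select_stable_set(m, sets, k = 2)
  expect_equal(res$selected_set_index, 1)
  expect_true(res$plateau_found)
  expect_true(all(res$agreement == 1))

  # sets with < 2 families are skipped with a warning
  sets2 <- sets
  sets2[[1]]$family_ids <- "F1"
  expect_warning(res2 <- select_stable_set(m, sets2, k = 2), "fewer than 2")
  expect_equal(res2$selected_set_index, 2)

  # deterministic rerun is identical
  d <- simulate_diet_dataset(sim_config(plateau = TRUE, seed = 77))
  mm <- suppressMessages(build_matrix(d$annotations, d$metadata))
  fs <- build_family_sets(mm)
  r1 <- suppressWarnings(select_stable_set(mm, fs, k = 5))
  r2 <- suppressWarnings(select_stable_set(mm, fs, k = 5))
  expect_identical(r1, r2)
})

test_that("a planted >20% plateau is found at set 17 with its partition", {
  d <- simulate_diet_dataset(sim_config(plateau = TRUE, seed = 123))
  m <- suppressMessages(build_matrix(d$annotations, d$metadata))
  sets <- build_family_sets(m)
  res <- suppressWarnings(select_stable_set(m, sets, k = 5))
  expect_true(res$plateau_found)
  expect_equal(res$selected_set_index, 17)
  expect_equal(res$selected_threshold_percent, 20)
  expect_equal(adjusted_rand(res$partitions[[17]], d$truth$planted_partition),
               1, tolerance = 1e-12)
})

test_that("no consecutive agreement yields the last set with no plateau", {
  # hand-build nested sets whose partitions all differ: each set adds a
  # family that dominates the distances with a different split
  counts <- matrix(0L, 6, 4, dimnames = list(sprintf("s%d", 1:6),
                                             c("F1", "F2", "F3", "F4")))
  counts[, 1] <- c(0L, 0L, 0L, 5L, 5L, 5L)
  counts[, 2] <- c(0L, 60L, 60L, 60L, 0L, 0L)
  counts[, 3] <- c(900L, 0L, 900L, 0L, 900L, 0L)
  counts[, 4] <- c(9000L, 9000L, 0L, 0L, 0L, 0L)
  class(counts) <- c("trait_matrix", "matrix", "array")
  sets <- structure(lapply(1:3, function(i) {
    structure(list(set_index = i, threshold_percent = c(100, 95, 90)[i],
                   family_ids = list(c("F1", "F2"), c("F1", "F2", "F3"),
                                     c("F1", "F2", "F3", "F4"))[[i]]),
              class = "family_set")
  }), class = c("family_set_list", "list"))
  expect_warning(res <- select_stable_set(counts, sets, k = 2,
                                          m_consecutive = 1),
                 NA)
  expect_false(res$plateau_found)
  expect_equal(res$selected_set_index, 3)
})

test_that("suggest_k prefers the planted number of groups", {
  cfg <- sim_config(n_strains = 40, n_families = 30, n_groups = 4,
                    effect_multipliers = planted_effect_multipliers(4, 30,
                                                                    multiplier = 8),
                    prevalence_tiers = NULL, seed = 33)
  d <- simulate_diet_dataset(cfg)
  m <- suppressMessages(build_matrix(d$annotations, d$metadata))
  expect_equal(suggest_k(m, k_range = 2:6)$best_k, 4)
})
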