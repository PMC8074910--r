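make_fixture <- function() {
  ann <- as_annotation_table(data.frame(
    strain_id = c("s1", "s1", "s2", "s2", "s3"),
    family_id = c("GH13", "GH3", "GH13", "GH43", "GH3"),
    gene_count = c(4L, 2L, 1L, 3L, 5L)))
  md <- as_strain_metadata(data.frame(
    strain_id = c("s1", "s2", "s3"),
    diet_group = c("Herbi", "Omni", "Herbi"),
    total_cds = c(2000L, 1000L, 500L)))
  list(ann = ann, md = md)
}

test_that("build_matrix pivots with structural zeros, deterministically", {
  fx <- make_fixture()
  m <- build_matrix(fx$ann, fx$md)
  expect_equal(rownames(m), c("s1", "s2", "s3"))
  expect_equal(colnames(m), c("GH13", "GH3", "GH43"))
  expect_equal(unname(unclass(m)["s3", ]), c(0L, 5L, 0L))
  # permuted record order gives the identical matrix
  perm <- fx$ann[c(4, 2, 5, 1, 3), ]
  expect_identical(build_matrix(perm, fx$md), m)
  # unknown strain errors unless drop flag set
  extra <- rbind(fx$ann, data.frame(strain_id = "sX", family_id = "GH13",
                                    gene_count = 1L))
  expect_error(build_matrix(extra, fx$md), "sX")
  expect_warning(m2 <- build_matrix(extra, fx$md, drop_unknown_strains = TRUE),
                 "dropping")
  expect_identical(m2, m)
})

test_that("matrix row sums equal per-strain totals of the raw records", {
  d <- simulate_diet_dataset(sim_config(seed = 17))
  m <- suppressMessages(build_matrix(d$annotations, d$metadata))
  raw <- tapply(d$annotations$gene_count, d$annotations$strain_id, sum)
  expect_equal(unname(rowSums(m)[names(raw)]), unname(as.numeric(raw)))
})

test_that("prevalence is presence-based and matches a per-column scan", {
  fx <- make_fixture()
  m <- build_matrix(fx$ann, fx$md)
  prev <- family_prevalence(m)
  expect_equal(unname(prev["GH13"]), 2 / 3)
  expect_equal(unname(prev["GH3"]), 2 / 3)
  expect_equal(unname(prev["GH43"]), 1 / 3)
  d <- simulate_diet_dataset(sim_config(seed = 9))
  mm <- suppressMessages(build_matrix(d$annotations, d$metadata))
  brute <- apply(unclass(mm), 2, function(col) sum(col >= 1) / length(col))
  expect_equal(family_prevalence(mm), brute)
  # presence semantics: scaling nonzero counts changes nothing
  mm2 <- unclass(mm)
  mm2[mm2 > 0] <- mm2[mm2 > 0] * 7L
  class(mm2) <- class(mm)
  expect_equal(family_prevalence(mm2), family_prevalence(mm))
})

test_that("the 21 family sets use strict thresholds except the 100% set", {
  # prevalences planted across 5 strains: 1.0, 0.6, 0.2, 0.2 (boundary)
  counts <- matrix(0L, 5, 4,
                   dimnames = list(paste0("s", 1:5), paste0("F", 1:4)))
  counts[, 1] <- 1L
  counts[1:3, 2] <- 2L
  counts[1, 3] <- 1L
  counts[5, 4] <- 1L
  class(counts) <- c("trait_matrix", "matrix", "array")
  sets <- build_family_sets(counts)
  expect_length(sets, 21)
  expect_equal(sapply(sets, function(s) s$threshold_percent),
               c(100, seq(95, 0, by = -5)))
  # F1 (prevalence 1) in every set
  expect_true(all(sapply(sets, function(s) "F1" %in% s$family_ids)))
  # prevalence exactly 0.20: excluded from the >20% set, in the >15% set
  expect_false("F3" %in% sets[[17]]$family_ids)
  expect_true("F3" %in% sets[[18]]$family_ids)
  # nesting
  for (i in 1:20) {
    expect_true(all(sets[[i]]$family_ids %in% sets[[i + 1]]$family_ids))
  }
})

test_that("family-set sizes match a brute-force enumeration on random data", {
  for (seed in c(1, 2, 3)) {
    d <- simulate_diet_dataset(sim_config(n_strains = 20, n_families = 30,
                                          n_groups = 4, seed = seed))
    m <- suppressMessages(build_matrix(d$annotations, d$metadata))
    prev <- family_prevalence(m)
    sets <- build_family_sets(m)
    for (s in sets) {
      expected <- if (s$threshold_percent == 100) {
        names(prev)[prev == 1]
      } else {
        names(prev)[prev > s$threshold_percent / 100]
      }
      expect_setequal(s$family_ids, expected)
    }
  }
})

test_that("the >=80% convenience screen is inclusive", {
  counts <- matrix(0L, 5, 2, dimnames = list(paste0("s", 1:5), c("A", "B")))
  counts[1:4, 1] <- 1L   # prevalence exactly 0.8
  counts[1:3, 2] <- 1L
  class(counts) <- c("trait_matrix", "matrix", "array")
  expect_equal(prevalent_families(counts), "A")
})

test_that("gh_content is 100 * rowsum / total_cds and validates cds", {
  fx <- make_fixture()
  m <- build_matrix(fx$ann, fx$md)
  gc <- gh_content(m, fx$md)
  expect_equal(gc$gh_percent[gc$strain_id == "s1"], 100 * 6 / 2000)
  expect_equal(gc$gh_percent[gc$strain_id == "s3"], 100 * 5 / 500)
  md2 <- fx$md
  md2$total_cds[2] <- NA
  expect_error(gh_content(m, md2), "s2")
})

test_that("cog_ratio_trend recovers composition from the definition", {
  pres <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0))
  rownames(pres) <- c("c1", "c2")
  pam <- as_presence_matrix(c("c1", "c2"), c("G", "E"), pres)
  trend <- cog_ratio_trend(pam, c(100, 50))
  expect_equal(trend[[1]]$cog_ratios, c(G = 1))
  expect_equal(trend[[2]]$cog_ratios[c("E", "G")], c(E = 0.5, G = 0.5))
  # ratios sum to 1 at every level of a sweep
  set.seed(31)
  pres2 <- matrix(rbinom(200, 1, 0.9), 20, 10,
                  dimnames = list(sprintf("c%d", 1:20), NULL))
  pam2 <- as_presence_matrix(rownames(pres2),
                             sample(c("G", "E", "K", "unassigned"), 20, TRUE),
                             pres2)
  trend2 <- cog_ratio_trend(pam2, 100:83)
  for (tr in trend2) expect_equal(sum(tr$cog_ratios), 1, tolerance = 1e-9)
  expect_warning(cog_ratio_trend(pam2, c(100.0)), NA)
  # empty core warns, not errors
  pres3 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  pam3 <- as_presence_matrix(c("a", "b"), c("G", "E"), pres3)
  expect_warning(tr3 <- cog_ratio_trend(pam3, 100), "no core")
  expect_length(tr3[[1]]$cog_ratios, 0)
})
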