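test_that("the simulator is fully determined by its seed", {
  cfg <- sim_config(n_pops = 3, pop_sizes = 30, generations = 20,
                    sample_size = 10, seed = 42)
  c1 <- simulate_metapopulation(cfg)
  c2 <- simulate_metapopulation(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genotype_table(c1, f1); write_genotype_table(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$meta, c2$meta)
  ## a different seed gives different genotypes
  c3 <- simulate_metapopulation(sim_config(n_pops = 3, pop_sizes = 30,
                                           generations = 20, sample_size = 10,
                                           seed = 43))
  expect_false(identical(c1$alleles, c3$alleles))
})

test_that("isolation builds differentiation and panmixia erases it", {
  iso <- uni <- c()
  for (s in 1:3) {
    ci <- simulate_metapopulation(sim_config(
      n_pops = 4, pop_sizes = 40, generations = 120, n_appellations = 1,
      migration_matrix = diag(4), selfing_rate = 0, starter_fraction = 0,
      missing_rate = 0, sample_size = 20, clonal_skew = 100, n_founders = 40,
      seed = 100 + s))
    fi <- pairwise_fst(ci, "estate", n_perm = 0, method = "wc")
    iso <- c(iso, mean(fi$fst[upper.tri(fi$fst)]))
    cu <- simulate_metapopulation(sim_config(
      n_pops = 4, pop_sizes = 40, generations = 120, n_appellations = 1,
      migration_matrix = matrix(0.25, 4, 4), selfing_rate = 0,
      starter_fraction = 0, missing_rate = 0, sample_size = 20,
      clonal_skew = 100, n_founders = 40, seed = 100 + s))
    fu <- pairwise_fst(cu, "estate", n_perm = 0, method = "wc")
    uni <- c(uni, mean(fu$fst[upper.tri(fu$fst)]))
  }
  expect_gt(mean(iso), 0.2)
  expect_lt(mean(uni), 0.02)
})

test_that("mean Fst decreases monotonically with the migration rate", {
  grid <- c(0.002, 0.02, 0.2)
  means <- sapply(grid, function(m) {
    mean(sapply(1:10, function(s) {
      coll <- simulate_metapopulation(sim_config(
        n_pops = 4, pop_sizes = 30, generations = 80, n_appellations = 1,
        migration_matrix = island_migration(4, m), selfing_rate = 0,
        starter_fraction = 0, missing_rate = 0, sample_size = 15,
        clonal_skew = 100, n_founders = 30, seed = 500 + s))
      f <- pairwise_fst(coll, "estate", n_perm = 0, method = "wc")
      mean(f$fst[upper.tri(f$fst)])
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("selfing drives the heterozygote deficit toward fixation", {
  coll <- panmictic_sample(n = 60, seed = 5, selfing = 1)
  ps <- pop_summary(coll, "estate")
  expect_lt(ps$Ho, 0.05)
  expect_gt(ps$Fis, 0.8)
  ## random mating keeps Fis near zero
  coll0 <- panmictic_sample(n = 60, seed = 5, selfing = 0)
  expect_lt(abs(pop_summary(coll0, "estate")$Fis), 0.15)
})

test_that("small clonal_skew concentrates samples on few genotypes", {
  rich <- function(skew) {
    coll <- simulate_metapopulation(sim_config(
      n_pops = 4, pop_sizes = 50, generations = 30, sample_size = 30,
      n_appellations = 1, starter_fraction = 0, missing_rate = 0,
      clonal_skew = skew, n_founders = 15, seed = 9))
    mean(tapply(seq_len(n_ind(coll)), coll$meta$estate, function(idx)
      length(unique(coll$meta$founder[idx]))))
  }
  expect_lt(rich(0.05), rich(5))
})

test_that("spike_starters replaces the requested fraction with near-copies", {
  coll <- random_coll(40, L = 17, seed = 1)
  starters <- simulate_starters(coll$panel, seed = 2)
  ## fraction 0: untouched
  c0 <- spike_starters(coll, starters, 0, seed = 1)
  expect_identical(c0$alleles, coll$alleles)
  expect_true(all(is.na(c0$meta$starter_truth)))
  ## max_edits 0: perfect copies of a starter
  c1 <- spike_starters(coll, starters, 0.25, max_edits = 0, seed = 1)
  spiked <- which(!is.na(c1$meta$starter_truth))
  expect_length(spiked, 10L)
  sm <- allele_sharing_matrix(subset_collection(c1, spiked), starters)
  expect_true(all(apply(sm, 1, max) == 1))
  ## max_edits 2: still above the 30/34 arithmetic bound
  c2 <- spike_starters(coll, starters, 0.25, max_edits = 2, seed = 3)
  spiked2 <- which(!is.na(c2$meta$starter_truth))
  sm2 <- allele_sharing_matrix(subset_collection(c2, spiked2), starters)
  expect_true(all(apply(sm2, 1, max) >= 30 / 34))
  ## errors
  expect_error(spike_starters(coll, starters, 0.2, max_edits = -1), "max_edits")
  empty <- subset_collection(starters, integer(0))
  expect_error(spike_starters(coll, empty, 0.2), "empty starter panel")
  expect_error(sim_config(starter_fraction = 0.25, starter_profiles = empty),
               "empty starter panel")
})
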