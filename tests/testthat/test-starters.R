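make_spiked <- function(seed = 1, fraction = 0.25, max_edits = 2) {
  cfg <- sim_config(n_pops = 4, pop_sizes = 60, generations = 60,
                    n_appellations = 2, sample_size = 30,
                    starter_fraction = fraction,
                    starter_max_edits = max_edits,
                    missing_rate = 0, seed = seed)
  simulate_metapopulation(cfg)
}

test_that("attribution categories follow sharing and locus differences", {
  coll <- random_coll(10, L = 17, seed = 61)
  starters <- simulate_starters(coll$panel, seed = 62)
  ## plant an exact copy, a 2-locus variant, and a > 2-locus relative
  coll$alleles[1, , ] <- starters$alleles["FX10", , ]
  coll$alleles[2, , ] <- starters$alleles["FX10", , ]
  coll$alleles[2, c(3, 8), ] <- coll$alleles[2, c(3, 8), ] + 300L
  coll$alleles[3, , ] <- starters$alleles["X5", , ]
  coll$alleles[3, 1:4, ] <- coll$alleles[3, 1:4, ] + 300L
  rep <- attribute_starters(coll, starters)
  expect_equal(as.character(rep$category[1]), "identical")
  expect_equal(rep$sharing[1], 1)
  expect_equal(rep$best_starter[1], "FX10")
  expect_equal(as.character(rep$category[2]), "clonal_variant")
  expect_equal(rep$sharing[2], 30 / 34)          # 34 - 2*2 = 30 shared
  expect_equal(rep$n_diff_loci[2], 2L)
  expect_equal(as.character(rep$category[3]), "related")  # 26/34 = 0.765
  expect_equal(rep$sharing[3], 26 / 34)
  ## categories exhaustive and exclusive
  expect_false(any(is.na(rep$category)))
  expect_equal(rep$related, rep$category != "unrelated")
  ## isolates with missing loci are ineligible whatever their sharing
  coll$alleles[1, 5, ] <- NA_integer_
  rep2 <- attribute_starters(coll, starters)
  expect_false(rep2$eligible[1])
  expect_equal(as.character(rep2$category[1]), "unrelated")
  expect_error(attribute_starters(coll, subset_collection(starters, integer(0))),
               "empty")
})

test_that("lowering the threshold never shrinks the related set", {
  coll <- make_spiked(seed = 5)
  starters <- attr(coll, "truth")$starter_panel
  r_hi <- attribute_starters(coll, starters, threshold = 0.9)
  r_lo <- attribute_starters(coll, starters, threshold = 0.6)
  expect_true(all(r_hi$related <= r_lo$related))
})

test_that("spiked simulations are recovered with perfect recall", {
  coll <- make_spiked(seed = 9)
  starters <- attr(coll, "truth")$starter_panel
  rep <- attribute_starters(coll, starters)
  truth <- !is.na(coll$meta$starter_truth)
  recall <- sum(rep$related & truth) / sum(truth)
  precision <- sum(rep$related & truth) / sum(rep$related)
  expect_equal(recall, 1)
  expect_gte(precision, 0.95)
  ## attributed name matches the spiked starter
  expect_true(all(rep$best_starter[truth] == coll$meta$starter_truth[truth]))
  ## removal drops exactly the related set and is idempotent
  kept <- remove_related(coll, rep)
  expect_equal(attr(kept, "n_removed"), sum(rep$related))
  rep2 <- attribute_starters(kept, starters)
  expect_equal(sum(rep2$related), 0L)
  kept2 <- remove_related(kept, rep2)
  expect_identical(kept2$alleles, kept$alleles)
})

test_that("starter networks are stars for recent clonal expansions", {
  coll <- random_coll(8, L = 17, seed = 71)
  starters <- simulate_starters(coll$panel, seed = 72)
  ## three exact copies -> zero-length star
  for (i in 1:3) coll$alleles[i, , ] <- starters$alleles["VL1", , ]
  net <- starter_network(coll, starters, "VL1")
  expect_equal(net$star_likeness, 1)
  expect_true(all(net$edges$weight == 0))
  ## single-step variants all attach next to the starter
  coll2 <- random_coll(8, L = 17, seed = 73)
  for (i in 1:4) {
    coll2$alleles[i, , ] <- starters$alleles["VL1", , ]
    coll2$alleles[i, i, 1] <- coll2$alleles[i, i, 1] + 3L
  }
  net2 <- starter_network(coll2, starters, "VL1")
  expect_equal(net2$star_likeness, 1)
  ## no related isolates: empty network with a warning
  far <- random_coll(5, L = 17, seed = 74)
  expect_warning(net3 <- starter_network(far, starters, "VL1"), "no isolates")
  expect_true(is.na(net3$star_likeness))
})

test_that("star-likeness separates recent expansion from an old cluster", {
  set.seed(99)
  pan <- toy_panel(17)
  starters <- simulate_starters(pan, seed = 80)
  base <- starters$alleles["F15", , ]
  mk <- function(prof, steps) {
    for (k in seq_len(steps)) {
      l <- sample(17, 1); s <- sample(2, 1)
      prof[l, s] <- prof[l, s] + sample(c(-3L, 3L), 1)
    }
    prof
  }
  wins <- 0
  for (rep in 1:10) {
    ## recent expansion: independent 1-step variants of the starter
    recent <- lapply(1:8, function(i) mk(base, 1))
    ## old cluster: serial accumulation, a chain drifting away
    prof <- base; old <- list()
    for (i in 1:8) { prof <- mk(prof, 1); old[[i]] <- prof }
    c_rec <- make_coll(recent, pan, ids = sprintf("r%02d", 1:8))
    c_old <- make_coll(old, pan, ids = sprintf("o%02d", 1:8))
    s_rec <- starter_network(c_rec, starters, "F15")$star_likeness
    s_old <- starter_network(c_old, starters, "F15")$star_likeness
    if (s_rec >= s_old) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
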