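test_that("AMOVA components match a hand-computed balanced micro-example", {
  ## 2 populations x 2 individuals x 1 locus, allele-identity distances
  pan <- toy_panel(1)
  genos <- list(matrix(c(120, 120), 1, 2), matrix(c(120, 123), 1, 2),
                matrix(c(126, 126), 1, 2), matrix(c(126, 123), 1, 2))
  coll <- make_coll(genos, pan, meta_extra = data.frame(pop = c("A", "A", "B", "B")))
  res <- amova(coll, "pop", n_perm = 0)
  oracle <- bf_amova_balanced(
    alleles_by_ind = list(c(120, 120), c(120, 123), c(126, 126), c(126, 123)),
    pop_of = c(1, 1, 2, 2))
  expect_equal(res$sigma, unname(oracle), tolerance = 1e-12)
  expect_equal(res$df, c(1L, 2L, 4L))
  ## Phi definitions from the components
  expect_equal(res$phi[1], oracle["pop"] / sum(oracle), ignore_attr = TRUE)
  expect_equal(res$phi[2], oracle["ind"] / (oracle["ind"] + oracle["within"]),
               ignore_attr = TRUE)
})

test_that("complete fixation gives Phi = Fst = 1; panmixia gives ~0 with null p", {
  pan <- toy_panel(5)
  a <- array(0L, dim = c(6, 5, 2))
  a[1:3, , ] <- 120L; a[4:6, , ] <- 150L
  coll <- mlg_collection(a, pan, data.frame(individual_id = sprintf("i%d", 1:6),
                                            pop = rep(c("A", "B"), each = 3)))
  res <- amova(coll, "pop", n_perm = 0)
  expect_equal(res$phi[1], 1)
  expect_equal(pairwise_fst(coll, "pop", n_perm = 0)$fst[1, 2], 1)
  expect_equal(pairwise_fst(coll, "pop", n_perm = 0, method = "wc")$fst[1, 2], 1)
  ## random labels on a panmictic sample: small Phi, non-significant p
  coll2 <- panmictic_sample(n = 40, seed = 17)
  coll2$meta$fake <- rep(c("g1", "g2"), 20)
  res2 <- amova(coll2, "fake", n_perm = 99, seed = 2)
  expect_lt(abs(res2$phi[1]), 0.05)
  expect_gt(res2$p_value[1], 0.05)
})

test_that("the two-level model decomposes estates within appellations", {
  coll <- simulate_metapopulation(sim_config(
    n_pops = 9, pop_sizes = 40, generations = 80, n_appellations = 3,
    m_within = 0.05, m_between = 0.002, selfing_rate = 0.5,
    starter_fraction = 0, missing_rate = 0, sample_size = 20,
    clonal_skew = 100, n_founders = 40, seed = 77))
  res <- amova(coll, c("appellation", "estate"), n_perm = 99, seed = 1)
  expect_equal(res$level, c("appellation", "estate", "individual",
                            "within_individual"))
  expect_equal(res$df[1:2], c(2L, 6L))
  ## appellations are the differentiated level under this migration scheme
  expect_gt(res$phi[1], 0.02)
  expect_lt(res$p_value[1], 0.05)
  ## components account for the total (percentages sum to 100)
  expect_equal(sum(res$pct), 100, tolerance = 1e-9)
  ## model validation
  expect_error(amova(coll, c("compartment")), "single group")
})

test_that("gene-copy AMOVA Phi_ST equals Weir-Cockerham theta under random mating", {
  coll <- island_sample(d = 4, N = 40, Nm = 1, seed = 31, sample_size = 25,
                        generations = 80)
  phi <- amova(coll, "estate", n_perm = 0)$phi[1]
  theta <- wc_fst(coll, "estate")
  expect_equal(phi, theta, tolerance = 1e-9)
})

test_that("pairwise Fst: symmetry, duplicates invariance, small-group exclusion", {
  coll <- island_sample(d = 3, N = 40, Nm = 0.5, seed = 13, sample_size = 15,
                        generations = 80)
  f <- pairwise_fst(coll, "estate", n_perm = 99, seed = 4)
  expect_equal(f$fst, t(f$fst))
  expect_true(all(diag(f$fst) == 0))
  expect_true(all(f$p[upper.tri(f$p)] >= 1 / 100))
  ## strong structure is detected
  expect_true(all(f$p[upper.tri(f$p)] <= 0.05))
  ## duplicating every individual leaves Fst nearly unchanged
  dup <- coll
  ids2 <- paste0(individual_ids(coll), "_b")
  dup$alleles <- coll$alleles; rownames(dup$alleles) <- ids2
  dup$meta$individual_id <- ids2
  both <- bind_collections(coll, dup)
  f2 <- pairwise_fst(both, "estate", n_perm = 0)
  expect_lt(max(abs(f2$fst - pairwise_fst(coll, "estate", n_perm = 0)$fst)),
            0.03)
  ## groups of size < 2 are dropped with a warning
  coll$meta$estate[1] <- "lonely"
  expect_warning(f3 <- pairwise_fst(coll, "estate", n_perm = 0), "n < 2")
  expect_false("lonely" %in% rownames(f3$fst))
})

test_that("Mantel: perfect correlation, exhaustive p, vegan parity", {
  set.seed(6)
  pts <- cbind(runif(5), runif(5))
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(letters[1:5], letters[1:5])
  mt <- mantel_test(dm, 2 * dm, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$p, 1 / 100)  # identity permutation is always >= itself
  ## exhaustive enumeration vs Monte Carlo within binomial error
  dm2 <- as.matrix(dist(cbind(runif(5), runif(5))))
  dimnames(dm2) <- dimnames(dm)
  ex <- mantel_test(dm, dm2, exhaustive = TRUE)
  expect_equal(ex$n_perm, factorial(5))
  mc <- mantel_test(dm, dm2, n_perm = 999, seed = 9)
  tol <- 3 * sqrt(ex$p * (1 - ex$p) / 999) + 2 / 1000
  expect_lt(abs(mc$p - ex$p), tol)
  ## statistic parity with vegan
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(dm, dm2, permutations = 0)
  expect_equal(mt <- mantel_test(dm, dm2, n_perm = 99, seed = 1)$r,
               as.numeric(vg$statistic), tolerance = 1e-12)
  ## label reordering is honored
  perm <- c(2:5, 1)
  expect_equal(mantel_test(dm, dm2[perm, perm], n_perm = 99, seed = 1)$r,
               mantel_test(dm, dm2, n_perm = 99, seed = 1)$r, tolerance = 1e-12)
  dm3 <- dm2; rownames(dm3) <- colnames(dm3) <- LETTERS[1:5]
  expect_error(mantel_test(dm, dm3), "labels differ")
})

test_that("pop_summary computes Ho, unbiased He, Fis and allelic richness", {
  pan <- toy_panel(1)
  ## all homozygous
  hom <- make_coll(list(matrix(c(120, 120), 1, 2), matrix(c(123, 123), 1, 2)),
                   pan, meta_extra = data.frame(pop = "A"))
  ps <- pop_summary(hom, "pop")
  expect_equal(ps$Ho, 0)
  ## two heterozygotes A/a: p = 0.5, n = 2 -> He = (4/3) * 0.5
  het <- make_coll(list(matrix(c(120, 123), 1, 2), matrix(c(120, 123), 1, 2)),
                   pan, meta_extra = data.frame(pop = "A"))
  ps2 <- pop_summary(het, "pop")
  expect_equal(ps2$Ho, 1)
  expect_equal(ps2$He, 4 / 3 * 0.5, tolerance = 1e-12)
  ## richness at full depth equals the observed allele count
  expect_equal(ps2$allelic_richness, 2, tolerance = 1e-9)
  expect_error(pop_summary(het, "pop", rarefy_to = 10), "exceeds")
  ## He ~ 0.5 for a biallelic HWE locus at p = 0.5
  set.seed(3)
  genos <- lapply(1:200, function(i)
    matrix(sort(sample(c(120L, 123L), 2, TRUE)), 1, 2))
  big <- make_coll(genos, pan, meta_extra = data.frame(pop = "A"),
                   ids = sprintf("x%03d", 1:200))
  expect_equal(pop_summary(big, "pop")$He, 0.5, tolerance = 0.05)
})

test_that("balanced_fst is deterministic, null-centered, and capped", {
  coll <- panmictic_sample(n = 80, seed = 23)
  coll$meta$compartment <- rep(c("grape", "cellar"), 40)
  coll$meta$estate2 <- rep(c("e1", "e2", "e3", "e4"), each = 20)
  b1 <- balanced_fst(coll, "compartment", "grape", "cellar",
                     group_stratum = "estate2", cap = 10, n_reps = 20, seed = 7)
  b2 <- balanced_fst(coll, "compartment", "grape", "cellar",
                     group_stratum = "estate2", cap = 10, n_reps = 20, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(abs(b1$mean_fst), 0.05)   # same panmictic pool on both sides
  expect_error(balanced_fst(coll, "compartment", "grape", "nope"), "empty side")
  expect_error(balanced_fst(coll, "compartment", "grape", "cellar", cap = 1),
               "cap")
})
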