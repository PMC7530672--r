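test_that("bruvo_locus reproduces the closed forms", {
  expect_equal(bruvo_locus(c(20, 22), c(20, 22)), 0)
  expect_equal(bruvo_locus(c(20, 20), c(21, 20)), (1 - 2^-1) / 2)  # one step, one allele
  expect_equal(bruvo_locus(c(10, 10), c(11, 12)), 0.625)           # min over matchings
  expect_equal(bruvo_locus(c(10, 12), c(12, 10)), 0)               # unordered pairs
  expect_true(is.na(bruvo_locus(c(NA, NA), c(10, 11))))
  ## symmetry and range on random pairs
  set.seed(1)
  for (k in 1:50) {
    a <- sample(10:40, 2, TRUE); b <- sample(10:40, 2, TRUE)
    d <- bruvo_locus(a, b)
    expect_identical(d, bruvo_locus(b, a))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("bruvo_matrix equals the brute-force oracle to 1e-12", {
  coll <- random_coll(12, L = 17, seed = 77)
  coll$alleles[3, 5, ] <- NA_integer_   # exercise locus exclusion
  coll$alleles[8, c(1, 9), ] <- NA_integer_
  d <- bruvo_matrix(coll)
  bf <- bf_bruvo_matrix(coll)
  expect_lt(max(abs(d - bf)), 1e-12)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  ## every allele comparison >= 8 repeats apart: distance approaches 1
  far <- coll
  far$alleles[1, , ] <- 90L                 # homozygous 30 repeats
  far$alleles[2, , ] <- 90L + 8L * 3L       # homozygous 38 repeats
  expect_gte(bruvo_matrix(far)["i01", "i02"], 1 - 2^-8)
})

test_that("allele sharing uses multiset intersection with locus exclusion", {
  coll <- random_coll(2, L = 17, seed = 5)
  coll$alleles[2, , ] <- coll$alleles[1, , ]
  expect_equal(as.numeric(allele_sharing(subset_collection(coll, 1),
                                         subset_collection(coll, 2))), 1)
  ## both alleles differ at 2 of 17 loci -> 30/34
  coll$alleles[2, 4, ] <- coll$alleles[1, 4, ] + 300L
  coll$alleles[2, 11, ] <- coll$alleles[1, 11, ] + 300L
  expect_equal(as.numeric(allele_sharing(subset_collection(coll, 1),
                                         subset_collection(coll, 2))), 30 / 34)
  ## heterozygote {10,12} vs homozygote {10,10}: that locus contributes 1/2
  pan <- toy_panel(2)
  a <- make_coll(list(matrix(c(30, 36, 60, 63), 2, 2, byrow = TRUE)), pan)
  b <- make_coll(list(matrix(c(30, 30, 60, 63), 2, 2, byrow = TRUE)), pan)
  expect_equal(as.numeric(allele_sharing(a, b)), 3 / 4)
  ## missing loci excluded and counted
  b2 <- b; b2$alleles[1, 1, ] <- NA_integer_
  s <- allele_sharing(a, b2)
  expect_equal(as.numeric(s), 1)
  expect_equal(attr(s, "n_excluded"), 1L)
  ## the pairwise matrix agrees with the per-pair oracle
  coll2 <- random_coll(8, L = 6, seed = 9)
  coll2$alleles[2, 3, ] <- NA_integer_
  m <- allele_sharing_matrix(coll2)
  for (i in 1:8) for (j in 1:8)
    expect_equal(m[i, j], bf_sharing(coll2, i, j))
})

test_that("NJ preserves additive distances and midpoint-roots deterministically", {
  ## 3 taxa: cophenetic distances solve the three-point formulas exactly
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  co <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(co, dm, tolerance = 1e-10)
  ## ultrametric 4-taxon matrix: generating topology recovered
  dm4 <- matrix(c(0, 2, 6, 6,
                  2, 0, 6, 6,
                  6, 6, 0, 3,
                  6, 6, 3, 0), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- nj_tree(dm4)
  ## (a,b) and (c,d) must be cherries
  pairs <- ape::prop.part(tr4)
  expect_equal(ape::cophenetic.phylo(tr4)[letters[1:4], letters[1:4]], dm4,
               tolerance = 1e-10)
  ## label-order permutation leaves the rooted topology unchanged
  perm <- c(3, 1, 4, 2)
  trp <- nj_tree(dm4[perm, perm])
  expect_equal(phangorn::RF.dist(tr4, trp, rooted = TRUE), 0)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("spanning networks are minimal, deterministic and star-aware", {
  ## 2 nodes: the single edge
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  n2 <- spanning_network(dm2)
  expect_equal(nrow(n2$edges), 1L)
  expect_equal(n2$edges$weight, 0.4)
  ## star-shaped truth is recovered
  k <- 5
  labs <- c("hub", paste0("s", 1:k))
  dm <- matrix(0.6, k + 1, k + 1, dimnames = list(labs, labs))
  dm[1, -1] <- dm[-1, 1] <- 0.1
  diag(dm) <- 0
  st <- spanning_network(dm)
  expect_true(all(st$edges$from == "hub" | st$edges$to == "hub"))
  ## exhaustive minimality for n <= 6 random matrices
  set.seed(8)
  for (n in 4:6) {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    net <- spanning_network(m)
    expect_equal(sum(net$edges$weight), bf_mst_weight(m), tolerance = 1e-12)
    if (requireNamespace("igraph", quietly = TRUE)) {
      g <- igraph::graph_from_adjacency_matrix(m, weighted = TRUE,
                                               mode = "undirected")
      expect_equal(sum(net$edges$weight),
                   sum(igraph::E(igraph::mst(g))$weight), tolerance = 1e-12)
    }
  }
  ## MLG multiplicities decorate the nodes
  coll <- random_coll(4, L = 5, seed = 2)
  coll$alleles[2, , ] <- coll$alleles[1, , ]
  part <- find_mlgs(coll)
  reps <- part$representatives
  dmm <- bruvo_matrix(subset_collection(coll, reps))
  net <- spanning_network(dmm, part)
  expect_equal(net$nodes$size[net$nodes$id == "i01"], 2L)
})
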