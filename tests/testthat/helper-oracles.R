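## Fixture builders and independent brute-force oracles.
## Oracles are written as plain loops, deliberately separate from the
## vectorized package implementations they check.

toy_panel <- function(L = 2, motif = 3L) {
  locus_panel(sprintf("L%02d", seq_len(L)), motif)
}

## build a collection from a list of genotypes: each element is an L x 2
## matrix of allele sizes (NA = missing)
make_coll <- function(genos, panel = NULL, meta_extra = NULL,
                      ids = sprintf("i%02d", seq_along(genos))) {
  L <- nrow(genos[[1]])
  if (is.null(panel)) panel <- toy_panel(L)
  a <- array(NA_integer_, dim = c(length(genos), L, 2),
             dimnames = list(ids, panel$locus, NULL))
  for (i in seq_along(genos)) a[i, , ] <- as.integer(genos[[i]])
  meta <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta_extra)) meta <- cbind(meta, meta_extra)
  mlg_collection(a, panel, meta)
}

## random complete diploid genotypes in a small repeat range, bp scale
random_coll <- function(n, L = 17, motif = 3L, seed = 1,
                        meta_extra = NULL) {
  set.seed(seed)
  genos <- lapply(seq_len(n), function(i) {
    matrix(sample(30:45, 2 * L, replace = TRUE) * motif, L, 2)
  })
  make_coll(genos, toy_panel(L, motif), meta_extra)
}

## ---- Bruvo oracle: plain loops over loci and the two matchings ----------
bf_bruvo_matrix <- function(coll) {
  ru <- to_repeat_units(coll)
  n <- n_ind(coll)
  L <- n_loci(coll)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- 0; cnt <- 0
    for (l in seq_len(L)) {
      a <- ru[i, l, ]; b <- ru[j, l, ]
      if (anyNA(a) || anyNA(b)) next
      da <- function(x, y) 1 - 2^(-abs(x - y))
      m1 <- (da(a[1], b[1]) + da(a[2], b[2])) / 2
      m2 <- (da(a[1], b[2]) + da(a[2], b[1])) / 2
      acc <- acc + min(m1, m2)
      cnt <- cnt + 1
    }
    d[i, j] <- acc / cnt
  }
  d
}

## ---- allele-sharing oracle: explicit multiset intersection ---------------
bf_sharing <- function(coll, i, j) {
  num <- 0; den <- 0
  for (l in seq_len(n_loci(coll))) {
    a <- coll$alleles[i, l, ]; b <- coll$alleles[j, l, ]
    if (anyNA(a) || anyNA(b)) next
    bb <- b
    s <- 0
    for (x in a) {
      hit <- match(x, bb)
      if (!is.na(hit)) { s <- s + 1; bb <- bb[-hit] }
    }
    num <- num + s; den <- den + 2
  }
  if (den == 0) NA_real_ else num / den
}

## ---- minimum-spanning-tree oracle: enumerate all labeled trees ----------
## via Pruefer sequences (n^(n-2) trees), n <= 6
bf_mst_weight <- function(dm) {
  n <- nrow(dm)
  if (n == 2) return(dm[1, 2])
  prufer_to_edges <- function(seq) {
    n <- length(seq) + 2
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, seq[k])
      degree[leaf] <- 0L
      degree[seq[k]] <- degree[seq[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  combs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(combs))) {
    ed <- prufer_to_edges(combs[r, ])
    w <- sum(dm[ed])
    if (w < best) best <- w
  }
  best
}

## ---- balanced 2x2x2 nested ANOVA oracle for gene-copy AMOVA --------------
## pops/individuals/copies all balanced; allele-identity distance.
## Returns variance components (pop, ind, within) from classical mean squares.
bf_amova_balanced <- function(alleles_by_ind, pop_of) {
  copies <- unlist(alleles_by_ind)
  ind_of <- rep(seq_along(alleles_by_ind), lengths(alleles_by_ind))
  popc <- pop_of[ind_of]
  N <- length(copies)
  d2 <- outer(copies, copies, function(x, y) as.numeric(x != y))
  ssw_cells <- function(f) {
    s <- 0
    for (cc in unique(f)) {
      idx <- which(f == cc)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_wp <- ssw_cells(popc)
  ss_wi <- ssw_cells(ind_of)
  P <- length(unique(popc)); I <- length(alleles_by_ind)
  ms_p <- (ss_tot - ss_wp) / (P - 1)
  ms_i <- (ss_wp - ss_wi) / (I - P)
  ms_w <- ss_wi / (N - I)
  n_cop <- N / I           # copies per individual (balanced)
  n_ip <- I / P            # individuals per pop (balanced)
  sig_w <- ms_w
  sig_i <- (ms_i - ms_w) / n_cop
  sig_p <- (ms_p - ms_i) / (n_cop * n_ip)
  c(pop = sig_p, ind = sig_i, within = sig_w)
}

## ---- small panmictic simulated sample for null tests ---------------------
panmictic_sample <- function(n = 40, seed = 1, selfing = 0.5) {
  cfg <- sim_config(n_pops = 1, pop_sizes = 100, generations = 50,
                    n_appellations = 1, migration_matrix = matrix(1, 1, 1),
                    selfing_rate = selfing, starter_fraction = 0,
                    missing_rate = 0, sample_size = n, clonal_skew = 100,
                    n_founders = 100, seed = seed)
  simulate_metapopulation(cfg)
}

## island-model sample: d demes, Nm migrants per deme per generation
island_sample <- function(d = 16, N = 50, Nm = 1, seed = 1, sample_size = 30,
                          generations = 200) {
  cfg <- sim_config(n_pops = d, pop_sizes = N, generations = generations,
                    n_appellations = 1,
                    migration_matrix = island_migration(d, Nm / N),
                    selfing_rate = 0, starter_fraction = 0, missing_rate = 0,
                    sample_size = sample_size, clonal_skew = 100,
                    n_founders = N, mutation_rate = 1e-4, seed = seed)
  simulate_metapopulation(cfg)
}
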