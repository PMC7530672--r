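#' Jost's D between two populations
#'
#' Allelic differentiation `D` estimated per locus from heterozygosities with
#' the sample-size corrections of Nei & Chesson: with harmonic-mean sample
#' size `n~` over the two populations, `Hs_est = 2n~/(2n~ - 1) * Hs`,
#' `Ht_est = Ht + Hs_est/(2 n~ k)` and
#' `D = k/(k-1) * (Ht_est - Hs_est)/(1 - Hs_est)` with `k = 2`. Per-locus
#' values are averaged arithmetically over loci and the result clamped to
#' `[0, 1]`. Loci monomorphic in both populations contribute `D = 0`.
#'
#' @param pop_a,pop_b [mlg_collection()]s (n >= 2 each) on the same panel.
#' @return Jost's D in `[0, 1]`.
#' @export
jost_d <- function(pop_a, pop_b) {
  if (!identical(pop_a$panel$locus, pop_b$panel$locus)) stop("panels differ")
  if (n_ind(pop_a) < 2L || n_ind(pop_b) < 2L)
    stop("both populations need n >= 2")
  L <- n_loci(pop_a)
  k <- 2
  dvals <- numeric(0)
  for (l in seq_len(L)) {
    ga <- c(pop_a$alleles[, l, 1], pop_a$alleles[, l, 2])
    gb <- c(pop_b$alleles[, l, 1], pop_b$alleles[, l, 2])
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- length(ga) / 2; nb <- length(gb) / 2
    if (na < 1 || nb < 1) next
    alleles <- sort(unique(c(ga, gb)))
    pa <- tabulate(match(ga, alleles), length(alleles)) / length(ga)
    pb <- tabulate(match(gb, alleles), length(alleles)) / length(gb)
    if (length(alleles) == 1L) { dvals <- c(dvals, 0); next }
    ntil <- 2 / (1 / na + 1 / nb)
    hs <- 1 - (sum(pa^2) + sum(pb^2)) / 2
    hs_est <- (2 * ntil) / (2 * ntil - 1) * hs
    pbar <- (pa + pb) / 2
    ht <- 1 - sum(pbar^2)
    ht_est <- ht + hs_est / (2 * ntil * k)
    if (1 - hs_est <= 0) next
    dvals <- c(dvals, (ht_est - hs_est) / (1 - hs_est) * k / (k - 1))
  }
  if (!length(dvals)) return(0)
  min(1, max(0, mean(dvals)))
}

#' Relative directional migration between populations
#'
#' The pooled-population method: for each ordered pair `(i, j)` a
#' hypothetical migrant-pool population is built as the union of the two
#' populations' individuals, and the relative gene flow from `i` into `j` is
#' taken as `Nm = (1/D - 1)/4` where `D` is Jost's D between the pool and the
#' source `i`: a strong exporter keeps the pair's migrant pool stocked with
#' its own alleles and so sits closest to it, while the receiving population
#' accumulates diversity (forward simulations of one-way flow reproduce both
#' signatures). The matrix of directional values is normalized by its
#' maximum, so the strongest flow equals 1 exactly.
#'
#' Optional bootstrap (resampling individuals within populations with
#' replacement) yields percentile intervals for the directional asymmetry
#' `m[i,j] - m[j,i]`; a pair is flagged asymmetric when the 95% interval
#' excludes zero.
#'
#' @param coll an [mlg_collection()].
#' @param stratum metadata column defining the populations; groups with
#'   n < 2 are excluded.
#' @param n_boot bootstrap resamples for asymmetry intervals (0 = skip).
#' @param seed integer seed.
#' @return List of class `migration_matrix`: `m` (normalized directional
#'   migration, rows = source, cols = destination, diagonal `NA`), `d`
#'   (`d[i, j]` = Jost's D between the `(i, j)` pool and the source `i`),
#'   and when `n_boot > 0` `asym_ci`
#'   (lower/upper 95% bounds per ordered pair) and `asymmetric` (logical
#'   matrix).
#' @export
directional_migration <- function(coll, stratum, n_boot = 0L, seed = NULL) {
  g <- as.character(get_stratum(coll, stratum))
  sizes <- table(g)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < 2L) stop("need at least two populations with n >= 2")
  if (length(keep) < length(sizes))
    warning("excluding group(s) with n < 2: ",
            paste(setdiff(names(sizes), keep), collapse = ", "))
  pops <- sort(keep)
  idx <- lapply(pops, function(p) which(g == p))
  names(idx) <- pops
  if (!is.null(seed)) set.seed(seed)

  mig_matrix <- function(index_list) {
    k <- length(index_list)
    d <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    m <- d
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      pool <- subset_collection(coll, c(index_list[[i]], index_list[[j]]))
      src <- subset_collection(coll, index_list[[i]])
      dij <- jost_d(pool, src)
      d[i, j] <- dij
      m[i, j] <- (1 / max(dij, 1e-6) - 1) / 4
    }
    mx <- max(m, na.rm = TRUE)
    if (mx > 0) m <- m / mx
    list(m = m, d = d)
  }

  obs <- mig_matrix(idx)
  out <- list(m = obs$m, d = obs$d, populations = pops)
  if (n_boot > 0) {
    k <- length(pops)
    boots <- array(NA_real_, dim = c(k, k, n_boot))
    for (b in seq_len(n_boot)) {
      bidx <- lapply(idx, function(x) sample(x, length(x), replace = TRUE))
      boots[, , b] <- mig_matrix(bidx)$m
    }
    lo <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    hi <- lo
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i >= j) next
      diffs <- boots[i, j, ] - boots[j, i, ]
      qs <- stats::quantile(diffs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo[i, j] <- qs[1]; hi[i, j] <- qs[2]
    }
    out$asym_ci <- list(lower = lo, upper = hi)
    out$asymmetric <- !is.na(lo) & (lo > 0 | hi < 0)
  }
  class(out) <- "migration_matrix"
  out
}

#' @export
print.migration_matrix <- function(x, ...) {
  cat("<migration_matrix> relative directional migration",
      "(rows = source, cols = destination)\n")
  print(round(x$m, 3))
  invisible(x)
}
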