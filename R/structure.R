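## ---------------------------------------------------------------------------
## Nested variance-component engine (Excoffier-style AMOVA)
##
## Units (gene copies or individuals) are nested in K levels of cells.
## SS within cells at level l is computed either from allele counts
## (identity distance between gene copies) or from a squared-distance matrix:
##   SS_w(l) = sum_cells (1/N_c) sum_{i<j in c} d2_ij.
## Expected sums of squares for the random nested model give a triangular
## system in the variance components, solved per locus (or once for a
## distance matrix) with unbalanced-design coefficients
##   S_m(l) = sum_{cells d at level m} N_d^2 / N_{anc_l(d)}.
## ---------------------------------------------------------------------------

## coefficient matrix + df for a nested design; cells = list of integer cell
## codes per unit, top level first (must be nested)
nested_coeffs <- function(cells, N) {
  K <- length(cells)
  C <- vapply(cells, max, integer(1))
  ncomp <- K + 1L
  Sfun <- function(m, l) {
    cm <- cells[[m]]
    Nd <- tabulate(cm, C[m])
    if (l == 0L) return(sum(Nd^2) / N)
    clv <- cells[[l]]
    anc <- clv[match(seq_len(C[m]), cm)]
    Na <- tabulate(clv, C[l])[anc]
    sum(Nd^2 / Na)
  }
  vmat <- matrix(0, K + 1L, ncomp)
  for (l in 0:K) {
    for (m in seq_len(K)) vmat[l + 1L, m] <- if (m <= l) N else Sfun(m, l)
    vmat[l + 1L, ncomp] <- if (l == 0L) 1 else C[l]
  }
  vunits <- rep(N, ncomp)
  Amat <- rbind(vmat[-1L, , drop = FALSE] - vmat[-(K + 1L), , drop = FALSE],
                vunits - vmat[K + 1L, ])
  df <- c(C - c(1L, C[-K]), N - C[K])
  list(Amat = Amat, df = df, C = C)
}

## allele-identity AMOVA for one locus on gene copies
## al: allele codes (1..A) per gene copy; cells: nested cell codes per copy
amova_locus <- function(al, cells) {
  N <- length(al)
  K <- length(cells)
  cells <- lapply(cells, function(x) as.integer(factor(x)))
  A <- max(al)
  co <- nested_coeffs(cells, N)
  ssw <- numeric(K + 1L)
  cnt0 <- tabulate(al, A)
  ssw[1L] <- (N - sum(cnt0^2) / N) / 2
  for (l in seq_len(K)) {
    cl <- cells[[l]]
    Cl <- co$C[l]
    cnt <- tabulate((cl - 1L) * A + al, nbins = A * Cl)
    Nc <- tabulate(cl, Cl)
    sum2 <- colSums(matrix(cnt, A, Cl)^2)
    ok <- Nc > 0
    ssw[l + 1L] <- sum((Nc[ok] - sum2[ok] / Nc[ok]) / 2)
  }
  SS <- c(-diff(ssw), ssw[K + 1L])
  sigma <- tryCatch(as.numeric(solve(co$Amat, SS)),
                    error = function(e) rep(NA_real_, K + 1L))
  list(sigma = sigma, SS = SS, df = co$df)
}

## distance-based AMOVA: d2 = squared-distance matrix between units
amova_dist <- function(d2, cells) {
  N <- nrow(d2)
  K <- length(cells)
  cells <- lapply(cells, function(x) as.integer(factor(x)))
  co <- nested_coeffs(cells, N)
  ssw <- numeric(K + 1L)
  ssw[1L] <- sum(d2[upper.tri(d2)]) / N
  for (l in seq_len(K)) {
    cl <- cells[[l]]
    s <- 0
    for (cc in seq_len(co$C[l])) {
      idx <- which(cl == cc)
      if (length(idx) > 1L)
        s <- s + sum(d2[idx, idx, drop = FALSE][upper.tri(diag(length(idx)))]) /
          length(idx)
    }
    ssw[l + 1L] <- s
  }
  SS <- c(-diff(ssw), ssw[K + 1L])
  sigma <- tryCatch(as.numeric(solve(co$Amat, SS)),
                    error = function(e) rep(NA_real_, K + 1L))
  list(sigma = sigma, SS = SS, df = co$df)
}

## nested cell codes from a strata data frame (one row per unit)
strata_cells <- function(strata_df) {
  lapply(seq_along(strata_df), function(l) {
    as.integer(interaction(strata_df[seq_len(l)], drop = TRUE, lex.order = TRUE))
  })
}

## summed variance components over loci for the gene-copy allele AMOVA
## locus_data: list of (al, ind) per locus; strata_df over individuals;
## within = add an individual level below the strata
gc_amova_components <- function(locus_data, strata_df, within = TRUE) {
  base_cells <- strata_cells(strata_df)
  K <- length(base_cells) + if (within) 1L else 0L
  tot <- numeric(K + 1L)
  for (ld in locus_data) {
    cells <- lapply(base_cells, function(x) x[ld$ind])
    if (within) cells <- c(cells, list(ld$ind))
    a <- amova_locus(ld$al, cells)
    if (!anyNA(a$sigma)) tot <- tot + a$sigma
  }
  tot
}

## per-locus gene-copy data for the allele AMOVA
gc_locus_data <- function(coll) {
  codes <- locus_codes(coll, units = "bp")
  lapply(codes, function(cod) {
    valid <- which(!is.na(cod[, 1]))
    list(al = c(cod[valid, 1], cod[valid, 2]), ind = c(valid, valid))
  })
}

phi_from_sigma <- function(sigma) {
  K <- length(sigma)
  vapply(seq_len(K - 1L), function(m) {
    den <- sum(sigma[m:K])
    if (!is.finite(den) || den == 0) NA_real_ else sigma[m] / den
  }, numeric(1))
}

#' Hierarchical AMOVA with Phi statistics and permutation tests
#'
#' Analysis of molecular variance for codominant diploid microsatellite data.
#' With `distance = "allele"` (default) the decomposition runs per locus on
#' gene copies with allele-identity distances, including a within-individual
#' level (`within_individuals = TRUE`), and variance components are summed
#' over loci; the Phi for the individual level is the AMOVA analogue of Fis
#' ("Phi for individuals"). With `distance = "bruvo"` the analysis runs at the
#' individual level on the Bruvo matrix (treated as squared distances).
#'
#' P-values are permutational: for the lowest stratum, individuals are
#' permuted among groups within their parent stratum; for higher strata,
#' whole subgroups are permuted among groups. Each reported
#' `p >= 1/(n_perm+1)`.
#'
#' @param coll an [mlg_collection()].
#' @param strata character vector of metadata columns, outermost first, e.g.
#'   `c("appellation", "estate")`.
#' @param n_perm permutations per tested level (default 999; 0 skips tests).
#' @param distance `"allele"` or `"bruvo"`.
#' @param within_individuals include the within-individual level
#'   (`"allele"` distance only).
#' @param seed integer seed for the permutations.
#' @return An `amova_result`: data frame with one row per level (each
#'   stratum, `individual` when applicable, `within_individual`/`residual`)
#'   and columns `df`, `sigma` (variance component), `pct` (percent of total,
#'   from raw components), `phi`, `p_value`.
#' @export
amova <- function(coll, strata, n_perm = 999L,
                  distance = c("allele", "bruvo"),
                  within_individuals = TRUE, seed = NULL) {
  distance <- match.arg(distance)
  if (n_perm > 0 && n_perm < 99) stop("use n_perm >= 99 (or 0 to skip tests)")
  strata_df <- as.data.frame(lapply(strata, function(s)
    as.character(get_stratum(coll, s))), col.names = strata,
    stringsAsFactors = FALSE)
  cells0 <- strata_cells(strata_df)
  Cs <- vapply(cells0, max, integer(1))
  if (Cs[1] < 2L) stop("top stratum '", strata[1], "' has a single group")
  if (length(Cs) > 1L && any(diff(Cs) == 0L))
    stop("a nested stratum adds no groups below its parent")
  use_gc <- distance == "allele" && within_individuals
  n <- n_ind(coll)
  if (use_gc) {
    locus_data <- gc_locus_data(coll)
    comp_fn <- function(sdf) gc_amova_components(locus_data, sdf, within = TRUE)
    level_names <- c(strata, "individual", "within_individual")
    df_cells <- c(cells0, list(seq_len(n)))
    df <- nested_coeffs(lapply(df_cells, function(x) as.integer(factor(rep(x, 2)))),
                        2L * n)$df
  } else {
    d2 <- if (distance == "bruvo") bruvo_matrix(coll) else genotype_dist2(coll)
    comp_fn <- function(sdf) amova_dist(d2, strata_cells(sdf))$sigma
    level_names <- c(strata, "residual")
    df <- nested_coeffs(cells0, n)$df
  }
  sigma <- comp_fn(strata_df)
  phi <- phi_from_sigma(sigma)
  Ks <- length(strata)
  pvals <- rep(NA_real_, length(sigma))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (m in seq_len(Ks)) {
      obs <- phi[m]
      if (is.na(obs)) next
      hits <- 0L
      for (b in seq_len(n_perm)) {
        sdf <- permute_stratum(strata_df, m)
        ph <- phi_from_sigma(comp_fn(sdf))[m]
        if (!is.na(ph) && ph >= obs) hits <- hits + 1L
      }
      pvals[m] <- (hits + 1) / (n_perm + 1)
    }
  }
  tot <- sum(sigma)
  out <- data.frame(level = level_names, df = df, sigma = sigma,
                    pct = if (tot > 0) 100 * sigma / tot else NA_real_,
                    phi = c(phi, NA_real_), p_value = pvals,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "distance") <- distance
  if (any(sigma < 0, na.rm = TRUE))
    attr(out, "negative_components") <- TRUE
  class(out) <- c("amova_result", "data.frame")
  out
}

## permute level m of a strata data frame:
## m == ncol: shuffle the level-m labels of individuals within each parent
## m <  ncol: shuffle the level-m labels of the level-(m+1) subgroups within
##            each parent
permute_stratum <- function(strata_df, m) {
  K <- ncol(strata_df)
  parent <- if (m == 1L) rep("", nrow(strata_df))
            else do.call(paste, c(strata_df[seq_len(m - 1L)], sep = "\r"))
  out <- strata_df
  if (m == K) {
    for (p in unique(parent)) {
      idx <- which(parent == p)
      out[[m]][idx] <- strata_df[[m]][idx[sample.int(length(idx))]]
    }
  } else {
    sub <- do.call(paste, c(strata_df[seq_len(m + 1L)], sep = "\r"))
    usub <- unique(sub)
    up <- parent[match(usub, sub)]
    newlab <- strata_df[[m]][match(usub, sub)]
    for (p in unique(up)) {
      idx <- which(up == p)
      newlab[idx] <- newlab[idx[sample.int(length(idx))]]
    }
    out[[m]] <- newlab[match(sub, usub)]
  }
  out
}

#' Squared genotypic distance matrix (codominant allele metric)
#'
#' Per locus, half the squared Euclidean distance between the two genotypes'
#' allele-count vectors: 0 (identical pairs), 1 (one shared allele), and for
#' disjoint pairs 2 + (number of homozygotes among the two genotypes), summed
#' over loci typed in both individuals and rescaled by `L / L_compared`.
#' This is the genotypic distance underlying PhiPT-style AMOVA Fst.
#'
#' @param coll an [mlg_collection()].
#' @return Symmetric labelled matrix of squared distances.
#' @export
genotype_dist2 <- function(coll) {
  n <- n_ind(coll); L <- n_loci(coll)
  acc <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- coll$alleles[, l, 1]; a2 <- coll$alleles[, l, 2]
    ok <- !is.na(a1)
    A1 <- matrix(a1, n, n); A2 <- matrix(a2, n, n)
    B1 <- t(A1); B2 <- t(A2)
    sh <- matrix(shared_counts(A1, A2, B1, B2), n, n)
    hom <- a1 == a2
    H <- matrix(hom, n, n) + matrix(hom, n, n, byrow = TRUE)
    d <- ifelse(sh == 2L, 0, ifelse(sh == 1L, 1, 2 + H))
    okm <- outer(ok, ok, "&")
    d[!okm] <- 0
    acc <- acc + d
    cnt <- cnt + okm
  }
  if (any(cnt[upper.tri(cnt)] == 0L))
    stop("some pair of individuals shares no typed locus")
  out <- acc * L / cnt
  diag(out) <- 0
  dimnames(out) <- list(individual_ids(coll), individual_ids(coll))
  out
}

## one-level PhiPT from a squared-distance matrix and group factor
phipt_stat <- function(d2, g) {
  a <- amova_dist(d2, list(as.integer(g)))
  s <- a$sigma
  den <- sum(s)
  if (!is.finite(den) || den == 0) return(NA_real_)
  s[1] / den
}

#' Weir-Cockerham Fst (theta)
#'
#' Multi-locus, multi-allele theta of Weir & Cockerham (1984): per-locus,
#' per-allele components a (among populations), b (among individuals within
#' populations) and c (within individuals) are summed over alleles and loci;
#' `theta = sum(a) / sum(a + b + c)`.
#'
#' @param coll an [mlg_collection()].
#' @param stratum metadata column defining the populations.
#' @return theta (scalar).
#' @export
wc_fst <- function(coll, stratum) {
  g <- get_stratum(coll, stratum)
  wc_fst_factor(coll, g)
}

wc_fst_factor <- function(coll, g) {
  r <- nlevels(g)
  if (r < 2L) stop("need at least two populations")
  suma <- 0; sumabc <- 0
  for (l in seq_len(n_loci(coll))) {
    a1 <- coll$alleles[, l, 1]; a2 <- coll$alleles[, l, 2]
    ok <- !is.na(a1)
    gi <- g[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    ni <- as.numeric(table(gi))
    if (any(ni == 0)) next
    alleles <- unique(c(x1, x2))
    nbar <- mean(ni)
    rr <- length(ni)
    nc <- (rr * nbar - sum(ni^2) / (rr * nbar)) / (rr - 1)
    if (nc <= 0) next
    for (al in alleles) {
      cnt <- tapply((x1 == al) + (x2 == al), gi, sum)
      p_i <- as.numeric(cnt) / (2 * ni)
      h_i <- as.numeric(tapply((x1 == al) != (x2 == al), gi, mean))
      pbar <- sum(ni * p_i) / (rr * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((rr - 1) * nbar)
      hbar <- sum(ni * h_i) / (rr * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (rr - 1) / rr * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (rr - 1) / rr * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      suma <- suma + a
      sumabc <- sumabc + a + b + cc
    }
  }
  if (sumabc == 0) return(0)
  suma / sumabc
}

#' Pairwise Fst matrix with permutation tests
#'
#' For every pair of groups, Fst is estimated either as PhiPT (one-level
#' AMOVA on the squared genotypic distances, [genotype_dist2()]; default,
#' GenAlEx-compatible) or as Weir-Cockerham theta. Significance is assessed
#' by permuting individuals between the two groups;
#' `p = (1 + #(perm >= obs)) / (n_perm + 1)`.
#'
#' @param coll an [mlg_collection()].
#' @param stratum metadata column defining the groups; groups with fewer
#'   than 2 members are excluded with a warning.
#' @param n_perm permutations (default 999; 0 skips tests).
#' @param method `"phipt"` or `"wc"`.
#' @param seed integer seed.
#' @return List of class `fst_matrix`: `fst` and `p` (symmetric labelled
#'   matrices), `method`, `n_perm`.
#' @export
pairwise_fst <- function(coll, stratum, n_perm = 999L,
                         method = c("phipt", "wc"), seed = NULL) {
  method <- match.arg(method)
  g <- get_stratum(coll, stratum)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    coll <- subset_collection(coll, which(keep))
    g <- droplevels(g[keep])
  }
  grps <- levels(g)
  if (length(grps) < 2L) stop("need at least two groups of size >= 2")
  if (!is.null(seed)) set.seed(seed)
  k <- length(grps)
  fst <- matrix(0, k, k, dimnames = list(grps, grps))
  pm <- matrix(NA_real_, k, k, dimnames = list(grps, grps))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    idx <- which(g %in% c(grps[i], grps[j]))
    sub <- subset_collection(coll, idx)
    gg <- factor(as.character(g[idx]))
    if (method == "phipt") {
      d2 <- genotype_dist2(sub)
      obs <- phipt_stat(d2, gg)
      stat <- function(gp) phipt_stat(d2, gp)
    } else {
      obs <- wc_fst_factor(sub, gg)
      stat <- function(gp) wc_fst_factor(sub, gp)
    }
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gp <- gg[sample.int(length(gg))]
        s <- stat(gp)
        if (!is.na(s) && s >= obs) hits <- hits + 1L
      }
      pm[i, j] <- pm[j, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(fst = fst, p = pm, method = method, n_perm = n_perm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> method =", x$method, "\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles, with
#' significance from joint row/column permutation of the second matrix.
#' With `exhaustive = TRUE` (feasible for n <= 7) all `n!` permutations are
#' enumerated and the p-value is the exact proportion of permutations with
#' `r >= r_obs` (the identity included).
#'
#' @param dm1,dm2 symmetric labelled distance matrices over the same labels
#'   (dm2 is reordered to match dm1).
#' @param n_perm Monte-Carlo permutations (default 999).
#' @param exhaustive enumerate all permutations instead.
#' @param seed integer seed.
#' @return List `(r, p, n_perm, exhaustive)`.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 999L, exhaustive = FALSE,
                        seed = NULL) {
  dm1 <- as.matrix(dm1); dm2 <- as.matrix(dm2)
  n <- nrow(dm1)
  if (n < 4L) stop("need at least 4 labels")
  l1 <- rownames(dm1); l2 <- rownames(dm2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) stop("matrix labels differ")
    dm2 <- dm2[l1, l1]
  } else if (nrow(dm2) != n) stop("matrix dimensions differ")
  ut <- upper.tri(dm1)
  x <- dm1[ut]
  rstat <- function(perm) stats::cor(x, dm2[perm, perm][ut])
  r_obs <- rstat(seq_len(n))
  if (exhaustive) {
    perms <- all_perms(n)
    rs <- vapply(perms, rstat, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = length(perms), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (rstat(sample.int(n)) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       exhaustive = FALSE)
}

all_perms <- function(n) {
  if (n > 7L) stop("exhaustive enumeration limited to n <= 7")
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Great-circle distance matrix from site coordinates
#'
#' Haversine distances in kilometres from decimal-degree WGS84 coordinates.
#'
#' @param coords data frame with `id`, `latitude`, `longitude`
#'   (see [read_coordinates()]).
#' @return Symmetric labelled matrix (km).
#' @export
geo_distance_matrix <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(coords$id, coords$id))
  pts <- as.matrix(coords[, c("longitude", "latitude")])
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts) / 1000
  }
  (m + t(m)) / 2
}

#' Per-population heterozygosity and allelic richness summary
#'
#' For each group: sample size, observed heterozygosity `Ho` (mean over loci
#' of the fraction of heterozygous typed individuals), unbiased expected
#' heterozygosity `He = 2n/(2n-1) * (1 - sum p^2)` averaged over loci,
#' `Fis = 1 - Ho/He`, and allelic richness rarefied to `rarefy_to` gene
#' copies by the hypergeometric formula, averaged over loci.
#'
#' @param coll an [mlg_collection()].
#' @param stratum metadata column defining the populations.
#' @param rarefy_to gene-copy depth for allelic richness; default is the
#'   smallest number of typed gene copies over groups and loci. An explicit
#'   value exceeding that minimum is an error.
#' @return Data frame `(group, n, Ho, He, Fis, allelic_richness)`.
#' @export
pop_summary <- function(coll, stratum, rarefy_to = NULL) {
  g <- get_stratum(coll, stratum)
  L <- n_loci(coll)
  ## minimum typed gene copies per group x locus
  min_g <- Inf
  for (grp in levels(g)) {
    idx <- which(g == grp)
    for (l in seq_len(L)) {
      nt <- sum(!is.na(coll$alleles[idx, l, 1]))
      min_g <- min(min_g, 2 * nt)
    }
  }
  if (is.null(rarefy_to)) rarefy_to <- min_g
  if (rarefy_to > min_g)
    stop("rarefy_to = ", rarefy_to, " exceeds the smallest typed sample (",
         min_g, " gene copies)")
  out <- lapply(levels(g), function(grp) {
    idx <- which(g == grp)
    ho <- he <- ar <- numeric(0)
    for (l in seq_len(L)) {
      a1 <- coll$alleles[idx, l, 1]; a2 <- coll$alleles[idx, l, 2]
      ok <- !is.na(a1)
      nt <- sum(ok)
      if (nt == 0L) next
      ho <- c(ho, mean(a1[ok] != a2[ok]))
      cnt <- table(c(a1[ok], a2[ok]))
      p <- cnt / (2 * nt)
      he <- c(he, (2 * nt) / (2 * nt - 1) * (1 - sum(p^2)))
      ar <- c(ar, sum(1 - exp(lchoose(2 * nt - cnt, rarefy_to) -
                                lchoose(2 * nt, rarefy_to))))
    }
    Ho <- mean(ho); He <- mean(he)
    data.frame(group = grp, n = length(idx), Ho = Ho, He = He,
               Fis = if (He > 0) 1 - Ho / He else NA_real_,
               allelic_richness = mean(ar), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "rarefy_to") <- rarefy_to
  res
}

#' Balanced-subsample Fst between two compartments
#'
#' Clonal amplification inflates apparent differentiation when sample sizes
#' are unbalanced; this routine caps each group's contribution. Per
#' replicate, at most `cap` individuals are drawn without replacement from
#' every group (e.g. estate) on each side, the groups of a side are pooled
#' into one metapopulation, and Fst between the two pools is computed
#' (Weir-Cockerham theta by default). The mean, sd and replicate values over
#' `n_reps` draws are returned.
#'
#' @param coll an [mlg_collection()].
#' @param side_stratum metadata column splitting the two sides
#'   (e.g. `compartment`).
#' @param side_a,side_b the two values of `side_stratum` to compare.
#' @param group_stratum metadata column of the within-side groups capped at
#'   `cap` (e.g. `estate`); `NULL` caps each side as a single group.
#' @param cap maximum individuals drawn per group (>= 2).
#' @param n_reps number of random subsamples (default 100).
#' @param method `"wc"` (default) or `"phipt"`.
#' @param seed integer seed.
#' @return List `(mean_fst, sd_fst, replicates)`.
#' @export
balanced_fst <- function(coll, side_stratum, side_a, side_b,
                         group_stratum = NULL, cap = 20L, n_reps = 100L,
                         method = c("wc", "phipt"), seed = NULL) {
  method <- match.arg(method)
  if (cap < 2) stop("cap must be >= 2")
  side <- as.character(get_stratum(coll, side_stratum))
  ia <- which(side == side_a); ib <- which(side == side_b)
  if (!length(ia) || !length(ib))
    stop("empty side: ", if (!length(ia)) side_a else side_b)
  grp <- if (is.null(group_stratum)) side
         else paste(side, as.character(get_stratum(coll, group_stratum)))
  if (!is.null(seed)) set.seed(seed)
  reps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pick <- unlist(lapply(split(c(ia, ib), grp[c(ia, ib)]), function(idx) {
      if (length(idx) <= cap) idx else sort(sample(idx, cap))
    }), use.names = FALSE)
    sub <- subset_collection(coll, pick)
    gg <- factor(side[pick], levels = c(side_a, side_b))
    reps[r] <- if (method == "wc") wc_fst_factor(sub, gg)
               else phipt_stat(genotype_dist2(sub), gg)
  }
  list(mean_fst = mean(reps), sd_fst = stats::sd(reps), replicates = reps)
}
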