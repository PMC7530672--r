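#' Bruvo distance at a single diploid locus
#'
#' Per-allele distance between repeat counts `x`, `y` is
#' `d = 1 - 2^(-|x - y|)`. For a diploid locus the distance is the minimum
#' over the two perfect matchings of the mean per-pair allele distance.
#'
#' @param a,b length-2 vectors of repeat counts (unordered allele pairs).
#' @return Distance in `[0, 1]`, or `NA` if either pair is missing.
#' @examples
#' bruvo_locus(c(20, 22), c(20, 22))  # 0
#' bruvo_locus(c(10, 10), c(11, 12))  # 0.625
#' @export
bruvo_locus <- function(a, b) {
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  da <- function(x, y) 1 - 2^(-abs(x - y))
  m1 <- (da(a[1], b[1]) + da(a[2], b[2])) / 2
  m2 <- (da(a[1], b[2]) + da(a[2], b[1])) / 2
  min(m1, m2)
}

#' Pairwise Bruvo distance matrix
#'
#' Genotype distance is the mean of per-locus Bruvo distances over loci typed
#' in both individuals (missing-data model: locus exclusion). Allele sizes
#' are converted to repeat units via the panel ([to_repeat_units()]); loci
#' flagged `multi_motif` in the panel trigger a warning, since a single
#' repeat-unit scale only approximates compound motifs.
#'
#' @param coll an [mlg_collection()] with at least 2 individuals.
#' @return A symmetric [stats::dist]-compatible matrix (class `matrix`) with
#'   zero diagonal, labelled by individual id.
#' @export
bruvo_matrix <- function(coll) {
  if (n_ind(coll) < 2L) stop("need at least 2 genotypes")
  if (any(coll$panel$multi_motif))
    warning("panel contains compound-motif loci (",
            paste(coll$panel$locus[coll$panel$multi_motif], collapse = ", "),
            "); Bruvo's stepwise model is approximate there")
  ru <- to_repeat_units(coll)
  n <- n_ind(coll); L <- n_loci(coll)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- ru[, l, 1]; a2 <- ru[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) < 2L) next
    f <- function(x, y) 1 - 2^(-abs(outer(x, y, "-")))
    m1 <- (f(a1, a1) + f(a2, a2)) / 2
    m2 <- (f(a1, a2) + f(a2, a1)) / 2
    dl <- pmin(m1, m2)
    okm <- outer(ok, ok, "&")
    dl[!okm] <- 0
    acc <- acc + dl
    cnt <- cnt + okm
  }
  if (any(cnt[upper.tri(cnt)] == 0L))
    stop("undefined distance: some pair shares no typed locus")
  d <- acc / cnt
  diag(d) <- 0
  dimnames(d) <- list(individual_ids(coll), individual_ids(coll))
  d
}

#' Allele-sharing proportion between two diploid profiles
#'
#' Per locus, the shared-allele count is the size of the multiset
#' intersection of the two unordered pairs (0, 1 or 2); the proportion is the
#' total shared over `2 * L_compared`. Loci missing in either profile are
#' excluded from numerator and denominator; their count is reported in
#' `attr(, "n_excluded")`.
#'
#' @param a,b 1-individual [mlg_collection()]s (or use `allele_sharing_matrix`
#'   for all pairs), compared on the bp scale.
#' @return Sharing proportion in `[0, 1]` with attribute `n_excluded`.
#' @export
allele_sharing <- function(a, b) {
  if (n_ind(a) != 1L || n_ind(b) != 1L) stop("a and b must be single individuals")
  pa <- a$alleles[1, , , drop = TRUE]
  pb <- b$alleles[1, , , drop = TRUE]
  ok <- !is.na(pa[, 1]) & !is.na(pb[, 1])
  sh <- shared_counts(pa[ok, 1], pa[ok, 2], pb[ok, 1], pb[ok, 2])
  out <- if (sum(ok) == 0L) NA_real_ else sum(sh) / (2 * sum(ok))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

## multiset intersection size of sorted pairs (a1<=a2 vs b1<=b2), vectorized
shared_counts <- function(a1, a2, b1, b2) {
  exact <- a1 == b1 & a2 == b2
  anym <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
  ifelse(exact, 2L, ifelse(anym, 1L, 0L))
}

#' Pairwise allele-sharing matrix
#' @param a an [mlg_collection()].
#' @param b optional second collection (defaults to `a`); result is
#'   `n_ind(a) x n_ind(b)`.
#' @return Matrix of sharing proportions (NA when no locus is comparable).
#' @export
allele_sharing_matrix <- function(a, b = a) {
  if (!identical(a$panel$locus, b$panel$locus)) stop("panels differ")
  na <- n_ind(a); nb <- n_ind(b); L <- n_loci(a)
  num <- matrix(0L, na, nb); den <- matrix(0L, na, nb)
  for (l in seq_len(L)) {
    pa1 <- a$alleles[, l, 1]; pa2 <- a$alleles[, l, 2]
    pb1 <- b$alleles[, l, 1]; pb2 <- b$alleles[, l, 2]
    ok <- outer(!is.na(pa1), !is.na(pb1), "&")
    A1 <- matrix(pa1, na, nb); A2 <- matrix(pa2, na, nb)
    B1 <- matrix(pb1, na, nb, byrow = TRUE); B2 <- matrix(pb2, na, nb, byrow = TRUE)
    sh <- matrix(shared_counts(A1, A2, B1, B2), na, nb)
    sh[!ok] <- 0L
    num <- num + sh
    den <- den + 2L * ok
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  dimnames(out) <- list(individual_ids(a), individual_ids(b))
  out
}

#' Neighbor-joining tree with midpoint rooting
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero with the deficit transferred to the sibling edge at the
#' same node, then the tree is rooted at the midpoint of the longest
#' leaf-to-leaf path ([phangorn::midpoint()]).
#'
#' @param dm symmetric labelled distance matrix with >= 3 labels.
#' @return A rooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels for NJ")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) tr$edge.length[sibs] <- tr$edge.length[sibs] -
      tr$edge.length[e] / length(sibs)
    tr$edge.length[e] <- 0
  }
  phangorn::midpoint(tr)
}

#' Locus-resampling bootstrap support for a Bruvo NJ tree
#'
#' Loci are resampled with replacement `n_boot` times, the Bruvo NJ tree is
#' rebuilt, and bipartition support counted on the reference tree. Supports
#' below `min_support` (out of 100) are masked to `NA` in the returned
#' `node.label`, mirroring the convention of hiding weak bootstrap values.
#'
#' @param coll an [mlg_collection()].
#' @param n_boot bootstrap replicates (default 100).
#' @param min_support hide support below this percentage (default 25).
#' @param seed integer seed.
#' @return The midpoint-rooted reference tree with `node.label` support.
#' @export
nj_support <- function(coll, n_boot = 100L, min_support = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(bruvo_matrix(coll))
  L <- n_loci(coll)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(L, L, replace = TRUE)
    sub <- coll
    sub$alleles <- coll$alleles[, pick, , drop = FALSE]
    dimnames(sub$alleles)[[2]] <- sprintf("B%02d", seq_len(L))
    sub$panel <- locus_panel(sprintf("B%02d", seq_len(L)),
                             coll$panel$motif_bp[pick],
                             coll$panel$offset_bp[pick])
    boots[[b]] <- nj_tree(bruvo_matrix(sub))
  }
  cl <- ape::prop.clades(ref, boots, rooted = FALSE)
  supp <- round(100 * cl / n_boot)
  supp[!is.na(supp) & supp < min_support] <- NA
  ref$node.label <- supp
  ref
}

#' Minimum spanning network over MLG representatives
#'
#' Kruskal's algorithm with deterministic tie-breaking (edges sorted by
#' weight, then by the label pair in lexicographic order). Nodes carry the
#' MLG class multiplicity when a partition is supplied.
#'
#' @param dm symmetric labelled distance matrix.
#' @param partition optional [find_mlgs()] partition whose representatives
#'   are the matrix labels; supplies node multiplicities.
#' @return Object of class `spanning_network`: list with `nodes`
#'   (`id`, `size`) and `edges` (`from`, `to`, `weight`) data frames.
#' @export
spanning_network <- function(dm, partition = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  labs <- rownames(dm)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  if (n < 1L) stop("empty distance matrix")
  sizes <- rep(1L, n)
  if (!is.null(partition)) {
    m <- match(labs, partition$representatives)
    sizes[!is.na(m)] <- lengths(partition$classes)[m[!is.na(m)]]
  }
  nodes <- data.frame(id = labs, size = sizes, stringsAsFactors = FALSE)
  if (n == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0), to = character(0),
                                             weight = numeric(0))),
                     class = "spanning_network"))
  }
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  ed <- data.frame(i = ut[, 1], j = ut[, 2], w = dm[ut])
  ed <- ed[order(ed$w, labs[ed$i], labs[ed$j]), , drop = FALSE]
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(ed))
  taken <- 0L
  for (r in seq_len(nrow(ed))) {
    ri <- findp(ed$i[r]); rj <- findp(ed$j[r])
    if (ri != rj) {
      parent[max(ri, rj)] <- min(ri, rj)
      keep[r] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges <- data.frame(from = labs[ed$i[keep]], to = labs[ed$j[keep]],
                      weight = ed$w[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "spanning_network")
}

#' @export
print.spanning_network <- function(x, ...) {
  cat("<spanning_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, total weight ", format(sum(x$edges$weight), digits = 6), "\n",
      sep = "")
  invisible(x)
}
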