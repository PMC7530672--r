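## genotype key: canonical string of all sorted allele pairs, NA as "?"
mlg_keys <- function(coll) {
  a1 <- coll$alleles[, , 1, drop = FALSE]
  a2 <- coll$alleles[, , 2, drop = FALSE]
  m <- matrix(paste0(ifelse(is.na(a1), "?", a1), "/",
                     ifelse(is.na(a2), "?", a2)),
              nrow = n_ind(coll))
  apply(m, 1, paste, collapse = "|")
}

## TRUE iff the two individuals match at every locus typed in both
## (ignore_missing policy); i, j are row indices
match_ignore_missing <- function(alleles, i, j) {
  ai <- alleles[i, , , drop = TRUE]
  aj <- alleles[j, , , drop = TRUE]
  ok <- !is.na(ai[, 1]) & !is.na(aj[, 1])
  all(ai[ok, ] == aj[ok, ])
}

#' Identify multilocus genotype (MLG) classes
#'
#' Partitions individuals into clonal-identity classes. Under the `strict`
#' policy two individuals are clonemates iff their profiles are identical
#' including the placement of missing loci (so an individual with missing
#' data only joins a class of byte-identical profiles). Under
#' `ignore_missing`, loci missing in either individual are skipped in the
#' comparison; because that relation is not transitive, classes are the
#' connected components of the pairwise-match graph (single linkage), which
#' is the permissive reading of clone detection.
#'
#' @param coll a non-empty [mlg_collection()].
#' @param missing_policy `"strict"` (default) or `"ignore_missing"`.
#' @return An object of class `mlg_partition`: list with `class_id` (integer
#'   vector over individuals), `classes` (list of member id vectors) and
#'   `representatives` (lowest id per class).
#' @export
find_mlgs <- function(coll, missing_policy = c("strict", "ignore_missing")) {
  missing_policy <- match.arg(missing_policy)
  if (n_ind(coll) == 0L) stop("empty collection")
  ids <- individual_ids(coll)
  keys <- mlg_keys(coll)
  cls <- as.integer(factor(keys, levels = unique(keys)))
  if (missing_policy == "ignore_missing") {
    ## union-find over key-classes that match when missing loci are skipped
    ukeys <- unique(keys)
    rep_idx <- match(ukeys, keys)
    k <- length(rep_idx)
    parent <- seq_len(k)
    findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    has_na <- is.na(coll$alleles[rep_idx, , 1, drop = FALSE])
    any_na <- apply(has_na, 1, any)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        if (v <= u) next
        if (!any_na[u] && !any_na[v]) next  # complete profiles: key equality decides
        if (match_ignore_missing(coll$alleles, rep_idx[u], rep_idx[v])) {
          ru <- findp(u); rv <- findp(v)
          if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
        }
      }
    }
    roots <- vapply(seq_len(k), findp, integer(1))
    cls <- as.integer(factor(roots, levels = unique(roots)))[cls]
  }
  classes <- split(ids, cls)
  reps <- vapply(classes, function(m) sort(m)[1], character(1))
  structure(list(class_id = cls, classes = unname(classes),
                 representatives = unname(reps), ids = ids,
                 missing_policy = missing_policy),
            class = "mlg_partition")
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat("<mlg_partition> ", length(x$ids), " individuals in ",
      length(x$classes), " MLG classes (policy: ", x$missing_policy, ")\n",
      sep = "")
  invisible(x)
}

#' Clone-correct a collection within a stratum
#'
#' Within each group of `within_stratum` (e.g. each wine estate), a single
#' representative per MLG class is retained -- the lexicographically smallest
#' `individual_id`, for deterministic output. Identical MLGs occurring in
#' different groups are all retained, matching clone removal performed
#' per estate.
#'
#' @param coll an [mlg_collection()].
#' @param within_stratum metadata column defining the groups.
#' @param missing_policy passed to [find_mlgs()].
#' @return The clone-corrected `mlg_collection`; the number of removed
#'   individuals is in `attr(, "n_removed")`.
#' @export
clone_correct <- function(coll, within_stratum = "estate",
                          missing_policy = c("strict", "ignore_missing")) {
  missing_policy <- match.arg(missing_policy)
  g <- get_stratum(coll, within_stratum)
  ids <- individual_ids(coll)
  keep <- character(0)
  for (grp in levels(g)) {
    sub <- subset_collection(coll, which(g == grp))
    part <- find_mlgs(sub, missing_policy)
    keep <- c(keep, part$representatives)
  }
  keep <- sort(keep)
  out <- subset_collection(coll, keep)
  attr(out, "n_removed") <- n_ind(coll) - length(keep)
  out
}

#' Clonal variants of a focal profile
#'
#' Returns individuals whose profile differs from `focal` at no more than
#' `max_diff_loci` loci; a locus differs when the unordered allele pairs
#' differ as multisets. Loci missing in a candidate are skipped (not counted
#' as differences); the number of compared loci is reported.
#'
#' @param focal a 1-individual [mlg_collection()] (or an `mlg_collection`
#'   plus `focal_id`) with no missing loci.
#' @param coll collection to search.
#' @param max_diff_loci maximum number of differing loci (default 2).
#' @param focal_id optional id selecting the focal individual from `focal`.
#' @return Data frame `(individual_id, n_diff_loci, n_compared)`, sorted by
#'   `n_diff_loci` then id.
#' @export
clonal_variants <- function(focal, coll, max_diff_loci = 2L, focal_id = NULL) {
  if (!is.null(focal_id)) focal <- subset_collection(focal, focal_id)
  if (n_ind(focal) != 1L) stop("focal must be a single individual")
  fa <- focal$alleles[1, , , drop = TRUE]
  if (anyNA(fa)) stop("focal profile has missing loci")
  if (!identical(focal$panel$locus, coll$panel$locus)) stop("panels differ")
  n <- n_ind(coll)
  nd <- integer(n); nc <- integer(n)
  for (i in seq_len(n)) {
    ai <- coll$alleles[i, , , drop = TRUE]
    ok <- !is.na(ai[, 1])
    nc[i] <- sum(ok)
    nd[i] <- sum(ai[ok, 1] != fa[ok, 1] | ai[ok, 2] != fa[ok, 2])
  }
  sel <- nd <= max_diff_loci
  out <- data.frame(individual_id = individual_ids(coll)[sel],
                    n_diff_loci = nd[sel], n_compared = nc[sel],
                    stringsAsFactors = FALSE)
  out[order(out$n_diff_loci, out$individual_id), , drop = FALSE]
}
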