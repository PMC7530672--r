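#' Attribute isolates to commercial starter strains by allele sharing
#'
#' An isolate is "related" to a starter when it shares at least `threshold`
#' of its alleles over the 2L allele slots ([allele_sharing_matrix()]) and
#' carries no missing locus (isolates with any missing call are ineligible
#' and reported unrelated). A starter name may be represented by several
#' profiles (e.g. batch variants); attribution is to the name via the
#' maximum sharing over its profiles. Categories: `identical` (0 differing
#' loci vs the best profile), `clonal_variant` (1-2 loci),
#' `related` (above threshold but more than 2 loci), `unrelated`.
#'
#' @param coll an [mlg_collection()].
#' @param starters starter panel: an `mlg_collection` with no missing loci,
#'   optional metadata column `starter` naming profiles (several profiles may
#'   share a name).
#' @param threshold minimum sharing proportion, inclusive (default 0.75).
#' @return Data frame of class `attribution_report`: `individual_id`,
#'   `eligible`, `best_starter`, `tied_starters`, `sharing`, `n_diff_loci`,
#'   `category`, `related`.
#' @export
attribute_starters <- function(coll, starters, threshold = 0.75) {
  if (n_ind(starters) == 0L) stop("empty starter panel")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (any(is.na(starters$alleles))) stop("starter profiles must have no missing loci")
  sn <- if ("starter" %in% names(starters$meta)) starters$meta$starter
        else individual_ids(starters)
  sm <- allele_sharing_matrix(coll, starters)
  n <- n_ind(coll)
  eligible <- !apply(is.na(coll$alleles[, , 1, drop = FALSE]), 1, any)
  names_u <- sort(unique(sn))
  ## per-name max sharing
  share_name <- sapply(names_u, function(nm)
    apply(sm[, sn == nm, drop = FALSE], 1, max))
  share_name <- matrix(share_name, nrow = n,
                       dimnames = list(individual_ids(coll), names_u))
  best <- character(n); tied <- character(n); sharing <- numeric(n)
  ndiff <- rep(NA_integer_, n)
  cat_v <- rep("unrelated", n)
  for (i in seq_len(n)) {
    sharing[i] <- max(share_name[i, ])
    hit <- names_u[share_name[i, ] == sharing[i]]
    best[i] <- hit[1]
    tied[i] <- paste(hit, collapse = ",")
    if (!eligible[i]) next
    ## differing loci vs the best-sharing profile of the best name
    cand <- which(sn == best[i])
    prof <- cand[which.max(sm[i, cand])]
    pa <- coll$alleles[i, , , drop = TRUE]
    pb <- starters$alleles[prof, , , drop = TRUE]
    ndiff[i] <- sum(pa[, 1] != pb[, 1] | pa[, 2] != pb[, 2])
    if (sharing[i] >= threshold) {
      cat_v[i] <- if (ndiff[i] == 0L) "identical"
                  else if (ndiff[i] <= 2L) "clonal_variant"
                  else "related"
    }
  }
  out <- data.frame(individual_id = individual_ids(coll),
                    eligible = eligible, best_starter = best,
                    tied_starters = tied, sharing = sharing,
                    n_diff_loci = ndiff,
                    category = factor(cat_v, levels = c("identical",
                                                        "clonal_variant",
                                                        "related",
                                                        "unrelated")),
                    stringsAsFactors = FALSE)
  out$related <- out$category != "unrelated"
  attr(out, "threshold") <- threshold
  class(out) <- c("attribution_report", "data.frame")
  out
}

#' Remove starter-related isolates from a collection
#'
#' @param coll the collection the report was computed on.
#' @param report an [attribute_starters()] report.
#' @return The retained (non-related) collection, with `attr(, "n_removed")`.
#' @export
remove_related <- function(coll, report) {
  if (!identical(report$individual_id, individual_ids(coll)))
    stop("report does not match the collection")
  out <- subset_collection(coll, which(!report$related))
  attr(out, "n_removed") <- sum(report$related)
  out
}

#' Minimum spanning network around one starter
#'
#' Builds the Bruvo-distance minimum spanning network over a starter's
#' profile(s) plus its related isolates, and reports "star-likeness": the
#' fraction of related isolates whose network path to the nearest starter
#' node has at most 2 edges. A recently expanded clonal cloud is star-like
#' (most variants attach directly to the starter), while an old diversified
#' cluster forms longer chains.
#'
#' @param coll an [mlg_collection()].
#' @param starters starter panel (see [attribute_starters()]).
#' @param starter_name the starter to center on.
#' @param threshold sharing threshold for relatedness.
#' @return A `spanning_network` with extra fields `starter_nodes` and
#'   `star_likeness`; an empty network (with a warning) when no isolate is
#'   related.
#' @export
starter_network <- function(coll, starters, starter_name, threshold = 0.75) {
  sn <- if ("starter" %in% names(starters$meta)) starters$meta$starter
        else individual_ids(starters)
  if (!starter_name %in% sn) stop("unknown starter: ", starter_name)
  rep_ids <- individual_ids(starters)[sn == starter_name]
  rep_coll <- subset_collection(starters, which(sn == starter_name))
  report <- attribute_starters(coll, starters, threshold)
  rel <- report$individual_id[report$related & report$best_starter == starter_name]
  if (!length(rel)) {
    warning("no isolates related to ", starter_name)
    net <- spanning_network(matrix(0, length(rep_ids), length(rep_ids),
                                   dimnames = list(rep_ids, rep_ids)))
    net$starter_nodes <- rep_ids
    net$star_likeness <- NA_real_
    return(net)
  }
  sub <- subset_collection(coll, rel)
  both <- bind_collections(rep_coll, sub)
  dm <- bruvo_matrix(both)
  net <- spanning_network(dm)
  ## BFS hop counts from the starter nodes
  labs <- net$nodes$id
  adj <- lapply(labs, function(x) character(0))
  names(adj) <- labs
  for (r in seq_len(nrow(net$edges))) {
    adj[[net$edges$from[r]]] <- c(adj[[net$edges$from[r]]], net$edges$to[r])
    adj[[net$edges$to[r]]] <- c(adj[[net$edges$to[r]]], net$edges$from[r])
  }
  hops <- stats::setNames(rep(Inf, length(labs)), labs)
  frontier <- rep_ids
  hops[frontier] <- 0
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (hops[w] > hops[v] + 1) { hops[w] <- hops[v] + 1; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  net$starter_nodes <- rep_ids
  net$hops <- hops
  net$star_likeness <- mean(hops[rel] <= 2)
  net
}
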