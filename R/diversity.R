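#' Genotype abundance vector of a collection
#'
#' Counts individuals per MLG class (see [find_mlgs()]); the input for the
#' diversity indices and rarefaction.
#'
#' @param coll an [mlg_collection()].
#' @param missing_policy passed to [find_mlgs()].
#' @return Named integer vector of class sizes (names = representative ids).
#' @export
mlg_abundance <- function(coll, missing_policy = "strict") {
  part <- find_mlgs(coll, missing_policy)
  stats::setNames(lengths(part$classes), part$representatives)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(counts < 1) || any(counts != floor(counts)))
    stop("counts must be positive integers")
  counts
}

#' Shannon diversity index
#'
#' `H' = -sum(Pi * ln(Pi))` with `Pi = Ni / N`, `Ni` the number of
#' individuals of genotype `i` and `N` the total number of individuals
#' (natural log).
#'
#' @param counts positive integer abundances per genotype class.
#' @return H' in nats.
#' @examples
#' shannon_index(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_index <- function(counts) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Simpson index and its transforms
#'
#' Unbiased Simpson concentration `D = sum(Ni * (Ni - 1)) / (N * (N - 1))`,
#' with the complement `1 - D` and inverse `1 / D` (reported as `Inf` when
#' `D = 0`, i.e. all classes are singletons).
#'
#' @param counts positive integer abundances; `N >= 2` required.
#' @return List with `D`, `one_minus_D`, `inv_D`.
#' @export
simpson_index <- function(counts) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (N < 2) stop("Simpson index undefined for N < 2")
  D <- sum(counts * (counts - 1)) / (N * (N - 1))
  list(D = D, one_minus_D = 1 - D, inv_D = if (D > 0) 1 / D else Inf)
}

#' Pielou evenness
#'
#' `J' = H' / ln(S)`; by convention `J' = 1` for a single class (`S = 1`).
#'
#' @param counts positive integer abundances.
#' @return J' in `[0, 1]`.
#' @export
pielou_evenness <- function(counts) {
  counts <- check_counts(counts)
  S <- length(counts)
  if (S == 1L) return(1)
  shannon_index(counts) / log(S)
}

#' Exact expected rarefied genotype richness
#'
#' Hypergeometric closed form for subsampling `depth` individuals without
#' replacement: `E[S] = sum_i (1 - choose(N - Ni, depth) / choose(N, depth))`.
#'
#' @param counts positive integer abundances.
#' @param depth subsample size, `1 <= depth <= N`.
#' @return Expected number of classes.
#' @export
expected_richness <- function(counts, depth) {
  counts <- check_counts(counts)
  N <- sum(counts)
  stopifnot(depth >= 1, depth <= N)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Chao1 richness estimator
#'
#' `S_chao1 = S_obs + f1^2 / (2 f2)` with the bias-corrected form
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`, where `f1`, `f2` are
#' the singleton and doubleton class counts.
#'
#' @param counts positive integer abundances.
#' @return List with `S_obs`, `f1`, `f2`, `S_chao1`.
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  S <- length(counts)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / (2 * (f2 + 1))
  list(S_obs = S, f1 = f1, f2 = f2, S_chao1 = S + f0)
}

#' Rarefy (or extrapolate) genotype richness
#'
#' For `depth <= N`: Monte-Carlo subsampling without replacement (`reps`
#' replicates), reporting mean and sd of the class count; the hypergeometric
#' expectation ([expected_richness()]) is attached for reference. For
#' `depth > N`: abundance-based Chao1 extrapolation,
#' `S(N + m) = S_obs + f0 * (1 - (1 - f1 / (N * f0 + f1))^m)` with
#' `f0 = S_chao1 - S_obs` (sd reported as `NA`).
#'
#' @param counts positive integer abundances.
#' @param depth target number of individuals (may exceed `N`).
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed integer seed.
#' @return List with `depth`, `mean_S`, `sd_S`, `method`
#'   (`"rarefaction"`/`"extrapolation"`), and `expected` (closed form, for
#'   rarefaction only).
#' @export
rarefy_richness <- function(counts, depth, reps = 1000L, seed = NULL) {
  counts <- check_counts(counts)
  if (reps < 1) stop("reps must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  N <- sum(counts)
  if (depth <= N) {
    if (!is.null(seed)) set.seed(seed)
    units <- rep(seq_along(counts), counts)
    s <- vapply(seq_len(reps), function(r)
      length(unique(units[sample.int(N, depth)])), numeric(1))
    list(depth = depth, mean_S = mean(s), sd_S = stats::sd(s),
         method = "rarefaction", expected = expected_richness(counts, depth))
  } else {
    ch <- chao1(counts)
    f0 <- ch$S_chao1 - ch$S_obs
    m <- depth - N
    ext <- if (f0 == 0 || ch$f1 == 0) ch$S_obs else
      ch$S_obs + f0 * (1 - (1 - ch$f1 / (N * f0 + ch$f1))^m)
    list(depth = depth, mean_S = ext, sd_S = NA_real_,
         method = "extrapolation", expected = NA_real_)
  }
}

#' Per-stratum genotype diversity report
#'
#' Computes, per group of `by` (and overall when `by` is `NULL`): number of
#' individuals `n`, number of MLG classes `S`, Shannon `H`, Pielou `J`,
#' Simpson complement `one_minus_D` and inverse `inv_D` -- the layout of a
#' classic genotype-diversity table.
#'
#' @param coll an [mlg_collection()].
#' @param by metadata column to stratify on, or `NULL` for a single row.
#' @param missing_policy passed to [find_mlgs()].
#' @return Data frame, one row per group.
#' @export
diversity_report <- function(coll, by = NULL, missing_policy = "strict") {
  one <- function(sub, label) {
    ab <- mlg_abundance(sub, missing_policy)
    si <- if (sum(ab) >= 2) simpson_index(ab) else
      list(one_minus_D = NA_real_, inv_D = NA_real_)
    data.frame(group = label, n = sum(ab), S = length(ab),
               H = shannon_index(ab), J = pielou_evenness(ab),
               one_minus_D = si$one_minus_D, inv_D = si$inv_D,
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(coll, "all"))
  g <- get_stratum(coll, by)
  out <- do.call(rbind, lapply(levels(g), function(grp)
    one(subset_collection(coll, which(g == grp)), grp)))
  rownames(out) <- NULL
  out
}
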