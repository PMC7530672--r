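#' Migration matrix helpers
#'
#' `island_migration()` builds the classic n-island matrix: each gene stays in
#' its deme with probability `1 - m` and immigrates from each other deme with
#' probability `m / (n - 1)`. `hierarchical_migration()` nests demes in blocks
#' (e.g. estates within appellations) with a higher within-block rate.
#'
#' @param n_pops number of demes.
#' @param m total immigration rate per gene per generation.
#' @param blocks integer/character vector of length `n_pops` assigning demes
#'   to blocks.
#' @param m_in immigration rate from demes of the same block.
#' @param m_out immigration rate from demes of other blocks.
#' @return A row-stochastic `n_pops x n_pops` matrix of backward migration
#'   probabilities (row = destination deme, column = source deme).
#' @export
island_migration <- function(n_pops, m) {
  stopifnot(n_pops >= 1, m >= 0, m <= 1)
  if (n_pops == 1L) return(matrix(1, 1, 1))
  M <- matrix(m / (n_pops - 1), n_pops, n_pops)
  diag(M) <- 1 - m
  M
}

#' @rdname island_migration
#' @export
hierarchical_migration <- function(blocks, m_in, m_out) {
  n <- length(blocks)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    same <- which(blocks == blocks[i] & seq_len(n) != i)
    diff <- which(blocks != blocks[i])
    if (length(same)) M[i, same] <- m_in / length(same)
    if (length(diff)) M[i, diff] <- m_out / length(diff)
    M[i, i] <- 1 - sum(M[i, -i])
  }
  M
}

## deterministic child seeds for the per-stage RNG streams
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 777767 * k) %% (.Machine$integer.max - 1)) + 1L
}

#' Simulation configuration
#'
#' Default values emulate the sampling design of a vineyard/cellar yeast
#' survey: 24 estate demes nested in 5 appellations, 17 diploid microsatellite
#' loci mutating by single repeat steps, high selfing (heterozygote deficit),
#' within-sample clonal expansion, 25% of sampled isolates replaced by
#' commercial-starter clonal variants, and sparse random missing data.
#'
#' @param n_pops number of demes ("estates").
#' @param pop_sizes diploid census size per deme (recycled).
#' @param n_loci number of microsatellite loci.
#' @param motif_lens repeat motif lengths in bp (recycled over loci).
#' @param mutation_rate per-allele per-generation stepwise mutation rate.
#' @param migration_matrix row-stochastic backward migration matrix
#'   (`NULL` = hierarchical island model from `m_within` / `m_between`).
#' @param m_within,m_between immigration rates within / between appellation
#'   blocks used when `migration_matrix` is `NULL`.
#' @param n_appellations number of appellation blocks (demes split as evenly
#'   as possible, in order).
#' @param generations forward-time generations simulated.
#' @param selfing_rate probability an offspring is produced by selfing.
#' @param n_founders number of distinct individuals seeding each sample's
#'   clonal expansion.
#' @param clonal_skew symmetric Dirichlet concentration for founder weights;
#'   small values make a few genotypes dominate each sample.
#' @param sample_size isolates sampled per deme.
#' @param starter_profiles an `mlg_collection` of starter genotypes (no
#'   missing loci), or `NULL` to auto-generate `5` synthetic starters.
#' @param starter_fraction fraction of sampled isolates replaced by
#'   starter-derived clonal variants.
#' @param starter_max_edits maximum single-step allelic edits per spiked
#'   isolate.
#' @param missing_rate per-individual per-locus probability of a missing call.
#' @param init_alleles number of distinct alleles per locus in the ancestral
#'   pool.
#' @param seed integer seed; fully determines the output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 24L, pop_sizes = 100L, n_loci = 17L,
                       motif_lens = c(3L, 2L, 4L, 3L, 2L, 3L, 6L, 3L, 2L),
                       mutation_rate = 1e-4,
                       migration_matrix = NULL,
                       m_within = 0.02, m_between = 0.005,
                       n_appellations = 5L,
                       generations = 200L,
                       selfing_rate = 0.8,
                       n_founders = 15L,
                       clonal_skew = 0.3,
                       sample_size = 40L,
                       starter_profiles = NULL,
                       starter_fraction = 0.25,
                       starter_max_edits = 2L,
                       missing_rate = 0.01,
                       init_alleles = 8L,
                       seed = 1L) {
  cfg <- list(
    n_pops = as.integer(n_pops),
    pop_sizes = rep_len(as.integer(pop_sizes), n_pops),
    n_loci = as.integer(n_loci),
    motif_lens = rep_len(as.integer(motif_lens), n_loci),
    mutation_rate = mutation_rate,
    m_within = m_within, m_between = m_between,
    n_appellations = as.integer(min(n_appellations, n_pops)),
    generations = as.integer(generations),
    selfing_rate = selfing_rate,
    n_founders = as.integer(n_founders),
    clonal_skew = clonal_skew,
    sample_size = as.integer(sample_size),
    starter_profiles = starter_profiles,
    starter_fraction = starter_fraction,
    starter_max_edits = as.integer(starter_max_edits),
    missing_rate = missing_rate,
    init_alleles = as.integer(init_alleles),
    seed = as.integer(seed))
  blocks <- sort(rep_len(seq_len(cfg$n_appellations), cfg$n_pops))
  cfg$appellation_of <- paste0("app", blocks)
  if (is.null(migration_matrix)) {
    migration_matrix <- if (cfg$n_appellations > 1L)
      hierarchical_migration(blocks, m_within, m_between)
    else island_migration(cfg$n_pops, m_within)
  }
  if (!is.matrix(migration_matrix) ||
      any(dim(migration_matrix) != cfg$n_pops))
    stop("migration_matrix must be ", cfg$n_pops, " x ", cfg$n_pops)
  if (any(abs(rowSums(migration_matrix) - 1) > 1e-9))
    stop("migration_matrix rows must sum to 1")
  if (any(migration_matrix < 0)) stop("negative migration rate")
  cfg$migration_matrix <- migration_matrix
  rates <- c(cfg$mutation_rate, cfg$selfing_rate, cfg$starter_fraction,
             cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (cfg$starter_fraction > 0 && !is.null(cfg$starter_profiles) &&
      n_ind(cfg$starter_profiles) == 0L)
    stop("starter_fraction > 0 with an empty starter panel")
  if (cfg$clonal_skew <= 0) stop("clonal_skew must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate synthetic commercial-starter genotypes
#'
#' Starter profiles are drawn locus-wise from a broad repeat-count range so
#' that chance allele sharing with an endemic simulated population is rare;
#' they carry no missing data. These are synthetic stand-ins for a commercial
#' starter reference panel.
#'
#' @param panel a [locus_panel()].
#' @param names starter names.
#' @param seed integer seed.
#' @return An `mlg_collection` with metadata column `starter = names`.
#' @export
simulate_starters <- function(panel,
                              names = c("S522D", "FX10", "F15", "X5", "VL1"),
                              seed = 1L) {
  set.seed(seed)
  n <- length(names)
  L <- nrow(panel)
  al <- array(NA_integer_, dim = c(n, L, 2), dimnames = list(names, panel$locus, NULL))
  for (l in seq_len(L)) {
    ru <- matrix(sample(30:80, n * 2, replace = TRUE), n, 2)
    ## make some loci homozygous, as in real starters
    hom <- stats::runif(n) < 0.4
    ru[hom, 2] <- ru[hom, 1]
    al[, l, ] <- ru * panel$motif_bp[l] + panel$offset_bp[l]
  }
  mlg_collection(al, panel,
                 data.frame(individual_id = names, starter = names,
                            stringsAsFactors = FALSE))
}

#' Simulate a microsatellite metapopulation sample
#'
#' Forward-time Wright-Fisher island model: each generation, every offspring
#' draws its parent deme(s) from the backward migration matrix
#' (migration-then-reproduction), is produced by selfing with probability
#' `selfing_rate`, inherits one random allele per parent per locus (loci
#' unlinked), and each transmitted allele mutates by +-1 repeat unit with
#' probability `mutation_rate` (strict stepwise mutation model). Sampling then
#' emulates enrichment-fermentation isolation: per deme, `n_founders` distinct
#' individuals receive Dirichlet(`clonal_skew`) weights and `sample_size`
#' isolates are drawn from them with replacement (clonal expansion). Finally a
#' `starter_fraction` of isolates is replaced by starter-derived clonal
#' variants ([spike_starters()]) and missing calls injected at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return An [mlg_collection()] with metadata columns `estate`,
#'   `appellation`, `farming`, `compartment`, `vintage`, `latitude`,
#'   `longitude`, `founder` (truth: deme-local founder index) and
#'   `starter_truth` (truth: starter name or `NA`). The full truth record
#'   (migration matrix, per-deme founder counts, the starter panel used for
#'   spiking) is in `attr(, "truth")`.
#' @export
simulate_metapopulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$n_pops
  sizes <- cfg$pop_sizes
  NT <- sum(sizes)
  L <- cfg$n_loci
  M <- cfg$migration_matrix
  deme <- rep(seq_len(d), sizes)
  start <- c(0L, cumsum(sizes))[seq_len(d)]

  set.seed(child_seed(cfg$seed, 1L))
  ## ancestral allele pools, one per locus, in repeat units
  base <- sample(30:70, L, replace = TRUE)
  cur <- array(0L, dim = c(NT, L, 2))
  for (l in seq_len(L)) {
    pool <- base[l] + seq_len(cfg$init_alleles) - 1L
    cur[, l, ] <- sample(pool, NT * 2, replace = TRUE)
  }

  set.seed(child_seed(cfg$seed, 2L))
  pick_parents <- function() {
    src <- integer(NT)
    for (i in seq_len(d)) {
      idx <- which(deme == i)
      src[idx] <- sample.int(d, length(idx), replace = TRUE, prob = M[i, ])
    }
    start[src] + floor(stats::runif(NT) * sizes[src]) + 1L
  }
  gamete <- function(parents) {
    slot <- 1L + (stats::runif(NT * L) < 0.5)
    g <- matrix(cur[cbind(rep(parents, L), rep(seq_len(L), each = NT), slot)],
                NT, L)
    if (cfg$mutation_rate > 0) {
      mut <- stats::runif(NT * L) < cfg$mutation_rate
      if (any(mut)) {
        stp <- sample(c(-1L, 1L), sum(mut), replace = TRUE)
        g[mut] <- pmax(2L, g[mut] + stp)
      }
    }
    g
  }
  for (g in seq_len(cfg$generations)) {
    p1 <- pick_parents()
    self <- stats::runif(NT) < cfg$selfing_rate
    p2 <- ifelse(self, p1, pick_parents())
    nxt <- array(0L, dim = c(NT, L, 2))
    nxt[, , 1] <- gamete(p1)
    nxt[, , 2] <- gamete(p2)
    cur <- nxt
  }

  ## sampling with clonal expansion
  set.seed(child_seed(cfg$seed, 3L))
  ns <- cfg$sample_size
  samp_idx <- integer(d * ns)
  founder_of <- integer(d * ns)
  for (i in seq_len(d)) {
    nf <- min(cfg$n_founders, sizes[i])
    founders <- start[i] + sample.int(sizes[i], nf)
    w <- stats::rgamma(nf, shape = cfg$clonal_skew)
    if (all(w == 0)) w <- rep(1, nf)
    pick <- sample.int(nf, ns, replace = TRUE, prob = w / sum(w))
    samp_idx[(i - 1L) * ns + seq_len(ns)] <- founders[pick]
    founder_of[(i - 1L) * ns + seq_len(ns)] <- pick
  }
  estates <- sprintf("e%02d", seq_len(d))
  ids <- sprintf("%s_i%03d", rep(estates, each = ns), rep(seq_len(ns), d))
  panel <- locus_panel(sprintf("L%02d", seq_len(L)), cfg$motif_lens)
  alleles <- array(NA_integer_, dim = c(d * ns, L, 2),
                   dimnames = list(ids, panel$locus, NULL))
  for (l in seq_len(L)) {
    alleles[, l, 1] <- cur[samp_idx, l, 1] * cfg$motif_lens[l]
    alleles[, l, 2] <- cur[samp_idx, l, 2] * cfg$motif_lens[l]
  }

  set.seed(child_seed(cfg$seed, 4L))
  lat <- round(44.4 + stats::runif(d) * 0.8, 5)
  lon <- round(-0.9 + stats::runif(d) * 0.9, 5)
  farming <- rep(c("organic", "conventional"), length.out = d)
  meta <- data.frame(
    individual_id = ids,
    estate = rep(estates, each = ns),
    appellation = rep(cfg$appellation_of, each = ns),
    farming = rep(farming, each = ns),
    compartment = "grape",
    vintage = 2012L,
    latitude = rep(lat, each = ns),
    longitude = rep(lon, each = ns),
    founder = founder_of,
    stringsAsFactors = FALSE)
  coll <- mlg_collection(alleles, panel, meta)

  starters <- NULL
  if (cfg$starter_fraction > 0) {
    starters <- cfg$starter_profiles
    if (is.null(starters))
      starters <- simulate_starters(panel, seed = child_seed(cfg$seed, 5L))
    coll <- spike_starters(coll, starters, cfg$starter_fraction,
                           max_edits = cfg$starter_max_edits,
                           seed = child_seed(cfg$seed, 6L))
  } else {
    coll$meta$starter_truth <- NA_character_
  }

  if (cfg$missing_rate > 0) {
    set.seed(child_seed(cfg$seed, 7L))
    drop <- matrix(stats::runif(n_ind(coll) * L) < cfg$missing_rate, ncol = L)
    a <- coll$alleles
    a[, , 1][drop] <- NA_integer_
    a[, , 2][drop] <- NA_integer_
    coll$alleles <- a
  }

  founders_per_estate <- tapply(coll$meta$founder, coll$meta$estate,
                                function(x) length(unique(x[!is.na(x)])))
  attr(coll, "truth") <- list(
    seed = cfg$seed,
    migration_matrix = M,
    founders_per_estate = founders_per_estate,
    starter_panel = starters,
    n_spiked = sum(!is.na(coll$meta$starter_truth)))
  coll
}

#' Replace a fraction of isolates by starter-derived clonal variants
#'
#' Exactly `round(fraction * n)` individuals (chosen at random) are replaced
#' by a copy of a random starter profile carrying `0..max_edits` single-step
#' allelic edits (+-1 repeat unit at a uniformly chosen locus and allele
#' slot). Provenance is recorded in metadata column `starter_truth` for
#' recall/precision scoring against [attribute_starters()].
#'
#' @param coll an [mlg_collection()].
#' @param starters an `mlg_collection` of starter profiles (see
#'   [simulate_starters()]); its panel must match `coll`'s loci.
#' @param fraction fraction of individuals to replace, in `[0, 1]`.
#' @param max_edits maximum number of edits per spiked isolate (>= 0).
#' @param seed integer seed.
#' @return `coll` with spiked genotypes and a `starter_truth` metadata column.
#' @export
spike_starters <- function(coll, starters, fraction, max_edits = 2L,
                           seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (max_edits < 0) stop("max_edits must be >= 0")
  if (!identical(starters$panel$locus, coll$panel$locus))
    stop("starter panel loci do not match the collection")
  if (!is.null(seed)) set.seed(seed)
  n <- n_ind(coll)
  k <- round(fraction * n)
  coll$meta$starter_truth <- NA_character_
  if (k == 0L) return(coll)
  if (n_ind(starters) == 0L) stop("empty starter panel")
  who <- sample.int(n, k)
  src <- sample.int(n_ind(starters), k, replace = TRUE)
  sn <- if ("starter" %in% names(starters$meta)) starters$meta$starter
        else individual_ids(starters)
  for (j in seq_len(k)) {
    prof <- starters$alleles[src[j], , , drop = TRUE]
    ne <- if (max_edits > 0) sample.int(max_edits + 1L, 1L) - 1L else 0L
    for (e in seq_len(ne)) {
      l <- sample.int(n_loci(coll), 1L)
      s <- sample.int(2L, 1L)
      prof[l, s] <- prof[l, s] + sample(c(-1L, 1L), 1L) * coll$panel$motif_bp[l]
    }
    ## keep the unordered-pair canonical form
    coll$alleles[who[j], , 1] <- pmin(prof[, 1], prof[, 2])
    coll$alleles[who[j], , 2] <- pmax(prof[, 1], prof[, 2])
    coll$meta$starter_truth[who[j]] <- sn[src[j]]
  }
  coll
}
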