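#' Default pipeline configuration
#'
#' @param max_missing missing-loci admission threshold per individual.
#' @param clone_stratum stratum for clone correction (default `"estate"`).
#' @param starter_threshold allele-sharing threshold for starter relatedness.
#' @param remove_starters drop starter-related isolates before the
#'   structure analyses.
#' @param amova_models list of strata vectors (outermost first).
#' @param fst_stratum stratum for the pairwise Fst matrix and migration.
#' @param n_perm permutations for AMOVA/Fst/Mantel tests.
#' @param balanced list with `side_stratum`, `side_a`, `side_b`,
#'   `group_stratum`, `cap`, `n_reps`; set to `NULL` to skip.
#' @param rarefy_depth depth for genotype-richness rarefaction or
#'   extrapolation (may exceed the sample size); `NULL` skips.
#' @param rarefy_reps Monte-Carlo replicates for rarefaction.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_missing = 3L,
                            clone_stratum = "estate",
                            starter_threshold = 0.75,
                            remove_starters = TRUE,
                            amova_models = list("appellation",
                                                c("appellation", "estate"),
                                                "estate",
                                                "farming"),
                            fst_stratum = "appellation",
                            n_perm = 199L,
                            balanced = list(side_stratum = "compartment",
                                            side_a = "grape",
                                            side_b = "cellar",
                                            group_stratum = "estate",
                                            cap = 20L, n_reps = 100L),
                            rarefy_depth = NULL,
                            rarefy_reps = 10L,
                            seed = 1L) {
  cfg <- list(max_missing = max_missing, clone_stratum = clone_stratum,
              starter_threshold = starter_threshold,
              remove_starters = remove_starters,
              amova_models = amova_models, fst_stratum = fst_stratum,
              n_perm = n_perm, balanced = balanced,
              rarefy_depth = rarefy_depth, rarefy_reps = rarefy_reps,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full study-shaped analysis
#'
#' Stage order: missing-data filter, clone correction within
#' `clone_stratum`, starter attribution (and optional removal), genotype
#' diversity by farming system and by appellation, AMOVA models, pairwise
#' Fst with permutation tests, Mantel isolation-by-distance test (when
#' coordinates are present), relative directional migration, and the
#' balanced-subsample compartment Fst (when both compartments are present).
#' Deterministic given `config$seed`.
#'
#' @param coll an [mlg_collection()] (metadata should carry the strata named
#'   in `config`).
#' @param starters optional starter panel for attribution.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: reports are written there as CSV/JSON
#'   with byte-stable content.
#' @return List of class `pipeline_result`: `manifest` (stage-by-stage record
#'   counts, config echo, seeds), `diversity`, `attribution`, `amova`,
#'   `pairwise_fst`, `mantel`, `migration`, `balanced_fst`.
#' @export
run_pipeline <- function(coll, starters = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  for (s in unique(c(config$clone_stratum, unlist(config$amova_models),
                     config$fst_stratum))) {
    if (!s %in% names(coll$meta))
      stop("pipeline aborted at stage 'validate': unknown stratum '", s, "'")
  }
  counts <- c(collected = n_ind(coll))

  ## stage: missing-data filter
  nmiss <- apply(is.na(coll$alleles[, , 1, drop = FALSE]), 1, sum)
  coll <- subset_collection(coll, which(nmiss <= config$max_missing))
  counts["genotyped"] <- n_ind(coll)

  ## stage: clone correction
  cc <- clone_correct(coll, config$clone_stratum)
  counts["unique"] <- n_ind(cc)

  ## stage: starter attribution
  attribution <- NULL
  work <- cc
  if (!is.null(starters)) {
    attribution <- attribute_starters(cc, starters, config$starter_threshold)
    if (config$remove_starters) work <- remove_related(cc, attribution)
  }
  counts["starter_removed"] <- n_ind(work)

  ## stage: diversity -- computed on the admitted isolates BEFORE clone
  ## correction: genotype abundances (clonal expansion included) carry the
  ## evenness signal the indices are meant to summarize
  seed_div <- child_seed(config$seed, 11L)
  diversity <- list(
    by_farming = if ("farming" %in% names(coll$meta))
      diversity_report(coll, "farming") else NULL,
    by_appellation = if ("appellation" %in% names(coll$meta))
      diversity_report(coll, "appellation") else NULL,
    overall = diversity_report(coll))
  if (!is.null(config$rarefy_depth)) {
    diversity$rarefaction <- rarefy_richness(mlg_abundance(coll),
                                             config$rarefy_depth,
                                             reps = config$rarefy_reps,
                                             seed = seed_div)
  }

  ## stage: AMOVA models
  amova_out <- list()
  for (k in seq_along(config$amova_models)) {
    model <- config$amova_models[[k]]
    amova_out[[paste(model, collapse = "/")]] <-
      amova(work, model, n_perm = config$n_perm,
            seed = child_seed(config$seed, 20L + k))
  }

  ## stage: pairwise Fst
  fst <- pairwise_fst(work, config$fst_stratum, n_perm = config$n_perm,
                      seed = child_seed(config$seed, 31L))

  ## stage: Mantel (genetic vs geographic distance between groups)
  mantel <- NULL
  if (all(c("latitude", "longitude") %in% names(work$meta))) {
    g <- get_stratum(work, config$fst_stratum)
    cen <- data.frame(
      id = levels(g),
      latitude = as.numeric(tapply(work$meta$latitude, g, mean)),
      longitude = as.numeric(tapply(work$meta$longitude, g, mean)))
    common <- intersect(rownames(fst$fst), cen$id)
    if (length(common) >= 4) {
      geo <- geo_distance_matrix(cen[match(common, cen$id), ])
      mantel <- mantel_test(fst$fst[common, common], geo,
                            n_perm = max(99L, config$n_perm),
                            seed = child_seed(config$seed, 32L))
    }
  }

  ## stage: directional migration
  migration <- tryCatch(
    directional_migration(work, config$fst_stratum,
                          seed = child_seed(config$seed, 33L)),
    error = function(e) NULL)

  ## stage: balanced compartment Fst
  balanced <- NULL
  bc <- config$balanced
  if (!is.null(bc) && bc$side_stratum %in% names(work$meta)) {
    side <- as.character(get_stratum(work, bc$side_stratum))
    if (all(c(bc$side_a, bc$side_b) %in% side)) {
      balanced <- balanced_fst(work, bc$side_stratum, bc$side_a, bc$side_b,
                               group_stratum = bc$group_stratum,
                               cap = bc$cap, n_reps = bc$n_reps,
                               seed = child_seed(config$seed, 34L))
    }
  }

  manifest <- list(
    counts = as.list(counts),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    n_loci = n_loci(coll))
  res <- list(manifest = manifest, diversity = diversity,
              attribution = attribution, amova = amova_out,
              pairwise_fst = fst, mantel = mantel, migration = migration,
              balanced_fst = balanced)
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  counts:",
      paste(names(x$manifest$counts), unlist(x$manifest$counts),
            sep = "=", collapse = " -> "), "\n")
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Plain CSV/JSON only; content is byte-stable for a fixed result.
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (nm in names(res$diversity)) {
    d <- res$diversity[[nm]]
    if (is.data.frame(d)) w(d, paste0("diversity_", nm, ".csv"))
  }
  if (!is.null(res$attribution)) w(as.data.frame(res$attribution), "attribution.csv")
  for (nm in names(res$amova)) {
    w(as.data.frame(res$amova[[nm]]),
      paste0("amova_", gsub("/", "_", nm), ".csv"))
  }
  utils::write.csv(round(res$pairwise_fst$fst, 6),
                   file.path(out_dir, "pairwise_fst.csv"), quote = FALSE)
  utils::write.csv(round(res$pairwise_fst$p, 6),
                   file.path(out_dir, "pairwise_fst_p.csv"), quote = FALSE)
  if (!is.null(res$mantel))
    jsonlite::write_json(res$mantel, file.path(out_dir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$migration))
    utils::write.csv(round(res$migration$m, 6),
                     file.path(out_dir, "migration.csv"), quote = FALSE)
  if (!is.null(res$balanced_fst))
    jsonlite::write_json(res$balanced_fst[c("mean_fst", "sd_fst")],
                         file.path(out_dir, "balanced_fst.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
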