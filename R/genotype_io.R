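#' Read a wide-format microsatellite genotype table
#'
#' Two dialects are supported. `two_column_wide`: a CSV with an
#' `individual_id` column followed by two columns per locus named
#' `LOCUS.1`, `LOCUS.2`, allele sizes in bp, missing encoded as `0`.
#' `genalex`: a GenAlEx-style CSV with two preamble rows, then a header
#' `individual_id, pop, LOCUS, , LOCUS, , ...` (one name per locus, second
#' allele column unnamed); the `pop` column is kept as metadata column `pop`.
#'
#' Admission rule: an individual is rejected (with a logged reason, reported
#' in `attr(, "rejected")`) when more than `max_missing` loci are missing.
#' A half-missing locus (one allele present, one absent) is a parse error.
#'
#' @param path CSV file path.
#' @param panel a [locus_panel()]; header locus names must match it.
#' @param meta optional metadata data frame (or CSV path) with
#'   `individual_id`; joined by exact, case-sensitive id match.
#' @param dialect `"two_column_wide"` (default) or `"genalex"`.
#' @param max_missing maximum number of fully-missing loci tolerated per
#'   individual (default 3).
#' @param missing_code file encoding of a missing allele (default `"0"`).
#' @return An [mlg_collection()]; rejected individuals are recorded in
#'   `attr(, "rejected")` as a data frame `(individual_id, n_missing)`.
#' @export
read_genotype_table <- function(path, panel,
                                meta = NULL,
                                dialect = c("two_column_wide", "genalex"),
                                max_missing = 3L,
                                missing_code = "0") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "two_column_wide") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    idcol <- "individual_id"
    expected <- as.vector(rbind(paste0(panel$locus, ".1"), paste0(panel$locus, ".2")))
    extra <- setdiff(names(df), c(idcol, expected))
    if (length(extra)) stop("unknown locus column(s): ", paste(extra, collapse = ", "))
    if (!all(c(idcol, expected) %in% names(df)))
      stop("missing column(s): ",
           paste(setdiff(c(idcol, expected), names(df)), collapse = ", "))
    ids <- df[[idcol]]
    mat <- as.matrix(df[, expected, drop = FALSE])
  } else {
    raw <- utils::read.csv(path, header = FALSE, skip = 2, check.names = FALSE,
                           colClasses = "character")
    hdr <- as.character(unlist(raw[1, ]))
    body <- raw[-1, , drop = FALSE]
    ids <- body[[1]]
    pop <- body[[2]]
    loc_first <- seq(3, by = 2, length.out = (ncol(body) - 2) / 2)
    got <- hdr[loc_first]
    if (!identical(got, panel$locus))
      stop("genalex locus header does not match panel: ",
           paste(setdiff(got, panel$locus), collapse = ", "))
    mat <- as.matrix(body[, 3:ncol(body), drop = FALSE])
    colnames(mat) <- as.vector(rbind(paste0(panel$locus, ".1"), paste0(panel$locus, ".2")))
  }
  mat[mat == missing_code | mat == ""] <- NA
  num <- suppressWarnings(matrix(as.integer(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  if (anyNA(num[!is.na(mat)])) stop("non-integer allele size in ", path)
  L <- nrow(panel)
  alleles <- array(NA_integer_, dim = c(length(ids), L, 2),
                   dimnames = list(ids, panel$locus, NULL))
  alleles[, , 1] <- num[, seq(1, 2 * L, by = 2)]
  alleles[, , 2] <- num[, seq(2, 2 * L, by = 2)]
  ## half-missing check happens in the constructor, but name things here first
  half <- xor(is.na(alleles[, , 1, drop = FALSE]), is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)
    stop("parse error: half-missing locus for individual '", ids[bad[1, 1]],
         "' at locus '", panel$locus[bad[1, 2]], "'")
  }
  n_missing <- rowSums(is.na(alleles[, , 1, drop = FALSE]))
  keep <- n_missing <= max_missing
  rejected <- data.frame(individual_id = ids[!keep],
                         n_missing = as.integer(n_missing[!keep]),
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    message(nrow(rejected), " individual(s) rejected: more than ", max_missing,
            " missing loci (", paste(rejected$individual_id, collapse = ", "), ")")
  if (is.character(meta)) meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  if (dialect == "genalex") {
    popdf <- data.frame(individual_id = ids, pop = pop, stringsAsFactors = FALSE)
    meta <- if (is.null(meta)) popdf else merge(popdf, meta, by = "individual_id",
                                                all.x = TRUE, sort = FALSE)
  }
  if (!is.null(meta)) meta <- meta[meta$individual_id %in% ids[keep], , drop = FALSE]
  coll <- mlg_collection(alleles[keep, , , drop = FALSE], panel, meta)
  attr(coll, "rejected") <- rejected
  coll
}

#' Write a genotype table
#'
#' Output is byte-stable for a fixed collection: rows are sorted by
#' `individual_id` and missing alleles written as `0`.
#'
#' @param coll a non-empty [mlg_collection()].
#' @param path output CSV path.
#' @param dialect `"two_column_wide"` or `"genalex"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(coll, path,
                                 dialect = c("two_column_wide", "genalex")) {
  dialect <- match.arg(dialect)
  if (n_ind(coll) == 0L) stop("cannot write an empty collection")
  ord <- order(individual_ids(coll))
  coll <- subset_collection(coll, ord)
  L <- n_loci(coll)
  mat <- matrix("0", n_ind(coll), 2 * L)
  mat[, seq(1, 2 * L, by = 2)] <- ifelse(is.na(coll$alleles[, , 1]), "0",
                                         as.character(coll$alleles[, , 1]))
  mat[, seq(2, 2 * L, by = 2)] <- ifelse(is.na(coll$alleles[, , 2]), "0",
                                         as.character(coll$alleles[, , 2]))
  if (dialect == "two_column_wide") {
    df <- data.frame(individual_id = individual_ids(coll), mat,
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[-1] <- as.vector(rbind(paste0(coll$panel$locus, ".1"),
                                     paste0(coll$panel$locus, ".2")))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    pop <- if ("pop" %in% names(coll$meta)) as.character(coll$meta$pop)
           else rep("1", n_ind(coll))
    con <- file(path, "w")
    on.exit(close(con))
    npop <- length(unique(pop))
    writeLines(paste(c(L, n_ind(coll), npop, rep("", 2 * L - 1)), collapse = ","), con)
    writeLines(paste(c("mlgpop export", rep("", 2 * L + 1)), collapse = ","), con)
    hdr <- c("individual_id", "pop", as.vector(rbind(coll$panel$locus, "")))
    writeLines(paste(hdr, collapse = ","), con)
    rows <- cbind(individual_ids(coll), pop, mat)
    writeLines(apply(rows, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a locus panel CSV
#'
#' Columns: `locus`, `motif_bp`, optional `offset_bp`, `multi_motif`.
#' @param path CSV path.
#' @return A [locus_panel()].
#' @export
read_locus_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  locus_panel(df$locus, df$motif_bp,
              offset_bp = if ("offset_bp" %in% names(df)) df$offset_bp else 0L,
              multi_motif = if ("multi_motif" %in% names(df)) df$multi_motif else FALSE)
}

#' Read a site-coordinate table
#'
#' @param path CSV with columns `id`, `latitude`, `longitude`
#'   (decimal degrees, WGS84).
#' @return Data frame with those columns.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("coordinate table needs columns: ", paste(need, collapse = ", "))
  df[need]
}
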