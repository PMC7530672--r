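#' Locus panel: names and repeat-motif lengths
#'
#' A locus panel records, for each microsatellite locus, its name, the length
#' of the repeat motif in base pairs, and an optional flanking-sequence offset
#' subtracted from the amplicon size before conversion to repeat units.
#'
#' @param locus character vector of unique locus names.
#' @param motif_bp integer vector of repeat-motif lengths in bp (>= 1).
#' @param offset_bp integer vector of primer/flank offsets in bp subtracted
#'   before dividing by `motif_bp`; defaults to 0.
#' @param multi_motif logical flag per locus marking compound-motif loci (the
#'   stepwise model underlying Bruvo distance is only approximate for these;
#'   a warning is raised when they enter distance computations).
#' @return A `locus_panel` data frame with columns `locus`, `motif_bp`,
#'   `offset_bp`, `multi_motif`.
#' @examples
#' locus_panel(c("C5", "C11"), motif_bp = c(3, 3))
#' @export
locus_panel <- function(locus, motif_bp, offset_bp = 0L, multi_motif = FALSE) {
  locus <- as.character(locus)
  if (anyDuplicated(locus)) stop("locus names must be unique")
  motif_bp <- as.integer(motif_bp)
  if (length(motif_bp) == 1L) motif_bp <- rep(motif_bp, length(locus))
  if (any(motif_bp < 1L)) stop("motif_bp must be >= 1")
  offset_bp <- rep_len(as.integer(offset_bp), length(locus))
  multi_motif <- rep_len(as.logical(multi_motif), length(locus))
  out <- data.frame(locus = locus, motif_bp = motif_bp,
                    offset_bp = offset_bp, multi_motif = multi_motif,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_panel", "data.frame")
  out
}

#' Multilocus genotype collection
#'
#' The central container: `n` diploid individuals typed at `L` microsatellite
#' loci, with unordered allele pairs stored as amplicon sizes in bp, a
#' [locus_panel()], and a metadata table carrying the population hierarchy
#' (e.g. appellation, estate, farming system, compartment, vintage,
#' coordinates). Missing data are `NA`; a locus is either fully missing (both
#' slots `NA`) or fully typed -- half-missing calls are rejected.
#'
#' @param alleles integer array `n x L x 2` of allele sizes in bp (`NA` =
#'   missing). Pairs are canonicalized so slot 1 <= slot 2.
#' @param panel a [locus_panel()] whose loci match `dim(alleles)[2]`.
#' @param meta data frame with one row per individual; must contain an
#'   `individual_id` column matching `rownames(alleles)` (created from row
#'   order if absent).
#' @return An object of class `mlg_collection`.
#' @export
mlg_collection <- function(alleles, panel, meta = NULL) {
  stopifnot(is.array(alleles), length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  if (!inherits(panel, "locus_panel")) stop("panel must be a locus_panel")
  if (dim(alleles)[2] != nrow(panel))
    stop("alleles has ", dim(alleles)[2], " loci but panel has ", nrow(panel))
  n <- dim(alleles)[1]
  if (is.null(rownames(alleles))) {
    if (!is.null(meta) && "individual_id" %in% names(meta)) {
      rownames(alleles) <- as.character(meta$individual_id)
    } else {
      rownames(alleles) <- sprintf("ind%04d", seq_len(n))
    }
  }
  storage.mode(alleles) <- "integer"
  dimnames(alleles)[[2]] <- panel$locus
  half <- xor(is.na(alleles[, , 1, drop = FALSE]), is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)
    stop("half-missing locus call for individual '",
         rownames(alleles)[bad[1, 1]], "' at locus '",
         panel$locus[bad[1, 2]], "': one allele present, one absent")
  }
  if (any(alleles <= 0L, na.rm = TRUE)) stop("allele sizes must be positive")
  ## canonical unordered pair: slot1 <= slot2
  a1 <- pmin(alleles[, , 1], alleles[, , 2])
  a2 <- pmax(alleles[, , 1], alleles[, , 2])
  alleles[, , 1] <- a1
  alleles[, , 2] <- a2
  if (is.null(meta)) {
    meta <- data.frame(individual_id = rownames(alleles), stringsAsFactors = FALSE)
  }
  if (!"individual_id" %in% names(meta)) stop("meta must have an individual_id column")
  meta$individual_id <- as.character(meta$individual_id)
  if (anyDuplicated(meta$individual_id)) stop("duplicated individual_id in meta")
  idx <- match(rownames(alleles), meta$individual_id)
  if (anyNA(idx)) {
    stop("metadata missing for individual(s): ",
         paste(utils::head(setdiff(rownames(alleles), meta$individual_id), 5), collapse = ", "))
  }
  meta <- meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(alleles = alleles, panel = panel, meta = meta),
            class = "mlg_collection")
}

#' @export
print.mlg_collection <- function(x, ...) {
  cat("<mlg_collection> ", n_ind(x), " individuals x ", n_loci(x), " loci\n", sep = "")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat("  missing locus calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  strata <- setdiff(names(x$meta), c("individual_id", "latitude", "longitude"))
  if (length(strata)) cat("  metadata: ", paste(strata, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a collection
#' @param coll an `mlg_collection`.
#' @return An integer count.
#' @export
n_ind <- function(coll) dim(coll$alleles)[1]

#' @rdname n_ind
#' @export
n_loci <- function(coll) dim(coll$alleles)[2]

#' Individual identifiers of a collection
#' @param coll an `mlg_collection`.
#' @return Character vector of ids, in storage order.
#' @export
individual_ids <- function(coll) rownames(coll$alleles)

#' Subset a collection by individuals
#'
#' @param coll an `mlg_collection`.
#' @param i logical, integer, or character (ids) index.
#' @return The subsetted `mlg_collection` (metadata rows follow).
#' @export
subset_collection <- function(coll, i) {
  if (is.character(i)) i <- match(i, individual_ids(coll))
  if (anyNA(i)) stop("unknown individual id in subset")
  alleles <- coll$alleles[i, , , drop = FALSE]
  meta <- coll$meta[if (is.logical(i)) which(i) else i, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(alleles = alleles, panel = coll$panel, meta = meta),
            class = "mlg_collection")
}

#' Retrieve a stratum as a factor
#'
#' @param coll an `mlg_collection`.
#' @param stratum name of a metadata column defining the grouping.
#' @return A factor of length `n_ind(coll)`.
#' @export
get_stratum <- function(coll, stratum) {
  if (!stratum %in% names(coll$meta))
    stop("unknown stratum '", stratum, "'; available: ",
         paste(setdiff(names(coll$meta), "individual_id"), collapse = ", "))
  factor(coll$meta[[stratum]])
}

#' Convert allele sizes to repeat units
#'
#' Repeat counts are `round((size_bp - offset_bp) / motif_bp)` with R's
#' round-half-to-even rule; `NA` (missing) propagates. Bruvo distance and the
#' stepwise-mutation simulator operate on these units.
#'
#' @param coll an `mlg_collection`.
#' @return Integer array `n x L x 2` of repeat counts (`NA` = missing).
#' @examples
#' pan <- locus_panel("L1", motif_bp = 3)
#' a <- array(c(150L, 151L, 150L, 151L), dim = c(2, 1, 2))
#' to_repeat_units(mlg_collection(a, pan))[, 1, ]
#' @export
to_repeat_units <- function(coll) {
  ru <- coll$alleles
  for (l in seq_len(n_loci(coll))) {
    ru[, l, ] <- as.integer(round((coll$alleles[, l, ] - coll$panel$offset_bp[l]) /
                                    coll$panel$motif_bp[l]))
  }
  ru
}

#' Combine two collections sharing a panel
#' @param a,b `mlg_collection`s on identical panels; ids must not clash.
#' @return The concatenated `mlg_collection`.
#' @export
bind_collections <- function(a, b) {
  if (!identical(a$panel$locus, b$panel$locus)) stop("panels differ")
  if (length(intersect(individual_ids(a), individual_ids(b))))
    stop("individual ids overlap")
  al <- array(NA_integer_, dim = c(n_ind(a) + n_ind(b), n_loci(a), 2),
              dimnames = list(c(individual_ids(a), individual_ids(b)),
                              a$panel$locus, NULL))
  al[seq_len(n_ind(a)), , ] <- a$alleles
  al[n_ind(a) + seq_len(n_ind(b)), , ] <- b$alleles
  cols <- union(names(a$meta), names(b$meta))
  ma <- a$meta; mb <- b$meta
  for (cc in setdiff(cols, names(ma))) ma[[cc]] <- NA
  for (cc in setdiff(cols, names(mb))) mb[[cc]] <- NA
  mlg_collection(al, a$panel, rbind(ma[cols], mb[cols]))
}

## internal: per-locus integer allele codes on repeat-unit scale (or bp);
## returns list of n x 2 matrices of codes, NA preserved
locus_codes <- function(coll, units = c("bp", "repeat")) {
  units <- match.arg(units)
  x <- if (units == "repeat") to_repeat_units(coll) else coll$alleles
  lapply(seq_len(n_loci(coll)), function(l) {
    m <- x[, l, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 2)
    vals <- sort(unique(as.vector(m[!is.na(m)])))
    cod <- matrix(match(m, vals), ncol = 2)
    attr(cod, "values") <- vals
    cod
  })
}
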