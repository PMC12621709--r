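#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Parameter container for the synthetic snm3C-seq cohort generator. Create
#' with [simConfig()]; fields are accessed with `$`. The defaults describe a
#' cohort mirroring the study design the package targets: 11 AD and 9 control
#' donors, three cortical regions (VC, PFC, TC) sampled from every donor,
#' three global-methylation subgroups, a two-instrument batch structure with
#' a linear cross-instrument relationship, short- and long-range contact
#' decay classes, block (TAD) and checkerboard (compartment) contact
#' structure, and telomere-proximal deleted bins confined to Stressed cells.
#'
#' @slot params named list of configuration values (see [simConfig()]).
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig", representation(params = "list"))

#' @export
setMethod("$", "SimConfig", function(x, name) x@params[[name]])

#' @export
setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$n_ad_donors, "AD +", p$n_control_donors,
      "control donors x", length(p$regions), "regions,",
      p$cells_per_sample, "cells/sample\n")
  cat("  genome:", paste(names(p$chrom_lengths), collapse = ", "),
      "| methyl bins", p$bin_size_methyl, "bp | contact bins",
      p$bin_size_contact, "bp\n")
  cat("  seed:", p$seed, "| deleted bins:", p$n_deleted_bins, "\n")
})

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- character()
  for (f in c("n_ad_donors", "n_control_donors", "cells_per_sample",
              "contacts_per_cell"))
    if (p[[f]] <= 0 || p[[f]] != round(p[[f]]))
      msg <- c(msg, sprintf("field '%s' must be a positive integer", f))
  for (f in c("bin_size_methyl", "bin_size_contact", "bin_size_boundary"))
    if (p[[f]] <= 0) msg <- c(msg, sprintf("field '%s' must be positive", f))
  if (any(p$chrom_lengths <= 0))
    msg <- c(msg, "field 'chrom_lengths' must be strictly positive")
  bad_cen <- names(p$centromeres)[p$centromeres <= 0 |
    p$centromeres >= p$chrom_lengths[names(p$centromeres)]]
  if (length(bad_cen))
    msg <- c(msg, sprintf(
      "field 'centromeres' must lie inside the chromosome (%s)",
      paste(bad_cen, collapse = ", ")))
  sp <- p$subgroup_proportions
  if (any(abs(rowSums(sp[, c("p0", "p1", "p2")]) - 1) > 1e-9))
    msg <- c(msg, "field 'subgroup_proportions' rows must sum to 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' Planted ground truth of a synthetic cohort
#'
#' Per-cell labels (subgroup, decay class, Homeostatic/Stressed state),
#' planted deleted bins, planted batch/instrument parameters, planted
#' region-by-disease methylation effects, and planted TAD boundary
#' positions. Sufficient to score every downstream recovery test.
#'
#' @slot cells data.frame with one row per cell: `cell_id`, `subgroup`
#'   (0/1/2), `decay_class` ("Short"/"Long"), `state`
#'   ("Homeostatic"/"Stressed").
#' @slot deleted_bins data.frame (`chrom`, `bin_index`, `start`, `end`) of
#'   contact-resolution bins with planted contact loss in Stressed cells.
#' @slot region_effects data.frame (`region`, `disease`, `shift`): planted CG
#'   methylation shift.
#' @slot batch_offset numeric planted instrument-B methylation offset.
#' @slot instrument_relation numeric `(intercept, slope)` of the planted
#'   linear map from instrument-A to instrument-B global levels.
#' @slot boundaries data.frame (`chrom`, `position`) of planted TAD
#'   boundaries.
#' @slot shared_libraries data.frame (`context`, `level_a`, `level_b`):
#'   libraries measured on both instruments, for normalization fitting.
#' @slot subgroup_offsets numeric matrix (3 subgroups x CG/CH) of planted
#'   global-methylation offsets.
#' @exportClass SimTruth
setClass("SimTruth", representation(
  cells = "data.frame", deleted_bins = "data.frame",
  region_effects = "data.frame", batch_offset = "numeric",
  instrument_relation = "numeric", boundaries = "data.frame",
  shared_libraries = "data.frame", subgroup_offsets = "matrix"))

setValidity("SimTruth", function(object) {
  if (anyDuplicated(object@cells$cell_id))
    return("every cell must appear exactly once in the label mapping")
  TRUE
})

#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@cells), "cells;",
      nrow(object@deleted_bins), "planted deleted bins;",
      nrow(object@boundaries), "planted boundaries\n")
})

#' @describeIn SimTruth per-cell truth labels.
#' @param x,object a `SimTruth`.
#' @export
truthCells <- function(x) x@cells

#' @describeIn SimTruth planted deleted contact bins.
#' @export
deletedBins <- function(x) x@deleted_bins

#' @describeIn SimTruth planted TAD boundary positions.
#' @export
plantedBoundaries <- function(x) x@boundaries

## ---------------------------------------------------------------------------
## MethylBinCounts
## ---------------------------------------------------------------------------

#' Binned methylation counts for a set of cells
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' genomic bins (0-based half-open intervals stored as `GRanges`) and whose
#' columns are cells. For each cytosine context (CG, CH, optionally CCC) the
#' object carries a pair of integer assays `mc_<ctx>` (methylated read count)
#' and `cov_<ctx>` (total coverage), with `mc <= cov` elementwise.
#'
#' @aliases MethylBinCounts
#' @exportClass MethylBinCounts
setClass("MethylBinCounts", contains = "RangedSummarizedExperiment")

setValidity("MethylBinCounts", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  ctx <- sub("^mc_", "", grep("^mc_", an, value = TRUE))
  if (!length(ctx)) return("needs at least one mc_<context> assay")
  for (cc in ctx) {
    if (!paste0("cov_", cc) %in% an)
      return(sprintf("assay mc_%s has no matching cov_%s", cc, cc))
    mc <- SummarizedExperiment::assay(object, paste0("mc_", cc))
    cov <- SummarizedExperiment::assay(object, paste0("cov_", cc))
    if (any(mc > cov, na.rm = TRUE))
      return(sprintf("mc_%s exceeds cov_%s", cc, cc))
    if (any(mc < 0, na.rm = TRUE) || any(cov < 0, na.rm = TRUE))
      return("counts must be nonnegative")
  }
  gr <- SummarizedExperiment::rowRanges(object)
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    st <- GenomicRanges::start(g)
    if (is.unsorted(st))
      return("bins must be sorted within chromosome")
    if (length(g) > 1 &&
        any(GenomicRanges::start(g)[-1] < GenomicRanges::end(g)[-length(g)] + 1 - 1))
      if (any(GenomicRanges::start(g)[-1] <= GenomicRanges::end(g)[-length(g)] - 1))
        return("bins must be non-overlapping within chromosome")
  }
  TRUE
})

#' Construct a MethylBinCounts object
#'
#' @param bins `GRanges` of genomic bins (sorted, non-overlapping per
#'   chromosome).
#' @param mc,cov named lists of bins-by-cells integer matrices, one entry per
#'   context (e.g. `CG`, `CH`); names and dimensions must match.
#' @param cellData optional `DataFrame`/data.frame of per-cell columns; row
#'   names become cell ids if matrices carry none.
#' @return a [MethylBinCounts-class] object.
#' @export
MethylBinCounts <- function(bins, mc, cov, cellData = NULL) {
  stopifnot(is.list(mc), is.list(cov), identical(sort(names(mc)), sort(names(cov))))
  assays <- c(
    stats::setNames(mc, paste0("mc_", names(mc))),
    stats::setNames(cov, paste0("cov_", names(cov))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = bins,
    colData = if (is.null(cellData)) {
      S4Vectors::DataFrame(row.names = colnames(mc[[1]]))
    } else S4Vectors::DataFrame(cellData))
  new("MethylBinCounts", se)
}

#' @describeIn MethylBinCounts contexts present in the object.
#' @param object a `MethylBinCounts`.
#' @export
methContexts <- function(object) {
  sub("^mc_", "", grep("^mc_",
      SummarizedExperiment::assayNames(object), value = TRUE))
}

#' @export
setMethod("show", "MethylBinCounts", function(object) {
  cat("MethylBinCounts:", nrow(object), "bins x", ncol(object), "cells;",
      "contexts:", paste(methContexts(object), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ContactSet
## ---------------------------------------------------------------------------

#' Per-cell chromatin contact lists
#'
#' A container for pairs-format chromatin contacts across a set of cells:
#' one long table with columns `cell_id`, `chrom1`, `pos1`, `chrom2`, `pos2`
#' plus the chromosome sizes the positions live on.
#'
#' @slot contacts a `data.table` of contacts.
#' @slot chrom_lengths named numeric vector of chromosome lengths (bp).
#' @aliases ContactSet
#' @exportClass ContactSet
setClass("ContactSet", representation(
  contacts = "data.frame", chrom_lengths = "numeric"))

setValidity("ContactSet", function(object) {
  need <- c("cell_id", "chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(object@contacts)))
    return(paste("contacts must have columns", paste(need, collapse = ", ")))
  cl <- object@chrom_lengths
  dt <- object@contacts
  if (!all(unique(c(dt$chrom1, dt$chrom2)) %in% names(cl)))
    return("contacts reference chromosomes absent from chrom_lengths")
  TRUE
})

#' Construct a ContactSet
#' @param contacts data.frame/data.table with `cell_id`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`.
#' @param chrom_lengths named numeric chromosome lengths in bp.
#' @return a [ContactSet-class].
#' @export
ContactSet <- function(contacts, chrom_lengths) {
  new("ContactSet", contacts = data.table::as.data.table(contacts),
      chrom_lengths = chrom_lengths)
}

#' @describeIn ContactSet the underlying contact table (`data.table`).
#' @param x,object a `ContactSet`.
#' @export
contactsTable <- function(x) data.table::as.data.table(x@contacts)

#' @describeIn ContactSet named chromosome lengths.
#' @export
chromLengths <- function(x) x@chrom_lengths

#' @export
setMethod("show", "ContactSet", function(object) {
  cat("ContactSet:", nrow(object@contacts), "contacts from",
      length(unique(object@contacts$cell_id)), "cells on",
      length(object@chrom_lengths), "chromosomes\n")
})

## ---------------------------------------------------------------------------
## BinnedContactMatrix
## ---------------------------------------------------------------------------

#' Symmetric binned contact matrix for one chromosome
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot matrix symmetric nonnegative numeric matrix (bins x bins).
#' @slot weights per-bin ICE balancing weights (`NA` where masked); empty
#'   until [balanceICE()] is applied.
#' @slot n_cells number of cells merged into this matrix.
#' @aliases BinnedContactMatrix
#' @exportClass BinnedContactMatrix
setClass("BinnedContactMatrix", representation(
  chrom = "character", resolution = "numeric", matrix = "matrix",
  weights = "numeric", n_cells = "numeric"))

setValidity("BinnedContactMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(m < 0, na.rm = TRUE)) return("matrix must be nonnegative")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9 * max(1, max(abs(m), na.rm = TRUE)))
    return("matrix must be symmetric")
  if (length(object@weights) &&
      length(object@weights) != nrow(m))
    return("weights length must match matrix dimension")
  if (length(object@weights) && any(object@weights[!is.na(object@weights)] <= 0))
    return("defined weights must be positive")
  TRUE
})

#' Construct a BinnedContactMatrix
#' @param chrom chromosome name.
#' @param resolution bin size (bp).
#' @param matrix square symmetric nonnegative matrix.
#' @param weights optional balancing weights (NA = masked bin).
#' @param n_cells cells contributing.
#' @return a [BinnedContactMatrix-class].
#' @export
BinnedContactMatrix <- function(chrom, resolution, matrix,
                                weights = numeric(0), n_cells = NA_real_) {
  new("BinnedContactMatrix", chrom = chrom, resolution = resolution,
      matrix = matrix, weights = weights, n_cells = n_cells)
}

#' @describeIn BinnedContactMatrix the dense contact matrix.
#' @param x,object a `BinnedContactMatrix`.
#' @export
contactMatrix <- function(x) x@matrix

#' @describeIn BinnedContactMatrix balancing weights (empty if unbalanced).
#' @export
balancingWeights <- function(x) x@weights

#' @export
setMethod("show", "BinnedContactMatrix", function(object) {
  cat("BinnedContactMatrix:", object@chrom, "@", object@resolution, "bp,",
      nrow(object@matrix), "bins,",
      if (length(object@weights)) "balanced" else "raw", "\n")
})
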