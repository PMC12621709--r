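## Plain-text readers/writers for the package's external interfaces:
## metadata TSV, 4DN-like pairs TSV, long-format methylation TSV, truth
## JSON, dense matrix TSV with a JSON header, bedGraph and BED.

#' Write / read cell metadata TSV
#'
#' Fixed header starting with `cell_id, donor, region, disease, sex, age,
#' instrument, cell_type`; extra QC columns are preserved.
#'
#' @param meta metadata data.frame.
#' @param path file path.
#' @return `readCellMeta` returns the data.frame.
#' @export
writeCellMeta <- function(meta, path) {
  lead <- c("cell_id", "donor", "region", "disease", "sex", "age",
            "instrument", "cell_type")
  cols <- c(intersect(lead, names(meta)), setdiff(names(meta), lead))
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellMeta
#' @param path file path.
#' @export
readCellMeta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read contacts in a pairs-like TSV
#'
#' Columns `readID, chr1, pos1, chr2, pos2` (plain, uncompressed). The
#' `readID` carries the cell id and a per-cell counter.
#'
#' @param contacts a [ContactSet-class].
#' @param path file path.
#' @export
writeContactsPairs <- function(contacts, path) {
  dt <- contactsTable(contacts)
  out <- data.frame(
    readID = paste0(dt$cell_id, ".", stats::ave(seq_len(nrow(dt)),
                                                dt$cell_id, FUN = seq_along)),
    chr1 = dt$chrom1, pos1 = dt$pos1, chr2 = dt$chrom2, pos2 = dt$pos2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContactsPairs
#' @param chrom_lengths named chromosome lengths for the restored object.
#' @export
readContactsPairs <- function(path, chrom_lengths) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  ContactSet(data.frame(
    cell_id = sub("\\.[0-9]+$", "", x$readID),
    chrom1 = x$chr1, pos1 = x$pos1, chrom2 = x$chr2, pos2 = x$pos2),
    chrom_lengths)
}

#' Write / read binned methylation counts as a long TSV
#'
#' Long format `cell_id, chrom, bin_start, context, mc, cov` with 0-based
#' half-open bins; zero-coverage entries are omitted.
#'
#' @param counts a [MethylBinCounts-class].
#' @param path file path.
#' @export
writeMethylLong <- function(counts, path) {
  gr <- SummarizedExperiment::rowRanges(counts)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr) - 1
  rows <- list()
  for (ctx in methContexts(counts)) {
    mc <- SummarizedExperiment::assay(counts, paste0("mc_", ctx))
    cov <- SummarizedExperiment::assay(counts, paste0("cov_", ctx))
    idx <- which(cov > 0, arr.ind = TRUE)
    rows[[ctx]] <- data.frame(
      cell_id = colnames(counts)[idx[, 2]], chrom = chrom[idx[, 1]],
      bin_start = st[idx[, 1]], context = ctx,
      mc = mc[idx], cov = cov[idx])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$chrom, out$bin_start, out$context), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMethylLong
#' @param chrom_lengths named chromosome lengths.
#' @param bin_size methylation bin size (bp).
#' @export
readMethylLong <- function(path, chrom_lengths, bin_size) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    st <- seq(0, chrom_lengths[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = st,
               end = pmin(st + bin_size, chrom_lengths[[ch]]))
  }))
  gr <- GenomicRanges::GRanges(bins$chrom,
    IRanges::IRanges(bins$start + 1, bins$end))
  cells <- sort(unique(x$cell_id))
  key <- paste(bins$chrom, bins$start)
  ridx <- match(paste(x$chrom, x$bin_start), key)
  cidx <- match(x$cell_id, cells)
  mcl <- list(); covl <- list()
  for (ctx in unique(x$context)) {
    sel <- x$context == ctx
    mc <- matrix(0L, nrow(bins), length(cells),
                 dimnames = list(NULL, cells))
    cov <- mc
    mc[cbind(ridx[sel], cidx[sel])] <- x$mc[sel]
    cov[cbind(ridx[sel], cidx[sel])] <- x$cov[sel]
    mcl[[ctx]] <- mc; covl[[ctx]] <- cov
  }
  MethylBinCounts(gr, mc = mcl, cov = covl)
}

#' Write a dense matrix TSV with a JSON header sidecar
#'
#' @param x a [BinnedContactMatrix-class] or plain matrix.
#' @param path TSV path; the header goes to `<path>.json`.
#' @export
writeMatrixTSV <- function(x, path) {
  m <- if (is(x, "BinnedContactMatrix")) contactMatrix(x) else x
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hdr <- if (is(x, "BinnedContactMatrix")) {
    list(chrom = x@chrom, resolution = x@resolution, n_bins = nrow(m),
         n_cells = x@n_cells,
         weights = if (length(x@weights)) x@weights else NULL)
  } else list(n_bins = nrow(m))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  hp <- paste0(path, ".json")
  if (file.exists(hp)) {
    h <- jsonlite::read_json(hp, simplifyVector = TRUE)
    if (!is.null(h$chrom))
      return(BinnedContactMatrix(h$chrom, h$resolution, m,
        weights = if (!is.null(h$weights)) as.numeric(h$weights)
                  else numeric(0),
        n_cells = if (!is.null(h$n_cells))
          suppressWarnings(as.numeric(h$n_cells)) else NA_real_))
  }
  m
}

#' Write planted truth as a JSON sidecar
#'
#' @param truth a [SimTruth-class].
#' @param path file path.
#' @export
writeTruthJSON <- function(truth, path) {
  jsonlite::write_json(list(
    cells = truth@cells, deleted_bins = truth@deleted_bins,
    region_effects = truth@region_effects,
    batch_offset = truth@batch_offset,
    instrument_relation = as.list(truth@instrument_relation),
    boundaries = truth@boundaries,
    shared_libraries = truth@shared_libraries,
    subgroup_offsets = list(
      values = as.numeric(truth@subgroup_offsets),
      dim = dim(truth@subgroup_offsets),
      dimnames = dimnames(truth@subgroup_offsets))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJSON
#' @export
readTruthJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  so <- matrix(x$subgroup_offsets$values,
               nrow = x$subgroup_offsets$dim[1],
               dimnames = x$subgroup_offsets$dimnames)
  new("SimTruth", cells = as.data.frame(x$cells),
      deleted_bins = as.data.frame(x$deleted_bins),
      region_effects = as.data.frame(x$region_effects),
      batch_offset = x$batch_offset,
      instrument_relation = unlist(x$instrument_relation),
      boundaries = as.data.frame(x$boundaries),
      shared_libraries = as.data.frame(x$shared_libraries),
      subgroup_offsets = so)
}

#' Write a per-bin score track as bedGraph
#'
#' @param chrom chromosome name (recycled).
#' @param start,end 0-based half-open bin coordinates.
#' @param score numeric scores (NA rows dropped).
#' @param path file path.
#' @export
writeBedGraph <- function(chrom, start, end, score, path) {
  ok <- !is.na(score)
  utils::write.table(
    data.frame(chrom = chrom, start = start, end = end, score = score)[ok, ],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write deletion calls as BED (plus full TSV annotations)
#'
#' @param calls output of [detectPutativeDeletions()].
#' @param bed_path BED path (chrom, start, end, name = n_missing).
#' @param tsv_path optional annotated TSV path.
#' @export
writeDeletionsBED <- function(calls, bed_path, tsv_path = NULL) {
  utils::write.table(
    data.frame(calls$chrom, calls$start, calls$end,
               paste0("miss", calls$n_missing)),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bed_path)
}
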