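#' Quality-control thresholds for snm3C-seq cells
#'
#' The defaults are the study-standard cutoffs: overall mCCC < 0.05 (upper
#' bound on bisulfite non-conversion), mCH < 0.2, mCG > 0.5, total reads
#' between 0.5 M and 10 M, mapping rate > 0.5, and — for the 3C modality —
#' more than 50,000 cis long-range contacts (anchors > 2,500 bp apart). All
#' comparisons are strict.
#'
#' @param mccc_max,mch_max,mcg_min,reads_min,reads_max,mapping_rate_min,cis_long_min,cis_long_anchor_gap
#'   numeric cutoffs; see Description.
#' @return a named list of class `QCThresholds`.
#' @export
qcThresholds <- function(mccc_max = 0.05, mch_max = 0.2, mcg_min = 0.5,
                         reads_min = 5e5, reads_max = 1e7,
                         mapping_rate_min = 0.5, cis_long_min = 5e4,
                         cis_long_anchor_gap = 2500) {
  th <- list(mccc_max = mccc_max, mch_max = mch_max, mcg_min = mcg_min,
             reads_min = reads_min, reads_max = reads_max,
             mapping_rate_min = mapping_rate_min,
             cis_long_min = cis_long_min,
             cis_long_anchor_gap = cis_long_anchor_gap)
  for (f in names(th)) .check_number(th[[f]], f)
  if (th$mcg_min >= 1) .stop_config("mcg_min", "must be < 1")
  structure(th, class = "QCThresholds")
}

#' Filter cells on methylome (and optionally 3C) QC metrics
#'
#' A cell passes iff mCCC < 0.05 AND mCH < 0.2 AND mCG > 0.5 AND
#' 0.5M <= reads <= 10M AND mapping rate > 0.5; with `require_3c`, it must
#' additionally have more than 50,000 cis long-range contacts. Boundary
#' values fail: all inequalities are strict except the read-count interval,
#' whose endpoints are inclusive ("between 0.5 M and 10 M").
#'
#' @param meta cell metadata with columns `mccc`, `mch`, `mcg`, `reads`,
#'   `mapping_rate`, and (when `require_3c`) `cis_long`.
#' @param thresholds a [qcThresholds()] list.
#' @param require_3c also require the cis long-range contact cutoff.
#' @return list with `pass` (cell ids) and `failures` (named per-criterion
#'   failure counts).
#' @export
qcFilter <- function(meta, thresholds = qcThresholds(), require_3c = FALSE) {
  need <- c("cell_id", "mccc", "mch", "mcg", "reads", "mapping_rate")
  if (require_3c) need <- c(need, "cis_long")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks QC column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  th <- thresholds
  crit <- list(
    mccc = meta$mccc < th$mccc_max,
    mch = meta$mch < th$mch_max,
    mcg = meta$mcg > th$mcg_min,
    reads = meta$reads >= th$reads_min & meta$reads <= th$reads_max,
    mapping_rate = meta$mapping_rate > th$mapping_rate_min)
  if (require_3c) crit$cis_long <- meta$cis_long > th$cis_long_min
  pass <- Reduce(`&`, crit)
  list(pass = meta$cell_id[pass],
       failures = vapply(crit, function(x) sum(!x), integer(1)))
}

#' Select analysis bins by coverage, blacklist overlap and variance
#'
#' Keeps autosomal bins whose total coverage (summed over cells) lies
#' strictly between `coverage_min` and `coverage_max` and whose overlap with
#' blacklist intervals is below 20% of the bin, then ranks the survivors by
#' the variance of the per-cell methylation fraction and keeps the top
#' `top_k` (ties broken by genomic order).
#'
#' @param counts a [MethylBinCounts-class].
#' @param blacklist `GRanges` of excluded intervals (may be empty).
#' @param coverage_min,coverage_max strict bounds on per-bin total coverage.
#' @param top_k number of highly variable bins to keep.
#' @param context context used for coverage/variance (default "CG").
#' @param max_blacklist_overlap maximal tolerated overlap fraction (0.20).
#' @return integer vector of kept bin indices (rows of `counts`).
#' @export
filterBins <- function(counts, blacklist = GenomicRanges::GRanges(),
                       coverage_min = 500, coverage_max = 3000,
                       top_k = 20000, context = "CG",
                       max_blacklist_overlap = 0.20) {
  cov <- SummarizedExperiment::assay(counts, paste0("cov_", context))
  mc <- SummarizedExperiment::assay(counts, paste0("mc_", context))
  gr <- SummarizedExperiment::rowRanges(counts)
  tot <- rowSums(cov)
  keep <- tot > coverage_min & tot < coverage_max
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- keep & !chrom %in% c("chrX", "chrY", "chrM")
  if (length(blacklist)) {
    ov <- GenomicRanges::findOverlaps(gr, blacklist)
    frac <- numeric(length(gr))
    if (length(ov)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        gr[S4Vectors::queryHits(ov)], blacklist[S4Vectors::subjectHits(ov)]))
      frac <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                          levels = seq_along(gr)), sum))
      frac[is.na(frac)] <- 0
      frac <- frac / GenomicRanges::width(gr)
    }
    keep <- keep & frac < max_blacklist_overlap
  }
  idx <- which(keep)
  if (!length(idx)) return(integer(0))
  frac <- mc[idx, , drop = FALSE] / ifelse(cov[idx, , drop = FALSE] > 0,
                                           cov[idx, , drop = FALSE], NA)
  v <- apply(frac, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  if (top_k > length(idx)) {
    warning("top_k exceeds surviving bins; keeping all ", length(idx))
    top_k <- length(idx)
  }
  ## ties broken by genomic order: stable sort on decreasing variance
  sort(idx[order(-v, seq_along(idx))][seq_len(top_k)])
}

#' Binomial hypomethylation score
#'
#' For each cell, the expected methylation probability `p` is the mean of
#' the per-bin methylation fractions over the cell's covered bins. The score
#' of a bin with coverage `c` and methylated count `m` is the binomial
#' survival probability `P(X > m)` for `X ~ Binomial(c, p)` — the likelihood
#' of observing more methylated reads than seen, so hypomethylated bins
#' score near 1. Bins with zero coverage are `NA`. Computed via the
#' regularized incomplete beta form of the binomial survival function
#' (`pbinom(..., lower.tail = FALSE)`), stable for large coverage.
#'
#' @param counts a [MethylBinCounts-class].
#' @param context cytosine context (default "CG").
#' @return cells x bins numeric matrix of scores in `[0, 1]` (NA where
#'   coverage is 0).
#' @export
hypoScore <- function(counts, context = "CG") {
  mc <- SummarizedExperiment::assay(counts, paste0("mc_", context))
  cov <- SummarizedExperiment::assay(counts, paste0("cov_", context))
  frac <- ifelse(cov > 0, mc / cov, NA)
  p <- colMeans(frac, na.rm = TRUE)            # per-cell expectation
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("internal error: expected probability outside [0, 1]")
  out <- matrix(NA_real_, ncol(mc), nrow(mc),
                dimnames = list(colnames(mc), rownames(mc)))
  for (j in seq_len(ncol(mc))) {
    cv <- cov[, j]; mm <- mc[, j]
    s <- stats::pbinom(mm, cv, p[j], lower.tail = FALSE)
    s[cv == 0] <- NA_real_
    out[j, ] <- s
  }
  out
}

#' Binarize hypomethylation scores
#'
#' Scores strictly above the cutoff become 1, all others (including missing
#' scores) 0.
#'
#' @param scores numeric matrix from [hypoScore()].
#' @param cutoff binarization cutoff (default 0.9, strict ">").
#' @return integer matrix of the same shape.
#' @export
binarizeScores <- function(scores, cutoff = 0.9) {
  out <- (scores > cutoff)
  out[is.na(out)] <- FALSE
  storage.mode(out) <- "integer"
  out
}

#' Median global methylation levels per group
#'
#' A cell's global level in a context is its total methylated count divided
#' by its total coverage; the group value is the median over the group's
#' cells. Empty groups are dropped with a warning.
#'
#' @param counts a [MethylBinCounts-class].
#' @param meta cell metadata aligned with the columns of `counts` via
#'   `cell_id`.
#' @param group_by character vector of metadata columns to group by.
#' @return data.frame with the grouping columns, `n_cells`, and one
#'   `<context>_median` column per context.
#' @export
globalLevels <- function(counts, meta, group_by = c("cell_type", "region",
                                                    "disease")) {
  cells <- colnames(counts)
  m <- meta[match(cells, meta$cell_id), , drop = FALSE]
  if (any(is.na(m$cell_id)))
    stop("metadata does not cover all cells in `counts`", call. = FALSE)
  lev <- lapply(methContexts(counts), function(ctx) {
    mc <- SummarizedExperiment::assay(counts, paste0("mc_", ctx))
    cov <- SummarizedExperiment::assay(counts, paste0("cov_", ctx))
    colSums(mc) / pmax(colSums(cov), 1)
  })
  names(lev) <- methContexts(counts)
  key <- interaction(m[, group_by, drop = FALSE], drop = TRUE, sep = "\r")
  out <- unique(m[, group_by, drop = FALSE])
  okey <- interaction(out, drop = TRUE, sep = "\r")
  out$n_cells <- as.integer(table(key)[as.character(okey)])
  for (ctx in names(lev))
    out[[paste0(ctx, "_median")]] <- as.numeric(
      tapply(lev[[ctx]], key, stats::median)[as.character(okey)])
  rownames(out) <- NULL
  out
}

#' Per-cell global methylation levels
#'
#' Convenience accessor: total mc / total cov per context for every cell.
#'
#' @param counts a [MethylBinCounts-class].
#' @return data.frame with `cell_id` and one column per context (`cg`,
#'   `ch`, ... lower-cased).
#' @export
cellGlobalLevels <- function(counts) {
  out <- data.frame(cell_id = colnames(counts))
  for (ctx in methContexts(counts)) {
    mc <- SummarizedExperiment::assay(counts, paste0("mc_", ctx))
    cov <- SummarizedExperiment::assay(counts, paste0("cov_", ctx))
    out[[tolower(ctx)]] <- colSums(mc) / pmax(colSums(cov), 1)
  }
  out
}
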