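#' Geometric distance-bin edges for contact-decay profiles
#'
#' Factor-2 geometric edges from `from` (default 25 kb) to `to` (default
#' half the largest chromosome).
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param from smallest edge (bp).
#' @param factor geometric factor.
#' @param to largest edge; default `max(chrom_lengths) / 2`.
#' @return strictly increasing numeric vector of edges.
#' @export
decayEdges <- function(chrom_lengths, from = 25e3, factor = 2, to = NULL) {
  if (is.null(to)) to <- max(chrom_lengths) / 2
  e <- from * factor^(0:ceiling(log(to / from, factor)))
  unique(c(e[e < to], to))
}

#' Per-cell contact-distance decay profiles
#'
#' Counts each cell's cis contacts into distance bins and normalizes to
#' fractions. Trans contacts and contacts below the smallest edge are
#' excluded. Cells with zero usable cis contacts get an all-zero profile
#' and are flagged in the `"zero_cells"` attribute.
#'
#' @param contacts a [ContactSet-class].
#' @param edges strictly increasing distance-bin edges (bp); bin i is
#'   `[edges[i], edges[i+1])`.
#' @return cells x bins matrix of fractions (rows sum to 1 or 0).
#' @export
decayProfile <- function(contacts, edges = decayEdges(chromLengths(contacts))) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("distance-bin edges must be strictly increasing", call. = FALSE)
  dt <- contactsTable(contacts)
  cells <- unique(dt$cell_id)
  cis <- dt[dt$chrom1 == dt$chrom2, ]
  d <- abs(cis$pos2 - cis$pos1)
  keep <- d >= edges[1] & d < edges[length(edges)]
  cis <- cis[keep, ]; d <- d[keep]
  bin <- findInterval(d, edges)
  nb <- length(edges) - 1
  m <- matrix(0, length(cells), nb,
              dimnames = list(cells, sprintf("d%02d", seq_len(nb))))
  tab <- table(factor(cis$cell_id, levels = cells),
               factor(bin, levels = seq_len(nb)))
  m[] <- as.numeric(tab)
  tot <- rowSums(m)
  zero <- tot == 0
  m[!zero, ] <- m[!zero, , drop = FALSE] / tot[!zero]
  attr(m, "zero_cells") <- cells[zero]
  m
}

#' Gaussian-kernel contact-distance enrichment score
#'
#' A Gaussian kernel over the distance-bin axis, centered at the profile
#' midpoint `c = (N + 1) / 2` (1-based bin index) with standard deviation
#' `sigma = N / 6`, normalized to sum to 1; the score of a cell is the
#' kernel-weighted average of its distance-bin fractions. Higher scores
#' indicate enrichment of mid/short-range contacts for decay-shaped
#' profiles (verified empirically on the synthetic decay classes, not
#' assumed).
#'
#' @param profiles cells x bins matrix from [decayProfile()], or a single
#'   profile vector.
#' @param sigma kernel standard deviation; default `N / 6`.
#' @return list with `weights` (length N, summing to 1) and `score`
#'   (named per cell).
#' @export
contactScore <- function(profiles, sigma = NULL) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, 1,
                                                 length(profiles))
  N <- ncol(profiles)
  if (N < 1) stop("need at least one distance bin", call. = FALSE)
  if (is.null(sigma)) sigma <- N / 6
  ctr <- (N + 1) / 2
  w <- exp(-0.5 * ((seq_len(N) - ctr) / sigma)^2)
  w <- w / sum(w)
  list(weights = w, score = as.numeric(profiles %*% w))
}

#' Classify cells into Short- and Long-range contact classes
#'
#' Optionally z-scores each distance bin across cells, reduces the profile
#' matrix to two principal components, runs k-means (k = 2, 10 restarts,
#' seeded) in PC space, and names the cluster with the higher mean
#' Gaussian-kernel contact score "Short" (cells enriched in long-range
#' contacts are "Long").
#'
#' @param profiles cells x bins fraction matrix.
#' @param standardize z-score bins across cells before PCA (default TRUE).
#' @param seed RNG seed for k-means restarts.
#' @return character vector ("Short"/"Long") named by cell.
#' @export
classifyShortLong <- function(profiles, standardize = TRUE, seed = 1) {
  if (nrow(profiles) < 2) stop("need at least two cells", call. = FALSE)
  sc <- contactScore(profiles)$score
  X <- profiles
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("identical profiles; assigning all cells to one class")
    return(stats::setNames(rep("Short", nrow(profiles)), rownames(profiles)))
  }
  pc <- stats::prcomp(X, center = !standardize, rank. = 2)
  km <- .with_seed(seed, stats::kmeans(pc$x[, seq_len(min(2, ncol(pc$x))),
                                            drop = FALSE],
                                       centers = 2, nstart = 10))
  means <- tapply(sc, km$cluster, mean)
  short <- as.integer(names(means)[which.max(means)])
  stats::setNames(ifelse(km$cluster == short, "Short", "Long"),
                  rownames(profiles))
}

#' Insulation-based boundary calling (pipeline plumbing)
#'
#' A deliberately simple single-matrix boundary caller used so the synthetic
#' pipeline runs end-to-end; it is not a reimplementation of any published
#' TAD caller. The insulation of bin `b` is the mean of the `w x w` diamond
#' upstream-by-downstream of `b`; boundaries are local insulation minima
#' whose depth below the smaller of the flanking maxima (within `w` bins)
#' exceeds `min_depth` times the insulation scale. Edge bins are never
#' boundaries.
#'
#' @param matrix square symmetric contact matrix at boundary resolution.
#' @param window_bins diamond half-width `w` in bins (default 10).
#' @param min_depth minimal relative prominence of a boundary (default 0.1;
#'   a tuning constant of this caller, not a published value).
#' @return integer(0/1) vector, one per bin.
#' @export
callBoundariesInsulation <- function(matrix, window_bins = 10,
                                     min_depth = 0.1) {
  n <- nrow(matrix)
  w <- window_bins
  if (2 * w + 1 > n) stop("window larger than matrix", call. = FALSE)
  ins <- rep(NA_real_, n)
  for (b in (w + 1):(n - w))
    ins[b] <- mean(matrix[(b - w):(b - 1), (b + 1):(b + w)])
  scale <- mean(ins, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  out <- integer(n)
  for (b in (w + 1):(n - w)) {
    lo <- max(w + 1, b - w); hi <- min(n - w, b + w)
    if (ins[b] > min(ins[lo:hi])) next        # not a local minimum
    left <- if (b > lo) max(ins[lo:(b - 1)]) else -Inf
    right <- if (b < hi) max(ins[(b + 1):hi]) else -Inf
    prom <- min(left, right) - ins[b]
    if (is.finite(prom) && prom > min_depth * scale) out[b] <- 1L
  }
  ## keep only one call per contiguous run of flagged bins (plateau ties)
  r <- rle(out)
  pos <- cumsum(r$lengths)
  for (k in which(r$values == 1L & r$lengths > 1)) {
    run <- (pos[k] - r$lengths[k] + 1):pos[k]
    best <- run[which.min(ins[run])]
    out[setdiff(run, best)] <- 0L
  }
  out
}

#' Boundary density in 1-Mb windows per sample
#'
#' A sample is a (region, disease, donor, cell type) group. Each 25-kb bin
#' is assigned to the 1-Mb window containing its genomic start coordinate;
#' the density of a (sample, window) is the number of (cell, bin) boundary
#' events divided by the sample's cell count. Samples with zero cells are
#' dropped.
#'
#' @param calls sparse boundary event table (`cell_id`, `chrom`,
#'   `bin_start`, `value`) as from [simulateBoundaryCalls()].
#' @param meta cell metadata.
#' @param sample_by metadata columns defining a sample.
#' @param window window size in bp (default 1 Mb).
#' @return data.frame: sample columns, `chrom`, `window_start`, `n_cells`,
#'   `density`.
#' @export
boundaryDensity <- function(calls, meta,
                            sample_by = c("region", "disease", "donor",
                                          "cell_type"),
                            window = 1e6) {
  m <- data.table::as.data.table(meta)[, c("cell_id", sample_by),
                                       with = FALSE]
  m$sample <- do.call(paste, c(m[, sample_by, with = FALSE], sep = "/"))
  ncells <- m[, .(n_cells = .N), by = c("sample", sample_by)]
  ev <- data.table::as.data.table(calls)[value == 1]
  ev <- merge(ev, m[, .(cell_id, sample)], by = "cell_id")
  ev$window_start <- floor(ev$bin_start / window) * window
  cnt <- ev[, .(events = .N), by = .(sample, chrom, window_start)]
  out <- merge(cnt, ncells, by = "sample")
  out$density <- out$events / out$n_cells
  data.table::setorder(out, sample, chrom, window_start)
  as.data.frame(out)
}

#' Covariate-adjust boundary densities within each window
#'
#' Per (chrom, window), regresses density on a per-sample covariate —
#' typically the sample's mean cis long-range contact count, a
#' coverage/quality proxy — and returns the OLS residuals as the adjusted
#' density. Windows with fewer than 3 samples fall back to mean-centering
#' with a warning.
#'
#' @param density output of [boundaryDensity()].
#' @param covariate named numeric vector, one value per sample (names =
#'   the `sample` key of `density`).
#' @return `density` with an `adjusted` column.
#' @export
adjustBoundaryDensity <- function(density, covariate) {
  if (!all(density$sample %in% names(covariate)))
    stop("covariate missing for some samples", call. = FALSE)
  x_all <- covariate[density$sample]
  out <- density
  out$adjusted <- NA_real_
  few <- FALSE
  for (key in unique(paste(density$chrom, density$window_start))) {
    idx <- which(paste(density$chrom, density$window_start) == key)
    y <- density$density[idx]; x <- x_all[idx]
    if (length(idx) < 3 || stats::sd(x) == 0) {
      few <- few || length(idx) < 3
      out$adjusted[idx] <- y - mean(y)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      out$adjusted[idx] <- fit$residuals
    }
  }
  if (few) warning("windows with < 3 samples were mean-centered only")
  out
}

#' Mean cis long-range contact count per sample
#'
#' The covariate used by [adjustBoundaryDensity()]: per sample, the mean
#' over cells of the number of cis contacts whose anchors are more than
#' `anchor_gap` apart (the same definition as the QC metric).
#'
#' @param contacts a [ContactSet-class].
#' @param meta cell metadata.
#' @param sample_by metadata columns defining a sample.
#' @param anchor_gap minimal anchor separation (default 2,500 bp).
#' @return named numeric vector keyed by `sample`.
#' @export
meanCisLongPerSample <- function(contacts, meta,
                                 sample_by = c("region", "disease", "donor",
                                               "cell_type"),
                                 anchor_gap = 2500) {
  dt <- contactsTable(contacts)
  cis <- dt[dt$chrom1 == dt$chrom2 & abs(dt$pos2 - dt$pos1) > anchor_gap, ]
  per_cell <- cis[, .(n = .N), by = cell_id]
  m <- data.table::as.data.table(meta)
  m$sample <- do.call(paste, c(m[, sample_by, with = FALSE], sep = "/"))
  m <- merge(m[, .(cell_id, sample)], per_cell, by = "cell_id", all.x = TRUE)
  m$n[is.na(m$n)] <- 0
  v <- m[, .(mean_cis_long = mean(n)), by = sample]
  stats::setNames(v$mean_cis_long, v$sample)
}
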