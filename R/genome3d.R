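#' Merge single-cell contacts into pseudo-bulk matrices
#'
#' Sums binned cis contacts over a group of cells into one symmetric matrix
#' per chromosome. Each contact contributes once to its (i, j) bin pair
#' (mirrored below the diagonal), so the upper triangle including the
#' diagonal conserves the group's total cis contact count per chromosome.
#'
#' @param contacts a [ContactSet-class].
#' @param cells cell ids forming the group (default: all cells).
#' @param resolution bin size in bp (default 100 kb).
#' @return named list of [BinnedContactMatrix-class], one per chromosome.
#' @export
pseudoBulk <- function(contacts, cells = NULL, resolution = 1e5) {
  dt <- contactsTable(contacts)
  if (!is.null(cells)) {
    if (!length(cells)) stop("empty cell group", call. = FALSE)
    dt <- dt[dt$cell_id %in% cells, ]
    if (!nrow(dt)) stop("cell group has no contacts", call. = FALSE)
    n_cells <- length(unique(cells))
  } else n_cells <- length(unique(dt$cell_id))
  cl <- chromLengths(contacts)
  cis <- dt[dt$chrom1 == dt$chrom2, ]
  out <- lapply(names(cl), function(ch) {
    nb <- ceiling(cl[[ch]] / resolution)
    m <- matrix(0, nb, nb)
    cc <- cis[cis$chrom1 == ch, ]
    if (nrow(cc)) {
      i <- pmin(floor((cc$pos1 - 1) / resolution) + 1, nb)
      j <- pmin(floor((cc$pos2 - 1) / resolution) + 1, nb)
      agg <- data.table::data.table(lo = pmin(i, j),
                                    hi = pmax(i, j))[, .N, by = .(lo, hi)]
      m[cbind(agg$lo, agg$hi)] <- agg$N
      m[cbind(agg$hi, agg$lo)] <- m[cbind(agg$lo, agg$hi)]
    }
    BinnedContactMatrix(ch, resolution, m, n_cells = n_cells)
  })
  stats::setNames(out, names(cl))
}

#' Pseudo-bulk matrices for every level of a grouping
#'
#' @param contacts a [ContactSet-class].
#' @param meta cell metadata.
#' @param group_by metadata columns defining the pseudo-bulk key.
#' @param resolution bin size (bp).
#' @return named list (group key, `/`-separated) of per-chromosome
#'   [BinnedContactMatrix-class] lists.
#' @export
pseudoBulkGroups <- function(contacts, meta, group_by, resolution = 1e5) {
  key <- do.call(paste, c(meta[, group_by, drop = FALSE], sep = "/"))
  out <- lapply(split(meta$cell_id, key), function(cells)
    pseudoBulk(contacts, cells, resolution))
  out[order(names(out))]
}

#' ICE balancing by iterative correction
#'
#' Iteratively equalizes row/column sums of a symmetric nonnegative contact
#' matrix using square-root-damped correction steps. Rows without support —
#' all-zero rows, and (iteratively) rows with fewer than `min_nnz` nonzero
#' entries, whose bias is not identifiable — are masked (weight `NA`) and
#' excluded, as contact-matrix balancers routinely do for low-coverage
#' bins. Iteration stops when the maximal relative change of the bias
#' vector drops below `tol` (default 1e-5) or after `max_iter` (default
#' 200) iterations, in which case a warning is issued and the last iterate
#' returned. The balanced matrix satisfies `balanced = raw / (w_i * w_j)`
#' for the returned weights.
#'
#' @param x a [BinnedContactMatrix-class] or plain symmetric matrix.
#' @param tol convergence tolerance on the bias vector.
#' @param max_iter maximal iterations.
#' @param min_nnz minimal nonzero entries per unmasked row (default 2).
#' @return same type as `x`, balanced, with weights set (for a plain
#'   matrix: a list `(matrix, weights)`).
#' @export
balanceICE <- function(x, tol = 1e-5, max_iter = 200, min_nnz = 2) {
  m <- if (is(x, "BinnedContactMatrix")) contactMatrix(x) else x
  n <- nrow(m)
  mask <- rowSums(m) == 0
  repeat {
    W <- m; W[mask, ] <- 0; W[, mask] <- 0
    new_mask <- mask | rowSums(W > 0) < min_nnz
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  W <- m; W[mask, ] <- 0; W[, mask] <- 0
  b <- rep(1, n)
  converged <- all(mask)
  if (!converged) for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    s_rel <- sqrt(s / mean(s[!mask]))   # damped step: robust to
    s_rel[mask] <- 1                    # near-bipartite support
    W <- W / outer(s_rel, s_rel)
    b <- b * s_rel
    if (max(abs(s_rel[!mask]^2 - 1)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICE balancing did not converge within ", max_iter,
            " iterations; returning last iterate")
  w <- b
  w[mask] <- NA_real_
  if (is(x, "BinnedContactMatrix")) {
    BinnedContactMatrix(x@chrom, x@resolution, W, weights = w,
                        n_cells = x@n_cells)
  } else list(matrix = W, weights = w)
}

#' Distance-decay expected matrix from diagonal-band means
#'
#' Replaces every entry of diagonal band `d = |i - j|` by that band's mean.
#'
#' @param m square matrix.
#' @return matrix of the same shape, constant within each band.
#' @export
expectedByBand <- function(m) {
  d <- abs(row(m) - col(m))
  means <- tapply(as.numeric(m), d, mean)
  matrix(means[as.character(d)], nrow(m), ncol(m))
}

#' Observed-over-expected matrix
#'
#' @param m square observed matrix.
#' @param fill value where the expected is 0 (default `NA`).
#' @return O/E matrix.
#' @export
oeMatrix <- function(m, fill = NA_real_) {
  e <- expectedByBand(m)
  out <- m / e
  out[e == 0] <- fill
  out
}

#' Compartment eigenvector (PC1) with GC sign correction
#'
#' Computes the O/E matrix of a balanced contact matrix (band-mean
#' expected), the Pearson correlation matrix of its columns over unmasked
#' bins, and the leading eigenvector; the sign is flipped if the
#' correlation of the eigenvector with per-bin GC content is negative, so
#' that A compartments (GC-rich) carry positive PC1.
#'
#' @param x balanced [BinnedContactMatrix-class] (weights set), or a plain
#'   balanced matrix.
#' @param gc per-bin GC fraction (length = bins).
#' @return data.frame with `bin` (1-based), `pc1` (NA for masked bins) and
#'   `gc`.
#' @export
compartmentPc1 <- function(x, gc) {
  m <- if (is(x, "BinnedContactMatrix")) contactMatrix(x) else x
  w <- if (is(x, "BinnedContactMatrix") && length(x@weights)) x@weights
       else rep(1, nrow(m))
  stopifnot(length(gc) == nrow(m))
  unmask <- !is.na(w) & rowSums(m) > 0
  if (sum(unmask) < 4) stop("fewer than 4 unmasked bins", call. = FALSE)
  sub <- m[unmask, unmask, drop = FALSE]
  oe <- oeMatrix(sub, fill = 0)
  C <- suppressWarnings(stats::cor(oe))
  C[!is.finite(C)] <- 0
  eig <- eigen(C, symmetric = TRUE)
  v <- eig$vectors[, 1]
  r <- suppressWarnings(stats::cor(v, gc[unmask]))
  if (is.finite(r) && r < 0) v <- -v
  pc1 <- rep(NA_real_, nrow(m))
  pc1[unmask] <- v
  data.frame(bin = seq_len(nrow(m)), pc1 = pc1, gc = gc)
}

#' Saddle matrix: mean O/E by PC1 quantile pair
#'
#' Bins with defined PC1 are ranked into `n_quantiles` groups (ties broken
#' by bin order); entry (q1, q2) is the mean cis O/E over all bin pairs in
#' those groups, pooled across the supplied chromosomes.
#'
#' @param matrices balanced [BinnedContactMatrix-class] (or plain matrix),
#'   or a list of them (one per chromosome).
#' @param pc1s matching PC1 data.frame from [compartmentPc1()], or list.
#' @param n_quantiles number of PC1 quantile groups (default 10).
#' @return `n_quantiles` x `n_quantiles` symmetric matrix (NA where a
#'   quantile pair has no data).
#' @export
saddle <- function(matrices, pc1s, n_quantiles = 10) {
  if (!is.list(matrices) || is(matrices, "BinnedContactMatrix"))
    matrices <- list(matrices)
  if (is.data.frame(pc1s)) pc1s <- list(pc1s)
  stopifnot(length(matrices) == length(pc1s))
  acc <- matrix(0, n_quantiles, n_quantiles)
  cnt <- matrix(0, n_quantiles, n_quantiles)
  for (k in seq_along(matrices)) {
    x <- matrices[[k]]
    m <- if (is(x, "BinnedContactMatrix")) contactMatrix(x) else x
    pc1 <- pc1s[[k]]$pc1
    def <- which(!is.na(pc1))
    if (length(def) < n_quantiles)
      stop("PC1 defined on fewer bins than quantiles", call. = FALSE)
    oe <- oeMatrix(m[def, def, drop = FALSE])
    rk <- rank(pc1[def], ties.method = "first")
    g <- ceiling(rk * n_quantiles / length(def))
    for (q1 in seq_len(n_quantiles)) for (q2 in seq_len(n_quantiles)) {
      block <- oe[g == q1, g == q2, drop = FALSE]
      ok <- is.finite(block)
      acc[q1, q2] <- acc[q1, q2] + sum(block[ok])
      cnt[q1, q2] <- cnt[q1, q2] + sum(ok)
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Ratio of two saddle matrices (state comparison)
#'
#' Elementwise `stressed / homeostatic`; zero denominators give `NA`.
#'
#' @param stressed,homeostatic saddle matrices of identical shape.
#' @return ratio matrix.
#' @export
saddleStateRatio <- function(stressed, homeostatic) {
  if (!identical(dim(stressed), dim(homeostatic)))
    stop("saddle matrices differ in shape", call. = FALSE)
  out <- stressed / homeostatic
  out[!is.na(homeostatic) & homeostatic == 0] <- NA_real_
  out
}

## Bilinear resize of a matrix to (nr, nc), mapping corners to corners with
## clamped edges. Degenerate 1-row/1-column sources are replicated.
.bilinear_resize <- function(A, nr, nc) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0 || n == 0) return(matrix(0, nr, nc))
  if (m == 1) A <- rbind(A, A)
  if (n == 1) A <- cbind(A, A)
  m <- nrow(A); n <- ncol(A)
  yp <- if (nr == 1) (m + 1) / 2 else 1 + (seq_len(nr) - 1) * (m - 1) / (nr - 1)
  xp <- if (nc == 1) (n + 1) / 2 else 1 + (seq_len(nc) - 1) * (n - 1) / (nc - 1)
  yp <- pmin(pmax(yp, 1), m); xp <- pmin(pmax(xp, 1), n)
  grid_x <- rep(xp, each = nr)
  grid_y <- rep(yp, times = nc)
  v <- pracma::interp2(x = seq_len(n), y = seq_len(m), Z = A,
                       xp = grid_x, yp = grid_y, method = "linear")
  matrix(v, nr, nc)
}

#' Centromere-aligned average O/E contact map
#'
#' For each eligible autosome (centromere known, at least `min_chrom_bins`
#' bins, not chrX/chrY): replace NaN by 0 in the observed matrix, split at
#' the centromere bin into p-p, p-q, q-p and q-q blocks, bilinearly resize
#' each block to a fixed shape (`p_bins` and `q_bins` per arm), build the
#' band-mean expected matrix and resize it the same way, divide to get the
#' per-chromosome O/E (0 where expected is 0), and average over
#' chromosomes. Any remaining NaN/Inf is set to 0. The result summarizes
#' arm-scaled contact patterns on a shape independent of chromosome
#' lengths.
#'
#' @param matrices named list (chromosome -> [BinnedContactMatrix-class] or
#'   plain matrix).
#' @param centromeres named centromere positions (bp).
#' @param resolution bin size in bp (needed when plain matrices are given).
#' @param p_bins,q_bins fixed arm shapes (default 50 each).
#' @param min_chrom_bins minimal chromosome size in bins (default 50).
#' @return `(p_bins + q_bins)` square averaged O/E matrix, with the
#'   per-chromosome count in attribute `"n_chroms"`.
#' @export
centromereAlignedAverage <- function(matrices, centromeres,
                                     resolution = NULL, p_bins = 50,
                                     q_bins = 50, min_chrom_bins = 50) {
  tot <- matrix(0, p_bins + q_bins, p_bins + q_bins)
  n_used <- 0L
  for (ch in names(matrices)) {
    if (ch %in% c("chrX", "chrY", "chrM")) next
    if (!ch %in% names(centromeres)) next
    x <- matrices[[ch]]
    m <- if (is(x, "BinnedContactMatrix")) contactMatrix(x) else x
    res <- if (is(x, "BinnedContactMatrix")) x@resolution else resolution
    if (is.null(res)) stop("resolution required for plain matrices",
                           call. = FALSE)
    nb <- nrow(m)
    if (nb < min_chrom_bins) next
    m[!is.finite(m)] <- 0
    ## centromere bin by binary search on bin starts
    cb <- findInterval(centromeres[[ch]], (seq_len(nb) - 1) * res)
    cb <- max(1L, min(nb - 1L, cb))
    e <- expectedByBand(m)
    blocks <- function(M) list(pp = M[1:cb, 1:cb, drop = FALSE],
                               pq = M[1:cb, (cb + 1):nb, drop = FALSE],
                               qp = M[(cb + 1):nb, 1:cb, drop = FALSE],
                               qq = M[(cb + 1):nb, (cb + 1):nb, drop = FALSE])
    rs <- function(bl) rbind(
      cbind(.bilinear_resize(bl$pp, p_bins, p_bins),
            .bilinear_resize(bl$pq, p_bins, q_bins)),
      cbind(.bilinear_resize(bl$qp, q_bins, p_bins),
            .bilinear_resize(bl$qq, q_bins, q_bins)))
    robs <- rs(blocks(m))
    rexp <- rs(blocks(e))
    oe <- robs / rexp
    oe[rexp == 0 | !is.finite(oe)] <- 0
    tot <- tot + oe
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no eligible chromosomes", call. = FALSE)
  out <- tot / n_used
  out[!is.finite(out)] <- 0
  attr(out, "n_chroms") <- n_used
  out
}

#' Detect bins with widespread contact loss (putative deletions)
#'
#' For every 100-kb bin and every pseudo-bulk, computes the row sum of the
#' observed balanced matrix; zeros (and ICE-masked rows) are recoded to
#' missing. Bins missing in at least `min_missing` pseudo-bulks are
#' selected; bins missing in every pseudo-bulk are then removed (no data
#' anywhere). Each call is annotated with its distance to the nearest
#' telomere, `min(bin_start, chrom_length - bin_end)`.
#'
#' @param pseudo_bulks named list: pseudo-bulk key -> named list
#'   (chromosome -> balanced [BinnedContactMatrix-class]).
#' @param min_missing minimal number of missing pseudo-bulks per call
#'   (default 10, as used against 12+ pseudo-bulk columns).
#' @param chrom_lengths optional named lengths (bp); defaults to
#'   `bins * resolution` per chromosome.
#' @return data.frame of calls: `chrom`, `bin_index` (0-based), `start`,
#'   `end`, `n_missing`, `telomere_distance`; the bins-by-pseudo-bulks
#'   row-sum matrix of called bins is attached as attribute `"row_sums"`.
#' @export
detectPutativeDeletions <- function(pseudo_bulks, min_missing = 10,
                                    chrom_lengths = NULL) {
  npb <- length(pseudo_bulks)
  empty <- data.frame(chrom = character(), bin_index = integer(),
                      start = numeric(), end = numeric(),
                      n_missing = integer(), telomere_distance = numeric())
  if (npb < min_missing) {
    warning("fewer pseudo-bulks (", npb, ") than min_missing (",
            min_missing, "); no calls possible")
    return(empty)
  }
  chroms <- names(pseudo_bulks[[1]])
  calls <- list(); rs_keep <- list()
  for (ch in chroms) {
    rows <- sapply(pseudo_bulks, function(pb) {
      x <- pb[[ch]]
      m <- contactMatrix(x)
      rs <- rowSums(m)
      if (length(x@weights)) rs[is.na(x@weights)] <- NA_real_
      rs[rs == 0] <- NA_real_
      rs
    })
    nmiss <- rowSums(is.na(rows))
    sel <- which(nmiss >= min_missing & nmiss < npb)
    if (!length(sel)) next
    x1 <- pseudo_bulks[[1]][[ch]]
    res <- x1@resolution
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      nrow(contactMatrix(x1)) * res
    start <- (sel - 1) * res
    end <- pmin(start + res, L)
    calls[[ch]] <- data.frame(
      chrom = ch, bin_index = sel - 1L, start = start, end = end,
      n_missing = nmiss[sel],
      telomere_distance = pmin(start, L - end))
    rs_keep[[ch]] <- rows[sel, , drop = FALSE]
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  attr(out, "row_sums") <- do.call(rbind, rs_keep)
  out
}

#' Per-state deletion counts from a deletion-call table
#'
#' Given the calls of [detectPutativeDeletions()] (run over all state
#' pseudo-bulks) and a mapping from pseudo-bulk column to state, counts for
#' each state the called bins that are missing in at least `min_missing` of
#' that state's columns — the per-state tally of putative deletions.
#'
#' @param calls output of [detectPutativeDeletions()] (with its
#'   `"row_sums"` attribute).
#' @param states named character vector mapping pseudo-bulk key -> state.
#' @param min_missing per-state missing threshold (default: half the
#'   state's columns, capped at 10).
#' @return named integer vector of per-state call counts.
#' @export
deletionStateCounts <- function(calls, states, min_missing = NULL) {
  rs <- attr(calls, "row_sums")
  if (is.null(rs) || !nrow(calls))
    return(stats::setNames(integer(length(unique(states))),
                           unique(states)))
  out <- integer(0)
  for (st in unique(states)) {
    cols <- names(states)[states == st]
    mm <- if (is.null(min_missing)) min(10, ceiling(length(cols) / 2))
          else min_missing
    nmiss <- rowSums(is.na(rs[, cols, drop = FALSE]))
    out[st] <- sum(nmiss >= mm)
  }
  out
}

#' Synthetic GC track aligned with the planted compartment checkerboard
#'
#' A synthetic per-bin GC fraction for the simulated genome: A blocks (even
#' 2-Mb compartment blocks) are GC-rich, B blocks GC-poor. Used to exercise
#' the GC sign correction of [compartmentPc1()]; it is not a real GC
#' annotation.
#'
#' @param config a [SimConfig-class].
#' @param chrom chromosome name.
#' @param resolution bin size (default the contact bin size).
#' @return numeric GC fraction per bin.
#' @export
syntheticGCTrack <- function(config, chrom,
                             resolution = config@params$bin_size_contact) {
  p <- config@params
  L <- p$chrom_lengths[[chrom]]
  nb <- ceiling(L / resolution)
  start <- (seq_len(nb) - 1) * resolution
  block <- floor(start / p$comp_block)
  0.40 + 0.08 * (block %% 2 == 0)
}
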