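#' Accumulate per-sample contact matrices into a group accumulator
#'
#' Per-sample inputs are the mean contact matrix over the sample's cells,
#' the matrix of squared means (elementwise mean of squares), and the cell
#' count; each is multiplied by the number of contributing cells and
#' summed, yielding the group's cumulative sum (`sum_x`), cumulative sum of
#' squares (`sum_x2`) and total cell count `n`. Accumulators are additive:
#' combining two partitions of the samples equals accumulating all samples.
#'
#' @param per_sample list of lists, each with `mean` (matrix), `sqmean`
#'   (matrix of per-cell squared values averaged), and `n_cells`.
#' @param label optional group label.
#' @return list of class `GroupContactAccumulator`: `sum_x`, `sum_x2`, `n`,
#'   `label`.
#' @export
accumulateGroup <- function(per_sample, label = NA_character_) {
  stopifnot(length(per_sample) >= 1)
  dims <- dim(per_sample[[1]]$mean)
  sx <- matrix(0, dims[1], dims[2]); sx2 <- matrix(0, dims[1], dims[2])
  n <- 0
  for (s in per_sample) {
    if (!identical(dim(s$mean), dims) || !identical(dim(s$sqmean), dims))
      stop("per-sample matrices differ in shape", call. = FALSE)
    if (s$n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
    sx <- sx + s$n_cells * s$mean
    sx2 <- sx2 + s$n_cells * s$sqmean
    n <- n + s$n_cells
  }
  if (any(sx2 < -1e-12)) stop("sum of squares must be nonnegative",
                              call. = FALSE)
  structure(list(sum_x = sx, sum_x2 = sx2, n = n, label = label),
            class = "GroupContactAccumulator")
}

#' Build a group accumulator directly from per-cell pixel values
#'
#' Convenience constructor treating every cell as a one-cell sample.
#'
#' @param values cells x pixels matrix, or a list of per-cell matrices.
#' @param label group label.
#' @return `GroupContactAccumulator` over pixel matrices of shape
#'   1 x pixels (vector pixels) or the per-cell matrix shape.
#' @export
accumulateCells <- function(values, label = NA_character_) {
  if (is.matrix(values)) {
    per <- lapply(seq_len(nrow(values)), function(i)
      list(mean = matrix(values[i, ], 1), sqmean = matrix(values[i, ]^2, 1),
           n_cells = 1))
  } else {
    per <- lapply(values, function(v)
      list(mean = v, sqmean = v^2, n_cells = 1))
  }
  accumulateGroup(per, label)
}

#' Per-pixel one-way F statistic between groups
#'
#' From the groups' cumulative sums and sums of squares, computes per pixel
#' the within-group sum of squares `SSW = sum_g (sum_x2_g - sum_x_g^2 /
#' n_g)`, the total `SST` from the pooled accumulator, the between-group
#' `SSB = SST - SSW`, and the one-way ANOVA statistic
#' `F = (SSB / (g - 1)) / (SSW / (N - g))`. Pixels with `SSW = 0` but
#' `SSB > 0` get an `Inf` sentinel (ranked above all finite F); pixels with
#' `SST = 0` get `F = 0` by convention.
#'
#' @param groups list of >= 2 `GroupContactAccumulator`s of equal shape.
#' @return list with matrices `F`, `ssb`, `ssw`, group count `g`, total `N`,
#'   and `df = c(g - 1, N - g)`.
#' @export
pixelFStatistic <- function(groups) {
  stopifnot(length(groups) >= 2)
  dims <- dim(groups[[1]]$sum_x)
  for (gr in groups) {
    if (!identical(dim(gr$sum_x), dims))
      stop("group accumulators differ in shape", call. = FALSE)
    if (gr$n < 1) stop("every group needs at least one cell", call. = FALSE)
  }
  g <- length(groups)
  N <- sum(vapply(groups, `[[`, numeric(1), "n"))
  if (N <= g) stop("total cells must exceed the number of groups",
                   call. = FALSE)
  ssw <- matrix(0, dims[1], dims[2])
  sx_tot <- matrix(0, dims[1], dims[2]); sx2_tot <- matrix(0, dims[1], dims[2])
  for (gr in groups) {
    ssw <- ssw + (gr$sum_x2 - gr$sum_x^2 / gr$n)
    sx_tot <- sx_tot + gr$sum_x
    sx2_tot <- sx2_tot + gr$sum_x2
  }
  sst <- sx2_tot - sx_tot^2 / N
  ssb <- sst - ssw
  ## numerical floors: tiny negative SS from cancellation are zero
  tolm <- 1e-10 * pmax(sx2_tot, 1)
  ssw[ssw < 0] <- 0
  ssb[ssb < 0] <- 0
  Fm <- (ssb / (g - 1)) / (ssw / (N - g))
  Fm[ssw <= 0 & ssb > 0] <- Inf
  Fm[sst <= tolm] <- 0
  list(F = Fm, ssb = ssb, ssw = ssw, g = g, N = N, df = c(g - 1, N - g))
}

#' Mask pixels by blacklist proximity, distance range and triangle
#'
#' Excludes pixels with either anchor within `pad` bins of a blacklisted
#' bin, pixels outside the genomic distance range `[dmin, dmax]` bins, and
#' lower-triangle/diagonal pixels (`i >= j`). Masking is idempotent and
#' order-independent.
#'
#' @param n_bins matrix dimension (pixels are (i, j) bin pairs).
#' @param blacklist_bins integer vector of blacklisted bin indices
#'   (1-based; may be empty).
#' @param pad blacklist padding in bins (default 7).
#' @param dmin,dmax distance range in bins (defaults 5 and 500,
#'   inclusive).
#' @return list with logical `keep` matrix and character `reason` matrix
#'   (`"none"`, `"blacklist"`, `"distance"`, `"lower_triangle"`; the first
#'   applicable reason in that order is recorded).
#' @export
maskPixels <- function(n_bins, blacklist_bins = integer(0), pad = 7,
                       dmin = 5, dmax = 500) {
  i <- row(matrix(0, n_bins, n_bins)); j <- col(matrix(0, n_bins, n_bins))
  reason <- matrix("none", n_bins, n_bins)
  near_bl <- rep(FALSE, n_bins)
  if (length(blacklist_bins)) {
    for (b in blacklist_bins)
      near_bl[max(1, b - pad):min(n_bins, b + pad)] <- TRUE
  }
  bl <- near_bl[i] | near_bl[j]
  d <- j - i
  reason[i >= j] <- "lower_triangle"
  reason[reason == "none" & (abs(d) < dmin | abs(d) > dmax)] <- "distance"
  reason[reason == "none" & bl] <- "blacklist"
  list(keep = reason == "none", reason = reason)
}

#' Extract candidate differential pixels above an F cutoff
#'
#' @param fstat output of [pixelFStatistic()].
#' @param mask output of [maskPixels()] for the same matrix shape.
#' @param f_min minimal F value (default: 95th percentile of the F
#'   distribution with the statistic's degrees of freedom). `Inf` pixels
#'   rank above all finite ones.
#' @return data.frame (`bin1`, `bin2`, `F`), sorted by decreasing F.
#' @export
candidatePixels <- function(fstat, mask, f_min = NULL) {
  if (is.null(f_min))
    f_min <- stats::qf(0.95, fstat$df[1], fstat$df[2])
  Fm <- fstat$F
  sel <- which(mask$keep & Fm > f_min, arr.ind = TRUE)
  out <- data.frame(bin1 = sel[, 1], bin2 = sel[, 2],
                    F = Fm[sel])
  out[order(-out$F), , drop = FALSE]
}

#' Covariate regression on candidate loop pixels
#'
#' For each candidate pixel, regresses the per-sample contact strength on
#' disease, age and sex (and any further covariates in the supplied design)
#' via [fitFeatureModel()], reporting the disease term alongside the rest.
#' Samples with non-finite values (e.g. from `Inf` sentinel pixels) are
#' dropped per pixel.
#'
#' @param per_sample_values pixels x samples matrix (rownames identify the
#'   pixel, e.g. `"chr1:12_45"`).
#' @param meta per-sample covariates.
#' @param spec a [designSpec()]; default `~ disease + age + sex` with
#'   Control/Female references.
#' @param min_donors minimum unique donors (default 5).
#' @return a [fitFeatureModel()] association table.
#' @export
loopCovariateRegression <- function(per_sample_values, meta,
                                    spec = designSpec(
                                      ~ disease + age + sex,
                                      ref = c(disease = "Control",
                                              sex = "Female")),
                                    min_donors = 5) {
  v <- as.matrix(per_sample_values)
  v[!is.finite(v)] <- NA_real_
  fitFeatureModel(v, meta, spec, min_donors = min_donors)
}
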