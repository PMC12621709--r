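#' Normalize global methylation levels across sequencing instruments
#'
#' Libraries sequenced on both instruments exhibit a strong linear
#' relationship in global CG/CH levels; this fits, per context, an OLS line
#' mapping instrument-B levels onto the instrument-A scale and applies it to
#' every instrument-B cell. Instrument-A cells are unchanged. With fewer
#' than two shared measurements, or a degenerate (zero-variance) fit, the
#' identity map is used with a warning.
#'
#' @param levels data.frame of per-cell global levels (`cell_id`, `cg`,
#'   `ch`) as from [cellGlobalLevels()].
#' @param meta cell metadata with `cell_id` and `instrument` ("A"/"B").
#' @param shared_libraries data.frame (`context`, `level_a`, `level_b`) of
#'   paired measurements of the same libraries on both instruments.
#' @return `levels` with instrument-B values mapped to the A scale; the
#'   fitted `(intercept, slope)` per context is attached as attribute
#'   `"fits"`.
#' @export
normalizeInstruments <- function(levels, meta, shared_libraries) {
  m <- meta[match(levels$cell_id, meta$cell_id), ]
  is_b <- m$instrument == "B"
  out <- levels
  fits <- list()
  for (ctx in intersect(c("cg", "ch"), names(levels))) {
    sh <- shared_libraries[tolower(shared_libraries$context) == ctx, ]
    if (nrow(sh) < 2 || stats::sd(sh$level_b) == 0) {
      warning("instrument normalization for context '", ctx,
              "' degenerate; using identity map")
      fits[[ctx]] <- c(intercept = 0, slope = 1)
      next
    }
    fit <- stats::lm.fit(cbind(1, sh$level_b), sh$level_a)
    fits[[ctx]] <- c(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2]))
    out[[ctx]][is_b] <- fits[[ctx]][1] + fits[[ctx]][2] * levels[[ctx]][is_b]
  }
  attr(out, "fits") <- fits
  out
}

#' Partition cells into three global-methylation subgroups
#'
#' Runs k-means (k = 3, 10 restarts, seeded) on the normalized (CG, CH)
#' global levels separately within each stratum (neuronal / non-neuronal),
#' then relabels clusters to the semantic subgroups by centroid rank: the
#' lowest-CG centroid is subgroup 0 (low CG / low CH); of the remaining two,
#' the lower-CH centroid is subgroup 1 (high CG / low CH) and the higher-CH
#' centroid is subgroup 2 (high CG / high CH).
#'
#' @param levels data.frame with `cell_id`, `cg`, `ch`.
#' @param strata character/factor per cell (e.g. "neuron"/"non-neuron").
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `stratum`, `cg`, `ch`, `subgroup`
#'   (0/1/2; NA for skipped strata).
#' @export
kmeansSubgroups <- function(levels, strata, k = 3, seed = 1) {
  stopifnot(length(strata) == nrow(levels))
  out <- data.frame(cell_id = levels$cell_id, stratum = as.character(strata),
                    cg = levels$cg, ch = levels$ch,
                    subgroup = NA_integer_)
  for (s in unique(out$stratum)) {
    idx <- which(out$stratum == s)
    if (length(idx) < k) {
      warning("stratum '", s, "' has fewer than k cells; skipped")
      next
    }
    km <- .with_seed(seed, stats::kmeans(cbind(out$cg[idx], out$ch[idx]),
                                         centers = k, nstart = 10))
    cen <- km$centers
    relab <- integer(k)
    low_cg <- order(cen[, 1], cen[, 2])[1]
    relab[low_cg] <- 0L
    rest <- setdiff(seq_len(k), low_cg)
    rest <- rest[order(cen[rest, 2], cen[rest, 1])]
    relab[rest] <- seq_along(rest)   # lower CH -> 1, higher CH -> 2
    out$subgroup[idx] <- relab[km$cluster]
  }
  out
}

#' Associate subgroup proportions with disease
#'
#' Computes, per (donor, region, cell type), the proportion of cells in each
#' subgroup, treats each (cell type, subgroup) as a feature, and fits the
#' standard association model `ratio ~ diagnosis x region + age + sex`
#' via [fitFeatureModel()] (minimum 5 donors per feature).
#'
#' @param assignments output of [kmeansSubgroups()].
#' @param meta cell metadata (`cell_id`, `donor`, `region`, `disease`,
#'   `sex`, `age`, `cell_type`).
#' @param spec a [designSpec()].
#' @param min_donors minimum unique donors per feature.
#' @return a [fitFeatureModel()] table with features named
#'   `<cell_type>|subgroup<g>`.
#' @export
subgroupRatioAssociation <- function(assignments, meta, spec = designSpec(),
                                     min_donors = 5) {
  m <- meta[match(assignments$cell_id, meta$cell_id), ]
  dt <- data.table::data.table(
    donor = m$donor, region = m$region, cell_type = m$cell_type,
    subgroup = assignments$subgroup)
  dt <- dt[!is.na(subgroup)]
  tot <- dt[, .(total = .N), by = .(donor, region, cell_type)]
  cnt <- dt[, .(n = .N), by = .(donor, region, cell_type, subgroup)]
  grid <- data.table::CJ(sample = seq_len(nrow(tot)),
                         subgroup = sort(unique(dt$subgroup)))
  full <- cbind(tot[grid$sample], subgroup = grid$subgroup)
  full <- merge(full, cnt, by = c("donor", "region", "cell_type", "subgroup"),
                all.x = TRUE)
  full$n[is.na(full$n)] <- 0L
  full$ratio <- full$n / full$total
  full$feature <- sprintf("%s|subgroup%d", full$cell_type, full$subgroup)
  samp <- unique(full[, .(donor, region)])
  samp <- merge(samp, unique(data.table::as.data.table(
    meta)[, .(donor, region, disease, sex, age)]), by = c("donor", "region"))
  wide <- data.table::dcast(full, feature ~ donor + region,
                            value.var = "ratio")
  keys <- paste(samp$donor, samp$region, sep = "_")
  values <- as.matrix(wide[, -1])[, keys, drop = FALSE]
  rownames(values) <- wide$feature
  fitFeatureModel(values, as.data.frame(samp), spec, min_donors = min_donors)
}

#' Map stress/homeostasis module scores to a state label
#'
#' Each score is categorized as positive (>= `pos`), negative (<= `neg`) or
#' neutral; double-positive cells are "DP", double-negative "DN", and every
#' other combination is labelled over the 3x3 grid as
#' `S<cat>_H<cat>` (e.g. `Sneg_Hpos`, `Sneu_Hneu`).
#'
#' @param stressed_score,homeostatic_score numeric vectors of module scores.
#' @param pos,neg positive / negative cutoffs (defaults +2.5 / -2.5).
#' @return character vector of labels.
#' @export
scoreStateLabels <- function(stressed_score, homeostatic_score,
                             pos = 2.5, neg = -2.5) {
  stopifnot(length(stressed_score) == length(homeostatic_score),
            all(is.finite(stressed_score)), all(is.finite(homeostatic_score)))
  cat3 <- function(x) ifelse(x >= pos, "pos", ifelse(x <= neg, "neg", "neu"))
  s <- cat3(stressed_score); h <- cat3(homeostatic_score)
  ifelse(s == "pos" & h == "pos", "DP",
    ifelse(s == "neg" & h == "neg", "DN",
           paste0("S", s, "_H", h)))
}

#' Cluster subtypes by their pairwise log2 fold-change profiles
#'
#' Implements the subtype-similarity tensor procedure that separates the
#' Homeostatic and Stressed clusters: (1) for each gene build a directed
#' adjacency matrix over subtypes, `A[i,j] = log2FC(i vs j)`,
#' antisymmetrized when only one direction is present, diagonal 0, missing
#' entries 0; (2) stack to a (subtype x subtype x gene) tensor, flatten to
#' (S*S) x genes and apply PCA (gene columns mean-centered, components
#' capped at the matrix rank); (3) embed each subtype as the mean of its
#' row of PCA-transformed contrasts; (4) cosine similarity K and distance
#' D = 1 - K; (5) average-linkage hierarchical clustering cut at
#' `n_clusters`.
#'
#' @param log2fc data.frame with a `gene` column and
#'   `celltype:SubtypeA_vs_SubtypeB` columns (or a matrix with such column
#'   names).
#' @param n_components PCA components (default 50, capped at rank).
#' @param n_clusters clusters to cut (default 2).
#' @param seed unused by the deterministic pipeline, kept for interface
#'   stability.
#' @return list with `subtypes`, `embedding` (subtypes x components),
#'   `similarity` (K), `distance` (D), `cluster` (integer labels) and
#'   `hclust`.
#' @export
subtypeSimilarityCluster <- function(log2fc, n_components = 50,
                                     n_clusters = 2, seed = 1) {
  df <- as.data.frame(log2fc)
  if ("gene" %in% names(df)) df$gene <- NULL
  cmp <- parseComparison(names(df))
  subtypes <- sort(unique(c(paste0(cmp$celltype, ":", cmp$a),
                            paste0(cmp$celltype, ":", cmp$b))))
  S <- length(subtypes)
  if (S < 2) stop("need at least two subtypes", call. = FALSE)
  ## warn on cell types with too few comparisons to connect their subtypes
  for (cc in unique(cmp$celltype)) {
    ns <- length(unique(c(cmp$a[cmp$celltype == cc], cmp$b[cmp$celltype == cc])))
    if (sum(cmp$celltype == cc) < ns - 1)
      warning("cell type '", cc, "' has fewer comparisons than subtypes - 1")
  }
  G <- nrow(df)
  flat <- matrix(0, S * S, G)   # row-major over (i, j) pairs
  pos <- function(i, j) (i - 1L) * S + j
  for (k in seq_len(ncol(df))) {
    i <- match(paste0(cmp$celltype[k], ":", cmp$a[k]), subtypes)
    j <- match(paste0(cmp$celltype[k], ":", cmp$b[k]), subtypes)
    v <- df[[k]]
    flat[pos(i, j), ] <- v
    rev_name <- sprintf("%s:%s_vs_%s", cmp$celltype[k], cmp$b[k], cmp$a[k])
    if (!rev_name %in% names(df)) flat[pos(j, i), ] <- -v
  }
  ncomp <- min(n_components, S * S - 1, G)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE, rank. = ncomp)
  scores <- pc$x          # (S*S) x ncomp
  emb <- matrix(0, S, ncol(scores), dimnames = list(subtypes, NULL))
  for (i in seq_len(S))
    emb[i, ] <- colMeans(scores[pos(i, seq_len(S)), , drop = FALSE])
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  K <- (emb / nrm) %*% t(emb / nrm)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  D <- 1 - K
  D[D < 0] <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = min(n_clusters, S))
  list(subtypes = subtypes, embedding = emb, similarity = K, distance = D,
       cluster = cl, hclust = hc)
}

#' Attach state names to subtype clusters from marker scores
#'
#' The tensor clustering returns neutral cluster ids; which cluster is
#' "Stressed" is decided by marker evidence supplied by the caller (the
#' study used GO enrichment of cluster-specific genes). The cluster with
#' the higher mean marker score is named `high_label`.
#'
#' @param clustering output of [subtypeSimilarityCluster()].
#' @param marker_scores named numeric vector (per subtype) of stress-marker
#'   evidence.
#' @param high_label,low_label names for the high/low scoring cluster.
#' @return named character vector mapping subtype -> state label.
#' @export
labelStateClusters <- function(clustering, marker_scores,
                               high_label = "Stressed",
                               low_label = "Homeostatic") {
  cl <- clustering$cluster
  ms <- marker_scores[clustering$subtypes]
  means <- tapply(ms, cl, mean)
  hi <- as.integer(names(means)[which.max(means)])
  lab <- ifelse(cl == hi, high_label, low_label)
  stats::setNames(lab, clustering$subtypes)
}
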