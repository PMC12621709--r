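#' Build a synthetic cohort configuration
#'
#' Returns a validated [SimConfig-class]. Defaults mirror the study design
#' the package targets: 11 Alzheimer's-disease and 9 control donors, each
#' sampled in three cortical regions (VC, PFC, TC; 60 samples), with
#' region-opposed planted CG methylation shifts (TC hypermethylated in AD,
#' VC hypomethylated), three CG/CH global-methylation subgroups, a
#' two-instrument batch offset with a linear cross-instrument relationship,
#' short- vs long-range contact-decay cell classes, block (TAD) and
#' checkerboard (compartment) contact structure, and telomere-proximal
#' deleted bins confined to Stressed cells. The synthetic genome is three
#' 20-Mb autosomes with centromeres at 40% of length: small enough for
#' minutes-scale analysis yet large enough to carry arms, compartments and
#' TADs.
#'
#' @param ... named overrides of any default listed below. Unknown names are
#'   rejected.
#' @return a [SimConfig-class] object.
#' @details Principal fields (all overridable):
#' \describe{
#'   \item{seed}{master RNG seed; all per-cell substreams derive from it.}
#'   \item{n_ad_donors, n_control_donors}{cohort sizes (11 / 9).}
#'   \item{regions}{region labels, default `c("VC","PFC","TC")`.}
#'   \item{cells_per_sample}{cells per (donor, region), default 100.}
#'   \item{cell_types}{cell-type labels cycled over cells.}
#'   \item{chrom_lengths, centromeres}{synthetic genome.}
#'   \item{bin_size_methyl, bin_size_contact, bin_size_boundary}{bin sizes
#'     (bp) for methylation counts (100 kb), contact matrices (100 kb) and
#'     boundary calls (25 kb).}
#'   \item{subgroup_proportions}{data.frame (region, disease, p0, p1, p2);
#'     rows sum to 1.}
#'   \item{region_effect}{data.frame (region, disease, shift): planted CG
#'     methylation shift.}
#'   \item{batch_offset, instrument_relation}{planted instrument-B
#'     methylation offset and the (intercept, slope) of the cross-instrument
#'     linear relation of global levels.}
#'   \item{decay_exponents}{power-law exponents `c(short=, long=)` of the
#'     two contact-decay classes.}
#'   \item{n_deleted_bins, deletion_max_telomere_distance}{planted deleted
#'     contact bins, placed within 2 Mb of a chromosome end.}
#'   \item{cov_mean, cov_dispersion}{negative-binomial coverage model.}
#'   \item{noise_sd}{per-(cell,bin) Gaussian jitter on the methylation
#'     probability; 0 switches methylated counts to their rounded
#'     expectation (degenerate no-noise mode).}
#' }
#' @examples
#' cfg <- simConfig(cells_per_sample = 10)
#' cfg
#' @export
simConfig <- function(...) {
  regions <- c("VC", "PFC", "TC")
  sp <- expand.grid(region = regions, disease = c("Control", "AD"),
                    stringsAsFactors = FALSE)
  sp$p0 <- 0.30; sp$p1 <- 0.50; sp$p2 <- 0.20
  sp[sp$region == "TC" & sp$disease == "AD", c("p0", "p1")] <- c(0.15, 0.65)
  sp[sp$region == "VC" & sp$disease == "AD", c("p0", "p1")] <- c(0.45, 0.35)
  re <- expand.grid(region = regions, disease = c("Control", "AD"),
                    stringsAsFactors = FALSE)
  re$shift <- 0
  re$shift[re$region == "TC" & re$disease == "AD"] <- 0.05
  re$shift[re$region == "PFC" & re$disease == "AD"] <- 0.02
  re$shift[re$region == "VC" & re$disease == "AD"] <- -0.05
  chrom_lengths <- c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7)
  defaults <- list(
    seed = 1L,
    n_ad_donors = 11L, n_control_donors = 9L,
    regions = regions,
    cells_per_sample = 100L,
    cell_types = c("ExcL23", "ExcL5", "Inh", "ODC"),
    neuron_cell_types = c("ExcL23", "ExcL5", "Inh"),
    chrom_lengths = chrom_lengths,
    centromeres = round(chrom_lengths * 0.4),
    bin_size_methyl = 1e5, bin_size_contact = 1e5, bin_size_boundary = 25e3,
    subgroup_proportions = sp,
    region_effect = re,
    batch_offset = 0.02,
    instrument_relation = c(intercept = 0.02, slope = 0.96),
    shared_library_noise_sd = 0,
    n_shared_libraries = 20L,
    decay_exponents = c(short = 1.5, long = 0.8),
    prop_long = 0.5,
    stressed_fraction = 0.3,
    contacts_per_cell = 1200L,
    trans_fraction = 0.02,
    tad_weight = 0.25, comp_weight = 0.25,
    tad_size = 1e6, comp_block = 2e6,
    n_deleted_bins = 20L,
    deletion_max_telomere_distance = 2e6,
    cov_mean = 6, cov_dispersion = 1,
    noise_sd = 0.01,
    baseline_cg = 0.75, baseline_ch = 0.05,
    subgroup_offsets = matrix(
      c(-0.10, 0.04, 0.04, -0.02, -0.02, 0.04), ncol = 2,
      dimnames = list(c("0", "1", "2"), c("CG", "CH"))),
    boundary_miss_rate = 0.1,
    boundary_jitter_rate = 0.2,
    boundary_jitter_bins = 1L,
    boundary_extra_rate = 0.002,
    stressed_extra_multiplier = 3,
    qc_fail_fraction = 0.05,
    age_range = c(60, 95))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    .stop_config(unknown[1], "is not a recognized configuration field")
  defaults[names(over)] <- over
  obj <- new("SimConfig", params = defaults)
  validObject(obj)
  obj
}

## Interior planted boundary positions for one chromosome.
.planted_boundaries <- function(config) {
  out <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    pos <- seq(config$tad_size, L - config$tad_size, by = config$tad_size)
    data.frame(chrom = ch, position = pos)
  })
  do.call(rbind, out)
}

## Sample deleted contact-resolution bins near either telomere.
.planted_deletions <- function(config) {
  n <- config$n_deleted_bins
  if (n == 0)
    return(data.frame(chrom = character(), bin_index = integer(),
                      start = numeric(), end = numeric()))
  res <- config$bin_size_contact
  cand <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    nb <- ceiling(L / res)
    idx <- seq_len(nb) - 1L
    start <- idx * res; end <- pmin(start + res, L)
    keep <- pmin(start, L - end) <= config$deletion_max_telomere_distance
    ## never delete the terminal bins themselves: keep some coverage anchor
    data.frame(chrom = ch, bin_index = idx, start = start, end = end)[keep, ]
  }))
  if (n > nrow(cand)) .stop_config("n_deleted_bins", "exceeds candidate telomeric bins")
  cand[sort(sample.int(nrow(cand), n)), ]
}

#' Simulate a cohort: metadata plus planted ground truth
#'
#' Generates per-cell metadata (donor, region, disease, sex, age, instrument,
#' cell type, QC metrics) for a donor-by-region design in which every donor
#' contributes every region, together with a [SimTruth-class] object holding
#' all planted labels and effects. Reproducible: the same configuration
#' (including seed) yields byte-identical output.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `meta` (data.frame, one row per cell) and
#'   `truth` ([SimTruth-class]).
#' @examples
#' sim <- simulateCohort(simConfig(cells_per_sample = 5))
#' head(sim$meta)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  p <- config@params
  .with_seed(p$seed, {
    donors <- c(sprintf("AD%02d", seq_len(p$n_ad_donors)),
                sprintf("CT%02d", seq_len(p$n_control_donors)))
    disease <- rep(c("AD", "Control"), c(p$n_ad_donors, p$n_control_donors))
    donor_tab <- data.frame(
      donor = donors, disease = disease,
      sex = sample(c("Female", "Male"), length(donors), replace = TRUE),
      age = round(stats::runif(length(donors), p$age_range[1], p$age_range[2])))
    samples <- expand.grid(donor = donors, region = p$regions,
                           stringsAsFactors = FALSE)
    samples <- samples[order(samples$donor, samples$region), ]
    samples$instrument <- sample(c("A", "B"), nrow(samples), replace = TRUE)
    meta <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      dn <- donor_tab[donor_tab$donor == s$donor, ]
      n <- p$cells_per_sample
      data.frame(
        cell_id = sprintf("%s_%s_c%04d", s$donor, s$region, seq_len(n)),
        donor = s$donor, region = s$region, disease = dn$disease,
        sex = dn$sex, age = dn$age, instrument = s$instrument,
        cell_type = rep_len(p$cell_types, n))
    }))
    rownames(meta) <- NULL

    ## per-cell truth labels, drawn per sample from the configured mixtures
    sp <- p$subgroup_proportions
    key <- paste(meta$region, meta$disease)
    spk <- paste(sp$region, sp$disease)
    probs <- as.matrix(sp[match(key, spk), c("p0", "p1", "p2")])
    u <- stats::runif(nrow(meta))
    cum <- cbind(probs[, 1], probs[, 1] + probs[, 2])
    subgroup <- ifelse(u < cum[, 1], 0L, ifelse(u < cum[, 2], 1L, 2L))
    decay_class <- ifelse(stats::runif(nrow(meta)) < p$prop_long, "Long", "Short")
    state <- ifelse(stats::runif(nrow(meta)) < p$stressed_fraction,
                    "Stressed", "Homeostatic")

    ## QC metrics: mostly-passing draws with a configured failing fraction
    n <- nrow(meta)
    meta$mccc <- stats::runif(n, 0.001, 0.01)
    meta$mch <- stats::runif(n, 0.02, 0.12)
    meta$mcg <- stats::runif(n, 0.6, 0.85)
    meta$reads <- round(stats::runif(n, 8e5, 6e6))
    meta$mapping_rate <- stats::runif(n, 0.55, 0.8)
    meta$cis_long <- round(stats::runif(n, 6e4, 5e5))
    fail <- which(stats::runif(n) < p$qc_fail_fraction)
    if (length(fail)) {
      crit <- sample(6, length(fail), replace = TRUE)
      meta$mccc[fail[crit == 1]] <- stats::runif(sum(crit == 1), 0.05, 0.2)
      meta$mch[fail[crit == 2]] <- stats::runif(sum(crit == 2), 0.25, 0.5)
      meta$mcg[fail[crit == 3]] <- stats::runif(sum(crit == 3), 0.2, 0.45)
      meta$reads[fail[crit == 4]] <- round(stats::runif(sum(crit == 4), 1e4, 4e5))
      meta$mapping_rate[fail[crit == 5]] <- stats::runif(sum(crit == 5), 0.1, 0.45)
      meta$cis_long[fail[crit == 6]] <- round(stats::runif(sum(crit == 6), 0, 4e4))
    }

    irel <- p$instrument_relation
    la <- stats::runif(p$n_shared_libraries, 0.6, 0.85)
    lch <- stats::runif(p$n_shared_libraries, 0.02, 0.1)
    shared <- rbind(
      data.frame(context = "CG", level_a = la,
                 level_b = irel[["intercept"]] + irel[["slope"]] * la),
      data.frame(context = "CH", level_a = lch,
                 level_b = irel[["intercept"]] + irel[["slope"]] * lch))
    if (p$shared_library_noise_sd > 0)
      shared$level_b <- shared$level_b +
        stats::rnorm(nrow(shared), 0, p$shared_library_noise_sd)

    truth <- new("SimTruth",
      cells = data.frame(cell_id = meta$cell_id, subgroup = subgroup,
                         decay_class = decay_class, state = state),
      deleted_bins = .planted_deletions(config),
      region_effects = p$region_effect,
      batch_offset = p$batch_offset,
      instrument_relation = c(intercept = unname(irel[["intercept"]]),
                              slope = unname(irel[["slope"]])),
      boundaries = .planted_boundaries(config),
      shared_libraries = shared,
      subgroup_offsets = p$subgroup_offsets)
    list(meta = meta, truth = truth)
  })
}

#' Simulate binned methylation counts
#'
#' For every cell and genomic bin, coverage is drawn from a negative
#' binomial and the methylated count from a binomial whose success
#' probability is `baseline + subgroup offset + region-by-disease shift
#' (CG only) + batch offset (instrument B) + Gaussian bin noise`, clipped to
#' `[0, 1]`. With `noise_sd = 0` the binomial draw is replaced by the
#' rounded expectation (degenerate no-noise mode). The number of clipped
#' probabilities is recorded in `metadata(x)$n_clipped`.
#'
#' @param meta cohort metadata from [simulateCohort()].
#' @param truth matching [SimTruth-class].
#' @param config the [SimConfig-class] used for the cohort.
#' @return a [MethylBinCounts-class] with CG and CH contexts.
#' @export
simulateMethylome <- function(meta, truth, config) {
  stopifnot(nrow(meta) > 0)
  p <- config@params
  res <- p$bin_size_methyl
  bins <- do.call(rbind, lapply(names(p$chrom_lengths), function(ch) {
    L <- p$chrom_lengths[[ch]]
    st <- seq(0, L - 1, by = res)
    data.frame(chrom = ch, start = st, end = pmin(st + res, L))
  }))
  gr <- GenomicRanges::GRanges(bins$chrom,
    IRanges::IRanges(start = bins$start + 1, end = bins$end))
  nb <- nrow(bins)
  tc <- truth@cells[match(meta$cell_id, truth@cells$cell_id), ]
  rk <- paste(p$region_effect$region, p$region_effect$disease)
  shift <- p$region_effect$shift[match(paste(meta$region, meta$disease), rk)]
  off <- p$subgroup_offsets
  n_clipped <- 0L
  mk <- function(ctx) matrix(0L, nb, nrow(meta),
                             dimnames = list(NULL, meta$cell_id))
  mc_cg <- mk(); cov_cg <- mk(); mc_ch <- mk(); cov_ch <- mk()
  for (i in seq_len(nrow(meta))) {
    cell <- meta$cell_id[i]
    .with_seed(.substream_seed(p$seed, cell), {
      batch <- if (meta$instrument[i] == "B") p$batch_offset else 0
      sg <- as.character(tc$subgroup[i])
      for (ctx in c("CG", "CH")) {
        base <- if (ctx == "CG") p$baseline_cg else p$baseline_ch
        pr <- base + off[sg, ctx] + batch +
          if (ctx == "CG") shift[i] else 0
        pv <- pr + if (p$noise_sd > 0) stats::rnorm(nb, 0, p$noise_sd) else 0
        n_clipped <- n_clipped + sum(pv < 0 | pv > 1)
        pv <- pmin(pmax(pv, 0), 1)
        cov <- stats::rnbinom(nb, size = p$cov_dispersion, mu = p$cov_mean)
        mc <- if (p$noise_sd > 0) stats::rbinom(nb, cov, pv) else
          as.integer(round(cov * pv))
        if (ctx == "CG") { mc_cg[, i] <- mc; cov_cg[, i] <- cov }
        else { mc_ch[, i] <- mc; cov_ch[, i] <- cov }
      }
    })
  }
  x <- MethylBinCounts(gr, mc = list(CG = mc_cg, CH = mc_ch),
                       cov = list(CG = cov_cg, CH = cov_ch),
                       cellData = meta)
  metadata(x)$n_clipped <- n_clipped
  x
}

## Inverse-CDF sample from a truncated continuous power law d^-alpha on
## [dmin, dmax].
.rpowerlaw <- function(n, alpha, dmin, dmax) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(dmin) + u * (log(dmax) - log(dmin)))
  } else {
    a1 <- 1 - alpha
    (dmin^a1 + u * (dmax^a1 - dmin^a1))^(1 / a1)
  }
}

#' Simulate per-cell chromatin contact lists
#'
#' Draws exactly `contacts_per_cell` contacts per cell from a mixture of
#' (i) a power-law distance background with a class-specific exponent
#' (Short vs Long decay classes), (ii) within-TAD pairs confined between
#' consecutive planted boundaries, (iii) within-compartment pairs drawn from
#' alternating 2-Mb blocks (checkerboard structure), and (iv) a small trans
#' fraction. For Stressed cells any contact landing in a planted deleted bin
#' is rejected and redrawn, so pooled Stressed coverage of deleted bins is
#' exactly zero.
#'
#' @inheritParams simulateMethylome
#' @return a [ContactSet-class].
#' @export
simulateContacts <- function(meta, truth, config) {
  p <- config@params
  cl <- p$chrom_lengths
  chroms <- names(cl)
  tc <- truth@cells[match(meta$cell_id, truth@cells$cell_id), ]
  bnd <- truth@boundaries
  del <- truth@deleted_bins
  res <- p$bin_size_contact
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(bnd$position[bnd$chrom == ch])
    edges <- c(0, pos, cl[[ch]])
    data.frame(chrom = ch, start = edges[-length(edges)], end = edges[-1])
  }))
  in_deleted <- function(chrom, pos) {
    if (!nrow(del)) return(rep(FALSE, length(pos)))
    idx <- floor(pos / res)
    paste(chrom, idx) %in% paste(del$chrom, del$bin_index)
  }
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cell <- meta$cell_id[i]
    stressed <- tc$state[i] == "Stressed"
    alpha <- p$decay_exponents[[tolower(tc$decay_class[i])]]
    out[[i]] <- .with_seed(.substream_seed(p$seed, paste0(cell, ":3c")), {
      n <- p$contacts_per_cell
      draw <- function(k) {
        if (k == 0)
          return(data.frame(chrom1 = character(), pos1 = numeric(),
                            chrom2 = character(), pos2 = numeric()))
        comp <- sample(c("trans", "tad", "comp", "bg"), k, replace = TRUE,
                       prob = c(p$trans_fraction,
                                (1 - p$trans_fraction) * p$tad_weight,
                                (1 - p$trans_fraction) * p$comp_weight,
                                (1 - p$trans_fraction) *
                                  (1 - p$tad_weight - p$comp_weight)))
        ch1 <- sample(chroms, k, replace = TRUE, prob = cl)
        pos1 <- pos2 <- numeric(k); ch2 <- ch1
        bg <- comp == "bg"
        if (any(bg)) {
          L <- cl[ch1[bg]]
          d <- pmin(.rpowerlaw(sum(bg), alpha, 1000, max(cl) / 2), L - 2)
          s <- stats::runif(sum(bg), 0, L - d)
          pos1[bg] <- s; pos2[bg] <- s + d
        }
        td <- comp == "tad"
        if (any(td)) {
          ti <- sample(nrow(tads), sum(td), replace = TRUE,
                       prob = tads$end - tads$start)
          ch1[td] <- ch2[td] <- tads$chrom[ti]
          pos1[td] <- stats::runif(sum(td), tads$start[ti], tads$end[ti])
          pos2[td] <- stats::runif(sum(td), tads$start[ti], tads$end[ti])
        }
        cp <- comp == "comp"
        if (any(cp)) {
          L <- cl[ch1[cp]]
          nblk <- floor(L / p$comp_block)
          b1 <- floor(stats::runif(sum(cp)) * nblk)
          ## partner block drawn uniformly among blocks of the same parity
          ## (the checkerboard: even blocks = A, odd blocks = B)
          parity <- b1 %% 2
          n_par <- floor((nblk - parity + 1) / 2)
          b2 <- parity + 2 * floor(stats::runif(sum(cp)) * n_par)
          pos1[cp] <- (b1 + stats::runif(sum(cp))) * p$comp_block
          pos2[cp] <- (b2 + stats::runif(sum(cp))) * p$comp_block
        }
        tr <- comp == "trans"
        if (any(tr) && length(chroms) > 1) {
          ch2[tr] <- vapply(ch1[tr], function(c1)
            sample(setdiff(chroms, c1), 1), character(1))
          pos1[tr] <- stats::runif(sum(tr), 0, cl[ch1[tr]])
          pos2[tr] <- stats::runif(sum(tr), 0, cl[ch2[tr]])
        }
        data.frame(chrom1 = ch1,
                   pos1 = pmin(floor(pos1) + 1, cl[ch1]),
                   chrom2 = ch2,
                   pos2 = pmin(floor(pos2) + 1, cl[ch2]))
      }
      dt <- draw(n)
      if (stressed && nrow(del)) {
        for (iter in 1:100) {
          bad <- in_deleted(dt$chrom1, dt$pos1 - 1) |
                 in_deleted(dt$chrom2, dt$pos2 - 1)
          if (!any(bad)) break
          dt[bad, ] <- draw(sum(bad))
        }
      }
      cbind(cell_id = cell, dt)
    })
  }
  ContactSet(data.table::rbindlist(out), cl)
}

#' Simulate per-cell binary TAD-boundary calls
#'
#' Each cell's boundary set is the planted set with (i) boundaries dropped at
#' `boundary_miss_rate`, (ii) positions jittered by up to
#' `boundary_jitter_bins` 25-kb bins at `boundary_jitter_rate`, and (iii)
#' extra boundaries added at `boundary_extra_rate` per bin, multiplied by
#' `stressed_extra_multiplier` for Stressed cells.
#'
#' @inheritParams simulateMethylome
#' @return `data.table` of boundary events (`cell_id`, `chrom`, `bin_start`,
#'   `value = 1`); densify with [boundaryCallsMatrix()] if needed.
#' @export
simulateBoundaryCalls <- function(meta, truth, config) {
  p <- config@params
  res <- p$bin_size_boundary
  bnd <- truth@boundaries
  tc <- truth@cells[match(meta$cell_id, truth@cells$cell_id), ]
  nbins <- vapply(p$chrom_lengths, function(L) ceiling(L / res), numeric(1))
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cell <- meta$cell_id[i]
    out[[i]] <- .with_seed(.substream_seed(p$seed, paste0(cell, ":tad")), {
      keep <- stats::runif(nrow(bnd)) >= p$boundary_miss_rate
      b <- bnd[keep, , drop = FALSE]
      idx <- floor(b$position / res)
      jit <- stats::runif(nrow(b)) < p$boundary_jitter_rate
      if (any(jit) && p$boundary_jitter_bins > 0)
        idx[jit] <- idx[jit] + sample(c(-p$boundary_jitter_bins,
                                        p$boundary_jitter_bins),
                                      sum(jit), replace = TRUE)
      idx <- pmax(0, pmin(idx, nbins[b$chrom] - 1))
      rate <- p$boundary_extra_rate *
        if (tc$state[i] == "Stressed") p$stressed_extra_multiplier else 1
      extra <- do.call(rbind, lapply(names(nbins), function(ch) {
        k <- stats::rpois(1, rate * nbins[[ch]])
        if (k == 0) return(NULL)
        data.frame(chrom = ch, idx = sample.int(nbins[[ch]], k) - 1L)
      }))
      ev <- rbind(data.frame(chrom = b$chrom, idx = idx),
                  if (is.null(extra)) NULL else extra)
      ev <- unique(ev)
      data.frame(cell_id = cell, chrom = ev$chrom,
                 bin_start = ev$idx * res, value = 1L)
    })
  }
  data.table::rbindlist(out)
}

#' Densify sparse boundary calls into a cells-by-bins binary matrix
#'
#' @param calls sparse event table from [simulateBoundaryCalls()].
#' @param config the [SimConfig-class] defining genome and bin size.
#' @param cells optional cell ids fixing row order.
#' @return binary matrix with `cell_id` rows and `chrom:bin_start` columns.
#' @export
boundaryCallsMatrix <- function(calls, config, cells = NULL) {
  p <- config@params
  res <- p$bin_size_boundary
  bins <- do.call(rbind, lapply(names(p$chrom_lengths), function(ch) {
    st <- seq(0, p$chrom_lengths[[ch]] - 1, by = res)
    data.frame(chrom = ch, bin_start = st)
  }))
  if (is.null(cells)) cells <- unique(calls$cell_id)
  m <- matrix(0L, length(cells), nrow(bins),
              dimnames = list(cells, paste0(bins$chrom, ":", bins$bin_start)))
  key <- paste0(calls$chrom, ":", calls$bin_start)
  m[cbind(match(calls$cell_id, cells), match(key, colnames(m)))] <- 1L
  m
}

#' Parse a pairwise-comparison column name
#'
#' Comparison columns are named `celltype:SubtypeA_vs_SubtypeB`.
#'
#' @param x character vector of column names.
#' @return data.frame with `celltype`, `a`, `b`.
#' @export
parseComparison <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):(.+)_vs_(.+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad))
    stop("unparseable comparison name(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  data.frame(celltype = vapply(m, `[`, "", 2),
             a = vapply(m, `[`, "", 3),
             b = vapply(m, `[`, "", 4))
}

#' Simulate a genes-by-comparisons log2 fold-change table
#'
#' For every within-cell-type subtype pair, between-cluster comparisons have
#' per-gene mean effect of magnitude `delta` (random sign per gene, direction
#' set by cluster order) and within-cluster comparisons mean 0, plus Gaussian
#' noise. Column names follow `celltype:SubtypeA_vs_SubtypeB`.
#'
#' @param subtypes character vector of subtype ids (`celltype:Subtype`).
#' @param planted_clusters named vector mapping each subtype id to a cluster.
#' @param n_genes number of genes.
#' @param delta planted between-cluster effect magnitude (log2 units).
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return data.frame with a `gene` column plus one column per comparison.
#' @export
simulateLog2fcTensor <- function(subtypes, planted_clusters, n_genes = 200,
                                 delta = 2, noise_sd = 0.1, seed = 1) {
  if (length(subtypes) < 2) stop("need at least two subtypes", call. = FALSE)
  if (!all(subtypes %in% names(planted_clusters)))
    stop("every subtype must be assigned to exactly one planted cluster",
         call. = FALSE)
  info <- do.call(rbind, strsplit(subtypes, ":", fixed = TRUE))
  ct <- info[, 1]
  .with_seed(seed, {
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    cols <- list(); cn <- character()
    for (cc in unique(ct)) {
      idx <- which(ct == cc)
      if (length(idx) < 2) next
      for (i in idx) for (j in idx) {
        if (i >= j) next
        nm <- sprintf("%s:%s_vs_%s", cc, info[i, 2], info[j, 2])
        if (nm %in% cn)
          stop("duplicate comparison name: ", nm, call. = FALSE)
        ci <- planted_clusters[[subtypes[i]]]
        cj <- planted_clusters[[subtypes[j]]]
        mu <- if (identical(ci, cj)) 0 else
          delta * sgn * (if (as.character(ci) < as.character(cj)) 1 else -1)
        cols[[nm]] <- mu + stats::rnorm(n_genes, 0, noise_sd)
        cn <- c(cn, nm)
      }
    }
    out <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)))
    for (nm in cn) out[[nm]] <- cols[[nm]]
    out
  })
}
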