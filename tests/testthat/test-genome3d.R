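## Checkerboard matrix: alternating blocks of `blk` bins; same-parity
## blocks interact strongly, cross-parity weakly.
checkerboard <- function(n, blk = 5, hi = 8, lo = 1, decay = 0) {
  lab <- (ceiling(seq_len(n) / blk) - 1) %% 2
  m <- ifelse(outer(lab, lab, "=="), hi, lo) * 1
  if (decay > 0) m <- m * exp(-decay * abs(outer(seq_len(n), seq_len(n), "-")))
  m
}

test_that("pseudo-bulk merging sums and conserves contacts", {
  dt <- data.frame(
    cell_id = c("a", "a", "b", "b", "b"),
    chrom1 = "chr1", pos1 = c(1e5, 3e5, 5e5, 5e5, 9e5),
    chrom2 = "chr1", pos2 = c(2e5, 4e5, 6e5, 6e5, 9.5e5))
  ct <- ContactSet(dt, c(chr1 = 1e6))
  pb <- pseudoBulk(ct, resolution = 1e5)[["chr1"]]
  m <- contactMatrix(pb)
  # conservation: upper triangle incl. diagonal equals total cis contacts
  expect_equal(sum(m[upper.tri(m, diag = TRUE)]), nrow(dt))
  # disjoint cells sum elementwise
  ma <- contactMatrix(pseudoBulk(ct, "a", 1e5)[["chr1"]])
  mb <- contactMatrix(pseudoBulk(ct, "b", 1e5)[["chr1"]])
  expect_equal(ma + mb, m)
  expect_error(pseudoBulk(ct, character(0)), "empty")
  expect_error(pseudoBulk(ct, "nonexistent"), "no contacts")
})

test_that("ICE balancing equalizes row sums and recovers planted scalings", {
  # planted per-bin scaling of a flat matrix
  set.seed(4)
  n <- 20
  base <- matrix(1, n, n) + diag(n)
  f <- runif(n, 0.5, 2)
  m <- base * outer(f, f)
  out <- balanceICE(m)
  rs <- rowSums(out$matrix)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-3)
  # weights proportional to the planted factors (up to global scale)
  ratio <- out$weights / f
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  # already balanced: weights constant, output proportional to input
  outb <- balanceICE(out$matrix)
  expect_lt(diff(range(outb$weights)) / mean(outb$weights), 1e-4)
  # zero row masked and excluded
  m0 <- m; m0[3, ] <- 0; m0[, 3] <- 0
  out0 <- balanceICE(m0)
  expect_true(is.na(out0$weights[3]))
  rs0 <- rowSums(out0$matrix)[-3]
  expect_lt(max(abs(rs0 / mean(rs0) - 1)), 1e-3)
  # BinnedContactMatrix round trip keeps class and validity
  bcm <- balanceICE(BinnedContactMatrix("chr1", 1e5, m))
  expect_s4_class(bcm, "BinnedContactMatrix")
  expect_equal(length(balancingWeights(bcm)), n)
})

test_that("band-mean expected matrices follow the worked examples", {
  expect_equal(expectedByBand(matrix(c(4, 2, 2, 8), 2)),
               matrix(c(6, 2, 2, 6), 2))
  # band-constant matrix is its own expectation; O/E is all ones
  n <- 12
  bc <- outer(seq_len(n), seq_len(n),
              function(i, j) 10 * 0.8^abs(i - j))
  expect_equal(expectedByBand(bc), bc, tolerance = 1e-12)
  expect_equal(oeMatrix(bc), matrix(1, n, n), tolerance = 1e-12)
})

test_that("compartment PC1 separates checkerboard blocks with the GC sign law", {
  n <- 40
  m <- checkerboard(n, blk = 5)
  gc <- ifelse((ceiling(seq_len(n) / 5) - 1) %% 2 == 0, 0.48, 0.40)
  pc <- compartmentPc1(m, gc)
  expect_true(all(pc$pc1[gc > 0.44] > 0))
  expect_true(all(pc$pc1[gc < 0.44] < 0))
  expect_gte(cor(pc$pc1, pc$gc), 0)
  # flipping the GC track flips the eigenvector sign
  pc_f <- compartmentPc1(m, rev(gc))
  expect_equal(pc_f$pc1, -pc$pc1, tolerance = 1e-9)
  # sign law on random symmetric instances
  set.seed(5)
  for (rep in 1:20) {
    r <- matrix(runif(n * n), n)
    rm <- r + t(r)
    gcr <- runif(n, 0.3, 0.6)
    pcr <- compartmentPc1(rm, gcr)
    r2 <- suppressWarnings(cor(pcr$pc1, gcr, use = "complete.obs"))
    if (is.finite(r2)) expect_gte(r2, 0)
  }
  # permutation equivariance of the A/B partition (the distance-decay
  # expected depends on bin order, so only the sign pattern is preserved)
  perm <- sample(n)
  pc_p <- compartmentPc1(m[perm, perm], gc[perm])
  expect_equal(sign(pc_p$pc1), sign(pc$pc1[perm]))
  expect_error(compartmentPc1(matrix(0, 6, 6), runif(6)), "unmasked")
})

test_that("saddle matrices expose corner enrichment and divide to one", {
  n <- 40
  m <- checkerboard(n, blk = 5, decay = 0.05)
  gc <- ifelse((ceiling(seq_len(n) / 5) - 1) %% 2 == 0, 0.48, 0.40)
  pc <- compartmentPc1(m, gc)
  sad <- saddle(m, pc, n_quantiles = 5)
  expect_equal(sad, t(sad), tolerance = 1e-9)
  expect_gt(sad[1, 1], sad[1, 5])   # BB corner beats the anti-corner
  expect_gt(sad[5, 5], sad[1, 5])   # AA corner too
  # identical states divide to an all-ones matrix
  ratio <- saddleStateRatio(sad, sad)
  expect_equal(ratio, matrix(1, 5, 5), tolerance = 1e-9)
  expect_error(saddleStateRatio(sad, sad[1:3, 1:3]), "shape")
  # constant PC1: every cell is the global mean O/E
  pc_c <- pc; pc_c$pc1 <- rep(0.1, n)
  sad_c <- saddle(m, pc_c, n_quantiles = 4)
  oe <- oeMatrix(m)
  expect_equal(mean(sad_c), mean(oe), tolerance = 0.05)
})

test_that("centromere-aligned averaging is exact on band-constant maps", {
  n <- 80
  bc <- outer(seq_len(n), seq_len(n),
              function(i, j) 20 * 0.9^abs(i - j))
  mats <- list(chr1 = bc)
  avg <- centromereAlignedAverage(mats, c(chr1 = 32.5e5), resolution = 1e5,
                                  p_bins = 20, q_bins = 20)
  expect_equal(dim(avg), c(40, 40))
  expect_equal(max(abs(avg - 1)), 0, tolerance = 1e-6)
  # two identical chromosomes average to the same map
  avg2 <- centromereAlignedAverage(list(chr1 = bc, chr2 = bc),
                                   c(chr1 = 32.5e5, chr2 = 32.5e5),
                                   resolution = 1e5, p_bins = 20,
                                   q_bins = 20)
  expect_equal(avg2, avg, ignore_attr = TRUE)
  expect_equal(attr(avg2, "n_chroms"), 2L)
  # chromosomes below the bin threshold are excluded
  small <- matrix(1, 49, 49)
  avg3 <- centromereAlignedAverage(list(chr1 = bc, chr9 = small),
                                   c(chr1 = 32.5e5, chr9 = 2e6),
                                   resolution = 1e5, p_bins = 20,
                                   q_bins = 20)
  expect_equal(attr(avg3, "n_chroms"), 1L)
  expect_error(centromereAlignedAverage(list(chr9 = small),
                                        c(chr9 = 2e6), resolution = 1e5),
               "eligible")
})

test_that("deletion detection applies the missingness threshold exactly", {
  n <- 30
  mkpb <- function(zero_bins = integer(0)) {
    m <- matrix(5, n, n)
    m[zero_bins, ] <- 0; m[, zero_bins] <- 0
    list(chr1 = BinnedContactMatrix("chr1", 1e5, m))
  }
  # bin 4 empty in 10 of 12 pseudo-bulks; bin 9 in 9 of 12
  pbs <- c(lapply(1:10, function(i) mkpb(4)),
           lapply(1:2, function(i) mkpb()))
  pbs <- lapply(seq_along(pbs), function(i) {
    if (i <= 9) list(chr1 = BinnedContactMatrix("chr1", 1e5, {
      m <- contactMatrix(pbs[[i]]$chr1); m[9, ] <- 0; m[, 9] <- 0; m
    })) else pbs[[i]]
  })
  names(pbs) <- sprintf("pb%02d", seq_along(pbs))
  calls <- detectPutativeDeletions(pbs, min_missing = 10)
  expect_equal(calls$bin_index, 3L)          # 0-based: bin 4 only
  expect_equal(calls$n_missing, 10L)
  expect_equal(calls$telomere_distance, 3 * 1e5)
  # a bin missing everywhere is not a call (no data anywhere)
  pbs_all <- lapply(pbs, function(pb) list(chr1 = BinnedContactMatrix(
    "chr1", 1e5, { m <- contactMatrix(pb$chr1); m[7, ] <- 0; m[, 7] <- 0; m })))
  calls_all <- detectPutativeDeletions(pbs_all, min_missing = 10)
  expect_false(6L %in% calls_all$bin_index)
  # fewer pseudo-bulks than the threshold: warning + empty result
  expect_warning(none <- detectPutativeDeletions(pbs[1:3], 10), "fewer")
  expect_equal(nrow(none), 0L)
})

test_that("planted deletions are recovered from the synthetic cohort", {
  cfg <- simConfig(cells_per_sample = 8, contacts_per_cell = 800, seed = 17L)
  sim <- simulateCohort(cfg)
  ct <- simulateContacts(sim$meta, sim$truth, cfg)
  tc <- truthCells(sim$truth)
  m2 <- cbind(sim$meta,
              state = tc$state[match(sim$meta$cell_id, tc$cell_id)])
  pbs <- pseudoBulkGroups(ct, m2, c("region", "cell_type", "state"), 1e5)
  pbs <- lapply(pbs, function(g) lapply(g, balanceICE))
  calls <- detectPutativeDeletions(pbs, 10, cfg$chrom_lengths)
  del <- deletedBins(sim$truth)
  recall <- mean(paste(del$chrom, del$bin_index) %in%
                   paste(calls$chrom, calls$bin_index))
  expect_gte(recall, 0.9)
  # per-state direction: all planted loss sits in the Stressed columns
  st <- setNames(vapply(strsplit(names(pbs), "/"), `[`, "", 3), names(pbs))
  cnt <- deletionStateCounts(calls, st)
  expect_gt(cnt["Stressed"], cnt["Homeostatic"])
  # called bins cluster near telomeres
  expect_lte(median(calls$telomere_distance),
             cfg$deletion_max_telomere_distance)
})
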