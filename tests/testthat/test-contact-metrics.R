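mkContacts <- function(cell, d, chrom = "chr1", L = 2e7) {
  ContactSet(data.frame(cell_id = cell, chrom1 = chrom, pos1 = 1e6,
                        chrom2 = chrom, pos2 = 1e6 + d),
             c(chr1 = L))
}

test_that("decay profiles count cis contacts into distance fractions", {
  edges <- c(25e3, 50e3, 1e5, 2e5)
  # all contacts at one distance
  ct <- mkContacts(rep("a", 20), 60e3)
  p <- decayProfile(ct, edges)
  expect_equal(unname(p["a", ]), c(0, 1, 0))
  # trans and sub-minimum contacts excluded
  dt <- rbind(contactsTable(ct),
              data.frame(cell_id = "a", chrom1 = "chr1", pos1 = 1,
                         chrom2 = "chr2", pos2 = 1),
              data.frame(cell_id = "a", chrom1 = "chr1", pos1 = 1,
                         chrom2 = "chr1", pos2 = 1000))
  p2 <- decayProfile(ContactSet(dt, c(chr1 = 2e7, chr2 = 2e7)), edges)
  expect_equal(unname(p2["a", ]), c(0, 1, 0))
  expect_error(decayProfile(ct, c(2, 1, 3)), "increasing")
  # 50/50 mixture lands within 3 binomial SE
  set.seed(1)
  n <- 4000
  d <- ifelse(runif(n) < 0.5, 30e3, 150e3)
  p3 <- decayProfile(mkContacts(rep("a", n), d), edges)
  se <- sqrt(0.25 / n)
  expect_lt(abs(p3["a", 1] - 0.5), 3 * se)
  expect_lt(abs(p3["a", 3] - 0.5), 3 * se)
  # zero usable contacts flagged
  p0 <- decayProfile(mkContacts("b", 1000), edges)
  expect_equal(attr(p0, "zero_cells"), "b")
  expect_true(all(p0 == 0))
})

test_that("kernel score matches the closed form and kernel laws", {
  # worked value: N = 3, R = (0, 1, 0), sigma = N/6 = 0.5
  cs <- contactScore(matrix(c(0, 1, 0), 1))
  expect_equal(cs$score, 1 / (1 + 2 * exp(-2)), tolerance = 1e-12)
  expect_equal(sum(cs$weights), 1, tolerance = 1e-12)
  # constant profile: score = 1/N exactly, any N
  for (N in c(1, 4, 9, 17)) {
    csN <- contactScore(matrix(rep(1 / N, N), 1))
    expect_equal(csN$score, 1 / N, tolerance = 1e-12)
    expect_equal(sum(csN$weights), 1, tolerance = 1e-12)
  }
  # score bounded by profile extremes
  set.seed(2)
  r <- runif(7); r <- r / sum(r)
  s <- contactScore(matrix(r, 1))$score
  expect_gte(s, min(r)); expect_lte(s, max(r))
  expect_error(contactScore(matrix(numeric(0), 1, 0)), "at least one")
})

test_that("short/long classification recovers planted decay classes", {
  cfg <- simConfig(cells_per_sample = 12, contacts_per_cell = 600,
                   seed = 31L)
  sim <- simulateCohort(cfg)
  sub <- sim$meta[sim$meta$region == "VC", ]
  ct <- simulateContacts(sub, sim$truth, cfg)
  prof <- decayProfile(ct)
  cls <- classifyShortLong(prof, seed = 1)
  tc <- truthCells(sim$truth)
  truth <- tc$decay_class[match(rownames(prof), tc$cell_id)]
  expect_gte(mean(cls == truth), 0.95)
  # label rule: the higher-mean-score cluster is Short
  sc <- contactScore(prof)$score
  expect_gt(mean(sc[cls == "Short"]), mean(sc[cls == "Long"]))
  # invariant to cell order
  ord <- rev(seq_len(nrow(prof)))
  cls_r <- classifyShortLong(prof[ord, ], seed = 1)
  expect_equal(cls_r[rownames(prof)], cls)
  # degenerate: identical profiles collapse to one class with warning
  same <- matrix(rep(prof[1, ], 5), 5, byrow = TRUE,
                 dimnames = list(paste0("c", 1:5), NULL))
  expect_warning(cd <- classifyShortLong(same), "identical")
  expect_equal(length(unique(cd)), 1L)
})

test_that("insulation caller finds block junctions and nothing else", {
  blockMatrix <- function(sizes, hi = 10, lo = 0.5) {
    n <- sum(sizes)
    m <- matrix(lo, n, n)
    at <- cumsum(c(0, sizes))
    for (k in seq_along(sizes)) {
      idx <- (at[k] + 1):at[k + 1]
      m[idx, idx] <- hi
    }
    m
  }
  # two blocks: single boundary at the junction
  m2 <- blockMatrix(c(15, 15))
  b2 <- callBoundariesInsulation(m2, window_bins = 5, min_depth = 0.1)
  expect_equal(which(b2 == 1), 15)
  # constant matrix: no boundaries
  expect_equal(sum(callBoundariesInsulation(matrix(1, 30, 30), 5, 0.1)), 0)
  # planted 5-TAD matrix, noiseless: all 4 internal junctions, no spurious
  m5 <- blockMatrix(rep(12, 5))
  b5 <- callBoundariesInsulation(m5, window_bins = 5, min_depth = 0.1)
  expect_equal(which(b5 == 1), c(12, 24, 36, 48))
  expect_error(callBoundariesInsulation(matrix(1, 4, 4), 5), "window")
})

test_that("boundary density and its covariate adjustment follow OLS laws", {
  calls <- data.frame(
    cell_id = c("c1", "c1", "c2", "c3", "c3", "c4"),
    chrom = "chr1",
    bin_start = c(0, 25e3, 50e3, 0, 975e3, 1e6),
    value = 1L)
  meta <- data.frame(cell_id = paste0("c", 1:4), region = "VC",
                     disease = "AD", donor = "D1", cell_type = "T")
  dens <- boundaryDensity(calls, meta)
  # 5 events in window [0, 1 Mb) over 4 cells; 1 event in the next window
  expect_equal(dens$density[dens$window_start == 0], 5 / 4)
  expect_equal(dens$density[dens$window_start == 1e6], 1 / 4)

  # noiseless linear dependence: residuals vanish
  samples <- sprintf("s%02d", 1:10)
  cov <- setNames(seq(1000, 1900, by = 100), samples)
  d2 <- data.frame(sample = samples, chrom = "chr1", window_start = 0,
                   events = 1, n_cells = 1,
                   density = 2 + 0.001 * cov)
  adj <- adjustBoundaryDensity(d2, cov)
  expect_true(all(abs(adj$adjusted) < 1e-9))
  # uncorrelated covariate (zero planted slope): adjusted = density - mean
  d3 <- d2; d3$density <- rep(c(1, 2), 5)
  cov3 <- setNames(rep(7, 10), samples)   # constant -> slope undefined
  adj3 <- adjustBoundaryDensity(d3, cov3)
  expect_equal(adj3$adjusted, d3$density - mean(d3$density))
  # residuals sum to zero within each window
  set.seed(3)
  d4 <- d2; d4$density <- rnorm(10)
  adj4 <- adjustBoundaryDensity(d4, cov)
  expect_lt(abs(sum(adj4$adjusted)), 1e-10)
  expect_error(adjustBoundaryDensity(d2, cov[1:3]), "missing")
})

test_that("per-cell boundary counts associate with the planted state effect", {
  sc <- smallCohort()
  calls <- simulateBoundaryCalls(sc$meta, sc$truth, sc$config)
  tc <- truthCells(sc$truth)
  per_cell <- as.data.frame(table(calls$cell_id), stringsAsFactors = FALSE)
  names(per_cell) <- c("cell_id", "n")
  m <- merge(sc$meta, per_cell, by = "cell_id")
  m$state <- tc$state[match(m$cell_id, tc$cell_id)]
  fit <- fitFeatureModel(matrix(m$n, 1, dimnames = list("bcount", NULL)), m,
                         designSpec(~ state + age + sex,
                                    ref = c(state = "Homeostatic",
                                            sex = "Female")),
                         min_donors = 1)
  expect_gt(fit$stateStressed_coef, 0)
  expect_lt(fit$stateStressed_p, 0.05)
})
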