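test_that("cohort layout matches the configured design", {
  sc <- smallCohort()
  meta <- sc$meta
  expect_equal(length(unique(paste(meta$donor, meta$region))), 60)
  expect_equal(length(unique(meta$donor)), 20)
  expect_setequal(unique(meta$region), c("VC", "PFC", "TC"))
  # every donor appears in every region with the configured cell count
  tab <- table(meta$donor, meta$region)
  expect_true(all(tab == sc$config$cells_per_sample))
  expect_equal(sum(meta$disease == "AD"),
               11 * 3 * sc$config$cells_per_sample)
})

test_that("invalid configurations are rejected with the field name", {
  expect_error(simConfig(cells_per_sample = 0), "cells_per_sample")
  expect_error(simConfig(bogus_field = 1), "bogus_field")
  expect_error(simConfig(centromeres = c(chr1 = 5e7, chr2 = 8e6, chr3 = 8e6)),
               "centromeres")
  sp <- simConfig()@params$subgroup_proportions
  sp$p0 <- sp$p0 + 0.1
  expect_error(simConfig(subgroup_proportions = sp), "subgroup_proportions")
})

test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(cells_per_sample = 3, seed = 7L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(truthCells(a$truth), truthCells(b$truth))
  ma <- simulateMethylome(a$meta[1:6, ], a$truth, cfg)
  mb <- simulateMethylome(b$meta[1:6, ], b$truth, cfg)
  expect_identical(SummarizedExperiment::assay(ma, "mc_CG"),
                   SummarizedExperiment::assay(mb, "mc_CG"))
  ca <- simulateContacts(a$meta[1:4, ], a$truth, cfg)
  cb <- simulateContacts(b$meta[1:4, ], b$truth, cfg)
  expect_identical(contactsTable(ca), contactsTable(cb))
})

test_that("planted region-by-disease methylation shift is recovered", {
  # isolate the regional shift: no subgroup offsets, no batch effect
  cfg <- simConfig(cells_per_sample = 30, seed = 11L,
                   subgroup_offsets = matrix(0, 3, 2,
                     dimnames = list(c("0", "1", "2"), c("CG", "CH"))),
                   batch_offset = 0, noise_sd = 0.005)
  sim <- simulateCohort(cfg)
  keep <- sim$meta$region == "TC"
  mb <- simulateMethylome(sim$meta[keep, ], sim$truth, cfg)
  lv <- cellGlobalLevels(mb)
  dis <- sim$meta$disease[keep][match(lv$cell_id, sim$meta$cell_id[keep])]
  diff <- mean(lv$cg[dis == "AD"]) - mean(lv$cg[dis == "Control"])
  # binomial moment oracle: per-cell level averages ~600 bins x mean cov 6,
  # so the SE of the group difference is far below 0.01
  n_ad <- sum(dis == "AD"); n_ct <- sum(dis == "Control")
  p <- cfg$baseline_cg
  se_cell <- sqrt(p * (1 - p) / (600 * cfg$cov_mean))
  se_diff <- se_cell * sqrt(1 / n_ad + 1 / n_ct)
  expect_lt(abs(diff - 0.05), 3 * se_diff + 0.002)
})

test_that("subgroup draws follow the configured mixture", {
  sp <- simConfig()@params$subgroup_proportions
  sp$p0 <- 0.2; sp$p1 <- 0.5; sp$p2 <- 0.3
  cfg <- simConfig(cells_per_sample = 50, seed = 3L,
                   subgroup_proportions = sp)
  sim <- simulateCohort(cfg)
  n <- nrow(sim$meta)
  cnt <- table(factor(truthCells(sim$truth)$subgroup, levels = 0:2))
  # multinomial 99% bounds per category (normal approximation)
  for (g in 1:3) {
    pg <- c(0.2, 0.5, 0.3)[g]
    se <- sqrt(n * pg * (1 - pg))
    expect_lt(abs(cnt[g] - n * pg), qnorm(0.995) * se * 1.1)
  }
})

test_that("no-noise mode degenerates to the deterministic expectation", {
  cfg <- simConfig(cells_per_sample = 2, seed = 5L, noise_sd = 0,
                   batch_offset = 0,
                   subgroup_offsets = matrix(0, 3, 2,
                     dimnames = list(c("0", "1", "2"), c("CG", "CH"))),
                   region_effect = within(simConfig()@params$region_effect,
                                          shift <- 0))
  sim <- simulateCohort(cfg)
  mb <- simulateMethylome(sim$meta[1:3, ], sim$truth, cfg)
  mc <- SummarizedExperiment::assay(mb, "mc_CG")
  cov <- SummarizedExperiment::assay(mb, "cov_CG")
  frac <- mc[cov > 0] / cov[cov > 0]
  # methylated counts are the rounded expectation of Binomial(cov, 0.75):
  # fractions sit within half a read of the baseline, exactly on it when
  # cov * p is integral
  expect_true(all(abs(frac - 0.75) <= 0.5 / cov[cov > 0] + 1e-12))
  exact <- cov > 0 & (cov * 0.75) %% 1 == 0
  expect_true(all(mc[exact] / cov[exact] == 0.75))
})

test_that("contact depth is conserved exactly per cell", {
  sc <- smallCohort()
  ct <- simulateContacts(sc$meta[1:8, ], sc$truth, sc$config)
  cnt <- table(contactsTable(ct)$cell_id)
  expect_true(all(cnt == sc$config$contacts_per_cell))
})

test_that("planted deletions are empty in Stressed cells and absent otherwise", {
  sc <- smallCohort()
  tc <- truthCells(sc$truth)
  del <- deletedBins(sc$truth)
  expect_equal(nrow(del), sc$config$n_deleted_bins)
  stressed <- sc$meta[sc$meta$cell_id %in%
                        tc$cell_id[tc$state == "Stressed"], ][1:30, ]
  ct <- simulateContacts(stressed, sc$truth, sc$config)
  dt <- contactsTable(ct)
  res <- sc$config$bin_size_contact
  hits <- paste(dt$chrom1, floor((dt$pos1 - 1) / res)) %in%
            paste(del$chrom, del$bin_index) |
          paste(dt$chrom2, floor((dt$pos2 - 1) / res)) %in%
            paste(del$chrom, del$bin_index)
  expect_equal(sum(hits), 0)
  # telomere proximity of the planted bins
  L <- sc$config$chrom_lengths[del$chrom]
  expect_true(all(pmin(del$start, L - del$end) <=
                    sc$config$deletion_max_telomere_distance))
})

test_that("deletion-free cohorts have no empty bins at default depth", {
  cfg <- simConfig(cells_per_sample = 6, n_deleted_bins = 0,
                   contacts_per_cell = 800, seed = 9L)
  sim <- simulateCohort(cfg)
  ct <- simulateContacts(sim$meta, sim$truth, cfg)
  pb <- pseudoBulk(ct, resolution = cfg$bin_size_contact)
  for (ch in names(pb))
    expect_true(all(rowSums(contactMatrix(pb[[ch]])) > 0))
})

test_that("boundary-call noise model behaves as configured", {
  sc <- smallCohort()
  cfg0 <- simConfig(cells_per_sample = 4, seed = 42L,
                    boundary_miss_rate = 0, boundary_jitter_rate = 0,
                    boundary_extra_rate = 0)
  calls <- simulateBoundaryCalls(sc$meta[1:5, ], sc$truth, cfg0)
  planted <- plantedBoundaries(sc$truth)
  res <- cfg0$bin_size_boundary
  pk <- sort(paste(planted$chrom, floor(planted$position / res) * res))
  for (cell in unique(calls$cell_id)) {
    got <- calls[calls$cell_id == cell, ]
    expect_identical(sort(paste(got$chrom, got$bin_start)), pk)
  }

  # extra boundaries: Poisson rate check on non-stressed cells
  r <- 0.01
  cfgE <- simConfig(cells_per_sample = 4, seed = 42L,
                    boundary_miss_rate = 1, boundary_jitter_rate = 0,
                    boundary_extra_rate = r, stressed_extra_multiplier = 1)
  n_cells <- 40
  callsE <- simulateBoundaryCalls(sc$meta[1:n_cells, ], sc$truth, cfgE)
  nbins <- sum(ceiling(cfgE$chrom_lengths / cfgE$bin_size_boundary))
  lambda <- r * nbins
  mean_extra <- nrow(callsE) / n_cells
  se <- sqrt(lambda / n_cells)
  expect_lt(abs(mean_extra - lambda), 4 * se)

  # Stressed cells carry more boundaries than Homeostatic on average
  callsS <- simulateBoundaryCalls(sc$meta, sc$truth, sc$config)
  tc <- truthCells(sc$truth)
  per_cell <- table(callsS$cell_id)
  st <- tc$state[match(names(per_cell), tc$cell_id)]
  expect_gt(mean(per_cell[st == "Stressed"]),
            mean(per_cell[st == "Homeostatic"]))
})

test_that("log2FC tensor generator formats and validates", {
  subs <- c("Exc:g0", "Exc:g1", "ODC:g0", "ODC:g1")
  cl <- setNames(c("S", "H", "S", "H"), subs)
  lfc <- simulateLog2fcTensor(subs, cl, n_genes = 50, delta = 2,
                              noise_sd = 0.1, seed = 1)
  cmp <- parseComparison(setdiff(names(lfc), "gene"))
  expect_setequal(cmp$celltype, c("Exc", "ODC"))
  # round trip
  rebuilt <- sprintf("%s:%s_vs_%s", cmp$celltype, cmp$a, cmp$b)
  expect_identical(rebuilt, setdiff(names(lfc), "gene"))
  expect_error(parseComparison("nocolon_here"), "unparseable")
  expect_error(simulateLog2fcTensor("Exc:g0", cl), "two subtypes")
  expect_error(simulateLog2fcTensor(c("Exc:g0", "Exc:g1"),
                                    c(`Exc:g0` = "S")), "planted cluster")
})
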