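## Shared small metadata: 10 donors x 3 regions, balanced.
lmMeta <- function(n_donors = 10) {
  donors <- sprintf("D%02d", seq_len(n_donors))
  meta <- expand.grid(donor = donors, region = c("VC", "PFC", "TC"),
                      stringsAsFactors = FALSE)
  meta$disease <- ifelse(as.integer(sub("D", "", meta$donor)) <=
                           n_donors / 2, "AD", "Control")
  meta$sex <- ifelse(as.integer(sub("D", "", meta$donor)) %% 2 == 0,
                     "Female", "Male")
  meta$age <- 60 + as.integer(sub("D", "", meta$donor))
  meta
}

test_that("coefficients and P values match the normal-equations oracle", {
  set.seed(101)
  meta <- lmMeta()
  d <- epistate3c:::.build_design(meta, designSpec())
  for (rep in 1:100) {
    y <- rnorm(nrow(meta))
    fit <- fitFeatureModel(matrix(y, 1, dimnames = list("f", NULL)), meta,
                           min_donors = 1)
    orc <- olsOracle(d$X, y)
    names(orc$coef) <- names(orc$p) <- colnames(d$X)
    for (tm in attr(fit, "terms")) {
      expect_equal(fit[[paste0(tm, "_coef")]], unname(orc$coef[tm]),
                   tolerance = 1e-8)
      expect_equal(fit[[paste0(tm, "_p")]], unname(orc$p[tm]),
                   tolerance = 1e-8)
    }
  }
})

test_that("a noiseless VC-only disease effect is decomposed exactly", {
  meta <- lmMeta()
  y <- ifelse(meta$disease == "AD" & meta$region == "VC", 0.2, 0)
  fit <- fitFeatureModel(matrix(y, 1), meta, min_donors = 1)
  expect_equal(fit$diseaseAD_coef, 0.2, tolerance = 1e-10)
  expect_equal(fit$`diseaseAD:regionPFC_coef`, -0.2, tolerance = 1e-10)
  expect_equal(fit$`diseaseAD:regionTC_coef`, -0.2, tolerance = 1e-10)
  expect_equal(fit$regionPFC_coef, 0, tolerance = 1e-10)
  expect_equal(fit$age_coef, 0, tolerance = 1e-10)
})

test_that("donor, missingness and degenerate-response conventions hold", {
  meta <- lmMeta()
  vals <- rbind(
    few = ifelse(meta$donor %in% sprintf("D%02d", 1:4), rnorm(nrow(meta)), NA),
    empty = rep(NA_real_, nrow(meta)),
    const = rep(1.5, nrow(meta)),
    ok = rnorm(nrow(meta)))
  fit <- fitFeatureModel(vals, meta, min_donors = 5)
  expect_equal(fit$status,
               c("skipped_min_donors", "skipped_all_missing", "ok", "ok"))
  expect_true(is.na(fit$diseaseAD_coef[1]))
  expect_equal(fit$diseaseAD_coef[3], 0)
  expect_equal(fit$diseaseAD_p[3], 1)
  # unknown reference level is a configuration error
  expect_error(
    fitFeatureModel(vals["ok", , drop = FALSE], meta,
                    designSpec(ref = c(disease = "Ctl", region = "VC",
                                       sex = "Female"))),
    "reference level")
})

test_that("BH q-values reproduce the hand step-up and the brute force", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(1), 1)
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), bhOracle(p), tolerance = 1e-12)
    # monotone nondecreasing in sorted-p order
    q <- bhFdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # NA propagation: non-missing entries match brute force on the subset
  p <- c(0.01, NA, 0.2, 0.8, NA)
  q <- bhFdr(p)
  expect_true(all(is.na(q[c(2, 5)])))
  expect_equal(q[!is.na(p)], bhOracle(p[!is.na(p)]))
})

test_that("batch correction removes the batch component and nothing else", {
  meta <- lmMeta()
  meta$instrument <- rep(c("A", "B"), length.out = nrow(meta))
  # single batch: identity
  m1 <- meta; m1$instrument <- "A"
  y <- rnorm(nrow(meta))
  expect_identical(batchCorrect(matrix(y, 1), m1), matrix(y, 1))
  # pure mean offset, no other variation: removed exactly
  base <- rnorm(1)
  y2 <- base + 0.05 * (meta$instrument == "B")
  cor2 <- batchCorrect(matrix(y2, 1), meta,
                       keep_covariates = character(0))
  expect_lt(abs(mean(cor2[meta$instrument == "B"]) -
                  mean(cor2[meta$instrument == "A"])), 1e-10)
  # planted disease + batch: disease coefficient preserved after correction
  y3 <- 0.3 * (meta$disease == "AD") + 0.05 * (meta$instrument == "B") +
    0.002 * meta$age
  cor3 <- batchCorrect(matrix(y3, 1), meta)
  refit <- fitFeatureModel(cor3, meta,
                           designSpec(~ disease + age,
                                      ref = c(disease = "Control")),
                           min_donors = 1)
  expect_equal(refit$diseaseAD_coef, 0.3, tolerance = 1e-8)
  expect_equal(refit$age_coef, 0.002, tolerance = 1e-8)
  # corrected values equal the biology-only signal exactly
  expect_equal(as.numeric(cor3),
               0.3 * (meta$disease == "AD") + 0.002 * meta$age,
               tolerance = 1e-10)
  # batch effect itself is gone once biology is adjusted for
  chk <- fitFeatureModel(cor3, meta,
                         designSpec(~ instrument + disease + age,
                                    ref = c(disease = "Control")),
                         min_donors = 1)
  expect_equal(chk$instrumentB_coef, 0, tolerance = 1e-8)
})

test_that("cutoff selection uses strict inequalities on both criteria", {
  assoc <- data.frame(
    feature = c("a", "b", "c", "d"),
    diseaseAD_coef = c(0.011, 0.5, -0.26, 0.009),
    diseaseAD_p = c(0.049, 0.05, 0.01, 0.001))
  expect_equal(selectByCutoffs(assoc, "diseaseAD", 0.05, 0.01),
               c("a", "c"))
  # PC1 mode: |beta| > 0.25
  expect_equal(selectByCutoffs(assoc, "diseaseAD", 0.05, 0.25), "c")
  expect_error(selectByCutoffs(assoc, "nosuch"), "nosuch")
})

test_that("planted effects are recovered with small bias on synthetic cohorts", {
  set.seed(13)
  meta <- lmMeta(20)
  eff <- 0.2
  bias <- replicate(20, {
    y <- eff * (meta$disease == "AD") *
      (meta$region == "TC") + rnorm(nrow(meta), 0, 0.05)
    fit <- fitFeatureModel(matrix(y, 1), meta, min_donors = 1)
    fit$`diseaseAD:regionTC_coef` - eff
  })
  expect_lt(abs(mean(bias)), 0.05 * eff)
})
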