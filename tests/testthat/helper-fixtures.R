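## Shared fixtures and independent oracles used across the suite.

## Small cohort memoized per session: 4 cells/sample keeps module tests fast.
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(cells_per_sample = 4, contacts_per_cell = 400,
                       seed = 42L)
      sim <- simulateCohort(cfg)
      cache <<- list(config = cfg, meta = sim$meta, truth = sim$truth)
    }
    cache
  }
})

## Independent binomial survival oracle: direct enumeration over the pmf.
binomSurvivalOracle <- function(m, size, prob) {
  if (m >= size) return(0)
  ks <- (m + 1):size
  sum(choose(size, ks) * prob^ks * (1 - prob)^(size - ks))
}

## Independent OLS oracle: normal equations + classical t-tests.
olsOracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(coef = as.numeric(beta),
       p = as.numeric(2 * pt(abs(tval), df, lower.tail = FALSE)))
}

## Brute-force BH step-up on a P vector without missing values.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

## Adjusted Rand index between two labelings (via mclust when available,
## else a direct contingency-table computation).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- si * sj / n
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}
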