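#' Describe an association design
#'
#' Captures the model formula and the explicit reference levels of its
#' categorical covariates. The package's association analyses all use the
#' same design: `~ Disease * Region + Age + Sex` with Control, VC and Female
#' as reference levels, so that the disease main effect is the AD-Control
#' difference in VC and the interaction terms test region-specific disease
#' effects.
#'
#' @param formula right-hand-side model formula over metadata columns, e.g.
#'   `~ disease * region + age + sex`.
#' @param ref named character vector of reference levels, e.g.
#'   `c(disease = "Control", region = "VC", sex = "Female")`.
#' @return an object of class `DesignSpec`.
#' @export
designSpec <- function(formula = ~ disease * region + age + sex,
                       ref = c(disease = "Control", region = "VC",
                               sex = "Female")) {
  structure(list(formula = formula, ref = ref), class = "DesignSpec")
}

#' @export
print.DesignSpec <- function(x, ...) {
  cat("DesignSpec:", deparse(x$formula), "\n  reference levels:",
      paste(names(x$ref), x$ref, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## Build the one-hot drop-first design matrix with explicit reference
## levels; returns list(X, complete) where `complete` marks metadata rows
## with no missing covariate.
.build_design <- function(meta, spec) {
  vars <- all.vars(spec$formula)
  missing_vars <- setdiff(vars, names(meta))
  if (length(missing_vars))
    stop("metadata lacks covariate(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  m <- meta[, vars, drop = FALSE]
  for (v in names(spec$ref)) {
    if (!v %in% vars) next
    f <- factor(m[[v]])
    if (!spec$ref[[v]] %in% levels(f))
      stop(sprintf("unknown reference level '%s' for covariate '%s'",
                   spec$ref[[v]], v), call. = FALSE)
    m[[v]] <- stats::relevel(f, ref = spec$ref[[v]])
  }
  complete <- stats::complete.cases(m)
  X <- stats::model.matrix(spec$formula, data = m[complete, , drop = FALSE])
  list(X = X, complete = complete, meta = m)
}

## OLS with classical t-tests on one response vector given a design matrix.
## Returns coef, p, rank flag.
.ols_t <- function(X, y) {
  qrx <- qr(X)
  p <- ncol(X); n <- nrow(X)
  if (qrx$rank < p) return(list(rank_deficient = TRUE))
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - p
  if (df <= 0) return(list(rank_deficient = TRUE))
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  pval[se == 0] <- 1
  names(pval) <- names(beta) <- colnames(X)
  list(rank_deficient = FALSE, coef = beta, p = pval)
}

#' Per-feature OLS association models
#'
#' Fits, for each feature (gene, bin, pixel, subgroup ratio, ...), an
#' ordinary least squares model of the feature's values on the covariates of
#' a [designSpec()] — by default `value ~ Disease x Region + Age + Sex` with
#' explicit reference levels — and reports the coefficient and two-sided
#' t-test P value of every non-intercept term, plus per-term
#' Benjamini-Hochberg Q values across features. Features observed in fewer
#' than `min_donors` unique donors, or with entirely missing values, are
#' flagged and excluded from the FDR. Observations with a missing value or
#' covariate are dropped listwise per feature. A constant response yields
#' zero coefficients and P = 1 by convention; rank-deficient designs flag
#' the feature rather than failing.
#'
#' @param values numeric matrix, features x observations (rownames =
#'   feature ids). Columns align with rows of `meta`.
#' @param meta data.frame of per-observation covariates; must contain the
#'   covariates of `spec` and (if donor filtering is wanted) `donor_col`.
#' @param spec a [designSpec()].
#' @param min_donors minimum unique donors per feature (default 5).
#' @param donor_col metadata column naming the donor (default "donor";
#'   `NULL` disables the donor filter).
#' @return data.frame with `feature`, `status`
#'   (`ok`/`skipped_min_donors`/`skipped_all_missing`/`rank_deficient`),
#'   `n_donors`, and `<term>_coef`, `<term>_p`, `<term>_q` columns.
#' @export
fitFeatureModel <- function(values, meta, spec = designSpec(),
                            min_donors = 5, donor_col = "donor") {
  stopifnot(is.matrix(values) || is.data.frame(values))
  values <- as.matrix(values)
  if (ncol(values) != nrow(meta))
    stop("columns of `values` must align with rows of `meta`", call. = FALSE)
  if (min_donors < 1) stop("min_donors must be >= 1", call. = FALSE)
  d <- .build_design(meta, spec)
  terms <- setdiff(colnames(d$X), "(Intercept)")
  nf <- nrow(values)
  feats <- rownames(values)
  if (is.null(feats)) feats <- sprintf("feature%05d", seq_len(nf))
  coefm <- pm <- matrix(NA_real_, nf, length(terms),
                        dimnames = list(feats, terms))
  status <- character(nf); nd <- integer(nf)
  comp_idx <- which(d$complete)
  for (f in seq_len(nf)) {
    y_all <- values[f, ]
    use <- comp_idx[!is.na(y_all[comp_idx])]
    if (!length(use)) {
      status[f] <- "skipped_all_missing"; nd[f] <- 0L; next
    }
    nd[f] <- if (!is.null(donor_col) && donor_col %in% names(meta))
      length(unique(meta[[donor_col]][use])) else NA_integer_
    if (!is.na(nd[f]) && nd[f] < min_donors) {
      status[f] <- "skipped_min_donors"; next
    }
    y <- y_all[use]
    if (stats::sd(y) == 0) {
      coefm[f, ] <- 0; pm[f, ] <- 1; status[f] <- "ok"; next
    }
    X <- d$X[match(use, comp_idx), , drop = FALSE]
    fit <- .ols_t(X, y)
    if (fit$rank_deficient) { status[f] <- "rank_deficient"; next }
    coefm[f, ] <- fit$coef[terms]
    pm[f, ] <- fit$p[terms]
    status[f] <- "ok"
  }
  qm <- pm
  ok <- status == "ok"
  for (j in seq_along(terms)) {
    qm[, j] <- NA_real_
    if (any(ok)) qm[ok, j] <- bhFdr(pm[ok, j])
  }
  out <- data.frame(feature = feats, status = status, n_donors = nd,
                    row.names = NULL, check.names = FALSE)
  for (j in seq_along(terms)) {
    out[[paste0(terms[j], "_coef")]] <- coefm[, j]
    out[[paste0(terms[j], "_p")]] <- pm[, j]
    out[[paste0(terms[j], "_q")]] <- qm[, j]
  }
  attr(out, "terms") <- terms
  out
}

#' Benjamini-Hochberg step-up Q values
#'
#' Standard BH FDR transform of a P-value vector; missing values are
#' propagated and excluded from the step-up.
#'
#' @param p numeric vector of P values in `[0, 1]` (NA allowed).
#' @return numeric vector of Q values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("P values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Remove a fitted batch component from per-feature values
#'
#' For each feature, fits the full OLS model
#' `value ~ batch + keep covariates` (one-hot, drop-first), computes the
#' fitted batch component `B %*% beta_batch` only, and subtracts it. All
#' non-batch variation, including the intercept, is preserved, so the values
#' are aligned to the reference batch baseline.
#'
#' @param values features x observations matrix.
#' @param meta per-observation covariates.
#' @param batch_covariate metadata column holding the batch (default
#'   "instrument").
#' @param keep_covariates covariate columns whose variation must be
#'   preserved (default donor, age, sex, region, disease where present).
#' @return corrected matrix of the same shape.
#' @export
batchCorrect <- function(values, meta, batch_covariate = "instrument",
                         keep_covariates = intersect(
                           c("age", "sex", "region", "disease", "donor"),
                           names(meta))) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(meta))
    stop("columns of `values` must align with rows of `meta`", call. = FALSE)
  if (!batch_covariate %in% names(meta))
    stop("metadata lacks batch covariate '", batch_covariate, "'",
         call. = FALSE)
  if (ncol(values) < 2) {
    warning("fewer than two observations; returning values unchanged")
    return(values)
  }
  b <- factor(meta[[batch_covariate]])
  if (nlevels(b) < 2) return(values)  # nothing to correct after drop-first
  keep_covariates <- setdiff(keep_covariates, batch_covariate)
  dat <- data.frame(.batch = b, meta[, keep_covariates, drop = FALSE])
  ## drop keep covariates that are constant (model.matrix would fail)
  for (v in keep_covariates)
    if (length(unique(dat[[v]][!is.na(dat[[v]])])) < 2) dat[[v]] <- NULL
  fml <- stats::as.formula(paste("~", paste(colnames(dat), collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  batch_cols <- grep("^\\.batch", colnames(X))
  qrx <- qr(X)
  out <- values
  for (f in seq_len(nrow(values))) {
    y <- values[f, ]
    ok <- !is.na(y)
    if (sum(ok) < 2) next
    beta <- if (all(ok)) qr.coef(qrx, y) else
      qr.coef(qr(X[ok, , drop = FALSE]), y[ok])
    bb <- beta[batch_cols]
    bb[is.na(bb)] <- 0   # aliased batch columns contribute nothing
    out[f, ok] <- y[ok] - as.numeric(
      X[ok, batch_cols, drop = FALSE] %*% bb)
  }
  out
}

#' Select features by P-value and effect-size cutoffs
#'
#' Strict inequalities, as used for calling differentially methylated genes
#' (P < 0.05 and |coef| > 0.01) and differential compartment bins
#' (P < 0.05 and |coef| > 0.25).
#'
#' @param assoc output of [fitFeatureModel()].
#' @param term model term name (a `<term>` prefix of the assoc columns).
#' @param p_max strict upper bound on the raw P value.
#' @param coef_min_abs strict lower bound on |coefficient|.
#' @return character vector of selected feature ids.
#' @export
selectByCutoffs <- function(assoc, term, p_max = 0.05, coef_min_abs = 0.01) {
  pc <- paste0(term, "_p"); cc <- paste0(term, "_coef")
  if (!all(c(pc, cc) %in% names(assoc)))
    stop("term '", term, "' not present in association table", call. = FALSE)
  sel <- !is.na(assoc[[pc]]) & assoc[[pc]] < p_max &
    abs(assoc[[cc]]) > coef_min_abs
  assoc$feature[sel]
}
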