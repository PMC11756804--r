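#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's counts are compared with
#' the per-feature geometric mean across samples (the pseudo-reference),
#' and the sample's factor is the median of those ratios over features with
#' all-positive counts. A matrix with identical columns yields factors of 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param fallback what to do when no feature is positive in every sample:
#'   `"error"` (default) or `"poscounts"` (geometric mean over the positive
#'   counts only, zero-inflated data).
#' @return numeric vector of positive factors, one per sample.
#' @export
#' @examples
#' m <- rbind(a = c(10, 20), b = c(30, 60), c = c(5, 10))
#' size_factors(m)  # c(1, 2) / sqrt(2)
size_factors <- function(counts, fallback = c("error", "poscounts")) {
  fallback <- match.arg(fallback)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("sample with all-zero counts", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (fallback == "error")
      stop(paste0("no feature has positive counts in every sample; ",
                  "rerun with fallback = \"poscounts\""), call. = FALSE)
    lgm <- apply(counts, 1L, function(x) {
      p <- x[x > 0]
      if (length(p) == 0L) return(NA_real_)
      mean(log(p))
    })
    use <- !is.na(lgm)
    lc <- log(counts[use, , drop = FALSE])
    lc[!is.finite(lc)] <- NA
    sf <- apply(lc - lgm[use], 2L, stats::median, na.rm = TRUE)
    return(exp(sf))
  }
  lgm <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(log(counts[all_pos, , drop = FALSE]) - lgm, 2L,
              stats::median)
  exp(sf)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `fdr_i = min over j with p_j >= p_i of (m * p_j / rank_j)`, capped at 1,
#' returned in input order. Delegates to [stats::p.adjust()], which
#' implements exactly this step-up rule.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

## Per-feature dispersion by method of moments on normalized counts,
## shrunk toward a fitted mean-dispersion trend a0 + a1 / mu.
## Returns list(alpha, alpha_raw, alpha_trend, trend_coef).
estimate_dispersions <- function(counts, sf, groups, df_prior = 10) {
  q <- sweep(counts, 2L, sf, "/")
  lv <- unique(groups)
  n <- ncol(counts)
  ss <- 0
  for (g in lv) {
    qa <- q[, groups == g, drop = FALSE]
    ss <- ss + rowSums((qa - rowMeans(qa))^2)
  }
  df_res <- n - length(lv)
  var_w <- ss / df_res
  mu <- rowMeans(q)
  xi <- mean(1 / sf)
  alpha_raw <- (var_w - mu * xi) / mu^2
  alpha_raw[!is.finite(alpha_raw)] <- NA_real_
  alpha_raw <- pmin(pmax(alpha_raw, 1e-8), 20)

  ## robust trend: median raw dispersion within mean-quantile bins,
  ## least-squares fit of a0 + a1/mu through the bin medians
  ok <- which(is.finite(alpha_raw) & mu > 0)
  a0 <- 1e-6; a1 <- 0
  if (length(ok) >= 20L) {
    nb <- min(20L, max(4L, floor(length(ok) / 25)))
    br <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out = nb + 1)))
    if (length(br) >= 3L) {
      bin <- cut(mu[ok], br, include.lowest = TRUE)
      bmu <- tapply(mu[ok], bin, stats::median)
      bal <- tapply(alpha_raw[ok], bin, stats::median)
      good <- is.finite(bmu) & is.finite(bal)
      if (sum(good) >= 2L) {
        fit <- stats::lm(bal[good] ~ I(1 / bmu[good]))
        a0 <- max(unname(stats::coef(fit)[1L]), 1e-6)
        a1 <- max(unname(stats::coef(fit)[2L]), 0)
      }
    }
  } else if (length(ok) > 0L) {
    a0 <- max(stats::median(alpha_raw[ok]), 1e-6)
  }
  alpha_trend <- a0 + a1 / pmax(mu, 1e-8)
  alpha <- (df_res * alpha_raw + df_prior * alpha_trend) /
    (df_res + df_prior)
  alpha[!is.finite(alpha)] <- alpha_trend[!is.finite(alpha)]
  alpha <- pmin(pmax(alpha, 1e-8), 20)
  list(alpha = alpha, alpha_raw = alpha_raw, alpha_trend = alpha_trend,
       trend_coef = c(a0 = a0, a1 = a1), df_res = df_res,
       df_prior = df_prior)
}

#' Negative-binomial Wald test, two groups
#'
#' Normalizes with median-of-ratios [size_factors()], estimates a
#' per-feature NB dispersion (`var = mu + alpha * mu^2`) by method of
#' moments shrunk toward a fitted mean-dispersion trend, and tests the
#' test-vs-control log fold change with a Wald statistic referenced to a
#' t distribution (residual + prior degrees of freedom). The reported
#' `log2fc` adds a pseudo-count of 0.5 to each group mean for display only;
#' the test statistic never uses it (except as a documented fallback when a
#' group mean is exactly zero, where no finite MLE exists).
#'
#' Features with all-zero counts are kept with `p = 1`, `fdr = 1`,
#' `log2fc = 0`, `direction = "ns"` and flag `"all_zero"`.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   feature ids as row names.
#' @param groups character/factor of length `ncol(counts)` with exactly two
#'   levels; at least two samples per group.
#' @param ref which group is the control (denominator of the fold change).
#'   Defaults to the first unique value of `groups`.
#' @param layer one of `"lncRNA"`, `"miRNA"`, `"mRNA"`; selects the
#'   direction-calling thresholds from `config`.
#' @param config a [pipeline_config()].
#' @return data.frame (one row per feature, input order): `feature_id`,
#'   `layer`, `base_mean`, `log2fc`, `p_value`, `fdr`, `direction`
#'   (`up`/`down`/`ns`), `flag`.
#' @export
nb_test <- function(counts, groups, ref = NULL,
                    layer = c("lncRNA", "miRNA", "mRNA"),
                    config = pipeline_config()) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(ref)) ref <- lv[1L]
  if (!ref %in% lv) stop("ref '", ref, "' not a group level", call. = FALSE)
  tst <- setdiff(lv, ref)

  sf <- size_factors(counts, fallback = config$sf_fallback)
  ia <- groups == ref
  ib <- groups == tst
  mu_a <- rowSums(counts[, ia, drop = FALSE]) / sum(sf[ia])
  mu_b <- rowSums(counts[, ib, drop = FALSE]) / sum(sf[ib])
  base_mean <- rowMeans(sweep(counts, 2L, sf, "/"))

  disp <- estimate_dispersions(counts, sf, groups)
  alpha <- disp$alpha

  all_zero <- rowSums(counts) == 0
  zero_grp <- (mu_a == 0 | mu_b == 0) & !all_zero

  ## fallback for a zero group mean: pretend half a count was seen there
  eps_a <- 0.5 / sum(sf[ia])
  eps_b <- 0.5 / sum(sf[ib])
  mu_a_t <- ifelse(mu_a == 0, eps_a, mu_a)
  mu_b_t <- ifelse(mu_b == 0, eps_b, mu_b)

  fisher_info <- function(mu, s) {
    ## I = sum_j s_j * mu / (1 + alpha * s_j * mu), per feature
    num <- outer(mu, s)
    rowSums(num / (1 + sweep(num, 1L, alpha, "*")))
  }
  ia_info <- fisher_info(mu_a_t, sf[ia])
  ib_info <- fisher_info(mu_b_t, sf[ib])
  se <- sqrt(1 / ia_info + 1 / ib_info)
  stat <- log(mu_b_t / mu_a_t) / se
  df_t <- disp$df_res + disp$df_prior
  p <- 2 * stats::pt(-abs(stat), df = df_t)
  p[all_zero] <- 1

  log2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  log2fc[all_zero] <- 0

  res <- data.frame(
    feature_id = rownames(counts),
    layer = layer,
    base_mean = unname(base_mean),
    log2fc = unname(log2fc),
    p_value = unname(p),
    fdr = bh_adjust(unname(p)),
    stringsAsFactors = FALSE
  )
  res$flag <- ifelse(all_zero, "all_zero",
                     ifelse(zero_grp, "zero_group", ""))
  res <- classify_direction(res, layer = layer, config = config)$records
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- disp
  res
}

layer_thresholds <- function(layer, config) {
  switch(layer,
    lncRNA = list(lfc = config$lnc_lfc, lfc_strict = FALSE,
                  fdr = config$lnc_fdr, p = config$lnc_p),
    miRNA = list(lfc = config$mirna_lfc, lfc_strict = TRUE,
                 fdr = config$mirna_fdr, p = NA_real_),
    mRNA = list(lfc = config$mrna_lfc, lfc_strict = TRUE,
                fdr = config$mrna_fdr, p = NA_real_),
    stop("unknown layer: ", layer, call. = FALSE))
}

#' Call differential-expression direction
#'
#' Applies the layer's thresholds (see [pipeline_config()]) to a table of
#' test results: `up` if `log2fc` clears the positive threshold and all
#' significance gates pass, `down` for the negative threshold, `ns`
#' otherwise.
#'
#' @param records data.frame with columns `log2fc`, `p_value`, `fdr`
#'   (single layer).
#' @param layer `"lncRNA"`, `"miRNA"` or `"mRNA"`.
#' @param config a [pipeline_config()].
#' @return list with `records` (input plus/overwriting `direction`),
#'   `n_up`, `n_down`.
#' @export
classify_direction <- function(records, layer = c("lncRNA", "miRNA",
                                                  "mRNA"),
                               config = pipeline_config()) {
  layer <- match.arg(layer)
  th <- layer_thresholds(layer, config)
  if (nrow(records) == 0L) {
    records$direction <- character(0)
    return(list(records = records, n_up = 0L, n_down = 0L))
  }
  lfc_pass <- if (th$lfc_strict) abs(records$log2fc) > th$lfc
              else abs(records$log2fc) >= th$lfc
  sig <- records$fdr < th$fdr
  if (!is.na(th$p)) sig <- sig & records$p_value < th$p
  de <- lfc_pass & sig
  records$direction <- ifelse(de & records$log2fc > 0, "up",
                              ifelse(de & records$log2fc < 0, "down",
                                     "ns"))
  list(records = records,
       n_up = sum(records$direction == "up"),
       n_down = sum(records$direction == "down"))
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt(test) - dCt(control)`; returns `2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl finite
#'   cycle-threshold values (vectors recycle as usual).
#' @return relative expression of the target in test vs control.
#' @export
#' @examples
#' ddct(20, 18, 24, 18)  # 16
ddct <- function(ct_target_test, ct_ref_test, ct_target_ctrl,
                 ct_ref_ctrl) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  dct_test <- ct_target_test - ct_ref_test
  dct_ctrl <- ct_target_ctrl - ct_ref_ctrl
  2^-(dct_test - dct_ctrl)
}
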