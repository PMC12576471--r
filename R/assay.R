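# Quantification of the fast-track nitrification-inhibition bioassay:
# nitrite calibration, AOI%, EC50 fitting, and the strain/domain/origin
# comparison statistics.

#' Calibrate nitrite concentration from absorbance
#'
#' Ordinary least-squares line through (absorbance, concentration)
#' standards, then inverse prediction for the samples. Negative predictions
#' (absorbance below the blank) are clipped to 0 with a warning.
#'
#' @param absorbance sample absorbances (AU).
#' @param standards data.frame with columns `absorbance`, `concentration`
#'   (>= 3 rows).
#' @return Predicted nitrite concentrations (same units as standards).
#' @export
nitrite_from_absorbance <- function(absorbance, standards) {
  if (nrow(standards) < 3) stop("need at least 3 calibration standards")
  if (stats::var(standards$absorbance) == 0)
    stop("calibration standards have zero absorbance variance")
  fit <- stats::lm(concentration ~ absorbance, data = standards)
  pred <- unname(stats::predict(fit, data.frame(absorbance = absorbance)))
  if (any(pred < 0)) {
    warning("absorbance below blank: negative predictions clipped to 0")
    pred <- pmax(pred, 0)
  }
  pred
}

#' Single-timepoint ammonia oxidation inhibition percentage
#'
#' `AOI% = (1 - mean(treated) / mean(control)) * 100`. Values above the
#' control give negative AOI (growth stimulation), which is preserved.
#'
#' @param treated nitrite values under the inhibitor.
#' @param control nitrite values of the untreated control (mean must be
#'   positive).
#' @param replicate_level if `TRUE`, return one AOI per treated replicate
#'   (each against the control mean) instead of the mean AOI.
#' @return AOI percentage (scalar, or vector if `replicate_level`).
#' @export
aoi_single_timepoint <- function(treated, control, replicate_level = FALSE) {
  cm <- mean(control)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean nitrite must be positive")
  if (replicate_level) (1 - treated / cm) * 100
  else (1 - mean(treated) / cm) * 100
}

#' Slope-based AOI% for linear nitrite kinetics
#'
#' For each concentration, fits nitrite ~ time by least squares and forms
#' `AOI%_c = (1 - slope_c / slope_0) * 100` against the zero-concentration
#' control slope.
#'
#' @param series a `"dose_response"` data.frame (columns `concentration`,
#'   `timepoint`, `replicate`, `nitrite`) including concentration 0.
#' @return A data.frame (`concentration`, `slope`, `aoi`) for the nonzero
#'   concentrations.
#' @export
aoi_slope_based <- function(series) {
  conc <- sort(unique(series$concentration))
  if (!0 %in% conc) stop("series must include a concentration-0 control")
  slopes <- vapply(conc, function(cc) {
    sub <- series[series$concentration == cc, ]
    if (length(unique(sub$timepoint)) < 3)
      stop("need >= 3 timepoints per concentration")
    unname(stats::coef(stats::lm(nitrite ~ timepoint, data = sub))[2])
  }, numeric(1))
  s0 <- slopes[conc == 0]
  if (s0 <= 0) stop("control slope <= 0: inactive culture")
  keep <- conc != 0
  data.frame(concentration = conc[keep], slope = slopes[keep],
             aoi = (1 - slopes[keep] / s0) * 100)
}

#' Fit an EC50 from (concentration, AOI%) pairs
#'
#' Fits the four-parameter logistic
#' `AOI(c) = bottom + (top - bottom) / (1 + (ec50/c)^h)` by bounded
#' nonlinear least squares (bottom in \[-40, 20\], top in \[60, 110\]),
#' from a small multi-start grid, and reports the concentration where the
#' fitted curve crosses 50% inhibition. If the fit fails or does not cross
#' 50%, falls back to log-linear interpolation between the doses bracketing
#' 50%.
#'
#' @param conc concentrations (uM), > 0, >= 4 distinct values.
#' @param aoi AOI% at each concentration.
#' @return A `"dose_response_fit"` list: `model`, `ec50`, `hill`, `bottom`,
#'   `top`, `residual_sse`, `converged`, `extrapolated` (no AOI on both
#'   sides of 50%).
#' @export
fit_ec50 <- function(conc, aoi) {
  if (length(conc) != length(aoi)) stop("conc and aoi lengths differ")
  keep <- conc > 0
  conc <- conc[keep]; aoi <- aoi[keep]
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct nonzero concentrations")
  extrapolated <- !(any(aoi < 50) && any(aoi > 50))
  if (max(aoi) <= 0 || stats::var(aoi) == 0) {
    if (all(abs(aoi - 50) > 1e-9) && extrapolated)
      stop("EC50 not estimable: response never approaches 50%")
  }

  lc <- log10(conc)
  resid_fn <- function(par) {
    aoi - (par[1] + (par[2] - par[1]) / (1 + 10^((par[3] - lc) * par[4])))
  }
  lower <- c(-40, 60, min(lc) - 3, 0.1)
  upper <- c(20, 110, max(lc) + 3, 10)
  best <- NULL
  starts <- expand.grid(le = unname(stats::quantile(lc, c(0.25, 0.5, 0.75))),
                        h = c(0.8, 1.5))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(bottom = 0, top = 100, le = starts$le[i], h = starts$h[i]),
        lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(resid_fn(fit$par)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse)
    }
  }

  if (!is.null(best)) {
    cf <- as.list(best$fit$par)
    # concentration where the fitted curve equals AOI = 50
    if (cf[["bottom"]] < 50 && cf[["top"]] > 50) {
      frac <- (50 - cf[["bottom"]]) / (cf[["top"]] - cf[["bottom"]])
      ec50 <- 10^(cf[["le"]] - log10(1 / frac - 1) / cf[["h"]])
      return(structure(list(model = "four_param_logistic", ec50 = ec50,
                            hill = cf[["h"]], bottom = cf[["bottom"]],
                            top = cf[["top"]], residual_sse = best$sse,
                            converged = TRUE, extrapolated = extrapolated),
                       class = "dose_response_fit"))
    }
  }

  # fallback: log-linear interpolation between doses bracketing 50%
  ord <- order(conc)
  co <- conc[ord]; ao <- aoi[ord]
  lo <- which(ao < 50); hi <- which(ao > 50)
  if (!length(lo) || !length(hi))
    stop("EC50 not estimable: no bracketing pair around 50% inhibition")
  i <- max(lo[lo < max(hi)]); j <- min(hi[hi > i])
  lec <- log10(co[i]) + (50 - ao[i]) / (ao[j] - ao[i]) *
    (log10(co[j]) - log10(co[i]))
  structure(list(model = "slope_interpolation", ec50 = 10^lec, hill = NA,
                 bottom = NA, top = NA, residual_sse = NA,
                 converged = FALSE, extrapolated = extrapolated),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s: EC50 = %.4g (hill = %.3g)\n",
              x$model, x$ec50, x$hill))
  invisible(x)
}

#' Compare AOI% distributions across strains, domains or origins
#'
#' Two groups: two-sided Wilcoxon rank-sum test; the reported `W` is the
#' rank-sum of the first-listed group (the Mann-Whitney `U` is also
#' returned). More than two groups: Kruskal-Wallis test with tie
#' correction, plus Dunn's pairwise z-tests with Bonferroni adjustment and
#' a compact letter display (groups sharing a letter do not differ at
#' `alpha`).
#'
#' @param inh an `"inhibition_matrix"`.
#' @param grouping `"strain"`, `"domain"`, or `"origin"`.
#' @param genotype_meta data.frame with `genotype`, `origin` (needed for
#'   `grouping = "origin"`).
#' @param level `"replicate"` (default) or `"mean"` AOI values.
#' @param alpha significance level for the letter display (default 0.05).
#' @return A `"bni_stat_test"` list: `test`, `statistic`, `p_value`,
#'   `groups`, and for > 2 groups `pairwise` (Dunn table) and `letters`.
#' @export
compare_strains <- function(inh, grouping = c("strain", "domain", "origin"),
                            genotype_meta = NULL,
                            level = c("replicate", "mean"), alpha = 0.05) {
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  if (level == "replicate") {
    vals <- inh$replicates$aoi
    strain <- inh$replicates$strain
    genotype <- inh$replicates$genotype
  } else {
    vals <- as.vector(inh$aoi)
    strain <- rep(colnames(inh$aoi), each = nrow(inh$aoi))
    genotype <- rep(rownames(inh$aoi), ncol(inh$aoi))
  }
  g <- switch(grouping,
    strain = strain,
    domain = {
      if (is.null(inh$strains)) stop("no strain -> domain map on object")
      unname(inh$strains[strain])
    },
    origin = {
      if (is.null(genotype_meta)) stop("genotype_meta required for origin")
      genotype_meta$origin[match(genotype, genotype_meta$genotype)]
    })
  g <- factor(g)
  if (any(table(g) < 3)) stop("every group needs >= 3 values")
  if (nlevels(g) < 2) stop("need >= 2 groups")

  if (nlevels(g) == 2L) {
    x <- vals[g == levels(g)[1]]; y <- vals[g == levels(g)[2]]
    r <- rank(c(x, y))
    W <- sum(r[seq_along(x)])
    U <- W - length(x) * (length(x) + 1) / 2
    p <- .wilcox_p(x, y)
    return(structure(list(test = "wilcoxon_rank_sum", statistic = W,
                          U = U, p_value = p, groups = levels(g)),
                     class = "bni_stat_test"))
  }

  kw <- stats::kruskal.test(vals, g)
  dunn <- dunn_test(vals, g)
  letters <- letter_display(dunn, levels(g), alpha = alpha)
  structure(list(test = "kruskal_wallis", statistic = unname(kw$statistic),
                 p_value = kw$p.value, groups = levels(g),
                 pairwise = dunn, letters = letters),
            class = "bni_stat_test")
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction; p-values are two-sided and Bonferroni-adjusted
#' over all pairs.
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @return A data.frame (`group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  r <- rank(x)
  n <- length(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  combs <- utils::combn(levels(g), 2)
  z <- apply(combs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    (mr[[pr[1]]] - mr[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
             p_value = p,
             p_adjusted = pmin(1, p * ncol(combs)),
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`; groups sharing no letter are.
#'
#' @param pairwise data.frame with `group1`, `group2`, `p_adjusted`.
#' @param groups character vector of all group names.
#' @param alpha significance level.
#' @return Named character vector of letter strings per group.
#' @export
letter_display <- function(pairwise, groups, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[i]; b <- pairwise$group2[i]
    sig[a, b] <- sig[b, a] <- pairwise$p_adjusted[i] < alpha
  }
  # letters = maximal sets of mutually non-different groups
  sets <- list(groups[1])
  for (gi in groups[-1]) {
    placed <- FALSE
    for (j in seq_along(sets)) {
      if (!any(sig[gi, sets[[j]]])) {
        sets[[j]] <- c(sets[[j]], gi); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gi
    # absorb: drop sets that are subsets of another
    keep <- rep(TRUE, length(sets))
    for (u in seq_along(sets)) for (v in seq_along(sets)) {
      if (u != v && keep[u] && keep[v] && all(sets[[u]] %in% sets[[v]]))
        keep[u] <- FALSE
    }
    sets <- sets[keep]
  }
  out <- stats::setNames(rep("", k), groups)
  for (j in seq_along(sets))
    out[sets[[j]]] <- paste0(out[sets[[j]]], letters[j])
  out
}

#' Hierarchical clustering of the mean AOI matrix
#'
#' Agglomerative clustering of genotypes (rows) and strains (columns) on
#' Euclidean distances. Leaf order is made deterministic by reordering each
#' dendrogram against the row/column ids.
#'
#' @param inh an `"inhibition_matrix"`.
#' @param method linkage (default `"complete"`).
#' @param impute mean-impute missing AOI cells (default `FALSE`: error).
#' @return A list with `row_hclust`, `col_hclust`, `row_order`,
#'   `col_order` (leaf id orders).
#' @export
cluster_inhibition <- function(inh, method = "complete", impute = FALSE) {
  m <- inh$aoi
  if (anyNA(m)) {
    if (!impute) stop("missing AOI values (set impute = TRUE to mean-impute)")
    mu <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  }
  hr <- stats::hclust(stats::dist(m), method = method)
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  # deterministic leaf order: tie-break by id rank
  hr <- stats::as.hclust(stats::reorder(stats::as.dendrogram(hr),
                                        rank(rownames(m)), agglo.FUN = mean))
  hc <- stats::as.hclust(stats::reorder(stats::as.dendrogram(hc),
                                        rank(colnames(m)), agglo.FUN = mean))
  list(row_hclust = hr, col_hclust = hc,
       row_order = rownames(m)[hr$order],
       col_order = colnames(m)[hc$order])
}
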