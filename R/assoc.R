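# Metabolite-by-metabolite Spearman screening of abundances against
# per-strain inhibition activity.

#' Default per-strain correlation thresholds
#'
#' Positive cutoff 0.40 for every strain; negative cutoffs are
#' strain-specific (-0.45 for NF and NM, -0.40 for NV and NU), with
#' significance at raw p <= 0.05.
#'
#' @param strains character vector of strain ids.
#' @return A data.frame (`strain`, `r_pos`, `r_neg`, `alpha`).
#' @export
default_thresholds <- function(strains = c("NF", "NV", "NM", "NU")) {
  neg <- ifelse(strains %in% c("NF", "NM"), -0.45, -0.40)
  data.frame(strain = strains, r_pos = 0.40, r_neg = neg, alpha = 0.05,
             stringsAsFactors = FALSE)
}

#' Spearman screen of metabolites against per-strain AOI%
#'
#' For every (metabolite, strain) pair, Spearman's rho is computed as the
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom. Metabolites are flagged
#' `positive` when `rho >= r_pos` and `p <= alpha`, `negative` when
#' `rho <= r_neg` and `p <= alpha`, else `ns`. No multiple-testing
#' correction enters the flags (the screen thresholds on raw p plus an
#' effect-size cut); a Benjamini-Hochberg column is emitted alongside for
#' transparency.
#'
#' @param a an `"abundance_matrix"`.
#' @param inh an `"inhibition_matrix"` sharing genotype ids.
#' @param thresholds data.frame as from [default_thresholds()].
#' @return A `"correlation_table"` data.frame: `metabolite`,
#'   `chemical_class`, `strain`, `rho`, `p_value`, `p_bh`, `n`, `flag`.
#' @export
spearman_screen <- function(a, inh, thresholds = NULL) {
  shared <- intersect(rownames(a$values), rownames(inh$aoi))
  if (length(shared) < 5) stop("need >= 5 shared genotypes")
  if (is.null(thresholds)) thresholds <- default_thresholds(colnames(inh$aoi))
  x <- a$values[shared, , drop = FALSE]
  y <- inh$aoi[shared, , drop = FALSE]
  n <- length(shared)

  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning("constant metabolite column(s) flagged ns: ",
            paste(colnames(x)[const], collapse = ", "))
  rx <- apply(x, 2, rank)
  ry <- apply(y, 2, rank)
  rho <- suppressWarnings(stats::cor(rx, ry))  # metabolite x strain
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0

  out <- do.call(rbind, lapply(colnames(y), function(s) {
    th <- thresholds[thresholds$strain == s, ]
    if (nrow(th) == 0) th <- data.frame(r_pos = 0.40, r_neg = -0.40,
                                        alpha = 0.05)
    r <- rho[, s]; pv <- p[, s]
    flag <- rep("ns", length(r))
    flag[!is.na(r) & r >= th$r_pos & pv <= th$alpha] <- "positive"
    flag[!is.na(r) & r <= th$r_neg & pv <= th$alpha] <- "negative"
    flag[const | is.na(r)] <- "ns"
    data.frame(metabolite = colnames(x),
               chemical_class = a$metabolite_meta$chemical_class[
                 match(colnames(x), a$metabolite_meta$metabolite)],
               strain = s, rho = unname(r), p_value = unname(pv),
               p_bh = stats::p.adjust(pv, "BH"), n = n, flag = flag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Long table for correlation scatter plots of the top metabolites
#'
#' For the `top_k` significant metabolites of a strain (largest |rho|
#' among non-`ns` flags), returns per-genotype rows of abundance, AOI% and
#' origin, ready for plotting.
#'
#' @param ct a `"correlation_table"` from [spearman_screen()].
#' @param a the `"abundance_matrix"` used for the screen.
#' @param inh the `"inhibition_matrix"` used for the screen.
#' @param strain strain id to extract.
#' @param top_k number of metabolites (default 9). If fewer are
#'   significant, all are returned with a `note` attribute.
#' @return A data.frame (`metabolite`, `genotype`, `origin`, `abundance`,
#'   `aoi`, `rho`).
#' @export
correlation_scatter_table <- function(ct, a, inh, strain, top_k = 9) {
  sub <- ct[ct$strain == strain & ct$flag != "ns", ]
  sub <- sub[order(-abs(sub$rho)), ]
  note <- NULL
  if (nrow(sub) < top_k && nrow(sub) > 0)
    note <- sprintf("only %d significant metabolites available", nrow(sub))
  sel <- utils::head(sub$metabolite, top_k)
  if (!length(sel)) {
    out <- data.frame(metabolite = character(0), genotype = character(0),
                      origin = character(0), abundance = numeric(0),
                      aoi = numeric(0), rho = numeric(0))
    return(out)
  }
  shared <- intersect(rownames(a$values), rownames(inh$aoi))
  out <- do.call(rbind, lapply(sel, function(m) {
    data.frame(metabolite = m, genotype = shared,
               origin = a$genotype_meta$origin[
                 match(shared, a$genotype_meta$genotype)],
               abundance = a$values[shared, m],
               aoi = inh$aoi[shared, strain],
               rho = sub$rho[match(m, sub$metabolite)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "note") <- note
  out
}
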