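# Normalizations, transforms, group contrasts, ordination and class
# aggregation applied to abundance tables before association analysis.

#' Weight-normalize and log10-transform a GC-MS abundance table
#'
#' Each genotype's intensities are divided by its root dry weight, then
#' log10(x + 1) transformed; exact zeros therefore stay zero.
#'
#' @param a an `"abundance_matrix"`.
#' @return The transformed `"abundance_matrix"`.
#' @export
normalize_gcms <- function(a) {
  w <- a$genotype_meta$root_dry_weight
  if (is.null(w) || anyNA(w)) {
    missing <- a$genotype_meta$genotype[is.na(w)]
    stop("missing root dry weight for genotype(s): ",
         paste(missing, collapse = ", "))
  }
  a$values <- log10(sweep(a$values, 1, w, `/`) + 1)
  a
}

#' Abundance-balance an LC-MS peak-area table
#'
#' Sample-centric scaling: each genotype row is divided by its total
#' intensity and multiplied by the mean total intensity across genotypes,
#' so every row sum becomes the grand mean of the original row sums and
#' the total matrix intensity is conserved.
#'
#' @param a an `"abundance_matrix"`.
#' @return The balanced `"abundance_matrix"`.
#' @export
abundance_balance <- function(a) {
  rs <- rowSums(a$values)
  if (any(rs == 0)) {
    stop("all-zero abundance row for genotype(s): ",
         paste(rownames(a$values)[rs == 0], collapse = ", "))
  }
  a$values <- sweep(a$values, 1, rs, `/`) * mean(rs)
  a
}

#' Volcano contrast between the two origin groups
#'
#' For each metabolite, the signed fold change between origin group means
#' (positive when enriched in group A: `FC = mA/mB` if `mA >= mB`, else
#' `-(mB/mA)`) and a two-sided Wilcoxon rank-sum p-value. Metabolites with
#' `|FC| >= fc_cut` and `p <= p_cut` are categorized `up_A`/`up_B`, the
#' rest `ns`.
#'
#' @param a an `"abundance_matrix"` with exactly two origin groups.
#' @param fc_cut fold-change threshold (default 2).
#' @param p_cut p-value threshold (default 0.01).
#' @return A data.frame (`metabolite`, `mean_A`, `mean_B`,
#'   `signed_fold_change`, `p_value`, `category`).
#' @export
volcano <- function(a, fc_cut = 2, p_cut = 0.01) {
  origin <- a$genotype_meta$origin
  grp <- sort(unique(origin))
  if (length(grp) != 2L) stop("volcano requires exactly two origin groups")
  in_a <- origin == grp[1]
  if (sum(in_a) < 2 || sum(!in_a) < 2)
    stop("each origin group needs at least 2 genotypes")
  m_a <- colMeans(a$values[in_a, , drop = FALSE])
  m_b <- colMeans(a$values[!in_a, , drop = FALSE])
  fc <- ifelse(m_a >= m_b,
               ifelse(m_b == 0, Inf, m_a / m_b),
               -ifelse(m_a == 0, Inf, m_b / m_a))
  fc[m_a == 0 & m_b == 0] <- 1
  p <- apply(a$values, 2, function(v) {
    if (all(v == v[1])) return(1)  # constant feature: no evidence
    .wilcox_p(v[in_a], v[!in_a])
  })
  category <- rep("ns", length(fc))
  category[fc >= fc_cut & p <= p_cut] <- "up_A"
  category[fc <= -fc_cut & p <= p_cut] <- "up_B"
  data.frame(metabolite = colnames(a$values), mean_A = m_a, mean_B = m_b,
             signed_fold_change = fc, p_value = p, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided Wilcoxon rank-sum p; exact enumeration for small tie-free
# groups, normal approximation with tie and continuity correction otherwise.
.wilcox_p <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Presence/absence Venn membership of features across two origins
#'
#' A feature is "present" in a group when nonzero in at least
#' `presence_fraction` of that group's genotypes.
#'
#' @param a an `"abundance_matrix"` with two origin groups.
#' @param presence_fraction fraction in (0, 1] (default 0.5).
#' @return A data.frame (`metabolite`, `present_A`, `present_B`,
#'   `membership` in `A_only`/`B_only`/`shared`/`absent`).
#' @export
venn_membership <- function(a, presence_fraction = 0.5) {
  if (presence_fraction <= 0 || presence_fraction > 1)
    stop("presence_fraction must be in (0, 1]")
  origin <- a$genotype_meta$origin
  grp <- sort(unique(origin))
  if (length(grp) != 2L) stop("venn_membership requires two origin groups")
  pres <- function(rows) {
    colMeans(a$values[rows, , drop = FALSE] > 0) >= presence_fraction
  }
  p_a <- pres(origin == grp[1]); p_b <- pres(origin == grp[2])
  membership <- ifelse(p_a & p_b, "shared",
                ifelse(p_a, "A_only", ifelse(p_b, "B_only", "absent")))
  data.frame(metabolite = colnames(a$values), present_A = p_a,
             present_B = p_b, membership = membership,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal component analysis of an abundance matrix
#'
#' Centered (optionally unit-variance scaled) PCA via singular value
#' decomposition.
#'
#' @param a an `"abundance_matrix"`.
#' @param scale scale metabolites to unit variance (default `FALSE`;
#'   constant columns are dropped before scaling).
#' @param n_components number of components to keep (default all).
#' @return A `"bni_pca"` list: `scores` (genotype x component), `loadings`
#'   (metabolite x component, orthonormal), `variance_explained`
#'   (fractions, non-increasing).
#' @export
pca_ordination <- function(a, scale = FALSE, n_components = NULL) {
  x <- a$values
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs >= 2 genotypes and metabolites")
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) stop("constant abundance matrix: PCA undefined")
  if (scale) x <- x[, v > 0, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- if (is.null(n_components)) length(ve) else min(n_components, length(ve))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 variance_explained = ve[seq_len(k)],
                 center = p$center, scale = p$scale),
            class = "bni_pca")
}

#' Chemical-class mean profile, scaled by the sum across genotypes
#'
#' Averages metabolites within each chemical class per genotype, then
#' scales every class row to sum to 1 across genotypes.
#'
#' @param a an `"abundance_matrix"`; metabolites without a class label are
#'   pooled into `"other"` with a warning.
#' @return A class x genotype matrix whose rows sum to 1.
#' @export
aggregate_by_class <- function(a) {
  cls <- a$metabolite_meta$chemical_class
  if (anyNA(cls) || any(!nzchar(cls))) {
    warning("unlabeled metabolites assigned to class 'other'")
    cls[is.na(cls) | !nzchar(cls)] <- "other"
  }
  means <- t(rowsum(t(a$values), cls) / as.vector(table(cls)[sort(unique(cls))]))
  prof <- t(means)  # class x genotype
  sweep(prof, 1, rowSums(prof), `/`)
}

#' Rank genotypes into inhibition quartiles
#'
#' Genotypes are ranked by mean AOI% across strains and split into four
#' near-equal groups, Q1 holding the highest inhibition. Ties are broken by
#' genotype id (lexicographic), which makes the assignment deterministic.
#'
#' @param inh an `"inhibition_matrix"`.
#' @return A named factor (levels Q1..Q4) of quartile labels per genotype.
#' @export
quartiles_by_inhibition <- function(inh) {
  means <- rowMeans(inh$aoi)
  n <- length(means)
  if (n < 4) stop("quartile assignment needs >= 4 genotypes")
  ord <- order(-means, names(means))
  sizes <- diff(floor(seq(0, n, length.out = 5)))
  q <- factor(rep(paste0("Q", 1:4), sizes), levels = paste0("Q", 1:4))
  out <- q[order(ord)]
  names(out) <- names(means)
  out
}
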