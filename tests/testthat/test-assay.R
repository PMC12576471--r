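# Bioassay quantification: calibration, AOI%, EC50 fitting, comparison
# statistics and clustering.

test_that("nitrite calibration inverts the standard curve", {
  # calibration line with a positive blank: conc = 100 * A - 2
  std <- data.frame(absorbance = c(0.05, 0.1, 0.2, 0.4),
                    concentration = c(3, 8, 18, 38))
  expect_equal(nitrite_from_absorbance(c(0.1, 0.25), std), c(8, 23),
               tolerance = 1e-9)
  expect_warning(out <- nitrite_from_absorbance(0.001, std), "blank")
  expect_identical(out, 0)
  expect_error(nitrite_from_absorbance(0.1, std[1:2, ]), "3")
  std0 <- data.frame(absorbance = rep(0.1, 4), concentration = 1:4)
  expect_error(nitrite_from_absorbance(0.1, std0), "variance")
})

test_that("single-timepoint AOI identities and unit invariance hold", {
  ctrl <- c(10, 12, 11)
  expect_equal(aoi_single_timepoint(ctrl, ctrl), 0)
  expect_equal(aoi_single_timepoint(c(0, 0, 0), ctrl), 100)
  expect_equal(aoi_single_timepoint(ctrl * 1.5, ctrl), -50)
  # rescaling nitrite units (uM -> mM) leaves AOI unchanged
  tr <- c(4, 5, 6)
  expect_equal(aoi_single_timepoint(tr, ctrl),
               aoi_single_timepoint(tr / 1000, ctrl / 1000))
  expect_equal(aoi_single_timepoint(tr, ctrl, replicate_level = TRUE),
               (1 - tr / mean(ctrl)) * 100)
  expect_error(aoi_single_timepoint(tr, c(0, 0)), "positive")
})

test_that("slope-based AOI recovers simulated rate ratios", {
  sr <- simulate_doseresponse(ec50 = 1, hill = 1, top = 10, n_conc = 6,
                              noise_cv = 0, kinetics = "linear")
  out <- aoi_slope_based(sr)
  # the linear kinetics law gives AOI = 50 * c / ec50 capped at 100
  expect_equal(out$aoi, pmin(100, 50 * out$concentration), tolerance = 1e-9)
  # equal slopes -> 0%; halved slope -> 50%
  tp <- c(0, 2, 4, 6)
  flat <- data.frame(concentration = rep(c(0, 1), each = 4),
                     timepoint = rep(tp, 2), replicate = 1,
                     nitrite = c(2 * tp, 2 * tp))
  expect_equal(aoi_slope_based(flat)$aoi, 0)
  half <- flat; half$nitrite[5:8] <- tp
  expect_equal(aoi_slope_based(half)$aoi, 50)
  dead <- flat; dead$nitrite[1:4] <- 0
  expect_error(aoi_slope_based(dead), "control slope")
})

test_that("EC50 fitting recovers noise-free curves and falls back to
          interpolation", {
  for (h in c(0.8, 1, 2)) {
    sr <- simulate_doseresponse(ec50 = 1.5, hill = h, top = 10,
                                n_conc = 8, noise_cv = 0)
    aoi <- aoi_slope_based(sr)
    fit <- fit_ec50(aoi$concentration, aoi$aoi)
    expect_true(fit$converged)
    expect_lt(abs(fit$ec50 - 1.5) / 1.5, 0.01)
    expect_equal(fit$hill, h, tolerance = 0.02)
  }
  expect_error(fit_ec50(c(0.1, 1, 10, 100), rep(0, 4)), "not estimable")
  # bracketing pair: estimate must land between the bracketing doses
  fit <- fit_ec50(c(0.1, 0.5, 2, 10), c(20, 40, 60, 75))
  expect_gt(fit$ec50, 0.5); expect_lt(fit$ec50, 2)
  expect_error(fit_ec50(c(1, 2, 4), c(10, 20, 30)), "4 distinct")
})

test_that("two-group comparison reports the rank-sum W convention", {
  reps <- data.frame(
    genotype = rep(paste0("g", 1:5), 2),
    strain = rep(c("NF", "NM"), each = 5),
    replicate = 1L,
    aoi = c(11, 12, 13, 14, 15, 1, 2, 3, 4, 5))
  inh <- inhibition_matrix(reps, strains = c(NF = "AOA", NM = "AOB"))
  res <- compare_strains(inh, "strain")
  expect_identical(res$test, "wilcoxon_rank_sum")
  # complete separation, first group (NF) holds the larger ranks
  expect_equal(res$statistic, 40)
  expect_equal(res$U, 25)
  expect_equal(res$p_value, oracle_wilcox_exact_p(reps$aoi[1:5],
                                                  reps$aoi[6:10]),
               tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
})

test_that("Kruskal-Wallis grouping letters agree with Dunn-Bonferroni", {
  set.seed(8)
  reps <- data.frame(
    genotype = rep(paste0("g", 1:12), 4),
    strain = rep(c("NF", "NV", "NM", "NU"), each = 12),
    replicate = 1L,
    aoi = c(rnorm(12, 60, 4), rnorm(12, 58, 4),
            rnorm(12, 20, 4), rnorm(12, 5, 4)))
  inh <- inhibition_matrix(reps, strains = c(NF = "AOA", NV = "AOA",
                                             NM = "AOB", NU = "AOB"))
  res <- compare_strains(inh, "strain")
  expect_identical(res$test, "kruskal_wallis")
  expect_equal(res$statistic,
               oracle_kruskal_H(reps$aoi, reps$strain), tolerance = 1e-12)
  # adjusted never below raw
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_value - 1e-15))
  # letters consistent with pairwise significance at alpha = 0.05
  for (i in seq_len(nrow(res$pairwise))) {
    shared <- length(intersect(
      strsplit(res$letters[[res$pairwise$group1[i]]], "")[[1]],
      strsplit(res$letters[[res$pairwise$group2[i]]], "")[[1]])) > 0
    expect_identical(shared, res$pairwise$p_adjusted[i] >= 0.05)
  }
  # identical distributions in every group -> H = 0
  reps0 <- reps; reps0$aoi <- rep(c(1, 2, 3), 16)
  inh0 <- inhibition_matrix(reps0)
  expect_equal(compare_strains(inh0, "strain")$statistic, 0,
               tolerance = 1e-12)
  # domain and origin groupings run end to end
  expect_identical(compare_strains(inh, "domain")$test,
                   "wilcoxon_rank_sum")
  gm <- data.frame(genotype = paste0("g", 1:12),
                   origin = rep(c("A", "B"), 6))
  expect_identical(compare_strains(inh, "origin",
                                   genotype_meta = gm)$test,
                   "wilcoxon_rank_sum")
})

test_that("inhibition clustering is deterministic with sane dendrograms", {
  set.seed(9)
  m <- matrix(rnorm(28, 50, 10), 7, 4,
              dimnames = list(paste0("g", 1:7), c("NF", "NV", "NM", "NU")))
  m[2, ] <- m[1, ]  # identical pair merges first at height 0
  reps <- data.frame(genotype = rep(rownames(m), 4),
                     strain = rep(colnames(m), each = 7),
                     replicate = 1L, aoi = as.vector(m))
  inh <- inhibition_matrix(reps)
  cl <- cluster_inhibition(inh)
  expect_equal(min(cl$row_hclust$height), 0, tolerance = 1e-12)
  expect_true(all(diff(cl$row_hclust$height) >= -1e-12))
  expect_identical(cl$row_order, cluster_inhibition(inh)$row_order)
  inh_na <- inh; inh_na$aoi[3, 2] <- NA
  expect_error(cluster_inhibition(inh_na), "impute")
  expect_silent(cluster_inhibition(inh_na, impute = TRUE))
})
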