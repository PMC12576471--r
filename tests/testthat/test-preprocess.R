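# Normalization, balancing, volcano contrasts, Venn membership, PCA,
# class aggregation and inhibition quartiles.

test_that("weight normalization divides by root mass then log-transforms", {
  v <- matrix(c(0, 99 * 2, 99 * 1,
                9, 99, 999), 3, 2,
              dimnames = list(paste0("g0", 1:3), c("m001", "m002")))
  a <- toy_abundance(v, weights = c(0.5, 2, 1))
  out <- normalize_gcms(a)
  expect_identical(out$values["g01", "m001"], 0)       # zero stays zero
  expect_equal(out$values["g02", "m001"], 2)           # log10(99w/w + 1)
  # heavier roots give uniformly smaller normalized values
  a2 <- a; a2$genotype_meta$root_dry_weight <- a$genotype_meta$root_dry_weight * 2
  out2 <- normalize_gcms(a2)
  nz <- a$values > 0
  expect_true(all(out2$values[nz] < out$values[nz]))
  a$genotype_meta$root_dry_weight[2] <- NA
  expect_error(normalize_gcms(a), "g02")
})

test_that("abundance balancing equalizes row sums and conserves intensity", {
  set.seed(4)
  v <- matrix(rexp(60, rate = 1e-4), 6, 10)
  a <- toy_abundance(v)
  out <- abundance_balance(a)
  expect_equal(unname(rowSums(out$values)),
               rep(mean(rowSums(v)), 6), tolerance = 1e-12)
  expect_equal(sum(out$values), sum(v), tolerance = 1e-9)
  # fixed point: already-equal row sums
  v2 <- matrix(1, 4, 5)
  expect_equal(abundance_balance(toy_abundance(v2))$values, v2,
               ignore_attr = TRUE)
  # single metabolite: every entry becomes the column mean
  v3 <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(unname(abundance_balance(toy_abundance(v3))$values[, 1]),
               rep(2.5, 4))
  v[2, ] <- 0
  expect_error(abundance_balance(toy_abundance(v)), "g02")
})

test_that("volcano applies signed fold change and Wilcoxon thresholds", {
  set.seed(11)
  base <- matrix(rlnorm(16 * 3, 5, 0.1), 16, 3)
  a <- toy_abundance(base)
  in_a <- a$genotype_meta$origin == "A"
  # identical groups: FC 1, ns
  sym <- base; sym[!in_a, ] <- sym[in_a, ]
  vs <- volcano(toy_abundance(sym))
  expect_true(all(abs(vs$signed_fold_change - 1) < 0.01 |
                    vs$p_value > 0.01))
  # strong enrichment in A -> up_A with signed (not log) ratio
  up <- base; up[in_a, 1] <- up[in_a, 1] * 4
  vu <- volcano(toy_abundance(up))
  expect_identical(vu$category[1], "up_A")
  expect_gt(vu$signed_fold_change[1], 2)
  dn <- base; dn[in_a, 2] <- dn[in_a, 2] / 4
  expect_identical(volcano(toy_abundance(dn))$category[2], "up_B")
  # rank test: permuting genotypes within a group changes nothing
  perm <- up; perm[in_a, ] <- perm[sample(which(in_a)), ]
  expect_equal(volcano(toy_abundance(perm))$p_value, vu$p_value)
  # categories invariant under global positive rescaling
  expect_identical(volcano(toy_abundance(up * 1e3))$category, vu$category)
})

test_that("Venn membership follows the presence-fraction rule", {
  v <- matrix(1, 8, 4,
              dimnames = list(paste0("g0", 1:8), paste0("m00", 1:4)))
  v[, 2] <- 0                      # absent everywhere
  v[5:8, 3] <- 0                   # A-only (first half is A)
  v[c(1:4, 5), 4] <- 0             # B-only at the 50% default
  m <- venn_membership(toy_abundance(v))
  expect_identical(m$membership, c("shared", "absent", "A_only", "B_only"))
  # a stricter presence fraction can demote a group
  m2 <- venn_membership(toy_abundance(v), presence_fraction = 1)
  expect_identical(m2$membership[4], "absent")
  expect_error(venn_membership(toy_abundance(v), presence_fraction = 0),
               "presence_fraction")
})

test_that("PCA matches brute-force eigendecomposition and reconstructs", {
  set.seed(2)
  # rank-1 matrix: PC1 carries all variance
  u <- rnorm(6); w <- rnorm(5)
  a1 <- toy_abundance(abs(outer(u, w)) + 1)
  p1 <- pca_ordination(a1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-10)
  # general case: fractions equal eigenvalue ratios of the covariance
  v <- matrix(rnorm(48, 10), 8, 6)
  a <- toy_abundance(abs(v))
  p <- pca_ordination(a)
  ev <- eigen(cov(a$values), symmetric = TRUE)$values
  expect_equal(p$variance_explained, (ev / sum(ev))[1:length(p$variance_explained)],
               tolerance = 1e-10)
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  # loadings reproduce scores from the centered data
  Xc <- sweep(a$values, 2, colMeans(a$values))
  expect_equal(Xc %*% p$loadings, p$scores, tolerance = 1e-8)
  expect_error(pca_ordination(toy_abundance(matrix(3, 4, 4))), "constant")
})

test_that("class aggregation averages within class and scales by sum", {
  set.seed(6)
  v <- abs(matrix(rnorm(40, 10), 5, 8))
  cls <- rep(c("amines", "sugars"), each = 4)
  a <- toy_abundance(v, classes = cls)
  prof <- aggregate_by_class(a)
  expect_equal(unname(rowSums(prof)), rep(1, 2), tolerance = 1e-12)
  # brute-force group-by means before scaling
  manual <- rbind(colMeans(t(v[, 1:4])), colMeans(t(v[, 5:8])))
  manual <- manual / rowSums(manual)
  expect_equal(unname(prof), unname(manual), tolerance = 1e-12)
  # single class, single genotype
  a1 <- toy_abundance(matrix(7, 1, 2), origin = "A")
  expect_equal(unname(aggregate_by_class(a1)[1, 1]), 1)
  a$metabolite_meta$chemical_class[3] <- NA
  expect_warning(aggregate_by_class(a), "other")
})

test_that("inhibition quartiles are near-equal, ranked and tie-stable", {
  d <- study_design(seed = 2)
  st <- simulate_study(d)
  q <- quartiles_by_inhibition(st$inhibition)
  expect_identical(as.integer(table(q)), rep(11L, 4))
  means <- rowMeans(st$inhibition$aoi)
  expect_identical(unname(q[which.max(means)]), factor("Q1",
                                                       levels = paste0("Q", 1:4)))
  # Q1 mean strictly above Q4 mean
  expect_gt(mean(means[q == "Q1"]), mean(means[q == "Q4"]))
  # all-equal means: assignment falls back to id order
  reps <- st$inhibition$replicates
  reps$aoi <- 50
  flat <- inhibition_matrix(reps)
  qf <- quartiles_by_inhibition(flat)
  expect_identical(unname(qf[sort(names(qf))[1]]),
                   factor("Q1", levels = paste0("Q", 1:4)))
  small <- st$inhibition
  small$aoi <- small$aoi[1:3, ]
  expect_error(quartiles_by_inhibition(small), ">= 4")
})
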