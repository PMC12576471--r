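# NIPALS PLS, relevance networks and quartile PLS-DA.

test_that("PLS1 first component points along X^T y", {
  set.seed(31)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- X %*% rnorm(10) + rnorm(40, sd = 0.3)
  m <- fit_pls(X, y, n_components = 2)
  Xs <- scale(X); ys <- drop(scale(y))
  d <- drop(crossprod(Xs, ys))
  cosine <- abs(sum(m$x_weights[, 1] * d)) /
    sqrt(sum(m$x_weights[, 1]^2) * sum(d^2))
  expect_gte(cosine, 0.999)
  # duplicated response: identical coefficient columns
  m2 <- fit_pls(X, cbind(y, y), n_components = 2)
  expect_equal(m2$coefficients[, 1], m2$coefficients[, 2],
               tolerance = 1e-10)
  expect_error(fit_pls(X, y, n_components = 0), ">= 1")
  expect_error(fit_pls(X, rep(1, 40)), "variance")
})

test_that("full-component PLS reconstructs the standardized matrix", {
  set.seed(37)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12)
  m <- fit_pls(X, y, n_components = 5)
  Xs <- scale(X)
  expect_equal(m$scores %*% t(m$x_loadings), unclass(Xs),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("coefficients match an independent NIPALS oracle and mixOmics", {
  set.seed(41)
  X <- matrix(rnorm(6 * 4), 6, 4); colnames(X) <- paste0("m", 1:4)
  Y <- matrix(rnorm(6 * 2), 6, 2)
  m <- fit_pls(X, Y, n_components = 2)
  expect_equal(unname(m$coefficients), oracle_pls_coef(X, Y, 2),
               tolerance = 1e-10)
  # cross-check the first latent direction against mixOmics
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  w_pkg <- m$x_weights[, 1]; w_mo <- mo$loadings$X[, 1]
  cosine <- abs(sum(w_pkg * w_mo)) /
    sqrt(sum(w_pkg^2) * sum(w_mo^2))
  expect_gte(cosine, 0.999)
})

test_that("networks threshold edges with monotone nesting", {
  set.seed(43)
  X <- matrix(rnorm(30 * 8), 30, 8)
  colnames(X) <- paste0("m", 1:8)
  y <- cbind(NF = X[, 1] - X[, 2] + rnorm(30, sd = 0.2))
  m <- fit_pls(X, y, n_components = 2)
  sim <- pls_similarity(m)
  expect_true(all(abs(sim) <= 1))
  n_lo <- build_network(sim, 0.2)
  n_hi <- build_network(sim, 0.6)
  expect_true(all(abs(n_hi$edges$weight) >= 0.6))
  # lowering the cutoff never removes edges
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(n_hi) %in% key(n_lo)))
  # cutoff 1.0 keeps only perfect associations (none here)
  expect_identical(nrow(build_network(sim, 1)$edges), 0L)
  expect_error(build_network(sim, 0), "cutoff")
  expect_error(build_network(sim, 1.2), "cutoff")
})

test_that("planted drivers connect to their strain at low noise", {
  d <- study_design(n_genotypes = 30, origin_split = c(A = 15, B = 15),
                    n_metabolites = 15, n_classes = 3, seed = 47)
  tr <- planted_truth(active_sets = list(NF = c(m002 = 50, m009 = 40)),
                      noise_sd = 0, replicate_sd = 0)
  a <- simulate_abundances(d, tr, zero_fraction = 0)
  inh <- simulate_inhibition(a, tr)
  lg <- a; lg$values <- log10(a$values + 1)
  m <- fit_pls(lg, cbind(NF = inh$aoi[, "NF"]), n_components = 2)
  net <- build_network(pls_similarity(m), 0.4,
                       metabolite_meta = a$metabolite_meta,
                       dl_selected = "m002")
  hit <- net$edges$source %in% c("m002", "m009") & net$edges$target == "NF"
  expect_equal(sum(hit), 2)
  expect_true(all(net$edges$weight[hit] > 0))
  expect_true(net$nodes$dl_selected[net$nodes$id == "m002"])
})

test_that("quartile PLS-DA separates classes and collapses under permutation", {
  set.seed(53)
  n <- 24; p <- 12
  q <- factor(rep(paste0("Q", 1:4), each = 6), levels = paste0("Q", 1:4))
  centers <- matrix(rnorm(4 * p, sd = 4), 4, p)
  X <- centers[as.integer(q), ] + matrix(rnorm(n * p, sd = 0.3), n, p)
  X <- X - min(X) + 1
  a <- toy_abundance(X)
  names(q) <- rownames(a$values)
  fit <- plsda_quartiles(a, q, n_components = 3, cutoff = 0.4)
  expect_equal(fit$accuracy, 1)
  # permuting labels destroys the class structure
  set.seed(54)
  qp <- setNames(sample(q), names(q))
  fitp <- plsda_quartiles(a, qp, n_components = 3, cutoff = 0.4)
  expect_lt(fitp$accuracy, fit$accuracy)
  q1 <- q; q1[q1 == "Q4"] <- "Q3"  # empties quartile Q4
  expect_error(plsda_quartiles(a, q1), ">= 2")
})

test_that("network export writes edge list and GraphML", {
  set.seed(59)
  sim <- matrix(runif(6, -1, 1), 3, 2,
                dimnames = list(paste0("m", 1:3), c("NF", "NV")))
  net <- build_network(sim, 0.1)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "edges.tsv"); gml <- file.path(dir, "net.graphml")
  write_network(net, tsv, gml)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(net$edges))
  doc <- xml2::read_xml(gml)
  expect_identical(length(xml2::xml_find_all(doc, ".//d1:edge",
                                             xml2::xml_ns(doc))),
                   nrow(net$edges))
})
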