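# Independent brute-force oracles used across the suite. These are written
# from the defining formulas, not by calling the package's own code paths.

# Spearman rho: rank both vectors (average ranks), then the explicit
# product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided permutation p for Spearman on small n (enumerates all n!
# orderings of y).
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  obs <- abs(oracle_spearman(x, y))
  vals <- vapply(perms(seq_len(n)),
                 function(p) abs(oracle_spearman(x, y[p])), numeric(1))
  mean(vals >= obs - 1e-12)
}

# Rank-sum statistic of the first group (Wilcoxon W as a rank sum).
oracle_ranksum <- function(x, y) {
  sum(rank(c(x, y))[seq_along(x)])
}

# Exact two-sided Wilcoxon p by enumerating all assignments of the pooled
# tie-free values to the first group.
oracle_wilcox_exact_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Kruskal-Wallis H with tie correction, from the defining formula.
oracle_kruskal_H <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Classical linear CCA correlation between a matrix and a vector.
oracle_cca <- function(X, y) {
  stats::cancor(X, matrix(y, ncol = 1))$cor[1]
}

# Independent plain-loop NIPALS PLS (regression mode) for tiny problems;
# returns the coefficient matrix on the standardized scale.
oracle_pls_coef <- function(X, Y, H) {
  Xd <- scale(X); Yd <- scale(Y)
  p <- ncol(Xd); q <- ncol(Yd)
  W <- matrix(0, p, H); P <- matrix(0, p, H); Q <- matrix(0, q, H)
  for (h in 1:H) {
    u <- Yd[, 1]
    for (it in 1:200) {
      w <- t(Xd) %*% u; w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      qq <- t(Yd) %*% tt / sum(tt^2)
      u_new <- Yd %*% qq / sum(qq^2)
      if (sum((u_new - u)^2) < 1e-24) { u <- u_new; break }
      u <- u_new
    }
    s <- sign(w[which.max(abs(w))]); if (s == 0) s <- 1
    w <- w * s; tt <- tt * s; qq <- qq * s
    pp <- t(Xd) %*% tt / sum(tt^2)
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(qq)
    W[, h] <- w; P[, h] <- pp; Q[, h] <- qq
  }
  W %*% solve(t(P) %*% W) %*% t(Q)
}

# Small hand-built abundance container for unit tests.
toy_abundance <- function(values, origin = NULL, weights = NULL,
                          classes = NULL) {
  n_g <- nrow(values); n_m <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", 1:n_g)
  if (is.null(colnames(values))) colnames(values) <- sprintf("m%03d", 1:n_m)
  if (is.null(origin))
    origin <- rep(c("A", "B"), c(ceiling(n_g / 2), floor(n_g / 2)))
  if (is.null(weights)) weights <- rep(1, n_g)
  if (is.null(classes)) classes <- rep("class01", n_m)
  abundance_matrix(
    values,
    data.frame(genotype = rownames(values), origin = origin,
               root_dry_weight = weights, stringsAsFactors = FALSE),
    data.frame(metabolite = colnames(values), chemical_class = classes,
               stringsAsFactors = FALSE))
}
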