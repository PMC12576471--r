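# Combinatorial metabolite selection: a genetic algorithm over metabolite
# triplets whose fitness is the canonical correlation between the triplet's
# abundances and a strain's inhibition activity. Two fitness backends:
# a small deep-CCA model (paired neural encoders trained to maximize the
# correlation of their latent outputs) and closed-form linear CCA.

#' Configuration for the deep CCA fitness model
#'
#' @param hidden_layers hidden-layer widths of both encoders
#'   (default `c(16, 16)`).
#' @param activation hidden activation, `"tanh"` only.
#' @param latent_dim latent dimension (1 supported).
#' @param epochs full-batch training epochs (default 300).
#' @param learning_rate Adam learning rate (default 1e-2).
#' @param covariance_regularizer ridge added to the latent variances in
#'   the correlation objective (default 1e-4).
#' @param seed integer seed for weight initialization.
#' @return A `"dcca_config"` list.
#' @export
dcca_config <- function(hidden_layers = c(16, 16), activation = "tanh",
                        latent_dim = 1, epochs = 300,
                        learning_rate = 1e-2,
                        covariance_regularizer = 1e-4, seed = 1L) {
  if (latent_dim != 1) stop("only latent_dim = 1 is supported")
  if (epochs < 1) stop("epochs must be >= 1")
  if (activation != "tanh") stop("only tanh activation is supported")
  structure(list(hidden_layers = hidden_layers, activation = activation,
                 latent_dim = latent_dim, epochs = epochs,
                 learning_rate = learning_rate,
                 covariance_regularizer = covariance_regularizer,
                 seed = as.integer(seed)),
            class = "dcca_config")
}

#' Configuration for the genetic algorithm
#'
#' @param subset_size metabolites per individual (default 3: triplets).
#' @param population individuals per generation (default 40, >= 4).
#' @param generations generations per repetition (default 30).
#' @param mutation_rate per-slot mutation probability (default 0.10).
#' @param elitism individuals carried over unchanged (default 2).
#' @param repetitions independent GA repetitions whose best triplets are
#'   counted (default 200).
#' @param tournament tournament size for selection (default 3).
#' @param seed master integer seed; repetition r uses `seed + r`.
#' @return A `"ga_config"` list.
#' @export
ga_config <- function(subset_size = 3, population = 40, generations = 30,
                      mutation_rate = 0.10, elitism = 2,
                      repetitions = 200, tournament = 3, seed = 1L) {
  if (subset_size < 1) stop("subset_size must be >= 1")
  if (population < 4) stop("population must be >= 4")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(list(subset_size = subset_size, population = population,
                 generations = generations, mutation_rate = mutation_rate,
                 elitism = elitism, repetitions = repetitions,
                 tournament = tournament, seed = as.integer(seed)),
            class = "ga_config")
}

# ---- fitness backends -------------------------------------------------

# Closed-form linear CCA between X (n x k) and scalar y: the maximal
# correlation over linear combinations of X's columns equals the multiple
# correlation sqrt(R^2) of the regression of y on X.
.linear_cca_fitness <- function(X, y, ridge = 1e-8) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  G <- crossprod(Xc)
  diag(G) <- diag(G) + ridge * mean(diag(G))
  b <- solve(G, crossprod(Xc, yc))
  yhat <- Xc %*% b
  ss <- sum(yhat^2)
  if (sum(yc^2) == 0) return(0)
  sqrt(min(1, ss / sum(yc^2)))
}

# Tiny fully connected net: list of (W, b); tanh hidden, linear output.
.mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = 1 / sqrt(fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

.mlp_forward <- function(net, X) {
  acts <- list(X)
  L <- length(net)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% net[[l]]$W, 2, net[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  acts
}

# Backprop of dLoss/d(output) through the net; returns per-layer gradients.
.mlp_backward <- function(net, acts, dout) {
  L <- length(net)
  grads <- vector("list", L)
  delta <- dout
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(net[[l]]$W)) * (1 - acts[[l]]^2)
    }
  }
  grads
}

# Deep CCA with scalar latents: train both encoders by full-batch Adam to
# maximize the regularized correlation of their outputs.
.dcca_fitness_deep <- function(X, y, cfg) {
  n <- nrow(X)
  set.seed(cfg$seed)
  fx <- .mlp_init(c(ncol(X), cfg$hidden_layers, 1))
  fy <- .mlp_init(c(1, cfg$hidden_layers, 1))
  Y <- matrix(y, ncol = 1)
  reg <- cfg$covariance_regularizer
  lr <- cfg$learning_rate
  adam <- function(net) lapply(net, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  sx <- adam(fx); sy <- adam(fy)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  step <- function(net, st, gr, t) {
    for (l in seq_along(net)) {
      st[[l]]$mW <- b1 * st[[l]]$mW + (1 - b1) * gr[[l]]$W
      st[[l]]$vW <- b2 * st[[l]]$vW + (1 - b2) * gr[[l]]$W^2
      st[[l]]$mb <- b1 * st[[l]]$mb + (1 - b1) * gr[[l]]$b
      st[[l]]$vb <- b2 * st[[l]]$vb + (1 - b2) * gr[[l]]$b^2
      mW <- st[[l]]$mW / (1 - b1^t); vW <- st[[l]]$vW / (1 - b2^t)
      mb <- st[[l]]$mb / (1 - b1^t); vb <- st[[l]]$vb / (1 - b2^t)
      # gradient ascent on the correlation objective
      net[[l]]$W <- net[[l]]$W + lr * mW / (sqrt(vW) + eps)
      net[[l]]$b <- net[[l]]$b + lr * mb / (sqrt(vb) + eps)
    }
    list(net = net, st = st)
  }

  for (t in seq_len(cfg$epochs)) {
    ax <- .mlp_forward(fx, X); ay <- .mlp_forward(fy, Y)
    a <- drop(ax[[length(ax)]]); b <- drop(ay[[length(ay)]])
    ac <- a - mean(a); bc <- b - mean(b)
    sxx <- sum(ac^2) / (n - 1) + reg
    syy <- sum(bc^2) / (n - 1) + reg
    sxy <- sum(ac * bc) / (n - 1)
    r <- sxy / sqrt(sxx * syy)
    sgn <- if (r >= 0) 1 else -1   # ascend |r|
    # d|r|/da_i and d|r|/db_i (centering absorbed: gradients are centered)
    da <- sgn * (bc / sqrt(sxx * syy) - r * ac / sxx) / (n - 1)
    db <- sgn * (ac / sqrt(sxx * syy) - r * bc / syy) / (n - 1)
    gx <- .mlp_backward(fx, ax, matrix(da, ncol = 1))
    gy <- .mlp_backward(fy, ay, matrix(db, ncol = 1))
    up <- step(fx, sx, gx, t); fx <- up$net; sx <- up$st
    up <- step(fy, sy, gy, t); fy <- up$net; sy <- up$st
  }
  a <- drop(.mlp_forward(fx, X)[[length(fx) + 1]])
  b <- drop(.mlp_forward(fy, Y)[[length(fy) + 1]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  abs(stats::cor(a, b))
}

#' Canonical-correlation fitness of a metabolite triplet
#'
#' Measures how strongly a metabolite subset relates to a strain's
#' inhibition activity. Under the `"linear"` backend this is the classical
#' canonical correlation (the multiple correlation of the regression of
#' the standardized activity on the standardized triplet columns), in
#' closed form. Under the `"deep"` backend two small tanh encoders (one
#' per view) are trained by full-batch Adam to maximize the regularized
#' correlation of their scalar latents; the fitness is the absolute final
#' training-set correlation. Both backends are deterministic given
#' `cfg$seed`.
#'
#' @param triplet metabolite ids (columns of `a`).
#' @param a an `"abundance_matrix"` or numeric matrix.
#' @param y strain AOI vector (non-constant), aligned with the rows of
#'   `a`.
#' @param cfg a `"dcca_config"`.
#' @param backend `"linear"` or `"deep"`.
#' @return Fitness in \[0, 1\].
#' @export
dcca_fitness <- function(triplet, a, y, cfg = dcca_config(),
                         backend = c("linear", "deep")) {
  backend <- match.arg(backend)
  X <- if (inherits(a, "abundance_matrix")) a$values else as.matrix(a)
  if (stats::sd(y) == 0) stop("constant activity vector: fitness undefined")
  miss <- setdiff(triplet, colnames(X))
  if (length(miss)) stop("unknown metabolite id(s): ",
                         paste(miss, collapse = ", "))
  Xt <- X[, triplet, drop = FALSE]
  const <- apply(Xt, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant column(s) dropped from triplet: ",
            paste(triplet[const], collapse = ", "))
    Xt <- Xt[, !const, drop = FALSE]
    if (ncol(Xt) == 0) return(0)
  }
  Xt <- scale(Xt)
  ys <- drop(scale(y))
  if (backend == "linear") .linear_cca_fitness(Xt, ys)
  else .dcca_fitness_deep(Xt, ys, cfg)
}

# ---- genetic algorithm ------------------------------------------------

# One GA repetition over column indices 1..p; returns best individual
# (sorted indices) and its fitness. `fit_fn(idx)` must accept an integer
# vector. A memoization cache (environment) is shared across repetitions.
.ga_run_once <- function(p, ga, fit_fn, cache) {
  k <- ga$subset_size
  npop <- ga$population
  eval_memo <- function(idx) {
    idx <- sort(idx)
    key <- paste(idx, collapse = "-")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- fit_fn(idx)
      cache[[key]] <- f
    }
    f
  }
  pop <- replicate(npop, sort(sample.int(p, k)), simplify = FALSE)
  fits <- vapply(pop, eval_memo, numeric(1))
  best_i <- which.max(fits)
  best <- list(idx = pop[[best_i]], fit = fits[best_i])

  for (gen in seq_len(ga$generations)) {
    ord <- order(-fits)
    new_pop <- pop[ord[seq_len(ga$elitism)]]
    while (length(new_pop) < npop) {
      pick <- function() {
        cand <- sample.int(npop, min(ga$tournament, npop))
        pop[[cand[which.max(fits[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      # uniform crossover with duplicate repair
      take1 <- stats::runif(k) < 0.5
      child <- ifelse(take1, p1, p2)
      child <- unique(child)
      while (length(child) < k) {
        child <- unique(c(child, sample.int(p, 1)))
      }
      # per-slot mutation: replace with a uniformly random unused index
      mut <- which(stats::runif(k) < ga$mutation_rate)
      for (m in mut) {
        repl <- sample.int(p, 1)
        while (repl %in% child) repl <- sample.int(p, 1)
        child[m] <- repl
      }
      new_pop[[length(new_pop) + 1]] <- sort(child)
    }
    pop <- new_pop
    fits <- vapply(pop, eval_memo, numeric(1))
    gi <- which.max(fits)
    if (fits[gi] > best$fit) best <- list(idx = pop[[gi]], fit = fits[gi])
  }
  best
}

#' Genetic-algorithm metabolite selection with CCA fitness
#'
#' Runs `ga$repetitions` independent GA searches (repetition r seeded with
#' `ga$seed + r`), each evolving a population of metabolite subsets under
#' tournament selection, uniform crossover with duplicate repair, per-slot
#' mutation and elitism. The members of the single best subset of each
#' repetition are counted into a per-metabolite frequency `f`; metabolites
#' with `f` above `select_threshold` are flagged as selected (a secondary
#' `highlight_threshold` tier, default 5, is also reported).
#'
#' @param a an `"abundance_matrix"` or numeric matrix.
#' @param y strain AOI vector aligned with the rows of `a`.
#' @param ga a `"ga_config"`.
#' @param dcca a `"dcca_config"` (used by the deep backend).
#' @param backend fitness backend, `"linear"` (default) or `"deep"`.
#' @param select_threshold frequency above which a metabolite is flagged
#'   selected (default 10).
#' @param highlight_threshold secondary reporting tier (default 5).
#' @return A `"triplet_frequency_table"` data.frame: `metabolite`,
#'   `frequency`, `mean_fitness` (over best triplets containing it),
#'   `selected`, `highlighted`; attribute `best_triplets` holds the per-
#'   repetition winners.
#' @export
ga_select <- function(a, y, ga = ga_config(), dcca = dcca_config(),
                      backend = c("linear", "deep"),
                      select_threshold = 10, highlight_threshold = 5) {
  backend <- match.arg(backend)
  X <- if (inherits(a, "abundance_matrix")) a$values else as.matrix(a)
  p <- ncol(X)
  if (p <= ga$subset_size)
    stop("need more metabolites than the subset size")
  if (stats::sd(y) == 0) stop("constant activity vector")
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0
  ys <- drop(scale(y))
  fit_fn <- if (backend == "linear") {
    function(idx) .linear_cca_fitness(Xs[, idx, drop = FALSE], ys)
  } else {
    function(idx) .dcca_fitness_deep(Xs[, idx, drop = FALSE], ys, dcca)
  }
  cache <- new.env(parent = emptyenv())
  freq <- stats::setNames(numeric(p), colnames(X))
  fit_sum <- freq
  winners <- vector("list", ga$repetitions)
  for (r in seq_len(ga$repetitions)) {
    set.seed(ga$seed + r)
    best <- .ga_run_once(p, ga, fit_fn, cache)
    ids <- colnames(X)[best$idx]
    freq[ids] <- freq[ids] + 1
    fit_sum[ids] <- fit_sum[ids] + best$fit
    winners[[r]] <- list(triplet = ids, fitness = best$fit)
  }
  out <- data.frame(
    metabolite = colnames(X),
    frequency = unname(freq),
    mean_fitness = ifelse(freq > 0, unname(fit_sum / freq), NA_real_),
    selected = unname(freq > select_threshold),
    highlighted = unname(freq >= highlight_threshold),
    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$metabolite), ]
  rownames(out) <- NULL
  attr(out, "best_triplets") <- winners
  attr(out, "repetitions") <- ga$repetitions
  attr(out, "subset_size") <- ga$subset_size
  class(out) <- c("triplet_frequency_table", "data.frame")
  out
}

#' Stability of GA frequency rankings under data resplits
#'
#' Reruns [ga_select()] on `repeats` random 80/20 genotype splits (training
#' portion only) and reports the pairwise Spearman rank correlation of the
#' frequency vectors and the overlap of the top-`top_k` metabolites.
#'
#' @param a abundance matrix (rows = genotypes).
#' @param y activity vector.
#' @param ga,dcca,backend as in [ga_select()].
#' @param split_fraction training fraction (default 0.8).
#' @param repeats number of resplits (default 5).
#' @param top_k size of the top set compared (default 5).
#' @param seed seed for the splits.
#' @return A `"stability_report"` list: `frequencies` (metabolite x
#'   repeat), `rank_correlation` (mean pairwise Spearman, `NA` when
#'   `repeats` < 2), `pairwise_correlations`, `top_overlap` (mean pairwise
#'   top-k overlap fraction), `top_sets`.
#' @export
stability_check <- function(a, y, ga = ga_config(), dcca = dcca_config(),
                            backend = "linear", split_fraction = 0.8,
                            repeats = 5, top_k = 5, seed = 1L) {
  X <- if (inherits(a, "abundance_matrix")) a$values else as.matrix(a)
  n <- nrow(X)
  n_train <- round(split_fraction * n)
  if (n_train < 10) stop("training split would retain fewer than 10 genotypes")
  set.seed(seed)
  splits <- replicate(repeats, sort(sample.int(n, n_train)),
                      simplify = FALSE)
  freqs <- sapply(seq_len(repeats), function(i) {
    idx <- splits[[i]]
    ga_i <- ga; ga_i$seed <- ga$seed + 1000L * i
    tab <- ga_select(X[idx, , drop = FALSE], y[idx], ga_i, dcca,
                     backend = backend)
    tab$frequency[match(colnames(X), tab$metabolite)]
  })
  rownames(freqs) <- colnames(X)
  top_sets <- lapply(seq_len(repeats), function(i)
    rownames(freqs)[order(-freqs[, i], rownames(freqs))][seq_len(top_k)])
  if (repeats >= 2) {
    pairs <- utils::combn(repeats, 2)
    rc <- apply(pairs, 2, function(pr)
      stats::cor(freqs[, pr[1]], freqs[, pr[2]], method = "spearman"))
    ov <- apply(pairs, 2, function(pr)
      length(intersect(top_sets[[pr[1]]], top_sets[[pr[2]]])) / top_k)
    mean_rc <- mean(rc); mean_ov <- mean(ov)
  } else {
    rc <- ov <- numeric(0); mean_rc <- NA_real_; mean_ov <- NA_real_
  }
  structure(list(frequencies = freqs, rank_correlation = mean_rc,
                 pairwise_correlations = rc, top_overlap = mean_ov,
                 top_sets = top_sets, single_repeat = repeats < 2),
            class = "stability_report")
}

#' @export
print.triplet_frequency_table <- function(x, n = 10, ...) {
  cat("<triplet_frequency_table>", attr(x, "repetitions"),
      "repetitions, subset size", attr(x, "subset_size"), "\n")
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> mean rank correlation:",
      format(x$rank_correlation, digits = 3),
      "| mean top-set overlap:", format(x$top_overlap, digits = 3), "\n")
  if (x$single_repeat) cat("  (single repeat: correlations undefined)\n")
  invisible(x)
}
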