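# Partial-least-squares regression of inhibition on the metabolite matrix,
# PLS-DA on inhibition quartiles, and thresholded association networks.

#' Fit a two-block PLS model (NIPALS, regression mode)
#'
#' Classical NIPALS with deflation of both blocks. Columns of `X` and `Y`
#' are centered and scaled to unit variance before fitting. The sign of
#' each component is fixed deterministically by forcing the
#' largest-magnitude x-weight positive, so models are reproducible across
#' runs and platforms.
#'
#' @param a an `"abundance_matrix"`, or a numeric genotype x metabolite
#'   matrix.
#' @param y response vector, or genotype x response matrix (e.g. one AOI
#'   column per strain, or one-hot class indicators).
#' @param n_components number of latent components (default 2).
#' @param tol NIPALS inner-loop convergence tolerance.
#' @return A `"pls_model"` list: `scores` (n x H), `x_weights`,
#'   `x_loadings` (p x H), `y_loadings` (q x H), `coefficients` (p x q, on
#'   the standardized scale), `x_center`, `x_scale`, `y_center`, `y_scale`,
#'   `explained_x` (fraction of X variance per component).
#' @export
fit_pls <- function(a, y, n_components = 2, tol = 1e-10) {
  X <- if (inherits(a, "abundance_matrix")) a$values else as.matrix(a)
  Y <- as.matrix(y)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  if (nrow(Y) != nrow(X)) stop("X and y disagree on the number of samples")
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(dim(X))")
  if (any(apply(Y, 2, stats::var) == 0))
    stop("zero-variance response column")

  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  yc <- colMeans(Y); ys <- apply(Y, 2, stats::sd)
  Xd <- scale(X, xc, xs); Yd <- scale(Y, yc, ys)
  X0 <- Xd
  n <- nrow(Xd); p <- ncol(Xd); q <- ncol(Yd)
  H <- n_components
  W <- matrix(0, p, H); P <- matrix(0, p, H); Q <- matrix(0, q, H)
  Tm <- matrix(0, n, H)
  ssx <- sum(Xd^2)
  explained <- numeric(H)

  for (h in seq_len(H)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var)), drop = TRUE]
    w_old <- rep(0, p)
    for (it in 1:500) {
      w <- drop(crossprod(Xd, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xd %*% w)
      qq <- drop(crossprod(Yd, tt)) / sum(tt^2)
      if (q > 1L) {
        u <- drop(Yd %*% qq) / sum(qq^2)
      }
      if (sum((w - w_old)^2) < tol^2 || q == 1L) break
      w_old <- w
    }
    # deterministic sign: largest-|w| entry positive
    s <- sign(w[which.max(abs(w))]); if (s == 0) s <- 1
    w <- w * s; tt <- tt * s; qq <- qq * s
    pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
    explained[h] <- sum(tt^2) * sum(pp^2) / ssx
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, qq)
    W[, h] <- w; P[, h] <- pp; Q[, h] <- qq; Tm[, h] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(X), colnames(Y))
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- colnames(Y)
  rownames(Tm) <- rownames(X)
  structure(list(scores = Tm, x_weights = W, x_loadings = P,
                 y_loadings = Q, coefficients = B,
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 X0 = X0, Y0 = scale(Y, yc, ys),
                 n_components = H, explained_x = explained),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", nrow(x$x_weights), "predictors,",
      nrow(x$y_loadings), "response(s),", x$n_components, "components\n")
  invisible(x)
}

#' Relevance-network similarity between predictors and responses
#'
#' mixOmics-style score: the (i, j) similarity is the sum over latent
#' components of `cor(x_i, t_h) * cor(y_j, t_h)`, i.e. the correlation
#' between variable i and response j as transmitted through the latent
#' space; values are clipped to \[-1, 1\].
#'
#' @param model a `"pls_model"`.
#' @param n_components components to use (default all fitted).
#' @return A predictor x response similarity matrix.
#' @export
pls_similarity <- function(model, n_components = model$n_components) {
  h <- seq_len(n_components)
  cx <- stats::cor(model$X0, model$scores[, h, drop = FALSE])
  cy <- stats::cor(model$Y0, model$scores[, h, drop = FALSE])
  sim <- tcrossprod(cx, cy)
  pmin(pmax(sim, -1), 1)
}

#' Build a thresholded association network
#'
#' Retains edges whose absolute similarity is at least `cutoff`. Per-strain
#' edge cutoffs of 0.40 (NF), 0.35 (NV), 0.38 (NM) and 0.45 (NU) are the
#' study defaults; the quartile PLS-DA network uses 0.35-0.40.
#'
#' @param sim predictor x response similarity matrix (rows metabolites,
#'   columns responses), or a `"pls_model"` (similarity computed via
#'   [pls_similarity()]).
#' @param cutoff absolute-similarity threshold in (0, 1].
#' @param metabolite_meta optional data.frame (`metabolite`,
#'   `chemical_class`) for node annotation.
#' @param dl_selected optional character vector of metabolite ids selected
#'   by the deep-learning screen, flagged on nodes.
#' @return A `"bni_network"` list: `nodes` (id, type, chemical_class,
#'   dl_selected), `edges` (source, target, weight, sign).
#' @export
build_network <- function(sim, cutoff, metabolite_meta = NULL,
                          dl_selected = character(0)) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (inherits(sim, "pls_model")) sim <- pls_similarity(sim)
  idx <- which(abs(sim) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(sim)[idx[, 1]],
    target = colnames(sim)[idx[, 2]],
    weight = sim[idx],
    sign = ifelse(sim[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  used <- unique(c(edges$source, edges$target))
  nodes <- data.frame(
    id = c(rownames(sim), colnames(sim)),
    type = rep(c("metabolite", "response"),
               c(nrow(sim), ncol(sim))),
    stringsAsFactors = FALSE)
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  nodes$chemical_class <- if (!is.null(metabolite_meta))
    metabolite_meta$chemical_class[match(nodes$id,
                                         metabolite_meta$metabolite)]
  else rep(NA_character_, nrow(nodes))
  nodes$dl_selected <- nodes$id %in% dl_selected
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "bni_network")
}

#' @export
print.bni_network <- function(x, ...) {
  cat("<bni_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges at |similarity| >=", x$cutoff, "\n")
  invisible(x)
}

#' PLS-DA on inhibition quartiles with an association network
#'
#' Fits a PLS-DA model with the quartile assignment one-hot encoded as the
#' response block, classifies training genotypes by the largest fitted
#' class score, and builds the thresholded relevance network.
#'
#' @param a an `"abundance_matrix"`.
#' @param q quartile factor from [quartiles_by_inhibition()] (named by
#'   genotype).
#' @param n_components latent components (default 2).
#' @param cutoff network edge cutoff (default 0.4).
#' @param dl_selected metabolite ids flagged as deep-learning-selected.
#' @return A list: `model` (`"pls_model"`), `network` (`"bni_network"`),
#'   `predicted_class` (named factor), `accuracy` (training).
#' @export
plsda_quartiles <- function(a, q, n_components = 2, cutoff = 0.4,
                            dl_selected = character(0)) {
  q <- q[rownames(a$values)]
  if (any(table(q) < 2)) stop("every quartile needs >= 2 genotypes")
  Y <- stats::model.matrix(~ 0 + q)
  colnames(Y) <- levels(q)
  stopifnot(all(rowSums(Y) == 1))
  model <- fit_pls(a, Y, n_components = n_components)
  # training-set class scores on the standardized scale
  Xd <- scale(a$values, model$x_center, model$x_scale)
  Yhat <- Xd %*% model$coefficients
  pred <- factor(colnames(Y)[max.col(Yhat, ties.method = "first")],
                 levels = levels(q))
  names(pred) <- rownames(a$values)
  net <- build_network(pls_similarity(model), cutoff,
                       metabolite_meta = a$metabolite_meta,
                       dl_selected = dl_selected)
  list(model = model, network = net, predicted_class = pred,
       accuracy = mean(pred == q))
}

#' Write a network edge list as TSV and GraphML
#'
#' @param net a `"bni_network"`.
#' @param path_tsv edge-list TSV path (`source`, `target`, `weight`,
#'   `sign`); `NULL` to skip.
#' @param path_graphml GraphML path for Cytoscape-type viewers; `NULL` to
#'   skip.
#' @return Invisibly, the network.
#' @export
write_network <- function(net, path_tsv = NULL, path_graphml = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(net$edges, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_graphml)) {
    con <- file(path_graphml, "w", encoding = "UTF-8")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="type" for="node" attr.name="type" attr.type="string"/>')
    w('  <key id="class" for="node" attr.name="chemical_class" attr.type="string"/>')
    w('  <key id="dl" for="node" attr.name="dl_selected" attr.type="boolean"/>')
    w('  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>')
    w('  <graph edgedefault="undirected">')
    for (i in seq_len(nrow(net$nodes))) {
      nd <- net$nodes[i, ]
      w('    <node id="', nd$id, '">',
        '<data key="type">', nd$type, '</data>',
        '<data key="class">',
        ifelse(is.na(nd$chemical_class), "", nd$chemical_class), '</data>',
        '<data key="dl">', tolower(nd$dl_selected), '</data>',
        '</node>')
    }
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      w('    <edge source="', e$source, '" target="', e$target, '">',
        '<data key="weight">', format(e$weight, digits = 10), '</data>',
        '</edge>')
    }
    w('  </graph>')
    w('</graphml>')
  }
  invisible(net)
}
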