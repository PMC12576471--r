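# Seed-reproducible synthetic studies with planted ground truth.
#
# The generator emulates the structure of a root-exudate BNI screen:
# 44 wheat genotypes from two origins (20 "A" / 24 "B"), ~357 annotated
# metabolites in 12 chemical classes, and four ammonia-oxidizer strains
# (two archaeal: NF, NV; two bacterial: NM, NU). A planted truth object
# declares which metabolites drive inhibition (additively, as a synergistic
# triplet, or as stimulators) so every downstream stage can be validated
# against known signal.

#' Describe a synthetic study design
#'
#' @param n_genotypes number of genotypes (default 44).
#' @param origin_split genotypes per origin group, named `A`/`B`
#'   (default 20/24, emulating the Austrian/Indian split).
#' @param n_metabolites number of annotated metabolites (default 357).
#' @param n_unannotated_features extra unannotated m/z features (default 0).
#' @param n_classes number of chemical classes (default 12).
#' @param strains named character vector: strain id -> domain tag
#'   (`"AOA"`/`"AOB"`).
#' @param seed integer seed governing all randomness downstream.
#' @return A `"study_design"` list.
#' @export
study_design <- function(n_genotypes = 44,
                         origin_split = c(A = 20, B = 24),
                         n_metabolites = 357,
                         n_unannotated_features = 0,
                         n_classes = 12,
                         strains = c(NF = "AOA", NV = "AOA",
                                     NM = "AOB", NU = "AOB"),
                         seed = 1L) {
  if (n_metabolites < 1) stop("design needs at least one metabolite")
  if (sum(origin_split) != n_genotypes)
    stop("origin_split must sum to n_genotypes")
  if (n_classes > n_metabolites)
    stop("cannot have more classes than metabolites")
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    origin_split = origin_split,
    n_metabolites = as.integer(n_metabolites),
    n_unannotated_features = as.integer(n_unannotated_features),
    n_classes = as.integer(n_classes),
    strains = strains,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' Declare the planted ground truth of a synthetic study
#'
#' @param active_sets named list (one element per strain) of named numeric
#'   vectors: metabolite id -> additive effect weight in AOI-percentage
#'   units at full saturation.
#' @param synergy_triplet character vector of 3 metabolite ids acting
#'   multiplicatively (individually weak, jointly strong).
#' @param synergy_weight AOI weight of the triplet interaction; a scalar or
#'   a named per-strain vector.
#' @param stimulators named list per strain of named negative weights
#'   (growth stimulation: negative AOI).
#' @param origin_shifted named numeric vector: metabolite id -> additive
#'   log10 shift applied in origin group `A`.
#' @param noise_sd sd of the per-(genotype, strain) AOI noise (AOI units).
#' @param replicate_sd sd of within-cell replicate noise (AOI units).
#' @param additive_only if `TRUE`, the synergy term is replaced by equal
#'   additive contributions of the triplet members (ablation switch).
#' @return A `"planted_truth"` list.
#' @export
planted_truth <- function(active_sets = list(),
                          synergy_triplet = character(0),
                          synergy_weight = 0,
                          stimulators = list(),
                          origin_shifted = numeric(0),
                          noise_sd = 5,
                          replicate_sd = 2,
                          additive_only = FALSE) {
  if (length(synergy_triplet) && length(synergy_triplet) != 3L)
    stop("synergy_triplet must contain exactly 3 metabolite ids")
  structure(list(
    active_sets = active_sets,
    synergy_triplet = synergy_triplet,
    synergy_weight = synergy_weight,
    stimulators = stimulators,
    origin_shifted = origin_shifted,
    noise_sd = noise_sd,
    replicate_sd = replicate_sd,
    additive_only = isTRUE(additive_only)
  ), class = "planted_truth")
}

#' Default planted truth for a design
#'
#' Plants, reproducibly from the design seed: a synergistic triplet
#' (default weight 60) shared by all strains, three additive inhibitors
#' per strain (weights 20-40), one stimulator per strain (weight -15), and
#' 20 origin-shifted metabolites (+1 log10 unit in group A).
#'
#' @param design a `"study_design"`.
#' @param synergy_weight weight of the triplet interaction (default 60;
#'   around 120 the synergy dominates the assay noise, the regime in which
#'   combinatorial selection is expected to recover the triplet).
#' @return A `"planted_truth"`.
#' @export
default_truth <- function(design, synergy_weight = 60) {
  ids <- .metab_ids(design)
  set.seed(design$seed + 101L)
  pool <- sample(ids, min(length(ids), 40L))
  if (length(pool) < 4L) stop("design too small for the default truth")
  triplet <- pool[1:3]
  avail <- pool[-(1:3)]
  strains <- names(design$strains)
  act <- list(); stim <- list()
  for (s in strains) {
    k <- min(3L, length(avail))
    act[[s]] <- if (k > 0)
      stats::setNames(stats::runif(k, 20, 40), avail[seq_len(k)])
    else numeric(0)
    if (k > 0) avail <- avail[-seq_len(k)]
    stim[[s]] <- if (length(avail))
      stats::setNames(-15, avail[1]) else numeric(0)
    if (length(avail)) avail <- avail[-1]
  }
  shifted <- utils::head(avail, 20L)
  planted_truth(
    active_sets = act,
    synergy_triplet = triplet,
    synergy_weight = synergy_weight,
    stimulators = stim,
    origin_shifted = stats::setNames(rep(1, length(shifted)), shifted)
  )
}

.metab_ids <- function(design) {
  n <- design$n_metabolites + design$n_unannotated_features
  sprintf("m%03d", seq_len(n))
}

.genotype_ids <- function(design) {
  sprintf("g%02d", seq_len(design$n_genotypes))
}

#' Construct an abundance matrix container
#'
#' @param values genotype x metabolite non-negative matrix with dimnames.
#' @param genotype_meta data.frame with columns `genotype`, `origin`,
#'   `root_dry_weight`.
#' @param metabolite_meta data.frame with columns `metabolite`,
#'   `chemical_class`.
#' @return An `"abundance_matrix"` list.
#' @export
abundance_matrix <- function(values, genotype_meta, metabolite_meta) {
  if (any(values < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("genotype and metabolite ids must be unique")
  if (!identical(rownames(values), genotype_meta$genotype))
    stop("genotype metadata does not match matrix rows")
  if (!identical(colnames(values), metabolite_meta$metabolite))
    stop("metabolite metadata does not match matrix columns")
  if (any(genotype_meta$root_dry_weight <= 0))
    stop("root dry weights must be positive")
  structure(list(values = values, genotype_meta = genotype_meta,
                 metabolite_meta = metabolite_meta),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix>", nrow(x$values), "genotypes x",
      ncol(x$values), "metabolites;",
      length(unique(x$metabolite_meta$chemical_class)), "classes\n")
  invisible(x)
}

#' Simulate a genotype x metabolite abundance matrix
#'
#' Abundances are log-normal: each metabolite has a log10 mean drawn from
#' U(3, 7) and a class-level log10 sd drawn from U(0.2, 0.6). Metabolites
#' listed in `truth$origin_shifted` get an additive log10 shift in origin
#' group A (default +1, i.e. a ten-fold enrichment). A fraction of entries
#' (`zero_fraction`) is set to exact zero ("feature not detected"), giving
#' presence/absence structure for Venn-type analyses. Root dry weights are
#' drawn from U(0.2, 2.0) g.
#'
#' @param design a `"study_design"`.
#' @param truth a `"planted_truth"` (origin shifts are read from it).
#' @param zero_fraction fraction of entries zeroed at random (default 0.1).
#' @return An `"abundance_matrix"`.
#' @export
simulate_abundances <- function(design, truth = planted_truth(),
                                zero_fraction = 0.1) {
  ids <- .metab_ids(design)
  bad <- setdiff(names(truth$origin_shifted), ids)
  if (length(bad))
    stop("origin_shifted references unknown metabolite id(s): ",
         paste(bad, collapse = ", "))
  set.seed(design$seed)
  g_ids <- .genotype_ids(design)
  origin <- rep(names(design$origin_split), design$origin_split)
  n_g <- design$n_genotypes
  n_m <- length(ids)

  classes <- sprintf("class%02d", seq_len(design$n_classes))
  metab_class <- sample(rep_len(classes, n_m))
  class_sd <- stats::setNames(stats::runif(design$n_classes, 0.2, 0.6), classes)

  mu <- stats::runif(n_m, 3, 7)
  logv <- matrix(stats::rnorm(n_g * n_m, sd = rep(class_sd[metab_class],
                                                  each = n_g)),
                 n_g, n_m)
  logv <- sweep(logv, 2, mu, `+`)
  shift_idx <- match(names(truth$origin_shifted), ids)
  if (length(shift_idx))
    logv[origin == "A", shift_idx] <-
      sweep(logv[origin == "A", shift_idx, drop = FALSE], 2,
            truth$origin_shifted, `+`)
  vals <- 10^logv
  if (zero_fraction > 0)
    vals[stats::runif(n_g * n_m) < zero_fraction] <- 0
  dimnames(vals) <- list(g_ids, ids)

  gm <- data.frame(genotype = g_ids, origin = origin,
                   root_dry_weight = stats::runif(n_g, 0.2, 2.0),
                   stringsAsFactors = FALSE)
  mm <- data.frame(metabolite = ids, chemical_class = metab_class,
                   annotated = seq_len(n_m) <= design$n_metabolites,
                   stringsAsFactors = FALSE)
  out <- abundance_matrix(vals, gm, mm)
  attr(out, "design") <- design
  out
}

#' Construct an inhibition matrix container
#'
#' @param replicates long data.frame with columns `genotype`, `strain`,
#'   `replicate`, `aoi`.
#' @param strains named character vector strain -> domain, optional.
#' @return An `"inhibition_matrix"` with mean and standard-error matrices
#'   computed from the replicate table.
#' @export
inhibition_matrix <- function(replicates, strains = NULL) {
  req <- c("genotype", "strain", "replicate", "aoi")
  if (!all(req %in% names(replicates)))
    stop("replicate table needs columns: ", paste(req, collapse = ", "))
  if (any(replicates$aoi > 100 + 1e-9))
    stop("AOI% cannot exceed 100 (complete inhibition)")
  g <- unique(replicates$genotype); s <- unique(replicates$strain)
  mean_mat <- tapply(replicates$aoi,
                     list(factor(replicates$genotype, g),
                          factor(replicates$strain, s)), mean)
  se_mat <- tapply(replicates$aoi,
                   list(factor(replicates$genotype, g),
                        factor(replicates$strain, s)),
                   function(v) stats::sd(v) / sqrt(length(v)))
  structure(list(aoi = mean_mat, se = se_mat, replicates = replicates,
                 strains = strains),
            class = "inhibition_matrix")
}

#' @export
print.inhibition_matrix <- function(x, ...) {
  cat("<inhibition_matrix>", nrow(x$aoi), "genotypes x", ncol(x$aoi),
      "strains; AOI% range",
      sprintf("[%.1f, %.1f]\n", min(x$aoi), max(x$aoi)))
  invisible(x)
}

# logistic squashing of a standardized log-abundance
.squash <- function(z) stats::plogis(z)

#' Simulate per-strain inhibition (AOI%) from abundances and planted truth
#'
#' For genotype g and strain s the expected AOI is
#' `sum over active metabolites of w * sigma(z) + w_syn * prod over triplet
#' of sigma(z) + sum over stimulators of w' * sigma(z)`, where `z` is the
#' column-standardized log10(abundance + 1) and `sigma` the logistic
#' function; Gaussian noise (`truth$noise_sd`) is added per cell and
#' replicate noise (`truth$replicate_sd`) per replicate, then values are
#' clipped to [-40, 100]. Negative AOI (growth stimulation) is preserved.
#'
#' @param abundance an `"abundance_matrix"`.
#' @param truth a `"planted_truth"`.
#' @param strains named character vector strain -> domain; defaults to the
#'   design stored on `abundance`, else the four-strain default.
#' @param n_replicates replicates per (genotype, strain) cell (default 3).
#' @param seed integer; defaults to the design seed + 1.
#' @return An `"inhibition_matrix"`.
#' @export
simulate_inhibition <- function(abundance, truth, strains = NULL,
                                n_replicates = 3, seed = NULL) {
  design <- attr(abundance, "design")
  if (is.null(strains))
    strains <- if (!is.null(design)) design$strains else
      c(NF = "AOA", NV = "AOA", NM = "AOB", NU = "AOB")
  if (is.null(seed))
    seed <- if (!is.null(design)) design$seed + 1L else 1L
  ids <- colnames(abundance$values)
  referenced <- unique(c(unlist(lapply(truth$active_sets, names)),
                         truth$synergy_triplet,
                         unlist(lapply(truth$stimulators, names))))
  bad <- setdiff(referenced, ids)
  if (length(bad))
    stop("planted truth references unknown metabolite id(s): ",
         paste(bad, collapse = ", "))

  z <- scale(log10(abundance$values + 1))
  z[is.nan(z)] <- 0  # constant columns carry no signal
  sig <- .squash(z)
  g_ids <- rownames(abundance$values)
  n_g <- length(g_ids)
  set.seed(seed)

  syn_w <- truth$synergy_weight
  if (length(syn_w) == 1L && is.null(names(syn_w)))
    syn_w <- stats::setNames(rep(syn_w, length(strains)), names(strains))

  rep_rows <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    s <- names(strains)[i]
    mu <- rep(0, n_g)
    aw <- truth$active_sets[[s]]
    if (length(aw)) mu <- mu + sig[, names(aw), drop = FALSE] %*% aw
    sw <- truth$stimulators[[s]]
    if (length(sw)) mu <- mu + sig[, names(sw), drop = FALSE] %*% sw
    if (length(truth$synergy_triplet)) {
      tri <- sig[, truth$synergy_triplet, drop = FALSE]
      w <- if (s %in% names(syn_w)) syn_w[[s]] else 0
      if (truth$additive_only) {
        mu <- mu + rowSums(tri) * (w / 3)
      } else {
        mu <- mu + apply(tri, 1, prod) * w
      }
    }
    mu <- mu + stats::rnorm(n_g, sd = truth$noise_sd)
    reps <- matrix(rep(mu, n_replicates), n_g, n_replicates) +
      matrix(stats::rnorm(n_g * n_replicates, sd = truth$replicate_sd),
             n_g, n_replicates)
    reps <- pmin(pmax(reps, -40), 100)
    rep_rows[[i]] <- data.frame(
      genotype = rep(g_ids, n_replicates),
      strain = s,
      replicate = rep(seq_len(n_replicates), each = n_g),
      aoi = as.vector(reps),
      stringsAsFactors = FALSE)
  }
  inhibition_matrix(do.call(rbind, rep_rows), strains = strains)
}

#' Simulate a full synthetic study
#'
#' @param design a `"study_design"`.
#' @param truth a `"planted_truth"`; defaults to [default_truth()].
#' @param ... passed to [simulate_abundances()].
#' @return A `"synthetic_study"` list with `abundance`, `inhibition`,
#'   `truth`, `design`.
#' @export
simulate_study <- function(design = study_design(),
                           truth = default_truth(design), ...) {
  ab <- simulate_abundances(design, truth, ...)
  inh <- simulate_inhibition(ab, truth)
  structure(list(abundance = ab, inhibition = inh, truth = truth,
                 design = design),
            class = "synthetic_study")
}

#' Simulate a nitrite dose-response series
#'
#' Nitrite accumulates linearly in time at a dose-dependent rate. Under
#' `"sigmoidal"` kinetics the rate is `top * (1 - c^h / (c^h + ec50^h))`
#' (four-parameter-logistic inhibition with floor 0); under `"linear"`
#' kinetics it is `top * max(0, 1 - c / (2 * ec50))`. Both cross 50% of the
#' control rate exactly at `c = ec50`. Concentration 0 is the untreated
#' control. Replicate noise is multiplicative with coefficient of variation
#' `noise_cv`.
#'
#' @param ec50 concentration halving activity (uM), > 0.
#' @param hill Hill slope (dimensionless), sigmoidal kinetics only.
#' @param top control nitrite production rate (uM/h), > 0.
#' @param n_conc number of nonzero concentrations, log-spaced over
#'   `conc_range` (default ec50/30 .. ec50*30).
#' @param noise_cv replicate coefficient of variation (fraction).
#' @param kinetics `"sigmoidal"` or `"linear"`.
#' @param timepoints sampling times (h).
#' @param n_replicates replicates per well.
#' @param conc_range length-2 range of nonzero concentrations (uM).
#' @param seed integer seed.
#' @return A `"dose_response"` data.frame with columns `concentration`,
#'   `timepoint`, `replicate`, `nitrite`; attributes record the generating
#'   parameters.
#' @export
simulate_doseresponse <- function(ec50, hill = 1, top = 10, n_conc = 8,
                                  noise_cv = 0,
                                  kinetics = c("sigmoidal", "linear"),
                                  timepoints = c(0, 2, 4, 6, 8),
                                  n_replicates = 3,
                                  conc_range = c(ec50 / 30, ec50 * 30),
                                  seed = 1L) {
  kinetics <- match.arg(kinetics)
  if (ec50 <= 0 || top <= 0) stop("ec50 and top must be positive")
  if (n_conc < 1) stop("need at least one nonzero concentration")
  conc <- c(0, 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                      length.out = n_conc))
  rate <- switch(kinetics,
    sigmoidal = top * (1 - conc^hill / (conc^hill + ec50^hill)),
    linear = top * pmax(0, 1 - conc / (2 * ec50)))
  rate[conc == 0] <- top
  grid <- expand.grid(concentration = conc, timepoint = timepoints,
                      replicate = seq_len(n_replicates))
  set.seed(seed)
  mult <- if (noise_cv > 0)
    pmax(0, 1 + stats::rnorm(nrow(grid), sd = noise_cv)) else 1
  grid$nitrite <- rate[match(grid$concentration, conc)] * grid$timepoint * mult
  structure(grid,
            class = c("dose_response", "data.frame"),
            ec50 = ec50, hill = hill, top = top, kinetics = kinetics)
}

#' Write a synthetic study to disk as plain-text tables
#'
#' Writes the abundance matrix, genotype metadata, metabolite metadata and
#' replicate-level inhibition table as TSV, and the planted truth as JSON.
#'
#' @param study a `"synthetic_study"`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    inhibition = file.path(dir, "inhibition.tsv"),
    truth = file.path(dir, "truth.json"))
  ab <- study$abundance
  utils::write.table(
    data.frame(genotype = rownames(ab$values), ab$values,
               check.names = FALSE),
    paths["abundance"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ab$genotype_meta, paths["genotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ab$metabolite_meta, paths["metabolites"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$inhibition$replicates, paths["inhibition"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(study$truth), paths["truth"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a synthetic study written by [write_study()]
#'
#' @param dir directory containing the study tables.
#' @return A list with `abundance` and `inhibition` (the planted truth is
#'   re-read verbatim into `truth` when present).
#' @export
read_study <- function(dir) {
  ab_tab <- utils::read.delim(file.path(dir, "abundance.tsv"),
                              check.names = FALSE)
  vals <- as.matrix(ab_tab[, -1, drop = FALSE])
  rownames(vals) <- ab_tab$genotype
  gm <- utils::read.delim(file.path(dir, "genotypes.tsv"))
  mm <- utils::read.delim(file.path(dir, "metabolites.tsv"))
  ab <- abundance_matrix(vals, gm, mm)
  reps <- utils::read.delim(file.path(dir, "inhibition.tsv"))
  inh <- inhibition_matrix(reps)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(abundance = ab, inhibition = inh, truth = truth)
}
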