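# Molecular-formula parsing, monoisotopic masses, adduct ion m/z and ppm
# mass accuracy for metabolite annotation records.

# Monoisotopic masses (Da) of the lightest stable isotope, CODATA/AME values.
.MONO_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

.PROTON_MASS <- 1.00727646688  # m(1H) - m(e-), Da

# Supported ion species: label -> (mass delta added to the neutral
# monoisotopic mass, charge). Water loss uses the monoisotopic mass of H2O.
.ION_SPECIES <- list(
  "[M+H]+"      = list(mass_delta = 1.00727646688, charge = 1L),
  "[M-H2O+H]+"  = list(mass_delta = 1.00727646688 - (2 * 1.00782503207 + 15.9949146196),
                       charge = 1L)
)

#' Parse a molecular formula string
#'
#' Parses an element-count formula such as `"C5H4N4O3"` into a named integer
#' vector of element counts. Underscores and unicode subscript digits, as they
#' appear in typeset annotation tables (`"C_5_H_4_N_4_O_3_"`), are tolerated
#' and stripped before parsing. Only the elements C, H, N, O, P and S are
#' supported; any other symbol is an error, never a silent zero mass.
#'
#' @param text a single formula string.
#' @return An object of class `"formula_counts"`: a named integer vector of
#'   per-element atom counts in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C5H4N4O3")
#' parse_formula("C_6_H_6_N_2_O_")   # typeset variant
#' @seealso [monoisotopic_mass()], [ion_mz()], [format_formula()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single formula string")
  clean <- gsub("_", "", text)
  # map unicode subscript digits to ASCII
  subs <- c("₀", "₁", "₂", "₃", "₄",
            "₅", "₆", "₇", "₈", "₉")
  for (i in seq_along(subs)) clean <- gsub(subs[i], as.character(i - 1L), clean)
  clean <- gsub("[[:space:]]", "", clean)
  if (!nzchar(clean)) stop("empty formula string")
  if (grepl("[^A-Za-z0-9]", clean))
    stop("formula contains unsupported characters: ", text)

  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(clean))
    stop("could not parse formula: ", text)

  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.MONO_MASS))
      stop("unknown element symbol '", sym, "' (supported: ",
           paste(names(.MONO_MASS), collapse = ", "), ")")
    if (n < 1L) stop("element count must be >= 1 for ", sym)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  if (sum(counts) < 1L) stop("formula must contain at least one atom")
  structure(.hill_order(counts), class = "formula_counts")
}

# Hill convention: carbon first, then hydrogen, then remaining alphabetical;
# no carbon -> all alphabetical.
.hill_order <- function(counts) {
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  counts[ord]
}

#' Format element counts as a canonical Hill-order formula string
#'
#' @param f a `"formula_counts"` object or named count vector.
#' @return A single string, e.g. `"C5H4N4O3"`; unit counts are printed
#'   without a digit.
#' @export
format_formula <- function(f) {
  f <- .as_formula_counts(f)
  paste0(vapply(names(f), function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

.as_formula_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (!is.numeric(f) || is.null(names(f)) || length(f) == 0L)
    stop("formula must be a string or a named count vector")
  bad <- setdiff(names(f), names(.MONO_MASS))
  if (length(bad))
    stop("unknown element symbol '", bad[1], "' (supported: ",
         paste(names(.MONO_MASS), collapse = ", "), ")")
  if (any(f < 1) || any(f != round(f))) stop("element counts must be integers >= 1")
  structure(.hill_order(stats::setNames(as.integer(f), names(f))),
            class = "formula_counts")
}

#' Monoisotopic mass of a neutral molecule
#'
#' Sums per-element monoisotopic masses over the formula's atom counts.
#'
#' @param f formula string or parsed `"formula_counts"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0105646...
#' monoisotopic_mass("C5H4N4O3")   # uric acid, 168.02834
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula_counts(f)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Theoretical m/z of an adduct ion
#'
#' Computes `(M + mass_delta) / |z|` for a supported ion species, where `M`
#' is the neutral monoisotopic mass. The protonated species uses the proton
#' mass (electron-corrected), which reproduces high-resolution annotation
#' m/z values to 4 decimals; `"[M-H2O+H]+"` additionally subtracts one
#' monoisotopic water.
#'
#' @param f formula string or parsed counts.
#' @param ion ion-species label, `"[M+H]+"` or `"[M-H2O+H]+"`.
#' @return Theoretical m/z in Da (not rounded).
#' @examples
#' ion_mz("C5H4N4O3", "[M+H]+")   # 169.03562 (uric acid)
#' @export
ion_mz <- function(f, ion = "[M+H]+") {
  spec <- .ION_SPECIES[[ion]]
  if (is.null(spec))
    stop("unknown ion species '", ion, "'; supported: ",
         paste(names(.ION_SPECIES), collapse = ", "))
  (monoisotopic_mass(f) + spec$mass_delta) / abs(spec$charge)
}

#' Signed mass error in parts per million
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da), must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6` (ppm, signed).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Round half away from zero
#'
#' Display rounding used for theoretical m/z values; unlike [round()],
#' halves move away from zero (169.03565 -> 169.0357 at 4 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Validate and enrich a metabolite annotation table
#'
#' Reads (or takes) an annotation sidecar with columns `name`,
#' `annotation_level`, `formula`, `chemical_class`, `ion_species`, `mz`,
#' `rt_min` and optional `inchikey`, `mass_accuracy_ppm`. Recomputes the
#' theoretical ion m/z from the formula, the ppm error against the observed
#' m/z, and flags rows where the recomputed ppm differs from a reported ppm
#' by more than `flag_ppm` (reported ppm values are instrument metadata
#' computed from unrounded masses and need not be recoverable from rounded
#' printed m/z).
#'
#' @param x a data.frame or a path to a CSV/TSV file.
#' @param flag_ppm discrepancy threshold in ppm for `ppm_flag` (default 2).
#' @return The input data.frame with added columns `theoretical_mz`
#'   (rounded to 4 decimals), `recomputed_ppm`, and logical `ppm_flag`.
#' @export
annotate_records <- function(x, flag_ppm = 2) {
  if (is.character(x)) x <- read_table_auto(x)
  req <- c("name", "annotation_level", "formula", "chemical_class",
           "ion_species", "mz", "rt_min")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$mz <= 0)) stop("observed m/z must be positive")
  if (any(x$rt_min < 0)) stop("retention time must be non-negative")
  if (!all(x$annotation_level %in% 1:4))
    stop("annotation_level must be in 1..4")
  theo <- mapply(function(f, ion) ion_mz(f, ion), x$formula, x$ion_species)
  x$theoretical_mz <- round_half_away(theo, 4)
  x$recomputed_ppm <- ppm_error(x$mz, theo)
  if ("mass_accuracy_ppm" %in% names(x)) {
    x$ppm_flag <- abs(x$recomputed_ppm - x$mass_accuracy_ppm) > flag_ppm
  } else {
    x$ppm_flag <- FALSE
  }
  x
}

# Read CSV or TSV by extension (".tsv"/".txt" -> tab).
read_table_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.formula_counts <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}
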