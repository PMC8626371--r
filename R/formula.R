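# Molecular formula algebra: parsing, peptide conversion, masses.

#' Parse a molecular formula string
#'
#' Accepts the usual Hill-style element-count grammar: an element symbol
#' (capital letter plus optional lowercase letter) followed by an optional
#' positive count, repeated; whitespace between tokens is tolerated.
#' `"C46H83N15O14"` and `"C46 H83 N15 O14"` are equivalent.
#'
#' @param text A single formula string.
#' @param isotopes Isotope reference table (see [isotope_table()]); element
#'   symbols must be present in it.
#' @return A `molecular_formula`: a named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C23H38N7O17P3S")  # acetyl-CoA
#' @export
parse_formula <- function(text, isotopes = isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single string", call. = FALSE)
  }
  stripped <- gsub("[[:space:]]+", "", text)
  if (!nzchar(stripped)) {
    stop("empty formula: '", text, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", stripped)[[1]]
  tokens <- regmatches(stripped, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(stripped)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(counts), suppressWarnings(as.integer(counts)), 1L)
  if (anyNA(n) || any(n <= 0L) || any(grepl("^0", counts))) {
    stop("formula counts must be positive integers: '", text, "'",
         call. = FALSE)
  }
  out <- tapply(n, factor(elements, levels = unique(elements)), sum)
  as_formula(stats::setNames(as.integer(out), names(out)), isotopes = isotopes)
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named non-negative integer vector (names are element
#'   symbols), or a formula string (delegated to [parse_formula()]).
#' @param isotopes Isotope reference table.
#' @return A `molecular_formula` object.
#' @export
as_formula <- function(counts, isotopes = isotope_table()) {
  if (inherits(counts, "molecular_formula")) return(counts)
  if (is.character(counts)) return(parse_formula(counts, isotopes))
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  known <- unique(isotopes$element)
  unknown <- setdiff(names(counts), known)
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  out <- stats::setNames(as.integer(counts), names(counts))
  out <- out[order(match(names(out), c("C", "H", setdiff(sort(known), c("C", "H")))))]
  structure(out, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty formula)")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

# Sum of two formulas (or subtraction with negative check).
formula_add <- function(a, b, sign = 1L) {
  elements <- union(names(a), names(b))
  ca <- stats::setNames(integer(length(elements)), elements)
  ca[names(a)] <- unclass(a)
  cb <- stats::setNames(integer(length(elements)), elements)
  cb[names(b)] <- unclass(b)
  out <- ca + sign * cb
  if (any(out < 0L)) {
    stop("formula subtraction gives negative counts for: ",
         paste(elements[out < 0L], collapse = ", "), call. = FALSE)
  }
  as_formula(out)
}

# Monomer residue compositions (residue = amino acid minus water).
AMINO_ACID_RESIDUES <- list(
  G = c(C = 2L, H = 3L, N = 1L, O = 1L),
  A = c(C = 3L, H = 5L, N = 1L, O = 1L),
  S = c(C = 3L, H = 5L, N = 1L, O = 2L),
  P = c(C = 5L, H = 7L, N = 1L, O = 1L),
  V = c(C = 5L, H = 9L, N = 1L, O = 1L),
  T = c(C = 4L, H = 7L, N = 1L, O = 2L),
  C = c(C = 3L, H = 5L, N = 1L, O = 1L, S = 1L),
  L = c(C = 6L, H = 11L, N = 1L, O = 1L),
  I = c(C = 6L, H = 11L, N = 1L, O = 1L),
  N = c(C = 4L, H = 6L, N = 2L, O = 2L),
  D = c(C = 4L, H = 5L, N = 1L, O = 3L),
  Q = c(C = 5L, H = 8L, N = 2L, O = 2L),
  K = c(C = 6L, H = 12L, N = 2L, O = 1L),
  E = c(C = 5L, H = 7L, N = 1L, O = 3L),
  M = c(C = 5L, H = 9L, N = 1L, O = 1L, S = 1L),
  H = c(C = 6L, H = 7L, N = 3L, O = 1L),
  F = c(C = 9L, H = 9L, N = 1L, O = 1L),
  R = c(C = 6L, H = 12L, N = 4L, O = 1L),
  Y = c(C = 9L, H = 9L, N = 1L, O = 2L),
  W = c(C = 11L, H = 10L, N = 2L, O = 1L)
)

#' Shipped post-translational modification dictionary
#'
#' Reads the packaged (or a user-supplied) two-column CSV mapping modification
#' names to the formula added to the peptide, e.g. acetyl = C2H2O.
#'
#' @param path Optional path to a custom `name,formula` CSV.
#' @return Named list of `molecular_formula` deltas.
#' @export
modification_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.csv", package = "isofine",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(lapply(tab$formula, parse_formula), tolower(tab$name))
}

#' Elemental composition of a peptide
#'
#' Sums the residue compositions of a one-letter amino-acid sequence, adds one
#' water for the termini, and adds the formula delta of each modification.
#' Modifications are given by name (looked up in [modification_table()]) or as
#' formula strings / `molecular_formula` objects.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param modifications Character vector of modification names (repeated names
#'   mean multiple occurrences, e.g. `c("acetyl", "acetyl")`), or a list of
#'   formula deltas.
#' @param mod_table Modification dictionary, default [modification_table()].
#' @return A `molecular_formula`.
#' @examples
#' peptide_formula("G")                                    # C2H5NO2, glycine
#' peptide_formula("KQLATKAAR", c("acetyl", "acetyl"))     # C46H83N15O14
#' @export
peptide_formula <- function(sequence, modifications = character(),
                            mod_table = modification_table()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  letters1 <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  unknown <- setdiff(letters1, names(AMINO_ACID_RESIDUES))
  if (length(unknown) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  out <- as_formula(c(H = 2L, O = 1L))  # termini
  for (aa in letters1) out <- formula_add(out, AMINO_ACID_RESIDUES[[aa]])
  if (is.character(modifications)) {
    mods <- lapply(tolower(modifications), function(nm) {
      if (!nm %in% names(mod_table)) {
        stop("unknown modification: '", nm, "' (known: ",
             paste(names(mod_table), collapse = ", "), ")", call. = FALSE)
      }
      mod_table[[nm]]
    })
  } else {
    mods <- lapply(modifications, as_formula)
  }
  for (m in mods) out <- formula_add(out, m)
  out
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula A `molecular_formula` (or anything [as_formula()] accepts).
#' @param isotopes Isotope reference table.
#' @return Mass in Da using principal-isotope exact masses.
#' @export
monoisotopic_mass <- function(formula, isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  if (length(formula) == 0L) stop("empty formula", call. = FALSE)
  sum(unclass(formula) * principal_masses(names(formula), isotopes))
}

#' Monoisotopic m/z of a protonated ion
#'
#' Computes `(M + shift + z * 1.007276) / z` where `M` is the monoisotopic
#' neutral mass and `shift` the exact mass shift of an optional tracer label.
#' Protonation is the only adduct modelled.
#'
#' @param formula A `molecular_formula`.
#' @param charge Positive integer charge state.
#' @param label Optional [label_spec()] (or label name string) whose exact
#'   shift is added to the neutral mass, e.g. `"2C13"` for a peptide carrying
#'   one 13C2-acetyl group.
#' @param isotopes Isotope reference table.
#' @return m/z in Da.
#' @examples
#' f <- peptide_formula("KQLATKAAR", c("acetyl", "acetyl"))
#' monoisotopic_mz(f, charge = 2)                  # 535.8195
#' monoisotopic_mz(f, charge = 2, label = "2C13")  # 536.8228
#' @export
monoisotopic_mz <- function(formula, charge, label = NULL,
                            isotopes = isotope_table()) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  mass <- monoisotopic_mass(formula, isotopes)
  if (!is.null(label)) {
    label <- as_label(label, isotopes)
    mass <- mass + label$shift
  }
  (mass + charge * PROTON_MASS) / charge
}

#' Residual formula after removing tracer-labelled atoms
#'
#' Atoms carrying the tracer label are isotopically defined, so they are
#' removed from the pool of atoms that can carry *natural* heavy isotopes: a
#' molecule with all light atoms replaced by heavy tracer atoms has no heavier
#' natural isotopologues. This is the basis of the skewed correction matrix.
#'
#' @param formula A `molecular_formula`.
#' @param label A [label_spec()] (or label name string such as `"2C13 1N15"`).
#' @param isotopes Isotope reference table.
#' @return The `molecular_formula` of the unlabelled atoms.
#' @examples
#' residual_formula(parse_formula("C2H3O"), "2C13")  # H3O
#' @export
residual_formula <- function(formula, label, isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  label <- as_label(label, isotopes)
  if (length(label$counts) == 0L) return(formula)
  elems <- sub("[0-9]+$", "", names(label$counts))
  removed <- tapply(label$counts, elems, sum)
  avail <- stats::setNames(integer(length(removed)), names(removed))
  present <- intersect(names(removed), names(formula))
  avail[present] <- unclass(formula)[present]
  if (any(removed > avail)) {
    bad <- names(removed)[removed > avail]
    stop("label '", label$name, "' exceeds available atoms of: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  formula_add(formula, stats::setNames(as.integer(removed), names(removed)),
              sign = -1L)
}
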