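# Tracer label specifications ("2C13", "1N15", "2C13 1N15", "No label").

#' Construct a tracer label specification
#'
#' A label specifies how many atoms of the molecule carry each tracer isotope.
#' The canonical name grammar is a space-separated list of `<count><Element>
#' <mass number>` tokens such as `"2C13"` (two \eqn{^{13}}C) or `"2C13 1N15"`
#' (two \eqn{^{13}}C plus one \eqn{^{15}}N); the unlabelled species is the
#' literal `"No label"`. Tracer atoms are treated as isotopically pure.
#'
#' @param counts Named integer vector of labelled-atom counts keyed by isotope
#'   code (e.g. `c(C13 = 2, N15 = 1)`), or a name string in the grammar above.
#' @param isotopes Isotope reference table; tracer isotopes must be
#'   non-principal entries of it.
#' @return A `label_spec`: list with `name` (canonical string), `counts`
#'   (named integer vector) and `shift` (exact mass shift in Da, the sum of
#'   count times isotope mass shift; 0 for "No label").
#' @examples
#' label_spec("2C13 1N15")$shift  # 2*1.003355 + 0.997035
#' label_spec(c(C13 = 4))$name    # "4C13"
#' @export
label_spec <- function(counts, isotopes = isotope_table()) {
  if (is.character(counts)) return(parse_label(counts, isotopes))
  if (length(counts) > 0L && (is.null(names(counts)) || anyNA(counts) ||
                              any(counts < 0) || any(counts != round(counts)))) {
    stop("label counts must be a named vector of non-negative integers",
         call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (is.null(names(counts))) names(counts) <- character(0)
  codes <- isotope_code(isotopes)
  idx <- match(names(counts), codes)
  if (anyNA(idx)) {
    stop("unknown isotope code(s): ",
         paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (any(isotopes$principal[idx])) {
    stop("principal isotopes cannot be tracers: ",
         paste(names(counts)[isotopes$principal[idx]], collapse = ", "),
         call. = FALSE)
  }
  ord <- order(names(counts))
  counts <- stats::setNames(as.integer(counts[ord]), names(counts)[ord])
  idx <- idx[ord]
  shift <- sum(counts * isotopes$shift[idx])
  name <- if (length(counts) == 0L) {
    "No label"
  } else {
    paste0(counts, names(counts), collapse = " ")
  }
  structure(list(name = name, counts = counts, shift = shift),
            class = "label_spec")
}

#' Parse a label name string
#'
#' @param text Label name in the canonical grammar (see [label_spec()]).
#' @param isotopes Isotope reference table.
#' @return A `label_spec`.
#' @export
parse_label <- function(text, isotopes = isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("label must be a single string", call. = FALSE)
  }
  trimmed <- trimws(text)
  if (tolower(trimmed) %in% c("no label", "nolabel", "unlabelled", "unlabeled")) {
    return(label_spec(stats::setNames(integer(0), character(0)), isotopes))
  }
  tokens <- strsplit(trimmed, "[[:space:]]+")[[1]]
  m <- regmatches(tokens, regexec("^([1-9][0-9]*)([A-Z][a-z]?)([1-9][0-9]*)$",
                                  tokens))
  bad <- tokens[vapply(m, length, 1L) == 0L]
  if (length(bad) > 0L) {
    stop("cannot parse label '", text, "': token(s) ",
         paste0("'", bad, "'", collapse = ", "),
         " do not match the grammar '<count><Element><mass number>' ",
         "(e.g. '2C13', '1N15') or the literal 'No label'", call. = FALSE)
  }
  counts <- vapply(m, function(x) as.integer(x[2]), 1L)
  codes <- vapply(m, function(x) paste0(x[3], x[4]), "")
  if (anyDuplicated(codes)) {
    stop("duplicate isotope code in label '", text, "'", call. = FALSE)
  }
  label_spec(stats::setNames(counts, codes), isotopes)
}

# Coerce strings / label_spec.
as_label <- function(x, isotopes = isotope_table()) {
  if (inherits(x, "label_spec")) return(x)
  label_spec(x, isotopes)
}

#' @export
print.label_spec <- function(x, ...) {
  cat(sprintf("<label> %s (shift %+0.6f Da)\n", x$name, x$shift))
  invisible(x)
}

# Check a label is feasible for a formula (enough atoms of each element).
validate_label_for <- function(label, formula, isotopes = isotope_table()) {
  invisible(residual_formula(formula, label, isotopes))
}
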