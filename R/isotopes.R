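# Element/isotope reference data.

the <- new.env(parent = emptyenv())

#' Load an element/isotope reference table
#'
#' Reads a CSV table of stable isotopes (columns `element`, `mass_number`,
#' `exact_mass` in Da, `abundance` as a fraction) and validates it. The
#' packaged default covers C, H, N, O, P and S with the standard natural
#' abundances (e.g. 1.07% for \eqn{^{13}}C). Per element the *principal*
#' isotope is the most abundant one, which for these elements is also the
#' lightest; every other isotope is characterised by its positive mass shift
#' relative to the principal isotope.
#'
#' @param path Path to a CSV file in the format above, or `NULL` for the
#'   packaged default table. Users can supply their own table to override
#'   abundances (e.g. for enriched growth media).
#' @return A `data.frame` with columns `element`, `mass_number`, `exact_mass`,
#'   `abundance`, `principal` (logical) and `shift` (Da, 0 for the principal
#'   isotope), ordered by element and mass number.
#' @examples
#' it <- isotope_table()
#' subset(it, element == "C")
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$isotopes)) return(the$isotopes)
    path <- system.file("extdata", "isotopes.csv", package = "isofine",
                        mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("element", "mass_number", "exact_mass", "abundance")
  if (!all(required %in% names(tab))) {
    stop("isotope table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$abundance < 0 | tab$abundance > 1)) {
    stop("isotope abundances must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(tab$exact_mass - tab$mass_number) >= 0.2)) {
    stop("exact masses deviate from mass numbers by >= 0.2 Da", call. = FALSE)
  }
  tab <- tab[order(tab$element, tab$mass_number), , drop = FALSE]
  sums <- tapply(tab$abundance, tab$element, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    bad <- names(sums)[abs(sums - 1) > 1e-6]
    stop("abundances do not sum to 1 for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab$principal <- stats::ave(tab$abundance, tab$element,
                              FUN = function(a) a == max(a)) > 0
  pr <- tab[tab$principal, c("element", "exact_mass")]
  tab$shift <- tab$exact_mass - pr$exact_mass[match(tab$element, pr$element)]
  if (any(tab$shift < 0)) {
    stop("non-principal isotopes lighter than the principal isotope are not ",
         "supported", call. = FALSE)
  }
  rownames(tab) <- NULL
  if (default) the$isotopes <- tab
  tab
}

#' @keywords internal
isotope_code <- function(tab) paste0(tab$element, tab$mass_number)

# Rows of the isotope table for one element; principal first.
element_isotopes <- function(element, isotopes = isotope_table()) {
  rows <- isotopes[isotopes$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown element: '", element, "'", call. = FALSE)
  }
  rows[order(!rows$principal, rows$mass_number), , drop = FALSE]
}

# Mass of the principal isotope of each requested element.
principal_masses <- function(elements, isotopes = isotope_table()) {
  pr <- isotopes[isotopes$principal, , drop = FALSE]
  idx <- match(elements, pr$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ",
         paste(elements[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(pr$exact_mass[idx], elements)
}

PROTON_MASS <- 1.007276
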