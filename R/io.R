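# Reading and writing measurement tables.
#
# The canonical on-disk form is a TSV (or CSV) with one row per sample, an
# optional `sample` identifier column, an optional `time` column (hours,
# triggers time-course analysis in the CLI) and one column per measured
# isotopologue, named in the label grammar: "No label", "2C13", "4C13",
# "2C13 1N15", ...

#' Read a measurement table
#'
#' @param path Path to a tab-delimited (`.tsv`/`.txt`) or comma-separated
#'   (`.csv`) file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param isotopes Isotope reference table used to validate label columns.
#' @return A validated data.frame; isotopologue columns renamed to canonical
#'   label names, metadata columns (`sample`, `time`, ...) untouched. The
#'   dialect used is stored in attribute `"dialect"`.
#' @export
read_measurements <- function(path, dialect = c("auto", "tsv", "csv"),
                              isotopes = isotope_table()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    dialect <- if (ext == "csv") "csv" else "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  meta <- tolower(names(df)) %in% c("sample", "time", "compound", "charge")
  for (ci in which(!meta)) {
    lb <- tryCatch(parse_label(names(df)[ci], isotopes), error = function(e) e)
    if (inherits(lb, "error")) {
      stop("column '", names(df)[ci], "' in ", path,
           " is not a valid isotopologue label: ", conditionMessage(lb),
           call. = FALSE)
    }
    names(df)[ci] <- lb$name
    if (!is.numeric(df[[ci]])) {
      stop("column '", names(df)[ci], "' must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(df[[ci]]) | df[[ci]] < 0)
    if (length(bad) > 0L) {
      stop("negative or non-finite intensity in column '", names(df)[ci],
           "', row(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  label_names <- names(df)[!meta]
  if (anyDuplicated(label_names)) {
    stop("duplicate isotopologue columns: ",
         paste(unique(label_names[duplicated(label_names)]), collapse = ", "),
         call. = FALSE)
  }
  attr(df, "dialect") <- dialect
  df
}

#' Write a correction result
#'
#' Writes the corrected intensity table to `path` in the requested dialect,
#' the relative-fraction table (when present) next to it with a `_fractions`
#' suffix, and a plain-text log of warnings (clipped negatives, all-zero
#' samples) with a `.log` suffix when any occurred. Reruns on identical input
#' produce byte-identical files.
#'
#' @param result A [correct_isotopologues()] result, or a bare data.frame.
#' @param path Output path; extension `.csv` selects the CSV dialect,
#'   anything else tab-delimited.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    dialect <- if (ext == "csv") "csv" else "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  write_one <- function(df, p) {
    utils::write.table(df, p, sep = sep, quote = FALSE, row.names = FALSE,
                       na = "")
  }
  paths <- character(0)
  if (inherits(result, "correction_result")) {
    write_one(result$corrected, path)
    paths <- path
    if (!is.null(result$fractions)) {
      fp <- sub("(\\.[A-Za-z0-9]+)?$", "", path)
      fp <- paste0(fp, "_fractions.", if (dialect == "csv") "csv" else "tsv")
      write_one(result$fractions, fp)
      paths <- c(paths, fp)
    }
    if (nrow(result$warnings) > 0L) {
      lp <- paste0(path, ".log")
      lines <- vapply(seq_len(nrow(result$warnings)), function(i) {
        w <- result$warnings[i, ]
        if (is.na(w$label)) {
          sprintf("sample %s: all-zero intensities; fractions undefined",
                  w$sample)
        } else {
          sprintf("sample %s, %s: negative corrected value clipped to 0 (magnitude %.6g)",
                  w$sample, w$label, w$clipped)
        }
      }, "")
      writeLines(lines, lp)
      paths <- c(paths, lp)
    }
  } else {
    write_one(as.data.frame(result, check.names = FALSE), path)
    paths <- path
  }
  invisible(paths)
}

#' Resolve a compound name or formula string
#'
#' Looks the string up in the packaged compound dictionary (a two-column
#' `name,formula` CSV, extensible by the user) and falls back to parsing it
#' as a formula.
#'
#' @param x Compound name (case-insensitive) or formula string.
#' @param path Optional custom dictionary path.
#' @return A `molecular_formula`.
#' @examples
#' compound_formula("acetyl-CoA")
#' @export
compound_formula <- function(x, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.csv", package = "isofine",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  hit <- match(tolower(trimws(x)), tolower(tab$name))
  if (!is.na(hit)) return(parse_formula(tab$formula[hit]))
  parse_formula(x)
}
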