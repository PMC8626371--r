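# Skewed (and classical) correction matrices and their inversion.
#
# The correction matrix T over the measured isotopologues has
# T[i, j] = probability that a molecule truly carrying label j is detected at
# the peak position of isotopologue i. In the skewed approach each column is
# computed from the fine structure of label j's *residual* formula (tracer
# atoms removed), so a fully labelled species cannot leak to heavier masses.
# The classical matrix (provided for comparison) reuses the full unlabelled
# formula's fine structure for every column, which biases estimates towards
# heavy isotopologues.

#' Probability that label j is detected at peak i
#'
#' Sums the probabilities of all natural fine-structure species of the
#' residual formula of `label_from` whose exact mass shift is unresolved from
#' `shift(label_to) - shift(label_from)` at the instrument's resolving power.
#' For `label_to == label_from` this is (essentially) the residual all-light
#' probability; for a target shift no residual species can reach, it is 0.
#'
#' @param formula `molecular_formula` of the compound.
#' @param label_from True label carried by the molecule ([label_spec()] or
#'   name string).
#' @param label_to Label defining the observed peak position; its exact shift
#'   must be at least that of `label_from`.
#' @param model A [resolution_model()] or `NULL` for nominal (unit-mass)
#'   merging. The resolving window is evaluated at the monoisotopic m/z of
#'   the unlabelled compound.
#' @param charge Positive integer charge state.
#' @param prune Probability threshold for the fine-structure enumeration.
#' @param isotopes Isotope reference table.
#' @return Probability in \[0, 1\].
#' @export
transition_probability <- function(formula, label_from, label_to, model = NULL,
                                   charge = 1L, prune = 1e-10,
                                   isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  label_from <- as_label(label_from, isotopes)
  label_to <- as_label(label_to, isotopes)
  target <- label_to$shift - label_from$shift
  if (target < -1e-9) {
    stop("label_to must be at least as heavy as label_from", call. = FALSE)
  }
  residual <- residual_formula(formula, label_from, isotopes)
  mz <- monoisotopic_mz(formula, charge, isotopes = isotopes)
  window <- min_separable_mass_diff(model, mz, charge)
  if (length(residual) == 0L) {
    # every atom carries the tracer: the only species is the exact label mass
    return(as.numeric(is_unresolved(0, target, model, mz, charge)))
  }
  spectrum <- fine_structure(residual, max_shift = target + window,
                             prune = prune, isotopes = isotopes)
  sum(spectrum$probability[abs(spectrum$shift - target) < window])
}

#' Build the correction matrix over the measured isotopologues
#'
#' @param formula `molecular_formula` of the compound (or peptide formula from
#'   [peptide_formula()]).
#' @param labels List (or character vector) of the measured isotopologues'
#'   labels; need not cover all possible isotopologues. Sorted internally by
#'   ascending exact shift.
#' @param model A [resolution_model()] or `NULL` for nominal merging.
#' @param charge Positive integer charge state.
#' @param method `"skewed"` (each column from its residual formula, the
#'   default) or `"classical"` (full formula for every column).
#' @param prune Fine-structure pruning threshold.
#' @param isotopes Isotope reference table.
#' @return A `correction_matrix`: list with the matrix `T` (lower-triangular
#'   in shift order, rows/columns named by canonical label names), `labels`
#'   (list of `label_spec`s, ascending shift), and the `formula`, `model`,
#'   `charge`, `method` used.
#' @examples
#' f <- peptide_formula("KQLATKAAR", c("acetyl", "acetyl"))
#' cm <- correction_matrix(f, c("No label", "2C13", "4C13"),
#'                         resolution_model(60000, 200), charge = 2)
#' cm$T
#' @export
correction_matrix <- function(formula, labels, model = NULL, charge = 1L,
                              method = c("skewed", "classical"),
                              prune = 1e-10, isotopes = isotope_table()) {
  method <- match.arg(method)
  formula <- as_formula(formula, isotopes)
  labels <- lapply(labels, as_label, isotopes = isotopes)
  names(labels) <- NULL
  nm <- vapply(labels, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate labels: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  }
  for (lb in labels) validate_label_for(lb, formula, isotopes)
  shifts <- vapply(labels, `[[`, 0, "shift")
  ord <- order(shifts)
  labels <- labels[ord]
  shifts <- shifts[ord]
  nm <- nm[ord]
  n <- length(labels)
  T <- matrix(0, n, n, dimnames = list(nm, nm))
  for (j in seq_len(n)) {
    for (i in j:n) {
      if (method == "classical") {
        # full-formula fine structure evaluated at the shift difference
        T[i, j] <- transition_probability(
          formula, label_spec(integer(0), isotopes),
          shifted_pseudo_label(shifts[i] - shifts[j], isotopes),
          model, charge, prune, isotopes)
      } else {
        T[i, j] <- transition_probability(formula, labels[[j]], labels[[i]],
                                          model, charge, prune, isotopes)
      }
    }
  }
  structure(list(T = T, labels = labels, formula = formula, model = model,
                 charge = charge, method = method, prune = prune),
            class = "correction_matrix")
}

# A label-like object carrying only an exact shift, used by the classical
# matrix where the target is a shift difference rather than a real label.
shifted_pseudo_label <- function(shift, isotopes) {
  structure(list(name = sprintf("+%.6f Da", shift),
                 counts = stats::setNames(integer(0), character(0)),
                 shift = shift),
            class = "label_spec")
}

#' @export
print.correction_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<correction matrix> %s, %s method, charge %d%s\n",
              format(x$formula), x$method, x$charge,
              if (is.null(x$model)) ", nominal resolution" else
                sprintf(", R = %g at m/z %g", x$model$resolution,
                        x$model$mz_ref)))
  print(round(x$T, digits))
  invisible(x)
}

#' Correct measured isotopologue intensities
#'
#' Solves `observed = T %*% true` per sample by forward substitution in
#' ascending shift order: `c_j = (obs_j - sum_{k<j} T[j,k] c_k) / T[j,j]`.
#' Negative solutions (from measurement noise) are clipped to zero and
#' recorded as warnings. The diagonal division rescales each isotopologue's
#' monoisotopic-peak intensity to whole-envelope species abundance.
#'
#' @param measurements A data.frame with one column per measured isotopologue
#'   (named by label, e.g. `"No label"`, `"2C13"`, `"4C13"`); any other
#'   columns (e.g. `sample`, `time`) are carried through untouched. A bare
#'   numeric vector or matrix with label names is also accepted.
#' @param matrix A [correction_matrix()].
#' @param normalize If `TRUE` (default) also return per-sample relative
#'   fractions (summing to 1 for samples with positive total).
#' @return A `correction_result`: list with `corrected` (data.frame, same
#'   shape as the input), `fractions` (or `NULL`), `warnings` (data.frame of
#'   clipped negatives: sample, label, clipped magnitude), and the `matrix`
#'   used.
#' @export
correct_isotopologues <- function(measurements, matrix, normalize = TRUE) {
  stopifnot(inherits(matrix, "correction_matrix"))
  nm <- colnames(matrix$T)
  if (is.numeric(measurements)) {
    measurements <- as.data.frame(as.list(
      stats::setNames(measurements, names(measurements))),
      check.names = FALSE, optional = TRUE)
  }
  df <- as.data.frame(measurements, check.names = FALSE)
  canon <- canonical_column_labels(names(df))
  label_cols <- which(!is.na(canon))
  missing <- setdiff(nm, canon[label_cols])
  if (length(missing) > 0L) {
    stop("measurement table lacks column(s) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(canon[label_cols], nm)
  if (length(extra) > 0L) {
    stop("measurement column(s) not in the correction matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  col_idx <- label_cols[match(nm, canon[label_cols])]
  obs <- as.matrix(df[, col_idx, drop = FALSE])
  if (!is.numeric(obs) || any(!is.finite(obs))) {
    stop("intensities must be finite numbers", call. = FALSE)
  }
  if (any(obs < 0)) stop("intensities must be >= 0", call. = FALSE)
  samples <- if ("sample" %in% names(df)) as.character(df$sample) else
    as.character(seq_len(nrow(df)))
  n <- length(nm)
  T <- matrix$T
  corrected <- obs
  warn <- list()
  for (r in seq_len(nrow(obs))) {
    x <- numeric(n)
    for (j in seq_len(n)) {
      inflow <- if (j > 1L) sum(T[j, seq_len(j - 1L)] * x[seq_len(j - 1L)]) else 0
      v <- (obs[r, j] - inflow) / T[j, j]
      if (v < 0) {
        warn[[length(warn) + 1L]] <- data.frame(
          sample = samples[r], label = nm[j], clipped = -v,
          stringsAsFactors = FALSE)
        v <- 0
      }
      x[j] <- v
    }
    corrected[r, ] <- x
  }
  out <- df
  out[, col_idx] <- corrected
  fractions <- NULL
  if (normalize) {
    totals <- rowSums(corrected)
    frac <- corrected / ifelse(totals > 0, totals, NA_real_)
    zero <- which(totals <= 0)
    for (r in zero) {
      warn[[length(warn) + 1L]] <- data.frame(
        sample = samples[r], label = NA_character_, clipped = NA_real_,
        stringsAsFactors = FALSE)
    }
    fractions <- df
    fractions[, col_idx] <- frac
  }
  warnings_df <- if (length(warn) > 0L) do.call(rbind, warn) else
    data.frame(sample = character(0), label = character(0),
               clipped = numeric(0), stringsAsFactors = FALSE)
  structure(list(corrected = out, fractions = fractions,
                 warnings = warnings_df, matrix = matrix),
            class = "correction_result")
}

# Canonical label name per column, NA for metadata columns.
canonical_column_labels <- function(cols) {
  vapply(cols, function(cl) {
    if (tolower(cl) %in% c("sample", "time", "compound", "charge")) {
      return(NA_character_)
    }
    lb <- tryCatch(parse_label(cl), error = function(e) NULL)
    if (is.null(lb)) NA_character_ else lb$name
  }, "")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction result>\n")
  print(x$corrected)
  if (!is.null(x$fractions)) {
    cat("relative fractions:\n")
    print(x$fractions)
  }
  if (nrow(x$warnings) > 0L) {
    cat(nrow(x$warnings), "warning(s); see $warnings\n")
  }
  invisible(x)
}

#' Plausible isotopologues missing from the measured set
#'
#' The correction tolerates incomplete isotopologue lists, but an unmeasured
#' intermediate receives (and contributes) nothing. This helper flags integer
#' nominal shifts strictly between measured shifts that carry appreciable
#' natural probability, so users can be warned.
#'
#' @param matrix A [correction_matrix()].
#' @param threshold Minimum natural probability (relative to the all-light
#'   species of the full formula) for a gap to be reported.
#' @return Integer vector of nominal shifts (possibly empty).
#' @export
missing_intermediates <- function(matrix, threshold = 0.01) {
  shifts <- vapply(matrix$labels, `[[`, 0, "shift")
  lo <- min(shifts)
  hi <- max(shifts)
  if (hi - lo < 1.5) return(integer(0))
  spec <- fine_structure(matrix$formula, max_shift = hi - lo,
                         prune = matrix$prune)
  agg <- nominal_aggregate(spec)
  agg$probability <- agg$probability / agg$probability[agg$nominal == 0][1]
  candidates <- agg$nominal[agg$probability >= threshold & agg$nominal > 0]
  measured_nom <- round(shifts - lo)
  setdiff(candidates, measured_nom)
}
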