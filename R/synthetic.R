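# Forward simulation and brute-force oracles.
#
# These make the whole pipeline testable without instrument data: the forward
# model is the adjoint of the correction (observed = T %*% true), the
# brute-force enumerator recomputes fine structure atom by atom, and the
# time-course simulator emulates a media-switch labelling experiment.

#' Forward-observe true isotopologue abundances
#'
#' Applies the correction matrix in the forward direction: the intensities an
#' instrument would record if the true species abundances were `x` and the
#' only distortion were natural isotope abundance.
#'
#' @param x Numeric vector of true abundances, one per matrix label (in
#'   ascending shift order, or named by label).
#' @param matrix A [correction_matrix()].
#' @return Named numeric vector of observed peak intensities.
#' @export
forward_observe <- function(x, matrix) {
  stopifnot(inherits(matrix, "correction_matrix"))
  nm <- colnames(matrix$T)
  if (length(x) != length(nm)) {
    stop("x must have one entry per matrix label (", length(nm), ")",
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    canon <- vapply(names(x), function(s) parse_label(s)$name, "")
    if (!setequal(canon, nm)) {
      stop("names of x do not match the matrix labels", call. = FALSE)
    }
    x <- x[match(nm, canon)]
  }
  if (any(x < 0)) stop("true abundances must be >= 0", call. = FALSE)
  stats::setNames(drop(matrix$T %*% x), nm)
}

#' Brute-force fine structure by per-atom enumeration
#'
#' Independent oracle for [fine_structure()]: assigns an isotope to every
#' individual atom, multiplies abundances, and groups identical heavy-count
#' signatures. Exact but exponential, hence restricted to tiny formulas.
#'
#' @param formula A `molecular_formula` with at most `max_atoms` atoms.
#' @param max_atoms Safety cap, default 8.
#' @param isotopes Isotope reference table.
#' @return A `fine_structure` data.frame (shift, probability, signature).
#' @export
brute_force_fine_structure <- function(formula, max_atoms = 8L,
                                       isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  n_atoms <- sum(unclass(formula))
  if (n_atoms > max_atoms) {
    stop("brute force is limited to ", max_atoms, " atoms (got ", n_atoms, ")",
         call. = FALSE)
  }
  atom_elements <- rep(names(formula), times = unclass(formula))
  choices <- lapply(atom_elements, function(el) {
    iso <- element_isotopes(el, isotopes)
    seq_len(nrow(iso))
  })
  grid <- expand.grid(choices)
  iso_by_el <- lapply(stats::setNames(nm = names(formula)), element_isotopes,
                      isotopes = isotopes)
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    p <- 1
    shift <- 0
    heavy <- character(0)
    for (a in seq_along(atom_elements)) {
      iso <- iso_by_el[[atom_elements[a]]]
      row <- grid[r, a]
      p <- p * iso$abundance[row]
      shift <- shift + iso$shift[row]
      if (!iso$principal[row]) heavy <- c(heavy, isotope_code(iso)[row])
    }
    sig <- if (length(heavy) == 0L) "" else {
      tb <- table(heavy)
      paste0(names(tb), ":", as.integer(tb), collapse = ";")
    }
    key <- sig
    prev <- if (!is.null(acc[[paste0("k", key)]])) acc[[paste0("k", key)]] else
      list(shift = shift, p = 0)
    acc[[paste0("k", key)]] <- list(shift = shift, p = prev$p + p, sig = sig)
  }
  entries <- mget(ls(acc), envir = acc)
  out <- data.frame(
    shift = vapply(entries, `[[`, 0, "shift"),
    probability = vapply(entries, `[[`, 0, "p"),
    signature = vapply(entries, `[[`, "", "sig"),
    stringsAsFactors = FALSE)
  ord <- order(out$shift, out$signature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, formula = formula, max_shift = Inf, prune = 0,
            class = c("fine_structure", "data.frame"))
}

#' Simulate a stable-isotope labelling time course
#'
#' Emulates a media-switch experiment on a compound with `n_sites`
#' independently labelled sites: each site is replaced by the tracer with
#' first-order kinetics, `f(t) = 1 - exp(-k t)`, giving binomial species
#' fractions `choose(n, i) f^i (1-f)^(n-i)` for `i` labelled sites. True
#' fractions are pushed through the forward model and multiplicative Gaussian
#' noise (truncated at 0) is added per replicate peak.
#'
#' @param matrix A [correction_matrix()] whose labels are the `n_sites + 1`
#'   labelling states in ascending shift order (e.g. `"No label"`, `"2C13"`,
#'   `"4C13"` for two acetyl sites).
#' @param times Numeric vector of sampling times (h).
#' @param rate First-order site replacement rate `k` (per h).
#' @param cv Coefficient of variation of the multiplicative noise (default
#'   0.02); 0 for noise-free tables.
#' @param replicates Number of replicates per time point (default 3).
#' @param total Total intensity scale per sample (arbitrary units).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame in the measurement-table layout: `sample`, `time`,
#'   one column per label. Attribute `"truth"` holds the noise-free true
#'   fraction table (same layout).
#' @export
simulate_timecourse <- function(matrix, times, rate, cv = 0.02,
                                replicates = 3L, total = 1e6, seed = NULL) {
  stopifnot(inherits(matrix, "correction_matrix"))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nm <- colnames(matrix$T)
  n_sites <- length(nm) - 1L
  rows <- list()
  truth_rows <- list()
  for (t in times) {
    f <- 1 - exp(-rate * t)
    frac <- stats::dbinom(0:n_sites, n_sites, f)
    observed <- forward_observe(frac, matrix) * total
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      time = t, as.list(stats::setNames(frac, nm)), check.names = FALSE)
    for (r in seq_len(replicates)) {
      noisy <- observed * pmax(0, stats::rnorm(length(observed), 1, cv))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("t%g_r%d", t, r), time = t,
        as.list(stats::setNames(noisy, nm)), check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  out
}
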