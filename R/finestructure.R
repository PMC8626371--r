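# Isotopic fine structure: exact-mass-resolved natural isotope species.
#
# A fine-structure species is one combination of heavy natural isotopes, e.g.
# {13C x2} or {18O, 15N}. Its probability follows the per-element multinomial
# model; its exact mass shift is the sum of the isotope mass shifts. Species
# are enumerated per element (bounded by the requested maximum shift) and
# convolved across elements. Exact shifts are kept as real masses throughout;
# only the resolution module decides which species merge.

#' Probability of one fine-structure species
#'
#' For element e with n atoms, isotope abundances \eqn{a_0, a_1, \dots} and
#' heavy counts \eqn{k_1, k_2, \dots}, the per-element term is the multinomial
#' \deqn{\binom{n}{k_1, k_2, \dots} a_0^{n - \sum k_i} \prod_i a_i^{k_i}}
#' and the species probability is the product over elements.
#'
#' @param formula A `molecular_formula`.
#' @param heavy_counts Named integer vector of heavy-isotope counts keyed by
#'   isotope code (e.g. `c(C13 = 2, O18 = 1)`); may be empty for the all-light
#'   species.
#' @param isotopes Isotope reference table.
#' @return Probability in \[0, 1\].
#' @examples
#' species_probability(parse_formula("C1"), c(C13 = 1))  # 0.0107
#' @export
species_probability <- function(formula, heavy_counts = integer(0),
                                isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  heavy_counts <- heavy_counts[heavy_counts > 0]
  codes <- names(heavy_counts)
  if (length(heavy_counts) > 0L &&
      (is.null(codes) || any(heavy_counts != round(heavy_counts)))) {
    stop("heavy_counts must be a named vector of non-negative integers",
         call. = FALSE)
  }
  idx <- match(codes, isotope_code(isotopes))
  if (anyNA(idx)) {
    stop("unknown isotope code(s): ", paste(codes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  elems <- isotopes$element[idx]
  extra <- setdiff(elems, names(formula))
  if (length(extra) > 0L) {
    stop("heavy counts exceed atoms for element(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  logp <- 0
  for (el in names(formula)) {
    iso <- element_isotopes(el, isotopes)
    n <- unclass(formula)[[el]]
    k <- stats::setNames(integer(nrow(iso) - 1L), isotope_code(iso)[-1L])
    here <- codes[elems == el]
    k[here] <- heavy_counts[here]
    if (sum(k) > n) {
      stop("heavy counts exceed atoms for element(s): ", el, call. = FALSE)
    }
    logp <- logp + multinomial_logp(n, k, iso)
  }
  exp(logp)
}

# log multinomial probability for one element; iso has principal row first,
# k is aligned with iso rows 2..m.
multinomial_logp <- function(n, k, iso) {
  k0 <- n - sum(k)
  a <- iso$abundance
  lgamma(n + 1) - lgamma(k0 + 1) - sum(lgamma(k + 1)) +
    k0 * log(a[1]) + sum(ifelse(k > 0, k * log(a[-1]), 0))
}

# All heavy-count vectors for one element: data.frame(shift, logp, sig).
element_species <- function(element, n, max_shift, isotopes) {
  iso <- element_isotopes(element, isotopes)
  if (nrow(iso) == 1L) {  # monoisotopic element (e.g. P)
    return(data.frame(shift = 0, logp = n * log(iso$abundance), sig = "",
                      stringsAsFactors = FALSE))
  }
  shifts <- iso$shift[-1L]
  codes <- isotope_code(iso)[-1L]
  caps <- pmin(n, ifelse(shifts > 0, floor(max_shift / shifts), 0L))
  grid <- expand.grid(lapply(caps, function(cap) 0:cap))
  keep <- rowSums(grid) <= n &
    drop(as.matrix(grid) %*% shifts) <= max_shift + 1e-9
  grid <- grid[keep, , drop = FALSE]
  shift <- as.numeric(as.matrix(grid) %*% shifts)
  logp <- apply(grid, 1L, function(k) {
    multinomial_logp(n, stats::setNames(as.integer(k), codes), iso)
  })
  sig <- apply(grid, 1L, function(k) {
    nz <- k > 0
    if (!any(nz)) "" else paste0(codes[nz], ":", k[nz], collapse = ";")
  })
  data.frame(shift = shift, logp = logp, sig = sig, stringsAsFactors = FALSE)
}

#' Natural isotopic fine structure of a formula
#'
#' Enumerates every combination of heavy natural isotopes of the formula with
#' exact mass shift up to `max_shift` (plus half a Da of headroom so that a
#' nominal isotopologue's full cluster is retained) and probability at least
#' `prune`. The all-light species (shift 0) is always kept.
#'
#' @param formula A `molecular_formula`.
#' @param max_shift Largest exact mass shift of interest, Da.
#' @param prune Absolute probability below which species are dropped
#'   (default 1e-10); the all-light species is exempt.
#' @param isotopes Isotope reference table.
#' @return A `fine_structure` data.frame with columns `shift` (Da, ascending;
#'   ties broken by signature), `probability` and `signature` (e.g.
#'   `"C13:2;N15:1"`, `""` for all-light), with the source formula, `max_shift`
#'   and `prune` stored as attributes.
#' @examples
#' fine_structure(parse_formula("C2"), max_shift = 3)
#' @export
fine_structure <- function(formula, max_shift, prune = 1e-10,
                           isotopes = isotope_table()) {
  formula <- as_formula(formula, isotopes)
  if (length(max_shift) != 1L || is.na(max_shift) || max_shift < 0) {
    stop("max_shift must be a single non-negative number", call. = FALSE)
  }
  if (length(prune) != 1L || is.na(prune) || prune < 0 || prune >= 1) {
    stop("prune must lie in [0, 1)", call. = FALSE)
  }
  bound <- max_shift + 0.5
  acc <- data.frame(shift = 0, logp = 0, sig = "", stringsAsFactors = FALSE)
  log_prune <- if (prune > 0) log(prune) else -Inf
  for (el in names(formula)) {
    sp <- element_species(el, unclass(formula)[[el]], bound, isotopes)
    acc <- merge_species(acc, sp, bound, log_prune)
  }
  keep <- acc$logp >= log_prune | acc$sig == ""
  acc <- acc[keep, , drop = FALSE]
  ord <- order(acc$shift, acc$sig)
  out <- data.frame(shift = acc$shift[ord],
                    probability = exp(acc$logp[ord]),
                    signature = acc$sig[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, formula = formula, max_shift = max_shift, prune = prune,
            class = c("fine_structure", "data.frame"))
}

# Cross-convolve two partial species sets; pruning partial products is safe
# because remaining factors are probabilities <= 1.
merge_species <- function(a, b, bound, log_prune) {
  ia <- rep(seq_len(nrow(a)), times = nrow(b))
  ib <- rep(seq_len(nrow(b)), each = nrow(a))
  shift <- a$shift[ia] + b$shift[ib]
  logp <- a$logp[ia] + b$logp[ib]
  sig <- ifelse(b$sig[ib] == "", a$sig[ia],
                ifelse(a$sig[ia] == "", b$sig[ib],
                       paste(a$sig[ia], b$sig[ib], sep = ";")))
  keep <- shift <= bound + 1e-9 & (logp >= log_prune | sig == "")
  data.frame(shift = shift[keep], logp = logp[keep], sig = sig[keep],
             stringsAsFactors = FALSE)
}

#' Aggregate a fine structure by nominal mass shift
#'
#' Groups species by rounded mass shift, the low-resolution view in which all
#' fine structure under one nominal isotopologue peak merges.
#'
#' @param spectrum A [fine_structure()] data.frame.
#' @return data.frame with columns `nominal` (integer shift) and `probability`
#'   (sum over member species), ordered by nominal shift.
#' @export
nominal_aggregate <- function(spectrum) {
  if (!inherits(spectrum, "fine_structure")) {
    stop("spectrum must be a fine_structure object", call. = FALSE)
  }
  nominal <- as.integer(round(spectrum$shift))
  agg <- tapply(spectrum$probability, nominal, sum)
  data.frame(nominal = as.integer(names(agg)),
             probability = as.numeric(agg),
             row.names = NULL)
}
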