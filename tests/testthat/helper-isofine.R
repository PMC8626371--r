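# Shared fixtures and independent oracles.
#
# The oracles here deliberately avoid the package's enumeration code paths:
# probabilities are recomputed from stats::dbinom / dmultinom and hand-written
# abundance constants, so that agreement is a genuine cross-check.

# Standard natural abundances, written out independently of the packaged CSV.
AB <- list(
  C = c(0.9893, 0.0107),                   # 12C, 13C
  H = c(0.999885, 0.000115),               # 1H, 2H
  N = c(0.99636, 0.00364),                 # 14N, 15N
  O = c(0.99757, 0.00038, 0.00205),        # 16O, 17O, 18O
  S = c(0.9499, 0.0075, 0.0425, 0.0001)    # 32S, 33S, 34S, 36S
)
SHIFT <- list(C13 = 1.0033548378, H2 = 1.0062767461, N15 = 0.9970348932,
              O17 = 1.0042168779, O18 = 2.0042457779,
              S33 = 0.9993878100, S34 = 1.9957961400, S36 = 3.9950101900)

# Multinomial probability for one element: n atoms, k = heavy counts in the
# order of AB[[el]][-1].
elem_p <- function(el, n, k = rep(0, length(AB[[el]]) - 1L)) {
  stats::dmultinom(c(n - sum(k), k), size = n, prob = AB[[el]])
}

# Fully acetylated H3(18-26) peptide composition, kept literal here.
H3_FORMULA <- c(C = 46, H = 83, N = 15, O = 14)

# Measured H3 acetylation time course (relative %, means of 3 replicates).
h3_measurements <- function() {
  data.frame(sample = c("t0", "t24"), time = c(0, 24),
             "No label" = c(84.1, 28.3), "2C13" = c(15.9, 46.2),
             "4C13" = c(0, 25.6), check.names = FALSE)
}

h3_matrix <- function(method = "skewed") {
  correction_matrix(as_formula(H3_FORMULA), c("No label", "2C13", "4C13"),
                    resolution_model(60000, 200), charge = 2, method = method)
}

# A degenerate isotope table with zero heavy abundances (correction becomes
# the identity); written to a temp CSV in the packaged format.
degenerate_isotope_table <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "element,mass_number,exact_mass,abundance",
    "H,1,1.0078250319,1.0", "H,2,2.0141017780,0.0",
    "C,12,12.0,1.0", "C,13,13.0033548378,0.0",
    "N,14,14.0030740052,1.0", "N,15,15.0001088984,0.0",
    "O,16,15.9949146221,1.0", "O,17,16.9991315,0.0", "O,18,17.9991604,0.0"),
    path)
  isotope_table(path)
}

expect_formula_equal <- function(f, counts) {
  got <- unclass(f)[unclass(f) > 0]
  got <- got[order(names(got))]
  want <- stats::setNames(as.integer(counts), names(counts))
  want <- want[order(names(want))]
  expect_equal(got, want)
}
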