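# Skewed correction matrix construction and inversion.

test_that("matrix entries match independent closed-form sums", {
  cm <- h3_matrix()
  T <- cm$T
  # structure: lower triangular in shift order, diagonal in (0, 1]
  expect_true(all(T[upper.tri(T)] == 0))
  expect_true(all(diag(T) > 0 & diag(T) <= 1))
  expect_true(all(colSums(T) <= 1 + 1e-12))
  # all-light probability of the full formula (no merge candidates near 0)
  p0 <- AB$C[1]^46 * AB$H[1]^83 * AB$N[1]^15 * AB$O[1]^14
  expect_equal(T["No label", "No label"], p0, tolerance = 1e-12)

  # independent oracle for the No label -> M+2 peak entry: enumerate the
  # heavy-isotope combinations whose exact shift falls inside the resolving
  # window around 2 x the 13C shift, with dmultinom probabilities
  window <- 1.66 * (536.8195 / (60000 * sqrt(200 / 536.8195))) * 2
  target <- 2 * SHIFT$C13
  combos <- list(
    list(sh = 2 * SHIFT$C13,          p = elem_p("C", 46, 2) * elem_p("H", 83) * elem_p("N", 15) * elem_p("O", 14)),
    list(sh = SHIFT$C13 + SHIFT$N15,  p = elem_p("C", 46, 1) * elem_p("H", 83) * elem_p("N", 15, 1) * elem_p("O", 14)),
    list(sh = SHIFT$C13 + SHIFT$H2,   p = elem_p("C", 46, 1) * elem_p("H", 83, 1) * elem_p("N", 15) * elem_p("O", 14)),
    list(sh = SHIFT$C13 + SHIFT$O17,  p = elem_p("C", 46, 1) * elem_p("H", 83) * elem_p("N", 15) * elem_p("O", 14, c(1, 0))),
    list(sh = 2 * SHIFT$N15,          p = elem_p("C", 46) * elem_p("H", 83) * elem_p("N", 15, 2) * elem_p("O", 14)),
    list(sh = SHIFT$N15 + SHIFT$H2,   p = elem_p("C", 46) * elem_p("H", 83, 1) * elem_p("N", 15, 1) * elem_p("O", 14)),
    list(sh = SHIFT$N15 + SHIFT$O17,  p = elem_p("C", 46) * elem_p("H", 83) * elem_p("N", 15, 1) * elem_p("O", 14, c(1, 0))),
    list(sh = 2 * SHIFT$H2,           p = elem_p("C", 46) * elem_p("H", 83, 2) * elem_p("N", 15) * elem_p("O", 14)),
    list(sh = SHIFT$H2 + SHIFT$O17,   p = elem_p("C", 46) * elem_p("H", 83, 1) * elem_p("N", 15) * elem_p("O", 14, c(1, 0))),
    list(sh = 2 * SHIFT$O17,          p = elem_p("C", 46) * elem_p("H", 83) * elem_p("N", 15) * elem_p("O", 14, c(2, 0))),
    list(sh = SHIFT$O18,              p = elem_p("C", 46) * elem_p("H", 83) * elem_p("N", 15) * elem_p("O", 14, c(0, 1)))
  )
  inside <- vapply(combos, function(cb) abs(cb$sh - target) < window, TRUE)
  expect_true(all(inside))  # all land inside the window at this resolution
  oracle <- sum(vapply(combos, `[[`, 0, "p"))
  expect_equal(T["2C13", "No label"], oracle, tolerance = 1e-8)

  # residual columns have fewer carbons, so spillover shrinks down the bands
  expect_lt(T["4C13", "2C13"], T["2C13", "No label"])
})

test_that("fully labelled species cannot leak to heavier peaks (skewed only)", {
  f <- parse_formula("C2")
  skewed <- transition_probability(f, "2C13", "3C13",
                                   resolution_model(60000, 200))
  expect_identical(skewed, 0)
  # classical mode reuses the full formula's spectrum and does leak
  classical <- transition_probability(
    f, "No label", isofine:::shifted_pseudo_label(SHIFT$C13, isotope_table()),
    resolution_model(60000, 200))
  expect_equal(classical, 2 * AB$C[2] * AB$C[1], tolerance = 1e-12)
  expect_gt(classical, 0)
  # the fully labelled diagonal is exactly 1: no residual atoms at all
  cm <- correction_matrix(f, c("No label", "1C13", "2C13"),
                          resolution_model(60000, 200))
  expect_equal(cm$T["2C13", "2C13"], 1)
})

test_that("classical and skewed matrices differ exactly as expected", {
  f <- compound_formula("acetyl-CoA")
  labels <- c("No label", "2C13", "5C13", "7C13")
  m <- resolution_model(60000, 200)
  sk <- correction_matrix(f, labels, m, charge = 1, method = "skewed")
  cl <- correction_matrix(f, labels, m, charge = 1, method = "classical")
  # the unlabelled column sees the full formula either way
  expect_equal(sk$T[, "No label"], cl$T[, "No label"], tolerance = 1e-12)
  # equally spaced columns: classical repeats the same factors, skewed shrinks
  expect_equal(cl$T["7C13", "5C13"], cl$T["2C13", "No label"],
               tolerance = 1e-12)
  expect_lt(sk$T["7C13", "5C13"], sk$T["2C13", "No label"])
  # a fully labelled input passes through skewed correction unchanged but
  # classical correction of the same observation moves mass around
  cm4 <- correction_matrix(parse_formula("C4"),
                           c("No label", "2C13", "4C13"), m)
  x <- c(0, 0, 1)
  obs <- forward_observe(x, cm4)
  expect_equal(obs, c("No label" = 0, "2C13" = 0, "4C13" = 1))
  back <- correct_isotopologues(obs, cm4, normalize = FALSE)
  expect_equal(as.numeric(back$corrected[1, ]), x, tolerance = 1e-12)
  cl4 <- correction_matrix(parse_formula("C4"),
                           c("No label", "2C13", "4C13"), m,
                           method = "classical")
  back_cl <- correct_isotopologues(obs, cl4, normalize = FALSE)
  expect_gt(as.numeric(back_cl$corrected[1, "4C13"]), 1)  # inflated
})

test_that("correction inverts the forward model on random abundance vectors", {
  m <- resolution_model(60000, 200)
  cases <- list(
    list(formula = "C6H12O6", labels = c("No label", "2C13", "4C13"), z = 1),
    list(formula = "C46H83N15O14", labels = c("No label", "2C13", "4C13"), z = 2),
    list(formula = "C9H14N4O3", labels = c("No label", "1N15", "2C13 1N15"), z = 1)
  )
  set.seed(42)
  for (cs in cases) {
    cm <- correction_matrix(parse_formula(cs$formula), cs$labels, m, cs$z)
    for (i in 1:5) {
      x <- stats::runif(length(cs$labels))
      obs <- forward_observe(x, cm)
      res <- correct_isotopologues(obs, cm, normalize = FALSE)
      expect_equal(as.numeric(res$corrected[1, ]), x, tolerance = 1e-9)
      expect_equal(nrow(res$warnings), 0L)
    }
  }
})

test_that("total corrected abundance is never below the observed total", {
  cm <- h3_matrix()
  set.seed(7)
  for (i in 1:5) {
    x <- stats::runif(3)
    obs <- forward_observe(x, cm)
    res <- correct_isotopologues(obs, cm, normalize = FALSE)
    expect_gte(sum(res$corrected[1, ]), sum(obs) - 1e-12)
  }
})

test_that("negative solutions are clipped to zero and logged", {
  cm <- h3_matrix()
  # M+2 intensity below the natural spillover from M+0 forces a negative
  obs <- data.frame(sample = "s1", "No label" = 100, "2C13" = 1, "4C13" = 0,
                    check.names = FALSE)
  res <- correct_isotopologues(obs, cm)
  expect_equal(as.numeric(res$corrected[1, "2C13"]), 0)
  expect_gte(nrow(res$warnings), 1L)
  expect_true("2C13" %in% res$warnings$label)
  expect_true(all(res$warnings$clipped > 0, na.rm = TRUE))
  fr <- as.numeric(res$fractions[1, c("No label", "2C13", "4C13")])
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("a degenerate zero-heavy-abundance table gives identity correction", {
  iso0 <- degenerate_isotope_table()
  cm <- correction_matrix(parse_formula("C6H12O6", iso0),
                          c("No label", "2C13"), resolution_model(60000, 200),
                          isotopes = iso0)
  expect_equal(unname(cm$T), diag(2))
  obs <- c("No label" = 70, "2C13" = 30)
  res <- correct_isotopologues(obs, cm, normalize = FALSE)
  expect_equal(as.numeric(res$corrected[1, ]), c(70, 30))
})

test_that("raising the resolving power never increases off-diagonal entries", {
  f <- as_formula(H3_FORMULA)
  labels <- c("No label", "2C13", "4C13")
  Ts <- lapply(c(1e4, 6e4, 2.4e5, 1e6), function(R) {
    correction_matrix(f, labels, resolution_model(R, 200), charge = 2)$T
  })
  for (k in seq_len(length(Ts) - 1L)) {
    lowR <- Ts[[k]]
    hiR <- Ts[[k + 1L]]
    off <- lower.tri(lowR)
    expect_true(all(hiR[off] <= lowR[off] + 1e-15))
  }
})

test_that("column order of the input does not affect the result", {
  cm1 <- correction_matrix(as_formula(H3_FORMULA),
                           c("4C13", "No label", "2C13"),
                           resolution_model(60000, 200), charge = 2)
  cm2 <- h3_matrix()
  expect_equal(cm1$T, cm2$T)
  obs <- data.frame("4C13" = 0, "No label" = 84.1, "2C13" = 15.9,
                    check.names = FALSE)
  r1 <- correct_isotopologues(obs, cm1)
  r2 <- correct_isotopologues(h3_measurements()[1, ], cm2)
  expect_equal(as.numeric(r1$fractions[1, c("No label", "2C13", "4C13")]),
               as.numeric(r2$fractions[1, c("No label", "2C13", "4C13")]),
               tolerance = 1e-6)
})

test_that("invalid labels and inputs raise named errors", {
  f <- as_formula(H3_FORMULA)
  m <- resolution_model(60000, 200)
  expect_error(correction_matrix(f, c("No label", "2C13", "2C13"), m),
               "duplicate")
  expect_error(correction_matrix(f, c("No label", "50C13"), m),
               "exceeds available")
  cm <- h3_matrix()
  bad <- data.frame("No label" = -1, "2C13" = 0, "4C13" = 0,
                    check.names = FALSE)
  expect_error(correct_isotopologues(bad, cm), ">= 0")
  nanrow <- data.frame("No label" = NaN, "2C13" = 0, "4C13" = 0,
                       check.names = FALSE)
  expect_error(correct_isotopologues(nanrow, cm), "finite")
  expect_error(correct_isotopologues(data.frame("No label" = 1,
                                                check.names = FALSE), cm),
               "lacks column")
})

test_that("all-zero samples return zeros with a flagged undefined fraction", {
  cm <- h3_matrix()
  obs <- data.frame(sample = "blank", "No label" = 0, "2C13" = 0, "4C13" = 0,
                    check.names = FALSE)
  res <- correct_isotopologues(obs, cm)
  expect_equal(as.numeric(res$corrected[1, c("No label", "2C13", "4C13")]),
               c(0, 0, 0))
  expect_true(any(is.na(res$warnings$label)))
  expect_true(all(is.na(res$fractions[1, c("No label", "2C13", "4C13")])))
})

test_that("plausible unmeasured intermediates are flagged", {
  cm <- h3_matrix()
  gaps <- missing_intermediates(cm, threshold = 0.01)
  expect_true(1 %in% gaps)  # the +1 carbon-13 cluster is sizeable but unmeasured
  expect_false(any(c(0, 2, 4) %in% gaps))
})
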