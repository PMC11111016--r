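test_that("monoisotopic masses match hand-summed atomic masses", {
  expect_identical(monoisotopic_mass(""), 0)
  # 2 x 1.00782503207 + 15.99491461957
  expect_equal(monoisotopic_mass("H2O"), 18.01056468, tolerance = 1e-6)
  # 9 x 12 + 8 x 1.00782503207 + 14.00307400443
  expect_equal(monoisotopic_mass("C9H8N"), 130.06567426, tolerance = 1e-6)
  expect_error(monoisotopic_mass("C2Xx3"), "unknown element symbol: 'Xx'")
})

test_that("formula parsing handles implicit counts, repeats and errors", {
  expect_equal(parse_formula("C10H9NO2"),
               c(C = 10L, H = 9L, N = 1L, O = 2L))
  expect_equal(parse_formula("CHCH")[["C"]], 2L)
  expect_error(parse_formula("C0H2"), "counts")
})

test_that("ion m/z applies the proton and electron-mass conventions", {
  # quinolinium cation: center of the printed 130.0641-130.0661 window
  expect_equal(round(ion_mz("C9H8N"), 4), 130.0651)
  # protonated IAA: 175.063329 + 1.00727646
  expect_equal(ion_mz("C10H9NO2", protonated = TRUE), 176.070605,
               tolerance = 1e-6)
  expect_equal(ion_mz("H"), 1.007276, tolerance = 1e-6)  # bare proton
  expect_error(ion_mz("C9H8N", charge = 0), "charge")
})

test_that("isotope table yields the printed heavy-isotope mass increments", {
  expect_equal(round(mass_shift("13C1"), 5), 1.00335)
  expect_equal(round(mass_shift("2H1"), 5), 1.00628)
  expect_equal(round(mass_shift("15N1"), 5), 0.99703)
})

test_that("isotope table abundances sum to 1 and masses increase", {
  tab <- isotope_table()
  for (el in unique(tab$element)) {
    rows <- tab[tab$element == el, ]
    rows <- rows[order(rows$mass_number), ]
    expect_equal(sum(rows$abundance), 1, tolerance = 1e-6)
    expect_true(all(diff(rows$mass) > 0))
  }
})

test_that("labeled m/z shifts reproduce the printed window centers", {
  q <- ion_mz("C9H8N")
  expect_equal(round(labeled_mz(q, "15N1"), 4), 131.0622)
  expect_equal(round(labeled_mz(q, "13C6"), 4), 136.0853)
  expect_equal(round(labeled_mz(q, "2H4"), 4), 134.0902)
  expect_equal(labeled_mz(q, ""), q)  # identity scheme
  expect_error(labeled_mz(q, "15N2", formula = "C9H8N"), "substitutes")
  expect_error(label_scheme("14C6"), "no isotope")
})

test_that("label shifts are additive across schemes", {
  q <- ion_mz("C9H8N")
  two_step <- labeled_mz(labeled_mz(q, "13C6"), "15N1")
  expect_equal(two_step, labeled_mz(q, "13C6,15N1"), tolerance = 1e-9)
})

test_that("all five printed quinolinium windows reproduce at 4 decimals", {
  q <- ion_mz("C9H8N")
  windows <- stats::setNames(
    list(c(130.0641, 130.0661), c(131.0612, 131.0632),
         c(134.0892, 134.0912), c(136.0843, 136.0863),
         c(139.0880, 139.0900)),
    c("", "15N1", "2H4", "13C6", "13C8,15N1"))
  for (i in seq_along(windows)) {
    w <- mz_window(labeled_mz(q, names(windows)[i], formula = "C9H8N"))
    expect_identical(unname(unclass(w)), windows[[i]],
                     label = paste("scheme", names(windows)[i]))
  }
})

test_that("window construction validates and supports ppm mode", {
  expect_equal(unclass(mz_window(100.0000)), c(low = 99.9990, high = 100.0010))
  expect_error(mz_window(100, half_width = 0), "positive")
  w <- mz_window(200, half_width = 5, ppm = TRUE)
  expect_equal(unname(w[["high"]] - w[["low"]]), 2 * 200 * 5e-6,
               tolerance = 1e-9)
})

test_that("isotopologue envelope matches brute-force enumeration", {
  for (f in c("H2O", "C1", "C3H5NO2", "C2H6S")) {
    expect_equal(unname(isotopologue_envelope(f, 3L)),
                 unname(brute_force_envelope(f, 3L)),
                 tolerance = 1e-9, label = f)
  }
  # direct single-atom ratio
  tab <- isotope_table()
  c13 <- tab[tab$element == "C", ]
  expect_equal(isotopologue_envelope("C1", 1L)[["M+1"]],
               100 * c13$abundance[2] / c13$abundance[1], tolerance = 1e-12)
  expect_error(isotopologue_envelope("H2O", 0L), "max_shift")
})

test_that("IAA M+1 abundance is near the 11.1% benchmark", {
  m1 <- isotopologue_envelope("C10H9NO2", 1L)[["M+1"]]
  expect_lt(abs(m1 - 11.1), 0.5)
})

test_that("envelope is monotone non-increasing beyond M+1 for CHNO molecules", {
  set.seed(7)
  for (i in 1:20) {
    counts <- c(C = sample(1:10, 1), H = sample(1:10, 1),
                N = sample(1:3, 1), O = sample(1:2, 1))
    counts <- counts[seq_len(sample(2:4, 1))]
    if (sum(counts) > 25) next
    env <- isotopologue_envelope(counts, 3L)
    expect_true(all(diff(env[-1L]) <= 1e-12),
                label = silkr:::.formula_string(counts))
  }
})

test_that("target tables expand compounds x channels with printed m/z", {
  cmp <- data.frame(name = "IAA", ion_formula = "C9H8N", protonated = FALSE,
                    rt_min = 4.9, rt_max = 5.5)
  tt <- build_target_table(cmp, list(baseline = "15N1", tracer = "13C6",
                                     internal_standard = "2H4"))
  expect_equal(nrow(tt), 3L)
  expect_equal(round(tt$mz[match(c("endogenous", "tracer",
                                   "internal_standard"), tt$channel)], 4),
               c(131.0622, 136.0853, 134.0902))
  expect_false(any(tt$crosstalk))
  # the 13C8,15N1 tracer variant
  tt2 <- build_target_table(cmp, list(tracer = "13C8,15N1"))
  expect_equal(round(tt2$mz[tt2$channel == "tracer"], 4), 139.0890)
})

test_that("identical channel schemes trigger a cross-talk warning", {
  cmp <- data.frame(name = "X", ion_formula = "C9H8N", protonated = FALSE,
                    rt_min = 1, rt_max = 2)
  expect_warning(
    tt <- build_target_table(cmp, list(baseline = "15N1", tracer = "15N1")),
    "cross-talk")
  expect_true(all(tt$crosstalk))
})

test_that("the natural 13C1 satellite falls outside the 15N1 window", {
  sat <- labeled_mz(ion_mz("C9H8N"), "13C1")
  w <- mz_window(labeled_mz(ion_mz("C9H8N"), "15N1"))
  expect_gt(sat, w[["high"]])
})

test_that("target config round-trips through YAML and TSV export", {
  tt <- read_target_config(system.file("extdata", "iaa_targets.yaml",
                                       package = "silkr"))
  expect_s3_class(tt, "target_table")
  iaa <- tt[tt$compound == "IAA", ]
  expect_equal(sort(round(iaa$mz_low, 4)),
               c(131.0612, 134.0892, 136.0843))
  tsv <- tempfile(fileext = ".tsv")
  write_target_table(tt, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(tt))
  inc <- tempfile(fileext = ".tsv")
  write_target_table(tt, inc, format = "inclusion")
  expect_true(all(c("mz", "charge", "rt_start") %in%
                    names(utils::read.delim(inc))))
})
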