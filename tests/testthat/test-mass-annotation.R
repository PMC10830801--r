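test_that("formula parsing handles plain and subscript-marked notation", {
  expect_equal(unclass(parse_formula("C22H43NO")),
               c(C = 22L, H = 43L, N = 1L, O = 1L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C_42_H_79_N_2_O_8_P")),
               c(C = 42L, H = 79L, N = 2L, O = 8L, P = 1L))
  expect_error(parse_formula("C22X5"), "unknown element")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("22C"), "position")
})

test_that("monoisotopic mass matches independent atomic-mass sums", {
  # independent oracle: explicit sums from the isotope masses
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, P = 30.97376151, S = 31.97207069)
  expect_equal(monoisotopic_mass("H"), masses[["H"]])
  hand <- 22 * masses["C"] + 43 * masses["H"] + masses["N"] + masses["O"]
  expect_equal(monoisotopic_mass("C22H43NO"), unname(hand), tolerance = 1e-10)
  expect_equal(round(monoisotopic_mass("C22H43NO"), 5), 337.33446)
  expect_equal(round(monoisotopic_mass("C20H36O2"), 5), 308.27153)
})

test_that("mass additivity holds for disjoint formula sums", {
  a <- monoisotopic_mass("C6H12O6")
  b <- monoisotopic_mass("C3H7NO2S")
  expect_equal(monoisotopic_mass("C9H19NO8S"), a + b, tolerance = 1e-10)
})

test_that("adduct m/z reproduces tabulated exact masses (h_atom convention)", {
  expect_equal(adduct_mz("C22H43NO"), 338.3423)
  expect_equal(adduct_mz("C21H30O5"), 363.2171)
  expect_equal(adduct_mz("C28H60NO6P"), 538.4237)
  expect_error(adduct_mz("CH4", adduct = "[M+Na]+"), "unsupported")
})

test_that("fragment cations use atomic sum minus the electron mass", {
  expect_equal(adduct_mz("C5H15NO4P", "M+.", "proton_electron"), 184.0733)
  expect_equal(adduct_mz("C5H14NO", "M+.", "proton_electron"), 104.1070)
})

test_that("the two [M+H]+ conventions differ by exactly one electron mass", {
  for (f in c("C22H43NO", "C42H79N2O8P", "C6H12O6", "H2O")) {
    gap <- adduct_mz(f, convention = "h_atom", digits = NULL) -
      adduct_mz(f, convention = "proton_electron", digits = NULL)
    expect_equal(round(gap, 6), round(0.0005486, 6))
  }
})

test_that("display rounding is half-up at 4 decimals", {
  expect_equal(round_half_up(538.42365, 4), 538.4237)
  expect_equal(round_half_up(1.00005, 4), 1.0001)
  expect_equal(round_half_up(-1.00005, 4), -1.0001)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("nitrogen parity distinguishes sphingomyelin-like formulas", {
  expect_equal(nitrogen_parity("C42H79N2O8P"), "even")
  expect_equal(nitrogen_parity("C22H43NO"), "odd")
  expect_equal(nitrogen_parity("C6H12O6"), "even")
})

test_that("feature matching reports hits within ppm tolerance, sorted", {
  lib <- demo_compound_library()
  tab <- make_table(
    matrix(1, 3, 2), groups = c("N", "D"),
    mz = c(338.3438, adduct_mz("C21H30O5", digits = NULL), 338.60)
  )
  hits <- match_features(tab, lib, tol_ppm = 10)
  expect_setequal(hits$feature_id, c("F001", "F002"))
  h1 <- hits[hits$feature_id == "F001", ]
  expect_equal(h1$name, "FAM(22:1)")
  expect_equal(h1$error_ppm, (338.3438 - h1$theoretical_mz) / h1$theoretical_mz * 1e6)
  expect_gt(h1$error_ppm, 4)
  expect_lt(h1$error_ppm, 5)
  expect_equal(hits$error_ppm[hits$feature_id == "F002"], 0, tolerance = 1e-9)
})

test_that("diagnostic fragment support counts matches within mDa tolerance", {
  lib <- demo_compound_library()
  sm <- lib[lib$name == "SM(d17:1/20:3)", ]
  expect_equal(check_fragments(c(184.0733, 104.1070), sm), 2L)
  expect_equal(check_fragments(numeric(), sm), 0L)
  expect_equal(check_fragments(c(184.0733, 124.9999, 104.1070), sm), 3L)
  # 6 mDa off is outside the default 5 mDa window
  expect_equal(check_fragments(c(184.0793), sm), 0L)
})

test_that("compound library round-trips through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lib <- demo_compound_library()
  readr::write_tsv(
    dplyr::mutate(dplyr::distinct(dplyr::select(tibble::as_tibble(lib),
      -"adduct", -"theoretical_mz")), adducts = "[M+H]+"),
    path
  )
  lib2 <- read_compound_library(path)
  expect_equal(lib2$theoretical_mz, lib$theoretical_mz)
  expect_equal(lib2$fragments, lib$fragments)
})
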