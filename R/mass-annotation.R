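# Formula-driven monoisotopic mass arithmetic, adduct m/z computation and
# feature-to-compound matching. Values are computed from most-abundant-isotope
# atomic masses, so theoretical m/z reproduce printed metabolite tables to
# 4 decimals.

# most-abundant-isotope atomic masses (Da)
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, P = 30.97376151, S = 31.97207069
)

# particle masses (Da)
PROTON_MASS <- 1.0072764669
ELECTRON_MASS <- 0.0005485799
H_ATOM_MASS <- 1.0078250319

#' Parse a molecular formula
#'
#' Accepts Hill-like notation with optional underscore subscript markers
#' (`"C22H43NO"`, `"C_42_H_79_N_2_O_8_P"`). Element symbols are restricted to
#' C, H, N, O, P, S.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts, class `chemical_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  clean <- gsub("_", "", trimws(text))
  if (!nzchar(clean)) abort("empty formula")
  counts <- integer()
  pos <- 1L
  while (pos <= nchar(clean)) {
    rest <- substr(clean, pos, nchar(clean))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0 || !nzchar(m[2])) {
      abort(sprintf("malformed formula '%s' at position %d", text, pos))
    }
    elem <- m[2]
    if (!elem %in% names(MONOISOTOPIC_MASS)) {
      abort(sprintf("unknown element '%s' in formula '%s'", elem, text))
    }
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (n < 1) abort(sprintf("non-positive count for %s in '%s'", elem, text))
    counts[elem] <- if (elem %in% names(counts)) counts[[elem]] + n else n
    pos <- pos + nchar(m[1])
  }
  structure(counts, class = "chemical_formula")
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula A `chemical_formula` (see [parse_formula()]) or a formula
#'   string.
#' @return Mass in Da (sum of most-abundant-isotope atomic masses).
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(MONOISOTOPIC_MASS[names(formula)] * as.numeric(formula))
}

#' Theoretical adduct m/z
#'
#' Two conventions are implemented. `"h_atom"` adds/subtracts a full
#' hydrogen atom (electron included): the convention behind printed
#' "exact mass" columns of LC-MS metabolite tables, and the default.
#' `"proton_electron"` uses the physically exact proton mass for protonation
#' and subtracts the electron mass for radical/fragment cations. For any
#' formula the two `[M+H]+` values differ by exactly one electron mass.
#'
#' @param formula A `chemical_formula` or string.
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"M+."` (radical/fragment
#'   cation: atomic-mass sum minus one electron).
#' @param convention `"h_atom"` (default) or `"proton_electron"`.
#' @param digits Decimals for display rounding (half-up); `NULL` disables.
#' @return m/z in Th.
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+",
                      convention = c("h_atom", "proton_electron"),
                      digits = 4) {
  convention <- match.arg(convention)
  m <- monoisotopic_mass(formula)
  mz <- switch(adduct,
    "[M+H]+" = if (convention == "h_atom") m + H_ATOM_MASS else m + PROTON_MASS,
    "[M-H]-" = if (convention == "h_atom") m - H_ATOM_MASS else m - PROTON_MASS,
    "M+." = m - ELECTRON_MASS,
    abort(sprintf("unsupported adduct '%s'", adduct))
  )
  if (is.null(digits)) mz else round_half_up(mz, digits)
}

#' Nitrogen parity of a formula
#'
#' The nitrogen-rule check used to discriminate compound classes (e.g.
#' sphingomyelins carry an even number of nitrogen atoms).
#'
#' @param formula A `chemical_formula` or string.
#' @return `"even"` or `"odd"` (a formula without N counts as even).
#' @export
nitrogen_parity <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  n <- if ("N" %in% names(formula)) formula[["N"]] else 0L
  if (n %% 2 == 0) "even" else "odd"
}

#' Build a compound library
#'
#' @param compounds Data frame with columns `compound_id`, `name`, `class`,
#'   `formula` (string), optional `adducts` (default `"[M+H]+"`) and
#'   `fragments` (semicolon-separated fragment formulas or fixed m/z values).
#' @return A tibble with parsed theoretical m/z per (compound, adduct), class
#'   `compound_library`.
#' @export
compound_library <- function(compounds) {
  compounds <- tibble::as_tibble(compounds)
  stopifnot(all(c("compound_id", "name", "class", "formula") %in% names(compounds)))
  if (!"adducts" %in% names(compounds)) compounds$adducts <- "[M+H]+"
  if (!"fragments" %in% names(compounds)) compounds$fragments <- ""
  compounds$fragments <- dplyr::coalesce(compounds$fragments, "")
  lib <- compounds |>
    dplyr::mutate(adduct = strsplit(.data$adducts, ";", fixed = TRUE)) |>
    tidyr::unnest("adduct") |>
    dplyr::mutate(
      theoretical_mz = purrr::map2_dbl(
        .data$formula, .data$adduct,
        ~ adduct_mz(.x, .y, digits = NULL)
      )
    ) |>
    dplyr::select(-"adducts")
  class(lib) <- c("compound_library", class(lib))
  lib
}

#' Read a compound library TSV
#'
#' @param path TSV with the columns documented in [compound_library()].
#' @return A `compound_library` tibble.
#' @export
read_compound_library <- function(path) {
  compound_library(readr::read_tsv(path, show_col_types = FALSE))
}

#' Demonstration serum-lipid compound library
#'
#' Seven serum metabolites spanning the classes the screening workflow
#' targets (fatty acid amide, acylcarnitine, sphingomyelin, steroid
#' derivatives, lysophosphatidylcholine, long-chain fatty acid), each with
#' diagnostic fragments where the class has them. Phosphocholine-containing
#' classes carry the canonical head-group fragments: the C5H15NO4P+
#' phosphocholine ion, the 124.9999 cyclic phosphate ion (stored as a fixed
#' value) and the C5H14NO+ choline ion.
#'
#' @return A `compound_library` tibble.
#' @export
demo_compound_library <- function() {
  pc_frag <- "C5H15NO4P;124.9999;C5H14NO"
  compound_library(tibble::tibble(
    compound_id = sprintf("L%02d", 1:7),
    name = c(
      "FAM(22:1)", "AC(20:4)", "SM(d17:1/20:3)",
      "Trihydroxypregnenedione", "LysoPC(O-20:0)", "LCFA(20:2)",
      "Acetoxyandrostenedione"
    ),
    class = c("FAM", "AC", "SM", "steroid", "LysoPL", "FA/LCFA", "steroid"),
    formula = c(
      "C22H43NO", "C27H45NO4", "C42H79N2O8P",
      "C21H30O5", "C28H60NO6P", "C20H36O2", "C21H28O4"
    ),
    adducts = "[M+H]+",
    fragments = c("", "", pc_frag, "", pc_frag, "", "")
  ))
}

#' Match features against a compound library
#'
#' For each feature, every library (compound, adduct) whose theoretical m/z
#' lies within `tol_ppm` of the observed m/z is reported, sorted by absolute
#' ppm error (ties broken by compound id).
#'
#' @param table A [feature_table()] (only feature m/z metadata is used).
#' @param library A [compound_library()].
#' @param tol_ppm Match tolerance in parts per million.
#' @return A tibble of annotation hits: `feature_id`, `compound_id`, `name`,
#'   `class`, `adduct`, `theoretical_mz`, `observed_mz`, `error_ppm`,
#'   `error_mda`.
#' @export
match_features <- function(table, library, tol_ppm = 10) {
  stopifnot(inherits(table, "feature_table"), nrow(library) > 0)
  feats <- table$feature_meta
  hits <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    obs <- feats$mz[i]
    err_ppm <- (obs - library$theoretical_mz) / library$theoretical_mz * 1e6
    sel <- which(abs(err_ppm) <= tol_ppm)
    if (length(sel) == 0) return(NULL)
    tibble::tibble(
      feature_id = feats$feature_id[i],
      compound_id = library$compound_id[sel],
      name = library$name[sel],
      class = library$class[sel],
      adduct = library$adduct[sel],
      theoretical_mz = library$theoretical_mz[sel],
      observed_mz = obs,
      error_ppm = err_ppm[sel],
      error_mda = (obs - library$theoretical_mz[sel]) * 1000
    ) |>
      dplyr::arrange(abs(.data$error_ppm), .data$compound_id)
  })
  hits
}

# parse a semicolon-separated fragment spec into theoretical m/z values;
# formulas are fragment cations (atomic sum minus one electron), bare numbers
# are fixed diagnostic values
fragment_mz <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(numeric())
  parts <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  vapply(parts, function(p) {
    if (grepl("^[0-9.]+$", p)) as.numeric(p) else
      adduct_mz(p, adduct = "M+.", convention = "proton_electron", digits = NULL)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count matched diagnostic fragments
#'
#' @param observed_fragments Numeric vector of observed fragment m/z.
#' @param record One row of a [compound_library()] (needs a `fragments` spec).
#' @param tol_mda Match tolerance in millidaltons.
#' @return Integer count of diagnostic fragments matched within `tol_mda`.
#' @export
check_fragments <- function(observed_fragments, record, tol_mda = 5) {
  theo <- fragment_mz(record$fragments[1])
  if (length(theo) == 0 || length(observed_fragments) == 0) return(0L)
  sum(vapply(theo, function(t) {
    any(abs(observed_fragments - t) <= tol_mda / 1000)
  }, logical(1)))
}

#' Annotate features and attach fragment support
#'
#' Convenience wrapper: [match_features()] plus [check_fragments()] when
#' observed fragment lists are supplied.
#'
#' @param table A [feature_table()].
#' @param library A [compound_library()].
#' @param observed_fragments Optional named list: feature_id -> numeric m/z
#'   vector of observed fragments.
#' @param tol_ppm Precursor tolerance (ppm).
#' @param tol_mda Fragment tolerance (mDa).
#' @return Annotation-hit tibble with a `fragment_support` column.
#' @export
annotate_features <- function(table, library, observed_fragments = NULL,
                              tol_ppm = 10, tol_mda = 5) {
  hits <- match_features(table, library, tol_ppm = tol_ppm)
  if (nrow(hits) == 0) {
    hits$fragment_support <- integer()
    return(hits)
  }
  hits$fragment_support <- purrr::map2_int(
    hits$feature_id, hits$compound_id,
    function(fid, cid) {
      obs <- observed_fragments[[fid]] %||% numeric()
      rec <- library[library$compound_id == cid, , drop = FALSE]
      check_fragments(obs, rec, tol_mda = tol_mda)
    }
  )
  hits
}
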