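# Molecular-formula arithmetic: monoisotopic masses, adduct m/z values and
# the curated mass-offset table used to interpret analog precursor shifts.

# Monoisotopic masses of the most abundant isotope, Da (NIST, 6 dp).
.atomic_masses <- c(
  H  = 1.007825,  C  = 12.000000, N  = 14.003074, O  = 15.994915,
  S  = 31.972071, P  = 30.973762, F  = 18.998403, Cl = 34.968853,
  Br = 78.918338, I  = 126.904473, Na = 22.989770, K = 38.963707,
  Ca = 39.962591, Mg = 23.985042, Si = 27.976927, Se = 79.916522,
  B  = 11.009305, Li = 7.016004
)

.electron_mass <- 0.000549
.proton_mass <- 1.007276

# Supported ionization forms: mass added to the neutral and charge.
# Deltas are sums of atomic masses minus charge * electron mass, so that
# [M+H]+ reproduces the conventional proton mass 1.007276 Da.
.adduct_table <- function() {
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+Ca-H]+", "[M+NH4]+", "[M-H]-"),
    delta = c(
      .atomic_masses[["H"]] - .electron_mass,
      .atomic_masses[["Na"]] - .electron_mass,
      .atomic_masses[["K"]] - .electron_mass,
      .atomic_masses[["Ca"]] - .atomic_masses[["H"]] - .electron_mass,
      .atomic_masses[["N"]] + 4 * .atomic_masses[["H"]] - .electron_mass,
      -.atomic_masses[["H"]] + .electron_mass
    ),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L),
    polarity = c("+", "+", "+", "+", "+", "-")
  )
}

#' Supported adduct specifications
#'
#' @return A tibble with one row per supported ion form: the adduct
#'   specification string, the mass delta added to the neutral monoisotopic
#'   mass (Da, electron-corrected), the absolute charge, and the polarity.
#' @export
#' @examples
#' supported_adducts()
supported_adducts <- function() .adduct_table()

#' Parse a molecular formula string
#'
#' Parses a Hill-style molecular formula (e.g. `"C17H19N3O3S"`) into a named
#' integer vector of element counts. Only recognized element symbols are
#' allowed and the formula must contain at least one atom.
#'
#' @param formula A single formula string, or an already-parsed named
#'   integer vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("H2O")
#' parse_formula("C17H19N3O3S")
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
      stop("`formula` must be a single formula string", call. = FALSE)
    }
    formula <- gsub("[[:space:]]", "", formula)
    if (!nzchar(formula)) {
      stop("empty formula", call. = FALSE)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(formula)) {
      stop("malformed formula string: '", formula, "'", call. = FALSE)
    }
    sym <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Za-z]+", "", tokens)
    n <- ifelse(n == "", 1L, as.integer(n))
    counts <- tapply(n, sym, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.atomic_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty formula", call. = FALSE)
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' @inheritParams parse_formula
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")   # 18.0106
#' monoisotopic_mass("CH2")   # 14.0157, the methylation offset
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.atomic_masses[names(counts)] * counts)
}

#' Theoretical m/z of an ionized molecule
#'
#' Computes the precursor m/z of a neutral molecule under a supported
#' ionization form: `(neutral mass + adduct delta) / charge`, with the
#' proton mass taken as 1.007276 Da.
#'
#' @inheritParams parse_formula
#' @param adduct_spec One of `supported_adducts()$adduct`.
#' @return m/z value.
#' @export
#' @examples
#' ion_mz("C17H19N3O3S", "[M+H]+")  # omeprazole, 346.122
ion_mz <- function(formula, adduct_spec) {
  tab <- .adduct_table()
  i <- match(adduct_spec, tab$adduct)
  if (length(adduct_spec) != 1L || is.na(i)) {
    stop("unsupported adduct_spec; see supported_adducts()", call. = FALSE)
  }
  (monoisotopic_mass(formula) + tab$delta[i]) / tab$charge[i]
}

#' Precursor spacing between two ion forms of the same neutral
#'
#' Signed m/z difference `ion_mz(adduct_a) - ion_mz(adduct_b)` for a
#' singly-charged neutral; independent of the formula.
#'
#' @param adduct_a,adduct_b Adduct specification strings.
#' @return Signed spacing in Da.
#' @export
#' @examples
#' adduct_offset("[M+Na]+", "[M+H]+")  # +21.98, sodium adduct spacing
adduct_offset <- function(adduct_a, adduct_b) {
  tab <- .adduct_table()
  ia <- match(adduct_a, tab$adduct)
  ib <- match(adduct_b, tab$adduct)
  if (is.na(ia) || is.na(ib)) {
    stop("unsupported adduct_spec; see supported_adducts()", call. = FALSE)
  }
  tab$delta[ia] / tab$charge[ia] - tab$delta[ib] / tab$charge[ib]
}

#' Read a mass-offset table
#'
#' Reads and validates a CSV of curated precursor mass offsets used to decide
#' whether an analog's precursor shift is explainable by common drug
#' metabolism, an adduct, or an isotope. Columns: `delta_mass` (signed Da),
#' `label`, `category` (one of metabolism/adduct/isotope), `composition`
#' (optional formula of the absolute elemental change).
#'
#' @param path CSV file path.
#' @param max_abs_da Maximum allowed |delta_mass|; defaults to the 200 Da
#'   analog search window.
#' @return Tibble of validated offsets.
#' @export
read_mass_offsets <- function(path, max_abs_da = 200) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         delta_mass = readr::col_double(),
                         label = readr::col_character(),
                         category = readr::col_character(),
                         composition = readr::col_character()
                       ))
  if (!all(c("delta_mass", "label", "category") %in% names(x))) {
    stop("mass-offset table must have columns delta_mass, label, category",
         call. = FALSE)
  }
  if (any(abs(x$delta_mass) > max_abs_da)) {
    stop("mass offsets must satisfy |delta_mass| <= ", max_abs_da, " Da",
         call. = FALSE)
  }
  if (any(!nzchar(x$label) | is.na(x$label))) {
    stop("mass-offset labels must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(x$category), c("metabolism", "adduct", "isotope"))
  if (length(bad)) {
    stop("unknown offset category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # where a composition is given it must parse and agree with delta_mass
  has_comp <- !is.na(x$composition) & nzchar(x$composition)
  if (any(has_comp)) {
    comp_mass <- vapply(x$composition[has_comp], monoisotopic_mass, numeric(1))
    if (any(abs(comp_mass - abs(x$delta_mass[has_comp])) > 0.05)) {
      stop("composition inconsistent with |delta_mass| in mass-offset table",
           call. = FALSE)
    }
  }
  tibble::as_tibble(x)
}

#' Packaged default mass-offset table
#'
#' The curated list shipped with the package: common drug-metabolism
#' transformations (methylation +14.02, glucuronidation +176.03, oxidation
#' +15.99, dehydration -18.01, (de)ethylation ±28.03, ...), electrospray
#' adduct spacings (Na +21.98, Ca +37.95, K +37.96, ammonium +17.03), and
#' carbon isotope spacings (+1.00, +2.01).
#'
#' @return Tibble as for [read_mass_offsets()].
#' @export
default_mass_offsets <- function() {
  read_mass_offsets(system.file("extdata", "mass_offsets.csv",
                                package = "drugtrace", mustWork = TRUE))
}
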