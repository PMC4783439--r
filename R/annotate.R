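# Monoisotopic atomic masses (u), most abundant isotope, CODATA/AME values.
# 12C is exact by definition of the unified mass scale.
MONOISOTOPIC_MASS <- c(
  C  = 12.0,            # definition
  H  = 1.0078250319,    # 1H
  N  = 14.0030740052,   # 14N
  O  = 15.9949146221,   # 16O
  P  = 30.9737615120,   # 31P
  S  = 31.9720707300,   # 32S
  Na = 22.9897692820,   # 23Na
  K  = 38.9637064864    # 39K
)
ELECTRON_MASS <- 0.0005485799     # m_e in u
C13_DELTA <- 1.0033548351         # 13C - 12C mass difference in u

#' Parse a molecular formula
#'
#' Parses element-count text such as `"C24H50NO7P"` into a named integer
#' vector. Element symbols must be known (C, H, N, O, P, S, Na, K); an
#' omitted count means 1. [formula_string()] writes the counts back in Hill
#' order (C, H, then remaining elements alphabetically), so formulas
#' round-trip.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts, class `ms_formula`.
#' @export
#' @examples
#' parse_formula("C24H50NO7P")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    abort("`text` must be a single non-empty formula string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(text)) {
    abort(sprintf("cannot parse formula '%s'", text))
  }
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(MONOISOTOPIC_MASS)) {
      abort(sprintf("unknown element symbol '%s' in '%s'", sym, text))
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  if (sum(counts) < 1) abort("formula must contain at least one atom")
  structure(counts, class = "ms_formula")
}

#' @rdname parse_formula
#' @param formula An `ms_formula` or formula string.
#' @export
formula_string <- function(formula) {
  f <- as_formula(formula)
  f <- f[f > 0]
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(hill, function(s) {
    if (f[[s]] == 1) s else paste0(s, f[[s]])
  }, character(1)), collapse = "")
}

as_formula <- function(x) {
  if (inherits(x, "ms_formula")) x else parse_formula(x)
}

#' @export
print.ms_formula <- function(x, ...) {
  cat("<ms_formula>", formula_string(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral molecule
#'
#' Sum of most-abundant-isotope atomic masses over the formula's atoms.
#'
#' @param formula An `ms_formula` or formula string.
#' @return Mass in Daltons.
#' @export
#' @examples
#' monoisotopic_mass("H2O")  # 18.01056
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Cation adduct specification
#'
#' Describes a +1 ionization product: `[M+H]+`, `[M+Na]+` or `[M+K]+`. The
#' charge carrier adds its atomic mass and removes one electron.
#'
#' @param name Adduct name: `"[M+H]+"`, `"[M+Na]+"` or `"[M+K]+"` (the bare
#'   element symbols `"H"`, `"Na"`, `"K"` are accepted shorthand).
#' @return An `adduct_spec`: `name`, `added_atoms`, `charge`,
#'   `electron_correction`.
#' @export
adduct_spec <- function(name) {
  key <- c("[M+H]+" = "H", "[M+Na]+" = "Na", "[M+K]+" = "K",
           "H" = "H", "Na" = "Na", "K" = "K")
  if (!name %in% names(key)) {
    abort(sprintf("unsupported adduct '%s' (only +1 H/Na/K cations)", name))
  }
  el <- key[[name]]
  structure(
    list(name = sprintf("[M+%s]+", el),
         added_atoms = stats::setNames(1L, el),
         charge = 1L, electron_correction = TRUE),
    class = "adduct_spec"
  )
}

#' Theoretical m/z of an ionization product
#'
#' m/z of the +1 cation adduct of a neutral molecule, optionally carrying
#' 13C substitutions: monoisotopic mass, plus the charge carrier's atomic
#' mass, minus one electron mass (the ion is one electron short), plus
#' `n_13C` times the 13C-12C mass difference.
#'
#' @param formula An `ms_formula` or formula string.
#' @param adduct An [adduct_spec()] or adduct name.
#' @param n_13C Number of 13C substitutions (0 or more, at most the carbon
#'   count).
#' @return Theoretical m/z in Daltons (full precision; presentation is
#'   conventionally at 5 decimal places).
#' @export
#' @examples
#' round(adduct_mz("C24H50NO7P", "[M+Na]+"), 5)      # 518.32171
#' round(adduct_mz("C24H50NO7P", "[M+Na]+", 1), 5)   # 519.32507
adduct_mz <- function(formula, adduct, n_13C = 0) {
  f <- as_formula(formula)
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  if (adduct$charge != 1L) abort("only +1 charge is supported")
  n_c <- if ("C" %in% names(f)) f[["C"]] else 0L
  if (n_13C < 0 || n_13C > n_c) {
    abort(sprintf("`n_13C` must be between 0 and the carbon count (%d)", n_c))
  }
  monoisotopic_mass(f) +
    sum(MONOISOTOPIC_MASS[names(adduct$added_atoms)] *
          as.numeric(adduct$added_atoms)) -
    ELECTRON_MASS + n_13C * C13_DELTA
}

#' Parts-per-million mass difference
#'
#' Relative difference between an observed accurate mass and a theoretical
#' mass, in ppm of the theoretical mass.
#'
#' @param observed,theoretical Masses in Daltons, both positive.
#' @return ppm difference (non-negative; presentation conventionally at 2
#'   decimal places).
#' @export
ppm_delta <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0)) {
    abort("masses must be positive")
  }
  abs(observed - theoretical) / theoretical * 1e6
}

#' Match an observed accurate mass against candidate formulas
#'
#' Enumerates every (formula, adduct, 13C count) combination and keeps those
#' whose theoretical m/z falls within `tol_ppm` of the observed mass, sorted
#' by ascending |ppm| (ties by formula text). This is the adduct/isotope rule
#' engine used to put putative (MSI level 2) annotations on accurate masses.
#'
#' @param observed Observed accurate m/z (Daltons).
#' @param candidates Character vector (or list of `ms_formula`) of neutral
#'   candidate formulas.
#' @param adducts Adduct names to consider (default H, Na, K cations).
#' @param max_13C Maximum number of 13C substitutions to enumerate
#'   (default 1).
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return A tibble: `formula`, `adduct`, `n_13C`, `theoretical_mz`,
#'   `observed_mz`, `ppm_delta`, sorted by `ppm_delta`.
#' @export
#' @examples
#' match_candidates(518.3224, c("C24H50NO7P", "C26H54NO7P"))
match_candidates <- function(observed, candidates,
                             adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                             max_13C = 1, tol_ppm = 5) {
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) abort("`tol_ppm` must be > 0")
  if (!length(candidates)) {
    return(tibble(formula = character(), adduct = character(),
                  n_13C = integer(), theoretical_mz = numeric(),
                  observed_mz = numeric(), ppm_delta = numeric()))
  }
  grid <- tidyr::expand_grid(
    formula = vapply(candidates, formula_string, character(1),
                     USE.NAMES = FALSE),
    adduct = vapply(adducts, function(a) adduct_spec(a)$name, character(1),
                    USE.NAMES = FALSE),
    n_13C = 0:max_13C
  )
  grid <- dplyr::filter(
    grid,
    purrr::map2_lgl(.data$formula, .data$n_13C, function(f, k) {
      cf <- parse_formula(f)
      k <= (if ("C" %in% names(cf)) cf[["C"]] else 0L)
    })
  )
  grid$theoretical_mz <- purrr::pmap_dbl(
    list(grid$formula, grid$adduct, grid$n_13C), adduct_mz)
  grid$observed_mz <- observed
  grid$ppm_delta <- ppm_delta(observed, grid$theoretical_mz)
  out <- dplyr::filter(grid, .data$ppm_delta <= tol_ppm)
  dplyr::arrange(out, .data$ppm_delta, .data$formula)
}

#' Interpret nominal-mass relations within a correlation cluster
#'
#' Labels member-bin pairs of a [correlation_clusters()] component by the
#' characteristic nominal-mass spacings of ionization products of one
#' metabolite: a 16 m/z difference marks an [M+Na]+/[M+K]+ adduct pair
#' (K - Na = 15.97 u), a 1 m/z difference marks a 13C isotopologue pair.
#' All other spacings are labelled unknown.
#'
#' @param cluster A `feature_cluster`, or an integer vector of member bins.
#' @return A tibble: `bin_a`, `bin_b`, `nominal_diff`, `relation`
#'   (`"na_k_adduct_pair"`, `"isotopologue_pair"` or `"unknown"`). Zero rows
#'   for singletons.
#' @export
#' @examples
#' interpret_cluster(c(136, 152))  # Na/K adduct pair
interpret_cluster <- function(cluster) {
  bins <- if (inherits(cluster, "feature_cluster")) cluster$member_bins
          else sort(as.numeric(cluster))
  if (!length(bins)) abort("cluster must have >= 1 member")
  if (length(bins) < 2) {
    return(tibble(bin_a = numeric(), bin_b = numeric(),
                  nominal_diff = numeric(), relation = character()))
  }
  pairs <- t(utils::combn(bins, 2))
  d <- abs(pairs[, 2] - pairs[, 1])
  tibble(
    bin_a = pairs[, 1], bin_b = pairs[, 2], nominal_diff = d,
    relation = dplyr::case_when(
      d == 16 ~ "na_k_adduct_pair",
      d == 1 ~ "isotopologue_pair",
      TRUE ~ "unknown"
    )
  )
}
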