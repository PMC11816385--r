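#' bwsle: Bragg-Williams modeling of binary solid-liquid equilibria
#'
#' Single-parameter regular-solution (Bragg-Williams) modeling of the
#' liquidus of binary eutectic mixtures: closed-form liquidus branches,
#' eutectic-point location, estimation of the interaction parameter `zw`
#' from melting-point data, analytic error propagation, and a seeded
#' synthetic-data generator for parameter-recovery studies.
#'
#' All internal arithmetic is in SI units (K, J/mol) with the molar gas
#' constant R = 8.31446 J/(mol K). Files and user-facing reports carry
#' enthalpies and `zw` in kJ/mol.
#'
#' @keywords internal
"_PACKAGE"

# Molar gas constant, J/(mol K)
.R_GAS <- 8.31446

#' A pure compound's melting data
#'
#' Bundles the two pure-compound quantities the model needs: the melting
#' temperature and the molar enthalpy of melting (fusion). Enthalpies are
#' held internally in J/mol; [read_compounds()] converts from the kJ/mol
#' used in files.
#'
#' @param name Compound name (non-empty string).
#' @param tm Melting temperature of the pure compound, K (> 0).
#' @param dhm Molar enthalpy of melting, J/mol (> 0).
#'
#' @return An object of class `pure_compound`: a list with elements
#'   `name`, `tm` (K) and `dhm` (J/mol).
#' @examples
#' menthol <- pure_compound("Menthol", tm = 315.7, dhm = 12890)
#' menthol
#' @seealso [bw_compounds()] for the packaged registry.
#' @export
pure_compound <- function(name, tm, dhm) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(tm) || length(tm) != 1L || !is.finite(tm) || tm <= 0) {
    stop(sprintf("melting temperature of '%s' must be a positive number (got %s)",
                 name, format(tm)), call. = FALSE)
  }
  if (!is.numeric(dhm) || length(dhm) != 1L || !is.finite(dhm) || dhm <= 0) {
    stop(sprintf("enthalpy of melting of '%s' must be a positive number (got %s)",
                 name, format(dhm)), call. = FALSE)
  }
  structure(list(name = name, tm = as.numeric(tm), dhm = as.numeric(dhm)),
            class = "pure_compound")
}

#' @export
print.pure_compound <- function(x, ...) {
  cat(sprintf("<pure_compound> %s: Tm = %g K, dHm = %g kJ/mol\n",
              x$name, x$tm, x$dhm / 1000))
  invisible(x)
}

#' An ordered binary pair of compounds
#'
#' Defines a binary mixture A/B. Throughout the package the molar fraction
#' `x` (or `x_a`) refers to compound A; compound B has fraction `1 - x`.
#'
#' @param a,b [pure_compound()] objects with distinct names.
#'
#' @return An object of class `binary_pair`: a list with elements `a`, `b`.
#' @examples
#' reg <- bw_compounds()
#' binary_pair(compound(reg, "menthol"), compound(reg, "lauric acid"))
#' @export
binary_pair <- function(a, b) {
  stopifnot(inherits(a, "pure_compound"), inherits(b, "pure_compound"))
  if (identical(a$name, b$name)) {
    stop("a binary pair needs two distinct compounds (both are '",
         a$name, "')", call. = FALSE)
  }
  structure(list(a = a, b = b), class = "binary_pair")
}

#' @export
print.binary_pair <- function(x, ...) {
  cat(sprintf("<binary_pair> A = %s (Tm %g K), B = %s (Tm %g K); x is the molar fraction of A\n",
              x$a$name, x$a$tm, x$b$name, x$b$tm))
  invisible(x)
}

#' A Bragg-Williams mixture model
#'
#' A binary pair together with the single interaction parameter `zw`: the
#' number of contacts per molecule, z, times the energy change
#' w = E_AB - E_AA/2 - E_BB/2 of replacing like contacts by an unlike
#' contact. `zw = 0` recovers the ideal solution exactly; `zw < 0` lowers
#' the liquidus below the ideal curve at every interior composition
#' (deepening the eutectic), `zw > 0` raises it.
#'
#' @param pair A [binary_pair()].
#' @param zw Interaction parameter, J/mol (finite).
#'
#' @return An object of class `bw_model`.
#' @examples
#' reg <- bw_compounds()
#' pair <- binary_pair(compound(reg, "Menthol"), compound(reg, "Lauric acid"))
#' bw_model(pair, zw = -8000)
#' @export
bw_model <- function(pair, zw) {
  stopifnot(inherits(pair, "binary_pair"))
  if (!is.numeric(zw) || length(zw) != 1L || !is.finite(zw)) {
    stop("'zw' must be a single finite number (J/mol)", call. = FALSE)
  }
  structure(list(pair = pair, zw = as.numeric(zw)), class = "bw_model")
}

#' @export
print.bw_model <- function(x, ...) {
  cat(sprintf("<bw_model> %s / %s, zw = %g kJ/mol%s\n",
              x$pair$a$name, x$pair$b$name, x$zw / 1000,
              if (x$zw == 0) " (ideal solution)" else ""))
  invisible(x)
}

#' Compound registry
#'
#' A named collection of [pure_compound()]s with case-insensitive lookup.
#' `compound_registry()` builds one from a list; [bw_compounds()] loads the
#' packaged registry of thirteen compounds used in type V deep eutectic
#' solvents; [compound()] looks a compound up by name.
#'
#' @param compounds A list of [pure_compound()] objects.
#'
#' @return An object of class `compound_registry`.
#' @export
compound_registry <- function(compounds) {
  stopifnot(is.list(compounds),
            all(vapply(compounds, inherits, logical(1), "pure_compound")))
  nms <- vapply(compounds, `[[`, character(1), "name")
  dup <- duplicated(tolower(nms))
  if (any(dup)) {
    stop("duplicate compound name(s): ",
         paste(unique(nms[dup]), collapse = ", "), call. = FALSE)
  }
  names(compounds) <- nms
  structure(list(compounds = compounds), class = "compound_registry")
}

#' @rdname compound_registry
#' @export
bw_compounds <- function() {
  path <- system.file("extdata", "pure_compounds.csv", package = "bwsle",
                      mustWork = TRUE)
  read_compounds(path)
}

#' @rdname compound_registry
#' @param registry A `compound_registry`.
#' @param name Compound name; matching is case-insensitive.
#' @export
compound <- function(registry, name) {
  stopifnot(inherits(registry, "compound_registry"),
            is.character(name), length(name) == 1L)
  nms <- names(registry$compounds)
  hit <- match(tolower(name), tolower(nms))
  if (is.na(hit)) {
    stop(sprintf("unknown compound '%s'; available: %s", name,
                 paste(nms, collapse = ", ")), call. = FALSE)
  }
  registry$compounds[[hit]]
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf("<compound_registry> %d compounds\n", length(x$compounds)))
  for (cmp in x$compounds) {
    cat(sprintf("  %-24s Tm = %8.2f K  dHm = %8.4f kJ/mol\n",
                cmp$name, cmp$tm, cmp$dhm / 1000))
  }
  invisible(x)
}

#' @export
length.compound_registry <- function(x) length(x$compounds)
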