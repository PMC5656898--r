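#' Unit conversion between bohr and ångström
#'
#' All coordinates inside a [topology()] are stored in bohr (atomic units).
#' These helpers convert at the presentation boundary (XYZ input, mesh
#' export). The conversion factor is the 2018 CODATA Bohr radius in Å.
#'
#' @param x numeric vector, matrix or array of lengths.
#' @return `x` converted to the target unit.
#' @export
#' @examples
#' angstrom_to_bohr(0.74)  # H2 bond length in bohr
angstrom_to_bohr <- function(x) x / .bohr_in_angstrom

#' @rdname angstrom_to_bohr
#' @export
bohr_to_angstrom <- function(x) x * .bohr_in_angstrom

.bohr_in_angstrom <- 0.529177210903

# package-level cache for bundled data tables
.rhotop_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "rhotop")
  if (!nzchar(path)) {
    # during in-source development (pkgload) inst/ is on the search path
    path <- system.file("inst", "extdata", file, package = "rhotop")
  }
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

#' Bundled periodic data
#'
#' Returns the packaged element table: symbol, atomic number, Bondi-style
#' van der Waals radius (Å) and a PyMOL-compatible display color.
#'
#' @return a data.frame with columns `symbol`, `z`, `vdw_angstrom`,
#'   `color_r`, `color_g`, `color_b`.
#' @export
element_data <- function() {
  if (is.null(.rhotop_cache$elements)) {
    .rhotop_cache$elements <- utils::read.csv(.extdata("element_data.csv"),
                                              stringsAsFactors = FALSE)
  }
  .rhotop_cache$elements
}

# look up a single element row; error (or NA row) when unknown
.element_row <- function(symbol, required = TRUE) {
  tab <- element_data()
  i <- match(symbol, tab$symbol)
  if (is.na(i) && required) {
    stop("unrecognized element symbol: ", symbol)
  }
  if (is.na(i)) NULL else tab[i, ]
}

# van der Waals radius in bohr
.vdw_bohr <- function(symbol) {
  row <- .element_row(symbol, required = FALSE)
  if (is.null(row)) return(NA_real_)
  angstrom_to_bohr(row$vdw_angstrom)
}

.element_color <- function(symbol) {
  row <- .element_row(symbol, required = FALSE)
  if (is.null(row)) {
    warning("element ", symbol, " missing from bundled color table; using gray")
    return(c(0.5, 0.5, 0.5))
  }
  c(row$color_r, row$color_g, row$color_b)
}
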