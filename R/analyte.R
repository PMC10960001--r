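#' Structured analyte ground truth
#'
#' An `analyte_label` records the structural characteristics of one analyte
#' class in the cerebroside panel: its category (MPBA blank, monosaccharide,
#' or cerebroside), hexose identity (glucosyl/galactosyl), ceramide
#' saturation degree Y (number of C=C bonds, 0 or 1) and ceramide acyl chain
#' length X (carbons). Blanks carry no hexose; monosaccharides carry no
#' ceramide attributes.
#'
#' @param category one of `"blank"`, `"monosaccharide"`, `"cerebroside"`.
#' @param hexose one of `"glc"`, `"gal"`, `"none"` (blanks must be `"none"`).
#' @param saturation integer 0 or 1 (cerebrosides only), else `NA`.
#' @param chain_length integer in `{8, 12, 16, 18, 24}` (cerebrosides only),
#'   else `NA`.
#' @return An object of class `"analyte_label"`.
#' @examples
#' analyte_label("cerebroside", "glc", saturation = 1, chain_length = 24)
#' @export
analyte_label <- function(category = c("blank", "monosaccharide", "cerebroside"),
                          hexose = c("none", "glc", "gal"),
                          saturation = NA_integer_,
                          chain_length = NA_integer_) {
  category <- match.arg(category)
  hexose <- match.arg(hexose)
  if (category == "blank" && hexose != "none") {
    stop("blank implies hexose 'none'", call. = FALSE)
  }
  if (category != "blank" && hexose == "none") {
    stop(category, " requires a hexose ('glc' or 'gal')", call. = FALSE)
  }
  if (category == "cerebroside") {
    saturation <- as.integer(saturation)
    chain_length <- as.integer(chain_length)
    if (is.na(saturation) || !saturation %in% c(0L, 1L)) {
      stop("cerebroside requires saturation Y in {0, 1}", call. = FALSE)
    }
    if (is.na(chain_length) || !chain_length %in% c(8L, 12L, 16L, 18L, 24L)) {
      stop("cerebroside requires chain length X in {8, 12, 16, 18, 24}",
           call. = FALSE)
    }
  } else {
    if (!is.na(saturation) || !is.na(chain_length)) {
      stop(category, " carries no ceramide attributes", call. = FALSE)
    }
    saturation <- NA_integer_
    chain_length <- NA_integer_
  }
  structure(list(category = category, hexose = hexose,
                 saturation = saturation, chain_length = chain_length),
            class = "analyte_label")
}

is_analyte_label <- function(x) inherits(x, "analyte_label")

#' @export
print.analyte_label <- function(x, ...) {
  cat("analyte:", nomenclature(x), "\n")
  invisible(x)
}

#' @export
format.analyte_label <- function(x, ...) nomenclature(x)

#' Canonical nomenclature string of an analyte
#'
#' Pure function of the label fields. Cerebrosides follow the field
#' convention `GlcCerX` (saturated) / `GlcCerX:1` (monounsaturated), e.g.
#' chain length 8, saturated, glucosyl gives `"GlcCer8"`, and Y = 1, X = 24
#' gives `"GlcCer24:1"`. Blanks map to `"MPBA blank"`, monosaccharides to
#' `"glucose"` / `"galactose"`.
#'
#' @param label an [analyte_label()].
#' @return character scalar.
#' @export
nomenclature <- function(label) {
  stopifnot(is_analyte_label(label))
  switch(label$category,
    blank = "MPBA blank",
    monosaccharide = if (label$hexose == "glc") "glucose" else "galactose",
    cerebroside = {
      stem <- if (label$hexose == "glc") "GlcCer" else "GalCer"
      suffix <- if (label$saturation > 0L) paste0(":", label$saturation) else ""
      paste0(stem, label$chain_length, suffix)
    })
}

#' Parse a nomenclature string back into an analyte label
#'
#' Inverse of [nomenclature()] over the in-scope classes, e.g.
#' `"GalCer24:1"` parses to a galactosyl cerebroside with Y = 1, X = 24.
#'
#' @param x character scalar such as `"MPBA blank"`, `"glucose"`,
#'   `"GlcCer8"`, `"GalCer24:1"`.
#' @return An [analyte_label()].
#' @export
parse_nomenclature <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x %in% c("MPBA blank", "blank", "MPBA")) return(analyte_label("blank"))
  if (x == "glucose") return(analyte_label("monosaccharide", "glc"))
  if (x == "galactose") return(analyte_label("monosaccharide", "gal"))
  m <- regmatches(x, regexec("^(Glc|Gal)Cer([0-9]+)(?::([0-9]+))?$", x))[[1]]
  if (length(m) == 0L) {
    stop("unknown analyte nomenclature: '", x, "'", call. = FALSE)
  }
  hex <- if (m[2] == "Glc") "glc" else "gal"
  sat <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  tryCatch(
    analyte_label("cerebroside", hex, saturation = sat,
                  chain_length = as.integer(m[3])),
    error = function(e) stop("unknown analyte nomenclature: '", x, "'",
                             call. = FALSE))
}

#' The 14 analyte classes of the default panel
#'
#' One MPBA blank, two monosaccharide interferents (glucose, galactose),
#' five glucocerebrosides (chains 8, 12, 16, 18 saturated and 24:1) and six
#' galactocerebrosides (8, 12, 16, 18, 24 saturated and 24:1).
#'
#' @return Named list of [analyte_label()] objects keyed by nomenclature.
#' @export
analyte_panel <- function() {
  labs <- list(analyte_label("blank"),
               analyte_label("monosaccharide", "glc"),
               analyte_label("monosaccharide", "gal"))
  for (x in c(8L, 12L, 16L, 18L)) {
    labs <- c(labs, list(analyte_label("cerebroside", "glc", 0L, x)))
  }
  labs <- c(labs, list(analyte_label("cerebroside", "glc", 1L, 24L)))
  for (x in c(8L, 12L, 16L, 18L, 24L)) {
    labs <- c(labs, list(analyte_label("cerebroside", "gal", 0L, x)))
  }
  labs <- c(labs, list(analyte_label("cerebroside", "gal", 1L, 24L)))
  names(labs) <- vapply(labs, nomenclature, character(1))
  labs
}

#' Names of the 11 cerebroside classes
#' @return character vector of cerebroside nomenclature strings.
#' @export
cerebroside_names <- function() {
  panel <- analyte_panel()
  names(panel)[vapply(panel, function(l) l$category == "cerebroside",
                      logical(1))]
}
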