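#' Construct a Raman/SERS spectrum object
#'
#' A `spectrum` is the atomic I/O unit of the package: a strictly increasing
#' Raman-shift axis (cm^-1), a parallel intensity vector (arbitrary units) and
#' a free-form metadata map of character values (analyte identity,
#' concentration, replicate id, preprocessing state).
#'
#' @param wavenumbers numeric vector of Raman shifts in cm^-1, strictly
#'   increasing after sorting; duplicates are an error.
#' @param intensities numeric vector of the same length, all finite.
#' @param meta named list of character scalars attached to the spectrum.
#' @return An object of class `"spectrum"`.
#' @examples
#' sp <- spectrum(c(400, 1100, 1800), c(0, 1, 0))
#' sp
#' @export
spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("empty spectrum: need at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(!is.finite(intensities))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  intensities <- intensities[ord]
  if (any(diff(wavenumbers) == 0)) {
    stop("duplicate wavenumbers are not allowed", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = lapply(meta, as.character)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("SERS spectrum: %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavenumbers)

is_spectrum <- function(x) inherits(x, "spectrum")

#' Read a two-column delimited spectrum file
#'
#' Reads wavenumber/intensity pairs from a delimited text file. Lines starting
#' with `comment_char` are treated as metadata headers of the form
#' `# key: value` and collected into the spectrum's `meta` map. Rows are
#' sorted by ascending wavenumber.
#'
#' @param path file to read.
#' @param sep field delimiter; `NULL` (default) auto-detects comma, tab,
#'   semicolon or whitespace from the first data line.
#' @param comment_char prefix marking header/comment lines.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sep = NULL, comment_char = "#") {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- startsWith(trimws(lines), comment_char)
  for (ln in lines[is_comment]) {
    body <- sub(paste0("^\\s*", comment_char, "\\s*"), "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      if (nzchar(key)) meta[[key]] <- val
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) < 2L) {
    stop("empty spectrum: fewer than 2 data rows in ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    probe <- lines[data_idx[1]]
    sep <- if (grepl(",", probe)) "," else if (grepl("\t", probe)) "\t"
           else if (grepl(";", probe)) ";" else ""
  }
  n <- length(data_idx)
  wn <- numeric(n); it <- numeric(n)
  for (i in seq_len(n)) {
    row <- lines[data_idx[i]]
    parts <- if (identical(sep, "")) strsplit(trimws(row), "\\s+")[[1]]
             else strsplit(row, sep, fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (length(parts) < 2L || any(is.na(vals))) {
      stop(sprintf("parse error at line %d of %s: %s",
                   data_idx[i], path, row), call. = FALSE)
    }
    wn[i] <- vals[1]; it[i] <- vals[2]
  }
  spectrum(wn, it, meta)
}

#' Write a spectrum to a two-column delimited file
#'
#' Metadata are written as `# key: value` header lines; data rows as
#' `wavenumber,intensity`.
#'
#' @param sp a [spectrum()].
#' @param path output file.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path, sep = ",") {
  stopifnot(is_spectrum(sp))
  header <- if (length(sp$meta)) {
    paste0("# ", names(sp$meta), ": ", unlist(sp$meta))
  } else character()
  rows <- paste(format(sp$wavenumbers, trim = TRUE, digits = 10),
                format(sp$intensities, trim = TRUE, digits = 10), sep = sep)
  writeLines(c(header, rows), path)
  invisible(path)
}
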