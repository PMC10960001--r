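#' Assemble a labeled collection of spectra
#'
#' A `spectrum_set` holds parallel collections: spectra, analyte labels,
#' molar concentrations and replicate ids, plus optional file references.
#' Concentrations are carried both numerically and as the original decimal
#' strings so that manifests round-trip without float drift.
#'
#' @param spectra list of [spectrum()] objects (entries may be `NULL` for a
#'   manifest skeleton that references files not yet loaded).
#' @param labels list of [analyte_label()] objects, same length.
#' @param concentration molar concentrations; numeric vector or character
#'   vector of decimal strings. Use `NA` for blanks.
#' @param replicate integer replicate ids (default `1..n` within each
#'   label/concentration cell).
#' @param file optional character vector of spectrum file references.
#' @return An object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(spectra, labels, concentration,
                         replicate = NULL, file = NULL) {
  n <- length(labels)
  if (length(spectra) != n || length(concentration) != n) {
    stop("spectra, labels and concentration must be parallel collections",
         call. = FALSE)
  }
  ok <- vapply(labels, is_analyte_label, logical(1))
  if (!all(ok)) stop("labels must be analyte_label objects", call. = FALSE)
  conc_chr <- as.character(concentration)
  conc_num <- suppressWarnings(as.numeric(conc_chr))
  if (is.null(replicate)) {
    key <- paste(vapply(labels, nomenclature, character(1)), conc_chr)
    replicate <- stats::ave(seq_len(n), key, FUN = seq_along)
  }
  if (is.null(file)) file <- rep(NA_character_, n)
  structure(list(spectra = spectra, labels = labels,
                 concentration = conc_num, concentration_chr = conc_chr,
                 replicate = as.integer(replicate),
                 file = as.character(file)),
            class = "spectrum_set")
}

#' @export
length.spectrum_set <- function(x) length(x$labels)

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra, %d classes\n", length(x),
              length(unique(vapply(x$labels, nomenclature, character(1))))))
  print(replicate_counts(x))
  invisible(x)
}

#' Replicate counts per (analyte, concentration) cell
#'
#' @param set a [spectrum_set()].
#' @return data.frame with columns `analyte`, `concentration_M`, `n`.
#' @export
replicate_counts <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  analyte <- vapply(set$labels, nomenclature, character(1))
  conc <- set$concentration_chr
  conc[is.na(conc)] <- ""  # blanks carry no concentration
  agg <- stats::aggregate(list(n = seq_along(analyte)),
                          by = list(analyte = analyte,
                                    concentration_M = conc),
                          FUN = length)
  agg[order(agg$analyte, agg$concentration_M), , drop = FALSE]
}

manifest_columns <- c("file", "category", "hexose", "saturation",
                      "chain_length", "concentration_M", "replicate")

#' Write a manifest describing a spectrum set
#'
#' The manifest is a plain CSV with columns `file`, `category`, `hexose`,
#' `saturation`, `chain_length`, `concentration_M`, `replicate`.
#' `write_manifest` followed by [read_manifest()] reproduces labels,
#' concentration strings and file references exactly, and a second write is
#' byte-identical.
#'
#' @param set a [spectrum_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(
    file = set$file,
    category = vapply(set$labels, function(l) l$category, character(1)),
    hexose = vapply(set$labels, function(l) l$hexose, character(1)),
    saturation = vapply(set$labels, function(l)
      ifelse(is.na(l$saturation), "", as.character(l$saturation)), character(1)),
    chain_length = vapply(set$labels, function(l)
      ifelse(is.na(l$chain_length), "", as.character(l$chain_length)), character(1)),
    concentration_M = ifelse(is.na(set$concentration_chr) |
                               set$concentration_chr == "NA", "",
                             set$concentration_chr),
    replicate = set$replicate,
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) {
    writeLines(paste(manifest_columns, collapse = ","), path)
    return(invisible(path))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a manifest into a spectrum-set skeleton
#'
#' Returns a [spectrum_set()] whose `spectra` entries are `NULL`; labels,
#' concentrations and file references are restored from the CSV.
#'
#' @param path manifest CSV written by [write_manifest()].
#' @return A [spectrum_set()] skeleton.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    cat_i <- df$category[i]
    if (!cat_i %in% c("blank", "monosaccharide", "cerebroside")) {
      stop("unknown category token '", cat_i, "' at manifest row ", i,
           call. = FALSE)
    }
    labels[[i]] <- analyte_label(
      cat_i, df$hexose[i],
      saturation = if (nzchar(df$saturation[i]))
        as.integer(df$saturation[i]) else NA_integer_,
      chain_length = if (nzchar(df$chain_length[i]))
        as.integer(df$chain_length[i]) else NA_integer_
    )
  }
  conc <- ifelse(nzchar(df$concentration_M), df$concentration_M, NA_character_)
  spectrum_set(vector("list", n), labels, conc,
               replicate = as.integer(df$replicate), file = df$file)
}
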