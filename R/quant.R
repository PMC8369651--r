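#' Protein quantification table
#'
#' Container for a proteins x samples label-free abundance matrix with
#' per-sample condition and replicate-batch annotation. `kind` records the
#' normalization stage and may only progress iBAQ -> FOT -> FOT_normalized.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein IDs),
#'   samples in columns (colnames = sample IDs); `NA` marks missing.
#' @param condition character vector per sample, e.g. `"control"`,
#'   `"treated"`, `"undigested"`.
#' @param batch per-sample replicate/batch tag.
#' @param kind one of `"iBAQ"`, `"FOT"`, `"FOT_normalized"`.
#' @return an object of class `QuantTable`.
#' @export
quant_table <- function(values, condition, batch = NULL,
                        kind = c("iBAQ", "FOT", "FOT_normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein IDs")
  if (length(condition) != ncol(values))
    stop("condition must have one entry per sample")
  if (is.null(batch)) batch <- rep(NA_character_, ncol(values))
  if (length(batch) != ncol(values))
    stop("batch must have one entry per sample")
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  structure(list(values = values, condition = as.character(condition),
                 batch = as.character(batch), kind = kind),
            class = "QuantTable")
}

#' @export
print.QuantTable <- function(x, ...) {
  cat("QuantTable:", nrow(x$values), "proteins x", ncol(x$values),
      "samples [", x$kind, "],",
      sum(is.na(x$values)), "missing values\n")
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Load a label-free quantification table
#'
#' Reads a delimiter-separated text file whose first column holds protein
#' IDs and remaining columns per-sample iBAQ values. Empty cells, `"NA"` and
#' unparseable cells become missing. Every sample column must be covered by
#' the metadata.
#'
#' @param path tab- (or `sep`-) separated file with a header line.
#' @param metadata data frame with columns `sample`, `condition` and
#'   optionally `batch`.
#' @param sep field separator (default tab).
#' @return a [quant_table()] of kind `iBAQ`.
#' @export
load_quant_table <- function(path, metadata, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(raw)[-1]
  missing_meta <- setdiff(samples, metadata$sample)
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, samples))
  idx <- match(samples, metadata$sample)
  quant_table(vals, condition = metadata$condition[idx],
              batch = if ("batch" %in% names(metadata))
                        metadata$batch[idx] else NULL,
              kind = "iBAQ")
}

#' Write a quantification table to delimited text
#'
#' Missing values are written as `NA`; [load_quant_table()] reads them back
#' as missing.
#'
#' @param qt a [quant_table()].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path, sep = "\t") {
  df <- data.frame(protein = rownames(qt$values),
                   qt$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
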