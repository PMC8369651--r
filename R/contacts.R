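#' Intra-chromosomal contact matrix
#'
#' Sparse symmetric contact map for one chromosome: only the upper triangle
#' (`bin1 <= bin2`, 0-based bins) is stored; counts supplied at `(j, i)` are
#' folded into `(i, j)` and duplicate pixels are summed.
#'
#' @param chrom chromosome name (must be in the binning).
#' @param binning a [genome_binning()].
#' @param pixels data frame with columns `bin1`, `bin2`, `count`.
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(chrom, binning, pixels) {
  nb <- n_bins(binning, chrom)
  pixels <- as.data.frame(pixels)
  stopifnot(all(c("bin1", "bin2", "count") %in% names(pixels)))
  if (any(pixels$count < 0)) stop("negative contact count")
  if (nrow(pixels) && (min(pixels$bin1, pixels$bin2) < 0 ||
                       max(pixels$bin1, pixels$bin2) >= nb))
    stop("bin index out of range for ", chrom, " (", nb, " bins)")
  i <- pmin(pixels$bin1, pixels$bin2)
  j <- pmax(pixels$bin1, pixels$bin2)
  key <- i * nb + j
  agg <- rowsum(pixels$count, key)
  k <- as.numeric(rownames(agg))
  px <- data.frame(bin1 = k %/% nb, bin2 = k %% nb, count = agg[, 1])
  px <- px[order(px$bin1, px$bin2), , drop = FALSE]
  rownames(px) <- NULL
  structure(list(chrom = chrom, binning = binning, pixels = px),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix:", x$chrom, "(", n_bins(x$binning, x$chrom), "bins at",
      x$binning$resolution, "bp ),", nrow(x$pixels), "pixels, total count",
      sum(x$pixels$count), "\n")
  invisible(x)
}

#' Load a sparse triplet contact matrix
#'
#' Accepts either 3-column lines `bin_i bin_j count` or 5-column lines
#' `chrom1 pos1 chrom2 pos2 count` (positions are assigned to bins by
#' integer division). All records must lie on the requested chromosome.
#'
#' @param path triplet text file.
#' @param binning a [genome_binning()].
#' @param chrom chromosome name.
#' @return a [contact_matrix()].
#' @export
load_contacts <- function(path, binning, chrom) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(contact_matrix(chrom, binning,
                          data.frame(bin1 = integer(), bin2 = integer(),
                                     count = numeric())))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 5L))) stop("lines must have 3 or 5 fields")
  res <- binning$resolution
  recs <- lapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    if (length(f) == 3L) {
      c(bin1 = as.numeric(f[[1]]), bin2 = as.numeric(f[[2]]),
        count = as.numeric(f[[3]]))
    } else {
      if (f[[1]] != chrom || f[[3]] != chrom)
        stop("line ", k, ": chromosome mismatch (expected ", chrom, ")")
      c(bin1 = as.numeric(f[[2]]) %/% res, bin2 = as.numeric(f[[4]]) %/% res,
        count = as.numeric(f[[5]]))
    }
  })
  px <- as.data.frame(do.call(rbind, recs))
  if (anyNA(px)) stop("unparseable numeric field")
  contact_matrix(chrom, binning, px)
}

#' Write a contact matrix as bin-pair triplet text
#'
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path) {
  writeLines(sprintf("%d\t%d\t%s", cm$pixels$bin1, cm$pixels$bin2,
                     format(cm$pixels$count, digits = 17, trim = TRUE,
                            scientific = FALSE)),
             path)
  invisible(path)
}

#' Densify a contact matrix
#'
#' @param cm a [contact_matrix()].
#' @return dense symmetric numeric matrix (bins x bins).
#' @export
as_dense <- function(cm) {
  nb <- n_bins(cm$binning, cm$chrom)
  m <- matrix(0, nb, nb)
  if (nrow(cm$pixels)) {
    i <- cm$pixels$bin1 + 1L; j <- cm$pixels$bin2 + 1L
    m[cbind(i, j)] <- cm$pixels$count
    m[cbind(j, i)] <- cm$pixels$count
  }
  m
}
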