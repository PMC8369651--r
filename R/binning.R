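#' Fixed-resolution genome binning
#'
#' A binning partitions each chromosome into consecutive fixed-width bins.
#' Bin `i` (0-based) covers the half-open interval `[i*resolution,
#' (i+1)*resolution)`; the last bin of a chromosome may be short. All
#' coordinates in this package are 0-based, half-open (BED convention).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param resolution bin width in bp (positive integer).
#' @return an object of class `GenomeBinning`.
#' @examples
#' gb <- genome_binning(c(chr1 = 1e6), 1e5)
#' n_bins(gb, "chr1")
#' @export
genome_binning <- function(chrom_sizes, resolution) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  resolution <- as.integer(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0L)
    stop("resolution must be a positive integer")
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution),
            class = "GenomeBinning")
}

#' @rdname genome_binning
#' @param binning a `GenomeBinning`.
#' @param chrom chromosome name.
#' @export
n_bins <- function(binning, chrom) {
  stopifnot(inherits(binning, "GenomeBinning"))
  size <- binning$chrom_sizes[[chrom]]
  if (is.null(size)) stop("unknown chromosome: ", chrom)
  as.integer(ceiling(size / binning$resolution))
}

#' @export
print.GenomeBinning <- function(x, ...) {
  cat("GenomeBinning:", length(x$chrom_sizes), "chromosome(s) at",
      x$resolution, "bp resolution\n")
  invisible(x)
}

#' Per-bin scalar track
#'
#' Holds one scalar per bin of one chromosome (PC1, insulation score, gene
#' density, motif density, ...). Missing bins are `NA`.
#'
#' @param binning a [genome_binning()].
#' @param chrom chromosome name present in the binning.
#' @param values numeric vector of length `n_bins(binning, chrom)`.
#' @return an object of class `BinTrack`.
#' @export
bin_track <- function(binning, chrom, values) {
  nb <- n_bins(binning, chrom)
  if (length(values) != nb)
    stop("values has length ", length(values), " but chromosome ", chrom,
         " has ", nb, " bins")
  structure(list(chrom = chrom, binning = binning,
                 values = as.numeric(values)),
            class = "BinTrack")
}

#' @export
print.BinTrack <- function(x, ...) {
  cat("BinTrack on", x$chrom, "(", length(x$values), "bins at",
      x$binning$resolution, "bp;", sum(is.na(x$values)), "missing )\n")
  invisible(x)
}

#' Write a bin track as bedGraph
#'
#' One line per defined bin; missing bins are omitted. The interval end is
#' clipped at the chromosome length for the final (possibly short) bin.
#'
#' @param track a [bin_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "BinTrack"))
  res <- track$binning$resolution
  size <- track$binning$chrom_sizes[[track$chrom]]
  keep <- which(!is.na(track$values))
  starts <- (keep - 1L) * res
  ends <- pmin(starts + res, size)
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, starts, ends,
                   format(track$values[keep], digits = 17, trim = TRUE,
                          scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a bin track
#'
#' Every interval must coincide exactly with a bin of `binning`; bins absent
#' from the file become `NA`.
#'
#' @param path bedGraph file (4 columns, no header).
#' @inheritParams bin_track
#' @return a [bin_track()].
#' @export
read_bedgraph <- function(path, binning, chrom) {
  nb <- n_bins(binning, chrom)
  res <- binning$resolution
  size <- binning$chrom_sizes[[chrom]]
  vals <- rep(NA_real_, nb)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "[ \t]+")[[1]]
    if (length(f) < 4L) stop("bedGraph line ", k, ": expected 4 columns")
    if (f[[1]] != chrom) stop("bedGraph line ", k, ": chromosome ", f[[1]],
                              " does not match ", chrom)
    start <- as.numeric(f[[2]]); end <- as.numeric(f[[3]])
    if (start %% res != 0 || end != min(start + res, size))
      stop("bedGraph line ", k, ": interval [", start, ",", end,
           ") is not aligned to the ", res, " bp binning")
    i <- start %/% res + 1L
    if (i > nb) stop("bedGraph line ", k, ": interval beyond chromosome end")
    vals[i] <- as.numeric(f[[4]])
  }
  bin_track(binning, chrom, vals)
}

#' Motif occurrence density track
#'
#' Counts exact occurrences of a DNA motif per fixed-width bin across each
#' sequence of a FASTA file (occurrence start position determines the bin;
#' overlapping occurrences all count; matching is case-insensitive). Only the
#' given strand is scanned: no reverse-complement search, which is exact for
#' palindromic recognition sites such as HaeIII's GGCC.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param motif motif string over A/C/G/T, no longer than `binsize`.
#' @param binsize bin width in bp (default 500, the conventional window for
#'   restriction-site frequency tracks).
#' @return a named list of [bin_track()] objects, one per sequence.
#' @export
motif_density_track <- function(fasta, motif, binsize = 500) {
  if (!grepl("^[ACGTacgt]+$", motif))
    stop("motif must contain only A/C/G/T characters")
  if (nchar(motif) > binsize) stop("motif longer than binsize")
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sizes <- stats::setNames(Biostrings::width(seqs), names(seqs))
  gb <- genome_binning(sizes, binsize)
  pat <- Biostrings::DNAString(toupper(motif))
  out <- lapply(names(seqs), function(nm) {
    hits <- Biostrings::matchPattern(pat, seqs[[nm]])
    starts0 <- Biostrings::start(hits) - 1L  # to 0-based
    counts <- tabulate(starts0 %/% binsize + 1L, nbins = n_bins(gb, nm))
    bin_track(gb, nm, counts)
  })
  stats::setNames(out, names(seqs))
}

#' Mean signal profile around interval midpoints
#'
#' Extracts a window of `2*flank/resolution + 1` bins centered on each
#' interval midpoint and averages element-wise over intervals (missing values
#' excluded per position). Windows truncated by a chromosome edge are
#' dropped. The midpoint of an interval is `floor((start + end) / 2)`.
#'
#' @param track a [bin_track()].
#' @param centers an `IntervalSet` (see [load_intervals()]) or data frame
#'   with `chrom`, `start`, `end`.
#' @param flank flank size in bp on each side; must be a multiple of the
#'   track resolution.
#' @return numeric vector over relative bin positions (-flank .. +flank),
#'   with an attribute `n_intervals` giving the number of windows averaged.
#' @export
aggregate_track_at_intervals <- function(track, centers, flank) {
  stopifnot(inherits(track, "BinTrack"))
  centers <- as.data.frame(centers)
  centers <- centers[centers$chrom == track$chrom, , drop = FALSE]
  if (nrow(centers) == 0L) stop("empty interval set for chromosome ",
                                track$chrom)
  res <- track$binning$resolution
  if (flank %% res != 0) stop("flank must be a multiple of the resolution")
  w <- flank %/% res
  nb <- length(track$values)
  mids <- floor((centers$start + centers$end) / 2)
  cbin <- mids %/% res + 1L
  keep <- cbin - w >= 1L & cbin + w <= nb
  if (!any(keep)) stop("all windows truncated at chromosome edges")
  rows <- lapply(cbin[keep], function(b) track$values[(b - w):(b + w)])
  m <- do.call(rbind, rows)
  prof <- colMeans(m, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  names(prof) <- seq(-w, w) * res
  attr(prof, "n_intervals") <- sum(keep)
  prof
}
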