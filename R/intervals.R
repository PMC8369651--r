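#' Genomic interval and paired-anchor (loop) sets
#'
#' `interval_set()` validates a BED-like table (`chrom`, `start`, `end`,
#' optional `name`, `score`); `loop_set()` validates a BEDPE-like table of
#' anchor pairs. Coordinates are 0-based half-open. Cis loop records are
#' stored with anchor1 genomically upstream of (or equal to) anchor2.
#'
#' @param df data frame with the required columns.
#' @return the validated data frame with class `IntervalSet` or `LoopSet`.
#' @export
interval_set <- function(df) {
  df <- as.data.frame(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stop("need columns chrom, start, end")
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("start >= end at record ", bad[[1]])
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' @rdname interval_set
#' @export
loop_set <- function(df) {
  df <- as.data.frame(df)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(need %in% names(df))) stop("need BEDPE columns chrom1..end2")
  bad <- which(df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad)) stop("start >= end at record ", bad[[1]])
  flip <- df$chrom1 == df$chrom2 & df$start1 > df$start2
  if (any(flip)) {
    tmp <- df[flip, c("start1", "end1")]
    df[flip, c("start1", "end1")] <- df[flip, c("start2", "end2")]
    df[flip, c("start2", "end2")] <- tmp
  }
  class(df) <- c("LoopSet", "data.frame")
  df
}

#' Read BED or BEDPE interval files
#'
#' BED needs at least 3 columns (optional 4th = name, 5th = score); BEDPE at
#' least 6 (optional 7th = name, 8th = score, further columns kept as
#' attribute columns `attr1`, `attr2`, ...). Records with `start >= end` are
#' rejected with their line number. BEDPE cis records are reordered so
#' anchor1 precedes anchor2.
#'
#' @param path input file, whitespace- or tab-delimited, no header.
#' @param kind `"BED"` or `"BEDPE"`.
#' @return an `IntervalSet` or `LoopSet` data frame.
#' @export
load_intervals <- function(path, kind = c("BED", "BEDPE")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  fields <- strsplit(lines, "[ \t]+")
  if (kind == "BED") {
    recs <- lapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      if (length(f) < 3L) stop("line ", k, ": BED needs >= 3 columns")
      start <- as.numeric(f[[2]]); end <- as.numeric(f[[3]])
      if (is.na(start) || is.na(end)) stop("line ", k, ": non-numeric coordinate")
      if (start >= end) stop("line ", k, ": start >= end")
      data.frame(chrom = f[[1]], start = start, end = end,
                 name = if (length(f) >= 4L && f[[4]] != ".") f[[4]]
                        else NA_character_,
                 score = if (length(f) >= 5L && f[[5]] != ".")
                           as.numeric(f[[5]]) else NA_real_)
    })
    interval_set(do.call(rbind, recs))
  } else {
    recs <- lapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      if (length(f) < 6L) stop("line ", k, ": BEDPE needs >= 6 columns")
      co <- as.numeric(f[2:3]); co2 <- as.numeric(f[5:6])
      if (anyNA(c(co, co2))) stop("line ", k, ": non-numeric coordinate")
      if (co[[1]] >= co[[2]] || co2[[1]] >= co2[[2]])
        stop("line ", k, ": start >= end")
      rec <- data.frame(chrom1 = f[[1]], start1 = co[[1]], end1 = co[[2]],
                        chrom2 = f[[4]], start2 = co2[[1]], end2 = co2[[2]],
                        name = if (length(f) >= 7L && f[[7]] != ".") f[[7]]
                               else NA_character_,
                        score = if (length(f) >= 8L && f[[8]] != ".")
                                  as.numeric(f[[8]]) else NA_real_)
      if (length(f) > 8L)
        for (j in 9:length(f)) rec[[paste0("attr", j - 8L)]] <- f[[j]]
      rec
    })
    ncols <- vapply(recs, ncol, 0L)
    if (length(unique(ncols)) > 1L)
      stop("inconsistent number of BEDPE attribute columns")
    loop_set(do.call(rbind, recs))
  }
}

#' Write interval / loop sets back to BED / BEDPE text
#'
#' @param x an `IntervalSet` or `LoopSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  fmt <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  if (inherits(x, "LoopSet")) {
    cols <- cbind(x$chrom1, fmt(x$start1), fmt(x$end1),
                  x$chrom2, fmt(x$start2), fmt(x$end2))
    extra <- setdiff(names(x), c("chrom1", "start1", "end1",
                                 "chrom2", "start2", "end2"))
  } else {
    cols <- cbind(x$chrom, fmt(x$start), fmt(x$end))
    extra <- setdiff(names(x), c("chrom", "start", "end"))
  }
  keep <- which(vapply(extra, function(e) !all(is.na(x[[e]])), logical(1)))
  if (length(keep)) {
    for (e in extra[seq_len(max(keep))]) {  # trailing all-NA columns dropped
      v <- x[[e]]
      cols <- cbind(cols, ifelse(is.na(v), ".", as.character(v)))
    }
  }
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

# plain interval overlap on 0-based half-open coordinates
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
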