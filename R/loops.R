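# anchor midpoint -> 0-based bin at the matrix resolution
.anchor_bins <- function(loops, resolution) {
  loops <- as.data.frame(loops)
  m1 <- floor((loops$start1 + loops$end1) / 2)
  m2 <- floor((loops$start2 + loops$end2) / 2)
  b1 <- m1 %/% resolution
  b2 <- m2 %/% resolution
  data.frame(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2))
}

#' Per-loop contact-probability change
#'
#' For each loop, the ratio of depth-normalized contact probability
#' (balanced value / total balanced sum) at the loop pixel, after over
#' before. Loop anchors are mapped to bins via their midpoints. Loops whose
#' pixel is masked in either matrix, or whose before-probability is zero,
#' are flagged `undefined` and excluded from the summary mean.
#'
#' @param before,after [kr_balance()] results on the same binning.
#' @param loops a `LoopSet` (cis, on this chromosome).
#' @return list with `loops` (per-loop data frame: `bin1`, `bin2`, `ratio`,
#'   `flag`) and `mean_ratio` over defined loops.
#' @export
loop_signal_change <- function(before, after, loops) {
  stopifnot(inherits(before, "BalancedView"), inherits(after, "BalancedView"))
  res <- before$binning$resolution
  ab <- .anchor_bins(loops, res)
  n <- nrow(before$balanced)
  ratio <- rep(NA_real_, nrow(ab))
  flag <- rep("ok", nrow(ab))
  for (k in seq_len(nrow(ab))) {
    i <- ab$bin1[k] + 1L; j <- ab$bin2[k] + 1L
    if (i < 1L || j > n) { flag[k] <- "undefined"; next }
    vb <- before$balanced[i, j]; va <- after$balanced[i, j]
    if (is.na(vb) || is.na(va)) { flag[k] <- "undefined"; next }
    pb <- vb / before$total; pa <- va / after$total
    if (pb <= 0) { flag[k] <- "undefined"; next }
    ratio[k] <- pa / pb
  }
  list(loops = cbind(ab, ratio = ratio, flag = flag),
       mean_ratio = mean(ratio[flag == "ok"]))
}

#' Aggregate peak analysis (APA)
#'
#' Element-wise mean of `(2*half_window+1)`-square O/E submatrices centered
#' on each loop pixel, optionally split by a grouping attribute (each group
#' aggregated and divided by its own loop count). Loops whose window leaves
#' the matrix or crosses the diagonal are dropped. The center enrichment is
#' the center value divided by the mean of the `half_window x half_window`
#' lower-left corner block (rows below, columns left of center), the
#' conventional APA background.
#'
#' @param b a [kr_balance()] result (conventionally at 5 kb resolution).
#' @param loops a `LoopSet`.
#' @param half_window half side of the aggregation window in bins.
#' @param group_by optional name of a loop attribute column (e.g. a
#'   subcompartment label) to aggregate per group.
#' @return an `APAResult` (list with `matrix`, `n_loops`,
#'   `center_enrichment`), or a named list of them when grouping.
#' @export
apa <- function(b, loops, half_window = 10, group_by = NULL) {
  stopifnot(inherits(b, "BalancedView"))
  oe <- observed_over_expected(b)
  n <- nrow(oe)
  h <- as.integer(half_window)
  ab <- .anchor_bins(loops, b$binning$resolution)
  usable <- ab$bin1 - h >= 0 & ab$bin2 + h <= n - 1L &
            (ab$bin2 - ab$bin1) > 2L * h
  if (!any(usable)) stop("no usable loops after edge/diagonal filtering")
  one_group <- function(rows) {
    acc <- matrix(0, 2L * h + 1L, 2L * h + 1L)
    cnt <- matrix(0, 2L * h + 1L, 2L * h + 1L)
    for (k in rows) {
      i <- ab$bin1[k] + 1L; j <- ab$bin2[k] + 1L
      sub <- oe[(i - h):(i + h), (j - h):(j + h)]
      ok <- !is.na(sub)
      acc[ok] <- acc[ok] + sub[ok]
      cnt <- cnt + ok
    }
    agg <- acc / cnt
    agg[cnt == 0] <- NA_real_
    center <- agg[h + 1L, h + 1L]
    corner <- agg[(h + 2L):(2L * h + 1L), 1:h]
    structure(list(matrix = agg, n_loops = length(rows),
                   center_enrichment = center / mean(corner, na.rm = TRUE)),
              class = "APAResult")
  }
  rows <- which(usable)
  if (is.null(group_by)) return(one_group(rows))
  g <- as.data.frame(loops)[[group_by]][usable]
  lapply(split(rows, g), one_group)
}

#' @export
print.APAResult <- function(x, ...) {
  cat("APAResult:", x$n_loops, "loops,", nrow(x$matrix), "x", ncol(x$matrix),
      "window, center enrichment", round(x$center_enrichment, 3), "\n")
  invisible(x)
}

#' Differential loops between two conditions
#'
#' A before-loop is `kept` if some after-loop on the same chromosome pair
#' overlaps it on *both* anchors (order-preserving: anchor1 with anchor1,
#' anchor2 with anchor2) after expanding every anchor by `slop` bp on each
#' side; otherwise it is `lost`. After-loops matching no before-loop are
#' `gained`.
#'
#' @param before,after `LoopSet` objects.
#' @param slop anchor expansion in bp (default 10 kb, guarding against
#'   small anchor shifts between independent loop calls).
#' @return list with logical `kept` per before-loop, index vectors `lost`
#'   and `gained`, and `lost_fraction`.
#' @export
differential_loops <- function(before, after, slop = 1e4) {
  bf <- as.data.frame(before); af <- as.data.frame(after)
  kept <- vapply(seq_len(nrow(bf)), function(k) {
    cand <- af$chrom1 == bf$chrom1[k] & af$chrom2 == bf$chrom2[k] &
      .overlaps(bf$start1[k] - slop, bf$end1[k] + slop,
                af$start1 - slop, af$end1 + slop) &
      .overlaps(bf$start2[k] - slop, bf$end2[k] + slop,
                af$start2 - slop, af$end2 + slop)
    any(cand)
  }, logical(1))
  matched_after <- vapply(seq_len(nrow(af)), function(k) {
    any(bf$chrom1 == af$chrom1[k] & bf$chrom2 == af$chrom2[k] &
        .overlaps(af$start1[k] - slop, af$end1[k] + slop,
                  bf$start1 - slop, bf$end1 + slop) &
        .overlaps(af$start2[k] - slop, af$end2[k] + slop,
                  bf$start2 - slop, bf$end2 + slop))
  }, logical(1))
  list(kept = kept, lost = which(!kept), gained = which(!matched_after),
       lost_fraction = if (nrow(bf)) mean(!kept) else NA_real_)
}

#' Aggregate stripe signal
#'
#' A stripe is a line of enriched contacts emanating from one anchor (a
#' loop-extrusion intermediate). For a left-anchored stripe at bin `a` the
#' profile is O/E at pixels `(a, a+k)`, k = 1..extent; for a right-anchored
#' stripe, `(a-k, a)`. Profiles are averaged over stripes; the background is
#' the same profile read `bg_offset` bins off the stripe on either side
#' (perpendicular to the stripe direction), and the stripe-to-background
#' ratio summarizes enrichment. Stripes running past the matrix edge are
#' truncated; fully off-matrix stripes are dropped.
#'
#' @param b a [kr_balance()] result.
#' @param stripes data frame with columns `chrom`, `start`, `end` (anchor
#'   interval) and `orientation` (`"left"` or `"right"`).
#' @param extent stripe length in bins.
#' @param bg_offset perpendicular background offset in bins.
#' @return list with `profile`, `background` (mean vectors over k),
#'   `ratio` (mean profile / mean background), `n_stripes`.
#' @export
stripe_aggregate <- function(b, stripes, extent = 20, bg_offset = 5) {
  stopifnot(inherits(b, "BalancedView"))
  if (extent < 1) stop("extent must be at least 1 bin")
  oe <- observed_over_expected(b)
  n <- nrow(oe)
  res <- b$binning$resolution
  stripes <- as.data.frame(stripes)
  abin <- (floor((stripes$start + stripes$end) / 2) %/% res) + 1L
  prof <- bg <- matrix(NA_real_, nrow(stripes), extent)
  used <- 0L
  for (s in seq_len(nrow(stripes))) {
    a <- abin[s]
    if (a < 1L || a > n) next
    left <- identical(stripes$orientation[s], "left")
    ks <- seq_len(extent)
    i <- if (left) rep(a, extent) else a - ks
    j <- if (left) a + ks else rep(a, extent)
    ok <- i >= 1L & j <= n & i <= j
    if (!any(ok)) next
    used <- used + 1L
    prof[s, ok] <- oe[cbind(i[ok], j[ok])]
    # perpendicular offsets: shift the anchor-side index off the stripe
    for (off in c(-bg_offset, bg_offset)) {
      i2 <- if (left) i + off else i
      j2 <- if (left) j else j + off
      ok2 <- ok & i2 >= 1L & j2 <= n & i2 < j2
      bgv <- rep(NA_real_, extent)
      bgv[ok2] <- oe[cbind(i2[ok2], j2[ok2])]
      bg[s, ] <- if (off == -bg_offset) bgv
                 else rowMeans(cbind(bg[s, ], bgv), na.rm = TRUE)
    }
  }
  if (used == 0L) stop("no stripe lies on the matrix")
  profile <- colMeans(prof, na.rm = TRUE)
  background <- colMeans(bg, na.rm = TRUE)
  list(profile = profile, background = background,
       ratio = mean(profile, na.rm = TRUE) / mean(background, na.rm = TRUE),
       n_stripes = used)
}

#' Classify loops by stripe-anchor overlap
#'
#' Counts how many of a loop's two anchors overlap any stripe-anchor
#' interval (plain interval overlap, no slop): 2 -> `"both"`, 1 -> `"one"`,
#' 0 -> `"none"`.
#'
#' @param loops a `LoopSet`.
#' @param stripe_anchors an `IntervalSet` of stripe anchors.
#' @return character vector per loop.
#' @export
classify_loops_by_stripe <- function(loops, stripe_anchors) {
  lp <- as.data.frame(loops); sa <- as.data.frame(stripe_anchors)
  hit <- function(chrom, s, e)
    any(sa$chrom == chrom & .overlaps(s, e, sa$start, sa$end))
  vapply(seq_len(nrow(lp)), function(k) {
    cnt <- hit(lp$chrom1[k], lp$start1[k], lp$end1[k]) +
           hit(lp$chrom2[k], lp$start2[k], lp$end2[k])
    c("none", "one", "both")[cnt + 1L]
  }, character(1))
}
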