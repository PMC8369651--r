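#' Insulation score profile
#'
#' Slides a `window x window` square along the matrix diagonal: the raw
#' insulation score of bin i is the mean balanced contact value between the
#' `w` bins to its left and the `w` bins to its right (`w = window /
#' resolution`). Bins within `w` of a chromosome edge, or whose square
#' touches a masked bin, are missing. The normalized score is
#' `log2(raw / chromosome mean raw)`; local minima of this track mark TAD
#' boundaries.
#'
#' @param b a [kr_balance()] result (conventionally at 40 kb resolution).
#' @param window square side in bp (default 1 Mb); must be a multiple of
#'   the resolution and at least 2 bins.
#' @return list of class `InsulationProfile` with `score`
#'   ([bin_track()] of normalized scores), `raw` and `window_bins`.
#' @export
insulation_profile <- function(b, window = 1e6) {
  stopifnot(inherits(b, "BalancedView"))
  res <- b$binning$resolution
  if (window %% res != 0) stop("window must be a multiple of the resolution")
  w <- as.integer(window %/% res)
  if (w < 2L) stop("window must span at least 2 bins")
  bal <- b$balanced
  n <- nrow(bal)
  if (n < 3L * w) stop("chromosome shorter than 3 windows")
  raw <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w)) {
    block <- bal[(i - w):(i - 1L), (i + 1L):(i + w)]
    raw[i] <- mean(block)              # any masked bin -> NA
  }
  m <- mean(raw, na.rm = TRUE)
  norm <- ifelse(!is.na(raw) & raw > 0, log2(raw / m), NA_real_)
  structure(list(score = bin_track(b$binning, b$chrom, norm),
                 raw = bin_track(b$binning, b$chrom, raw),
                 window_bins = w),
            class = "InsulationProfile")
}

#' Call TAD boundaries from an insulation profile
#'
#' Builds the delta vector `delta(i) = mean(IS[i+1 .. i+d]) -
#' mean(IS[i-d .. i-1])` (`d = delta_window / resolution`); a boundary
#' candidate sits at each negative-to-positive zero crossing of delta,
#' i.e. at a local insulation minimum. Its strength is the delta amplitude
#' around the crossing, `max(delta over [i, i+d]) - min(delta over
#' [i-d, i])`; weak candidates (strength below `min_strength`) are
#' discarded.
#'
#' @param ins an [insulation_profile()].
#' @param delta_window averaging window for the delta vector in bp
#'   (default 200 kb).
#' @param min_strength minimum boundary strength (default 0.1).
#' @return data frame with columns `bin` (0-based), `strength`, `delta_at`
#'   (delta value at the crossing), sorted by bin.
#' @export
call_boundaries <- function(ins, delta_window = 2e5, min_strength = 0.1) {
  stopifnot(inherits(ins, "InsulationProfile"))
  res <- ins$score$binning$resolution
  if (delta_window %% res != 0)
    stop("delta_window must be a multiple of the resolution")
  d <- as.integer(delta_window %/% res)
  if (d < 1L) stop("delta_window must span at least 1 bin")
  is_v <- ins$score$values
  n <- length(is_v)
  delta <- rep(NA_real_, n)
  for (i in (d + 1L):(n - d)) {
    left <- is_v[(i - d):(i - 1L)]
    right <- is_v[(i + 1L):(i + d)]
    if (anyNA(left) || anyNA(right)) next
    delta[i] <- mean(right) - mean(left)
  }
  cand <- integer()
  for (i in seq_len(n - 1L)) {
    if (is.na(delta[i]) || is.na(delta[i + 1L])) next
    if (delta[i] <= 0 && delta[i + 1L] > 0) {
      # boundary at the insulation minimum of the two crossing bins
      pick <- if (!is.na(is_v[i + 1L]) && !is.na(is_v[i]) &&
                  is_v[i + 1L] < is_v[i]) i + 1L else i
      cand <- c(cand, pick)
    }
  }
  if (!length(cand))
    return(data.frame(bin = integer(), strength = numeric(),
                      delta_at = numeric()))
  strength <- vapply(cand, function(i) {
    up <- delta[i:min(n, i + d)]
    dn <- delta[max(1L, i - d):i]
    max(up, na.rm = TRUE) - min(dn, na.rm = TRUE)
  }, numeric(1))
  keep <- strength >= min_strength
  out <- data.frame(bin = cand[keep] - 1L, strength = strength[keep],
                    delta_at = delta[cand[keep]])
  out[order(out$bin), , drop = FALSE]
}

#' Match TAD boundaries between two conditions
#'
#' Greedy closest-pair matching: boundary centers within `slop` bp of each
#' other are paired (closest distances first, ties to the leftmost pair),
#' each boundary at most once. Matched pairs are `stable`; unmatched
#' before-boundaries are `lost`, unmatched after-boundaries `gained`.
#'
#' @param before,after boundary data frames from [call_boundaries()] (or
#'   any data frame with a `bin` column), on the same binning.
#' @param resolution bin size in bp.
#' @param slop maximum center distance in bp for a match (default 80 kb,
#'   i.e. 2 bins at 40 kb).
#' @return list with `stable` (data frame `bin_before`, `bin_after`),
#'   `lost`, `gained` (0-based bin vectors), `lost_fraction`,
#'   `gained_fraction`.
#' @export
match_boundaries <- function(before, after, resolution, slop = 8e4) {
  bb <- sort(unique(as.data.frame(before)$bin))
  ab <- sort(unique(as.data.frame(after)$bin))
  cb <- (bb + 0.5) * resolution
  ca <- (ab + 0.5) * resolution
  pairs <- expand.grid(i = seq_along(bb), j = seq_along(ab))
  if (nrow(pairs)) {
    pairs$dist <- abs(cb[pairs$i] - ca[pairs$j])
    pairs <- pairs[pairs$dist <= slop, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$i, pairs$j), , drop = FALSE]
  }
  used_b <- logical(length(bb)); used_a <- logical(length(ab))
  stable <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_b[i] || used_a[j]) next
    used_b[i] <- used_a[j] <- TRUE
    stable[[length(stable) + 1L]] <- data.frame(bin_before = bb[i],
                                                bin_after = ab[j])
  }
  stable <- if (length(stable)) do.call(rbind, stable)
            else data.frame(bin_before = integer(), bin_after = integer())
  list(stable = stable,
       lost = bb[!used_b], gained = ab[!used_a],
       lost_fraction = if (length(bb)) sum(!used_b) / length(bb) else NA_real_,
       gained_fraction = if (length(ab)) sum(!used_a) / length(ab) else NA_real_)
}

#' Intra-/inter-TAD interaction change by subcompartment
#'
#' Assigns each TAD a subcompartment by majority base-pair overlap, groups
#' subcompartments (by default A1 alone, A2 with B1, and B2 with B3,
#' reflecting their similar chromatin character), and reports per group the
#' after/before ratio of summed depth-normalized contact probability over
#' (a) within-TAD pixels and (b) pixels joining two *different* TADs of the
#' *same* group, capped at `max_sep` bp separation. Pixels joining TADs of
#' different groups are skipped.
#'
#' @param before,after [kr_balance()] results on the same binning.
#' @param tads an `IntervalSet` of non-overlapping TADs on the chromosome.
#' @param subcomp an `IntervalSet` of subcompartment annotations
#'   (`name` in A1/A2/B1/B2/B3).
#' @param groups named list mapping group label -> subcompartment labels.
#' @param max_sep maximum pixel separation in bp for inter-TAD sums.
#' @return data frame with columns `group`, `intra_ratio`, `inter_ratio`,
#'   `n_tads`.
#' @export
tad_interaction_change <- function(before, after, tads, subcomp,
                                   groups = list(A1 = "A1",
                                                 `A2/B1` = c("A2", "B1"),
                                                 `B2/B3` = c("B2", "B3")),
                                   max_sep = 1e7) {
  stopifnot(inherits(before, "BalancedView"), inherits(after, "BalancedView"))
  n <- nrow(before$balanced)
  if (nrow(after$balanced) != n) stop("matrices must share a binning")
  res <- before$binning$resolution
  tads <- as.data.frame(tads)
  subcomp <- as.data.frame(subcomp)
  # majority-overlap subcompartment per TAD
  tad_label <- vapply(seq_len(nrow(tads)), function(k) {
    s <- tads$start[k]; e <- tads$end[k]
    sc <- subcomp[subcomp$chrom == tads$chrom[k] &
                  subcomp$start < e & subcomp$end > s, , drop = FALSE]
    if (nrow(sc) == 0L) return(NA_character_)
    ov <- pmin(sc$end, e) - pmax(sc$start, s)
    agg <- rowsum(ov, sc$name)
    rownames(agg)[which.max(agg[, 1])]
  }, character(1))
  # per-bin TAD id (bins fully inside a TAD)
  tad_of_bin <- rep(NA_integer_, n)
  for (k in seq_len(nrow(tads))) {
    b0 <- tads$start[k] %/% res
    b1 <- (tads$end[k] - 1L) %/% res
    b0 <- max(0L, b0); b1 <- min(n - 1L, b1)
    if (b0 <= b1) tad_of_bin[(b0:b1) + 1L] <- k
  }
  sep_ok <- abs(row(before$balanced) - col(before$balanced)) * res <= max_sep
  ut <- upper.tri(before$balanced, diag = TRUE)
  out <- lapply(names(groups), function(g) {
    gt <- which(tad_label %in% groups[[g]])
    if (!length(gt))
      return(data.frame(group = g, intra_ratio = NA_real_,
                        inter_ratio = NA_real_, n_tads = 0L))
    inb <- !is.na(tad_of_bin) & tad_of_bin %in% gt
    tid <- ifelse(inb, tad_of_bin, NA_integer_)
    both <- outer(inb, inb)
    same_tad <- outer(tid, tid, "==")
    same_tad[is.na(same_tad)] <- FALSE
    intra_sel <- both & same_tad & ut
    inter_sel <- both & !same_tad & ut & sep_ok
    ratio_over <- function(sel) {
      pb <- sum(before$balanced[sel], na.rm = TRUE) / before$total
      pa <- sum(after$balanced[sel], na.rm = TRUE) / after$total
      if (pb > 0) pa / pb else NA_real_
    }
    data.frame(group = g, intra_ratio = ratio_over(intra_sel),
               inter_ratio = ratio_over(inter_sel), n_tads = length(gt))
  })
  resdf <- do.call(rbind, out)
  rownames(resdf) <- NULL
  resdf
}
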