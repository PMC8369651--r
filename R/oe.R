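#' Observed-over-expected transform
#'
#' Divides each balanced contact value by the expected value at its genomic
#' distance, where the expectation is the per-chromosome mean balanced value
#' over all unmasked pixels at that bin distance (no smoothing). Removes the
#' polymer distance decay so compartment and loop structure become visible.
#'
#' @param b a [kr_balance()] result.
#' @return dense O/E matrix (`NA` at masked bins and at distances whose
#'   expected value is zero), with the per-distance expected values attached
#'   as attribute `expected`.
#' @export
observed_over_expected <- function(b) {
  stopifnot(inherits(b, "BalancedView"))
  bal <- b$balanced
  n <- nrow(bal)
  expected <- numeric(n)
  for (s in 0:(n - 1L)) {
    idx <- cbind(1:(n - s), (1 + s):n)
    expected[s + 1L] <- mean(bal[idx], na.rm = TRUE)
  }
  expected[is.nan(expected)] <- NA_real_
  d <- abs(row(bal) - col(bal)) + 1L
  ex <- matrix(expected[d], n, n)
  oe <- bal / ex
  oe[!is.na(ex) & ex == 0] <- NA_real_
  attr(oe, "expected") <- expected
  oe
}

#' Pearson correlation matrix of O/E rows
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the O/E
#' matrix (missing entries pairwise-excluded). Bins whose O/E row is
#' constant get undefined correlations. The long-range similarity structure
#' captured here is what the compartment eigenvector decomposes.
#'
#' @param oe an [observed_over_expected()] matrix.
#' @return symmetric correlation matrix with unit diagonal where defined.
#' @export
pearson_matrix <- function(oe) {
  p <- suppressWarnings(stats::cor(t(oe), use = "pairwise.complete.obs"))
  defined <- !apply(oe, 1L, function(r) all(is.na(r)))
  diag(p)[defined] <- 1
  p
}

#' Contact probability versus genomic distance
#'
#' Mean balanced contact value per genomic distance, optionally stratified
#' by compartment label (pairs with both bins in A, or both in B). Distances
#' are pooled in logarithmic bins (successive edges differ by the factor
#' `log_ratio`) and each stratum's curve is normalized so that the
#' pair-count-weighted sum of probabilities is 1.
#'
#' @param b a [kr_balance()] result.
#' @param labels optional per-bin character labels (`"A"`/`"B"`, `NA`
#'   allowed), aligned with the bins.
#' @param log_ratio ratio between successive distance-bin edges.
#' @return data frame with columns `stratum` (`all`, `AA`, `BB`),
#'   `dist_bp` (geometric midpoint), `prob`, `n_pairs`.
#' @export
contact_probability_curve <- function(b, labels = NULL, log_ratio = 1.15) {
  stopifnot(inherits(b, "BalancedView"))
  bal <- b$balanced
  n <- nrow(bal)
  res <- b$binning$resolution
  if (!is.null(labels) && length(labels) != n)
    stop("labels must align with the bins")
  strata <- list(all = rep(TRUE, n))
  if (!is.null(labels)) {
    strata$AA <- !is.na(labels) & labels == "A"
    strata$BB <- !is.na(labels) & labels == "B"
  }
  out <- list()
  for (nm in names(strata)) {
    inset <- strata[[nm]]
    sums <- counts <- numeric(n - 1L)
    for (s in 1:(n - 1L)) {
      i <- 1:(n - s); j <- (1 + s):n
      sel <- inset[i] & inset[j]
      if (!any(sel)) next
      v <- bal[cbind(i[sel], j[sel])]
      sums[s] <- sum(v, na.rm = TRUE)
      counts[s] <- sum(!is.na(v))
    }
    if (all(counts == 0)) next
    edges <- res * log_ratio^(0:ceiling(log((n * res) / res, log_ratio)))
    bin_of <- findInterval((1:(n - 1L)) * res, edges)
    agg_s <- rowsum(sums, bin_of)
    agg_c <- rowsum(counts, bin_of)
    keep <- agg_c[, 1] > 0
    mids <- vapply(as.integer(rownames(agg_s)), function(k)
      sqrt(edges[k] * edges[min(k + 1L, length(edges))]), numeric(1))
    prob <- agg_s[keep, 1] / agg_c[keep, 1]
    npairs <- agg_c[keep, 1]
    z <- sum(prob * npairs)
    if (z > 0) prob <- prob / z
    out[[nm]] <- data.frame(stratum = nm, dist_bp = mids[keep],
                            prob = prob, n_pairs = npairs)
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Assign bins to interval states by majority overlap
#'
#' Each bin gets the state label covering the largest share of it; ties are
#' broken by the order in which states first appear in the interval set.
#' Bins with no overlap stay unassigned (`NA`).
#'
#' @param binning a [genome_binning()].
#' @param chrom chromosome name.
#' @param states an `IntervalSet` with a `name` column holding state labels.
#' @return character vector of per-bin labels.
#' @export
assign_bins_to_states <- function(binning, chrom, states) {
  nb <- n_bins(binning, chrom)
  res <- binning$resolution
  states <- as.data.frame(states)
  states <- states[states$chrom == chrom, , drop = FALSE]
  labs <- unique(states$name)          # file order defines tie-break priority
  cover <- matrix(0, nb, length(labs), dimnames = list(NULL, labs))
  for (k in seq_len(nrow(states))) {
    s <- states$start[k]; e <- states$end[k]
    lab <- states$name[k]
    b0 <- max(0L, s %/% res); b1 <- min(nb - 1L, (e - 1L) %/% res)
    if (b0 > b1) next
    for (bb in b0:b1) {
      ov <- min(e, (bb + 1) * res) - max(s, bb * res)
      cover[bb + 1L, lab] <- cover[bb + 1L, lab] + ov
    }
  }
  apply(cover, 1L, function(r) {
    if (all(r == 0)) NA_character_ else labs[which.max(r)]
  })
}

#' Per-state interaction change between two conditions
#'
#' For each chromatin state, sums the depth-normalized contact probability
#' (balanced value divided by the matrix's total balanced sum) over pixels
#' whose two bins are both assigned to that state, and reports the
#' after/before ratio. A ratio below 1 means that state's internal contacts
#' were depleted by the treatment.
#'
#' @param before,after [kr_balance()] results on the same binning.
#' @param states an `IntervalSet` of state annotations (`name` = state).
#' @return data frame with columns `state`, `ratio`, `n_bins`, `n_pixels`;
#'   states covering no bins get `NA` ratios.
#' @export
region_state_interaction_change <- function(before, after, states) {
  stopifnot(inherits(before, "BalancedView"), inherits(after, "BalancedView"))
  if (nrow(before$balanced) != nrow(after$balanced))
    stop("matrices must share a binning")
  lab <- assign_bins_to_states(before$binning, before$chrom, states)
  all_states <- unique(as.data.frame(states)$name)
  ut <- upper.tri(before$balanced, diag = TRUE)
  out <- lapply(all_states, function(st) {
    inb <- !is.na(lab) & lab == st
    if (!any(inb))
      return(data.frame(state = st, ratio = NA_real_, n_bins = 0L,
                        n_pixels = 0L))
    sel <- outer(inb, inb) & ut
    pb <- sum(before$balanced[sel], na.rm = TRUE) / before$total
    pa <- sum(after$balanced[sel], na.rm = TRUE) / after$total
    data.frame(state = st, ratio = if (pb > 0) pa / pb else NA_real_,
               n_bins = sum(inb), n_pixels = sum(sel))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
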