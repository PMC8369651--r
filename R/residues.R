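#' Correlate residue composition with AICAP
#'
#' For proteins with AICAP below 1 (the chromatin-retained, potentially
#' condensate-forming range), computes the fraction of each of the 20
#' standard amino acids within four region classes of each protein -- the
#' whole sequence, the whole sequence minus intrinsically disordered regions
#' (IDRs), the IDRs themselves, and prion-like domains (PLDs) -- and the
#' Spearman rank correlation (average ranks for ties) of each fraction with
#' AICAP. A negative correlation for a residue means proteins richer in that
#' residue are more 1,6-HD sensitive.
#'
#' Region coordinates are 0-based half-open positions within the protein
#' sequence. Proteins lacking a region class (e.g. no annotated IDR) are
#' excluded from that class only; residues absent from every protein give an
#' undefined (NA) correlation.
#'
#' @param aicap named numeric vector of AICAP values.
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   protein sequences.
#' @param regions data frame with columns `protein`, `start`, `end`, `type`
#'   (`"IDR"` or `"PLD"`).
#' @return data frame with columns `residue`, `region` (one of `whole`,
#'   `no_idr`, `idr`, `pld`), `rho`, `n` (proteins used).
#' @export
residue_composition_correlation <- function(aicap, sequences, regions) {
  if (inherits(sequences, "AAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  regions <- as.data.frame(regions)
  keep <- names(aicap)[!is.na(aicap) & aicap < 1]
  keep <- intersect(keep, names(sequences))
  if (length(keep) == 0L) stop("no proteins with AICAP < 1 and a sequence")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  classes <- c("whole", "no_idr", "idr", "pld")

  # per protein, per class: residue count vector (or NULL if class empty)
  comp <- lapply(keep, function(p) {
    s <- strsplit(toupper(sequences[[p]]), "")[[1]]
    len <- length(s)
    mask_of <- function(type) {
      m <- rep(FALSE, len)
      r <- regions[regions$protein == p & regions$type == type, , drop = FALSE]
      for (k in seq_len(nrow(r))) {
        lo <- max(r$start[k] + 1L, 1L); hi <- min(r$end[k], len)
        if (lo <= hi) m[lo:hi] <- TRUE
      }
      m
    }
    idr <- mask_of("IDR"); pld <- mask_of("PLD")
    masks <- list(whole = rep(TRUE, len), no_idr = !idr, idr = idr, pld = pld)
    lapply(masks, function(m) {
      if (!any(m)) return(NULL)
      counts <- table(factor(s[m], levels = aa))
      as.numeric(counts) / sum(m)
    })
  })
  names(comp) <- keep

  out <- expand.grid(residue = aa, region = classes,
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    cls <- out$region[r]
    ri <- match(out$residue[r], aa)
    frac <- vapply(keep, function(p) {
      v <- comp[[p]][[cls]]
      if (is.null(v)) NA_real_ else v[ri]
    }, numeric(1))
    ok <- !is.na(frac)
    out$n[r] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(frac[ok]) > 0)
      out$rho[r] <- suppressWarnings(
        stats::cor(frac[ok], aicap[keep][ok], method = "spearman"))
  }
  out
}
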