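#' Convert iBAQ abundances to fraction of total (FOT)
#'
#' FOT expresses each protein's abundance as its share of the summed iBAQ of
#' all proteins quantified in the same sample, scaled by 1e6 for
#' readability. Missing values stay missing and do not contribute to the
#' sample total, so each sample's present FOTs sum to exactly 1e6.
#'
#' @param qt a [quant_table()] of kind `iBAQ`.
#' @return a `QuantTable` of kind `FOT`.
#' @export
ibaq_to_fot <- function(qt) {
  stopifnot(inherits(qt, "QuantTable"))
  if (qt$kind != "iBAQ") stop("expected a table of kind iBAQ, got ", qt$kind)
  totals <- colSums(qt$values, na.rm = TRUE)
  bad <- which(totals <= 0 | colSums(!is.na(qt$values)) == 0L)
  if (length(bad))
    stop("sample(s) with no positive values: ",
         paste(colnames(qt$values)[bad], collapse = ", "))
  out <- sweep(qt$values, 2L, totals, "/") * 1e6
  quant_table(out, qt$condition, qt$batch, kind = "FOT")
}

#' Impute missing abundances with the per-sample minimum
#'
#' Left-censored imputation: each missing cell is replaced by the minimum
#' present value of its own sample column, reflecting that values below a
#' sample-specific detection floor are the ones that go unobserved.
#'
#' @param qt a `QuantTable` (any kind) with at least one present value per
#'   sample.
#' @return the table with no missing entries.
#' @export
impute_missing <- function(qt) {
  stopifnot(inherits(qt, "QuantTable"))
  v <- qt$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (all(miss)) stop("sample ", colnames(v)[j], " has no present values")
    if (any(miss)) v[miss, j] <- min(v[!miss, j])
  }
  out <- qt
  out$values <- v
  out
}

#' Quantile-normalize a complete quantification table
#'
#' Forces every sample column onto a common distribution: rank r in each
#' column receives the mean of the columns' r-th order statistics, with tied
#' values receiving the average of the target values across their tied
#' ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param qt a `QuantTable` of kind `FOT` with no missing entries (impute
#'   first).
#' @return a `QuantTable` of kind `FOT_normalized`.
#' @export
quantile_normalize <- function(qt) {
  stopifnot(inherits(qt, "QuantTable"))
  if (anyNA(qt$values))
    stop("missing entries present; run impute_missing() first")
  v <- limma::normalizeQuantiles(qt$values, ties = TRUE)
  dimnames(v) <- dimnames(qt$values)
  quant_table(v, qt$condition, qt$batch, kind = "FOT_normalized")
}

#' Compute AICAP values and significance per protein
#'
#' The anti-1,6-hexanediol index of chromatin-associated proteins (AICAP)
#' is the ratio of a protein's mean normalized abundance in 1,6-HD-treated
#' samples over its mean in untreated (digested) control samples. Values
#' below 1 indicate depletion from chromatin after condensate disruption;
#' the lower the value, the more 1,6-HD-sensitive the association.
#' Significance is a two-sided Welch two-sample t-test on the normalized
#' values.
#'
#' @param qt a `QuantTable` of kind `FOT_normalized`.
#' @param control condition label of the untreated control samples.
#' @param treated condition label of the 1,6-HD-treated samples.
#' @return data frame with columns `protein`, `aicap`, `p_value`,
#'   `mean_control`, `mean_treated`, `n_control`, `n_treated`, `group`,
#'   `flag` (`"ok"` or `"undefined"` when the control mean is zero; undefined
#'   proteins carry `NA` AICAP and are excluded from rankings).
#' @export
compute_aicap <- function(qt, control = "control", treated = "treated") {
  stopifnot(inherits(qt, "QuantTable"))
  if (qt$kind != "FOT_normalized")
    stop("expected a quantile-normalized table (kind FOT_normalized)")
  ci <- which(qt$condition == control)
  ti <- which(qt$condition == treated)
  if (length(ci) < 2L || length(ti) < 2L)
    stop("need at least 2 replicates per condition (control: ", length(ci),
         ", treated: ", length(ti), ")")
  v <- qt$values
  mc <- rowMeans(v[, ci, drop = FALSE])
  mt <- rowMeans(v[, ti, drop = FALSE])
  p <- vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ci]; y <- v[i, ti]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(y, x, var.equal = FALSE)$p.value
  }, numeric(1))
  aicap <- ifelse(mc > 0, mt / mc, NA_real_)
  flag <- ifelse(mc > 0, "ok", "undefined")
  data.frame(protein = rownames(v), aicap = aicap, p_value = p,
             mean_control = mc, mean_treated = mt,
             n_control = length(ci), n_treated = length(ti),
             group = ifelse(is.na(aicap), NA_character_,
                            assign_aicap_group(pmax(aicap, 0))),
             flag = flag, row.names = NULL)
}

#' Assign AICAP values to sensitivity groups
#'
#' Six left-closed bins: `[0,0.3) [0.3,0.5) [0.5,0.7) [0.7,0.9) [0.9,1.1)
#' [1.1,Inf)`. The lowest bin collects the most 1,6-HD-sensitive proteins
#' (e.g. MED1 at AICAP 0.072); values around 1 indicate insensitivity
#' (histones) and above 1.1 mostly cytoplasmic contaminants.
#'
#' @param aicap numeric vector of non-negative AICAP values.
#' @return character vector of group labels.
#' @export
assign_aicap_group <- function(aicap) {
  if (any(is.na(aicap))) stop("aicap values must be defined")
  if (any(aicap < 0)) stop("aicap values must be non-negative")
  labs <- c("0-0.3", "0.3-0.5", "0.5-0.7", "0.7-0.9", "0.9-1.1", "1.1+")
  as.character(cut(aicap, c(0, 0.3, 0.5, 0.7, 0.9, 1.1, Inf),
                   labels = labs, right = FALSE))
}

#' Run the full proteomics pipeline from iBAQ to AICAP
#'
#' Convenience composition: iBAQ -> FOT -> minimum imputation -> quantile
#' normalization -> AICAP + Welch test.
#'
#' @inheritParams compute_aicap
#' @param qt a `QuantTable` of kind `iBAQ`.
#' @return see [compute_aicap()].
#' @export
aicap_pipeline <- function(qt, control = "control", treated = "treated") {
  compute_aicap(quantile_normalize(impute_missing(ibaq_to_fot(qt))),
                control = control, treated = treated)
}
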