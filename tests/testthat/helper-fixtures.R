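# shared fixture builders

# quant table straight from a matrix, first half control / second treated
qt_from_matrix <- function(m, kind = "iBAQ") {
  nrep <- ncol(m) / 2
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- c(paste0("c", seq_len(nrep)), paste0("t", seq_len(nrep)))
  quant_table(m, condition = rep(c("control", "treated"), each = nrep),
              kind = kind)
}

# contact matrix from a dense symmetric count matrix
cm_from_dense <- function(m, resolution = 1e5, chrom = "chrT") {
  n <- nrow(m)
  gb <- genome_binning(stats::setNames(n * resolution, chrom), resolution)
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_matrix(chrom, gb,
                 data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                            count = m[ut]))
}

# hand-constructed balanced view (identity weights), for direct-construction
# oracles that must bypass the balancing step
bview_from_dense <- function(m, resolution = 1e5, chrom = "chrT") {
  n <- nrow(m)
  gb <- genome_binning(stats::setNames(n * resolution, chrom), resolution)
  structure(list(chrom = chrom, binning = gb, balanced = m,
                 weights = rep(1, n), mask = rep(FALSE, n),
                 total = sum(m[upper.tri(m, diag = TRUE)])),
            class = "BalancedView")
}

# full compartment call from a raw contact matrix and a truth sign vector
compartments_of <- function(cm, comp_signs, min_nnz = 5) {
  b <- kr_balance(cm, min_nnz = min_nnz)
  p <- pearson_matrix(observed_over_expected(b))
  ref <- bin_track(cm$binning, cm$chrom, ifelse(comp_signs > 0, 5, 1))
  call_compartments(p, ref)
}

# BEDPE loop set covering given 0-based pixel bins at a resolution
loops_at_bins <- function(bin1, bin2, resolution, chrom = "chrS") {
  loop_set(data.frame(chrom1 = chrom, start1 = bin1 * resolution,
                      end1 = (bin1 + 1) * resolution,
                      chrom2 = chrom, start2 = bin2 * resolution,
                      end2 = (bin2 + 1) * resolution))
}
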