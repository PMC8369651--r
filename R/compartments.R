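#' Call A/B compartments from a Pearson matrix
#'
#' Takes the leading eigenvector (PC1) of the Pearson correlation matrix
#' over defined bins, orients it so that it correlates positively with a
#' per-bin activity reference (gene density or equivalent), and labels bins
#' A where PC1 > 0 and B where PC1 < 0. The eigenvector is returned at unit
#' norm.
#'
#' @param pearson a [pearson_matrix()].
#' @param reference a [bin_track()] of an activity proxy on the same binning
#'   (gene density; A compartments are gene-dense).
#' @return list of class `CompartmentProfile` with `pc1` ([bin_track()]) and
#'   `labels` (per-bin `"A"`/`"B"`/`NA`).
#' @export
call_compartments <- function(pearson, reference) {
  stopifnot(inherits(reference, "BinTrack"))
  n <- nrow(pearson)
  if (length(reference$values) != n)
    stop("reference track does not align with the matrix bins")
  ok <- !apply(pearson, 1L, function(r) all(is.na(r)))
  # drop bins that still have undefined entries against other kept bins
  sub <- pearson[ok, ok, drop = FALSE]
  if (anyNA(sub)) {
    drop_more <- apply(sub, 1L, anyNA)
    ok[ok] <- !drop_more
    sub <- pearson[ok, ok, drop = FALSE]
  }
  if (sum(ok) < 3L) stop("fewer than 3 usable bins for eigendecomposition")
  eig <- eigen(sub, symmetric = TRUE)
  v <- eig$vectors[, 1]
  refv <- reference$values[ok]
  rc <- suppressWarnings(stats::cor(v, refv, use = "complete.obs"))
  if (!is.na(rc) && rc < 0) v <- -v
  pc1 <- rep(NA_real_, n)
  pc1[ok] <- v
  labels <- rep(NA_character_, n)
  labels[ok] <- ifelse(v > 0, "A", ifelse(v < 0, "B", NA_character_))
  structure(list(pc1 = bin_track(reference$binning, reference$chrom, pc1),
                 labels = labels,
                 eigenvalue = max(eig$values[1], 0)),
            class = "CompartmentProfile")
}

#' @export
print.CompartmentProfile <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c("A", "B")))
  cat("CompartmentProfile:", length(x$labels), "bins; A =", tb[["A"]],
      ", B =", tb[["B"]], "\n")
  invisible(x)
}

#' Classify per-bin compartment changes between conditions
#'
#' Eigenvectors are defined only up to scale, so each profile's unit-norm
#' PC1 is first multiplied by the square root of its leading eigenvalue
#' (the principal-component score scale, which carries the strength of the
#' compartment signal and is comparable across libraries); profiles built
#' by hand without an eigenvalue are used as given. Then, per bin:
#' opposite signs -> `flipped`; otherwise the PC1 ratio r = after/before
#' is `stable` when within +/- `threshold` of 1 (boundaries inclusive),
#' `strengthened` when r > 1 + threshold, and `weakened` when
#' r < 1 - threshold. Bins undefined (missing or zero PC1) in either
#' condition are `undefined` and excluded from the reported fractions,
#' which are also given separately for bins that were A or B before
#' treatment.
#'
#' @param before,after `CompartmentProfile` objects on the same binning.
#' @param threshold relative-change threshold (default 0.2, i.e. +/- 20%).
#' @return list of class `CompartmentChange` with `table` (per-bin data
#'   frame: `bin`, `pc1_before`, `pc1_after`, `ratio`, `change_type`,
#'   `label_before`) and `fractions` (data frame of change-type fractions
#'   for all/A/B bins).
#' @export
classify_compartment_change <- function(before, after, threshold = 0.2) {
  if (threshold <= 0) stop("threshold must be positive")
  pb <- before$pc1$values
  pa <- after$pc1$values
  if (length(pb) != length(pa)) stop("profiles must share a binning")
  shared <- !is.na(pb) & !is.na(pa)
  if (!any(shared)) stop("no shared defined bins")
  if (!is.null(before$eigenvalue)) pb <- pb * sqrt(before$eigenvalue)
  if (!is.null(after$eigenvalue)) pa <- pa * sqrt(after$eigenvalue)
  n <- length(pb)
  ratio <- rep(NA_real_, n)
  type <- rep("undefined", n)
  defined <- shared & pb != 0 & pa != 0
  flip <- defined & sign(pb) != sign(pa)
  type[flip] <- "flipped"
  same <- defined & !flip
  r <- pa[same] / pb[same]
  ratio[same] <- r
  type[same] <- ifelse(r > 1 + threshold, "strengthened",
                       ifelse(r < 1 - threshold, "weakened", "stable"))
  lvls <- c("strengthened", "stable", "weakened", "flipped")
  lab_before <- ifelse(defined, ifelse(pb > 0, "A", "B"), NA_character_)
  frac_of <- function(sel) {
    tb <- table(factor(type[sel], levels = lvls))
    if (sum(tb) == 0) rep(NA_real_, length(lvls)) else as.numeric(tb / sum(tb))
  }
  fractions <- data.frame(
    change_type = lvls,
    all = frac_of(defined),
    A = frac_of(defined & lab_before == "A"),
    B = frac_of(defined & lab_before == "B"))
  structure(list(table = data.frame(bin = 0:(n - 1L), pc1_before = pb,
                                    pc1_after = pa, ratio = ratio,
                                    change_type = type,
                                    label_before = lab_before),
                 fractions = fractions),
            class = "CompartmentChange")
}

#' Neighbor-context of compartment segments by change type
#'
#' Merges consecutive bins sharing an A/B label into segments, assigns each
#' segment its dominant (majority) change type, and records whether its two
#' flanking segments carry the same A/B label as itself (`same`), a
#' different one (`different`), or whether the segment touches a chromosome
#' edge (`edge`). In practice alternating-label profiles make every interior
#' neighbor `different`; this summarizes whether weakened compartments tend
#' to sit in discordant neighborhoods.
#'
#' @param change a [classify_compartment_change()] result.
#' @param labels per-bin A/B labels used for segmentation (e.g. the
#'   before-treatment labels); defaults to the change table's
#'   `label_before`.
#' @return contingency table (change type x neighbor context) plus the
#'   per-segment data frame, as a list.
#' @export
neighbor_context <- function(change, labels = NULL) {
  stopifnot(inherits(change, "CompartmentChange"))
  tab <- change$table
  if (is.null(labels)) labels <- tab$label_before
  n <- length(labels)
  keep <- !is.na(labels)
  # segment runs of identical labels (NA bins break runs)
  rid <- cumsum(c(TRUE, labels[-1] != labels[-n] |
                        is.na(labels[-1]) != is.na(labels[-n])))
  segs <- lapply(split(seq_len(n), rid), function(ix) {
    if (is.na(labels[ix[1]])) return(NULL)
    types <- tab$change_type[ix]
    types <- types[types != "undefined"]
    dom <- if (length(types)) names(sort(table(types), decreasing = TRUE))[1]
           else "undefined"
    data.frame(first = ix[1], last = ix[length(ix)],
               label = labels[ix[1]], dominant = dom)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) stop("no labeled segments")
  rownames(segs) <- NULL
  ctx <- vapply(seq_len(nrow(segs)), function(k) {
    if (k == 1L || k == nrow(segs)) return("edge")
    same_l <- segs$label[k - 1L] == segs$label[k]
    same_r <- segs$label[k + 1L] == segs$label[k]
    if (same_l && same_r) "same"
    else if (!same_l && !same_r) "different"
    else "mixed"
  }, character(1))
  segs$context <- ctx
  counts <- table(change_type = segs$dominant, context = segs$context)
  list(counts = counts, segments = segs)
}
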