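#' Simulate a label-free quantification experiment with planted depletion
#'
#' Generates an iBAQ-kind [quant_table()] for control and 1,6-HD-treated
#' samples. Each protein has a log-normal true abundance; treated values are
#' multiplied by a per-protein depletion factor `d` (the planted sensitivity
#' index: d < 1 means the protein is stripped from chromatin by the
#' treatment). Multiplicative log-normal replicate noise with the given
#' coefficient of variation is applied per cell, and cells go missing with
#' probability `sigmoid((mu - log value) / s)` -- an abundance-dependent
#' (left-censoring) mechanism, since low-abundance proteins drop below the
#' detection limit. The midpoint `mu` is calibrated by root finding so the
#' expected overall missing rate equals `missing_rate`.
#'
#' By default the 20% most abundant proteins are insensitive (`d = 1`,
#' histone-like structural bulk) and the rest draw `d` from a log-normal
#' centred at 1 (log-sd `depletion_sdlog`, clipped to \[0.02, 3\]):
#' condensate proteins lose chromatin association (d < 1) while cytoplasmic
#' background proteins gain relative abundance (d > 1), as in the observed
#' AICAP distribution.
#'
#' @param n_proteins number of proteins.
#' @param n_replicates replicates per condition (>= 2).
#' @param depletion optional explicit per-protein depletion factors.
#' @param prop_insensitive fraction of proteins with `d = 1` when
#'   `depletion` is not given (assigned to the most abundant proteins,
#'   emulating the histone-dominated insensitive bulk of chromatin mass).
#' @param depletion_sdlog log-sd of the log-symmetric planted response
#'   factors of the remaining proteins.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#'   (defaults give an iBAQ dynamic range of several orders of magnitude).
#' @param noise_cv replicate coefficient of variation.
#' @param missing_rate target overall fraction of missing cells (0
#'   disables missingness).
#' @param missing_scale logistic scale `s` of the censoring curve on the
#'   log-abundance axis.
#' @param seed RNG seed.
#' @return list with `table` (a `QuantTable`, kind iBAQ) and `truth` (list
#'   with `abundance`, `depletion`, `missing_mu`, parameters and seed).
#' @export
simulate_quant_experiment <- function(n_proteins = 500, n_replicates = 3,
                                      depletion = NULL,
                                      prop_insensitive = 0.2,
                                      depletion_sdlog = 0.9,
                                      abundance_meanlog = log(1e6),
                                      abundance_sdlog = 2,
                                      noise_cv = 0.2,
                                      missing_rate = 0.2,
                                      missing_scale = 0.5,
                                      seed = 1) {
  if (n_proteins <= 0 || n_replicates < 2)
    stop("need n_proteins > 0 and n_replicates >= 2")
  set.seed(seed)
  abundance <- stats::rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
  if (is.null(depletion)) {
    # planted response factors are log-symmetric around 1: condensate
    # proteins are depleted (d < 1, down to MED1-like few-percent retention)
    # while cytoplasmic background proteins gain relative abundance (d > 1),
    # spanning the roughly two-decade range of observed AICAP values. The
    # exactly-insensitive block (d = 1) is assigned to the most abundant
    # proteins: chromatin mass is dominated by 1,6-HD-insensitive
    # structural proteins such as histones, which both matches the biology
    # and keeps the sample composition approximately conserved
    depletion <- pmin(pmax(stats::rlnorm(n_proteins, 0, depletion_sdlog),
                           0.02), 3)
    ins <- order(abundance, decreasing = TRUE)[
      seq_len(round(prop_insensitive * n_proteins))]
    depletion[ins] <- 1
  } else if (length(depletion) != n_proteins || any(depletion <= 0)) {
    stop("depletion must be positive and one per protein")
  }
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  nsamp <- 2L * n_replicates
  noise <- if (sdlog_noise > 0)
    matrix(stats::rlnorm(n_proteins * nsamp, -sdlog_noise^2 / 2, sdlog_noise),
           n_proteins, nsamp)
  else matrix(1, n_proteins, nsamp)
  expected <- cbind(matrix(abundance, n_proteins, n_replicates),
                    matrix(abundance * depletion, n_proteins, n_replicates))
  values <- expected * noise
  if (missing_rate > 0) {
    lv <- log(values)
    mu <- stats::uniroot(function(m) mean(stats::plogis((m - lv) /
                                                        missing_scale)) -
                           missing_rate,
                         range(lv) + c(-10, 10) * missing_scale)$root
    pm <- stats::plogis((mu - lv) / missing_scale)
    values[stats::runif(length(values)) < pm] <- NA_real_
    # a sample must keep at least one value; extremely unlikely to trigger
    for (j in seq_len(nsamp))
      if (all(is.na(values[, j]))) values[which.max(pm[, j]), j] <- expected[which.max(pm[, j]), j]
  } else {
    mu <- -Inf
  }
  dimnames(values) <- list(sprintf("P%04d", seq_len(n_proteins)),
                           c(sprintf("control_%d", seq_len(n_replicates)),
                             sprintf("treated_%d", seq_len(n_replicates))))
  qt <- quant_table(values,
                    condition = rep(c("control", "treated"),
                                    each = n_replicates),
                    batch = rep(seq_len(n_replicates), 2L),
                    kind = "iBAQ")
  list(table = qt,
       truth = list(abundance = abundance, depletion = depletion,
                    missing_mu = mu, noise_cv = noise_cv,
                    missing_rate = missing_rate, seed = seed))
}

#' Ground truth for a paired Hi-C simulation
#'
#' Lays out the structural truth of one synthetic chromosome: alternating
#' A/B compartment blocks (checkerboard sign vector), a TAD partition, loop
#' pixels at TAD-corner-like positions, stripe anchors, per-bin biases and
#' a power-law distance decay. "Before" and "after" share the layout; the
#' treatment effect enters through per-bin compartment strengths
#' (`delta_after` defaults to halving A-bin strength, matching the
#' preferential weakening of active compartments by 1,6-HD), depleted loop
#' factors and optionally changed boundaries or stripe factors.
#'
#' @param n_bins number of bins (>= 100 recommended for compartment work).
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param block_range min/max compartment block length in bins.
#' @param delta compartment strength before treatment (0 <= delta < 1).
#' @param delta_after_factor_A,delta_after_factor_B multipliers on the
#'   per-bin strength after treatment for A and B bins.
#' @param tad_range min/max TAD length in bins.
#' @param boundaries optional explicit 0-based TAD boundary bins (overrides
#'   the random partition).
#' @param tad_factor,tad_factor_after within-TAD contact enrichment.
#' @param n_loops number of planted loops.
#' @param loop_factor,loop_factor_after loop pixel enrichment (>= 1); the
#'   default after-value 4 corresponds to a 60% drop in loop contact
#'   probability.
#' @param loop_sigma Gaussian spill of the loop enrichment in bins.
#' @param n_stripes number of stripes; @param stripe_extent stripe length
#'   in bins; @param stripe_factor,stripe_factor_after stripe enrichment.
#' @param alpha distance-decay exponent of `(s+1)^(-alpha)`.
#' @param bias_sdlog log-sd of per-bin multiplicative biases.
#' @param depth expected total raw count per matrix (upper triangle).
#' @param seed RNG seed for the structural layout.
#' @return list of class `HiCTruth`.
#' @export
hic_truth <- function(n_bins = 200, resolution = 1e5, chrom = "chrS",
                      block_range = c(5, 15), delta = 0.3,
                      delta_after_factor_A = 0.5,
                      delta_after_factor_B = 1,
                      tad_range = c(10, 25), boundaries = NULL,
                      tad_factor = 2, tad_factor_after = tad_factor,
                      n_loops = 10, loop_factor = 10, loop_factor_after = 4,
                      loop_sigma = 0.5,
                      n_stripes = 2, stripe_extent = 15,
                      stripe_factor = 3, stripe_factor_after = stripe_factor,
                      alpha = 1, bias_sdlog = 0.2,
                      depth = 1e6, seed = 1) {
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  if (loop_factor < 1 || loop_factor_after < 1)
    stop("loop enrichment factors must be >= 1")
  set.seed(seed)
  # compartment blocks
  comp <- integer(0); sgn <- 1L
  while (length(comp) < n_bins) {
    len <- sample(block_range[1]:block_range[2], 1L)
    comp <- c(comp, rep(sgn, len)); sgn <- -sgn
  }
  comp <- comp[seq_len(n_bins)]
  delta_bin <- rep(delta, n_bins)
  delta_bin_after <- delta_bin *
    ifelse(comp > 0, delta_after_factor_A, delta_after_factor_B)
  # TAD partition: boundaries are 0-based first bins of each new TAD
  if (is.null(boundaries)) {
    bounds <- integer(0); pos <- 0L
    repeat {
      len <- sample(tad_range[1]:tad_range[2], 1L)
      pos <- pos + len
      if (pos >= n_bins) break
      bounds <- c(bounds, pos)
    }
  } else {
    bounds <- sort(as.integer(boundaries))
    if (length(bounds) && (min(bounds) < 1L || max(bounds) >= n_bins))
      stop("boundaries must lie strictly inside the chromosome")
  }
  # loops: pick random TAD corner-ish pixels at medium distance
  loops <- NULL
  if (n_loops > 0) {
    if (n_bins < 70) stop("need >= 70 bins to place loops (or n_loops = 0)")
    # keep loops >= 12 bins from the edges and > 21 bins off the diagonal
    # so they survive aggregate-peak-analysis windowing at half_window 10
    span <- sample(25:40, n_loops, replace = TRUE)
    i0 <- sample(12:(n_bins - 55L), n_loops)
    loops <- data.frame(bin1 = i0, bin2 = i0 + span,
                        factor_before = loop_factor,
                        factor_after = loop_factor_after)
  }
  stripes <- NULL
  if (n_stripes > 0) {
    anchors <- sample.int(n_bins - stripe_extent - 1L, n_stripes)
    stripes <- data.frame(anchor = anchors - 1L,
                          orientation = sample(c("left", "right"), n_stripes,
                                               replace = TRUE),
                          extent = stripe_extent,
                          factor_before = stripe_factor,
                          factor_after = stripe_factor_after)
    # right stripes need room below the anchor
    flip <- stripes$orientation == "right" & stripes$anchor < stripe_extent
    stripes$orientation[flip] <- "left"
  }
  bias <- if (bias_sdlog > 0) stats::rlnorm(n_bins, 0, bias_sdlog)
          else rep(1, n_bins)
  structure(list(n_bins = n_bins, resolution = resolution, chrom = chrom,
                 comp = comp, delta_bin = delta_bin,
                 delta_bin_after = delta_bin_after,
                 boundaries = bounds, boundaries_after = bounds,
                 tad_factor = tad_factor, tad_factor_after = tad_factor_after,
                 loops = loops, loop_sigma = loop_sigma, stripes = stripes,
                 alpha = alpha, bias = bias, depth = depth, seed = seed),
            class = "HiCTruth")
}

# expected-count matrix for one condition of a HiCTruth
.hic_lambda <- function(truth, condition = c("before", "after")) {
  condition <- match.arg(condition)
  n <- truth$n_bins
  after <- condition == "after"
  db <- if (after) truth$delta_bin_after else truth$delta_bin
  tf <- if (after) truth$tad_factor_after else truth$tad_factor
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (s + 1)^(-truth$alpha)
  lam <- lam * (1 + outer(truth$comp * sqrt(db), truth$comp * sqrt(db)))
  bounds <- if (after) truth$boundaries_after else truth$boundaries
  tad_id <- findInterval(seq_len(n) - 1L, bounds)
  lam <- lam * ifelse(outer(tad_id, tad_id, "=="), tf, 1)
  if (!is.null(truth$loops)) {
    fac <- if (after) truth$loops$factor_after else truth$loops$factor_before
    ri <- row(lam); ci <- col(lam)
    for (k in seq_len(nrow(truth$loops))) {
      i0 <- truth$loops$bin1[k] + 1L; j0 <- truth$loops$bin2[k] + 1L
      d2 <- (ri - i0)^2 + (ci - j0)^2
      d2t <- (ri - j0)^2 + (ci - i0)^2   # mirror pixel
      spill <- exp(-pmin(d2, d2t) / (2 * truth$loop_sigma^2))
      lam <- lam * (1 + (fac[k] - 1) * spill)
    }
  }
  if (!is.null(truth$stripes)) {
    fac <- if (after) truth$stripes$factor_after
           else truth$stripes$factor_before
    S <- matrix(1, n, n)
    for (k in seq_len(nrow(truth$stripes))) {
      a <- truth$stripes$anchor[k] + 1L
      ext <- truth$stripes$extent[k]
      if (truth$stripes$orientation[k] == "left") {
        cols <- (a + 1L):min(n, a + ext)
        S[a, cols] <- pmax(S[a, cols], fac[k])
        S[cols, a] <- S[a, cols]
      } else {
        rows <- max(1L, a - ext):(a - 1L)
        S[rows, a] <- pmax(S[rows, a], fac[k])
        S[a, rows] <- S[rows, a]
      }
    }
    lam <- lam * S
  }
  lam <- lam * outer(truth$bias, truth$bias)
  scale <- truth$depth / sum(lam[upper.tri(lam, diag = TRUE)])
  lam * scale
}

#' Simulate a paired before/after Hi-C contact-matrix experiment
#'
#' Draws Poisson counts for every upper-triangle pixel from the expected
#' model `lambda_ij = depth_scale * b_i b_j * (|i-j|+1)^(-alpha) * (1 +
#' c_i c_j sqrt(delta_i delta_j)) * T_ij * L_ij * S_ij`, where T is the
#' within-TAD enrichment, L the loop enrichment (with Gaussian spill so
#' aggregate peak analysis sees a peak rather than a single pixel) and S
#' the stripe enrichment. Both conditions are drawn from the same random
#' substream, so identical truths produce identical matrices (a paired
#' design); the "after" matrix differs only through the perturbed truth
#' parameters.
#'
#' @param truth a [hic_truth()].
#' @param seed RNG seed for the count draws.
#' @return list with `before`, `after` ([contact_matrix()] objects) and
#'   `truth`.
#' @export
simulate_hic_pair <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "HiCTruth"))
  gb <- genome_binning(stats::setNames(truth$n_bins * truth$resolution,
                                       truth$chrom),
                       truth$resolution)
  draw <- function(condition) {
    lam <- .hic_lambda(truth, condition)
    n <- nrow(lam)
    ut <- which(upper.tri(lam, diag = TRUE), arr.ind = TRUE)
    set.seed(seed)
    counts <- stats::rpois(nrow(ut), lam[ut])
    keep <- counts > 0
    contact_matrix(truth$chrom, gb,
                   data.frame(bin1 = ut[keep, 1] - 1L,
                              bin2 = ut[keep, 2] - 1L,
                              count = counts[keep]))
  }
  list(before = draw("before"), after = draw("after"), truth = truth)
}

#' Simulate a FRAP trace from the exponential recovery model
#'
#' Post-bleach intensity follows `A * (1 - exp(-t / tau)) + y0` plus
#' Gaussian noise; three pre-bleach frames at intensity 1.0 are prepended
#' (at 1 s spacing before t = 0). The control channel is constant 1 and the
#' background 0, so [normalize_trace()] reproduces the model values
#' exactly in the noiseless case.
#'
#' @param A mobile-population amplitude (>= 0).
#' @param tau recovery time constant in seconds (> 0).
#' @param y0 intensity at the first post-bleach frame.
#' @param times post-bleach time points (non-negative, increasing).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return a [frap_trace()].
#' @export
simulate_frap_trace <- function(A, tau, y0, times = 0:100, noise_sd = 0,
                                seed = 1) {
  if (tau <= 0) stop("tau must be positive")
  if (A < 0) stop("A must be non-negative")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and increasing")
  set.seed(seed)
  model <- A * (1 - exp(-times / tau)) + y0
  noisy <- model + stats::rnorm(length(times), 0, noise_sd)
  pre_t <- min(times) - (3:1)
  frap_trace(times = c(pre_t, times),
             bleached = c(rep(1, 3), noisy),
             control = rep(1, length(times) + 3L),
             background = rep(0, length(times) + 3L),
             n_prebleach = 3)
}
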