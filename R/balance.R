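#' Knight-Ruiz matrix balancing
#'
#' Computes per-bin weights `w` so that the balanced matrix
#' `B_ij = w_i * raw_ij * w_j` has equal row sums (target 1) over unmasked
#' bins, removing multiplicative per-bin biases (coverage, mappability,
#' restriction-site density). Bins with fewer than `min_nnz` nonzero pixels
#' are masked before balancing, as is standard for low-coverage Hi-C bins.
#' Uses the Knight-Ruiz inner-outer Newton iteration; if it fails to reach
#' `tol`, falls back to a damped symmetric Sinkhorn fixed-point iteration.
#'
#' @param cm a [contact_matrix()].
#' @param tol maximum allowed absolute deviation of balanced row sums from 1.
#' @param max_iter iteration cap (shared by KR and the Sinkhorn fallback).
#' @param min_nnz minimum nonzero pixels for a bin to stay unmasked.
#' @return an object of class `BalancedView`: list with `chrom`, `binning`,
#'   `balanced` (dense matrix, `NA` rows/cols at masked bins), `weights`
#'   (`NA` at masked bins), `mask` (TRUE = excluded) and `total` (sum of
#'   balanced values over the upper triangle including the diagonal).
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000, min_nnz = 10) {
  stopifnot(inherits(cm, "ContactMatrix"))
  raw <- as_dense(cm)
  nb <- nrow(raw)
  nnz <- rowSums(raw > 0)
  mask <- nnz < min_nnz | rowSums(raw) == 0
  if (all(mask)) stop("all bins masked on ", cm$chrom)
  A <- raw[!mask, !mask, drop = FALSE]
  x <- .kr_weights(A, tol, max_iter)
  if (is.null(x)) x <- .sinkhorn_weights(A, tol, max_iter)
  if (is.null(x))
    stop("matrix balancing did not converge on ", cm$chrom)
  w <- rep(NA_real_, nb)
  w[!mask] <- x
  bal <- matrix(NA_real_, nb, nb)
  bal[!mask, !mask] <- A * outer(x, x)
  ut <- upper.tri(bal, diag = TRUE)
  structure(list(chrom = cm$chrom, binning = cm$binning, balanced = bal,
                 weights = w, mask = mask,
                 total = sum(bal[ut], na.rm = TRUE)),
            class = "BalancedView")
}

#' @export
print.BalancedView <- function(x, ...) {
  cat("BalancedView:", x$chrom, "(", nrow(x$balanced), "bins,",
      sum(x$mask), "masked )\n")
  invisible(x)
}

# Knight-Ruiz algorithm (inner conjugate-gradient, outer Newton) for
# symmetric nonnegative A; returns weights or NULL on failure.
.kr_weights <- function(A, tol, max_iter) {
  n <- nrow(A)
  if (n == 1L) return(if (A[1, 1] > 0) 1 / sqrt(A[1, 1]) else NULL)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 50) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    if (mvp > max_iter) return(NULL)
    if (!is.finite(rout)) return(NULL)
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
  }
  dev <- max(abs(x * as.vector(A %*% x) - 1))
  if (!is.finite(dev) || dev > tol) return(NULL)
  x
}

# damped symmetric Sinkhorn: fixed point of x = x / sqrt(x * (A x))
.sinkhorn_weights <- function(A, tol, max_iter) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(A %*% x)
    if (any(r <= 0) || any(!is.finite(r))) return(NULL)
    dev <- max(abs(r - 1))
    if (dev <= tol) return(x)
    x <- x / sqrt(r)
  }
  NULL
}
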