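#' Blocking analysis of a weighted series
#'
#' Flyvbjerg-Petersen-style standard-error estimate for correlated,
#' weighted time series.  For each block size b the frames are partitioned
#' into contiguous blocks; each block contributes its weighted mean with the
#' block weight sum as its mass, and the standard error of the overall
#' weighted mean is estimated from the weighted spread of block means:
#' SE^2 = sum_k p_k (m_k - M)^2 / (K - 1) with p_k the normalized block
#' masses (this reduces to sd(block means)/sqrt(K) for uniform weights).
#' For correlated data the SE rises with block size and plateaus at the
#' autocorrelation-corrected value once blocks exceed the correlation time.
#'
#' @param series numeric vector, one value per frame.
#' @param weights frame weights (default uniform), normalized internally.
#' @param blockSizes integer block sizes in frames (default: powers of 2 up
#'   to n/4).  Sizes above n/2 are skipped with a warning.
#' @return list of class \code{"blockingCurve"} with \code{blockSizes},
#'   \code{se}, \code{nBlocks}.
#' @export
blockingError <- function(series, weights = NULL, blockSizes = NULL) {
  n <- length(series)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("series and weights must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)
  if (is.null(blockSizes))
    blockSizes <- 2^(0:floor(log2(n / 4)))
  blockSizes <- sort(unique(as.integer(blockSizes)))
  drop <- blockSizes > n / 2
  if (any(drop)) {
    warning(sprintf("skipping block sizes > n/2: %s",
                    paste(blockSizes[drop], collapse = ", ")))
    blockSizes <- blockSizes[!drop]
  }
  se <- nb <- numeric(length(blockSizes))
  for (s in seq_along(blockSizes)) {
    b <- blockSizes[s]
    K <- n %/% b
    use <- seq_len(K * b)
    grp <- rep(seq_len(K), each = b)
    W <- tapply(weights[use], grp, sum)
    m <- tapply(weights[use] * series[use], grp, sum) / W
    p <- W / sum(W)
    M <- sum(p * m)
    se[s] <- sqrt(sum(p * (m - M)^2) / (K - 1))
    nb[s] <- K
  }
  structure(list(blockSizes = blockSizes, se = se, nBlocks = nb),
            class = "blockingCurve")
}

#' Free-energy surface with block standard errors
#'
#' Weighted histogram of a CV series converted to a free energy
#' F = -ln p (in kB T units, shifted so the minimum is 0), with per-bin
#' standard errors from the block-to-block spread of the bin probabilities:
#' the series is split into \code{nBlocks} contiguous blocks, the weighted
#' bin probability is computed per block, SE_p is the weighted standard
#' error over blocks, and SE_F = SE_p / p.  Bins that are empty in any
#' block get an NA standard error (not zero); bins empty overall get
#' infinite free energy.
#'
#' @param series CV values, one per frame.
#' @param weights frame weights (default uniform).
#' @param breaks histogram breaks covering the data range, or a bin count.
#' @param nBlocks number of contiguous blocks (>= 2, default 4).
#' @return list with \code{binCenters}, \code{freeEnergy} (kB T, min 0),
#'   \code{se}, \code{probability}.
#' @export
fesError <- function(series, weights = NULL, breaks = 30, nBlocks = 4) {
  n <- length(series)
  if (nBlocks < 2) stop("need at least 2 blocks")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  if (length(breaks) == 1)
    breaks <- seq(min(series), max(series), length.out = breaks + 1)
  if (min(series) < breaks[1] || max(series) > breaks[length(breaks)])
    stop("breaks must cover the data range")
  nbin <- length(breaks) - 1
  bin <- findInterval(series, breaks, rightmost.closed = TRUE)
  grp <- pmin(ceiling(seq_len(n) / (n / nBlocks)), nBlocks)
  pBlock <- matrix(0, nBlocks, nbin)
  for (k in seq_len(nBlocks)) {
    inK <- grp == k
    wk <- weights[inK] / sum(weights[inK])
    pBlock[k, ] <- vapply(seq_len(nbin),
                          function(j) sum(wk[bin[inK] == j]), numeric(1))
  }
  p <- vapply(seq_len(nbin), function(j) sum(weights[bin == j]), numeric(1))
  seP <- apply(pBlock, 2, stats::sd) / sqrt(nBlocks)
  seF <- ifelse(apply(pBlock > 0, 2, all) & p > 0, seP / p, NA_real_)
  fe <- -log(p)
  fe <- fe - min(fe[is.finite(fe)])
  list(binCenters = (breaks[-1] + breaks[-length(breaks)]) / 2,
       freeEnergy = fe, se = seF, probability = p)
}

#' Plateau detection on a blocking curve
#'
#' The curve is converged when the relative change of the SE across the
#' last three block sizes stays below \code{tolerance} (default 0.10); the
#' plateau SE is the mean of those three values.
#'
#' @param curve a \code{"blockingCurve"} from \code{\link{blockingError}}.
#' @param tolerance relative slope tolerance.
#' @return list with \code{converged} (logical) and \code{plateauSE}.
#' @export
plateauDetect <- function(curve, tolerance = 0.10) {
  se <- curve$se
  if (length(se) < 4) stop("need at least 4 block sizes")
  tail3 <- se[(length(se) - 2):length(se)]
  if (all(tail3 == 0))
    return(list(converged = TRUE, plateauSE = 0))
  rel <- abs(diff(tail3)) / pmax(abs(tail3[-3]), .Machine$double.eps)
  list(converged = all(rel < tolerance), plateauSE = mean(tail3))
}
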