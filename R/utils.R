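## Internal helpers shared across modules.

#' Otsu threshold of an intensity sample
#'
#' Global automatic threshold maximizing between-class variance on a 256-bin
#' histogram; returns a value strictly between the two classes.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return the threshold (same units as \code{x}).
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(rng[1], rng[2], length.out = nbins + 1L),
    rightmost.closed = TRUE), 1L), nbins), nbins)
  w <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nbins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  mids[k] + (mids[2] - mids[1]) / 2
}

## Clip-limited global histogram equalization. Unlimited rank equalization on
## a background-dominated volume flattens the histogram and defeats the
## downstream automatic threshold, so the histogram is clipped at
## clipLimit x the uniform bin count and the excess redistributed before the
## cumulative mapping (global analogue of the CLAHE clip step).
equalizeClipped <- function(x, clipLimit = 4, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(x)
  bin <- pmin(pmax(findInterval(
    x, seq(rng[1], rng[2], length.out = nbins + 1L),
    rightmost.closed = TRUE), 1L), nbins)
  h <- tabulate(bin, nbins)
  cap <- clipLimit * length(x) / nbins
  excess <- sum(pmax(h - cap, 0))
  h <- pmin(h, cap) + excess / nbins
  cdf <- cumsum(h) / sum(h)
  cdf0 <- cdf[min(bin)]
  map <- (cdf - cdf0) / (1 - cdf0 + (cdf0 == 1))
  y <- map[bin]
  dim(y) <- dim(x)
  y * diff(rng) + rng[1]
}

## Running maximum then centred 3-point median (ends passed through):
## removes transient undercounts while keeping the curve monotone.
cleanCounts <- function(counts) {
  rm_ <- cummax(counts)
  n <- length(rm_)
  if (n < 3L) return(rm_)
  med <- rm_
  med[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    sort(rm_[(i - 1):(i + 1)])[2], numeric(1))
  med
}

## Minimum-cost one-to-one matching between two point sets (rows = points,
## 3 columns). Returns a two-column matrix of (row index in a, row index in b)
## for min(na, nb) matched pairs; extra points on the larger side are
## unmatched. Rectangular problems are solved by padding to a square with a
## large constant.
matchPoints <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(integer(), ncol = 2))
  d <- outer(seq_len(na), seq_len(nb), function(i, j) {
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2 + (a[i, 3] - b[j, 3])^2)
  })
  n <- max(na, nb)
  pad <- max(d) * n + 1
  cost <- matrix(pad, n, n)
  cost[seq_len(na), seq_len(nb)] <- d
  asg <- cpp_lap(cost)
  pairs <- cbind(seq_len(na), asg[seq_len(na)])
  pairs[pairs[, 2] <= nb, , drop = FALSE]
}

## Standard column order of a nucleus-observation table.
obsColumns <- c("embryo_id", "frame", "time_h", "x", "y", "z", "volume")

## Validate / normalize an observation table.
asObservations <- function(df) {
  need <- c("embryo_id", "frame", "time_h", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"volume" %in% names(df)) df$volume <- NA_real_
  df[order(df$embryo_id, df$frame), obsColumns]
}

## Deterministic 32-bit polynomial rolling hash of a character scalar
## (hex string); stamps reports with a config fingerprint.
configHash <- function(s) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
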