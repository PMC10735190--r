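#' @title Empirical mode decomposition by sifting
#' @name emd-core
#' @description
#' From-scratch empirical mode decomposition (EMD) of a single channel into
#' intrinsic mode functions (IMFs). A candidate mode is refined by *sifting*:
#' upper and lower envelopes are interpolated through the local maxima and
#' minima with natural cubic splines, their mean is subtracted, and the
#' process repeats until the normalized squared change between successive
#' iterates (the SD criterion) falls below `q`, with `0.2 <= q <= 0.3` the
#' conventional range. Each accepted IMF is subtracted from the running
#' residual and the next mode is sifted from what remains.
NULL

# Strict local extrema with plateau handling: a run of equal values that is
# higher (lower) than both neighbouring runs contributes one maximum
# (minimum) at the plateau centre. Endpoints are never extrema.
#' Locate local maxima and minima of a sampled signal
#'
#' @param x Numeric vector, length >= 3.
#' @return List with integer index vectors `maxima` and `minima` (possibly
#'   empty, e.g. for a monotone ramp).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) stop("signal too short for extrema detection (need >= 3 samples)",
                   call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  # compress runs of equal values; keep run start index and length
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-k]))
  centers <- starts + (r$lengths - 1L) %/% 2L
  v <- r$values
  mid <- 2:(k - 1L)
  is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  is_min <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  list(maxima = centers[mid][is_max], minima = centers[mid][is_min])
}

#' Sifting stop statistic (SD criterion)
#'
#' Normalized squared change between two successive sifting iterates,
#' `sum((s2 - s1)^2) / sum(s1^2)` (global normalization over all samples).
#' Sifting stops once this falls below the threshold `q`.
#'
#' @param s1 Previous sifting iterate.
#' @param s2 Current sifting iterate (`s1` minus the envelope mean).
#' @return Dimensionless non-negative scalar.
#' @export
sd_criterion <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("s1 and s2 must have equal length", call. = FALSE)
  denom <- sum(s1^2)
  if (denom == 0) stop("degenerate input: s1 is identically zero", call. = FALSE)
  sum((s2 - s1)^2) / denom
}

# Natural cubic spline envelope through the given extrema, with mirror
# extension of up to two extrema beyond each end to suppress edge swings.
.envelope <- function(x, idx, n) {
  xi <- as.numeric(idx)
  yi <- x[idx]
  m <- length(xi)
  take <- seq_len(min(2L, m - 1L)) + 1L          # extrema to mirror, nearest first
  lx <- 2 * xi[1] - xi[take];  ly <- yi[take]
  rt <- m - seq_len(min(2L, m - 1L))
  rx <- 2 * xi[m] - xi[rt];    ry <- yi[rt]
  xs <- c(rev(lx), xi, rx)
  ys <- c(rev(ly), yi, ry)
  stats::spline(xs, ys, xout = seq_len(n), method = "natural")$y
}

.too_few_extrema <- function(ext) {
  length(ext$maxima) < 2L || length(ext$minima) < 2L
}

#' Sift one intrinsic mode function out of a signal
#'
#' Repeatedly subtracts the mean of the cubic-spline upper/lower envelopes
#' until the SD criterion drops below `q` or `max_iter` is reached.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @param q SD-criterion threshold (conventional range 0.2--0.3).
#' @param max_iter Safety cap on sifting iterations.
#' @return List with `imf` (numeric vector) and `iterations` (count).
#' @export
sift <- function(x, q = 0.25, max_iter = 100L) {
  n <- length(x)
  ext <- find_extrema(x)
  if (.too_few_extrema(ext)) {
    stop(errorCondition("signal is not siftable: fewer than 2 maxima or 2 minima",
                        class = c("cogload_not_siftable", "error")))
  }
  s1 <- x
  for (it in seq_len(max_iter)) {
    upper <- .envelope(s1, ext$maxima, n)
    lower <- .envelope(s1, ext$minima, n)
    s2 <- s1 - (upper + lower) / 2
    crit <- sd_criterion(s1, s2)
    ext2 <- find_extrema(s2)
    if (crit < q || .too_few_extrema(ext2)) {
      return(list(imf = s2, iterations = it))
    }
    s1 <- s2
    ext <- ext2
  }
  list(imf = s1, iterations = max_iter)
}

#' Decompose a signal into intrinsic mode functions
#'
#' Extracts up to `n_modes` IMFs by repeated sifting, subtracting each
#' accepted mode from the running residual. Extraction stops early when the
#' residual is monotone or has too few extrema to be sifted. By
#' construction the modes and residual sum exactly back to the input.
#'
#' @param x Numeric vector (one EEG channel), length >= 8.
#' @param n_modes Maximum number of modes to extract (default 6: the first
#'   five carry features downstream and the sixth serves as the
#'   adjacent-band partner of the fifth).
#' @param q SD-criterion threshold.
#' @param max_iter Sifting iteration cap per mode.
#' @return Object of class `imf_set`: list with `imfs` (matrix, one row per
#'   mode), `residual`, and `sift_counts`.
#' @examples
#' t <- seq(0, 2, length.out = 600)
#' x <- sin(2 * pi * 20 * t) + sin(2 * pi * 3 * t)
#' d <- emd_decompose(x)
#' max(abs(colSums(d$imfs) + d$residual - x))  # reconstruction identity
#' @export
emd_decompose <- function(x, n_modes = 6L, q = 0.25, max_iter = 100L) {
  if (length(x) < 8L) stop("signal too short (need >= 8 samples)", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  n <- length(x)
  imfs <- matrix(numeric(0), nrow = 0L, ncol = n)
  counts <- integer(0)
  residual <- x
  for (k in seq_len(n_modes)) {
    ext <- find_extrema(residual)
    if (.too_few_extrema(ext)) break
    s <- sift(residual, q = q, max_iter = max_iter)
    imfs <- rbind(imfs, s$imf)
    counts <- c(counts, s$iterations)
    residual <- residual - s$imf
  }
  structure(list(imfs = imfs, residual = residual, sift_counts = counts),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", nrow(x$imfs), " mode(s) of length ", ncol(x$imfs),
      "; sift counts: ", paste(x$sift_counts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count zero crossings of a signal
#'
#' Sign changes between consecutive non-zero samples (exact zeros are
#' ignored, so a tangential touch does not count twice).
#'
#' @param x Numeric vector.
#' @return Integer count.
#' @export
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}
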