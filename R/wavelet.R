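# Periodized orthogonal wavelet transforms.
#
# The 0.0625 Hz band-energy features rest on a depth-3 wavelet packet
# decomposition; the denoising stage rests on the plain DWT.  Both are
# implemented here over circular (periodized) filtering, which keeps the
# transform exactly orthonormal on even-length signals, so band energies
# satisfy Parseval's identity to machine precision.

# Orthonormal scaling (low-pass) filters.  The matching wavelet filter is
# the quadrature mirror g[k] = (-1)^k h[L-1-k].
.wt_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605,
           -0.1432942383508097, -0.061273359067658524,
           0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904,
           -0.027219029917056003, 0.049137179673607506,
           0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609)
)

#' Wavelet filter bank
#'
#' Returns the orthonormal analysis filter pair for a named wavelet.
#'
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`, `"db8"`, `"sym8"`.
#' @return list with components `lo` (scaling filter) and `hi`
#'   (wavelet filter).
#' @export
wt_filters <- function(wavelet = "db4") {
  lo <- .wt_lo[[wavelet]]
  if (is.null(lo)) {
    stop(sp_condition("unknown_wavelet", sprintf(
      "unknown wavelet '%s'; available: %s",
      wavelet, paste(names(.wt_lo), collapse = ", "))))
  }
  L <- length(lo)
  hi <- (-1)^(1:L) * rev(lo)   # quadrature mirror, highpass sign convention
  list(lo = lo, hi = hi)
}

# Single-level periodized analysis step.  For even n,
#   a[k] = sum_m lo[m] x[(2k - m + L/2) mod n],   k = 0 .. n/2 - 1,
# i.e. circular convolution downsampled with an L/2 phase offset (the
# periodization convention used by standard wavelet toolboxes).  The
# analysis operator is orthonormal, so the synthesis step is its transpose.
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  L <- length(lo)
  idx <- outer(2L * (0:(n / 2 - 1L)) + L / 2, 0:(L - 1L), `-`) %% n + 1L
  xm <- matrix(x[idx], nrow = n / 2L)
  list(a = as.numeric(xm %*% lo), d = as.numeric(xm %*% hi))
}

.idwt_step <- function(a, d, lo, hi) {
  n <- 2L * length(a)
  L <- length(lo)
  x <- numeric(n)
  # transpose of the analysis operator
  pos <- outer(2L * (0:(length(a) - 1L)) + L / 2, 0:(L - 1L), `-`) %% n + 1L
  for (m in seq_len(L)) {
    contrib <- a * lo[m] + d * hi[m]
    x[pos[, m]] <- x[pos[, m]] + contrib
  }
  x
}

# Multi-level DWT (periodized).  Length must be divisible by 2^level.
.wavedec <- function(x, level, filt) {
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a, filt$lo, filt$hi)
    details[[j]] <- s$d
    a <- s$a
  }
  list(a = a, d = details)
}

.waverec <- function(dec, filt) {
  a <- dec$a
  for (j in rev(seq_along(dec$d))) {
    a <- .idwt_step(a, dec$d[[j]], filt$lo, filt$hi)
  }
  a
}

# Depth-d wavelet packet energies in natural (Paley) order: recursively
# split both branches, low branch first.
.wpd_energies_paley <- function(x, depth, filt) {
  if (depth == 0L) return(sum(x^2))
  s <- .dwt_step(x, filt$lo, filt$hi)
  c(.wpd_energies_paley(s$a, depth - 1L, filt),
    .wpd_energies_paley(s$d, depth - 1L, filt))
}

#' Wavelet packet band energies
#'
#' Depth-`depth` periodized wavelet packet decomposition of a uniformly
#' sampled series, returning the energy (sum of squared coefficients) of
#' each terminal node in natural-frequency order, so that node `k` covers
#' the frequency interval `[k, k+1) * fs / 2^(depth+1)`.
#'
#' The input is truncated to the largest multiple of `2^depth` samples;
#' with an orthonormal filter the energies then sum exactly to the energy
#' of the truncated series.
#'
#' @param x numeric series.
#' @param depth decomposition depth (number of terminal nodes is
#'   `2^depth`).
#' @param wavelet wavelet name, see [wt_filters()].
#' @return numeric vector of length `2^depth`, frequency-ordered energies.
#' @export
wpd_band_energies <- function(x, depth = 3L, wavelet = "db4") {
  filt <- wt_filters(wavelet)
  n_nodes <- 2L^depth
  n_use <- (length(x) %/% n_nodes) * n_nodes
  if (n_use < n_nodes) {
    stop(sp_condition("input_too_short", sprintf(
      "series of length %d too short for depth-%d packet decomposition (need >= %d)",
      length(x), depth, n_nodes)))
  }
  e_paley <- .wpd_energies_paley(x[seq_len(n_use)], depth, filt)
  # frequency order: leaf at frequency position f sits at Paley index
  # gray(f) = f XOR floor(f/2) (high-pass branches mirror their sub-bands)
  f <- 0:(n_nodes - 1L)
  gray <- bitwXor(f, f %/% 2L)
  e_paley[gray + 1L]
}

#' Wavelet denoising by soft thresholding
#'
#' Discrete wavelet decomposition to `level`, soft thresholding of all
#' detail coefficients at the universal threshold
#' `sigma * sqrt(2 log n)` (noise scale `sigma` estimated from the
#' finest-level details by `median(|d|) / 0.6745`), and reconstruction.
#' Length is preserved; signals whose length is not a multiple of
#' `2^level` are padded by edge replication before the transform and
#' truncated afterwards.
#'
#' @param x numeric series.
#' @param wavelet wavelet name, see [wt_filters()].
#' @param level decomposition depth, must satisfy `2^level <= length(x)`.
#' @param rule thresholding rule; `"soft"` (default) or `"hard"`.
#' @return denoised series, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "db4", level = 4L, rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  n <- length(x)
  max_level <- floor(log2(max(n, 1)))
  if (level < 1L || 2L^level > n) {
    stop(sp_condition("level_too_deep", sprintf(
      "level %d infeasible for length %d (max feasible level: %d)",
      level, n, max_level)))
  }
  filt <- wt_filters(wavelet)
  block <- 2L^level
  n_pad <- ceiling(n / block) * block
  xp <- c(x, rep(x[n], n_pad - n))
  dec <- .wavedec(xp, level, filt)
  sigma <- stats::median(abs(dec$d[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n_pad))
  dec$d <- lapply(dec$d, function(d) {
    if (rule == "soft") sign(d) * pmax(abs(d) - thr, 0) else d * (abs(d) > thr)
  })
  .waverec(dec, filt)[seq_len(n)]
}
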