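#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom stats median qt pt rnorm runif rbinom rlnorm fft mvfft sd var
#'   t.test aov cor quantile pnorm complete.cases
NULL

# Gaussian kernel truncated at `radius` samples, normalized to sum 1.
gaussian_kernel <- function(sd, radius = ceiling(4 * sd)) {
  stopifnot(sd > 0, radius >= 1)
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sd^2))
  w / sum(w)
}

#' Gaussian-weighted moving average
#'
#' Smooths a numeric series with a Gaussian kernel. Two edge/missing-value
#' policies are supported: `"renorm"` excludes missing samples (and samples
#' beyond the series edges) from the weighted average and renormalizes the
#' remaining weights, which is the behaviour required for velocity traces
#' with masked blinks; `"reflect"` pads the series by reflection, the
#' conventional choice for trial-averaged ERP waveforms without gaps.
#'
#' @param x numeric vector, possibly containing `NA`.
#' @param sd kernel standard deviation in samples.
#' @param radius kernel half-width in samples (default `ceiling(4 * sd)`).
#' @param pad `"renorm"` or `"reflect"`.
#' @return numeric vector of the same length as `x`. Samples that are `NA`
#'   on input stay `NA` on output under `"renorm"`.
#' @export
smooth_gaussian <- function(x, sd, radius = ceiling(4 * sd),
                            pad = c("renorm", "reflect")) {
  pad <- match.arg(pad)
  n <- length(x)
  if (sd <= 0 || n == 0) return(x)
  w <- gaussian_kernel(sd, radius)
  if (pad == "reflect" && radius < n) {
    xp <- c(x[radius:1 + 1], x, x[n - seq_len(radius)])
    out <- stats::filter(xp, w, sides = 2)
    return(as.numeric(out[radius + seq_len(n)]))
  }
  # renormalized convolution: missing and out-of-range samples get zero weight
  miss <- is.na(x)
  x0 <- x; x0[miss] <- 0
  ok <- as.numeric(!miss)
  if (length(w) * n > 2e6) {
    # FFT path for large kernels (e.g. across thousands of sorted trials)
    wr <- rev(w)
    num <- stats::convolve(x0, wr, type = "open")[radius + seq_len(n)]
    den <- stats::convolve(ok, wr, type = "open")[radius + seq_len(n)]
  } else {
    zp <- rep(0, radius)
    num <- stats::filter(c(zp, x0, zp), w, sides = 2)[radius + seq_len(n)]
    den <- stats::filter(c(zp, ok, zp), w, sides = 2)[radius + seq_len(n)]
  }
  out <- as.numeric(num) / as.numeric(den)
  out[den <= 1e-10] <- NA_real_
  out[miss] <- NA_real_
  out
}

# Row-wise renormalized Gaussian smoothing of a trials x time matrix,
# computed in one multivariate stats::filter pass over the transpose.
smooth_rows <- function(m, sd, radius = ceiling(4 * sd), pad = "renorm") {
  if (pad != "renorm")
    return(t(apply(m, 1L, smooth_gaussian, sd = sd, radius = radius,
                   pad = pad)))
  w <- gaussian_kernel(sd, radius)
  n <- ncol(m)
  miss <- is.na(m)
  x0 <- m; x0[miss] <- 0
  tok <- t(1 * !miss)
  zp <- matrix(0, radius, nrow(m))
  sel <- radius + seq_len(n)
  num <- stats::filter(rbind(zp, t(x0), zp), w, sides = 2)[sel, , drop = FALSE]
  den <- stats::filter(rbind(zp, tok, zp), w, sides = 2)[sel, , drop = FALSE]
  out <- t(num / den)
  out[t(den) <= 1e-10] <- NA_real_
  out[miss] <- NA_real_
  out
}

# Deterministic 31-bit seed derived from a tuple of integers (splitting a
# global seed into per-participant / per-trial substreams so that any trial
# regenerates identically regardless of generation order).
derive_seed <- function(...) {
  ids <- c(...)
  h <- 0
  for (k in ids) h <- (h * 1000003 + (abs(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Index vector of `time` values falling in the half-open interval [a, b).
window_idx <- function(time, window) {
  which(time >= window[1] & time < window[2])
}

stop_if_not_window <- function(window, range, what = "window") {
  if (length(window) != 2 || window[1] >= window[2])
    stop(what, " must be an increasing length-2 numeric", call. = FALSE)
  if (window[1] < range[1] || window[2] > range[2])
    stop(what, " [", window[1], ", ", window[2], ") lies outside [",
         range[1], ", ", range[2], ")", call. = FALSE)
  invisible(window)
}
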