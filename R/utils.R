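## Internal numeric helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of determination of every prefix of a point cloud.
#'
#' For the simple regression of `y` on `x`, r-squared equals the squared
#' Pearson correlation, which lets all prefix fits be evaluated in one
#' cumulative-sum pass instead of n calls to lm().
#'
#' Degenerate windows: zero spread in y (constant response, horizontal
#' line fits exactly) gives 1, as does zero spread in both; zero spread in
#' x alone (a vertical segment no function can fit) gives 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return numeric vector `r2` with `r2[k]` the r-squared over points
#'   `1..k`; entries for k < 2 are NA.
#' @noRd
prefix_r2 <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) return(rep(NA_real_, n))
  k  <- seq_len(n)
  sx <- cumsum(x);  sy <- cumsum(y)
  sxx <- cumsum(x * x); syy <- cumsum(y * y); sxy <- cumsum(x * y)
  vx <- sxx - sx^2 / k
  vy <- syy - sy^2 / k
  cv <- sxy - sx * sy / k
  # guard tiny negative values from cancellation
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  scale2 <- (sxx / k) * (syy / k)
  eps <- 1e-12 * pmax(scale2, 1e-300) * k
  r2 <- rep(NA_real_, n)
  y0 <- vy <= eps
  x0 <- vx <= eps & !y0
  ok <- !y0 & !x0
  r2[y0] <- 1
  r2[x0] <- 0
  r2[ok] <- (cv[ok]^2) / (vx[ok] * vy[ok])
  r2[seq_len(min(1L, n))] <- NA_real_
  r2
}

#' OLS slope/intercept/r2 of y on x (simple regression).
#' @noRd
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  if (vx <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_, n = n))
  }
  cv <- sum((x - mx) * (y - my))
  vy <- sum((y - my)^2)
  slope <- cv / vx
  r2 <- if (vy <= 0) 1 else (cv^2) / (vx * vy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2, n = n)
}

#' Map a csaps-style smoothing parameter p in (0, 1] to the lambda of
#' stats::smooth.spline.
#'
#' The csaps criterion is p * RSS + (1 - p) * integral(f''^2) on the raw
#' x axis; dividing by p gives the smooth.spline form with raw-axis
#' lambda (1 - p) / p. smooth.spline rescales x to [0, 1] internally,
#' under which the curvature integral scales by range(x)^3.
#'
#' @noRd
csaps_lambda <- function(p, x_range) {
  stopifnot(p > 0, p <= 1, x_range > 0)
  ((1 - p) / p) / x_range^3
}

#' Fit a csaps-style smoothing spline to (x, y) and evaluate at xout.
#' @noRd
csaps_fit <- function(x, y, p, xout) {
  if (length(x) < 4L) {
    stop("smoothing spline requires >= 4 defined points, got ", length(x),
         call. = FALSE)
  }
  xr <- diff(range(x))
  if (xr <= 0) stop("smoothing spline requires distinct x values", call. = FALSE)
  lam <- csaps_lambda(p, xr)
  fit <- stats::smooth.spline(x, y, lambda = lam, all.knots = TRUE,
                              keep.data = FALSE, cv = NA)
  stats::predict(fit, x = xout)$y
}

#' Linear interpolation that fills leading/trailing NAs by extension.
#' @noRd
fill_na_linear <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0L) stop("no defined values to interpolate from", call. = FALSE)
  if (length(idx) == 1L) return(rep(v[idx], length(v)))
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Validate an integer-ish scalar.
#' @noRd
as_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x)) {
    stop("'", name, "' must be a single non-negative integer", call. = FALSE)
  }
  as.integer(x)
}

#' Half-open [start, end) integer row/column range given as length-2 vector
#' (1-based, end exclusive). Returns the integer index sequence.
#' @noRd
range_idx <- function(r, n, name) {
  if (length(r) != 2L || any(!is.finite(r)) || r[1] < 1 || r[2] > n + 1 ||
      r[2] <= r[1]) {
    stop("'", name, "' must be a half-open [start, end) range within 1..", n,
         call. = FALSE)
  }
  seq.int(from = as.integer(r[1]), to = as.integer(r[2]) - 1L)
}
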