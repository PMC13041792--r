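## shared numeric helpers (internal)

## shortest decimal representation that round-trips an IEEE double
fmt_num <- function(x) sprintf("%.17g", x)

#' Evaluate a polynomial in ascending-power order
#'
#' Horner evaluation of `a[1] + a[2]*x + ... + a[k]*x^(k-1)`.
#'
#' @param coeffs Numeric coefficients, ascending powers.
#' @param x Points at which to evaluate.
#' @return Numeric vector of polynomial values.
#' @export
polyval_asc <- function(coeffs, x) {
  if (length(coeffs) < 1L) stop("coeffs must be non-empty", call. = FALSE)
  acc <- rep(coeffs[length(coeffs)], length(x))
  for (k in rev(seq_len(length(coeffs) - 1L))) acc <- acc * x + coeffs[k]
  acc
}

## least-squares polynomial fit, ascending raw-basis coefficients.
## x is centered and scaled internally before the QR solve (a cubic on pixel
## indices up to ~2048 is otherwise badly conditioned), then the scaled-basis
## coefficients are expanded back to the raw basis.
polyfit_asc <- function(x, y, degree) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < degree + 1L)
    stop(sprintf("need at least %d points for a degree-%d fit", degree + 1L, degree),
         call. = FALSE)
  ctr <- mean(x)
  scl <- max(abs(x - ctr))
  if (scl == 0) stop("fit is rank deficient: all x values identical", call. = FALSE)
  z <- (x - ctr) / scl
  V <- outer(z, 0:degree, `^`)
  qr_v <- qr(V)
  if (qr_v$rank < degree + 1L)
    stop("fit is rank deficient: fewer distinct x values than coefficients",
         call. = FALSE)
  b <- qr.coef(qr_v, y)
  ## expand sum_k b_k ((x - ctr)/scl)^k into raw powers of x by polynomial
  ## convolution with the linear factor (x - ctr)/scl
  base <- c(-ctr / scl, 1 / scl)            # ascending coeffs of (x-ctr)/scl
  a <- c(b[1], rep(0, degree))
  pw <- 1                                    # coeffs of ((x-ctr)/scl)^k
  for (k in seq_len(degree)) {
    pw <- poly_mult(pw, base)
    a[seq_along(pw)] <- a[seq_along(pw)] + b[k + 1L] * pw
  }
  fitted <- polyval_asc(a, x)
  structure(a, residuals = y - fitted, rms = sqrt(mean((y - fitted)^2)))
}

## product of two polynomials in ascending-coefficient form
poly_mult <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

## nearest index of `value` in sorted numeric vector `axis`
nearest_index <- function(axis, value) which.min(abs(axis - value))

iso_timestamp <- function(time = Sys.time()) {
  format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

## filesystem-safe timestamp for output filenames
file_timestamp <- function(time = Sys.time()) {
  format(time, "%Y%m%dT%H%M%S", tz = "UTC")
}

## compact numeric formatting for filenames (3.5 -> "3.5", 900 -> "900")
fmt_compact <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  out <- ifelse(grepl(".", out, fixed = TRUE), sub("0+$", "", out), out)
  sub("\\.$", "", out)
}
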