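## Butterworth filter design as second-order sections (SOS).
##
## Filters are designed in the analog domain (prototype poles on the unit
## circle), frequency-transformed, mapped with the bilinear transform, and
## kept in factored biquad form throughout. Factored form matters here:
## the 0.05 Hz high-pass edge at a 1000 Hz sampling rate puts poles within
## ~1e-4 of the unit circle, where expanded polynomial coefficients lose
## the precision needed for stable filtering.

## analog Butterworth prototype poles (left half-plane, unit cutoff)
.butter_proto <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

## combine complex poles into real biquad denominators [1, a1, a2]
.poles_to_biquads <- function(poles) {
  # order by imaginary part magnitude so conjugates sit together
  poles <- poles[order(Re(poles), abs(Im(poles)))]
  used <- rep(FALSE, length(poles))
  sections <- list()
  for (i in seq_along(poles)) {
    if (used[i]) next
    p <- poles[i]
    used[i] <- TRUE
    if (abs(Im(p)) < 1e-10) {
      # look for another unused (near-)real pole to pair with
      j <- which(!used & abs(Im(poles)) < 1e-10)
      if (length(j) > 0) {
        q <- poles[j[1]]
        used[j[1]] <- TRUE
        sections[[length(sections) + 1]] <- c(1, -Re(p + q), Re(p * q))
      } else {
        sections[[length(sections) + 1]] <- c(1, -Re(p), 0)
      }
    } else {
      # conjugate partner
      j <- which(!used & abs(poles - Conj(p)) < 1e-8)
      if (length(j) == 0) stop("unpaired complex pole in filter design")
      used[j[1]] <- TRUE
      sections[[length(sections) + 1]] <- c(1, -2 * Re(p), Mod(p)^2)
    }
  }
  sections
}

## evaluate an SOS cascade at digital radian frequency w
.sos_response <- function(sos, w) {
  z1 <- exp(-1i * w)
  z2 <- z1^2
  h <- 1 + 0i
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z2
    den <- sos[s, 4] + sos[s, 5] * z1 + sos[s, 6] * z2
    h <- h * num / den
  }
  h
}

#' Design a digital Butterworth filter as second-order sections
#'
#' Supports low-pass, high-pass, and band-pass responses. The band-pass
#' of order `n` has `2n` poles. Cutoffs are pre-warped so the digital
#' -3 dB points land at the requested frequencies.
#'
#' @param n Filter order (of the analog prototype).
#' @param cutoff Cutoff frequency in Hz (length 2 for `"band"`).
#' @param fs Sampling rate in Hz.
#' @param type `"low"`, `"high"`, or `"band"`.
#' @return A matrix with one biquad per row, columns
#'   `b0 b1 b2 a0 a1 a2` (`a0 = 1`), normalised to unit gain at DC
#'   (low), Nyquist (high), or the band's geometric centre (band).
#' @export
butter_sos <- function(n, cutoff, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("cutoff frequencies must lie in (0, fs/2)")
  proto <- .butter_proto(n)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "band") {
    if (length(cutoff) != 2) stop("band-pass needs two cutoff frequencies")
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    half <- proto * bw / 2
    s_poles <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
    n_zero_pos <- n   # zeros at z = 1 (from s = 0) and z = -1 (from s = Inf)
  } else {
    wc <- warp(cutoff[1])
    s_poles <- if (type == "low") wc * proto else wc / proto
    n_zero_pos <- if (type == "low") 0L else n
  }
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  dens <- .poles_to_biquads(z_poles)
  ns <- length(dens)
  # distribute zeros over sections: band gets (z-1)(z+1) per biquad;
  # low gets (z+1)^2; high gets (z-1)^2; odd first-order tails get one.
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    den <- dens[[s]]
    first_order <- den[3] == 0
    num <- if (type == "band") {
      if (first_order) c(1, -1, 0) else c(1, 0, -1)
    } else if (type == "low") {
      if (first_order) c(1, 1, 0) else c(1, 2, 1)
    } else {
      if (first_order) c(1, -1, 0) else c(1, -2, 1)
    }
    sos[s, ] <- c(num, den)
  }
  w_ref <- switch(type,
                  low = 0,
                  high = pi,
                  band = 2 * atan(sqrt(tan(pi * cutoff[1] / fs) *
                                       tan(pi * cutoff[2] / fs))))
  g <- Mod(.sos_response(sos, w_ref))
  sos[1, 1:3] <- sos[1, 1:3] / g
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Applies the cascade forward and backward so the net phase response is
#' zero, with odd-reflection padding at both ends to suppress edge
#' transients (important for the very low high-pass edge used on pupil
#' data).
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x Numeric signal.
#' @param padlen Reflection pad length in samples; capped at
#'   `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = min(length(x) - 1L, 3L * 50L)) {
  n <- length(x)
  padlen <- max(0L, min(as.integer(padlen), n - 1L))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- sosfilt_cpp(sos, xp)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}
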