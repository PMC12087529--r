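## Internal numerical helpers shared across modules.

invlogit <- function(x) 1 / (1 + exp(-x))

## Circular Gaussian smoothing of a matrix by FFT convolution.
## sigma is the kernel SD in pixels; sigma <= 0 returns the input.
gaussSmooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  rd <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  cd <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  kr <- stats::dnorm(rd, sd = sigma)
  kc <- stats::dnorm(cd, sd = sigma)
  K <- outer(kr, kc)
  K <- K / sum(K)
  Re(stats::fft(stats::fft(mat) * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

## Smooth standard-normal-marginal random field: smoothed white noise
## rescaled to unit variance (so `sd` below is the marginal SD).
smoothField <- function(nr, nc, sigma, sd = 1) {
  z <- gaussSmooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  s <- stats::sd(as.vector(z))
  if (s < .Machine$double.eps) return(matrix(0, nr, nc))
  (z - mean(z)) / s * sd
}

## ISO week of year with weeks 53 merged into 52 (fixed 52-week cycle).
isoWeek52 <- function(dates) {
  w <- as.integer(format(as.Date(dates), "%V"))
  pmin(w, 52L)
}

## List-length class from the number of species on a visit.
listLengthClass <- function(n) {
  cls <- ifelse(n <= 1, "single", ifelse(n <= 3, "short", "long"))
  factor(cls, levels = c("single", "short", "long"))
}

## Population (divide-by-n) standard deviation.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

## Stage seed derivation: deterministic, stays within 32-bit range.
deriveSeed <- function(master, offset) {
  as.integer((as.numeric(master) * 97 + offset * 1009) %% 2147483647)
}

## Split-Rhat (Gelman-Rubin with split chains) for a draws matrix,
## columns = chains.
splitRhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mns <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- nn * stats::var(mns)
  W <- mean(vars)
  if (W < .Machine$double.eps) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
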