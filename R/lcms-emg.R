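#' Savitzky-Golay smoothing of a chromatogram
#'
#' Local least-squares polynomial smoothing on the chromatogram's own grid.
#' The instrument-software convention of a "30-point" quartic/quintic filter
#' is realized as the nearest odd window, 31 points.
#'
#' @param chrom a [Chromatogram-class].
#' @param windowPoints odd filter width in points (default 31).
#' @param polyOrder polynomial order, 4 or 5 (default 4).
#' @return a smoothed [Chromatogram-class] on the same time grid.
#' @export
smoothChromatogram <- function(chrom, windowPoints = 31L, polyOrder = 4L) {
  stopifnot(is(chrom, "Chromatogram"))
  n <- length(chromTime(chrom))
  if (windowPoints %% 2L == 0L) windowPoints <- windowPoints + 1L
  if (windowPoints > n) stop("smoothing window longer than the chromatogram")
  if (polyOrder >= windowPoints) stop("polyOrder must be < windowPoints")
  y <- signal::sgolayfilt(chromIntensity(chrom), p = polyOrder, n = windowPoints)
  chromatogram(chromTime(chrom), y, chrom@label)
}

#' Exponentially modified Gaussian peak profile
#'
#' The EMG is a Gaussian convolved with an exponential decay, the standard
#' model for tailing chromatographic peaks:
#' \deqn{h(t) = \frac{A}{2\tau}\exp\!\Big(\frac{\sigma^2}{2\tau^2} +
#'   \frac{\mu-t}{\tau}\Big)\,
#'   \mathrm{erfc}\!\Big(\frac{\sigma/\tau + (\mu-t)/\sigma}{\sqrt 2}\Big)}
#' and integrates to the area `A` over the whole line. Large `sigma/tau`
#' (nearly Gaussian peaks) overflow the naive expression; evaluation uses
#' the scaled complementary error function where needed.
#'
#' @param area peak area A (signal x min, >= 0).
#' @param mu Gaussian center (min).
#' @param sigma Gaussian width (min, > 0).
#' @param tau exponential time constant (min, > 0).
#' @param t time vector (min).
#' @return intensity vector over `t`.
#' @export
emgProfile <- function(area, mu, sigma, tau, t) {
  if (sigma <= 0) stop("sigma must be positive")
  if (tau <= 0) stop("tau must be positive")
  z <- (sigma / tau + (mu - t) / sigma) / sqrt(2)
  out <- numeric(length(t))
  pos <- z >= 0
  ## z >= 0: exp(arg) * erfc(z) = exp(arg - z^2) * erfcx(z),
  ## and arg - z^2 collapses to the plain Gaussian exponent.
  if (any(pos)) {
    out[pos] <- (area / (2 * tau)) *
      exp(-(t[pos] - mu)^2 / (2 * sigma^2)) * .erfcx(z[pos])
  }
  if (any(!pos)) {
    arg <- sigma^2 / (2 * tau^2) + (mu - t[!pos]) / tau
    out[!pos] <- (area / (2 * tau)) * exp(arg) * 2 * stats::pnorm(-z[!pos] * sqrt(2))
  }
  out
}

## Scaled complementary error function for non-negative arguments.
## exp(z^2) erfc(z) overflows past z ~ 27; switch to the asymptotic
## expansion 1/(z sqrt(pi)) (1 - 1/(2 z^2) + 3/(4 z^4) - 15/(8 z^6)),
## accurate to ~1e-9 relative at the switch point.
.erfcx <- function(z) {
  out <- numeric(length(z))
  small <- z < 20
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    iz2 <- 1 / zz^2
    out[!small] <- (1 - 0.5 * iz2 + 0.75 * iz2^2 - 1.875 * iz2^3) /
      (zz * sqrt(pi))
  }
  out
}

## Model evaluation for the least-squares fit: k EMG peaks + linear baseline.
## With shared shape, all peaks use the "sigma1"/"tau1" parameters.
.emgModel <- function(par, t, nPeaks, shareShape = FALSE) {
  y <- par[["b0"]] + par[["b1"]] * t
  for (k in seq_len(nPeaks)) {
    sg <- if (shareShape) par[["sigma1"]] else par[[paste0("sigma", k)]]
    tu <- if (shareShape) par[["tau1"]] else par[[paste0("tau", k)]]
    y <- y + emgProfile(par[[paste0("A", k)]], par[[paste0("mu", k)]], sg, tu, t)
  }
  y
}

## Initial guesses from the smoothed trace: the nPeaks highest local maxima,
## left peak first; sigma from the half-height width, tau = sigma.
.emgInit <- function(chrom, nPeaks) {
  n <- length(chromTime(chrom))
  win <- min(31L, if (n %% 2L == 1L) n else n - 1L)
  sm <- if (n >= 7) smoothChromatogram(chrom, win, min(4L, win - 1L)) else chrom
  t <- chromTime(sm); y <- chromIntensity(sm)
  dy <- diff(y)
  locmax <- which(c(FALSE, dy[-length(dy)] > 0 & dy[-1] <= 0, FALSE))
  locmax <- unique(c(locmax, which.max(y)))
  navail <- min(length(locmax), nPeaks)
  locmax <- locmax[order(y[locmax], decreasing = TRUE)][seq_len(navail)]
  locmax <- sort(locmax)
  init <- list(b0 = max(0, min(y)), b1 = 0)
  for (k in seq_len(navail)) {
    i <- locmax[k]
    half <- y[i] / 2
    li <- i; while (li > 1 && y[li] > half) li <- li - 1
    ri <- i; while (ri < n && y[ri] > half) ri <- ri + 1
    fwhm <- max(t[ri] - t[li], 4 * mean(diff(t)))
    sg <- fwhm / 2.355
    init[[paste0("A", k)]] <- max(y[i], 1e-8) * sg * sqrt(2 * pi)
    init[[paste0("mu", k)]] <- t[i]
    init[[paste0("sigma", k)]] <- sg
    init[[paste0("tau", k)]] <- sg
  }
  if (navail < nPeaks) {
    ## a merged pair shows a single mode: seed the second peak on the
    ## trailing shoulder and split the area
    for (k in seq(navail + 1L, nPeaks)) {
      init[[paste0("A", k)]] <- init$A1 / 2
      init$A1 <- init$A1 / 2
      init[[paste0("mu", k)]] <- init$mu1 + init$sigma1
      init[[paste0("sigma", k)]] <- init$sigma1
      init[[paste0("tau", k)]] <- init$tau1
    }
  }
  init
}

## Candidate starting points for the fit. A single default for one peak or
## two resolved maxima; for a merged two-peak mode, a small deterministic
## family of splits around the mode so the optimizer is not trapped in the
## one-peak solution.
.emgInitList <- function(chrom, nPeaks) {
  base <- .emgInit(chrom, nPeaks)
  if (nPeaks < 2L) return(list(base))
  inits <- list(base)
  m <- (base$mu1 + base$mu2) / 2
  sg <- base$sigma1
  Atot <- base$A1 + base$A2
  mk <- function(mu1, mu2, a1, a2, shrink) {
    cand <- base
    cand$mu1 <- mu1; cand$mu2 <- mu2
    cand$A1 <- a1; cand$A2 <- a2
    cand$sigma1 <- cand$sigma2 <- sg / shrink
    cand$tau1 <- cand$tau2 <- base$tau1 / shrink
    cand
  }
  # symmetric splits around the midpoint of the two seeds
  for (d in c(0.4, 0.75, 1.25)) {
    for (shrink in c(1.5, 2.5, 4)) {
      inits[[length(inits) + 1L]] <-
        mk(m - d * sg, m + d * sg, Atot / 2, Atot / 2, shrink)
    }
  }
  # asymmetric splits anchored at the dominant mode: a small satellite peak
  # hiding on either flank of a big one
  mode <- base$mu1
  for (d in c(0.6, 1)) {
    for (shrink in c(1.5, 2.5)) {
      inits[[length(inits) + 1L]] <-
        mk(mode - d * sg, mode, 0.25 * Atot, 0.75 * Atot, shrink)
      inits[[length(inits) + 1L]] <-
        mk(mode, mode + d * sg, 0.75 * Atot, 0.25 * Atot, shrink)
    }
  }
  inits
}

#' Fit one or two EMG peaks to a chromatogram
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) over the peak
#' parameters and a linear baseline; used to deconvolve co-eluting peaks such
#' as the leucyl-/isoleucyl-adenosine pair. The fit is deterministic given
#' identical initialization; default initial values are derived from the
#' smoothed signal (highest local maxima, half-height width). Areas are fit
#' parameters, so their standard errors come straight from the parameter
#' covariance.
#'
#' @param chrom a [Chromatogram-class] covering the peak region.
#' @param nPeaks 1 or 2.
#' @param init optional named list of starting values
#'   (`b0,b1,A1,mu1,sigma1,tau1[,A2,...]`).
#' @param baseline `"linear"` (default) or `"none"` (baseline fixed at zero).
#' @param sigmaBounds,tauBounds allowed ranges (min) for the shape parameters.
#' @param shareShape with two peaks, constrain both to one `sigma`/`tau`
#'   (default `TRUE`): co-eluting isomeric species on the same column share
#'   a peak shape, and the constraint is what keeps the strongly overlapped
#'   deconvolution well-conditioned.
#' @return an [EMGFit-class]; non-convergence raises an error of class
#'   `emgFitError` carrying the optimizer diagnostics. Parameters pinned at
#'   bounds are flagged in the peak table (`at_bounds`).
#' @export
fitEmgPeaks <- function(chrom, nPeaks = 1L, init = NULL,
                        baseline = c("linear", "none"),
                        sigmaBounds = c(1e-4, 5), tauBounds = c(1e-4, 5),
                        shareShape = TRUE) {
  stopifnot(is(chrom, "Chromatogram"), nPeaks %in% c(1L, 2L))
  baseline <- match.arg(baseline)
  t <- chromTime(chrom); y <- chromIntensity(chrom)
  inits <- if (is.null(init)) .emgInitList(chrom, nPeaks) else list(init)
  shareShape <- shareShape && nPeaks > 1L

  peakNames <- if (shareShape) {
    c(as.vector(t(outer(c("A", "mu"), seq_len(nPeaks), paste0))),
      "sigma1", "tau1")
  } else {
    as.vector(t(outer(c("A", "mu", "sigma", "tau"), seq_len(nPeaks), paste0)))
  }
  pnames <- if (baseline == "linear") c("b0", "b1", peakNames) else peakNames
  lower <- upper <- setNames(numeric(length(pnames)), pnames)
  if (baseline == "linear") {
    lower[c("b0", "b1")] <- -Inf
    upper[c("b0", "b1")] <- Inf
  }
  for (k in seq_len(nPeaks)) {
    lower[paste0(c("A", "mu"), k)] <- c(0, min(t))
    upper[paste0(c("A", "mu"), k)] <- c(Inf, max(t))
  }
  shapeNames <- grep("^(sigma|tau)", pnames, value = TRUE)
  lower[shapeNames] <- ifelse(grepl("^sigma", shapeNames),
                              sigmaBounds[1], tauBounds[1])
  upper[shapeNames] <- ifelse(grepl("^sigma", shapeNames),
                              sigmaBounds[2], tauBounds[2])

  evalModel <- function(p) {
    pl <- as.list(p)
    if (baseline == "none") pl$b0 <- pl$b1 <- 0
    .emgModel(pl, t, nPeaks, shareShape)
  }
  resid <- function(p) y - evalModel(p)

  fit <- NULL
  for (ini in inits) {
    start <- unlist(ini)[pnames]
    names(start) <- pnames
    if (any(is.na(start)))
      stop("init must provide: ", paste(pnames, collapse = ", "))
    start <- pmin(pmax(start, lower), upper)
    cand <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                               fn = resid,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-12, ptol = 1e-12))
    if (cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    stop(structure(class = c("emgFitError", "error", "condition"),
                   list(message = "EMG fit failed to converge from any start",
                        call = sys.call())))
  }
  p <- fit$par
  dof <- max(length(y) - length(p), 1)
  s2 <- fit$deviance / dof
  covmat <- tryCatch(s2 * chol2inv(chol(fit$hessian)),
                     error = function(e) s2 * MASS::ginv(fit$hessian))
  dimnames(covmat) <- list(pnames, pnames)
  covmat <- (covmat + t(covmat)) / 2

  btol <- 1e-6
  peaks <- do.call(rbind, lapply(seq_len(nPeaks), function(k) {
    nm <- intersect(c(paste0(c("A", "mu"), k),
                      if (shareShape) c("sigma1", "tau1")
                      else paste0(c("sigma", "tau"), k)), pnames)
    atb <- any(abs(p[nm] - lower[nm]) < btol * (1 + abs(lower[nm])) &
                 is.finite(lower[nm]) & lower[nm] != upper[nm]) ||
           any(abs(p[nm] - upper[nm]) < btol * (1 + abs(upper[nm])) &
                 is.finite(upper[nm]) & lower[nm] != upper[nm])
    sgName <- if (shareShape) "sigma1" else paste0("sigma", k)
    tuName <- if (shareShape) "tau1" else paste0("tau", k)
    data.frame(peak = k, area = p[[paste0("A", k)]], mu = p[[paste0("mu", k)]],
               sigma = p[[sgName]], tau = p[[tuName]],
               area_se = sqrt(max(covmat[paste0("A", k), paste0("A", k)], 0)),
               at_bounds = atb)
  }))
  peaks <- peaks[order(peaks$mu), ]
  peaks$peak <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  bl <- if (baseline == "linear") c(p[["b0"]], p[["b1"]]) else c(0, 0)
  new("EMGFit", peaks = peaks, baseline = bl,
      covariance = covmat, residualNorm = fit$deviance,
      fitted = evalModel(p))
}

#' Integrate a chromatographic peak by the trapezoidal rule
#'
#' Model-free area over a time interval, optionally above a linear baseline
#' through the interval endpoints. The area standard deviation is estimated
#' from local residual noise: the RMS deviation of the raw signal from its
#' smoothed version in flanking baseline windows, times `sqrt(n)` times the
#' mean sampling interval.
#'
#' @param chrom a [Chromatogram-class].
#' @param bounds numeric length-2 time interval (min).
#' @param baseline `"none"` or `"linear"` (through the interval endpoints).
#' @param flankWidth width (min) of the flanking windows used for the noise
#'   estimate (default 0.2).
#' @return list with `area` and `sd`.
#' @export
integratePeak <- function(chrom, bounds, baseline = c("none", "linear"),
                          flankWidth = 0.2) {
  stopifnot(is(chrom, "Chromatogram"), length(bounds) == 2)
  baseline <- match.arg(baseline)
  t <- chromTime(chrom); y <- chromIntensity(chrom)
  inb <- t >= bounds[1] & t <= bounds[2]
  if (sum(inb) < 2) stop("integration interval contains fewer than 2 points")
  ti <- t[inb]; yi <- y[inb]
  if (baseline == "linear") {
    base <- yi[1] + (yi[length(yi)] - yi[1]) * (ti - ti[1]) /
      (ti[length(ti)] - ti[1])
    yi <- yi - base
  }
  area <- pracma::trapz(ti, yi)

  ## noise: residual to the smoothed trace in windows flanking the interval
  n <- length(t)
  win <- min(31L, if (n %% 2L == 1L) n else n - 1L)
  sm <- if (n >= 7) chromIntensity(smoothChromatogram(chrom, win,
                                                      min(4L, win - 1L))) else y
  flank <- (t >= bounds[1] - flankWidth & t < bounds[1]) |
           (t > bounds[2] & t <= bounds[2] + flankWidth)
  rms <- if (any(flank)) sqrt(mean((y[flank] - sm[flank])^2)) else 0
  sdArea <- rms * sqrt(sum(inb)) * mean(diff(ti))
  list(area = area, sd = sdArea)
}
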