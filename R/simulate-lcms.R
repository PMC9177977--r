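#' Specification for a synthetic LC/MS acetylation experiment
#'
#' Ground truth for [simulateLcms]: per-amino-acid true acetylated fractions,
#' true relative response factors, total molar signal per species, EMG peak
#' shape for chromatogram rendering, and a multiplicative noise level.
#'
#' @param aminoAcids one-letter codes of the species to simulate.
#' @param trueFractions named true acetylated fractions in \[0,1\] (recycled
#'   if unnamed scalar).
#' @param trueRrf named true RRFs (> 0; Fmoc over acetyl), default 1.5.
#' @param totalSignal molar signal per species on the instrument scale
#'   (default 1e6).
#' @param noiseCV coefficient of variation of the log-normal multiplicative
#'   area noise (default 0.05, i.e. 5%).
#' @param nCalReplicates replicates of the equimolar split-sample RRF
#'   calibration (default 3).
#' @param retentionTimes named peak centers mu in minutes (defaults spread
#'   over 2..(n+1) min).
#' @param sigma,tau EMG shape parameters for rendering (min).
#' @param baseline length-2 `(intercept, slope)` for rendered chromatograms.
#' @param seed mandatory RNG seed.
#' @return an `LcmsSimSpec` (validated list).
#' @export
lcmsSimSpec <- function(aminoAcids = c("G", "A", "S", "T", "V", "I", "L", "E"),
                        trueFractions = 0.5, trueRrf = 1.5,
                        totalSignal = 1e6, noiseCV = 0.05,
                        nCalReplicates = 3L, retentionTimes = NULL,
                        sigma = 0.05, tau = 0.05,
                        baseline = c(0, 0), seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  aa <- aminoAcids
  stopifnot(all(aa %in% names(.AA_FORMULAS)))
  expand <- function(x, default) {
    if (is.null(names(x))) {
      stopifnot(length(x) %in% c(1L, length(aa)))
      stats::setNames(rep_len(x, length(aa)), aa)
    } else {
      out <- stats::setNames(rep(default, length(aa)), aa)
      out[intersect(names(x), aa)] <- x[intersect(names(x), aa)]
      out
    }
  }
  f <- expand(trueFractions, 0.5)
  r <- expand(trueRrf, 1.5)
  if (any(f < 0 | f > 1)) stop("true fractions must lie in [0,1]")
  if (any(r <= 0)) stop("true RRFs must be positive")
  if (noiseCV < 0) stop("noise CV must be non-negative")
  if (is.null(retentionTimes)) {
    retentionTimes <- stats::setNames(seq(2, length.out = length(aa)), aa)
  }
  structure(list(aminoAcids = aa, trueFractions = f, trueRrf = r,
                 totalSignal = totalSignal, noiseCV = noiseCV,
                 nCalReplicates = as.integer(nCalReplicates),
                 retentionTimes = retentionTimes, sigma = sigma, tau = tau,
                 baseline = baseline, seed = as.integer(seed)),
            class = "LcmsSimSpec")
}

#' Simulate LC/MS peak-area tables (and chromatograms) with known fractions
#'
#' For each amino acid, the acetyl- and Fmoc-derivative peak areas are drawn
#' as molar amount times response factor (acetyl response 1, Fmoc response
#' RRF) with log-normal multiplicative noise of the specified CV. An
#' equimolar split-sample calibration experiment is simulated with
#' `nCalReplicates` replicates and summarized into an RRF table (mean and sd
#' of the per-replicate area ratios). Optionally the sample is also rendered
#' as EMG chromatograms, including a single co-eluting trace for the
#' isobaric leucyl/isoleucyl pair when both are simulated.
#'
#' @param spec an [lcmsSimSpec].
#' @param dir optional output directory; writes `areas.csv`, `rrf.csv`,
#'   `ground_truth.json` and (if rendered) per-species chromatogram CSVs.
#' @param renderChromatograms render per-species EMG traces (default FALSE).
#' @param timeStep chromatogram sampling interval in minutes.
#' @param renderNoise additive rendering noise, relative to the tallest peak.
#' @return list with `areas` (long table: sample, amino_acid, derivative,
#'   area, area_sd), `rrfTable`, `groundTruth`, and `chromatograms` (named
#'   list of [Chromatogram-class], possibly empty).
#' @export
simulateLcms <- function(spec, dir = NULL, renderChromatograms = FALSE,
                         timeStep = 0.005, renderNoise = 0.01) {
  stopifnot(inherits(spec, "LcmsSimSpec"))
  set.seed(spec$seed)
  aa <- spec$aminoAcids
  sdlog <- if (spec$noiseCV > 0) sqrt(log(1 + spec$noiseCV^2)) else 0
  noise <- function(n) if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)

  molAc <- spec$trueFractions * spec$totalSignal
  molFm <- (1 - spec$trueFractions) * spec$totalSignal
  sAc <- molAc * noise(length(aa))
  sFm <- molFm * spec$trueRrf * noise(length(aa))
  areas <- data.frame(
    sample = "sim",
    amino_acid = rep(aa, 2),
    derivative = rep(c("acetyl", "fmoc"), each = length(aa)),
    area = c(sAc, sFm),
    area_sd = c(sAc, sFm) * spec$noiseCV,
    stringsAsFactors = FALSE)

  ## equimolar split-sample calibration
  nr <- spec$nCalReplicates
  ratios <- matrix(NA_real_, nrow = nr, ncol = length(aa),
                   dimnames = list(NULL, aa))
  for (k in seq_len(nr)) {
    acal <- 0.5 * spec$totalSignal * noise(length(aa))
    fcal <- 0.5 * spec$totalSignal * spec$trueRrf * noise(length(aa))
    ratios[k, ] <- fcal / acal
  }
  rrfTable <- data.frame(
    amino_acid = aa,
    rrf = colMeans(ratios),
    rrf_sd = if (nr > 1) apply(ratios, 2, stats::sd) else 0,
    stringsAsFactors = FALSE)

  chroms <- list()
  if (renderChromatograms) {
    tmax <- max(spec$retentionTimes) + 2
    tgrid <- seq(0.5, tmax, by = timeStep)
    mkTrace <- function(peaks, label) {
      y <- spec$baseline[1] + spec$baseline[2] * tgrid
      for (p in peaks) {
        y <- y + emgProfile(p$area, p$mu, spec$sigma, spec$tau, tgrid)
      }
      hmax <- max(y)
      y <- y + stats::rnorm(length(tgrid), 0, renderNoise * hmax)
      chromatogram(tgrid, y, label)
    }
    coelute <- all(c("L", "I") %in% aa)
    areaOf <- function(a, deriv) {
      areas$area[areas$amino_acid == a & areas$derivative == deriv]
    }
    for (a in aa) {
      for (deriv in c("acetyl", "fmoc")) {
        if (coelute && a %in% c("L", "I")) next
        lab <- paste0(deriv, "_", a)
        chroms[[lab]] <- mkTrace(list(list(area = areaOf(a, deriv),
                                           mu = spec$retentionTimes[[a]])),
                                 lab)
      }
    }
    if (coelute) {
      ## leucyl and isoleucyl derivatives are isobaric: one extracted-ion
      ## trace holds both peaks, 2 sigma apart, for deconvolution
      for (deriv in c("acetyl", "fmoc")) {
        lab <- paste0(deriv, "_LI")
        muL <- spec$retentionTimes[["L"]]
        chroms[[lab]] <- mkTrace(list(
          list(area = areaOf("L", deriv), mu = muL),
          list(area = areaOf("I", deriv), mu = muL + 2 * spec$sigma)), lab)
      }
    }
  }

  gt <- list(trueFractions = as.list(spec$trueFractions),
             trueRrf = as.list(spec$trueRrf),
             totalSignal = spec$totalSignal, noiseCV = spec$noiseCV,
             seed = spec$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(areas, file.path(dir, "areas.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(rrfTable, file.path(dir, "rrf.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    for (lab in names(chroms)) {
      writeChromatogramCsv(chroms[[lab]], file.path(dir, paste0(lab, ".csv")))
    }
  }
  list(areas = areas, rrfTable = rrfTable, groundTruth = gt,
       chromatograms = chroms)
}
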