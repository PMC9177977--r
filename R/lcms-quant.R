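#' Relative response factor from an equimolar split sample
#'
#' The RRF of an aminoacyl-adenosine species corrects for the difference in
#' ionization efficiency between its Fmoc and acetyl derivatives. From a
#' sample split into two equal aliquots (one Fmoc-derivatized, one
#' chemically acetylated), `RRF = S_Fmoc / S_Ac`, the ratio of the
#' \[M+H\]+ peak areas. The standard deviation follows by first-order
#' (delta-method) propagation treating the two areas as independent:
#' \eqn{sd(RRF) = RRF \sqrt{(sd_F/S_F)^2 + (sd_A/S_A)^2}}.
#'
#' @param fmocArea,acetylArea peak areas (> 0).
#' @param fmocSd,acetylSd their standard deviations (>= 0).
#' @return list with `rrf` and `sd`.
#' @examples
#' computeRrf(200, 100)          # rrf 2, sd 0
#' computeRrf(200, 100, 20, 10)  # rrf 2 with propagated sd
#' @export
computeRrf <- function(fmocArea, acetylArea, fmocSd = 0, acetylSd = 0) {
  if (acetylArea <= 0) stop("acetyl-derivative area must be positive")
  if (fmocArea <= 0) stop("Fmoc-derivative area must be positive")
  stopifnot(fmocSd >= 0, acetylSd >= 0)
  rrf <- fmocArea / acetylArea
  sd <- rrf * sqrt((fmocSd / fmocArea)^2 + (acetylSd / acetylArea)^2)
  list(rrf = rrf, sd = sd)
}

#' Acetylated fraction of an aminoacyl-tRNA pool
#'
#' The fraction of acetylated aminoacyl-tRNA is estimated from the acetyl-
#' and Fmoc-derivative peak areas of its adenosine digestion product:
#' \deqn{f = \frac{S_{Ac}}{S_{Ac} + S_{Fmoc}/RRF_i}}
#' The Fmoc area is divided by the relative response factor so that the two
#' areas are compared on a common molar scale; an equimolar acetyl/Fmoc pool
#' therefore gives exactly f = 0.5 (the orientation of the RRF, Fmoc over
#' acetyl, is fixed by [computeRrf]; set `rrfOrientation = "acetyl_over_fmoc"`
#' for the reciprocal dialect). The standard deviation is first-order
#' propagation treating S_Ac, S_Fmoc and RRF as independent.
#'
#' @param sAc acetyl-derivative area (>= 0).
#' @param sFmoc Fmoc-derivative area (>= 0); `sAc + sFmoc` must be positive.
#' @param rrf relative response factor (> 0).
#' @param sAcSd,sFmocSd,rrfSd standard deviations (>= 0).
#' @param rrfOrientation how `rrf` was formed: `"fmoc_over_acetyl"` (default)
#'   or `"acetyl_over_fmoc"`.
#' @return list with `fraction` (in \[0,1\]) and `sd`.
#' @examples
#' acetylatedFraction(100, 100, 1)          # 0.5
#' acetylatedFraction(300, 100, 2)          # 0.857
#' @export
acetylatedFraction <- function(sAc, sFmoc, rrf, sAcSd = 0, sFmocSd = 0,
                               rrfSd = 0,
                               rrfOrientation = c("fmoc_over_acetyl",
                                                  "acetyl_over_fmoc")) {
  rrfOrientation <- match.arg(rrfOrientation)
  stopifnot(sAc >= 0, sFmoc >= 0, rrf > 0, sAcSd >= 0, sFmocSd >= 0, rrfSd >= 0)
  if (sAc + sFmoc <= 0) stop("both areas are zero; fraction undefined")
  if (rrfOrientation == "acetyl_over_fmoc") {
    ## convert to the canonical orientation
    rrfSd <- rrfSd / rrf^2
    rrf <- 1 / rrf
  }
  denom <- sAc + sFmoc / rrf
  f <- sAc / denom
  ## partial derivatives of f = a / (a + b/r)
  dfa <- (sFmoc / rrf) / denom^2
  dfb <- -(sAc / rrf) / denom^2
  dfr <- (sAc * sFmoc / rrf^2) / denom^2
  sd <- sqrt((dfa * sAcSd)^2 + (dfb * sFmocSd)^2 + (dfr * rrfSd)^2)
  list(fraction = f, sd = sd)
}

#' Normalize peak areas to an internal-standard spike-in
#'
#' Divides every analyte peak area in a sample by the peak area of the
#' co-injected internal standard (e.g. 15N-AMP), putting samples on a common
#' scale. Proportional areas with proportional spikes normalize identically.
#'
#' @param areas named numeric vector or data.frame with an `area` column.
#' @param spikeArea internal-standard peak area (> 0).
#' @return same shape as `areas`, divided by `spikeArea`.
#' @export
spikeNormalize <- function(areas, spikeArea) {
  if (spikeArea <= 0) stop("spike-in area must be positive")
  if (is.data.frame(areas)) {
    stopifnot("area" %in% names(areas))
    areas$area <- areas$area / spikeArea
    areas
  } else {
    areas / spikeArea
  }
}

#' Acetylated fractions for a table of peak areas
#'
#' Joins a long peak-area table (one row per sample x amino acid x
#' derivative) with an RRF calibration table and computes the acetylated
#' fraction with propagated uncertainty for every sample/amino-acid pair.
#'
#' @param areas data.frame with columns `sample`, `amino_acid`, `derivative`
#'   (`"acetyl"` or `"fmoc"`), `area`, and optionally `area_sd`.
#' @param rrfTable data.frame with columns `amino_acid`, `rrf`, and optionally
#'   `rrf_sd`.
#' @return data.frame with columns `sample`, `amino_acid`, `s_ac`, `s_ac_sd`,
#'   `s_fmoc`, `s_fmoc_sd`, `rrf`, `fraction`, `fraction_sd`.
#' @export
quantifyFractions <- function(areas, rrfTable) {
  need <- c("sample", "amino_acid", "derivative", "area")
  stopifnot(all(need %in% names(areas)),
            all(c("amino_acid", "rrf") %in% names(rrfTable)))
  if (is.null(areas$area_sd)) areas$area_sd <- 0
  if (is.null(rrfTable$rrf_sd)) rrfTable$rrf_sd <- 0
  keys <- unique(areas[c("sample", "amino_acid")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- areas[areas$sample == keys$sample[i] &
                   areas$amino_acid == keys$amino_acid[i], ]
    ac <- sub[tolower(sub$derivative) == "acetyl", ]
    fm <- sub[tolower(sub$derivative) == "fmoc", ]
    if (nrow(ac) != 1L || nrow(fm) != 1L) {
      stop("need exactly one acetyl and one fmoc row for ",
           keys$sample[i], "/", keys$amino_acid[i])
    }
    r <- rrfTable[rrfTable$amino_acid == keys$amino_acid[i], ]
    if (nrow(r) != 1L) stop("no RRF entry for ", keys$amino_acid[i])
    q <- acetylatedFraction(ac$area, fm$area, r$rrf,
                            ac$area_sd, fm$area_sd, r$rrf_sd)
    data.frame(sample = keys$sample[i], amino_acid = keys$amino_acid[i],
               s_ac = ac$area, s_ac_sd = ac$area_sd,
               s_fmoc = fm$area, s_fmoc_sd = fm$area_sd,
               rrf = r$rrf, fraction = q$fraction, fraction_sd = q$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write chromatogram CSV files
#'
#' Chromatograms travel as two-column CSV files with header
#' `time_min,intensity`; the species label is taken from the file name unless
#' given.
#'
#' @param path CSV file path.
#' @param label optional species label.
#' @return a [Chromatogram-class].
#' @export
readChromatogramCsv <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "intensity") %in% names(df)))
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  chromatogram(df$time_min, df$intensity, label)
}

#' @rdname readChromatogramCsv
#' @param chrom a [Chromatogram-class] to write.
#' @export
writeChromatogramCsv <- function(chrom, path) {
  utils::write.csv(data.frame(time_min = chromTime(chrom),
                              intensity = chromIntensity(chrom)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
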