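#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Chromatogram: an extracted-ion time/intensity trace
#'
#' @slot time retention time in minutes, strictly increasing.
#' @slot intensity detector counts, same length as `time`, finite.
#' @slot label optional species label (e.g. the target m/z or analyte name).
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(time = "numeric", intensity = "numeric", label = "character"),
  prototype(label = NA_character_),
  validity = function(object) {
    if (length(object@time) != length(object@intensity))
      return("time and intensity must have equal length")
    if (length(object@time) >= 2 && any(diff(object@time) <= 0))
      return("time must be strictly increasing")
    if (any(!is.finite(object@intensity)))
      return("intensities must be finite")
    TRUE
  })

#' Construct a Chromatogram
#'
#' @param time retention times (min), strictly increasing.
#' @param intensity intensities (counts).
#' @param label optional species label.
#' @return a [Chromatogram-class] object.
#' @export
chromatogram <- function(time, intensity, label = NA_character_) {
  new("Chromatogram", time = as.numeric(time), intensity = as.numeric(intensity),
      label = as.character(label))
}

#' @rdname chromatogram
#' @param x a `Chromatogram`.
#' @export
chromTime <- function(x) x@time

#' @rdname chromatogram
#' @export
chromIntensity <- function(x) x@intensity

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram%s: %d points, %.2f-%.2f min\n",
              ifelse(is.na(object@label), "", paste0(" [", object@label, "]")),
              length(object@time),
              if (length(object@time)) min(object@time) else NA,
              if (length(object@time)) max(object@time) else NA))
})

#' EMGFit: fitted exponentially modified Gaussian peak model
#'
#' Result of a nonlinear least-squares fit of one or two EMG peaks plus a
#' linear baseline to a chromatogram.
#'
#' @slot peaks data.frame with one row per peak: `area`, `mu`, `sigma`, `tau`,
#'   `area_se`, `at_bounds`.
#' @slot baseline length-2 numeric `(intercept, slope)`.
#' @slot covariance parameter covariance matrix from the fit.
#' @slot residualNorm residual sum of squares.
#' @slot fitted fitted intensities on the chromatogram's time grid.
#' @exportClass EMGFit
setClass("EMGFit",
  representation(peaks = "data.frame", baseline = "numeric",
                 covariance = "matrix", residualNorm = "numeric",
                 fitted = "numeric"),
  validity = function(object) {
    need <- c("area", "mu", "sigma", "tau", "area_se")
    if (!all(need %in% names(object@peaks)))
      return("peaks must have columns area, mu, sigma, tau, area_se")
    if (any(object@peaks$sigma <= 0) || any(object@peaks$tau <= 0))
      return("sigma and tau must be positive")
    if (any(object@peaks$area_se < 0))
      return("area standard errors must be non-negative")
    if (nrow(object@covariance) &&
        max(abs(object@covariance - t(object@covariance))) > 1e-8 *
          (1 + max(abs(object@covariance))))
      return("covariance must be symmetric")
    TRUE
  })

setMethod("show", "EMGFit", function(object) {
  cat(sprintf("EMGFit: %d peak(s), RSS = %.4g\n", nrow(object@peaks),
              object@residualNorm))
  print(object@peaks, row.names = FALSE)
})

#' @rdname fitEmgPeaks
#' @param x an `EMGFit`.
#' @export
peakTable <- function(x) x@peaks

#' @rdname fitEmgPeaks
#' @export
peakAreas <- function(x) x@peaks$area

#' GenomeAnnotation: toy or real genome plus ORF annotation
#'
#' Contigs are held as a `DNAStringSet`; ORFs as a `GRanges` (1-based,
#' inclusive, stranded) with an `orf_id` metadata column. ORF lengths must be
#' divisible by 3 and lie within their contig. Ranges include the stop codon.
#'
#' @slot genome a `DNAStringSet` of contig sequences.
#' @slot orfs a `GRanges` of CDS ranges with `mcols()$orf_id`.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(genome = "DNAStringSet", orfs = "GRanges"),
  validity = function(object) {
    if (is.null(object@orfs$orf_id)) return("orfs need an orf_id column")
    if (anyDuplicated(object@orfs$orf_id)) return("orf_id must be unique")
    w <- GenomicRanges::width(object@orfs)
    if (any(w %% 3L != 0L)) return("ORF lengths must be divisible by 3")
    cl <- Biostrings::width(object@genome)[
      match(as.character(GenomicRanges::seqnames(object@orfs)),
            names(object@genome))]
    if (any(is.na(cl))) return("ORF contig not found in genome")
    if (any(GenomicRanges::start(object@orfs) < 1L) ||
        any(GenomicRanges::end(object@orfs) > cl))
      return("ORF outside contig bounds")
    if (any(as.character(GenomicRanges::strand(object@orfs)) == "*"))
      return("ORFs must be stranded")
    TRUE
  })

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d contig(s) (%s bp), %d ORF(s)\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ","),
              length(object@orfs)))
})

#' @rdname genomeAnnotation
#' @param x a `GenomeAnnotation`.
#' @export
annGenome <- function(x) x@genome

#' @rdname genomeAnnotation
#' @export
annOrfs <- function(x) x@orfs

#' DensityTrack: per-position footprint 3'-end density
#'
#' Strand-specific vectors of footprint 3'-end counts per genome position,
#' normalized to reads per million uniquely mapped footprints (RPM). Raw
#' counts and the total are retained so that count conservation and
#' re-normalization are exact.
#'
#' @slot counts list per contig of `list(plus=, minus=)` integer vectors.
#' @slot totalUnique total number of uniquely mapped footprints.
#' @exportClass DensityTrack
setClass("DensityTrack",
  representation(counts = "list", totalUnique = "numeric"),
  validity = function(object) {
    if (object@totalUnique <= 0) return("totalUnique must be positive")
    for (ct in object@counts) {
      if (!all(c("plus", "minus") %in% names(ct)))
        return("each contig needs plus and minus vectors")
      if (any(ct$plus < 0) || any(ct$minus < 0))
        return("counts must be non-negative")
    }
    TRUE
  })

setMethod("show", "DensityTrack", function(object) {
  cat(sprintf("DensityTrack: %d contig(s), %s uniquely mapped footprints\n",
              length(object@counts),
              format(object@totalUnique, big.mark = ",")))
})

#' @rdname densityTrack
#' @param x a `DensityTrack`.
#' @export
totalUnique <- function(x) x@totalUnique

#' RPM density vector for one contig/strand
#'
#' @param x a `DensityTrack`.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of RPM values, one per genome position (1-based).
#' @export
trackRpm <- function(x, contig, strand = c("+", "-")) {
  strand <- match.arg(strand)
  v <- x@counts[[contig]][[if (strand == "+") "plus" else "minus"]]
  if (is.null(v)) stop("unknown contig: ", contig)
  v * 1e6 / x@totalUnique
}

#' @rdname trackRpm
#' @export
trackCounts <- function(x, contig, strand = c("+", "-")) {
  strand <- match.arg(strand)
  v <- x@counts[[contig]][[if (strand == "+") "plus" else "minus"]]
  if (is.null(v)) stop("unknown contig: ", contig)
  v
}

#' OffsetCalibration: metagene-calibrated 3'-end to A-site offset
#'
#' @slot offset nucleotides from a footprint 3' end to the first nucleotide of
#'   the A-site codon (negative: the A site lies upstream of the 3' end).
#' @slot startProfile metagene 3'-end density aligned at start codons
#'   (names: distance from the start-codon first nucleotide).
#' @slot stopProfile metagene aligned at stop codons.
#' @slot candidates data.frame of candidate offsets and their metagene signal.
#' @exportClass OffsetCalibration
setClass("OffsetCalibration",
  representation(offset = "integer", startProfile = "numeric",
                 stopProfile = "numeric", candidates = "data.frame"),
  validity = function(object) {
    if (length(object@offset) != 1L || object@offset >= 0)
      return("offset must be a single negative integer")
    TRUE
  })

setMethod("show", "OffsetCalibration", function(object) {
  cat(sprintf("OffsetCalibration: 3'-end to A-site offset = %d nt\n",
              object@offset))
})

#' @rdname calibrateAsiteOffset
#' @param x an `OffsetCalibration`.
#' @export
asiteOffset <- function(x) x@offset
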