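#' Filter ORFs by length and footprint coverage
#'
#' An ORF is retained only if its length is at least `minLen` bp AND its mean
#' ribosome density per codon is at least `minDensityPerCodon`; violating
#' either criterion discards it. Because densities near the start and stop
#' codons are systematically biased, the mean is computed over the trimmed
#' region (first `trim5` and last `trim3` codons excluded) — the same region
#' later used to normalize pause scores.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param track a [DensityTrack-class].
#' @param minLen minimum ORF length in bp (default 170).
#' @param minDensityPerCodon minimum trimmed-region mean density per codon,
#'   in RPM (default 1).
#' @param trim5,trim3 codons trimmed from the 5' and 3' ends (defaults 15, 7).
#' @return data.frame with columns `orf_id`, `length_bp`,
#'   `mean_density_per_codon`, `retained`.
#' @export
filterOrfs <- function(ann, track, minLen = 170L, minDensityPerCodon = 1,
                       trim5 = 15L, trim3 = 7L) {
  orfs <- annOrfs(ann)
  res <- lapply(seq_along(orfs), function(i) {
    orf <- orfs[i]
    L <- GenomicRanges::width(orf)
    idx <- .trimIndices(L, trim5, trim3)
    dens <- if (length(idx)) {
      d <- .orfDensity(ann, track, orf)
      sum(d[idx]) / (length(idx) / 3)
    } else NA_real_
    data.frame(orf_id = orf$orf_id, length_bp = L,
               mean_density_per_codon = dens,
               retained = !is.na(dens) && L >= minLen &&
                 dens >= minDensityPerCodon,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-position pause scores for retained ORFs
#'
#' The pause score (PS) of a position is its footprint 3'-end density divided
#' by the mean density of its ORF over the trimmed region, so the trimmed-
#' region mean PS of every ORF is exactly 1 and scores are comparable across
#' ORFs regardless of expression level.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param track a [DensityTrack-class].
#' @param orfIds ORFs to score (typically the retained set from
#'   [filterOrfs]).
#' @param trim5,trim3 codons trimmed from the 5' and 3' ends.
#' @return data.frame with columns `orf_id`, `position` (1-based position
#'   within the CDS, transcription order), `codon` (the codon containing the
#'   position), `ps`.
#' @export
pauseScores <- function(ann, track, orfIds, trim5 = 15L, trim3 = 7L) {
  orfs <- annOrfs(ann)
  orfs <- orfs[match(orfIds, orfs$orf_id)]
  seqs <- orfSequences(ann)
  res <- lapply(seq_along(orfs), function(i) {
    orf <- orfs[i]
    L <- GenomicRanges::width(orf)
    idx <- .trimIndices(L, trim5, trim3)
    d <- .orfDensity(ann, track, orf)
    m <- mean(d[idx])
    if (!is.finite(m) || m <= 0) stop("zero trimmed-region density in ORF ",
                                      orf$orf_id, "; filter ORFs first")
    codon <- substring(seqs[[orf$orf_id]],
                       3L * ((idx - 1L) %/% 3L) + 1L,
                       3L * ((idx - 1L) %/% 3L) + 3L)
    data.frame(orf_id = orf$orf_id, position = idx, codon = codon,
               ps = d[idx] / m, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Calibrate the 3'-end to A-site offset from metagene profiles
#'
#' Builds average (metagene) 3'-end density profiles across retained ORFs
#' aligned at the start and at the stop codon, each ORF's densities first
#' normalized by its trimmed-region mean. Terminating ribosomes hold the stop
#' codon in the A site, so the dominant stop-proximal peak sits downstream of
#' the stop codon's first nucleotide by exactly the (negative of the) offset;
#' the candidate offset in `searchRange` whose metagene signal is largest is
#' returned, ties going to the most 3' candidate. A flat profile with no
#' unambiguous peak is a calibration failure (error class
#' `calibrationError`): supply the offset manually instead.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param track a [DensityTrack-class].
#' @param orfIds retained ORFs to average over (>= `minOrfs`).
#' @param searchRange candidate offsets, default `c(-20L, -6L)`.
#' @param minOrfs minimum number of ORFs required (default 50).
#' @param peakRatio required ratio of the winning candidate's signal to the
#'   median candidate signal (default 1.5).
#' @param trim5,trim3 codons trimmed when computing the per-ORF normalizer.
#' @return an [OffsetCalibration-class].
#' @export
calibrateAsiteOffset <- function(ann, track, orfIds,
                                 searchRange = c(-20L, -6L), minOrfs = 50L,
                                 peakRatio = 1.5, trim5 = 15L, trim3 = 7L) {
  if (length(orfIds) < minOrfs) {
    stop("A-site calibration needs at least ", minOrfs, " retained ORFs; got ",
         length(orfIds))
  }
  orfs <- annOrfs(ann)
  orfs <- orfs[match(orfIds, orfs$orf_id)]
  win <- 30L
  dists <- (-win):win
  startAcc <- stopAcc <- matrix(NA_real_, nrow = length(orfs),
                                ncol = length(dists))
  for (i in seq_along(orfs)) {
    orf <- orfs[i]
    L <- GenomicRanges::width(orf)
    d <- .orfDensity(ann, track, orf, flank5 = win, flank3 = win)
    idx <- .trimIndices(L, trim5, trim3)
    m <- mean(d[win + idx], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) next
    norm <- d / m
    ## start-codon first nt is transcript position 1 -> index win + 1
    startAcc[i, ] <- norm[win + 1L + dists]
    ## stop-codon first nt is transcript position L - 2
    stopAcc[i, ] <- norm[win + (L - 2L) + dists]
  }
  startProfile <- colMeans(startAcc, na.rm = TRUE)
  stopProfile <- colMeans(stopAcc, na.rm = TRUE)
  names(startProfile) <- names(stopProfile) <- dists

  candOffsets <- seq(searchRange[1], searchRange[2])
  candDist <- -candOffsets  # peak lies downstream of the stop by |offset|
  signal <- stopProfile[as.character(candDist)]
  candidates <- data.frame(offset = candOffsets, distance = candDist,
                           signal = as.numeric(signal))
  med <- stats::median(candidates$signal, na.rm = TRUE)
  best <- which(candidates$signal == max(candidates$signal, na.rm = TRUE))
  best <- best[which.max(candidates$distance[best])]  # most 3' wins ties
  if (!is.finite(candidates$signal[best]) || candidates$signal[best] <= 0 ||
      (is.finite(med) && med > 0 &&
         candidates$signal[best] < peakRatio * med)) {
    stop(structure(class = c("calibrationError", "error", "condition"),
                   list(message = paste0(
                     "no unambiguous stop-proximal metagene peak; ",
                     "supply the offset manually"),
                     call = sys.call(), candidates = candidates)))
  }
  new("OffsetCalibration", offset = as.integer(candidates$offset[best]),
      startProfile = startProfile, stopProfile = stopProfile,
      candidates = candidates)
}

#' Mean pause scores per codon (or amino acid) at a ribosomal site
#'
#' For each ORF and codon type, the pause scores on all nucleotides
#' attributable to in-frame occurrences of that codon at the queried
#' ribosomal site are averaged; the per-ORF values are then averaged,
#' unweighted, across all ORFs with at least one occurrence. A footprint
#' 3' end at position p reports on a ribosome whose A-site codon starts at
#' p + offset; the codon in the P site is one codon (3 nt) upstream of the
#' A-site codon, the E-site codon two codons upstream. The amino-acid view
#' pools codons by translation before the per-ORF average.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param track a [DensityTrack-class].
#' @param orfIds retained ORFs.
#' @param offset calibrated 3'-end-to-A-site offset (negative integer) or an
#'   [OffsetCalibration-class].
#' @param site ribosomal site, `"A"`, `"P"` or `"E"`.
#' @param level `"codon"` (61 sense codons) or `"amino_acid"`.
#' @param trim5,trim3 codons trimmed from each ORF.
#' @return data.frame with columns `codon` (or `amino_acid`), `amino_acid`
#'   (codon level only), `site`, `mps`, `n_orfs`. Codon types never observed
#'   in any ORF have `mps = NA` and `n_orfs = 0`.
#' @export
codonMps <- function(ann, track, orfIds, offset, site = c("A", "P", "E"),
                     level = c("codon", "amino_acid"),
                     trim5 = 15L, trim3 = 7L) {
  site <- match.arg(site)
  level <- match.arg(level)
  if (is(offset, "OffsetCalibration")) offset <- asiteOffset(offset)
  offset <- as.integer(offset)
  if (offset >= 0) stop("offset must be negative (A site upstream of 3' end)")
  shift <- c(A = 0L, P = 3L, E = 6L)[[site]]

  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  orfs <- annOrfs(ann)
  orfs <- orfs[match(orfIds, orfs$orf_id)]
  seqs <- orfSequences(ann)

  keys <- if (level == "codon") sense else sort(unique(gc[sense]))
  sums <- counts <- matrix(0, nrow = length(orfs), ncol = length(keys),
                           dimnames = list(NULL, keys))
  flank3 <- -offset + shift + 2L
  for (i in seq_along(orfs)) {
    orf <- orfs[i]
    L <- GenomicRanges::width(orf)
    ncod <- L %/% 3L
    d <- .orfDensity(ann, track, orf, flank3 = flank3)
    idx <- .trimIndices(L, trim5, trim3)
    m <- mean(d[idx])
    if (!is.finite(m) || m <= 0) next
    if (trim5 + 1L > ncod - trim3) next
    jset <- seq(trim5 + 1L, ncod - trim3)
    cstart <- 3L * (jset - 1L) + 1L
    cods <- substring(seqs[[orf$orf_id]], cstart, cstart + 2L)
    keep <- cods %in% sense
    jset <- jset[keep]; cstart <- cstart[keep]; cods <- cods[keep]
    ## nucleotides attributed to codon j at this site: the three positions
    ## whose footprints have their A site shifted nt downstream of codon j
    p0 <- cstart + shift - offset
    ps <- (d[p0] + d[p0 + 1L] + d[p0 + 2L]) / (3 * m)
    ok <- is.finite(ps)
    key <- if (level == "codon") cods else unname(gc[cods])
    agg <- tapply(ps[ok], key[ok], mean)
    sums[i, names(agg)] <- unlist(agg)
    counts[i, names(agg)] <- 1
  }
  mps <- ifelse(colSums(counts) > 0,
                colSums(sums) / pmax(colSums(counts), 1), NA_real_)
  if (level == "codon") {
    data.frame(codon = keys, amino_acid = unname(gc[keys]), site = site,
               mps = as.numeric(mps), n_orfs = as.integer(colSums(counts)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(amino_acid = keys, site = site, mps = as.numeric(mps),
               n_orfs = as.integer(colSums(counts)), stringsAsFactors = FALSE)
  }
}

#' MPS matrix over the A, P and E sites
#'
#' Convenience wrapper running [codonMps] for all three sites.
#'
#' @inheritParams codonMps
#' @return data.frame stacking the three per-site tables.
#' @export
mpsMatrix <- function(ann, track, orfIds, offset, level = c("codon", "amino_acid"),
                      trim5 = 15L, trim3 = 7L) {
  level <- match.arg(level)
  do.call(rbind, lapply(c("A", "P", "E"), function(s)
    codonMps(ann, track, orfIds, offset, s, level, trim5, trim3)))
}

#' Decile occupancy profile along ORFs
#'
#' Each coding region's codons are partitioned into `nBins` contiguous,
#' near-equal bins from 5' to 3' (earlier bins take the remainder); the
#' fraction of the ORF's footprints per bin is computed with a 0.5-read
#' pseudocount per bin (so the geometric mean is defined for empty bins),
#' and the cross-ORF geometric mean per bin is reported.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param track a [DensityTrack-class].
#' @param orfIds retained ORFs.
#' @param nBins number of bins (default 10).
#' @return data.frame with columns `bin`, `geom_mean_fraction`; the per-ORF
#'   fraction matrix is attached as `attr(, "fractions")`.
#' @export
binProfile <- function(ann, track, orfIds, nBins = 10L) {
  orfs <- annOrfs(ann)
  orfs <- orfs[match(orfIds, orfs$orf_id)]
  fracs <- matrix(NA_real_, nrow = length(orfs), ncol = nBins,
                  dimnames = list(orfIds, NULL))
  for (i in seq_along(orfs)) {
    orf <- orfs[i]
    ncod <- GenomicRanges::width(orf) %/% 3L
    if (ncod < nBins) stop("ORF ", orf$orf_id, " has fewer codons than bins")
    d <- .orfDensity(ann, track, orf, scale = "counts")
    percodon <- d[seq(1, 3 * ncod, by = 3)] + d[seq(2, 3 * ncod, by = 3)] +
      d[seq(3, 3 * ncod, by = 3)]
    base <- ncod %/% nBins; extra <- ncod %% nBins
    sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
    binid <- rep(seq_len(nBins), sizes)
    cnt <- tapply(percodon, binid, sum) + 0.5
    fracs[i, ] <- cnt / sum(cnt)
  }
  out <- data.frame(bin = seq_len(nBins),
                    geom_mean_fraction = exp(colMeans(log(fracs), na.rm = TRUE)))
  attr(out, "fractions") <- fracs
  out
}

#' Contrast MPS matrices between two conditions
#'
#' Joins toxin and control MPS tables on codon (or amino acid) and site, and
#' reports the toxin/control ratio. Cells missing in either condition stay
#' missing (never infinite).
#'
#' @param toxin,control data.frames from [codonMps] or [mpsMatrix] over the
#'   same codon set.
#' @return joined data.frame with `mps_toxin`, `mps_control`, `ratio`.
#' @export
mpsContrast <- function(toxin, control) {
  keyBy <- intersect(intersect(names(toxin), names(control)),
                     c("codon", "amino_acid", "site"))
  if ("codon" %in% keyBy) keyBy <- setdiff(keyBy, "amino_acid")
  if (!length(keyBy)) stop("tables share no codon/amino-acid key columns")
  a <- toxin[c(keyBy, "mps")]; names(a)[ncol(a)] <- "mps_toxin"
  b <- control[c(keyBy, "mps")]; names(b)[ncol(b)] <- "mps_control"
  m <- merge(a, b, by = keyBy)
  if (nrow(m) == 0) stop("toxin and control tables share no codon/site cells")
  m$ratio <- m$mps_toxin / m$mps_control
  m
}

#' Run the full pause-score pipeline
#'
#' Alignment file to MPS matrices in one call: load and filter alignments,
#' build the RPM density track, filter ORFs, calibrate the A-site offset (or
#' accept a manual one), and compute pause scores, MPS matrices for the A, P
#' and E sites, and the decile occupancy profile.
#'
#' @param alignments path to a BAM/SAM file, or a data.frame from
#'   [loadAlignments].
#' @param ann a [GenomeAnnotation-class], or `list(fasta=, annot=)` paths.
#' @param offset `"auto"` to calibrate from the data or a negative integer.
#' @param minLen,minDensityPerCodon ORF filter thresholds.
#' @param trim5,trim3 codons trimmed per ORF.
#' @param minLenRead,maxLenRead accepted footprint lengths.
#' @param outDir optional directory; when given, writes `pause_scores.tsv`,
#'   `mps.tsv`, `bin_profile.tsv`, `calibration.json` and bedGraph tracks.
#' @return list with `track`, `filter`, `retained`, `calibration`, `offset`,
#'   `pauseScores`, `mps`, `binProfile`.
#' @export
runPausePipeline <- function(alignments, ann, offset = "auto",
                             minLen = 170L, minDensityPerCodon = 1,
                             trim5 = 15L, trim3 = 7L,
                             minLenRead = 15L, maxLenRead = 40L,
                             outDir = NULL) {
  if (is.character(ann) || is.list(ann) && !is(ann, "GenomeAnnotation")) {
    ann <- readGenomeAnnotation(ann$fasta, ann$annot)
  }
  if (is.character(alignments)) {
    alignments <- loadAlignments(alignments, minLenRead, maxLenRead)
  }
  track <- densityTrack(alignments, ann)
  filt <- filterOrfs(ann, track, minLen, minDensityPerCodon, trim5, trim3)
  retained <- filt$orf_id[filt$retained]
  if (!length(retained)) stop("no ORFs pass the length/density filters")
  calibration <- NULL
  if (identical(offset, "auto")) {
    calibration <- calibrateAsiteOffset(ann, track, retained,
                                        trim5 = trim5, trim3 = trim3)
    offset <- asiteOffset(calibration)
  }
  ps <- pauseScores(ann, track, retained, trim5, trim3)
  mps <- mpsMatrix(ann, track, retained, offset, "codon", trim5, trim3)
  bp <- binProfile(ann, track, retained)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ps, file.path(outDir, "pause_scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(mps, file.path(outDir, "mps.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(bp, file.path(outDir, "bin_profile.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(offset = offset,
                              calibrated = !is.null(calibration)),
                         file.path(outDir, "calibration.json"),
                         auto_unbox = TRUE)
    exportDensityBedGraph(track, file.path(outDir, "density"))
  }
  list(track = track, filter = filt, retained = retained,
       calibration = calibration, offset = offset, pauseScores = ps,
       mps = mps, binProfile = bp)
}
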