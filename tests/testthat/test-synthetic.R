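test_that("generated genomes are deterministic, in-frame and honor usage weights", {
  spec <- riboSimSpec(nOrfs = 25, orfLengthCodons = 60, seed = 1)
  ann1 <- genGenome(spec)
  ann2 <- genGenome(spec)
  expect_identical(as.character(annGenome(ann1)), as.character(annGenome(ann2)))

  # every ORF translates without internal stops
  seqs <- orfSequences(ann1)
  gc <- Biostrings::GENETIC_CODE
  for (s in seqs) {
    ncod <- nchar(s) / 3
    cods <- substring(s, 3 * (seq_len(ncod) - 1) + 1, 3 * (seq_len(ncod) - 1) + 3)
    expect_equal(cods[1], "ATG")
    expect_true(gc[cods[ncod]] == "*")
    expect_false(any(gc[cods[-ncod]] == "*"))
  }

  # zero usage weight removes a codon from every ORF body
  w <- setNames(rep(1, 61), names(gc)[gc != "*"])
  w["GGA"] <- 0
  specW <- riboSimSpec(nOrfs = 25, orfLengthCodons = 60, codonWeights = w,
                       seed = 2)
  seqsW <- orfSequences(genGenome(specW))
  for (s in seqsW) {
    ncod <- nchar(s) / 3
    cods <- substring(s, 3 * (seq_len(ncod) - 1) + 1, 3 * (seq_len(ncod) - 1) + 3)
    expect_false("GGA" %in% cods)
  }
  expect_error(riboSimSpec(seed = 1, offset = -25L), "offset")
  expect_error(riboSimSpec(nOrfs = 5), "seed")
})

test_that("footprint simulation is seed-deterministic and round-trips through BAM", {
  spec <- riboSimSpec(nOrfs = 20, orfLengthCodons = 80, depth = 2e4, seed = 3)
  ann <- genGenome(spec)
  s1 <- simulateFootprints(ann, spec)
  s2 <- simulateFootprints(ann, spec)
  expect_identical(s1$alignments, s2$alignments)

  d <- tempfile()
  s3 <- simulateFootprints(ann, spec, dir = d)
  expect_true(file.exists(s3$bam))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  back <- loadAlignments(s3$bam)
  key <- function(df) df[order(df$pos3, df$strand, df$length),
                         c("contig", "strand", "pos3", "length")]
  expect_equal(key(back), key(s3$alignments), ignore_attr = TRUE)
})

test_that("realized dwell matches the specified multiplier at depth", {
  spec <- riboSimSpec(nOrfs = 40, orfLengthCodons = 150, depth = 1e6,
                      stall = c(GGA = 4), seed = 19)
  ann <- genGenome(spec)
  sim <- simulateFootprints(ann, spec)
  aln <- sim$alignments
  # map each read back to its A-site codon and compare per-codon read share
  # to codon frequency, within one well-covered ORF
  orfs <- annOrfs(ann)
  seqs <- orfSequences(ann)
  i <- which.max(sim$groundTruth$readsPerOrf)
  orf <- orfs[i]
  st <- as.character(GenomicRanges::strand(orf))
  sub <- aln[aln$strand == st &
               (if (st == "+")
                 aln$pos3 >= GenomicRanges::start(orf) &
                   aln$pos3 <= GenomicRanges::end(orf) + 20
                else aln$pos3 >= GenomicRanges::start(orf) - 20 &
                   aln$pos3 <= GenomicRanges::end(orf)), ]
  tp <- if (st == "+") sub$pos3 - GenomicRanges::start(orf) + 1 else
    GenomicRanges::end(orf) - sub$pos3 + 1
  j <- (tp - 11 - 1) %/% 3 + 1   # A-site codon index (offset -11)
  ncod <- GenomicRanges::width(orf) / 3
  cods <- substring(seqs[[orf$orf_id]], 3 * (seq_len(ncod) - 1) + 1,
                    3 * (seq_len(ncod) - 1) + 3)
  body <- j >= 2 & j < ncod       # exclude terminal-dwell stop codon
  isGga <- cods[j[body]] == "GGA"
  nGgaCodons <- sum(cods[2:(ncod - 1)] == "GGA")
  nOther <- (ncod - 2) - nGgaCodons
  readsPerGga <- sum(isGga) / nGgaCodons
  readsPerOther <- sum(!isGga) / nOther
  expect_equal(readsPerGga / readsPerOther, 4, tolerance = 0.05)
})

test_that("LC/MS simulation is deterministic and exact when noiseless", {
  spec0 <- lcmsSimSpec(aminoAcids = c("G", "E"), trueFractions = 0.5,
                       trueRrf = 2, noiseCV = 0, seed = 5)
  sim0 <- simulateLcms(spec0)
  q0 <- quantifyFractions(sim0$areas, sim0$rrfTable)
  expect_equal(q0$fraction, c(0.5, 0.5))
  expect_equal(sim0$rrfTable$rrf, c(2, 2))

  spec1 <- lcmsSimSpec(seed = 8)
  expect_identical(simulateLcms(spec1)$areas, simulateLcms(spec1)$areas)
  expect_error(lcmsSimSpec(noiseCV = -0.1, seed = 1), "CV")
})

test_that("rendered chromatograms round-trip and deconvolve to the true ratio", {
  spec <- lcmsSimSpec(aminoAcids = c("L", "I"),
                      trueFractions = c(L = 0.6, I = 0.3),
                      trueRrf = 1.5, noiseCV = 0, seed = 12)
  d <- tempfile()
  sim <- simulateLcms(spec, dir = d, renderChromatograms = TRUE)
  # the isobaric pair shares one trace per derivative
  expect_true(all(c("acetyl_LI", "fmoc_LI") %in% names(sim$chromatograms)))
  back <- readChromatogramCsv(file.path(d, "acetyl_LI.csv"))
  expect_equal(chromIntensity(back),
               chromIntensity(sim$chromatograms$acetyl_LI), tolerance = 1e-10)

  fit <- fitEmgPeaks(sim$chromatograms$acetyl_LI, 2)
  pk <- peakTable(fit)
  trueL <- sim$areas$area[sim$areas$amino_acid == "L" &
                            sim$areas$derivative == "acetyl"]
  trueI <- sim$areas$area[sim$areas$amino_acid == "I" &
                            sim$areas$derivative == "acetyl"]
  expect_equal(pk$area[1] / pk$area[2], trueL / trueI, tolerance = 0.07)
})
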