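test_that("alignment loading filters by length/MAPQ and takes the right 3' ends", {
  sam <- writeTinySam(tempfile(fileext = ".sam"))
  aln <- loadAlignments(sam)
  expect_equal(nrow(aln), 2)  # r3 too short, r4 too long, r5 low MAPQ
  plus <- aln[aln$strand == "+", ]
  minus <- aln[aln$strand == "-", ]
  expect_equal(plus$pos3, 130)   # rightmost aligned base
  expect_equal(minus$pos3, 101)  # leftmost aligned base
  # relaxing uniqueness brings the MAPQ-3 read back
  expect_equal(nrow(loadAlignments(sam, uniqueOnly = FALSE)), 3)
})

test_that("density tracks are RPM-normalized and conserve counts", {
  ann <- nullSim$ann
  aln <- nullSim$sim$alignments
  track <- nullSim$track
  expect_equal(totalUnique(track), nrow(aln))
  total <- sum(trackCounts(track, "toy_contig_1", "+")) +
    sum(trackCounts(track, "toy_contig_1", "-"))
  expect_equal(total, nrow(aln))
  # RPM definition at a single position
  p <- aln$pos3[aln$strand == "+"][1]
  cnt <- sum(aln$pos3 == p & aln$strand == "+")
  expect_equal(trackRpm(track, "toy_contig_1", "+")[p],
               cnt * 1e6 / nrow(aln))
  # duplicating every read leaves RPM unchanged
  track2 <- densityTrack(rbind(aln, aln), ann)
  expect_equal(trackRpm(track2, "toy_contig_1", "+"),
               trackRpm(track, "toy_contig_1", "+"))
  expect_error(densityTrack(aln[0, ], ann), "no uniquely mapped")
})

test_that("ORF filtering needs both sufficient length and coverage", {
  set.seed(10)
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  mkOrf <- function(ncod) paste0("ATG", paste(rep("GCT", ncod - 2), collapse = ""), "TAA")
  # 168 bp (56 codons), and two 300 bp (100 codons) ORFs
  s1 <- mkOrf(56); s2 <- mkOrf(100); s3 <- mkOrf(100)
  genome <- Biostrings::DNAStringSet(paste0(
    substr(contig, 1, 100), s1, substr(contig, 1, 100), s2,
    substr(contig, 1, 100), s3, substr(contig, 1, 100)))
  names(genome) <- "c1"
  starts <- c(101, 101 + 168 + 100, 101 + 168 + 100 + 300 + 100)
  orfs <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(starts, width = c(168, 300, 300)), strand = "+",
    orf_id = c("short", "uncovered", "covered"))
  ann <- genomeAnnotation(genome, orfs, validateCodons = TRUE)
  # cover "short" and "covered" densely; leave "uncovered" empty
  pos <- c(outer(seq(starts[1] + 45, starts[1] + 168 - 22, by = 3), 0:4 * 0, `+`),
           rep(seq(starts[3] + 45, starts[3] + 300 - 22, by = 3), each = 5))
  aln <- data.frame(contig = "c1", strand = "+", pos3 = as.integer(pos),
                    length = 30L)
  track <- densityTrack(aln, ann)
  filt <- filterOrfs(ann, track)
  expect_false(filt$retained[filt$orf_id == "short"])      # 168 < 170 bp
  expect_false(filt$retained[filt$orf_id == "uncovered"])  # zero density
  expect_true(filt$retained[filt$orf_id == "covered"])
  expect_equal(filt$mean_density_per_codon[filt$orf_id == "uncovered"], 0)
})

test_that("pause scores are density over trimmed-region mean, mean exactly 1", {
  ps <- pauseScores(nullSim$ann, nullSim$track, nullSim$retained)
  means <- tapply(ps$ps, ps$orf_id, mean)
  expect_true(all(abs(means - 1) < 1e-9))

  # closed form: one position at 10x the mean of the others
  orf <- annOrfs(nullSim$ann)[match(nullSim$retained[1],
                                    annOrfs(nullSim$ann)$orf_id)]
  L <- GenomicRanges::width(orf)
  idx <- (15 * 3 + 1):(L - 7 * 3)
  n <- length(idx)
  # synthetic track: 1 read at every trimmed position, 10 at the first
  st <- as.character(GenomicRanges::strand(orf))
  gpos <- if (st == "+") GenomicRanges::start(orf) + idx - 1 else
    GenomicRanges::end(orf) - idx + 1
  aln <- data.frame(contig = "toy_contig_1", strand = st,
                    pos3 = rep(gpos, c(10, rep(1, n - 1))), length = 30L)
  tr <- densityTrack(aln, nullSim$ann)
  ps1 <- pauseScores(nullSim$ann, tr, orf$orf_id)
  expect_equal(max(ps1$ps), 10 * n / (n + 9), tolerance = 1e-9)
  # scaling all densities leaves PS unchanged (RPM + ratio are scale-free)
  tr2 <- densityTrack(rbind(aln, aln, aln), nullSim$ann)
  expect_equal(pauseScores(nullSim$ann, tr2, orf$orf_id)$ps, ps1$ps)
})

test_that("A-site offset calibration recovers simulated offsets exactly", {
  cal <- calibrateAsiteOffset(nullSim$ann, nullSim$track, nullSim$retained)
  expect_s4_class(cal, "OffsetCalibration")
  expect_identical(asiteOffset(cal), -11L)

  spec14 <- riboSimSpec(nOrfs = 55, orfLengthCodons = 110, depth = 1.2e5,
                        offset = -14L, seed = 21)
  ann14 <- genGenome(spec14)
  sim14 <- simulateFootprints(ann14, spec14)
  tr14 <- densityTrack(sim14$alignments, ann14)
  f14 <- filterOrfs(ann14, tr14)
  cal14 <- calibrateAsiteOffset(ann14, tr14, f14$orf_id[f14$retained])
  expect_identical(asiteOffset(cal14), -14L)

  # flat coverage has no stop-proximal peak
  lenC <- Biostrings::width(annGenome(nullSim$ann))[1]
  flat <- data.frame(contig = "toy_contig_1", strand = "+",
                     pos3 = seq_len(lenC), length = 30L)
  trFlat <- densityTrack(flat, nullSim$ann)
  plusIds <- annOrfs(nullSim$ann)$orf_id[
    as.character(GenomicRanges::strand(annOrfs(nullSim$ann))) == "+"]
  expect_error(
    calibrateAsiteOffset(nullSim$ann, trFlat, plusIds, minOrfs = 1),
    class = "calibrationError")
  expect_error(calibrateAsiteOffset(nullSim$ann, nullSim$track,
                                    nullSim$retained[1:3]), "at least")
})

test_that("codon MPS matches a naive re-implementation of its definition", {
  ann <- nullSim$ann; track <- nullSim$track
  ids <- nullSim$retained[1:10]
  got <- codonMps(ann, track, ids, -11L, "A")

  # independent brute force over the same definition
  seqs <- orfSequences(ann)
  orfs <- annOrfs(ann)
  perOrf <- list()
  for (id in ids) {
    orf <- orfs[match(id, orfs$orf_id)]
    L <- GenomicRanges::width(orf)
    st <- as.character(GenomicRanges::strand(orf))
    rpm <- trackRpm(track, "toy_contig_1", st)
    tpos2g <- function(tp) if (st == "+") GenomicRanges::start(orf) + tp - 1 else
      GenomicRanges::end(orf) - tp + 1
    dAll <- rpm[tpos2g(seq_len(L + 20))]
    m <- mean(dAll[(15 * 3 + 1):(L - 21)])
    vals <- list()
    for (j in 16:(L / 3 - 7)) {
      cod <- substr(seqs[[id]], 3 * (j - 1) + 1, 3 * (j - 1) + 3)
      p <- 3 * (j - 1) + 1 + 11
      vals[[cod]] <- c(vals[[cod]], mean(dAll[p:(p + 2)]) / m)
    }
    perOrf[[id]] <- vapply(vals, mean, numeric(1))
  }
  for (cod in got$codon) {
    ex <- unlist(lapply(perOrf, function(v)
      if (cod %in% names(v)) v[[cod]] else NULL))
    if (length(ex) == 0) {
      expect_true(is.na(got$mps[got$codon == cod]))
    } else {
      expect_equal(got$mps[got$codon == cod], mean(unlist(ex)),
                   tolerance = 1e-9, label = cod)
    }
  }
})

test_that("stall-free simulations give consistent A/P/E MPS near 1", {
  m <- mpsMatrix(nullSim$ann, nullSim$track, nullSim$retained, -11L)
  for (s in c("A", "P", "E")) {
    ms <- m$mps[m$site == s]
    expect_true(all(abs(ms[!is.na(ms)] - 1) < 0.15))
  }
  # the three sites agree within sampling error on the same codons
  wide <- reshape(m[, c("codon", "site", "mps")], idvar = "codon",
                  timevar = "site", direction = "wide")
  expect_lt(max(abs(wide$mps.A - wide$mps.P), na.rm = TRUE), 0.2)
})

test_that("injected stalls give A-site-specific, dwell-monotone MPS", {
  prev <- -Inf
  for (k in c(2, 4, 8)) {
    spec <- riboSimSpec(nOrfs = 60, orfLengthCodons = 120, depth = 1e5,
                        stall = c(GGA = k), seed = 13)
    ann <- genGenome(spec)
    sim <- simulateFootprints(ann, spec)
    tr <- densityTrack(sim$alignments, ann)
    f <- filterOrfs(ann, tr)
    m <- codonMps(ann, tr, f$orf_id[f$retained], -11L, "A")
    gga <- m$mps[m$codon == "GGA"]
    expect_gt(gga, max(m$mps[m$codon != "GGA"], na.rm = TRUE))
    expect_gt(gga, prev)
    prev <- gga
  }
})

test_that("MPS is invariant under reverse-complementing the world", {
  flip <- flipWorld(nullSim$ann, nullSim$sim$alignments)
  trF <- densityTrack(flip$alignments, flip$ann)
  m1 <- codonMps(nullSim$ann, nullSim$track, nullSim$retained, -11L, "A")
  m2 <- codonMps(flip$ann, trF, nullSim$retained, -11L, "A")
  expect_equal(m1$mps, m2$mps)
})

test_that("decile profiles are flat for uniform coverage and front-loaded reads show up", {
  # truly uniform coverage of every CDS position: every bin holds 1/10
  ids <- nullSim$retained[1:20]
  orfs <- annOrfs(nullSim$ann)[match(ids, annOrfs(nullSim$ann)$orf_id)]
  alnU <- do.call(rbind, lapply(seq_along(orfs), function(i) {
    o <- orfs[i]
    data.frame(contig = "toy_contig_1",
               strand = as.character(GenomicRanges::strand(o)),
               pos3 = seq(GenomicRanges::start(o), GenomicRanges::end(o)),
               length = 30L)
  }))
  trU <- densityTrack(alnU, nullSim$ann)
  bp <- binProfile(nullSim$ann, trU, ids)
  expect_equal(nrow(bp), 10)
  expect_equal(bp$geom_mean_fraction, rep(0.1, 10), tolerance = 1e-3)
  fr <- attr(bp, "fractions")
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # permuting ORF order leaves the geometric means unchanged
  bp2 <- binProfile(nullSim$ann, trU, rev(ids))
  expect_equal(bp2$geom_mean_fraction, bp$geom_mean_fraction)

  # all reads in the first decile of one ORF
  orf <- orfs[1]
  st <- as.character(GenomicRanges::strand(orf))
  g <- if (st == "+") GenomicRanges::start(orf) + 9 else
    GenomicRanges::end(orf) - 9
  aln1 <- data.frame(contig = "toy_contig_1", strand = st,
                     pos3 = rep(as.integer(g), 1000), length = 30L)
  bp1 <- binProfile(nullSim$ann, densityTrack(aln1, nullSim$ann),
                    orf$orf_id)
  expect_gt(bp1$geom_mean_fraction[1], 0.9)
  expect_error(binProfile(nullSim$ann, trU, ids, nBins = 1000L),
               "fewer codons")
})

test_that("MPS contrast joins conditions and propagates missing cells", {
  m <- data.frame(codon = c("GGA", "GGC"), amino_acid = "G", site = "A",
                  mps = c(6, 1.2), n_orfs = 10L)
  ctrl <- data.frame(codon = c("GGA", "GGC"), amino_acid = "G", site = "A",
                     mps = c(1.2, NA), n_orfs = 10L)
  cc <- mpsContrast(m, ctrl)
  expect_equal(cc$ratio[cc$codon == "GGA"], 5)
  expect_true(is.na(cc$ratio[cc$codon == "GGC"]))
  same <- mpsContrast(m, m)
  expect_equal(same$ratio, c(1, 1))
  expect_error(mpsContrast(m, data.frame(codon = "TTT", site = "P", mps = 1)),
               "share no")
})

test_that("the one-call pipeline runs from a BAM and writes its outputs", {
  spec <- riboSimSpec(nOrfs = 55, orfLengthCodons = 90, depth = 6e4, seed = 31)
  ann <- genGenome(spec)
  d <- tempfile()
  sim <- simulateFootprints(ann, spec, dir = d)
  out <- tempfile()
  res <- runPausePipeline(sim$bam, ann, offset = "auto", outDir = out)
  expect_identical(res$offset, -11L)
  expect_true(all(file.exists(file.path(out,
    c("pause_scores.tsv", "mps.tsv", "bin_profile.tsv", "calibration.json")))))
  expect_true(any(grepl("bedgraph", list.files(out))))
  expect_equal(sort(unique(res$mps$site)), c("A", "E", "P"))
})
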