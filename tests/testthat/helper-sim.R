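# Shared fixtures, built in code. The small footprint simulation is reused
# across ribo-seq tests; heavier study-scale runs live in test-acceptance.R.

aaCodes <- c("G", "A", "S", "T", "V", "I", "L", "E", "K")

# a small stall-free library for null-behaviour checks
nullSim <- local({
  spec <- riboSimSpec(nOrfs = 60, orfLengthCodons = 120, depth = 2e5, seed = 7)
  ann <- genGenome(spec)
  sim <- simulateFootprints(ann, spec)
  track <- densityTrack(sim$alignments, ann)
  filt <- filterOrfs(ann, track)
  list(spec = spec, ann = ann, sim = sim, track = track, filt = filt,
       retained = filt$orf_id[filt$retained])
})

# reverse-complement an annotation plus its alignments (for strand symmetry)
flipWorld <- function(ann, alignments) {
  g <- annGenome(ann)
  L <- Biostrings::width(g)[1]
  g2 <- Biostrings::DNAStringSet(Biostrings::reverseComplement(g[[1]]))
  names(g2) <- names(g)
  o <- annOrfs(ann)
  o2 <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(o),
    IRanges::IRanges(L + 1 - GenomicRanges::end(o),
                     L + 1 - GenomicRanges::start(o)),
    strand = ifelse(as.character(GenomicRanges::strand(o)) == "+", "-", "+"),
    orf_id = o$orf_id)
  al2 <- alignments
  al2$pos3 <- L + 1 - al2$pos3
  al2$strand <- ifelse(al2$strand == "+", "-", "+")
  list(ann = genomeAnnotation(g2, o2), alignments = al2)
}

# hand-rolled SAM text for alignment-loading tests
writeTinySam <- function(path, contigLen = 500) {
  lines <- c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:chr1\tLN:%d", contigLen),
    # + strand, span [101,130] 1-based, len 30 -> 3' end 130
    "r1\t0\tchr1\t101\t42\t30M\t*\t0\t0\t*\t*",
    # - strand, span [101,130], len 30 -> 3' end 101
    "r2\t16\tchr1\t101\t42\t30M\t*\t0\t0\t*\t*",
    # too short (14 nt)
    "r3\t0\tchr1\t201\t42\t14M\t*\t0\t0\t*\t*",
    # too long (41 nt)
    "r4\t0\tchr1\t201\t42\t41M\t*\t0\t0\t*\t*",
    # low MAPQ (multi-mapper proxy)
    "r5\t0\tchr1\t301\t3\t30M\t*\t0\t0\t*\t*"
  )
  writeLines(lines, path)
  path
}
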