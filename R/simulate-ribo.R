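#' Specification for a synthetic ribosome-profiling experiment
#'
#' Bundles the ground-truth parameters for [genGenome] and
#' [simulateFootprints]: a toy genome of non-overlapping ORFs, per-codon
#' dwell times with optional codon-specific stalls in the A site, a 3'-end
#' offset (fixed or a small discrete distribution), and sequencing depth.
#'
#' @param nOrfs number of ORFs (default 100).
#' @param orfLengthCodons ORF length in codons including start and stop; a
#'   scalar for fixed lengths or a vector to sample from (default 200).
#' @param codonWeights named non-negative usage weights over the 61 sense
#'   codons for ORF bodies (default uniform). Missing codons get weight 0.
#' @param stall named numeric vector: codon -> dwell multiplier (>= 1)
#'   applied when that codon is in the ribosomal A site, e.g. `c(GGA = 8)`.
#' @param offset 3'-end to A-site offset: a single negative integer in
#'   \[-20, -6\], or a named probability vector over such offsets.
#' @param depth number of footprints to simulate (default 1e6).
#' @param readLengths footprint lengths to draw uniformly from, within
#'   15-40 nt (default 24:32).
#' @param expressionCV coefficient of variation of the log-normal per-ORF
#'   expression weights (default 1).
#' @param terminalDwell dwell multiplier at the stop codon, emulating slow
#'   termination; this puts the stop-proximal metagene peak in place for
#'   A-site calibration (default 3).
#' @param spacer intergenic spacer length in nt (default 60).
#' @param seed mandatory RNG seed.
#' @return a `RiboSimSpec` (validated list).
#' @export
riboSimSpec <- function(nOrfs = 100L, orfLengthCodons = 200L,
                        codonWeights = NULL, stall = c(),
                        offset = -11L, depth = 1e6, readLengths = 24:32,
                        expressionCV = 1, terminalDwell = 3,
                        spacer = 60L, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  if (is.null(codonWeights)) {
    codonWeights <- stats::setNames(rep(1, length(sense)), sense)
  }
  w <- stats::setNames(numeric(length(sense)), sense)
  w[intersect(names(codonWeights), sense)] <-
    codonWeights[intersect(names(codonWeights), sense)]
  if (any(w < 0) || sum(w) <= 0) stop("codon weights must be >= 0, not all 0")
  if (length(stall) && (is.null(names(stall)) || any(stall < 1)))
    stop("stall must be a named vector of dwell multipliers >= 1")
  offs <- if (length(offset) > 1L) as.integer(names(offset)) else as.integer(offset)
  if (any(offs < -20L | offs > -6L)) stop("offset(s) must lie in [-20, -6]")
  if (length(offset) > 1L && abs(sum(offset) - 1) > 1e-8)
    stop("offset probabilities must sum to 1")
  stopifnot(depth >= 1, all(readLengths >= 15), all(readLengths <= 40),
            min(orfLengthCodons) >= 25, expressionCV >= 0, terminalDwell >= 1,
            spacer >= 40)
  structure(list(nOrfs = as.integer(nOrfs),
                 orfLengthCodons = as.integer(orfLengthCodons),
                 codonWeights = w, stall = stall, offset = offset,
                 depth = as.integer(depth),
                 readLengths = as.integer(readLengths),
                 expressionCV = expressionCV, terminalDwell = terminalDwell,
                 spacer = as.integer(spacer), seed = as.integer(seed)),
            class = "RiboSimSpec")
}

#' Generate a toy genome with annotated ORFs
#'
#' One contig of non-overlapping ORFs (ATG start, TAA stop, body codons drawn
#' from the spec's usage weights), alternating randomly between strands,
#' separated by random intergenic spacers. Deterministic given the spec's
#' seed: the same spec yields byte-identical output.
#'
#' @param spec a [riboSimSpec].
#' @param dir optional output directory; writes `genome.fa`, `orfs.gff3` and
#'   `ground_truth.json`.
#' @return a [GenomeAnnotation-class] with the ground truth attached as
#'   `attr(, "groundTruth")`.
#' @export
genGenome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "RiboSimSpec"))
  set.seed(spec$seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  w <- spec$codonWeights
  lens <- if (length(spec$orfLengthCodons) > 1L) {
    sample(spec$orfLengthCodons, spec$nOrfs, replace = TRUE)
  } else rep(spec$orfLengthCodons, spec$nOrfs)
  strands <- sample(c("+", "-"), spec$nOrfs, replace = TRUE)

  pieces <- character(2 * spec$nOrfs + 1)
  pieces[1] <- paste(sample(c("A", "C", "G", "T"), spec$spacer, TRUE),
                     collapse = "")
  starts <- ends <- integer(spec$nOrfs)
  orfSeqs <- character(spec$nOrfs)
  cursor <- spec$spacer
  for (i in seq_len(spec$nOrfs)) {
    body <- sample(sense, lens[i] - 2L, replace = TRUE, prob = w)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    orfSeqs[i] <- cds
    genomic <- if (strands[i] == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    starts[i] <- cursor + 1L
    ends[i] <- cursor + nchar(cds)
    cursor <- ends[i] + spec$spacer
    pieces[2 * i] <- genomic
    pieces[2 * i + 1] <- paste(sample(c("A", "C", "G", "T"), spec$spacer, TRUE),
                               collapse = "")
  }
  contig <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "toy_contig_1"
  orfs <- GenomicRanges::GRanges("toy_contig_1",
                                 IRanges::IRanges(starts, ends),
                                 strand = strands,
                                 orf_id = sprintf("orf%03d", seq_len(spec$nOrfs)))
  ann <- genomeAnnotation(genome, orfs, validateCodons = TRUE)
  gt <- list(spec = spec[setdiff(names(spec), "codonWeights")],
             orfLengths = lens, strands = strands)
  attr(ann, "groundTruth") <- gt
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    gff <- orfs
    gff$type <- "CDS"
    gff$ID <- gff$orf_id
    rtracklayer::export.gff3(gff, file.path(dir, "orfs.gff3"))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  ann
}

#' Simulate ribosome footprints over a toy genome
#'
#' Reads are placed by sampling an ORF proportionally to a log-normal
#' expression weight, then a ribosome position within the ORF proportionally
#' to per-codon dwell (the spec's stall multiplier applies when the A-site
#' codon is a stall codon; the stop codon carries the terminal dwell). Each
#' footprint's 3' end sits downstream of the first A-site nucleotide by the
#' (negative of the) spec's offset, and its length is drawn from the spec.
#' Ribosome positions run from the second codon (the first A-site codon after
#' initiation) through the stop codon. Deterministic given the spec's seed.
#'
#' @param ann a [GenomeAnnotation-class] from [genGenome] (or user-supplied).
#' @param spec a [riboSimSpec].
#' @param dir optional output directory; writes a sorted, indexed
#'   `footprints.bam` and `ground_truth.json`.
#' @return list with `alignments` (the data.frame format of
#'   [loadAlignments]), `groundTruth`, and `bam` (path or `NULL`).
#' @export
simulateFootprints <- function(ann, spec, dir = NULL) {
  stopifnot(inherits(spec, "RiboSimSpec"))
  set.seed(spec$seed + 1L)
  gc <- Biostrings::GENETIC_CODE
  orfs <- annOrfs(ann)
  n <- length(orfs)
  seqs <- orfSequences(ann)

  sdlog <- sqrt(log(1 + spec$expressionCV^2))
  exprW <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  nReads <- as.integer(stats::rmultinom(1, spec$depth, exprW))

  res <- vector("list", n)
  for (i in seq_len(n)) {
    cnt <- nReads[i]
    if (cnt == 0) next
    orf <- orfs[i]
    L <- GenomicRanges::width(orf)
    ncod <- L %/% 3L
    cstart <- 3L * (seq_len(ncod) - 1L) + 1L
    cods <- substring(seqs[[orf$orf_id]], cstart, cstart + 2L)
    dwell <- rep(1, ncod)
    if (length(spec$stall)) {
      hit <- cods %in% names(spec$stall)
      dwell[hit] <- spec$stall[cods[hit]]
    }
    dwell[gc[cods] == "*"] <- spec$terminalDwell
    jset <- 2:ncod  # first decoded A-site codon is codon 2
    j <- jset[sample.int(length(jset), cnt, replace = TRUE,
                         prob = dwell[jset])]
    off <- if (length(spec$offset) > 1L) {
      as.integer(names(spec$offset))[
        sample.int(length(spec$offset), cnt, replace = TRUE,
                   prob = spec$offset)]
    } else rep(as.integer(spec$offset), cnt)
    pT <- (3L * (j - 1L) + 1L) - off  # transcript position of the 3' end
    lenR <- spec$readLengths[sample.int(length(spec$readLengths), cnt,
                                        replace = TRUE)]
    st <- as.character(GenomicRanges::strand(orf))
    g3 <- if (st == "+") GenomicRanges::start(orf) + pT - 1L else
      GenomicRanges::end(orf) - pT + 1L
    res[[i]] <- data.frame(contig = as.character(GenomicRanges::seqnames(orf)),
                           strand = st, pos3 = as.integer(g3),
                           length = as.integer(lenR),
                           stringsAsFactors = FALSE)
  }
  alignments <- do.call(rbind, res)
  rownames(alignments) <- NULL
  gt <- list(expressionWeights = exprW, readsPerOrf = nReads,
             stall = as.list(spec$stall), offset = spec$offset,
             depth = spec$depth, seed = spec$seed)

  bam <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    bam <- writeFootprintBam(alignments, ann, file.path(dir, "footprints"))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(alignments = alignments, groundTruth = gt, bam = bam)
}

#' Write footprint alignments as a sorted, indexed BAM
#'
#' Emits the minimal SAM representation of simulated footprints (ungapped,
#' MAPQ 42, sequence omitted) and converts it with Rsamtools.
#'
#' @param alignments data.frame with `contig`, `strand`, `pos3`, `length`.
#' @param ann a [GenomeAnnotation-class] for the SAM header.
#' @param prefix output prefix; produces `<prefix>.bam` + index.
#' @return the BAM path.
#' @export
writeFootprintBam <- function(alignments, ann, prefix) {
  lens <- Biostrings::width(annGenome(ann))
  names(lens) <- names(annGenome(ann))
  sam <- paste0(prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  pos <- ifelse(alignments$strand == "+",
                alignments$pos3 - alignments$length + 1L,
                alignments$pos3)
  body <- data.table::data.table(
    qname = sprintf("fp%08d", seq_len(nrow(alignments))),
    flag = ifelse(alignments$strand == "+", 0L, 16L),
    rname = alignments$contig,
    pos = as.integer(pos),
    mapq = 42L,
    cigar = paste0(alignments$length, "M"),
    rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*")
  writeLines(header, sam)
  data.table::fwrite(body, sam, sep = "\t", append = TRUE, col.names = FALSE,
                     quote = FALSE)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
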