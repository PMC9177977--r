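#' Construct a GenomeAnnotation
#'
#' @param genome a `DNAStringSet` (named contigs) or path handled by
#'   [readGenomeAnnotation].
#' @param orfs a `GRanges` with an `orf_id` metadata column; 1-based inclusive
#'   CDS ranges including the stop codon, stranded.
#' @param validateCodons if `TRUE`, require every ORF to begin with a start
#'   codon (ATG/GTG/TTG) and end with a stop codon.
#' @return a [GenomeAnnotation-class].
#' @export
genomeAnnotation <- function(genome, orfs, validateCodons = FALSE) {
  ann <- new("GenomeAnnotation", genome = genome, orfs = orfs)
  if (validateCodons) {
    seqs <- orfSequences(ann)
    starts <- substring(seqs, 1L, 3L)
    L <- nchar(seqs)
    stops <- substring(seqs, L - 2L, L)
    if (!all(starts %in% c("ATG", "GTG", "TTG")))
      stop("ORF(s) without a start codon: ",
           paste(orfs$orf_id[!starts %in% c("ATG", "GTG", "TTG")], collapse = ", "))
    if (!all(stops %in% c("TAA", "TAG", "TGA")))
      stop("ORF(s) without a stop codon: ",
           paste(orfs$orf_id[!stops %in% c("TAA", "TAG", "TGA")], collapse = ", "))
  }
  ann
}

#' Read a genome plus ORF annotation from FASTA + GFF3/BED
#'
#' GFF3 coordinates are 1-based inclusive; BED is 0-based half-open
#' (rtracklayer converts both onto the 1-based `GRanges` convention used
#' throughout). Only `CDS` features are kept from GFF3.
#'
#' @param fastaPath genome FASTA.
#' @param annotPath GFF3 (`.gff`/`.gff3`) or BED file of CDS ranges.
#' @param validateCodons passed to [genomeAnnotation].
#' @return a [GenomeAnnotation-class].
#' @export
readGenomeAnnotation <- function(fastaPath, annotPath, validateCodons = FALSE) {
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(annotPath)
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "CDS"]
  id <- if (!is.null(gr$ID)) gr$ID else if (!is.null(gr$name)) gr$name
        else if (!is.null(gr$Name)) gr$Name
        else paste0("orf", seq_along(gr))
  orfs <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr), orf_id = as.character(id))
  genomeAnnotation(genome, orfs, validateCodons)
}

#' ORF sequences in transcription order
#'
#' @param ann a [GenomeAnnotation-class].
#' @return named character vector of CDS sequences (minus-strand ORFs are
#'   reverse-complemented).
#' @export
orfSequences <- function(ann) {
  orfs <- annOrfs(ann)
  genome <- annGenome(ann)
  seqs <- vapply(seq_along(orfs), function(i) {
    s <- Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(orfs[i]))]],
      GenomicRanges::start(orfs[i]), GenomicRanges::end(orfs[i]))
    if (as.character(GenomicRanges::strand(orfs[i])) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, character(1))
  stats::setNames(seqs, orfs$orf_id)
}

#' Load ribosome footprint alignments
#'
#' Reads a BAM (or SAM, converted on the fly) file of aligned footprints and
#' reduces each alignment to its 3'-end position: the rightmost aligned base
#' for plus-strand reads, the leftmost for minus-strand reads (1-based).
#' Reads outside the accepted length window are discarded, as are non-unique
#' alignments. Uniqueness uses MAPQ as an alignment-tool-agnostic proxy.
#'
#' @param path BAM or SAM file.
#' @param minLen,maxLen accepted read-length window in nt (default 15-40).
#' @param uniqueOnly drop reads with MAPQ below `minMapq` (default `TRUE`).
#' @param minMapq MAPQ threshold defining "uniquely mapped" (default 10).
#' @return data.frame with columns `contig`, `strand`, `pos3` (1-based
#'   genomic position of the 3' end) and `length` (query length, nt).
#' @export
loadAlignments <- function(path, minLen = 15L, maxLen = 40L,
                           uniqueOnly = TRUE, minMapq = 10L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  len <- GenomicAlignments::qwidth(gal)
  mapq <- S4Vectors::mcols(gal)$mapq
  keep <- len >= minLen & len <= maxLen
  if (uniqueOnly) keep <- keep & !is.na(mapq) & mapq >= minMapq
  gal <- gal[keep]
  len <- len[keep]
  strand <- as.character(GenomicAlignments::strand(gal))
  pos3 <- ifelse(strand == "+", GenomicAlignments::end(gal),
                 GenomicAlignments::start(gal))
  data.frame(contig = as.character(GenomicAlignments::seqnames(gal)),
             strand = strand, pos3 = as.integer(pos3),
             length = as.integer(len), stringsAsFactors = FALSE)
}

#' Build a 3'-end footprint density track
#'
#' Tallies footprint 3' ends at every genome position, strand-specifically,
#' and normalizes to reads per million uniquely mapped footprints (RPM).
#'
#' @param alignments data.frame from [loadAlignments] (columns `contig`,
#'   `strand`, `pos3`).
#' @param ann a [GenomeAnnotation-class] supplying contig names and lengths.
#' @return a [DensityTrack-class].
#' @export
densityTrack <- function(alignments, ann) {
  if (nrow(alignments) == 0) stop("no uniquely mapped footprints")
  lens <- Biostrings::width(annGenome(ann))
  names(lens) <- names(annGenome(ann))
  bad <- setdiff(unique(alignments$contig), names(lens))
  if (length(bad)) stop("alignments on contig(s) absent from the genome: ",
                        paste(bad, collapse = ", "))
  counts <- lapply(names(lens), function(ct) {
    sub <- alignments[alignments$contig == ct, ]
    list(
      plus = tabulate(sub$pos3[sub$strand == "+"], nbins = lens[[ct]]),
      minus = tabulate(sub$pos3[sub$strand == "-"], nbins = lens[[ct]])
    )
  })
  names(counts) <- names(lens)
  new("DensityTrack", counts = counts, totalUnique = nrow(alignments))
}

#' Export a density track as bedGraph (one file per strand)
#'
#' @param track a [DensityTrack-class].
#' @param prefix output path prefix; writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` with RPM values.
#' @return character vector of the two paths, invisibly.
#' @export
exportDensityBedGraph <- function(track, prefix) {
  paths <- character(2)
  for (i in 1:2) {
    st <- c("+", "-")[i]
    grl <- lapply(names(track@counts), function(ct) {
      v <- trackRpm(track, ct, st)
      nz <- which(v > 0)
      if (!length(nz)) return(GenomicRanges::GRanges())
      GenomicRanges::GRanges(ct, IRanges::IRanges(nz, width = 1),
                             score = v[nz])
    })
    gr <- suppressWarnings(do.call(c, grl))
    paths[i] <- paste0(prefix, c(".plus", ".minus")[i], ".bedgraph")
    rtracklayer::export.bedGraph(gr, paths[i])
  }
  invisible(paths)
}

## Density over one ORF in transcription order, with optional flanks.
## Returns numeric vector of length flank5 + L + flank3; transcript position
## t (1-based within the CDS) sits at index flank5 + t. Positions outside the
## contig are NA.
.orfDensity <- function(ann, track, orf, flank5 = 0L, flank3 = 0L,
                        scale = c("rpm", "counts")) {
  scale <- match.arg(scale)
  ct <- as.character(GenomicRanges::seqnames(orf))
  st <- as.character(GenomicRanges::strand(orf))
  v <- if (scale == "rpm") trackRpm(track, ct, st) else
    as.numeric(trackCounts(track, ct, st))
  s <- GenomicRanges::start(orf); e <- GenomicRanges::end(orf)
  if (st == "+") {
    pos <- (s - flank5):(e + flank3)
  } else {
    pos <- (e + flank5):(s - flank3)
  }
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1 & pos <= length(v)
  out[ok] <- v[pos[ok]]
  out
}

.trimIndices <- function(L, trim5 = 15L, trim3 = 7L) {
  from <- trim5 * 3L + 1L
  to <- L - trim3 * 3L
  if (from > to) return(integer(0))
  from:to
}
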