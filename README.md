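# AcylRibo

Quantification of aminoacyl-tRNA acetylation and ribosome pausing.

GNAT-family toxins of bacterial toxin–antitoxin systems acetylate the
α-amino group of the amino acid on charged tRNAs. The blocked aa-tRNAs
starve their cognate codons, and ribosomes stall with those codons in the
A site. AcylRibo is for researchers characterizing which tRNAs such an
acetyltransferase targets, with two independent readouts:

* **LC/MS**: nuclease digestion of tRNA releases the aminoacylated
  3′-terminal adenosine (RNase I → aa-adenosine; Nuclease P1 → aa-AMP).
  After Fmoc-OSu derivatization of the non-acetylated pool, each amino
  acid yields an acetyl- and an Fmoc-derivative peak. The acetylated
  fraction is

  *f* = S<sub>Ac</sub> / (S<sub>Ac</sub> + S<sub>Fmoc</sub> / RRF<sub>i</sub>),

  where S are extracted-ion peak areas and RRF<sub>i</sub> =
  S<sub>Fmoc</sub>/S<sub>Ac</sub> at equal molarity corrects ionization
  efficiency. The package provides monoisotopic mass/m/z bookkeeping for
  every digest species, isobar detection (e.g. Glu-AMP ≡ N-Ac-Ser-AMP at
  476.1057 Da), Savitzky–Golay smoothing, exponentially-modified-Gaussian
  (EMG) peak fitting with shared-shape deconvolution of the co-eluting
  Leu/Ile pair, trapezoidal integration, spike-in normalization, and
  first-order (delta-method) uncertainty propagation validated against
  Monte Carlo.

* **Ribosome profiling**: footprint 3′-end density tracks (RPM), ORF
  filtering (≥ 170 bp and ≥ 1 RPM per codon over the trimmed region),
  per-ORF pause scores PS = density / ORF mean (first 15 / last 7 codons
  trimmed), metagene calibration of the 3′-end→A-site offset, and mean
  pause scores (MPS) per codon for the A, P and E sites. An A-site-specific
  MPS elevation at a codon is the signature of starvation for the tRNA
  decoding it.

A seed-deterministic synthetic-data generator produces ground-truthed
chromatograms and footprint libraries (toy genome, codon-specific dwell
multipliers, configurable 3′ offset and depth), so the entire pipeline is
validated end to end without instrument data.

## Worked example

Simulate a library with an 8× dwell at GGA codons (a glycine-specific
toxin signature), then recover the offset and the stall:

```r
library(AcylRibo)

spec <- riboSimSpec(nOrfs = 60, orfLengthCodons = 120, depth = 2e5,
                    stall = c(GGA = 8), seed = 101)
ann   <- genGenome(spec)
sim   <- simulateFootprints(ann, spec)
track <- densityTrack(sim$alignments, ann)
filt  <- filterOrfs(ann, track)
retained <- filt$orf_id[filt$retained]

calibrateAsiteOffset(ann, track, retained)
#> OffsetCalibration: 3'-end to A-site offset = -11 nt

mps <- codonMps(ann, track, retained, -11L, site = "A")
head(mps[order(-mps$mps), ])
#>    codon amino_acid site       mps n_orfs
#> 60   GGA          G    A 6.9473910     47
#> 34   ACT          T    A 0.9563903     47
#> 58   GGT          G    A 0.9550583     50
```

The stalled codon's A-site MPS (6.95) stands an order of magnitude above
every other codon (all ≈ 1, the no-pause baseline); the simulated −11 nt
offset is recovered exactly. On the LC/MS side, known acetylated fractions
are recovered with propagated uncertainties:

```r
lspec <- lcmsSimSpec(aminoAcids = c("G", "I", "L"),
                     trueFractions = c(G = 0.7, I = 0.2, L = 0.1),
                     noiseCV = 0.05, seed = 7)
lsim <- simulateLcms(lspec)
quantifyFractions(lsim$areas, lsim$rrfTable)[, c("amino_acid", "rrf",
                                                 "fraction", "fraction_sd")]
#>   amino_acid      rrf   fraction fraction_sd
#> 1          G 1.512091 0.72913122  0.02162243
#> 2          I 1.490467 0.19718719  0.01336184
#> 3          L 1.463546 0.09892864  0.01421269
```

Estimated fractions (0.729, 0.197, 0.099) sit within one to two standard
deviations of the simulated truths (0.7, 0.2, 0.1). Mass bookkeeping
reproduces the quoted instrument values, e.g.
`truncateAt(mzMH(buildProduct("P", "Fmoc", "RNaseI")))` → 587.22 and
`neutralMass(buildProduct("E", "none", "NucleaseP1"))` → 476.1057, the
value shared with N-acetyl-Ser-AMP (one isobar group).

See `vignettes/quantifying-acetylation-and-pausing.Rmd` for the model
details, parameter defaults and design decisions.

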