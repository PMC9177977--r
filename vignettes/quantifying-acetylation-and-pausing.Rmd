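---
title: "Quantifying aminoacyl-tRNA acetylation and ribosome pausing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aminoacyl-tRNA acetylation and ribosome pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcylRibo)
```

# Background

GNAT-family toxins of type II toxin–antitoxin systems acetylate the
α-amino group of the amino acid carried by charged (aminoacylated) tRNAs.
The blocked aa-tRNA can no longer be delivered to the ribosome, so the
cognate codons starve and ribosomes stall with those codons in the A site.
AcylRibo implements the two quantitative readouts of this biology:

1. **LC/MS quantification of acetylated aa-tRNA fractions.** Nuclease
   digestion of tRNA releases the aminoacylated 3′-terminal adenosine:
   RNase I gives aminoacyl-adenosine (aa-A), Nuclease P1 gives the
   5′-monophosphate (aa-AMP). Pre-treating the RNA with Fmoc-OSu both
   stabilises the labile ester of non-acetylated aa-tRNA and mass-tags it,
   so each amino acid yields an acetyl- and an Fmoc-derivative peak whose
   areas report the acetylated and non-acetylated pools.
2. **Ribosome-profiling pause scores.** Footprint 3′-end densities are
   converted to per-ORF normalized pause scores, the 3′-end→A-site offset
   is calibrated from metagene profiles, and mean pause scores (MPS) per
   codon are computed for the A, P and E sites, localizing stalls to the
   decoded codon.

A synthetic-data generator supplies ground-truthed chromatograms and
footprint libraries so both engines are testable without instrument data.

# Mass bookkeeping

Digest product formulas follow a single condensation rule:

> product = amino acid + adenosine (C10H13N5O4) − H2O + modification delta
> [+ HPO3 for Nuclease P1]

with modification deltas acetyl +C2H2O, formyl +CO, Fmoc +C15H10O2.
Monoisotopic atomic masses are used throughout, and \[M+H\]⁺ adds the
proton mass (1.0072765 Da), not the H-atom mass, per MS convention.
Two conventions deserve explicit mention:

* Instrument reports quote masses at two decimals by **truncation**, not
  rounding: the computed Fmoc-Pro-adenosine \[M+H\]⁺ of 587.2249 is quoted
  as 587.22 and fMet-adenosine's 427.1394 as 427.13. `truncateAt()`
  reproduces this dialect.
* The glutamyl/N-acetyl-seryl isobar is quoted as an \[M+H\]⁺ ion at m/z
  476.1057, but that number equals the **neutral** monoisotopic mass of
  Glu-AMP (and of N-acetyl-Ser-AMP — the two formulas are identical,
  C15H21N6O10P). The package computes both and notes that the printed
  figure matches the neutral mass; the \[M+H\]⁺ is 477.1130.

```{r masses}
tab <- digestProductTable("NucleaseP1", mods = c("none", "acetyl"))
subset(tab, (code == "E" & modification == "none") |
            (code == "S" & modification == "acetyl"))
```

Isobar grouping uses the transitive closure of a ppm tolerance relation —
deterministic and entirely adequate for the ≤ ~100 species this chemistry
produces. Leu/Ile are identical formulas under every modification, so they
always co-group; their chromatographic deconvolution is handled below.

# Chromatogram model and deconvolution

Peaks are modeled as exponentially modified Gaussians (EMG), the standard
model for tailing chromatographic peaks:

$$h(t) = \frac{A}{2\tau}\,
  \exp\!\left(\frac{\sigma^2}{2\tau^2} + \frac{\mu-t}{\tau}\right)
  \mathrm{erfc}\!\left(\frac{\sigma/\tau + (\mu-t)/\sigma}{\sqrt 2}\right)$$

which integrates to the area $A$. The naive expression overflows for
nearly-Gaussian peaks (large $\sigma/\tau$); evaluation switches to the
scaled complementary error function, under which the exponent collapses to
the plain Gaussian term, with an asymptotic expansion beyond the range of
`pracma::erfcx`.

Fitting is bounded Levenberg–Marquardt least squares over peak parameters
plus a linear baseline. Defaults that matter:

* **Smoothing**: Savitzky–Golay, 31-point window (the nearest odd width to
  the instrument software's 30-point convention), polynomial order 4.
* **Bounds**: $\sigma, \tau \in [10^{-4}, 5]$ min; $\mu$ within the data
  window; $A \ge 0$. Parameters pinned at bounds are flagged.
* **Initialization**: highest local maxima of the smoothed trace (left
  peak first), $\sigma$ from the half-height width, $\tau = \sigma$. For
  two-peak fits a deterministic family of additional starting points
  (symmetric and asymmetric splits around the dominant mode) is tried and
  the lowest-RSS solution kept, because a merged doublet offers a
  one-peak local optimum that a single start frequently falls into.
* **Shared shape**: with two peaks, both share one $\sigma$ and $\tau$ by
  default (`shareShape = TRUE`). Isomeric species co-eluting on one
  column have the same peak shape, and the constraint is what keeps the
  overlapped problem well-conditioned: with fully free shapes, a collapsed
  single-peak fit reaches noise-level residuals already at moderate
  tailing, making the areas unidentifiable.

Even with shared shape, identifiability degrades as the separation
$\Delta\mu$ shrinks toward $1.5\sigma$ and tailing grows: at
$\Delta\mu = 1.5\sigma$, 1% noise and a 1:4 area ratio, the global optimum
itself misses the small peak's area by more than 5%. The validated regime
used in the tests is $\Delta\mu = 2\sigma$ with $\tau = \sigma = 0.05$
min, where all area ratios in $\{0.25, 1, 4\}$ are recovered within a few
percent. Model-free integration (`integratePeak`) is trapezoidal with an
optional linear endpoint baseline; its noise estimate is the RMS residual
to the smoothed trace in 0.2-min flanking windows × $\sqrt{n}$ × the
sampling interval — a deliberately simple, testable estimator.

# From areas to acetylated fractions

The relative response factor corrects the ionization-efficiency difference
between the two derivatives. From a sample split into equal aliquots (one
Fmoc-treated, one chemically acetylated), $RRF_i = S_{Fmoc}/S_{Ac}$. The
acetylated fraction is then

$$f = \frac{S_{Ac}}{S_{Ac} + S_{Fmoc}/RRF_i},$$

the only orientation consistent with that RRF definition and with the
requirement that an equimolar pool gives $f = 0.5$ exactly. Should data
arrive with the reciprocal convention, `rrfOrientation =
"acetyl_over_fmoc"` flips it.

Standard deviations propagate to first order (delta method) treating
$S_{Ac}$, $S_{Fmoc}$ and $RRF$ as independent — conservative for ratios of
separately measured areas. The tests verify the propagated sds against
$10^6$-draw Monte Carlo within 10% for input CVs up to 10%. Spike-in
normalization (division by the 15N-AMP internal-standard area) is provided
for cross-sample comparisons of Nuclease P1 data.

# Ribosome profiling pipeline

All coordinates are held as 1-based `GRanges`; every output table is
1-based. The processing chain and its conventions:

* **3′ ends.** Each footprint is reduced to its 3′-end position: the
  rightmost aligned base on the plus strand, leftmost on the minus strand.
  Reads outside 15–40 nt are discarded; "uniquely mapped" means MAPQ ≥ 10,
  an alignment-tool-agnostic proxy (configurable).
* **Density.** Strand-specific per-position 3′-end counts, normalized to
  reads per million uniquely mapped footprints (RPM). Raw counts are kept
  alongside, so count conservation is exact.
* **ORF filter.** Retained ORFs need length ≥ 170 bp AND trimmed-region
  mean density ≥ 1 RPM per codon; violating either discards. The mean is
  computed over the trimmed region (first 15, last 7 codons excluded)
  because the start/stop-proximal biases the trim exists to remove should
  not leak into the normalizer either.
* **Pause scores.** PS = density / trimmed-region mean, so each retained
  ORF's trimmed mean PS is exactly 1.
* **A-site calibration.** Metagene 3′-end profiles are built for retained
  ORFs aligned at start and stop codons, each ORF normalized by its
  trimmed mean. Terminating ribosomes hold the stop codon in the A site,
  so the offset is read off the dominant stop-proximal peak; candidates
  run over \[−20, −6\] nt and ties go to the most 3′ candidate. A flat
  profile raises a calibration error rather than guessing; `-11` nt is the
  documented manual default for 3′-aligned bacterial footprints.
* **MPS.** A 3′ end at $p$ reports a ribosome decoding the codon starting
  at $p + \text{offset}$; P- and E-site codons sit 3 and 6 nt upstream.
  Scores on the three nucleotides attributed to each in-frame codon
  occurrence are averaged within an ORF, then unweighted across ORFs —
  expression differences cancel by construction. Codons never observed
  yield `NA`, not zero. The amino-acid view pools codons by translation
  before the per-ORF average.
* **Decile profile.** Codons are split into ten contiguous near-equal bins
  (earlier bins take the remainder); per-bin footprint fractions get a
  0.5-read pseudocount per bin so the cross-ORF geometric mean is defined
  for empty bins.

Overlapping or nested ORFs are scored independently from the shared track,
and no multiple-testing machinery is attached: MPS is a descriptive
statistic.

# The synthetic-data generator

`genGenome()` packs non-overlapping ORFs (ATG…TAA, body codons drawn from
configurable usage weights, random strand) into one contig with 60-nt
spacers. `simulateFootprints()` places each read by sampling an ORF from
log-normal expression weights (CV 1 by default, so the density filter has
real work to do), then a ribosome position proportional to per-codon
dwell, then emits a read whose 3′ end sits $|\text{offset}|$ nt downstream
of the first A-site nucleotide with length uniform on 24–32 nt. Stalls are
multiplicative dwell at the A-site codon only, matching the A-site-specific
biology of tRNA starvation. Ribosome positions run from codon 2 (the first
decoded codon after initiation) through the stop codon, and the stop codon
carries a terminal dwell multiplier (default 3×) emulating slow
termination — this is what gives the stop-aligned metagene its calibration
peak; it cannot contaminate MPS because the last 7 codons are trimmed.
Everything is deterministic given the spec's seed.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real libraries: nuclease sequence bias, read-length-
dependent offsets, sequencing errors, multi-mapping, rRNA/tRNA
contamination, and chromatographic retention drift between samples on the
LC/MS side.

Problem sizes used in the validation suite were chosen as the smallest
that make the statistics sharp: 100 ORFs × 200 codons at $10^6$ reads for
the study-scale checks (null A-site MPS stays within \[0.9, 1.1\]; an 8×
GGA stall ranks first in the A-site column with MPS ≈ 7 while staying
unremarkable in P/E), and 55–60 ORFs at $1$–$2 \times 10^5$ reads for the
faster unit checks. Offset recovery is exact in \[−16, −8\] at these
depths.

# Worked example

```{r example}
spec <- riboSimSpec(nOrfs = 60, orfLengthCodons = 120, depth = 2e5,
                    stall = c(GGA = 8), seed = 101)
ann <- genGenome(spec)
sim <- simulateFootprints(ann, spec)
track <- densityTrack(sim$alignments, ann)
filt <- filterOrfs(ann, track)
retained <- filt$orf_id[filt$retained]
cal <- calibrateAsiteOffset(ann, track, retained)
cal
mps <- codonMps(ann, track, retained, cal, site = "A")
head(mps[order(-mps$mps), ])
```

```{r example-lcms}
lspec <- lcmsSimSpec(aminoAcids = c("G", "I", "L"),
                     trueFractions = c(G = 0.7, I = 0.2, L = 0.1),
                     noiseCV = 0.05, seed = 7)
lsim <- simulateLcms(lspec)
quantifyFractions(lsim$areas, lsim$rrfTable)
```

# Known limitations

* The EMG deconvolution guarantees hold in the validated overlap regime
  described above; closer, heavier-tailed doublets are flagged by large
  area SEs rather than silently mis-fit.
* Chromatograms are assumed already extracted per target m/z; vendor
  formats and mzML are out of scope (the digest-product table supplies the
  target list).
* The pipeline starts at aligned footprints; trimming, contaminant
  depletion and genome alignment are upstream concerns.
* Offset calibration assumes a single dominant offset; libraries with
  strongly length-dependent offsets need per-length calibration, which is
  not implemented.
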