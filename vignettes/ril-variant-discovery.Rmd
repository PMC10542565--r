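---
title: "Finding spontaneously arising causal variants in recombinant inbred lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding spontaneously arising causal variants in recombinant inbred lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilseg)
```

## The problem

Recombinant inbred lines (RILs) of a selfing organism such as
*Caenorhabditis elegans* are produced by crossing two homozygous founder
strains and propagating single descendants of the F1 by self-fertilization
for many generations. Each line ends up homozygous for a mosaic of the two
parental genomes -- but propagation takes long enough that *de novo*
mutations arise and fix along the way. A line with a striking phenotype may
therefore owe it not to a parental allele but to a variant that exists in no
parent at all. rilseg implements the inference used to identify such a
variant: derive sub-lines from the aberrant RIL, classify each line's
phenotype, and ask which called variants segregate exactly with each
phenotype class across the panel. The package also provides the two
supporting analyses that accompany that inference in practice -- a windowed
scan of alignments for soft-clipped and chimeric reads marking
structural-variant breakpoints, and the behavioral statistics (thermotaxis
bias, exploration count, chemotaxis index) used to classify the lines in
the first place -- plus a fully synthetic data generator so the whole
pipeline is testable end to end without any sequencing data.

## The segregation filter

The central object is a boolean presence/absence matrix: rows are variant
keys (`chrom:pos:ref:alt`), columns are strains, a cell is `TRUE` iff the
strain's call set contains the variant. Zygosity is deliberately collapsed
to presence, which is how shared-variant tables are reported and compared.
Candidate causal variants for a phenotype are the rows that are present in
*every* strain showing the phenotype and absent from *every* informative
strain that does not. `candidate_report()` builds one such pattern per
phenotype label, with two refinements taken from how this reasoning is
actually applied:

* **Masking.** Some phenotypes make others unreadable: a line that circles
  continuously cannot be scored for directed thermotaxis. Strains whose
  phenotype for label `L` is masked by another label are left
  *unconstrained* in the pattern for `L` rather than being scored
  wild-type. The default mask (`thermotaxis` masked by `circling`) encodes
  this structurally; it is not a tunable threshold.
* **Parental masking.** A variant inherited from a founder could be
  phenotypically silent in that founder's own genetic background. A third
  hypothesis therefore asks for variants shared between the divergent
  founder and all defective lines but absent from wild-type lines.

No scoring or ranking is applied anywhere: the inference is purely boolean,
and the report carries full provenance (pattern, matrix checksum, notes on
unconstrained strains).

A transcription of the published six-strain table of thirteen
protein-coding variants ships with the package (`table1_fixture()`), so the
published inference is reproducible in milliseconds: the thermotaxis-only
pattern returns exactly the *efn-4* missense variant, the circling pattern
returns twelve variants including the *ttx-1* missense change at
V:20064174, and the parental-masking pattern returns nothing.

```{r}
rep <- reproduce_table1(quiet = TRUE)
sapply(rep$hypotheses, function(h) nrow(h$candidates))
```

Noncoding and synonymous rows are excluded from the matrix by default
(`include_noncoding = FALSE`), matching the coding-first strategy of this
kind of analysis; the flag exists because a thermotaxis defect that no
coding variant explains plausibly lives in regulatory sequence.

## The panel simulator

`generate_ril_panel()` is a first-class, tested component, not a test
fixture. It models:

* **Meiosis.** Per chromosome, crossover count is Poisson with mean equal
  to the genetic length in Morgans and crossover positions are uniform in
  genetic distance (Haldane model, no interference). Haldane is the default
  because it has closed-form recombinant fractions --
  `r = (1 - exp(-2d))/2` -- against which the simulator is tested.
  *C. elegans* in fact shows near-complete crossover interference, so an
  `xo_model = "obligate"` option (exactly one crossover per chromosome) is
  provided; the choice does not affect the boolean filter logic.
* **Selfing with single-individual transfer.** One offspring is formed from
  two independent gametes of the current individual, per generation.
  Generations count selfing steps from the F1, so the classic design --
  F2 founders selfed for eight further generations -- is `g_generations = 9`,
  the default, and marker heterozygosity decays as `(1/2)^g`.
* **De novo mutation.** Events are Poisson per transmitted gamete per
  generation (`de_novo_rate`, default 0.3 -- the order of magnitude of the
  *C. elegans* spontaneous SNV rate over a ~100 Mb genome), placed
  uniformly on the physical map, never colliding with a parental variant
  position, and tracked to their final zygosity (`het`, `hom_alt`, `lost`)
  in a truth table.
* **Phenotypes.** A line expresses a phenotype iff homozygous for the
  mapped causal variant, with configurable penetrance (default 1). A line
  still heterozygous at a causal locus segregates the phenotype on the
  plate; such lines are flagged `indeterminate` and left unconstrained by
  the filter, which is what an experimenter faced with a segregating plate
  would do.

The default genetic map has six chromosomes (I--V, X) of 15.1, 15.3, 13.8,
17.5, 20.9 and 17.7 Mb at 50 cM each -- configurable approximations to the
*C. elegans* genome chosen for realism, not measured values of any
particular reference build. Coordinates are 1-based and inclusive (VCF
convention); genetic-to-physical conversion is linear with
round-half-away-from-zero rounding, documented and tested, and windows
elsewhere are half-open.

The default in-silico study (`simulate_study()`) mirrors the design under
investigation: a reference-like founder with no variants crossed to a
divergent founder carrying eight coding and four noncoding variants (three
of the coding ones on chromosome V at increasing distance from the causal
locus, so realistic linkage structure survives into the candidate sets),
one causal missense variant planted on the divergent F1 haplotype at
V:20064174, thirty lines, nine selfing generations. Because the causal
variant is planted at the F1, roughly half the lines fix it -- giving both
phenotype classes in one panel, as in the real two-stage design where
derived sub-lines of the aberrant RIL are compared.

## The breakpoint scan

Reads whose terminal bases are soft/hard-clipped, and reads with split
(supplementary/`SA`-tagged) alignments, pile up at structural-variant
breakpoints. `window_counts()` tiles each chromosome with 1 kb windows
(the scale of the clipped-read cluster expected upstream of a breakpoint)
and assigns each read to the window containing its leftmost mapped base --
simple, deterministic, and conserving totals. What counts as "a large
number" of such reads is not defined by eye here but by an explicit rule,
which is this package's own design decision: the pooled count
`n_clipped + n_chimeric` is tested one-sided against a Poisson expectation
of `background x n_reads` (background defaulting to the genome-wide
signature rate of the input), with Benjamini--Hochberg correction across
covered windows and a flag at adjusted `p <= alpha` (default 0.05). Clip
calls require a terminal clip of at least `min_clip = 20` bp, which
separates breakpoint signatures from alignment-edge noise. All three
knobs -- window size, `min_clip`, `alpha` -- are exposed. The scan flags
regions only; assembling or classifying the underlying rearrangement is
out of scope.

## The behavioral statistics

The thermotaxis bias of a track has no single canonical formula in the
literature (published analyses defer to prior methods papers and custom
scripts), so this package fixes one, documents it, and calibrates it:
each inter-sample step is classified toward-cold / toward-warm / neutral by
a speed threshold (`speed_min = 0.02` mm/s) and an angular band
(`angle_band = 45` degrees around the gradient axis), and

```
bias = (t_toward_cold - t_toward_warm) / (t_toward_cold + t_toward_warm)
```

over the gradient-directed moving time. The statistic is bounded in
[-1, 1], negates exactly under axis reversal, is invariant under rigid
motions of track-plus-axis, and recovers `2p - 1` on a Bernoulli walk with
cold-ward step probability `p` -- the property the calibration tests check
at `p` in {0.3, 0.5, 0.7, 0.9}. Positive bias means net cold-ward
movement, i.e. stronger negative thermotaxis, so the wild-type laboratory
phenotype is positive. Equivalence with any particular prior formula is
not claimed.

The track generator runs at 1 Hz for 2100 steps (a 35-minute assay) on a
10-cm plate with a 23--28 degC gradient at 0.5 degC/cm, starting at the
plate center. Published figure legends for such assays sometimes state
0.05 degC/cm; on a 10-cm plate only 0.5 degC/cm is consistent with a
23--28 degC span, so 0.5 is the default and steepness remains an explicit
parameter rather than a silently resolved constant. The default step
length is 0.025 mm: the walk models gradient-directed displacement
statistics, not absolute crawling speed, and this value keeps even a
strongly biased 35-minute walk in the plate interior so that the
`2p - 1` calibration is exact rather than wall-censored. Wall reflection
is implemented (and tested) for parameter choices that do reach the edge.

The exploration count enumerates grid-line crossings of each straight
inter-sample segment exactly, so the count is invariant to refining the
sampling of the same geometric path, and positions are clamped to the
arena so it can never exceed `(arena/grid)^2` (100 for the standard
35-mm plate with 3.5-mm squares). The chemotaxis index is the standard
`(n_odorant - n_diluent) / n_total`.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the real inputs: mosaic
genotypes with residual heterozygosity, truth-tracked de novo variants,
clip/chimera pileups at a known breakpoint over a uniform noise floor, and
biased random-walk tracks. It does not model read sequences or base
qualities, variant-calling error, alignment artifacts in repetitive
sequence, crossover interference (unless the obligate model is chosen),
selection during line propagation, or the experience-dependence and
isothermal tracking of real worm navigation. Passing the packaged tests
therefore demonstrates that the inference machinery is correct under its
stated model, not that any particular real dataset would yield the same
candidates; real inputs enter through the same VCF/SAM/CSV interfaces and
inherit whatever artifacts their upstream pipelines carry.

## Numerical and interface choices

* Variant identity is the exact `(chrom, pos, ref, alt)` tuple; long indel
  allele strings are kept verbatim.
* Unknown effect-annotation tokens map to `noncoding` with a warning,
  never a hard failure; `ANN=`, `EFF=`, and plain `EFFECT=`/`GENE=`
  dialects are accepted.
* The VCF and SAM readers implement the documented subsets consumed here
  (eight fixed VCF columns; FLAG/RNAME/POS/CIGAR/`SA:Z` from SAM) with
  line-numbered parse errors; unmapped and secondary alignments are
  skipped, supplementary alignments are kept and flagged chimeric.
* All randomness flows from explicit seeds; a pipeline run derives one
  sub-seed per stage from the root seed and records them, with file
  checksums, in a JSON manifest. Identical seeds give byte-identical
  outputs.
* Test and acceptance problem sizes -- 2000 lineages for heterozygosity
  decay, 10000 gametes per map distance, 50 seeded replicates for
  recovery and scan calibration, 200 tracks per drift level -- were chosen
  as the smallest sizes at which the 3-standard-error Monte Carlo checks
  are meaningfully tight.

## Known limitations

The filter is exact boolean matching: a single miscalled cell removes a
true candidate, and no statistical rescue is attempted (by design -- the
method under study is boolean). Linked passenger variants are expected
among candidates, exactly as in the motivating analysis. The scan's
Poisson background assumes clip/chimera noise is homogeneous along the
genome, which real data violate near repeats; the `background` parameter
lets a user supply a better estimate. QTL interval mapping, linkage
statistics, epistasis modeling, CRISPR design, and fluorescence
quantification are out of scope.
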