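---
title: "CRISPR-Select assay design and analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR-Select assay design and analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprselect)
```

## The assay in one paragraph

CRISPR-Select measures the functional effect of a single genetic variant in
its native genomic context. A cell population is transfected with a cassette
of three reagents: a Cas9-gRNA cutting next to the site of interest, an ssODN
repair template carrying the variant, and a second ssODN identical except
for a synonymous mutation ("WT′") at — or within a few bases of — the
variant position. Both edits are knocked in by homology-directed repair at
similar frequencies, and both destroy the Cas9 site (they sit in the PAM or
seed region), so edited alleles are not re-cut. Deep amplicon sequencing at
two assay points (two days, two compartments, or two FACS states) yields the
variant:WT′ read ratio at each point; since cells carrying WT′ are
functionally wild type, the *change* in that ratio between the points is a
direct, internally controlled measure of selection for or against the
variant. `crisprselect` implements the computational side of this assay:
cassette design, read classification, ratio analysis, depth guidance,
single-cell zygosity tabulation and a full forward simulator.

## Cassette design rules

`assemble_cassette()` applies the assay's design rules in order, and fails
loudly at the first stage that cannot be satisfied:

1. **Guide selection** (`enumerate_guides()`). SpCas9 with NGG PAM only; the
   blunt cut is modelled 3 nt 5′ of the PAM (between protospacer positions
   17 and 18), a standard constant exposed in the config. A candidate is
   retained only if every edited base of the variant falls in the seed
   region (the 10 PAM-proximal protospacer bases; `seed_max`) or on a G of
   the PAM's GG. The PAM's first base is degenerate, so a variant hitting
   only the N does **not** count as disruption — only the GG confers
   recognition. Candidates are ranked by distance of the variant from the
   cut (knock-in efficiency decays with distance), then by smaller seed
   offset, then plus strand first, making the choice deterministic.
2. **WT′ design** (`design_wtprime()`). Single-nucleotide substitutions
   within 3 nt of the variant (`wtprime_max_distance`) that (a) leave the
   translated protein unchanged, (b) do not create a splice motif, (c) do
   not create a rare codon — below 5 occurrences per thousand in the bundled
   human codon usage table (`min_codon_freq`), and (d) independently disrupt
   the chosen guide. By default the guide must be disrupted by variant *and*
   WT′ separately (`joint_disruption = TRUE`): both knock-ins must prevent
   re-cutting, and the design is iterated over ranked guides until one
   admits a valid WT′. Candidates are ranked by distance (0, 1, 2, 3), then
   by the frequency of the created codon, descending. For splice-site
   variants (`splice_mode = "exon_offset"`) the variant itself may be
   intronic and no synonymous change exists at its position, so WT′
   candidates are drawn from the exonic positions nearest the affected exon
   boundary instead.
3. **Off-target rule** (`screen_offtargets()`). A desk-scale exhaustive scan
   of user-supplied sequences (the locus plus any decoys; genome-wide
   scoring is out of scope) for 20-nt+NGG sites within 3 protospacer
   mismatches. The design rule is that the closest potential off-target must
   carry at least one mismatch in the PAM or seed; since only sites that
   retain an NGG are candidate off-targets at all, the check reduces to a
   seed mismatch in every minimal-mismatch hit.
4. **ssODN construction** (`build_ssodn()`). Homology arms of 45 nt flank
   the edit (total 91 nt for an SNV). Polarity follows the asymmetric-donor
   rule: for edits more than 4 bp from the cut, sense oligos for edits left
   of the break and antisense for edits right of it; at 4 bp or closer the
   rule is not informative and the sense construction is used — a
   deterministic default we chose because *some* polarity must be emitted.
5. **Primer placement** (`design_primers()`). Primers must anneal entirely
   outside the region covered by either ssODN — otherwise templated and
   untemplated alleles would amplify differently — at offsets of 40–120 nt
   from the covered region, with products of 230–350 bp. Composition
   filtering is deliberately simple: length 18–25 nt, GC 35–65 %, Wallace
   melting temperature (2·AT + 4·GC) between 50 and 72. The search returns
   the smallest-total-offset valid pair, ties broken toward balanced GC,
   so repeated runs are byte-identical. Thermodynamic primer design
   (nearest-neighbour models, dimer checks) is a non-goal.

### The splice screen

The original workflow screened WT′ candidates with an external web
predictor. Here the screen is a small position-weight-matrix model of the
two canonical motifs: the 9-nt donor site (consensus `MAG|GTRAGT`) and the
acceptor region (a 10-nt polypyrimidine tract, spacer, invariant AG). Scores
are summed log2 odds against a uniform background; a candidate is rejected
if it creates a window scoring at or above 8 bits (donor max ≈ 13) where the
reference scored below it. This is a conservative simplification, not a
splicing predictor; positions can be exempted with `splice_allowlist` when
the user has better evidence.

## Read classification

`quantify_sample()` streams a FASTQ of pre-merged amplicon reads (paired-end
merging is assumed upstream; products are 230–350 bp) and classifies every
read into one of eight mutually exclusive categories: `VARIANT_KI`,
`WTPRIME_KI`, `MIXED_KI`, `FRAMESHIFT_INDEL`, `INFRAME_INDEL`, `WT`,
`OTHER`, `DISCARDED`. The decision order is:

1. reads shorter than 50 nt or with mean Phred quality below 20 are
   `DISCARDED`;
2. reads are globally aligned to the amplicon (affine gaps: match +2,
   mismatch −4, open 10, extend 1); identity below 60 % is `OTHER`
   (unalignable);
3. any InDel overlapping the quantification window — by default the
   ssODN-covered region, since only edits there can derive from the
   templates — takes precedence over point edits: the net length change
   within coding segments decides `FRAMESHIFT_INDEL` (not a multiple of 3)
   versus `INFRAME_INDEL`. A purely non-coding InDel has no defined frame
   and is reported with the in-frame class;
4. otherwise the bases at the two edit positions decide `VARIANT_KI`,
   `WTPRIME_KI`, `MIXED_KI` (both; excluded from ratios) or `WT`; a third
   base at an edit position is `OTHER`.

Substitutions elsewhere in the window are tolerated by default — Illumina
error (~0.1–1 %) would otherwise inflate `OTHER` — and a `strict` mode
disqualifies them instead. Indel placement is made deterministic by shifting
every gap run to its leftmost equivalent position (the usual variant-
normalization convention). Two numerical choices are worth noting. First,
the scoring makes two gap openings (cost 22) dearer than three mismatches
(cost 18), so short error tracts are read as substitutions, never as
spurious indel pairs; this also licenses a fast path in which a read of
reference length within Hamming distance 3 is scored gaplessly, which is
provably the optimal alignment under these scores and covers the large
majority of reads at realistic error rates. Second, unique read sequences
are classified once and counts propagated, so deep samples cost little more
than their unique-sequence count.

### Absolute cell numbers

Because the template mass entering the PCR is known,
`estimate_absolute_cells()` converts it to diploid genome equivalents
(mass × 1000 / 6.0 pg per diploid human genome; 100 ng ≈ 17,000
equivalents) and multiplies by a category's read frequency to estimate the
number of cells carrying it. Note the assumption: read frequency is treated
as a per-cell frequency, which is the assay's published arithmetic; the
allele-count interpretation (two alleles per equivalent) is reported
alongside as `alleles` so users can apply either convention.

## Selection analysis

`compute_ratios()` forms the variant:WT′ and frameshift:WT′ read ratios per
sample, with a log-normal 95 % CI (`se = sqrt(1/a + 1/b)`, half-count
correction when a count is zero) and an explicit undefined flag when WT′
reads are absent — never a silent infinity. `normalize_to_baseline()`
divides each replicate's ratios by that replicate's baseline ratio, so the
baseline maps to exactly 1 and the readout is invariant to the initial
variant:WT′ stoichiometry — the property that makes the assay robust to
skewed template delivery. `summarise_selection()` aggregates per-replicate
fold changes (mean ± s.d.), tests them against no change, and attaches a
verdict:

* `depleted` / `enriched` — mean fold outside the neutral band (default
  2/3–1.5);
* `validated_neutral` — variant fold inside the band **and** the frameshift
  knock-out control fold at or below 2/3: knock-outs deplete whenever there
  is selection pressure on gene function, so a flat variant with a falling
  control is genuinely neutral;
* `inconclusive` — variant and control both flat: the assay had no
  selection pressure and a deleterious variant could hide (the
  false-negative guard).

Two-tailed paired t-tests (`paired_test()`) compare matched conditions at
the 0.05 level; the same arithmetic serves time points, FACS states and
spatial compartments — a point comparison is a point comparison. Tests run
on the linear fold scale by default, matching the quantity plotted in
practice; a log-scale option is provided and recommended for strongly
skewed ratios. The band and control thresholds are configurable; the
defaults are symmetric on the ratio scale (2/3 and 1.5) and were fixed
before any simulation was run. A vehicle-style post-normalization
(`normalize_to_condition()`, reference set to 100 %) covers drug-response
comparisons.

### Depth guidance

`recommend_depth()` answers "how many reads do I need at knock-in frequency
*k* to detect a fold change *f* with power 1−β?". The log ratio-of-ratios
of four approximately Poisson counts has variance ≈ (3 + 1/f)/(N·k) per
replicate, giving

N = (z₁₋α/₂ + z₁₋β)² · (3 + 1/f) / (n · k · log²f).

This is a guideline-compatible normal approximation, cross-checked by a
seeded Monte-Carlo simulation of the four-count experiment
(`simulate_depth_power()`); the test suite requires agreement within five
percentage points. It is not a reproduction of any published closed form.
Depths above 10⁷ are reported infeasible rather than extrapolated.

## The simulator

`simulate_experiment()` is first-class, tested code, not a fixture: it
forward-simulates editing outcomes, selection, gDNA subsampling and
sequencing so every other module can be exercised end to end without any
external data.

* **Editing** (`simulate_editing()`): each diploid cell draws cut/no-cut per
  allele (default cut probability 0.8), and each cut allele draws a repair
  outcome from a categorical distribution. The defaults — unedited 0.32,
  variant knock-in 0.085, WT′ knock-in 0.085, frameshift InDel 0.425,
  in-frame InDel 0.085 — encode the empirical regime of such experiments:
  knock-in of a few percent of alleles and frameshift InDels about five
  times more frequent than either knock-in. Allele outcomes are independent
  given cutting; real cells show biallelic dependence beyond what the
  per-allele cut probability induces, so an explicit `joint_table` of
  biallelic outcomes can be supplied where that matters (the zygosity tests
  use it).
* **Selection** (`simulate_selection()`): expectation-based exponential
  growth — class count × fitnessᵗ — with multinomial resampling only at
  passaging. No birth–death noise; this keeps closed-form expectations
  available as oracles in the test suite.
* **Sequencing** (`emit_reads()`): the configured template mass is converted
  to genome equivalents, alleles are drawn multinomially from the weighted
  population (two per cell), reads are drawn from the sampled alleles, and
  uniform per-base substitution errors (default 0.003) are applied. InDels
  are placed at the cut site. Qualities are written as the constant Phred
  value matching the error rate — sufficient for the classifier's filters;
  realistic quality profiles, PCR bias, and chimeric reads are out of
  scope. The seed is mandatory and the same seed yields byte-identical
  FASTQ.

What passing simulator-based tests shows — and does not. They demonstrate
that the pipeline recovers configured truths under the stated generative
model: binomial read sampling, uniform errors, cut-site indels, exponential
selection. They do not certify behaviour under PCR jackpots, context-
dependent error, large structural lesions or template switching, which real
amplicon data can contain.

## Single-cell zygosity

`tabulate_zygosity()` counts unordered biallelic outcome pairs across cells
and the conditional distribution of the second allele given the first —
the "built-in loss of heterozygosity" readout: most cells with a knock-in
on one allele carry a disruptive edit on the other, so recessive
loss-of-function phenotypes surface without breeding to homozygosity.
Homozygous cells are counted once in the conditioning set. `loh_assessment()`
sums the conditional mass on disruptive second-allele outcomes; which
categories count as disruptive is a per-cassette configuration defaulting to
frameshift InDels, biallelic knock-in and in-frame InDels (in-frame InDels
at the cut typically destroy the assayed residue). Input is a per-cell
table of two allele calls; trace deconvolution from mixed Sanger
chromatograms is out of scope.

## Problem sizes and reproducibility

All randomness flows through explicit seeds (`withr::with_seed`); no
function draws from an unseeded RNG. The test suite exercises the designer
on a battery of 20 synthetic SNV fixtures in a 2-kb locus; the classifier
against an exhaustive rule-table oracle over all ≤2-edit reads (several
thousand distinguishable sequences) on a 60-nt toy amplicon; and the full
round trip at 30,000 reads per sample, two time points, three replicates —
sizes chosen to match the assay's routine operating point while keeping the
suite comfortably runnable on a laptop. The acceptance script
(`scripts/acceptance.R`) regenerates its fixture battery from the supplied
seed at every run.

## Conventions and known limitations

* Coordinates are 1-based and inclusive throughout, the R/Bioconductor
  convention; sequences are upper-cased on input and IUPAC ambiguity codes
  are rejected, because the design rules are defined on concrete bases.
* One coding frame per locus; transcript isoforms and genome-scale
  annotation are out of scope.
* NGG Cas9 only; non-NGG effectors and multi-variant multiplex cassettes
  are unsupported.
* The off-target screen is desk-scale (supplied sequences only) and reports
  mismatch counts, not cutting-probability scores.
* The classifier assumes reads span the amplicon; UMIs and PCR-duplicate
  handling are out of scope.
* Where several edit histories produce the same read sequence (e.g. an
  insertion–deletion pair equivalent to substitutions), the classifier
  reports the alignment-optimal interpretation; such reads are inherently
  ambiguous from sequence alone.
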