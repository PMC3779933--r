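---
title: "Methods: pooled activity screening and tetranucleotide-frequency binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled activity screening and tetranucleotide-frequency binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`screenbin` models the computational side of a function-first metagenomics
workflow: large-insert (fosmid) clone libraries are screened in pooled
96-well assays for enzymatic activities, positives are deconvolved and
confirmed clone by clone, annotated genes are compared against the
biochemistry, and clone sequences are attributed to genome bins by
tetranucleotide composition. This vignette explains the models behind each
stage, the parameters that matter, and the design choices made where the
underlying protocol leaves the computation under-determined.

## The pooled screening design

A library is picked to 96-well *source plates*, 95 clones per plate with one
well (H12 in our row-major layout) left as a negative control. Sixteen
source plates are pooled onto one *assay plate*: source well `w` of every
plate in the pool lands in assay well `w`, so each assay well carries 16
distinct clones and one assay plate represents 16 × 95 = 1,520 clones.
Eight pooling rounds a day and a 14-assay substrate panel give 12,160
clones and 170,240 reactions per day; `verify_design_arithmetic()` checks
exactly this bookkeeping. The panel (see `substrate_panel()`) spans 13
physical substrates; BCIP is assayed at pH 6 and pH 8 (acid and alkaline
phosphatase), which is why assays per clone is 14.

Pooling trades reactions for a second phase: each positive assay well only
localizes the activity to 16 candidate clones (`deconvolve()`), which are
then expanded one clone per well and re-screened individually
(`build_expansion_design()`, `confirm_clones()`).

## Hit calling

For every (plate, substrate, timepoint) group the threshold is

    threshold = mean + k * sd       (k = 2 by default)

computed over **all** wells of the plate, negative controls included, and a
well is positive when its signal **strictly exceeds** the threshold at
**any** timepoint (readings are taken at 24 h and 5 d). Four conventions
here are genuinely open, and each is an explicit switch:

* *SD flavor* — the wells of a plate are the entire population under test,
  so the default divides by *n* (`sd_type = "population"`); `"sample"`
  gives the n−1 estimator.
* *Timepoint combination* — `combine_timepoints` is `"any"` by default
  (an activity detectable early or only after the 5-day incubation both
  count), with `"all"` or a single named timepoint available.
* *Controls* — included in the plate statistics (the threshold is defined
  over "all wells on the respective plate").
* *Inequality* — strict by default (`strict = TRUE`).

Visual solid-media assays (BCIP, skim milk) carry binary readings and
bypass the threshold entirely: any non-zero value is positive.

Under a 2-SD rule a noise-only 96-well plate is *expected* to produce about
2% positive wells, so false positives are a property of the method, not a
bug. Two mechanisms keep them from propagating: the second screening phase
(a pooled false positive must fire again on its expansion plate), and a
borderline rule — a positive clearing its threshold by less than 10% of the
threshold is flagged `near_threshold` and, when a second seeded re-screen
is supplied, confirmed only if it reproduces there. This mirrors the
practical observation that activities close to the cutoff tend not to be
reproducible.

`determine_lod()` implements the validation-side rule: the limit of
detection of an assay is the lowest concentration in a dilution series
whose signal exceeds the negative-control background.

## Tetranucleotide-frequency binning

Only sequences of at least `min_sequence_length` (2 kb) enter the analysis;
each is cut into non-overlapping 2 kb fragments, with sub-window remainders
discarded (`fragment_sequences()` records exclusions). Each fragment yields
a 256-vector of 4-mer frequencies counted on both strands — a fosmid
insert's orientation is arbitrary, so the representation must be
strand-invariant; `strand_symmetric = FALSE` is available for oriented
inputs. Windows containing `N` are skipped; a fragment with no valid window
returns a flagged zero vector. Columns are fixed in lexicographic order
(AAAA … TTTT). Features are z-scored per column (population SD;
zero-variance columns map to 0) before map training — the Euclidean metric
of the map should not be dominated by the high-variance common 4-mers.
`normalization = "none"` switches this off.

### The emergent map

`train_esom()` implements the classic online SOM with the two parameters
that define an *emergent* map: many more neurons than data points (5.5 per
fragment) and a large starting neighborhood (radius 24 grid units). The
remaining schedule is fixed to common emergent-map practice and fully
exposed in the arguments: 20 epochs, Gaussian neighborhood, linear radius
decay 24 → 1 and learning-rate decay 0.5 → 0.05, grid aspect ≈ 1.6, and a
**toroidal** topology (edges wrap), which avoids the border artifacts that
planar maps concentrate mass into. The codebook is initialized uniformly
within the per-feature data range from the seeded RNG; training order is
reshuffled per epoch from the same stream, so a run is a pure function of
its seed. Best-matching units are Euclidean argmins with ties broken to the
lowest row-major index; the C++ search uses the expanded-norm identity and
is tested against a brute-force oracle.

### From U-matrix to bins

The U-matrix assigns every neuron the mean codebook distance to its eight
toroidal neighbors: clusters appear as low basins separated by high ridges.
The original protocol extracted bins by visual inspection; `extract_bins()`
replaces that with a deterministic procedure:

1. neurons with height at or below the `q`-th percentile (default 60) form
   the foreground;
2. toroidal 8-connected components of the foreground are candidate bins;
3. **hysteresis merge**: plain thresholding over-segments — a genuine basin
   can be cut in two by a spurious internal ridge a hair above the cutoff,
   whereas real bin boundaries are wide, high ridges. Two components are
   therefore fused (transitively) when a single boundary neuron touches
   both and its height stays below the `merge_q`-th percentile (default
   80). Setting `merge_q <= q` disables the step;
4. components smaller than `min_neurons` (default 5) are folded into label
   0 (boundary/unassigned).

A k-medoids alternative (`method = "kmedoids"`) and a `manual` neuron-label
override (for maps that *were* inspected visually) are provided. Clones
inherit the bin holding the plurality of their fragments' BMUs
(`assign_clones()`); boundary fragments are ignored unless a clone has
nothing else, majority fractions are reported, and ties go to the bin whose
fragments sit closer to their codebooks, flagged as ties. "Majority" is
deliberately read as plurality — a chimeric clone's fragments may span more
than two bins.

## Annotation concordance

`filter_annotations()` applies the e-value cutoff (default 1e-1) and keeps
the lowest-e-value hit per ORF — per ORF, not per clone, so a clone with
several carbohydrate-active genes keeps them all. Families map to
assayable substrates through an editable two-column config
(`inst/extdata/gh_substrate_map.tsv`): GH1/GH3 to the small beta-glycoside
substrates, GH9 and GH10 to the cellulose/xylan polymers plus
4-MUB-cellobiose, GH13/15/31/97 to starch, GH2/20/84/109 to
N-acetylglucosaminides, phosphatase and peptidase domains to the solid
assays. The shipped map is a best-effort reconstruction from reported
family activities and is data, not code — users should review it.
Carbohydrate-binding modules predict nothing on their own and are logged
separately. Each clone × substrate pair then lands in exactly one of four
states (`classify_concordance()`): `both`, `predicted_only`,
`confirmed_only`, `neither`; `summarize_concordance()` reports
confirmed-given-predicted ratios per substrate (undefined — `NA`, never
0 — when nothing was predicted), and `bin_trait_table()` crosses the states
with genome bins to expose trait co-occurrence within taxa.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
chain assumes, plus full ground truth:

* **Genomes.** Each taxon is an order-3 Markov chain whose transition
  weights are an independent Dirichlet-style draw (gamma weights,
  concentration 0.5, chosen a priori to give clearly distinct signatures);
  by construction different taxa have different 4-mer distributions, which
  is precisely the signal TNF binning uses. Genomes default to 500 kb — a
  desk-scale stand-in; real genomes are larger but the insert-level
  statistics are unaffected.
* **Libraries.** Inserts are uniform 36–48 kb windows at uniform offsets
  (size selection of sheared DNA); clones carry 0–3 planted enzyme genes
  (Poisson with mean `active_gene_rate`, default 0.003 to match the rarity
  of positives in large environmental screens) whose families map to true
  activities; optional linkage groups make families co-occur on one insert.
* **Readings.** Additive: background N(5, 0.5) per liquid substrate +
  host background (0 by default, modelling an expression host whose
  interfering amylase/phosphatase genes are knocked out) + one N(50, 5)
  draw per active clone per timepoint, clipped at zero. Solid-media assays
  are binary. Signal magnitudes are placeholders — the protocol reports no
  plate-reader units — but the *ratios* (signal ≫ plate SD) are what the
  2-SD rule sees.
* **Annotations.** Planted genes are reported with probability 1 − fn_rate
  at e-values log-uniform in [1e-30, 1e-2]; spurious records appear at
  fp_rate per clone with e-values log-uniform in [1e-3, 1], deliberately
  straddling the 0.1 filter.

What the generator does **not** emulate: sequencing reads and assembly
error (the chain consumes assembled clone sequences), cloning bias, host
toxicity, expression failure, and real signal kinetics over the 5-day
incubation. Passing tests therefore demonstrate that the chain recovers
planted truth under its own statistical assumptions — not that those
assumptions hold for any particular wet-lab dataset.

## Numerical and bookkeeping choices

* Seeds are explicit everywhere; `run_pipeline()` derives fixed offsets
  from one master seed, so a report is byte-reproducible from its config.
* Degenerate inputs have defined behavior: a plate of identical wells has
  SD 0 and (strict rule) zero positives; a single-row matrix cannot be
  z-scored (error); a fragment of all `N`s yields a flagged zero vector; an
  empty dilution series is an error while an all-background one returns
  `NA`; clones shorter than 2 kb are excluded with a record rather than
  silently dropped.
* Ratios with empty denominators are reported `NA`, never 0.
* When an operator-supplied clone total disagrees with a count table's own
  sum, both denominators are kept and reported side by side.
* Test and validation problem sizes were chosen to exercise the method at
  realistic signal-to-noise on one CPU: 50-plate null simulations for the
  false-positive rate, a 50-assay-plate (76,000-clone) pooled screen for
  confirmation sensitivity, and taxon-recovery runs of 5 × 30 and 2 × 30
  clones with full-size 36–48 kb inserts (≈ 3,000 2-kb fragments, ≈ 17,000
  neurons).

## Known limitations

* The ESOM replaces visual bin inspection with a thresholded U-matrix;
  `q`, `merge_q` and `min_neurons` are sensible defaults, not universal
  constants, and the U-matrix and partition are exported precisely so that
  a human can override them (`extract_bins(manual = ...)`).
* Composition binning cannot separate taxa with near-identical 4-mer
  usage, and chimeric inserts are assigned to their plurality bin with only
  the majority fraction and tie flag as warnings.
* The family → substrate map is coarse: family membership constrains but
  does not determine substrate range, which is exactly why the concordance
  classification keeps `predicted_only` and `confirmed_only` as first-class
  states rather than treating either list as ground truth.
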