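---
title: "Methods: de novo-guided focused database searching for wastewater metaproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo-guided focused database searching for wastewater metaproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `wwproteome`, the
assumptions behind it, every tunable parameter with its default and the
reason for that default, what the synthetic-data generator emulates and
deliberately does not, and the numerical and open design choices made along
the way. It states no empirical result beyond what the package's test suite
and `scripts/acceptance.R` compute.

## 1. The problem and the model

Shotgun metaproteomics of raw wastewater must identify peptides from an
essentially open taxonomic space. Searching against a comprehensive
reference inflates the search space, which both slows the search and
weakens target-decoy statistics. The strategy implemented here constrains
the space *per sample*:

1. de novo peptide reads taxonomically profile the sample,
2. the profile selects a small focused protein database,
3. identification proceeds in two rounds against that database under
   target-decoy FDR control,
4. identified proteins are grouped by parsimony and quantified by top-3
   peptide areas,
5. quantified groups feed standard community ecology statistics.

### Sequence-level matching in place of spectral scoring

The package operates on peptide *sequences*, not spectra. A de novo read
consists of a peptide string (possibly carrying modification annotations
such as `(+15.99)`), an average local confidence (ALC) in [0, 100], and a
peak area. Canonicalization strips modification annotations and maps both
isoleucine and leucine to the single letter `J`, since the two residues are
isobaric and indistinguishable by mass. "Searching" a read against a
database means looking its canonical sequence up in a hash index of all
tryptic peptides of the database, either exactly (`max_subs = 0`) or
allowing one amino-acid substitution (`max_subs = 1`). The read's ALC
serves as the match score throughout, including in FDR estimation. This is
the substantive simplification of the package: all of the pipeline logic
(profiling, focusing, two rounds, decoys, FDR, grouping, quantification) is
implemented faithfully, while the spectrum-to-peptide scoring function is
replaced by an already-scored sequence read.

### Tryptic digestion

`digest()` cleaves after K or R except when the next residue is P, and
returns every product spanning at most `missed_cleavages` internal cleavage
sites with length within `[min_len, max_len]` (defaults 6 and 50, the
conventional detectable-peptide range). The implementation is verified in
the test suite against an independent brute-force enumeration of all
substrings with tryptic boundaries.

## 2. Stages and parameters

### De novo profiling (`filter_alc`, `profile_sample`)

* `alc = 70` (inclusive): reads with ALC ≥ 70 are kept. This is the
  customary confidence floor for usable de novo reads; below it the
  substitution error rate dominates.
* Duplicate canonical peptides within a sample are merged (areas summed)
  before matching, so profiling counts *distinct* peptides.
* Each matched peptide is assigned the lowest common ancestor (LCA) of all
  taxa its matches belong to; the LCA is then projected to the family rank.
* `min_family_peptides = 2`: a family is *identified* only when at least 2
  distinct peptides resolve to it. A single peptide is too weak an
  observation to admit an entire family's proteome into the search space.
* Profiling matches exactly (`max_subs = 0`) by default: at this stage a
  spurious one-substitution match can pull in a whole family, whereas a
  missed peptide costs little because families need only 2 supporting
  peptides out of many.

### Focused database (`select_by_family`, `merge_databases`)

All global-reference records whose taxon lies under an identified family
form the focused database. Records without a taxon annotation cannot be
placed and are excluded. `merge_databases()` deduplicates by accession with
first occurrence winning, and tags the provenance of appended records.

### Two-round search (`round1`, `build_round2_db`, `round2`)

* Round 1: `mc_round1 = 1` missed cleavage against the focused database,
  no score cutoff — its only job is to shortlist proteins with any
  sequence-level evidence.
* Round 2: the round-1 hit proteins are merged with the full human
  reference proteome (tagged `human_UP000005640`), so human proteins are
  always searchable regardless of the microbial profile. `mc_round2 = 3`
  missed cleavages: the final round is deliberately more permissive so that
  imperfectly digested peptides can still be assigned.
* Decoys: every database entry is reversed (`DECOY_` prefix). Reversal
  preserves length and composition, the standard choice.
* FDR: at candidate threshold *s*, FDR̂(s) = #decoy PSMs ≥ s /
  max(1, #target PSMs ≥ s); the threshold is the *lowest* score with
  FDR̂ ≤ `fdr_alpha = 0.05`, and ties at the threshold are admitted. No +1
  correction is applied to the decoy count — with ALC as the score and
  desk-scale databases the uncorrected estimator is the simpler, more
  transparent choice, and the entrapment experiment provides an independent
  check on it.
* A read matching both target and decoy entries is competed: the decoy
  labels are dropped and the read counts as a target PSM.
* `min_unique = 2`: a protein (group) is significant only with ≥ 2 unique
  peptides, where uniqueness is evaluated at the parsimony-group level.

### Grouping and quantification (`group_proteins`, `build_quant_table`)

* Parsimony grouping: proteins are processed in decreasing peptide-set
  size; a protein whose peptide set is a subset of an existing group's set
  joins that group, otherwise it founds one. A peptide is *unique* when it
  occurs in exactly one group's maximal set.
* Top-3 quantification: a group's abundance in a sample is the sum of its
  three largest peptide areas there (all of them if fewer than three).
  Top-3 is robust to the long tail of weak peptides and is the conventional
  label-free protein-level estimator.
* Retention filters: `min_unique = 2` (inclusive) *and* overall area
  strictly greater than `min_overall_area = 5e5`. The area floor removes
  trace-level groups whose quantification is noise-dominated; the strict
  inequality is deliberate and tested.

### Community analysis

* The microbial dataset contains groups whose representative has a known
  superkingdom other than Eukaryota; the human dataset contains groups of
  genus *Homo*. Groups failing both rules (including taxonomically
  unplaced ones) enter neither.
* `composition()` aggregates per-sample abundance at a chosen rank
  (`composition_rank = "genus"`), weighting by area (default) or by
  presence count, normalizing over *classified* mass and reporting the
  unclassified fraction separately as an attribute rather than as a
  pseudo-taxon.
* Shannon diversity uses `vegan::diversity`, Bray-Curtis uses
  `vegan::vegdist`, and classical PCoA uses `stats::cmdscale` — these are
  standard, well-tested implementations and reimplementing them would add
  risk without substance. Axes dropped by `cmdscale` (negative eigenvalues)
  are zero-padded so the embedding always has the requested width.
* Gut/pathogen categorization assigns each genus to `both`, `pathogen`,
  `gut` or `other` with `both` taking precedence, and reports mean
  composition-weighted fractions.
* The human heatmap normalizes each sample column to 100% and sorts rows
  by the reference sample (first sample by default), so temporal trends are
  read against a fixed ordering.

## 3. The synthetic-data generator

`sim_config()` / `simulate_study()` produce complete, seeded studies:
taxonomy dump (NCBI `nodes.dmp`/`names.dmp` dialect), global and human
reference FASTAs, entrapment FASTA, per-sample de novo read CSVs, genus
annotation lists and ground truth. Defaults:

* **Design**: `n_sites = 2`, `n_timepoints = 5`, `n_replicates = 2`
  (20 samples, named `S<site>T<time>-<rep>`), mirroring a two-site
  longitudinal sampling campaign with technical duplicates. These problem
  sizes are the package's own choice of a desk-scale study that exercises
  every pipeline branch.
* **Reference**: `n_families = 20` community families (bacterial, plant,
  animal, and Hominidae with *Homo sapiens*), `proteins_per_family`
  uniform in [5, 15], `n_human_proteins = 30`, protein lengths uniform in
  [100, 600] with K/R drawn at 2.5× base weight so tryptic peptides are
  plentiful; every generated protein is regenerated until it yields at
  least 2 fully tryptic peptides, guaranteeing it is in principle
  identifiable.
* **Entrapment**: `n_entrapment_families = 5` *additional* families are
  placed in the taxonomy but never expressed in the community; their
  proteins exist only in the entrapment FASTA. Design note: the taxonomy
  therefore contains `n_families + n_entrapment_families` family nodes —
  entrapment families are modelled as real (but absent) taxa rather than
  as anonymous foreign sequences, so that an entrapment hit is a
  taxonomically coherent false positive.
* **Community**: per-site family abundances are log-normal
  (`community_meanlog = 0`, `community_sdlog = 1`); each timepoint
  perturbs them by a log-normal factor (sdlog 0.3); within-family protein
  weights are Dirichlet. This yields the skewed, temporally drifting
  compositions typical of sewershed communities.
* **Reads**: `reads_per_sample = 500`; a read picks a protein
  proportionally to abundance, a peptide from its ≤ 1-missed-cleavage
  digest, and an area equal to the protein weight × 10⁸ × log-normal noise
  (sdlog 0.5). The 10⁸ scale places areas in the range where the 5×10⁵
  overall-area filter is a meaningful, occasionally binding constraint.
* **Error channel**: with probability `error_rate = 0.1` a read carries
  exactly one residue substitution. Correct reads draw ALC from
  N(85, 5), errorful reads from N(65, 10), both clamped to [0, 100] —
  clamped truncation keeps the generator simple, and the overlap between
  the two distributions is what makes FDR control non-trivial: some
  errorful reads pass the ALC ≥ 70 filter and must be caught (or
  correctly admitted at bounded rate) by the target-decoy procedure.
* Every read carries a `read_id` threaded through to surviving PSMs, so
  the realized false-discovery proportion is measurable exactly against
  ground truth.

### What the generator does *not* emulate

* No spectra, retention times, masses or charge states exist; ALC is
  generated, not computed from signal, so the score distribution's shape is
  an assumption rather than an emergent property.
* Protein sequences are independent random strings. Real proteomes share
  homologous peptides across taxa far more than independent sequences do,
  so LCA assignments here are more decisive, and parsimony groups smaller,
  than in real data. Recovery rates on these fixtures are accordingly an
  upper bound, not a field estimate.
* The error channel is a single uniform substitution per errorful read;
  real de novo errors cluster at fragmentation-poor positions and include
  inversions and mass-equivalent substitutions.
* Human proteins follow the same abundance model as microbial ones; real
  wastewater human signal is dominated by a few secreted proteins.

## 4. Numerical and design choices

* The peptide index is an environment-backed hash map; one-substitution
  matching enumerates all single-position variants over the canonical
  alphabet (which includes `J` and `X`) rather than scanning the database,
  making its cost independent of database size.
* Seeds: all derived seeds come from
  `derive_seed(seed, tag) = (seed × 48271 + hash(tag)) mod 2147483587`,
  keeping every seed below 2³¹ and decoupling the random streams of
  different samples and replicates.
* Report writers round to 6 significant digits and sort deterministically
  (descending overall area, then accession) so byte-identical reruns are
  byte-identical outputs; `manifest.json` records MD5 checksums.
* All error signalling uses classed conditions rooted at `ww_error`
  (e.g. `ww_validation_error`, `ww_empty_database`), so callers can
  distinguish bad input from empty-but-valid results programmatically.
* Open decision — FDR estimator: the uncorrected decoy/target ratio was
  chosen over the +1-corrected variant; at desk scale the correction is
  material, and the entrapment experiment exists precisely to validate the
  chosen estimator empirically rather than by construction.
* Open decision — package shape: the artifact is a staged data-processing
  tool, so it exposes one function per stage plus `process_study()` /
  `run_pipeline()` orchestrators, rather than a single fit-style entry
  point returning a model object.

## 5. Limitations

Passing tests demonstrate that the implemented logic is internally
consistent, agrees with brute-force oracles on its primitives, controls the
realized false-discovery proportion on the generator's error model, and
recovers error-free synthetic communities. They do not demonstrate
performance on real spectra, robustness to homology-rich references, or
calibration under error models other than single substitutions. The
package is a faithful, testable implementation of the pipeline's logic at
desk scale, not a drop-in replacement for a spectral search engine.
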