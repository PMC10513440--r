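---
title: "Modelling and calling partial TRBD1-TRBD2 rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and calling partial TRBD1-TRBD2 rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddloop)
```

## The two-synapse model of D1-D2 recombination

In the T-cell receptor beta (TRB) locus each D gene is flanked by two
recombination signals (RS): a 12-spacer RS at its 5' end and a 23-spacer RS
at its 3' end. Because RAG-mediated recombination only joins one 12-RS to
one 23-RS (the 12/23 rule), the TRBD1-TRBD2 pair admits **two** legal
synapses, and each leaves a different product on the chromosome:

* **Coding-joint synapse** (3'D1-RS with 5'D2-RS): the chromosome keeps a
  D1-D2 coding joint — both coding regions, trimmed at their facing ends by
  exonuclease, joined through a nontemplated (TdT) insert. The reciprocal
  RS-RS signal joint leaves on an excision circle.
* **Signal-joint synapse** (5'D1-RS with 3'D2-RS): the chromosome keeps a
  5'D1-RS-3'D2-RS signal joint — usually precise, sometimes with a few
  nontemplated nucleotides — and the intact D1-D2 coding material is excised
  onto the circle.

The chromosomal inter-RS junction is therefore drawn from a **mixture**:
"long" junctions with two D remnants from the first synapse, and "short"
junctions consisting only of the insert from the second. That mixture, its
decomposition, and its detectable by-products (circle signal joints, D1-D2
remnants inside D-J and V-D-J rearrangements) are what this package
simulates and measures.

## Simulator

`sample_dd_events()` draws events under this model; `simulate_dd_reads()`
renders them as the amplicon a primer pair in the genomic flanks would
capture (`flank5 + 5'D1-RS + junction + 3'D2-RS + flank3`) and writes
Phred+33 FASTQ (constant Q30). Both synapses are asserted against the 12/23
rule on every call; constructing a same-class synapse is an error, not a
silent no-op.

Default parameters (all overridable through `sim_params()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `p_signal` | 0.5 | — | the two synapses use structurally equivalent RS pairs; repertoires show both classes in comparable numbers |
| `trim_mean` | 5 | nt/end | memoryless (geometric) exonucleolytic trimming is the standard null; draws are capped at the coding length rather than resampled so events stay well defined |
| `coding_insert` | Poisson(6) | nt | reproduces the observed ~6 nt mean insert at coding joints |
| `signal_insert` | zero-inflated: P(0) = 0.38, else 1 + geometric, non-zero mean 9.677 | nt | precise signal joints are the single most common rearrangement (38% of short-class cells); the law's marginal mean is 6 nt, matching the short-class mean length |
| `insert_base_weights` | uniform | — | no composition bias is assumed; a G-biased TdT profile can be configured |
| `error_rate` | 0 | per base | substitution-only error model; indels are not simulated |
| `clone_size_alpha` | `NA` (off) | — | see below |

With these laws the expected long-junction length is
$12 - E[\min(T_1, 12)] + 6 + 16 - E[\min(T_2, 16)] \approx 24.8$ nt and the
expected short length is 6 nt — the two modes the length mixture should
recover.

**Clone sizes are opt-in.** Clonal expansion is modelled as a discrete power
law $P(k) \propto k^{-\alpha}$ truncated at the event count, which
reproduces the familiar rank-abundance shape. It is disabled by default
because junction-length and decomposition analyses describe recombination
chemistry, and read multiplicity would confound them with expansion: with a
heavy-tailed law a single clone can contribute a third of all reads and
dominate any read-weighted statistic. Rank-abundance and publicity analyses,
where the skew is the object of study, set `clone_size_alpha` explicitly
(the demo pipeline uses 2.5).

`simulate_signal_joint_reads()` renders the excision-circle amplicon
(`dir_primer + 5'D2-RS + insert + 3'D1-RS + revcomp(rev_primer)`), with the
insert drawn from the signal-joint law. `simulate_junction_table()` builds
D1-J2 junction tables and in-frame, stop-free CDR3-like V-D-J2 tables with a
controlled fraction of rows carrying planted D remnants. Planted segments
are contiguous coding substrings drawn to span at least one conservative
motif window: remnants confined to the low-complexity 3' tail would be real
but undetectable by any 7-mer rule, so they belong to the biological miss
rate, not to detector sensitivity, which is what the truth flags calibrate.

## Junction caller

`extract_junctions()` anchors each read on the full 5'D1-RS
(nonamer-spacer-heptamer, 28 nt) and 3'D2-RS (heptamer-spacer-nonamer,
39 nt) on either strand, tolerating one mismatch per 20 anchor bases
(rounded down) — enough to absorb the simulated substitution rate while
keeping the conserved RS discriminative. The junction is the sequence
strictly between the two coding-proximal heptamer edges, i.e. lengths
exclude both RS; reverse-strand reads are normalized to the forward
convention; coordinates are 0-based half-open internally. A read missing
either anchor is a no-call, and anchors in inverted order are a structural
no-call — neither raises an error.

`decompose_junctions()` applies maximal germline matching: the longest
junction prefix identical to TRBD1, then within the remainder the longest
suffix identical to a TRBD2 allele (the longer-matching allele wins, ties
break toward `*01`), the middle being the nontemplated insert. Maximizing
the D1 match first is deterministic and order-stable and matches the
left-to-right reading of junction logos. Insert bases that happen to
continue germline are absorbed into the germline match, so reported matches
are upper bounds on the true retained lengths; the test suite verifies both
the brute-force equivalence of the greedy rule and exact truth recovery
when insert edges are constrained to be non-absorbable.

`classify_calls()` calls a junction **long** when both D matches reach
`min_germline` and **short** when neither does; mixed cases are
**ambiguous**. The default `min_germline = 7` is the most conservative
criterion (a full 7-mer of each D gene); 3 is exposed as a lenient mode.

## The junction-length mixture

`fit_length_mixture()` fits a two-component mixture by EM with
deterministic initialisation (locations at the 25th/75th percentiles, equal
weights, pooled sd), convergence at a log-likelihood gain below $10^{-6}$
(500 iterations at most), and Gaussian standard deviations floored at
0.5 nt against singularities.

A two-Gaussian mixture — the classical descriptive choice — cannot
represent this data: junction lengths carry an atom at exactly zero (the
precise signal joint) and a geometric insert tail. With the atom present
the likelihood is maximised by collapsing one floored-sd Gaussian onto the
spike, which yields component means near 0 and 20 rather than the two
biological modes; this is the global optimum, not an initialisation
artefact. The package therefore also fits a mechanistic family — a
zero-inflated shifted geometric short component (atom for precise joints,
geometric tail for TdT insert lengths, which are geometric under a
memoryless polymerase) plus a Gaussian long component — and selects between
the two families by BIC (`family = "auto"`). On smooth well-separated data
BIC keeps the Gaussian pair; on spiky junction data it selects the
zero-atom family, whose short-component mean is the biologically meaningful
$(1-\pi_0)/q$. Both families expose the same interface (`tidy()`,
`glance()`, `predict()` posteriors, `autoplot()`), and the reported means
are always ascending.

Because the short and long length distributions genuinely overlap (a
geometric insert of 20+ nt is possible), no length-only posterior can fully
agree with the sequence-based caller; the tests therefore check that the
fitted posterior matches the Bayes classifier built from the true
generative densities, rather than demanding near-perfect agreement with the
caller.

## Repertoire statistics

* `aggregate_clonotypes()` merges identical junctions per sample; since
  decomposition is a pure function of the junction string, conflicting
  annotations are treated as corrupted input.
* `diversity_per_cells()` converts DNA input mass to cells at 6 pg of
  genomic DNA per diploid cell (600 ng ≈ 100,000 cells), configurable.
* `indel_stats()` summarizes insert lengths and deletions
  (`len(D1) + len(D2) − d1_match − d2_match`); deletions are only defined
  where germline is identifiable, i.e. for the long class, and are reported
  as missing elsewhere. Summaries are over unique clonotypes by default
  (`weighted = TRUE` weights by clone count): clonotype-level statistics
  describe the generation process, read-level ones fold in expansion.
* `mann_whitney_u()` counts pairs with $x_i > y_j$ (plus 0.5 per tie); the
  exact mode enumerates all group labelings (practical to $n_1+n_2 = 20$),
  and two-sided p-values double the smaller tail, capped at 1. The normal
  approximation applies tie and continuity corrections.
* `publicity()` counts clonotypes present in two or more samples over the
  pooled unique set — presence-based, hence invariant to sample order and
  per-sample depth.
* `position_frequency_matrix()` produces per-column base frequencies over
  non-gap entries (left- or right-aligned), consumable by logo renderers.

## Conservative motif detection

`build_motif_set()` derives gene-specific k-mers from the coding regions of
a gene's alleles. The default exclusion rules keep windows that start
within the first *k* bases of the coding region but not at position 0, and
drop windows containing a homopolymer run of 5 or more:

* the position-0 window is not discriminative — the D gene 5' termini are
  shared (TRBD1 and TRBD2 both begin `GGGAC`);
* windows beyond the first *k* starts lie in the 3' tail, which in TRBD2 is
  low-complexity poly-G and is the part most often destroyed by trimming;
* long homopolymer runs match repetitive background.

For human TRBD2 (`GGGACTAGCGGGGGGG`, `GGGACTAGCGGGAGGG`) with `k = 7` this
derivation yields exactly the seven-motif conservative set bundled as
`TRBD2_MOTIFS_7`; the literal list can also be supplied via
`motif_exclude_rules(literal = ...)`, making derivation a cross-check
rather than a dependency.

`detect_motif_fraction()` is presence/absence per motif set (overlapping,
case-insensitive), with a conjunction over sets: a V-D1-D2-J2 call requires
both a D1 and a D2 motif. The default search window is the full junction
string, matching a plain text-search protocol; `window_trim` can mask
germline V/J termini of CDR3 tables (off by default). Expected chance hit
rates on random sequence are computable exactly with a prefix-automaton
dynamic programme (the test suite does this); the familiar
$1-(1-m4^{-k})^{w-k+1}$ formula overestimates slightly because the motifs
overlap each other.

`call_signal_joints()` reuses the anchor machinery with the 5'D2-RS and
3'D1-RS in head-to-head orientation and reports the bases strictly between
the heptamers; `summarize_signal_joints()` gives the consensus view
(majority insert, fraction of precise joints) that capillary sequencing
would show.

## Pipeline

`run_dd_pipeline()` chains simulate → call → stats → detect from a YAML
config (see `inst/extdata/demo_config.yaml`), validates the configuration
before any stage runs, labels stage failures, and writes a JSON manifest
with per-stage row counts, class fractions, mixture means and detection
fractions. With a fixed seed the manifest is byte-identical across runs.
The package's functions and this vignette are the intended interface; the
pipeline runner is a convenience wrapper, not a shell tool.

## Problem sizes, numerical choices, limitations

The test suite and the bundled acceptance script use 20,000 events for
distribution-level checks (law-of-large-numbers comparisons at ±0.5 nt,
mixture-mean recovery at ±1 nt), 6,000-20,000 rows for detector
calibration, and a few hundred reads for exact-recovery checks; these sizes
make the stochastic assertions comfortably stable under their stated
tolerances. EM tolerance is $10^{-6}$ log-likelihood units, the sd floor
0.5 nt, and all sequence handling is upper-case canonical.

What the simulator deliberately does not model — and what passing tests
therefore do not establish about real data: PCR amplification bias and
chimeric reads, indel sequencing errors (the caller is substitution-only),
paired-end structure, allele-specific RS variation, V/J context beyond the
J2-proximal stub in junction tables, and any estimate of the *biological*
rate of D-D-bearing rearrangements (planted-spike fractions are detector
calibration, not biology). The bundled reference uses real IMGT D coding
sequences, but consensus RS elements and constructed spacers, J regions and
flanks (files are named `*_synthetic` accordingly); analyses of real
libraries should load a full locus reference through
`read_trb_reference()`.
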