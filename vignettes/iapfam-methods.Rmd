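---
title: "Methods: curating and characterizing an expanded IAP gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and characterizing an expanded IAP gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iapfam)
```

This vignette documents the methods implemented in `iapfam`: the
curation rules, the BIR classification model, the architecture rule
table, the expression-status definitions, and the co-expression network
procedure — together with the parameter defaults, numerical choices,
and the design decisions that were genuinely open.

## 1. Curation of the gene set

Candidate IAP proteins enter as HMM hits (Pfam BIR model) plus an
InterProScan-style domain-scan table. Curation applies four stages, in
a fixed order that `run_characterize()` asserts and logs as a funnel:

1. **E-value filter.** A candidate is retained when its HMM E-value is
   strictly below `hmm_evalue_max` (default `0.001`).
2. **CDD confirmation.** The protein must carry at least one BIR hit
   from the CDD source database. BIR evidence is recognized by a
   configurable accession list (`bir_scan_accessions()`: cd00022,
   PF00653, IPR001370, SM00238) or a whole-word "BIR" in the hit
   description — whole-word so that BIRC6-domain hits (IPR022103) are
   not mistaken for BIR repeats.
3. **Identical collapse.** Proteins with byte-identical residues are
   collapsed to one representative. The representative is the
   lexicographically smallest id; any deterministic rule would do, and
   this one needs no auxiliary data.
4. **Haplotig collapse.** Proteins are clustered by single linkage on
   global pairwise identity above `haplotig_identity_min` (default
   0.95). Within a cluster, a member is removed when its read coverage
   is strictly below `haplotig_coverage_ratio` (default 0.5) times the
   cluster maximum; removed members map to the highest-coverage member,
   and `merge_haplotig_counts()` later folds their expression counts
   into that parent, conserving totals. "Similarity" is taken as global
   alignment identity (matches / alignment columns, BLOSUM62, gap open
   10 / extend 1) because the curation literature rarely states a
   formula; single linkage mirrors the greedy clustering of the
   CD-HIT family of tools at these problem sizes.

Pairwise identity is computed by a compiled Gotoh kernel
(`pairwise_identity()`). Because identity can never exceed
min(len)/max(len), pairs below a `screen_min` length ratio can be
skipped exactly — for a 0.95 clustering threshold this prunes the
all-pairs matrix to the near-equal-length pairs that could possibly
matter.

**Flags.** A gene is *intronless* only when every transcript has one
exon; a gene with one single-exon and one spliced isoform is not
flagged (the stricter reading of "genes with a single exon" for
multi-isoform genes). *Tandem arrays* are maximal runs of ≥ 2 IAP genes
on a chromosome with at most `tandem_max_intervening` (default 2)
non-IAP genes between consecutive members and gaps of at most
`tandem_max_gap_bp` (default 200 kb); both values are quantifications
of "tandem" chosen to match how adjacent duplicate blocks look in
annotated molluscan chromosomes, and both are configurable.
*Retroposition* flags fire on the Tc1-like transposase accessions
(IPR002492, IPR027805, IPR038717) and on a configurable
reverse-transcriptase accession list
(`reverse_transcriptase_accessions()`), since the RT domain is usually
named, not pinned to one accession, in annotation practice.

## 2. BIR typing

Typing is a pure function of the residues observed at canonical key
positions; everything before it is alignment plumbing.

**Reference and numbering.** The package bundles a gap-free reference
alignment of Type I and Type II BIR sequences with a positions table
defining canonical numbering 1–100, the nine key positions (34, 57,
60, 76, 77, 80, 81, 82, 84) and fifteen canonically conserved
positions. The bundled alignment is *synthetic*: a consensus backbone
with the canonical residues planted, constructed because a
redistributable curated model-organism alignment is not available to
ship. Classification only ever reads residues at canonical positions,
so the backbone's realism is immaterial to rule logic; what the
synthetic reference cannot provide is agreement, sequence by sequence,
with calls made on real oyster proteins against a real model-organism
alignment. Canonical numbering is fixed by the bundled files and never
re-derived at runtime, so calls are reproducible.

**Anchoring.** `anchor_to_reference()` aligns the reference consensus
globally *within* the query (query flanks free) using BLOSUM62 with
affine gaps (open 10, extend 1), then converts the alignment to a
monotone map between query indices and canonical positions. Canonical
positions with no aligned query residue are deletions. An alignment
score below `score_floor` (default 100; a genuine BIR scores several
hundred, random sequence near or below zero) raises an `Unanchorable`
error rather than producing garbage calls. Anchoring is invariant to
flanking extensions, which the tests exercise to ±30 residues.

**Rules and precedence.** `classify_bir()` tries rules in the fixed
order NZBIR → TypeY → TypeX → TypeII → TypeI → TypeII-like →
TypeI-like:

| type | rule |
| --- | --- |
| NZBIR | T at 57 (first zinc-coordinating Cys lost) |
| TypeY | ≥ 3 consecutive deleted canonical positions spanning 80 |
| TypeX | G80 and R82 |
| TypeII | E/Q 76, H77, W/H 80, C84 |
| TypeI | H77, V/L 80, C84 |
| TypeII-like | E76 and H77 (not full TypeII) |
| TypeI-like | I/V/L at 80 and/or S81 (nothing above) |

The rules themselves imply no ordering; the package places the
single-position novel diagnostics first because they are strictly more
specific observations than the broad conserved patterns — an NZBIR with
an otherwise perfect Type II helix should be reported as NZBIR, not
hidden inside TypeII. The precedence is an argument and is reported
with the calls. Two narrower decisions: only E76 (not Q76) qualifies
for TypeII-like, matching the stated "E76 prior to the conserved H77";
and only the two explicit TypeI-like patterns (hydrophobic 80, S81)
are implemented, since no further Type I-like diagnostics are
defined. "Loss of three amino acids including position 80" is
operationalized as a deletion run of length ≥ 3 covering canonical 80.

**BIR\* calls.** BIR domains whose scan evidence lacks a CDD hit are
still typed but flagged `bir_star`, and tokenize as `BIR_STAR` in
architectures.

## 3. Architecture typing

`tokenize_architecture()` converts a transcript's hits into an ordered
N→C token string: non-BIR hits map through a configurable
accession→token table (RING, DD, UBA, UBC, BIRC6 domain, WD40);
same-token hits in one connected overlap component collapse to a single
token; BIR spans are replaced by their typed tokens. Unknown accessions
become `OTHER` and are ignored during matching — the defined types are
determined by the canonical domains, not by incidental hits.

`classify_architecture()` returns the first rule in table order whose
pattern matches exactly; the table is ordered longest-pattern-first.
The textually defined types (BIRC2/3-like, BIRC5/6/7-like, BIRC10,
BIRC11) ship as stated; the figure-only compositions (BIRC9, BIRC12,
DIAP1-like, BIRC4-like) ship as editable placeholders and results
depending on them should be treated as provisional. `ANY_BIR+` in the
BIRC6-like patterns matches one or more BIR tokens, since BIRC6-like
proteins vary in BIR count.

**Clusters.** `extract_supported_clusters()` returns the outermost
clades with bootstrap support > 90 containing both required species
tags; clusters are disjoint by construction. `cluster_consensus()`
reports the shared type when all members agree (a *conserved*
architecture), otherwise the majority type flagged mixed, with ties
listed explicitly.

## 4. Expression status

Statuses are computed strictly downstream of a DE model's decision
rule. Per experiment: a transcript is *significant* when `padj ≤ 0.05`
in any comparison; transcripts with total counts < 10 are removed
outright; a transcript is *constitutive* when never significant and
detected (count ≥ 1, configurable) in every sample. Genes aggregate to
`differential` / `constitutive` / `mixed` / `not_expressed`, which
partitions the gene set. Haplotig counts are folded into parents before
classification.

"Shared" differential expression is reported as the fraction of the
DEG union found in ≥ 2 experiments; because the sharing denominator is
a reporting convention rather than a defined statistic, the
all-experiments variant is emitted alongside.

## 5. The co-expression network

All network mathematics is implemented in the package (the correlation,
adjacency, TOM, and module steps are the package's own code, checked in
tests against direct-formula and exhaustive oracles).

* **bicor** uses Tukey biweights around the median with the 9·MAD
  scale; weights vanish for |u| ≥ 1. Zero-MAD genes fall back to the
  Pearson transform for affected pairs; constant genes yield 0 with a
  warning. Values are clamped to [−1, 1].
* **Signed-hybrid adjacency**: a_ij = cor^β for cor > 0, else 0.
* **Soft threshold**: for each candidate power 1–20, connectivity is
  binned (10 quantile bins of log10 k), log10 frequency is regressed on
  log10 mean-k, and the signed R² (−sign(slope)·R²) is compared to 0.8.
  The smallest passing power wins; with no passing power and < 30
  samples the fallback β = 9 applies (the stated signed-hybrid
  small-sample convention). With ≥ 30 samples and no passing power the
  best-fitting power is used — the fallback rule is defined only for
  the small-sample case.
* **Modules**: average-linkage clustering on 1 − TOM with a static
  cut. The cut height is chosen by scanning a grid of fractions of the
  maximum merge height (default 0.5–0.999) and keeping the cut that
  yields the most *accepted* clusters, where a cluster is accepted when
  it has ≥ `min_module_size` (default 30) genes and its mean
  within-cluster TOM is at least `module_density_min` (default 2)
  times its mean TOM to the rest of the network. The density gate is
  what keeps unstructured data module-free: white noise produces large
  clusters at high cuts, but never clusters twice as dense as their
  surroundings. A dynamic tree cut was deliberately not reimplemented;
  the height scan is reproducible, and the accepted-cluster criterion
  is the static analogue of what a dynamic cut's minimum-cluster rules
  achieve at these problem sizes.
* **Eigengenes** are the first principal component of the module's
  standardized expression, sign-aligned to the module mean; modules
  whose eigengenes correlate above 1 − `merge_height` (default 0.25)
  merge iteratively.
* **Module–trait**: Pearson r of eigengene and trait, p from
  t = r√(n−2)/√(1−r²) on n − 2 df; a module is significant only when
  p ≤ 0.05 *and* it contains ≥ 1 IAP transcript and > 1
  apoptosis-related transcript.
* **Direct edges**: within significant modules, IAP–apoptosis pairs
  with adjacency ≥ `edge_adjacency_min` (default 0.1). "Sharing an
  edge" needs a quantitative cutoff; 0.1 on the adjacency scale
  was chosen once as the smallest weight clearly separated from the
  near-zero background that β = 9 produces, is configurable, and is
  reported with every edge list. Edge lists are therefore
  method-sensitive in a way the significance calls are not.

The trait is a binary challenged/control indicator by default;
multi-level designs are handled by splitting experiments before network
construction, mirroring per-experiment analysis practice.

## 6. What the synthetic data emulates — and what it does not

The generators produce every input format the pipeline reads, with
serialized truth:

* `gen_bir()` instantiates the reference backbone with a type's key
  residues, optional random flanks, and mutations restricted to
  non-key, non-conserved positions.
* `gen_family()` concatenates domain templates per architecture with
  random 15-residue linkers; plants haplotigs as near-copies (3%
  substitutions, 0.3× parent coverage), decoys that fail exactly one
  curation rule each, intronless genes, tandem arrays (placed with 4
  background genes between singletons so that only planted arrays
  qualify), and retroposition ORF hits.
* `gen_expression()` builds module genes as loading·factor + noise
  (pairwise within-module correlation equals the loading²), with the
  module factor correlated to the binary trait at a specified r in
  expectation — the null (r = 0) keeps its proper sampling
  distribution, which the type-I-rate test relies on.
* `gen_de_tables()` draws padj below/above 0.05 and counts consistent
  with each planted status.

All generators restore the caller's RNG state and are byte-reproducible
given their seed. Scales used by the tests and the verification script:
700 BIR instances (100 per type), 200 proteins across all architecture
types, a 500-gene annotation with 50 haplotigs, and 4-module expression
at 200 genes × 20 samples over 10 seeds — sizes at which every stage
runs in seconds to a couple of minutes.

What passing on synthetic data does **not** show: realism of the
backbone outside the canonical positions; scanner behaviour (domain
boundaries are exact in synthetic tables, fuzzy in real InterProScan
output); count properties of real RNA-seq (the expression generator
works on the transformed scale and the DE model is out of scope);
evolutionary structure in the trees (cluster tests use random labelled
topologies). Recovery percentages on synthetic data are closure checks
of the pipeline's logic, not estimates of accuracy on real genomes.

## 7. Degenerate inputs and numerical conventions

* Coordinates are 0-based half-open internally; conversion happens only
  at I/O boundaries (GFF3 and scan tables are 1-based inclusive).
* Ties in `cluster_consensus()` list all tied types; empty clusters are
  errors, as are exons without parents, padj outside [0, 1], duplicate
  FASTA ids, unbalanced Newick parentheses, and missing coverage for a
  clustered protein.
* `bicor` on fewer than 4 samples is refused; correlations of constant
  genes are reported as 0 with a warning rather than NA so adjacency
  stays well-defined.
* The boundary of the haplotig rule is strict: exactly half the cluster
  maximum coverage is *not* "< half" and the member is kept. The padj
  boundary is inclusive: exactly 0.05 is significant.
* Equality tolerances in tests: 1e-10 for bicor against the direct
  formula, exact integer equality for position maps against the DP
  oracle (asserted on substitution-only mutants, where the optimum is
  unique; gapped optima can tie, making traceback comparison
  ill-posed).

## 8. Known limitations

* Architecture patterns for BIRC9/BIRC12/DIAP1-like/BIRC4-like are
  placeholders (see §3).
* The haplotig screen's single-linkage clustering is adequate at
  hundreds of proteins but would chain at much larger scales.
* Secondary structure is not modelled; NZBIR's presumed loss of zinc
  coordination is a sequence-level call only.
* The network stage assumes a real-valued, already-normalized
  expression matrix; batch correction and variance-stabilization are
  upstream concerns.
* Published intronless-gene counts for the two oyster species vary
  between reports; the package reports what it computes from the
  annotation it is given and does not attempt to reconcile published
  counts.
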