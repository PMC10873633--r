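---
title: "Methods: clonal and maturation analysis of CSF BCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal and maturation analysis of CSF BCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrcsf)
```

## The problem

In LGI1 and CASPR2 antibody encephalitis, autoantibodies of the IgG4
subclass attack neuronal surface antigens. A central question is where the
pathogenic B-lineage cells mature: in peripheral germinal centres before
entering the central nervous system, or intrathecally, inside the CSF
compartment. `bcrcsf` implements the single-cell BCR repertoire analyses
that address this question: clonal inference, reconstruction of each
clone's naive precursor (the unmutated common ancestor, UCA), a
peripheral-versus-intrathecal maturation contrast, clone-size-stratified
autoantigen-specificity enrichment, and supporting cell-state and antibody
index computations. Because primary patient repertoires of this kind are
access-controlled, the package ships a V(D)J recombination simulator with
complete ground truth, so every inference step can be validated against
known answers.

## Clonal model

Cells are grouped into clones when their heavy chains share the
(allele-stripped) V gene and J gene, have identical junction nucleotide
length, and their junctions lie within Hamming distance strictly below 6
under single-linkage clustering (`cluster_clones()`). The strict threshold
matters: a pair at distance exactly 6 is split. Single linkage means
clones are the connected components of the thresholded distance graph, and
the implementation is tested against an exhaustive transitive-closure
oracle. Within each clone the *founder* is the member with the fewest
total (heavy plus light) somatic mutations, ties broken by smallest cell
id (`identify_founder()`); it is taken as the cell closest to the clone's
state on CNS entry.

The junction distance is computed on nucleotides. The clone definition in
the field is sometimes stated on amino acids; nucleotide distance is the
Immcantation convention and the one used here (the threshold is a
parameter, so an amino-acid variant can be emulated by clustering on
translated junctions).

## UCA reconstruction

`assign_germline()` aligns candidate germline V and J segments without
gaps over a small window of offsets, maximising identity
(matches/aligned length) with lexicographic tie-breaking.
`reconstruct_uca()` then replaces mutated bases with their germline
template. Two modes are provided:

* `revert_nonsilent` (default): only substitutions that change the encoded
  amino acid are reverted, and non-templated N-region nucleotides are
  never modified. Silent/nonsilent status is evaluated codon-wise against
  the progressively reverted sequence and swept to a fixpoint, which makes
  the operation idempotent even when one codon carries two substitutions.
* `revert_all`: every templated mismatch is reverted. This is the
  conventional UCA definition, and on simulated (substitution-only) data
  it provably recovers the true naive sequence at every templated
  position, which the tests assert at scale.

When a chain carries an N-region mask (simulated or annotated data), the
mask delimits the templated V, D and J regions exactly and the D segment
is placed by best substring match inside the junction interior. Without a
mask, positions not covered by the V or J alignment — the N regions, the
D segment and any trimmed V tail — are conservatively treated as
non-templated and left unreverted. This slightly under-reverts real data
near the junction; it is the price of refusing to guess templates where
the alignment is ambiguous.

## Compartment contrast

For each clone, `compartment_contrast()` compares

* `d_peripheral`: normalised Hamming distance between the founder's heavy
  chain and its UCA — maturation acquired before CNS entry, and
* `d_intrathecal`: the maximum distance from the founder to any clone
  member — maturation acquired inside the CNS (0 for singletons),

with a paired two-sided Wilcoxon signed-rank test across clones, overall
and stratified by clone size (< 4 versus >= 4 members). The distance is a
plain mismatch fraction on the heavy V(D)J, a transparent proxy for
codon-model phylogenetic distances; absolute values are therefore not
comparable to likelihood-based scales, and conclusions are drawn from the
ordering and the paired test, not from magnitudes.

## Specificity enrichment

Autoantigen reactivity is treated as a clone-level property — observed
repertoires of this disease show clone members sharing reactivity — so
`propagate_reactivity()` extends tested members' labels to untested
members of the same clone (conflicting tested labels are an error, not a
vote). `stratify_by_clone_size()` reports reactive fractions for
singletons, 2-3-member and >= 4-member clones, with an exact test on the
category-by-reactivity table. `adjusted_specificity()` implements the
untested-singleton adjustment
\((n_\text{reactive} + r_1 n_\text{untested}) / (n_\text{tested} + n_\text{untested})\),
where \(r_1\) is the observed singleton rate; the formula is stated
explicitly because published descriptions of such adjustments are usually
verbal.

`fisher_exact()` computes the two-sided p-value by direct hypergeometric
enumeration using the point-probability rule (all tables with the observed
margins whose probability is at most that of the observed table, within
relative tolerance 1e-7). Conventions for two-sided exact tests differ;
this is the most common one, and the implementation is verified against an
independent exact-test routine on every 2x2 table with margins up to 12.

The antibody index is \((\text{auto}_{CSF}/\text{auto}_{serum}) /
(\text{IgG}_{CSF}/\text{IgG}_{serum})\) with a strict cutoff of 4 for
intrathecal synthesis; it is invariant to rescaling the autoantibody assay
units. CDR3 charge counts K/R as +1 and D/E as -1 with histidine at 0 by
default (yielding integer medians; `h_charge = 0.1` approximates partial
protonation). Privacy of a BCR is summarised by `closest_identity()`: the
maximum ungapped percent identity to a reference CDR set, with "private"
meaning strictly below 80%.

## The simulator

`simulate_repertoire()` generates clones by recombining V (D) J segments
from a bundled synthetic germline library (`toy_segment_library()`: 5 V,
3 D, 3 J for IGH and 5 V, 3 J for IGK, with conserved Cys/Trp/Phe anchor
codons and stop-free V frames), with exonuclease trimming (up to 3 nt per
end by default) and at least one non-templated N nucleotide per join
(mean 4), length-adjusted so junctions stay in frame.

Mutation is substitution-only and two-tiered, mirroring the biology the
analysis probes: a peripheral load applied once from naive to founder
(`mu_peripheral = 0.05` per site, giving founders of roughly 25-45 total
mutations, a realistic IgG load) and a much smaller intrathecal rate per
branching step within the clone (`mu_intrathecal = 0.002`, giving the
near-zero intraclonal diversification reported for CSF expansions). Clone
sizes are mostly 1 with a tail to 8; reactivity is drawn per clone with
probabilities 0.6/0.8/1.0 for singletons, 2-3 and >= 4-member clones,
reproducing the observed 62% → 79% → 100% specificity gradient in
expectation. Subclass usage starts IgG4-dominated and may add one
downstream target per clone (IGHG3 < IGHG1 < IGHG2 < IGHG4) that members
adopt with probability 0.15, so clones express one or two subclasses and
never switch upstream. Endpoint concentrations of reactive cells fall
log-normally with total mutation load
(\(\log_{10} c = 1.5 - 0.06\,m + \varepsilon\), \(\varepsilon \sim N(0, 0.35)\)),
so the mutation-affinity rank correlation is recoverable with a negative
sign.

Two generator properties are enforced rather than left to chance, because
they define the regime the clustering contract describes: within every
(V gene, J gene, junction length) group, junctions of different clones
are kept at Hamming distance >= 6 and intraclonal junctions below 6, by
rejection sampling. Under these conditions clonal inference is exactly
recoverable (adjusted Rand index 1), which is what the corresponding test
asserts. What passing these tests does *not* show: robustness to indel
SHM (the simulator and the UCA algorithm are substitution-only by
design), to SHM hotspot targeting, to allelic germline novelty, or to
borderline clones whose junctions straddle the threshold — real
repertoires contain all of these.

## Cell states and expression

`classify_cells()` assigns each cell the reference profile (memory B cell,
preplasmablast, plasmablast, plasma cell) with the highest Spearman
correlation over the 500 most variable reference genes — a single-pass
nearest-reference classifier, deliberately without iterative marker
fine-tuning; rank correlation makes it invariant to monotone per-cell
transformations. `xbp1_positive()` flags engagement of the secretory
program. `pseudobulk_contrast()` is a consistency-across-donors
fold-change screen ((mean+1)/(mean+1) per donor on the linear scale,
threshold 100-fold in every donor): it is labelled as a screen, not a
variance-modelled differential expression test, because the aim is a
reproducible shortlist rather than calibrated p-values.

## Numerical choices and degenerate inputs

* All file coordinates (FASTA anchors, N-region masks) are 0-based; R
  internals are 1-based with conversion at the IO boundary.
* Ties are always broken deterministically (lexicographically smallest
  segment or cell id; fixed label order MBC < prePB < PB < PC).
* Constant vectors make rank correlations undefined; these are reported
  as not-applicable rather than 0.
* A compartment contrast in which every clone has equal peripheral and
  intrathecal distances has no paired information; the p-value is `NA`.
* Cells with more than one productive heavy chain are excluded at import
  (with a logged reason) — the conservative choice when the true pairing
  is unknowable; cells without a light chain are retained for
  heavy-chain-only analyses.
* Germline assignment failing 50% identity excludes the cell downstream
  rather than attempting gapped alignment.

## Problem sizes

The validation suite runs the clone-recovery check on 200 simulated
clones, UCA recovery on 500 cells, the compartment contrast power check on
100 independent 30-clone simulations, and enrichment recovery on 500
clones; these sizes give the binomial checks useful power while keeping
the whole suite fast on a laptop.

## Known limitations

* Substitution-only SHM: insertions/deletions in real lineages will break
  the equal-length assumptions; affected chains should be excluded
  upstream.
* The `revert_nonsilent` UCA retains silent mutations by construction; it
  matches the reversion protocol used for expressed UCA constructs in
  this disease context but is not the phylogenetic UCA (`revert_all` is).
* Without an N-region mask, junction-interior mutations are invisible to
  reversion and mutation counts are slightly conservative.
* The lineage distance is not a calibrated evolutionary distance.
* The cell-state classifier has no "none of the above" class besides the
  degenerate `unknown`.
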