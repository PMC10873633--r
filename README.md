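# bcrcsf

Clonal and maturation analysis of cerebrospinal-fluid (CSF) B cell
receptor (BCR) repertoires in autoantibody-mediated encephalitis.

In LGI1 and CASPR2 antibody encephalitis, IgG4-dominated autoantibodies
target neuronal surface proteins, and single-cell sequencing of CSF
B-lineage cells can reveal where the pathogenic cells matured: in the
periphery before entering the CNS, or intrathecally. `bcrcsf` is an R
package for the repertoire analyses this question requires, aimed at
immunologists and computational biologists working with paired heavy/light
single-cell BCR data:

* **Clonal inference** — clones share heavy-chain V gene and J gene with
  identical junction length and junction nucleotide Hamming distance < 6
  under single linkage; the clone **founder** is the member with the
  fewest heavy+light mutations.
* **UCA reconstruction** — the unmutated common ancestor is rebuilt by
  germline reversion (nonsilent-only, per the expressed-construct
  protocol, or full reversion), never touching non-templated N-region
  nucleotides.
* **Compartment contrast** — per clone, d(UCA, founder) estimates
  peripheral maturation and max d(founder, member) estimates intrathecal
  maturation (normalised Hamming distances); the two are compared with a
  paired Wilcoxon signed-rank test.
* **Specificity enrichment** — clone-level reactivity propagation,
  reactive fractions stratified by clone size (singletons / 2–3 / ≥ 4
  members), an untested-singleton adjustment
  (n_reactive + r₁·n_untested)/(n_tested + n_untested), and exact 2×2
  contingency tests by hypergeometric enumeration
  (point-probability rule).
* **Clinical indices** — intrathecal antibody index
  AI = (auto CSF/serum)/(IgG CSF/serum) with the > 4 cutoff, IgG4:IgG
  ratios, IgG subclass switch-order checks
  (IGHG3 < IGHG1 < IGHG2 < IGHG4), CDR3 charge/length features, and
  closest-identity ("privacy") search against a reference CDR set.
* **Cell states** — rank-correlation nearest-reference classification
  (MBC / prePB / PB / PC), XBP1 positivity, and a per-donor pseudobulk
  fold-change screen.
* **A ground-truth simulator** — `simulate_repertoire()` generates
  clonally structured IgG repertoires by V(D)J recombination with
  two-tier somatic hypermutation (peripheral germline→founder, sparse
  intraclonal), clone-linked reactivity rising with clone size,
  downstream-only subclass switching, and full per-cell truth (naive
  sequences, N-region masks, clone ids, mutation counts), so every
  inference step is testable against known answers.

Input is the AIRR Rearrangement TSV format (one row per chain) plus an
optional per-cell metadata CSV and a pipe-annotated germline FASTA
(`id|locus|type|anchor`, 0-based anchors).

## Worked example

```r
library(bcrcsf)

lib <- toy_segment_library()
sim <- simulate_repertoire(lib, sim_config(n_clones = 120, seed = 42))

clones <- cluster_clones(sim$cells)
asg    <- assign_repertoire(sim$cells, lib)
counts <- count_mutations_repertoire(sim$cells, asg)
clones <- annotate_founders(clones, counts)
ucas   <- reconstruct_uca_repertoire(sim$cells, asg, mode = "revert_all")

cc <- compartment_contrast(clones, sim$cells, ucas)
cells <- propagate_reactivity(sim$cells, clones)
strat <- stratify_by_clone_size(cells, clones)
corr  <- correlate_mutations_affinity(cells, clones, counts)
```

This prints (numbers from the run above):

```
cells: 202
clones: 120  expanded: 28
median d_peripheral: 0.0466   median d_intrathecal: 0   p: 1.99e-21
  size_category n_tested n_reactive      rate
1     singleton       92         58 0.6304348
2         small       39         26 0.6666667
3         large       71         71 1.0000000
overall enrichment p: 1.49e-10
spearman rho: -0.68  p: 2.6e-12  n: 81
```

Reading the output: the 202 simulated cells fall into 120 clones;
peripheral distances (median 0.047) dwarf intrathecal ones (median 0,
paired p ≈ 2e-21), i.e. the mutation load was acquired before CNS entry;
reactive fractions climb from 63% in singletons to 100% in ≥ 4-member
clones; and founders with more mutations have lower endpoint
concentrations (stronger binding), Spearman ρ = −0.68. The clinical
antibody index works the same way:

```r
antibody_index(auto_csf = 8, auto_serum = 2, igg_csf = 40, igg_serum = 9000)
#> $index: 900      $intrathecal: TRUE
```

## Documentation

The methods vignette (`vignettes/csf-bcr-repertoire.Rmd`) describes the
models, parameter choices, numerical conventions, what the simulator does
and does not emulate, and known limitations.
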