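# bitterevo

Evolutionary analysis of strychnine recognition by bitter taste receptors.

Two human bitter taste receptors (Class A GPCRs), hT2R10 and hT2R46, are
activated by the plant alkaloid strychnine, but mutagenesis and modeling
show they bind it in two different modes built from largely different
binding-site residues. `bitterevo` provides the comparative pipeline for
asking when and how each binding mode arose in the receptor family:

* **Formats & numbering** — FASTA/Newick I/O, homolog filtering by global
  alignment identity (default ≥ 55%) and fragment length (> 265 residues),
  and anchoring of Ballesteros–Weinstein (BW) labels (e.g. `3.32`, `7.39`,
  `ECL2`) onto alignment columns via a reference sequence.
* **Phylogenetics core** — reversible amino-acid substitution models
  (Poisson and empirical JTT from a bundled PAML-format file, optional
  discrete-gamma rates), Felsenstein pruning log-likelihoods with scaling,
  model-based pairwise distances, neighbor-joining topologies and
  maximum-likelihood branch lengths.
* **Ancestral reconstruction** — marginal posteriors per node and site
  (`marginal_asr()`), joint reconstructions (`joint_asr()`), dual-call
  reporting at ambiguous sites (`"T/A"`), majority-rule gap flags, and
  extraction of key-residue matrices with posteriors.
* **Relative dating** — `relative_rates()` assigns relative node times
  (ingroup root = 1, tips = 0) and mean-normalized lineage rates under the
  sibling-elapsed-time-equality constraint of RelTime-style dating.
* **Site-specific selection** — `site_dnds()`, a counting (NG86/SLAC-style)
  estimator of per-codon-site dN/dS with a binomial score test and
  positive/neutral/purifying classification.
* **Binder classification** — a bundled, data-driven catalog of the 12
  (hT2R10 mode) and 15 (hT2R46 mode) key binding-site positions over 20
  distinct BW labels with mutagenesis-derived substitution rules, and
  `classify_binder()`, which scores any residue map under both modes and
  returns `binder` / `reduced_binder` / `uncertain` / `non_binder`.
* **Simulators** — protein and codon (Gillespie, true syn/nonsyn event
  counts) evolution along known trees with recorded ancestral truth, plus
  binder gain/loss histories for convergence scenarios.
* **Pipeline & CLI** — `run_pipeline()` orchestrates filter → tree → ASR →
  dating → classification → selection from one YAML/JSON config;
  `inst/scripts/bitterevo` exposes `filter`, `tree`, `asr`, `reltime`,
  `dnds`, `classify`, `simulate`, `run-all` subcommands.

## The model in brief

Sequence likelihoods use reversible CTMC models `Q = S diag(pi)` scaled to
one expected substitution/site/unit length, `P(t) = exp(Qt)`. Ancestral
posteriors at node *v* are `P(state | data) ∝ F_v · G_v` (subtree and
rest-of-tree messages). Relative times satisfy
`T(child) = T(parent) · L(child)/(b + L(child))` with `L` the mean tip-path
length, so sibling lineages span equal time. Per codon site,
`omega = (Nd/N)/(Sd/S)` with NG86 fractional site counts and observed
changes summed over branches between reconstructed codons. Binder verdicts
follow ordered substitution-effect rules (exact match → binder; abolishing
change → non-binder; non-conservative change at a critical position →
non-binder; unknown effects → uncertain; tolerated/reduced → reduced
binder), per binding mode, best mode wins.

## Worked example

Classify the reconstructed common ancestor of the two receptor clades
(column `N2` of the bundled key-residue matrix) against the catalog:

```r
library(bitterevo)
catalog <- load_catalog()
n2 <- residue_map("N2")
classify_binder(n2, catalog)
#> binder_call: non_binder (R10: non_binder, R46: non_binder)
#>  mode bw_label observed key criticality     effect
#>   R10     3.33        T   V  supporting disruptive
#>   R10     3.37        H   Q    critical disruptive
#>   R10     5.39        N   K  supporting disruptive
#>   R10     5.40        M   Q    critical disruptive
#>   R10     7.42        A   T    critical disruptive
#>   R46     2.61        G   W  supporting disruptive
#>   R46     2.65        V   E  supporting  tolerated
#>   R46     2.66        F   L  supporting disruptive
#>   R46     4.65        D   N  supporting disruptive
#>   R46     5.42        L   V  supporting    similar
#>   R46     6.63        N   E  supporting disruptive
#>   R46     7.39        M   E    critical disruptive
#>   R46     7.43        I   F    critical    reduced

conserved_count(n2, catalog, "both")$n_conserved
#> [1] 11
```

The deep ancestor conserves 11 of the 20 key positions, but the pattern is
a mosaic of the two modes — non-conservative changes at critical positions
of *both* modes — so it is called a non-binder under each, consistent with
the two clades acquiring strychnine recognition independently. Ancestors
close to each human receptor (e.g. `N94`, `N34`) classify as binders or
reduced binders instead; see `load_reference_residues()` for all columns.

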