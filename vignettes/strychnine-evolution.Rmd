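---
title: "Tracing the evolution of strychnine recognition in bitter taste receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the evolution of strychnine recognition in bitter taste receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the approach

Two human bitter taste receptors, T2R10 and T2R46, respond to the alkaloid
strychnine, yet site-directed mutagenesis shows they hold the ligand in two
different binding modes built from largely different sets of binding-site
residues. `bitterevo` packages the comparative machinery needed to ask when
each binding mode arose: it reconstructs ancestral receptor sequences on a
phylogeny with per-site posterior probabilities, places relative divergence
times on the nodes, estimates site-specific dN/dS on codon alignments, and —
the receptor-specific layer — reads every extant and reconstructed sequence
out at the 20 mutagenesis-annotated Ballesteros–Weinstein (BW) positions and
classifies it as `binder`, `reduced_binder`, `uncertain` or `non_binder`
under each binding mode.

All positions are indexed by BW labels (`X.50` is the most conserved residue
of transmembrane helix `X`; loop residues carry labels such as `"ECL2"`), so
the same catalog applies to any receptor aligned to the references.

## Substitution model and likelihood machinery

Likelihoods use reversible continuous-time Markov models: `poisson_equal`
(uniform exchangeabilities and frequencies; useful because many quantities
then have closed forms) and `empirical`, by default the JTT matrix shipped
as a PAML-format data file (`inst/extdata/jtt.dat`) and parsed by
`read_paml_dat()`. The generator is `Q = S diag(pi)` rescaled to one
expected substitution per site per unit branch length; `P(t) = exp(Qt)` is
computed from the symmetric eigendecomposition of the reversible generator.
Optional rate heterogeneity uses Yang's discrete-gamma approximation with
`k` equal-probability categories (category means; `k = 4` by default when a
shape is supplied).

`log_likelihood()` is Felsenstein pruning over unique column patterns with
per-node rescaling (log accumulators), so alignments of a few hundred taxa
and sites stay in range. Gaps and unknown residues (`X`, and `N` for DNA)
are missing data: their tip partial is a vector of ones. The package never
searches topologies; a user Newick is used when given, otherwise neighbor
joining (`ape::nj`, negative branch lengths clamped to zero) on model-based
pairwise distances, with optional maximum-likelihood branch lengths by
coordinate ascent (Brent per branch on the exact conditional likelihood of
that branch; the log-likelihood is non-decreasing across sweeps).

## Ancestral reconstruction

`marginal_asr()` returns, for every internal node and column, the posterior
distribution over residues (up/down message passing; mixed over gamma
categories weighted by per-site category likelihoods), the MAP residue and
its posterior, and the runner-up. `joint_asr()` returns the single jointly
most probable assignment (max-product dynamic programming in log space).
Two reporting conventions matter:

* **Ties.** When the top two posteriors differ by less than `tie_delta`
  (default 0.05), `extract_key_residues()` reports both, `"T/A"`, with the
  primary first — matching how dual predictions are reported at highly
  variable positions such as 7.42. Downstream classification uses the
  primary residue.
* **Gaps.** A node-site is flagged as a gap when more than 50% of its
  descendant leaves are gapped there (a simple majority rule rather than a
  likelihood model of indels; the rule is deliberately crude but
  deterministic and testable) and is excluded from residue calls.

Reconstruction requires a rooted tree; root by outgroup first. On data
simulated under the shipped JTT model the posteriors are calibrated: among
site–node pairs with posterior above 0.99 the MAP residue matches the true
simulated ancestor in over 99% of cases, and per posterior decile the mean
posterior tracks empirical accuracy within five points (both are asserted
by the test suite at 16 taxa and 1000–2000 sites).

## Relative divergence times

`relative_rates()` implements a deliberately simplified, fully testable
variant of relative-time dating: bottom-up, each node's tip-count-weighted
mean tip-path length `L(v)` is computed; node times follow
`T(child) = T(parent) * L(child) / (b + L(child))`, which forces every
sibling lineage to span the same elapsed time from the shared parent to the
present (tips sit at 0, the ingroup root at 1); each branch's relative rate
is its length divided by its elapsed time, mean-normalized over ingroup
branches. Zero-elapsed branches get rate 1 by convention. We chose this
variant over the full published implementation (with its iterative
rate-merging tests) because it preserves the defining constraint — sibling
elapsed-time equality — while every intermediate quantity has a closed form
a test can check: ultrametric input gives all rates exactly 1 and times
proportional to node heights, and all outputs are invariant to global
branch-length rescaling.

Two caveats belong here. First, per-branch lineage rates are only
identifiable when rate variation is heritable along lineages (clade-wise
shifts); independent per-branch rate noise cannot be recovered by any
sibling-equalizing method. Second, a measurement subtlety: when the true
rates form two classes, the tie-corrected Spearman correlation between
estimated and true branch rates is capped well below 1 (about 0.87 at a
balanced split, lower otherwise) *even for an estimator that separates the
classes perfectly*, simply because the truth vector is two-valued. The test
suite therefore also checks complete separation of the two classes
directly, and the acceptance script reports both the Spearman value and the
separation AUC.

## Site-specific dN/dS

`site_dnds()` is a counting (SLAC-style) estimator, chosen over a Bayesian
site-model fit because the downstream analysis consumes only the sign of
`omega` and the positive/purifying site classes, which counting recovers
and simulation can verify. Per codon site:

* expected synonymous/nonsynonymous site counts are NG86 one-step
  enumerations, `S_i = syn_i/3` per position with changes to stop codons
  excluded from the numerators (so `S + N` equals 3 minus the stop-change
  fraction), averaged over the codons observed at the site;
* observed changes are summed over branches between reconstructed endpoint
  codons (joint nucleotide-level reconstruction assembled into codons);
  multi-step codon changes average over all minimal mutational orderings,
  preferring stop-free paths — counts are therefore fractional;
* `omega = (Nd/N_sites)/(Sd/S_sites)`, infinite when `Sd = 0` with changes
  observed, undefined when the site never changes;
* the per-site test is the two-sided large-sample (score) binomial
  proportion test of `Nd` among `Nd + Sd` changes against the neutral
  expectation `N_sites/(N_sites + S_sites)`. The score form is used because
  the averaged counts are fractional and an exact test's discreteness makes
  small-count sites untestable. No multiple-testing correction by default
  (`adjust = TRUE` applies Benjamini–Hochberg).

Known limitation: per-site power for *significant* positive calls is low at
realistic sample sizes — with a few dozen branches the minimal-path
collapse caps the observable nonsynonymous fraction, and strongly positive
sites (`omega = 5`) mostly fail to reach `p < 0.05` even when the true
ancestors are supplied. What the estimator does deliver, and what the tests
assert, is regime recovery: the `omega` estimates rank-order the simulated
regimes (0.2 / 1 / 5), most `omega = 5` sites are estimated above 1, and
the type-I error of the positive call stays at or below the nominal level.

## The key-position catalog and the rule engine

The catalog (`inst/extdata/key_position_catalog.json`) is data, not code:
12 T2R10-mode and 15 T2R46-mode entries over 20 distinct BW positions
(7 carry both modes), each with the key residue, a criticality flag, and
ordered substitution-effect rules (`tolerated`, `reduced`, `abolished`)
sourced from the published mutagenesis of the two human receptors. Rules
match either explicit residues or property classes.

Property classes: charge negative `{D,E}` / positive `{K,R,H}` / neutral;
hydrophobic when the Kyte–Doolittle index is above 0; side-chain volume
small (≤ 117 Å³), medium (≤ 170 Å³), large (> 170 Å³) on Zamyatnin volumes.
Two residues are *chemically similar* when all three classes agree — strict
same-class volume (rather than ±1 class) is required so that, e.g., L→F
counts as non-conservative, which the published per-species verdicts imply.

`classify_binder()` scores a residue map against each mode and keeps the
better verdict (`binder > reduced_binder > uncertain > non_binder`):

1. every key residue present → `binder`;
2. any rule-listed abolishing substitution → `non_binder`;
3. any non-conservative substitution at a *critical* position, or two or
   more non-conservative substitutions anywhere → `non_binder`;
4. otherwise any unknown-effect substitution (including chemically similar
   ones) → `uncertain`;
5. otherwise (all substitutions tolerated or merely sensitivity-reducing)
   → `reduced_binder`.

Critical positions are those where mutagenesis reports loss of function:
{3.37, 5.40, 5.43, 7.39, 7.42} in the T2R10 mode and {7.39, 7.42, 7.43} in
the T2R46 mode. One catalog choice deserves a note: A→R at 7.42 (T2R46
mode) is encoded as `reduced` (steric hindrance) rather than `abolished`,
although the corresponding mutant in the human receptor background nearly
abolishes responsiveness. The published analysis itself treats ancestors
predicted to carry R at 7.42 as plausible (modest-sensitivity) binders in
their own sequence context; encoding the human-background datum as
`abolished` would contradict those ancestor verdicts, and the regression
suite pins the verdicts. The position's positive charge in combination with
a charge-altering change at 7.39 still yields `non_binder` through rule 3.

The bundled residue matrices (`key_residue_matrix.tsv`,
`species_key_variants.tsv`, `ancestor_verdicts.tsv`) transcribe the
published key-residue tables and per-taxon calls; the regression tests
reproduce every published verdict (14 binder species; pig, cow, sheep
non-binders; marmoset uncertain; ancestors N94–N82 binders, N81 uncertain,
N80 and the deep common ancestor N2 non-binders; N34/N24/N23 reduced).

## Synthetic data: what it emulates and what it does not

`simulate_protein()` draws a root from the model equilibrium and evolves it
with exact transition probabilities per branch (optionally with per-branch
lineage rate multipliers and gamma site rates), recording every internal
node. `simulate_codon()` runs a Gillespie simulation over the 61 sense
codons with Muse–Gaut rates (`kappa` for transitions, per-site `omega` for
nonsynonymous changes, neutral expected rate scaled to 1), recording true
per-site synonymous/nonsynonymous event counts — exact event counting is
the reason for Gillespie rather than matrix-exponential sampling here.
`simulate_binder_history()` evolves the 20 key positions by a Markov jump
process among rule-listed alternatives and returns per-node verdicts,
supporting forced substitutions for constructing convergent-gain scenarios.

The simulators deliberately omit insertions/deletions, alignment error,
structural constraints and among-site compositional heterogeneity. Passing
tests therefore demonstrate internal correctness of the estimators under
the stated models, not robustness to misalignment or indel-rich histories.
Fixed integer seeds make every simulation byte-reproducible.

## Problem sizes and numerical choices

The test and acceptance workloads use 4–5 taxa for exhaustive-enumeration
oracles (posterior equality to 1e-8), 16 taxa × 1000–2000 sites for ASR
calibration, 8 taxa × 5000 sites for branch-length recovery (within 15%),
20 taxa for dating, and 16–32 taxa × 300–500 codon sites for selection.
Tolerances: transition-matrix row sums 1e-10; Chapman–Kolmogorov 1e-8;
likelihood closed forms 1e-9 or better; branch optimization converges when
a full sweep improves the log-likelihood by less than 1e-6 (branches capped
at 10 substitutions/site; saturated pairwise distances return the cap with
a warning). Posterior ties are broken toward the first state in the fixed
PAML residue order, making every output deterministic.

## Limitations

* Topology inference is out of scope; neighbor joining is a fallback, not a
  substitute for a maximum-likelihood tree search.
* The indel model is a majority-rule gap flag, not a reconstruction.
* Counting-based dN/dS has low per-site power for significant positive
  calls (see above); use it for regime classification, not hypothesis
  tests at single sites.
* The rule engine is only as good as its catalog: verdicts extrapolate
  human-receptor mutagenesis to other backgrounds and ignore epistasis
  beyond the encoded combination rules.
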