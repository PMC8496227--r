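---
title: "Detecting retrocopies and measuring selection on them: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retrocopies and measuring selection on them: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retroforge studies the life cycle of retrocopies (processed pseudogenes):
intronless genomic copies of a parent gene created when LINE-1 machinery
reverse-transcribes the parent mRNA and reinserts the cDNA. The package
covers three stages — detecting retrocopies in a genome, quantifying
selection on them with codon models, and classifying the structural impact
of their substitutions at a protein–protein interface — together with a
truth-tracked synthetic-data generator that makes every stage testable
without external downloads. This vignette explains the models, the
defaults, the numerical choices, and what the synthetic tests do and do not
establish about real data.

## Retrocopy detection

A candidate locus is called a retrocopy of a parent gene when it satisfies
two criteria, and only these two:

1. **Intronless**: the local alignment of the spliced parent mRNA against
   the locus crosses at least one exon–exon junction without a target-side
   gap of `minIntronGap` (default 40 bp, below typical minimum intron
   size). A junction counts as crossed only when the alignment anchors at
   least 8 bp on each side of it; a one-base chance extension across an
   exon boundary is not evidence. Target-side gaps that fall mostly
   (≥ 80%) inside a user-supplied repeat mask are ignored, because a
   transposable-element insertion into a retrocopy is not an intron. For
   single-exon parents the criterion cannot distinguish a retrocopy from a
   DNA-level duplication, and the call is flagged `uninformative`.
2. **Reciprocal best hit**: queried against the transcript database, the
   candidate's top-scoring transcript must be the parent. Ties are broken
   by identity and then alphabetical id, and recorded.

Target-site duplications (TSDs) and genomic poly-A tails — the hallmarks of
LINE-1 mediated insertion — are attached to every call as *evidence*, not
as filters: real retrocopy surveys report them descriptively because decay
erases them over time.

### The aligner

The scanner is a seed-and-extend search: exact k-mer seeds (default
k = 12) are clustered by diagonal, each cluster window is aligned with an
affine-gap Smith–Waterman kernel (match +1, mismatch −2, gap open −4, gap
extend −1 per base; all configurable), and hits below `minIdentity`
(default 0.8) or `minLen` (default 100 bp) are dropped. The scoring favours
contiguous high-identity hits over noisy chains, which is the regime
retrocopies live in. The kernel's scores are checked in the test suite
against an independent dynamic-programming implementation
(`Biostrings::pairwiseAlignment`); the check holds exactly because both
implement the same affine-gap recursion. The scanner is built for
desk-scale genomes (tens of Mb); it holds no persistent index.

### TSD and poly-A inference

Locating a TSD requires the insert boundaries, but the 3′ boundary is
obscured by the poly-A tail: tails decay (we model 5% non-A contamination),
and a purity-threshold run-scanner misplaces the boundary whenever an
impurity lands near the junction. retroforge therefore infers the TSD and
the tail *jointly*: the body-side TSD copy is pinned near the alignment
boundary (± 20 bp of slop, because alignment extension over- or
under-shoots decayed ends), the tail-side copy slides across the whole tail
region (up to 80 bp), and every candidate must imply an A-rich tail at the
junction with the scanned copy (the 8 nt abutting it must be ≥ 70% tail
base). Among qualifying repeats the mismatch-penalized score
`length − 4 × mismatches` is maximized, with ties broken by fewer
mismatches, higher implied tail purity, then smaller slop. The penalty
matters: under the naive "longest repeat wins" rule, a repeat one base
longer than the true TSD that buys its extra length with a mismatch
displaces the exact answer, and poly-A-adjacent junctions generate such
candidates constantly. The stand-alone `findTsd()` operation keeps the
simpler symmetric-slop interface for callers that already know the insert
boundaries exactly.

The standalone poly-A detector (`findPolyA()`) reports the longest
purity-qualifying run (default window 30 bp, minimum run 8 nt, purity
0.85) downstream of the hit's 3′ end — upstream on the plus strand as
poly-T for minus-strand hits. `callRetrocopies()` widens the window to
60 bp because simulated (and real) tails reach 40 nt.

### Empty-site classification

For a call in genome A, the syntenic status in genome B is read from the
call's two flanks: both flanks located adjacently in B (gap ≤ 30 bp) means
the site is `empty` — one contiguous copy of the target sequence, insert
absent — and the pre-insertion sequence is reconstructed from B. A gap
comparable to the insert length is `filled`; an unalignable flank is
`deleted/ambiguous`, never an exception, because large secondary deletions
at retrocopy loci are common in real genomes.

## Codon-model selection analysis

All likelihood machinery works on the 61 sense codons under a GY94-type
substitution model: single-nucleotide changes only, a transition
multiplier κ, a nonsynonymous multiplier ω, and target-codon frequency
factors (F61, estimated from the alignment's observed codon usage, floored
at 10⁻⁶ and renormalized so the reversible generator stays well
conditioned). Likelihoods are computed by Felsenstein pruning with
per-branch matrix exponentials obtained from the eigendecomposition of the
symmetrized generator; site patterns are compressed and partial likelihoods
rescaled per node.

* **Free-ratio model**: kappa, all branch lengths, and one ω per branch
  are optimized jointly (bounded quasi-Newton, ω ∈ [10⁻⁴, 99], seeded
  multi-starts, convergence tolerance 10⁻⁸ on the log-likelihood by
  default). Branches estimated at zero length carry no substitutions and
  their ω is flagged unidentifiable rather than reported.
* **Branch-site Model A** and its null: four site classes (0, 1, 2a, 2b)
  with 0 ≤ ω₀ ≤ 1, ω₁ = 1, and on labeled foreground branches a shared
  ω₂ ≥ 1 for classes 2a/2b; the null fixes ω₂ = 1. Foreground branches are
  labeled in newick input by the conventional `#1` suffix, so published
  trees import directly. The reported `p2plus3` is p₂ₐ + p₂ᵦ. Branch
  lengths, kappa and the mixture are re-optimized for each model, matching
  the likelihoods being compared in a test.
* **LRT**: 2Δℓ against the upper tail of χ² at the stated degrees of
  freedom. Statistics negative within 10⁻⁴ (optimizer noise) are clamped
  to zero with a warning; anything worse is an error. Because ω₂ = 1 sits
  on the boundary of the alternative, the branch-site statistic follows a
  boundary mixture rather than a clean χ²₁; referring it to χ²₁ (the
  package's choice, and the field's standard recommendation) keeps the
  test near or below nominal size in our calibrations, and a uniformity
  check of p-values against χ²₁ is only meaningful for regular
  (non-boundary) nested comparisons. `branchSiteTest()` runs the full
  recipe — null fit, warm-started alternative, then a null refit
  warm-started from the alternative — because asymmetric convergence of
  the two fits otherwise leaks optimizer progress on the shared
  parameters into the statistic.
* **Ancestral reconstruction**: marginal, maximum-posterior codons per
  internal node from an inside–outside pass under a fitted single-class
  (per-branch ω) model; posteriors sum to one per site.
* **Site posteriors**: naive empirical Bayes — fitted parameters are
  plugged in and the posterior mass of classes 2a + 2b is reported per
  site, with a 0.5 flagging threshold. Modern Bayes-empirical-Bayes
  averages over parameter uncertainty and is deliberately out of scope;
  at desk scale the naive posteriors are adequate for ranking sites, and
  the difference matters mainly for short alignments.

### Optimization internals

Three implementation choices make the fits fast enough for calibration
studies while leaving the maximum-likelihood problem unchanged:

* Eigendecompositions are cached across objective evaluations keyed by
  (κ, ω), so branch-length perturbations in the quasi-Newton gradient
  reuse them.
* Generators are scaled internally by the neutral (ω = 1) mean rate
  instead of the mixture mean rate. A scaling factor shared by all classes
  is absorbed by the free branch lengths, so the likelihood optimum is
  identical; the reported branch lengths are converted back to expected
  substitutions per codon under the fitted mixture.
* The Model A mixture weights are profiled out of the outer search: given
  the class site likelihoods, the 2-parameter mixture maximum is found by
  damped Newton from three fixed starts. The profile surface has a known
  ridge at p₂+p₃ → 0 where ω₂ is unidentifiable; the fixed multi-starts,
  plus an additional deterministic high-ω₂ outer start for the
  alternative model, guard against it. The alternative fit also always
  considers the null fit's own optimum (ω₂ → 1) as a candidate, which
  enforces the nested-likelihood inequality by construction.

### NG86 and the Monte-Carlo neutral null

Pairwise dN/dS uses NG86 counting: per-codon synonymous site fractions by
enumerating the 9 single-nucleotide neighbours (changes to stop codons are
excluded and each position contributes one site, so N + S = 3 per codon),
differences for multi-hit codons averaged over all minimal substitution
paths that avoid stops (all paths, if every path is blocked), and
Jukes–Cantor correction of the proportions. dS = 0 yields an explicitly
undefined ω, never an infinity.

The neutral null conditions on the observed amount of change, mirroring
the logic of divergence-matched Monte-Carlo tools: K substitutions (default
the observed Nd + Sd) are placed uniformly at random on the template with
transition/transversion weighting, ignoring synonymous/nonsynonymous
status; substitutions creating stops are resampled so K stays exact; the
NG86 ω of each replicate against the template forms the null, and the
p-value is the continuity-corrected upper tail (r + 1)/(n + 1), which can
never be zero. Null draws with undefined ω (no synonymous changes) count
as extreme, keeping the p-value conservative. Replicate counts, the ts/tv
ratio and the conditioning choice are documented assumptions — the
published description of this procedure does not fix them.

One estimator property worth knowing: with transition weighting
(ts/tv > 1) the null mean of NG86's ω plateaus below 1 (≈ 0.91 at
ts/tv = 2), because NG86's site counting assumes equal rates. This is the
estimator's textbook behaviour, not a simulation artifact; the consistency
check that the null mean approaches 1 at large K therefore runs with
unweighted substitutions.

## Interface classification

Substitutions mapped onto a two-chain structure are partitioned by the
minimum Euclidean distance between any atom of the mutated residue and any
atom of the partner chain, using all atoms present in the coordinate file.
The classifier is total and uses strict inequalities throughout, so
boundary values fall in the permissive class: distance > 5 Å is
`far_from_interface`; otherwise a folding free-energy change outside the
open interval (−3, 3) kcal/mol is `fold_perturbed`; otherwise binding
free-energy change > 2 kcal/mol is `binding_disruptive`; otherwise
`functional`. The `fold_perturbed` class exists because a total classifier
needs somewhere to put points outside the fold band that the two-region
figure-legend rule leaves undefined. Residues unresolved in the structure
are excluded from the partition with a warning. Group summaries report the
sample standard deviation (n − 1); at two-decimal rounding the choice
between sample and population SD is immaterial for group sizes around ten.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions every calibration in the package runs under.

* Parent genes: random multi-exon loci whose CDS starts with ATG, ends
  with a stop, and contains no internal stops; spliced mRNA is the exon
  concatenation in transcript order (reverse-complemented for minus-strand
  genes).
* Insertions: `[TSD][5′-truncated mRNA or its reverse complement][poly-A]
  [TSD]`, the TSD copied from the integration site. Defaults: TSD length
  uniform 5–25 bp (the typical LINE-1 range), poly-A 10–40 nt with 5%
  non-A contamination, 5′ truncation up to 30% of the mRNA, per-copy
  identity 85–97% (decay substitution rate drawn as 1 − identity).
* Decay: per-base substitutions and short indels with a deterministic
  event log; optional 300 bp cassette insertions imitate
  transposable-element disruption of a retrocopy.
* Decoy: one intron-containing copy of the whole parent locus (a
  segmental-duplication mimic) that the scanner must reject as
  intron-containing.
* Codon alignments: site classes are assigned by the spec's proportions
  and each branch/class transition matrix is the exact matrix exponential
  of the scaled generator, so sampling child codons from it is exact CTMC
  endpoint sampling — no discretization and, because the state space is
  the 61 sense codons, no stop codons to reject.

Two generator policies exist purely to make *exact* TSD recovery a
well-posed target. First, insertion sites are redrawn when the planted
junction is ambiguous — when the flanking bases happen to extend the
direct repeat, when the TSD begins or ends on a base the adjacent poly-A
(or poly-T) run would swallow, or when the local context genuinely
contains a competing direct repeat that outscores the planted one. Second,
tail contamination is kept out of the 2 nt abutting the TSD. Real genomes
of course contain such ambiguous junctions; on real data the detector
still returns the best-scoring repeat, but "the" TSD is then genuinely
ill-defined at single-base resolution.

What passing the synthetic benchmarks shows — and what it does not: the
generator emulates point decay, truncation, tails, TSDs and one
duplication decoy on a uniform-random background. It does not emulate
repeat-dense genomic landscapes, GC heterogeneity, segmental-duplication
families, codon-usage bias along genes, or alignment ambiguity from
paralogous exons. Recall/precision on these genomes is therefore an upper
bound on real-genome performance, and the published human retrocopy counts
depend on assembly versions this package does not ship.

## Problem sizes and calibration designs

The calibration studies in the test suite use deliberately small designs
chosen once: free-ratio recovery on a 3-taxon star (ω = 0.5, 2000 codons,
50 replicates; the pooled per-branch median must sit within 10% of truth);
branch-site type-I error on a 3-taxon tree with a single foreground tip
(ω = 1 everywhere, 300 codons — the same alignment length as the power
design — 200 replicates at nominal 5%; the realized statistic tracks χ²₁,
so the rate sits near or just below nominal); branch-site power on a
4-taxon tree whose foreground is a 2-tip clade plus its stem — the natural
design for a retrocopy lineage traced back to its origin — at ω₂ = 5,
p₂+p₃ = 0.1, 300 codons, 100 replicates; Monte-Carlo null calibration with
500 replicates of 500 draws on a 120-codon template. Scanner benchmarks
plant 5 retrocopies plus one decoy in 0.5 Mb genomes, 20 seeds. All seeds
are fixed in the tests; the sizes are the package's own choices for
desk-scale reproducibility.

## Known limitations

* The scanner is quadratic within candidate windows and holds the genome
  in memory: tens of megabases, not whole mammalian genomes.
* ω₂ estimates from Model A are noisy whenever p₂+p₃ is small; the LRT is
  the reliable signal, the point estimate is not.
* Naive empirical-Bayes site posteriors understate uncertainty relative
  to Bayes-empirical-Bayes.
* NG86's equal-rate site counting biases pairwise ω downward under strong
  transition bias; the likelihood machinery does not share this bias.
* Codon-model fits assume a single alignment without recombination and a
  known topology; topology search is out of scope.
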