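---
title: "Methods: building a cross-kingdom TIR domain atlas"
author: "tiratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a cross-kingdom TIR domain atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Toll/interleukin-1 receptor (TIR) domains are small α/β modules — five
parallel β-strands wrapped by five α-helices — that act in immune
signaling and NAD⁺ cleavage across bacteria, archaea and eukaryotes.
Because the family is ancient and extremely diverged, no single sequence
model detects all of it: atlas construction proceeds by *iterative*
profile search, with structural plausibility used as a brake on profile
drift, followed by phylogenetic organization of the hits into
reproducible clades and reconstruction of gene gain and loss in lineages
of interest. `tiratlas` implements that pipeline as reusable, testable
components, together with a synthetic-data generator that plants ground
truth so every stage can be verified end to end without external
databases.

## The discovery engine

A seed alignment is compiled into a position-specific scoring model. With
weighted residue frequencies $f_c(a)$ at column $c$ (Henikoff
position-based weights, so duplicated rows change nothing), background
frequencies $p(a)$, pseudocount weight $\alpha$ (default 1) and effective
observation count $w$ (the number of distinct rows), the match score is

$$ S(c,a) = \log_2 \frac{w\,f_c(a) + \alpha\,p(a)}{(w+\alpha)\,p(a)}. $$

Columns with gap fraction above 0.5 are excluded from the match model.
Targets are scanned by local alignment with affine gaps (defaults: open
11 bits, extend 1 bit; a length-$k$ gap costs $11 + (k-1)$). The
envelope of a hit is the target interval of the optimal local alignment;
additional non-overlapping envelopes per target are found by masking the
reported interval and re-running the alignment, each re-scored.

Scores become E-values by an extreme-value calibration: optimal local
scores against 200 background-composition decoys of length 200 are fit
to a Gumbel distribution by maximum likelihood, giving
$E(S) = K\,m\,n\,e^{-\lambda S}$ with $m$ the model length and $n$ the
database residue count. The reporting and inclusion threshold is
$E \le 10^{-3}$, applied inclusively; the same value serves both roles
and is exposed as a parameter. Accepted envelopes must span at least 50
residues (configurable).

Iteration folds accepted envelopes back into the model: hits are stacked
by their model-aligned coordinates (no multiple-alignment recomputation
inside the loop, which keeps the iteration deterministic), the model is
rebuilt and recalibrated, and the database rescanned. A hit counts as
*new* when no accepted envelope on the same record matches it at ≥ 50%
reciprocal overlap. The loop always performs at least two scans and then
stops when a scan yields no new hits, or when every new hit was rejected
by the fold gate. Multiple seeds run in a fixed order, each to
saturation; a final boundary pass rescans all accepted records with all
final models, resolves overlapping calls by keeping the longest (ties:
lower E-value, then lower start — a total order, so the outcome is
independent of input order), and trims records to their envelopes.

The engine is a PSSM with Gumbel-calibrated E-values rather than a full
profile hidden Markov model. Every behavior the pipeline depends on —
iterative broadening, E-thresholded envelopes, saturation stopping — is
preserved at desk scale, and the operation contract (`iterate_search`,
`scan_database`) is the adapter point where an external profile-HMM
engine can be substituted.

## The structural gate

Candidate structures (predicted models in practice; idealized backbones
or precomputed secondary-structure strings here) are reduced to
per-residue H/E/C labels from backbone φ/ψ dihedrals: helical for
φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; extended for φ ∈ [−170°, −70°],
ψ ∈ [90°, 180°] ∪ [−180°, −170°]; coil otherwise, with single-residue
islands smoothed into their flanks. Maximal runs of at least 4 H or 3 E
residues become elements (these minima are exposed as parameters — no
published value fixes them). A model passes when it shows **at least 4
helix elements and at least 3 strand elements** of the 5 + 5 expected
for the fold. "Sheets" are read as strand elements: the fold's five
strands form a single sheet, so counting strands is the only consistent
reading of a 3-of-5 rule. The rule is a lower bound; extra elements
never cause failure. Dihedral-region assignment was chosen over
hydrogen-bond-based assignment because it is dependency-free and
adequate for counting elements on predicted models; the gate also
accepts external secondary-structure strings, so a hydrogen-bond
assigner can be swapped in.

## Trees, trimming and consensus clades

Alignment columns are trimmed by gap threshold: a column is kept when
its fraction of non-gap residues is at least `gt` (0.10 and 0.20 are the
two levels used for tree variants). The internal tree engine is
neighbor joining on p-distances (pairwise deletion), with negative
branch estimates clamped to zero and the deficit moved to the sibling
edge, plus a nonparametric column bootstrap whose supports (0–100) are
the percentage of replicates containing each bipartition of the point
tree. This engine is a desk-scale stand-in: at atlas scale the package
*ingests* externally produced alignments and maximum-likelihood trees
(Newick with support labels; both 0–1 and 0–100 dialects are accepted
and normalized). The four replicate-tree variants of the analysis (two
aligners × two trims in the original design) are realized hermetically
as two trim levels × two bootstrap seeds.

Consensus clades are defined across the replicate trees. Per tree, a
*supported clade* is an internal node with support strictly above 70 and
at least 100 descendant leaves (inclusive); trees are rooted on a
designated outgroup leaf set, with a bipartition fallback when none is
given. Each supported clade, taken as a candidate, is matched in every
tree to the supported clade maximizing Jaccard similarity (ties: higher
support, smaller clade, lexicographic). The candidate is *found* in a
tree when that Jaccard is at least 0.5 — the matching rule itself is not
fixed by any published value, so `j_min` is a parameter — and survives
when found in at least 3 of the 4 trees, counting its own source tree
(whether the source tree counts is unstated in the original rule; we
count it and document that choice). Members absent from the matched
clade in 3 or more reproducing trees are pruned, and candidates are
reported only when strictly more than 20 members survive. Because
nested and overlapping candidates can both qualify and no published rule
resolves them, the package reports the nested set with recorded nesting
relations *and* offers a disjoint post-filter (greedy by retained size,
mean support, smallest member id) rather than guessing; leaves in no
reported clade are listed as unassigned.

## Phylogenetic-diversity downsampling

The diversity of a leaf subset is the total branch length of the minimal
connected subtree spanning it (unrooted convention: the root edge is not
charged, matching the standard objective; users of rooted PD should
note the difference). Selection is greedy: initialize with the
maximal-path-distance leaf pair, then repeatedly add the leaf with the
largest attachment distance to the current spanned subtree, with
lexicographic tie-breaks throughout. For this objective the greedy
procedure provably attains the optimum for every subset size, which the
test suite confirms against exhaustive enumeration. Group policy mirrors
the atlas analysis: eukaryote groups other than Metazoa and Amoebozoa
are capped at 1,000 sequences, prokaryote families at 100 per family,
and exempt groups pass through untouched.

## Gain/loss reconstruction

Presence/absence of a gene family on a species tree is explained under
Dollo parsimony: the single origin is placed at the most recent common
ancestor of the carriers, and a branch is a loss exactly when its
subtree contains no carrier while its parent lineage is inferred
present — the minimal loss set, certified against brute-force
enumeration in tests. Dollo (one gain) is imposed rather than inferred
because the biological framing is a single horizontal-transfer event.
Copy-number histories are handled separately by integer parsimony over
per-node counts (unit cost per ±1 along a branch, dynamic programming),
with ties resolved toward tip-ward (later) events: the root takes the
smallest minimal state and children take the state closest to their
parent. Duplications are the total positive increments excluding the
single origin gain; losses the total decrements. Parsimony counts are
lower bounds on true event counts: simulated losses are recovered
exactly when phylogenetically independent, and collapse (two sister
losses read as one deeper loss) is expected otherwise — the simulation
tests assert both sides of that bound.

## The synthetic generator

The generator emulates the statistical structure of a real search
universe: `n_clades` domain families evolved from one root ancestor
(long inter-family branches, factor 10 over the intra-family mean, so
families are well separated yet genuinely homologous), embedded in host
proteins with random flanks, plus residue-shuffled decoys that preserve
composition so E-value calibration is honest. Defaults are the desk
study conditions: 6 families × 40 members, domain length 120, flanks
30–80 residues, 600 decoys.

Substitutions are Poisson with uniform replacement over the 19
alternatives — no rate matrix, because the pipeline never assumes one —
at 0.05 expected substitutions per site per unit branch length, which
yields ~70–80% intra-family and ~20–30% inter-family identity, the
regime in which iterative search is both necessary and feasible. Indels
are geometric with mean length 2 at 0.002 events per site per unit
branch; domain cores are strongly length-constrained in reality, and
higher rates erode the homologous column set that profile search and
true-alignment reconstruction rely on. Each residue carries its
root-ancestor column, so the generator can emit the true multiple
alignment; the hermetic pipeline run uses it as the stand-in for an
ingested aligner output, and the first family is designated the known
outgroup set for rooting (the analogue of curated outgroup sequences).
Fold-gate inputs are synthesized per record: family members receive
5-helix/5-strand topologies, decoys impoverished ones; idealized
backbones built from canonical dihedrals (helix −60°/−45°, strand
−120°/+120°, coil outside both regions) exercise the geometric route.

What the generator does *not* emulate — site-rate heterogeneity,
realistic substitution matrices, compositional drift across lineages,
alignment error — bounds what passing tests show about real data: they
certify the *logic* of every rule (thresholds, stopping, matching,
parsimony) and calibrated error rates under honest decoys, not
performance on real proteomes.

## Problem sizes and numerical choices

Hermetic runs use the desk profile above with 100 bootstrap replicates
per tree variant and scaled consensus thresholds (minimum clade size 8,
minimum retained 5, in place of 100 and 20) so that 40-member families
are in scope; the logical rules are never altered, only the sizes.
Gumbel fitting solves the profile likelihood equation for the scale by
bisection with the score minimum as the numerical shift; calibration
requires at least 100 decoys and rejects zero-variance score
distributions. All randomness is seeded through configuration; a fixed
configuration reproduces every output byte for byte, and each artifact
file carries its configuration hash.

## Known limitations

The engine does not reproduce any external tool's exact scores; E-values
are calibrated against background-composition decoys, so strongly biased
real sequences would need composition-matched calibration. NJ bootstrap
supports are a stand-in for ultrafast ML bootstraps. Secondary-structure
assignment ignores hydrogen bonding and sheet topology
(parallel/antiparallel is out of scope, as is any loop-extension
geometry). Count parsimony caps copy numbers at 10. Atlas-scale absolute
counts from the original analysis depend on external databases and
stochastic ML inference and are out of scope by design.
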