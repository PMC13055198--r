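---
title: "Composition-matching proteome searches: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-matching proteome searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compmatch)
```

## The problem and the score

Intrinsically disordered regions (IDRs), and prion-like domains (PrLDs) in
particular, often owe their cellular behavior — phase separation, recruitment
to stress granules and other membraneless organelles — to their bulk amino-acid
composition rather than to the exact order of residues. Homology search tools
(BLAST and its relatives) rank candidates by primary-sequence similarity and
are therefore the wrong instrument for finding regions that *act* like a query
IDR but share no ancestry with it. `compmatch` searches a proteome for the
nearest *compositional* matches instead.

Every sequence window is summarized as a 20-dimensional percent-composition
vector over the canonical amino acids
$A = \{\mathrm{A}, \mathrm{C}, \mathrm{D}, \ldots, \mathrm{Y}\}$, with
$c_a = 100\,n_a / w$ for a window of length $w$ containing $n_a$ copies of
amino acid $a$. Two windows are compared by the Manhattan distance of their
composition vectors, and similarity is expressed as the **compositional
identity**

$$\mathrm{CI} = 100 - \frac{1}{2}\sum_{a \in A}\left|c_a^{q} - c_a^{s}\right|,$$

where $q$ is the query and $s$ the subject window. The factor $\tfrac12$ maps
the Manhattan range $[0, 200]$ onto an identity-like scale: CI is 100 exactly
when the two compositions coincide — in particular for *any* permutation of
the same residues — and 0 when they share no amino acid at all. CI is
deterministic, symmetric, and inherits the triangle inequality from the
Manhattan metric; the test suite checks all three properties on randomized
inputs.

## The search procedure

A search takes one query sequence and a proteome. The query composition is
computed once over the **entire** query sequence as given, even when the query
length lies outside the window range — the query defines the target
composition, not a window to be re-found. Then, for every protein:

1. every window size $w$ in `[min_window, max_window]` is slid across the
   sequence, with residue counts updated incrementally (one residue leaves,
   one enters), so each window costs a constant 20 operations regardless of
   $w$; the total work is $\sum_w \max(0, L - w + 1)$ windows per protein of
   length $L$, linear in $L$ per window size;
2. the single best window — the one minimizing the selected distance — becomes
   the protein's match region. One region per protein, never several: the
   search asks "where in this protein is the closest compositional match",
   and downstream experiments clone exactly one candidate region per protein;
3. proteins shorter than `min_window` go to a skip log rather than being
   silently dropped.

Proteins are finally ranked by their best window: descending CI for the
Manhattan metric, ascending raw distance for the Euclidean alternative. With
the Euclidean metric the reported `ci` column is still the Manhattan-based
quantity above — CI is only defined for the Manhattan distance, and keeping
its meaning fixed lets rankings under the two metrics be compared hit by hit
(`rank_difference()`), while the `distance` column carries the actual ranking
key.

### Default parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_window` | 90 | residues | PrLDs much shorter than ~80–90 residues rarely carry composition-driven granule recruitment on their own |
| `max_window` | 120 | residues | the median length of active PrLDs is ~120 residues; a narrow band keeps candidate regions clonable |
| `metric` | Manhattan | — | the CI definition is Manhattan-based; Euclidean is provided for robustness analyses |
| `strict_noncanonical` | off | — | see below |
| prominence threshold | 10 | % | an amino acid exceeding 10% of either sequence is worth highlighting when inspecting a match |

### Numerical choices

*Exact tie-breaking.* With an integer-count query of length $L_q$, the window
distance is $d = 100\,N / (L_q w)$ with an integer numerator
$N = \sum_a |n_a^{q} w - n_a^{s} L_q|$. Distances are compared after
cross-multiplying by window lengths, so equality of rational distances is
detected exactly, never through a floating-point epsilon. Ties are resolved
deterministically: smallest distance, then leftmost start, then largest
window (the larger window carries more context for downstream cloning).
Ranking ties between different proteins break by protein id, ascending
bytewise, so results are identical across platforms and input orders.
Because $N$ changes in integer steps, distinct distances differ by at least
$100/(L_q w w')$ — about $10^{-2}$ at the default scales — which is why the
exhaustive-search oracle in the test suite can compare coordinates exactly.

*Non-canonical residues.* Symbols outside the 20 canonical amino acids (X, B,
Z, U, O, J) contribute to no canonical percent but still count toward window
length. Under this *dilution* model an unknown residue can only lower CI —
it never fabricates composition. A strict mode (`strict_noncanonical`)
instead skips every window containing such a residue; a protein with no clean
window is then reported as skipped. Dilution is the default because
reference proteomes contain occasional X runs and discarding whole proteins
for one ambiguous residue is rarely what a screen wants.

*Rendering.* All internal arithmetic is double precision; tabular output
rounds to 4 decimals, enough to discriminate neighboring ranks in practice
while keeping files diffable — two runs with identical inputs are
byte-identical.

*Coordinates* are reported 1-based inclusive, matching the conventions used
when carrying candidate regions into cloning primers.

## Primary-sequence identity

To show that compositional matches are not merely homologs, matched regions
are also compared by global alignment. `global_alignment()` implements the
Gotoh dynamic program with affine gap costs (gap of length $l$ costs
`gap_open + gap_extend * l`; defaults 10 and 0.5 with BLOSUM62, the published
defaults of the EMBOSS Needle program) and, by default, free end gaps.
Percent identity uses the alignment-length convention: identical columns
divided by *all* columns, gaps — including end gaps — in the denominator.
The traceback prefers substitutions over gaps among equal-scoring paths;
when several optimal alignments exist their identities can differ slightly,
and the reported value belongs to the returned alignment. Alignment scores
are cross-checked in the test suite against the independent implementation
in Biostrings (ends-free and end-gap-penalized variants).

`pairwise_matrix()` assembles the two symmetric layers — CI of full-sequence
compositions and alignment identity — over a labeled sequence set, the
standard picture in which strong matches show high CI with low
primary-sequence identity.

## What the synthetic generator emulates — and what it does not

All validation runs on seeded synthetic data, generated in code at test time:

* `random_proteome()` draws independent residues from a background
  composition, by default `charged_background()` (D/E/K/R together ~46%,
  Q and N at 2% each) — a deliberately PrLD-poor background against which a
  Q/N-rich region is a needle in a haystack, analogous to searching a folded,
  charged proteome for a disordered domain. Protein lengths are uniform on
  200–600 residues, bracketing typical proteome means. The package's
  validation suite uses proteomes of 1,000 such proteins.
* `plant_region()` overwrites one random in-bounds slice with a random
  permutation of the *exact* residue multiset of a target composition
  (`qn_rich_target()` by default: Q 23, N 19, S 11, G 10, P 8, Y 7, A 6,
  T 5, M 3, F 3, L 3, H 2 — Q/N-rich with uncharged-polar and aromatic
  secondary enrichment, and no charged residues). Compositions that imply
  non-integer counts at the chosen window are rejected, never rounded, so
  the planted optimum is CI 100 exactly. Several of these percentages (23,
  19, 11, 7, 3) are coprime to 100, so the target is realizable *only* at
  window 100 within the default 90–120 range — no other window size can tie.
  The generator additionally guarantees the planted window is the unique
  zero-distance window of its length: if a flanking background residue
  happens to complete the multiset in a shifted window (which would
  otherwise happen in roughly one planting in twenty), the placement is
  deterministically resampled.

Every generator is a pure function of its arguments and seed, and restores
the caller's RNG state.

What this emulates well: the *identifiability* questions — can an exact
compositional match be found, localized, and ranked first against a
dissimilar background; does the incremental scan equal an exhaustive search;
is CI blind to residue order while alignment identity is not. What it does
not emulate: real proteomes are not i.i.d. — they contain repeats, paralog
families, multiple genuinely PrLD-like regions, and length/composition
correlations. Passing the planted-recovery suite therefore demonstrates
correctness of the search machinery, not that any particular biological
proteome contains a match of a given CI, and CI itself carries no
significance model (no null distribution is defined; ranks, not p-values,
are the output). Searches of real UniProt reference proteomes work
unchanged — `read_fasta()` accepts any FASTA file — but their biological
top hits are a matter for experimental validation, not for this test suite.

## Rank-robustness utilities

Re-running a search with a different window range or metric perturbs the
ranking. Two small utilities quantify this: `rank_percentile()` scores a hit
within another search's ranking as $100 (N - r + 1)/N$ — a convention chosen
so the top hit scores exactly 100 (its documented fixed point; the bottom
hit scores $100/N$, not 0) — and `rank_difference()` reports the signed rank
change of one protein between two searches. Both are deliberately simple
bookkeeping on ranked results, usable with any pair of searches sharing a
proteome.

## Validation problem sizes

The shipped test suite, all seeded and offline, exercises: CI identities on
200 random sequences (lengths 50–500) and bounds/symmetry on 10,000 random
composition pairs; scan-vs-exhaustive-oracle equality on 100 random proteins
(lengths ≤ 300, window ranges ≤ 40 wide), where the oracle recomputes every
window from a cumulative-sum matrix — a different route than the incremental
C++ scan; planted-region recovery on 50 replicate proteomes of 1,000
proteins each (rank 1, CI exactly 100, true coordinates, in all 50);
composition/identity dissociation on 50 planted pairs (CI 100 with
alignment identity expected below 60%); and the rank-percentile fixed point
and default-parameter fidelity. `scripts/acceptance.R` recomputes the same
quantities end to end from a command-line seed.

## Known limitations

* CI weights every amino acid equally; physicochemically conservative
  differences (D↔E, I↔L) cost as much as radical ones. Reduced or
  property-projected alphabets are out of scope.
* One region per protein: a protein with two strong compositional matches
  surfaces only its best one.
* No statistical significance: CI thresholds for "interesting" are
  empirical and depend on the query's composition entropy.
* The Euclidean metric is provided for robustness comparisons only; CI, and
  therefore the reported identity scale, remains Manhattan-based.
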