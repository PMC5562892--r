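---
title: "Methods: multi-objective alignment search by bacterial foraging"
author: "bfoga authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective alignment search by bacterial foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfoga)
```

## The problem and the model

Aligning three or more protein (or DNA) sequences means inserting gap
characters so that homologous residues share columns. Exact dynamic
programming is exponential in the number of sequences, so `bfoga` treats
the alignment itself as the state of a stochastic search: a population of
candidate alignments ("bacteria", by analogy with *E. coli* foraging) is
evolved by local moves and genetic recombination, and candidates are
compared not by a single score but by a vector of three objectives:

* **Similarity (SM)**, maximized. For column $y$ let $f(x, y)$ be the
  frequency of residue $x$ among the $n$ rows (gaps count in the
  denominator, never as the dominant symbol), and
  $ce(y) = \max_x f(x, y)$. Then $SM = \frac{1}{h}\sum_{y=1}^{h} ce(y)$
  over the $h$ columns. $SM = 1$ iff every column is perfectly
  conserved.
* **Gap penalty**, minimized. In *affine* mode every maximal gap run of
  length $g$ in the pairwise projection of two rows costs
  $G_{open} + G_{ext}(g-1)$, summed over all unordered row pairs;
  columns gapped in both rows of a pair are dropped first, since a
  shared gap carries no information. In *variable* mode the opening
  cost is position-specific (below).
* **Non-gap percentage (NGP)**, maximized: the share of alignment cells
  holding residues, times 100. It counterweights the similarity
  objective, which on its own would tolerate heavy gapping.

No scalarization is used anywhere: candidate $a$ beats $b$ only when it
Pareto-dominates it (no worse on all three, strictly better on at
least one). Populations are ranked by fast non-dominated sorting with
crowding distances, the standard NSGA-II machinery, and selection uses
binary crowded tournaments.

## The variable gap penalty

Uniform gap costs ignore everything known about where gaps actually
occur in structural alignments. The position-specific scheme rescales
the base costs per sequence pair and then modulates the opening cost
along the alignment, in the tradition of progressive aligners:

1. *Pair level.* For ungapped lengths $R, T$ the opening cost becomes
   $(G_{open} + \ln\min(R,T)) \cdot \bar{n} \cdot m$, where $\bar{n}$
   is the (sign-flipped) mean off-diagonal substitution-matrix score
   and $m$ the pair's fractional identity on its current projection;
   the extension cost becomes $G_{ext}(1 + |\ln(R/T)|)$.
2. *Position level*, first matching rule wins, per sequence and column:
   inside an existing gap column the opening factor is
   $0.3 \times (\text{rows without a gap}/\text{rows})$; within 8
   columns of a gap column ($d$ columns in between) it is
   $2 + (8-d)\cdot 2/8$, i.e. $\times 4$ right at a gap edge decaying
   to $\times 2$; inside a hydrophilic stretch (five or more
   consecutive residues from `GPSNDQEKR`) it is $\times 0.5$;
   otherwise a residue-specific gap-propensity multiplier applies
   (Pascarella–Argos-style values, normalized to mean 1, fully
   overridable).
3. A run in sequence $a$ of pair $(a,b)$ then opens at
   $GOT_a(c) + GOT_b(c)$ for its opening column $c$ and extends at the
   pair's extension cost.

Under degenerate constant tables this reduces *exactly* to the affine
penalty, which the test suite uses as an oracle. Natural logarithms are
used throughout; the identity factor falls back to $1/\min(R,T)$ when a
pair shares no aligned column, keeping the cost positive.

Because extension costs carry no positional modulation, the extension
table depends on one sequence of the pair only; this asymmetry is kept
deliberately simple and is config-exposed through the base costs.

## The optimizer

Each bacterium carries one alignment. Per outer generation:

* **Chemotaxis.** A *tumble* draws a random move — relocating a single
  gap, a whole gap run, part of a run (split), or parking one run
  against another (merge) — with a uniformly random direction and a
  magnitude of at most `max_step` columns. All four kinds are one
  invertible primitive: move a block of $j$ gaps within a row. If the
  moved alignment dominates its predecessor the bacterium *swims*,
  reapplying the same move while each application keeps dominating, at
  most `swim_length` (default 5) times. A non-dominating,
  non-dominated move is kept as a sideways step; a dominated one is
  reverted. All-gap columns created mid-swim are carried transiently
  (so coordinates stay stable) but never enter an evaluated or
  reported alignment.
* **Swarming.** Every bacterium is charged its distance to the current
  fittest one (lowest rank, highest crowding), measured as the
  normalized symmetric difference of their gap-coordinate sets. The
  charge enters the health tuple, pulling the population toward the
  incumbent.
* **Reproduction.** Bacteria are ordered by health — rank, then
  crowding (descending), then swarming charge, then index — and the
  healthier half is duplicated over the other half, keeping the
  population size constant (hence the even-size requirement).
* **Genetic phase.** $\lceil \chi J_e / 2 \rceil$ parent pairs
  (default $\chi = 0.3$) are drawn by crowded tournament. Single-point
  crossover is residue-anchored: a random row and residue ordinal fix
  the cut in each parent, rows are spliced at their own residue-count
  boundary and gap-padded at the junction, so offspring always strip
  back to the input sequences without repair. Offspring mutate with
  probability $\mu = 0.8$ (one or two random gap relocations).
* **Elimination–dispersal.** While the best remaining offspring
  dominates or out-healths the worst population member, they swap;
  then each bacterium is dispersed to a fresh random alignment with
  probability `disp_prob` (default 0.25), the escape hatch from
  stagnation.

An external elitist archive collects every non-dominated alignment
found, pruned to non-dominated, deduplicated members each generation.
The archive, not the volatile population, is the reported result, which
makes the per-generation best-objective traces monotone by
construction. The returned `best` alignment is the archive member with
the largest crowding distance — a compromise solution rather than a
single-objective extreme.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 20 | bacteria; even, so halves can swap at reproduction |
| `chem_steps` | 5 | chemotactic sweeps per reproduction block |
| `swim_length` | 5 | max reapplications of an improving move |
| `repro_steps` | 2 | reproduction blocks per dispersal block |
| `disp_steps` | 1 | dispersal blocks per generation |
| `disp_prob` | 0.25 | per-bacterium dispersal probability |
| `crossover_frac` | 0.3 | population fraction replaced by crossover |
| `mutation_rate` | 0.8 | offspring mutation probability |
| `generations` | 500 | outer cycles |
| `gap_fraction` | 0.19 | initialization gap budget |
| `gap_open`, `gap_extend` | 10, 1 | base gap costs |

Initialization pads every row with randomly placed gaps to width
$\lceil L_{max}(1 + \text{gap\_fraction})\rceil$; the budget is capped
at one fifth of the longest sequence, and 0.19 is the default because
gap budgets just under that cap leave enough slack to rearrange gaps
without drowning the objectives in them. The nesting counts
(`disp_steps` × `repro_steps` × `chem_steps`, default 1 × 2 × 5 = 10
sweeps per generation) are this package's own choice: enough local
search per generation to make swims matter, while a default
500-generation run of 6 × 120-residue families remains an
interactive-scale computation in interpreted R. All of them are plain
configuration knobs. The default gap mode is `affine` because it is
evaluated tens of thousands of times inside a run; `variable` mode is
the richer scoring and is typically what final alignments are judged
with. Crossover tournament size is the standard binary one.

## Benchmark scoring

Against a reference alignment of the same sequences, the **sum-of-pairs
score** (SP) is the fraction of the reference's co-aligned residue
pairs that the test alignment reproduces, and the **total column
score** (TCS) is the fraction of test columns whose complete
residue-ordinal tuple occurs as a reference column. Both are computed
on residue ordinals (gap-free positions), making them independent of
alignment coordinates; both equal 1 exactly when test and reference
agree up to all-gap columns. Full columns are scored — annotated
core-region masking as used by curated benchmark suites is out of
scope. Paired per-dataset scores of two methods are compared with the
two-sided Wilcoxon matched-pair signed-rank test at the conventional
5% level, dropping zero differences; exact p-values are used whenever
the implementation in `stats` can provide them.

## The synthetic family generator

Curated benchmark databases are external downloads; the generator
replaces them for testing. It draws an ancestor uniformly over the
alphabet and evolves each descendant independently (star topology):
point substitutions at `substitution_rate` (replacement always differs
from the original), and indel events at `indel_rate` per site with
geometric lengths truncated at `max_indel_length`. Because the edit
history is recorded, the true alignment is assembled directly from it —
deletions become gaps in their carrier, insertions open gap columns in
everyone else — giving an exact reference for SP/TC scoring. A
`two_level` topology adds two internal nodes whose edges carry only
substitutions, so ancestor coordinates remain valid for assembly; a
`twilight` preset sets the substitution rate to 0.55, which under the
uniform substitution model puts expected pairwise identity near
$0.45^2 + 0.55^2/19 \approx 0.22$, at or below the ~25% twilight zone.

What the generator does *not* emulate: substitution biases toward
chemically similar residues, rate heterogeneity across sites, domain
shuffling, and realistic phylogenies. Tests passing on these families
show the machinery is correct and that the optimizer recovers signal
under uniform noise; they do not certify accuracy on real protein
families.

## Numerical and degenerate-input choices

* Ties in column dominance are broken deterministically (first residue
  in alphabet order); equal objective vectors never dominate each
  other.
* Crowding distances use per-front min–max normalization; a zero range
  contributes nothing, and per-objective boundary members get `Inf`.
* Tournament ties after rank and crowding fall to the seeded RNG, so
  whole runs are reproducible from one integer seed.
* All-gap columns are deleted everywhere on construction, so alignment
  width can shrink during optimization; NGP is therefore always
  positive.
* Ambiguity codes (B, Z, X; N for DNA) are accepted and scored through
  the substitution matrix when it covers them, else 0; residues absent
  from the gap-propensity table get multiplier 1.
* Gap-free alignments tumble to an explicit no-op move; two-sequence
  inputs are rejected by the optimizer (three or more sequences define
  the problem) but scored fine by the SP/TC layer.
* The literal NGP convention (gaps/residues ratio) flips that
  objective's orientation to keep "discourage gaps" semantics; the
  default convention needs no flip.

## Problem sizes used by the tests and reports

The packaged study family is 6 sequences of ancestor length 120 at 15%
substitutions and 3% indels. The optimizer acceptance checks run it
for 50 generations at population 20 (a couple of tens of seconds); the
reduced multi-run protocol uses 5 runs × 20 generations; oracle
equivalence checks use 500 random populations (size ≤ 12) and 500
random alignment pairs (≤ 6 × 10 columns, plus initialization slack).
These sizes are the package's own reporting choices, small enough to
rerun casually and large enough to exercise every phase.

## Known limitations

* The optimizer is a stochastic local-search hybrid: no optimality
  guarantee, and on hard families the front after a short run can sit
  far from the true alignment (TCS in particular is a strict,
  all-rows-agree measure and stays low unless runs are long).
* Health is a lexicographic tuple, not a calibrated scalar; swarming
  only breaks ties among equally ranked, equally crowded bacteria.
* Variable-mode evaluation rebuilds its tables per alignment, which is
  markedly slower than affine mode inside the hot loop.
* DNA input is supported through the shared alphabet machinery, but
  the bundled matrices and the hydrophilic/propensity heuristics are
  protein notions; DNA users should supply a 4 × 4 matrix file and
  expect the variable mode's biology to be vestigial.
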