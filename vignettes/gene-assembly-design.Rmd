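---
title: "Designing synthetic genes for decreasing-temperature LCR assembly"
author: "LCRDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic genes for decreasing-temperature LCR assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LCRDesign)
```

## The design problem

Chemical oligonucleotide synthesis is reliable only up to roughly 80 nt, so a
synthetic gene of several hundred base pairs must be assembled from shorter
oligos. LCRDesign plans assemblies for a ligase-chain-reaction (LCR) protocol
run under a slowly decreasing temperature: *main chains* tile the coding
strand without gaps or overlaps, and *helper chains* — reverse complements of
windows spanning each junction — hold adjacent main chains together so that
ligase can seal the nicks. Because the mixture cools slowly from a fully
denaturing temperature, duplexes form in order of decreasing melting
temperature; a well-designed fragment set is one in which every
high-temperature event is a designed junction duplex, so the molecule
self-assembles deterministically. Unlike designs that tile both strands, the
template strand may remain gapped between helpers, which saves synthesis cost.

Sequence design and assembly design interact: synonymous codon substitutions
change fragment thermodynamics, and an awkward assembly can be fixed by
re-coding. The package therefore treats the whole task as one multicriteria
optimization over three coupled choices: the codon for every residue, the cut
positions partitioning the coding strand into main chains, and the placement
of every helper window.

## Fitness

A candidate design is scored by

$$F = \frac{1}{1 + F_C + F_N + F_S}$$

with three non-negative penalties:

* **Codon usage.** $F_C = w_C\sqrt{\sum_j n_j (C_{rj} - C_{ij})^2 / n}$, the
  count-weighted RMS difference between the host's required per-amino-acid
  codon frequencies $C_{rj}$ and the frequencies $C_{ij}$ observed in the
  design, over the $n$ sense codons. Both frequency sets are normalized per
  amino acid; codons that are not used contribute nothing ($n_j = 0$). The
  designed CDS ends in a stop codon (default `TAA`, configurable), which is
  excluded from $F_C$: usage tables often omit or distort stop counts, and
  the stop codon is not subject to synonymous choice during the search.
* **Nucleotide cost.** $F_N = w_N (N - N_{\min})/(N_{\max} - N_{\min})$,
  where $N$ sums all fragment lengths, $N_{\min} = N_{\mathrm{main}} +
  (k-1)L_{\min}$ (every one of the $k-1$ helpers at the minimum length
  $L_{\min}$) and $N_{\max} = 2N_{\mathrm{main}}$ (helpers covering the whole
  template).
* **Protocol complexity.** $F_S = w_S (S-1)^2$, where $S$ counts
  base-protocol executions: leaf tubes plus merge steps. A single-tube plan
  costs nothing; a two-tube plan with one merge has $S = 3$.

All weights default to 1 and are exposed in `eaConfig()`.

## Thermodynamic model

Duplex and fold stabilities use the unified DNA nearest-neighbor model:
Watson–Crick stack terms as $(\Delta H°, \Delta S°)$ pairs, a bimolecular
initiation term, terminal A·T corrections (applied to explicit duplex
energies), and a symmetry entropy for self-complementary duplexes. Loop
penalties (hairpin, bulge, interior) are tabulated as $\Delta G_{37}$ by loop
size and treated as purely entropic, the standard assumption for DNA loops;
intermediate sizes are interpolated and larger sizes extrapolated
logarithmically ($1.75\,RT\ln(n/n_{\mathrm{tab}})$). Multiloops use an affine
model ($a + b\cdot\text{branches} + c\cdot\text{unpaired}$, defaults
3.4/0.4/0.1 kcal/mol at 37 °C). Keeping energies as $(\Delta H, \Delta S)$
lets the package re-evaluate $\Delta G$ at any temperature and, crucially,
derive melting temperatures, which drive the decreasing-temperature event
ordering. The parameter file ships with the package
(`inst/extdata/dna_nn_unified.json`) and its checksum is logged on load.

Minimum-free-energy structures come from a Zuker-style dynamic program
(implemented in C++) over Watson–Crick pairs with hairpin loops of at least
three bases, interior/bulge loops capped at 30 nt, and multiloops. Strand
pairs are folded as the concatenation of the two strands with a junction
between them: any loop whose unpaired span contains the junction is free and
exempt from the hairpin-size and loop-cap rules (it is really an exterior
region between two duplex ends), and a structure containing an inter-strand
pair pays the bimolecular initiation term. When folding the two strands
separately is at least as favorable, the pair is reported as having no joint
structure. The traceback is deterministic (first matching decomposition in a
fixed scan order), so reruns are bit-identical. Dangling-end and coaxial
stacking terms, mismatch/wobble pairs, and partition-function ensembles are
deliberately out of model; the reference scorer `structureEnergy()` defines
the model authoritatively, and the test suite checks the dynamic program
against exhaustive structure enumeration on short strands (lengths up to 16,
where enumeration is exact).

Melting temperatures use the two-state model: $T_m = \Delta H/(\Delta S +
R\ln(C_T/x))$ for bimolecular structures ($x = 1$ for a pair of identical
strands, 4 otherwise; default $C_T$ = 0.4 µM, i.e. 20 pmol in 50 µL) and
$T_m = \Delta H/\Delta S$ for unimolecular ones. The choice of a two-state
$T_m$ as "the temperature at which a structure melts" is a documented model
decision; nothing finer (ensemble melting curves) is attempted.

## The folding-order correctness check

For a fragment mixture, every unordered pair — including each fragment with
itself — is co-folded; pairs that form a joint structure yield a bimolecular
$T_m$, and self-pairs whose strands prefer intramolecular structure yield a
unimolecular one. Sorting events by descending $T_m$ predicts the order in
which structures appear during cooling. Designed events are helper–main
duplexes at the designed junctions. The verdict rule is:

> an undesigned event is **improper** only if its $T_m$ reaches the weakest
> designed junction event; undesigned events below every designed event occur
> after the molecule is fully assembled and are harmless.

This threshold is a design decision of the package: published single-tube
oligo sets exhibit plenty of weak self-structure far below their designed
junctions, so a rule that forbade any undesigned structure at any temperature
would reject designs that demonstrably work. Improper pairs are reported by
name with their $T_m$ and the threshold they beat.

`planProtocol()` turns verdicts into a protocol: junctions not covered by any
helper force a tube boundary (they cannot be ligated in one mixture); within
a segment, conflicts are resolved greedily by splitting the tiling at the
junction separating the most conflicting pairs (ties: balance, then
position), recursing on each side. The helper spanning a split travels with
the left product and does its work in the merge step. A plan with $L$ leaves
runs $S = 2L - 1$ base protocols. Exact minimal partitioning is graph
coloring (NP-hard); the greedy split plus the optimizer's $F_S$ pressure is
the intended compensation. A conflict that no partition can separate — a
fragment conflicting with itself — marks the design infeasible, which the
optimizer penalizes with a capped $S$ (default 10) rather than an exception,
keeping the search connected.

## The evolutionary search

An individual is the triple (coding sequence, cuts, helper windows); the
initial population reverse-translates the peptide with uniformly random
synonymous codons, draws the number of main chains uniformly among feasible
values and cut positions uniformly subject to the length bounds
$[L_{\min}, L_{\max}]$ (defaults 20/80 nt), and centers random-length helpers
on the junctions with at least `minOverlap` (default 10 nt) on each side.
`eaConfig()` enforces $L_{\min} \ge 2\,\texttt{minOverlap}$, since otherwise
helpers at the two junctions of a minimal main chain would have to overlap.

Each generation every individual produces one child by exactly one of three
equally likely mutations — a random synonymous codon swap, a ±1 shift of a
random cut, or a one-step shrink/grow/move of a random helper — resampled
within the chosen operator until valid (bounded retries, then the parent is
returned unchanged). Parents and offspring compete for succession under
proportional, linear-ranking, or tournament ($k = 2$) selection, with one
elite preserved; these are (µ+µ) semantics. Pair energies are memoized in a
cache shared across evaluations: a mutation touches at most three fragments,
so most of a child's pair events are inherited from its parent, and caching
is checked in tests to be bit-identical to fresh evaluation. A
steepest-ascent hill climber (full single-step neighborhood, applied by
default to the final best individual only) performs fine tuning; applying it
each generation is configurable but quadratically more expensive.

Defaults for the search (population 20, 50 generations) suit the package's
worked examples and tests; production-scale designs of several hundred
codons warrant hundreds of individuals and generations, at proportionally
higher cost dominated by the $O(n^3)$ folding of fragment pairs.

## The Monte Carlo mixture study

`estimateSuccessRate()` reproduces a simple study of how often *random*
(undesigned) three-strand mixtures survive the base protocol: draw a uniform
random target of 60–80 nt, split it uniformly so both main chains fall in
20–40 nt, take the helper as the reverse complement of a window centered on
the split ("a region near the position", implemented as a centered window of
random 20–40 nt length), and ask `checkBaseProtocol()` for a verdict; 10 000
trials give the success fraction with an exact binomial CI. Targets use
uniform base composition. The generator emulates unoptimized mixtures only —
it does not model kinetics, enzyme behavior, or concentration imbalances —
so passing it says nothing about sequences with biased composition or
engineered repeats, which the conflict tests probe separately.

Under this package's model and threshold rule the computed success fraction
is high (around 90%): random designed junctions of 10–20 bp almost always
outrank the weak spurious structure of random 20–40-mers. Stricter verdict
readings (treating any undesigned structure at any temperature as fatal)
drive the rate down by two orders of magnitude but would also reject
known-good single-tube oligo sets, as discussed above; the rate is therefore
best read as strongly model- and rule-dependent, and the packaged study
fixes one explicit, tested convention.

## Numerical and interface conventions

* Coordinates are 1-based and closed (`IRanges` convention): `cuts = p`
  separates mains between positions `p` and `p+1`; helper windows are
  intervals on the coding strand whose oligos are their reverse complements.
* Ties in event ordering break lexicographically by fragment names; DP
  tracebacks use a fixed scan order; all stochastic steps consume the R RNG,
  so a single `set.seed()`/`seed` argument reproduces runs exactly.
* Fold results satisfy $\Delta G = \Delta H - T\Delta S$ to 1e-6 by
  construction: the C++ engine's energy is re-derived by the R reference
  scorer for every traceback and a disagreement is an error, so the two
  implementations continuously cross-validate.
* Degenerate inputs: peptides must be non-empty standard residues; an
  unpaired structure has $\Delta G = 0$ and no melting temperature; `F_C`
  errors on sequences with no sense codons; infeasible fragmentations
  ($N_{\mathrm{main}} < L_{\min}$) error before the search starts.
* Test problem sizes: enumeration oracles run at total length ≤ 16 (hundreds
  of structures; exact), search reproducibility at 6–8 individuals for a few
  generations, and cache identity on 50 random 15-residue designs; the
  bundled 11- and 34-oligo sets exercise the full planning path.

## Known limitations

* No mismatch, wobble, dangling-end or coaxial-stacking terms: spurious
  duplex stability in repeat-poor random sequence is underestimated relative
  to richer models, which matters for the absolute (not relative) mixture
  success rate.
* The two-state $T_m$ collapses a structure to one melting event; partial
  melting of long heterogeneous duplexes is not represented.
* Tube partitioning is greedy, not exact, and merge-step mixtures are
  assumed conflict-free (their products are long and their designed duplexes
  strong).
* Restriction-site and regulatory-motif avoidance, codon-pair bias, and PCR
  primer design are out of scope; primers bundled with the fixtures are data
  only.
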