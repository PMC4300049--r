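# LCRDesign

Design synthetic genes *and* their assembly protocols in one optimization.

Chemical DNA synthesis tops out around 80 nt, so a synthetic gene must be
assembled from short oligos. LCRDesign targets ligase-chain-reaction (LCR)
assembly under a slowly decreasing temperature: **main chains** tile the
coding strand end-to-end, **helper chains** (reverse complements of windows
spanning each junction) clamp adjacent main chains together for ligation,
and the template strand may stay gapped between helpers — fewer nucleotides
than full double-strand tilings. Because the mixture cools slowly, duplexes
form in order of decreasing melting temperature; the design goal is that
every high-temperature event is a designed junction duplex.

The package is for molecular biologists and bioinformaticians planning gene
synthesis, and for method developers who want an inspectable, fully tested
reference implementation of the underlying models.

## What it computes

A design is the triple (codon choice, cut positions, helper windows). An
evolutionary algorithm with three mutation operators searches this space,
scoring each candidate with

    F = 1 / (1 + F_C + F_N + F_S)

where

* `F_C = w_C * sqrt( sum_j n_j (C_rj - C_ij)^2 / n )` — count-weighted RMS
  deviation of the design's per-amino-acid codon frequencies `C_ij` from the
  host's required frequencies `C_rj`;
* `F_N = w_N * (N - N_min) / (N_max - N_min)` — total synthesized
  nucleotides `N` between `N_min = N_main + (k-1) L_min` and
  `N_max = 2 N_main`;
* `F_S = w_S * (S - 1)^2` — protocol complexity, with `S` the number of
  base-protocol runs (leaf tubes plus merge steps).

`S` comes from a folding-order correctness check: every fragment pair
(including each fragment with itself) is co-folded with a Zuker-style
minimum-free-energy dynamic program under unified DNA nearest-neighbor
thermodynamics, events are ranked by two-state melting temperature, and any
undesigned duplex that outranks the weakest designed junction is a conflict.
Conflicting fragments are partitioned into separate tubes (a "complex
protocol") whose products merge in later base-protocol steps.

See `vignettes/gene-assembly-design.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(LCRDesign)
par   <- nnParameters()                     # packaged DNA NN parameter set
usage <- readCodonUsage(system.file("extdata", "example_host_usage.tsv",
                                    package = "LCRDesign"))

pep <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"  # 33 residues
cfg <- eaConfig(populationSize = 12, generations = 15, seed = 42)
res <- runEA(pep, usage, cfg, par)

res$fitness
#> FitnessBreakdown: F = 0.8214 (FC = 0.2175, FN = 0.0000, FS = 0.0000)
#>   N = 182 in [182, 204], k = 5, S = 1
res$protocol
#> AssemblyProtocol: 1 tube(s), S = 1
#>   tube 1: M1, M2, M3, M4, M5, H1, H2, H3, H4
```

Reading: the 33-residue peptide became a 102-nt CDS cut into five main
chains (20–22 nt) clamped by four 20-nt helpers, all assemblable in a single
tube (`S = 1`, so `F_S = 0`); helpers sit at their minimum length, so the
nucleotide cost is at its lower bound (`F_N = 0`); the remaining penalty is
codon-usage deviation (`F_C = 0.22` — a short peptide cannot match the host
frequency table exactly). `buildFragments(res$design)` lists the oligos with
their phosphorylation flags (main chains need 5' phosphates for ligation),
and `writeFragmentsTSV()` / `writeFragmentsFasta()` export them.

The package also bundles the oligo sets of a published protease-gene
analogue design as fixtures:

```r
fx <- loadFixture("ubp4_prime")       # 11 oligos
reconstructStrand(fx$fragments)$length
#> [1] 276
planProtocol(fx$fragments, par)
#> AssemblyProtocol: 1 tube(s), S = 1
```

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/lcrdesign.R fold --seq GCGCAAAAAAGCGC
Rscript inst/cli/lcrdesign.R simulate --trials 1000 --seed 1
```

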