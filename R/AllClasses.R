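#' @import methods
#' @importFrom stats setNames
NULL

#' Host codon-usage table
#'
#' Holds the required per-amino-acid codon frequencies \eqn{C_{rj}} of a host
#' organism. Every sense codon of the standard genetic code is present exactly
#' once and synonymous frequencies sum to one within each amino acid.
#'
#' @slot table data.frame with columns `codon`, `aa`, `freq`.
#' @seealso [readCodonUsage()]
#' @export
setClass("CodonUsageTable", representation(table = "data.frame"))

setValidity("CodonUsageTable", function(object) {
  tb <- object@table
  if (!all(c("codon", "aa", "freq") %in% names(tb)))
    return("table must have columns codon, aa, freq")
  code <- .geneticCode()
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, tb$codon)
  if (length(missing))
    return(paste0("missing codon ", paste(missing, collapse = ", ")))
  if (anyDuplicated(tb$codon))
    return("duplicated codon entries")
  if (any(tb$freq < 0 | tb$freq > 1))
    return("frequencies must lie in [0, 1]")
  sums <- tapply(tb$freq, tb$aa, sum)
  sums <- sums[names(sums) != "*"]
  if (any(abs(sums - 1) > 1e-9))
    return(paste0("frequencies do not sum to 1 for amino acid(s) ",
                  paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", ")))
  TRUE
})

#' Nearest-neighbor thermodynamic parameter set for DNA
#'
#' Watson-Crick stack enthalpies/entropies, loop penalties (free energies at
#' 37 degC, treated as purely entropic), duplex initiation and terminal A/T
#' terms, and the multiloop model. Loaded from a versioned JSON file whose
#' checksum is recorded.
#'
#' @slot stacks data.frame with columns `step`, `dH` (kcal/mol), `dS`
#'   (cal/(mol K)); one row per 5'->3' dinucleotide step.
#' @slot initiation,terminalAT numeric `c(dH, dS)` duplex corrections.
#' @slot symmetryDS numeric, entropy correction for self-complementary duplexes.
#' @slot hairpinG37,bulgeG37,internalG37 named numeric, loop free energies at
#'   37 degC by loop size (anchor lengths; intermediate sizes interpolated
#'   logarithmically, larger sizes extrapolated logarithmically).
#' @slot multiloop numeric `c(a, b, c)`: closing, per-branch and per-unpaired
#'   free energies at 37 degC.
#' @slot loopCap integer, largest admissible interior/bulge loop.
#' @slot extrapCoef numeric, coefficient of the logarithmic loop extrapolation.
#' @slot source,checksum character, provenance of the parameter file.
#' @seealso [nnParameters()]
#' @export
setClass("NNParameterSet", representation(
  stacks = "data.frame", initiation = "numeric", terminalAT = "numeric",
  symmetryDS = "numeric", hairpinG37 = "numeric", bulgeG37 = "numeric",
  internalG37 = "numeric", multiloop = "numeric", loopCap = "integer",
  extrapCoef = "numeric", source = "character", checksum = "character"))

setValidity("NNParameterSet", function(object) {
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  if (!setequal(object@stacks$step, steps))
    return("all 16 Watson-Crick stack steps must be present")
  if (object@loopCap < 3L) return("loopCap must be >= 3")
  for (nm in c("hairpinG37", "bulgeG37", "internalG37")) {
    g <- slot(object, nm)
    l <- as.integer(names(g))
    if (is.unsorted(l)) return(paste(nm, "anchors must be sorted by length"))
  }
  TRUE
})

#' Minimum-free-energy folding result
#'
#' Secondary structure of a strand or a strand pair with its thermodynamic
#' summary. For strand pairs the two sequences are concatenated; base indices
#' in `pairs` beyond `nchar(strandA)` belong to the second strand.
#'
#' @slot strandA,strandB character; `strandB` is `NA` for a single strand.
#' @slot pairs two-column integer matrix of paired base indices (1-based over
#'   the concatenation).
#' @slot dG,dH,dS numeric: free energy at `temperature` (kcal/mol), enthalpy
#'   (kcal/mol) and entropy (cal/(mol K)) of the structure.
#' @slot temperature numeric, evaluation temperature in degC.
#' @slot bimolecular logical, `TRUE` when the structure joins the two strands
#'   through at least one inter-strand pair.
#' @seealso [mfeFold()], [mfeCofold()], [meltingTemperature()]
#' @export
setClass("FoldResult", representation(
  strandA = "character", strandB = "character", pairs = "matrix",
  dG = "numeric", dH = "numeric", dS = "numeric", temperature = "numeric",
  bimolecular = "logical"))

setValidity("FoldResult", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (nrow(p)) {
    idx <- as.vector(p)
    if (anyDuplicated(idx)) return("a base participates in two pairs")
    if (any(p[, 2] <= p[, 1])) return("pairs must satisfy i < j")
  }
  tK <- object@temperature + 273.15
  if (abs(object@dG - (object@dH - tK * object@dS / 1000)) > 1e-6)
    return("dG inconsistent with dH - T*dS")
  TRUE
})

#' A candidate gene-synthesis design
#'
#' The coding-strand DNA of the target gene together with the partition into
#' main chains and the placement of helper chains. Coordinates are 1-based:
#' `cuts[i] = p` separates main chains between positions `p` and `p + 1`;
#' helper `i` covers the closed interval `helpers[i]` on the coding strand
#' (its oligo is the reverse complement of that interval) and must overlap cut
#' `i` by at least `minOverlap` nucleotides on each side.
#'
#' @slot dna character, coding strand (5'->3').
#' @slot cuts integer, sorted cut positions (may be empty).
#' @slot helpers [IRanges::IRanges], one range per cut, non-overlapping.
#' @slot Lmin,Lmax integer, chemical-synthesis length bounds for every
#'   fragment.
#' @slot minOverlap integer, minimum helper overlap on each side of its cut.
#' @seealso [geneDesign()], [buildFragments()]
#' @export
setClass("GeneDesign", representation(
  dna = "character", cuts = "integer", helpers = "IRanges",
  Lmin = "integer", Lmax = "integer", minOverlap = "integer"))

setValidity("GeneDesign", function(object) {
  n <- nchar(object@dna)
  if (n == 0L) return("empty sequence")
  if (!grepl("^[ACGT]+$", object@dna)) return("dna must be over A/C/G/T")
  cuts <- object@cuts
  if (length(cuts)) {
    if (is.unsorted(cuts, strictly = TRUE)) return("cuts must be strictly increasing")
    if (any(cuts < 1L | cuts >= n)) return("cuts out of range")
  }
  bounds <- c(0L, cuts, n)
  mains <- diff(bounds)
  if (any(mains < object@Lmin | mains > object@Lmax))
    return(sprintf("main chain %d has length %d outside [%d, %d]",
                   which(mains < object@Lmin | mains > object@Lmax)[1],
                   mains[which(mains < object@Lmin | mains > object@Lmax)[1]],
                   object@Lmin, object@Lmax))
  h <- object@helpers
  if (length(h) != length(cuts))
    return("one helper per cut is required")
  if (length(h)) {
    w <- IRanges::width(h)
    if (any(w < object@Lmin | w > object@Lmax))
      return(sprintf("helper %d has length %d outside [%d, %d]",
                     which(w < object@Lmin | w > object@Lmax)[1],
                     w[which(w < object@Lmin | w > object@Lmax)[1]],
                     object@Lmin, object@Lmax))
    s <- IRanges::start(h); e <- IRanges::end(h)
    if (any(s < 1L | e > n)) return("helper outside the coding strand")
    ov <- object@minOverlap
    bad <- which(s > cuts - ov + 1L | e < cuts + ov)
    if (length(bad))
      return(sprintf("helper %d does not overlap cut %d by >= %d nt on each side",
                     bad[1], bad[1], ov))
    # a helper must span only its own junction
    for (i in seq_along(h)) {
      others <- cuts[-i]
      if (length(others) && any(s[i] <= others & others < e[i]))
        return(sprintf("helper %d spans a junction other than its own", i))
    }
    if (length(h) > 1L && any(s[-1L] <= e[-length(h)]))
      return("helpers overlap one another")
  }
  TRUE
})

#' Conflict report of the base-protocol folding-order check
#'
#' @slot verdict character, `"correct"` or `"conflicting"`.
#' @slot events data.frame of all predicted duplex-formation events (columns
#'   `f1`, `f2`, `tm`, `bimolecular`, `class`), sorted by descending melting
#'   temperature; `class` is one of `designed`, `improper`, `post-assembly`.
#' @slot conflicts data.frame of offending pairs with a `reason` column.
#' @slot threshold numeric, melting temperature of the weakest designed
#'   junction event (degC).
#' @seealso [checkBaseProtocol()]
#' @export
setClass("ConflictReport", representation(
  verdict = "character", events = "data.frame", conflicts = "data.frame",
  threshold = "numeric"))

#' Assembly protocol plan
#'
#' Partition of the fragments into leaf tubes plus a binary merge tree; `S`
#' counts base-protocol executions (leaf tubes and merge steps).
#'
#' @slot tubes list of character vectors of fragment names, one per leaf tube.
#' @slot mergeTree list, nested binary merge structure over tube indices.
#' @slot S integer, number of base-protocol executions.
#' @slot feasible logical, `FALSE` when a conflict cannot be separated by any
#'   tube partition (for example a fragment conflicting with itself).
#' @slot events data.frame, the full-set folding-order events.
#' @slot conflicts data.frame, conflicts detected while planning.
#' @seealso [planProtocol()]
#' @export
setClass("AssemblyProtocol", representation(
  tubes = "list", mergeTree = "list", S = "integer", feasible = "logical",
  events = "data.frame", conflicts = "data.frame"))

setValidity("AssemblyProtocol", function(object) {
  if (object@S < 1L) return("S must be >= 1")
  if (length(object@tubes) == 1L && object@S != 1L)
    return("a single tube implies S = 1")
  TRUE
})

#' Fitness decomposition of a gene-synthesis design
#'
#' Composite fitness \eqn{F = 1 / (1 + F_C + F_N + F_S)} with the codon-usage
#' deviation \eqn{F_C}, the nucleotide-cost component
#' \eqn{F_N = w_N (N - N_{min}) / (N_{max} - N_{min})} and the protocol
#' complexity \eqn{F_S = w_S (S - 1)^2}.
#'
#' @slot FC,FN,FS,F numeric fitness components and composite.
#' @slot N,Nmin,Nmax,Nmain,k,S integer quantities entering the components:
#'   total nucleotides over all fragments, its bounds
#'   \eqn{N_{min} = N_{main} + (k - 1) L_{min}} and \eqn{N_{max} = 2 N_{main}},
#'   target length, number of main chains and number of base protocols.
#' @seealso [designFitness()]
#' @export
setClass("FitnessBreakdown", representation(
  FC = "numeric", FN = "numeric", FS = "numeric", F = "numeric",
  N = "integer", Nmin = "integer", Nmax = "integer", Nmain = "integer",
  k = "integer", S = "integer"))

setValidity("FitnessBreakdown", function(object) {
  if (abs(object@F - 1 / (1 + object@FC + object@FN + object@FS)) > 1e-9)
    return("F inconsistent with its components")
  if (object@F <= 0 || object@F > 1) return("F must lie in (0, 1]")
  TRUE
})
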