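## Nearest-neighbor thermodynamics and MFE folding front-end.
## Energies are kept as (dH, dS) so that free energies can be re-evaluated at
## any temperature; loop penalties are stored as dG(37 degC) and treated as
## purely entropic (dH = 0).

.GAS_CONSTANT <- 1.9872      # cal / (mol K)
.T37 <- 310.15               # K

.baseCode <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.seqToInt <- function(x) {
  v <- .baseCode[strsplit(x, "", fixed = TRUE)[[1]]]
  if (anyNA(v)) stop("sequence contains a non-ACGT character: ", x)
  unname(v)
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Load a DNA nearest-neighbor parameter set
#'
#' Reads the packaged (or a user-supplied) JSON parameter file containing
#' Watson-Crick stack dH/dS terms, loop free-energy tables, initiation and
#' terminal A/T corrections and the multiloop model. The file's MD5 checksum
#' is stored for provenance.
#'
#' @param file path to a parameter JSON file; defaults to the packaged
#'   unified DNA set.
#' @return an [NNParameterSet-class] object.
#' @export
#' @examples
#' par <- nnParameters()
#' par
nnParameters <- function(file = system.file("extdata", "dna_nn_unified.json",
                                            package = "LCRDesign")) {
  if (!nzchar(file) || !file.exists(file)) stop("parameter file not found")
  js <- jsonlite::read_json(file, simplifyVector = TRUE)
  st <- js$stacks
  stacks <- data.frame(step = names(st),
                       dH = vapply(st, function(x) x$dH, 0),
                       dS = vapply(st, function(x) x$dS, 0),
                       stringsAsFactors = FALSE)
  anch <- function(x) setNames(as.numeric(unlist(x)), names(x))
  new("NNParameterSet",
      stacks = stacks,
      initiation = c(dH = js$initiation$dH, dS = js$initiation$dS),
      terminalAT = c(dH = js$terminal_AT$dH, dS = js$terminal_AT$dS),
      symmetryDS = js$symmetry_dS,
      hairpinG37 = anch(js$hairpin_g37),
      bulgeG37 = anch(js$bulge_g37),
      internalG37 = anch(js$internal_g37),
      multiloop = c(a = js$multiloop$a, b = js$multiloop$b, c = js$multiloop$c),
      loopCap = as.integer(js$loop_cap),
      extrapCoef = js$loop_extrapolation_coefficient,
      source = file,
      checksum = unname(tools::md5sum(file)))
}

#' @describeIn nnParameters concise display
#' @param object an [NNParameterSet-class]
#' @export
setMethod("show", "NNParameterSet", function(object) {
  cat("NNParameterSet (", basename(object@source), ", md5 ",
      substr(object@checksum, 1, 8), ")\n", sep = "")
  cat("  16 WC stacks; loop cap ", object@loopCap,
      "; multiloop a/b/c = ", paste(object@multiloop, collapse = "/"), "\n",
      sep = "")
})

## dense loop dG37 table for sizes 1..maxLen from anchors, with logarithmic
## interpolation between anchors and logarithmic extrapolation beyond
.denseLoopG37 <- function(anchors, maxLen, coef) {
  lens <- as.integer(names(anchors))
  out <- rep(NA_real_, maxLen)
  for (l in seq_len(maxLen)) {
    if (l < lens[1]) { out[l] <- NA_real_; next }
    if (l %in% lens) { out[l] <- anchors[[as.character(l)]]; next }
    if (l > lens[length(lens)]) {
      lmax <- lens[length(lens)]
      out[l] <- anchors[[length(anchors)]] +
        coef * .GAS_CONSTANT / 1000 * .T37 * log(l / lmax)
    } else {
      hi <- which(lens > l)[1]; lo <- hi - 1L
      a <- lens[lo]; b <- lens[hi]
      out[l] <- anchors[[lo]] + (anchors[[hi]] - anchors[[lo]]) *
        log(l / a) / log(b / a)
    }
  }
  out
}

## per-temperature dG tables for the C++ engine
.energyTables <- function(par, temperature, maxLen) {
  tK <- temperature + 273.15
  scale <- tK / .T37   # purely entropic loop terms scale linearly with T
  stackG <- numeric(16)
  for (i in seq_len(nrow(par@stacks))) {
    st <- par@stacks$step[i]
    b <- .baseCode[strsplit(st, "")[[1]]]
    stackG[4 * b[1] + b[2] + 1] <-
      par@stacks$dH[i] - tK * par@stacks$dS[i] / 1000
  }
  cap <- par@loopCap
  hp <- .denseLoopG37(par@hairpinG37, max(maxLen, 4L), par@extrapCoef) * scale
  hp[is.na(hp)] <- 1e9
  bg <- .denseLoopG37(par@bulgeG37, cap, par@extrapCoef) * scale
  ig <- .denseLoopG37(par@internalG37, cap, par@extrapCoef) * scale
  ig[is.na(ig)] <- 1e9
  ## C indexes these 0-based by loop size, so element s+1 holds size s
  list(stackG = stackG,
       hairpinG = c(1e9, hp),
       bulgeG = c(1e9, bg),
       internalG = c(1e9, ig),
       mlA = par@multiloop[["a"]] * scale,
       mlB = par@multiloop[["b"]] * scale,
       mlC = par@multiloop[["c"]] * scale,
       cap = cap, tK = tK)
}

## loop dH/dS accessors for the structure scorer (loops purely entropic)
.loopDS <- function(par, type, size) {
  anchors <- switch(type, hairpin = par@hairpinG37, bulge = par@bulgeG37,
                    internal = par@internalG37)
  g37 <- .denseLoopG37(anchors, max(size, 4L), par@extrapCoef)[size]
  if (is.na(g37)) stop("no ", type, " loop of size ", size)
  -g37 * 1000 / .T37
}

.stackDHDS <- function(par, x, y) {
  i <- match(paste0(x, y), par@stacks$step)
  c(dH = par@stacks$dH[i], dS = par@stacks$dS[i])
}

#' Nearest-neighbor energy of a perfect Watson-Crick duplex
#'
#' Sums stack terms over the duplex plus the bimolecular initiation term,
#' a terminal A/T correction per duplex end, and the symmetry entropy
#' correction for self-complementary strands.
#'
#' @param strandA DNA string (5'->3').
#' @param strandB DNA string; must be the reverse complement of `strandA`
#'   (the default).
#' @param par an [NNParameterSet-class].
#' @param temperature evaluation temperature in degC.
#' @return list with `dG` (kcal/mol at `temperature`), `dH` (kcal/mol) and
#'   `dS` (cal/(mol K)).
#' @export
#' @examples
#' par <- nnParameters()
#' duplexEnergy("ACGTACGTAC", par = par)
duplexEnergy <- function(strandA, strandB = .revComp(strandA),
                         par = nnParameters(), temperature = 37) {
  a <- .seqToInt(strandA); b <- .seqToInt(strandB)
  if (length(a) != length(b)) stop("duplex strands differ in length")
  n <- length(a)
  mismatch <- which(a + rev(b) != 3L)
  if (length(mismatch))
    stop("non-complementary position ", mismatch[1], " inside claimed duplex")
  dH <- par@initiation[["dH"]]; dS <- par@initiation[["dS"]]
  for (i in seq_len(n - 1L)) {
    st <- .stackDHDS(par, substr(strandA, i, i), substr(strandA, i + 1L, i + 1L))
    dH <- dH + st[["dH"]]; dS <- dS + st[["dS"]]
  }
  for (end in c(1L, n)) {
    if (substr(strandA, end, end) %in% c("A", "T")) {
      dH <- dH + par@terminalAT[["dH"]]; dS <- dS + par@terminalAT[["dS"]]
    }
  }
  if (identical(strandA, strandB)) dS <- dS + par@symmetryDS
  tK <- temperature + 273.15
  list(dG = dH - tK * dS / 1000, dH = dH, dS = dS)
}

## ---------------------------------------------------------------------------
## Structure scoring (the energy-model reference, independent of the DP)

## classify the loops of a secondary structure and return dH/dS sums.
## pairs: 2-column matrix over the concatenation; nA = length of strand A
## (nA = total length for a single strand).
.scoreStructure <- function(seqInt, seqChar, pairs, nA, par) {
  dH <- 0; dS <- 0
  cap <- par@loopCap
  if (nrow(pairs) == 0L) return(c(dH = 0, dS = 0))
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  n <- length(seqInt)
  idx <- as.vector(pairs)
  if (anyDuplicated(idx)) stop("base in two pairs")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
  ## crossing check + nesting: find parent of each pair
  np <- nrow(pairs)
  parent <- rep(0L, np)            # 0 = exterior
  stack <- integer(0)
  events <- order(c(pairs[, 1], pairs[, 2]))
  pos <- c(pairs[, 1], pairs[, 2])
  isOpen <- c(rep(TRUE, np), rep(FALSE, np))
  for (e in events) {
    p <- ((e - 1L) %% np) + 1L
    if (isOpen[e]) {
      parent[p] <- if (length(stack)) stack[length(stack)] else 0L
      stack <- c(stack, p)
    } else {
      if (!length(stack) || stack[length(stack)] != p)
        stop("crossing pairs (pseudoknot)")
      stack <- stack[-length(stack)]
    }
  }
  containsJ <- function(i, j) i <= nA && j > nA
  crossPairs <- pairs[, 1] <= nA & pairs[, 2] > nA
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    kids <- which(parent == p)
    ## does the loop (as opposed to a child) contain the junction?
    loopHasJ <- containsJ(i, j) &&
      !any(pairs[kids, 1] <= nA & pairs[kids, 2] > nA)
    if (loopHasJ) next                       # junction loop: no penalty
    if (length(kids) == 0L) {                # hairpin
      size <- j - i - 1L
      if (size < 3L) stop("hairpin loop smaller than 3")
      dS <- dS + .loopDS(par, "hairpin", size)
    } else if (length(kids) == 1L) {         # stack / bulge / internal
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      g1 <- k - i - 1L; g2 <- j - l - 1L
      if (g1 == 0L && g2 == 0L) {
        st <- .stackDHDS(par, seqChar[i], seqChar[k])
        dH <- dH + st[["dH"]]; dS <- dS + st[["dS"]]
      } else {
        g <- g1 + g2
        if (g > cap) return(c(dH = NA_real_, dS = NA_real_))  # excluded
        type <- if (g1 == 0L || g2 == 0L) "bulge" else "internal"
        dS <- dS + .loopDS(par, type, g)
      }
    } else {                                 # multiloop
      u <- (j - i - 1L) - sum(pairs[kids, 2] - pairs[kids, 1] + 1L)
      g37 <- par@multiloop[["a"]] + par@multiloop[["b"]] * (length(kids) + 1L) +
        par@multiloop[["c"]] * u
      dS <- dS - g37 * 1000 / .T37
    }
  }
  if (any(crossPairs)) {
    dH <- dH + par@initiation[["dH"]]
    dS <- dS + par@initiation[["dS"]]
    if (nA < n && identical(paste(seqChar[1:nA], collapse = ""),
                            paste(seqChar[(nA + 1):n], collapse = "")))
      dS <- dS + par@symmetryDS
  }
  c(dH = dH, dS = dS)
}

#' Energy of a given secondary structure
#'
#' Scores an explicit secondary structure (set of base pairs) under the
#' package's nearest-neighbor model: stacks, hairpin/bulge/internal loop
#' penalties (capped interior loops), an affine multiloop model, free
#' junction-spanning loops and bimolecular initiation for strand pairs. This
#' is the reference implementation of the energy model against which the
#' dynamic-programming engine is validated.
#'
#' @param strandA,strandB DNA strings; `strandB = NULL` for a single strand.
#' @param pairs two-column integer matrix of paired positions, 1-based over
#'   the concatenation of `strandA` and `strandB`.
#' @inheritParams duplexEnergy
#' @return list with `dG`, `dH`, `dS`; `dG` is `Inf` for structures excluded
#'   by the interior-loop cap.
#' @export
structureEnergy <- function(strandA, strandB = NULL, pairs,
                            par = nnParameters(), temperature = 37) {
  seqChar <- strsplit(paste0(strandA, if (is.null(strandB)) "" else strandB),
                      "")[[1]]
  seqInt <- .baseCode[seqChar]
  if (anyNA(seqInt)) stop("sequence contains a non-ACGT character")
  nA <- if (is.null(strandB)) length(seqInt) else nchar(strandA)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    comp <- seqInt[pairs[, 1]] + seqInt[pairs[, 2]]
    if (any(comp != 3L)) stop("non-Watson-Crick pair in structure")
  }
  hs <- .scoreStructure(seqInt, seqChar, pairs, nA, par)
  tK <- temperature + 273.15
  if (anyNA(hs)) return(list(dG = Inf, dH = NA_real_, dS = NA_real_))
  list(dG = hs[["dH"]] - tK * hs[["dS"]] / 1000,
       dH = hs[["dH"]], dS = hs[["dS"]])
}

## run the C++ engine on an integer sequence; cut = nA for single strand
.foldEngine <- function(seqInt, cut, par, temperature) {
  et <- .energyTables(par, temperature, maxLen = length(seqInt) + 1L)
  c_fold(seqInt, cut, et$stackG, et$hairpinG, et$bulgeG, et$internalG,
         et$mlA, et$mlB, et$mlC, et$cap)
}

.mkFoldResult <- function(strandA, strandB, pairs, bimolecular, par,
                          temperature) {
  en <- structureEnergy(strandA, strandB, pairs, par, temperature)
  new("FoldResult", strandA = strandA,
      strandB = if (is.null(strandB)) NA_character_ else strandB,
      pairs = matrix(as.integer(pairs), ncol = 2), dG = en$dG, dH = en$dH,
      dS = en$dS, temperature = temperature, bimolecular = bimolecular)
}

#' Minimum-free-energy structure of a single DNA strand
#'
#' Zuker-style dynamic programming over Watson-Crick pairs with hairpin,
#' bulge/internal (capped) and affine multiloop energies. When no structure
#' has negative free energy the open chain (no pairs, dG = 0) is returned.
#'
#' @param strand DNA string (5'->3').
#' @inheritParams duplexEnergy
#' @return a [FoldResult-class].
#' @export
#' @examples
#' par <- nnParameters()
#' mfeFold("GCGCAAAAAAGCGC", par = par)
mfeFold <- function(strand, par = nnParameters(), temperature = 37) {
  s <- .seqToInt(strand)
  res <- .foldEngine(s, length(s), par, temperature)
  fr <- .mkFoldResult(strand, NULL, res$pairs, FALSE, par, temperature)
  if (abs(fr@dG - res$dG) > 1e-6)
    stop("internal error: DP and scorer disagree (", fr@dG, " vs ", res$dG, ")")
  fr
}

#' Minimum-free-energy structure of a strand pair
#'
#' Folds the concatenation of the two strands with a junction between them:
#' loops spanning the junction are free and exempt from hairpin-size and
#' loop-cap rules, and structures containing an inter-strand pair incur the
#' bimolecular initiation term (plus the symmetry correction when both
#' strands are identical). When folding the strands separately is at least
#' as favorable, the separate folds are returned with
#' `bimolecular = FALSE`. Symmetric in its two arguments.
#'
#' @param strandA,strandB DNA strings (5'->3'); `strandB` may equal
#'   `strandA` (a fragment with itself).
#' @inheritParams duplexEnergy
#' @return a [FoldResult-class] over the concatenation.
#' @export
#' @examples
#' par <- nnParameters()
#' mfeCofold("ACGTACGTAC", "GTACGTACGT", par = par)
mfeCofold <- function(strandA, strandB, par = nnParameters(),
                      temperature = 37) {
  ## canonical argument order makes the result symmetric by construction
  if (strandA > strandB) { tmp <- strandA; strandA <- strandB; strandB <- tmp }
  a <- .seqToInt(strandA); b <- .seqToInt(strandB)
  nA <- length(a)
  tK <- temperature + 273.15
  fa <- .foldEngine(a, nA, par, temperature)
  fb <- .foldEngine(b, length(b), par, temperature)
  joint <- .foldEngine(c(a, b), nA, par, temperature)
  initG <- par@initiation[["dH"]] - tK * par@initiation[["dS"]] / 1000
  if (identical(strandA, strandB)) initG <- initG - tK * par@symmetryDS / 1000
  jp <- joint$pairs
  hasCross <- nrow(jp) > 0 && any(jp[, 1] <= nA & jp[, 2] > nA)
  sepG <- fa$dG + fb$dG
  if (hasCross && joint$dG + initG < sepG - 1e-9) {
    fr <- .mkFoldResult(strandA, strandB, jp, TRUE, par, temperature)
    target <- joint$dG + initG
  } else {
    pairs <- rbind(fa$pairs, fb$pairs + nA)
    fr <- .mkFoldResult(strandA, strandB, pairs, FALSE, par, temperature)
    target <- sepG
  }
  if (abs(fr@dG - target) > 1e-6)
    stop("internal error: DP and scorer disagree (", fr@dG, " vs ", target, ")")
  fr
}

#' Two-state melting temperature of a folded structure
#'
#' For bimolecular structures
#' \eqn{T_m = \Delta H / (\Delta S + R \ln(C_T / x)) - 273.15} with
#' \eqn{x = 1} for a pair of identical strands and \eqn{x = 4} otherwise;
#' for unimolecular structures \eqn{T_m = \Delta H / \Delta S - 273.15}.
#'
#' @param fold a [FoldResult-class].
#' @param concentration total single-strand concentration \eqn{C_T} in mol/L
#'   (default 0.4 uM, i.e. 20 pmol in 50 uL).
#' @return melting temperature in degC, or `NA` when the structure has no
#'   pairs.
#' @export
meltingTemperature <- function(fold, concentration = 4e-7) {
  if (nrow(fold@pairs) == 0L) return(NA_real_)
  if (fold@dH >= 0)
    stop("non-negative enthalpy with pairs present; corrupted parameters?")
  if (fold@bimolecular) {
    x <- if (identical(fold@strandA, fold@strandB)) 1 else 4
    tK <- fold@dH * 1000 / (fold@dS + .GAS_CONSTANT * log(concentration / x))
  } else {
    tK <- fold@dH * 1000 / fold@dS
  }
  tK - 273.15
}

#' @describeIn mfeFold display method for fold results
#' @param object a [FoldResult-class]
#' @export
setMethod("show", "FoldResult", function(object) {
  kind <- if (is.na(object@strandB)) "single strand"
          else if (object@bimolecular) "strand pair (bimolecular)"
          else "strand pair (separate folds)"
  cat("FoldResult: ", kind, ", ", nrow(object@pairs), " pairs\n", sep = "")
  cat(sprintf("  dG = %.2f kcal/mol at %.1f degC (dH = %.1f, dS = %.1f)\n",
              object@dG, object@temperature, object@dH, object@dS))
})
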