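## Fragment construction, reconstruction, folding-order correctness, and
## base/complex protocol planning.

#' Construct a gene-synthesis design
#'
#' @param dna coding-strand DNA string.
#' @param cuts integer vector of cut positions: cut `p` separates main chains
#'   between positions `p` and `p + 1` (1-based).
#' @param helpers an [IRanges::IRanges] (or 2-column matrix of start/end) of
#'   helper intervals on the coding strand, one per cut.
#' @param Lmin,Lmax fragment length bounds (chemical synthesis limits).
#' @param minOverlap minimum helper overlap on each side of its cut, in nt.
#' @return a validated [GeneDesign-class].
#' @export
#' @examples
#' d <- geneDesign(strrep("ACGT", 15), cuts = 30,
#'                 helpers = IRanges::IRanges(21, 40))
geneDesign <- function(dna, cuts = integer(0), helpers = IRanges::IRanges(),
                       Lmin = 20L, Lmax = 80L, minOverlap = 10L) {
  if (is.matrix(helpers))
    helpers <- IRanges::IRanges(start = helpers[, 1], end = helpers[, 2])
  new("GeneDesign", dna = toupper(dna), cuts = as.integer(cuts),
      helpers = helpers, Lmin = as.integer(Lmin), Lmax = as.integer(Lmax),
      minOverlap = as.integer(minOverlap))
}

#' @describeIn geneDesign display method
#' @param object a [GeneDesign-class]
#' @export
setMethod("show", "GeneDesign", function(object) {
  cat("GeneDesign: ", nchar(object@dna), " nt, ",
      length(object@cuts) + 1L, " main chains, ",
      length(object@helpers), " helpers\n", sep = "")
})

#' Build a fragment set
#'
#' Construct a named [Biostrings::DNAStringSet] of oligos with metadata
#' columns `role` (`main`/`helper`) and `phosphorylated`. Either from a
#' [GeneDesign-class] (main chains are the cut pieces of the coding strand,
#' 5'-phosphorylated; helper chains are the reverse complements of the helper
#' intervals, unphosphorylated) or from explicit sequences.
#'
#' @param x a [GeneDesign-class], or a character vector of sequences.
#' @param role for character input, a vector of `"main"`/`"helper"`.
#' @param names fragment names (defaults to `M1..Mk`, `H1..`).
#' @return a [Biostrings::DNAStringSet] with `role` and `phosphorylated`
#'   metadata columns.
#' @export
buildFragments <- function(x, role = NULL, names = NULL) {
  if (is(x, "GeneDesign")) {
    methods::validObject(x)
    bounds <- c(0L, x@cuts, nchar(x@dna))
    mains <- substring(x@dna, head(bounds, -1L) + 1L, bounds[-1L])
    helpers <- vapply(seq_along(x@helpers), function(i)
      .revComp(substr(x@dna, IRanges::start(x@helpers)[i],
                      IRanges::end(x@helpers)[i])), character(1))
    seqs <- c(mains, helpers)
    role <- c(rep("main", length(mains)), rep("helper", length(helpers)))
    names <- c(paste0("M", seq_along(mains)),
               if (length(helpers)) paste0("H", seq_along(helpers)))
  } else {
    seqs <- as.character(x)
    if (is.null(role) || length(role) != length(seqs))
      stop("role must be given for every fragment")
    if (is.null(names)) names <- paste0("F", seq_along(seqs))
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, names))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    role = role, phosphorylated = role == "main")
  out
}

#' Reconstruct the coding strand from a fragment set
#'
#' Concatenates the main chains (in their listed order) and validates every
#' helper: its reverse complement must occur exactly once in the
#' concatenation and span at least one junction between adjacent main chains.
#'
#' @param fragments a [Biostrings::DNAStringSet] with a `role` metadata
#'   column (`main`/`helper`); primers must not be included.
#' @return list with `dna` (the coding strand), `length`, `junctions`
#'   (positions after which main chains abut), `helperJunction` (named
#'   integer: the junction index each helper spans), and `uncovered`
#'   (junction indices no helper spans).
#' @export
reconstructStrand <- function(fragments) {
  role <- S4Vectors::mcols(fragments)$role
  if (is.null(role)) stop("fragments lack a 'role' metadata column")
  mains <- as.character(fragments[role == "main"])
  helpers <- as.character(fragments[role == "helper"])
  if (!length(mains)) stop("no main chains")
  dna <- paste(mains, collapse = "")
  junctions <- cumsum(nchar(mains))
  junctions <- junctions[-length(junctions)]
  helperJunction <- integer(0)
  for (h in names(helpers)) {
    rc <- .revComp(helpers[[h]])
    hits <- gregexpr(rc, dna, fixed = TRUE)[[1]]
    if (hits[1] == -1L)
      stop("helper ", h, " matches the reconstructed strand nowhere")
    if (length(hits) > 1L)
      stop("helper ", h, " matches the reconstructed strand ",
           length(hits), " times (repeat in design)")
    st <- hits[1]; en <- st + nchar(rc) - 1L
    spanned <- which(junctions >= st & junctions < en)
    if (!length(spanned))
      stop("helper ", h, " spans no junction between main chains")
    helperJunction[h] <- spanned[1]
  }
  list(dna = dna, length = nchar(dna), junctions = junctions,
       helperJunction = helperJunction,
       uncovered = setdiff(seq_along(junctions),
                           unname(helperJunction)))
}

## cached pair evaluation: key on the two sequences; cache is an environment
## whose entries survive across fitness evaluations
.pairEvent <- function(seqA, seqB, par, temperature, concentration, cache) {
  key <- paste(seqA, seqB, sep = "|")
  if (!is.null(cache)) {
    hit <- cache$store[[key]]
    if (!is.null(hit)) { cache$hits <- cache$hits + 1L; return(hit) }
    cache$misses <- cache$misses + 1L
  }
  fold <- mfeCofold(seqA, seqB, par, temperature)
  ev <- if (fold@bimolecular) {
    list(tm = meltingTemperature(fold, concentration), bimolecular = TRUE)
  } else if (identical(seqA, seqB)) {
    single <- mfeFold(seqA, par, temperature)
    if (nrow(single@pairs)) {
      list(tm = meltingTemperature(single, concentration), bimolecular = FALSE)
    } else list(tm = NA_real_, bimolecular = FALSE)
  } else list(tm = NA_real_, bimolecular = FALSE)
  if (!is.null(cache)) cache$store[[key]] <- ev
  ev
}

#' Create a pair-energy cache
#'
#' An environment memoizing fragment-pair melting temperatures across fitness
#' evaluations; a mutation changes at most three fragments, so most pair
#' energies of the mutated individual are inherited.
#'
#' @return an environment with `store`, `hits`, `misses`.
#' @export
newPairEnergyCache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$hits <- 0L; e$misses <- 0L
  e
}

#' Predicted folding order of a fragment mixture
#'
#' Evaluates every unordered fragment pair, including each fragment with
#' itself, by co-folding; pairs whose minimum-free-energy structure joins the
#' two molecules yield a bimolecular melting temperature, self-pairs whose
#' strands prefer intramolecular structure yield a unimolecular one, and
#' pairs with no structure are omitted. Events are returned ordered by
#' descending melting temperature (ties broken lexicographically by fragment
#' names).
#'
#' @inheritParams reconstructStrand
#' @param par an [NNParameterSet-class].
#' @param temperature folding evaluation temperature in degC.
#' @param concentration per-strand concentration in mol/L.
#' @param cache optional [newPairEnergyCache()] environment.
#' @return data.frame with columns `f1`, `f2`, `tm`, `bimolecular`.
#' @export
foldingOrder <- function(fragments, par = nnParameters(), temperature = 37,
                         concentration = 4e-7, cache = NULL) {
  nms <- names(fragments)
  if (is.null(nms) || anyDuplicated(nms)) stop("fragments need unique names")
  seqs <- as.character(fragments)
  out <- list()
  for (i in seq_along(nms)) {
    for (j in i:length(nms)) {
      sA <- seqs[[i]]; sB <- seqs[[j]]
      ev <- .pairEvent(min(sA, sB), max(sA, sB), par, temperature,
                       concentration, cache)
      if (is.na(ev$tm)) next
      nm <- sort(c(nms[i], nms[j]))
      out[[length(out) + 1L]] <- data.frame(
        f1 = nm[1], f2 = nm[2], tm = ev$tm, bimolecular = ev$bimolecular,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(f1 = character(0), f2 = character(0),
                      tm = numeric(0), bimolecular = logical(0)))
  ev <- do.call(rbind, out)
  ev[order(-ev$tm, ev$f1, ev$f2), , drop = FALSE]
}

## designed events of a tiling: helper x each of its two adjacent mains
.designedPairs <- function(fragments, recon) {
  role <- S4Vectors::mcols(fragments)$role
  mainNames <- names(fragments)[role == "main"]
  out <- list()
  for (h in names(recon$helperJunction)) {
    jx <- recon$helperJunction[[h]]
    for (m in c(mainNames[jx], mainNames[jx + 1L])) {
      nm <- sort(c(h, m))
      out[[length(out) + 1L]] <- data.frame(f1 = nm[1], f2 = nm[2],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(f1 = character(0), f2 = character(0)))
  unique(do.call(rbind, out))
}

#' Folding-order correctness check of the base (one-tube) protocol
#'
#' Walks the predicted duplex-formation events in order of decreasing melting
#' temperature. Designed events are those joining a helper with one of its
#' two adjacent main chains. Any other event whose melting temperature
#' reaches the weakest designed junction event is improper: it would occur
#' before assembly completes and risks mis-assembly. The verdict is
#' `"correct"` iff no improper event exists and every designed junction forms
#' a predicted duplex.
#'
#' @inheritParams foldingOrder
#' @param events optional precomputed [foldingOrder()] result.
#' @return a [ConflictReport-class].
#' @export
checkBaseProtocol <- function(fragments, par = nnParameters(),
                              temperature = 37, concentration = 4e-7,
                              cache = NULL, events = NULL) {
  recon <- reconstructStrand(fragments)
  if (is.null(events))
    events <- foldingOrder(fragments, par, temperature, concentration, cache)
  designed <- .designedPairs(fragments, recon)
  key <- function(df) paste(df$f1, df$f2, sep = "~")
  evKey <- key(events)
  desKey <- key(designed)
  conflicts <- list()
  missing <- setdiff(desKey, evKey)
  for (mk in missing) {
    p <- strsplit(mk, "~", fixed = TRUE)[[1]]
    conflicts[[length(conflicts) + 1L]] <- data.frame(
      f1 = p[1], f2 = p[2], tm = NA_real_,
      reason = "designed junction forms no predicted duplex",
      stringsAsFactors = FALSE)
  }
  desTm <- events$tm[evKey %in% desKey]
  threshold <- if (length(desTm)) min(desTm) else Inf
  cls <- ifelse(evKey %in% desKey, "designed",
                ifelse(events$tm >= threshold - 1e-9, "improper",
                       "post-assembly"))
  events$class <- cls
  imp <- which(cls == "improper")
  for (i in imp) {
    conflicts[[length(conflicts) + 1L]] <- data.frame(
      f1 = events$f1[i], f2 = events$f2[i], tm = events$tm[i],
      reason = "undesigned duplex outranks a designed junction",
      stringsAsFactors = FALSE)
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(f1 = character(0), f2 = character(0), tm = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  new("ConflictReport",
      verdict = if (nrow(conflicts)) "conflicting" else "correct",
      events = events, conflicts = conflicts,
      threshold = if (is.finite(threshold)) threshold else NA_real_)
}

#' @describeIn checkBaseProtocol display method
#' @param object a [ConflictReport-class]
#' @export
setMethod("show", "ConflictReport", function(object) {
  cat("ConflictReport: verdict ", object@verdict, ", ",
      nrow(object@events), " events, weakest designed Tm ",
      round(object@threshold, 1), " degC\n", sep = "")
  if (nrow(object@conflicts)) {
    cat("  conflicts:\n")
    print(object@conflicts, row.names = FALSE)
  }
})

## plan one contiguous segment of the tiling (indices into mains);
## returns list of leaf tubes (character vectors) and collected conflicts
.planSegment <- function(mainIdx, fragments, recon, par, temperature,
                         concentration, cache, depth = 0L) {
  role <- S4Vectors::mcols(fragments)$role
  mainNames <- names(fragments)[role == "main"]
  juncHelpers <- character(0)                    # junction -> helper name
  if (length(recon$helperJunction))
    juncHelpers <- setNames(names(recon$helperJunction),
                            recon$helperJunction)
  internal <- mainIdx[-length(mainIdx)]          # junction indices inside
  helperNames <- unname(juncHelpers[as.character(internal)])
  helperNames <- helperNames[!is.na(helperNames)]
  frNames <- c(mainNames[mainIdx], helperNames)
  sub <- fragments[frNames]
  if (length(frNames) == 1L)
    return(list(tubes = list(frNames), conflicts = NULL, feasible = TRUE))
  rep <- checkBaseProtocol(sub, par, temperature, concentration, cache)
  if (rep@verdict == "correct")
    return(list(tubes = list(frNames), conflicts = NULL, feasible = TRUE))
  confl <- rep@conflicts
  if (length(mainIdx) == 1L || depth > 32L)
    return(list(tubes = list(frNames), conflicts = confl, feasible = FALSE))
  ## greedy: split at the internal junction separating most conflict pairs,
  ## keeping designed neighbors together where possible
  memberSide <- function(splitAfter) {
    ## fragments going left of a split after main index `splitAfter`
    leftMains <- mainIdx[mainIdx <= splitAfter]
    leftJuncs <- leftMains[-length(leftMains)]
    leftHelpers <- unname(juncHelpers[as.character(c(leftJuncs, splitAfter))])
    c(mainNames[leftMains], leftHelpers[!is.na(leftHelpers)])
  }
  best <- NULL
  for (sp in internal) {
    left <- memberSide(sp)
    sep <- sum(xor(confl$f1 %in% left, confl$f2 %in% left), na.rm = TRUE)
    bal <- abs(sum(mainIdx <= sp) - sum(mainIdx > sp))
    cand <- list(sp = sp, sep = sep, bal = bal)
    if (is.null(best) || cand$sep > best$sep ||
        (cand$sep == best$sep && cand$bal < best$bal)) best <- cand
  }
  if (is.null(best) || best$sep == 0L)
    return(list(tubes = list(frNames), conflicts = confl, feasible = FALSE))
  leftIdx <- mainIdx[mainIdx <= best$sp]
  rightIdx <- mainIdx[mainIdx > best$sp]
  l <- .planSegment(leftIdx, fragments, recon, par, temperature,
                    concentration, cache, depth + 1L)
  r <- .planSegment(rightIdx, fragments, recon, par, temperature,
                    concentration, cache, depth + 1L)
  ## the helper spanning the split joins the merge step; assign it to the
  ## left leaf product so every fragment lives in exactly one leaf tube
  spHelper <- unname(juncHelpers[as.character(best$sp)])
  if (!is.na(spHelper))
    l$tubes[[length(l$tubes)]] <- c(l$tubes[[length(l$tubes)]], spHelper)
  list(tubes = c(l$tubes, r$tubes),
       conflicts = rbind(confl, l$conflicts, r$conflicts),
       feasible = l$feasible && r$feasible)
}

#' Plan an assembly protocol
#'
#' Plans a base (single-tube) or complex (multi-tube) protocol for a design
#' or fragment set. Junctions not covered by any helper force a tube
#' boundary (they cannot be ligated in a single mixture); within each
#' segment, conflicting fragment pairs are separated greedily by splitting
#' the tiling at the junction that resolves the most conflicts, recursively.
#' Leaf-tube products are combined pairwise, so a plan with `L` leaves runs
#' `S = 2L - 1` base protocols. A conflict that no partition can separate
#' (for example a fragment conflicting with itself) marks the plan
#' infeasible.
#'
#' @param x a [GeneDesign-class] or a fragment [Biostrings::DNAStringSet].
#' @inheritParams foldingOrder
#' @return an [AssemblyProtocol-class].
#' @export
planProtocol <- function(x, par = nnParameters(), temperature = 37,
                         concentration = 4e-7, cache = NULL) {
  fragments <- if (is(x, "GeneDesign")) buildFragments(x) else x
  recon <- reconstructStrand(fragments)
  role <- S4Vectors::mcols(fragments)$role
  k <- sum(role == "main")
  ## forced boundaries at uncovered junctions
  boundaries <- sort(recon$uncovered)
  segStart <- c(1L, boundaries + 1L)
  segEnd <- c(boundaries, k)
  tubes <- list(); conflicts <- NULL; feasible <- TRUE
  for (s in seq_along(segStart)) {
    res <- .planSegment(seq(segStart[s], segEnd[s]), fragments, recon, par,
                        temperature, concentration, cache)
    tubes <- c(tubes, res$tubes)
    conflicts <- rbind(conflicts, res$conflicts)
    feasible <- feasible && res$feasible
  }
  L <- length(tubes)
  mergeTree <- if (L == 1L) list(1L) else Reduce(function(a, b) list(a, b),
                                                 as.list(seq_len(L)))
  events <- foldingOrder(fragments, par, temperature, concentration, cache)
  if (is.null(conflicts))
    conflicts <- data.frame(f1 = character(0), f2 = character(0),
                            tm = numeric(0), reason = character(0),
                            stringsAsFactors = FALSE)
  new("AssemblyProtocol", tubes = tubes, mergeTree = mergeTree,
      S = as.integer(2L * L - 1L), feasible = feasible, events = events,
      conflicts = conflicts)
}

#' @describeIn planProtocol display method
#' @param object an [AssemblyProtocol-class]
#' @export
setMethod("show", "AssemblyProtocol", function(object) {
  cat("AssemblyProtocol: ", length(object@tubes), " tube(s), S = ",
      object@S, if (!object@feasible) " [INFEASIBLE]", "\n", sep = "")
  for (i in seq_along(object@tubes))
    cat("  tube ", i, ": ", paste(object@tubes[[i]], collapse = ", "),
        "\n", sep = "")
})
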