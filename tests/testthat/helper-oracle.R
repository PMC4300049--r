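# Test helpers: brute-force secondary-structure enumeration (the independent
# oracle for the folding DP) and small utilities.

PAR <- nnParameters()
USAGE <- readCodonUsage(system.file("extdata", "example_host_usage.tsv",
                                    package = "LCRDesign"))

rcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# enumerate every valid secondary structure (list of pair matrices) of the
# integer-coded sequence; nA = first-strand length (nA = n for single strand).
# Watson-Crick pairs only; intra-strand pairs need >= 3 unpaired in between.
enumStructures <- function(seqInt, nA) {
  n <- length(seqInt)
  canPair <- function(i, j) {
    if (seqInt[i] + seqInt[j] != 3L) return(FALSE)
    if (i <= nA && j > nA) return(TRUE)
    j - i - 1L >= 3L
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + 1L):j) {
      if (!canPair(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# minimum free energy over all enumerated structures, scored by the package's
# reference structure scorer (the DP never enters this computation)
oracleMFE <- function(strandA, strandB = NULL, par = PAR, temperature = 37) {
  seqInt <- c(A = 0L, C = 1L, G = 2L, T = 3L)[
    strsplit(paste0(strandA, if (is.null(strandB)) "" else strandB), "")[[1]]]
  nA <- nchar(strandA)
  structs <- enumStructures(unname(seqInt), if (is.null(strandB))
    length(seqInt) else nA)
  best <- 0
  for (st in structs) {
    if (!nrow(st)) next
    dG <- structureEnergy(strandA, strandB, st, par, temperature)$dG
    if (dG < best) best <- dG
  }
  best
}

# hand-summed nearest-neighbor duplex energy, written independently of
# duplexEnergy(): reads the parameter slots directly
handDuplex <- function(strand, par = PAR, temperature = 37) {
  tK <- temperature + 273.15
  bases <- strsplit(strand, "")[[1]]
  dH <- par@initiation[["dH"]]; dS <- par@initiation[["dS"]]
  for (i in seq_len(length(bases) - 1L)) {
    row <- which(par@stacks$step == paste0(bases[i], bases[i + 1L]))
    dH <- dH + par@stacks$dH[row]; dS <- dS + par@stacks$dS[row]
  }
  for (b in bases[c(1L, length(bases))]) {
    if (b %in% c("A", "T")) {
      dH <- dH + par@terminalAT[["dH"]]; dS <- dS + par@terminalAT[["dS"]]
    }
  }
  if (identical(strand, rcomp(strand))) dS <- dS + par@symmetryDS
  list(dG = dH - tK * dS / 1000, dH = dH, dS = dS)
}

# --- engineered design fixtures ---------------------------------------------
# A/C-only strands cannot form Watson-Crick pairs with themselves or with
# other A/C-only strands (their complements need G/T), so an irregular
# A/C-only target yields exactly the designed helper duplexes and nothing
# else; the irregularity keeps the helper window unique for reconstruction.

acOnly <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

# conflict-free two-main design (60 nt, cut at 30, helper 21..40)
acDesign <- function() {
  geneDesign(acOnly(60, 99), cuts = 30L,
             helpers = IRanges::IRanges(21L, 40L))
}

# two mains carrying an engineered 15-nt reverse-complement repeat (G/T-only
# against A/C-only, far from the junction) whose mutual duplex outranks the
# designed junction events
repeatConflictDesign <- function() {
  rep15 <- "GGTGGTGGTGGTGGT"
  m1 <- paste0(rep15, acOnly(15, 5))
  m2 <- paste0(acOnly(15, 6), rcomp(rep15))
  geneDesign(paste0(m1, m2), cuts = 30L,
             helpers = IRanges::IRanges(21L, 40L))
}

# first main opens with a strong GC hairpin: a self-conflict no tube
# partition can separate
selfConflictDesign <- function() {
  m1 <- paste0("GGGCGGGCGAAAACGCCCGCCC", acOnly(8, 7))
  geneDesign(paste0(m1, acOnly(30, 8)), cuts = 30L,
             helpers = IRanges::IRanges(21L, 40L))
}
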