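## Codon-usage tables, reverse translation, translation, and the codon-usage
## fitness component.

.geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

## synonymous sense codons per amino acid
.codonsByAA <- function() {
  code <- .geneticCode()
  sense <- code[code != "*"]
  split(names(sense), sense)
}

#' Read a host codon-usage table
#'
#' Accepts a TSV/CSV file or a data.frame with columns `codon`,
#' `amino_acid` (or `aa`) and `frequency` (or `count`/`freq`). Raw counts or
#' per-thousand frequencies are normalized to per-amino-acid relative
#' frequencies \eqn{C_{rj}}. Stop codons may be present but are dropped.
#'
#' @param source file path or data.frame.
#' @return a [CodonUsageTable-class].
#' @export
#' @examples
#' tab <- readCodonUsage(system.file("extdata", "example_host_usage.tsv",
#'                                   package = "LCRDesign"))
#' requiredFrequency(tab, "TTC")
readCodonUsage <- function(source) {
  df <- if (is.character(source)) {
    utils::read.delim(source, comment.char = "#", stringsAsFactors = FALSE,
                      sep = "")
  } else as.data.frame(source)
  names(df) <- tolower(names(df))
  cod <- df[["codon"]]
  if (is.null(cod)) stop("source lacks a 'codon' column")
  val <- df[["frequency"]]
  if (is.null(val)) val <- df[["freq"]]
  if (is.null(val)) val <- df[["count"]]
  if (is.null(val)) stop("source lacks a frequency or count column")
  cod <- toupper(gsub("U", "T", cod))
  code <- .geneticCode()
  unknown <- setdiff(cod, names(code))
  if (length(unknown))
    stop("unknown codon(s): ", paste(unknown, collapse = ", "))
  aa <- unname(code[cod])
  keep <- aa != "*"
  cod <- cod[keep]; aa <- aa[keep]; val <- as.numeric(val[keep])
  missing <- setdiff(names(code)[code != "*"], cod)
  if (length(missing))
    stop("missing codon ", paste(missing, collapse = ", "))
  if (any(val < 0) || any(!is.finite(val))) stop("negative or non-finite value")
  tot <- tapply(val, aa, sum)
  if (any(tot == 0))
    stop("zero total usage for amino acid(s) ",
         paste(names(tot)[tot == 0], collapse = ", "))
  freq <- val / tot[aa]
  new("CodonUsageTable",
      table = data.frame(codon = cod, aa = aa, freq = unname(freq),
                         stringsAsFactors = FALSE))
}

#' Required frequency of a codon
#'
#' @param table a [CodonUsageTable-class].
#' @param codon three-letter DNA codon.
#' @return the per-amino-acid relative frequency \eqn{C_{rj}}.
#' @export
requiredFrequency <- function(table, codon) {
  i <- match(codon, table@table$codon)
  if (is.na(i)) stop("unknown codon ", codon)
  table@table$freq[i]
}

#' @describeIn readCodonUsage display method
#' @param object a [CodonUsageTable-class]
#' @export
setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable: 61 sense codons,",
      length(unique(object@table$aa)), "amino acids\n")
})

.checkPeptide <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide))
    stop("peptide must be a non-empty character scalar")
  aas <- strsplit(peptide, "")[[1]]
  valid <- sort(unique(.geneticCode()[.geneticCode() != "*"]))
  bad <- setdiff(aas, valid)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  aas
}

#' Reverse-translate a peptide
#'
#' Chooses, independently for every residue, one of its synonymous codons
#' uniformly at random (seed via [set.seed()]). No stop codon is appended;
#' the design layer adds one.
#'
#' @param peptide one-letter amino-acid string (20 standard residues).
#' @return a DNA string encoding `peptide`.
#' @export
#' @examples
#' set.seed(1)
#' reverseTranslate("MW")   # "ATGTGG": both residues have a single codon
reverseTranslate <- function(peptide) {
  aas <- .checkPeptide(peptide)
  syn <- .codonsByAA()
  paste(vapply(aas, function(a) {
    cods <- syn[[a]]
    if (length(cods) == 1L) cods else cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Translate DNA with the standard genetic code
#'
#' @param dna DNA string, length divisible by 3, over A/C/G/T.
#' @return the peptide string, with `*` for stop codons. An internal stop
#'   (any stop before the final codon) raises an error naming its codon
#'   index; a terminal stop is reported as a trailing `*`.
#' @export
#' @examples
#' translateDNA("ATGTGG")
translateDNA <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L) stop("dna must be a scalar")
  if (nchar(dna) %% 3L != 0L) stop("length not divisible by 3")
  if (!grepl("^[ACGT]*$", dna)) stop("ambiguity character in DNA")
  if (!nzchar(dna)) return("")
  cods <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  aas <- unname(.geneticCode()[cods])
  internal <- which(aas == "*")
  internal <- internal[internal < length(aas)]
  if (length(internal))
    stop("internal stop codon at codon ", internal[1])
  paste(aas, collapse = "")
}

.codonTally <- function(dna) {
  cods <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  table(factor(cods, levels = names(.geneticCode())))
}

#' Codon-usage deviation of a coding sequence
#'
#' Root-mean-square difference between the required per-amino-acid codon
#' frequencies \eqn{C_{rj}} and the frequencies observed in the sequence
#' \eqn{C_{ij}}, weighted by codon counts:
#' \deqn{F_C = w_C \sqrt{\sum_j n_j (C_{rj} - C_{ij})^2 / n}.}
#' Stop codons are excluded from the tally.
#'
#' @param dna coding DNA string (length divisible by 3, may end in a stop
#'   codon).
#' @param table a [CodonUsageTable-class].
#' @param wC non-negative weight.
#' @return the non-negative deviation \eqn{F_C}.
#' @export
#' @examples
#' tab <- readCodonUsage(system.file("extdata", "example_host_usage.tsv",
#'                                   package = "LCRDesign"))
#' codonDeviation("TTTTTC", tab)
codonDeviation <- function(dna, table, wC = 1) {
  if (wC < 0) stop("wC must be non-negative")
  tally <- .codonTally(dna)
  code <- .geneticCode()
  tally <- tally[code[names(tally)] != "*"]
  n <- sum(tally)
  if (n == 0L) stop("sequence contains no sense codons")
  used <- tally[tally > 0]
  aaOf <- code[names(used)]
  aaTotals <- tapply(as.numeric(used), aaOf, sum)
  acc <- 0
  for (j in names(used)) {
    nj <- as.numeric(used[[j]])
    cij <- nj / aaTotals[[code[[j]]]]
    crj <- requiredFrequency(table, j)
    acc <- acc + nj * (crj - cij)^2
  }
  wC * sqrt(acc / n)
}
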