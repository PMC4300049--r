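## Readers and writers for fragment sets, the packaged oligo fixtures, and
## run manifests.

#' Load a packaged oligo fixture
#'
#' The package bundles the oligo sets of a protease-gene analogue design:
#' `"ubp4_prime"` (11 assembly fragments for a 276-nt gene), and
#' `"ubp4_dprime_a"` / `"ubp4_dprime_b"` (17 fragments each for the two
#' halves, 540 + 543 nt, of a 1083-nt gene). Odd-numbered oligos are main
#' chains (5'-phosphorylated), even-numbered ones helper chains; the PCR
#' primers are returned separately and never enter assembly computations.
#'
#' @param name one of `"ubp4_prime"`, `"ubp4_dprime_a"`, `"ubp4_dprime_b"`.
#' @return list with `fragments` (a [Biostrings::DNAStringSet] with `role`
#'   and `phosphorylated` metadata) and `primers`.
#' @export
#' @examples
#' fx <- loadFixture("ubp4_prime")
#' length(fx$fragments)
loadFixture <- function(name = c("ubp4_prime", "ubp4_dprime_a",
                                 "ubp4_dprime_b")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0(name, "_fragments.tsv"),
                      package = "LCRDesign")
  d <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  frag <- d[d$role != "primer", ]
  prim <- d[d$role == "primer", ]
  fragments <- buildFragments(frag$sequence, role = frag$role,
                              names = frag$name)
  primers <- Biostrings::DNAStringSet(setNames(prim$sequence, prim$name))
  list(fragments = fragments, primers = primers)
}

#' Read and write fragment sets as TSV
#'
#' The TSV interchange format has columns `name`, `role`, `sequence`,
#' `phosphorylated` and optionally `tube`.
#'
#' @param fragments a fragment [Biostrings::DNAStringSet] (as from
#'   [buildFragments()]).
#' @param file path.
#' @param tubes optional list of name vectors (tube assignment).
#' @return `readFragmentsTSV` returns a fragment set; `writeFragmentsTSV`
#'   returns `file` invisibly.
#' @export
writeFragmentsTSV <- function(fragments, file, tubes = NULL) {
  mc <- S4Vectors::mcols(fragments)
  df <- data.frame(name = names(fragments), role = mc$role,
                   sequence = as.character(fragments),
                   phosphorylated = mc$phosphorylated,
                   stringsAsFactors = FALSE)
  if (!is.null(tubes)) {
    assign <- rep(NA_integer_, nrow(df))
    for (i in seq_along(tubes)) assign[df$name %in% tubes[[i]]] <- i
    df$tube <- assign
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFragmentsTSV
#' @export
readFragmentsTSV <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("name", "role", "sequence")
  if (!all(need %in% names(d)))
    stop("fragment TSV must have columns ", paste(need, collapse = ", "))
  buildFragments(d$sequence, role = d$role, names = d$name)
}

#' Write fragments as FASTA
#'
#' Role and phosphorylation are carried in the description line
#' (`name role=main phospho=1`).
#'
#' @inheritParams writeFragmentsTSV
#' @export
writeFragmentsFasta <- function(fragments, file) {
  mc <- S4Vectors::mcols(fragments)
  out <- fragments
  names(out) <- sprintf("%s role=%s phospho=%d", names(fragments), mc$role,
                        as.integer(mc$phosphorylated))
  Biostrings::writeXStringSet(out, file)
  invisible(file)
}

#' Read a single-record peptide FASTA
#'
#' @param file FASTA path with exactly one amino-acid record.
#' @return the peptide string.
#' @export
readPeptideFasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  if (length(aa) != 1L)
    stop("expected exactly one FASTA record, found ", length(aa))
  pep <- as.character(aa[[1]])
  pep <- sub("\\*$", "", pep)
  .checkPeptide(pep)
  pep
}

#' Write a protocol report as JSON
#'
#' @param protocol an [AssemblyProtocol-class].
#' @param fragments the fragment set the protocol was planned for.
#' @param file output path.
#' @param manifest optional [runManifest()] list.
#' @export
writeProtocolJSON <- function(protocol, fragments, file, manifest = NULL) {
  mc <- S4Vectors::mcols(fragments)
  assign <- rep(NA_integer_, length(fragments))
  for (i in seq_along(protocol@tubes))
    assign[names(fragments) %in% protocol@tubes[[i]]] <- i
  obj <- list(
    fragments = data.frame(name = names(fragments), role = mc$role,
                           sequence = as.character(fragments),
                           phosphorylated = mc$phosphorylated, tube = assign,
                           stringsAsFactors = FALSE),
    events = protocol@events,
    conflicts = protocol@conflicts,
    S = protocol@S, feasible = protocol@feasible)
  if (!is.null(manifest)) obj$manifest <- manifest
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Run manifest for reproducibility
#'
#' @param config configuration used (an [eaConfig()] or similar list).
#' @param seed seed used.
#' @param par an [NNParameterSet-class] (its checksum is recorded).
#' @return a list echoing configuration, seed, parameter checksum, package
#'   version and timestamp.
#' @export
runManifest <- function(config = NULL, seed = NULL, par = NULL) {
  list(config = config, seed = seed,
       parameterChecksum = if (!is.null(par)) par@checksum else NULL,
       package = "LCRDesign",
       version = as.character(utils::packageVersion("LCRDesign")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
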