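## Monte Carlo study: fraction of random three-strand mixtures (two main
## chains plus one junction helper) that pass the base-protocol
## folding-order check.

#' One random three-strand mixture trial
#'
#' Draws a uniform-random target of length in `targetLengthRange`, splits it
#' uniformly among positions leaving both main chains within
#' `fragmentLengthRange`, and places a helper (random length from
#' `fragmentLengthRange`) centered on the split as the reverse complement of
#' that window. Returns the [checkBaseProtocol()] verdict of the resulting
#' three-fragment mixture.
#'
#' @param par an [NNParameterSet-class].
#' @param targetLengthRange length-2 integer range of target lengths in nt.
#' @param fragmentLengthRange length-2 integer range of fragment lengths in nt.
#' @param temperature,concentration folding conditions.
#' @return logical: `TRUE` when the mixture assembles correctly under the
#'   base protocol.
#' @export
mixtureTrial <- function(par = nnParameters(),
                         targetLengthRange = c(60L, 80L),
                         fragmentLengthRange = c(20L, 40L),
                         temperature = 37, concentration = 4e-7) {
  lt <- sample(targetLengthRange[1]:targetLengthRange[2], 1L)
  target <- paste(sample(c("A", "C", "G", "T"), lt, replace = TRUE),
                  collapse = "")
  fmin <- fragmentLengthRange[1]; fmax <- fragmentLengthRange[2]
  smin <- max(fmin, lt - fmax); smax <- min(fmax, lt - fmin)
  if (smax < smin) stop("no admissible split for target length ", lt)
  s <- sample(smin:smax, 1L)
  len <- sample(fmin:fmax, 1L)
  st <- s - (len %/% 2L) + 1L
  en <- st + len - 1L
  st <- max(1L, st); en <- min(lt, en)
  fragments <- buildFragments(
    c(substr(target, 1L, s), substr(target, s + 1L, lt),
      .revComp(substr(target, st, en))),
    role = c("main", "main", "helper"), names = c("M1", "M2", "H1"))
  verdict <- tryCatch(
    checkBaseProtocol(fragments, par, temperature, concentration)@verdict,
    error = function(e) "conflicting")
  verdict == "correct"
}

#' Estimate the base-protocol success rate of random mixtures
#'
#' Repeats [mixtureTrial()] and reports the success fraction with an exact
#' 95% binomial confidence interval. Deterministic for a given seed.
#'
#' @inheritParams mixtureTrial
#' @param nTrials number of trials (>= 1).
#' @param seed integer seed (`NULL` = leave RNG alone).
#' @return list with `successRate`, `ci` (length 2), `nTrials`, `nSuccess`.
#' @export
estimateSuccessRate <- function(nTrials = 10000L, seed = NULL,
                                par = nnParameters(),
                                targetLengthRange = c(60L, 80L),
                                fragmentLengthRange = c(20L, 40L),
                                temperature = 37, concentration = 4e-7) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ok <- vapply(seq_len(nTrials), function(i)
    mixtureTrial(par, targetLengthRange, fragmentLengthRange, temperature,
                 concentration), logical(1))
  nSuccess <- sum(ok)
  ci <- as.numeric(stats::binom.test(nSuccess, nTrials)$conf.int)
  list(successRate = nSuccess / nTrials, ci = ci, nTrials = nTrials,
       nSuccess = nSuccess)
}
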