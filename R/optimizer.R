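## Evolutionary search over (codon choice, main-chain cuts, helper placement)
## with the composite fitness F = 1 / (1 + F_C + F_N + F_S), plus a
## steepest-ascent hill climber for fine tuning.

#' Configuration of the evolutionary design search
#'
#' @param populationSize number of individuals (>= 2).
#' @param generations number of generations (stop condition).
#' @param selection `"proportional"`, `"ranking"` or `"tournament"`.
#' @param tournamentK tournament size.
#' @param wC,wN,wS non-negative weights of the fitness components.
#' @param Lmin,Lmax fragment length bounds in nt (chemical-synthesis limits;
#'   the default maximum of 80 nt reflects routine oligo synthesis).
#' @param minOverlap minimum helper overlap on each side of a junction.
#' @param stopCodon stop codon appended to the coding sequence.
#' @param temperature folding evaluation temperature in degC.
#' @param concentration per-strand concentration in mol/L.
#' @param sCap penalty value of S assigned to infeasible protocols.
#' @param mutationRetries resampling attempts before a mutation returns the
#'   parent unchanged.
#' @param hillClimbFinal apply [hillClimb()] to the final best individual.
#' @param seed integer seed for reproducible runs (`NULL` = leave RNG alone).
#' @return a validated configuration list of class `EAConfig`.
#' @export
eaConfig <- function(populationSize = 20L, generations = 50L,
                     selection = c("tournament", "proportional", "ranking"),
                     tournamentK = 2L, wC = 1, wN = 1, wS = 1,
                     Lmin = 20L, Lmax = 80L, minOverlap = 10L,
                     stopCodon = "TAA", temperature = 37,
                     concentration = 4e-7, sCap = 10L,
                     mutationRetries = 20L, hillClimbFinal = TRUE,
                     seed = NULL) {
  selection <- match.arg(selection)
  cfg <- list(populationSize = as.integer(populationSize),
              generations = as.integer(generations), selection = selection,
              tournamentK = as.integer(tournamentK), wC = wC, wN = wN,
              wS = wS, Lmin = as.integer(Lmin), Lmax = as.integer(Lmax),
              minOverlap = as.integer(minOverlap), stopCodon = stopCodon,
              temperature = temperature, concentration = concentration,
              sCap = as.integer(sCap),
              mutationRetries = as.integer(mutationRetries),
              hillClimbFinal = hillClimbFinal, seed = seed)
  if (cfg$populationSize < 2L) stop("populationSize must be >= 2")
  if (cfg$Lmin < 1L || cfg$Lmin > cfg$Lmax) stop("need 1 <= Lmin <= Lmax")
  if (cfg$Lmin < 2L * cfg$minOverlap)
    stop("Lmin must be >= 2*minOverlap, otherwise helpers at adjacent ",
         "junctions of a minimal main chain must overlap")
  if (any(c(wC, wN, wS) < 0)) stop("weights must be non-negative")
  if (!cfg$stopCodon %in% c("TAA", "TAG", "TGA")) stop("invalid stop codon")
  class(cfg) <- "EAConfig"
  cfg
}

## random cuts: uniform k among feasible values, then rejection-sampled
## composition with every part in [Lmin, Lmax]
.randomCuts <- function(n, Lmin, Lmax) {
  kmin <- max(1L, ceiling(n / Lmax))
  kmax <- floor(n / Lmin)
  if (kmax < kmin) stop("no feasible fragmentation: N_main = ", n,
                        " with bounds [", Lmin, ", ", Lmax, "]")
  k <- if (kmax == kmin) kmin else sample(kmin:kmax, 1L)
  if (k == 1L) return(integer(0))
  for (try in 1:1000) {
    cuts <- sort(sample(seq_len(n - 1L), k - 1L))
    parts <- diff(c(0L, cuts, n))
    if (all(parts >= Lmin & parts <= Lmax)) return(cuts)
  }
  ## deterministic fallback: near-even split (always feasible for this k)
  cumsum(rep(n %/% k, k - 1L) + (seq_len(k - 1L) <= n %% k))
}

## a random helper interval for the junction after position `cut`
.randomHelper <- function(cut, n, Lmin, Lmax, minOverlap, lo, hi) {
  ## [lo, hi]: admissible span (stays inside strand, clear of neighbors)
  for (try in 1:50) {
    len <- sample(Lmin:Lmax, 1L)
    left <- sample(minOverlap:max(minOverlap, len - minOverlap), 1L)
    st <- cut - left + 1L
    en <- st + len - 1L
    if (st >= lo && en <= hi && en - cut >= minOverlap && cut - st + 1L >= minOverlap)
      return(c(st, en))
  }
  ## minimal symmetric helper, padded to Lmin within [lo, hi]
  st <- cut - minOverlap + 1L; en <- cut + minOverlap
  while (en - st + 1L < Lmin) {
    if (en < hi) en <- en + 1L
    else if (st > lo) st <- st - 1L
    else stop("cannot place a helper at the junction after position ", cut)
  }
  c(st, en)
}

#' Draw a random valid design for a peptide
#'
#' Reverse-translates the peptide with uniformly random synonymous codons,
#' appends the stop codon, draws cuts uniformly subject to the fragment
#' length bounds, and centers a random-length helper on every junction.
#'
#' @param peptide amino-acid string.
#' @param config an [eaConfig()].
#' @return a valid [GeneDesign-class].
#' @export
randomDesign <- function(peptide, config = eaConfig()) {
  dna <- paste0(reverseTranslate(peptide), config$stopCodon)
  n <- nchar(dna)
  if (n < config$Lmin)
    stop("target shorter than Lmin: infeasible constraints")
  cuts <- .randomCuts(n, config$Lmin, config$Lmax)
  helpers <- matrix(integer(0), ncol = 2)
  if (length(cuts)) {
    helpers <- matrix(0L, nrow = length(cuts), ncol = 2)
    prevEnd <- 0L
    for (i in seq_along(cuts)) {
      hi <- if (i < length(cuts)) cuts[i + 1L] - config$minOverlap else n
      h <- .randomHelper(cuts[i], n, config$Lmin, config$Lmax,
                         config$minOverlap, prevEnd + 1L, hi)
      helpers[i, ] <- h
      prevEnd <- h[2]
    }
  }
  geneDesign(dna, cuts, helpers, config$Lmin, config$Lmax, config$minOverlap)
}

#' Initial population
#'
#' @inheritParams randomDesign
#' @return list of [GeneDesign-class] individuals.
#' @export
initPopulation <- function(peptide, config = eaConfig()) {
  replicate(config$populationSize, randomDesign(peptide, config),
            simplify = FALSE)
}

## the three mutation operators -----------------------------------------------

.mutateCodon <- function(design) {
  nCod <- nchar(design@dna) / 3L - 1L      # exclude the stop codon
  pos <- sample.int(nCod, 1L)
  cod <- substr(design@dna, 3L * pos - 2L, 3L * pos)
  syn <- .codonsByAA()[[.geneticCode()[[cod]]]]
  newCod <- syn[sample.int(length(syn), 1L)]
  dna <- design@dna
  substr(dna, 3L * pos - 2L, 3L * pos) <- newCod
  design@dna <- dna                      # validated by the caller
  design
}

.mutateCut <- function(design) {
  if (!length(design@cuts)) return(NULL)
  i <- sample.int(length(design@cuts), 1L)
  delta <- sample(c(-1L, 1L), 1L)
  cuts <- design@cuts
  cuts[i] <- cuts[i] + delta
  design@cuts <- cuts                    # validated by the caller
  design
}

.mutateHelper <- function(design) {
  if (!length(design@helpers)) return(NULL)
  i <- sample.int(length(design@helpers), 1L)
  op <- sample(c("shrink", "grow", "left", "right"), 1L)
  end <- sample(c("start", "end"), 1L)
  s <- IRanges::start(design@helpers); e <- IRanges::end(design@helpers)
  switch(op,
         shrink = if (end == "start") s[i] <- s[i] + 1L else e[i] <- e[i] - 1L,
         grow   = if (end == "start") s[i] <- s[i] - 1L else e[i] <- e[i] + 1L,
         left   = { s[i] <- s[i] - 1L; e[i] <- e[i] - 1L },
         right  = { s[i] <- s[i] + 1L; e[i] <- e[i] + 1L })
  if (any(e < s)) return(design)
  design@helpers <- IRanges::IRanges(s, e)   # validated by the caller
  design
}

#' Mutate a design
#'
#' Applies, with equal probability, one of three operators: replace a random
#' codon by a random synonymous codon; shift a random cut by one position
#' (shortening one main chain and extending its neighbor); or shrink, grow
#' or move a random helper by one position. Draws are resampled within the
#' chosen operator until the child is valid; after `config$mutationRetries`
#' failures the parent is returned unchanged.
#'
#' @param design a [GeneDesign-class].
#' @param config an [eaConfig()].
#' @return a valid child [GeneDesign-class] encoding the same peptide.
#' @export
mutateDesign <- function(design, config = eaConfig()) {
  op <- sample.int(3L, 1L)
  for (try in seq_len(config$mutationRetries)) {
    child <- switch(op, .mutateCodon(design), .mutateCut(design),
                    .mutateHelper(design))
    if (is.null(child)) break
    ok <- tryCatch({ methods::validObject(child); TRUE },
                   error = function(e) FALSE)
    if (ok) return(child)
  }
  design
}

#' Fitness of a design
#'
#' Computes the codon-usage deviation \eqn{F_C} (stop codon excluded), plans
#' the assembly protocol to obtain \eqn{S} (infeasible protocols are
#' penalized with `config$sCap`), sums fragment lengths into \eqn{N}, and
#' combines them into \eqn{F = 1 / (1 + F_C + F_N + F_S)}.
#'
#' @inheritParams mutateDesign
#' @param table a [CodonUsageTable-class].
#' @param par an [NNParameterSet-class].
#' @param cache optional [newPairEnergyCache()].
#' @return a [FitnessBreakdown-class].
#' @export
designFitness <- function(design, table, config = eaConfig(),
                          par = nnParameters(), cache = NULL) {
  fragments <- buildFragments(design)
  protocol <- planProtocol(fragments, par, config$temperature,
                           config$concentration, cache)
  S <- if (protocol@feasible) protocol@S else max(config$sCap, protocol@S)
  FC <- codonDeviation(design@dna, table, config$wC)
  Nmain <- nchar(design@dna)
  k <- length(design@cuts) + 1L
  N <- sum(Biostrings::width(fragments))
  Nmin <- Nmain + (k - 1L) * config$Lmin
  Nmax <- 2L * Nmain
  FN <- if (Nmax > Nmin) config$wN * (N - Nmin) / (Nmax - Nmin) else 0
  FS <- config$wS * (S - 1L)^2
  new("FitnessBreakdown", FC = FC, FN = FN, FS = FS,
      F = 1 / (1 + FC + FN + FS), N = as.integer(N), Nmin = as.integer(Nmin),
      Nmax = as.integer(Nmax), Nmain = as.integer(Nmain), k = as.integer(k),
      S = as.integer(S))
}

#' @describeIn designFitness display method
#' @param object a [FitnessBreakdown-class]
#' @export
setMethod("show", "FitnessBreakdown", function(object) {
  cat(sprintf("FitnessBreakdown: F = %.4f (FC = %.4f, FN = %.4f, FS = %.4f)\n",
              object@F, object@FC, object@FN, object@FS))
  cat(sprintf("  N = %d in [%d, %d], k = %d, S = %d\n", object@N,
              object@Nmin, object@Nmax, object@k, object@S))
})

#' Select survivors from a pool
#'
#' @param pool list of individuals.
#' @param fitness numeric vector of composite fitnesses.
#' @param config an [eaConfig()]; `config$selection` picks the scheme:
#'   proportional (probability ∝ F; uniform fallback when all F are zero),
#'   linear ranking (probability ∝ rank, worst = 1), or tournament of size
#'   `config$tournamentK`.
#' @param n number of survivors to draw.
#' @return integer indices into `pool` of the selected individuals.
#' @export
selectIndices <- function(pool, fitness, config = eaConfig(),
                          n = config$populationSize) {
  m <- length(pool)
  switch(config$selection,
         proportional = {
           w <- fitness
           if (all(w <= 0)) w <- rep(1, m)
           sample.int(m, n, replace = TRUE, prob = w)
         },
         ranking = {
           w <- rank(fitness, ties.method = "first")
           sample.int(m, n, replace = TRUE, prob = w)
         },
         tournament = {
           vapply(seq_len(n), function(i) {
             cand <- sample.int(m, config$tournamentK, replace = TRUE)
             cand[which.max(fitness[cand])]
           }, integer(1))
         })
}

## all single-step neighbors of a design (valid ones only)
.neighborhood <- function(design) {
  out <- list()
  syn <- .codonsByAA(); code <- .geneticCode()
  nCod <- nchar(design@dna) / 3L - 1L
  for (pos in seq_len(nCod)) {
    cod <- substr(design@dna, 3L * pos - 2L, 3L * pos)
    for (alt in setdiff(syn[[code[[cod]]]], cod)) {
      d2 <- design
      dna <- design@dna
      substr(dna, 3L * pos - 2L, 3L * pos) <- alt
      d2@dna <- dna
      out[[length(out) + 1L]] <- d2
    }
  }
  for (i in seq_along(design@cuts)) {
    for (d in c(-1L, 1L)) {
      d2 <- design
      d2@cuts[i] <- d2@cuts[i] + d
      out[[length(out) + 1L]] <- d2
    }
  }
  for (i in seq_along(design@helpers)) {
    for (mv in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                    c(1L, 1L), c(-1L, -1L))) {
      s <- IRanges::start(design@helpers); e <- IRanges::end(design@helpers)
      s[i] <- s[i] + mv[1]; e[i] <- e[i] + mv[2]
      if (any(e < s)) next
      d2 <- design
      d2@helpers <- IRanges::IRanges(s, e)
      out[[length(out) + 1L]] <- d2
    }
  }
  Filter(function(d) tryCatch({ methods::validObject(d); TRUE },
                              error = function(e) FALSE), out)
}

#' Steepest-ascent hill climbing
#'
#' Repeatedly evaluates the full single-step neighborhood (every synonymous
#' single-codon swap, every one-position cut shift, every one-position helper
#' move, grow or shrink) and moves to the best neighbor until no neighbor
#' improves the fitness. The returned design never has lower fitness than
#' the input.
#'
#' @inheritParams designFitness
#' @param maxIter safety bound on the number of moves.
#' @return list with `design` and `fitness`.
#' @export
hillClimb <- function(design, table, config = eaConfig(),
                      par = nnParameters(), cache = NULL, maxIter = 100L) {
  cur <- design
  curFit <- designFitness(cur, table, config, par, cache)
  for (it in seq_len(maxIter)) {
    nb <- .neighborhood(cur)
    if (!length(nb)) break
    fits <- lapply(nb, designFitness, table = table, config = config,
                   par = par, cache = cache)
    Fs <- vapply(fits, function(f) f@F, 0)
    best <- which.max(Fs)
    if (Fs[best] <= curFit@F + 1e-12) break
    cur <- nb[[best]]; curFit <- fits[[best]]
  }
  list(design = cur, fitness = curFit)
}

#' Run the evolutionary design search
#'
#' Every generation, every individual produces one mutated child; parents and
#' offspring compete for succession under the configured selection scheme
#' (with one-elite preservation), and pair energies are cached across
#' evaluations. After the final generation the best individual is refined by
#' [hillClimb()] (when `config$hillClimbFinal`). Fully reproducible given
#' `config$seed`.
#'
#' @param peptide amino-acid string to encode.
#' @param table a [CodonUsageTable-class] of the host.
#' @param config an [eaConfig()].
#' @param par an [NNParameterSet-class].
#' @return list with `design`, `fitness` ([FitnessBreakdown-class]),
#'   `protocol` ([AssemblyProtocol-class]), `trace` (per-generation best and
#'   mean fitness) and `cacheStats`.
#' @export
runEA <- function(peptide, table, config = eaConfig(),
                  par = nnParameters()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cache <- newPairEnergyCache()
  pop <- initPopulation(peptide, config)
  fits <- lapply(pop, designFitness, table = table, config = config,
                 par = par, cache = cache)
  best <- NULL; bestFit <- NULL
  trace <- data.frame(generation = integer(0), bestF = numeric(0),
                      meanF = numeric(0))
  noteBest <- function(pop, fits) {
    Fs <- vapply(fits, function(f) f@F, 0)
    i <- which.max(Fs)
    if (is.null(bestFit) || Fs[i] > bestFit@F) {
      best <<- pop[[i]]; bestFit <<- fits[[i]]
    }
  }
  noteBest(pop, fits)
  for (gen in seq_len(config$generations)) {
    offspring <- lapply(pop, mutateDesign, config = config)
    offFits <- lapply(offspring, designFitness, table = table,
                      config = config, par = par, cache = cache)
    pool <- c(pop, offspring)
    poolFits <- c(fits, offFits)
    Fs <- vapply(poolFits, function(f) f@F, 0)
    idx <- selectIndices(pool, Fs, config)
    if (!which.max(Fs) %in% idx) idx[which.min(Fs[idx])] <- which.max(Fs)
    pop <- pool[idx]; fits <- poolFits[idx]
    noteBest(pop, fits)
    trace <- rbind(trace, data.frame(generation = gen, bestF = bestFit@F,
                                     meanF = mean(vapply(fits, function(f) f@F, 0))))
  }
  if (config$hillClimbFinal) {
    hc <- hillClimb(best, table, config, par, cache)
    best <- hc$design; bestFit <- hc$fitness
  }
  protocol <- planProtocol(best, par, config$temperature,
                           config$concentration, cache)
  list(design = best, fitness = bestFit, protocol = protocol, trace = trace,
       cacheStats = c(hits = cache$hits, misses = cache$misses))
}
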