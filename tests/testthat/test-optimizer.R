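# Evolutionary search: population initialization, mutation operators,
# fitness arithmetic, selection statistics, hill climbing, full runs, and
# pair-energy caching.

# small search problems so folding stays cheap
tinyConfig <- function(...) {
  args <- utils::modifyList(list(Lmin = 10L, Lmax = 40L, minOverlap = 5L,
                                 populationSize = 6L, generations = 3L),
                            list(...))
  do.call(eaConfig, args)
}

test_that("initial populations are valid and encode the peptide", {
  set.seed(41)
  pep <- "MKLVNQWERT"
  pop <- initPopulation(pep, tinyConfig())
  expect_length(pop, 6L)
  for (d in pop) {
    expect_true(methods::validObject(d))
    expect_identical(translateDNA(d@dna), paste0(pep, "*"))
  }
  set.seed(77); p1 <- initPopulation(pep, tinyConfig())
  set.seed(77); p2 <- initPopulation(pep, tinyConfig())
  expect_identical(lapply(p1, function(d) d@dna), lapply(p2, function(d) d@dna))
  expect_identical(lapply(p1, function(d) d@cuts), lapply(p2, function(d) d@cuts))
})

test_that("fragment counts follow the feasible range for 93-nt targets", {
  # 30 aa + stop = 93 nt with bounds [20, 80]: k must be 2, 3 or 4
  cfg <- eaConfig(Lmin = 20L, Lmax = 80L, populationSize = 2L)
  pep <- strrep("A", 30)
  set.seed(42)
  ks <- replicate(200, length(randomDesign(pep, cfg)@cuts) + 1L)
  expect_true(all(ks %in% 2:4))
  expect_setequal(sort(unique(ks)), 2:4)
})

test_that("mutation changes exactly one aspect and keeps the child valid", {
  set.seed(43)
  cfg <- tinyConfig()
  d <- randomDesign("MKLVNQWERTYHISAK", cfg)
  for (i in 1:50) {
    child <- mutateDesign(d, cfg)
    expect_true(methods::validObject(child))
    expect_identical(translateDNA(child@dna), translateDNA(d@dna))
    changed <- c(dna = !identical(child@dna, d@dna),
                 cuts = !identical(child@cuts, d@cuts),
                 helpers = !identical(as.data.frame(child@helpers),
                                      as.data.frame(d@helpers)))
    expect_lte(sum(changed), 1L)
  }
})

test_that("the codon operator is a no-op on peptides without synonyms", {
  cfg <- tinyConfig()
  d <- randomDesign("MWMWMW", cfg)     # Met and Trp have single codons
  set.seed(44)
  for (i in 1:20) {
    child <- LCRDesign:::.mutateCodon(d)
    expect_identical(child@dna, d@dna)
  }
})

test_that("cut shifts at the length bound never violate it", {
  # one main pinned at Lmin: only the extending direction is admissible
  cfg <- eaConfig(Lmin = 10L, Lmax = 40L, minOverlap = 5L)
  dna <- acOnly(30, 66)
  d <- geneDesign(dna, cuts = 10L, helpers = IRanges::IRanges(6L, 15L),
                  Lmin = 10L, Lmax = 40L, minOverlap = 5L)
  set.seed(45)
  for (i in 1:1000) {
    child <- mutateDesign(d, cfg)
    expect_true(methods::validObject(child))
    parts <- diff(c(0L, child@cuts, nchar(child@dna)))
    expect_true(all(parts >= 10L & parts <= 40L))
  }
})

test_that("fitness components follow the composite formula", {
  cfg <- eaConfig(Lmin = 20L, Lmax = 80L)
  # N_main = 100, k = 2, helper width 60: N = 160, F_N = (160-120)/80 = 0.5
  d <- geneDesign(acOnly(100, 12), cuts = 50L,
                  helpers = IRanges::IRanges(21L, 80L))
  fit <- designFitness(d, USAGE, cfg, PAR)
  expect_equal(fit@Nmin, 120L)
  expect_equal(fit@Nmax, 200L)
  expect_equal(fit@N, 160L)
  expect_equal(fit@FN, 0.5)
  expect_equal(fit@S, 1L)
  expect_equal(fit@FS, 0)
  expect_equal(fit@F, 1 / (1 + fit@FC + 0.5))
  # a helper covering the whole template hits the N_max endpoint (F_N = w_N)
  dMax <- geneDesign(acOnly(60, 12), cuts = 30L,
                     helpers = IRanges::IRanges(1L, 60L))
  expect_equal(designFitness(dMax, USAGE, cfg, PAR)@FN, 1)
  # minimal helper hits the N_min endpoint
  dMin <- geneDesign(acOnly(100, 12), cuts = 50L,
                     helpers = IRanges::IRanges(41L, 60L))
  expect_equal(designFitness(dMin, USAGE, cfg, PAR)@FN, 0)
  # a separated conflict costs S = 3, F_S = (3-1)^2 = 4
  fitC <- designFitness(repeatConflictDesign(), USAGE, cfg, PAR)
  expect_equal(fitC@S, 3L)
  expect_equal(fitC@FS, 4)
  # infeasible self-conflicts are penalized at the configured cap
  fitS <- designFitness(selfConflictDesign(), USAGE, cfg, PAR)
  expect_equal(fitS@S, cfg$sCap)
})

test_that("proportional selection tracks fitness ratios", {
  cfg <- eaConfig(selection = "proportional", populationSize = 2L)
  set.seed(46)
  idx <- selectIndices(list(1, 2), c(0.9, 0.1), cfg, n = 10000L)
  expect_lt(abs(mean(idx == 1L) - 0.9), 5 * sqrt(0.9 * 0.1 / 10000))
})

test_that("ranking selection is invariant under monotone fitness transforms", {
  cfg <- eaConfig(selection = "ranking", populationSize = 4L)
  f <- c(0.2, 0.9, 0.5, 0.7)
  set.seed(47); a <- selectIndices(as.list(1:4), f, cfg, n = 200L)
  set.seed(47); b <- selectIndices(as.list(1:4), log(f) + 10, cfg, n = 200L)
  expect_identical(a, b)
})

test_that("binary tournaments between two individuals favor the better one", {
  cfg <- eaConfig(selection = "tournament", tournamentK = 2L,
                  populationSize = 2L)
  set.seed(48)
  idx <- selectIndices(list(1, 2), c(0.8, 0.2), cfg, n = 4000L)
  # the worse individual wins only when sampled twice: probability 1/4
  expect_lt(abs(mean(idx == 2L) - 0.25), 5 * sqrt(0.25 * 0.75 / 4000))
})

test_that("hill climbing is monotone and reaches the exact codon fix", {
  # Phe table at 0.5/0.5; three Phe codons 2:1 leave one codon off target
  df <- utils::read.delim(system.file("extdata", "example_host_usage.tsv",
                                      package = "LCRDesign"),
                          comment.char = "#")
  df$count[df$codon == "TTT"] <- 50
  df$count[df$codon == "TTC"] <- 50
  tab <- readCodonUsage(df)
  cfg <- eaConfig(Lmin = 10L, Lmax = 40L, minOverlap = 5L)
  d <- geneDesign("TTTTTTTTTTTCTAA", Lmin = 10L)   # FFFF*, observed 3:1
  start <- designFitness(d, tab, cfg, PAR)
  expect_gt(start@FC, 0)
  hc <- hillClimb(d, tab, cfg, PAR)
  expect_equal(hc$fitness@FC, 0)
  expect_gte(hc$fitness@F, start@F)
  # a local optimum is a fixed point
  hc2 <- hillClimb(hc$design, tab, cfg, PAR)
  expect_identical(hc2$design@dna, hc$design@dna)
  expect_equal(hc2$fitness@F, hc$fitness@F)
})

test_that("seeded runs are reproducible with non-decreasing best fitness", {
  cfg <- tinyConfig(seed = 7L, generations = 4L, hillClimbFinal = FALSE)
  r1 <- runEA("MKLVNQWE", USAGE, cfg, PAR)
  r2 <- runEA("MKLVNQWE", USAGE, cfg, PAR)
  expect_identical(r1$design@dna, r2$design@dna)
  expect_identical(r1$design@cuts, r2$design@cuts)
  expect_equal(r1$fitness@F, r2$fitness@F)
  expect_true(all(diff(r1$trace$bestF) >= -1e-12))
})

test_that("single-codon peptides always reach zero codon deviation", {
  cfg <- tinyConfig(seed = 9L, generations = 2L, hillClimbFinal = FALSE)
  r <- runEA("MWMWMW", USAGE, cfg, PAR)
  expect_equal(r$fitness@FC, 0)
})

test_that("pair-energy caching preserves fitness bit for bit", {
  set.seed(49)
  cfg <- eaConfig(Lmin = 20L, Lmax = 40L)
  cache <- newPairEnergyCache()
  for (i in 1:10) {
    pep <- paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"),
                        15, replace = TRUE), collapse = "")
    d <- randomDesign(pep, cfg)
    fOn <- designFitness(d, USAGE, cfg, PAR, cache = cache)
    fOn2 <- designFitness(d, USAGE, cfg, PAR, cache = cache)  # warm cache
    fOff <- designFitness(d, USAGE, cfg, PAR, cache = NULL)
    expect_identical(fOn@F, fOff@F)
    expect_identical(fOn2@F, fOff@F)
    expect_identical(fOn@S, fOff@S)
  }
  expect_gt(cache$hits, 0L)
})

test_that("a mutation invalidates at most three fragments' pair energies", {
  set.seed(50)
  cfg <- eaConfig(Lmin = 20L, Lmax = 30L)   # forces many fragments
  pep <- paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"),
                      40, replace = TRUE), collapse = "")
  d <- randomDesign(pep, cfg)
  nf <- length(buildFragments(d))
  totalPairs <- nf * (nf + 1) / 2
  cache <- newPairEnergyCache()
  designFitness(d, USAGE, cfg, PAR, cache = cache)
  for (i in 1:5) {
    child <- mutateDesign(d, cfg)
    before <- cache$misses
    designFitness(child, USAGE, cfg, PAR, cache = cache)
    added <- cache$misses - before
    # <= 3 changed strands each add at most nf + 2 new pair keys
    expect_lte(added, 3 * (nf + 2))
    expect_lt(added, totalPairs)
  }
})
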