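# Nearest-neighbor duplex energies, MFE folding vs the enumeration oracle,
# co-folding, and melting temperatures.

test_that("duplex energies equal the hand-summed nearest-neighbor value", {
  # 1-bp duplex: no stacks, only initiation + terminal corrections
  one <- duplexEnergy("G", par = PAR)
  expect_equal(one$dH, PAR@initiation[["dH"]])
  expect_equal(one$dS, PAR@initiation[["dS"]])
  oneAT <- duplexEnergy("A", par = PAR)
  expect_equal(oneAT$dH, PAR@initiation[["dH"]] + 2 * PAR@terminalAT[["dH"]])
  # 10-bp duplex vs an independent sum over the 9 stacks + corrections
  s <- "ACGTACGTAC"
  expect_equal(duplexEnergy(s, par = PAR), handDuplex(s))
  # the same physical duplex seen from the other strand
  expect_equal(duplexEnergy(s, par = PAR)$dG,
               duplexEnergy(rcomp(s), par = PAR)$dG)
  # self-complementary duplex gets the symmetry correction
  expect_equal(duplexEnergy("GGATCC", par = PAR), handDuplex("GGATCC"))
  expect_error(duplexEnergy("ACGT", "AGGT", par = PAR), "non-complementary")
})

test_that("single strands with no complementarity stay unfolded", {
  f <- mfeFold("AAAAAAAAAA", PAR)
  expect_equal(nrow(f@pairs), 0L)
  expect_equal(f@dG, 0)
  expect_error(mfeFold("ACGTN", PAR), "non-ACGT")
})

test_that("a GC stem closing an A-rich hairpin folds as predicted", {
  f <- mfeFold("GCGCAAAAAAGCGC", PAR)
  expect_gt(nrow(f@pairs), 0L)
  expect_lt(f@dG, 0)
  expect_equal(f@dG, oracleMFE("GCGCAAAAAAGCGC"))
})

test_that("DP minimum equals exhaustive enumeration on random strands", {
  set.seed(21)
  for (i in 1:30) {
    s <- randomDNA(sample(12:16, 1))
    expect_equal(mfeFold(s, PAR)@dG, oracleMFE(s), tolerance = 1e-9,
                 info = s)
  }
})

test_that("co-folding finds duplexes and is symmetric", {
  a <- "ACGTACGTAC"
  f <- mfeCofold(a, rcomp(a), PAR)
  expect_true(f@bimolecular)
  expect_equal(nrow(f@pairs), 10L)      # the full 10-bp duplex
  f2 <- mfeCofold(rcomp(a), a, PAR)
  expect_equal(f@dG, f2@dG)
  expect_equal(meltingTemperature(f), meltingTemperature(f2))
  # no pairable bases at all
  g <- mfeCofold("AAAA", "AAAA", PAR)
  expect_false(g@bimolecular)
  expect_equal(nrow(g@pairs), 0L)
  expect_equal(g@dG, 0)
  # a self-complementary strand duplexes with its own copy
  h <- mfeCofold("GGATCC", "GGATCC", PAR)
  expect_true(h@bimolecular)
  expect_true(any(h@pairs[, 1] <= 6 & h@pairs[, 2] > 6))
})

test_that("cofold DP equals the enumeration oracle on random pairs", {
  set.seed(22)
  for (i in 1:30) {
    a <- randomDNA(sample(5:8, 1))
    b <- if (i %% 5 == 0) a else randomDNA(sample(5:8, 1))
    lo <- min(a, b); hi <- max(a, b)
    expect_equal(mfeCofold(a, b, PAR)@dG, oracleMFE(lo, hi),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("results are unchanged when the loop cap is raised (short strands)", {
  parWide <- PAR
  parWide@loopCap <- 60L
  set.seed(23)
  for (i in 1:10) {
    s <- randomDNA(14)
    expect_equal(mfeFold(s, PAR)@dG, mfeFold(s, parWide)@dG)
  }
})

test_that("melting temperatures follow the two-state model", {
  expect_true(is.na(meltingTemperature(mfeFold("AAAAAAAAAA", PAR))))
  # hand plug-in for a 10-bp duplex at 0.25 uM per strand: the fold model
  # sums the 9 stacks plus initiation (no terminal correction inside folds)
  s <- "ACGTACGTAC"
  f <- mfeCofold(s, rcomp(s), PAR)
  dH <- PAR@initiation[["dH"]]; dS <- PAR@initiation[["dS"]]
  bases <- strsplit(s, "")[[1]]
  for (i in 1:9) {
    row <- which(PAR@stacks$step == paste0(bases[i], bases[i + 1]))
    dH <- dH + PAR@stacks$dH[row]; dS <- dS + PAR@stacks$dS[row]
  }
  expect_equal(f@dH, dH)
  expect_equal(f@dS, dS)
  tmHand <- dH * 1000 / (dS + 1.9872 * log(5e-7 / 4)) - 273.15
  expect_equal(meltingTemperature(f, 5e-7), tmHand)
  # a 20-bp duplex melts strictly above its central 10-bp sub-duplex
  long <- "GATCGGCTAGACGTACGTAC"
  sub <- substr(long, 6, 15)
  tmLong <- meltingTemperature(mfeCofold(long, rcomp(long), PAR))
  tmSub <- meltingTemperature(mfeCofold(sub, rcomp(sub), PAR))
  expect_gt(tmLong, tmSub)
})

test_that("fold results satisfy dG = dH - T*dS at any evaluation temperature", {
  set.seed(24)
  for (temp in c(22, 37, 60)) {
    s <- randomDNA(30)
    f <- mfeFold(s, PAR, temperature = temp)
    tK <- temp + 273.15
    expect_lt(abs(f@dG - (f@dH - tK * f@dS / 1000)), 1e-6)
  }
})

test_that("cached pair events equal freshly computed ones exactly", {
  set.seed(25)
  frags <- buildFragments(vapply(1:4, function(i) randomDNA(25), ""),
                          role = c("main", "main", "helper", "helper"))
  cache <- newPairEnergyCache()
  ev1 <- foldingOrder(frags, PAR, cache = cache)
  ev2 <- foldingOrder(frags, PAR, cache = cache)   # all hits
  ev3 <- foldingOrder(frags, PAR)                  # no cache
  expect_identical(ev1, ev2)
  expect_identical(ev1, ev3)
  expect_gt(cache$hits, 0L)
})
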