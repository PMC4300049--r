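# Fragment construction, reconstruction, folding order, conflict detection
# and protocol planning.

test_that("fragments are built with roles and phosphorylation flags", {
  d <- acDesign()
  fr <- buildFragments(d)
  expect_equal(length(fr), 3L)
  mc <- S4Vectors::mcols(fr)
  expect_equal(mc$role, c("main", "main", "helper"))
  expect_equal(mc$phosphorylated, c(TRUE, TRUE, FALSE))
  expect_equal(unname(Biostrings::width(fr)), c(30L, 30L, 20L))
  # helpers are reverse complements of the coding-strand window
  expect_identical(as.character(fr[["H1"]]),
                   rcomp(substr(d@dna, 21, 40)))
})

test_that("length bounds are enforced with the offending fragment named", {
  expect_error(geneDesign(strrep("AC", 30), cuts = 5L,
                          helpers = IRanges::IRanges(1L, 20L)),
               "main chain 1 has length 5")
  expect_error(geneDesign(strrep("AC", 30), cuts = 30L,
                          helpers = IRanges::IRanges(26L, 35L)),
               "helper 1 has length 10")
  expect_error(geneDesign(strrep("AC", 30), cuts = 30L,
                          helpers = IRanges::IRanges(28L, 47L)),
               "does not overlap cut")
})

test_that("reconstruction inverts fragment construction on random designs", {
  set.seed(31)
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  cfg <- eaConfig(Lmin = 15L, Lmax = 60L, minOverlap = 7L)
  for (i in 1:100) {
    pep <- paste(sample(aas, sample(15:60, 1), replace = TRUE), collapse = "")
    d <- randomDesign(pep, cfg)
    fr <- buildFragments(d)
    rec <- reconstructStrand(fr)
    expect_identical(rec$dna, d@dna)
    expect_equal(length(rec$uncovered), 0L)
    # total nucleotide bounds: N_min <= N <= N_max
    N <- sum(Biostrings::width(fr))
    k <- length(d@cuts) + 1L
    expect_gte(N, nchar(d@dna) + (k - 1L) * 15L)
    expect_lte(N, 2L * nchar(d@dna))
  }
})

test_that("reconstruction rejects helpers that match nowhere or twice", {
  fr <- buildFragments(acDesign())
  # a helper whose reverse complement occurs nowhere in the strand
  bad <- buildFragments(c(as.character(fr[1:2]), "GGGGGGGGGGGGGGGGGGGG"),
                        role = c("main", "main", "helper"),
                        names = names(fr))
  expect_error(reconstructStrand(bad), "matches the reconstructed strand nowhere")
  # identical mains make the helper window ambiguous (a designed repeat)
  b <- acOnly(30, 55)
  rep2 <- buildFragments(c(b, b, rcomp(substr(b, 11, 30))),
                         role = c("main", "main", "helper"))
  expect_error(reconstructStrand(rep2), "times")
})

test_that("folding order ranks the strong designed duplex first", {
  a <- "GATCGGCTAGACGTACGTAC"
  frags <- buildFragments(c(a, rcomp(a), strrep("A", 20)),
                          role = c("main", "helper", "main"),
                          names = c("F1", "F2", "F3"))
  ev <- foldingOrder(frags, PAR)
  expect_lte(nrow(ev), 6L)             # C(3,2) cross + 3 self pairs
  expect_setequal(c(ev$f1[1], ev$f2[1]), c("F1", "F2"))
  # a lone unstructured fragment yields no events
  solo <- buildFragments(strrep("A", 20), role = "main", names = "F1")
  expect_equal(nrow(foldingOrder(solo, PAR)), 0L)
})

test_that("a clean two-main design passes the base-protocol check", {
  rep <- checkBaseProtocol(buildFragments(acDesign()), PAR)
  expect_identical(rep@verdict, "correct")
  expect_equal(nrow(rep@conflicts), 0L)
  expect_identical(sort(unique(rep@events$class)), "designed")
})

test_that("an engineered repeat between mains is flagged as improper", {
  fr <- buildFragments(repeatConflictDesign())
  rep <- checkBaseProtocol(fr, PAR)
  expect_identical(rep@verdict, "conflicting")
  expect_true(any(rep@conflicts$f1 == "M1" & rep@conflicts$f2 == "M2"))
  # the conflicting duplex outranks the weakest designed junction
  bad <- rep@conflicts[rep@conflicts$f1 == "M1" & rep@conflicts$f2 == "M2", ]
  expect_gte(max(bad$tm), rep@threshold)
})

test_that("protocol planning: conflict-free designs run in one tube", {
  plan <- planProtocol(acDesign(), PAR)
  expect_equal(length(plan@tubes), 1L)
  expect_equal(plan@S, 1L)
  expect_true(plan@feasible)
})

test_that("a conflicting pair is split into two tubes with one merge", {
  plan <- planProtocol(repeatConflictDesign(), PAR)
  expect_equal(length(plan@tubes), 2L)
  expect_equal(plan@S, 3L)             # 2 leaf tubes + 1 merge
  expect_true(plan@feasible)
  inTube <- function(nm) which(vapply(plan@tubes, function(t) nm %in% t,
                                      TRUE))
  expect_false(inTube("M1") == inTube("M2"))   # conflict separated
})

test_that("an uncovered junction forces a tube boundary", {
  d <- acDesign()
  fr <- buildFragments(d)
  noHelper <- fr[S4Vectors::mcols(fr)$role == "main"]
  plan <- planProtocol(noHelper, PAR)
  expect_equal(length(plan@tubes), 2L)
  expect_equal(plan@S, 3L)
})

test_that("self-conflicts cannot be separated and mark the plan infeasible", {
  plan <- planProtocol(selfConflictDesign(), PAR)
  expect_false(plan@feasible)
  expect_true(any(plan@conflicts$f1 == plan@conflicts$f2))
})
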