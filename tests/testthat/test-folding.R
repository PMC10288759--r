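test_that("unpairable sequences fold to the open chain with zero energy", {
  st <- fold("AAAAAA")
  expect_identical(dotbracket(st), "......")
  expect_identical(freeEnergy(st), 0)
  expect_error(fold(""), "empty")
  expect_error(fold("ACGX"), "invalid alphabet")
})

test_that("GGGAAAACCC folds to the unique maximum-pair minimum-energy hairpin", {
  # brute-force confirmation that (((....))) is the unique 3-pair optimum
  structs <- enumerateStructures("GGGAAAACCC")
  nPairs <- vapply(structs, nrow, integer(1))
  expect_identical(max(nPairs), 3L)
  expect_identical(sum(nPairs == 3L), 1L)
  best <- structs[[which.max(nPairs)]]
  expect_identical(unname(best),
                   matrix(c(1L, 10L, 2L, 9L, 3L, 8L), ncol = 2,
                          byrow = TRUE))
  st <- fold("GGGAAAACCC")
  expect_identical(dotbracket(st), "(((....)))")
  expect_equal(freeEnergy(st), oracleMinEnergy("GGGAAAACCC"))
  expect_identical(dotbracket(foldMaxpair("GGGAAAACCC")), "(((....)))")
  expect_identical(freeEnergy(foldMaxpair("GGGAAAACCC")), -3)
})

test_that("minimum-loop constraint forbids tight hairpins", {
  expect_identical(dotbracket(foldMaxpair("GCGC")), "....")
})

test_that("enumeration oracle matches hand counts on tiny cases", {
  expect_identical(length(enumerateStructures("AAAA")), 1L)
  gaaac <- enumerateStructures("GAAAC")
  expect_identical(length(gaaac), 2L)
  expect_identical(gaaac[[2]][1, ], c(i = 1L, j = 5L))
  # independent recursive count (counts only, no structures)
  countNested <- function(seq, minLoop = 3L) {
    v <- strsplit(seq, "")[[1]]
    ok <- function(a, b)
      paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    cnt <- function(i, j) {
      if (j - i < minLoop + 1L) return(1L)
      total <- cnt(i + 1L, j)
      for (k in seq(i + minLoop + 1L, j))
        if (ok(v[i], v[k]))
          total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
      total
    }
    cnt(1L, length(v))
  }
  for (s in c("GGGAAAACCC", "GCGCAAAAGCGC", "GGUUAAACCAA")) {
    expect_identical(length(enumerateStructures(s)), as.integer(countNested(s)))
  }
  expect_error(enumerateStructures(strrep("A", 17)), "length <= 16")
})

test_that("maximum-pair engine matches exhaustive enumeration", {
  # exhaustive over short sequences, random over longer ones
  for (n in 1:5) {
    for (s in allSeqs(n)) {
      expect_identical(-freeEnergy(foldMaxpair(s)),
                       as.numeric(oracleMaxPairs(s)))
    }
  }
  set.seed(101)
  for (i in 1:120) {
    s <- randomRNA(sample(6:14, 1L))
    expect_identical(-freeEnergy(foldMaxpair(s)),
                     as.numeric(oracleMaxPairs(s)))
  }
})

test_that("energy engine matches the scored enumeration oracle", {
  set.seed(202)
  for (i in 1:100) {
    s <- randomRNA(sample(5:12, 1L))
    st <- fold(s)
    expect_equal(freeEnergy(st), oracleMinEnergy(s), tolerance = 1e-12)
    # the returned structure scores to its reported energy
    expect_equal(scoreStructure(s, basePairs(st)), freeEnergy(st),
                 tolerance = 1e-12)
  }
})

test_that("returned structures are balanced and respect the minimum loop", {
  set.seed(303)
  for (i in 1:400) {
    s <- randomRNA(sample(2:40, 1L))
    for (st in list(fold(s), foldMaxpair(s))) {
      expect_true(validObject(st))
      bp <- basePairs(st)
      if (nrow(bp)) expect_true(all(bp[, "j"] - bp[, "i"] - 1L >= 3L))
      expect_lte(freeEnergy(st), 0)
    }
  }
})

test_that("appending unpairable residues never improves the fold", {
  set.seed(404)
  for (i in 1:40) {
    s <- randomRNA(sample(5:20, 1L), c("A", "C", "G"))  # AU-free
    base <- abs(freeEnergy(foldMaxpair(s)))
    ext <- abs(freeEnergy(foldMaxpair(paste0(s, "AAAA"))))
    expect_lte(ext, base + 1e-12)
  }
})

test_that("a hairpin split across the origin needs circular folding", {
  hairpin <- "GGGGAAAACCCC"
  split <- paste0(substr(hairpin, 7, 12), substr(hairpin, 1, 6))
  linPairs <- -freeEnergy(foldMaxpair(split))
  circPairs <- -freeEnergy(foldMaxpair(split, circular = TRUE))
  expect_identical(circPairs, as.numeric(oracleMaxPairs(split, circular = TRUE)))
  expect_identical(linPairs, as.numeric(oracleMaxPairs(split)))
  expect_gt(circPairs, linPairs)
  expect_identical(circPairs, 4)
  # energy engine finds the cross-origin stem too
  expect_lt(freeEnergy(fold(split, circular = TRUE)),
            freeEnergy(fold(split)))
})

test_that("circular-mode optimum is never worse than linear", {
  set.seed(505)
  for (i in 1:60) {
    s <- randomRNA(sample(8:25, 1L))
    expect_lte(freeEnergy(fold(s, circular = TRUE)),
               freeEnergy(fold(s)) + 1e-9)
    expect_gte(-freeEnergy(foldMaxpair(s, circular = TRUE)),
               -freeEnergy(foldMaxpair(s)))
  }
})

test_that("folding is deterministic across repeated calls", {
  set.seed(606)
  for (i in 1:20) {
    s <- randomRNA(30)
    expect_identical(dotbracket(fold(s)), dotbracket(fold(s)))
    expect_identical(dotbracket(foldMaxpair(s)),
                     dotbracket(foldMaxpair(s)))
  }
})

test_that("the external-engine output parser honours its contract", {
  st <- parseViennaOutput("((....)) (-1.20)")
  expect_identical(dotbracket(st), "((....))")
  expect_identical(freeEnergy(st), -1.20)
  expect_true(validObject(st))
  expect_error(parseViennaOutput("((....)) broken"), "unparseable")
  # multi-line RNAfold-style output with header and sequence echo
  st2 <- parseViennaOutput(c(">x", "GGGAAAACCC", "(((....))) ( -2.10)"))
  expect_identical(freeEnergy(st2), -2.10)
})

test_that("the RNAfold adapter returns valid structures that agree on easy folds", {
  st <- foldVienna("GGGAAAACCC")
  expect_identical(dotbracket(st), "(((....)))")
  expect_match(engineId(st), "^vienna:RNAfold")
  expect_true(validObject(st))
  # adapter structures satisfy the class invariants on random inputs
  set.seed(707)
  for (i in 1:10) {
    s <- randomRNA(40)
    expect_true(validObject(foldVienna(s)))
  }
  # circular mode parses cross-origin structures
  expect_true(validObject(foldVienna("AACCCCGGGGAA", circular = TRUE)))
})
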