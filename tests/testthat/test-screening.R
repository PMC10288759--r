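test_that("library combinatorics match the extension space", {
  expect_identical(length(enumerateExtensions(5L)), 1024L)
  expect_identical(length(enumerateExtensions(5:7)), 21504L)
  expect_identical(length(unique(enumerateExtensions(5:7))), 21504L)
  # exhaustive pair enumeration on a tiny space: 16 * 16 = 256 pairs
  cfg <- screenConfig(extLengths = 2L)
  lib <- generateLinkerLibrary(cfg)
  expect_identical(length(lib), 256L)
  expect_true(all(vapply(lib, function(p) startsWith(p@linker5,
                                                     "ACACACACAC"),
                         logical(1))))
})

test_that("sampled libraries are unique and reproducible from the seed", {
  cfg <- screenConfig(librarySize = 100, seed = 17L)
  a <- generateLinkerLibrary(cfg)
  b <- generateLinkerLibrary(cfg)
  key <- function(lib) vapply(lib, function(p)
    paste(p@linker5, p@linker3), character(1))
  expect_identical(key(a), key(b))
  expect_identical(anyDuplicated(key(a)), 0L)
  expect_identical(length(a), 100L)
  c2 <- generateLinkerLibrary(screenConfig(librarySize = 100, seed = 18L))
  expect_false(identical(key(a), key(c2)))
  expect_error(generateLinkerLibrary(screenConfig(extLengths = 1L,
                                                  librarySize = 17)),
               "exceeds enumerable space")
})

test_that("motif correctness reports identity, absence and invasion", {
  # identity: the part folded alone reproduces its own template
  part <- getPart(fixReg, "scaffold_syn")
  st <- fold(chartr("T", "U", partSeq(part)))
  ft <- IRanges::IRanges(1L, nchar(partSeq(part)),
                         names = "scaffold_syn")
  S4Vectors::mcols(ft)$role <- "scaffold"
  motif <- structureMotif("scaffold_syn", partMotif(part))
  chk <- checkCorrectness(st, ft, list(motif))
  expect_true(chk$overall)
  expect_identical(chk$report$recovery, 1)
  expect_identical(chk$report$cross, 0L)

  # zero template pairs present: open chain over the footprint
  open <- parseViennaOutput(sprintf("%s (0.00)",
                                    strrep(".", nchar(partSeq(part)))))
  chk0 <- checkCorrectness(open, ft, list(motif))
  expect_false(chk0$overall)
  expect_identical(chk0$report$recovery, 0)

  # a linker invading the scaffold stem counts cross pairs and fails
  inv <- foldFixtureCandidate(fixtureLinkerPairs()$invading)
  chkInv <- checkCorrectness(inv$structure, inv$features,
                             fixtureMotifs(inv$features))
  expect_false(chkInv$overall)
  scafRows <- chkInv$report[chkInv$report$part == "scaffold_syn", ]
  expect_gte(max(scafRows$cross), 1L)

  expect_error(
    checkCorrectness(st, ft, list(structureMotif("scaffold_syn", "..."))),
    "template length")
  expect_error(
    checkCorrectness(st, ft, list(structureMotif("nope", "..."))),
    "unknown feature")
})

test_that("ranking orders correct candidates by dG and drops the rest", {
  res <- data.frame(
    linker5 = c("B", "A", "C"), linker3 = c("B", "A", "C"),
    dG_primary = c(-28.1, -30.2, -50.0),
    correct_primary = c(TRUE, TRUE, FALSE))
  ranked <- rankByDG(res)
  expect_identical(ranked$rank[ranked$linker5 == "A"], 1L)
  expect_identical(ranked$rank[ranked$linker5 == "B"], 2L)
  expect_true(is.na(ranked$rank[ranked$linker5 == "C"]))
  # ranks are a permutation of 1..N over correct candidates
  expect_identical(sort(ranked$rank[!is.na(ranked$rank)]), 1:2)
  # ties broken lexicographically by linker sequence
  tie <- data.frame(linker5 = c("B", "A"), linker3 = c("B", "A"),
                    dG_primary = c(-5, -5),
                    correct_primary = c(TRUE, TRUE))
  expect_identical(rankByDG(tie)$linker5, c("A", "B"))
  # 30 correct candidates, topN = 20 -> exactly 20 retained
  many <- data.frame(linker5 = sprintf("L%02d", 1:30), linker3 = "x",
                     dG_primary = -(1:30), correct_primary = TRUE)
  rk <- rankByDG(many)
  expect_identical(sum(rk$rank <= 20L, na.rm = TRUE), 20L)
})

test_that("coarse shapes collapse stems and distinguish branch patterns", {
  expect_identical(shapeString("((..))"), "[]")
  expect_identical(shapeString("(((...)))"), "[]")
  expect_identical(shapeString("((..))..((..))"), "[][]")
  expect_identical(shapeString("((..((..))..))"), "[[]]")
  expect_identical(shapeString("......"), "")
  g <- groupBySimilarity(list(parseViennaOutput("((..)) (0.00)"),
                              parseViennaOutput("(((...))) (0.00)"),
                              parseViennaOutput("((..))..((..)) (0.00)")))
  expect_identical(g, c("G1", "G1", "G2"))
})

test_that("base-pair distance is a metric on pair sets", {
  set.seed(99)
  structs <- lapply(1:12, function(i) fold(randomRNA(25)))
  open <- parseViennaOutput(sprintf("%s (0.00)", strrep(".", 25)))
  for (st in structs) {
    expect_identical(basePairDistance(st, st), 0L)
    expect_identical(basePairDistance(st, open), nrow(basePairs(st)))
  }
  for (i in 1:30) {
    tri <- sample(structs, 3L)
    dab <- basePairDistance(tri[[1]], tri[[2]])
    dbc <- basePairDistance(tri[[2]], tri[[3]])
    dac <- basePairDistance(tri[[1]], tri[[3]])
    expect_lte(dac, dab + dbc)
    expect_identical(dab, basePairDistance(tri[[2]], tri[[1]]))
  }
})

test_that("shape grouping is an equivalence relation on random structures", {
  set.seed(123)
  structs <- lapply(1:20, function(i) fold(randomRNA(sample(15:30, 1))))
  g <- groupBySimilarity(structs)
  shapes <- vapply(structs, shapeString, character(1))
  # same group <=> same shape (reflexive, symmetric, transitive for free)
  for (i in 1:19) for (j in (i + 1):20) {
    expect_identical(g[i] == g[j], shapes[i] == shapes[j])
  }
})

test_that("representative selection requires confirmation-correct members", {
  res <- data.frame(
    linker5 = c("a", "b", "c"), linker3 = c("a", "b", "c"),
    dG_primary = c(-30, -32, -10),
    group_id = c("G1", "G1", "G2"),
    correct_confirm = c(TRUE, FALSE, FALSE))
  out <- selectRepresentatives(res)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE))  # B fails confirm
  expect_identical(attr(out, "unrepresented"), "G2")
  solo <- data.frame(linker5 = "a", linker3 = "a", dG_primary = -5,
                     group_id = "G1", correct_confirm = TRUE)
  expect_true(selectRepresentatives(solo)$selected)
})

test_that("the end-to-end screen selects the preserving pair and rejects the invader", {
  pairs <- fixtureLinkerPairs()
  cfg <- screenConfig(seed = 7L, topN = 10L)
  rep <- runScreen(fixSp, "C-L7", fixReg, cfg,
                   library = list(pairs$preserving, pairs$invading))
  res <- screenResults(rep)
  pres <- res[res$linker3 == pairs$preserving@linker3, ]
  inv <- res[res$linker3 == pairs$invading@linker3, ]
  expect_true(pres$correct_primary)
  expect_true(pres$correct_confirm)
  expect_true(pres$selected)
  expect_identical(pres$rank, 1L)
  expect_false(inv$correct_primary)
  expect_false(inv$selected)
  expect_true(is.na(inv$rank))
  # selected implies correct under both engines
  expect_true(all(res$correct_primary[res$selected] &
                  res$correct_confirm[res$selected]))
})

test_that("screen reports are deterministic and permutation-invariant", {
  pairs <- c(fixtureLinkerPairs(),
             list(linkerPair("AAACA", "ACAAC"),
                  linkerPair("CACAA", "AACCA"),
                  linkerPair("GGGGG", "CCCCC")))
  cfg <- screenConfig(seed = 3L, topN = 5L)
  repA <- runScreen(fixSp, "C-L7", fixReg, cfg, library = pairs)
  repB <- runScreen(fixSp, "C-L7", fixReg, cfg, library = rev(pairs))
  fA <- tempfile(fileext = ".tsv"); fB <- tempfile(fileext = ".tsv")
  writeScreenReport(repA, fA); writeScreenReport(repB, fB)
  expect_identical(readLines(fA), readLines(fB))
  # two identical runs are byte-identical end to end
  repC <- runScreen(fixSp, "C-L7", fixReg, cfg, library = pairs)
  fC <- tempfile(fileext = ".tsv"); writeScreenReport(repC, fC)
  expect_identical(readLines(fA), readLines(fC))
  # structural bounds: selected <= groups <= topN
  res <- screenResults(repA)
  nGroups <- length(unique(stats::na.omit(res$group_id)))
  expect_lte(sum(res$selected), nGroups)
  expect_lte(nGroups, 5L)
})

test_that("the selected set ignores added incorrect candidates", {
  pairs <- list(fixtureLinkerPairs()$preserving,
                linkerPair("AAACA", "ACAAC"))
  cfg <- screenConfig(seed = 5L, topN = 5L)
  base <- screenResults(runScreen(fixSp, "C-L7", fixReg, cfg,
                                  library = pairs))
  extra <- c(pairs, list(fixtureLinkerPairs()$invading,
                         linkerPair("GGGGG", "GGGGG")))
  ext <- screenResults(runScreen(fixSp, "C-L7", fixReg, cfg,
                                 library = extra))
  sel <- function(r) paste(r$linker5[r$selected], r$linker3[r$selected])
  expect_identical(sel(base), sel(ext))
})

test_that("tightening correctness thresholds never admits more candidates", {
  set.seed(31)
  libs <- replicate(8, lapply(1:12, function(i) randomLinkerPair()),
                    simplify = FALSE)
  for (lib in libs) {
    folded <- lapply(lib, foldFixtureCandidate)
    passAt <- function(recovery, cross) {
      sum(vapply(folded, function(f) {
        motifs <- lapply(fixtureMotifs(f$features), function(m)
          structureMotif(m@partName, m@template, recovery, cross))
        checkCorrectness(f$structure, f$features, motifs)$overall
      }, logical(1)))
    }
    loose <- passAt(0.5, 3L)
    mid <- passAt(0.8, 1L)
    strict <- passAt(1.0, 0L)
    expect_lte(strict, mid)
    expect_lte(mid, loose)
  }
})
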