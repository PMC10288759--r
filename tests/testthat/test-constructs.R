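test_that("Pre cassette is a spacer flanked by two scaffold copies", {
  cass <- assembleConstruct(fixSp, "Pre", fixReg)
  expect_identical(unname(S4Vectors::mcols(cassetteFeatures(cass))$role),
                   c("promoter", "scaffold", "spacer", "scaffold"))
  expect_identical(topology(cass), "pre_gRNA")
})

test_that("gRNA+T4AT4 cassette ends with the TTTTATTTT extension", {
  cass <- assembleConstruct(fixSp, "gRNA+T4AT4", fixReg)
  seqn <- cassetteSeq(cass)
  expect_identical(substr(seqn, nchar(seqn) - 8L, nchar(seqn)),
                   "TTTTATTTT")
  ft <- cassetteFeatures(cass)
  expect_identical(S4Vectors::mcols(ft)$role[length(ft)], "extension_3p")
})

test_that("an empty spacer set is rejected", {
  expect_error(spacerSet(character()), "at least one spacer")
  expect_error(spacerSet(c(x = "ACGT")), "length outside")
})

test_that("assembly errors are informative", {
  expect_error(assembleConstruct(fixSp, "no-such-variant", fixReg),
               "unknown variant")
  expect_error(assembleConstruct(fixSp, "C-L7", fixReg),
               "requires a LinkerPair")
  thin <- partRegistry(getPart(fixReg, "hU6p27_syn"))
  expect_error(assembleConstruct(fixSp, "Pre", thin), "missing part")
})

test_that("C-Sp1 feature coordinates agree with independent substring search", {
  cass <- assembleConstruct(fixSp, "C-Sp1", fixReg)
  ft <- cassetteFeatures(cass)
  seqn <- cassetteSeq(cass)
  partLens <- IRanges::width(ft)
  expect_identical(nchar(seqn), sum(partLens))
  # recompute each start by scanning the concatenated sequence
  cursor <- 1L
  for (i in seq_along(ft)) {
    sub <- substr(seqn, IRanges::start(ft)[i], IRanges::end(ft)[i])
    hit <- regexpr(sub, substr(seqn, cursor, nchar(seqn)), fixed = TRUE)
    expect_identical(cursor + as.integer(hit) - 1L, IRanges::start(ft)[i])
    cursor <- IRanges::end(ft)[i] + 1L
  }
})

test_that("features tile every assembled cassette without gaps or overlaps", {
  set.seed(42)
  variants <- c("U6+27", "Pre", "L-Sp1", "L-Sp1-F30", "C-Sp1", "C-Sp1-F30",
                "C-L3", "C-L3-d27", "gRNA+9", "gRNA+59", "gRNA+T4AT4")
  for (rep in 1:40) {
    v <- sample(variants, 1L)
    sp <- spacerSet(stats::setNames(randomRNA(sample(20:23, 1L),
                                              c("A", "C", "G", "T")), "t"))
    lp <- randomLinkerPair()
    cass <- assembleConstruct(sp, v, fixReg, linkers = lp)
    ft <- cassetteFeatures(cass)
    expect_identical(IRanges::start(ft)[1], 1L)
    expect_identical(IRanges::end(ft)[length(ft)],
                     nchar(cassetteSeq(cass)))
    if (length(ft) > 1L)
      expect_identical(IRanges::start(ft)[-1],
                       IRanges::end(ft)[-length(ft)] + 1L)
    # concatenation of feature subsequences equals the sequence
    pieces <- substring(cassetteSeq(cass), IRanges::start(ft),
                        IRanges::end(ft))
    expect_identical(paste(pieces, collapse = ""), cassetteSeq(cass))
  }
})

test_that("assembly is idempotent", {
  lp <- fixtureLinkerPairs()$preserving
  a <- assembleConstruct(fixSp, "C-L7", fixReg, linkers = lp)
  b <- assembleConstruct(fixSp, "C-L7", fixReg, linkers = lp)
  expect_identical(cassetteSeq(a), cassetteSeq(b))
  expect_identical(cassetteFeatures(a), cassetteFeatures(b))
})

test_that("the d27 variant drops exactly the 27-nt leader", {
  lp <- fixtureLinkerPairs()$preserving
  base <- assembleConstruct(fixSp, "C-L7", fixReg, linkers = lp)
  d27 <- assembleConstruct(fixSp, "C-L7-d27", fixReg, linkers = lp)
  promoter <- getPart(fixReg, role = "promoter")
  expect_identical(nchar(cassetteSeq(base)) - nchar(cassetteSeq(d27)), 27L)
  # removing the trailing 27 nt of the promoter reproduces the d27 cassette
  lead <- substr(partSeq(promoter), nchar(partSeq(promoter)) - 26L,
                 nchar(partSeq(promoter)))
  expect_identical(sub(lead, "", cassetteSeq(base), fixed = TRUE),
                   cassetteSeq(d27))
})

test_that("multiplexed arrays follow the (scaffold, spacer) unit grammar", {
  sp3 <- fixtureSpacers(3)
  lin <- assembleArray(sp3, "multiplex-linear", fixReg)
  roles <- S4Vectors::mcols(cassetteFeatures(lin))$role
  expect_identical(sum(roles == "spacer"), 3L)
  expect_identical(sum(roles == "scaffold"), 4L)  # trailing scaffold
  expect_identical(roles[length(roles)], "scaffold")

  lp <- fixtureLinkerPairs()$preserving
  sp5 <- fixtureSpacers(5)
  circ <- assembleArray(sp5, "multiplex-circular", fixReg, linkers = lp)
  ft <- cassetteFeatures(circ)
  roles <- S4Vectors::mcols(ft)$role
  expect_identical(sum(roles == "spacer"), 5L)
  expect_gte(sum(roles == "scaffold"), 5L)
  expect_identical(names(ft)[roles == "spacer"],
                   names(fixtureSpacers(5)))
  expect_identical(topology(circ), "circular_precursor")

  expect_error(assembleArray(fixtureSpacers(1), "multiplex-circular",
                             fixReg, linkers = lp), "at least 2")
})

test_that("predictCircle excises the ribozymes and joins at the ligation sites", {
  lp <- fixtureLinkerPairs()$preserving
  pre <- assembleConstruct(fixSp, "C-L7", fixReg, linkers = lp)
  circ <- predictCircle(pre)
  ft <- cassetteFeatures(pre)
  roles <- S4Vectors::mcols(ft)$role
  a <- IRanges::end(ft)[roles == "ribozyme_5p"]       # 0-based cut
  b <- IRanges::start(ft)[roles == "ribozyme_3p"] - 1L
  expect_identical(nchar(cassetteSeq(circ)), b - a)
  croles <- S4Vectors::mcols(cassetteFeatures(circ))$role
  expect_false(any(grepl("ribozyme", croles)))
  expect_false(any(grepl("promoter", croles)))
  expect_identical(croles[1], "ligation_5p")
  expect_identical(croles[length(croles)], "ligation_3p")
  # retained nucleotides keep identity and order
  expect_true(grepl(cassetteSeq(circ), cassetteSeq(pre), fixed = TRUE))
  expect_error(predictCircle(assembleConstruct(fixSp, "Pre", fixReg)),
               "circular_precursor")
})

test_that("circle rotations are equivalent and canonicalisable", {
  lp <- fixtureLinkerPairs()$preserving
  circ <- predictCircle(assembleConstruct(fixSp, "C-L7", fixReg,
                                          linkers = lp))
  s <- cassetteSeq(circ)
  for (k in c(1L, 17L, nchar(s) - 3L)) {
    expect_true(sameCircle(s, rotateSeq(s, k)))
  }
  expect_false(sameCircle(s, paste0("G", substr(s, 2, nchar(s)))))
  # canonical form starts at the 5' ligation junction
  expect_identical(canonicalizeCircle(circ), circ)
})

test_that("transcription maps T to U, drops the promoter and keeps the leader", {
  expect_identical(transcribe("TTTTATTTT"), "UUUUAUUUU")
  expect_identical(transcribe(""), "")
  set.seed(7)
  s <- randomRNA(100, c("A", "C", "G", "T"))
  expect_identical(nchar(transcribe(s)), 100L)
  expect_false(grepl("T", transcribe(s)))
  expect_error(transcribe("ACGN"), "DNA string")

  tx <- transcribe(assembleConstruct(fixSp, "U6+27", fixReg))
  # 27-nt leader + scaffold + spacer
  expect_identical(nchar(tx$rna), 27L + 20L + 21L)
  expect_identical(names(tx$features)[1], "hU6p27_syn_leader")
  txd <- transcribe(assembleConstruct(fixSp, "gRNA+9", fixReg))
  # leaderless U6: transcript starts at the 9-nt extension
  expect_identical(nchar(txd$rna), 9L + 20L + 21L)
})
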