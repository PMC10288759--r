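# Shared fixtures and independent oracles for the test suite.

fixReg <- fixtureParts()
fixSp <- fixtureSpacers(1)

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

randomRNA <- function(n, bases = c("A", "C", "G", "U"))
  paste(sample(bases, n, replace = TRUE), collapse = "")

# independent maximum-pair count over the enumeration oracle
oracleMaxPairs <- function(seq, minLoop = 3L, circular = FALSE) {
  structs <- enumerateStructures(seq, minLoop = minLoop,
                                 circular = circular)
  max(vapply(structs, nrow, integer(1)))
}

# independent minimum energy over the enumeration oracle
oracleMinEnergy <- function(seq, model = energyModel()) {
  structs <- enumerateStructures(seq, minLoop = model$minLoop)
  min(vapply(structs, function(s) scoreStructure(seq, s, model),
             numeric(1)))
}

# all sequences of length n over an alphabet
allSeqs <- function(n, bases = c("A", "C", "G", "U")) {
  if (n == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), n), stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

# precursor transcript + features for a linker pair on the fixture parts
foldFixtureCandidate <- function(pair, engine = "energy",
                                 variant = "C-L1") {
  cass <- assembleConstruct(fixSp, variant, fixReg, linkers = pair)
  tx <- transcribe(cass)
  st <- foldWith(tx$rna, engine)
  list(cassette = cass, rna = tx$rna, features = tx$features,
       structure = st)
}

fixtureMotifs <- function(features) {
  Filter(function(m) m@partName %in% names(features),
         motifsFromRegistry(fixReg))
}

randomLinkerPair <- function() {
  linkerPair(randomRNA(sample(5:7, 1L), c("A", "C", "G", "T")),
             randomRNA(sample(5:7, 1L), c("A", "C", "G", "T")))
}
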