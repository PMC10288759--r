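#' @include parts.R screening.R
NULL

## Unpairable filler for inert fixture parts: an A/C string with no CC run,
## so it can neither stack against the pure-G/C motif stems nor pair with
## itself (pairs need G or U on one side).
.acFiller <- function(n) substr(strrep("AAC", ceiling(n / 3) + 1L), 1L, n)

.revcompDNA <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## a synthetic stem-loop part: A/C flanks, pure-G/C stem, GAAA tetraloop
.hairpinPart <- function(name, role, arm, flank5, flank3, loop = "GAAA",
                         cleavageOffset = NA_integer_) {
  k <- nchar(arm)
  seqn <- paste0(.acFiller(flank5), arm, loop, .revcompDNA(arm),
                 .acFiller(flank3))
  motif <- paste0(strrep(".", flank5), strrep("(", k),
                  strrep(".", nchar(loop)),
                  strrep(")", k), strrep(".", flank3))
  cassettePart(name, role, seqn, motif = motif,
               cleavageOffset = cleavageOffset)
}

#' Synthetic fixture part registry
#'
#' A complete, deterministic registry of neutral parts matching the
#' published cassette architecture and its stated lengths (27-nt promoter
#' leader, 42-nt and 41-nt inert spacer regions, 10-nt polyAC linker
#' cores, the TTTTATTTT 3' extension) but with synthetic sequences: the
#' real ribozyme/scaffold/aptamer sequences are supplied by users via
#' [readPartsYaml()]. Structured parts (ribozymes, scaffold, F30,
#' Broccoli) are stem-loops with pure-G/C stems and GAAA tetraloops over
#' an unpairable A/C background, each annotated with its reference
#' dot-bracket motif; the motifs are verified self-consistent against the
#' folding engines in the test suite.
#'
#' @return a [PartRegistry-class].
#' @examples
#' fixtureParts()
#' @export
fixtureParts <- function() {
  promoterBody <- .acFiller(20)
  leader <- .acFiller(27)
  partRegistry(
    cassettePart("hU6p27_syn", "promoter", paste0(promoterBody, leader),
                 leaderLength = 27L),
    .hairpinPart("twister5_syn", "ribozyme_5p", "GGGGCGGGGC", 6L, 6L,
                 cleavageOffset = 0L),
    .hairpinPart("twister3_syn", "ribozyme_3p", "GGGCGGGCGG", 6L, 6L,
                 cleavageOffset = 0L),
    cassettePart("lig5_syn", "ligation_5p", .acFiller(12)),
    cassettePart("lig3_syn", "ligation_3p", .acFiller(12)),
    cassettePart("region5_syn", "spacer_region_5p", .acFiller(42)),
    cassettePart("region3_syn", "spacer_region_3p", .acFiller(41)),
    .hairpinPart("f30_syn", "f30_junction", "GGCCGCGG", 5L, 5L),
    .hairpinPart("broccoli_syn", "broccoli", "GCGGGCC", 4L, 4L),
    .hairpinPart("scaffold_syn", "scaffold", "GGCGC", 3L, 3L),
    cassettePart("sp1_linker5_syn", "linker_5p",
                 paste0("ACACACACAC", "AACAC")),
    cassettePart("sp1_linker3_syn", "linker_3p",
                 paste0("ACACACACAC", "CAACA")),
    cassettePart("ext_plus9", "extension_5p", .acFiller(9)),
    cassettePart("ext_plus59", "extension_5p", .acFiller(59)),
    cassettePart("ext_t4at4", "extension_3p", "TTTTATTTT")
  )
}

#' A fixture spacer set
#'
#' @param n number of spacers (1 for single-guide fixtures, up to 5 for
#'   multiplex fixtures, named after the published multiplex panel).
#' @param casSystem Cas effector.
#' @return a [SpacerSet-class] of unpairable 21-nt A/C spacers.
#' @export
fixtureSpacers <- function(n = 1L, casSystem = "LbCas12a") {
  targets <- c("mNeonGreen", "CD47-S3", "VEGFA-S1", "DNMT1-S3", "EMX1",
               "RUNX1")
  stopifnot(n >= 1L, n <= length(targets))
  tri <- c("AAA", "AAC", "ACA", "CAA", "CAC", "ACAA")
  seqs <- vapply(seq_len(n), function(i)
    paste0(tri[i], .acFiller(18)), character(1))
  spacerSet(stats::setNames(seqs, targets[seq_len(n)]),
            casSystem = casSystem)
}

#' The motif-preserving and scaffold-invading fixture linker pairs
#'
#' The preserving pair extends both linkers with unpairable A/C bases;
#' the invading pair's 3' extension is the reverse complement of the
#' 7-nt window spanning the fixture scaffold's 5' stem arm plus one
#' flanking and one loop base, a 7-bp duplex that out-competes the
#' scaffold's own 5-bp stem and so destroys the guide structure the
#' screen must protect.
#'
#' @return list with elements `preserving` and `invading`
#'   ([LinkerPair-class]).
#' @export
fixtureLinkerPairs <- function() {
  scaffoldArm <- "GGCGC"    # matches fixtureParts()'s scaffold stem
  invader <- .revcompDNA(paste0("C", scaffoldArm, "G"))
  list(preserving = linkerPair("AACAC", "CAACA"),
       invading = linkerPair("AACAC", invader))
}

#' Write the fixture data set to disk
#'
#' Emits a parts registry (YAML), fixture spacers (FASTA), and toy
#' quantification tables (TSV): a site read-count table, a FACS count
#' table and an actinomycin-D decay time course at 1, 3, 6, 9 and 18 h.
#' Deterministic given the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the toy count tables.
#' @return named character vector of the written file paths, invisibly.
#' @export
makeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    parts = file.path(dir, "parts.yaml"),
    spacers = file.path(dir, "spacers.fa"),
    site_reads = file.path(dir, "site_reads.tsv"),
    facs = file.path(dir, "facs.tsv"),
    decay = file.path(dir, "decay.tsv"))
  writePartsYaml(fixtureParts(), paths[["parts"]])
  sp <- fixtureSpacers(5L)
  writeFasta(sp@spacers, paths[["spacers"]])
  withr::with_seed(seed, {
    sites <- data.frame(
      condition = rep(c("U6+27", "C-Sp1", "C-L7"), each = 6L),
      site = rep(c(paste0("site", 1:4),
                   "site1_off1", "site2_off1"), times = 3L),
      kind = rep(c(rep("on_target", 4L), rep("off_target", 2L)),
                 times = 3L),
      reads = c(stats::rpois(4L, 2000), stats::rpois(2L, 20),
                stats::rpois(4L, 3500), stats::rpois(2L, 90),
                stats::rpois(4L, 4200), stats::rpois(2L, 130)))
    facs <- data.frame(
      sample = c("U6+27", "Pre", "C-L7"),
      total = 10000L,
      mcherry_pos = c(4100L, 3900L, 4000L),
      neon_neg_mcherry_pos = c(1400L, 1300L, 2100L))
    tp <- c(1, 3, 6, 9, 18)
    decay <- data.frame(
      guide = rep(c("linear", "circular"), each = length(tp)),
      hours = rep(tp, 2L),
      abundance = c(exp(-0.231 * tp) * exp(stats::rnorm(5, 0, 0.05)),
                    exp(-0.02 * tp) * exp(stats::rnorm(5, 0, 0.05))))
  })
  utils::write.table(sites, paths[["site_reads"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(facs, paths[["facs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(decay, paths[["decay"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
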