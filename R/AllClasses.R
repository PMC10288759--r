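#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges start end width
#' @useDynLib circguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Controlled vocabulary for cassette parts.  "promoter" may carry a
## trailing Pol III leader (see `leaderLength`); "scaffold" is the Cas12a /
## CasRx direct repeat.
.PART_ROLES <- c(
  "promoter", "ribozyme_5p", "ribozyme_3p", "ligation_5p", "ligation_3p",
  "spacer_region_5p", "spacer_region_3p", "f30_junction", "broccoli",
  "scaffold", "spacer", "linker_5p", "linker_3p", "extension_5p",
  "extension_3p"
)

.TOPOLOGIES <- c("linear_gRNA", "pre_gRNA", "circular_precursor", "circular_rna")
.CAS_SYSTEMS <- c("LbCas12a", "AsCas12a", "CasRx")

.isDNA <- function(x) !grepl("[^ACGT]", x)
.isRNA <- function(x) !grepl("[^ACGU]", x)

#' CassettePart: one named building block of a guide-RNA expression cassette
#'
#' A part is a named DNA segment with a role in the cassette grammar
#' (promoter, ribozyme, ligation sequence, scaffold/direct repeat, linker,
#' aptamer, ...), optionally annotated with a reference secondary-structure
#' motif in dot-bracket notation over its own footprint and, for ribozymes,
#' a cleavage offset relative to the part boundary facing the ligation
#' sequence.
#'
#' @slot name identifier.
#' @slot role one of the cassette grammar roles (see [partRoles()]).
#' @slot sequence DNA string (cassette space; transcribed on demand).
#' @slot motif reference dot-bracket over this part, or `NA`.
#' @slot cleavageOffset integer offset (nt) of the ribozyme cleavage site
#'   from the part boundary adjacent to the ligation sequence; 0 means the
#'   cut falls exactly on the boundary. `NA` for non-ribozyme parts.
#' @slot leaderLength for promoter parts, the number of trailing promoter
#'   nucleotides that appear at the 5' end of the transcript (the "+27"
#'   leader of the U6+27 cassette); 0 otherwise.
#' @exportClass CassettePart
setClass("CassettePart",
  representation(
    name = "character",
    role = "character",
    sequence = "character",
    motif = "character",
    cleavageOffset = "integer",
    leaderLength = "integer"
  ),
  prototype(
    motif = NA_character_,
    cleavageOffset = NA_integer_,
    leaderLength = 0L
  )
)

setValidity("CassettePart", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@role) != 1L || !(object@role %in% .PART_ROLES))
    msg <- c(msg, sprintf("'role' must be one of: %s",
                          paste(.PART_ROLES, collapse = ", ")))
  if (length(object@sequence) != 1L)
    msg <- c(msg, "'sequence' must be a single string")
  else {
    allowEmpty <- object@role %in% c("extension_5p", "extension_3p")
    if (!nzchar(object@sequence) && !allowEmpty)
      msg <- c(msg, "'sequence' must be non-empty for this role")
    if (!.isDNA(object@sequence))
      msg <- c(msg, "'sequence' must use the DNA alphabet {A,C,G,T}")
  }
  if (!is.na(object@motif) &&
      nchar(object@motif) != nchar(object@sequence))
    msg <- c(msg, "'motif' must have the same length as 'sequence'")
  if (!is.na(object@motif) && grepl("[^().]", object@motif))
    msg <- c(msg, "'motif' must be a dot-bracket string over {(, ), .}")
  if (object@leaderLength < 0L || object@leaderLength > nchar(object@sequence))
    msg <- c(msg, "'leaderLength' out of range")
  if (length(msg)) msg else TRUE
})

#' PartRegistry: the set of parts available to the assembler
#'
#' @slot parts named list of [CassettePart-class] objects (names = part
#'   names).
#' @exportClass PartRegistry
setClass("PartRegistry", representation(parts = "list"))

setValidity("PartRegistry", function(object) {
  if (!all(vapply(object@parts, is, logical(1), "CassettePart")))
    return("all elements of 'parts' must be CassettePart objects")
  nms <- vapply(object@parts, function(p) p@name, character(1))
  if (!identical(unname(nms), names(object@parts)))
    return("list names must equal the part names")
  if (anyDuplicated(nms))
    return("part names must be unique")
  TRUE
})

#' SpacerSet: an ordered set of targeting spacers
#'
#' @slot spacers named character vector of spacer sequences (DNA); names
#'   are target identifiers, order is the multiplexing order.
#' @slot casSystem "LbCas12a", "AsCas12a" or "CasRx".
#' @slot bounds length-2 integer vector: allowed spacer length range.
#' @exportClass SpacerSet
setClass("SpacerSet",
  representation(spacers = "character", casSystem = "character",
                 bounds = "integer"),
  prototype(casSystem = "LbCas12a", bounds = c(20L, 23L))
)

setValidity("SpacerSet", function(object) {
  msg <- character()
  if (length(object@spacers) < 1L)
    msg <- c(msg, "a SpacerSet needs at least one spacer")
  if (is.null(names(object@spacers)) || any(!nzchar(names(object@spacers))))
    msg <- c(msg, "every spacer must carry a target name")
  if (!all(vapply(object@spacers, .isDNA, logical(1))))
    msg <- c(msg, "spacers must use the DNA alphabet {A,C,G,T}")
  if (length(object@bounds) != 2L || object@bounds[1] > object@bounds[2])
    msg <- c(msg, "'bounds' must be an increasing length-2 integer vector")
  else {
    n <- nchar(object@spacers)
    if (any(n < object@bounds[1] | n > object@bounds[2]))
      msg <- c(msg, sprintf("spacer length outside [%d, %d] nt",
                            object@bounds[1], object@bounds[2]))
  }
  if (!(object@casSystem %in% .CAS_SYSTEMS))
    msg <- c(msg, sprintf("'casSystem' must be one of: %s",
                          paste(.CAS_SYSTEMS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' LinkerPair: the flexible linkers joining ligation sequences to the guide
#'
#' Each linker is a fixed polyAC core (10 nt by default) followed by a
#' short variable extension (5-7 nt in the screened libraries).
#'
#' @slot linker5,linker3 full linker sequences (core + extension, DNA).
#' @slot coreLength length of the constant core.
#' @slot extLength5,extLength3 lengths of the variable extensions.
#' @exportClass LinkerPair
setClass("LinkerPair",
  representation(linker5 = "character", linker3 = "character",
                 coreLength = "integer", extLength5 = "integer",
                 extLength3 = "integer")
)

setValidity("LinkerPair", function(object) {
  msg <- character()
  if (!.isDNA(object@linker5) || !.isDNA(object@linker3))
    msg <- c(msg, "linkers must use the DNA alphabet {A,C,G,T}")
  if (nchar(object@linker5) != object@coreLength + object@extLength5)
    msg <- c(msg, "linker5 length must equal coreLength + extLength5")
  if (nchar(object@linker3) != object@coreLength + object@extLength3)
    msg <- c(msg, "linker3 length must equal coreLength + extLength3")
  if (object@extLength5 < 0L || object@extLength3 < 0L)
    msg <- c(msg, "extension lengths must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GuideCassette: an assembled expression cassette or processed circle
#'
#' The central container: a nucleotide sequence plus an ordered,
#' gap-free feature annotation (one feature per part, 0-based half-open
#' coordinates internally, stored as 1-based [IRanges::IRanges] with a
#' `role` metadata column).
#'
#' @slot name construct identifier (usually the variant name).
#' @slot topology "linear_gRNA", "pre_gRNA", "circular_precursor" or
#'   "circular_rna".
#' @slot sequence cassette sequence (DNA for cassettes; the processed
#'   circle keeps the cassette alphabet until [transcribe()]).
#' @slot features `IRanges` (1-based, inclusive) named by part, with
#'   `mcols(features)$role` giving each feature's grammar role.
#' @slot casSystem Cas effector the cassette is built for.
#' @slot variant the assembly variant identifier.
#' @slot leaderLength number of trailing promoter nucleotides retained on
#'   the transcript (0 if the promoter carries no leader or there is no
#'   promoter feature).
#' @exportClass GuideCassette
setClass("GuideCassette",
  representation(
    name = "character",
    topology = "character",
    sequence = "character",
    features = "IRanges",
    casSystem = "character",
    variant = "character",
    leaderLength = "integer"
  ),
  prototype(variant = NA_character_, leaderLength = 0L)
)

setValidity("GuideCassette", function(object) {
  msg <- character()
  if (!(object@topology %in% .TOPOLOGIES))
    msg <- c(msg, sprintf("'topology' must be one of: %s",
                          paste(.TOPOLOGIES, collapse = ", ")))
  if (!(object@casSystem %in% .CAS_SYSTEMS))
    msg <- c(msg, "unknown 'casSystem'")
  n <- nchar(object@sequence)
  ft <- object@features
  if (length(ft) == 0L) {
    msg <- c(msg, "a cassette needs at least one feature")
  } else {
    if (is.null(names(ft)) || any(!nzchar(names(ft))))
      msg <- c(msg, "features must be named by part")
    rl <- mcols(ft)$role
    if (is.null(rl) || !all(rl %in% .PART_ROLES))
      msg <- c(msg, "features must carry a valid 'role' metadata column")
    ## tiling: gap-free, overlap-free, covering [1, n]
    if (start(ft)[1] != 1L || end(ft)[length(ft)] != n ||
        (length(ft) > 1L &&
         !all(start(ft)[-1] == end(ft)[-length(ft)] + 1L)))
      msg <- c(msg, "features must tile the sequence without gaps or overlaps")
  }
  if (!.isDNA(object@sequence) && !.isRNA(object@sequence))
    msg <- c(msg, "sequence must be DNA or RNA")
  if (length(msg)) msg else TRUE
})

#' SecondaryStructure: a predicted RNA secondary structure
#'
#' @slot dotbracket structure string over `(`, `)`, `.`.
#' @slot dG predicted free energy (kcal/mol for the energy engine;
#'   -(pair count) pseudo-units for the maximum-pair engine).
#' @slot pairTable integer vector of 1-based partner indices, 0 = unpaired.
#' @slot circular whether the sequence was folded as a cycle.
#' @slot engineId identifier of the predicting engine.
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
  representation(dotbracket = "character", dG = "numeric",
                 pairTable = "integer", circular = "logical",
                 engineId = "character")
)

setValidity("SecondaryStructure", function(object) {
  msg <- character()
  db <- object@dotbracket
  if (grepl("[^().]", db))
    msg <- c(msg, "'dotbracket' may only contain '(', ')' and '.'")
  v <- strsplit(db, "")[[1]]
  depth <- cumsum((v == "(") - (v == ")"))
  if (object@circular) {
    ## a circular structure may cross the sequence origin; brackets then
    ## balance only under rotation, so check counts here
    if (length(depth) && depth[length(depth)] != 0)
      msg <- c(msg, "'(' and ')' counts must balance")
  } else if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    msg <- c(msg, "brackets must be balanced and properly nested")
  }
  pt <- object@pairTable
  if (length(pt) != nchar(db))
    msg <- c(msg, "'pairTable' length must match 'dotbracket'")
  else {
    paired <- which(pt > 0L)
    if (any(pt[pt > 0L] < 1L | pt[pt > 0L] > length(pt)) ||
        !all(pt[pt[paired]] == paired))
      msg <- c(msg, "'pairTable' must be a symmetric partner map")
    chars <- strsplit(db, "")[[1]]
    if (!identical(which(pt == 0L), which(chars == ".")))
      msg <- c(msg, "'pairTable' inconsistent with 'dotbracket'")
  }
  if (length(msg)) msg else TRUE
})

#' StructureMotif: a reference sub-structure that must be preserved
#'
#' Anchors a dot-bracket template to a named cassette feature; a predicted
#' structure is "correct" for the motif when at least `minPairRecovery` of
#' the template's base pairs are reproduced inside the feature footprint
#' and at most `maxCrossPairs` predicted pairs reach across the footprint
#' boundary.
#'
#' @slot partName feature the motif anchors to.
#' @slot template dot-bracket over the part's footprint.
#' @slot minPairRecovery minimum recovered-pair fraction (default 1.0).
#' @slot maxCrossPairs maximum allowed boundary-crossing pairs (default 0).
#' @exportClass StructureMotif
setClass("StructureMotif",
  representation(partName = "character", template = "character",
                 minPairRecovery = "numeric", maxCrossPairs = "integer"),
  prototype(minPairRecovery = 1.0, maxCrossPairs = 0L)
)

setValidity("StructureMotif", function(object) {
  msg <- character()
  if (grepl("[^().]", object@template))
    msg <- c(msg, "'template' must be dot-bracket")
  v <- strsplit(object@template, "")[[1]]
  depth <- cumsum((v == "(") - (v == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    msg <- c(msg, "'template' brackets must balance within the footprint")
  if (object@minPairRecovery < 0 || object@minPairRecovery > 1)
    msg <- c(msg, "'minPairRecovery' must lie in [0, 1]")
  if (object@maxCrossPairs < 0L)
    msg <- c(msg, "'maxCrossPairs' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ScreenConfig: parameters of the digital linker-library screen
#'
#' @slot coreLength linker core length (nt).
#' @slot coreSeq the constant core sequence (polyAC by default).
#' @slot extLengths allowed extension lengths (default 5:7).
#' @slot librarySize `"exhaustive"` or a number of pairs to sample.
#' @slot seed RNG seed for sampled libraries.
#' @slot topN how many ranked candidates go into similarity grouping.
#' @slot motifs list of [StructureMotif-class] objects.
#' @slot distanceMode "shape" or "base-pair".
#' @slot threshold merge threshold for base-pair-distance clustering.
#' @slot engines length-2 character: primary and confirmation engine ids
#'   ("energy", "maxpair" or "vienna").
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(
    coreLength = "integer", coreSeq = "character", extLengths = "integer",
    librarySize = "ANY", seed = "integer", topN = "integer",
    motifs = "list", distanceMode = "character", threshold = "numeric",
    engines = "character"
  ),
  prototype(
    coreLength = 10L, coreSeq = "ACACACACAC", extLengths = 5:7,
    librarySize = "exhaustive", seed = 1L, topN = 20L, motifs = list(),
    distanceMode = "shape", threshold = 2, engines = c("energy", "vienna")
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@topN < 1L) msg <- c(msg, "'topN' must be >= 1")
  if (nchar(object@coreSeq) != object@coreLength)
    msg <- c(msg, "'coreSeq' length must equal 'coreLength'")
  if (!all(vapply(object@motifs, is, logical(1), "StructureMotif")))
    msg <- c(msg, "'motifs' must be StructureMotif objects")
  if (!(object@distanceMode %in% c("shape", "base-pair")))
    msg <- c(msg, "'distanceMode' must be \"shape\" or \"base-pair\"")
  if (length(object@engines) != 2L)
    msg <- c(msg, "'engines' must name a primary and a confirmation engine")
  ok <- identical(object@librarySize, "exhaustive") ||
    (is.numeric(object@librarySize) && length(object@librarySize) == 1L &&
     object@librarySize >= 1)
  if (!ok) msg <- c(msg, "'librarySize' must be \"exhaustive\" or a count")
  if (length(msg)) msg else TRUE
})

#' ScreenReport: results and provenance of a linker screen
#'
#' @slot results `DataFrame` with one row per screened linker pair
#'   (columns linker5, linker3, dG_primary, dG_confirm, correct_primary,
#'   correct_confirm, rank, group_id, selected).
#' @slot manifest list with seed, engine ids, config hash and counts; a
#'   re-run from the same manifest reproduces the report byte for byte.
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(results = "DataFrame", manifest = "list")
)
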