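#' @include AllClasses.R
NULL

#' Construct a cassette part
#'
#' @param name part identifier.
#' @param role grammar role; see [partRoles()].
#' @param sequence DNA sequence of the part.
#' @param motif optional reference dot-bracket over the part.
#' @param cleavageOffset for ribozymes, offset (nt) of the cleavage site
#'   from the boundary facing the ligation sequence (default 0: cut at the
#'   boundary).
#' @param leaderLength for promoters, number of trailing nucleotides
#'   retained at the 5' end of the transcript.
#' @return a [CassettePart-class].
#' @examples
#' cassettePart("ext_t4at4", "extension_3p", "TTTTATTTT")
#' @export
cassettePart <- function(name, role, sequence, motif = NA_character_,
                         cleavageOffset = NA_integer_, leaderLength = 0L) {
  sequence <- toupper(as.character(sequence))
  if (role %in% c("ribozyme_5p", "ribozyme_3p") && is.na(cleavageOffset))
    cleavageOffset <- 0L
  new("CassettePart", name = name, role = role, sequence = sequence,
      motif = as.character(motif),
      cleavageOffset = as.integer(cleavageOffset),
      leaderLength = as.integer(leaderLength))
}

#' The cassette part role vocabulary
#' @return character vector of valid roles.
#' @export
partRoles <- function() .PART_ROLES

#' Build a part registry
#'
#' @param ... [CassettePart-class] objects, or a single list of them.
#' @return a [PartRegistry-class].
#' @export
partRegistry <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is(parts[[1]], "CassettePart"))
    parts <- parts[[1]]
  names(parts) <- vapply(parts, function(p) p@name, character(1))
  new("PartRegistry", parts = parts)
}

#' Look up a part by name or role
#'
#' @param registry a [PartRegistry-class].
#' @param name part name (preferred), or `NULL` to look up by role.
#' @param role grammar role to search when `name` is `NULL`.
#' @return a [CassettePart-class]; error if absent or ambiguous.
#' @export
getPart <- function(registry, name = NULL, role = NULL) {
  stopifnot(is(registry, "PartRegistry"))
  if (!is.null(name)) {
    if (!name %in% names(registry@parts))
      stop("missing part: '", name, "' is not in the registry", call. = FALSE)
    return(registry@parts[[name]])
  }
  hits <- Filter(function(p) p@role == role, registry@parts)
  if (length(hits) == 0L)
    stop("missing part: no part with role '", role, "'", call. = FALSE)
  if (length(hits) > 1L)
    stop("ambiguous role '", role, "': ",
         paste(names(hits), collapse = ", "), call. = FALSE)
  hits[[1]]
}

#' @describeIn getPart `TRUE` if some part fills the role.
#' @export
hasPartRole <- function(registry, role) {
  any(vapply(registry@parts, function(p) p@role == role, logical(1)))
}

#' Construct a spacer set
#'
#' @param spacers named character vector (or named list) of DNA spacer
#'   sequences; names are target identifiers and define multiplex order.
#' @param casSystem Cas effector ("LbCas12a", "AsCas12a", "CasRx").
#' @param bounds allowed spacer length range in nt.
#' @return a [SpacerSet-class].
#' @examples
#' spacerSet(c(mNeonGreen = "GTTGATGGAGTAGTAGGTTGT"))
#' @export
spacerSet <- function(spacers, casSystem = "LbCas12a", bounds = c(20L, 23L)) {
  spacers <- vapply(spacers, function(s) toupper(as.character(s)),
                    character(1))
  if (length(spacers) == 0L)
    stop("a SpacerSet needs at least one spacer", call. = FALSE)
  new("SpacerSet", spacers = spacers, casSystem = casSystem,
      bounds = as.integer(bounds))
}

#' Construct a linker pair from its variable extensions
#'
#' @param ext5,ext3 variable extensions (DNA strings, typically 5-7 nt).
#' @param core the constant core sequence, 10-nt polyAC by default.
#' @return a [LinkerPair-class]; each linker is `core` followed by its
#'   extension.
#' @examples
#' linkerPair("ACGTA", "TTGCA")
#' @export
linkerPair <- function(ext5, ext3, core = "ACACACACAC") {
  ext5 <- toupper(ext5); ext3 <- toupper(ext3); core <- toupper(core)
  new("LinkerPair",
      linker5 = paste0(core, ext5), linker3 = paste0(core, ext3),
      coreLength = nchar(core),
      extLength5 = nchar(ext5), extLength3 = nchar(ext3))
}

#' Construct a structure motif
#'
#' @param partName cassette feature the motif anchors to.
#' @param template reference dot-bracket over the part's footprint.
#' @param minPairRecovery minimum fraction of template pairs that the
#'   predicted structure must reproduce (default 1.0, the strictest
#'   reading of "correct structure").
#' @param maxCrossPairs maximum number of predicted pairs allowed to cross
#'   the footprint boundary (default 0).
#' @return a [StructureMotif-class].
#' @export
structureMotif <- function(partName, template, minPairRecovery = 1.0,
                           maxCrossPairs = 0L) {
  new("StructureMotif", partName = partName, template = template,
      minPairRecovery = minPairRecovery,
      maxCrossPairs = as.integer(maxCrossPairs))
}

#' Configure a linker screen
#'
#' @param extLengths allowed extension lengths (default `5:7`).
#' @param librarySize `"exhaustive"` or a number of pairs to sample
#'   without replacement.
#' @param seed RNG seed for sampled libraries.
#' @param topN ranked candidates carried into similarity grouping
#'   (default 20; the screened window is the top 10-20).
#' @param motifs list of [StructureMotif-class] to enforce.
#' @param core constant linker core sequence.
#' @param distanceMode "shape" (coarse-shape equality, default) or
#'   "base-pair" (single-linkage on base-pair-set distance).
#' @param threshold merge threshold for "base-pair" mode.
#' @param engines length-2 character: primary and confirmation engines
#'   among "energy", "maxpair", "vienna".
#' @return a [ScreenConfig-class].
#' @export
screenConfig <- function(extLengths = 5:7, librarySize = "exhaustive",
                         seed = 1L, topN = 20L, motifs = list(),
                         core = "ACACACACAC", distanceMode = "shape",
                         threshold = 2, engines = c("energy", "vienna")) {
  new("ScreenConfig", coreLength = nchar(core), coreSeq = toupper(core),
      extLengths = as.integer(extLengths), librarySize = librarySize,
      seed = as.integer(seed), topN = as.integer(topN), motifs = motifs,
      distanceMode = distanceMode, threshold = threshold, engines = engines)
}

#' Read a parts registry from a YAML config
#'
#' The config maps part names to `role`, `sequence` and optional `motif`,
#' `cleavage_offset` and `leader_length` keys.
#'
#' @param path YAML file path.
#' @return a [PartRegistry-class].
#' @export
readPartsYaml <- function(path) {
  if (!file.exists(path))
    stop("parts config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  parts <- lapply(names(cfg), function(nm) {
    e <- cfg[[nm]]
    cassettePart(
      name = nm, role = e$role, sequence = e$sequence,
      motif = if (is.null(e$motif)) NA_character_ else e$motif,
      cleavageOffset = if (is.null(e$cleavage_offset)) NA_integer_
                       else as.integer(e$cleavage_offset),
      leaderLength = if (is.null(e$leader_length)) 0L
                     else as.integer(e$leader_length))
  })
  partRegistry(parts)
}

#' Write a parts registry to YAML
#'
#' @param registry a [PartRegistry-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePartsYaml <- function(registry, path) {
  stopifnot(is(registry, "PartRegistry"))
  cfg <- lapply(registry@parts, function(p) {
    e <- list(role = p@role, sequence = p@sequence)
    if (!is.na(p@motif)) e$motif <- p@motif
    if (!is.na(p@cleavageOffset)) e$cleavage_offset <- p@cleavageOffset
    if (p@leaderLength > 0L) e$leader_length <- p@leaderLength
    e
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}
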