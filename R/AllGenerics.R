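#' @include AllClasses.R
NULL

#' Accessors for circguide classes
#'
#' Small accessor generics: `dotbracket()`, `freeEnergy()`, `pairTable()`
#' and `engineId()` read a [SecondaryStructure-class]; `cassetteSeq()`,
#' `topology()` and `casSystem()` read a [GuideCassette-class];
#' `partSeq()`, `partRole()` and `partMotif()` read a
#' [CassettePart-class]; `screenResults()` and `screenManifest()` read a
#' [ScreenReport-class].
#'
#' @param x an object of the relevant class.
#' @return the slot value.
#' @name accessors
#' @aliases dotbracket freeEnergy pairTable engineId cassetteSeq topology
#'   casSystem partSeq partRole partMotif screenResults screenManifest
NULL

#' @rdname accessors
#' @export
setGeneric("dotbracket", function(x) standardGeneric("dotbracket"))
#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("engineId", function(x) standardGeneric("engineId"))
#' @rdname accessors
#' @export
setGeneric("cassetteSeq", function(x) standardGeneric("cassetteSeq"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("casSystem", function(x) standardGeneric("casSystem"))
#' @rdname accessors
#' @export
setGeneric("partSeq", function(x) standardGeneric("partSeq"))
#' @rdname accessors
#' @export
setGeneric("partRole", function(x) standardGeneric("partRole"))
#' @rdname accessors
#' @export
setGeneric("partMotif", function(x) standardGeneric("partMotif"))
#' @rdname accessors
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))
#' @rdname accessors
#' @export
setGeneric("screenManifest", function(x) standardGeneric("screenManifest"))

#' Feature table of a cassette
#'
#' @param x a [GuideCassette-class].
#' @return the feature `IRanges` (1-based inclusive, named by part, with a
#'   `role` metadata column).
#' @export
setGeneric("cassetteFeatures", function(x) standardGeneric("cassetteFeatures"))

#' Transcribe a cassette to RNA
#'
#' Maps the cassette DNA to its Pol III transcript: `T` becomes `U`, the
#' promoter body is excluded, and for U6+27-driven variants the 27-nt
#' leader (the trailing `leaderLength` nucleotides of the promoter part)
#' is retained at the transcript's 5' end.
#'
#' @param x a [GuideCassette-class] (DNA alphabet) or a plain DNA string.
#' @return for a cassette, a list with `rna` (the transcript string) and
#'   `features` (transcript-coordinate `IRanges`); for a string, the
#'   T-to-U mapped string.
#' @examples
#' transcribe("TTTTATTTT")
#' @export
setGeneric("transcribe", function(x) standardGeneric("transcribe"))

setMethod("dotbracket", "SecondaryStructure", function(x) x@dotbracket)
setMethod("freeEnergy", "SecondaryStructure", function(x) x@dG)
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)
setMethod("engineId", "SecondaryStructure", function(x) x@engineId)
setMethod("cassetteSeq", "GuideCassette", function(x) x@sequence)
setMethod("topology", "GuideCassette", function(x) x@topology)
setMethod("casSystem", "GuideCassette", function(x) x@casSystem)
setMethod("casSystem", "SpacerSet", function(x) x@casSystem)
setMethod("cassetteFeatures", "GuideCassette", function(x) x@features)
setMethod("partSeq", "CassettePart", function(x) x@sequence)
setMethod("partRole", "CassettePart", function(x) x@role)
setMethod("partMotif", "CassettePart", function(x) x@motif)
setMethod("screenResults", "ScreenReport", function(x) x@results)
setMethod("screenManifest", "ScreenReport", function(x) x@manifest)

setMethod("length", "SpacerSet", function(x) length(x@spacers))
setMethod("names", "SpacerSet", function(x) names(x@spacers))

setMethod("show", "CassettePart", function(object) {
  cat(sprintf("CassettePart '%s' (%s), %d nt%s\n", object@name, object@role,
              nchar(object@sequence),
              if (is.na(object@motif)) "" else ", with structure motif"))
})

setMethod("show", "PartRegistry", function(object) {
  cat(sprintf("PartRegistry with %d parts\n", length(object@parts)))
  for (p in object@parts)
    cat(sprintf("  %-22s %-16s %4d nt\n", p@name, p@role, nchar(p@sequence)))
})

setMethod("show", "SpacerSet", function(object) {
  cat(sprintf("SpacerSet (%s): %d spacer(s)\n", object@casSystem,
              length(object@spacers)))
  for (i in seq_along(object@spacers))
    cat(sprintf("  %s: %s\n", names(object@spacers)[i], object@spacers[i]))
})

setMethod("show", "LinkerPair", function(object) {
  cat(sprintf("LinkerPair: 5' %s | 3' %s (core %d nt, ext %d/%d nt)\n",
              object@linker5, object@linker3, object@coreLength,
              object@extLength5, object@extLength3))
})

setMethod("show", "GuideCassette", function(object) {
  cat(sprintf("GuideCassette '%s' [%s, %s], %d nt, %d features\n",
              object@name, object@topology, object@casSystem,
              nchar(object@sequence), length(object@features)))
  ft <- object@features
  cat(sprintf("  %-22s %-16s %9s\n", "part", "role", "span"))
  for (i in seq_along(ft))
    cat(sprintf("  %-22s %-16s %4d..%-4d\n", names(ft)[i],
                mcols(ft)$role[i], start(ft)[i], end(ft)[i]))
})

setMethod("show", "SecondaryStructure", function(object) {
  n <- nchar(object@dotbracket)
  db <- if (n > 60) paste0(substr(object@dotbracket, 1, 57), "...")
        else object@dotbracket
  cat(sprintf("SecondaryStructure [%s%s], %d nt, %d pairs, dG = %.2f\n  %s\n",
              object@engineId, if (object@circular) ", circular" else "",
              n, sum(object@pairTable > 0L) %/% 2L, object@dG, db))
})

setMethod("show", "ScreenReport", function(object) {
  r <- object@results
  cat(sprintf(
    "ScreenReport: %d candidates, %d correct (primary), %d selected\n",
    nrow(r), sum(r$correct_primary), sum(r$selected)))
  cat(sprintf("  engines: %s (primary), %s (confirmation); seed %s\n",
              object@manifest$engines[1], object@manifest$engines[2],
              object@manifest$seed))
})
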