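#' @include AllClasses.R parts.R
NULL

## Variant grammars.  Each token is a grammar role resolved against the
## registry; SPACER is filled from the SpacerSet, LINK5/LINK3 from the
## LinkerPair argument (C-L<k> variants) or from registry linker parts
## (Sp1 variants).  UNIT marks the multiplex (scaffold, spacer) repeat.

.CIRC_SHELL_5 <- c("ribozyme_5p", "ligation_5p", "spacer_region_5p")
.CIRC_SHELL_3 <- c("spacer_region_3p", "ligation_3p", "ribozyme_3p")

.variantGrammar <- function(variant) {
  guide <- c("scaffold", "SPACER", "scaffold")
  f30 <- c("f30_junction", "broccoli")
  sp1core <- function(withF30)
    c("ligation_5p", "spacer_region_5p", "LINK5",
      if (withF30) f30, guide, "LINK3", .CIRC_SHELL_3[1:2])
  if (variant == "U6+27")
    return(list(tokens = c("promoter", "scaffold", "SPACER"),
                topology = "linear_gRNA", leader = TRUE, linkers = "none"))
  if (variant == "Pre")
    return(list(tokens = c("promoter", "scaffold", "SPACER", "scaffold"),
                topology = "pre_gRNA", leader = TRUE, linkers = "none"))
  if (variant %in% c("L-Sp1-F30", "L-Sp1"))
    return(list(tokens = c("promoter", sp1core(variant == "L-Sp1-F30")),
                topology = "linear_gRNA", leader = TRUE,
                linkers = "registry"))
  if (variant %in% c("C-Sp1-F30", "C-Sp1"))
    return(list(tokens = c("promoter", "ribozyme_5p",
                           sp1core(variant == "C-Sp1-F30"), "ribozyme_3p"),
                topology = "circular_precursor", leader = TRUE,
                linkers = "registry"))
  if (grepl("^C-(L|linker)[0-9]+(-d27)?$", variant)) {
    d27 <- grepl("-d27$", variant)
    return(list(tokens = c("promoter", .CIRC_SHELL_5, "LINK5", guide,
                           "LINK3", .CIRC_SHELL_3),
                topology = "circular_precursor", leader = !d27,
                linkers = "pair"))
  }
  ## 5'/3' extended linear guides; built on the leaderless U6 cassette
  if (variant == "gRNA+9")
    return(list(tokens = c("promoter", "PART:ext_plus9", "scaffold",
                           "SPACER"),
                topology = "linear_gRNA", leader = FALSE, linkers = "none"))
  if (variant == "gRNA+59")
    return(list(tokens = c("promoter", "PART:ext_plus59", "scaffold",
                           "SPACER"),
                topology = "linear_gRNA", leader = FALSE, linkers = "none"))
  if (variant == "gRNA+T4AT4")
    return(list(tokens = c("promoter", "scaffold", "SPACER",
                           "PART:ext_t4at4"),
                topology = "linear_gRNA", leader = FALSE, linkers = "none"))
  if (variant == "multiplex-linear")
    return(list(tokens = c("promoter", "UNIT", "scaffold"),
                topology = "pre_gRNA", leader = TRUE, linkers = "none"))
  if (variant == "multiplex-circular")
    return(list(tokens = c("promoter", .CIRC_SHELL_5, "LINK5", "UNIT",
                           "LINK3", .CIRC_SHELL_3),
                topology = "circular_precursor", leader = TRUE,
                linkers = "pair"))
  stop("unknown variant: '", variant, "'", call. = FALSE)
}

#' Cassette variants known to the assembler
#' @return character vector of variant identifiers (`C-L<k>` and
#'   `C-L<k>-d27` stand for any numbered linker variant).
#' @export
cassetteVariants <- function() {
  c("U6+27", "Pre", "L-Sp1-F30", "L-Sp1", "C-Sp1-F30", "C-Sp1", "C-L<k>",
    "C-L<k>-d27", "gRNA+9", "gRNA+59", "gRNA+T4AT4", "multiplex-linear",
    "multiplex-circular")
}

.resolveToken <- function(token, parts, linkers, variant) {
  if (startsWith(token, "PART:")) {
    p <- getPart(parts, name = sub("^PART:", "", token))
    return(list(name = p@name, role = p@role, seq = p@sequence,
                offset = p@cleavageOffset))
  }
  if (token %in% c("LINK5", "LINK3")) {
    role <- if (token == "LINK5") "linker_5p" else "linker_3p"
    if (!is.null(linkers)) {
      seq <- if (token == "LINK5") linkers@linker5 else linkers@linker3
      return(list(name = role, role = role, seq = seq, offset = NA_integer_))
    }
    p <- getPart(parts, role = role)
    return(list(name = p@name, role = role, seq = p@sequence,
                offset = NA_integer_))
  }
  p <- getPart(parts, role = token)
  list(name = p@name, role = p@role, seq = p@sequence,
       offset = p@cleavageOffset)
}

.buildCassette <- function(tokens, spacers, parts, linkers, variant,
                           topology, leader, casSystem, name) {
  pieces <- list()
  spacerIdx <- 0L
  emit <- function(nm, role, seq, offset = NA_integer_)
    pieces[[length(pieces) + 1L]] <<- list(name = nm, role = role,
                                           seq = seq, offset = offset)
  for (tok in tokens) {
    if (tok == "SPACER") {
      spacerIdx <- spacerIdx + 1L
      emit(names(spacers@spacers)[spacerIdx], "spacer",
           spacers@spacers[[spacerIdx]])
    } else if (tok == "UNIT") {
      sc <- getPart(parts, role = "scaffold")
      for (i in seq_along(spacers@spacers)) {
        emit(sc@name, "scaffold", sc@sequence)
        emit(names(spacers@spacers)[i], "spacer", spacers@spacers[[i]])
      }
    } else {
      r <- .resolveToken(tok, parts, linkers, variant)
      if (tok == "promoter" && !leader && r$role == "promoter") {
        p <- getPart(parts, role = "promoter")
        if (p@leaderLength > 0L)
          r$seq <- substr(r$seq, 1L, nchar(r$seq) - p@leaderLength)
      }
      emit(r$name, r$role, r$seq, r$offset)
    }
  }
  seqs <- vapply(pieces, `[[`, character(1), "seq")
  widths <- nchar(seqs)
  ends <- cumsum(widths)
  ft <- IRanges::IRanges(start = c(1L, head(ends, -1L) + 1L), end = ends,
                         names = vapply(pieces, `[[`, character(1), "name"))
  mcols(ft)$role <- vapply(pieces, `[[`, character(1), "role")
  mcols(ft)$cleavage_offset <- vapply(pieces, `[[`, integer(1), "offset")
  leaderLen <- 0L
  if (leader && "promoter" %in% mcols(ft)$role)
    leaderLen <- getPart(parts, role = "promoter")@leaderLength
  new("GuideCassette", name = name, topology = topology,
      sequence = paste(seqs, collapse = ""), features = ft,
      casSystem = casSystem, variant = variant, leaderLength = leaderLen)
}

#' Assemble a guide-RNA expression cassette
#'
#' Builds the DNA cassette for one of the known variants: the mature-guide
#' cassette `U6+27`, the unprocessed guide `Pre` (spacer flanked by two
#' scaffold copies), the linear stabilised cassettes `L-Sp1[-F30]`, the
#' circular precursors `C-Sp1[-F30]` and `C-L<k>[-d27]` (guide wrapped in
#' ligation sequences, inert spacer regions, flexible linkers and the two
#' Twister ribozymes), the 5'/3' extended guides `gRNA+9`, `gRNA+59`,
#' `gRNA+T4AT4`, and the multiplexed arrays (see [assembleArray()]).
#' `-d27` variants and the extended guides are driven by the leaderless U6
#' cassette: the 27-nt leader is trimmed from the promoter part.
#'
#' @param spacers a [SpacerSet-class] (one spacer unless multiplexing).
#' @param variant variant identifier; see [cassetteVariants()].
#' @param parts a [PartRegistry-class] supplying the structural parts.
#' @param linkers a [LinkerPair-class]; required for `C-L<k>` variants,
#'   ignored where the grammar pulls the registry's Sp1 linkers.
#' @return a [GuideCassette-class] whose features tile the sequence.
#' @examples
#' reg <- fixtureParts()
#' sp <- spacerSet(c(mNeonGreen = "GTTGATGGAGTAGTAGGTTGT"))
#' assembleConstruct(sp, "Pre", reg)
#' @export
assembleConstruct <- function(spacers, variant, parts, linkers = NULL) {
  stopifnot(is(spacers, "SpacerSet"), is(parts, "PartRegistry"))
  validObject(spacers)
  if (variant %in% c("multiplex-linear", "multiplex-circular"))
    return(assembleArray(spacers, variant, parts, linkers))
  g <- .variantGrammar(variant)
  if (length(spacers@spacers) != 1L)
    stop("variant '", variant, "' takes exactly one spacer; got ",
         length(spacers@spacers), call. = FALSE)
  if (g$linkers == "pair" && is.null(linkers))
    stop("variant '", variant, "' requires a LinkerPair", call. = FALSE)
  .buildCassette(g$tokens, spacers, parts,
                 if (g$linkers == "pair") linkers else NULL,
                 variant, g$topology, g$leader, spacers@casSystem,
                 name = variant)
}

#' Assemble a multiplexed guide array
#'
#' The internal grammar is one (scaffold, spacer) unit per spacer; linear
#' `Pre`-style arrays add a trailing scaffold, circular arrays wrap the
#' units in the ribozyme / ligation / linker shell.
#'
#' @inheritParams assembleConstruct
#' @param variant `"multiplex-linear"` or `"multiplex-circular"`.
#' @return a [GuideCassette-class].
#' @export
assembleArray <- function(spacers, variant, parts, linkers = NULL) {
  stopifnot(is(spacers, "SpacerSet"), is(parts, "PartRegistry"))
  validObject(spacers)
  if (!variant %in% c("multiplex-linear", "multiplex-circular"))
    stop("unknown variant: '", variant, "'", call. = FALSE)
  if (length(spacers@spacers) < 2L)
    stop("a multiplexed array needs at least 2 spacers", call. = FALSE)
  g <- .variantGrammar(variant)
  if (g$linkers == "pair" && is.null(linkers))
    stop("variant '", variant, "' requires a LinkerPair", call. = FALSE)
  .buildCassette(g$tokens, spacers, parts,
                 if (g$linkers == "pair") linkers else NULL,
                 variant, g$topology, g$leader, spacers@casSystem,
                 name = variant)
}

#' Predict the circular guide produced from a precursor cassette
#'
#' Models Twister autocleavage followed by RtcB ligation: the returned
#' circle is the precursor between the two ribozyme cleavage points
#' (each the part/ligation boundary shifted by the part's configured
#' `cleavageOffset`), canonicalised to start at the 5' ligation junction.
#'
#' @param precursor a [GuideCassette-class] with topology
#'   `"circular_precursor"`.
#' @return a [GuideCassette-class] with topology `"circular_rna"`.
#' @export
predictCircle <- function(precursor) {
  stopifnot(is(precursor, "GuideCassette"))
  if (precursor@topology != "circular_precursor")
    stop("predictCircle() needs a circular_precursor cassette", call. = FALSE)
  ft <- precursor@features
  roles <- mcols(ft)$role
  i5 <- which(roles == "ribozyme_5p")
  i3 <- which(roles == "ribozyme_3p")
  if (length(i5) != 1L || length(i3) != 1L)
    stop("precursor must contain exactly one 5' and one 3' ribozyme",
         call. = FALSE)
  off5 <- mcols(ft)$cleavage_offset[i5]
  off3 <- mcols(ft)$cleavage_offset[i3]
  if (is.na(off5) || is.na(off3))
    stop("missing cleavage offsets on the ribozyme parts", call. = FALSE)
  ## 0-based cut positions: a after the 5' ribozyme 3' boundary (+off5),
  ## b before the 3' ribozyme 5' boundary (+off3); circle = (a, b]
  a <- end(ft)[i5] + off5
  b <- start(ft)[i3] - 1L + off3
  if (a >= b) stop("cleavage points leave an empty circle", call. = FALSE)
  keep <- which(start(ft) - 1L >= a & end(ft) <= b)
  sub <- ft[keep]
  newft <- IRanges::IRanges(start = start(sub) - a, end = end(sub) - a,
                            names = names(sub))
  mcols(newft)$role <- mcols(ft)$role[keep]
  mcols(newft)$cleavage_offset <- rep(NA_integer_, length(keep))
  new("GuideCassette", name = paste0(precursor@name, "_circle"),
      topology = "circular_rna",
      sequence = substr(precursor@sequence, a + 1L, b),
      features = newft, casSystem = precursor@casSystem,
      variant = precursor@variant, leaderLength = 0L)
}

#' Rotate a circular sequence
#'
#' @param seq nucleotide string representing a circle.
#' @param k rotation (nt); the residue at 0-based position `k` becomes the
#'   new origin.
#' @return the rotated string.
#' @export
rotateSeq <- function(seq, k) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

#' Are two sequences the same circle?
#'
#' @param a,b nucleotide strings.
#' @return `TRUE` if `b` is a rotation of `a`.
#' @export
sameCircle <- function(a, b) {
  nchar(a) == nchar(b) &&
    (nchar(a) == 0L || grepl(b, paste0(a, a), fixed = TRUE))
}

#' Canonicalise a circle to start at its 5' ligation junction
#'
#' @param circle a [GuideCassette-class] with topology `"circular_rna"`.
#' @return the cassette rotated so that the `ligation_5p` feature starts
#'   at position 1 (a no-op for circles from [predictCircle()]).
#' @export
canonicalizeCircle <- function(circle) {
  stopifnot(is(circle, "GuideCassette"))
  if (circle@topology != "circular_rna")
    stop("canonicalizeCircle() needs a circular_rna cassette", call. = FALSE)
  ft <- circle@features
  i <- which(mcols(ft)$role == "ligation_5p")
  if (length(i) != 1L)
    stop("circle carries no unique 5' ligation feature", call. = FALSE)
  k <- start(ft)[i] - 1L
  if (k == 0L) return(circle)
  ord <- c(seq(i, length(ft)), seq_len(i - 1L))
  w <- width(ft)[ord]
  ends <- cumsum(w)
  newft <- IRanges::IRanges(start = c(1L, head(ends, -1L) + 1L), end = ends,
                            names = names(ft)[ord])
  mcols(newft)$role <- mcols(ft)$role[ord]
  mcols(newft)$cleavage_offset <- mcols(ft)$cleavage_offset[ord]
  new("GuideCassette", name = circle@name, topology = "circular_rna",
      sequence = rotateSeq(circle@sequence, k), features = newft,
      casSystem = circle@casSystem, variant = circle@variant,
      leaderLength = 0L)
}

#' @rdname transcribe
#' @export
setMethod("transcribe", "character", function(x) {
  if (grepl("[^ACGT]", x))
    stop("transcribe() needs a DNA string over {A,C,G,T}", call. = FALSE)
  chartr("T", "U", x)
})

#' @rdname transcribe
#' @export
setMethod("transcribe", "GuideCassette", function(x) {
  ft <- x@features
  roles <- mcols(ft)$role
  ip <- which(roles == "promoter")
  keepFrom <- 1L
  if (length(ip) == 1L) {
    ## transcript starts after the promoter body; a U6+27 cassette keeps
    ## the trailing 27-nt leader on the transcript
    keepFrom <- end(ft)[ip] - x@leaderLength + 1L
  } else if (length(ip) > 1L) {
    stop("cassette has more than one promoter feature", call. = FALSE)
  }
  rna <- chartr("T", "U", substr(x@sequence, keepFrom, nchar(x@sequence)))
  keep <- which(end(ft) >= keepFrom)
  sub <- ft[keep]
  st <- pmax(start(sub), keepFrom) - keepFrom + 1L
  en <- end(sub) - keepFrom + 1L
  nms <- names(sub)
  if (length(ip) == 1L && ip %in% keep && x@leaderLength > 0L)
    nms[which(keep == ip)] <- paste0(names(ft)[ip], "_leader")
  newft <- IRanges::IRanges(start = st, end = en, names = nms)
  mcols(newft)$role <- mcols(ft)$role[keep]
  list(rna = rna, features = newft)
})
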