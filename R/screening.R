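#' @include AllClasses.R parts.R assemble.R folding.R vienna.R
NULL

.DNA_BASES <- c("A", "C", "G", "T")

## number of extensions per side for the configured lengths
.extSpace <- function(extLengths) sum(4^extLengths)

## i-th extension (1-based) in the canonical order: lengths ascending,
## sequences lexicographic (A < C < G < T) within each length
.extensionAt <- function(i, extLengths) {
  lens <- sort(unique(extLengths))
  for (L in lens) {
    block <- 4^L
    if (i <= block) {
      idx <- i - 1L
      digits <- integer(L)
      for (p in seq(L, 1L)) {
        digits[p] <- idx %% 4L
        idx <- idx %/% 4L
      }
      return(paste(.DNA_BASES[digits + 1L], collapse = ""))
    }
    i <- i - block
  }
  stop("extension index out of range", call. = FALSE)
}

#' Enumerate all linker extensions for one side
#'
#' @param extLengths allowed extension lengths (nt).
#' @return character vector of all `sum(4^L)` extensions, lengths
#'   ascending and lexicographic within a length.
#' @examples
#' length(enumerateExtensions(5))        # 1024
#' length(enumerateExtensions(5:7))      # 21504
#' @export
enumerateExtensions <- function(extLengths) {
  vapply(seq_len(.extSpace(extLengths)), .extensionAt, character(1),
         extLengths = extLengths)
}

#' Generate a digital linker-pair library
#'
#' Every linker is the configured polyAC core plus a variable extension.
#' Exhaustive mode enumerates all 5'/3' extension combinations; sampled
#' mode draws that many distinct pairs uniformly without replacement,
#' reproducibly from the config seed.
#'
#' @param config a [screenConfig()].
#' @return list of [LinkerPair-class] objects.
#' @export
generateLinkerLibrary <- function(config) {
  stopifnot(is(config, "ScreenConfig"))
  validObject(config)
  nSide <- .extSpace(config@extLengths)
  space <- nSide * nSide
  if (identical(config@librarySize, "exhaustive")) {
    if (space > 1e6)
      stop("exhaustive pair space has ", format(space, big.mark = ","),
           " members; sample a library instead", call. = FALSE)
    idx <- seq_len(space)
  } else {
    nWant <- as.numeric(config@librarySize)
    if (nWant > space)
      stop("library_size exceeds enumerable space (", space, " pairs)",
           call. = FALSE)
    idx <- withr::with_seed(config@seed,
                            sample.int(space, nWant, replace = FALSE))
  }
  lapply(idx, function(i) {
    i5 <- (i - 1L) %/% nSide + 1L
    i3 <- (i - 1L) %% nSide + 1L
    linkerPair(.extensionAt(i5, config@extLengths),
               .extensionAt(i3, config@extLengths),
               core = config@coreSeq)
  })
}

#' Derive structure motifs from a part registry
#'
#' Collects every part annotated with a reference dot-bracket into a
#' [StructureMotif-class], the "correct ribozyme structure and gRNA
#' scaffold structure" requirement of the screen.
#'
#' @param registry a [PartRegistry-class].
#' @param minPairRecovery,maxCrossPairs thresholds applied to each motif.
#' @return list of [StructureMotif-class] objects.
#' @export
motifsFromRegistry <- function(registry, minPairRecovery = 1.0,
                               maxCrossPairs = 0L) {
  parts <- Filter(function(p) !is.na(p@motif), registry@parts)
  unname(lapply(parts, function(p)
    structureMotif(p@name, p@motif, minPairRecovery, maxCrossPairs)))
}

#' Check a predicted structure against reference motifs
#'
#' For each motif anchored to a cassette feature, computes the fraction of
#' the template's base pairs recovered by the prediction inside the
#' feature footprint and the number of predicted pairs crossing the
#' footprint boundary. A motif passes when recovery >=
#' `minPairRecovery` and crossing pairs <= `maxCrossPairs`; when several
#' features share the anchored name (multiplexed scaffold copies), every
#' copy must pass.
#'
#' @param structure a [SecondaryStructure-class] over the construct (or
#'   its transcript).
#' @param construct a [GuideCassette-class], or an `IRanges` of features
#'   in the structure's coordinates.
#' @param motifs list of [StructureMotif-class].
#' @return list with `report` (data.frame: part, copy, recovery, cross,
#'   pass) and `overall` (all motifs pass).
#' @export
checkCorrectness <- function(structure, construct, motifs) {
  ft <- if (is(construct, "GuideCassette")) construct@features else construct
  pt <- pairTable(structure)
  n <- length(pt)
  if (is(construct, "GuideCassette") &&
      nchar(construct@sequence) != n)
    stop("structure length does not match the construct", call. = FALSE)
  rows <- list()
  for (m in motifs) {
    hits <- which(names(ft) == m@partName)
    if (length(hits) == 0L)
      stop("motif anchors to unknown feature '", m@partName, "'",
           call. = FALSE)
    tpl <- dotbracketToPairTable(m@template)
    tplPairs <- which(tpl > seq_along(tpl))
    for (ci in seq_along(hits)) {
      s <- start(ft)[hits[ci]]; e <- end(ft)[hits[ci]]
      if (e - s + 1L != nchar(m@template))
        stop("template length does not match the footprint of '",
             m@partName, "'", call. = FALSE)
      nTpl <- length(tplPairs)
      hitPairs <- 0L
      for (i in tplPairs) {
        gi <- s + i - 1L
        gj <- s + tpl[i] - 1L
        if (gi <= n && pt[gi] == gj) hitPairs <- hitPairs + 1L
      }
      recovery <- if (nTpl == 0L) 1.0 else hitPairs / nTpl
      inFoot <- seq(s, e)
      cross <- sum(pt[inFoot] > 0L & (pt[inFoot] < s | pt[inFoot] > e))
      pass <- recovery >= m@minPairRecovery && cross <= m@maxCrossPairs
      rows[[length(rows) + 1L]] <-
        data.frame(part = m@partName, copy = ci, recovery = recovery,
                   cross = cross, pass = pass)
    }
  }
  report <- do.call(rbind, rows)
  list(report = report, overall = all(report$pass))
}

#' Rank screened candidates by predicted free energy
#'
#' Correct candidates are sorted ascending by `dG_primary` (most negative,
#' i.e. most stable, first); ties break lexicographically on the linker
#' sequences. Incorrect candidates are excluded from the ranking (rank
#' `NA`).
#'
#' @param results data.frame/`DataFrame` with columns `linker5`,
#'   `linker3`, `dG_primary`, `correct_primary`.
#' @return the input with a `rank` column, rows ordered rank-first, then
#'   unranked candidates lexicographically.
#' @export
rankByDG <- function(results) {
  stopifnot(all(c("linker5", "linker3", "dG_primary", "correct_primary")
                %in% colnames(results)))
  rank <- rep(NA_integer_, nrow(results))
  ok <- which(results$correct_primary)
  ord <- ok[order(results$dG_primary[ok], results$linker5[ok],
                  results$linker3[ok])]
  rank[ord] <- seq_along(ord)
  results$rank <- rank
  bad <- which(!results$correct_primary)
  badOrd <- bad[order(results$linker5[bad], results$linker3[bad])]
  results[c(ord, badOrd), , drop = FALSE]
}

#' Coarse shape abstraction of a secondary structure
#'
#' Collapses every maximal helix (run of directly stacked pairs) to a
#' single `[]` and drops unpaired stretches, so structures that differ
#' only in stem and loop lengths share a shape. Used as the default
#' "structural similarity" for grouping library candidates of unequal
#' length.
#'
#' @param x a [SecondaryStructure-class] or a dot-bracket string.
#' @return the shape string over `[` and `]` (empty for an open chain).
#' @examples
#' shapeString("((..))")              # "[]"
#' shapeString("((..))..((..))")      # "[][]"
#' @export
shapeString <- function(x) {
  pt <- if (is(x, "SecondaryStructure")) pairTable(x)
        else dotbracketToPairTable(x)
  n <- length(pt)
  rec <- function(i, j) {
    out <- ""
    k <- i
    while (k <= j) {
      if (pt[k] > k) {
        a <- k; b <- pt[k]
        while (a + 1L < b - 1L && pt[a + 1L] == b - 1L) {
          a <- a + 1L; b <- b - 1L
        }
        out <- paste0(out, "[", rec(a + 1L, b - 1L), "]")
        k <- pt[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    out
  }
  rec(1L, n)
}

#' Base-pair-set distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets: 0 for
#' identical structures, `|pairs|` against the open chain, and a metric
#' (it is a set symmetric-difference cardinality).
#'
#' @param a,b [SecondaryStructure-class] objects, pair matrices from
#'   [basePairs()], or character vectors of pair keys (for comparisons
#'   across unequal-length candidates, endpoints mapped to invariant
#'   coordinates).
#' @param normalize divide by the union size (Jaccard distance)?
#' @return the distance.
#' @export
basePairDistance <- function(a, b, normalize = FALSE) {
  asKeys <- function(x) {
    if (is(x, "SecondaryStructure")) x <- basePairs(x)
    if (is.matrix(x)) x <- paste(x[, 1L], x[, 2L], sep = "-")
    as.character(x)
  }
  ka <- asKeys(a); kb <- asKeys(b)
  d <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  if (!normalize) return(d)
  u <- length(union(ka, kb))
  if (u == 0L) 0 else d / u
}

#' Group structures by similarity
#'
#' `mode = "shape"` (default): candidates with identical coarse shapes
#' (see [shapeString()]) share a group; group ids follow the
#' lexicographic order of the shape strings, so grouping is independent
#' of input order. `mode = "base-pair"`: single-linkage clustering on
#' [basePairDistance()], cutting at `threshold`; `pairKeys` supplies the
#' invariant-coordinate pair sets.
#'
#' @param structures list of [SecondaryStructure-class].
#' @param mode "shape" or "base-pair".
#' @param threshold merge threshold for "base-pair" mode.
#' @param pairKeys optional list of character vectors of pair keys
#'   (defaults to raw base pairs).
#' @return character vector of group ids ("G1", "G2", ...).
#' @export
groupBySimilarity <- function(structures, mode = c("shape", "base-pair"),
                              threshold = 2, pairKeys = NULL) {
  mode <- match.arg(mode)
  if (length(structures) == 0L) return(character())
  if (mode == "shape") {
    shapes <- vapply(structures, shapeString, character(1))
    lev <- sort(unique(shapes))
    return(paste0("G", match(shapes, lev)))
  }
  keys <- if (is.null(pairKeys)) lapply(structures, basePairs) else pairKeys
  k <- length(keys)
  if (k == 1L) return("G1")
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k)) {
      d[i, j] <- d[j, i] <- basePairDistance(keys[[i]], keys[[j]])
    }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = threshold)
  ## canonicalise labels by first occurrence
  paste0("G", match(cl, unique(cl)))
}

#' Select one representative per similarity group
#'
#' Within each group, the most stable candidate (lowest primary dG) that
#' is also structurally correct under the confirmation engine is flagged
#' `selected`; groups without a doubly-correct member select nothing and
#' are reported in the `unrepresented` attribute.
#'
#' @param results data.frame/`DataFrame` with `dG_primary`, `linker5`,
#'   `linker3`, `group_id` and `correct_confirm` columns.
#' @return the input with a logical `selected` column;
#'   `attr(, "unrepresented")` lists groups with no valid member.
#' @export
selectRepresentatives <- function(results) {
  stopifnot(all(c("dG_primary", "group_id", "correct_confirm")
                %in% colnames(results)))
  selected <- rep(FALSE, nrow(results))
  empty <- character()
  for (g in unique(results$group_id[!is.na(results$group_id)])) {
    members <- which(results$group_id == g & results$correct_confirm %in% TRUE)
    if (length(members) == 0L) {
      empty <- c(empty, g)
      next
    }
    pick <- members[order(results$dG_primary[members],
                          results$linker5[members],
                          results$linker3[members])][1L]
    selected[pick] <- TRUE
  }
  results$selected <- selected
  attr(results, "unrepresented") <- empty
  results
}

## map a structure's base pairs to feature-relative keys so candidates of
## different linker-extension lengths become comparable
.invariantPairKeys <- function(structure, features) {
  bp <- basePairs(structure)
  if (nrow(bp) == 0L) return(character())
  lab <- function(pos) {
    i <- which(start(features) <= pos & end(features) >= pos)[1L]
    paste0(names(features)[i], ":", pos - start(features)[i])
  }
  vapply(seq_len(nrow(bp)), function(r)
    paste(lab(bp[r, 1L]), lab(bp[r, 2L]), sep = "|"), character(1))
}

#' Run the digital linker-library screen end to end
#'
#' Composes the full pipeline: generate the linker library, assemble each
#' candidate precursor, fold its transcript with the primary engine,
#' filter by ribozyme/scaffold motif correctness, rank the correct
#' candidates by dG, keep the top `topN`, group them by structural
#' similarity, confirm the groups with the second engine and select one
#' representative per group.
#'
#' @param spacers a [SpacerSet-class].
#' @param variant cassette variant to screen (typically a circular
#'   `C-L<k>` variant; the candidate linkers fill its linker features).
#' @param parts a [PartRegistry-class]; parts carrying motif annotations
#'   define the correctness filter unless `config` supplies motifs.
#' @param config a [screenConfig()].
#' @param foldCircular fold the post-ligation circle instead of the
#'   precursor transcript? Default `FALSE`: the correctness language
#'   targets the ribozyme-containing precursor.
#' @param model energy model for the built-in primary engine.
#' @param library optional explicit list of [LinkerPair-class] candidates;
#'   when supplied it replaces the generated library (used for screening
#'   hand-picked designs).
#' @return a [ScreenReport-class].
#' @export
runScreen <- function(spacers, variant, parts, config = screenConfig(),
                      foldCircular = FALSE, model = energyModel(),
                      library = NULL) {
  stopifnot(is(spacers, "SpacerSet"), is(parts, "PartRegistry"),
            is(config, "ScreenConfig"))
  motifs <- config@motifs
  if (length(motifs) == 0L) {
    motifs <- motifsFromRegistry(parts)
    ## registry-derived motifs are a convenience default: keep only those
    ## anchored to parts the chosen variant actually uses
    probe <- assembleConstruct(spacers, variant, parts,
                               linkers = linkerPair("AAAAA", "AAAAA",
                                                    core = config@coreSeq))
    motifs <- Filter(function(m) m@partName %in% names(probe@features),
                     motifs)
  }
  if (length(motifs) == 0L)
    stop("no structure motifs: annotate registry parts or supply ",
         "config motifs", call. = FALSE)
  explicitLibrary <- !is.null(library)
  if (is.null(library)) {
    library <- generateLinkerLibrary(config)
  } else {
    stopifnot(all(vapply(library, is, logical(1), "LinkerPair")))
  }
  primary <- config@engines[1]
  confirm <- config@engines[2]

  foldCandidate <- function(pair, engine) {
    cassette <- assembleConstruct(spacers, variant, parts, linkers = pair)
    if (foldCircular) {
      circle <- predictCircle(cassette)
      rna <- chartr("T", "U", circle@sequence)
      ft <- circle@features
      st <- foldWith(rna, engine, circular = TRUE, model = model)
    } else {
      tx <- transcribe(cassette)
      rna <- tx$rna
      ft <- tx$features
      st <- foldWith(rna, engine, circular = FALSE, model = model)
    }
    chk <- checkCorrectness(st, ft, motifs)
    list(structure = st, features = ft, correct = chk$overall)
  }

  prim <- lapply(library, foldCandidate, engine = primary)
  res <- data.frame(
    linker5 = vapply(library, function(p) p@linker5, character(1)),
    linker3 = vapply(library, function(p) p@linker3, character(1)),
    dG_primary = vapply(prim, function(x) freeEnergy(x$structure),
                        numeric(1)),
    correct_primary = vapply(prim, function(x) x$correct, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(res$linker5, res$linker3)
  res <- res[ord, , drop = FALSE]
  prim <- prim[ord]
  library <- library[ord]
  rownames(res) <- NULL

  res <- rankByDG(res)
  prim <- prim[as.integer(rownames(res))]
  library <- library[as.integer(rownames(res))]
  rownames(res) <- NULL

  res$dG_confirm <- NA_real_
  res$correct_confirm <- NA
  res$group_id <- NA_character_
  top <- which(!is.na(res$rank) & res$rank <= config@topN)
  if (length(top)) {
    topStructs <- lapply(prim[top], `[[`, "structure")
    keys <- lapply(top, function(i)
      .invariantPairKeys(prim[[i]]$structure, prim[[i]]$features))
    res$group_id[top] <- groupBySimilarity(
      topStructs, mode = config@distanceMode, threshold = config@threshold,
      pairKeys = keys)
    for (i in top) {
      cf <- foldCandidate(library[[i]], confirm)
      res$dG_confirm[i] <- freeEnergy(cf$structure)
      res$correct_confirm[i] <- cf$correct
    }
  }
  res <- selectRepresentatives(res)
  manifest <- list(
    tool = "circguide", version = as.character(utils::packageVersion("circguide")),
    command = "screen", variant = variant,
    casSystem = spacers@casSystem,
    spacers = as.list(spacers@spacers),
    seed = config@seed, engines = c(primary, confirm),
    engine_versions = c(
      primary = if (primary == "vienna") .viennaVersion() else primary,
      confirm = if (confirm == "vienna") .viennaVersion() else confirm),
    fold_circular = foldCircular,
    top_n = config@topN, distance_mode = config@distanceMode,
    library_size = if (explicitLibrary) nrow(res)
      else if (identical(config@librarySize, "exhaustive")) "exhaustive"
      else as.numeric(config@librarySize),
    n_candidates = nrow(res),
    n_correct_primary = sum(res$correct_primary),
    n_groups = length(unique(stats::na.omit(res$group_id))),
    n_selected = sum(res$selected),
    unrepresented_groups = attr(res, "unrepresented"),
    config_hash = rlang::hash(list(
      core = config@coreSeq, ext = config@extLengths,
      size = config@librarySize, seed = config@seed, topN = config@topN,
      engines = config@engines, mode = config@distanceMode,
      threshold = config@threshold,
      motifs = lapply(motifs, function(m)
        list(m@partName, m@template, m@minPairRecovery, m@maxCrossPairs)))))
  new("ScreenReport", results = S4Vectors::DataFrame(res),
      manifest = manifest)
}

.viennaVersion <- function() {
  if (!viennaAvailable()) return("vienna:unavailable")
  tryCatch(paste0("vienna:RNAfold ",
                  sub("^RNAfold\\s+", "",
                      system2("RNAfold", "--version", stdout = TRUE)[1])),
           error = function(e) "vienna:unknown")
}
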