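#' @include AllClasses.R
NULL

.PAIR_TYPES <- c("CG", "GC", "UA", "AU", "UG", "GU")

#' The bundled nearest-neighbour energy model
#'
#' A deliberately simple, fully editable model: each stack of two adjacent
#' base pairs contributes a negative stacking energy drawn from a table
#' over the 6 x 6 ordered pair types; each hairpin loop of size s pays
#' `hairpinA + hairpinB * log(s / minLoop)` kcal/mol; a pair closing any
#' other loop (interior, bulge, multibranch) pays the flat
#' `closePenalty`. The default table is derived
#' from per-pair strengths (GC 3, AU 2, GU 1) scaled so that a GC-on-GC
#' stack is -3.3 kcal/mol. The model makes no claim to Turner-rule
#' accuracy; use [foldVienna()] for production-grade energies.
#'
#' @param stackScale multiplier applied to the summed pair strengths
#'   (kcal/mol per strength unit).
#' @param hairpinA,hairpinB hairpin penalty parameters (kcal/mol).
#' @param closePenalty flat penalty for a pair closing a non-hairpin loop
#'   (kcal/mol); keeps isolated long-range pairings from being free.
#' @param minLoop minimum hairpin loop size (nt).
#' @param stack optional 6 x 6 replacement stacking table (rows = outer
#'   pair, columns = inner pair, order CG, GC, UA, AU, UG, GU).
#' @return an object of class `EnergyModel`.
#' @examples
#' energyModel()$stack["GC", "GC"]
#' @export
energyModel <- function(stackScale = 0.55, hairpinA = 4.5, hairpinB = 1.0,
                        closePenalty = 4.0, minLoop = 3L, stack = NULL) {
  strength <- c(CG = 3, GC = 3, UA = 2, AU = 2, UG = 1, GU = 1)
  if (is.null(stack)) {
    stack <- -stackScale * outer(strength, strength, "+")
    dimnames(stack) <- list(.PAIR_TYPES, .PAIR_TYPES)
  }
  stopifnot(identical(dim(stack), c(6L, 6L)), all(stack <= 0))
  structure(list(stack = stack, hairpinA = hairpinA, hairpinB = hairpinB,
                 closePenalty = closePenalty, minLoop = as.integer(minLoop),
                 pairs = .PAIR_TYPES),
            class = "EnergyModel")
}

.checkRNA <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L)
    stop("cannot fold an empty sequence", call. = FALSE)
  if (grepl("[^ACGU]", seq))
    stop("invalid alphabet: folding needs an RNA string over {A,C,G,U}",
         call. = FALSE)
  seq
}

.newStructure <- function(pt, dG, circular, engineId, cut = 0L) {
  n <- length(pt)
  chars <- rep(".", n)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) {
      ri <- (i - 1L - cut) %% n
      rj <- (j - 1L - cut) %% n
      if (ri < rj) { chars[i] <- "("; chars[j] <- ")" }
      else         { chars[j] <- "("; chars[i] <- ")" }
    }
  }
  new("SecondaryStructure", dotbracket = paste(chars, collapse = ""),
      dG = dG, pairTable = as.integer(pt), circular = circular,
      engineId = engineId)
}

#' Predict the minimum-energy secondary structure
#'
#' Dynamic-programming minimisation under the bundled nearest-neighbour
#' model (see [energyModel()]). Deterministic: ties are broken by a fixed
#' left-to-right traceback that prefers pairing the leftmost free base
#' with its smallest admissible partner. With `circular = TRUE` the
#' sequence is folded as a cycle (doubled-sequence reduction; a helix may
#' run across the origin).
#'
#' @param seq RNA string over \{A,C,G,U\}.
#' @param circular fold as a circle?
#' @param model an [energyModel()].
#' @return a [SecondaryStructure-class] with `engineId = "energy"`; the
#'   open chain has `dG = 0` and the reported dG is never positive.
#' @examples
#' dotbracket(fold("GGGAAAACCC"))
#' @export
fold <- function(seq, circular = FALSE, model = energyModel()) {
  seq <- .checkRNA(seq)
  res <- .foldEnergyC(seq, circular, model$minLoop,
                      unname(model$stack), model$hairpinA, model$hairpinB,
                      model$closePenalty)
  .newStructure(res$pairTable, res$dG, circular, "energy", res$cut)
}

#' Predict the maximum-base-pair structure (Nussinov)
#'
#' The confirmation engine: maximises the number of Watson-Crick/wobble
#' pairs subject to the minimum-loop constraint, with the same
#' deterministic tie-breaking as [fold()]. Reported `dG` is the negative
#' pair count, in pseudo-units.
#'
#' @inheritParams fold
#' @param minLoop minimum hairpin loop size.
#' @return a [SecondaryStructure-class] with `engineId = "maxpair"`.
#' @examples
#' freeEnergy(foldMaxpair("GGGAAAACCC"))  # -3: three pairs
#' @export
foldMaxpair <- function(seq, circular = FALSE, minLoop = 3L) {
  seq <- .checkRNA(seq)
  res <- .foldMaxpairC(seq, circular, as.integer(minLoop))
  .newStructure(res$pairTable, res$dG, circular, "maxpair", res$cut)
}

#' Fold with a named engine
#'
#' @param seq RNA string.
#' @param engine "energy", "maxpair" or "vienna".
#' @param circular fold as a circle?
#' @param model energy model for the "energy" engine.
#' @return a [SecondaryStructure-class].
#' @export
foldWith <- function(seq, engine, circular = FALSE, model = energyModel()) {
  switch(engine,
    energy = fold(seq, circular, model),
    maxpair = foldMaxpair(seq, circular, model$minLoop),
    vienna = foldVienna(seq, circular),
    stop("unknown folding engine: '", engine, "'", call. = FALSE))
}

#' Enumerate all nested secondary structures (test oracle)
#'
#' Exhaustively lists every structure over the allowed pairs (AU, UA, GC,
#' CG, GU, UG) that respects the minimum-loop constraint. Guarded to
#' short sequences; this is the brute-force oracle the DP engines are
#' tested against, and is deliberately independent of them.
#'
#' @param seq RNA string, at most 16 nt.
#' @param minLoop minimum hairpin loop size.
#' @param circular enumerate circular structures (nested under some
#'   rotation)?
#' @return list of structures, each an integer matrix with columns `i`,
#'   `j` (1-based pair positions; 0 rows = open chain).
#' @examples
#' length(enumerateStructures("GAAAC"))  # open chain + one pair
#' @export
enumerateStructures <- function(seq, minLoop = 3L, circular = FALSE) {
  seq <- .checkRNA(seq)
  n <- nchar(seq)
  if (n > 16L)
    stop("enumerateStructures() is guarded to sequences of length <= 16",
         call. = FALSE)
  v <- strsplit(seq, "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% .PAIR_TYPES
  enumLinear <- function(bases) {
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
      if (j - i < minLoop + 1L) return(list(list()))
      key <- paste(i, j)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      out <- rec(i + 1L, j)
      ks <- seq(i + minLoop + 1L, j)
      for (k in ks) {
        if (!ok(bases[i], bases[k])) next
        for (L in rec(i + 1L, k - 1L))
          for (R in rec(k + 1L, j))
            out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
      }
      memo[[key]] <- out
      out
    }
    rec(1L, n)
  }
  asMatrix <- function(s) {
    if (length(s) == 0L)
      return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
    m <- do.call(rbind, s)
    m <- m[order(m[, 1L]), , drop = FALSE]
    dimnames(m) <- list(NULL, c("i", "j"))
    m
  }
  if (!circular) return(lapply(enumLinear(v), asMatrix))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in 0:(n - 1L)) {
    rot <- c(v[(r + 1L):n], if (r > 0L) v[1:r])
    for (s in enumLinear(rot)) {
      if (length(s)) {
        s <- lapply(s, function(p) sort(((p - 1L + r) %% n) + 1L))
      }
      m <- asMatrix(s)
      key <- paste0("k", paste(t(m), collapse = ","))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

#' Score a structure's energy under the bundled model
#'
#' Independent (non-DP) evaluation of a pair set: sums stacking energies
#' over directly stacked pairs and hairpin penalties over hairpin loops.
#' Used to cross-check the DP engine on enumerable sequences.
#'
#' @param seq RNA string.
#' @param pairs integer matrix with columns `i`, `j`.
#' @param model an [energyModel()].
#' @return energy in kcal/mol (0 for the open chain).
#' @export
scoreStructure <- function(seq, pairs, model = energyModel()) {
  seq <- .checkRNA(seq)
  v <- strsplit(seq, "")[[1]]
  if (nrow(pairs) == 0L) return(0)
  pt <- integer(nchar(seq))
  pt[pairs[, 1L]] <- pairs[, 2L]
  pt[pairs[, 2L]] <- pairs[, 1L]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    inner <- if (i + 1L <= length(pt)) pt[i + 1L] else 0L
    if (inner == j - 1L && inner > i + 1L) {
      e <- e + model$stack[paste0(v[i], v[j]), paste0(v[i + 1L], v[j - 1L])]
    } else if (all(pt[seq(i + 1L, j - 1L)] == 0L)) {
      s <- j - i - 1L
      e <- e + model$hairpinA + model$hairpinB * log(s / model$minLoop)
    } else {
      e <- e + model$closePenalty
    }
  }
  unname(e)
}

#' Base-pair set of a structure
#' @param structure a [SecondaryStructure-class].
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
basePairs <- function(structure) {
  pt <- pairTable(structure)
  i <- which(pt > seq_along(pt))
  matrix(c(i, pt[i]), ncol = 2L, dimnames = list(NULL, c("i", "j")))
}

#' Convert a dot-bracket string to a pair table
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector of 1-based partners (0 = unpaired).
#' @export
dotbracketToPairTable <- function(db) {
  v <- strsplit(db, "")[[1]]
  if (any(!v %in% c("(", ")", ".")))
    stop("not a dot-bracket string", call. = FALSE)
  pt <- integer(length(v))
  stack <- integer()
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      if (!length(stack))
        stop("unbalanced brackets in dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced brackets in dot-bracket string", call. = FALSE)
  pt
}
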