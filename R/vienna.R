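#' @include folding.R
NULL

#' Is the external ViennaRNA engine available?
#' @return `TRUE` if an `RNAfold` binary is on the PATH.
#' @export
viennaAvailable <- function() nzchar(Sys.which("RNAfold"))

#' Parse RNAfold-style output
#'
#' Accepts the structure line format `"((....)) (-1.20)"` (whitespace
#' inside the energy parentheses tolerated). Multi-line input may carry a
#' FASTA-style header and the echoed sequence before the structure line.
#'
#' @param lines character vector of engine output lines.
#' @param circular whether the fold was circular.
#' @param engineId engine identifier recorded on the structure.
#' @return a [SecondaryStructure-class].
#' @export
parseViennaOutput <- function(lines, circular = FALSE,
                              engineId = "vienna") {
  lines <- lines[nzchar(lines)]
  pat <- "^([().]+)\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)\\s*$"
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L)
    stop("unparseable engine output: no structure/energy line found",
         call. = FALSE)
  db <- sub(pat, "\\1", hit[1])
  dG <- as.numeric(sub(pat, "\\2", hit[1]))
  pt <- if (circular) .circularPairTable(db) else dotbracketToPairTable(db)
  new("SecondaryStructure", dotbracket = db, dG = dG,
      pairTable = pt, circular = circular, engineId = engineId)
}

## pair table for a dot-bracket that may cross the origin (RNAfold --circ
## emits structures balanced only under rotation)
.circularPairTable <- function(db) {
  v <- strsplit(db, "")[[1]]
  n <- length(v)
  if (sum(v == "(") != sum(v == ")"))
    stop("unbalanced brackets in dot-bracket string", call. = FALSE)
  ## rotate to the cut with minimal prefix depth (cycle lemma), match
  ## there, then map back
  depth <- cumsum((v == "(") - (v == ")"))
  cut <- which.min(depth)  # rotate to start after this position
  ord <- c(seq_len(n)[-seq_len(cut)], seq_len(cut))
  ptRot <- dotbracketToPairTable(paste(v[ord], collapse = ""))
  pt <- integer(n)
  for (k in seq_len(n)) if (ptRot[k] > 0L) pt[ord[k]] <- ord[ptRot[k]]
  pt
}

#' Fold with the external ViennaRNA RNAfold engine
#'
#' Thin adapter around the `RNAfold` command-line binary; use it when
#' production-grade Turner energies are wanted instead of the bundled
#' model. Fails loudly when the binary is absent - there is no silent
#' fallback to the built-in engines.
#'
#' @inheritParams fold
#' @return a [SecondaryStructure-class] whose `engineId` records the
#'   engine name and version, e.g. `"vienna:RNAfold 2.7.2"`.
#' @export
foldVienna <- function(seq, circular = FALSE) {
  seq <- .checkRNA(seq)
  if (!viennaAvailable())
    stop("external folding engine not available: 'RNAfold' is not on the ",
         "PATH", call. = FALSE)
  ver <- tryCatch(
    sub("^RNAfold\\s+", "", system2("RNAfold", "--version", stdout = TRUE)[1]),
    error = function(e) "unknown")
  args <- c("--noPS", if (circular) "--circ")
  out <- system2("RNAfold", args, stdout = TRUE, stderr = FALSE, input = seq)
  parseViennaOutput(out, circular = circular,
                    engineId = paste0("vienna:RNAfold ", ver))
}
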