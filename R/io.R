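#' @include AllClasses.R assemble.R
NULL

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences, in file order
#'   (the record order defines multiplex order for [readFastaSpacers()]).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to a FASTA file (60-column wrapping)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @describeIn readFasta read a FASTA file as a [SpacerSet-class].
#' @param casSystem Cas effector for the spacer set.
#' @export
readFastaSpacers <- function(path, casSystem = "LbCas12a") {
  spacerSet(readFasta(path), casSystem = casSystem)
}

#' Feature table of a cassette as a data.frame
#'
#' @param cassette a [GuideCassette-class].
#' @param zeroBased report 0-based half-open coordinates instead of the
#'   1-based inclusive ranges stored internally?
#' @return data.frame with columns `part`, `role`, `start`, `end`.
#' @export
featureTable <- function(cassette, zeroBased = FALSE) {
  ft <- cassette@features
  s <- start(ft); e <- end(ft)
  if (zeroBased) { s <- s - 1L }       # end stays: half-open end == 1-based end
  data.frame(part = names(ft), role = mcols(ft)$role, start = s, end = e,
             stringsAsFactors = FALSE)
}

#' Convert between the 0-based half-open and GenBank span conventions
#'
#' @param start,end 0-based half-open feature coordinates.
#' @return `zeroBasedToGenBank()`: the GenBank location string (1-based,
#'   inclusive); `genBankToZeroBased()`: integer vector `c(start, end)` in
#'   0-based half-open coordinates.
#' @examples
#' zeroBasedToGenBank(0, 10)   # "1..10"
#' genBankToZeroBased("1..10") # c(0, 10)
#' @export
zeroBasedToGenBank <- function(start, end) paste0(start + 1L, "..", end)

#' @rdname zeroBasedToGenBank
#' @param span a GenBank location string like `"1..10"`.
#' @export
genBankToZeroBased <- function(span) {
  m <- regmatches(span, regexec("^([0-9]+)\\.\\.([0-9]+)$", span))[[1]]
  if (length(m) != 3L) stop("not a GenBank span: ", span, call. = FALSE)
  c(as.integer(m[2]) - 1L, as.integer(m[3]))
}

#' Write a cassette as a GenBank flat file
#'
#' One `misc_feature` per part with a `/label` qualifier; topology and
#' Cas system are recorded in the LOCUS line and a COMMENT. The output
#' carries no timestamps and is byte-stable for fixed input.
#'
#' @param cassette a [GuideCassette-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(cassette, path) {
  stopifnot(is(cassette, "GuideCassette"))
  n <- nchar(cassette@sequence)
  circular <- cassette@topology %in% c("circular_rna")
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("LOCUS       %-20s %d bp    DNA     %-8s SYN", substr(cassette@name, 1, 20),
     n, if (circular) "circular" else "linear")
  wr("DEFINITION  %s guide-RNA expression cassette.", cassette@name)
  wr("COMMENT     topology: %s", cassette@topology)
  wr("COMMENT     cas_system: %s", cassette@casSystem)
  wr("COMMENT     variant: %s", cassette@variant)
  wr("FEATURES             Location/Qualifiers")
  ft <- cassette@features
  for (i in seq_along(ft)) {
    wr("     misc_feature    %d..%d", start(ft)[i], end(ft)[i])
    wr("                     /label=%s", names(ft)[i])
    wr("                     /note=role:%s", mcols(ft)$role[i])
  }
  wr("ORIGIN")
  seqLower <- tolower(cassette@sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(seqLower, p, min(p + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wr("%9d %s", p, paste(blocks, collapse = " "))
  }
  wr("//")
  invisible(path)
}

#' Read a GenBank flat file written by [writeGenBank()]
#'
#' A minimal parser for the subset this package writes: LOCUS name,
#' `misc_feature` spans with `/label` and `/note=role:` qualifiers,
#' COMMENT metadata and the ORIGIN sequence.
#'
#' @param path GenBank file.
#' @return a [GuideCassette-class].
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  gbName <- sub("^LOCUS\\s+(\\S+).*$", "\\1", grep("^LOCUS", lines,
                                                   value = TRUE)[1])
  meta <- function(key, default) {
    hit <- grep(paste0("^COMMENT\\s+", key, ": "), lines, value = TRUE)
    if (length(hit)) sub(paste0("^COMMENT\\s+", key, ": "), "", hit[1])
    else default
  }
  topo <- meta("topology", "linear_gRNA")
  cas <- meta("cas_system", "LbCas12a")
  variant <- meta("variant", NA_character_)
  featIdx <- grep("^\\s{5}misc_feature\\s", lines)
  starts <- integer(); ends <- integer(); labels <- character()
  roles <- character()
  for (i in featIdx) {
    span <- sub("^\\s*misc_feature\\s+", "", lines[i])
    m <- regexec("^([0-9]+)\\.\\.([0-9]+)", span)[[1]]
    if (m[1] < 0)
      stop("parse error at line ", i, ": bad feature span '", span, "'",
           call. = FALSE)
    starts <- c(starts, as.integer(substr(span, m[2], m[2] +
                                          attr(m, "match.length")[2] - 1L)))
    ends <- c(ends, as.integer(sub("^[0-9]+\\.\\.", "",
                                   regmatches(span, regexec(
                                     "^[0-9]+\\.\\.[0-9]+", span))[[1]])))
    labels <- c(labels, sub("^\\s*/label=", "", lines[i + 1L]))
    roles <- c(roles, sub("^\\s*/note=role:", "", lines[i + 2L]))
  }
  oriAt <- grep("^ORIGIN", lines)[1]
  endAt <- grep("^//", lines)[1]
  seqLines <- lines[seq(oriAt + 1L, endAt - 1L)]
  seqn <- toupper(gsub("[^a-zA-Z]", "", paste(seqLines, collapse = "")))
  ft <- IRanges::IRanges(start = starts, end = ends, names = labels)
  mcols(ft)$role <- roles
  mcols(ft)$cleavage_offset <- ifelse(
    roles %in% c("ribozyme_5p", "ribozyme_3p"), 0L, NA_integer_)
  new("GuideCassette", name = gbName, topology = topo, sequence = seqn,
      features = ft, casSystem = cas, variant = variant, leaderLength = 0L)
}

#' Write a structure in Vienna dot-bracket format
#'
#' Three lines: `>name`, sequence, then structure and energy as
#' `"((...)) (-1.20)"`.
#'
#' @param structure a [SecondaryStructure-class].
#' @param seq the folded sequence.
#' @param path output file.
#' @param name record header.
#' @return `path`, invisibly.
#' @export
writeDotBracket <- function(structure, seq, path, name = "structure") {
  stopifnot(is(structure, "SecondaryStructure"),
            nchar(seq) == nchar(structure@dotbracket))
  writeLines(c(paste0(">", name), seq,
               sprintf("%s (%.2f)", structure@dotbracket, structure@dG)),
             path)
  invisible(path)
}

#' Read a Vienna dot-bracket file
#'
#' @param path dot-bracket file (`>name` header, sequence line,
#'   structure+energy line).
#' @param circular interpret the structure as circular?
#' @return list with `name`, `seq` and `structure`
#'   ([SecondaryStructure-class]).
#' @export
readDotBracket <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L || !startsWith(lines[1], ">"))
    stop("parse error: expected '>name', sequence and structure lines",
         call. = FALSE)
  m <- regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", lines[3])[[1]]
  if (m[1] < 0)
    stop("parse error at line 3: bad structure/energy line", call. = FALSE)
  db <- regmatches(lines[3], regexec("^([().]+)", lines[3]))[[1]][2]
  dG <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", lines[3]))
  pt <- if (circular) .circularPairTable(db) else dotbracketToPairTable(db)
  structure <- new("SecondaryStructure", dotbracket = db, dG = dG,
                   pairTable = pt, circular = circular, engineId = "file")
  list(name = sub("^>", "", lines[1]), seq = lines[2],
       structure = structure)
}

#' Write a structure as a connectivity table (CT) file
#'
#' @inheritParams writeDotBracket
#' @export
writeCT <- function(structure, seq, path, name = "structure") {
  stopifnot(nchar(seq) == length(structure@pairTable))
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  pt <- structure@pairTable
  lines <- c(sprintf("%5d %s dG = %.2f", n, name, structure@dG),
             sprintf("%5d %s %7d %7d %7d %7d",
                     seq_len(n), v, seq_len(n) - 1L,
                     c(seq_len(n - 1L) + 1L, 0L), pt, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a connectivity table (CT) file
#'
#' @param path CT file.
#' @return list with `name`, `seq` and `structure`
#'   ([SecondaryStructure-class]); circularity is inferred from the pair
#'   table (a structure whose brackets only balance under rotation).
#' @export
readCT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("parse error: bad CT header", call. = FALSE)
  name <- if (length(hdr) > 1L) hdr[2] else "structure"
  fields <- strsplit(trimws(lines[seq(2L, n + 1L)]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 6L)
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, ": expected 6 CT columns",
         call. = FALSE)
  v <- vapply(fields, `[`, character(1), 2L)
  pt <- as.integer(vapply(fields, `[`, character(1), 5L))
  seqn <- paste(v, collapse = "")
  paired <- which(pt > 0L)
  if (any(pt < 0L | pt > n) || any(pt[pt[paired]] != paired))
    stop("parse error: inconsistent CT pair column", call. = FALSE)
  ## brackets that only balance under rotation mean a cross-origin
  ## (circular) structure; the cycle-lemma cut makes them nested again
  chars <- rep(".", n)
  for (i in seq_len(n)) if (pt[i] > i) { chars[i] <- "("; chars[pt[i]] <- ")" }
  depth <- cumsum((chars == "(") - (chars == ")"))
  circular <- any(depth < 0)
  dG <- 0
  m <- regexec("dG\\s*=\\s*(-?[0-9.]+)", lines[1])[[1]]
  if (m[1] > 0)
    dG <- as.numeric(substr(lines[1], m[2],
                            m[2] + attr(m, "match.length")[2] - 1L))
  st <- .newStructure(pt, dG = dG, circular = circular, engineId = "file",
                      cut = if (circular) which.min(depth) else 0L)
  list(name = name, seq = seqn, structure = st)
}

#' Write a screen report as TSV plus a JSON run manifest
#'
#' @param report a [ScreenReport-class].
#' @param path output TSV; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return named character vector of the two paths, invisibly.
#' @export
writeScreenReport <- function(report, path) {
  stopifnot(is(report, "ScreenReport"))
  df <- as.data.frame(report@results)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mpath <- paste0(path, ".manifest.json")
  jsonlite::write_json(report@manifest, mpath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(report = path, manifest = mpath))
}
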