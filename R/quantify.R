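#' @include AllClasses.R
NULL

#' Specificity index of a guide condition
#'
#' SI = total on-target reads / (on-target + off-target reads). By default
#' reads are summed across all sites of the condition before the ratio is
#' taken; `perSite = TRUE` instead returns one index per on-target site
#' against the condition's off-target pool.
#'
#' @param table data.frame with columns `site`, `kind` ("on_target" /
#'   "off_target"), `reads`, and optionally `condition`.
#' @param condition condition to evaluate; `NULL` uses the whole table.
#' @param perSite return a per-site breakdown?
#' @return a fraction in \[0, 1\] (or a named vector, for `perSite`).
#' @examples
#' tbl <- data.frame(site = c("s1", "s1_off"),
#'                   kind = c("on_target", "off_target"),
#'                   reads = c(98, 2))
#' specificityIndex(tbl)  # 0.98
#' @export
specificityIndex <- function(table, condition = NULL, perSite = FALSE) {
  stopifnot(all(c("site", "kind", "reads") %in% colnames(table)))
  if (!is.null(condition)) {
    if (!"condition" %in% colnames(table))
      stop("table has no 'condition' column", call. = FALSE)
    table <- table[table$condition == condition, , drop = FALSE]
  }
  if (any(table$reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (!any(table$kind == "on_target"))
    stop("no on-target rows for this condition", call. = FALSE)
  on <- sum(table$reads[table$kind == "on_target"])
  off <- sum(table$reads[table$kind == "off_target"])
  if (on + off == 0) stop("zero total reads", call. = FALSE)
  if (!perSite) return(on / (on + off))
  onRows <- table[table$kind == "on_target", , drop = FALSE]
  stats::setNames(
    vapply(seq_len(nrow(onRows)), function(i) {
      denom <- onRows$reads[i] + off
      if (denom == 0) NA_real_ else onRows$reads[i] / denom
    }, numeric(1)),
    onRows$site)
}

#' FACS cleavage efficiency
#'
#' E = (mNeonGreen-negative AND mCherry-positive events) / mCherry-positive
#' events: the fraction of transfected (mCherry+) reporter cells that
#' lost mNeonGreen fluorescence.
#'
#' @param facs data.frame with columns `total`, `mcherry_pos`,
#'   `neon_neg_mcherry_pos` (one row per sample), or a single sample given
#'   as a named vector/list.
#' @return numeric vector of efficiencies in \[0, 1\].
#' @examples
#' cleavageEfficiency(data.frame(total = 5000, mcherry_pos = 1000,
#'                               neon_neg_mcherry_pos = 400))  # 0.4
#' @export
cleavageEfficiency <- function(facs) {
  if (!is.data.frame(facs)) facs <- as.data.frame(as.list(facs))
  stopifnot(all(c("total", "mcherry_pos", "neon_neg_mcherry_pos")
                %in% colnames(facs)))
  with(facs, {
    if (any(neon_neg_mcherry_pos > mcherry_pos | mcherry_pos > total |
            neon_neg_mcherry_pos < 0))
      stop("invalid FACS counts: need 0 <= mNeonGreen-/mCherry+ <= ",
           "mCherry+ <= total", call. = FALSE)
    if (any(mcherry_pos == 0))
      stop("zero transfected (mCherry+) events", call. = FALSE)
    neon_neg_mcherry_pos / mcherry_pos
  })
}

#' Fold change of expression between a test and a control condition
#'
#' Ratio of means of the two expression-value vectors, the normalisation
#' used to compare each guide against the linear U6+27 control.
#'
#' @param test,control numeric vectors of expression values.
#' @return mean(test) / mean(control).
#' @examples
#' foldChange(c(9, 10, 11), c(1.9, 2.0, 2.1))  # 5
#' @export
foldChange <- function(test, control) {
  m <- mean(control)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive", call. = FALSE)
  mean(test) / m
}

#' Fold change from qPCR Ct values (2^-ddCt)
#'
#' @param testCt,controlCt target-gene Ct values in the test and control
#'   conditions.
#' @param testRefCt,controlRefCt reference-gene Ct values.
#' @return 2^-ddCt where ddCt = (testCt - testRefCt) -
#'   (controlCt - controlRefCt); means are taken over replicates.
#' @export
foldChangeDDCt <- function(testCt, controlCt, testRefCt, controlRefCt) {
  ddct <- (mean(testCt) - mean(testRefCt)) -
          (mean(controlCt) - mean(controlRefCt))
  2^(-ddct)
}

#' Guide decay rate and half-life from an RNA time course
#'
#' Fits ln(abundance) ~ time by ordinary least squares over an
#' actinomycin D chase (e.g. samples at 1, 3, 6, 9 and 18 h); the decay
#' rate is minus the slope and the half-life is ln(2)/k. Non-positive
#' estimated rates flag the species as stable (infinite half-life), the
#' signature of a circularised guide in such an assay.
#'
#' @param timepoints hours, strictly increasing, at least 3.
#' @param abundance relative expression (> 0) at each timepoint.
#' @return list with `k` (1/h), `tHalf` (h), `stable` (logical) and the
#'   underlying `fit`.
#' @examples
#' decayHalfLife(c(1, 3, 6, 9, 18), exp(-0.231 * c(1, 3, 6, 9, 18)))
#' @export
decayHalfLife <- function(timepoints, abundance) {
  if (length(timepoints) < 3L)
    stop("need at least 3 timepoints", call. = FALSE)
  if (length(abundance) != length(timepoints))
    stop("timepoints and abundance differ in length", call. = FALSE)
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (any(abundance <= 0))
    stop("abundances must be positive for the log-linear fit",
         call. = FALSE)
  fit <- stats::lm(log(abundance) ~ timepoints)
  k <- -unname(stats::coef(fit)[2L])
  if (k <= 0)
    return(list(k = k, tHalf = Inf, stable = TRUE, fit = fit))
  list(k = k, tHalf = log(2) / k, stable = FALSE, fit = fit)
}

#' Read a site read-count table (TSV)
#'
#' Expected columns: `condition`, `site`, `kind` (`on_target` /
#' `off_target`), `reads`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSiteReads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "site", "kind", "reads")
  if (!all(need %in% colnames(df)))
    stop("site read table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a FACS count table (TSV)
#'
#' Expected columns: `sample`, `total`, `mcherry_pos`,
#' `neon_neg_mcherry_pos` (optionally `mfi`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readFacsCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "total", "mcherry_pos", "neon_neg_mcherry_pos")
  if (!all(need %in% colnames(df)))
    stop("FACS table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
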