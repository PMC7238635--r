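# Assembly summary statistics and N-gap discovery.

#' Find N-gaps in a sequence record
#'
#' Returns maximal runs of N strictly longer than \code{minExcludedRun}
#' (default 10, the "gaps longer than 10 Ns" accounting rule), as 0-based
#' half-open intervals sorted by start.
#'
#' @param record a \linkS4class{SeqRecord} (or plain DNA string)
#' @param minExcludedRun runs of at most this many N are not gaps
#' @param kind gap kind to annotate ("unknown", "estimated" or "overlap13N")
#' @return data.frame with columns \code{start}, \code{end}, \code{kind}
#' @export
findNGaps <- function(record, minExcludedRun = 10L, kind = "unknown") {
  s <- if (is(record, "SeqRecord")) record@seq else record
  runs <- nRuns(s)
  runs <- runs[runs$end - runs$start > minExcludedRun, , drop = FALSE]
  if (nrow(runs)) runs$kind <- kind else runs$kind <- character(0)
  rownames(runs) <- NULL
  runs
}

#' Assembly contiguity metrics
#'
#' N50 is the smallest contig length L such that contigs of length >= L sum
#' to at least 50\% of the assembly; N90 analogously at 90\%.  Gap length
#' counts only N-runs longer than 10 N (see \code{\link{findNGaps}}).
#' All values are exact integer bp; megabase formatting is left to reports.
#'
#' @param records list of \linkS4class{SeqRecord}
#' @return object of class \code{AssemblyMetrics}: list with \code{n50},
#'   \code{n90}, \code{max_len}, \code{total_len}, \code{gap_len},
#'   \code{n_contigs}
#' @export
assemblyMetrics <- function(records) {
  if (length(records) == 0L) stop("assemblyMetrics: empty record list")
  if (is(records, "SeqRecord")) records <- list(records)
  lens <- sort(vapply(records, seqLen, 0), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  n50 <- lens[which(cum >= 0.5 * total)[1]]
  n90 <- lens[which(cum >= 0.9 * total)[1]]
  gap <- sum(vapply(records, function(r) {
    g <- findNGaps(r); sum(g$end - g$start)
  }, 0))
  structure(list(n50 = n50, n90 = n90, max_len = lens[1], total_len = total,
                 gap_len = gap, n_contigs = length(lens)),
            class = "AssemblyMetrics")
}

#' @export
print.AssemblyMetrics <- function(x, ...) {
  cat(sprintf("contigs: %d  total: %s bp  N50: %s  N90: %s  max: %s  gap bp (>10 N): %s\n",
              x$n_contigs, format(x$total_len, big.mark = ","),
              format(x$n50, big.mark = ","), format(x$n90, big.mark = ","),
              format(x$max_len, big.mark = ","), format(x$gap_len, big.mark = ",")))
  invisible(x)
}
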