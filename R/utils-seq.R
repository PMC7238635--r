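# Low-level sequence helpers shared across modules.

#' Reverse complement of a plain DNA string
#'
#' @param s character string over ACGTN
#' @return the reverse complement string
#' @export
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Vectorized reverse complement for plain character vectors (one batched
# Biostrings call; names preserved).
revCompVec <- function(x) {
  if (!length(x)) return(x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Random uniform DNA
#'
#' Draws i.i.d. bases.  Used by the simulator and by tests; honours the
#' current RNG state.
#'
#' @param n length in bp
#' @param exclude optional motif that must not occur (on either strand);
#'   occurrences are resampled
#' @return a DNA string of length \code{n}
#' @export
randomDNA <- function(n, exclude = NULL) {
  s <- rawToChar(sample(charToRaw("ACGT"), n, replace = TRUE))
  if (!is.null(exclude)) {
    pat <- unique(c(exclude, revComp(exclude)))
    for (iter in 1:50) {
      hit <- FALSE
      for (p in pat) {
        m <- gregexpr(p, s, fixed = TRUE)[[1]]
        if (m[1] != -1) {
          hit <- TRUE
          r <- charToRaw(s)
          for (pos in m) {  # rewrite the first base of each occurrence
            r[pos] <- charToRaw(sample(setdiff(c("A", "C", "G", "T"),
                                               substr(s, pos, pos)), 1))
          }
          s <- rawToChar(r)
        }
      }
      if (!hit) break
    }
  }
  s
}

#' Apply substitution and indel errors to a DNA string
#'
#' Substitutions replace a base by a different uniformly chosen base.
#' Indels are short (1-3 bp) insertions or deletions.  Positions with N are
#' left untouched by substitutions.
#'
#' @param s DNA string
#' @param subRate per-base substitution probability
#' @param indelRate per-base probability of starting an indel
#' @return mutated string
#' @export
mutateSequence <- function(s, subRate = 0, indelRate = 0) {
  n <- nchar(s)
  if (n == 0L) return(s)
  if (subRate > 0) {
    k <- stats::rbinom(1, n, subRate)
    if (k > 0) {
      pos <- sample.int(n, k)
      r <- charToRaw(s)
      bases <- charToRaw("ACGT")
      cur <- r[pos]
      keep <- cur != charToRaw("N")
      pos <- pos[keep]; cur <- cur[keep]
      if (length(pos)) {
        repl <- bases[(match(cur, bases) + sample.int(3, length(pos), replace = TRUE) - 1L) %% 4L + 1L]
        r[pos] <- repl
        s <- rawToChar(r)
      }
    }
  }
  if (indelRate > 0) {
    k <- stats::rbinom(1, n, indelRate)
    if (k > 0) {
      pos <- sort(sample.int(n, k))
      sizes <- sample.int(3, k, replace = TRUE)
      ins <- stats::runif(k) < 0.5
      pieces <- character(2L * k + 1L)
      prev <- 1L
      for (i in seq_len(k)) {
        if (ins[i]) {
          pieces[2L * i - 1L] <- substr(s, prev, pos[i])
          pieces[2L * i] <- paste(sample(c("A", "C", "G", "T"), sizes[i], replace = TRUE), collapse = "")
          prev <- pos[i] + 1L
        } else {
          pieces[2L * i - 1L] <- substr(s, prev, pos[i] - 1L)
          prev <- min(pos[i] + sizes[i], n + 1L)
        }
      }
      pieces[2L * k + 1L] <- substr(s, prev, n)
      s <- paste(pieces, collapse = "")
    }
  }
  s
}

# Maximal runs of N in a string: data.frame(start, end) 0-based half-open.
nRuns <- function(s) {
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Tandem-fill a monomer to an exact span
#'
#' Concatenates copies of \code{monomer} and truncates to exactly
#' \code{span} bp.
#'
#' @param monomer repeat unit
#' @param span target length in bp
#' @return DNA string of length \code{span}
#' @export
tandemFill <- function(monomer, span) {
  reps <- ceiling(span / nchar(monomer))
  substr(strrep(monomer, reps), 1L, span)
}

stopifnot_scalar <- function(x, nm) {
  if (length(x) != 1L || is.na(x)) stop(sprintf("%s must be a non-NA scalar", nm))
}
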