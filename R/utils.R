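#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement; handles upper/lower case A/C/G/T and
#' leaves other characters (e.g. N) unchanged apart from reversal.
#'
#' @param x a single character string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  chartr("ACGTacgt", "TGCAtgca", intToUtf8(rev(utf8ToInt(x))))
}

## Accept either a plain string or a reference_sequence object.
.seq_of <- function(x) {
  if (is.character(x) && length(x) == 1L) return(x)
  if (is.list(x) && !is.null(x$seq)) return(x$seq)
  stop("expected a nucleotide string or an object with a $seq field")
}

.name_of <- function(x, default = "seq") {
  if (is.list(x) && !is.null(x$name)) return(x$name)
  default
}

## Split a sequence into a character vector of single bases.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Fraction of bases inside homopolymer runs
#'
#' Computes the fraction of positions lying in maximal runs of identical
#' nucleotides of at least `min_run` bases, the composition statistic that
#' drives the elevated 454 error probability.
#'
#' @param seq nucleotide string or reference object.
#' @param min_run minimal run length counted (default 3).
#' @return a fraction in \[0, 1\].
#' @export
hp_run_fraction <- function(seq, min_run = 3L) {
  s <- .seq_of(seq)
  r <- rle(.chars(s))
  sum(r$lengths[r$lengths >= min_run]) / nchar(s)
}

#' GC fraction of a sequence
#'
#' @param seq nucleotide string or reference object.
#' @return fraction of G/C among A/C/G/T bases.
#' @export
gc_fraction <- function(seq) {
  s <- toupper(.seq_of(seq))
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_acgt <- nchar(gsub("[^ACGT]", "", s))
  if (n_acgt == 0L) stop("sequence contains no A/C/G/T bases")
  n_gc / n_acgt
}

## Count pairs (i < j) with v[i] > v[j], O(n log n) divide and conquer.
.count_inversions <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  mid <- n %/% 2L
  left <- v[seq_len(mid)]
  right <- v[(mid + 1L):n]
  cl <- .count_inversions(left)
  cr <- .count_inversions(right)
  sl <- sort(left)
  ## for each element of the right half, count left elements strictly greater
  cross <- sum(length(sl) - findInterval(right, sl))
  cl + cr + cross
}

## Draw integers from a normal clamped below at `lower` (censoring keeps the
## sample mean close to the nominal mean when the lower tail mass is small).
.rnorm_clamped <- function(n, mean, sd, lower) {
  pmax(as.integer(round(stats::rnorm(n, mean, sd))), as.integer(lower))
}

## Rejection-sample from a normal restricted to [lower, upper].
.rnorm_bounded <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  attempts <- 0L
  while (length(out) < n) {
    need <- n - length(out)
    x <- stats::rnorm(ceiling(need * 1.6) + 10L, mean, sd)
    x <- x[x >= lower & x <= upper]
    out <- c(out, x)
    attempts <- attempts + 1L
    if (attempts > 1000L) stop("bounds [", lower, ", ", upper,
                               "] too far from N(", mean, ", ", sd, ")")
  }
  round(out[seq_len(n)])
}
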