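#' Replace ambiguous bases (N) by frequency-matched draws
#'
#' Every N in the input is replaced by a base drawn with probability
#' proportional to that base's frequency in the non-N portion of the same
#' sequence. Non-N positions are untouched and the length is preserved, so the
#' prepared reference has no ambiguity codes left.
#'
#' @param seq nucleotide string possibly containing N (case-insensitive).
#' @return string of the same length over A/C/G/T.
#' @export
replace_ambiguous <- function(seq) {
  s <- .seq_of(seq)
  stopifnot(nchar(s) > 0L)
  ch <- .chars(toupper(s))
  is_n <- ch == "N"
  if (!any(is_n)) return(s)
  bases <- c("A", "C", "G", "T")
  freq <- tabulate(match(ch[!is_n], bases), nbins = 4L)
  if (sum(freq) == 0L) stop("all-N input: base frequencies cannot be estimated")
  ch[is_n] <- sample(bases, sum(is_n), replace = TRUE, prob = freq / sum(freq))
  paste(ch, collapse = "")
}

## iid background with no homopolymer run of length >= 3; base probabilities
## split GC mass between G/C and AT mass between A/T.
.background_no_runs <- function(length, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(p)
  ch <- sample(bases, length, replace = TRUE, prob = p)
  for (iter in 1:200) {
    if (length < 3L) break
    bad <- which(ch[-c(1L, 2L)] == ch[-c(1L, length)] &
                 ch[-c(1L, 2L)] == ch[seq_len(length - 2L)]) + 2L
    if (length(bad) == 0L) break
    ## resample the third base of each triple; any draw may still collide,
    ## so iterate until clean
    ch[bad] <- sample(bases, length(bad), replace = TRUE, prob = p)
    if (iter == 200L) stop("failed to remove homopolymer runs from background")
  }
  ch
}

## Nudge the base composition toward the target GC by flipping unprotected
## background bases between the AT and GC classes, never creating a
## homopolymer run of length >= 3. Run-free triple-fixing and run placement
## both bias GC slightly; this pass removes the bias.
.balance_gc <- function(ch, gc, protected) {
  n <- length(ch)
  gcset <- c("G", "C"); atset <- c("A", "T")
  for (round in 1:50) {
    cur <- sum(ch %in% gcset) / n
    delta <- round((cur - gc) * n)
    if (abs(delta) < max(2L, n %/% 5000L)) break
    from <- if (delta > 0L) gcset else atset
    toset <- if (delta > 0L) atset else gcset
    cand <- which(!protected & ch %in% from)
    if (length(cand) == 0L) break
    pick <- sort(sample(cand, min(abs(delta), length(cand))))
    ## keep picks >= 3 apart so safety checks stay independent
    if (length(pick) > 1L) pick <- pick[c(TRUE, diff(pick) >= 3L)]
    at <- function(i) ifelse(i >= 1L & i <= n, ch[pmax(pmin(i, n), 1L)], "")
    l1 <- at(pick - 1L); l2 <- at(pick - 2L)
    r1 <- at(pick + 1L); r2 <- at(pick + 2L)
    safe <- function(b) !((l1 == b & l2 == b) | (l1 == b & r1 == b) |
                          (r1 == b & r2 == b))
    b1 <- sample(toset, length(pick), replace = TRUE)
    b2 <- ifelse(b1 == toset[1L], toset[2L], toset[1L])
    use1 <- safe(b1)
    use2 <- !use1 & safe(b2)
    ch[pick[use1]] <- b1[use1]
    ch[pick[use2]] <- b2[use2]
  }
  ch
}

#' Generate a synthetic reference with controlled composition
#'
#' Builds a random reference sequence with a requested GC fraction, a
#' requested fraction of bases lying inside homopolymer runs of length >= 3,
#' and optional repeat families inserted verbatim at recorded positions. The
#' generator emulates the compositional spread of real plant genomes (GC
#' roughly 0.33-0.47, widely varying repeat content) so that simulators and
#' scores can be exercised without downloading any genome.
#'
#' Homopolymer runs are placed as disjoint, spaced blocks over a run-free
#' background, so the realised run fraction tracks the request closely
#' (within about 0.02 at lengths of 100 kbp and above, as is the GC target).
#'
#' @param length reference length in bases.
#' @param gc target GC fraction in (0, 1).
#' @param homopolymer_frac target fraction of bases in runs >= 3 (default 0).
#' @param repeat_spec optional list with fields `length`, `copies` (and
#'   optionally `unit`, a literal sequence) describing one repeat family to
#'   insert; copies are placed at evenly spread, recorded positions.
#' @param name sequence name.
#' @return an object of class `reference_sequence`: a list with `name`,
#'   `seq`, `length`, and `repeats` (data frame of inserted copies, if any).
#' @export
make_synthetic_reference <- function(length, gc = 0.4, homopolymer_frac = 0,
                                     repeat_spec = NULL, name = "synthetic") {
  stopifnot(length >= 1, gc > 0, gc < 1,
            homopolymer_frac >= 0, homopolymer_frac < 1)
  length <- as.integer(length)
  run_bases <- round(homopolymer_frac * length)
  if (run_bases > 0 && run_bases < 3)
    stop("homopolymer_frac too small to place a run of length 3")

  ch <- .background_no_runs(length, gc)

  if (run_bases > 0) {
    ## draw run lengths in 3..8 summing to the target
    lens <- integer(0)
    while (sum(lens) < run_bases)
      lens <- c(lens, sample(3:8, max(16L, ceiling(run_bases / 5)), replace = TRUE))
    lens <- lens[cumsum(lens) <= run_bases]
    if (sum(lens) < run_bases && run_bases - sum(lens) >= 3)
      lens <- c(lens, run_bases - sum(lens))
    k <- length(lens)
    ## each run needs its own bases plus one background base on each side
    if (sum(lens) + 2L * k > length)
      stop("homopolymer_frac infeasible at this length")
    gap_total <- length - sum(lens)
    starts <- cumsum(c(1L, lens[-k] + floor(gap_total / k)))
    bases <- c("A", "C", "G", "T")
    pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    for (r in seq_len(k)) {
      i0 <- starts[r]
      i1 <- i0 + lens[r] - 1L
      ## run base must differ from both flanking bases so the run stays maximal
      banned <- c(if (i0 > 1L) ch[i0 - 1L], if (i1 < length) ch[i1 + 1L])
      ok <- !(bases %in% banned)
      b <- sample(bases[ok], 1L, prob = pb[ok])
      ch[i0:i1] <- b
    }
  }

  protected <- logical(length)
  if (run_bases > 0) {
    for (r in seq_len(k)) {
      i0 <- max(1L, starts[r] - 1L)
      i1 <- min(length, starts[r] + lens[r])
      protected[i0:i1] <- TRUE
    }
  }
  ch <- .balance_gc(ch, gc, protected)

  seq <- paste(ch, collapse = "")
  repeats <- NULL
  if (!is.null(repeat_spec)) {
    unit <- repeat_spec$unit
    if (is.null(unit))
      unit <- paste(.background_no_runs(repeat_spec$length, gc), collapse = "")
    L <- nchar(unit)
    copies <- repeat_spec$copies
    if (copies * L > length) stop("repeat copies do not fit in the reference")
    starts <- floor(seq(1, length - L + 1, length.out = copies))
    ## nudge copies apart if the spread makes them overlap
    if (copies > 1L && any(diff(starts) < L))
      stop("repeat copies would overlap at this length")
    for (s0 in starts) substr(seq, s0, s0 + L - 1L) <- unit
    repeats <- data.frame(start = starts, end = starts + L - 1L,
                          length = L, unit_id = 1L)
  }

  structure(list(name = name, seq = seq, length = length, repeats = repeats),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("reference_sequence '%s': %d bp, GC %.3f, hp-run fraction %.3f\n",
              x$name, x$length, gc_fraction(x), hp_run_fraction(x)))
  invisible(x)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
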