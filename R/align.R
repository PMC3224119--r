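#' Parse BLAST tabular (outfmt 6) alignments into match intervals
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) with the reference as
#' query and the assembly as subject. Rows whose alignment length is below
#' `min_len` are dropped (only hits of at least 1 kbp inform the scores, by
#' default). Subject coordinates given in descending order are normalised to
#' an ascending interval on the minus strand.
#'
#' @param path TSV file of BLAST hits.
#' @param min_len minimum alignment length kept (default 1000).
#' @return a data frame of match intervals: ref_start, ref_end, asm_start,
#'   asm_end, strand, identity, length.
#' @export
parse_blast_tab <- function(path, min_len = 1000L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_matches())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed BLAST tabular row at line ", which(nf != 12L)[1L],
         ": expected 12 columns, found ", nf[nf != 12L][1L])
  m <- do.call(rbind, fields)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("malformed BLAST tabular row at line ", which(is.na(v))[1L],
           ": non-numeric value in column ", j)
    v
  }
  pident <- num(3L); alen <- num(4L)
  qs <- num(7L); qe <- num(8L); ss <- num(9L); se <- num(10L)
  rev_s <- ss > se
  out <- data.frame(
    ref_start = as.integer(pmin(qs, qe)),
    ref_end = as.integer(pmax(qs, qe)),
    asm_start = as.integer(pmin(ss, se)),
    asm_end = as.integer(pmax(ss, se)),
    strand = ifelse(rev_s, "-", "+"),
    identity = pident,
    stringsAsFactors = FALSE)
  out$length <- out$ref_end - out$ref_start + 1L
  out[alen >= min_len, , drop = FALSE]
}

#' @rdname parse_blast_tab
#' @export
empty_matches <- function() {
  data.frame(ref_start = integer(0), ref_end = integer(0),
             asm_start = integer(0), asm_end = integer(0),
             strand = character(0), identity = numeric(0),
             length = integer(0), stringsAsFactors = FALSE)
}

#' Filter match intervals by length
#'
#' @param matches match-interval data frame.
#' @param min_len minimum reference span kept.
#' @return the filtered data frame.
#' @export
filter_matches <- function(matches, min_len = 1000L) {
  matches[matches$ref_end - matches$ref_start + 1L >= min_len, , drop = FALSE]
}

## k-mer starts of a string as a character vector
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

## maximal exact diagonal runs (length >= k) between two char vectors,
## restricted to diagonals holding at least one anchor pair (i, j); a run is
## reported when it contains an anchor
.diagonal_runs <- function(refc, asmc, anchors_i, anchors_j, k) {
  nr <- length(refc); na <- length(asmc)
  d <- anchors_j - anchors_i
  res <- list()
  for (dd in unique(d)) {
    i0 <- max(1L, 1L - dd)
    i1 <- min(nr, na - dd)
    if (i1 - i0 + 1L < k) next
    eq <- refc[i0:i1] == asmc[(i0 + dd):(i1 + dd)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ai <- anchors_i[d == dd]
    for (t in which(r$values & r$lengths >= k)) {
      rs <- i0 + starts[t] - 1L
      re <- i0 + ends[t] - 1L
      if (!any(ai >= rs & ai <= re - k + 1L)) next
      res[[length(res) + 1L]] <- c(rs, re, rs + dd, re + dd)
    }
  }
  if (length(res) == 0L) return(NULL)
  unique(do.call(rbind, res))
}

#' Exact anchor matcher (test-scale alternative to BLAST)
#'
#' Finds maximal exact matches between a reference and an assembly, anchored
#' by k-mers that occur exactly once in each sequence, extended to maximal
#' exact runs along their diagonal. Minus-strand matches are found on the
#' reverse complement of the assembly. Identity is 100 by construction.
#' Intended for simulated fixtures up to a few hundred kbp; real data should
#' come through [parse_blast_tab()].
#'
#' @param reference reference sequence or object.
#' @param assembly assembly sequence (string).
#' @param k anchor length (>= 12, default 20).
#' @return match-interval data frame as in [parse_blast_tab()] (unfiltered;
#'   apply [filter_matches()] before scoring).
#' @export
anchor_match <- function(reference, assembly, k = 20L) {
  stopifnot(k >= 12L)
  ref <- toupper(.seq_of(reference))
  asm <- toupper(.seq_of(assembly))
  refc <- .chars(ref)
  rkm <- .kmers(ref, k)
  runq <- !(duplicated(rkm) | duplicated(rkm, fromLast = TRUE))

  one_strand <- function(asm_s) {
    akm <- .kmers(asm_s, k)
    ## anchors are k-mers unique in the reference; assembly copies of such a
    ## k-mer each anchor their own diagonal, so duplications are still found
    hit <- match(akm, ifelse(runq, rkm, NA_character_))
    j <- which(!is.na(hit))
    if (length(j) == 0L) return(NULL)
    .diagonal_runs(refc, .chars(asm_s), hit[j], j, k)
  }

  fw <- one_strand(asm)
  rcruns <- one_strand(revcomp(asm))
  na <- nchar(asm)
  rows <- list()
  if (!is.null(fw))
    rows[[1L]] <- data.frame(ref_start = fw[, 1L], ref_end = fw[, 2L],
                             asm_start = fw[, 3L], asm_end = fw[, 4L],
                             strand = "+", stringsAsFactors = FALSE)
  if (!is.null(rcruns))
    rows[[length(rows) + 1L]] <- data.frame(
      ref_start = rcruns[, 1L], ref_end = rcruns[, 2L],
      asm_start = na - rcruns[, 4L] + 1L, asm_end = na - rcruns[, 3L] + 1L,
      strand = "-", stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  out <- unique(out)
  out$identity <- 100
  out$length <- out$ref_end - out$ref_start + 1L
  out <- out[order(out$ref_start, out$asm_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## interpolate assembly coordinates for reference positions of one interval
.interp_j <- function(is, iv) {
  Lr <- iv$ref_end - iv$ref_start
  La <- iv$asm_end - iv$asm_start
  off <- if (Lr == 0L) rep(0L, length(is)) else
    as.integer(round((is - iv$ref_start) * (La / Lr)))
  as.integer(if (iv$strand == "+") iv$asm_start + off else iv$asm_end - off)
}

## coerce interval coordinates to integers once, before table construction
.int_matches <- function(matches) {
  for (col in c("ref_start", "ref_end", "asm_start", "asm_end"))
    matches[[col]] <- as.integer(matches[[col]])
  matches
}

#' Build the reference match table T
#'
#' For each reference position i covered by at least one match interval,
#' T\[i\] holds the closest matching assembly coordinate j (linear
#' interpolation within each interval); minus-strand matches are stored as
#' -j, and uncovered positions as 0. When several intervals cover i, the
#' candidate minimising |i - j| wins; ties go to the smaller |j|, then the
#' smaller j.
#'
#' @param matches match-interval data frame.
#' @param n reference length.
#' @return a `match_table`: list with `T` (integer vector of length n),
#'   `n`, and `l` (number of nonzero entries).
#' @export
build_match_table <- function(matches, n) {
  n <- as.integer(n)
  matches <- .int_matches(matches)
  Tv <- integer(n)
  best_d <- rep(Inf, n)
  if (nrow(matches) > 0L) {
    if (any(matches$ref_end > n | matches$ref_start < 1L))
      stop("match interval outside the reference")
    for (r in seq_len(nrow(matches))) {
      iv <- matches[r, ]
      is <- iv$ref_start:iv$ref_end
      js <- .interp_j(is, iv)
      cand <- if (iv$strand == "+") js else -js
      d <- abs(is - js)
      old <- Tv[is]
      take <- d < best_d[is] |
        (d == best_d[is] & (abs(cand) < abs(old) |
                            (abs(cand) == abs(old) & cand < old)))
      if (any(take)) {
        Tv[is[take]] <- cand[take]
        best_d[is[take]] <- d[take]
      }
    }
  }
  structure(list(T = Tv, n = n, l = sum(Tv != 0L)), class = "match_table")
}

#' Build the assembly table U
#'
#' Symmetric to [build_match_table()]: U\[j\] is the closest matching
#' reference position for each assembly position j, and 0 where the
#' assembly is unmatched (including spacer X/N content, which the matchers
#' can never align).
#'
#' @param matches match-interval data frame.
#' @param m assembly length.
#' @return an `assembly_table`: list with `U` (integer vector of length m)
#'   and `m`.
#' @export
build_assembly_table <- function(matches, m) {
  m <- as.integer(m)
  matches <- .int_matches(matches)
  U <- integer(m)
  best_d <- rep(Inf, m)
  if (nrow(matches) > 0L) {
    if (any(matches$asm_end > m | matches$asm_start < 1L))
      stop("match interval outside the assembly")
    for (r in seq_len(nrow(matches))) {
      iv <- matches[r, ]
      js <- iv$asm_start:iv$asm_end
      Lr <- iv$ref_end - iv$ref_start
      La <- iv$asm_end - iv$asm_start
      off <- if (La == 0L) rep(0L, length(js)) else
        as.integer(round((js - iv$asm_start) * (Lr / La)))
      is <- as.integer(if (iv$strand == "+") iv$ref_start + off
                       else iv$ref_end - off)
      d <- abs(is - js)
      old <- U[js]
      take <- d < best_d[js] |
        (d == best_d[js] & (old == 0L | is < old))
      if (any(take)) {
        U[js[take]] <- is[take]
        best_d[js[take]] <- d[take]
      }
    }
  }
  structure(list(U = U, m = m), class = "assembly_table")
}

#' Dot-plot segments from match intervals
#'
#' Returns the intervals as plot-ready segments sorted by reference start,
#' labelled "forward" (correct orientation) or "reversed". Lossless: one
#' segment per input interval.
#'
#' @param matches match-interval data frame.
#' @return data frame: ref_start, ref_end, asm_start, asm_end, orientation.
#' @export
dotplot_segments <- function(matches) {
  out <- matches[order(matches$ref_start, matches$asm_start),
                 c("ref_start", "ref_end", "asm_start", "asm_end", "strand"),
                 drop = FALSE]
  out$orientation <- ifelse(out$strand == "+", "forward", "reversed")
  out$strand <- NULL
  rownames(out) <- NULL
  out
}

#' Write match intervals or dot-plot segments as TSV
#'
#' @param x data frame from [anchor_match()], [parse_blast_tab()] or
#'   [dotplot_segments()].
#' @param path output TSV; a header comment states that coordinates are
#'   1-based inclusive.
#' @export
write_match_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates 1-based inclusive", con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
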