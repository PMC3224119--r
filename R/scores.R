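#' Parameters of the match score
#'
#' The match score rewards long contiguous matching segments and penalises
#' gaps. Matching and gap segment lengths enter as (|u|/n)^eta1 and
#' (|v|/n)^eta2 with weights alpha and beta. Two variants are available:
#' `"complement-gap"` (default) scores
#' (alpha * sum(u^eta1) + beta * (1 - sum(v^eta2))) / (alpha + beta), so a
#' single full-length match scores 1 and an all-gap table scores 0; the
#' `"literal"` variant adds the gap term instead of its complement,
#' (alpha * sum(u^eta1) + beta * sum(v^eta2)) / (alpha + beta).
#'
#' @param alpha match weight (> 0, default 1).
#' @param beta gap weight (> 0, default 1).
#' @param eta1,eta2 exponents (>= 1, default 2).
#' @param variant "complement-gap" (default) or "literal".
#' @return a `match_score_params` object.
#' @export
match_score_params <- function(alpha = 1, beta = 1, eta1 = 2, eta2 = 2,
                               variant = c("complement-gap", "literal")) {
  stopifnot(alpha > 0, beta > 0, eta1 >= 1, eta2 >= 1)
  structure(list(alpha = alpha, beta = beta, eta1 = eta1, eta2 = eta2,
                 variant = match.arg(variant)),
            class = "match_score_params")
}

## Segment the match table into matching and gap segments. Matching
## segments additionally break where the mapping is discontinuous (signed
## step outside 0..2 or a strand flip), so two abutting hits that map to
## distant assembly locations do not masquerade as one long match.
.segment_table <- function(Tv) {
  n <- length(Tv)
  nz <- Tv != 0L
  if (n == 0L) return(list(u = integer(0), v = integer(0)))
  step <- diff(Tv)
  brk <- c(FALSE, nz[-1L] & nz[-n] &
             (step < 0L | step > 2L | (sign(Tv[-1L]) != sign(Tv[-n]))))
  grp <- cumsum(c(TRUE, nz[-1L] != nz[-n]) | brk)
  lens <- tabulate(grp)
  vals <- nz[!duplicated(grp)]
  list(u = lens[vals], v = lens[!vals])
}

#' Match score M
#'
#' @param table a `match_table` from [build_match_table()].
#' @param params a [match_score_params()].
#' @return score in \[0, 1\].
#' @export
match_score <- function(table, params = match_score_params()) {
  n <- table$n
  if (n == 0L) stop("empty reference")
  seg <- .segment_table(table$T)
  su <- sum((seg$u / n)^params$eta1)
  sv <- sum((seg$v / n)^params$eta2)
  gap_term <- if (params$variant == "literal") sv else 1 - sv
  (params$alpha * su + params$beta * gap_term) / (params$alpha + params$beta)
}

#' Relocation score RL
#'
#' Detects pairs of positions assembled in the wrong order. The match table
#' is sampled systematically, one point every n/x positions; unmatched
#' (zero) entries are skipped. For the x' retained points, every unordered
#' pair whose |T| magnitudes decrease while the positions increase is a
#' disagreement counted for both endpoints, giving #d out of
#' p = x'^2 - x' possible, and RL = 1 - #d / p. Magnitudes are compared
#' (inversions are penalised by the inversion score, not here); equal
#' magnitudes do not disagree. RL = 1 when fewer than two points remain.
#'
#' @param table a `match_table`.
#' @param x number of sample locations (default 10000).
#' @return score in \[0, 1\].
#' @export
relocation_score <- function(table, x = 10000L) {
  stopifnot(x >= 2L)
  n <- table$n
  idx <- unique(as.integer(floor((seq_len(min(x, n)) - 1L) * (n / min(x, n)))) + 1L)
  v <- abs(table$T[idx])
  v <- v[v > 0L]
  xp <- length(v)
  if (xp < 2L) return(1)
  nd <- 2 * .count_inversions(v)
  p <- as.numeric(xp)^2 - xp
  1 - nd / p
}

#' Inversion score I
#'
#' Fraction of matched reference positions whose match lies on the forward
#' strand of the assembly: I = 1 - #(T < 0) / l, and 1 vacuously when
#' nothing is matched.
#'
#' @param table a `match_table`.
#' @return score in \[0, 1\].
#' @export
inversion_score <- function(table) {
  if (table$l == 0L) return(1)
  1 - sum(table$T < 0L) / table$l
}

#' Redundancy score RD
#'
#' Penalises unnecessary assembly content: reference positions hit exactly
#' once among the nonzero entries of U count as unique, useful content, and
#' RD = #unique / m. Duplicated regions and unmatched assembly sequence both
#' lower the score.
#'
#' @param table an `assembly_table` from [build_assembly_table()].
#' @return score in \[0, 1\].
#' @export
redundancy_score <- function(table) {
  stopifnot(table$m > 0L)
  u <- table$U[table$U > 0L]
  if (length(u) == 0L) return(0)
  tab <- tabulate(u)
  sum(tab == 1L) / table$m
}

#' Coverage score C
#'
#' Fraction of reference positions with a match: C = l / n.
#'
#' @param table a `match_table`.
#' @return score in \[0, 1\].
#' @export
coverage_score <- function(table) {
  stopifnot(table$n > 0L)
  table$l / table$n
}

#' Score an assembly against a reference
#'
#' Builds the match table T and assembly table U from the supplied match
#' intervals (which should already be length-filtered, see
#' [filter_matches()]), computes the five correctness scores and the
#' combined sum used to rank assemblies.
#'
#' @param reference reference sequence, object, or its length in bases.
#' @param assembly assembly sequence or its length in bases.
#' @param matches match-interval data frame.
#' @param params match score parameters.
#' @param reloc_samples sample count for the relocation score.
#' @return a `score_report`: list with match, relocation, inversion,
#'   redundancy, coverage, combined, coverage_pct, n, m, l.
#' @export
score_assembly <- function(reference, assembly, matches,
                           params = match_score_params(),
                           reloc_samples = 10000L) {
  n <- if (is.numeric(reference)) as.integer(reference) else nchar(.seq_of(reference))
  m <- if (is.numeric(assembly)) as.integer(assembly) else nchar(.seq_of(assembly))
  tt <- build_match_table(matches, n)
  uu <- build_assembly_table(matches, m)
  sc <- list(match = match_score(tt, params),
             relocation = relocation_score(tt, reloc_samples),
             inversion = inversion_score(tt),
             redundancy = redundancy_score(uu),
             coverage = coverage_score(tt))
  sc$combined <- sc$match + sc$relocation + sc$inversion +
    sc$redundancy + sc$coverage
  sc$coverage_pct <- 100 * sc$coverage
  sc$n <- n; sc$m <- m; sc$l <- tt$l
  structure(sc, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(paste0(
    "assembly score report (reference %d bp, assembly %d bp)\n",
    "  match      M  = %.3f\n  relocation RL = %.3f\n  inversion  I  = %.3f\n",
    "  redundancy RD = %.3f\n  coverage   C  = %.3f (%.2f%%)\n",
    "  combined      = %.3f\n"),
    x$n, x$m, x$match, x$relocation, x$inversion, x$redundancy,
    x$coverage, x$coverage_pct, x$combined))
  invisible(x)
}

#' Write a score report as TSV or JSON
#'
#' @param x a `score_report`.
#' @param path output path.
#' @param format "tsv" or "json".
#' @export
write_score_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  vals <- x[c("match", "relocation", "inversion", "redundancy",
              "coverage", "combined", "coverage_pct")]
  if (format == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(data.frame(score = names(vals),
                                  value = unlist(vals)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Corrupt a reference into a misassembled fixture
#'
#' Applies structural edits to a copy of the reference and returns both the
#' corrupted "assembly" and a truth record of the expected score effects.
#' Supported edits (spans are 1-based inclusive on the reference and must
#' not overlap):
#' \itemize{
#'   \item `invert`: reverse-complement the span in place;
#'   \item `delete`: remove the span;
#'   \item `duplicate`: append a copy of the span at the end;
#'   \item `relocate`: move the span to the end.
#' }
#' The truth record includes the segment-level correspondence between the
#' reference and the corrupted assembly, usable directly as match intervals.
#'
#' @param reference reference sequence or object.
#' @param edits list of edits, each a list(op=, start=, end=).
#' @return list with `assembly` (string), `truth` (inverted_frac,
#'   deleted_frac, duplicated_frac, relocated_frac) and `segments`
#'   (match-interval data frame of the surviving correspondence).
#' @export
corrupt_assembly <- function(reference, edits = list()) {
  s <- .seq_of(reference)
  n <- nchar(s)
  if (length(edits)) {
    sp <- vapply(edits, function(e) c(e$start, e$end), numeric(2))
    stopifnot(all(sp[1, ] >= 1), all(sp[2, ] <= n), all(sp[1, ] <= sp[2, ]))
    o <- order(sp[1, ])
    if (any(sp[1, o][-1L] <= sp[2, o][-ncol(sp)]))
      stop("overlapping edit spans")
    edits <- edits[o]
  }
  ## cut the reference into pieces at edit boundaries
  bounds <- sort(unique(c(1L, n + 1L,
                          unlist(lapply(edits, function(e)
                            c(e$start, e$end + 1L))))))
  piece <- data.frame(start = bounds[-length(bounds)],
                      end = bounds[-1L] - 1L)
  piece <- piece[piece$end >= piece$start, ]
  piece$op <- "keep"
  for (e in edits)
    piece$op[piece$start == e$start & piece$end == e$end] <- e$op

  body <- piece[piece$op != "delete" & piece$op != "relocate", , drop = FALSE]
  tail_ops <- piece[piece$op %in% c("relocate"), , drop = FALSE]
  dups <- piece[piece$op == "duplicate", , drop = FALSE]

  seg <- list(); parts <- character(0); cursor <- 0L
  emit <- function(st, en, strand) {
    len <- en - st + 1L
    sq <- substring(s, st, en)
    if (strand == "-") sq <- revcomp(sq)
    parts[[length(parts) + 1L]] <<- sq
    seg[[length(seg) + 1L]] <<- data.frame(
      ref_start = st, ref_end = en,
      asm_start = cursor + 1L, asm_end = cursor + len,
      strand = strand, identity = 100, length = len,
      stringsAsFactors = FALSE)
    cursor <<- cursor + len
  }
  for (r in seq_len(nrow(body)))
    emit(body$start[r], body$end[r],
         if (body$op[r] == "invert") "-" else "+")
  for (r in seq_len(nrow(tail_ops)))
    emit(tail_ops$start[r], tail_ops$end[r], "+")
  for (r in seq_len(nrow(dups)))
    emit(dups$start[r], dups$end[r], "+")

  frac <- function(op) {
    p <- piece[piece$op == op, , drop = FALSE]
    sum(p$end - p$start + 1) / n
  }
  list(assembly = paste(unlist(parts), collapse = ""),
       truth = list(inverted_frac = frac("invert"),
                    deleted_frac = frac("delete"),
                    duplicated_frac = frac("duplicate"),
                    relocated_frac = frac("relocate")),
       segments = do.call(rbind, seg))
}
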