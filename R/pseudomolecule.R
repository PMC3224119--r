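#' Filter scaffold-vs-BES hits
#'
#' Keeps hits with E-value at most `max_e` and percent identity at least
#' `min_pid` (defaults E <= 1e-75, identity >= 98, the stringency used to
#' anchor scaffolds to the MTP BES set).
#'
#' @param hits data frame with at least `evalue` and `pident` columns.
#' @param max_e maximum E-value kept.
#' @param min_pid minimum percent identity kept.
#' @return the filtered data frame.
#' @export
filter_bes_hits <- function(hits, max_e = 1e-75, min_pid = 98) {
  hits[hits$evalue <= max_e & hits$pident >= min_pid, , drop = FALSE]
}

#' Order and orient scaffolds along the MTP from BES hits
#'
#' Each scaffold is keyed by the smallest MTP ordinal (`order_index`) among
#' its BES hits — its "first" BES — and scaffolds are sorted by that key.
#' Orientation is forward when the scaffold position of its first-ordinal
#' BES does not exceed that of its last-ordinal BES, reversed otherwise;
#' a scaffold with a single hit defaults to forward. Scaffolds without any
#' hit are reported as unplaced. Key ties are broken by the second-smallest
#' ordinal, then the scaffold name, with a warning.
#'
#' @param hits filtered data frame with columns `scaffold`, `bes_id`,
#'   `scaffold_pos`, and `order_index` (joinable from `bes_order`).
#' @param bes_order optional data frame (`bes_id`, `order_index`) used to
#'   fill in ordinals when `hits` lacks an `order_index` column.
#' @param scaffolds optional character vector of all scaffold names, used to
#'   report unplaced scaffolds.
#' @return a `scaffold_layout`: list with `layout` (data frame: scaffold,
#'   orientation, key), `unplaced`, `gap_char` ("X"), `gap_len` (70).
#' @export
order_scaffolds <- function(hits, bes_order = NULL, scaffolds = NULL) {
  if (is.null(hits$order_index)) {
    if (is.null(bes_order)) stop("hits lack order_index and no bes_order given")
    hits$order_index <- bes_order$order_index[match(hits$bes_id,
                                                    bes_order$bes_id)]
    if (anyNA(hits$order_index)) stop("BES id missing from bes_order")
  }
  per <- lapply(split(hits, hits$scaffold), function(d) {
    d <- d[order(d$order_index), , drop = FALSE]
    key <- d$order_index[1L]
    key2 <- if (nrow(d) > 1L) d$order_index[2L] else Inf
    ori <- if (nrow(d) < 2L) "+" else {
      first_pos <- d$scaffold_pos[1L]
      last_pos <- d$scaffold_pos[nrow(d)]
      if (first_pos <= last_pos) "+" else "-"
    }
    data.frame(scaffold = d$scaffold[1L], orientation = ori,
               key = key, key2 = key2, stringsAsFactors = FALSE)
  })
  lay <- do.call(rbind, per)
  if (any(duplicated(lay$key)))
    warning("scaffolds share an identical first-BES ordinal; ",
            "tie broken by second ordinal, then name")
  lay <- lay[order(lay$key, lay$key2, lay$scaffold), , drop = FALSE]
  rownames(lay) <- NULL
  unplaced <- character(0)
  if (!is.null(scaffolds))
    unplaced <- setdiff(scaffolds, lay$scaffold)
  structure(list(layout = lay[, c("scaffold", "orientation", "key")],
                 unplaced = unplaced, gap_char = "X", gap_len = 70L),
            class = "scaffold_layout")
}

#' Concatenate placed scaffolds into a gapped pseudomolecule
#'
#' Scaffolds are reverse-complemented where the layout orientation is "-"
#' and joined in layout order with exactly 70 X characters between
#' consecutive scaffolds (no leading or trailing spacer).
#'
#' @param layout a `scaffold_layout` from [order_scaffolds()].
#' @param scaffolds named character vector of scaffold sequences.
#' @return the pseudomolecule sequence (string).
#' @export
concat_with_gaps <- function(layout, scaffolds) {
  lay <- layout$layout
  miss <- setdiff(lay$scaffold, names(scaffolds))
  if (length(miss)) stop("missing sequence for scaffold: ", miss[1L])
  seqs <- scaffolds[lay$scaffold]
  rc <- lay$orientation == "-"
  if (any(rc)) seqs[rc] <- vapply(seqs[rc], revcomp, character(1),
                                  USE.NAMES = FALSE)
  paste(seqs, collapse = strrep(layout$gap_char, layout$gap_len))
}

#' Write a scaffold layout and its unplaced list
#'
#' @param layout a `scaffold_layout`.
#' @param path layout TSV path; unplaced names go to `<path>.unplaced`.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout$layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(layout$unplaced, paste0(path, ".unplaced"))
  invisible(path)
}

#' Locate BES in scaffolds by exact search
#'
#' Test-scale stand-in for BLASTN of scaffolds against a BES set: each BES
#' is searched for exactly in each scaffold on both strands. Hits are
#' reported with E-value 0 and identity 100, ready for
#' [filter_bes_hits()] and [order_scaffolds()].
#'
#' @param bes a `sim_bes` object or data frame with `id` and `seq`.
#' @param scaffolds named character vector of scaffold sequences.
#' @return data frame: scaffold, bes_id, scaffold_pos, evalue, pident,
#'   order_index (if available).
#' @export
match_bes_exact <- function(bes, scaffolds) {
  bt <- if (inherits(bes, "sim_bes")) bes$bes else bes
  rows <- list()
  for (sc in names(scaffolds)) {
    subj <- scaffolds[[sc]]
    for (r in seq_len(nrow(bt))) {
      for (query in c(bt$seq[r], revcomp(bt$seq[r]))) {
        p <- regexpr(query, subj, fixed = TRUE)
        if (p > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            scaffold = sc, bes_id = bt$id[r], scaffold_pos = as.integer(p),
            evalue = 0, pident = 100,
            order_index = if (!is.null(bt$order_index)) bt$order_index[r]
                          else NA_integer_,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(scaffold = character(0), bes_id = character(0),
                      scaffold_pos = integer(0), evalue = numeric(0),
                      pident = numeric(0), order_index = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
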