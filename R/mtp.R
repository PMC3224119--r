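#' Build a minimum tiling path (MTP) of BAC clones over a reference
#'
#' Clone sizes and pairwise overlaps are drawn from normal distributions
#' restricted to the printed bounds of a real rice tiling path: sizes
#' 47-191 kbp with mean about 145 kbp, overlaps 0.6-113 kbp with mean about
#' 36 kbp. A single template layout covering `template_span` bases is drawn
#' once and then repeated (shifted) as many times as needed, so larger
#' regions reuse the same MTP structure, and the final clone is clipped to
#' the reference end.
#'
#' @param reference a reference sequence/object, or a bare length in bases.
#' @param clone_min,clone_max,clone_mean,clone_sd clone size bounds and
#'   distribution (bases).
#' @param overlap_min,overlap_max,overlap_mean,overlap_sd clone-to-clone
#'   overlap bounds and distribution (bases).
#' @param template_span span covered by one template layout before it repeats
#'   (default 3 Mbp, the canonical pool size).
#' @return an object of class `mtp`: a data frame with columns `index`,
#'   `ref_start`, `ref_end`, `size` (1-based inclusive), with the covered
#'   span as attribute `span`.
#' @export
build_mtp <- function(reference,
                      clone_min = 47000, clone_max = 191000,
                      clone_mean = 145000, clone_sd = 35000,
                      overlap_min = 600, overlap_max = 113000,
                      overlap_mean = 36000, overlap_sd = 25000,
                      template_span = 3e6) {
  n <- if (is.numeric(reference)) as.integer(reference) else nchar(.seq_of(reference))
  if (n < clone_max)
    stop("reference (", n, " bp) shorter than the maximum clone size")
  span <- min(n, template_span)

  ## one template layout
  est <- ceiling(span / (clone_mean - overlap_mean)) + 8L
  sizes <- .rnorm_bounded(est, clone_mean, clone_sd, clone_min, clone_max)
  overlaps <- .rnorm_bounded(est - 1L, overlap_mean, overlap_sd,
                             overlap_min, overlap_max)
  overlaps <- pmin(overlaps, sizes[-est] - 1L)  # keep starts advancing
  starts <- cumsum(c(1, sizes[-est] - overlaps))
  ends <- starts + sizes - 1L
  last <- which(ends >= span)[1L]
  if (is.na(last)) last <- est
  tmpl <- data.frame(ref_start = starts[seq_len(last)],
                     ref_end = ends[seq_len(last)],
                     size = sizes[seq_len(last)])

  ## repeat the template until the reference is covered; successive copies
  ## are shifted so that the junction overlap equals the mean overlap
  out <- tmpl
  while (out$ref_end[nrow(out)] < n) {
    nxt <- tmpl
    off <- out$ref_end[nrow(out)] - overlap_mean
    nxt$ref_start <- nxt$ref_start + off
    nxt$ref_end <- nxt$ref_end + off
    out <- rbind(out, nxt[nxt$ref_start <= n, , drop = FALSE])
    if (nrow(nxt[nxt$ref_start <= n, , drop = FALSE]) == 0L) break
  }
  out <- out[out$ref_start <= n - clone_min + 1L, , drop = FALSE]
  ## clip the tail clone to the reference end, widening leftwards if the
  ## clipped clone would fall below the minimum size
  out$ref_end <- pmin(out$ref_end, n)
  lastr <- nrow(out)
  if (out$ref_end[lastr] - out$ref_start[lastr] + 1L < clone_min)
    out$ref_start[lastr] <- out$ref_end[lastr] - clone_min + 1L
  out$size <- out$ref_end - out$ref_start + 1L
  out$index <- seq_len(nrow(out))
  out <- out[, c("index", "ref_start", "ref_end", "size")]
  rownames(out) <- NULL
  structure(out, class = c("mtp", "data.frame"),
            span = out$ref_end[nrow(out)] - out$ref_start[1L] + 1L,
            template_clones = nrow(tmpl))
}

#' Partition an MTP into pools of approximately a target span
#'
#' Clones are accumulated greedily in MTP order; a pool closes as soon as its
#' span (first clone start to last clone end) first reaches the target.
#' Clones are atomic: a pool boundary never splits a clone. A trailing
#' remainder pool smaller than half the target is merged into the previous
#' pool.
#'
#' @param mtp an `mtp` object from [build_mtp()].
#' @param target target pool span in bases (default 3 Mbp).
#' @return the clone table with an added `pool` column; pool spans are in
#'   attribute `pools` (data frame pool/start/end/span).
#' @export
partition_pools <- function(mtp, target = 3e6) {
  if (nrow(mtp) == 0L) stop("empty MTP")
  if (target < max(mtp$size)) stop("target smaller than the largest clone")
  pool <- integer(nrow(mtp))
  p <- 1L
  pstart <- mtp$ref_start[1L]
  for (i in seq_len(nrow(mtp))) {
    pool[i] <- p
    if (mtp$ref_end[i] - pstart + 1L >= target && i < nrow(mtp)) {
      p <- p + 1L
      pstart <- mtp$ref_start[i + 1L]
    }
  }
  ## merge a short trailing remainder into the previous pool
  if (p > 1L) {
    lastspan <- max(mtp$ref_end[pool == p]) - min(mtp$ref_start[pool == p]) + 1L
    if (lastspan < target / 2) pool[pool == p] <- p - 1L
  }
  mtp$pool <- pool
  spans <- do.call(rbind, lapply(split(mtp, mtp$pool), function(d) {
    data.frame(pool = d$pool[1L], start = min(d$ref_start),
               end = max(d$ref_end))
  }))
  spans$span <- spans$end - spans$start + 1L
  rownames(spans) <- NULL
  structure(mtp, class = c("mtp", "data.frame"), pools = spans,
            span = attr(mtp, "span"))
}

#' Extract one pool's sequence from a reference
#'
#' @param reference reference sequence or object.
#' @param pooled clone table from [partition_pools()].
#' @param pool pool index.
#' @return a `reference_sequence` covering the pool span.
#' @export
pool_sequence <- function(reference, pooled, pool) {
  spans <- attr(pooled, "pools")
  row <- spans[spans$pool == pool, , drop = FALSE]
  if (nrow(row) != 1L) stop("no such pool: ", pool)
  s <- substring(.seq_of(reference), row$start, row$end)
  structure(list(name = paste0(.name_of(reference), "_pool", pool),
                 seq = s, length = nchar(s), repeats = NULL,
                 offset = row$start),
            class = "reference_sequence")
}

#' Write an MTP/pool layout as a BED-like TSV
#'
#' Columns: name, start, end, clone index and (if present) pool index;
#' coordinates are 1-based inclusive, stated in the header comment.
#'
#' @param mtp clone table from [build_mtp()] or [partition_pools()].
#' @param path output file.
#' @param name reference name used in the first column.
#' @export
write_mtp_layout <- function(mtp, path, name = "ref") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# MTP layout; coordinates 1-based inclusive", con)
  d <- data.frame(name = name, start = mtp$ref_start, end = mtp$ref_end,
                  clone = mtp$index)
  if (!is.null(mtp$pool)) d$pool <- mtp$pool
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
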