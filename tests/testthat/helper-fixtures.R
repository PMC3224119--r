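# Shared fixtures and independent oracles for the suite.

# fast iid random sequence (no composition control)
rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Brute-force exact matcher: all maximal diagonal runs of length >= k,
# both strands, scanning every diagonal. Quadratic; oracle only.
brute_matches <- function(ref, asm, k) {
  refc <- strsplit(ref, "")[[1]]
  one <- function(asmc) {
    nr <- length(refc); na <- length(asmc)
    res <- list()
    for (dd in (1L - nr):(na - 1L)) {
      i0 <- max(1L, 1L - dd); i1 <- min(nr, na - dd)
      if (i1 - i0 + 1L < k) next
      eq <- refc[i0:i1] == asmc[(i0 + dd):(i1 + dd)]
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (t in which(r$values & r$lengths >= k)) {
        rs <- i0 + starts[t] - 1L; re <- i0 + ends[t] - 1L
        res[[length(res) + 1L]] <- c(rs, re, rs + dd, re + dd)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  fw <- one(strsplit(asm, "")[[1]])
  na <- nchar(asm)
  rv <- one(strsplit(revcomp(asm), "")[[1]])
  rows <- list()
  if (!is.null(fw))
    rows[[1]] <- data.frame(ref_start = fw[, 1], ref_end = fw[, 2],
                            asm_start = fw[, 3], asm_end = fw[, 4],
                            strand = "+", stringsAsFactors = FALSE)
  if (!is.null(rv))
    rows[[length(rows) + 1]] <- data.frame(
      ref_start = rv[, 1], ref_end = rv[, 2],
      asm_start = na - rv[, 4] + 1, asm_end = na - rv[, 3] + 1,
      strand = "-", stringsAsFactors = FALSE)
  if (!length(rows))
    return(empty_matches()[, c("ref_start", "ref_end", "asm_start",
                               "asm_end", "strand")])
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_start, out$asm_start), ]
  rownames(out) <- NULL
  out
}

# Exhaustive relocation oracle: all ordered pairs over the nonzero |T|
# entries in position order, p = x'^2 - x'.
brute_relocation <- function(Tv) {
  v <- abs(Tv[Tv != 0])
  xp <- length(v)
  if (xp < 2) return(1)
  nd <- 0
  for (i in seq_len(xp - 1))
    nd <- nd + 2 * sum(v[i] > v[(i + 1):xp])
  1 - nd / (xp^2 - xp)
}

# small MTP parameters usable on references of a few hundred kbp
small_clone_args <- function(span = 5e5) {
  list(clone_min = 20000, clone_max = 60000, clone_mean = 40000,
       clone_sd = 8000, overlap_min = 600, overlap_max = 8000,
       overlap_mean = 3000, overlap_sd = 1500, template_span = span)
}

build_small_mtp <- function(ref_len, span = min(ref_len, 5e5)) {
  do.call(build_mtp, c(list(reference = ref_len), small_clone_args(span)))
}
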