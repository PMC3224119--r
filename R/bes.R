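#' Sanger error model for BAC-end sequences
#'
#' Substitutions at 0.006% per nucleotide, insertions and deletions at
#' 0.0002% each, consistent with Sanger per-base accuracy of about 99.999%.
#' At these rates a 600-700 bp BES is expected to carry less than one
#' erroneous base. No homopolymer weighting is applied.
#'
#' @param sub_rate,ins_rate,del_rate per-nucleotide probabilities.
#' @return an `error_model_sanger` object.
#' @export
error_model_sanger <- function(sub_rate = 6e-5, ins_rate = 2e-6,
                               del_rate = 2e-6) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 total = sub_rate + ins_rate + del_rate),
            class = "error_model_sanger")
}

## Vectorised per-base Bernoulli injection over many short sequences.
## Error counts per read are binomial; only reads that draw errors are
## mutated, which keeps 50+ Mbp of BES bases cheap.
.inject_sanger_batch <- function(seqs, model) {
  lens <- nchar(seqs)
  ks <- stats::rbinom(length(seqs), lens, model$total)
  hitr <- which(ks > 0L)
  epos <- vector("list", length(seqs))
  etype <- vector("list", length(seqs))
  alt <- c("A", "C", "G", "T")
  pr <- c(model$sub_rate, model$ins_rate, model$del_rate)
  for (i in hitr) {
    pos <- sort(sample.int(lens[i], ks[i]))
    type <- sample(c("sub", "ins", "del"), ks[i], replace = TRUE, prob = pr)
    ch <- .chars(seqs[i])
    subs <- pos[type == "sub"]
    if (length(subs)) {
      cur <- match(ch[subs], alt)
      pick <- 1L + floor(stats::runif(length(subs)) * 3)
      ch[subs] <- alt[((cur - 1L + pick) %% 4L) + 1L]
    }
    reps <- rep.int(1L, lens[i])
    reps[pos[type == "del"]] <- 0L
    reps[pos[type == "ins"]] <- 2L
    seqs[i] <- paste(rep.int(ch, reps), collapse = "")
    epos[[i]] <- pos
    etype[[i]] <- type
  }
  nerr <- lengths(epos)
  errors <- data.frame(read = rep.int(seq_along(seqs), nerr),
                       pos = unlist(epos, use.names = FALSE),
                       type = unlist(etype, use.names = FALSE),
                       stringsAsFactors = FALSE)
  if (nrow(errors) == 0L)
    errors <- data.frame(read = integer(0), pos = integer(0),
                         type = character(0), stringsAsFactors = FALSE)
  list(seqs = seqs, errors = errors)
}

#' Simulate BAC-end sequences (BES) over an MTP
#'
#' Two Sanger-style BES are extracted per MTP clone, one from each end,
#' facing inward (the right-end BES is reverse-complemented). Additional
#' singleton BES are placed along the reference as a homogeneous Poisson
#' process with one expected occurrence per `spacing` bases. Lengths are
#' uniform in 600-700 bp and errors follow the per-nucleotide Sanger model.
#' Records are ordered along the reference; `order_index` gives each BES's
#' ordinal in that order, the anchor ordering used for scaffold placement.
#'
#' @param mtp an `mtp` clone table from [build_mtp()].
#' @param reference the reference the MTP tiles (string or object).
#' @param spacing expected bases between additional BES (default 20000).
#' @param err an [error_model_sanger()].
#' @param len_range BES length range (default c(600, 700)).
#' @return a `sim_bes` object: list with `bes` (data frame: id, seq, clone,
#'   end in L/R/add, pos, strand, order_index, length) and `errors`
#'   (id, pos, type), plus `bases`, the total error-free BES bases.
#' @export
simulate_bes <- function(mtp, reference, spacing = 20000,
                         err = error_model_sanger(),
                         len_range = c(600L, 700L)) {
  s <- .seq_of(reference)
  n <- nchar(s)
  if (max(mtp$ref_end) > n) stop("reference does not cover the MTP span")
  if (any(mtp$size < len_range[2L])) stop("clone shorter than a maximal BES")

  k <- nrow(mtp)
  lenL <- as.integer(round(stats::runif(k, len_range[1L], len_range[2L])))
  lenR <- as.integer(round(stats::runif(k, len_range[1L], len_range[2L])))
  posL <- mtp$ref_start
  posR <- mtp$ref_end - lenR + 1L
  n_add <- stats::rpois(1L, n / spacing)
  lenA <- as.integer(round(stats::runif(n_add, len_range[1L], len_range[2L])))
  posA <- as.integer(floor(stats::runif(n_add, 1, n - len_range[2L] + 1)))
  strA <- sample(c("+", "-"), n_add, replace = TRUE)

  pos <- c(posL, posR, posA)
  len <- c(lenL, lenR, lenA)
  strand <- c(rep("+", k), rep("-", k), strA)
  clone <- c(mtp$index, mtp$index, rep(NA_integer_, n_add))
  end <- c(rep("L", k), rep("R", k), rep("add", n_add))

  seqs <- substring(s, pos, pos + len - 1L)
  rc <- strand == "-"
  if (any(rc)) seqs[rc] <- vapply(seqs[rc], revcomp, character(1),
                                  USE.NAMES = FALSE)
  bases <- sum(as.numeric(len))
  inj <- .inject_sanger_batch(seqs, err)

  ord <- order(pos, len)
  bes <- data.frame(
    id = character(length(pos)), seq = inj$seqs[ord],
    clone = clone[ord], end = end[ord], pos = pos[ord],
    strand = strand[ord], length = len[ord],
    order_index = seq_along(pos), stringsAsFactors = FALSE)
  bes$id <- sprintf("BES%06d", bes$order_index)
  ## error log read indices refer to pre-sort order; remap to sorted ids
  id_of_old <- character(length(pos))
  id_of_old[ord] <- bes$id
  errors <- data.frame(id = id_of_old[inj$errors$read], pos = inj$errors$pos,
                       type = inj$errors$type, stringsAsFactors = FALSE)
  structure(list(bes = bes, errors = errors, bases = bases,
                 n_additional = n_add, reference_length = n),
            class = "sim_bes")
}

#' @export
print.sim_bes <- function(x, ...) {
  cat(sprintf("sim_bes: %d BES (%d additional), %.0f bases, %d logged errors\n",
              nrow(x$bes), x$n_additional, x$bases, nrow(x$errors)))
  invisible(x)
}

#' Write BES to FASTA with provenance headers
#'
#' Headers carry `clone=<i|add> end=<L|R|add> pos=<ref position>` fields.
#'
#' @param x a `sim_bes` object.
#' @param path output FASTA.
#' @export
write_bes_fasta <- function(x, path) {
  hdr <- sprintf("%s clone=%s end=%s pos=%d", x$bes$id,
                 ifelse(is.na(x$bes$clone), "add", x$bes$clone),
                 x$bes$end, x$bes$pos)
  seqs <- x$bes$seq
  names(seqs) <- hdr
  write_fasta(seqs, path)
}

#' Write the BES truth/order table
#'
#' @param x a `sim_bes` object.
#' @param path output TSV (id, pos, strand, order_index).
#' @export
write_bes_truth <- function(x, path) {
  utils::write.table(x$bes[, c("id", "pos", "strand", "order_index")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
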