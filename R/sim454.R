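#' 454 error model
#'
#' Per-nucleotide error probabilities for pyrosequencing-style reads:
#' substitutions at 0.1%, insertions and deletions at 0.5% each, with bases
#' inside homopolymer runs of length >= 3 more error-prone. The probability
#' that a nucleotide carries an error is `a * totalErrorRate` in runs of
#' length 1-2 and `b * totalErrorRate` in runs of length >= 3, where
#' `totalErrorRate = sub_rate + ins_rate + del_rate`. The factors a = 0.8 and
#' b = 1.6 yield an overall rate of about 1.1% on sequence with a quarter of
#' its bases in long runs.
#'
#' @param sub_rate,ins_rate,del_rate per-nucleotide rates.
#' @param a,b run-length factors (short runs / long runs).
#' @return an `error_model_454` object.
#' @export
error_model_454 <- function(sub_rate = 0.001, ins_rate = 0.005,
                            del_rate = 0.005, a = 0.8, b = 1.6) {
  total <- sub_rate + ins_rate + del_rate
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate < 1, ins_rate < 1, del_rate < 1,
            a <= b, total < 1, a * total < 1, b * total < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, a = a, b = b, total = total),
            class = "error_model_454")
}

#' Non-uniform coverage model over fixed windows
#'
#' The sequence is divided into windows of `window_size` bases (the final
#' window may be partial). Each window receives a raw density drawn as
#' max(N(5, 1), 0); densities are then scaled to sum to one. Reads are later
#' assigned to windows with probability equal to the window density, which
#' reproduces the uneven coverage of real 454 runs.
#'
#' @param seq_length sequence length in bases.
#' @param window_size window width in bases (default 100).
#' @return a `coverage_model` object with fields `window_size`, `widths`
#'   and `densities`.
#' @export
make_coverage_model <- function(seq_length, window_size = 100L) {
  stopifnot(seq_length >= window_size)
  n_win <- ceiling(seq_length / window_size)
  widths <- rep(as.integer(window_size), n_win)
  widths[n_win] <- seq_length - (n_win - 1L) * window_size
  for (attempt in 1:100) {
    raw <- pmax(stats::rnorm(n_win, 5, 1), 0)
    if (sum(raw) > 0) break
    if (attempt == 100L) stop("all window densities drew zero")
  }
  structure(list(window_size = as.integer(window_size), widths = widths,
                 seq_length = as.integer(seq_length),
                 densities = raw / sum(raw)),
            class = "coverage_model")
}

#' Sample read (or insert) start positions from a coverage model
#'
#' A window is chosen with probability equal to its density, then the start
#' is uniform within the window.
#'
#' @param model a `coverage_model`.
#' @param n number of starts to draw.
#' @return integer vector of 1-based start positions.
#' @export
sample_read_start <- function(model, n = 1L) {
  w <- sample.int(length(model$densities), n, replace = TRUE,
                  prob = model$densities)
  offs <- 1L + floor(stats::runif(n) * model$widths[w])
  as.integer((w - 1L) * model$window_size + offs)
}

#' Draw read lengths
#'
#' Lengths are drawn from a normal with the regime's moments (linear reads
#' 350 +/- 150 bp, paired-end reads 170 +/- 70 bp), rounded to integers and
#' clamped below at `min_len`. Alternatively an empirical profile (a numeric
#' vector of observed lengths) can be supplied and is resampled directly.
#'
#' @param kind "linear" or "paired".
#' @param n number of draws.
#' @param mean,sd override the default moments of `kind`.
#' @param min_len minimum length (default 30).
#' @param profile optional numeric vector of empirical lengths to resample.
#' @return integer vector of lengths.
#' @export
draw_read_length <- function(kind = c("linear", "paired"), n = 1L,
                             mean = NULL, sd = NULL, min_len = 30L,
                             profile = NULL) {
  if (!is.null(profile))
    return(pmax(as.integer(sample(profile, n, replace = TRUE)), min_len))
  kind <- match.arg(kind)
  if (is.null(mean)) mean <- if (kind == "linear") 350 else 170
  if (is.null(sd)) sd <- if (kind == "linear") 150 else 70
  .rnorm_clamped(n, mean, sd, min_len)
}

## Core 454 error injection for one read held as a character vector.
## Returns list(chars = mutated character vector, pos = original positions,
## type = error types). Positions refer to the original read coordinates.
.inject_454_chars <- function(ch, model) {
  n <- length(ch)
  r <- rle(ch)
  run_id <- rep.int(seq_along(r$lengths), r$lengths)
  long <- rep.int(r$lengths >= 3L, r$lengths)
  p <- ifelse(long, model$b, model$a) * model$total
  hit <- which(stats::runif(n) < p)
  if (length(hit) == 0L)
    return(list(chars = ch, pos = integer(0), type = character(0)))
  type <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(model$sub_rate, model$ins_rate, model$del_rate))
  ## within one homopolymer run, the first indel locks out the opposite
  ## indel type for the rest of the run
  hr <- run_id[hit]
  dupruns <- unique(hr[duplicated(hr)])
  for (g in dupruns) {
    idx <- which(hr == g)
    lock <- ""
    for (k in idx) {
      if (type[k] == "sub") next
      if (lock == "") {
        lock <- type[k]
      } else if (type[k] != lock) {
        ## redraw among the allowed types (sub + locked indel type)
        allowed <- c("sub", lock)
        pr <- c(model$sub_rate,
                if (lock == "ins") model$ins_rate else model$del_rate)
        type[k] <- sample(allowed, 1L, prob = pr)
      }
    }
  }
  ## apply: substitution replaces the base; deletion drops it; insertion adds
  ## a duplicate of the run nucleotide after it (homopolymer over-call)
  subs <- hit[type == "sub"]
  if (length(subs)) {
    alt <- c("A", "C", "G", "T")
    cur <- match(ch[subs], alt)
    pick <- 1L + floor(stats::runif(length(subs)) * 3)
    ch[subs] <- alt[((cur - 1L + pick) %% 4L) + 1L]
  }
  reps <- rep.int(1L, n)
  reps[hit[type == "del"]] <- 0L
  reps[hit[type == "ins"]] <- 2L
  out <- rep.int(ch, reps)
  list(chars = out, pos = hit, type = type)
}

#' Inject 454-style errors into a read sequence
#'
#' The read is processed one homopolymer run at a time. Each nucleotide
#' carries an error with probability `a * totalErrorRate` (run length <= 2)
#' or `b * totalErrorRate` (run length >= 3); on error, the type is drawn
#' proportional to the substitution/insertion/deletion rates, with the
#' restriction that once an insertion has occurred in a run no deletion may
#' occur in the remaining positions of that run (and vice versa). Inserted
#' bases duplicate the run nucleotide (the dominant 454 over-call mode);
#' substituted bases are drawn uniformly from the other three.
#'
#' @param read_seq nucleotide string.
#' @param model an [error_model_454()].
#' @return list with `seq` (mutated string) and `errors` (data frame of
#'   original-coordinate `pos` and `type`).
#' @export
inject_454_errors <- function(read_seq, model = error_model_454()) {
  stopifnot(nchar(read_seq) > 0L)
  res <- .inject_454_chars(.chars(read_seq), model)
  list(seq = paste(res$chars, collapse = ""),
       errors = data.frame(pos = res$pos, type = res$type,
                           stringsAsFactors = FALSE))
}

## Batch error injection over a character vector of read sequences.
## Returns list(seqs, errors = data.frame(read, pos, type)).
.inject_454_batch <- function(seqs, model) {
  split_all <- strsplit(seqs, "", fixed = TRUE)
  out <- character(length(seqs))
  epos <- vector("list", length(seqs))
  etype <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    r <- .inject_454_chars(split_all[[i]], model)
    out[i] <- paste(r$chars, collapse = "")
    epos[[i]] <- r$pos
    etype[[i]] <- r$type
  }
  nerr <- lengths(epos)
  errors <- data.frame(read = rep.int(seq_along(seqs), nerr),
                       pos = unlist(epos, use.names = FALSE),
                       type = unlist(etype, use.names = FALSE),
                       stringsAsFactors = FALSE)
  list(seqs = out, errors = errors)
}

.qual_string <- function(len, q = 30L) {
  strrep(intToUtf8(q + 33L), len)
}

#' Simulate linear (unpaired) 454 reads
#'
#' Read starts follow the window coverage model, lengths the linear length
#' model (350 +/- 150 bp), and strands are uniform. Reads are emitted until
#' the total read bases first reach `coverage` times the source length (the
#' read crossing the threshold is kept). Reads overrunning the sequence end
#' are truncated and kept if still at least `min_len` long, otherwise
#' resampled. Errors are injected per read.
#'
#' @param source reference sequence, pool sequence or plain string.
#' @param coverage target fold coverage (> 0).
#' @param err an [error_model_454()].
#' @param model optional pre-built [make_coverage_model()]; drawn fresh
#'   otherwise.
#' @param read_mean,read_sd,min_len length model parameters.
#' @param length_profile optional empirical length profile.
#' @param id_prefix read name prefix.
#' @return a `sim_reads` object: list with `reads` (data frame: id, seq,
#'   qual, source, ref_start, ref_end, strand) and `errors` (data frame:
#'   id, pos, type), where error positions are original read coordinates.
#' @export
simulate_linear_reads <- function(source, coverage, err = error_model_454(),
                                  model = NULL, read_mean = 350, read_sd = 150,
                                  min_len = 30L, length_profile = NULL,
                                  id_prefix = "L") {
  stopifnot(coverage > 0)
  s <- .seq_of(source)
  n <- nchar(s)
  sname <- .name_of(source)
  if (is.null(model)) model <- make_coverage_model(n)
  target <- coverage * n

  starts <- integer(0); ends <- integer(0)
  emitted <- 0
  mean_eff <- if (is.null(length_profile)) read_mean else mean(length_profile)
  while (emitted < target) {
    k <- max(16L, ceiling((target - emitted) / mean_eff * 1.1))
    st <- sample_read_start(model, k)
    ln <- draw_read_length("linear", k, mean = read_mean, sd = read_sd,
                           min_len = min_len, profile = length_profile)
    en <- pmin(st + ln - 1L, n)
    keep <- (en - st + 1L) >= min_len
    st <- st[keep]; en <- en[keep]
    if (length(st) == 0L) next
    cum <- emitted + cumsum(as.numeric(en - st + 1L))
    cut <- which(cum >= target)[1L]
    if (!is.na(cut)) { st <- st[seq_len(cut)]; en <- en[seq_len(cut)] }
    starts <- c(starts, st); ends <- c(ends, en)
    emitted <- emitted + sum(as.numeric(en - st + 1L))
  }

  m <- length(starts)
  strand <- sample(c("+", "-"), m, replace = TRUE)
  seqs <- substring(s, starts, ends)
  rc <- strand == "-"
  if (any(rc)) seqs[rc] <- vapply(seqs[rc], revcomp, character(1), USE.NAMES = FALSE)
  inj <- .inject_454_batch(seqs, err)
  ids <- sprintf("%s%06d", id_prefix, seq_len(m))
  reads <- data.frame(id = ids, seq = inj$seqs,
                      qual = .qual_string(nchar(inj$seqs)),
                      source = sname, ref_start = starts, ref_end = ends,
                      strand = strand, stringsAsFactors = FALSE)
  errors <- data.frame(id = ids[inj$errors$read], pos = inj$errors$pos,
                       type = inj$errors$type, stringsAsFactors = FALSE)
  structure(list(reads = reads, errors = errors,
                 origin_bases = sum(as.numeric(ends - starts + 1L))),
            class = "sim_reads")
}

#' Insert library description for paired reads
#'
#' @param mean mean insert size in bases (default 3000).
#' @param sd insert size standard deviation in bases (default 20).
#' @param share fraction of paired coverage drawn from this library.
#' @return an `insert_library` object.
#' @export
insert_library <- function(mean = 3000, sd = 20, share = 1) {
  stopifnot(mean > 0, sd >= 0, share > 0)
  structure(list(mean = mean, sd = sd, share = share),
            class = "insert_library")
}

#' Simulate paired 454 reads from size-selected inserts
#'
#' Insert locations follow the window coverage model; insert lengths are
#' drawn per library (default a single 3 kbp +/- 20 bp library; several
#' libraries, e.g. 3 kbp + 8 kbp at equal shares, may be mixed). Two reads
#' are extracted from the ends of each insert, facing inward, the downstream
#' mate reverse-complemented; both carry the insert's index as a label.
#' Coverage counts read bases only; inserts overrunning the source are
#' resampled. Errors are injected per read.
#'
#' @param source reference/pool sequence or plain string.
#' @param coverage target fold coverage in read bases (> 0).
#' @param libraries list of [insert_library()] objects; shares are
#'   normalised to sum to one.
#' @param err an [error_model_454()].
#' @param model optional pre-built coverage model.
#' @param read_mean,read_sd,min_len paired read length model (170 +/- 70 bp).
#' @param id_prefix read name prefix.
#' @return a `sim_reads` object whose `reads` data frame additionally has
#'   `insert_id` and `mate` columns, plus an `inserts` data frame (insert_id,
#'   library, start, end, length).
#' @export
simulate_paired_reads <- function(source, coverage,
                                  libraries = list(insert_library()),
                                  err = error_model_454(), model = NULL,
                                  read_mean = 170, read_sd = 70,
                                  min_len = 30L, id_prefix = "P") {
  stopifnot(coverage > 0)
  if (inherits(libraries, "insert_library")) libraries <- list(libraries)
  s <- .seq_of(source)
  n <- nchar(s)
  sname <- .name_of(source)
  shares <- vapply(libraries, `[[`, numeric(1), "share")
  shares <- shares / sum(shares)
  if (any(vapply(libraries, `[[`, numeric(1), "mean") > n))
    stop("insert mean exceeds the source length")
  if (is.null(model)) model <- make_coverage_model(n)
  target <- coverage * n

  ist <- integer(0); ien <- integer(0); ilib <- integer(0)
  r1l <- integer(0); r2l <- integer(0)
  emitted <- 0
  while (emitted < target) {
    k <- max(16L, ceiling((target - emitted) / (2 * read_mean) * 1.15))
    lib <- sample.int(length(libraries), k, replace = TRUE, prob = shares)
    mu <- vapply(libraries, `[[`, numeric(1), "mean")[lib]
    sg <- vapply(libraries, `[[`, numeric(1), "sd")[lib]
    st <- sample_read_start(model, k)
    ln <- as.integer(round(stats::rnorm(k, mu, sg)))
    en <- st + ln - 1L
    keep <- en <= n & ln >= 2L * min_len
    st <- st[keep]; en <- en[keep]; lib <- lib[keep]
    if (length(st) == 0L) next
    l1 <- draw_read_length("paired", length(st), mean = read_mean,
                           sd = read_sd, min_len = min_len)
    l2 <- draw_read_length("paired", length(st), mean = read_mean,
                           sd = read_sd, min_len = min_len)
    l1 <- pmin(l1, en - st + 1L)
    l2 <- pmin(l2, en - st + 1L)
    cum <- emitted + cumsum(as.numeric(l1 + l2))
    cut <- which(cum >= target)[1L]
    if (!is.na(cut)) {
      st <- st[seq_len(cut)]; en <- en[seq_len(cut)]; lib <- lib[seq_len(cut)]
      l1 <- l1[seq_len(cut)]; l2 <- l2[seq_len(cut)]
    }
    ist <- c(ist, st); ien <- c(ien, en); ilib <- c(ilib, lib)
    r1l <- c(r1l, l1); r2l <- c(r2l, l2)
    emitted <- emitted + sum(as.numeric(l1 + l2))
  }

  np <- length(ist)
  insert_id <- seq_len(np)
  ## mate 1: upstream end, forward; mate 2: downstream end, reverse-complemented
  s1 <- substring(s, ist, ist + r1l - 1L)
  s2 <- vapply(substring(s, ien - r2l + 1L, ien), revcomp, character(1),
               USE.NAMES = FALSE)
  inj <- .inject_454_batch(c(s1, s2), err)
  ids <- c(sprintf("%s%06d/1", id_prefix, insert_id),
           sprintf("%s%06d/2", id_prefix, insert_id))
  reads <- data.frame(
    id = ids, seq = inj$seqs, qual = .qual_string(nchar(inj$seqs)),
    source = sname,
    ref_start = c(ist, ien - r2l + 1L),
    ref_end = c(ist + r1l - 1L, ien),
    strand = rep(c("+", "-"), each = np),
    insert_id = rep(insert_id, 2L),
    mate = rep(1:2, each = np),
    stringsAsFactors = FALSE)
  errors <- data.frame(id = ids[inj$errors$read], pos = inj$errors$pos,
                       type = inj$errors$type, stringsAsFactors = FALSE)
  inserts <- data.frame(insert_id = insert_id, library = ilib,
                        start = ist, end = ien, length = ien - ist + 1L)
  structure(list(reads = reads, errors = errors, inserts = inserts,
                 origin_bases = sum(as.numeric(reads$ref_end - reads$ref_start + 1L))),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d reads, %.0f origin bases, %d logged errors\n",
              nrow(x$reads), x$origin_bases, nrow(x$errors)))
  invisible(x)
}

#' Write simulated reads as FASTQ (Sanger Phred+33)
#'
#' Paired reads keep their `/1` `/2` suffixes and insert label in the read
#' name; use `split = TRUE` to write `_1`/`_2` files instead of one
#' interleaved file.
#'
#' @param x a `sim_reads` object.
#' @param path output FASTQ path (basename used for split files).
#' @param split write mates to separate `_1`/`_2` files.
#' @return invisibly, the path(s) written.
#' @export
write_fastq <- function(x, path, split = FALSE) {
  wr <- function(df, p) {
    con <- file(p, "wb")
    on.exit(close(con))
    txt <- paste0("@", df$id, "\n", df$seq, "\n+\n", df$qual)
    writeLines(txt, con, sep = "\n")
    p
  }
  if (split && !is.null(x$reads$mate)) {
    base <- sub("\\.f(ast)?q$", "", path)
    p1 <- wr(x$reads[x$reads$mate == 1L, ], paste0(base, "_1.fastq"))
    p2 <- wr(x$reads[x$reads$mate == 2L, ], paste0(base, "_2.fastq"))
    return(invisible(c(p1, p2)))
  }
  invisible(wr(x$reads, path))
}

#' Write the error log sidecar TSV
#'
#' @param x a `sim_reads` or `sim_bes` object.
#' @param path output TSV (columns: id, pos, type).
#' @export
write_error_log <- function(x, path) {
  utils::write.table(x$errors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
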