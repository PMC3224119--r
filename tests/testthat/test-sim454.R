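test_that("coverage model densities are a proper distribution", {
  set.seed(21)
  m <- make_coverage_model(1e6, 100)
  expect_length(m$densities, 10000L)
  expect_true(all(m$densities >= 0))
  expect_equal(sum(m$densities), 1, tolerance = 1e-9)
  # final partial window included
  m2 <- make_coverage_model(1050, 100)
  expect_length(m2$densities, 11L)
  expect_equal(m2$widths[11], 50L)
})

test_that("read starts follow window densities and are uniform in-window", {
  set.seed(22)
  m <- make_coverage_model(200, 100)
  m$densities <- c(1, 0)
  expect_true(all(sample_read_start(m, 1000) <= 100))

  m$densities <- c(0.5, 0.5)
  st <- sample_read_start(m, 1e5)
  expect_equal(mean(st <= 100), 0.5, tolerance = 0.01)
  # positions uniform within the window (chi-square GOF, 10 bins)
  within <- ((st - 1) %% 100) + 1
  p <- chisq.test(tabulate(ceiling(within / 10), 10))$p.value
  expect_gt(p, 0.01)
})

test_that("read length models reproduce the regime moments", {
  set.seed(23)
  expect_true(all(draw_read_length("linear", 100, sd = 0) == 350L))
  lin <- draw_read_length("linear", 1e5)
  expect_equal(mean(lin), 350, tolerance = 2 / 350)
  par <- draw_read_length("paired", 1e5)
  expect_lt(abs(mean(par) - 170), 1)
  expect_true(all(lin >= 30L) && all(par >= 30L))
  # empirical profiles are resampled as-is
  prof <- c(100, 200, 300)
  expect_true(all(draw_read_length("linear", 50, profile = prof) %in% prof))
})

test_that("zero-rate error model is the identity", {
  set.seed(24)
  s <- rand_seq(5000)
  out <- inject_454_errors(s, error_model_454(0, 0, 0))
  expect_identical(out$seq, s)
  expect_equal(nrow(out$errors), 0L)
})

test_that("error rates recover totalErrorRate scaled by run composition", {
  set.seed(25)
  ref <- make_synthetic_reference(2e6, gc = 0.4, homopolymer_frac = 0.25)
  out <- inject_454_errors(ref$seq, error_model_454())
  n <- nchar(ref$seq)
  # expected per-base rate: 0.011 * (0.75 * 0.8 + 0.25 * 1.6) = 0.011
  rate <- nrow(out$errors) / n
  se <- sqrt(0.011 * 0.989 / n)
  expect_lt(abs(rate - 0.011), 3 * se)
  sub_rate <- sum(out$errors$type == "sub") / n
  expect_lt(abs(sub_rate - 0.001), 3 * sqrt(0.001 * 0.999 / n))

  # long-run enrichment: rate inside runs >= 3 over rate outside is b/a = 2
  r <- rle(strsplit(ref$seq, "")[[1]])
  long <- rep(r$lengths >= 3, r$lengths)
  in_long <- long[out$errors$pos]
  ratio <- (sum(in_long) / sum(long)) / (sum(!in_long) / sum(!long))
  expect_equal(ratio, 2, tolerance = 0.1 / 2)
})

test_that("a homopolymer run never mixes insertions and deletions", {
  set.seed(26)
  model <- error_model_454(0.05, 0.2, 0.2)  # high rates to force collisions
  for (rep in 1:5) {
    s <- paste(rep(strrep(c("A", "C", "G", "T"), sample(3:9, 4, TRUE)), 50),
               collapse = "")
    out <- inject_454_errors(s, model)
    r <- rle(strsplit(s, "")[[1]])
    run_id <- rep(seq_along(r$lengths), r$lengths)
    bad <- vapply(split(out$errors$type, run_id[out$errors$pos]),
                  function(tp) all(c("ins", "del") %in% tp), logical(1))
    expect_false(any(bad))
  }
})

test_that("linear simulation obeys the coverage stopping rule and bounds", {
  set.seed(27)
  ref <- make_synthetic_reference(1e5, gc = 0.4)
  sim <- simulate_linear_reads(ref, coverage = 5)
  expect_gte(sim$origin_bases, 5e5)
  expect_lt(sim$origin_bases, 5e5 + 2000)  # one read past the threshold
  expect_true(all(sim$reads$ref_start >= 1))
  expect_true(all(sim$reads$ref_end <= 1e5))
  expect_true(all(sim$reads$ref_end - sim$reads$ref_start + 1 >= 30))
  # per-base depth averages the requested fold coverage
  depth <- numeric(1e5)
  for (i in seq_len(nrow(sim$reads))) {
    ix <- sim$reads$ref_start[i]:sim$reads$ref_end[i]
    depth[ix] <- depth[ix] + 1
  }
  expect_equal(mean(depth), 5, tolerance = 0.01)
})

test_that("paired simulation produces labelled inward-facing mates", {
  set.seed(28)
  ref <- make_synthetic_reference(1e6, gc = 0.4)
  sim <- simulate_paired_reads(ref, coverage = 3.4)
  rp <- sim$reads
  expect_true(all(sort(unique(rp$mate)) == c(1, 2)))
  m1 <- rp[rp$mate == 1, ]; m2 <- rp[rp$mate == 2, ]
  expect_identical(m1$insert_id, m2$insert_id)
  expect_true(all(m1$strand == "+") && all(m2$strand == "-"))
  # outer distance equals the insert span; mean 3 kbp within 1 bp at 10^4 pairs
  expect_gte(nrow(sim$inserts), 9000)
  outer <- m2$ref_end - m1$ref_start + 1
  expect_equal(outer, as.numeric(sim$inserts$length))
  expect_lt(abs(mean(outer) - 3000), 1)
  expect_true(all(sim$inserts$end <= 1e6))
})

test_that("mixed insert libraries give a bimodal insert distribution", {
  set.seed(29)
  ref <- make_synthetic_reference(1e6, gc = 0.4)
  libs <- list(insert_library(3000, 20, 0.5), insert_library(8000, 80, 0.5))
  sim <- simulate_paired_reads(ref, coverage = 2, libraries = libs)
  len <- sim$inserts$length
  near3 <- mean(abs(len - 3000) < 200)
  near8 <- mean(abs(len - 8000) < 400)
  expect_gt(near3, 0.4); expect_gt(near8, 0.4)
  expect_equal(near3 + near8, 1)
  expect_error(
    simulate_paired_reads(ref, 1, libraries = list(insert_library(2e6))),
    "insert mean")
})

test_that("identical seeds give byte-identical FASTQ output", {
  ref_seq <- local({set.seed(301); rand_seq(5e4)})
  run <- function() {
    set.seed(302)
    sim <- simulate_linear_reads(ref_seq, coverage = 2)
    f <- tempfile(fileext = ".fastq")
    write_fastq(sim, f)
    f
  }
  f1 <- run(); f2 <- run()
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # structural sanity of the FASTQ
  ln <- readLines(f1)
  expect_equal(length(ln) %% 4, 0)
  expect_true(all(startsWith(ln[seq(1, length(ln), 4)], "@")))
  expect_identical(nchar(ln[seq(2, length(ln), 4)]),
                   nchar(ln[seq(4, length(ln), 4)]))
})

test_that("paired FASTQ can be written interleaved or split", {
  set.seed(31)
  ref <- make_synthetic_reference(1e5, gc = 0.4)
  sim <- simulate_paired_reads(ref, coverage = 0.5)
  f <- tempfile(fileext = ".fastq")
  write_fastq(sim, f)
  expect_true(any(grepl("/1$", readLines(f, 200))))
  ps <- write_fastq(sim, f, split = TRUE)
  expect_length(ps, 2L)
  expect_true(all(file.exists(ps)))
  el <- tempfile(fileext = ".tsv")
  write_error_log(sim, el)
  expect_identical(readLines(el, 1), "id\tpos\ttype")
})
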