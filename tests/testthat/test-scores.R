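identity_matches <- function(n) {
  data.frame(ref_start = 1L, ref_end = n, asm_start = 1L, asm_end = n,
             strand = "+", identity = 100, length = n,
             stringsAsFactors = FALSE)
}

test_that("an identity assembly is the fixed point of all five scores", {
  n <- 20000L
  m <- identity_matches(n)
  rep <- score_assembly(n, n, m)
  expect_equal(rep$match, 1)
  expect_equal(rep$relocation, 1)
  expect_equal(rep$inversion, 1)
  expect_equal(rep$redundancy, 1)
  expect_equal(rep$coverage, 1)
  expect_equal(rep$combined, 5)
  expect_equal(rep$coverage_pct, 100)
})

test_that("relocation score matches brute force and handles extremes", {
  # two halves of the reference swapped
  n <- 10000L
  h <- n %/% 2L
  swapped <- data.frame(ref_start = c(1L, h + 1L), ref_end = c(h, n),
                        asm_start = c(h + 1L, 1L), asm_end = c(n, h),
                        strand = "+", identity = 100, length = h)
  tt <- build_match_table(swapped, n)
  expect_equal(relocation_score(tt, 10000L), 0.5, tolerance = 0.01)

  # strictly decreasing magnitudes: every pair disagrees
  dec <- list(T = seq(5000L, 1L, by = -1L), n = 5000L, l = 5000L)
  expect_equal(relocation_score(dec, 5000L), 0)

  # fewer than two nonzero samples is vacuously perfect
  sparse <- list(T = c(0L, 7L, 0L, 0L), n = 4L, l = 1L)
  expect_equal(relocation_score(sparse, 4L), 1)
})

test_that("sampled relocation equals the exhaustive all-pairs oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(500:5000, 1)
    Tv <- sample(-n:n, n, replace = TRUE)
    Tv[sample(n, n %/% 4)] <- 0L
    tbl <- list(T = Tv, n = n, l = sum(Tv != 0L))
    expect_equal(relocation_score(tbl, x = n), brute_relocation(Tv))
  }
})

test_that("inversion score is the matched minus-strand fraction", {
  tt <- list(T = c(1L, 2L, 3L, 4L), n = 4L, l = 4L)
  expect_equal(inversion_score(tt), 1)
  tt$T <- -tt$T
  expect_equal(inversion_score(tt), 0)
  tt$T <- c(1L, -2L, 3L, -4L)
  expect_equal(inversion_score(tt), 0.5)
  empty <- list(T = integer(4), n = 4L, l = 0L)
  expect_equal(inversion_score(empty), 1)   # vacuous
  expect_equal(coverage_score(empty), 0)
})

test_that("redundancy penalises duplication and junk content", {
  n <- 1000L
  u1 <- build_assembly_table(identity_matches(n), n)
  expect_equal(redundancy_score(u1), 1)

  # reference duplicated: every reference position occurs twice
  twice <- data.frame(ref_start = c(1L, 1L), ref_end = c(n, n),
                      asm_start = c(1L, n + 1L), asm_end = c(n, 2L * n),
                      strand = "+", identity = 100, length = n)
  u2 <- build_assembly_table(twice, 2L * n)
  expect_equal(redundancy_score(u2), 0)

  # reference plus unmatched junk of equal size
  u3 <- build_assembly_table(identity_matches(n), 2L * n)
  expect_equal(redundancy_score(u3), 0.5)
})

test_that("match score rewards long contiguous segments", {
  n <- 1000L
  full <- build_match_table(identity_matches(n), n)
  expect_equal(match_score(full), 1)

  none <- build_match_table(empty_matches(), n)
  expect_equal(match_score(none), 0)
  expect_equal(match_score(none, match_score_params(variant = "literal")), 0.5)

  # two half-length matches assembled far apart: (0.25 + 0.25 + 1) / 2
  h <- n %/% 2L
  split2 <- data.frame(ref_start = c(1L, h + 1L), ref_end = c(h, n),
                       asm_start = c(2001L, 5001L), asm_end = c(2000L + h, 5000L + h),
                       strand = "+", identity = 100, length = h)
  t2 <- build_match_table(split2, n)
  expect_equal(match_score(t2), 0.75)
  # literal variant adds the gap term instead of its complement
  expect_equal(match_score(t2, match_score_params(variant = "literal")), 0.25)
})

test_that("all scores stay in [0, 1] on random match tables", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(200:3000, 1)
    m <- sample(200:3000, 1)
    k <- sample(1:6, 1)
    st <- sort(sample(n - 20L, k))
    en <- pmin(st + sample(10:500, k, replace = TRUE), n)
    as <- sample(m - 20L, k)
    ae <- pmin(as + (en - st), m)
    en <- st + (ae - as)
    mt <- data.frame(ref_start = st, ref_end = en, asm_start = as,
                     asm_end = ae, strand = sample(c("+", "-"), k, TRUE),
                     identity = 100, length = en - st + 1L)
    rep_ <- score_assembly(n, m, mt, reloc_samples = 500L)
    sc <- unlist(rep_[c("match", "relocation", "inversion",
                        "redundancy", "coverage")])
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(rep_$combined, sum(sc))
  }
})

test_that("corrupted assemblies recover their truth fractions", {
  set.seed(63)
  ref <- make_synthetic_reference(50000, gc = 0.4)
  idn <- corrupt_assembly(ref)
  expect_identical(idn$assembly, ref$seq)

  inv <- corrupt_assembly(ref, list(list(op = "invert", start = 10001,
                                         end = 25000)))
  expect_equal(inv$truth$inverted_frac, 0.3)
  ri <- score_assembly(ref, inv$assembly, inv$segments)
  expect_equal(ri$inversion, 0.7, tolerance = 0.01)
  expect_equal(ri$coverage, 1, tolerance = 0.01)

  del <- corrupt_assembly(ref, list(list(op = "delete", start = 20001,
                                         end = 32500)))
  rd <- score_assembly(ref, del$assembly, del$segments)
  expect_equal(rd$coverage, 0.75, tolerance = 0.01)

  expect_error(corrupt_assembly(ref, list(
    list(op = "invert", start = 1, end = 100),
    list(op = "delete", start = 50, end = 150))), "overlap")
})

test_that("scores respond monotonically to growing corruption", {
  set.seed(64)
  ref <- make_synthetic_reference(40000, gc = 0.4)
  inv_at <- function(frac) {
    cr <- corrupt_assembly(ref, list(list(op = "invert", start = 1L,
                                          end = as.integer(frac * 40000))))
    score_assembly(ref, cr$assembly, cr$segments)$inversion
  }
  expect_true(inv_at(0.1) > inv_at(0.3))
  expect_true(inv_at(0.3) > inv_at(0.6))

  del_at <- function(frac) {
    cr <- corrupt_assembly(ref, list(list(op = "delete", start = 1L,
                                          end = as.integer(frac * 40000))))
    score_assembly(ref, cr$assembly, cr$segments)$coverage
  }
  expect_true(del_at(0.1) > del_at(0.3))

  base <- corrupt_assembly(ref)
  dup <- corrupt_assembly(ref, list(list(op = "duplicate", start = 5001,
                                         end = 15000)))
  rd0 <- score_assembly(ref, base$assembly,
                        anchor_match(ref, base$assembly))$redundancy
  rd1 <- score_assembly(ref, dup$assembly,
                        anchor_match(ref, dup$assembly))$redundancy
  expect_lt(rd1, rd0)
})

test_that("scoring via the anchor matcher recovers construction truth", {
  set.seed(65)
  ref <- make_synthetic_reference(60000, gc = 0.4)
  cr <- corrupt_assembly(ref, list(list(op = "delete", start = 10001,
                                        end = 22000)))
  m <- filter_matches(anchor_match(ref, cr$assembly), 1000L)
  rep <- score_assembly(ref, cr$assembly, m)
  expect_equal(rep$coverage, 0.8, tolerance = 0.02)
})

test_that("score reports serialise to TSV and JSON", {
  rep <- score_assembly(1000L, 1000L, identity_matches(1000L))
  fj <- tempfile(fileext = ".json")
  write_score_report(rep, fj, "json")
  back <- jsonlite::read_json(fj)
  expect_equal(back$combined, 5)
  ft <- tempfile(fileext = ".tsv")
  write_score_report(rep, ft, "tsv")
  d <- read.delim(ft)
  expect_equal(nrow(d), 7)
})
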