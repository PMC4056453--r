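# Projection over alignment blocks, conservation classes, pairwise
# sharing, divergence correlation, FDR sensitivity.

test_that("projection maps by offset, clips to blocks, handles reversal", {
  map <- toy_map(
    ~block_id, ~species, ~chrom, ~start, ~end, ~strand,
    "b1", "A", "chr1", 1000, 2000, "+",
    "b1", "B", "chr2", 5000, 6000, "+",
    "b2", "A", "chr1", 3000, 4000, "+",
    "b2", "B", "chr3", 8000, 9000, "-"
  )
  iv <- data.frame(chrom = "chr1", start = 1100, end = 1200)
  pr <- project_interval(iv, map, "A", "B")
  expect_equal(pr$chrom, "chr2")
  expect_equal(pr$start, 5100L)
  expect_equal(pr$end, 5200L)

  # identity projection clips to block coverage
  wide <- data.frame(chrom = "chr1", start = 900, end = 2100)
  self <- project_interval(wide, map, "A", "A")
  expect_equal(self$start, 1000L)
  expect_equal(self$end, 2000L)

  # strand reversal mirrors coordinates within the block
  rev <- project_interval(data.frame(chrom = "chr1", start = 3100, end = 3200),
                          map, "A", "B")
  expect_equal(rev$start, 8800L)
  expect_equal(rev$end, 8900L)
  expect_equal(rev$strand, "-")

  # outside all blocks -> empty; unknown species -> error
  expect_equal(nrow(project_interval(data.frame(chrom = "chr1", start = 10, end = 20),
                                     map, "A", "B")), 0)
  expect_error(project_interval(iv, map, "A", "Z"), "unknown species")
})

test_that("projection agrees with brute-force per-base mapping and round-trips", {
  set.seed(11)
  # random equal-length blocks between two species
  n_blocks <- 30
  b_start_a <- sort(sample(seq(0, 9e4, by = 3000), n_blocks))
  b_start_b <- sample(seq(0, 9e4, by = 3000), n_blocks)
  strand_b <- sample(c("+", "-"), n_blocks, replace = TRUE)
  blen <- 2000L
  map <- dplyr::bind_rows(
    tibble::tibble(block_id = sprintf("b%02d", 1:n_blocks), species = "A",
                   chrom = "chr1", start = b_start_a, end = b_start_a + blen,
                   strand = "+"),
    tibble::tibble(block_id = sprintf("b%02d", 1:n_blocks), species = "B",
                   chrom = "chr1", start = b_start_b, end = b_start_b + blen,
                   strand = strand_b)
  )
  brute <- function(iv) {
    # per-base offset mapping through each block
    out <- list()
    for (i in 1:n_blocks) {
      fa <- b_start_a[i]
      bases <- seq(iv$start, iv$end - 1)
      bases <- bases[bases >= fa & bases < fa + blen]
      if (length(bases) == 0) next
      off <- bases - fa
      tgt <- if (strand_b[i] == "+") b_start_b[i] + off else
        (b_start_b[i] + blen - 1) - off
      out[[length(out) + 1]] <- tibble::tibble(
        block = i, start = min(tgt), end = max(tgt) + 1L)
    }
    dplyr::bind_rows(
      tibble::tibble(block = integer(), start = integer(), end = integer()),
      out)
  }
  for (rep in 1:100) {
    s <- sample.int(95000, 1)
    iv <- data.frame(chrom = "chr1", start = s, end = s + sample.int(3000, 1))
    got <- project_interval(iv, map, "A", "B")
    want <- brute(iv)
    expect_equal(sort(as.integer(got$start)), sort(as.integer(want$start)))
    expect_equal(sort(as.integer(got$end)), sort(as.integer(want$end)))
    # round trip: projecting back overlaps the original
    if (nrow(got) > 0) {
      back <- project_intervals(got, map, "B", "A")
      expect_true(any(interval_overlaps(
        back[, c("chrom", "start", "end")],
        iv[rep(1, nrow(back)), ])))
    }
  }
})

test_that("unequal segment lengths project proportionally", {
  map <- toy_map(
    ~block_id, ~species, ~chrom, ~start, ~end, ~strand,
    "b1", "A", "chr1", 0, 1000, "+",
    "b1", "B", "chr1", 0, 2000, "+"
  )
  pr <- project_interval(data.frame(chrom = "chr1", start = 250, end = 500),
                         map, "A", "B")
  expect_equal(pr$start, 500L)
  expect_equal(pr$end, 1000L)
})

test_that("conservation classes follow sharing counts on a constructed toy", {
  sps <- c("A", "B", "C")
  map <- dplyr::bind_rows(
    identity_map(sps, start = 0, end = 10000),          # b1: all three
    toy_map(~block_id, ~species, ~chrom, ~start, ~end, ~strand,
            "b2", "A", "chr1", 20000, 30000, "+",
            "b2", "B", "chr1", 20000, 30000, "+")
  )
  sets <- list(
    A = ev_set("A", "CTCF", "chr1",
               c(100L, 2000L, 5000L, 22000L, 50000L),
               c(400L, 2300L, 5300L, 22300L, 50300L)),
    B = ev_set("B", "CTCF", "chr1", c(150L, 5100L), c(450L, 5400L)),
    C = ev_set("C", "CTCF", "chr1", c(120L, 9000L), c(420L, 9300L))
  )
  cls <- classify_conservation(sets, map, "A")
  expect_equal(as.character(cls$class),
               c("ALL",               # shared with B and C
                 "SPECIES_SPECIFIC",  # aligned (b1), no partner peak
                 "TWO_WAY",           # shared with B only
                 "SPECIES_SPECIFIC",  # b2 aligned toward B, no peak
                 "UNALIGNED"))        # outside every block
  # fractions sum to one and members are consistent with counts
  fr <- conservation_fractions(cls)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(cls$n_species, lengths(strsplit(cls$members, ",")))
  expect_error(classify_conservation(list(), map, "A"), "empty")
})

test_that("pairwise shared fraction averages the two directions", {
  map <- identity_map(c("A", "B"), end = 1e5)
  a <- ev_set("A", "CTCF", "chr1", c(100L, 1000L, 2000L, 3000L),
              c(300L, 1200L, 2200L, 3200L))
  b <- ev_set("B", "CTCF", "chr1", c(120L, 1050L), c(320L, 1250L))
  # a: 2 of 4 shared; b: 2 of 2 shared -> mean(0.5, 1) = 0.75
  expect_equal(pairwise_shared_fraction(a, b, map), 0.75)
  expect_equal(pairwise_shared_fraction(a, a, map), 1.0)
  disjoint <- ev_set("B", "CTCF", "chr1", 50000L, 50200L)
  expect_equal(pairwise_shared_fraction(a, disjoint, map), 0)
  empty <- ev_set("B", "CTCF", character(), integer(), integer())
  expect_error(pairwise_shared_fraction(a, empty, map), "empty")
})

test_that("divergence correlation matches the closed-form Pearson r", {
  lin <- tibble::tibble(fraction = c(0.9, 0.7, 0.5, 0.3),
                        divergence_my = c(5, 15, 25, 35))
  expect_equal(overlap_divergence_correlation(lin)$estimate, -1)

  d <- tibble::tibble(fraction = c(0.9, 0.7, 0.5), divergence_my = c(5, 25, 40))
  # closed form: r = sum((x - mx)(y - my)) / sqrt(sum sq * sum sq)
  x <- d$divergence_my - mean(d$divergence_my)
  y <- d$fraction - mean(d$fraction)
  r_hand <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(overlap_divergence_correlation(d)$estimate, r_hand)

  const <- tibble::tibble(fraction = c(0.5, 0.5, 0.5), divergence_my = c(1, 2, 3))
  expect_error(overlap_divergence_correlation(const), "constant")
  expect_error(overlap_divergence_correlation(d[1:2, ]), "at least 3")
})

test_that("FDR sensitivity is monotone and steps where peaks are rescued", {
  map <- identity_map(c("A", "B"), end = 1e5)
  anchor <- ev_set("A", "CTCF", "chr1", c(100L, 1000L, 2000L),
                   c(300L, 1200L, 2200L))
  other <- ev_set("B", "CTCF", "chr1", c(120L, 2050L), c(320L, 2250L),
                  fdr = c(0.01, 0.3))
  sens <- fdr_sensitivity_overlap(anchor, other, map,
                                  fdr_grid = c(0.05, 0.2, 0.3, 0.5))
  # at 0.05 only the first peak counts; the fdr 0.3 peak rescues one
  # anchor event exactly at the 0.3 grid point
  expect_equal(sens$shared_fraction, c(1, 1, 2, 2) / 3)
  expect_true(all(diff(sens$shared_fraction) >= 0))
  # grid = {0.05} reproduces the plain one-direction fraction
  one <- fdr_sensitivity_overlap(anchor, other, map, fdr_grid = 0.05)
  expect_equal(one$shared_fraction, 1 / 3)
  expect_warning(fdr_sensitivity_overlap(anchor, other, map, fdr_grid = 0.6),
                 "0.5")
})
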