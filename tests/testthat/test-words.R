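# PWM scanning, word tables, normWord scores, selection, repeat embedding.

make_pwm <- function(mat) as_pwm(mat)

test_that("PWM scan scores the consensus at 0 and others by log2 ratios", {
  pwm <- make_pwm(rbind(c(0.7, 0.1, 0.1, 0.1),
                        c(0.1, 0.1, 0.7, 0.1),
                        c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(pwm_consensus(pwm), "AGA")
  hits <- scan_pwm("AGA", pwm, cutoff = -15)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, 0)
  expect_equal(fwd$position, 0L)

  # hand-computed score for a mismatch word: per-position log2 ratio sums
  hits2 <- scan_pwm("CGA", pwm, cutoff = -15)
  want <- log2(0.1 / 0.7) + log2(0.7 / 0.7) + log2(0.25 / 0.25)
  expect_equal(hits2$score[hits2$strand == "+" & hits2$position == 0], want)

  # cutoff excludes low-scoring windows
  strict <- scan_pwm("CGA", pwm, cutoff = -1)
  expect_false(any(strict$strand == "+" & strict$position == 0))

  # windows containing N are skipped entirely
  hits_n <- scan_pwm("ANA", pwm, cutoff = -100)
  expect_equal(nrow(hits_n), 0)

  # a zero probability at a non-consensus base scores -Inf and is
  # excluded by any finite cutoff
  pwm0 <- make_pwm(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0)))
  h0 <- scan_pwm("AA", pwm0, cutoff = -1e6)
  expect_false(any(h0$strand == "+" & h0$position == 0))
})

test_that("scanning is strand-symmetric", {
  pwm <- make_pwm(rbind(c(0.6, 0.2, 0.1, 0.1),
                        c(0.1, 0.6, 0.2, 0.1),
                        c(0.1, 0.1, 0.6, 0.2),
                        c(0.2, 0.1, 0.1, 0.6)))
  seqs <- c("ACGTTTACGATCGA", "GGGGACGTCCCCAA")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (s in seqs) {
    h1 <- scan_pwm(s, pwm, cutoff = -100)
    h2 <- scan_pwm(rc(s), pwm, cutoff = -100)
    # mirrored positions, identical score multiset
    expect_equal(unname(sort(h1$score)), unname(sort(h2$score)))
    n <- nchar(s); L <- nrow(pwm)
    expect_setequal(n - L - h1$position, h2$position)
  }
})

test_that("word table normalizes counts by bound megabases", {
  # species X: 2 Mb bound -> factor 2; 10 occurrences -> nocc 5
  bound_x <- ev_set("X", "CTCF", "chr1", seq(0L, 1999000L, by = 1000L)[1:2000],
                    seq(0L, 1999000L, by = 1000L)[1:2000] + 1000L)
  bound_y <- ev_set("Y", "CTCF", "chr1", 0L, 500000L)
  hit_at <- function(pos, word) tibble::tibble(
    chrom = "chr1", position = pos, strand = "+", word = word, score = -1)
  hits <- list(
    X = hit_at(seq(100L, by = 1000L, length.out = 10), "AAAAT"),
    Y = hit_at(seq(100L, by = 1000L, length.out = 4), "AAAAT"))
  tab <- build_word_table(hits, list(X = bound_x, Y = bound_y))
  x <- tab[tab$species == "X", ]
  expect_equal(x$factor, 2)
  expect_equal(x$count, 10L)
  expect_equal(x$nocc, 5)

  # a word never reaching min_count anywhere is dropped
  hits$Y <- dplyr::bind_rows(hits$Y, hit_at(c(5000L, 6000L), "CCCCC"))
  tab2 <- build_word_table(hits, list(X = bound_x, Y = bound_y), min_count = 5)
  expect_false("CCCCC" %in% tab2$word)
  # but min_count in ONE species suffices (X has 10 >= 5, Y only 4)
  expect_true("AAAAT" %in% tab2$word)

  # hits outside bound regions do not count
  hits$X <- dplyr::bind_rows(hits$X, hit_at(2500000L, "AAAAT"))
  tab3 <- build_word_table(hits, list(X = bound_x, Y = bound_y))
  expect_equal(tab3$count[tab3$species == "X"], 10L)

  expect_error(build_word_table(hits, list(X = bound_x[0, ], Y = bound_y)),
               "zero bound bases")
})

test_that("nocc is invariant under joint scaling of counts and bound bases", {
  set.seed(2)
  n <- 20
  st <- seq(0L, by = 2000L, length.out = n)
  bound1 <- ev_set("X", "CTCF", "chr1", st, st + 1000L)
  st2 <- seq(0L, by = 2000L, length.out = 2 * n)
  bound2 <- ev_set("X", "CTCF", "chr1", st2, st2 + 1000L)
  h1 <- tibble::tibble(chrom = "chr1", position = st + 10L, strand = "+",
                       word = "AAAAA", score = -1)
  h2 <- tibble::tibble(chrom = "chr1", position = st2 + 10L, strand = "+",
                       word = "AAAAA", score = -1)
  t1 <- build_word_table(list(X = h1), list(X = bound1))
  t2 <- build_word_table(list(X = h2), list(X = bound2))
  expect_equal(t1$nocc, t2$nocc)   # doubling counts and bases cancels
})

test_that("normWord identities and antisymmetry hold exactly", {
  tab <- tibble::tibble(
    word = rep(c("w1", "w2", "w3"), each = 2),
    species = rep(c("S", "R"), 3),
    count = c(10L, 10L, 15L, 3L, 0L, 15L),
    factor = 1,
    nocc = c(10, 10, 15, 3, 0, 15))
  sc <- norm_word_scores(tab, "S", "R")
  expect_equal(sc$norm_word[sc$word == "w1"], 0)     # equal nocc
  expect_equal(sc$norm_word[sc$word == "w2"], 2)     # log2(16/4)
  expect_equal(sc$norm_word[sc$word == "w3"], -4)    # log2(1/16)
  rev <- norm_word_scores(tab, "R", "S")
  expect_equal(sc$norm_word, -rev$norm_word)         # single-species antisymmetry

  # clade focal set uses the clade maximum
  tab3 <- dplyr::bind_rows(tab, tibble::tibble(
    word = c("w1", "w2", "w3"), species = "S2", count = c(31L, 0L, 0L),
    factor = 1, nocc = c(31, 0, 0)))
  scc <- norm_word_scores(tab3, c("S", "S2"), "R")
  expect_equal(scc$norm_word[scc$word == "w1"], log2(32 / 11))
  expect_error(norm_word_scores(tab, "S", character()), "non-empty")
  expect_error(norm_word_scores(tab, "S", "S"), "disjoint")
})

test_that("word selection controls the null and recovers planted expansions", {
  set.seed(31)
  null_scores <- tibble::tibble(word = sprintf("w%05d", 1:10000),
                                norm_word = rnorm(10000, 0, 0.5))
  sel <- select_specific_words(null_scores, fdr = 0.05)
  expect_lte(nrow(sel$selected), 1)   # FDR control: essentially nothing
  expect_true(is.finite(sel$mean))

  planted <- null_scores
  planted$norm_word[1] <- 6   # a 10x-style expansion far in the upper tail
  sel2 <- select_specific_words(planted, fdr = 0.05)
  expect_true("w00001" %in% sel2$selected$word)
  expect_lte(sel2$cutoff, 6)

  expect_equal(select_specific_words(null_scores, fdr = 1e-12)$cutoff, Inf)
  expect_error(select_specific_words(null_scores[1:5, ]), "at least 10")
  const <- tibble::tibble(word = letters[1:10], norm_word = rep(1, 10))
  expect_error(select_specific_words(const), "zero variance")
})

test_that("repeat-embedded word counting requires full containment", {
  bound <- ev_set("X", "CTCF", "chr1", 0L, 10000L)
  hits <- tibble::tibble(chrom = "chr1",
                         position = c(100L, 200L, 300L, 400L, 500L),
                         strand = "+", word = "AAAAA", score = -1)
  # repeats cover hits 1-3 fully; hit 4 straddles a repeat edge
  repeats <- tibble::tibble(chrom = "chr1",
                            start = c(90L, 195L, 295L, 402L),
                            end = c(120L, 215L, 315L, 420L),
                            strand = "+", rep_name = "R", rep_class = "C",
                            rep_family = "F", milli_div = 10L)
  out <- count_repeat_embedded_words("AAAAA", hits, bound, repeats,
                                     word_length = 5L)
  expect_equal(out$n_bound, 5L)
  expect_equal(out$n_repeat_embedded, 3L)
  expect_equal(out$log10_count, log10(4))

  # no repeats -> zero; all hits embedded -> full count
  out0 <- count_repeat_embedded_words("AAAAA", hits, bound, repeats[0, ],
                                      word_length = 5L)
  expect_equal(out0$n_repeat_embedded, 0L)
  wide <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                         strand = "+", rep_name = "R", rep_class = "C",
                         rep_family = "F", milli_div = 10L)
  outw <- count_repeat_embedded_words("AAAAA", hits, bound, wide,
                                      word_length = 5L)
  expect_equal(outw$n_repeat_embedded, 5L)
})
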