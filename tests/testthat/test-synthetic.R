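# Synthetic-world generators: determinism, structural guarantees,
# ground-truth consistency.

test_that("alignment map tiles the requested fraction deterministically", {
  cfg <- small_world_config(seed = 4)
  m1 <- generate_alignment_map(cfg)
  m2 <- generate_alignment_map(cfg)
  expect_identical(m1, m2)   # same seed -> byte-identical

  # anchor coverage close to alignable_fraction (within one block)
  anchor <- m1[m1$species == "H.sap", ]
  covered <- sum(anchor$end - anchor$start)
  G <- sum(c(1.2e6, 8e5))
  expect_lte(abs(covered - 0.8 * G), cfg$block_length +
               0.2 * cfg$block_length * length(unique(anchor$chrom)))

  # anchor segments never overlap
  by_chrom <- split(anchor, anchor$chrom)
  for (seg in by_chrom) {
    seg <- seg[order(seg$start), ]
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
  }

  # membership declines with divergence
  counts <- table(m1$species)
  expect_gt(counts[["P.tro"]], counts[["S.oed"]])

  # zero alignability -> empty map
  cfg0 <- small_world_config(seed = 4, alignable_fraction = 0)
  expect_equal(nrow(generate_alignment_map(cfg0)), 0)
})

test_that("planted events occupy exactly their member species", {
  cfg <- small_world_config(seed = 8, n_events = 200)
  map <- generate_alignment_map(cfg)
  ev <- generate_binding_events(cfg, map)
  truth <- ev$truth
  sps <- names(ev$ctcf)
  for (sp in sps) {
    names_here <- ev$ctcf[[sp]]$name
    should <- vapply(strsplit(truth$members, ","), function(m) sp %in% m,
                     logical(1))
    expect_setequal(intersect(truth$event_id, names_here),
                    truth$event_id[should])
  }
  # determinism of the full event stage
  ev2 <- generate_binding_events(cfg, map)
  expect_identical(ev$truth, ev2$truth)
  expect_identical(ev$ctcf, ev2$ctcf)

  # UNALIGNED events overlap no block
  anchor_seg <- map[map$species == "H.sap", ]
  un <- truth[truth$class == "UNALIGNED", ]
  if (nrow(un) > 0) {
    ov <- vapply(seq_len(nrow(un)), function(i) {
      any(un$chrom[i] == anchor_seg$chrom &
            un$start[i] < anchor_seg$end & un$end[i] > anchor_seg$start)
    }, logical(1))
    expect_false(any(ov))
  }

  # every co-bound CTCF event has an overlapping YY1 event in the anchor
  co <- truth[truth$cobound, ]
  yy <- ev$yy1[["H.sap"]]
  hit <- vapply(seq_len(nrow(co)), function(i) {
    any(co$chrom[i] == yy$chrom & co$start[i] < yy$end & co$end[i] > yy$start)
  }, logical(1))
  expect_true(all(hit))

  # n_events = 0 -> empty sets
  ev0 <- generate_binding_events(small_world_config(seed = 1, n_events = 0), map)
  expect_true(all(vapply(ev0$ctcf, nrow, integer(1)) == 0))
})

test_that("repeat generator respects counts and the null case", {
  cfg <- single_species_config(seed = 13, n_events = 500)
  map <- generate_alignment_map(cfg)
  ev <- generate_binding_events(cfg, map)
  reps <- generate_repeat_annotation(cfg, ev$ctcf)[[1]]
  spec_counts <- vapply(cfg$repeat_spec, `[[`, numeric(1), "count")
  names(spec_counts) <- vapply(cfg$repeat_spec, `[[`, character(1), "rep_name")
  got <- table(reps$rep_name)
  for (nm in names(spec_counts)) {
    expect_equal(unname(got[[nm]]), unname(spec_counts[[nm]]))
  }
  expect_true(all(reps$milli_div >= 0))

  # count = 0 -> family absent
  cfg2 <- single_species_config(seed = 13, n_events = 100,
    repeat_spec = list(list(rep_name = "GONE", rep_class = "X",
                            rep_family = "X", count = 0, enrichment = 1,
                            milli_div_mean = 100, length = 500)))
  map2 <- generate_alignment_map(cfg2)
  ev2 <- generate_binding_events(cfg2, map2)
  reps2 <- generate_repeat_annotation(cfg2, ev2$ctcf)[[1]]
  expect_false("GONE" %in% reps2$rep_name)

  # enrichment = 1 -> overlap rate near the uniform background rate
  fam <- reps[reps$rep_name == "AluY", ]
  events <- ev$ctcf[[1]]
  obs <- mean(vapply(seq_len(nrow(events)), function(i) {
    any(events$chrom[i] == fam$chrom &
          events$start[i] < fam$end & events$end[i] > fam$start)
  }, logical(1)))
  p0 <- 400 * (300 + 300) / 1e7
  expect_lt(abs(obs - p0), 3 * sqrt(p0 * (1 - p0) / nrow(events)) + 0.01)

  # infeasible enrichment errors out
  cfg3 <- single_species_config(seed = 1, n_events = 2000,
    repeat_spec = list(list(rep_name = "HOT", rep_class = "X",
                            rep_family = "X", count = 5, enrichment = 50,
                            milli_div_mean = 100, length = 500)))
  map3 <- generate_alignment_map(cfg3)
  ev3 <- generate_binding_events(cfg3, map3)
  expect_error(generate_repeat_annotation(cfg3, ev3$ctcf), "infeasible")
})

test_that("expression generator is seeded and shifts class means", {
  cfg <- small_world_config(seed = 17)
  classes <- tibble::tibble(transcript_id = paste0("t", 1:600),
                            class = rep(c("CTCF_ONLY", "CTCF_YY1", "YY1_ONLY"),
                                        each = 200))
  e1 <- generate_expression(cfg, classes)
  e2 <- generate_expression(cfg, classes)
  expect_identical(e1, e2)

  mu <- tapply(e1$log2_estimate, e1$class, mean)
  expect_gt(mu[["CTCF_YY1"]], mu[["CTCF_ONLY"]] + 1)  # planted +2 shift

  # all-zero shifts give equal means within sampling error
  cfg0 <- small_world_config(seed = 17,
    expression_spec = list(baseline = 4, sd = 2,
                           shifts = c(CTCF_ONLY = 0, CTCF_YY1 = 0,
                                      YY1_ONLY = 0)))
  e0 <- generate_expression(cfg0, classes)
  mu0 <- tapply(e0$log2_estimate, e0$class, mean)
  se <- 2 / sqrt(200)
  expect_lt(max(mu0) - min(mu0), 6 * se)
})

test_that("word-hit generator plants the expansion in the focal species", {
  cfg <- small_world_config(seed = 23, n_events = 300)
  map <- generate_alignment_map(cfg)
  ev <- generate_binding_events(cfg, map)
  h1 <- generate_word_hits(cfg, ev$ctcf)
  h2 <- generate_word_hits(cfg, ev$ctcf)
  expect_identical(h1, h2)
  planted <- attr(h1, "planted_word")
  n_focal <- sum(h1[["H.sap"]]$word == planted)
  n_other <- mean(vapply(setdiff(names(h1), "H.sap"),
                         function(sp) sum(h1[[sp]]$word == planted),
                         numeric(1)))
  expect_gt(n_focal, 5 * max(n_other, 1))
  # hit positions fall inside the species' bound regions
  hs <- h1[["H.sap"]]
  bound <- ev$ctcf[["H.sap"]]
  inside <- vapply(seq_len(nrow(hs)), function(i) {
    any(hs$chrom[i] == bound$chrom & hs$position[i] >= bound$start &
          hs$position[i] < bound$end)
  }, logical(1))
  expect_true(all(inside))
})

test_that("world simulation is reproducible end to end", {
  cfg <- small_world_config(seed = 29, n_events = 150)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$expression, w2$expression)
  expect_identical(w1$repeats, w2$repeats)
  # transcripts carry one planted class per transcript
  expect_equal(nrow(w1$transcripts),
               nrow(w1$ctcf[["H.sap"]]) +
                 sum(grepl("^solo_", w1$yy1[["H.sap"]]$name)))
})
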