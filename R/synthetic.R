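# Seeded generator of multi-species synthetic "worlds": alignment blocks,
# planted binding events with known conservation classes, co-bound YY1
# events, repeat annotations with planted enrichments, motif-word hits with
# planted expansions, and expression values with planted class shifts.
#
# All generators are pure functions of (config, seed): sub-generators
# derive independent streams from the single world seed.

#' Species configuration
#'
#' @param name Species identifier.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param divergence_my Divergence time from the anchor species in million
#'   years (0 for the anchor itself).
#' @return A `species_config` list.
#' @export
species_config <- function(name, genome, divergence_my) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(is.numeric(genome), all(genome > 0), !is.null(names(genome)))
  stopifnot(divergence_my >= 0)
  structure(list(name = name, genome = genome,
                 divergence_my = divergence_my),
            class = "species_config")
}

#' Default seven-primate species panel
#'
#' Seven species with divergence times from the anchor (human) of 0, 6, 9,
#' 16, 29, 29 and 40 million years, mirroring the great ape / Old World
#' monkey / New World monkey panel typical of primate LCL comparisons. All
#' species share the same chromosome naming and lengths, which is the
#' simplification that lets orthology be simulated in a common ancestral
#' frame.
#'
#' @param genome Named vector of chromosome lengths (default two
#'   chromosomes totalling 10 Mb).
#' @return List of [species_config()] objects; the first is the anchor.
#' @export
default_primate_species <- function(genome = c(chr1 = 6e6, chr2 = 4e6)) {
  divs <- c(H.sap = 0, P.tro = 6, G.gor = 9, P.pyg = 16,
            M.mul = 29, P.ham = 29, S.oed = 40)
  purrr::imap(as.list(divs), function(d, nm) species_config(nm, genome, d))
}

default_class_proportions <- function() {
  c(UNALIGNED = 0.10, SPECIES_SPECIFIC = 0.10, TWO_WAY = 0.10,
    THREE_TO_FIVE = 0.25, SIX_WAY = 0.15, ALL = 0.30)
}

default_repeat_spec <- function() {
  list(
    list(rep_name = "LTR13", rep_class = "LTR", rep_family = "ERVK",
         count = 200, enrichment = 5, milli_div_mean = 110, length = 500),
    list(rep_name = "LTR41", rep_class = "LTR", rep_family = "ERVL",
         count = 150, enrichment = 3, milli_div_mean = 250, length = 500),
    list(rep_name = "MLT1J", rep_class = "LTR", rep_family = "ERVL-MaLR",
         count = 300, enrichment = 1, milli_div_mean = 300, length = 500),
    list(rep_name = "AluY", rep_class = "SINE", rep_family = "Alu",
         count = 400, enrichment = 1, milli_div_mean = 40, length = 300),
    list(rep_name = "L1PA3", rep_class = "LINE", rep_family = "L1",
         count = 250, enrichment = 1, milli_div_mean = 90, length = 1000),
    list(rep_name = "MIR", rep_class = "SINE", rep_family = "MIR",
         count = 300, enrichment = 1, milli_div_mean = 330, length = 260)
  )
}

default_word_spec <- function() {
  list(
    word_length = 14L,
    n_background_words = 1000L,
    base_rate = 8,
    planted = list(word = "TGGCCACCAGGGGG", species = NULL, fold = 10)
  )
}

default_expression_spec <- function() {
  list(baseline = 4, sd = 2,
       shifts = c(CTCF_ONLY = 0, CTCF_YY1 = 2, YY1_ONLY = 2))
}

#' Synthetic-world configuration
#'
#' Bundles every parameter the generators need. Defaults emulate a
#' seven-primate comparison: 2000 binding events over a 10 Mb anchor
#' genome, 80% alignability, conservation-class proportions weighted
#' toward highly shared binding, YY1 co-binding biased toward the highly
#' shared classes, one repeat family with a planted 5x binding enrichment,
#' one motif word with a planted 10x expansion in the anchor species, and
#' a +2 log2 expression shift for YY1-containing co-binding classes.
#'
#' @param species List of [species_config()]; the first entry is the
#'   anchor species (divergence 0).
#' @param n_events Number of planted CTCF events in the anchor species.
#' @param class_proportions Named vector over the six conservation classes
#'   summing to 1.
#' @param alignable_fraction Fraction of the anchor genome covered by
#'   alignment blocks, in \[0, 1\].
#' @param block_length Alignment-block length (bp).
#' @param event_length Binding-event length (bp).
#' @param membership_tau Exponential decay constant (My) for block
#'   species-membership probability `exp(-divergence / tau)`; pairwise
#'   sharing therefore declines with divergence time.
#' @param cobind_base,cobind_slope YY1 co-binding probability of a CTCF
#'   event shared by s of K species is
#'   `cobind_base + cobind_slope * (s - 1) / (K - 1)`.
#' @param yy1_solo_fraction Solo (YY1-only) events per species, as a
#'   fraction of `n_events`.
#' @param repeat_spec List of repeat-family entries (`rep_name`,
#'   `rep_class`, `rep_family`, `count`, `enrichment`, `milli_div_mean`,
#'   `length`); `enrichment` multiplies the uniform-background probability
#'   that a binding event overlaps the family.
#' @param word_spec Motif-word generation parameters (`word_length`,
#'   `n_background_words`, `base_rate`, `planted = list(word, species,
#'   fold)`; `species = NULL` plants in the anchor).
#' @param expression_spec Expression parameters (`baseline`, `sd`, named
#'   `shifts` per co-binding class, log2 units).
#' @param seed Integer world seed; all sub-generators derive their streams
#'   from it.
#' @return A `world_config` list.
#' @export
world_config <- function(species = default_primate_species(),
                         n_events = 2000L,
                         class_proportions = default_class_proportions(),
                         alignable_fraction = 0.8,
                         block_length = 5000L,
                         event_length = 300L,
                         membership_tau = 100,
                         cobind_base = 0.15,
                         cobind_slope = 0.35,
                         yy1_solo_fraction = 0.4,
                         repeat_spec = default_repeat_spec(),
                         word_spec = default_word_spec(),
                         expression_spec = default_expression_spec(),
                         seed = 1L) {
  stopifnot(length(species) >= 1)
  stopifnot(species[[1]]$divergence_my == 0)
  stopifnot(abs(sum(class_proportions) - 1) < 1e-9)
  stopifnot(all(class_proportions >= 0))
  stopifnot(setequal(names(class_proportions), CONSERVATION_CLASSES))
  stopifnot(alignable_fraction >= 0, alignable_fraction <= 1)
  stopifnot(cobind_base >= 0, cobind_base + cobind_slope <= 1)
  stopifnot(n_events >= 0, event_length > 0, block_length >= event_length)
  structure(list(
    species = species, n_events = as.integer(n_events),
    class_proportions = class_proportions,
    alignable_fraction = alignable_fraction,
    block_length = as.integer(block_length),
    event_length = as.integer(event_length),
    membership_tau = membership_tau,
    cobind_base = cobind_base, cobind_slope = cobind_slope,
    yy1_solo_fraction = yy1_solo_fraction,
    repeat_spec = repeat_spec, word_spec = word_spec,
    expression_spec = expression_spec,
    seed = as.integer(seed)
  ), class = "world_config")
}

species_names <- function(config) {
  vapply(config$species, `[[`, character(1), "name")
}

anchor_species <- function(config) config$species[[1]]$name

# Independent sub-stream seeds derived from the world seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483629) + 1L
}

# Deterministic block scaffold on the anchor genome (no RNG): per chrom,
# n blocks of block_length spread at even spacing; returns tibble
# chrom, block_index, anchor_start, spacing.
block_scaffold <- function(config) {
  genome <- config$species[[1]]$genome
  f <- config$alignable_fraction
  B <- config$block_length
  rows <- purrr::imap(as.list(genome), function(L, chrom) {
    n <- floor(L * f / B)
    if (n == 0) return(NULL)
    spacing <- floor(L / n)
    tibble::tibble(chrom = chrom,
                   block_index = seq_len(n) - 1L,
                   anchor_start = as.integer((seq_len(n) - 1L) * spacing),
                   spacing = as.integer(spacing))
  })
  out <- dplyr::bind_rows(rows)
  if (f > 0 && nrow(out) == 0) {
    stop("alignable_fraction not achievable: no chromosome can hold a block")
  }
  out
}

#' Generate a synthetic alignment map
#'
#' Non-overlapping blocks tile `alignable_fraction` of the anchor genome.
#' The anchor species is present in every block; every other species joins
#' a block independently with probability `exp(-divergence_my /
#' membership_tau)`, so distant species are aligned over less of the
#' genome. Member segments have equal length, are jittered within the
#' block's spacing window of their own genome (keeping per-species
#' segments non-overlapping), and are reverse-oriented with probability
#' 0.1.
#'
#' @param config A [world_config()].
#' @return An alignment-map tibble (`block_id`, `species`, `chrom`,
#'   `start`, `end`, `strand`).
#' @export
generate_alignment_map <- function(config) {
  scaffold <- block_scaffold(config)
  if (nrow(scaffold) == 0) {
    return(tibble::tibble(block_id = character(), species = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  B <- config$block_length
  sps <- species_names(config)
  divs <- vapply(config$species, `[[`, numeric(1), "divergence_my")
  withr::with_seed(sub_seed(config$seed, 1L), {
    rows <- purrr::map(seq_along(sps), function(si) {
      sp <- sps[si]
      if (si == 1) {
        member <- rep(TRUE, nrow(scaffold))
      } else {
        p <- exp(-divs[si] / config$membership_tau)
        member <- stats::runif(nrow(scaffold)) < p
      }
      sc <- scaffold[member, , drop = FALSE]
      if (nrow(sc) == 0) return(NULL)
      # jitter within the spacing window; anchor stays at the scaffold start
      room <- sc$spacing - B
      jit <- if (si == 1) 0L else as.integer(floor(stats::runif(nrow(sc)) * (room + 1)))
      strand <- if (si == 1) rep("+", nrow(sc)) else
        ifelse(stats::runif(nrow(sc)) < 0.1, "-", "+")
      tibble::tibble(
        block_id = sprintf("b_%s_%05d", sc$chrom, sc$block_index),
        species = sp,
        chrom = sc$chrom,
        start = as.integer(sc$block_index * sc$spacing + jit),
        end = as.integer(sc$block_index * sc$spacing + jit + B),
        strand = strand
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Slot tables: candidate non-overlapping event positions (anchor frame).
# Aligned slots live inside blocks; gap slots between/after blocks.
aligned_slots <- function(config, scaffold) {
  B <- config$block_length
  sw <- config$event_length + 100L
  k <- floor(B / sw)
  tidyr::crossing(scaffold, slot = seq_len(k) - 1L) |>
    dplyr::mutate(
      block_id = sprintf("b_%s_%05d", .data$chrom, .data$block_index),
      offset = .data$slot * sw
    ) |>
    dplyr::select("block_id", "chrom", "anchor_start", "offset")
}

gap_slots <- function(config, scaffold) {
  genome <- config$species[[1]]$genome
  sw <- config$event_length + 100L
  B <- config$block_length
  gaps <- purrr::imap(as.list(genome), function(L, ch) {
    sc <- scaffold[scaffold$chrom == ch, , drop = FALSE]
    if (nrow(sc) == 0) return(tibble::tibble(chrom = ch, gstart = 0L, gend = as.integer(L)))
    # gap after each block runs to the next block's scaffold start
    tibble::tibble(chrom = ch,
                   gstart = as.integer(sc$anchor_start + B),
                   gend = as.integer(pmin(sc$anchor_start + sc$spacing, L)))
  })
  gaps <- dplyr::bind_rows(gaps)
  gaps <- gaps[gaps$gend - gaps$gstart >= sw, , drop = FALSE]
  if (nrow(gaps) == 0) {
    return(tibble::tibble(chrom = character(), start = integer()))
  }
  rows <- purrr::pmap(gaps, function(chrom, gstart, gend) {
    k <- floor((gend - gstart) / sw)
    tibble::tibble(chrom = chrom,
                   start = as.integer(gstart + (seq_len(k) - 1L) * sw))
  })
  dplyr::bind_rows(rows)
}

#' Generate planted binding events with known conservation classes
#'
#' For each of `n_events` anchor CTCF events a conservation class is drawn
#' from `class_proportions`. `UNALIGNED` events are placed in the gaps
#' between alignment blocks; all other events are placed in
#' non-overlapping slots inside blocks whose member species can support
#' the class, and orthologous copies are planted at the projected
#' coordinates in exactly the chosen member species. A fraction of CTCF
#' events (increasing with sharing, see [world_config()]) receives a
#' co-located YY1 event in each member species; additional solo YY1-only
#' events are placed per species in block gaps. Summits are uniform within
#' events.
#'
#' @param config A [world_config()].
#' @param map Alignment map generated from the same config.
#' @return A list with elements `ctcf` and `yy1` (named lists of
#'   binding-event tibbles per species) and `truth` (tibble `event_id`,
#'   `class`, `members`, `cobound`, anchor coordinates).
#' @export
generate_binding_events <- function(config, map) {
  sps <- species_names(config)
  anchor <- anchor_species(config)
  K <- length(sps)
  len <- config$event_length
  scaffold <- block_scaffold(config)
  n <- config$n_events

  empty_set <- function(sp, fac) {
    binding_events(tibble::tibble(chrom = character(), start = integer(),
                                  end = integer()), sp, fac)
  }
  if (n == 0) {
    return(list(
      ctcf = stats::setNames(lapply(sps, empty_set, fac = "CTCF"), sps),
      yy1 = stats::setNames(lapply(sps, empty_set, fac = "YY1"), sps),
      truth = tibble::tibble(event_id = character(), class = character(),
                             members = character(), cobound = logical())
    ))
  }

  withr::with_seed(sub_seed(config$seed, 2L), {
    classes <- sample(names(config$class_proportions), n, replace = TRUE,
                      prob = config$class_proportions)
    # sharing count per event
    s_needed <- vapply(classes, function(cl) {
      switch(cl,
             UNALIGNED = 1L, SPECIES_SPECIFIC = 1L, TWO_WAY = 2L,
             THREE_TO_FIVE = sample(3:max(3L, K - 2L), 1L),
             SIX_WAY = K - 1L, ALL = K)
    }, integer(1))

    # block membership (non-anchor species per block)
    memb <- map |>
      dplyr::filter(.data$species != anchor) |>
      dplyr::group_by(.data$block_id) |>
      dplyr::summarise(others = list(.data$species), .groups = "drop")
    n_others <- stats::setNames(lengths(memb$others), memb$block_id)

    slots <- aligned_slots(config, scaffold)
    slots$n_others <- dplyr::coalesce(n_others[slots$block_id], 0L)
    slots <- slots[sample.int(nrow(slots)), ]  # random order
    avail <- rep(TRUE, nrow(slots))

    is_unaligned <- classes == "UNALIGNED"
    idx_aligned <- which(!is_unaligned)
    # assign slots, most demanding sharing counts first
    slot_of <- integer(n)
    for (s in sort(unique(s_needed[idx_aligned]), decreasing = TRUE)) {
      ev <- idx_aligned[s_needed[idx_aligned] == s]
      # aligned events need a block carrying >= 1 other species (so that
      # "included in the alignments" is meaningful), except in a
      # single-species world where no other species exists
      need_others <- if (K == 1L) 0L else max(s - 1L, 1L)
      ok <- which(avail & slots$n_others >= need_others)
      if (length(ok) < length(ev)) {
        stop("not enough alignment-block slots for sharing count ", s)
      }
      pick <- ok[seq_along(ev)]
      slot_of[ev] <- pick
      avail[pick] <- FALSE
    }
    gslots <- gap_slots(config, scaffold)
    n_un <- sum(is_unaligned)
    if (n_un > nrow(gslots)) {
      stop("not enough unaligned (gap) space for ", n_un, " UNALIGNED events")
    }
    gorder <- sample.int(nrow(gslots))
    gap_used <- gorder[seq_len(n_un)]

    # anchor coordinates
    chrom <- character(n); start <- integer(n)
    chrom[!is_unaligned] <- slots$chrom[slot_of[idx_aligned]]
    start[!is_unaligned] <- slots$anchor_start[slot_of[idx_aligned]] +
      slots$offset[slot_of[idx_aligned]]
    chrom[is_unaligned] <- gslots$chrom[gap_used]
    start[is_unaligned] <- gslots$start[gap_used]
    end <- start + len

    # sharing members: anchor plus (s-1) species drawn from block members
    members <- vector("list", n)
    block_of <- rep(NA_character_, n)
    block_of[idx_aligned] <- slots$block_id[slot_of[idx_aligned]]
    others_of <- stats::setNames(memb$others, memb$block_id)
    for (i in seq_len(n)) {
      if (is_unaligned[i] || s_needed[i] == 1L) {
        members[[i]] <- anchor
      } else {
        pool <- others_of[[block_of[i]]]
        members[[i]] <- c(anchor, sample(pool, s_needed[i] - 1L))
      }
    }

    summit_off <- as.integer(floor(stats::runif(n) * len))
    score <- round(stats::rgamma(n, shape = 2 + s_needed, rate = 0.2), 2)
    fdr <- round(stats::runif(n, 0, 0.05), 5)
    event_id <- sprintf("ev%05d", seq_len(n))

    p_cobind <- config$cobind_base +
      config$cobind_slope * (s_needed - 1) / max(K - 1, 1)
    cobound <- stats::runif(n) < p_cobind
    yy1_shift <- as.integer(10 + floor(stats::runif(n) * 41))  # 10..50

    anchor_ev <- tibble::tibble(
      chrom = chrom, start = start, end = end, name = event_id,
      score = score, strand = "*", fdr = fdr, summit = start + summit_off
    )

    truth <- tibble::tibble(
      event_id = event_id, class = classes,
      members = vapply(members, paste, character(1), collapse = ","),
      cobound = cobound, chrom = chrom, start = start, end = end
    )

    # per-species CTCF/YY1 sets via projection of the anchor events
    ctcf_sets <- list()
    yy1_sets <- list()
    ctcf_sets[[anchor]] <- binding_events(anchor_ev, anchor, "CTCF")
    yy1_anchor <- anchor_ev[cobound, , drop = FALSE]
    yy1_anchor$start <- yy1_anchor$start + yy1_shift[cobound]
    yy1_anchor$end <- yy1_anchor$end + yy1_shift[cobound]
    yy1_anchor$summit <- pmin(yy1_anchor$start + summit_off[cobound],
                              yy1_anchor$end - 1L)
    yy1_anchor$name <- sub("^ev", "yy", yy1_anchor$name)

    member_mat <- matrix(FALSE, n, K, dimnames = list(NULL, sps))
    for (i in seq_len(n)) member_mat[i, members[[i]]] <- TRUE

    for (sp in sps[-1]) {
      in_sp <- member_mat[, sp]
      ct <- project_planted(anchor_ev[in_sp, , drop = FALSE], map, anchor, sp)
      ctcf_sets[[sp]] <- binding_events(ct, sp, "CTCF")
      yw <- cobound & in_sp
      ysrc <- anchor_ev[yw, , drop = FALSE]
      ysrc$start <- ysrc$start + yy1_shift[yw]
      ysrc$end <- ysrc$end + yy1_shift[yw]
      ysrc$summit <- pmin(ysrc$start + summit_off[yw], ysrc$end - 1L)
      ysrc$name <- sub("^ev", "yy", ysrc$name)
      yy1_sets[[sp]] <- project_planted(ysrc, map, anchor, sp)
    }

    # solo YY1-only events, independent per species, placed in block gaps
    n_solo <- round(config$yy1_solo_fraction * n)
    free_gaps <- gslots[-gap_used, , drop = FALSE]
    for (sp in sps) {
      pool <- if (identical(sp, anchor)) free_gaps else gslots
      # keep solo events clear of the species' planted CTCF events
      if (nrow(pool) > 0) {
        cand <- tibble::tibble(chrom = pool$chrom, start = pool$start,
                               end = pool$start + len)
        pool <- pool[!overlap_any(cand, ctcf_sets[[sp]]), , drop = FALSE]
      }
      n_take <- min(n_solo, nrow(pool))
      take <- pool[sample.int(nrow(pool), n_take), , drop = FALSE]
      solo <- tibble::tibble(
        chrom = take$chrom, start = take$start, end = take$start + len,
        name = sprintf("solo_%s_%04d", sp, seq_len(n_take)),
        score = round(stats::rgamma(n_take, shape = 3, rate = 0.2), 2),
        strand = "*", fdr = round(stats::runif(n_take, 0, 0.05), 5),
        summit = take$start + as.integer(floor(stats::runif(n_take) * len))
      )
      prev <- if (identical(sp, anchor)) yy1_anchor else yy1_sets[[sp]]
      yy1_sets[[sp]] <- binding_events(
        dplyr::bind_rows(prev[intersect(names(prev), names(solo))], solo),
        sp, "YY1"
      )
    }
    list(ctcf = ctcf_sets[sps], yy1 = yy1_sets[sps], truth = truth)
  })
}

# Project planted events (each within a single block) to a member species,
# preserving names/scores and mapping the summit offset through strand
# reversal.
project_planted <- function(events, map, from_sp, to_sp) {
  if (nrow(events) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character(),
                          fdr = numeric(), summit = integer()))
  }
  pr <- project_intervals(events, map, from_sp, to_sp)
  src <- events[pr$query, , drop = FALSE]
  off <- src$summit - src$start
  len <- pr$end - pr$start
  summit <- ifelse(pr$strand == "+", pr$start + off, pr$end - 1L - off)
  tibble::tibble(
    chrom = pr$chrom, start = pr$start, end = pr$end,
    name = src$name, score = round(src$score * stats::runif(nrow(pr), 0.8, 1.2), 2),
    strand = "*", fdr = round(stats::runif(nrow(pr), 0, 0.05), 5),
    summit = as.integer(pmin(pmax(summit, pr$start), pr$end - 1L))
  )
}

#' Generate repeat annotations with planted binding enrichments
#'
#' For each family of `repeat_spec`, elements are placed so that the
#' probability a binding event overlaps the family is approximately
#' `enrichment` times the uniform-placement background rate: a computed
#' fraction of elements is centred on randomly chosen event summits, the
#' rest are uniform on the genome. milliDiv values are drawn around the
#' family's `milli_div_mean`.
#'
#' @param config A [world_config()].
#' @param events Named list of per-species binding-event tibbles (the CTCF
#'   sets of [generate_binding_events()]).
#' @return Named list (per species) of repeat tibbles; each carries a
#'   `planted` attribute with the family ground truth.
#' @export
generate_repeat_annotation <- function(config, events) {
  genome <- config$species[[1]]$genome
  G <- sum(genome)
  len_e <- config$event_length
  withr::with_seed(sub_seed(config$seed, 3L), {
    out <- purrr::imap(events, function(ev, sp) {
      fam_rows <- purrr::map(config$repeat_spec, function(fs) {
        count <- fs$count
        if (count == 0) return(NULL)
        p0 <- count * (fs$length + len_e) / G
        n_ev <- nrow(ev)
        extra <- (fs$enrichment - 1) * p0 * n_ev
        if (extra > count) {
          stop("enrichment infeasible for ", fs$rep_name,
               ": needs more planted elements than the family has")
        }
        pi_on <- max(0, extra / count)
        on_event <- stats::runif(count) < pi_on
        n_on <- sum(on_event)
        start <- integer(count)
        chrom <- character(count)
        if (n_on > 0 && n_ev > 0) {
          tgt <- ev[sample.int(n_ev, n_on, replace = TRUE), , drop = FALSE]
          chrom[on_event] <- tgt$chrom
          start[on_event] <- pmax(0L, as.integer(tgt$summit - fs$length %/% 2))
        }
        n_off <- count - n_on
        if (n_off > 0) {
          ch <- sample(names(genome), n_off, replace = TRUE,
                       prob = genome / G)
          chrom[!on_event] <- ch
          start[!on_event] <- as.integer(floor(
            stats::runif(n_off) * (genome[ch] - fs$length)))
        }
        md <- pmax(0L, as.integer(round(
          stats::rnorm(count, fs$milli_div_mean, fs$milli_div_mean * 0.15))))
        tibble::tibble(
          chrom = chrom, start = start,
          end = as.integer(start + fs$length),
          strand = sample(c("+", "-"), count, replace = TRUE),
          rep_name = fs$rep_name, rep_class = fs$rep_class,
          rep_family = fs$rep_family, milli_div = md
        )
      })
      empty_reps <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), rep_name = character(),
        rep_class = character(), rep_family = character(),
        milli_div = integer())
      reps <- dplyr::arrange(dplyr::bind_rows(empty_reps, fam_rows),
                             .data$chrom, .data$start)
      attr(reps, "planted") <- tibble::tibble(
        rep_name = vapply(config$repeat_spec, `[[`, character(1), "rep_name"),
        enrichment = vapply(config$repeat_spec, `[[`, numeric(1), "enrichment")
      )
      reps
    })
    out
  })
}

#' Generate motif-word scan hits with a planted expansion
#'
#' Background words receive Poisson(`base_rate`) occurrences per species,
#' placed at uniform offsets inside that species' bound regions; the
#' planted word receives `fold` times the base rate in its focal species.
#' The output mimics a PWM genome scan restricted to hits that downstream
#' word counting will find inside bound regions.
#'
#' @param config A [world_config()].
#' @param events Named list of per-species binding-event tibbles.
#' @return Named list (per species) of hit tibbles (`chrom`, `position`,
#'   `strand`, `word`, `score`); carries attribute `planted_word`.
#' @export
generate_word_hits <- function(config, events) {
  ws <- config$word_spec
  L <- ws$word_length
  focal <- ws$planted$species %||% anchor_species(config)
  withr::with_seed(sub_seed(config$seed, 4L), {
    bases <- c("A", "C", "G", "T")
    words <- unique(vapply(seq_len(ws$n_background_words), function(i) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1)))
    words <- setdiff(words, ws$planted$word)
    all_words <- c(words, ws$planted$word)
    out <- purrr::imap(events, function(ev, sp) {
      lambda <- rep(ws$base_rate, length(all_words))
      if (identical(sp, focal) && !is.null(ws$planted$word)) {
        lambda[length(all_words)] <- ws$base_rate * ws$planted$fold
      }
      counts <- stats::rpois(length(all_words), lambda)
      word <- rep(all_words, counts)
      m <- length(word)
      if (m == 0 || nrow(ev) == 0) {
        return(tibble::tibble(chrom = character(), position = integer(),
                              strand = character(), word = character(),
                              score = numeric()))
      }
      host <- ev[sample.int(nrow(ev), m, replace = TRUE), , drop = FALSE]
      offset <- as.integer(floor(stats::runif(m) * (host$end - host$start - L)))
      tibble::tibble(
        chrom = host$chrom,
        position = host$start + offset,
        strand = sample(c("+", "-"), m, replace = TRUE),
        word = word,
        score = round(-stats::runif(m) * 14, 3)
      ) |>
        dplyr::arrange(.data$chrom, .data$position)
    })
    out <- purrr::map(out, function(x) {
      attr(x, "planted_word") <- ws$planted$word
      x
    })
    attr(out, "planted_word") <- ws$planted$word
    attr(out, "planted_species") <- focal
    out
  })
}

#' Generate log2 expression values with planted class shifts
#'
#' @param config A [world_config()].
#' @param cobind_classes Tibble with columns `transcript_id` and `class`
#'   (one of `CTCF_ONLY`, `CTCF_YY1`, `YY1_ONLY`).
#' @return Tibble `transcript_id`, `class`, `log2_estimate`.
#' @export
generate_expression <- function(config, cobind_classes) {
  es <- config$expression_spec
  withr::with_seed(sub_seed(config$seed, 5L), {
    shift <- es$shifts[cobind_classes$class]
    shift[is.na(shift)] <- 0
    tibble::tibble(
      transcript_id = cobind_classes$transcript_id,
      class = cobind_classes$class,
      log2_estimate = stats::rnorm(nrow(cobind_classes),
                                   es$baseline + shift, es$sd)
    )
  })
}

#' Simulate a complete synthetic world
#'
#' Runs every generator in dependency order: alignment map, binding events
#' (CTCF + YY1 with ground-truth conservation classes and co-binding
#' flags), repeat annotations, motif-word hits, transcripts anchored on
#' the anchor species' events, and expression values.
#'
#' @param config A [world_config()].
#' @return A list: `config`, `map`, `ctcf`, `yy1`, `truth`, `repeats`,
#'   `word_hits`, `transcripts` (feature tibble with `kind =
#'   "transcript"`), `expression`.
#' @export
simulate_world <- function(config) {
  map <- generate_alignment_map(config)
  ev <- generate_binding_events(config, map)
  reps <- generate_repeat_annotation(config, ev$ctcf)
  hits <- generate_word_hits(config, ev$ctcf)
  anchor <- anchor_species(config)
  # transcripts: one per anchor CTCF event and per anchor solo YY1 event,
  # extended 50 bp each side (staying clear of neighbouring event slots);
  # planted class from the ground truth
  a_ctcf <- ev$ctcf[[anchor]]
  truth <- ev$truth
  cls <- ifelse(truth$cobound[match(a_ctcf$name, truth$event_id)],
                "CTCF_YY1", "CTCF_ONLY")
  a_yy1 <- ev$yy1[[anchor]]
  solo <- a_yy1[grepl("^solo_", a_yy1$name), , drop = FALSE]
  transcripts <- tibble::tibble(
    kind = "transcript",
    id = paste0("tx_", c(a_ctcf$name, solo$name)),
    chrom = c(a_ctcf$chrom, solo$chrom),
    start = pmax(0L, c(a_ctcf$start, solo$start) - 50L),
    end = c(a_ctcf$end, solo$end) + 50L
  )
  classes <- tibble::tibble(
    transcript_id = transcripts$id,
    class = c(cls, rep("YY1_ONLY", nrow(solo)))
  )
  expr <- generate_expression(config, classes)
  list(config = config, map = map, ctcf = ev$ctcf, yy1 = ev$yy1,
       truth = truth, repeats = reps, word_hits = hits,
       transcripts = transcripts, expression = expr)
}
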