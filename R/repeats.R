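# Randomization-calibrated binomial enrichment of binding events in
# repeat families, repeat age from milliDiv, and summit-centred profiles.

#' Randomize binding-event placements
#'
#' Each event is replaced by a uniformly placed interval of identical
#' length on its own chromosome; the per-chromosome length multiset is
#' preserved. Overlaps among randomized events are permitted.
#'
#' @param events Binding-event tibble.
#' @param genome Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @return A binding-event tibble with randomized coordinates.
#' @export
randomize_events <- function(events, genome, seed) {
  lens <- events$end - events$start
  L <- genome[events$chrom]
  if (any(is.na(L))) {
    stop("chromosome missing from genome: ",
         events$chrom[which(is.na(L))[1]])
  }
  if (any(lens > L)) stop("event longer than its chromosome")
  withr::with_seed(seed, {
    start <- as.integer(floor(stats::runif(nrow(events)) * (L - lens + 1)))
  })
  out <- events
  out$start <- start
  out$end <- start + lens
  out$summit <- start + (events$summit - events$start)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

# Internal: events overlapping >= 1 element per repeat name; an event
# overlapping several elements of a family counts once.
overlap_counts_by_name <- function(events, repeats) {
  p <- overlap_pairs(events, repeats)
  if (nrow(p) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  hits <- tibble::tibble(query = p$query,
                         rep_name = repeats$rep_name[p$subject]) |>
    dplyr::distinct()
  tab <- table(hits$rep_name)
  stats::setNames(as.integer(tab), names(tab))
}

#' Binomial repeat-family enrichment test with randomized background
#'
#' For each repeat name, `k` counts the binding events overlapping at
#' least one element of the family. The background probability is the
#' median, over `n_rand` seeded randomizations of the event set, of the
#' randomized overlap count divided by the number of events, floored at
#' `1 / (n * n_rand + 1)` to avoid zero backgrounds. The one-sided
#' binomial upper-tail p-value `P(X >= k | Binomial(n, p_bg))` is
#' corrected across families by Benjamini-Hochberg.
#'
#' @param events Binding-event tibble.
#' @param repeats Repeat tibble (see [read_repeatmasker()]).
#' @param genome Named vector of chromosome lengths (for randomization).
#' @param n_rand Number of randomizations (default 100, minimum 10).
#' @param seed Integer seed for the randomizations.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param use_adjusted Flag significance on the BH-adjusted p-value
#'   (default) or on the raw p-value.
#' @return A tibble sorted by p-value: `rep_name`, `species`, `k`, `n`,
#'   `p_bg`, `p_value`, `p_adj`, `neg_log_p` (-log10 of the raw p),
#'   `significant`.
#' @export
repeat_enrichment_test <- function(events, repeats, genome, n_rand = 100L,
                                   seed = 1L, alpha = 0.01,
                                   use_adjusted = TRUE) {
  stopifnot(n_rand >= 10)
  sp <- unique(events$species)
  if (length(sp) == 0) sp <- NA_character_
  if (nrow(repeats) == 0) {
    return(tibble::tibble(rep_name = character(), species = character(),
                          k = integer(), n = integer(), p_bg = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          neg_log_p = numeric(), significant = logical()))
  }
  names_all <- sort(unique(repeats$rep_name))
  n <- nrow(events)
  obs <- overlap_counts_by_name(events, repeats)
  k <- stats::setNames(rep(0L, length(names_all)), names_all)
  k[names(obs)] <- obs
  # all randomizations in one batch: uniform placement per chromosome
  # with per-chromosome length multisets preserved, then a single overlap
  # query against the repeat annotation
  lens <- events$end - events$start
  L <- genome[events$chrom]
  if (any(is.na(L))) stop("chromosome missing from genome")
  if (any(lens > L)) stop("event longer than its chromosome")
  starts <- withr::with_seed(seed, {
    as.integer(floor(stats::runif(n * n_rand) * rep(L - lens + 1, n_rand)))
  })
  rand_ev <- tibble::tibble(
    rand = rep(seq_len(n_rand), each = n),
    event = rep(seq_len(n), n_rand),
    chrom = rep(events$chrom, n_rand),
    start = starts,
    end = starts + rep(lens, n_rand)
  )
  rp <- overlap_pairs(rand_ev, repeats)
  rand_counts <- matrix(0L, nrow = n_rand, ncol = length(names_all),
                        dimnames = list(NULL, names_all))
  if (nrow(rp) > 0) {
    hits <- dplyr::distinct(tibble::tibble(
      rand = rand_ev$rand[rp$query],
      event = rand_ev$event[rp$query],
      rep_name = repeats$rep_name[rp$subject]
    ))
    tab <- table(hits$rand, hits$rep_name)
    rand_counts[as.integer(rownames(tab)), colnames(tab)] <- tab
  }
  p_floor <- 1 / (n * n_rand + 1)
  p_bg <- pmax(apply(rand_counts, 2, stats::median) / n, p_floor)
  p_bg <- pmin(p_bg, 1 - p_floor)
  p_value <- stats::pbinom(k - 1L, size = n, prob = p_bg,
                           lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_value, method = "BH")
  out <- tibble::tibble(
    rep_name = names_all, species = sp, k = unname(k), n = n,
    p_bg = unname(p_bg), p_value = unname(p_value), p_adj = unname(p_adj),
    neg_log_p = -log10(unname(p_value)),
    significant = (if (use_adjusted) p_adj else p_value) <= alpha
  )
  dplyr::arrange(out, .data$p_value, .data$rep_name)
}

#' Repeat age from milliDiv divergence
#'
#' Converts RepeatMasker milliDiv (substitutions per 1000 bp from the
#' repeat consensus) to an age in years by dividing the substitution rate
#' per base pair by the neutral mutation rate: 2.2e-9 substitutions per
#' bp per year for mammals, 4.5e-9 for rodents.
#'
#' @param milli_div Integer vector of milliDiv values (>= 0).
#' @param lineage `"mammal"` (default) or `"rodent"`.
#' @return Tibble `milli_div`, `mutation_rate`, `age_years`.
#' @examples
#' repeat_age(220)            # 1e8 years at the mammalian rate
#' repeat_age(90, "rodent")   # 2e7 years
#' @export
repeat_age <- function(milli_div, lineage = c("mammal", "rodent")) {
  lineage <- match.arg(lineage)
  stopifnot(all(milli_div >= 0))
  rate <- switch(lineage, mammal = 2.2e-9, rodent = 4.5e-9)
  tibble::tibble(
    milli_div = milli_div,
    mutation_rate = rate,
    age_years = (milli_div / 1000) / rate
  )
}

#' Summit-centred window profile
#'
#' Quantifies a track in `n_windows` windows of `window_bp` bases each,
#' centred on every event summit (the default 200 x 50 bp grid spans
#' 10 kb). In `repeat_coverage` mode the value is the fraction of window
#' bases covered by track elements; in `read_count` mode it is the number
#' of track intervals (reads) overlapping the window. Windows truncated
#' by a chromosome end are zero-filled and flagged.
#'
#' @param events Binding-event tibble with summits.
#' @param track Interval tibble (`chrom`, `start`, `end`): repeat elements
#'   or read placements.
#' @param mode `"repeat_coverage"` or `"read_count"`.
#' @param n_windows,window_bp Window grid (defaults 200 and 50).
#' @return A `summit_profile` list: `matrix` (events x windows),
#'   `profile` (column means), `truncated` (logical per event), `mode`,
#'   `window_bp`.
#' @export
summit_repeat_profile <- function(events, track,
                                  mode = c("repeat_coverage", "read_count"),
                                  n_windows = 200L, window_bp = 50L) {
  mode <- match.arg(mode)
  n <- nrow(events)
  half_span <- as.integer(n_windows * window_bp / 2)
  win_start <- outer(events$summit - half_span,
                     (seq_len(n_windows) - 1L) * window_bp, `+`)
  mat <- matrix(0, nrow = n, ncol = n_windows)
  truncated <- rep(FALSE, n)
  if (n > 0 && nrow(track) > 0) {
    if (mode == "repeat_coverage") {
      # merge overlapping elements so summed overlaps equal union coverage
      red <- GenomicRanges::reduce(as_granges(track))
      track <- tibble::tibble(
        chrom = as.character(GenomicRanges::seqnames(red)),
        start = GenomicRanges::start(red) - 1L,
        end = GenomicRanges::end(red)
      )
    }
    windows <- tibble::tibble(
      event = rep(seq_len(n), n_windows),
      win = rep(seq_len(n_windows), each = n),
      chrom = rep(events$chrom, n_windows),
      start = as.vector(win_start),
      end = as.vector(win_start) + window_bp
    )
    neg <- windows$start < 0
    truncated[unique(windows$event[neg])] <- TRUE
    windows$start[windows$start < 0] <- 0L
    ok <- windows$start < windows$end
    p <- overlap_pairs(windows[ok, ], track)
    if (nrow(p) > 0) {
      w <- windows[ok, ][p$query, ]
      t <- track[p$subject, ]
      if (mode == "repeat_coverage") {
        ovl <- pmin(w$end, t$end) - pmax(w$start, t$start)
        agg <- tapply(ovl, list(factor(w$event, levels = seq_len(n)),
                                factor(w$win, levels = seq_len(n_windows))),
                      sum, default = 0)
        mat <- pmin(unclass(agg) / window_bp, 1)
      } else {
        agg <- tapply(rep(1L, nrow(w)),
                      list(factor(w$event, levels = seq_len(n)),
                           factor(w$win, levels = seq_len(n_windows))),
                      sum, default = 0)
        mat <- unclass(agg)
      }
      dimnames(mat) <- NULL
    }
  }
  structure(list(
    matrix = mat,
    profile = if (n > 0) colMeans(mat) else rep(0, n_windows),
    truncated = truncated,
    mode = mode, window_bp = window_bp, n_windows = n_windows
  ), class = "summit_profile")
}

#' @export
print.summit_profile <- function(x, ...) {
  cat(sprintf("summit profile: %d events x %d windows of %d bp (%s mode)\n",
              nrow(x$matrix), x$n_windows, x$window_bp, x$mode))
  invisible(x)
}
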