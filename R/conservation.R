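# Cross-species projection of binding events over orthology alignment
# blocks and classification into the six conservation classes.
#
# An alignment map is a tidy block table: one row per (block, species)
# segment with columns block_id, species, chrom, start, end, strand.
# Blocks stand in for whole-genome multiple-alignment (EPO-style) blocks:
# all segments of a block are orthologous, and within a species the
# segments of the map never overlap.

CONSERVATION_CLASSES <- c(
  "UNALIGNED", "SPECIES_SPECIFIC", "TWO_WAY",
  "THREE_TO_FIVE", "SIX_WAY", "ALL"
)

#' Read / write an alignment block table
#'
#' The block-table TSV has one row per per-species segment with columns
#' `block_id`, `species`, `chrom`, `start`, `end`, `strand` (0-based
#' half-open coordinates).
#'
#' @param path Path to the TSV (with header).
#' @return A tibble with the six columns above.
#' @export
read_alignment_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "character"))
  df <- tibble::as_tibble(df)
  names(df) <- c("block_id", "species", "chrom", "start", "end", "strand")
  validate_intervals(df, "alignment block")
  df
}

#' @rdname read_alignment_blocks
#' @param map An alignment-map tibble.
#' @export
write_alignment_blocks <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

map_species <- function(map) unique(map$species)

# Internal: segments of one species.
species_segments <- function(map, sp) {
  map[map$species == sp, , drop = FALSE]
}

#' Project intervals from one species onto another
#'
#' Each query interval is intersected with the source-species segments of
#' the alignment blocks; every overlapped piece that has a segment in the
#' target species is mapped across by offset within the block
#' (proportional scaling when segment lengths differ, coordinate reversal
#' when the two segments lie on opposite strands). An interval covered by
#' no block, or only by blocks lacking the target species, contributes no
#' projection.
#'
#' @param intervals Data frame of query intervals (`chrom`, `start`, `end`).
#' @param map Alignment-map tibble (see [read_alignment_blocks()]).
#' @param from_sp,to_sp Source and target species identifiers.
#' @return A tibble with one row per projected piece: `query` (row index
#'   into `intervals`), `block_id`, `chrom`, `start`, `end`, `strand`
#'   (orientation of the mapping: `-` when reversed).
#' @export
project_intervals <- function(intervals, map, from_sp, to_sp) {
  sps <- map_species(map)
  if (!from_sp %in% sps) stop("unknown species in map: ", from_sp)
  if (!to_sp %in% sps) stop("unknown species in map: ", to_sp)
  empty <- tibble::tibble(
    query = integer(), block_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character()
  )
  if (nrow(intervals) == 0) return(empty)
  from_seg <- species_segments(map, from_sp)
  to_seg <- species_segments(map, to_sp)
  hits <- overlap_pairs(intervals, from_seg)
  if (nrow(hits) == 0) return(empty)
  f <- from_seg[hits$subject, ]
  q <- intervals[hits$query, ]
  t_idx <- match(f$block_id, to_seg$block_id)
  keep <- !is.na(t_idx)
  if (!any(keep)) return(empty)
  f <- f[keep, ]; q <- q[keep, ]
  t <- to_seg[t_idx[keep], ]
  qi <- hits$query[keep]
  # overlapped sub-interval, relative to the source segment
  ov_start <- pmax(q$start, f$start)
  ov_end <- pmin(q$end, f$end)
  rel_start <- ov_start - f$start
  rel_end <- ov_end - f$start
  f_len <- f$end - f$start
  t_len <- t$end - t$start
  scale_pos <- function(p) {
    as.integer(round(as.numeric(p) * (as.numeric(t_len) / as.numeric(f_len))))
  }
  ps <- scale_pos(rel_start)
  pe <- pmax(scale_pos(rel_end), ps + 1L)  # never collapse to zero width
  reversed <- f$strand != t$strand
  out_start <- ifelse(reversed, t$end - pe, t$start + ps)
  out_end <- ifelse(reversed, t$end - ps, t$start + pe)
  out <- tibble::tibble(
    query = qi,
    block_id = f$block_id,
    chrom = t$chrom,
    start = as.integer(out_start),
    end = as.integer(out_end),
    strand = ifelse(reversed, "-", "+")
  )
  dplyr::arrange(out, .data$query, .data$chrom, .data$start)
}

#' @rdname project_intervals
#' @param interval A single-row data frame; returned projections omit the
#'   `query` column.
#' @export
project_interval <- function(interval, map, from_sp, to_sp) {
  stopifnot(nrow(interval) == 1)
  dplyr::select(project_intervals(interval, map, from_sp, to_sp), -"query")
}

# Internal: logical per event of `a`: is the event shared with species of
# `b` (any projected piece overlapping, >= min_bp, any event of b)?
shared_with <- function(a, b, map, min_bp = 1L) {
  shared <- rep(FALSE, nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(shared)
  pr <- project_intervals(a, map, unique(a$species), unique(b$species))
  if (nrow(pr) == 0) return(shared)
  hit <- overlap_any(pr, b, min_bp)
  shared[unique(pr$query[hit])] <- TRUE
  shared
}

#' Classify binding events into cross-species conservation classes
#'
#' Each event of the anchor species is projected onto every other species
#' and tested for a >= 1 bp overlap with that species' binding events; the
#' event's sharing count (its own species plus every species where a
#' projection hits a peak) determines its class:
#'
#' * `UNALIGNED` -- no overlapping alignment block carries any other
#'   species (the event is absent from the multiple alignment);
#' * `SPECIES_SPECIFIC` -- aligned, but shared with no other species;
#' * `TWO_WAY` -- shared with exactly one other species;
#' * `THREE_TO_FIVE` -- shared among three to K-2 species;
#' * `SIX_WAY` -- shared among all but one species;
#' * `ALL` -- shared among all K species.
#'
#' Class names follow the canonical seven-species design; for other K the
#' boundary classes keep their meaning (all-but-one, all), with `TWO_WAY`
#' taking precedence over `SIX_WAY` for very small K.
#'
#' @param sets Named list of binding-event tibbles, one per species.
#' @param map Alignment-map tibble.
#' @param anchor Anchor species (must name an element of `sets`).
#' @param min_bp Minimum overlap (default 1).
#' @return A tibble of the anchor events with extra columns `n_species`
#'   (sharing count, including the anchor), `members` (comma-separated
#'   sharing species) and `class`; carries attribute `species` (all
#'   species considered) and class `"conservation_classification"`.
#' @export
classify_conservation <- function(sets, map, anchor, min_bp = 1L) {
  if (length(sets) == 0) stop("empty species set")
  if (!anchor %in% names(sets)) stop("anchor species not in sets: ", anchor)
  a <- sets[[anchor]]
  others <- setdiff(names(sets), anchor)
  n_sp <- length(sets)
  shared_mat <- matrix(FALSE, nrow = nrow(a), ncol = length(others),
                       dimnames = list(NULL, others))
  for (sp in others) {
    shared_mat[, sp] <- shared_with(a, sets[[sp]], map, min_bp)
  }
  # aligned: some overlapping block carries a segment for >= 1 other species
  anchor_seg <- species_segments(map, anchor)
  aligned <- rep(FALSE, nrow(a))
  if (nrow(anchor_seg) > 0) {
    p <- overlap_pairs(a, anchor_seg)
    if (nrow(p) > 0) {
      block_other <- map$block_id[map$species != anchor]
      has_other <- anchor_seg$block_id[p$subject] %in% block_other
      aligned[unique(p$query[has_other])] <- TRUE
    }
  }
  n_shared <- 1L + rowSums(shared_mat)
  cls <- dplyr::case_when(
    n_shared == 1L & !aligned ~ "UNALIGNED",
    n_shared == 1L ~ "SPECIES_SPECIFIC",
    n_shared == 2L ~ "TWO_WAY",
    n_shared == n_sp ~ "ALL",
    n_shared == n_sp - 1L ~ "SIX_WAY",
    TRUE ~ "THREE_TO_FIVE"
  )
  members <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(anchor, others[shared_mat[i, ]]), collapse = ",")
  }, character(1))
  out <- dplyr::mutate(
    a,
    n_species = n_shared,
    members = members,
    class = factor(cls, levels = CONSERVATION_CLASSES)
  )
  attr(out, "species") <- names(sets)
  attr(out, "anchor") <- anchor
  class(out) <- c("conservation_classification", class(out))
  out
}

#' Per-class fractions of a conservation classification
#'
#' @param classification Result of [classify_conservation()].
#' @return A tibble with `class`, `n`, `fraction` (fractions sum to 1).
#' @export
conservation_fractions <- function(classification) {
  tab <- table(classification$class)
  tibble::tibble(
    class = factor(names(tab), levels = CONSERVATION_CLASSES),
    n = as.integer(tab),
    fraction = as.integer(tab) / nrow(classification)
  )
}

#' Bidirectionally averaged pairwise shared fraction
#'
#' The fraction of `a`'s events shared with `b` (via projection + >= 1 bp
#' peak overlap) and the fraction of `b`'s events shared with `a` are
#' averaged, so that the result does not depend on which species anchors
#' the comparison.
#'
#' @param a,b Non-empty binding-event tibbles of two species.
#' @param map Alignment-map tibble.
#' @param min_bp Minimum overlap (default 1).
#' @return A single number in \[0, 1\].
#' @export
pairwise_shared_fraction <- function(a, b, map, min_bp = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty binding-event set")
  mean(c(mean(shared_with(a, b, map, min_bp)),
         mean(shared_with(b, a, map, min_bp))))
}

#' Correlation of shared fractions with divergence time
#'
#' Pearson correlation (with two-sided p-value) between pairwise shared
#' fractions and the divergence times of the compared species, the
#' standard summary of how binding conservation decays along the
#' phylogeny.
#'
#' @param data Data frame with columns `fraction` and `divergence_my`
#'   (million years), one row per species compared against the anchor.
#' @return One-row tibble: `estimate` (Pearson r), `p.value`, `n`.
#' @export
overlap_divergence_correlation <- function(data) {
  stopifnot(all(c("fraction", "divergence_my") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 species")
  if (stats::sd(data$fraction) == 0 || stats::sd(data$divergence_my) == 0) {
    stop("correlation undefined for constant values")
  }
  ct <- stats::cor.test(data$fraction, data$divergence_my,
                        method = "pearson", alternative = "two.sided")
  tibble::tibble(
    estimate = unname(ct$estimate),
    p.value = ct$p.value,
    n = nrow(data)
  )
}

#' Sensitivity of the shared fraction to the FDR cutoff
#'
#' The anchor set is held at its fixed FDR while the comparison species'
#' events are filtered at each cutoff of `fdr_grid`; the anchor-to-other
#' shared fraction is recomputed at each cutoff. Relaxing the cutoff can
#' only add peaks, so the fractions are non-decreasing.
#'
#' @param anchor_set Binding-event tibble (fixed-FDR anchor species).
#' @param other Binding-event tibble with per-event `fdr` values.
#' @param map Alignment-map tibble.
#' @param fdr_grid Ascending FDR cutoffs; values above 0.5 draw a warning.
#' @param min_bp Minimum overlap (default 1).
#' @return Tibble with columns `fdr` and `shared_fraction`.
#' @export
fdr_sensitivity_overlap <- function(anchor_set, other, map,
                                    fdr_grid = c(0.05, 0.1, 0.2, 0.3, 0.5),
                                    min_bp = 1L) {
  stopifnot(!is.unsorted(fdr_grid))
  if (any(fdr_grid > 0.5)) {
    warning("FDR grid values above 0.5 are unusually permissive")
  }
  frac <- vapply(fdr_grid, function(cut) {
    sub <- other[other$fdr <= cut, , drop = FALSE]
    mean(shared_with(anchor_set, sub, map, min_bp))
  }, numeric(1))
  tibble::tibble(fdr = fdr_grid, shared_fraction = frac)
}
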