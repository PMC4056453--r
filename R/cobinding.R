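# Partition of CTCF/YY1 binding events into CTCF-only, CTCF-YY1 and
# YY1-only classes, and the association of those classes with genomic
# features and transcript expression.

COBIND_CLASSES <- c("CTCF_ONLY", "CTCF_YY1", "YY1_ONLY")

#' Partition CTCF and YY1 events into co-binding classes
#'
#' A CTCF event is co-bound (`CTCF_YY1`) iff it overlaps any YY1 event by
#' at least `min_bp` bases, and symmetrically for YY1; every event is
#' assigned exactly one class. A CTCF event overlapping several YY1
#' events yields one pair per overlap but is counted once in class
#' tallies.
#'
#' @param ctcf,yy1 Binding-event tibbles of the same species.
#' @param min_bp Minimum overlap (default 1).
#' @return A `cobind_partition` list: `ctcf_only` and `yy1_only`
#'   (binding-event tibbles), `pairs` (tibble of overlapping CTCF/YY1
#'   index pairs with both events' coordinates), `species`.
#' @export
classify_cobinding <- function(ctcf, yy1, min_bp = 1L) {
  sp_c <- unique(ctcf$species)
  sp_y <- unique(yy1$species)
  if (length(sp_c) == 1 && length(sp_y) == 1 && !identical(sp_c, sp_y)) {
    stop("species mismatch: ", sp_c, " vs ", sp_y)
  }
  p <- overlap_pairs(ctcf, yy1, min_bp)
  cobound_c <- sort(unique(p$query))
  cobound_y <- sort(unique(p$subject))
  pairs <- tibble::tibble(
    ctcf_index = p$query,
    yy1_index = p$subject,
    ctcf_name = ctcf$name[p$query],
    yy1_name = yy1$name[p$subject],
    chrom = ctcf$chrom[p$query],
    ctcf_start = ctcf$start[p$query], ctcf_end = ctcf$end[p$query],
    yy1_start = yy1$start[p$subject], yy1_end = yy1$end[p$subject]
  )
  structure(list(
    ctcf_only = ctcf[setdiff(seq_len(nrow(ctcf)), cobound_c), , drop = FALSE],
    ctcf_cobound = ctcf[cobound_c, , drop = FALSE],
    yy1_cobound = yy1[cobound_y, , drop = FALSE],
    yy1_only = yy1[setdiff(seq_len(nrow(yy1)), cobound_y), , drop = FALSE],
    pairs = pairs,
    species = if (length(sp_c) == 1) sp_c else NA_character_
  ), class = "cobind_partition")
}

#' @export
print.cobind_partition <- function(x, ...) {
  n_c <- nrow(x$ctcf_only) + nrow(x$ctcf_cobound)
  n_y <- nrow(x$yy1_only) + nrow(x$yy1_cobound)
  cat("CTCF/YY1 co-binding partition",
      if (!is.na(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat(sprintf("  CTCF events: %d (%d co-bound, %.1f%%)\n", n_c,
              nrow(x$ctcf_cobound), 100 * nrow(x$ctcf_cobound) / max(n_c, 1)))
  cat(sprintf("  YY1 events:  %d (%d co-bound, %.1f%%)\n", n_y,
              nrow(x$yy1_cobound), 100 * nrow(x$yy1_cobound) / max(n_y, 1)))
  cat(sprintf("  overlapping pairs: %d\n", nrow(x$pairs)))
  invisible(x)
}

# Internal: per-class event tibbles of a partition. The CTCF_YY1 class is
# represented by the co-bound CTCF events (one row per event).
partition_class_events <- function(partition) {
  list(CTCF_ONLY = partition$ctcf_only,
       CTCF_YY1 = partition$ctcf_cobound,
       YY1_ONLY = partition$yy1_only)
}

#' Feature association of co-binding classes across species
#'
#' For each species and co-binding class, the fraction of events
#' overlapping at least one feature of `feature_kind` is computed; the
#' cross-species mean and standard error summarise each class, and the
#' CTCF-only and CTCF-YY1 per-species fractions are compared with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param partitions Named list (per species) of [classify_cobinding()]
#'   results.
#' @param features Named list (per species) of feature tibbles with
#'   columns `kind`, `chrom`, `start`, `end`.
#' @param feature_kind Feature kind to test (e.g. `"cpg_island"`).
#' @param min_bp Minimum overlap (default 1).
#' @return A list with `fractions` (species x class tibble), `summary`
#'   (class, mean, se, n_species) and `test` (one-row tibble with the
#'   rank-sum p-value for CTCF-only vs CTCF-YY1).
#' @export
feature_association <- function(partitions, features, feature_kind,
                                min_bp = 1L) {
  stopifnot(length(partitions) >= 1)
  rows <- purrr::imap(partitions, function(part, sp) {
    feat <- features[[sp]]
    feat <- feat[feat$kind == feature_kind, , drop = FALSE]
    cls <- partition_class_events(part)
    purrr::imap(cls, function(ev, cl) {
      tibble::tibble(
        species = sp, class = cl, n_events = nrow(ev),
        fraction = if (nrow(ev) == 0) NA_real_ else
          mean(overlap_any(ev, feat, min_bp))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  empty_classes <- rows[rows$n_events == 0, , drop = FALSE]
  if (nrow(empty_classes) > 0) {
    warning("empty class omitted: ",
            paste(empty_classes$species, empty_classes$class,
                  sep = "/", collapse = ", "))
  }
  summary <- rows |>
    dplyr::filter(!is.na(.data$fraction)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      mean = mean(.data$fraction),
      se = if (dplyr::n() > 1) stats::sd(.data$fraction) / sqrt(dplyr::n()) else 0,
      n_species = dplyr::n(), .groups = "drop"
    )
  keep <- rows[!is.na(rows$fraction), , drop = FALSE]
  co <- keep$fraction[keep$class == "CTCF_YY1"]
  only <- keep$fraction[keep$class == "CTCF_ONLY"]
  test <- if (length(co) >= 1 && length(only) >= 1) {
    wt <- suppressWarnings(stats::wilcox.test(only, co,
                                              alternative = "two.sided"))
    tibble::tibble(comparison = "CTCF_ONLY vs CTCF_YY1",
                   p.value = wt$p.value, available = TRUE)
  } else {
    tibble::tibble(comparison = "CTCF_ONLY vs CTCF_YY1",
                   p.value = NA_real_, available = FALSE)
  }
  list(fractions = rows, summary = summary, test = test,
       feature_kind = feature_kind)
}

#' Compare transcript expression across co-binding classes
#'
#' Transcripts are assigned to co-binding classes by >= 1 bp overlap with
#' the partition's events; a transcript overlapping at least one
#' CTCF-YY1 pair belongs to the `CTCF_YY1` class regardless of other
#' overlaps, and YY1-only takes precedence over CTCF-only when both
#' single-factor classes overlap (YY1 presence dominates the expression
#' phenotype). Per-class log2 values are summarised and compared with
#' two-sided Wilcoxon rank-sum tests.
#'
#' @param partition A [classify_cobinding()] result.
#' @param transcripts Feature tibble (`id`, `chrom`, `start`, `end`).
#' @param expression Tibble with `transcript_id` and `log2_estimate`.
#' @param min_bp Minimum overlap (default 1).
#' @param paired Use the signed-rank (paired) variant instead of the
#'   rank-sum test. Classes are unpaired collections, so the rank-sum
#'   test is the default; the flag exists for completeness and requires
#'   equal class sizes.
#' @return A list: `data` (transcript_id, class, log2_estimate),
#'   `summaries` (per class: n and five-number summary), `tests`
#'   (comparison, p.value, available).
#' @export
expression_comparison <- function(partition, transcripts, expression,
                                  min_bp = 1L, paired = FALSE) {
  stopifnot(all(c("transcript_id", "log2_estimate") %in% names(expression)))
  cls_ev <- partition_class_events(partition)
  # class assignment with priority CTCF_YY1 > YY1_ONLY > CTCF_ONLY
  assigned <- rep(NA_character_, nrow(transcripts))
  for (cl in c("CTCF_ONLY", "YY1_ONLY", "CTCF_YY1")) {
    hit <- overlap_any(transcripts, cls_ev[[cl]], min_bp)
    assigned[hit] <- cl
  }
  data <- tibble::tibble(
    transcript_id = transcripts$id,
    class = assigned
  ) |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::inner_join(
      expression[, c("transcript_id", "log2_estimate")],
      by = "transcript_id"
    )
  summaries <- data |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$log2_estimate),
      q1 = stats::quantile(.data$log2_estimate, 0.25),
      median = stats::median(.data$log2_estimate),
      q3 = stats::quantile(.data$log2_estimate, 0.75),
      max = max(.data$log2_estimate),
      .groups = "drop"
    )
  vals <- split(data$log2_estimate, data$class)
  one_test <- function(a, b, label) {
    x <- vals[[a]]; y <- vals[[b]]
    if (is.null(x) || is.null(y) || length(x) < 2 || length(y) < 2 ||
        (paired && length(x) != length(y))) {
      return(tibble::tibble(comparison = label, p.value = NA_real_,
                            available = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                              alternative = "two.sided"))
    tibble::tibble(comparison = label, p.value = wt$p.value,
                   available = TRUE)
  }
  tests <- dplyr::bind_rows(
    one_test("CTCF_ONLY", "CTCF_YY1", "CTCF_ONLY vs CTCF_YY1"),
    one_test("CTCF_ONLY", "YY1_ONLY", "CTCF_ONLY vs YY1_ONLY")
  )
  list(data = data, summaries = summaries, tests = tests)
}
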