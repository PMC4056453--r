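# PWM scanning, motif-word occurrence statistics (nocc, normWord),
# FDR-based selection of species-/clade-specific words, and
# repeat-embedded word counting.
#
# Word scoring convention: score(w) = sum_i log2(p_i(w_i) / p_i(c_i))
# where c is the per-position consensus base, so the consensus word scores
# exactly 0 and every other word scores below 0.

#' Read a PWM probability matrix
#'
#' Tab-separated position x base table with header `A C G T`; each row
#' gives the base probabilities of one motif position and must sum to 1.
#'
#' @param path Path to the PWM file.
#' @return A numeric matrix (positions x A/C/G/T), class `pwm`.
#' @export
read_pwm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  as_pwm(as.matrix(df[, c("A", "C", "G", "T")]))
}

#' @rdname read_pwm
#' @param x Numeric matrix (positions x 4) of base probabilities with
#'   columns A, C, G, T.
#' @export
as_pwm <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 4)
  colnames(x) <- c("A", "C", "G", "T")
  if (any(x < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(x) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  structure(x, class = c("pwm", class(x)))
}

#' @rdname read_pwm
#' @param pwm A `pwm` matrix.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm)[apply(pwm, 1, which.max)], collapse = "")
}

#' @rdname read_pwm
#' @export
write_pwm <- function(pwm, path) {
  utils::write.table(as.data.frame(unclass(pwm)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Internal: score every window of `seq_chars` (character vector) against
# the log2(p / p_consensus) lookup; windows containing N score NA.
score_windows <- function(seq_chars, lookup) {
  L <- nrow(lookup)
  n <- length(seq_chars) - L + 1L
  if (n < 1) return(numeric(0))
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  scores <- numeric(n)
  for (i in seq_len(L)) {
    col <- idx[i:(i + n - 1L)]
    scores <- scores + unname(lookup[i, ])[col]  # NA propagates for N
  }
  scores
}

#' Scan a DNA sequence with a PWM
#'
#' Both strands are scanned; the score of a window is
#' `sum_i log2(p_i(base_i) / p_i(consensus_i))`, so a perfect match to
#' the consensus scores exactly 0 and all other words score below 0.
#' Windows containing `N` are skipped. Hits scoring at or above `cutoff`
#' are returned sorted by position.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm A `pwm` matrix (see [read_pwm()]).
#' @param cutoff Minimum score (default -15).
#' @param chrom Chromosome name attached to the hits (default `"seq"`).
#' @return Tibble `chrom`, `position` (0-based start of the match on the
#'   forward strand), `strand`, `word` (forward-strand sequence at the
#'   site), `score`.
#' @export
scan_pwm <- function(sequence, pwm, cutoff = -15, chrom = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  cons <- apply(pwm, 1, which.max)
  p_cons <- pwm[cbind(seq_len(nrow(pwm)), cons)]
  if (any(p_cons == 0)) stop("PWM has zero probability at a consensus base")
  lookup <- log2(sweep(unclass(pwm), 1, p_cons, "/"))
  seq_up <- toupper(sequence)
  chars_f <- strsplit(seq_up, "", fixed = TRUE)[[1]]
  L <- nrow(pwm)
  n_pos <- length(chars_f) - L + 1L
  empty <- tibble::tibble(chrom = character(), position = integer(),
                          strand = character(), word = character(),
                          score = numeric())
  if (n_pos < 1) return(empty)
  fwd <- score_windows(chars_f, lookup)
  chars_r <- strsplit(reverse_complement(seq_up), "", fixed = TRUE)[[1]]
  rev <- score_windows(chars_r, lookup)
  # reverse-strand window j (1-based on the RC) covers forward positions
  # (n_pos - j + 1) .. + L - 1
  rev_pos <- rev(rev)
  word_at <- function(p) substr(seq_up, p, p + L - 1L)
  keep_f <- which(!is.na(fwd) & fwd >= cutoff)
  keep_r <- which(!is.na(rev_pos) & rev_pos >= cutoff)
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, position = keep_f - 1L, strand = "+",
                   word = vapply(keep_f, word_at, character(1)),
                   score = fwd[keep_f]),
    tibble::tibble(chrom = chrom, position = keep_r - 1L, strand = "-",
                   word = vapply(keep_r, word_at, character(1)),
                   score = rev_pos[keep_r])
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Build the motif-word occurrence table
#'
#' Bound words are the union, over species, of the words at scan hits
#' whose position lies inside a bound region. Raw per-species counts are
#' normalized by `factor = total bound bases / 1e6`, giving the
#' normalized occurrence `nocc = count / factor`. Words whose raw count
#' is below `min_count` in every species are dropped.
#'
#' @param hits Named list (per species) of scan-hit tibbles (`chrom`,
#'   `position`, `word`, ...).
#' @param bound Named list (per species) of binding-event tibbles.
#' @param min_count Minimum raw count in at least one species
#'   (default 5).
#' @return A tibble in long form (`word`, `species`, `count`, `factor`,
#'   `nocc`), class `motif_word_table`, with attribute `factors`.
#' @export
build_word_table <- function(hits, bound, min_count = 5L) {
  stopifnot(identical(sort(names(hits)), sort(names(bound))))
  sps <- names(hits)
  factors <- vapply(bound, function(b) sum(b$end - b$start) / 1e6,
                    numeric(1))
  if (any(factors <= 0)) {
    stop("zero bound bases in species: ",
         paste(sps[factors <= 0], collapse = ", "))
  }
  counts <- purrr::imap(hits, function(h, sp) {
    if (nrow(h) == 0) {
      return(tibble::tibble(word = character(), species = sp,
                            count = integer()))
    }
    pos <- tibble::tibble(chrom = h$chrom, start = h$position,
                          end = h$position + 1L)
    inside <- overlap_any(pos, bound[[sp]])
    h <- h[inside, , drop = FALSE]
    dplyr::count(h, .data$word, name = "count") |>
      dplyr::mutate(species = sp)
  }) |> dplyr::bind_rows()
  tab <- tidyr::complete(counts, word, species = sps,
                         fill = list(count = 0L))
  keep <- tab |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(mx = max(.data$count), .groups = "drop")
  tab <- tab |>
    dplyr::semi_join(keep[keep$mx >= min_count, ], by = "word") |>
    dplyr::mutate(factor = unname(factors[.data$species]),
                  nocc = .data$count / .data$factor) |>
    dplyr::arrange(.data$word, .data$species)
  attr(tab, "factors") <- factors
  class(tab) <- c("motif_word_table", class(tab))
  tab
}

#' normWord scores for a focal species or clade
#'
#' For each word, `normWord = log2((nocc(S) + 1) / (max_{r in R} nocc(r)
#' + 1))` where S is the species (or clade) of interest and R the
#' comparison species. For a clade, `nocc(S)` is aggregated as the clade
#' maximum, mirroring the maximum taken over R.
#'
#' @param table A [build_word_table()] result.
#' @param S Focal species, or character vector of species forming a
#'   clade.
#' @param R Comparison species (non-empty, disjoint from `S`).
#' @return Tibble `word`, `nocc_s`, `max_nocc_r`, `norm_word`.
#' @export
norm_word_scores <- function(table, S, R) {
  if (length(R) == 0) stop("comparison set R must be non-empty")
  if (any(S %in% R)) stop("S and R must be disjoint")
  sps <- unique(table$species)
  missing <- setdiff(c(S, R), sps)
  if (length(missing) > 0) {
    stop("species not in table: ", paste(missing, collapse = ", "))
  }
  wide <- table |>
    dplyr::select("word", "species", "nocc") |>
    tidyr::pivot_wider(names_from = "species", values_from = "nocc",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  nocc_s <- apply(m[, S, drop = FALSE], 1, max)
  max_r <- apply(m[, R, drop = FALSE], 1, max)
  tibble::tibble(
    word = wide$word,
    nocc_s = nocc_s,
    max_nocc_r = max_r,
    norm_word = log2((nocc_s + 1) / (max_r + 1))
  )
}

#' Select species-/clade-specific words at a target FDR
#'
#' A normal distribution is fitted (sample mean and SD) to all normWord
#' values; each word receives an upper-tail p-value from the fit, the
#' family is corrected by Benjamini-Hochberg, and words passing the FDR
#' threshold are selected. The implied normWord cutoff (the smallest
#' selected score, `Inf` when nothing is selected) is reported.
#'
#' @param scores A [norm_word_scores()] result (>= 10 rows).
#' @param fdr Target FDR (default 0.05).
#' @return A list: `selected` (tibble of selected words with `p_value`,
#'   `p_adj`), `scores` (all words annotated), `cutoff` (implied
#'   normWord cutoff), `mean`, `sd`.
#' @export
select_specific_words <- function(scores, fdr = 0.05) {
  if (nrow(scores) < 10) stop("need at least 10 scores to fit the null")
  mu <- mean(scores$norm_word)
  sigma <- stats::sd(scores$norm_word)
  if (sigma == 0) stop("zero variance in normWord scores")
  ann <- scores |>
    dplyr::mutate(
      p_value = stats::pnorm(.data$norm_word, mean = mu, sd = sigma,
                             lower.tail = FALSE),
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      selected = .data$p_adj <= fdr
    )
  sel <- ann[ann$selected, , drop = FALSE]
  list(
    selected = dplyr::arrange(sel, .data$p_value),
    scores = ann,
    cutoff = if (nrow(sel) > 0) min(sel$norm_word) else Inf,
    mean = mu, sd = sigma
  )
}

#' Count repeat-embedded occurrences of selected words
#'
#' For each selected word, counts the bound scan hits whose full word
#' lies inside an annotated repeat element. The log10 of (count + 1) is
#' reported alongside.
#'
#' @param selected Character vector of selected words.
#' @param hits Scan-hit tibble for one species.
#' @param bound Binding-event tibble for the same species.
#' @param repeats Repeat tibble.
#' @param word_length Word length (default: nchar of the first word).
#' @return Tibble `word`, `n_bound`, `n_repeat_embedded`, `log10_count`.
#' @export
count_repeat_embedded_words <- function(selected, hits, bound, repeats,
                                        word_length = NULL) {
  if (length(selected) == 0) {
    return(tibble::tibble(word = character(), n_bound = integer(),
                          n_repeat_embedded = integer(),
                          log10_count = numeric()))
  }
  L <- word_length %||% nchar(selected[1])
  h <- hits[hits$word %in% selected, , drop = FALSE]
  pos <- tibble::tibble(chrom = h$chrom, start = h$position,
                        end = h$position + 1L)
  in_bound <- overlap_any(pos, bound)
  h <- h[in_bound, , drop = FALSE]
  span <- tibble::tibble(chrom = h$chrom, start = h$position,
                         end = h$position + L)
  embedded <- overlap_any(span, repeats, min_bp = L)  # fully inside
  counts <- tibble::tibble(word = selected) |>
    dplyr::left_join(
      dplyr::count(tibble::tibble(word = h$word), .data$word,
                   name = "n_bound"),
      by = "word") |>
    dplyr::left_join(
      dplyr::count(tibble::tibble(word = h$word[embedded]), .data$word,
                   name = "n_repeat_embedded"),
      by = "word")
  counts$n_bound <- dplyr::coalesce(counts$n_bound, 0L)
  counts$n_repeat_embedded <- dplyr::coalesce(counts$n_repeat_embedded, 0L)
  counts$log10_count <- log10(counts$n_repeat_embedded + 1)
  counts
}
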