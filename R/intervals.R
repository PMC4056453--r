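# Core genomic-interval data model and overlap engine.
#
# All coordinates are 0-based half-open (BED convention): an interval
# [start, end) covers positions start .. end - 1. Overlap is strand-blind.

#' Construct a binding-event tibble
#'
#' The central container of the package: one species x one factor set of
#' scored, summit-annotated ChIP-seq binding events ("bound regions").
#' Events are validated, sorted by (chrom, start) and deduplicated on the
#' (chrom, start, end) coordinate triple.
#'
#' @param events A data frame with at least `chrom`, `start`, `end`.
#'   Optional columns: `name`, `score` (non-negative enrichment score),
#'   `strand` (`+`, `-` or `*`), `fdr` (per-event false-discovery estimate
#'   in \[0, 1\]; defaults to 0) and `summit` (absolute position of maximal
#'   enrichment; defaults to the interval midpoint).
#' @param species Species identifier, e.g. `"H.sap"`.
#' @param factor Factor label, e.g. `"CTCF"` or `"YY1"`.
#' @return A tibble with columns `species`, `factor`, `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `fdr`, `summit`, sorted and
#'   deduplicated.
#' @examples
#' binding_events(data.frame(chrom = "chr1", start = 100, end = 200),
#'                species = "H.sap", factor = "CTCF")
#' @export
binding_events <- function(events, species, factor) {
  stopifnot(is.data.frame(events))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  ev <- tibble::as_tibble(events)
  n <- nrow(ev)
  ev$chrom <- as.character(ev$chrom)
  ev$start <- as.integer(ev$start)
  ev$end <- as.integer(ev$end)
  if (!"name" %in% names(ev)) ev$name <- if (n) paste0("peak_", seq_len(n)) else character()
  if (!"score" %in% names(ev)) ev$score <- rep(0, n)
  if (!"strand" %in% names(ev)) ev$strand <- rep("*", n)
  if (!"fdr" %in% names(ev)) ev$fdr <- rep(0, n)
  if (!"summit" %in% names(ev)) ev$summit <- (ev$start + ev$end) %/% 2L
  ev$summit <- as.integer(ev$summit)
  validate_intervals(ev)
  if (any(ev$fdr < 0 | ev$fdr > 1)) stop("fdr must lie in [0, 1]")
  if (any(ev$summit < ev$start | ev$summit >= ev$end)) {
    stop("summit must lie inside its interval [start, end)")
  }
  ev <- dplyr::mutate(ev, species = species, factor = factor)
  ev <- dplyr::distinct(ev, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
  ev <- dplyr::arrange(ev, .data$chrom, .data$start, .data$end)
  dplyr::select(
    ev, "species", "factor", "chrom", "start", "end",
    "name", "score", "strand", "fdr", "summit"
  )
}

validate_intervals <- function(df, where = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end))) {
    stop(where, ": non-integer or missing coordinates")
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop(where, ": invalid coordinates (need 0 <= start < end) at row ",
         bad[1])
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) stop(where, ": empty chrom")
  invisible(df)
}

#' Read a binding-event BED file
#'
#' Reads the BED6+2 dialect used throughout the package: the six standard
#' BED columns followed by column 7 = per-event FDR and column 8 = summit
#' offset from `start`. Files with only the first three columns are
#' accepted; missing FDR defaults to 0 and a missing summit to the interval
#' midpoint.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param species,factor Identifiers attached to the returned set.
#' @return A binding-event tibble (see [binding_events()]).
#' @export
read_binding_bed <- function(path, species, factor) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(binding_events(
      tibble::tibble(chrom = character(), start = integer(), end = integer()),
      species, factor
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("line ", which(ncol < 3)[1], ": fewer than 3 columns")
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": malformed coordinates")
  }
  df <- tibble::tibble(
    chrom = get_col(1),
    start = start,
    end = end
  )
  if (max(ncol) >= 4) df$name <- get_col(4)
  if (max(ncol) >= 5) df$score <- suppressWarnings(as.numeric(get_col(5, "0")))
  if (max(ncol) >= 6) df$strand <- dplyr::coalesce(get_col(6, "*"), "*")
  if (max(ncol) >= 7) df$fdr <- suppressWarnings(as.numeric(get_col(7, "0")))
  if (max(ncol) >= 8) {
    offset <- suppressWarnings(as.integer(get_col(8, NA_character_)))
    df$summit <- ifelse(is.na(offset), (df$start + df$end) %/% 2L,
                        df$start + offset)
  }
  binding_events(df, species, factor)
}

#' Write a binding-event tibble to the BED6+2 dialect
#'
#' @param events A binding-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_bed <- function(events, path) {
  out <- data.frame(
    chrom = events$chrom,
    start = events$start,
    end = events$end,
    name = events$name,
    score = events$score,
    strand = events$strand,
    fdr = events$fdr,
    summit_offset = events$summit - events$start
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-style annotation table
#'
#' Expects tab-separated columns genoName, genoStart, genoEnd, strand,
#' repName, repClass, repFamily, milliDiv (header optional; genoStart is
#' 0-based, UCSC table convention). milliDiv is the number of substitutions
#' per 1000 bp from the repeat consensus.
#'
#' @param path Path to the table.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class`, `rep_family`, `milli_div`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), rep_name = character(), rep_class = character(),
    rep_family = character(), milli_div = integer()
  )
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  # tolerate an optional header row
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (suppressWarnings(is.na(as.integer(first[2])))) lines <- lines[-1]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8)) {
    stop("line ", which(lengths(fields) < 8)[1], ": expected 8 columns")
  }
  m <- do.call(rbind, fields)
  milli_div <- suppressWarnings(as.integer(m[, 8]))
  if (any(is.na(milli_div) | milli_div < 0)) {
    stop("line ", which(is.na(milli_div) | milli_div < 0)[1],
         ": milliDiv must be a non-negative integer")
  }
  df <- tibble::tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    strand = m[, 4],
    rep_name = m[, 5],
    rep_class = m[, 6],
    rep_family = m[, 7],
    milli_div = milli_div
  )
  validate_intervals(df, "repeat")
  df
}

#' Write a repeat annotation tibble
#'
#' @param repeats A repeat tibble as returned by [read_repeatmasker()].
#' @param path Output path.
#' @param header Write a header row? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(repeats, path, header = TRUE) {
  out <- data.frame(
    genoName = repeats$chrom, genoStart = repeats$start,
    genoEnd = repeats$end, strand = repeats$strand,
    repName = repeats$rep_name, repClass = repeats$rep_class,
    repFamily = repeats$rep_family, milliDiv = repeats$milli_div
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

# Internal: interval tibble -> GRanges (0-based half-open -> 1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Internal: all overlapping pairs (>= min_bp) between two interval tibbles.
# Returns a tibble with columns query, subject (row indices).
overlap_pairs <- function(query, subject, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  # findOverlaps warns when the two sides share no chromosome; disjoint
  # chromosome sets are a legitimate no-overlap answer here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges(query), as_granges(subject),
    minoverlap = as.integer(min_bp), ignore.strand = TRUE
  ))
  tibble::tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

# Internal: logical vector, one per query row: overlaps any subject row?
overlap_any <- function(query, subject, min_bp = 1L) {
  hit <- rep(FALSE, nrow(query))
  p <- overlap_pairs(query, subject, min_bp)
  hit[unique(p$query)] <- TRUE
  hit
}

#' Test overlap between interval pairs
#'
#' Two intervals overlap when they lie on the same chromosome and share at
#' least `min_bp` bases under 0-based half-open coordinates
#' (`max(0, min(end) - max(start)) >= min_bp`). Strand is ignored. The two
#' data frames are compared row by row (rows recycled if one has a single
#' row).
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`.
#' @param min_bp Minimum shared bases (default 1).
#' @return Logical vector.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 199, end = 300)
#' interval_overlaps(a, b)        # TRUE, one shared base
#' interval_overlaps(a, b, 2)     # FALSE
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  a$chrom == b$chrom & pmax(ov, 0) >= min_bp
}

#' Merge replicate peak sets within one species and factor
#'
#' Replicate peak sets are merged by taking the intersection (events
#' supported, via >= 1 bp overlap, by an event in every replicate; the
#' first replicate's coordinates are kept) and additionally adding
#' replicate-unique peaks -- events overlapping no event in any other
#' replicate -- whose FDR falls below `unique_fdr_cutoff`.
#'
#' @param replicates List of binding-event tibbles for the same species and
#'   factor.
#' @param unique_fdr_cutoff FDR threshold for rescuing replicate-unique
#'   peaks (default 0.05; the peak is kept when `fdr < unique_fdr_cutoff`).
#' @return A merged, sorted, deduplicated binding-event tibble.
#' @export
merge_replicate_peaks <- function(replicates, unique_fdr_cutoff = 0.05) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  sp <- unique(unlist(lapply(replicates, function(r) unique(r$species))))
  fc <- unique(unlist(lapply(replicates, function(r) unique(r$factor))))
  if (length(sp) > 1 || length(fc) > 1) {
    stop("replicates mix species or factors: ",
         paste(sp, collapse = "/"), " ", paste(fc, collapse = "/"))
  }
  if (length(replicates) == 1) return(replicates[[1]])
  first <- replicates[[1]]
  in_all <- rep(TRUE, nrow(first))
  for (r in replicates[-1]) {
    in_all <- in_all & overlap_any(first, r)
  }
  merged <- first[in_all, , drop = FALSE]
  # replicate-unique rescue: overlap no event of any OTHER replicate
  for (i in seq_along(replicates)) {
    ri <- replicates[[i]]
    seen <- rep(FALSE, nrow(ri))
    for (j in seq_along(replicates)) {
      if (i == j) next
      seen <- seen | overlap_any(ri, replicates[[j]])
    }
    rescue <- ri[!seen & ri$fdr < unique_fdr_cutoff, , drop = FALSE]
    merged <- dplyr::bind_rows(merged, rescue)
  }
  binding_events(merged[setdiff(names(merged), c("species", "factor"))],
                 species = sp, factor = fc)
}
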