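# Shared fixture builders: everything is generated in code at test time.

# Compact seven-species world for integration-style tests.
small_world_config <- function(seed = 1, n_events = 300, ...) {
  world_config(
    species = default_primate_species(genome = c(chr1 = 1.2e6, chr2 = 8e5)),
    n_events = n_events,
    seed = seed,
    ...
  )
}

# Single-species world: no orthology, useful for repeat-enrichment runs.
single_species_config <- function(seed = 1, n_events = 1000,
                                  genome = c(chr1 = 6e6, chr2 = 4e6), ...) {
  world_config(
    species = list(species_config("H.sap", genome, 0)),
    n_events = n_events,
    class_proportions = c(UNALIGNED = 0, SPECIES_SPECIFIC = 1, TWO_WAY = 0,
                          THREE_TO_FIVE = 0, SIX_WAY = 0, ALL = 0),
    seed = seed,
    ...
  )
}

# Minimal hand-built alignment map: one row per segment.
toy_map <- function(...) {
  df <- tibble::tribble(...)
  names(df) <- c("block_id", "species", "chrom", "start", "end", "strand")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

# Event tibble shorthand.
ev_set <- function(species, factor, chrom, start, end, fdr = 0,
                   name = NULL) {
  df <- tibble::tibble(chrom = chrom, start = start, end = end, fdr = fdr)
  if (!is.null(name)) df$name <- name
  binding_events(df, species, factor)
}

# Identity map covering one region in several species (same coordinates).
identity_map <- function(species, chrom = "chr1", start = 0, end = 1e5) {
  dplyr::bind_rows(lapply(species, function(sp) {
    tibble::tibble(block_id = "b1", species = sp, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = "+")
  }))
}
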