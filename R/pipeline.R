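#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end processing pipeline. Defaults
#' follow the field's conventions: MAPQ threshold 1, 30-Mbp phase
#' imputation window, 2.5-Mbp and 50-kbp matrix resolutions, 150-bp mock
#' mates.
#'
#' @param enzyme Enzyme choice (see [enzyme()]).
#' @param mapq_min MAPQ threshold for pair filtering (default 1).
#' @param phase_window Imputation window in bp (default 3e7).
#' @param bin_sizes Matrix resolutions in bp (default `c(2.5e6, 5e4)`).
#' @param mate_length Mock paired-end mate length (default 150).
#' @param seed Seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(enzyme = "DpnII", mapq_min = 1L,
                            phase_window = 3e7,
                            bin_sizes = c(2.5e6, 5e4),
                            mate_length = 150L, seed = 1L) {
  structure(list(enzyme = enzyme(enzyme), mapq_min = as.integer(mapq_min),
                 phase_window = phase_window, bin_sizes = bin_sizes,
                 mate_length = as.integer(mate_length),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the processing pipeline on aligned segments
#'
#' Executes the stage chain expand -> filter -> dedup -> phase ->
#' matrix/stats on a segment table (from [read_segments_sam()],
#' [read_segments_tsv()] or [truth_alignments()]) and writes text artifacts
#' plus a machine-readable stage summary. Re-running with identical inputs
#' and config is byte-identical: no timestamps enter the outputs.
#'
#' Stage accounting reconciles exactly: input pairs = retained +
#' unmapped_mate + low_mapq, and duplicate-read pairs are removed before
#' filtering.
#'
#' @param segments Segment table (all reads).
#' @param chrom_lengths Named chromosome lengths (bp) for binning and
#'   serialization.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `segments`, `pairs` (filtered),
#'   `phased` (post-imputation segment table), `matrices` (one
#'   `contact_matrix` per bin size), `summary` (nested list, also written
#'   to `summary.json`).
#' @export
run_pipeline <- function(segments, chrom_lengths, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segments <- segment_table(segments)
  summary <- list(config = list(
    enzyme = config$enzyme$name, mapq_min = config$mapq_min,
    phase_window = config$phase_window, bin_sizes = config$bin_sizes))

  # dedup
  dd <- mark_duplicates(segments)
  keep_ids <- dd$reads$read_id[!dd$reads$duplicate]
  segments_dd <- segments[segments$read_id %in% keep_ids, , drop = FALSE]
  summary$dedup <- list(reads_in = nrow(dd$reads),
                        duplicates_flagged = sum(dd$reads$duplicate),
                        duplicate_rate = dd$rate)

  # expand + filter
  pairs_all <- pairs_from_segments(segments_dd)
  fl <- filter_pairs(pairs_all, config$mapq_min)
  summary$pairs <- as.list(fl$tally)
  write_pairs(fl$pairs, chrom_lengths, file.path(out_dir, "contacts.pairs"),
              metadata = c(mapq_min = as.character(config$mapq_min),
                           enzyme = config$enzyme$name))

  # phasing
  ph <- impute_phase_all(segments_dd, window = config$phase_window)
  summary$phasing <- phasing_summary(segments_dd, ph$segments)
  write_segments_tsv(ph$segments, file.path(out_dir, "phased_segments.tsv"))

  # matrices
  matrices <- list()
  for (bs in config$bin_sizes) {
    m <- bin_contacts(fl$pairs, chrom_lengths, bs)
    key <- format(bs, scientific = FALSE, trim = TRUE)
    matrices[[key]] <- m
    write_matrix_coo(m, file.path(out_dir, paste0("matrix_", key, ".coo")))
    summary$matrices[[key]] <- list(bin_size = bs, bins = nrow(m$bins),
                                    total = matrix_total(m))
  }

  # stats
  if (nrow(segments_dd)) {
    st <- segment_stats(segments_dd)
    summary$segment_stats <- st
  }
  summary$distance_histogram_total <-
    sum(distance_histogram(fl$pairs)$count)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(segments = segments_dd, pairs = fl$pairs,
                 phased = ph$segments, matrices = matrices,
                 summary = summary))
}
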