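# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and Biostrings) so they can arbitrate.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

base_complement <- c(A = "T", C = "G", G = "C", T = "A",
                     R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                     B = "V", D = "H", H = "D", V = "B", N = "N")

naive_revcomp <- function(s) {
  paste(rev(unname(base_complement[strsplit(toupper(s), "")[[1]]])),
        collapse = "")
}

# position-by-position IUPAC motif scan: subject letters are literal
# (so N in the sequence matches nothing), motif codes are sets
naive_motif_starts <- function(chars, motif) {
  mot <- strsplit(motif, "")[[1]]
  m <- length(mot)
  L <- length(chars)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (k in seq_len(m))
    ok <- ok & chars[seq_len(L - m + 1L) + k - 1L] %in% iupac_sets[[mot[k]]]
  which(ok) - 1L
}

naive_cut_sites <- function(seq, enz) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  cuts <- naive_motif_starts(chars, enz$motif) + enz$cut_offset
  if (naive_revcomp(enz$motif) != enz$motif) {
    m <- nchar(enz$motif)
    rc_starts <- naive_motif_starts(chars, naive_revcomp(enz$motif))
    cuts <- c(cuts, rc_starts + (m - enz$cut_offset))
  }
  cuts <- sort(unique(as.integer(cuts)))
  cuts[cuts > 0L & cuts < L]
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# minimal segment-table builder for constructed fixtures
seg_row <- function(read_id, idx, chrom, start, end = start + 100,
                    strand = "+", mapq = 60L, hap = NA_integer_) {
  data.frame(read_id = read_id, segment_index = idx, chrom = chrom,
             ref_start = start, ref_end = end, strand = strand,
             mapq = mapq, haplotype = hap, stringsAsFactors = FALSE)
}

# shared small simulation (computed once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_reads = 120L,
                        chrom_lengths = c(chr1 = 6e5, chr2 = 4e5))
      gen <- simulate_genome(cfg)
      cache <<- list(cfg = cfg, gen = gen,
                     sim = simulate_concatemers(cfg, gen))
    }
    cache
  }
})
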