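#' Restriction enzyme definition
#'
#' Builds a restriction enzyme object from a recognition motif and the offset
#' of the cut position from the motif start on the top strand. Cut positions
#' used for in silico digestion are `motif match start + cut_offset`,
#' 0-based. All coordinates in this package are 0-based half-open; 1-based
#' conventions appear only in serialized formats.
#'
#' @param name Short label, e.g. `"DpnII"`.
#' @param motif Recognition motif as an IUPAC nucleotide string (length >= 1).
#' @param cut_offset Integer in `[0, nchar(motif)]`; position of the cut
#'   relative to the motif start on the top strand. DpnII cuts `^GATC`
#'   (offset 0), HindIII `A^AGCTT` (offset 1), NlaIII `CATG^` (offset 4).
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("DpnII", "GATC", 0)
#' enzyme("HindIII")
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 1L)
    stop("enzyme motif must have length >= 1")
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(motif, "")[[1]], iupac)
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif))
    stop("cut_offset must lie in [0, motif length]")
  structure(
    list(name = as.character(name), motif = motif, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  m <- x$motif
  cut <- paste0(substr(m, 1, x$cut_offset), "^",
                substr(m, x$cut_offset + 1L, nchar(m)))
  cat(sprintf("<restriction_enzyme> %s  %s (cut offset %d)\n",
              x$name, cut, x$cut_offset))
  invisible(x)
}

.enzyme_presets <- list(
  DpnII   = list(motif = "GATC",   cut_offset = 0L),
  HindIII = list(motif = "AAGCTT", cut_offset = 1L),
  NlaIII  = list(motif = "CATG",   cut_offset = 4L)
)

#' Built-in enzymes and preset lookup
#'
#' `enzyme()` resolves a preset name (DpnII, HindIII, NlaIII) or a custom
#' `"MOTIF@OFFSET"` string to a [restriction_enzyme].
#'
#' @param x Preset name, a `"MOTIF@OFFSET"` string, or an existing
#'   `restriction_enzyme` (returned unchanged).
#' @return A `restriction_enzyme`.
#' @examples
#' enzyme("DpnII")
#' enzyme("GANTC@1")
#' @export
enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) return(x)
  x <- as.character(x)
  if (x %in% names(.enzyme_presets)) {
    p <- .enzyme_presets[[x]]
    return(restriction_enzyme(x, p$motif, p$cut_offset))
  }
  if (grepl("@", x, fixed = TRUE)) {
    parts <- strsplit(x, "@", fixed = TRUE)[[1]]
    return(restriction_enzyme(paste0("custom_", parts[1]), parts[1],
                              as.integer(parts[2])))
  }
  stop("unknown enzyme '", x, "'; use DpnII, HindIII, NlaIII or MOTIF@OFFSET")
}

#' @rdname enzyme
#' @export
enzyme_presets <- function() names(.enzyme_presets)

.is_palindromic <- function(enz) {
  m <- Biostrings::DNAString(enz$motif)
  as.character(Biostrings::reverseComplement(m)) == enz$motif
}

#' Locate in silico cut sites on a sequence
#'
#' Scans the top strand for the enzyme motif (IUPAC ambiguity codes in the
#' motif are honoured; `N` bases in the sequence never match) and returns the
#' 0-based cut positions `match start + cut_offset`. For non-palindromic
#' motifs the reverse-complement strand is also scanned and its cuts mapped
#' to top-strand coordinates. Overlapping motif occurrences all count. Cut
#' positions at 0 or at the sequence end are dropped since they delimit
#' empty segments.
#'
#' @param sequence A single nucleotide string (A/C/G/T/N, case-insensitive)
#'   or a `DNAString`.
#' @param enz A [restriction_enzyme] or anything [enzyme()] accepts.
#' @return Sorted integer vector of distinct 0-based cut positions.
#' @examples
#' find_cut_sites("GATCGATC", enzyme("DpnII"))  # 4 (position 0 dropped)
#' @export
find_cut_sites <- function(sequence, enz) {
  enz <- enzyme(enz)
  subj <- if (inherits(sequence, "DNAString")) sequence
          else Biostrings::DNAString(toupper(as.character(sequence)))
  L <- length(subj)
  scan <- function(pattern) {
    hits <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    # ambiguous bases in the read (N etc.) never satisfy a motif code
    BiocGenerics::start(hits)[!grepl("[^ACGT]", as.character(hits))] - 1L
  }
  cuts <- scan(enz$motif) + enz$cut_offset
  if (!.is_palindromic(enz)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enz$motif)))
    m <- nchar(enz$motif)
    # bottom-strand motif over top-strand interval [s, s+m): the bottom-strand
    # cut at offset `co` from the bottom motif start lands at s + (m - co)
    cuts <- c(cuts, scan(rc) + (m - enz$cut_offset))
  }
  cuts <- sort(unique(as.integer(cuts)))
  cuts[cuts > 0L & cuts < L]
}
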