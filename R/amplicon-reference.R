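#' PAM-relative protospacer coordinates
#'
#' Converts a 1-based 5'-to-3' index within a protospacer to the PAM-relative
#' convention in which the PAM-proximal protospacer base is position 1 and
#' positions increase toward the 5' end: `position = spacer_length - index + 1`.
#' Applying the conversion twice returns the original index.
#'
#' @param index_from_5prime 1-based index (or vector) from the 5' end.
#' @param spacer_length Protospacer length (default 20).
#' @return Integer PAM-relative position(s).
#' @examples
#' pam_relative_position(8)  # 13
#' pam_relative_position(20) # 1: PAM-adjacent base
#' @export
pam_relative_position <- function(index_from_5prime, spacer_length = 20L) {
  idx <- as.integer(index_from_5prime)
  if (any(is.na(idx)) || any(idx < 1L | idx > spacer_length)) {
    abort(sprintf("index must lie in 1..%d.", spacer_length))
  }
  as.integer(spacer_length) - idx + 1L
}

#' Editable cytosines of a protospacer within a window
#'
#' Finds reference cytosines of a 20-nt protospacer whose PAM-relative
#' position (PAM-proximal base = 1) falls inside an inclusive window.
#'
#' @param spacer 20-nt protospacer (DNA string, target strand).
#' @param window Inclusive `c(low, high)` PAM-relative window, default the
#'   empirically determined high-activity window 12-17.
#' @return Sorted integer vector of PAM-relative cytosine positions (possibly
#'   empty).
#' @examples
#' find_editable_cytosines("GTAGGTTCGACTCCTATTAT")            # 13
#' find_editable_cytosines("GTCGTCTTCAACGTTCCTTC", c(12, 17)) # 12 15
#' @export
find_editable_cytosines <- function(spacer, window = c(12L, 17L)) {
  spacer <- assert_dna(spacer, len = 20L)
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < 1L || window[2] > 20L) {
    abort("`window` must be c(low, high) within 1..20, low <= high.")
  }
  idx <- which(strsplit(spacer, "")[[1]] == "C")
  pos <- pam_relative_position(idx, nchar(spacer))
  sort(pos[pos >= window[1] & pos <= window[2]])
}

#' Fixed 3' reference suffix for exogenous-target amplicons
#'
#' The 30-nt constant sequence appended after the PAM when constructing
#' analysis references for the integrated exogenous target cassettes.
#'
#' @return A 30-nt DNA string.
#' @export
emsg_fixed_suffix <- function() "AGCTTGGCGTAACGGCTTAACTAGATTAAT"

#' Construct an amplicon analysis reference
#'
#' Assembles the reference used to quantify editing outcomes at an
#' integrated exogenous target: barcode, then the constant `GA` linker, then
#' the 20-nt protospacer, the PAM, and a fixed 30-nt suffix. Records the
#' protospacer/PAM intervals and the analysis window (in PAM-relative
#' protospacer coordinates, default 11-19).
#'
#' @param barcode Sample barcode (DNA, non-empty).
#' @param protospacer 20-nt protospacer.
#' @param pam 3-nt PAM.
#' @param fixed_suffix Constant 3' sequence (default [emsg_fixed_suffix()]).
#' @param linker Constant linker between barcode and protospacer.
#' @param analysis_window Inclusive PAM-relative window `c(low, high)` within
#'   1..20 used for window aggregation.
#' @return An `amplicon_reference` object: list with `full_sequence`,
#'   component sequences, 1-based inclusive `protospacer_interval` and
#'   `pam_interval` on the full sequence, and `analysis_window`.
#' @examples
#' ref <- build_reference("ACGT", "GTAGGTTCGACTCCTATTAT", "TGG")
#' nchar(ref$full_sequence) # 4 + 2 + 20 + 3 + 30
#' @export
build_reference <- function(barcode, protospacer, pam,
                            fixed_suffix = emsg_fixed_suffix(),
                            linker = "GA",
                            analysis_window = c(11L, 19L)) {
  barcode <- assert_dna(barcode)
  protospacer <- assert_dna(protospacer, len = 20L)
  pam <- assert_dna(pam)
  if (nchar(pam) == 0L) abort("`pam` must be non-empty.")
  fixed_suffix <- assert_dna(fixed_suffix)
  linker <- assert_dna(linker)
  if (length(analysis_window) != 2L || analysis_window[1] > analysis_window[2] ||
      analysis_window[1] < 1L || analysis_window[2] > 20L) {
    abort("`analysis_window` must be c(low, high) within 1..20.")
  }
  full <- paste0(barcode, linker, protospacer, pam, fixed_suffix)
  ps_start <- nchar(barcode) + nchar(linker) + 1L
  ps_end <- ps_start + 19L
  pam_end <- ps_end + nchar(pam)
  structure(list(
    full_sequence = full,
    barcode = barcode, linker = linker, protospacer = protospacer,
    pam = pam, fixed_suffix = fixed_suffix,
    protospacer_interval = c(ps_start, ps_end),
    pam_interval = c(ps_end + 1L, pam_end),
    analysis_window = as.integer(analysis_window)
  ), class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("<amplicon_reference> ", nchar(x$full_sequence), " nt; protospacer at ",
      x$protospacer_interval[1], "-", x$protospacer_interval[2],
      ", PAM ", x$pam, ", window ", x$analysis_window[1], "-",
      x$analysis_window[2], " (PAM-relative)\n", sep = "")
  invisible(x)
}

# map a 1-based full-sequence coordinate to a PAM-relative protospacer
# position (NA outside the protospacer)
ref_to_pam_relative <- function(reference, coord) {
  iv <- reference$protospacer_interval
  idx <- coord - iv[1] + 1L
  out <- rep(NA_integer_, length(coord))
  ok <- idx >= 1L & idx <= 20L
  out[ok] <- pam_relative_position(idx[ok], 20L)
  out
}
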