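#' Call protein substitutions from a variant ORF
#'
#' Codon-wise comparison of a variant coding sequence against a reference
#' ORF. A length difference that is not a multiple of 3 sets the frameshift
#' flag (no substitutions are called); an in-frame length change is reported
#' separately. Equal-length sequences are translated codon by codon and
#' differences reported in `refAA position altAA` notation (e.g. `K31N`).
#'
#' @param variant_dna Variant coding sequence (DNA string).
#' @param reference_orf Reference ORF; length must be divisible by 3 and it
#'   must not contain an internal stop codon (a single terminal stop is
#'   allowed).
#' @return A `variant_call` object: list with `substitutions` (tibble
#'   `ref_aa`, `position`, `alt_aa`, `label`), `frameshift`,
#'   `inframe_indel`, `synonymous_only`.
#' @examples
#' ref <- paste0("ATG", "AAA", "GGC", "TGA")
#' var <- paste0("ATG", "AAT", "GGC", "TGA")
#' call_substitutions(var, ref) # K2N
#' @export
call_substitutions <- function(variant_dna, reference_orf) {
  variant_dna <- assert_dna(variant_dna)
  reference_orf <- assert_dna(reference_orf)
  if (nchar(reference_orf) %% 3L != 0L) {
    abort("reference ORF length must be divisible by 3.")
  }
  gc_tab <- Biostrings::GENETIC_CODE
  split_codons <- function(x) {
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  ref_codons <- split_codons(reference_orf)
  ref_aa <- unname(gc_tab[ref_codons])
  if (any(ref_aa[-length(ref_aa)] == "*")) {
    abort("reference ORF contains an internal stop codon.")
  }
  empty <- tibble(ref_aa = character(), position = integer(),
                  alt_aa = character(), label = character())
  diff_len <- nchar(variant_dna) - nchar(reference_orf)
  if (diff_len %% 3L != 0L) {
    return(structure(list(substitutions = empty, frameshift = TRUE,
                          inframe_indel = FALSE, synonymous_only = FALSE),
                     class = "variant_call"))
  }
  if (diff_len != 0L) {
    return(structure(list(substitutions = empty, frameshift = FALSE,
                          inframe_indel = TRUE, synonymous_only = FALSE),
                     class = "variant_call"))
  }
  var_codons <- split_codons(variant_dna)
  var_aa <- unname(gc_tab[var_codons])
  changed <- which(var_aa != ref_aa)
  ref_changed <- ref_aa[changed]
  alt_changed <- var_aa[changed]
  subs <- tibble(
    ref_aa = ref_changed,
    position = as.integer(changed),
    alt_aa = alt_changed,
    label = paste0(ref_changed, changed, alt_changed)
  )
  nt_diff <- any(var_codons != ref_codons)
  structure(list(
    substitutions = subs,
    frameshift = FALSE,
    inframe_indel = FALSE,
    synonymous_only = nt_diff && nrow(subs) == 0L
  ), class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  if (x$frameshift) {
    cat("<variant_call> FRAMESHIFT\n")
  } else if (x$inframe_indel) {
    cat("<variant_call> in-frame length change\n")
  } else if (nrow(x$substitutions) == 0L) {
    cat("<variant_call> no amino-acid change",
        if (x$synonymous_only) " (synonymous only)", "\n", sep = "")
  } else {
    cat("<variant_call>", paste(x$substitutions$label, collapse = ", "), "\n")
  }
  invisible(x)
}
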