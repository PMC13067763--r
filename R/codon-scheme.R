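IUPAC_NT <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)

#' Expand a degenerate codon
#'
#' Cartesian expansion of a three-letter IUPAC codon into its concrete
#' trinucleotides (e.g. V = A/C/G, S = C/G).
#'
#' @param codon Three IUPAC nucleotide symbols, e.g. `"VAS"`.
#' @return Character vector of concrete codons, lexicographically sorted;
#'   its length equals the product of the per-symbol degeneracies.
#' @examples
#' expand_codon("VAS") # 6 codons
#' expand_codon("ATG") # just ATG
#' @export
expand_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    abort("`codon` must be a single 3-letter IUPAC string.")
  }
  codon <- toupper(codon)
  sym <- strsplit(codon, "")[[1]]
  if (length(sym) != 3L || !all(sym %in% names(IUPAC_NT))) {
    abort(sprintf("invalid IUPAC codon '%s'.", codon))
  }
  parts <- lapply(IUPAC_NT[sym], function(s) strsplit(s, "")[[1]])
  grid <- expand.grid(parts[[1]], parts[[2]], parts[[3]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
}

#' Translate a set of concrete codons
#'
#' Standard genetic code translation with stop codons reported separately
#' from the amino-acid multiset.
#'
#' @param codons Character vector of concrete trinucleotides.
#' @return List with `amino_acids` (tibble `aa`, `count`) and `stops`
#'   (character vector of stop codons encountered).
#' @examples
#' translate_set(expand_codon("VAS")) # H, Q, N, K, D, E each once
#' @export
translate_set <- function(codons) {
  if (length(codons) == 0L) {
    return(list(amino_acids = tibble(aa = character(), count = integer()),
                stops = character()))
  }
  codons <- toupper(codons)
  bad <- !codons %in% names(Biostrings::GENETIC_CODE)
  if (any(bad)) abort(sprintf("not concrete codons: %s",
                              paste(codons[bad], collapse = ", ")))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- codons[aa == "*"]
  aa <- aa[aa != "*"]
  if (length(aa) == 0L) {
    return(list(amino_acids = tibble(aa = character(), count = integer()),
                stops = stops))
  }
  tab <- table(aa)
  list(
    amino_acids = tibble(aa = names(tab), count = as.integer(tab)) %>%
      arrange(.data$aa),
    stops = stops
  )
}

#' Construct a degenerate-codon scheme
#'
#' A scheme is an ordered set of degenerate codons mixed so that each
#' concrete codon appears once; the mixing ratio is therefore the vector of
#' expansion sizes. The reference scheme `VAS/DGG/TNC/VYC/ATG` encodes the
#' 20 standard amino acids (HQNKDE / WRG / FSYC / LPITVA / M) exactly once
#' each, mixed 6:3:4:6:1.
#'
#' @param codons Character vector of IUPAC degenerate codons.
#' @return A `codon_scheme` object.
#' @examples
#' tailored <- codon_scheme(c("VAS", "DGG", "TNC", "VYC", "ATG"))
#' mixing_ratio(tailored)
#' @export
codon_scheme <- function(codons) {
  if (length(codons) == 0L) abort("a scheme needs at least one codon.")
  codons <- toupper(codons)
  expansions <- map(codons, expand_codon)
  structure(list(codons = codons, expansions = expansions),
            class = "codon_scheme")
}

#' @export
print.codon_scheme <- function(x, ...) {
  cat("<codon_scheme> ", paste(x$codons, collapse = "/"),
      " (", paste(lengths(x$expansions), collapse = ":"), ")\n", sep = "")
  invisible(x)
}

#' Audit a codon scheme for balance
#'
#' Expands every degenerate codon, translates all concrete codons, and
#' reports per-amino-acid encoding multiplicities. A scheme is balanced when
#' every target amino acid is encoded exactly once and no expansion contains
#' a stop codon. Concrete codons produced by two different degenerate codons
#' are flagged as overlap.
#'
#' @param scheme A [codon_scheme()] (or character vector of codons).
#' @param targets Optional amino-acid set the scheme should cover; defaults
#'   to the amino acids actually encoded.
#' @return A `scheme_report` object: list with `multiplicities` (tibble
#'   `aa`, `count`), `n_codons`, `stops`, `overlap`, `balanced`, `covered`.
#' @examples
#' verify_scheme(c("VAS", "DGG", "TNC", "VYC", "ATG"))
#' @export
verify_scheme <- function(scheme, targets = NULL) {
  if (!inherits(scheme, "codon_scheme")) scheme <- codon_scheme(scheme)
  all_codons <- unlist(scheme$expansions)
  overlap <- unique(all_codons[duplicated(all_codons)])
  tr <- translate_set(all_codons)
  mult <- tr$amino_acids
  if (is.null(targets)) targets <- mult$aa
  targets <- sort(unique(toupper(targets)))
  covered <- all(targets %in% mult$aa)
  balanced <- covered && length(tr$stops) == 0L &&
    nrow(mult) > 0L && all(mult$count == 1L) &&
    all(mult$aa %in% targets)
  structure(list(
    multiplicities = mult,
    n_codons = length(all_codons),
    stops = tr$stops,
    overlap = overlap,
    covered = covered,
    balanced = balanced,
    targets = targets
  ), class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("<scheme_report> ", nrow(x$multiplicities), " amino acids over ",
      x$n_codons, " codons; ",
      if (x$balanced) "BALANCED (1:1, stop-free)" else "not balanced", "\n",
      sep = "")
  if (length(x$stops)) cat("  stop codons: ", paste(x$stops, collapse = ", "), "\n")
  if (length(x$overlap)) cat("  overlapping codons: ", paste(x$overlap, collapse = ", "), "\n")
  invisible(x)
}

#' Mixing ratio of a scheme
#'
#' Per-codon expansion sizes, reported raw (unreduced), which give the
#' primer molar mixing ratio that represents every concrete codon equally.
#'
#' @inheritParams verify_scheme
#' @return Integer vector, one entry per degenerate codon.
#' @examples
#' mixing_ratio(c("VAS", "DGG", "TNC", "VYC", "ATG")) # 6 3 4 6 1
#' @export
mixing_ratio <- function(scheme) {
  if (!inherits(scheme, "codon_scheme")) scheme <- codon_scheme(scheme)
  lengths(scheme$expansions)
}

#' Degenerate primer records for a scheme
#'
#' One primer per degenerate codon, flanked by constant sequence, with the
#' molar mixture fraction proportional to the codon's expansion size so that
#' every concrete codon (hence every encoded amino acid of a balanced
#' scheme) is equally represented.
#'
#' @inheritParams verify_scheme
#' @param flank5,flank3 Constant flanking DNA (non-empty).
#' @return Tibble: `codon`, `primer`, `n_codons`, `fraction` (sums to 1).
#' @export
build_primer_set <- function(scheme, flank5, flank3) {
  if (!inherits(scheme, "codon_scheme")) scheme <- codon_scheme(scheme)
  flank5 <- assert_dna(flank5)
  flank3 <- assert_dna(flank3)
  if (nchar(flank5) == 0L || nchar(flank3) == 0L) {
    abort("flanks must be non-empty.")
  }
  sizes <- lengths(scheme$expansions)
  tibble(
    codon = scheme$codons,
    primer = paste0(flank5, scheme$codons, flank3),
    n_codons = as.integer(sizes),
    fraction = sizes / sum(sizes)
  )
}
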