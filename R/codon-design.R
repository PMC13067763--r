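# Candidate table for balanced-scheme search: every degenerate codon whose
# expansion is stop-free and hits each amino acid at most once. Such codons
# are the only ones usable in a balanced (multiplicity-1) scheme, and their
# expansion size equals the size of the amino-acid set they encode. Cached
# after first construction (3375 codons scanned once).
.codon_design_cache <- new.env(parent = emptyenv())

balanced_codon_candidates <- function() {
  if (!is.null(.codon_design_cache$candidates)) {
    return(.codon_design_cache$candidates)
  }
  sym <- names(IUPAC_NT)
  grid <- expand.grid(sym, sym, sym, stringsAsFactors = FALSE)
  codons <- paste0(grid[[1]], grid[[2]], grid[[3]])
  gc_tab <- Biostrings::GENETIC_CODE
  rows <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    ex <- expand_codon(codons[i])
    aa <- unname(gc_tab[ex])
    if (any(aa == "*") || anyDuplicated(aa)) next
    rows[[i]] <- tibble(codon = codons[i],
                        aa_set = paste(sort(aa), collapse = ""),
                        size = length(aa))
  }
  out <- bind_rows(rows)
  .codon_design_cache$candidates <- out
  out
}

#' Design balanced degenerate-codon schemes by exact cover
#'
#' Searches the 3375 three-letter IUPAC degenerate codons for schemes that
#' encode every target amino acid exactly once with no stop codons: an
#' exact-cover problem in which each usable codon contributes a disjoint
#' amino-acid set. Candidates are deduplicated at the amino-acid-set level
#' (325 distinct stop-free sets), so the search enumerates set partitions of
#' the target and each returned scheme block lists every degenerate codon
#' realizing its set. The depth-first search is deterministic: blocks are
#' tried in canonical order (set size descending, then lexicographic), so
#' results do not depend on target-set ordering.
#'
#' @param target_aas Amino acids to cover: a character vector of one-letter
#'   codes or a single string like `"ACDEFGHIKLMNPQRSTVWY"`.
#' @param max_codons Maximum number of degenerate codons per scheme.
#' @param forbidden Concrete codons that must not appear in any expansion
#'   (e.g. rare codons to exclude outright).
#' @param rare_codons Optional character vector of concrete codons considered
#'   rare; schemes are ranked by how many rare codons they contain
#'   (down-ranked, not excluded).
#' @param max_schemes Cap on the number of schemes returned; default
#'   unlimited (full enumeration at the amino-acid-set level is cheap).
#' @return A list of class `scheme_designs`; each element is a tibble with
#'   one row per block: `aa_set`, `size`, `codons` (list column of the
#'   degenerate codons realizing that block). Empty list (with a
#'   `diagnostic` attribute) when the constraints are infeasible.
#' @examples
#' design_balanced_scheme("MW")  # ATG + TGG
#' @export
design_balanced_scheme <- function(target_aas,
                                   max_codons = 5L,
                                   forbidden = NULL,
                                   rare_codons = NULL,
                                   max_schemes = Inf) {
  aa20 <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(target_aas) == 1L && nchar(target_aas) > 1L) {
    target_aas <- strsplit(target_aas, "")[[1]]
  }
  target <- sort(unique(toupper(target_aas)))
  if (length(target) == 0L) abort("`target_aas` must be non-empty.")
  if (!all(target %in% aa20)) {
    abort(sprintf("unknown amino acids: %s",
                  paste(setdiff(target, aa20), collapse = ", ")))
  }
  cand <- balanced_codon_candidates()
  if (!is.null(forbidden)) {
    forbidden <- toupper(forbidden)
    keep <- map_lgl(cand$codon, ~ !any(expand_codon(.x) %in% forbidden))
    cand <- cand[keep, , drop = FALSE]
  }
  # keep candidates whose set is inside the target, grouped by amino-acid set
  inside <- map_lgl(cand$aa_set,
                    ~ all(strsplit(.x, "")[[1]] %in% target))
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(structure(list(), class = "scheme_designs",
                     diagnostic = "no usable codons for this target set"))
  }
  blocks <- cand %>%
    group_by(.data$aa_set, .data$size) %>%
    summarise(codons = list(sort(.data$codon)), .groups = "drop") %>%
    arrange(desc(.data$size), .data$aa_set)

  # bitmask exact cover over the target amino acids
  nt <- length(target)
  tomask <- function(set) {
    sum(bitwShiftL(1L, match(strsplit(set, "")[[1]], target) - 1L))
  }
  bmask <- vapply(blocks$aa_set, tomask, integer(1))
  bsize <- blocks$size
  full <- bitwShiftL(1L, nt) - 1L
  per_aa <- lapply(seq_len(nt), function(i) {
    which(bitwAnd(bmask, bitwShiftL(1L, i - 1L)) != 0L)
  })
  max_block <- max(bsize)
  solutions <- list()
  dfs <- function(rem, chosen, slots, nrem) {
    if (length(solutions) >= max_schemes) return()
    if (nrem == 0L) {
      solutions[[length(solutions) + 1L]] <<- chosen
      return()
    }
    if (slots == 0L || nrem > slots * max_block) return()
    first <- which(bitwAnd(rem, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L)[1]
    for (j in per_aa[[first]]) {
      b <- bmask[j]
      if (bitwAnd(b, rem) != b) next
      dfs(bitwAnd(rem, bitwXor(full, b)), c(chosen, j), slots - 1L,
          nrem - bsize[j])
    }
  }
  dfs(full, integer(0), as.integer(max_codons), nt)
  if (length(solutions) == 0L) {
    return(structure(list(), class = "scheme_designs",
                     diagnostic = sprintf(
                       "no exact cover of {%s} with <= %d codons",
                       paste(target, collapse = ""), max_codons)))
  }
  designs <- map(solutions, function(idx) {
    blocks[idx, , drop = FALSE] %>% arrange(desc(.data$size), .data$aa_set)
  })
  if (!is.null(rare_codons)) {
    rare_codons <- toupper(rare_codons)
    n_rare <- map_int(designs, function(d) {
      sum(map_int(d$codons, function(cods) {
        sum(map_int(cods, ~ sum(expand_codon(.x) %in% rare_codons)))
      }))
    })
    designs <- designs[order(n_rare)]
    attr(designs, "n_rare") <- sort(n_rare)
  }
  structure(designs, class = "scheme_designs", target = target)
}

#' @export
print.scheme_designs <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<scheme_designs> empty:", attr(x, "diagnostic"), "\n")
    return(invisible(x))
  }
  cat("<scheme_designs> ", length(x), " balanced scheme(s) for {",
      paste(attr(x, "target"), collapse = ""), "}\n", sep = "")
  show <- head(seq_along(x), 5L)
  for (i in show) {
    d <- x[[i]]
    cat(sprintf("  [%d] %s (%s)\n", i,
                paste(map_chr(d$codons, 1), collapse = "/"),
                paste(d$size, collapse = ":")))
  }
  if (length(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Pick a concrete scheme from a design
#'
#' @param design One element of a [design_balanced_scheme()] result.
#' @param choice `"first"` takes the lexicographically first codon of each
#'   block; or an integer vector selecting one codon per block.
#' @return A [codon_scheme()].
#' @export
as_scheme <- function(design, choice = "first") {
  design <- as_tibble(design)
  if (identical(choice, "first")) {
    codons <- map_chr(design$codons, 1)
  } else {
    codons <- map2_chr(design$codons, choice, ~ .x[[.y]])
  }
  codon_scheme(codons)
}

#' Does a design set contain a given scheme?
#'
#' Membership check: a scheme is contained when some returned design has
#' exactly its amino-acid-set partition and each of the scheme's degenerate
#' codons realizes the corresponding block.
#'
#' @param designs A [design_balanced_scheme()] result.
#' @param codons Character vector of degenerate codons (a concrete scheme).
#' @return Logical.
#' @export
design_contains_scheme <- function(designs, codons) {
  sch <- codon_scheme(codons)
  gc_tab <- Biostrings::GENETIC_CODE
  sets <- map_chr(sch$expansions,
                  ~ paste(sort(unname(gc_tab[.x])), collapse = ""))
  key <- sort(sets)
  any(map_lgl(designs, function(d) {
    if (!identical(sort(d$aa_set), key)) return(FALSE)
    all(vapply(seq_along(sets), function(i) {
      sch$codons[i] %in% d$codons[[match(sets[i], d$aa_set)]]
    }, logical(1)))
  }))
}

#' @importFrom purrr map2_chr keep
NULL
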