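#' Packaged sequence fixtures for the selection system
#'
#' The constants of the bacterial selection system and exogenous-target
#' analysis, packaged for tests and simulations: the three repeat-targeting
#' protospacers with their genomic copy numbers (2, 7, 12) and the
#' PAM-relative positions of their window-12-17 editable cytosines, the
#' fixed 30-nt reference suffix, the error-prone PCR primer flanks that
#' bound the mutagenized deaminase ORF, and the four-site combinatorial
#' library specification.
#'
#' @return List with elements `spacers` (tibble: `name`, `spacer`, `copies`,
#'   `editable_c` list column), `fixed_suffix`, `epcr_primers` (named
#'   character vector `fwd`/`rev`), and `sites_4mix`.
#' @examples
#' fixture_set()$spacers
#' @export
fixture_set <- function() {
  spacers <- tibble(
    name = c("pRep2", "pRep7", "pRep12"),
    spacer = c("GTAGGTTCGACTCCTATTAT",
               "GTCGTCTTCAACGTTCCTTC",
               "GCATGGAGCAGATTCTGCCA"),
    copies = c(2L, 7L, 12L)
  )
  spacers$editable_c <- map(spacers$spacer, find_editable_cytosines)
  list(
    spacers = spacers,
    fixed_suffix = emsg_fixed_suffix(),
    epcr_primers = c(
      fwd = "TCACCAAAGAAGAAGCGGAAAGTCAAGCTT",
      rev = "GCCGGAGCTGCCACCGGAGGAGCCTCCGCT"
    ),
    sites_4mix = sites_4mix()
  )
}
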