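# independent Cartesian-product oracle over IUPAC symbol meanings
oracle_expand <- function(codon) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
                R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
                Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
                H = c("A", "C", "T"), D = c("A", "G", "T"),
                B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (a in iupac[[s[1]]]) for (b in iupac[[s[2]]]) for (d in iupac[[s[3]]])
    out <- c(out, paste0(a, b, d))
  sort(out)
}

test_that("IUPAC expansion is the exact Cartesian product", {
  expect_identical(expand_codon("VAS"),
                   sort(c("AAC", "AAG", "CAC", "CAG", "GAC", "GAG")))
  expect_identical(expand_codon("ATG"), "ATG")
  expect_identical(length(expand_codon("NNN")), 64L)
  for (cd in c("VAS", "DGG", "TNC", "VYC", "NNK", "RRY", "BDH")) {
    expect_identical(expand_codon(cd), oracle_expand(cd))
  }
  expect_error(expand_codon("VAX"), "invalid IUPAC")
  expect_error(expand_codon("VA"), "invalid IUPAC")
})

test_that("translation gives the printed amino-acid groups", {
  expect_identical(translate_set(expand_codon("VAS"))$amino_acids$aa,
                   sort(c("H", "Q", "N", "K", "D", "E")))
  expect_identical(translate_set(expand_codon("DGG"))$amino_acids$aa,
                   sort(c("W", "R", "G")))
  expect_identical(translate_set(expand_codon("TNC"))$amino_acids$aa,
                   sort(c("F", "S", "Y", "C")))
  expect_identical(translate_set(expand_codon("VYC"))$amino_acids$aa,
                   sort(c("L", "P", "I", "T", "V", "A")))
  tr <- translate_set("TAA")
  expect_identical(nrow(tr$amino_acids), 0L)
  expect_identical(tr$stops, "TAA")
})

test_that("the tailored five-codon scheme is balanced 1:1 over 20 amino acids", {
  rep <- verify_scheme(TAILORED_SCHEME)
  expect_true(rep$balanced)
  expect_identical(nrow(rep$multiplicities), 20L)
  expect_true(all(rep$multiplicities$count == 1L))
  expect_identical(rep$n_codons, 20L)
  expect_identical(length(rep$stops), 0L)
  expect_identical(length(rep$overlap), 0L)
  expect_identical(mixing_ratio(TAILORED_SCHEME), c(6L, 3L, 4L, 6L, 1L))
})

test_that("NNK is unbalanced, matching exhaustive enumeration", {
  # oracle: translate all 32 NNK codons with the standard code
  code <- Biostrings::GENETIC_CODE
  aas <- unname(code[oracle_expand("NNK")])
  oracle_counts <- table(aas[aas != "*"])
  rep <- verify_scheme("NNK")
  expect_false(rep$balanced)
  got <- setNames(rep$multiplicities$count, rep$multiplicities$aa)
  expect_identical(got[sort(names(oracle_counts))],
                   setNames(as.integer(oracle_counts[sort(names(oracle_counts))]),
                            sort(names(oracle_counts))))
  expect_identical(got[["L"]], 3L)
  expect_identical(got[["R"]], 3L)
  expect_identical(got[["S"]], 3L)
  expect_identical(rep$stops, "TAG")
  expect_error(verify_scheme(character(0)), "at least one")
  # overlapping expansions are flagged
  expect_gt(length(verify_scheme(c("NNN", "ATG"))$overlap), 0L)
})

test_that("mixing ratios and primer fractions follow expansion sizes", {
  expect_identical(mixing_ratio("ATG"), 1L)
  expect_identical(mixing_ratio("NNN"), 64L)
  pr <- build_primer_set(codon_scheme(TAILORED_SCHEME), "AAGCTT", "GGATCC")
  expect_equal(pr$fraction, c(6, 3, 4, 6, 1) / 20)
  expect_equal(sum(pr$fraction), 1)
  expect_identical(pr$primer[5], paste0("AAGCTT", "ATG", "GGATCC"))
  expect_equal(build_primer_set(codon_scheme("ATG"), "A", "T")$fraction, 1)
})

test_that("the candidate table matches independent enumeration counts", {
  # frozen from an independent scan of all 3375 degenerate codons: those
  # with stop-free, duplicate-free translations, and their distinct sets
  cand <- bepitools:::balanced_codon_candidates()
  expect_identical(nrow(cand), 707L)
  expect_identical(length(unique(cand$aa_set)), 325L)
  # every candidate's expansion size equals its amino-acid set size
  expect_true(all(nchar(cand$aa_set) == cand$size))
})

test_that("balanced-scheme design solves small exact covers", {
  dM <- design_balanced_scheme("M")
  expect_identical(length(dM), 1L)
  expect_identical(dM[[1]]$codons[[1]], "ATG")
  dMW <- design_balanced_scheme("MW")
  expect_identical(length(dMW), 1L)
  expect_true(design_contains_scheme(dMW, c("ATG", "TGG")))
  # infeasible constraints give an empty list with a diagnostic
  d1 <- design_balanced_scheme("MW", max_codons = 1)
  expect_identical(length(d1), 0L)
  expect_match(attr(d1, "diagnostic"), "no exact cover")
})

test_that("every designed scheme verifies balanced (round trip)", {
  designs <- design_balanced_scheme("DEHKNQ", max_codons = 2)
  expect_gt(length(designs), 0L)
  for (d in designs) {
    sch <- as_scheme(d)
    rep <- verify_scheme(sch, targets = strsplit("DEHKNQ", "")[[1]])
    expect_true(rep$balanced)
  }
  # target order does not matter
  designs2 <- design_balanced_scheme("QNKHED", max_codons = 2)
  expect_identical(lapply(designs, function(d) d$aa_set),
                   lapply(designs2, function(d) d$aa_set))
})

test_that("rare codons down-rank but do not exclude schemes", {
  # make every codon of one block rare and check it sorts last
  designs <- design_balanced_scheme("MW")
  ranked <- design_balanced_scheme("MW", rare_codons = c("ATG"))
  expect_identical(length(ranked), length(designs))
  expect_identical(attr(ranked, "n_rare"), 1L)
})
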