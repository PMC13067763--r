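# shared fixtures, built in code

PREP2 <- "GTAGGTTCGACTCCTATTAT"
PREP7 <- "GTCGTCTTCAACGTTCCTTC"
PREP12 <- "GCATGGAGCAGATTCTGCCA"
TAILORED_SCHEME <- c("VAS", "DGG", "TNC", "VYC", "ATG")

test_reference <- function(spacer = PREP2, barcode = "ACGTACGT") {
  build_reference(barcode, spacer, "TGG")
}

# a 40-codon ORF with no internal stops; codon 31 is AAA (Lys)
test_orf <- function() {
  codons <- c("ATG", rep(c("GGC", "CTG", "GAT", "TTC", "CAG",
                           "AGC", "GTG", "TAT", "AAC", "AAA"), 4))
  paste(c(codons[1:39], "TGA"), collapse = "")
}

# coordinates realizing the four printed pocket-entrance distances:
# K31-K106 9.37, K31-Y76 11.93, K106-Y84 7.85, Y76-Y84 6.85 (Å).
# K31 at origin, K106 on the x axis, Y76 in the xy plane; Y84 solved as the
# intersection of the circles around K106 and Y76 (independent algebra, not
# the package's trilateration).
entrance_fixture_model <- function() {
  k31 <- c(0, 0, 0)
  k106 <- c(9.37, 0, 0)
  y76 <- c(5, sqrt(11.93^2 - 25), 0)
  # circles: |p - k106| = 7.85, |p - y76| = 6.85, p in z = 0 plane
  r1 <- 7.85; r2 <- 6.85
  d2 <- sum((y76 - k106)^2)
  # line: 2 p.(y76 - k106) = |y76|^2 - |k106|^2 + r1^2 - r2^2
  a <- y76 - k106
  c0 <- (sum(y76^2) - sum(k106^2) + r1^2 - r2^2) / 2
  # param: p = k106 + t*a + s*perp(a); solve
  perp <- c(-a[2], a[1], 0)
  t <- (c0 - sum(k106 * a)) / sum(a * a)
  base <- k106 + t * a
  s <- sqrt(r1^2 - sum((base - k106)^2))
  y84 <- base + s * perp / sqrt(sum(perp^2))
  atoms <- tibble::tibble(
    chain = "A",
    resno = c(31L, 76L, 84L, 106L),
    resid = c("LYS", "TYR", "TYR", "LYS"),
    elety = c("NZ", "OH", "OH", "NZ"),
    x = c(k31[1], y76[1], y84[1], k106[1]),
    y = c(k31[2], y76[2], y84[2], k106[2]),
    z = c(k31[3], y76[3], y84[3], k106[3])
  )
  structure_model(atoms)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
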