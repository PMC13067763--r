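test_that("paired-read merging reconstructs a known amplicon", {
  s <- random_dna(100, seed = 11)
  read1 <- substr(s, 1, 60)
  read2 <- bepitools:::revcomp(substr(s, 41, 100))
  m <- merge_pair(read1, read2)
  expect_true(m$merged)
  expect_identical(m$sequence, s)
  expect_identical(m$overlap, 20L)
  # full overlap: merging a read with its own reverse complement is identity
  r <- random_dna(40, seed = 12)
  m2 <- merge_pair(r, bepitools:::revcomp(r))
  expect_true(m2$merged)
  expect_identical(m2$sequence, r)
  # disjoint sequences fail to merge and are flagged, not an error
  m3 <- merge_pair(random_dna(30, seed = 13), random_dna(30, seed = 14))
  expect_false(m3$merged)
  expect_true(is.na(m3$sequence))
})

test_that("overlap disagreements resolve by quality, ties to read 1", {
  s <- random_dna(60, seed = 15)
  read1 <- substr(s, 1, 40)
  true2 <- substr(s, 21, 60)
  # corrupt one overlap base of read 2 then give read 1 higher quality
  r2 <- true2
  base <- substr(r2, 5, 5) # overlap position 25 of s
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  substr(r2, 5, 5) <- alt
  read2 <- bepitools:::revcomp(r2)
  hiq <- strrep("I", 40) # Q40
  loq <- strrep("#", 40) # Q2
  m_r1wins <- merge_pair(read1, read2, qual1 = hiq, qual2 = loq)
  expect_identical(m_r1wins$sequence, s)
  m_r2wins <- merge_pair(read1, read2, qual1 = loq, qual2 = hiq)
  expect_identical(substr(m_r2wins$sequence, 25, 25), alt)
  # equal qualities: read 1 wins
  m_tie <- merge_pair(read1, read2, qual1 = hiq, qual2 = hiq)
  expect_identical(m_tie$sequence, s)
})

test_that("variant counting is exact and order invariant", {
  ct <- count_variants(list(`1` = c("X", "X", "X", "Y"),
                            `2` = c("Y", "X")))
  expect_identical(ct$count[ct$variant == "X" & ct$round == 1], 3L)
  expect_identical(ct$count[ct$variant == "Y" & ct$round == 1], 1L)
  ct2 <- count_variants(list(`1` = c("Y", "X", "X", "X"),
                             `2` = c("X", "Y")))
  expect_identical(as.data.frame(ct), as.data.frame(ct2))
  # tibble input and per-round totals as column sums
  df <- tibble::tibble(round = c(1, 1, 2), sequence = c("A", "B", "A"))
  ct3 <- count_variants(df)
  expect_identical(sum(ct3$count[ct3$round == 1]), 2L)
  expect_identical(ct3$count[ct3$variant == "B" & ct3$round == 2], 0L)
})

test_that("fold enrichment follows the frequency-ratio definition", {
  # 1 read of 1e6 in round 1 (freq 1e-6), 2 of 1000 in round 4 (freq 2e-3)
  counts <- tibble::tibble(
    variant = c("hit", "bulk", "hit", "bulk"),
    round = c(1L, 1L, 4L, 4L),
    count = c(1L, 999999L, 2L, 998L))
  rec <- fold_enrichment(counts)
  expect_equal(rec$fold[rec$variant == "hit"], 2000)
  # identical frequencies give fold 1
  flat <- tibble::tibble(variant = rep(c("a", "b"), 2),
                         round = rep(c(1L, 2L), each = 2),
                         count = c(10L, 30L, 20L, 60L))
  expect_equal(fold_enrichment(flat)$fold, c(1, 1))
  # absent in the final round gives fold 0
  gone <- tibble::tibble(variant = rep(c("a", "b"), 2),
                         round = rep(c(1L, 2L), each = 2),
                         count = c(10L, 30L, 0L, 60L))
  expect_equal(fold_enrichment(gone)$fold[
    fold_enrichment(gone)$variant == "a"], 0)
  # per-round frequencies sum to 1
  rec2 <- fold_enrichment(flat)
  expect_equal(sum(rec2$freq_from), 1, tolerance = 1e-12)
  expect_equal(sum(rec2$freq_to), 1, tolerance = 1e-12)
  expect_error(fold_enrichment(counts[counts$round == 1, ]), "two rounds")
})

test_that("fold enrichment is scale invariant in round totals", {
  set.seed(31)
  counts <- tibble::tibble(
    variant = rep(letters[1:6], 2),
    round = rep(c(1L, 4L), each = 6),
    count = c(rpois(6, 50) + 1L, rpois(6, 80) + 1L))
  f1 <- fold_enrichment(counts)
  scaled <- counts
  scaled$count[scaled$round == 4L] <- scaled$count[scaled$round == 4L] * 10L
  f2 <- fold_enrichment(scaled)
  expect_equal(f1$fold, f2$fold, tolerance = 1e-12)
})

test_that("hit selection is strictly greater than the threshold", {
  rec <- tibble::tibble(variant = c("a", "b", "c"),
                        fold = c(2000, 1000, 999))
  hits <- select_hits(rec, threshold = 1000)
  expect_identical(hits$variant, "a")
  expect_identical(nrow(select_hits(rec, threshold = 5000)), 0L)
  expect_identical(nrow(select_hits(rec[0, ])), 0L)
})

test_that("substitution calling reports refAA-position-altAA codes", {
  ref <- test_orf()
  # codon 31 AAA -> AAT gives K31N
  expect_identical(substr(ref, 91, 93), "AAA")
  var <- ref
  substr(var, 93, 93) <- "T"
  call <- call_substitutions(var, ref)
  expect_identical(call$substitutions$label, "K31N")
  expect_false(call$frameshift)
  # identical sequences: empty call
  same <- call_substitutions(ref, ref)
  expect_identical(nrow(same$substitutions), 0L)
  expect_false(same$synonymous_only)
  # synonymous-only change: AAA -> AAG is still K
  syn <- ref
  substr(syn, 93, 93) <- "G"
  expect_true(call_substitutions(syn, ref)$synonymous_only)
  # 1-nt deletion in codon 31 is a frameshift
  fs <- paste0(substr(ref, 1, 91), substr(ref, 93, nchar(ref)))
  expect_true(call_substitutions(fs, ref)$frameshift)
  # reference with an internal stop is rejected
  bad <- ref
  substr(bad, 91, 93) <- "TAA"
  expect_error(call_substitutions(ref, bad), "internal stop")
  expect_error(call_substitutions(ref, substr(ref, 1, 100)), "divisible")
})

test_that("combinatorial library enumeration matches the product rule", {
  lib <- enumerate_combinatorial_library(sites_4mix())
  expect_identical(nrow(lib), 90L)
  expect_identical(nrow(lib), as.integer(prod(lengths(sites_4mix()))))
  expect_false(anyDuplicated(lib$name) > 0)
  # all-wild-type combination present
  expect_true("RQVK" %in% lib$name)
  expect_identical(attr(lib, "wild_type"), "RQVK")
  # one site, two residues
  expect_identical(nrow(enumerate_combinatorial_library(
    list(`5` = c("A", "G")))), 2L)
  expect_error(enumerate_combinatorial_library(
    list(`5` = "A", `5` = "G")), "duplicate")
  expect_error(enumerate_combinatorial_library(
    list(`5` = c("A", "X"))), "non-standard")
})

test_that("fold_change computes simple improvement ratios", {
  expect_equal(round(fold_change(28.2, 2.38), 1), 11.8)
  expect_equal(round(fold_change(29.64, 14.23), 1), 2.1)
  expect_error(fold_change(1, 0), "positive")
})
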