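test_that("PAM-relative conversion matches the printed spacer annotations", {
  expect_identical(pam_relative_position(8), 13L)
  expect_identical(pam_relative_position(20), 1L)
  expect_identical(pam_relative_position(6), 15L)
  # applying the conversion twice returns the original index
  for (i in 1:20) {
    expect_identical(pam_relative_position(pam_relative_position(i)), i)
  }
  expect_error(pam_relative_position(0), "1..20")
  expect_error(pam_relative_position(21), "1..20")
})

test_that("editable cytosines of the three repeat spacers are recovered", {
  expect_identical(find_editable_cytosines(PREP2, c(12, 17)), 13L)
  expect_identical(find_editable_cytosines(PREP7, c(12, 17)), c(12L, 15L))
  expect_identical(find_editable_cytosines(PREP12, c(12, 17)), 12L)
  expect_identical(find_editable_cytosines("AAAATTTTAAAATTTTAAAA"),
                   integer(0))
  expect_error(find_editable_cytosines("GTAGGTTCGACTCCTATTAN"), "non-ACGT")
  expect_error(find_editable_cytosines(PREP2, c(17, 12)), "window")
})

test_that("reference construction follows the stated component order", {
  ref <- build_reference("ACGT", PREP2, "TGG")
  expect_identical(ref$full_sequence,
                   paste0("ACGT", "GA", PREP2, "TGG", emsg_fixed_suffix()))
  expect_identical(nchar(ref$full_sequence), 4L + 2L + 20L + 3L + 30L)
  expect_identical(ref$protospacer_interval, c(7L, 26L))
  expect_identical(ref$pam_interval, c(27L, 29L))
  expect_identical(ref$analysis_window, c(11L, 19L))
  expect_identical(nchar(emsg_fixed_suffix()), 30L)
  expect_error(build_reference("ACGT", substr(PREP2, 1, 19), "TGG"), "20 nt")
})

test_that("alignment records substitutions and indels at the right places", {
  ref <- test_reference()
  # identical read: all-match
  a0 <- align_read(ref$full_sequence, ref)
  expect_true(a0$aligned)
  expect_identical(a0$identity, 1)
  expect_identical(unname(a0$ref_calls),
                   strsplit(ref$full_sequence, "")[[1]])
  expect_identical(nrow(a0$insertions), 0L)
  # single C->T at the protospacer index mapping to PAM-relative 13
  coord <- ref$protospacer_interval[1] + 8L - 1L
  s <- ref$full_sequence
  substr(s, coord, coord) <- "T"
  a1 <- align_read(s, ref)
  refv <- strsplit(ref$full_sequence, "")[[1]]
  subs_at <- which(a1$ref_calls != refv)
  expect_identical(subs_at, coord)
  expect_identical(a1$ref_calls[coord], "T")
  # 3-nt deletion inside the protospacer: one deletion overlapping it
  del_start <- ref$protospacer_interval[1] + 5L
  s2 <- paste0(substr(ref$full_sequence, 1, del_start - 1),
               substr(ref$full_sequence, del_start + 3,
                      nchar(ref$full_sequence)))
  a2 <- align_read(s2, ref)
  del_pos <- which(a2$ref_calls == "-")
  expect_identical(length(del_pos), 3L)
  expect_true(all(del_pos >= ref$protospacer_interval[1] &
                    del_pos <= ref$protospacer_interval[2]))
  # junk fails the identity threshold and is flagged, not an error
  a3 <- align_read(strrep("A", 59), ref)
  expect_false(a3$aligned)
})

test_that("quantification implements the indel-percentage definition", {
  ref <- test_reference()
  good <- ref$full_sequence
  del_start <- ref$protospacer_interval[1] + 5L
  deleted <- paste0(substr(good, 1, del_start - 1),
                    substr(good, del_start + 3, nchar(good)))
  reads <- c(rep(good, 8), rep(deleted, 2))
  q <- quantify_edits(align_reads(reads, ref), ref)
  expect_identical(q$summary$n_reads_aligned, 10L)
  expect_identical(q$summary$n_indel_reads, 2L)
  expect_equal(q$summary$indel_pct, 20)
  # identical reads give all-zero rates
  q0 <- quantify_edits(align_reads(rep(good, 5), ref), ref)
  expect_true(all(q0$positions$rate_c_to_t == 0))
  expect_identical(q0$summary$indel_pct, 0)
  # read order permutation leaves the result unchanged
  set.seed(42)
  qp <- quantify_edits(align_reads(sample(reads), ref), ref)
  expect_identical(q$summary, qp$summary)
})

test_that("read classes partition the input", {
  ref <- test_reference()
  good <- ref$full_sequence
  coord <- ref$protospacer_interval[1] + 8L - 1L
  edited <- good; substr(edited, coord, coord) <- "T"
  del_start <- ref$protospacer_interval[1] + 2L
  deleted <- paste0(substr(good, 1, del_start - 1),
                    substr(good, del_start + 2, nchar(good)))
  junk <- strrep("G", 59)
  reads <- c(junk, rep(deleted, 2), rep(edited, 3), rep(good, 4))
  q <- quantify_edits(align_reads(reads, ref), ref, window = c(12, 17))
  n_unaligned <- q$summary$n_reads - q$summary$n_reads_aligned
  n_sub_eligible <- q$summary$n_reads_aligned - q$summary$n_indel_reads
  expect_identical(n_unaligned, 1L)
  expect_identical(q$summary$n_indel_reads, 2L)
  expect_identical(n_sub_eligible, 7L)
  expect_identical(q$summary$n_reads, 10L)
  # 3 of the 7 substitution-eligible reads carry the window C->T
  expect_equal(q$summary$c_to_t_window_pct, 100 * 3 / 7)
  # C-to-T never exceeds C-to-D, per position and in aggregate
  expect_true(all(q$positions$n_c_to_t <=
                    q$positions$n_c_to_t + q$positions$n_c_to_a +
                    q$positions$n_c_to_g))
  expect_lte(q$summary$c_to_t_window_pct, q$summary$c_to_d_window_pct)
  expect_error(quantify_edits(align_reads(junk, ref), ref), "zero aligned")
})

test_that("the empirical editing window is the maximal qualifying run", {
  prof <- tibble::tibble(position = 1:20, rate_c_to_t = 0)
  prof$rate_c_to_t[12:17] <- c(0.2, 0.5, 0.6, 0.55, 0.4, 0.25)
  prof$rate_c_to_t[5] <- 0.05
  expect_identical(infer_editing_window(prof), c(12L, 17L))
  # single nonzero position
  single <- tibble::tibble(position = 1:20, rate_c_to_t = 0)
  single$rate_c_to_t[9] <- 0.4
  expect_identical(infer_editing_window(single), c(9L, 9L))
  # uniform profile: every position qualifies
  unif <- tibble::tibble(position = 1:20, rate_c_to_t = 0.3)
  expect_identical(infer_editing_window(unif), c(1L, 20L))
  # equal-length runs: PAM-proximal (lower positions) wins
  tie <- tibble::tibble(position = 1:20, rate_c_to_t = 0)
  tie$rate_c_to_t[c(3, 4, 10, 11)] <- 0.5
  expect_identical(infer_editing_window(tie), c(3L, 4L))
  allzero <- tibble::tibble(position = 1:20, rate_c_to_t = 0)
  expect_error(infer_editing_window(allzero), "no editing detected")
})
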