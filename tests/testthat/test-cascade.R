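# Cascade reconstruction: the three alignment filters, greedy 3'->5'
# chaining, and coverage/redundancy accounting.

test_that("three or more adjacent mismatches are discarded; G:U breaks a run", {
  keep2 <- mk_aln(paste0(strrep("|", 10), "##", strrep("|", 5), "#",
                         strrep("|", 6)))
  drop3 <- mk_aln(paste0(strrep("|", 10), "###", strrep("|", 11)))
  expect_equal(nrow(filter_alignments(keep2)), 1L)
  expect_equal(nrow(filter_alignments(drop3)), 0L)
  # a G:U between mismatches breaks the run (length keeps rule iii quiet)
  gu_break <- mk_aln(paste0(strrep("|", 20), "##:##", strrep("|", 20)))
  expect_equal(nrow(filter_alignments(gu_break)), 1L)
})

test_that("the mismatch/length ratio filter is strict at 1/8", {
  ratio_eq <- mk_aln(paste0(strrep("|", 7), "#", strrep("|", 7), "#"))
  expect_equal(8L * ratio_eq$n_mm, ratio_eq$length)    # exactly 1/8
  expect_equal(nrow(filter_alignments(ratio_eq)), 1L)
  ratio_hi <- mk_aln(paste0(strrep("|", 6), "#", strrep("|", 6), "#",
                            strrep("|", 1), "#"))      # 3/16 > 1/8
  expect_equal(nrow(filter_alignments(ratio_hi)), 0L)
})

test_that("alignments outside refined gene boundaries are discarded", {
  a <- mk_aln(strrep("|", 24))
  a$source_id <- "mc01"; a$source_strand <- "-"
  a$source_start <- 100L; a$source_end <- 124L
  genes <- data.frame(source_id = "mc01", strand = "-",
                      start = 100L, end = 124L)
  expect_equal(nrow(filter_alignments(a, genes)), 1L)
  genes_short <- data.frame(source_id = "mc01", strand = "-",
                            start = 100L, end = 119L)   # 5 nt short
  expect_equal(nrow(filter_alignments(a, genes_short)), 0L)
})

test_that("the filters commute", {
  set.seed(71)
  mk <- function() {
    ps <- paste(sample(c("|", ":", "#"), 24, TRUE, prob = c(.7, .15, .15)),
                collapse = "")
    mk_aln(ps)
  }
  alns <- do.call(rbind, replicate(30, mk(), simplify = FALSE))
  class(alns) <- c("duplex_alignments", "data.frame")
  f_ii <- function(x) { k <- !grepl("###", x$pair_string); y <- x[k, ]; class(y) <- class(x); y }
  f_iii <- function(x) { k <- 8L * x$n_mm <= x$length; y <- x[k, ]; class(y) <- class(x); y }
  expect_equal(f_ii(f_iii(alns))$pair_string,
               f_iii(f_ii(alns))$pair_string)
  expect_equal(filter_alignments(alns)$pair_string,
               f_ii(f_iii(alns))$pair_string)
})

test_that("a planted cascade is recovered in order with its overlaps", {
  sim <- small_sim()
  truth <- sim$truth
  id <- "CG1"
  mrna <- truth$cryptogenes[[id]]$edited_seq
  tg <- truth$grnas[truth$grnas$cryptogene_id == id, ]
  tg <- tg[order(tg$cascade_order), ]
  gseqs <- stats::setNames(tg$seq, tg$grna_id)
  alns <- cascade_alignments(gseqs, stats::setNames(mrna, id))
  cm <- build_cascade(filter_alignments(alns))
  expect_equal(cm$cascade$grna_id, tg$grna_id)
  expect_equal(cm$cascade$mrna_start, tg$mrna_start)
  expect_equal(sum(!cm$gaps$adjacent), 0L)
  expect_true(all(cm$cascade$overlap_with_prev[-1] >=
                    sim$cfg$anchor_overlap))
  # partition: cascade intervals plus gaps tile the edited domain
  covered <- rep(FALSE, cm$domain[2] - cm$domain[1])
  for (i in seq_len(nrow(cm$cascade))) {
    s <- cm$cascade$mrna_start[i] - cm$domain[1]
    e <- cm$cascade$mrna_end[i] - cm$domain[1]
    covered[(s + 1):e] <- TRUE
  }
  gap_real <- cm$gaps[!cm$gaps$adjacent, ]
  for (i in seq_len(nrow(gap_real)))
    covered[(gap_real$start[i] - cm$domain[1] + 1):(gap_real$end[i] - cm$domain[1])] <- TRUE
  expect_true(all(covered))
})

test_that("adjacent but non-overlapping neighbours are flagged", {
  a1 <- mk_aln(strrep("|", 20), mrna_start = 30L)
  a2 <- mk_aln(strrep("|", 20), mrna_start = 10L)
  a1$grna_id <- "g1"; a2$grna_id <- "g2"
  a1$score <- 40L; a2$score <- 40L
  alns <- rbind(a1, a2)
  class(alns) <- c("duplex_alignments", "data.frame")
  cm <- build_cascade(alns)
  expect_equal(cm$cascade$grna_id, c("g1", "g2"))
  expect_equal(cm$cascade$overlap_with_prev[2], 0L)
  expect_equal(sum(cm$gaps$adjacent), 1L)
  st <- cascade_coverage_stats(cm, all_grna_ids = c("g1", "g2", "o1", "o2"))
  expect_equal(st$n_adjacent, 1L)
  expect_equal(st$n_unassigned, 2L)
  expect_equal(st$mean_redundancy, 1)
  expect_equal(st$n_gaps, 0L)
})

test_that("planted coverage redundancy is recovered", {
  cfg <- sim_config(seed = 55, n_minicircles = 59, n_two_grna_minicircles = 1,
                    n_cryptogenes = 1, cryptogene_len = 1020, redundancy = 3,
                    grna_len_range = c(30L, 64L),
                    coverage = 5, small_rna_reads_per_grna = 1)
  truth <- simulate_kdna(cfg)
  id <- "CG1"
  tg <- truth$grnas
  gseqs <- stats::setNames(tg$seq, tg$grna_id)
  alns <- cascade_alignments(gseqs,
                             stats::setNames(truth$cryptogenes[[id]]$edited_seq, id))
  cm <- build_cascade(filter_alignments(alns))
  expect_lt(abs(mean(cm$redundancy) - 3) / 3, 0.1)
})
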