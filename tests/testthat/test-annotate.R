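# Structural annotation: motif scanning, circularization, inverted
# repeats, class deduplication, orientation.

test_that("CSB3 exact match and circular wrap-around are found", {
  h <- scan_motif("GGGGTTGGTGTGAA", "ggggttggtgtg", both_strands = FALSE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$strand, "+")
  # rotate so the 12-mer spans the origin of a circular 14-mer
  rot <- paste0("TGTGAAGGGGTTGG")   # motif wraps: starts at position 6
  hc <- scan_motif(rot, "GGGGTTGGTGTG", both_strands = FALSE, circular = TRUE)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$start, 6L)
  hl <- scan_motif(rot, "GGGGTTGGTGTG", both_strands = FALSE, circular = FALSE)
  expect_equal(nrow(hl), 0L)
  expect_error(scan_motif("ACGT", "AXG"), "IUPAC")
})

test_that("degenerate IUPAC scanning equals the naive per-position oracle", {
  set.seed(21)
  csb1 <- "YYRYRYRRRRYYYYRYRYRR"
  for (i in 1:40) {
    L <- sample(40:160, 1)
    s <- rand_dna(L)
    if (i %% 2 == 0) {
      # embed a consistent expansion at a known spot
      inst <- paste(vapply(strsplit(csb1, "")[[1L]], function(p)
        sample(iupac_sets[[p]], 1), ""), collapse = "")
      pos <- sample(L - 20, 1)
      s <- paste0(substring(s, 1, pos - 1), inst, substring(s, pos + 20))
    }
    circ <- i %% 3 == 0
    got <- scan_motif(s, csb1, both_strands = FALSE, circular = circ)
    expect_equal(got$start, naive_iupac_scan(s, csb1, circular = circ),
                 info = paste("case", i))
  }
  # inconsistent expansion must not match
  bad <- "CCACATAAAGCCCCATATAA"   # position 2 'C' vs pattern Y ok; flip a R->C
  bad <- paste0("TT", substring(bad, 3))
  expect_true(all(naive_iupac_scan(bad, csb1) ==
                    scan_motif(bad, csb1, both_strands = FALSE)$start))
})

test_that("terminal direct repeats circularize; degenerate repeats error", {
  core <- rand_dna(60)
  contig <- paste0("ACGTACGT", core, "ACGTACGT")
  out <- circularize_contig(contig, k_min = 8)
  expect_true(out$circular)
  expect_equal(nchar(out$seq), nchar(contig) - 8L)
  expect_equal(out$overlap, 8L)
  # no terminal repeat of the required length: unchanged and flagged
  set.seed(5)
  s2 <- paste0("AACC", rand_dna(50), "GGTT")
  out2 <- circularize_contig(s2, k_min = 20)
  expect_false(out2$circular)
  expect_equal(out2$seq, s2)
  expect_error(circularize_contig("AAAAAA"), "ambiguous")
})

test_that("inverted repeats respect the score threshold boundary", {
  # poly(A) flanks/loops cannot pair (A opposite complement(A) = T
  # mismatches), so the planted arms bound the attainable score exactly
  pad <- function(arm1, arm2) paste0(strrep("A", 12), arm1, strrep("A", 14),
                                     arm2, strrep("A", 12))
  # perfect 10-bp arms: score 40 -> reported at threshold 40
  arm10 <- "CCGGTCGTGC"
  ir <- find_inverted_repeats(pad(arm10, rc(arm10)))
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$score[1], 40L)
  expect_equal(ir$arm1_end[1] - ir$arm1_start[1], 10L)
  expect_equal(ir$arm1_start[1], 12L)
  expect_equal(ir$arm2_start[1], 36L)
  # 9-bp arms: score 36 -> absent at threshold 40
  arm9 <- "CCGGTCGTG"
  expect_equal(nrow(find_inverted_repeats(pad(arm9, rc(arm9)))), 0L)
  # 12-bp arms with one internal mismatch: 11*4 - 4 = 40 -> reported
  a <- "CCGGTCGTGCGC"
  b <- rc(a)
  substr(b, 6, 6) <- if (substring(b, 6, 6) == "C") "G" else "C"
  ir12 <- find_inverted_repeats(pad(a, b))
  expect_equal(nrow(ir12), 1L)
  expect_equal(ir12$score[1], 40L)
  expect_equal(ir12$mismatches[1], 1L)
})

test_that("best inverted-repeat score matches the split-point oracle", {
  set.seed(33)
  for (i in 1:25) {
    L <- sample(30:60, 1)
    s <- rand_dna(L)
    if (i %% 2 == 0) {
      arm <- rand_dna(sample(10:13, 1))
      s <- paste0(substring(s, 1, 5), arm, rand_dna(8), rc(arm),
                  substring(s, 6, 12))
    }
    want <- brute_best_ir(s)
    got <- find_inverted_repeats(s)
    if (want >= 40) {
      expect_gte(nrow(got), 1L)
      expect_equal(got$score[1], want, info = paste("case", i))
    } else {
      expect_equal(nrow(got), 0L, info = paste("case", i))
    }
  }
})

test_that("reported inverted repeats rescore consistently", {
  set.seed(35)
  arm <- rand_dna(15)
  s <- paste0(rand_dna(20), arm, rand_dna(30), rc(arm), rand_dna(20))
  ir <- find_inverted_repeats(s)
  expect_gte(nrow(ir), 1L)
  r <- ir[1, ]
  a1 <- substring(s, r$arm1_start + 1, r$arm1_end)
  a2 <- substring(s, r$arm2_start + 1, r$arm2_end)
  if (r$gaps == 0) {
    m <- sum(strsplit(a1, "")[[1L]] == strsplit(rc(a2), "")[[1L]])
    expect_equal(r$score, 4L * m - 4L * r$mismatches)
    expect_equal(nchar(a1) - m, r$mismatches)
  }
})

test_that("minicircle classes are rotation- and strand-invariant", {
  set.seed(41)
  a <- rand_dna(100)
  rotations <- vapply(c(1, 30, 77), function(p)
    paste0(substring(a, p, 100), substring(a, 1, p - 1)), "")
  circles <- c(mcA = a, mcB = rotations[2], mcC = rotations[3],
               mcD = rc(a))
  cl <- classify_minicircles(circles)
  expect_equal(length(unique(cl$class_id)), 1L)
  # identity boundary: 3 differences on 100 nt join at 0.97, 4 split
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1L]]
    idx <- sample(100, k)
    for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  cl3 <- classify_minicircles(c(x = a, y = mutate(a, 3)))
  expect_equal(length(unique(cl3$class_id)), 1L)
  cl4 <- classify_minicircles(c(x = a, y = mutate(a, 4)))
  expect_equal(length(unique(cl4$class_id)), 2L)
  # partition property: every circle in exactly one class
  expect_true(all(table(cl$id) == 1))
})

test_that("minicircles re-orient onto the CSB nearest the gRNA gene", {
  set.seed(43)
  s <- rand_dna(2000)
  csb <- data.frame(motif_name = "CSB3", start = c(500L, 1300L), length = 12L,
                    strand = "+", pattern = "p")
  gene <- data.frame(start = 700L, end = 740L, strand = "-")
  out <- reorient_minicircle(s, csb, gene)
  expect_equal(out$rotation, 500L)
  expect_equal(out$csb_hits$start[1], 0L)
  expect_equal(out$grna_genes$start, 200L)
  # nearer CSB wins: distances 150 and 800
  csb2 <- data.frame(motif_name = "CSB3", start = c(550L, 1500L), length = 12L,
                     strand = "+", pattern = "p")
  out2 <- reorient_minicircle(s, csb2, gene)
  expect_equal(out2$rotation, 550L)
  # tie in circular distance: lower coordinate wins
  csb3 <- data.frame(motif_name = "CSB3", start = c(600L, 800L), length = 12L,
                     strand = "+", pattern = "p")
  out3 <- reorient_minicircle(s, csb3, gene)
  expect_equal(out3$rotation, 600L)
  # strand flip when the gene shares the CSB strand
  gene_p <- data.frame(start = 700L, end = 740L, strand = "+")
  outf <- reorient_minicircle(s, csb, gene_p)
  expect_true(outf$flipped)
  expect_equal(outf$grna_genes$strand, "-")
  # idempotence
  again <- reorient_minicircle(out$seq, out$csb_hits, out$grna_genes)
  expect_equal(again$rotation, 0L)
  expect_false(again$flipped)
  expect_equal(again$seq, out$seq)
  expect_error(reorient_minicircle(s, csb[0, ], gene), "CSB")
  expect_error(reorient_minicircle(s, csb, gene[0, ]), "gene")
})
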