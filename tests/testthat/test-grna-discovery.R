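# gRNA gene discovery: alignment-based annotation, small-RNA
# preprocessing, tail stripping, clustering and consensus validation.

test_that("preprocessing enforces the 15-nt minimum length boundary", {
  adapter <- "AGATCGGAAGAGC"
  insert14 <- rand_dna(14); insert15 <- rand_dna(15)
  mk <- function(ins) {
    r1 <- stats::setNames(paste0(ins, adapter), "p")
    r2 <- stats::setNames(paste0(rc(ins), adapter), "p")
    preprocess_small_reads(r1, r2, adapter)
  }
  expect_length(mk(insert14), 0L)
  out <- mk(insert15)
  expect_length(out, 1L)
  expect_equal(unname(out[1]), insert15)
})

test_that("completely overlapping pairs merge into the insert", {
  insert <- rand_dna(40)
  r1 <- stats::setNames(insert, "a")
  r2 <- stats::setNames(rc(insert), "a")
  out <- preprocess_small_reads(r1, r2, "AGATCGGAAGAGC")
  expect_equal(unname(out[1]), insert)
  # embedded adapter truncates the read at its position
  r1b <- stats::setNames(paste0(substring(insert, 1, 20), "AGATCGGAAGAGC",
                                rand_dna(10)), "b")
  r2b <- stats::setNames(paste0(rc(substring(insert, 1, 20)), "AGATCGGAAGAGC",
                                rand_dna(10)), "b")
  outb <- preprocess_small_reads(r1b, r2b, "AGATCGGAAGAGC")
  expect_equal(unname(outb[1]), substring(insert, 1, 20))
  # overlap disagreements resolve towards the higher quality base
  ins2 <- strrep("ACGTG", 8)
  ins2_mut <- paste0("T", substring(ins2, 2))
  r1c <- structure(stats::setNames(ins2_mut, "c"),
                   qualities = stats::setNames("!", "c"))
  attr(r1c, "qualities") <- stats::setNames(strrep("!", 40), "c")
  r2c <- structure(stats::setNames(rc(ins2), "c"),
                   qualities = stats::setNames(strrep("I", 40), "c"))
  outc <- preprocess_small_reads(r1c, r2c, "AGATCGGAAGAGC")
  expect_equal(unname(outc[1]), ins2)
})

test_that("malformed FASTQ is reported by record number", {
  tf <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), tf)
  expect_error(kedit:::read_fastq_checked(tf), "record 2")
})

test_that("one trailing homopolymer tail is stripped", {
  expect_equal(strip_tails("ACGCTTTTT"), "ACGC")
  expect_equal(strip_tails("ACGCAAAA"), "ACGC")
  expect_equal(strip_tails("ACGCTT"), "ACGCTT")         # below min_tail
  expect_equal(strip_tails("ACGCTT", min_tail = 2), "ACGC")
  expect_equal(strip_tails("ACGAAATTT"), "ACGAAA")      # one run only
  expect_equal(strip_tails(c("GCAAAA", "GCTTTT")), c("GC", "GC"))
})

test_that("clustering splits at the 97% identity threshold", {
  set.seed(61)
  base <- rand_dna(100)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1L]]
    for (i in sample(100, k)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  near <- mutate(base, 3)    # 97% identity: same cluster
  far <- mutate(base, 4)     # 96%: splits
  src <- c(mc1 = paste0(rand_dna(50), base, rand_dna(50)))
  res3 <- call_expressed_grnas(c(a = base, b = near), src)
  expect_equal(nrow(res3$clusters), 1L)
  res4 <- call_expressed_grnas(c(a = base, b = far), src)
  expect_equal(nrow(res4$clusters), 2L)
  # unmappable consensus is an orphan, not a gene
  orphan <- rand_dna(60)
  reso <- call_expressed_grnas(c(a = base, o = orphan), src)
  expect_equal(sum(reso$clusters$validated), 1L)
  expect_length(reso$orphans, 1L)
  expect_false(any(is.na(reso$genes$start)))
})

test_that("alignment annotation recovers every planted gene exactly", {
  sim <- small_sim()
  truth <- sim$truth
  mrnas <- stats::setNames(vapply(truth$cryptogenes, `[[`, "", "edited_seq"),
                           names(truth$cryptogenes))
  genes <- annotate_grna_genes(truth$minicircles, mrnas,
                               maxicircle = stats::setNames(truth$maxicircle$seq,
                                                            "maxicircle"))
  tg <- truth$grnas
  key_t <- paste(tg$source_id, tg$start, tg$end, tg$strand)
  key_r <- paste(genes$source_id, genes$start, genes$end, genes$strand)
  expect_setequal(key_r, key_t)
  # a circle with no alignment to any edited mRNA is flagged
  extra <- c(truth$minicircles, list(mcX = rand_dna(1500)))
  genes2 <- annotate_grna_genes(extra, mrnas)
  expect_true("mcX" %in% attr(genes2, "unaligned_sources"))
})

test_that("a maxicircle-encoded gRNA is detected on the maxicircle", {
  cfg <- sim_config(seed = 99, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240,
                    n_maxicircle_grnas = 1)
  truth <- simulate_kdna(cfg)
  mrnas <- stats::setNames(vapply(truth$cryptogenes, `[[`, "", "edited_seq"),
                           names(truth$cryptogenes))
  genes <- annotate_grna_genes(truth$minicircles, mrnas,
                               maxicircle = stats::setNames(truth$maxicircle$seq,
                                                            "maxicircle"))
  mx <- genes[genes$source_id == "maxicircle", ]
  tmx <- truth$grnas[truth$grnas$source_id == "maxicircle", ]
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$start, tmx$start)
  expect_equal(mx$end, tmx$end)
})

test_that("expression-refined boundaries round-trip to their source", {
  sim <- small_sim()
  truth <- sim$truth
  cfg <- sim$cfg
  merged <- preprocess_small_reads(sim$reads$srna_r1, sim$reads$srna_r2,
                                   cfg$adapter_seq)
  stripped <- strip_tails(merged)
  called <- call_expressed_grnas(stripped, truth$minicircles,
                                 maxicircle = truth$maxicircle$seq)
  g <- called$genes
  tg <- truth$grnas
  key_t <- paste(tg$source_id, tg$start, tg$end, tg$strand)
  key_r <- paste(g$source_id, g$start, g$end, g$strand)
  expect_setequal(key_r, key_t)
  expect_true(all(g$boundaries_refined))
  expect_true(all(g$expression_support >= 1))
  # round-trip: the called consensus maps back at the recorded coordinates
  sources <- c(truth$minicircles, list(maxicircle = truth$maxicircle$seq))
  seqs <- guide_gene_seqs(g, sources)
  for (i in seq_len(nrow(g))) {
    cl <- called$clusters[called$clusters$validated &
                            called$clusters$source == g$source_id[i] &
                            called$clusters$start == g$start[i], ]
    expect_equal(unname(seqs[i]), cl$consensus[1])
  }
  # clustering is a partition and consensus is bounded by the longest member
  expect_true(all(called$clusters$size >= 1))
  expect_lte(max(nchar(called$clusters$consensus)), max(nchar(stripped)))
})
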