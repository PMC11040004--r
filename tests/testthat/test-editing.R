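# T-stripped alignment layer: site tables, read editing patterns,
# edited-read calling, coverage, ORF reconstruction, code-4 translation.

test_that("site tables decompose and rebuild sequences exactly", {
  tab <- build_site_table("ACTTGA")
  expect_equal(tab$backbone, "ACGA")
  expect_equal(tab$site_ucount, c(0L, 0L, 2L, 0L, 0L))
  expect_equal(tab$n_sites, 5L)
  expect_equal(build_site_table("TTAC")$site_ucount, c(2L, 0L, 0L))
  expect_error(build_site_table("TTTT"), "backbone")
  expect_error(build_site_table(""), "empty")
  set.seed(51)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE,
                      prob = c(.2, .2, .2, .4)), collapse = "")
    s <- sub("T+$", "", sub("^T+", paste0(rand_dna(1)), s))
    if (!nzchar(gsub("T", "", s))) next
    tab <- build_site_table(s)
    expect_equal(rebuild_sequence(tab), s)
    expect_equal(tab$n_sites, nchar(tab$backbone) + 1L)
  }
})

test_that("read patterns report per-site U differences", {
  tab <- build_site_table("ACTTGA", id = "ref")
  # deletion: one U fewer at the site before G
  p1 <- align_read_tstripped("ACTGA", tab)
  expect_equal(p1$cryptogene_id, "ref")
  expect_equal(p1$n_deletions, 1L)
  expect_equal(p1$n_insertions, 0L)
  expect_equal(p1$obs_ucount[p1$sites == 3 & !p1$partial], 1L)
  # insertion: two extra Us
  p2 <- align_read_tstripped("ACTTTTGA", tab)
  expect_equal(p2$n_insertions, 2L)
  expect_equal(p2$obs_ucount[p2$sites == 3 & !p2$partial], 4L)
  # reverse strand reads map too
  p3 <- align_read_tstripped(rc("ACTTGA"), tab)
  expect_equal(p3$strand, "-")
  expect_equal(p3$n_edited_sites, 0L)
})

test_that("staged simulated reads recover planted per-site counts exactly", {
  sim <- small_sim()
  truth <- sim$truth
  tables <- lapply(truth$cryptogenes, function(cg)
    build_site_table(cg$pre_seq, id = cg$id))
  mr <- sim$reads$mrna[grep("^mrna\\|CG1\\|", names(sim$reads$mrna))]
  al <- align_reads(mr, tables)
  expect_equal(al$n_unassigned, 0L)
  cg <- truth$cryptogenes$CG1
  full <- Filter(function(p) grepl(sprintf("stage=%d\\|",
    sum(truth$grnas$cryptogene_id == "CG1")), p$read_id), al$patterns)
  expect_gt(length(full), 5L)
  for (p in full[1:5]) {
    int <- which(!p$partial)
    expect_equal(p$obs_ucount[int], cg$ucount_edited[p$sites[int]])
  }
  pre <- Filter(function(p) grepl("stage=0\\|", p$read_id), al$patterns)
  for (p in pre) expect_equal(p$n_edited_sites, 0L)
})

test_that("the edited-read threshold sits at 5 edited sites", {
  tab <- build_site_table(strrep("ACTG", 30), id = "ref")
  u <- tab$site_ucount
  mk <- function(k) {
    u2 <- u
    u2[10 + seq_len(k) * 3L] <- u2[10 + seq_len(k) * 3L] + 1L
    rebuild_sequence(tab, u2)
  }
  p5 <- align_read_tstripped(mk(5), tab)
  p4 <- align_read_tstripped(mk(4), tab)
  expect_equal(p5$n_edited_sites, 5L)
  expect_true(is_edited(p5))
  expect_false(is_edited(p4))
  expect_false(is_edited(align_read_tstripped(rebuild_sequence(tab), tab)))
})

test_that("coverage profiles conserve aligned bases and count edited reads", {
  sim <- small_sim()
  truth <- sim$truth
  tables <- lapply(truth$cryptogenes, function(cg)
    build_site_table(cg$pre_seq, id = cg$id))
  rd <- sim$reads$mrna[grep("^mrna\\|(CG|ND)", names(sim$reads$mrna))]
  al <- align_reads(rd, tables)
  prof <- coverage_profile(al$patterns, tables)
  depth <- attr(prof, "depth")
  total_aligned <- sum(vapply(al$patterns, function(p)
    length(p$sites) - 1L, 0L))
  expect_equal(sum(unlist(depth)), total_aligned)
  # every pattern mapped to a known locus
  expect_equal(sum(prof$n_mapped), length(al$patterns))
  expect_true(all(prof$n_edited <= prof$n_mapped))
  expect_true(all(prof$n_edited > 0))   # pan-edited loci have edited reads
})

test_that("conflicting states resolve towards the better-supported branch", {
  tab <- build_site_table("ACGTTGACGTAGCATGCCGA", id = "toy")
  S <- tab$n_sites
  u_hi <- tab$site_ucount; u_hi[5] <- u_hi[5] + 2L   # majority variant
  u_lo <- tab$site_ucount; u_lo[5] <- u_lo[5] + 1L   # minority variant
  reads <- c(replicate(7, rebuild_sequence(tab, u_hi)),
             replicate(3, rebuild_sequence(tab, u_lo)))
  names(reads) <- paste0("r", seq_along(reads))
  al <- align_reads(reads, list(toy = tab))
  orf <- reconstruct_orf(al$patterns, tab, expected_protein_len = 1,
                         min_orf_fraction = 0)
  expect_equal(orf$consensus_ucount[5], u_hi[5])
  expect_error(reconstruct_orf(list(), tab), "no coverage")
})

test_that("zero-noise reconstruction returns the planted edited ORF", {
  sim <- small_sim()
  truth <- sim$truth
  tables <- lapply(truth$cryptogenes, function(cg)
    build_site_table(cg$pre_seq, id = cg$id))
  al <- align_reads(sim$reads$mrna[grep("^mrna\\|CG", names(sim$reads$mrna))],
                    tables)
  for (id in names(tables)) {
    cg <- truth$cryptogenes[[id]]
    pats <- Filter(function(p) p$cryptogene_id == id, al$patterns)
    orf <- reconstruct_orf(pats, tables[[id]],
                           expected_protein_len = cg$protein_len)
    expect_equal(orf$status, "ok")
    expect_equal(orf$edited_seq, cg$edited_seq)
    expect_equal(nchar(orf$protein), cg$protein_len)
    expect_false(grepl("\\*", substring(orf$protein, 1,
                                        nchar(orf$protein) - 1)))
    expect_true(orf$stop_codon %in% c("TAA", "TAG"))
  }
})

test_that("round-trip: a pattern plus the table reproduces the read", {
  sim <- small_sim()
  truth <- sim$truth
  tab <- build_site_table(truth$cryptogenes$CG2$pre_seq, id = "CG2")
  rd <- sim$reads$mrna[grep("^mrna\\|CG2\\|", names(sim$reads$mrna))][1:20]
  for (i in seq_along(rd)) {
    p <- align_read_tstripped(rd[i], list(CG2 = tab))
    expect_false(is.null(p))
    seg <- kedit:::read_segment(p, tab)
    expect_equal(seg$seq, unname(rd[i]))
    # insertion/deletion totals agree with the per-site differences
    int <- which(!p$partial)
    d <- p$obs_ucount[int] - p$ref_ucount[int]
    expect_equal(p$n_insertions - p$n_deletions, sum(d))
  }
})

test_that("translation table 4 reads UGA as tryptophan", {
  expect_equal(translate_code4("TGA"), "W")
  expect_equal(translate_code4("TAA"), "*")
  expect_equal(translate_code4("ATGTGATAA"), "MW*")
  expect_equal(translate_code4("ATGNNNTAA"), "MX*")
  expect_equal(translate_code4("GATGTGATAA", frame = 2), "MW*")
})
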