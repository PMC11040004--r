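# Ground-truthed generator: config-forced counts, limiting cases,
# determinism, and sampling-depth behaviour.

test_that("gene counts are forced by the configuration", {
  sim <- small_sim()
  cfg <- sim$cfg
  truth <- sim$truth
  expect_equal(nrow(truth$grnas),
               cfg$n_minicircles + cfg$n_two_grna_minicircles)
  expect_equal(length(truth$minicircles), cfg$n_minicircles)
  per_mc <- table(truth$grnas$source_id)
  expect_equal(sum(per_mc == 2), cfg$n_two_grna_minicircles)
  # one short class of the configured length
  lens <- nchar(unlist(truth$minicircles))
  expect_equal(sum(lens == cfg$small_minicircle_len), 1L)
  expect_equal(sum(lens >= cfg$minicircle_len_range[1] &
                     lens <= cfg$minicircle_len_range[2]),
               cfg$n_minicircles - 1L)
  # planted cascades jointly cover every edited site of their cryptogene
  for (id in names(truth$cryptogenes)) {
    cg <- truth$cryptogenes[[id]]
    tg <- truth$grnas[truth$grnas$cryptogene_id == id, ]
    pos <- cumsum(cg$ucount_edited[seq_len(nchar(cg$backbone))]) +
      seq_len(nchar(cg$backbone)) - 1L
    for (s in cg$edited_sites) {
      run_lo <- pos[s] - cg$ucount_edited[s]
      expect_true(any(tg$mrna_start <= run_lo & tg$mrna_end >= pos[s]),
                  info = paste(id, "site", s))
    }
    # each planted gRNA is the exact reverse complement of its interval
    for (i in seq_len(nrow(tg)))
      expect_equal(tg$seq[i], rc(substring(cg$edited_seq,
                                           tg$mrna_start[i] + 1L,
                                           tg$mrna_end[i])))
  }
})

test_that("zero editing fraction collapses edited and pre-edited states", {
  cfg <- sim_config(seed = 4, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240,
                    edited_fraction_of_sites = 0,
                    small_rna_reads_per_grna = 2, coverage = 2)
  truth <- simulate_kdna(cfg)
  for (cg in truth$cryptogenes) {
    expect_equal(cg$edited_seq, cg$pre_seq)
    expect_length(cg$edited_sites, 0L)
  }
})

test_that("identical seeds give byte-identical output files", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  cfg <- sim_config(seed = 8, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240,
                    small_rna_reads_per_grna = 3, coverage = 3)
  t1 <- simulate_kdna(cfg, out_dir = d1); simulate_reads(t1, cfg, out_dir = d1)
  t2 <- simulate_kdna(cfg, out_dir = d2); simulate_reads(t2, cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  cfg3 <- sim_config(seed = 9, n_minicircles = 12, n_two_grna_minicircles = 1,
                     n_cryptogenes = 2, cryptogene_len = 240,
                     small_rna_reads_per_grna = 3, coverage = 3)
  t3 <- simulate_kdna(cfg3, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "minicircles.fasta"))),
                         unname(tools::md5sum(file.path(d3, "minicircles.fasta")))))
})

test_that("per-base depth matches the requested coverage (Poisson check)", {
  cfg <- sim_config(seed = 14, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240, coverage = 30,
                    edited_fraction_of_sites = 0,
                    small_rna_reads_per_grna = 1)
  truth <- simulate_kdna(cfg)
  reads <- simulate_reads(truth, cfg)
  rd <- reads$mrna[grep("^mrna\\|CG1\\|", names(reads$mrna))]
  tab <- build_site_table(truth$cryptogenes$CG1$pre_seq, id = "CG1")
  al <- align_reads(rd, list(CG1 = tab))
  depth <- attr(coverage_profile(al$patterns, list(CG1 = tab)), "depth")$CG1
  mid <- depth[30:(length(depth) - 30)]
  # reads are laid down independently, so depth is approximately
  # Poisson(30); the mean over the interior must sit within 3 sigma of a
  # single Poisson draw scaled by the effective number of independent
  # read windows (length / read_len)
  n_eff <- length(mid) / 100
  expect_lt(abs(mean(mid) - 30), 3 * sqrt(30 / n_eff))
  expect_gt(min(mid), 5)   # no coverage holes at this depth
})

test_that("degenerate tails and absent adapters leave the bare gRNA read", {
  cfg <- sim_config(seed = 15, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240,
                    tail_len_distribution = c("0" = 1), adapter_seq = "",
                    small_rna_reads_per_grna = 2, coverage = 2)
  truth <- simulate_kdna(cfg)
  reads <- simulate_reads(truth, cfg)
  for (i in seq_len(min(10, length(reads$srna_r1)))) {
    gid <- sub("^srna\\|([^|]+)\\|.*$", "\\1", names(reads$srna_r1)[i])
    gseq <- truth$grnas$seq[truth$grnas$grna_id == gid]
    expect_equal(unname(reads$srna_r1[i]),
                 substring(gseq, 1, cfg$read_len))
  }
})

test_that("reads from unedited genes carry no editing events", {
  sim <- small_sim()
  truth <- sim$truth
  tabs <- lapply(truth$unedited, function(s) build_site_table(s))
  for (id in names(tabs)) tabs[[id]]$cryptogene_id <- id
  rd <- sim$reads$mrna[grep("^mrna\\|ND", names(sim$reads$mrna))]
  al <- align_reads(rd, tabs)
  expect_gt(length(al$patterns), 10L)
  for (p in al$patterns) expect_equal(p$n_edited_sites, 0L)
})

test_that("infeasible cascade tilings raise an explicit error", {
  expect_error(simulate_kdna(sim_config(seed = 1, n_minicircles = 6,
                                        n_two_grna_minicircles = 0,
                                        n_cryptogenes = 1,
                                        cryptogene_len = 900,
                                        small_rna_reads_per_grna = 1)),
               "infeasible tiling")
})

test_that("a full-mass fully-edited stage yields only edited-state reads", {
  cfg <- sim_config(seed = 16, n_minicircles = 12, n_two_grna_minicircles = 1,
                    n_cryptogenes = 2, cryptogene_len = 240,
                    editing_stage_distribution = c(pre = 0, intermediate = 0,
                                                   full = 1),
                    small_rna_reads_per_grna = 1, coverage = 5)
  truth <- simulate_kdna(cfg)
  reads <- simulate_reads(truth, cfg)
  tabs <- lapply(truth$cryptogenes, function(cg)
    build_site_table(cg$pre_seq, id = cg$id))
  al <- align_reads(reads$mrna[grep("^mrna\\|CG", names(reads$mrna))], tabs)
  for (p in al$patterns) {
    cg <- truth$cryptogenes[[p$cryptogene_id]]
    int <- which(!p$partial)
    expect_equal(p$obs_ucount[int], cg$ucount_edited[p$sites[int]])
  }
})
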