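# Antiparallel duplex alignment engine: pair classes, threshold
# behaviour, and equivalence with brute-force enumeration.

test_that("base pairs classify into WC, G:U wobble and mismatch", {
  expect_equal(classify_pair("G", "C"), "WC")
  expect_equal(classify_pair("A", "U"), "WC")
  expect_equal(classify_pair("U", "A"), "WC")
  expect_equal(classify_pair("C", "G"), "WC")
  expect_equal(classify_pair("G", "U"), "GU")
  expect_equal(classify_pair("U", "G"), "GU")
  expect_equal(classify_pair("A", "G"), "MM")
  expect_equal(classify_pair("C", "U"), "MM")
  expect_error(classify_pair("A", "X"), "non-RNA")
})

test_that("a perfect complement aligns full-length with additive score", {
  set.seed(1)
  m <- rand_dna(21)
  a <- align_duplex(rc(m), m, duplex_params("relaxed"))
  expect_equal(nrow(a), 1L)
  expect_equal(a$length, 21L)
  expect_equal(a$score, 42L)
  expect_equal(a$n_mm, 0L)
  expect_equal(a$pair_string, strrep("|", 21))
})

test_that("the G:U ceiling is enforced at the boundary (17 kept, 18 rejected)", {
  # an A-rich mRNA paired by a G-substituted complement yields G:U pairs:
  # mRNA U : gRNA G.  Build 30-nt duplex with exactly k GU pairs.
  set.seed(2)
  base <- paste(rep("T", 30), collapse = "")
  make_grna <- function(k) {
    g <- rep("A", 30)                 # U:A Watson-Crick
    if (k > 0) g[3 + seq_len(k)] <- "G"   # U:G wobble
    paste(rev(g), collapse = "")
  }
  p <- duplex_params("relaxed", min_anchor = 2)
  a17 <- align_duplex(make_grna(17), base, p)
  expect_equal(nrow(a17), 1L)
  expect_equal(a17$n_gu, 17L)
  a18 <- align_duplex(make_grna(18), base, p)
  expect_true(nrow(a18) == 0L || all(a18$n_gu <= 17L))
})

test_that("align_duplex equals brute-force enumeration on random cases", {
  set.seed(7)
  presets <- list(duplex_params("relaxed"), duplex_params("canonical"))
  n_match <- 0L
  for (case in 1:60) {
    p <- presets[[case %% 2L + 1L]]
    M <- sample(c(60, 90, 150, 300), 1)
    m <- rand_dna(M)
    # half the cases carry a planted complementary island
    g <- if (case %% 2L == 0L) {
      s <- sample(M - 30, 1)
      paste0(rand_dna(4), rc(substring(m, s, s + 24)), rand_dna(4))
    } else rand_dna(28)
    got <- align_duplex(g, m, p)
    want <- brute_duplex(g, m, p)
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("case %d row count", case))
    if (nrow(want)) {
      expect_equal(got$mrna_start, want$mrna_start, info = sprintf("case %d", case))
      expect_equal(got$mrna_end, want$mrna_end, info = sprintf("case %d", case))
      expect_equal(got$grna_start, want$grna_start, info = sprintf("case %d", case))
      expect_equal(got$score, want$score, info = sprintf("case %d", case))
      n_match <- n_match + nrow(want)
    }
  }
  expect_gt(n_match, 20)   # the planted cases must actually produce duplexes
})

test_that("score decomposes over pair classes for every reported duplex", {
  set.seed(11)
  p <- duplex_params("relaxed")
  for (i in 1:20) {
    m <- rand_dna(120)
    s <- sample(90, 1)
    g <- paste0(rand_dna(3), rc(substring(m, s, s + 23)), rand_dna(3))
    a <- align_duplex(g, m, p, prune_overlaps = FALSE)
    for (r in seq_len(nrow(a))) {
      ps <- strsplit(a$pair_string[r], "")[[1L]]
      expect_equal(a$score[r],
                   2L * sum(ps == "|") + sum(ps == ":") - sum(ps == "#"))
      expect_equal(a$length[r], length(ps))
      expect_equal(a$n_gu[r], sum(ps == ":"))
      expect_equal(a$n_mm[r], sum(ps == "#"))
    }
  }
})

test_that("reversing both sequences mirrors the coordinates", {
  set.seed(13)
  p <- duplex_params("relaxed", min_anchor = 0)
  m <- rand_dna(80)
  g <- paste0(rand_dna(3), rc(substring(m, 30, 54)), rand_dna(3))
  a <- align_duplex(g, m, p)
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
  b <- align_duplex(rev_str(g), rev_str(m), p)
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_setequal(nchar(m) - a$mrna_end, b$mrna_start)
    expect_setequal(nchar(g) - a$grna_end, b$grna_start)
    expect_setequal(a$score, b$score)
  }
})

test_that("rendering shows mRNA, pair line and reversed gRNA", {
  m <- "ACGU"
  g <- rc(chartr("U", "T", m))
  a <- align_duplex(g, chartr("U", "T", m),
                    duplex_params("relaxed", min_length = 4, min_score = 4,
                                  seed_length = 4, seed_score = 4,
                                  min_anchor = 0))
  txt <- render_duplex(a[1, ], chartr("U", "T", m), g)
  lines <- strsplit(txt, "\n")[[1L]]
  expect_length(lines, 3L)
  expect_match(lines[1], "ACGU")
  expect_match(lines[2], "\\|\\|\\|\\|")
  # mixed classes follow classify_pair column by column
  m2 <- "TTTTTTTTTTTTTTTTTTTTTTTTTT"
  g2 <- paste(rev(c(rep("A", 10), "G", "C", rep("A", 14))), collapse = "")
  p2 <- duplex_params("relaxed", min_anchor = 0)
  a2 <- align_duplex(g2, m2, p2)
  ps <- strsplit(a2$pair_string[1], "")[[1L]]
  mch <- strsplit(m2, "")[[1L]]
  gch <- strsplit(g2, "")[[1L]]
  for (k in seq_along(ps)) {
    cls <- classify_pair(mch[a2$mrna_start + k],
                         gch[a2$grna_end - k + 1L])
    expect_equal(ps[k], c(WC = "|", GU = ":", MM = "#")[[cls]])
  }
})

test_that("inserted uridines render as lowercase u against the site table", {
  ref <- "ACGTTGA"            # reference: 2 Us before G, site table built on it
  tab <- build_site_table(ref)
  edited <- rebuild_sequence(tab, tab$site_ucount + c(0, 0, 0, 2, 0, 0))
  g <- rc(edited)
  p <- duplex_params("relaxed", min_length = 5, min_score = 5, seed_length = 5,
                     seed_score = 5, min_anchor = 0)
  a <- align_duplex(g, edited, p)
  txt <- render_duplex(a[1, ], edited, g, site_table = tab)
  mline <- strsplit(txt, "\n")[[1L]][2]
  expect_equal(lengths(regmatches(mline, gregexpr("u", mline))), 2L)
})
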