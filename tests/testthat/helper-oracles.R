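# Independent oracles used to cross-check the fast implementations.
# These deliberately use naive, loop-based logic so that they share no
# code with the paths they verify.

rc <- function(x) chartr("ACGT", "TGCA", vapply(x, function(s)
  paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "", USE.NAMES = FALSE))

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## naive IUPAC scan: per-position set membership
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

naive_iupac_scan <- function(seq, pattern, circular = FALSE) {
  sch <- strsplit(toupper(seq), "")[[1L]]
  pch <- strsplit(toupper(pattern), "")[[1L]]
  L <- length(sch); P <- length(pch)
  if (circular) sch <- c(sch, sch[seq_len(P - 1L)])
  nstart <- if (circular) L else L - P + 1L
  hits <- integer(0)
  for (a in seq_len(max(0L, nstart))) {
    ok <- TRUE
    for (j in seq_len(P))
      if (!(sch[a + j - 1L] %in% iupac_sets[[pch[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, a - 1L)
  }
  hits
}

## naive pair classification for the duplex oracle
naive_pair <- function(m, g) {
  p <- paste0(m, g)
  if (p %in% c("AT", "TA", "GC", "CG")) "WC"
  else if (p %in% c("GT", "TG")) "GU"
  else "MM"
}

## Brute-force duplex enumeration: every (diagonal, start, length) window
## is scored from scratch; passing windows are grouped per diagonal by
## overlap and reduced to the best score (ties: longer, then leftmost);
## optionally mRNA-overlap-pruned with the same rule as the engine.
brute_duplex <- function(grna, mrna, p, prune = TRUE) {
  gch <- strsplit(grna, "")[[1L]]; mch <- strsplit(mrna, "")[[1L]]
  G <- length(gch); M <- length(mch)
  sc_of <- c(WC = p$score_wc, GU = p$score_gu, MM = p$score_mm)
  rows <- list()
  for (d in 0:(M + G - 2)) {
    i0 <- max(0L, d - (G - 1L)); i1 <- min(M - 1L, d)
    n <- i1 - i0 + 1L
    if (n < max(p$min_length, p$seed_length)) next
    cls <- vapply(0:(n - 1L), function(t)
      naive_pair(mch[i0 + t + 1L], gch[d - (i0 + t) + 1L]), "")
    pass <- list()
    for (a in 1:n) for (b in a:n) {
      len <- b - a + 1L
      if (len < p$min_length || len < p$seed_length) next
      w <- cls[a:b]
      if (sum(w == "MM") > p$max_mismatch) next
      if (sum(w == "GU") > p$max_gu) next
      if (sum(sc_of[w]) < p$min_score) next
      if (p$min_anchor > 0 && any(w[(len - p$min_anchor + 1L):len] != "WC")) next
      seeds <- vapply(1:(len - p$seed_length + 1L), function(t)
        sum(sc_of[w[t:(t + p$seed_length - 1L)]]), 0)
      if (max(seeds) < p$seed_score) next
      pass[[length(pass) + 1L]] <- c(a, b, sum(sc_of[w]))
    }
    if (!length(pass)) next
    pm <- do.call(rbind, pass)
    pm <- pm[order(pm[, 1L], pm[, 2L]), , drop = FALSE]
    # overlap groups on the diagonal
    grp <- integer(nrow(pm)); g <- 1L; reach <- pm[1L, 2L]; grp[1L] <- 1L
    for (i in seq_len(nrow(pm))[-1L]) {
      if (pm[i, 1L] > reach) { g <- g + 1L; reach <- pm[i, 2L] }
      else reach <- max(reach, pm[i, 2L])
      grp[i] <- g
    }
    for (gg in unique(grp)) {
      sub <- pm[grp == gg, , drop = FALSE]
      len <- sub[, 2L] - sub[, 1L]
      best <- order(-sub[, 3L], -len, sub[, 1L])[1L]
      a <- sub[best, 1L]; b <- sub[best, 2L]
      ia <- i0 + a - 1L; ib <- i0 + b - 1L
      rows[[length(rows) + 1L]] <-
        data.frame(mrna_start = ia, mrna_end = ib + 1L,
                   grna_start = d - ib, grna_end = d - ia + 1L,
                   score = sub[best, 3L])
    }
  }
  if (!length(rows)) return(data.frame(mrna_start = integer(),
                                       mrna_end = integer(),
                                       grna_start = integer(),
                                       grna_end = integer(),
                                       score = integer()))
  out <- do.call(rbind, rows)
  if (prune && nrow(out) > 1L) {
    ord <- order(-out$score, out$mrna_start, out$grna_start)
    keep <- logical(nrow(out)); ts <- integer(0); te <- integer(0)
    for (i in ord) {
      if (!any(out$mrna_start[i] < te & out$mrna_end[i] > ts)) {
        keep[i] <- TRUE
        ts <- c(ts, out$mrna_start[i]); te <- c(te, out$mrna_end[i])
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$mrna_start, out$grna_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## split-point Smith-Waterman oracle for inverted repeats: best local
## alignment of s[1..m] against revcomp(s[m+1..L]) over all split points
brute_best_ir <- function(seq, match = 4, mismatch = -4, gap = -14) {
  sch <- strsplit(seq, "")[[1L]]
  L <- length(sch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  for (m in 1:(L - 1L)) {
    left <- sch[1:m]
    right <- rev(comp[sch[(m + 1L):L]])   # revcomp of the right part
    n1 <- length(left); n2 <- length(right)
    H <- matrix(0, n1 + 1L, n2 + 1L)
    for (i in 1:n1) for (j in 1:n2) {
      sub <- if (left[i] == right[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + sub, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
    }
    best <- max(best, max(H))
  }
  best
}

## exhaustive expansion oracle for the targeting-signal pattern
brute_targeting <- function(protein) {
  ch <- strsplit(protein, "")[[1L]]
  set2 <- c("R", "H", "K", "F", "L"); set4 <- c("R", "K", "H", "S", "T")
  set6 <- c("S", "T", "R", "K")
  best <- NULL
  for (s1 in 0:1) for (s2 in 1:10) {
    p6 <- 3L + s1 + s2 + 1L
    if (p6 > length(ch)) next
    if (length(ch) >= 2L && ch[1L] == "M" && ch[2L] %in% set2 &&
        ch[3L + s1] %in% set4 && ch[p6] %in% set6) {
      if (is.null(best) || p6 < best) best <- p6
    }
  }
  best
}

## synthetic duplex-alignment row for filter tests
mk_aln <- function(pair_string, mrna_start = 0L) {
  n_mm <- sum(strsplit(pair_string, "")[[1L]] == "#")
  n_gu <- sum(strsplit(pair_string, "")[[1L]] == ":")
  df <- data.frame(grna_id = "g", mrna_id = "m", mrna_start = mrna_start,
                   mrna_end = mrna_start + nchar(pair_string),
                   grna_start = 0L, grna_end = nchar(pair_string),
                   length = nchar(pair_string), score = 0L,
                   n_wc = nchar(pair_string) - n_mm - n_gu,
                   n_gu = n_gu, n_mm = n_mm, pair_string = pair_string)
  class(df) <- c("duplex_alignments", "data.frame")
  df
}

## shared small simulation fixture (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_minicircles = 12,
                        n_two_grna_minicircles = 1, n_cryptogenes = 2,
                        cryptogene_len = 240, small_rna_reads_per_grna = 12)
      truth <- simulate_kdna(cfg)
      reads <- simulate_reads(truth, cfg)
      cache <<- list(cfg = cfg, truth = truth, reads = reads)
    }
    cache
  }
})
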