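# Guide-RNA gene discovery: alignment-based annotation against edited
# mRNAs, small-RNA read preprocessing, clustering at 97% identity,
# consensus calling and validation by re-mapping.

#' Annotate gRNA genes by minicircle:mRNA alignment
#'
#' Aligns both strands of every minicircle (and optionally the
#' maxicircle) to every edited mRNA with [align_duplex()]; each passing
#' locus becomes a candidate gRNA gene.  Overlapping loci on the same
#' source strand are merged (interval union, best-scoring support kept).
#' Sources with no alignment to any edited mRNA are flagged, mirroring
#' minicircle classes whose gRNAs are found only by expression.
#'
#' @param circles named character vector of minicircle sequences.
#' @param edited_mrnas named character vector of edited mRNA sequences.
#' @param maxicircle optional named character scalar.
#' @param params a [duplex_params()] set (default canonical discovery).
#' @return a `guide_genes` data frame: `gene_id`, `source_id`, `start`,
#'   `end` (0-based half-open on the source forward strand), `strand`,
#'   `mrna_id`, `mrna_start`, `mrna_end`, `score`, `expression_support`
#'   (NA here), `boundaries_refined` (FALSE here).  Attribute
#'   `unaligned_sources` lists sources with no gene.
#' @export
annotate_grna_genes <- function(circles, edited_mrnas, maxicircle = NULL,
                                params = duplex_params("canonical")) {
  if (!is.null(maxicircle) && is.null(names(maxicircle)))
    names(maxicircle) <- "maxicircle"
  sources <- c(as.list(circles), as.list(maxicircle))
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("sources must be named")
  rows <- list()
  for (src in names(sources)) {
    sseq <- unname(sources[[src]])
    L <- nchar(sseq)
    for (strand in c("+", "-")) {
      transcript <- if (strand == "+") sseq else revcomp(sseq)
      for (mid in names(edited_mrnas)) {
        # no mRNA-overlap pruning here: distinct gene loci on one source
        # may legitimately target overlapping mRNA regions (adjacent
        # cascade positions); deduplication happens on source coordinates
        alns <- align_duplex(transcript, edited_mrnas[[mid]], params,
                             grna_id = src, mrna_id = mid,
                             prune_overlaps = FALSE)
        if (!nrow(alns)) next
        gs <- if (strand == "+") alns$grna_start else L - alns$grna_end
        ge <- if (strand == "+") alns$grna_end else L - alns$grna_start
        rows[[length(rows) + 1L]] <-
          data.frame(source_id = src, start = gs, end = ge, strand = strand,
                     mrna_id = mid, mrna_start = alns$mrna_start,
                     mrna_end = alns$mrna_end, score = alns$score)
      }
    }
  }
  if (!length(rows)) {
    genes <- data.frame(gene_id = character(), source_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), mrna_id = character(),
                        mrna_start = integer(), mrna_end = integer(),
                        score = integer(), expression_support = integer(),
                        boundaries_refined = logical())
    attr(genes, "unaligned_sources") <- names(sources)
    class(genes) <- c("guide_genes", "data.frame")
    return(genes)
  }
  cand <- do.call(rbind, rows)
  # merge overlapping candidate loci per source/strand
  merged <- list()
  for (key in unique(paste(cand$source_id, cand$strand))) {
    sub <- cand[paste(cand$source_id, cand$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, -sub$score), , drop = FALSE]
    cur <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] < cur$end) {           # overlap: extend, keep best support
        cur$end <- max(cur$end, sub$end[i])
        if (sub$score[i] > cur$score) {
          cur$score <- sub$score[i]; cur$mrna_id <- sub$mrna_id[i]
          cur$mrna_start <- sub$mrna_start[i]; cur$mrna_end <- sub$mrna_end[i]
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  genes <- do.call(rbind, merged)
  genes <- genes[order(genes$source_id, genes$start), , drop = FALSE]
  genes <- data.frame(gene_id = sprintf("%s:g%d", genes$source_id,
                                        stats::ave(seq_len(nrow(genes)),
                                                   genes$source_id,
                                                   FUN = seq_along)),
                      genes, expression_support = NA_integer_,
                      boundaries_refined = FALSE, row.names = NULL)
  attr(genes, "unaligned_sources") <-
    setdiff(names(sources), unique(genes$source_id))
  class(genes) <- c("guide_genes", "data.frame")
  genes
}

#' Extract gRNA (transcript) sequences for annotated gene loci
#'
#' @param genes a `guide_genes` data frame.
#' @param sources named character vector of source sequences.
#' @return named character vector of gRNA sequences (5'->3', DNA
#'   alphabet), named by `gene_id`.
#' @export
guide_gene_seqs <- function(genes, sources) {
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- substring(unname(sources[[genes$source_id[i]]]),
                   genes$start[i] + 1L, genes$end[i])
    out[i] <- if (genes$strand[i] == "+") s else revcomp(s)
  }
  stats::setNames(out, genes$gene_id)
}

# strict FASTQ reader used by the preprocessing entry point so that
# malformed records are reported by record number.
read_fastq_checked <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): truncated record ",
         length(ln) %/% 4L + 1L)
  n <- length(ln) %/% 4L
  if (!n) return(structure(character(0), qualities = character(0)))
  h <- ln[seq(1L, by = 4L, length.out = n)]
  s <- ln[seq(2L, by = 4L, length.out = n)]
  p <- ln[seq(3L, by = 4L, length.out = n)]
  q <- ln[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(h, "@") | !startsWith(p, "+") |
                 nchar(s) != nchar(q))
  if (length(bad))
    stop("malformed FASTQ (", path, "): record ", bad[1L])
  out <- stats::setNames(toupper(s), sub("^@", "", sub("\\s.*$", "", h)))
  attr(out, "qualities") <- q
  out
}

trim_adapter_one <- function(seq, adapter, min_partial = 8L) {
  hit <- regexpr(adapter, seq, fixed = TRUE)
  if (hit != -1L) return(substring(seq, 1L, hit - 1L))
  ls <- nchar(seq)
  kmax <- min(nchar(adapter) - 1L, ls)
  for (k in kmax:min_partial) {
    if (k < min_partial) break
    if (substring(seq, ls - k + 1L, ls) == substring(adapter, 1L, k))
      return(substring(seq, 1L, ls - k))
  }
  seq
}

#' Preprocess paired small-RNA reads
#'
#' Adapter trimming (exact internal match, or terminal partial match of
#' at least `min_partial` nt), removal of reads shorter than `min_len`
#' (default 15), and merging of completely overlapping read pairs:
#' captured gRNA molecules are shorter than the read length, so the
#' reverse complement of read 2 fully overlaps read 1 and the pair
#' collapses to a single insert sequence, with overlap disagreements
#' resolved towards the higher base quality.
#'
#' @param r1,r2 named character vectors with a `qualities` attribute
#'   (as from [read_fastq()]), or FASTQ file paths.
#' @param adapter adapter sequence trimmed from the 3' ends.
#' @param min_len minimum post-trim read length (default 15).
#' @param min_partial minimum terminal adapter overlap (default 8).
#' @param max_mismatch_rate maximum disagreement rate tolerated in the
#'   read1/read2 overlap (default 0.1).
#' @return named character vector of merged insert sequences; attribute
#'   `n_unmerged` counts pairs dropped as not completely overlapping,
#'   `n_short` counts reads dropped at `min_len`.
#' @export
preprocess_small_reads <- function(r1, r2, adapter, min_len = 15L,
                                   min_partial = 8L,
                                   max_mismatch_rate = 0.1) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1))
    r1 <- read_fastq_checked(r1)
  if (is.character(r2) && length(r2) == 1L && file.exists(r2))
    r2 <- read_fastq_checked(r2)
  stopifnot(length(r1) == length(r2))
  q1 <- attr(r1, "qualities"); q2 <- attr(r2, "qualities")
  if (is.null(q1)) q1 <- vapply(r1, function(s) strrep("I", nchar(s)), "")
  if (is.null(q2)) q2 <- vapply(r2, function(s) strrep("I", nchar(s)), "")
  merged <- character(0)
  n_unmerged <- 0L; n_short <- 0L
  for (i in seq_along(r1)) {
    a <- trim_adapter_one(r1[[i]], adapter, min_partial)
    b <- trim_adapter_one(r2[[i]], adapter, min_partial)
    if (nchar(a) < min_len || nchar(b) < min_len) { n_short <- n_short + 1L; next }
    qa <- substring(q1[[i]], 1L, nchar(a))
    qb <- substring(q2[[i]], 1L, nchar(b))
    brc <- revcomp(b)
    qbr <- paste(rev(strsplit(qb, "")[[1L]]), collapse = "")
    m <- merge_complete_overlap(a, qa, brc, qbr, max_mismatch_rate)
    if (is.null(m)) { n_unmerged <- n_unmerged + 1L; next }
    merged[[length(merged) + 1L]] <- m
    names(merged)[length(merged)] <-
      if (!is.null(names(r1))) names(r1)[i] else paste0("pair", i)
  }
  attr(merged, "n_unmerged") <- n_unmerged
  attr(merged, "n_short") <- n_short
  merged
}

# complete-overlap merge: the shorter of a/brc must align fully inside
# the longer; best offset by match count; quality-resolved consensus.
merge_complete_overlap <- function(a, qa, b, qb, max_mismatch_rate = 0.1) {
  la <- nchar(a); lb <- nchar(b)
  if (la >= lb) { lo <- a; ql <- qa; sh <- b; qs <- qb }
  else          { lo <- b; ql <- qb; sh <- a; qs <- qa }
  nl <- nchar(lo); ns <- nchar(sh)
  lo_ch <- strsplit(lo, "")[[1L]]; sh_ch <- strsplit(sh, "")[[1L]]
  best <- NULL
  for (d in 0:(nl - ns)) {
    mism <- which(lo_ch[d + seq_len(ns)] != sh_ch)
    if (is.null(best) || length(mism) < best$n)
      best <- list(d = d, n = length(mism), mism = mism)
  }
  if (is.null(best) || best$n > max_mismatch_rate * ns) return(NULL)
  if (best$n) {
    ql_ch <- strsplit(ql, "")[[1L]]; qs_ch <- strsplit(qs, "")[[1L]]
    for (k in best$mism)
      if (qs_ch[k] > ql_ch[best$d + k])
        lo_ch[best$d + k] <- sh_ch[k]
  }
  paste(lo_ch, collapse = "")
}

#' Strip a post-transcriptional 3' tail
#'
#' Removes one trailing homopolymer run of T or of A (length at least
#' `min_tail`) from each sequence; gRNA small-RNA reads carry
#' post-transcriptionally added 3' poly(U) (sequenced as T) or poly(A)
#' extensions.  At most one run is removed; composite tails (e.g. a
#' U-tail followed by adenylation) lose only the terminal run.
#'
#' @param seq character vector of sequences.
#' @param min_tail minimum run length to strip (default 3).
#' @return character vector with tails removed.
#' @export
strip_tails <- function(seq, min_tail = 3L) {
  pat_t <- sprintf("T{%d,}$", min_tail)
  pat_a <- sprintf("A{%d,}$", min_tail)
  out <- sub(pat_t, "", seq)
  keep <- out == seq          # no T tail: try A
  out[keep] <- sub(pat_a, "", seq[keep])
  out
}

# best-offset ungapped identity of two near-identical reads:
# matches / overlap length; overlap must cover >= 80% of the shorter.
read_identity <- function(a, b, max_shift = NULL) {
  la <- nchar(a); lb <- nchar(b)
  if (is.null(max_shift)) max_shift <- abs(la - lb) + 3L
  ach <- strsplit(a, "")[[1L]]; bch <- strsplit(b, "")[[1L]]
  best <- 0
  for (d in -max_shift:max_shift) {
    sa <- max(1L, 1L + d); sb <- max(1L, 1L - d)
    ov <- min(la - sa + 1L, lb - sb + 1L)
    if (ov < max(1L, ceiling(0.8 * min(la, lb)))) next
    m <- sum(ach[sa:(sa + ov - 1L)] == bch[sb:(sb + ov - 1L)])
    best <- max(best, m / ov)
  }
  best
}

#' Cluster small-RNA reads and call expressed gRNAs
#'
#' Greedy length-sorted clustering of preprocessed, tail-stripped reads
#' at `identity` (default 0.97, matches/overlap of the best-offset
#' ungapped alignment); per-column majority consensus per cluster;
#' validation of each consensus by seed-and-extend mapping (exact
#' `seed_len`-mer, at most `max_mm` total mismatches) to the minicircles
#' or maxicircle.  Validated clusters define gRNA gene boundaries as the
#' consensus of member termini (mode, ties towards the wider extent).
#' When alignment-derived genes are supplied, expression-derived
#' boundaries replace overlapping alignment-derived ones (expression
#' wins); unvalidated consensuses are reported as orphans.
#'
#' @param reads named character vector of merged, tail-stripped reads.
#' @param circles named character vector of minicircle sequences.
#' @param maxicircle optional named character scalar.
#' @param genes optional alignment-derived `guide_genes` to refine.
#' @param identity clustering identity threshold (default 0.97).
#' @param seed_len exact seed length for validation mapping (default 18).
#' @param max_mm maximum total mismatches in validation (default 1).
#' @return list with `genes` (refined `guide_genes`), `clusters` (data
#'   frame: `cluster_id`, `size`, `consensus`, `source`, `start`, `end`,
#'   `strand`, `validated`) and `orphans` (unmappable consensuses).
#' @export
call_expressed_grnas <- function(reads, circles, maxicircle = NULL,
                                 genes = NULL, identity = 0.97,
                                 seed_len = 18L, max_mm = 1L) {
  if (!is.null(maxicircle) && is.null(names(maxicircle)))
    names(maxicircle) <- "maxicircle"
  sources <- c(as.list(circles), as.list(maxicircle))
  ord <- order(-nchar(reads), unname(reads))
  members <- list()
  reps <- character(0)
  offsets <- list()    # member offset of read start relative to rep start
  for (i in ord) {
    s <- reads[[i]]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (read_identity(s, reps[k]) >= identity) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      members[[length(reps)]] <- i
    }
  }
  clusters <- lapply(seq_along(reps), function(k) {
    mem <- reads[members[[k]]]
    list(members = names(reads)[members[[k]]],
         consensus = cluster_consensus(mem, reps[k]),
         size = length(mem), member_seqs = mem)
  })
  # validate consensuses against the sources
  rows <- list(); orphans <- character(0)
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    hit <- map_consensus(cl$consensus, sources, seed_len, max_mm)
    if (is.null(hit)) {
      orphans <- c(orphans, stats::setNames(cl$consensus, paste0("cluster", k)))
      rows[[k]] <- data.frame(cluster_id = k, size = cl$size,
                              consensus = cl$consensus, source = NA_character_,
                              start = NA_integer_, end = NA_integer_,
                              strand = NA_character_, validated = FALSE)
      next
    }
    # member-termini consensus: map each member's offset within the rep
    starts <- integer(0); ends <- integer(0)
    for (m in cl$member_seqs) {
      d <- member_offset(m, cl$consensus)
      if (is.na(d)) next
      if (hit$strand == "+") {
        starts <- c(starts, hit$start + d)
        ends <- c(ends, hit$start + d + nchar(m))
      } else {
        ends <- c(ends, hit$end - d)
        starts <- c(starts, hit$end - d - nchar(m))
      }
    }
    pick_mode <- function(x, wider_low) {
      t <- table(x)
      best <- as.integer(names(t)[t == max(t)])
      if (wider_low) min(best) else max(best)
    }
    st <- if (length(starts)) pick_mode(starts, TRUE) else hit$start
    en <- if (length(ends)) pick_mode(ends, FALSE) else hit$end
    rows[[k]] <- data.frame(cluster_id = k, size = cl$size,
                            consensus = cl$consensus, source = hit$source,
                            start = st, end = en, strand = hit$strand,
                            validated = TRUE)
  }
  ctab <- do.call(rbind, rows)
  val <- ctab[ctab$validated, , drop = FALSE]
  egenes <- data.frame(gene_id = sprintf("%s:e%d", val$source, val$cluster_id),
                       source_id = val$source, start = val$start,
                       end = val$end, strand = val$strand,
                       mrna_id = rep(NA_character_, nrow(val)),
                       mrna_start = rep(NA_integer_, nrow(val)),
                       mrna_end = rep(NA_integer_, nrow(val)),
                       score = rep(NA_integer_, nrow(val)),
                       expression_support = val$size,
                       boundaries_refined = rep(TRUE, nrow(val)),
                       row.names = NULL)
  if (!is.null(genes) && nrow(genes)) {
    keep <- rep(TRUE, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      ov <- egenes$source_id == genes$source_id[i] &
        egenes$strand == genes$strand[i] &
        egenes$start < genes$end[i] & egenes$end > genes$start[i]
      if (any(ov)) {   # expression-derived boundaries win
        keep[i] <- FALSE
        j <- which(ov)[1L]
        egenes$mrna_id[j] <- genes$mrna_id[i]
        egenes$mrna_start[j] <- genes$mrna_start[i]
        egenes$mrna_end[j] <- genes$mrna_end[i]
        egenes$score[j] <- genes$score[i]
      }
    }
    egenes <- rbind(egenes, genes[keep, , drop = FALSE])
  }
  egenes <- egenes[order(egenes$source_id, egenes$start), , drop = FALSE]
  class(egenes) <- c("guide_genes", "data.frame")
  list(genes = egenes, clusters = ctab, orphans = orphans)
}

# per-column majority consensus of a cluster against its representative;
# ties resolve towards the representative's own base
cluster_consensus <- function(members, rep_seq) {
  n <- nchar(rep_seq)
  counts <- matrix(0, nrow = 4L, ncol = n, dimnames = list(.BASES, NULL))
  rch <- strsplit(rep_seq, "")[[1L]]
  for (k in seq_len(n))
    if (rch[k] %in% .BASES)
      counts[rch[k], k] <- counts[rch[k], k] + 0.5
  for (m in members) {
    d <- member_offset(m, rep_seq)
    if (is.na(d)) next
    ch <- strsplit(m, "")[[1L]]
    for (k in seq_along(ch)) {
      col <- d + k
      if (col >= 1L && col <= n && ch[k] %in% .BASES)
        counts[ch[k], col] <- counts[ch[k], col] + 1L
    }
  }
  cons <- apply(counts, 2L, function(cc)
    if (sum(cc)) .BASES[which.max(cc)] else "N")
  paste(cons, collapse = "")
}

# offset of a member within/around the representative (0-based; may be
# negative if the member starts before the representative)
member_offset <- function(m, rep_seq) {
  lm <- nchar(m); lr <- nchar(rep_seq)
  max_shift <- abs(lm - lr) + 3L
  mch <- strsplit(m, "")[[1L]]; rch <- strsplit(rep_seq, "")[[1L]]
  best_d <- NA_integer_; best_m <- -1L
  for (d in -max_shift:max_shift) {
    sm <- max(1L, 1L - d); sr <- max(1L, 1L + d)
    ov <- min(lm - sm + 1L, lr - sr + 1L)
    if (ov < 10L) next
    mm <- sum(mch[sm:(sm + ov - 1L)] == rch[sr:(sr + ov - 1L)])
    if (mm > best_m) { best_m <- mm; best_d <- d }
  }
  best_d
}

# exact-seed + bounded-mismatch mapping of a consensus to the sources;
# returns source, 0-based half-open coords on the forward strand, strand.
map_consensus <- function(cons, sources, seed_len = 18L, max_mm = 1L) {
  lc <- nchar(cons)
  if (lc < seed_len) return(NULL)
  seeds <- unique(c(1L, lc - seed_len + 1L))
  for (src in names(sources)) {
    sseq <- unname(sources[[src]])
    for (strand in c("+", "-")) {
      tseq <- if (strand == "+") sseq else revcomp(sseq)
      for (so in seeds) {
        seed <- substring(cons, so, so + seed_len - 1L)
        hits <- gregexpr(seed, tseq, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in hits) {
          st <- h - so + 1L            # 1-based consensus start on tseq
          if (st < 1L || st + lc - 1L > nchar(tseq)) next
          win <- substring(tseq, st, st + lc - 1L)
          mm <- sum(strsplit(win, "")[[1L]] != strsplit(cons, "")[[1L]])
          if (mm <= max_mm) {
            if (strand == "+")
              return(list(source = src, start = st - 1L,
                          end = st - 1L + lc, strand = strand))
            L <- nchar(sseq)
            return(list(source = src, start = L - (st - 1L + lc),
                        end = L - (st - 1L), strand = strand))
          }
        }
      }
    }
  }
  NULL
}
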