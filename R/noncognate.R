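# Non-cognate guiding attribution: how much of the editing observed in
# hyper-edited reads is explainable by the known gRNA repertoire, plus
# cognate/non-cognate alignment-feature comparisons.

#' Extract hyper-edited reads
#'
#' Reads carrying at least `min_indels` U insertions plus deletions in
#' total (default 10, consistent with editing guided by more than one
#' gRNA) are the substrate of non-cognate attribution.
#'
#' @param patterns list of `read_editing_pattern`s.
#' @param min_indels minimum total U indels (default 10).
#' @return the qualifying subset (list).
#' @export
extract_hyperedited_reads <- function(patterns, min_indels = 10L) {
  Filter(function(p) p$n_insertions + p$n_deletions >= min_indels, patterns)
}

#' Attribute observed editing to non-cognate gRNA guiding
#'
#' For each hyper-edited read, the observed edited sequence (rebuilt
#' from its editing pattern) is aligned against every supplied gRNA
#' under relaxed duplex parameters.  An edited site is "explained" when
#' some passing alignment spans the site's U run together with its
#' flanking backbone bases, and every position of the run pairs the gRNA
#' as `U:A` (Watson-Crick) or `U:G` (wobble) -- i.e. the gRNA's guiding
#' nucleotides prescribe exactly the observed U count.  A site covered
#' by several alignments is explained if at least one matches.  Results
#' are aggregated per cryptogene.
#'
#' @param patterns list of hyper-edited `read_editing_pattern`s.
#' @param grnas named character vector of gRNA sequences.
#' @param tables list of `editing_site_table`s (for rebuilding observed
#'   sequences).
#' @param params a [duplex_params()] set (default relaxed).
#' @return a data frame of class `attribution_result`, one row per
#'   cryptogene: `cryptogene_id`, `n_reads`, `n_events_total`,
#'   `n_events_explained`, `pct_explained`; attribute `features` holds a
#'   per-alignment data frame (`cryptogene_id`, `grna_id`, `length`,
#'   `n_gu`, `n_mm`, `score`).
#' @export
attribute_editing <- function(patterns, grnas, tables,
                              params = duplex_params("relaxed")) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "cryptogene_id")
  tot <- expl <- nread <- integer(0)
  feats <- list()
  for (p in patterns) {
    tab <- tables[[p$cryptogene_id]]
    if (is.null(tab)) next
    id <- p$cryptogene_id
    if (!id %in% names(tot)) {
      tot[id] <- 0L; expl[id] <- 0L; nread[id] <- 0L
    }
    nread[id] <- nread[id] + 1L
    # rebuild the observed read segment and locate each edited site in it
    seg <- read_segment(p, tab)
    ed_local <- which(p$obs_ucount != p$ref_ucount & !p$partial)
    if (!length(ed_local)) next
    tot[id] <- tot[id] + length(ed_local)
    spans <- seg$spans
    explained <- rep(FALSE, length(ed_local))
    for (gid in names(grnas)) {
      alns <- align_duplex(grnas[[gid]], seg$seq, params, grna_id = gid,
                           mrna_id = p$read_id, prune_overlaps = FALSE)
      if (!nrow(alns)) next
      feats[[length(feats) + 1L]] <-
        data.frame(cryptogene_id = id, grna_id = gid, read_id = p$read_id,
                   length = alns$length, n_gu = alns$n_gu, n_mm = alns$n_mm,
                   score = alns$score)
      for (e in seq_along(ed_local)) {
        if (explained[e]) next
        sp <- spans[[ed_local[e]]]
        # alignment must cover both flanking backbone bases with paired
        # (non-mismatch) columns, and every U of the run must pair U:A or
        # U:G -- then the gRNA prescribes exactly the observed count
        hit <- which(alns$mrna_start < sp$left & alns$mrna_end >= sp$right)
        for (a in hit) {
          ps <- strsplit(alns$pair_string[a], "")[[1L]]
          cols <- (sp$left:sp$right) - alns$mrna_start[a]
          if (all(ps[cols] %in% c("|", ":"))) {
            explained[e] <- TRUE
            break
          }
        }
      }
    }
    expl[id] <- expl[id] + sum(explained)
  }
  out <- data.frame(cryptogene_id = names(tot), n_reads = as.integer(nread),
                    n_events_total = as.integer(tot),
                    n_events_explained = as.integer(expl),
                    pct_explained = ifelse(tot > 0, 100 * expl / tot, NA_real_),
                    row.names = NULL)
  attr(out, "features") <- if (length(feats)) do.call(rbind, feats) else
    data.frame(cryptogene_id = character(), grna_id = character(),
               read_id = character(), length = integer(), n_gu = integer(),
               n_mm = integer(), score = integer())
  class(out) <- c("attribution_result", "data.frame")
  out
}

# Rebuild the covered segment of a read from its editing pattern and the
# cryptogene table (5'->3'; terminal partial runs included as observed),
# together with the read-local span of every covered site: `spans[[k]]`
# gives 1-based positions `left` (flanking backbone base 5' of the run;
# 0 for the first site), `run_start`/`run_end` (the U run; empty when the
# observed count is 0) and `right` (flanking backbone base 3' of the
# run).  Only interior sites have both flanks.
read_segment <- function(p, tab) {
  n <- length(p$sites)
  bb_global <- strsplit(tab$backbone, "")[[1L]]
  bb <- bb_global[p$sites[-n]]       # backbone bases covered by the read
  parts <- character(2L * n - 1L)
  spans <- vector("list", n)
  cursor <- 1L
  for (k in seq_len(n)) {
    u <- p$obs_ucount[k]
    spans[[k]] <- list(left = cursor - 1L, run_start = cursor,
                       run_end = cursor + u - 1L, right = cursor + u)
    parts[2L * k - 1L] <- strrep("T", u)
    cursor <- cursor + u
    if (k < n) {
      parts[2L * k] <- bb[k]
      cursor <- cursor + 1L
    }
  }
  list(seq = paste(parts, collapse = ""), spans = spans)
}

#' Compare alignment-feature distributions between two groups
#'
#' Two-sided rank-sum (Wilcoxon) comparison of per-alignment features
#' (length, number of G:U pairs, number of mismatches) between two
#' groups of alignments, e.g. gRNA alignments to productively edited
#' transcripts (cognate) versus alignments to non-productively edited
#' reads (non-cognate).
#'
#' @param group_a,group_b data frames with columns `length`, `n_gu`,
#'   `n_mm` (as in the `features` attribute of [attribute_editing()]).
#' @param features which columns to compare.
#' @return data frame: `feature`, `median_a`, `median_b`, `direction`
#'   (`"a>b"`, `"a<b"`, `"a=b"` by median), `statistic` (rank-sum W),
#'   `p_value` (two-sided).
#' @export
compare_alignment_features <- function(group_a, group_b,
                                       features = c("length", "n_gu", "n_mm")) {
  if (!nrow(group_a) || !nrow(group_b)) stop("both groups must be non-empty")
  rows <- lapply(features, function(f) {
    a <- group_a[[f]]; b <- group_b[[f]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    ma <- stats::median(a); mb <- stats::median(b)
    data.frame(feature = f, median_a = ma, median_b = mb,
               direction = if (ma > mb) "a>b" else if (ma < mb) "a<b" else "a=b",
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  do.call(rbind, rows)
}
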