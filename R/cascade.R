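# Editing-cascade reconstruction: filtering of gRNA:mRNA alignments and
# greedy 3'->5' chaining into the ordered cascade that produces the fully
# edited mRNA, with redundancy and gap accounting.

#' Filter gRNA:mRNA alignments for cascade reconstruction
#'
#' Applies the three filters used before cascade assembly:
#' (i) alignments using source loci outside the refined gRNA gene
#' boundaries are discarded; (ii) alignments with three or more adjacent
#' mismatches are discarded (G:U pairs are not mismatches and break a
#' mismatch run); (iii) alignments with mismatch/length ratio strictly
#' greater than 1/8 are discarded (a ratio of exactly 1/8 is retained).
#' The filters are independent, so their application order is
#' irrelevant.
#'
#' @param alns a `duplex_alignments` data frame; for filter (i) it must
#'   carry `source_id`, `source_start`, `source_end` columns (as
#'   produced by [cascade_alignments()]), otherwise filter (i) is
#'   skipped.
#' @param gene_boundaries optional `guide_genes` data frame with refined
#'   boundaries; when `NULL`, filter (i) is skipped.
#' @return the filtered `duplex_alignments`.
#' @export
filter_alignments <- function(alns, gene_boundaries = NULL) {
  keep <- rep(TRUE, nrow(alns))
  if (!is.null(gene_boundaries) && !is.null(alns$source_id)) {
    for (i in seq_len(nrow(alns))) {
      inside <- gene_boundaries$source_id == alns$source_id[i] &
        gene_boundaries$strand == alns$source_strand[i] &
        gene_boundaries$start <= alns$source_start[i] &
        gene_boundaries$end >= alns$source_end[i]
      if (!any(inside)) keep[i] <- FALSE
    }
  }
  keep <- keep & !grepl("###", alns$pair_string, fixed = TRUE)
  keep <- keep & (8L * alns$n_mm <= alns$length)
  out <- alns[keep, , drop = FALSE]
  class(out) <- class(alns)
  out
}

#' Align a gRNA set to an mRNA with source-locus bookkeeping
#'
#' Runs [align_duplex()] for every gRNA against one edited mRNA and
#' annotates each alignment with the source locus it uses (so that
#' filter (i) of [filter_alignments()] can be applied).
#'
#' @param grnas named character vector of gRNA sequences (5'->3').
#' @param mrna edited mRNA sequence (named character scalar).
#' @param genes optional `guide_genes` giving each gRNA's source locus
#'   (`gene_id` matching `names(grnas)`).
#' @param params a [duplex_params()] set.
#' @return a `duplex_alignments` data frame, with `source_id`,
#'   `source_strand`, `source_start`, `source_end` columns when `genes`
#'   is given (alignment gRNA coordinates are mapped into source
#'   coordinates through the gene locus).
#' @export
cascade_alignments <- function(grnas, mrna, genes = NULL,
                               params = duplex_params("canonical")) {
  out <- list()
  for (gid in names(grnas)) {
    a <- align_duplex(grnas[[gid]], mrna, params, grna_id = gid,
                      mrna_id = if (!is.null(names(mrna))) names(mrna)[1] else "mRNA")
    if (!nrow(a)) next
    if (!is.null(genes)) {
      gi <- match(gid, genes$gene_id)
      if (!is.na(gi)) {
        glen <- genes$end[gi] - genes$start[gi]
        if (genes$strand[gi] == "+") {
          a$source_start <- genes$start[gi] + a$grna_start
          a$source_end <- genes$start[gi] + a$grna_end
        } else {
          a$source_start <- genes$end[gi] - a$grna_end
          a$source_end <- genes$end[gi] - a$grna_start
        }
        a$source_id <- genes$source_id[gi]
        a$source_strand <- genes$strand[gi]
      }
    }
    out[[length(out) + 1L]] <- a
  }
  if (!length(out)) {
    res <- data.frame()
    class(res) <- c("duplex_alignments", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  class(res) <- c("duplex_alignments", "data.frame")
  res
}

#' Build the ordered gRNA cascade for an edited mRNA
#'
#' Greedy 3'->5' chaining of filtered gRNA:mRNA alignments: the cascade
#' starts at the alignment reaching furthest 3' on the mRNA; each
#' successor must start 5' of the current frontier and is chosen to reach
#' furthest 3' among candidates (ties broken towards the higher-scoring
#' alignment), recording its anchor overlap with the predecessor.
#' Uncovered intervals are recorded as gaps; zero-length gaps mark
#' adjacent-but-not-overlapping neighbours.  The per-position redundancy
#' profile counts covering alignments among all filtered alignments.
#'
#' @param alns filtered `duplex_alignments` for one mRNA (best alignment
#'   per gRNA is used).
#' @param domain 0-based half-open bounds of the edited domain used for
#'   gap and redundancy accounting (default: the span of the
#'   alignments).
#' @return an object of class `cascade_map`: `mrna_id`, `cascade` (data
#'   frame: `order`, `grna_id`, `mrna_start`, `mrna_end`, `score`,
#'   `overlap_with_prev`), `gaps` (data frame `start`, `end`,
#'   `adjacent`), `redundancy` (integer vector over the domain),
#'   `domain`, `unchained` (gRNAs with alignments that never entered the
#'   chain).
#' @export
build_cascade <- function(alns, domain = NULL) {
  stopifnot(nrow(alns) >= 1L)
  # best alignment per gRNA (score, then leftmost)
  alns <- alns[order(alns$grna_id, -alns$score, alns$mrna_start), , drop = FALSE]
  best <- alns[!duplicated(alns$grna_id), , drop = FALSE]
  if (is.null(domain)) domain <- c(min(best$mrna_start), max(best$mrna_end))
  # greedy chain from the 3'-most end
  avail <- rep(TRUE, nrow(best))
  chain <- integer(0)
  i0 <- which(best$mrna_end == max(best$mrna_end))
  i0 <- i0[order(-best$score[i0], best$mrna_start[i0])][1L]
  chain <- i0; avail[i0] <- FALSE
  frontier <- best$mrna_start[i0]
  repeat {
    cand <- which(avail & best$mrna_start < frontier)
    if (!length(cand)) break
    nxt <- cand[order(-best$mrna_end[cand], -best$score[cand])][1L]
    chain <- c(chain, nxt); avail[nxt] <- FALSE
    frontier <- min(frontier, best$mrna_start[nxt])
  }
  casc <- best[chain, , drop = FALSE]
  ov <- c(NA_integer_,
          if (nrow(casc) > 1L)
            vapply(2:nrow(casc), function(k)
              casc$mrna_end[k] - casc$mrna_start[k - 1L], 0L))
  cascade <- data.frame(order = seq_len(nrow(casc)), grna_id = casc$grna_id,
                        mrna_start = casc$mrna_start, mrna_end = casc$mrna_end,
                        score = casc$score, overlap_with_prev = ov,
                        row.names = NULL)
  # coverage over the domain from all filtered alignments
  red <- integer(domain[2L] - domain[1L])
  for (i in seq_len(nrow(alns))) {
    s <- max(alns$mrna_start[i], domain[1L]); e <- min(alns$mrna_end[i], domain[2L])
    if (e > s) red[(s - domain[1L] + 1L):(e - domain[1L])] <-
        red[(s - domain[1L] + 1L):(e - domain[1L])] + 1L
  }
  gaps <- runs_of_zero(red, domain[1L])
  # adjacency: zero-length junctions in the chain (end meets start exactly)
  if (nrow(cascade) > 1L) {
    adj <- which(cascade$overlap_with_prev[-1L] == 0L) + 1L
    if (length(adj)) {
      gaps <- rbind(gaps,
                    data.frame(start = cascade$mrna_end[adj],
                               end = cascade$mrna_end[adj], adjacent = TRUE))
      gaps <- gaps[order(gaps$start), , drop = FALSE]
    }
  }
  structure(list(mrna_id = best$mrna_id[1L], cascade = cascade, gaps = gaps,
                 redundancy = red, domain = domain,
                 unchained = setdiff(best$grna_id, cascade$grna_id)),
            class = "cascade_map")
}

runs_of_zero <- function(v, offset) {
  if (!length(v))
    return(data.frame(start = integer(), end = integer(), adjacent = logical()))
  r <- rle(v == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  z <- which(r$values)
  data.frame(start = offset + starts[z] - 1L, end = offset + ends[z],
             adjacent = rep(FALSE, length(z)))
}

#' @export
print.cascade_map <- function(x, ...) {
  cat("Editing cascade for ", x$mrna_id, ": ", nrow(x$cascade),
      " gRNAs, 3'->5'\n", sep = "")
  cat(sprintf("  domain [%d, %d); mean redundancy %.2f; %d gap(s)\n",
              x$domain[1L], x$domain[2L], mean(x$redundancy), nrow(x$gaps)))
  invisible(x)
}

#' Cascade coverage statistics
#'
#' Summarises a [build_cascade()] map: mean and maximum per-position
#' redundancy over the edited domain, number and total length of gaps,
#' and the count of supplied gRNAs that aligned nowhere (unassigned).
#'
#' @param map a `cascade_map`.
#' @param all_grna_ids optional character vector of all known gRNA ids;
#'   ids absent from the map's alignments count as unassigned.
#' @return list with `mean_redundancy`, `max_redundancy`, `n_gaps`,
#'   `gap_length`, `n_adjacent`, `n_unassigned`.
#' @export
cascade_coverage_stats <- function(map, all_grna_ids = NULL) {
  seen <- unique(c(map$cascade$grna_id, map$unchained))
  n_un <- if (is.null(all_grna_ids)) 0L else length(setdiff(all_grna_ids, seen))
  real_gaps <- map$gaps[!map$gaps$adjacent, , drop = FALSE]
  list(mean_redundancy = mean(map$redundancy),
       max_redundancy = if (length(map$redundancy)) max(map$redundancy) else 0L,
       n_gaps = nrow(real_gaps),
       gap_length = sum(real_gaps$end - real_gaps$start),
       n_adjacent = sum(map$gaps$adjacent),
       n_unassigned = n_un)
}

#' @export
plot.cascade_map <- function(x, ...) {
  n <- nrow(x$cascade)
  graphics::plot(NA, xlim = x$domain, ylim = c(0, n + 1),
                 xlab = "mRNA position (nt)", ylab = "cascade order (3'->5')",
                 main = paste("gRNA cascade:", x$mrna_id), ...)
  graphics::segments(x$cascade$mrna_start, n + 1 - x$cascade$order,
                     x$cascade$mrna_end, n + 1 - x$cascade$order, lwd = 3)
  if (nrow(x$gaps))
    graphics::abline(v = x$gaps$start, col = "red", lty = 2)
  invisible(x)
}
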