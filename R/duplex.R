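#' Duplex alignment parameter sets
#'
#' Parameters controlling the antiparallel gRNA:mRNA duplex search.  Two
#' presets are provided.  The `"relaxed"` preset is the permissive search
#' used when asking whether any gRNA could have guided an observed editing
#' pattern (seed score 20 over a 16-nt nucleation window, minimum duplex
#' length 21, minimum total score 25, at most 17 G:U pairs and 4
#' mismatches, 2-nt Watson-Crick anchor).  The `"canonical"` preset is the
#' stricter discovery setting used to annotate gRNA genes (seed score 24,
#' minimum length 25, minimum score 35, at most 12 G:U and 2 mismatches,
#' 4-nt anchor).
#'
#' Per-pair scores default to +2 for a Watson-Crick pair, +1 for a G:U
#' wobble and -1 for a mismatch, so that a 21-nt all-WC duplex (score 42)
#' and a 16-nt seed (32) clear the relaxed thresholds with headroom while
#' G:U-rich duplexes score lower.  All values are overridable.
#'
#' @param preset `"canonical"` or `"relaxed"`.
#' @param ... named overrides of individual fields (`seed_score`,
#'   `seed_length`, `min_length`, `min_score`, `max_gu`, `max_mismatch`,
#'   `min_anchor`, `score_wc`, `score_gu`, `score_mm`).
#' @return an object of class `duplex_params` (named list).
#' @export
duplex_params <- function(preset = c("canonical", "relaxed"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    relaxed = list(seed_score = 20L, seed_length = 16L, min_length = 21L,
                   min_score = 25L, max_gu = 17L, max_mismatch = 4L,
                   min_anchor = 2L),
    canonical = list(seed_score = 24L, seed_length = 16L, min_length = 25L,
                     min_score = 35L, max_gu = 12L, max_mismatch = 2L,
                     min_anchor = 4L))
  p <- c(p, list(score_wc = 2L, score_gu = 1L, score_mm = -1L))
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown duplex parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- lapply(ov, as.integer)
  if (p$min_anchor > p$min_length) stop("min_anchor must not exceed min_length")
  if (p$max_mismatch < 0L) stop("max_mismatch must be non-negative")
  structure(c(p, list(preset = preset)), class = "duplex_params")
}

#' @export
print.duplex_params <- function(x, ...) {
  cat("Duplex search parameters (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  seed %d nt / score >= %d; length >= %d; score >= %d\n",
              x$seed_length, x$seed_score, x$min_length, x$min_score))
  cat(sprintf("  G:U <= %d; mismatches <= %d; WC anchor >= %d nt\n",
              x$max_gu, x$max_mismatch, x$min_anchor))
  cat(sprintf("  per-pair scores: WC %+d, G:U %+d, MM %+d\n",
              x$score_wc, x$score_gu, x$score_mm))
  invisible(x)
}

#' Classify a single mRNA:gRNA base pair
#'
#' Pair classes follow the usual duplex notation: Watson-Crick pairs
#' (`A:U`, `U:A`, `G:C`, `C:G`) are `"WC"`, wobble pairs (`G:U`, `U:G`)
#' are `"GU"`, anything else is a mismatch `"MM"`.
#'
#' @param mrna_base,grna_base single RNA bases (`A`, `C`, `G`, `U`; `T` is
#'   accepted as a synonym of `U`).
#' @return `"WC"`, `"GU"` or `"MM"` (vectorised over equal-length inputs).
#' @export
classify_pair <- function(mrna_base, grna_base) {
  norm <- function(b) {
    b <- toupper(chartr("T", "U", b))
    if (any(!b %in% c("A", "C", "G", "U")))
      stop("non-RNA base: ", paste(setdiff(b, c("A", "C", "G", "U")), collapse = ", "))
    b
  }
  m <- norm(mrna_base); g <- norm(grna_base)
  pair <- paste0(m, g)
  out <- rep("MM", length(pair))
  out[pair %in% c("AU", "UA", "GC", "CG")] <- "WC"
  out[pair %in% c("GU", "UG")] <- "GU"
  out
}

#' Antiparallel gRNA:mRNA duplex alignment
#'
#' Finds all maximal ungapped antiparallel duplexes between a gRNA and an
#' mRNA that satisfy a [duplex_params()] threshold set: the duplex must
#' contain a nucleation window of `seed_length` scoring at least
#' `seed_score`, reach `min_length` and `min_score` overall, contain at
#' most `max_gu` wobble pairs and `max_mismatch` mismatches, and end in
#' `min_anchor` contiguous Watson-Crick pairs at the mRNA-3' side (the
#' gRNA 5' anchor).  Overlapping passing windows on the same pairing
#' register are reduced to the best-scoring one (ties: longer, then
#' leftmost), so a perfect duplex is reported at its exact extent rather
#' than padded with flanking mismatches; remaining overlapping duplexes
#' (on the mRNA) are pruned to the best-scoring one (ties: leftmost on
#' the mRNA).
#'
#' Alignments are ungapped: guiding is modelled as base pairing of the
#' (already edited) mRNA, and U-indel differences are handled in the
#' editing-site layer, not by gapping the duplex.
#'
#' @param grna gRNA sequence (character scalar, RNA or DNA alphabet,
#'   written 5'->3') or a named vector of length 1.
#' @param mrna mRNA sequence, 5'->3'.
#' @param params a [duplex_params()] object.
#' @param grna_id,mrna_id identifiers stored in the result (default from
#'   names, else `"gRNA"`/`"mRNA"`).
#' @param prune_overlaps suppress overlapping duplexes, keeping the best
#'   per mRNA region (default `TRUE`).
#' @return a `duplex_alignments` data frame with one row per duplex:
#'   `grna_id`, `mrna_id`, 0-based half-open `mrna_start`/`mrna_end` and
#'   `grna_start`/`grna_end`, `length`, `score`, `n_wc`, `n_gu`, `n_mm`
#'   and `pair_string` (`|` WC, `:` G:U, `#` mismatch, 5'->3' along the
#'   mRNA).  The gRNA is antiparallel: its 5' end pairs the mRNA 3' end,
#'   i.e. mRNA position `mrna_start + k` pairs gRNA position
#'   `grna_end - 1 - k`.
#' @export
align_duplex <- function(grna, mrna, params = duplex_params("canonical"),
                         grna_id = NULL, mrna_id = NULL,
                         prune_overlaps = TRUE) {
  stopifnot(inherits(params, "duplex_params"))
  if (is.null(grna_id)) grna_id <- if (!is.null(names(grna))) names(grna)[1] else "gRNA"
  if (is.null(mrna_id)) mrna_id <- if (!is.null(names(mrna))) names(mrna)[1] else "mRNA"
  g <- seq_to_int(unname(grna[1])); m <- seq_to_int(unname(mrna[1]))
  res <- .duplex_scan_cpp(m, g, params$seed_score, params$seed_length,
                          params$min_length, params$min_score, params$max_gu,
                          params$max_mismatch, params$min_anchor,
                          params$score_wc, params$score_gu, params$score_mm)
  n <- length(res$mrna_start)
  df <- data.frame(grna_id = rep(grna_id, n), mrna_id = rep(mrna_id, n),
                   mrna_start = res$mrna_start, mrna_end = res$mrna_end,
                   grna_start = res$grna_start, grna_end = res$grna_end,
                   length = res$mrna_end - res$mrna_start,
                   score = res$score, n_wc = res$n_wc, n_gu = res$n_gu,
                   n_mm = res$n_mm, pair_string = res$pair_string,
                   stringsAsFactors = FALSE)
  if (prune_overlaps && nrow(df) > 1L) df <- prune_overlapping(df)
  class(df) <- c("duplex_alignments", "data.frame")
  df
}

# Greedy best-score-first pruning of mRNA-overlapping duplexes;
# ties broken towards the leftmost mRNA start.
prune_overlapping <- function(df) {
  ord <- order(-df$score, df$mrna_start, df$grna_start)
  keep <- logical(nrow(df))
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in ord) {
    s <- df$mrna_start[i]; e <- df$mrna_end[i]
    if (!any(s < taken_e & e > taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
    }
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$mrna_start), , drop = FALSE]
}

#' Render a duplex alignment as text
#'
#' Produces the standard three-line rendering of a gRNA:mRNA duplex: the
#' mRNA written 5'->3', a pair line using `|` (Watson-Crick), `:` (G:U)
#' and `#` (mismatch), and the gRNA written 3'->5' underneath.  When an
#' editing-site table is supplied, uridines inserted relative to the
#' pre-edited reference are written as lowercase `u` in the mRNA line,
#' and a top `ref` line shows the same columns with inserted positions
#' masked as `.` (deleted Us occupy no column of the edited mRNA).
#'
#' @param aln one row of a `duplex_alignments` data frame.
#' @param mrna,grna the full sequences the alignment refers to.
#' @param site_table optional [build_site_table()] result for the mRNA's
#'   cryptogene, used to mark inserted (lowercase `u`) and deleted Us.
#' @return a character scalar (lines separated by newlines), printed with
#'   `cat()` friendliness.
#' @export
render_duplex <- function(aln, mrna, grna, site_table = NULL) {
  stopifnot(nrow(aln) == 1L)
  ms <- aln$mrna_start + 1L; me <- aln$mrna_end
  gs <- aln$grna_start + 1L; ge <- aln$grna_end
  mseg <- chartr("T", "U", substring(unname(mrna[1]), ms, me))
  gseg <- chartr("T", "U", substring(unname(grna[1]), gs, ge))
  gseg_rev <- paste(rev(strsplit(gseg, "")[[1L]]), collapse = "")
  lines <- character(0)
  if (!is.null(site_table)) {
    ann <- annotate_inserted(unname(mrna[1]), site_table)
    if (!is.null(ann)) {
      mchars <- strsplit(mseg, "")[[1L]]
      ins <- ann$inserted[ms:me]
      mchars[ins & mchars == "U"] <- "u"
      mseg <- paste(mchars, collapse = "")
      lines <- c(lines, paste0("ref  5'-", ann$ref_line(ms, me), "-3'"))
    }
  }
  lines <- c(lines,
             paste0("mRNA 5'-", mseg, "-3'"),
             paste0("        ", aln$pair_string),
             paste0("gRNA 3'-", gseg_rev, "-5'"))
  paste(lines, collapse = "\n")
}

# Per-position insertion flags for an edited mRNA against its site table:
# a U at a site is "inserted" if it exceeds the reference U count for that
# site (the first `ref` Us of a run are treated as reference Us).
annotate_inserted <- function(mrna, table) {
  obs <- mrna_site_counts(mrna, table)
  if (is.null(obs)) return(NULL)
  n <- nchar(mrna)
  inserted <- logical(n)
  pos <- 1L
  B <- length(table$site_ucount)
  for (s in seq_len(B)) {
    k <- obs[s]
    if (k > 0L) {
      extra <- max(0L, k - table$site_ucount[s])
      if (extra > 0L)
        inserted[(pos + k - extra):(pos + k - 1L)] <- TRUE
      pos <- pos + k
    }
    if (s < B) pos <- pos + 1L  # the backbone base
  }
  ref_line <- function(a, b) {
    # per-column reference view: inserted Us are absent from the
    # reference and masked; deleted Us occupy no column at all
    chars <- strsplit(chartr("T", "U", mrna), "")[[1L]]
    chars[inserted] <- "."
    paste(chars[a:b], collapse = "")
  }
  list(inserted = inserted, ref_line = ref_line)
}

# observed U count per site of `mrna` given the cryptogene site table;
# NULL if the mRNA's backbone does not equal the table backbone.
mrna_site_counts <- function(mrna, table) {
  st <- build_site_table(chartr("U", "T", toupper(mrna)), id = "query")
  if (st$backbone != table$backbone) return(NULL)
  out <- st$site_ucount
  attr(out, "deleted_before") <- pmax(table$site_ucount - out, 0L)
  out
}
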