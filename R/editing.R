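#' Editing-site table of a cryptogene
#'
#' Decomposes a cryptogene sequence into its non-T backbone and the
#' reference number of Ts (uridines, on the transcript) preceding each
#' backbone base, plus one terminal site for trailing Ts.  U-indel editing
#' changes only these per-site U counts, never the backbone, so the table
#' is the substrate for T-stripped read alignment: a read and the
#' reference are compared on the backbone, and insertions/deletions of Us
#' are read off the per-site counts.
#'
#' @param seq cryptogene DNA sequence (character scalar; must contain at
#'   least one non-T base).
#' @param id cryptogene identifier (default from `names(seq)`).
#' @return an object of class `editing_site_table`: `cryptogene_id`,
#'   `backbone` (non-T string, 5'->3'), `site_ucount` (integer, one per
#'   backbone base plus a terminal site; `n_sites = nchar(backbone) + 1`),
#'   `site_coord_5p` (0-based coordinate of each backbone base in `seq`)
#'   and `n_sites`.  Sites are indexed 5'->3'; the 3'->5' site number used
#'   in cascade work is `n_sites + 1 - i`.
#' @export
build_site_table <- function(seq, id = NULL) {
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "cryptogene"
  s <- toupper(chartr("U", "T", unname(seq[1])))
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1L]]
  is_t <- chars == "T"
  if (all(is_t)) stop("all-T sequence has no backbone")
  bb_idx <- which(!is_t)
  nb <- length(bb_idx)
  ucount <- integer(nb + 1L)
  prev <- 0L
  for (k in seq_len(nb)) {
    ucount[k] <- bb_idx[k] - prev - 1L
    prev <- bb_idx[k]
  }
  ucount[nb + 1L] <- length(chars) - prev
  structure(list(cryptogene_id = id,
                 backbone = paste(chars[bb_idx], collapse = ""),
                 site_ucount = ucount,
                 site_coord_5p = bb_idx - 1L,
                 n_sites = nb + 1L),
            class = "editing_site_table")
}

#' @export
print.editing_site_table <- function(x, ...) {
  cat("Editing-site table for ", x$cryptogene_id, "\n", sep = "")
  cat(sprintf("  backbone %d nt, %d sites, reference U total %d\n",
              nchar(x$backbone), x$n_sites, sum(x$site_ucount)))
  invisible(x)
}

#' Rebuild a sequence from an editing-site table and per-site U counts
#'
#' Inverse of [build_site_table()]: interleaves `ucounts[i]` Ts before
#' backbone base `i` (and `ucounts[n_sites]` trailing Ts).  With the
#' table's own reference counts this reproduces the input sequence
#' exactly.
#'
#' @param table an `editing_site_table`.
#' @param ucounts integer vector of length `table$n_sites` (default: the
#'   reference counts).
#' @return the rebuilt sequence (character scalar).
#' @export
rebuild_sequence <- function(table, ucounts = table$site_ucount) {
  stopifnot(length(ucounts) == table$n_sites, all(ucounts >= 0L))
  bb <- strsplit(table$backbone, "")[[1L]]
  nb <- length(bb)
  parts <- character(2L * nb + 1L)
  parts[seq_len(nb) * 2L - 1L] <- strrep("T", ucounts[seq_len(nb)])
  parts[seq_len(nb) * 2L] <- bb
  parts[2L * nb + 1L] <- strrep("T", ucounts[nb + 1L])
  paste(parts, collapse = "")
}

# split a read into its T-stripped backbone and T-run lengths:
# runs[k] = Ts before backbone char k; plus leading/trailing runs.
strip_read <- function(seq) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1L]]
  is_t <- chars == "T"
  bb_idx <- which(!is_t)
  if (!length(bb_idx))
    return(list(backbone = "", runs = integer(0), trailing = nchar(seq)))
  runs <- integer(length(bb_idx))
  prev <- 0L
  for (k in seq_along(bb_idx)) {
    runs[k] <- bb_idx[k] - prev - 1L
    prev <- bb_idx[k]
  }
  list(backbone = paste(chars[bb_idx], collapse = ""),
       runs = runs, trailing = length(chars) - prev)
}

#' T-stripped alignment of a read to cryptogene site tables
#'
#' Strips Ts from the read, locates the resulting backbone in the
#' cryptogene backbones (both strands, up to `max_backbone_mm`
#' substitutions, unique best hit required) and extracts the observed U
#' count at every covered editing site.  The first and last covered sites
#' are flagged partial (the read may truncate their U runs) and are
#' excluded from the edited-site and indel totals.
#'
#' @param read read sequence (character scalar); name used as read id.
#' @param tables a single `editing_site_table` or a (named) list of them.
#' @param max_backbone_mm maximum backbone substitutions (default 1).
#' @param read_id read identifier.
#' @return an object of class `read_editing_pattern`, or `NULL` when the
#'   read has no hit or multiple equally good hits: fields `read_id`,
#'   `cryptogene_id`, `strand`, `sites` (5'->3' site indices covered),
#'   `obs_ucount`, `ref_ucount`, `partial` (logical per covered site),
#'   `n_insertions`, `n_deletions`, `n_edited_sites`, `n_backbone_mm`,
#'   `site_span_3p` (first..last covered site in 3'->5' numbering).
#' @export
align_read_tstripped <- function(read, tables, max_backbone_mm = 1L,
                                 read_id = NULL) {
  if (inherits(tables, "editing_site_table")) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "cryptogene_id")
  if (is.null(read_id))
    read_id <- if (!is.null(names(read))) names(read)[1] else "read"
  rseq <- unname(read[1])
  cands <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") rseq else revcomp(rseq)
    sr <- strip_read(sseq)
    if (nchar(sr$backbone) < 4L) next
    rb <- seq_to_int(sr$backbone)
    for (tn in names(tables)) {
      bb <- seq_to_int(tables[[tn]]$backbone)
      hit <- .hamming_scan_cpp(bb, rb, max_backbone_mm)
      for (h in seq_along(hit$pos))
        cands[[length(cands) + 1L]] <-
          list(table = tn, strand = strand, offset = hit$pos[h],
               dist = hit$dist[h], sr = sr)
    }
  }
  if (!length(cands)) return(NULL)
  dists <- vapply(cands, `[[`, 0L, "dist")
  best <- which(dists == min(dists))
  if (length(best) != 1L) return(NULL)   # ambiguous mapping
  c1 <- cands[[best]]
  tab <- tables[[c1$table]]
  nb_read <- nchar(c1$sr$backbone)
  sites <- (c1$offset + 1L):(c1$offset + nb_read + 1L)  # 5'->3' indices
  obs <- c(c1$sr$runs, c1$sr$trailing)
  ref <- tab$site_ucount[sites]
  partial <- rep(FALSE, length(sites))
  partial[1L] <- TRUE
  partial[length(sites)] <- TRUE
  interior <- !partial
  d <- obs[interior] - ref[interior]
  structure(list(read_id = read_id, cryptogene_id = tab$cryptogene_id,
                 strand = c1$strand, sites = sites, obs_ucount = obs,
                 ref_ucount = ref, partial = partial,
                 n_insertions = sum(pmax(d, 0L)),
                 n_deletions = sum(pmax(-d, 0L)),
                 n_edited_sites = sum(d != 0L),
                 n_backbone_mm = c1$dist,
                 site_span_3p = c(tab$n_sites + 1L - max(sites),
                                  tab$n_sites + 1L - min(sites))),
            class = "read_editing_pattern")
}

#' Align a read set against cryptogene tables
#'
#' Convenience wrapper applying [align_read_tstripped()] to a named vector
#' of reads.  Unassigned reads (no hit or ambiguous) are counted.
#'
#' @param reads named character vector of read sequences.
#' @param tables list of `editing_site_table`s.
#' @param max_backbone_mm see [align_read_tstripped()].
#' @return list with `patterns` (list of `read_editing_pattern`) and
#'   `n_unassigned`.
#' @export
align_reads <- function(reads, tables, max_backbone_mm = 1L) {
  pats <- vector("list", length(reads))
  for (i in seq_along(reads))
    pats[[i]] <- align_read_tstripped(reads[i], tables, max_backbone_mm,
                                      read_id = names(reads)[i])
  ok <- !vapply(pats, is.null, TRUE)
  list(patterns = pats[ok], n_unassigned = sum(!ok))
}

#' Is a read edited?
#'
#' A read counts as edited when it differs from the reference at
#' `min_sites` or more fully observed editing sites (default 5, the
#' threshold used for edited-read counting in expression profiles).
#'
#' @param pattern a `read_editing_pattern`.
#' @param min_sites minimum number of edited sites (default 5).
#' @return logical.
#' @export
is_edited <- function(pattern, min_sites = 5L) {
  stopifnot(inherits(pattern, "read_editing_pattern"))
  pattern$n_edited_sites >= min_sites
}

#' Per-gene coverage and editing profile
#'
#' Summarises aligned read patterns per cryptogene/gene: total mapped
#' reads, edited reads (at least `min_sites` edited sites), and per-base
#' depth along the backbone.
#'
#' @param patterns list of `read_editing_pattern`s.
#' @param tables list of `editing_site_table`s (defines loci and lengths).
#' @param min_sites passed to [is_edited()].
#' @return a `coverage_profile` data frame (one row per locus: `locus`,
#'   `n_mapped`, `n_edited`, `mean_depth`) with a `depth` attribute (list
#'   of per-backbone-base depth vectors).
#' @export
coverage_profile <- function(patterns, tables, min_sites = 5L) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "cryptogene_id")
  depth <- lapply(tables, function(t) integer(nchar(t$backbone)))
  n_mapped <- n_edited <- stats::setNames(integer(length(tables)), names(tables))
  for (p in patterns) {
    id <- p$cryptogene_id
    if (!id %in% names(tables)) next
    n_mapped[id] <- n_mapped[id] + 1L
    if (is_edited(p, min_sites)) n_edited[id] <- n_edited[id] + 1L
    bb <- p$sites[-length(p$sites)]      # backbone bases covered
    depth[[id]][bb] <- depth[[id]][bb] + 1L
  }
  out <- data.frame(locus = names(tables), n_mapped = as.integer(n_mapped),
                    n_edited = as.integer(n_edited),
                    mean_depth = vapply(depth, function(d)
                      if (length(d)) mean(d) else 0, 0),
                    row.names = NULL)
  attr(out, "depth") <- depth
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Reconstruct the edited ORF of a cryptogene from read patterns
#'
#' Builds a graph whose nodes are (site, observed U count) states and
#' whose edges connect states at adjacent sites co-observed within a read,
#' weighted by the number of supporting reads.  Starting from the majority
#' state at the 3'-most interiorly observed site, the maximum-bottleneck
#' path (maximising the minimum edge support; ties broken by total
#' support, then by fewer edits relative to the reference) is followed
#' 3'->5'.  Sites never observed in a read interior fall back to the
#' majority of raw observations, then to the reference count.  The
#' resulting per-site consensus is rebuilt into an edited sequence, which
#' is scanned in all three frames for the longest ATG-initiated open
#' reading frame terminating in UAA/UAG under translation table 4 (UGA is
#' tryptophan, never stop).  If no such ORF reaches `min_orf_fraction` of
#' the expected protein length, the reconstruction is reported as failed.
#'
#' @param patterns list of `read_editing_pattern`s for one cryptogene.
#' @param table the cryptogene's `editing_site_table`.
#' @param expected_protein_len expected protein length in residues
#'   (default: the codon capacity of the rebuilt sequence minus the stop).
#' @param min_orf_fraction minimum fraction of the expected protein length
#'   (default 0.85) for a successful reconstruction.
#' @return an object of class `edited_orf`: `cryptogene_id`,
#'   `edited_seq`, `consensus_ucount`, `orf_start`/`orf_stop` (0-based
#'   half-open on the edited sequence), `protein`, `support` (bottleneck
#'   read support along the chosen path), `status` (`"ok"` or
#'   `"failed"`).
#' @export
reconstruct_orf <- function(patterns, table, expected_protein_len = NULL,
                            min_orf_fraction = 0.85) {
  patterns <- Filter(function(p) p$cryptogene_id == table$cryptogene_id, patterns)
  if (!length(patterns)) stop("no coverage for ", table$cryptogene_id)
  S <- table$n_sites
  # interior observation tallies: obs_tab[[site]] is a named count vector
  obs_tab <- vector("list", S)
  raw_tab <- vector("list", S)
  edge_tab <- new.env(parent = emptyenv())
  for (p in patterns) {
    int_idx <- which(!p$partial)
    for (k in seq_along(p$sites)) {
      s <- p$sites[k]; v <- as.character(p$obs_ucount[k])
      raw_tab[[s]][v] <- (if (is.null(raw_tab[[s]][v]) ||
                              is.na(raw_tab[[s]][v])) 0L else raw_tab[[s]][v]) + 1L
      if (!p$partial[k])
        obs_tab[[s]][v] <- (if (is.null(obs_tab[[s]][v]) ||
                                is.na(obs_tab[[s]][v])) 0L else obs_tab[[s]][v]) + 1L
    }
    if (length(int_idx) >= 2L) {
      for (k in int_idx[-length(int_idx)]) {
        if (!((k + 1L) %in% int_idx)) next
        key <- paste(p$sites[k], p$obs_ucount[k], p$obs_ucount[k + 1L], sep = "_")
        edge_tab[[key]] <- (if (is.null(edge_tab[[key]])) 0L else edge_tab[[key]]) + 1L
      }
    }
  }
  has_int <- vapply(obs_tab, function(x) !is.null(x) && sum(x) > 0L, TRUE)
  majority_state <- function(tab, s, fallback) {
    t <- tab[[s]]
    if (is.null(t) || !sum(t)) return(fallback)
    # majority; ties towards the reference, then smaller count
    best <- names(t)[t == max(t)]
    if (as.character(fallback) %in% best) return(fallback)
    as.integer(min(as.integer(best)))
  }
  consensus <- table$site_ucount
  if (!any(has_int)) {
    for (s in seq_len(S))
      consensus[s] <- majority_state(raw_tab, s, table$site_ucount[s])
    support <- 0L
  } else {
    s3 <- max(which(has_int))       # 3'-most interiorly observed site
    s5 <- min(which(has_int))       # 5'-most interiorly observed site
    start_state <- majority_state(obs_tab, s3, table$site_ucount[s3])
    consensus[s3] <- start_state
    # sites outside the interiorly observed range: raw majority, then
    # reference (terminal runs can only be under-reported, so a zero
    # reference count stays exact)
    if (s3 < S)
      for (s in (s3 + 1L):S)
        consensus[s] <- majority_state(raw_tab, s, table$site_ucount[s])
    if (s5 > 1L)
      for (s in 1L:(s5 - 1L))
        consensus[s] <- majority_state(raw_tab, s, table$site_ucount[s])
    # bottleneck DP from s3 down to s5 (3'->5')
    # f[[s]]: for each state, c(bottleneck, total, edits) + backpointer
    states_at <- function(s) {
      st <- unique(c(as.integer(names(obs_tab[[s]])), table$site_ucount[s]))
      sort(st)
    }
    support <- Inf
    if (s3 > s5) {
      f <- list()
      f[[as.character(start_state)]] <- list(bot = Inf, tot = 0, prev = NULL)
      chain <- vector("list", s3)
      chain[[s3]] <- f
      for (s in (s3 - 1L):s5) {
        f_new <- list()
        for (st in states_at(s)) {
          bestv <- NULL
          for (pv in names(chain[[s + 1L]])) {
            key <- paste(s, st, pv, sep = "_")
            w <- if (is.null(edge_tab[[key]])) 0L else edge_tab[[key]]
            prevf <- chain[[s + 1L]][[pv]]
            cand <- list(bot = min(prevf$bot, w), tot = prevf$tot + w, prev = pv)
            if (is.null(bestv) || cand$bot > bestv$bot ||
                (cand$bot == bestv$bot && cand$tot > bestv$tot))
              bestv <- cand
          }
          f_new[[as.character(st)]] <- bestv
        }
        chain[[s]] <- f_new
      }
      # choose final state at the 5' end: bottleneck, total, fewer edits
      fin <- chain[[s5]]
      pick <- NULL
      for (st in names(fin)) {
        ed <- abs(as.integer(st) - table$site_ucount[s5])
        cand <- c(fin[[st]]$bot, fin[[st]]$tot, -ed)
        if (is.null(pick) || cand[1] > pick$v[1] ||
            (cand[1] == pick$v[1] && cand[2] > pick$v[2]) ||
            (cand[1] == pick$v[1] && cand[2] == pick$v[2] && cand[3] > pick$v[3]))
          pick <- list(st = st, v = cand)
      }
      # backtrack s5 -> s3
      st <- pick$st
      for (s in s5:s3) {
        consensus[s] <- as.integer(st)
        nxt <- chain[[s]][[st]]$prev
        if (is.null(nxt)) break
        st <- nxt
      }
      support <- pick$v[1]
    }
    if (!is.finite(support)) support <- 0L
  }
  edited_seq <- rebuild_sequence(table, consensus)
  orf <- find_longest_orf(edited_seq)
  if (is.null(expected_protein_len))
    expected_protein_len <- max(1L, nchar(edited_seq) %/% 3L - 1L)
  ok <- !is.null(orf) && nchar(orf$protein) >= min_orf_fraction * expected_protein_len
  structure(list(cryptogene_id = table$cryptogene_id, edited_seq = edited_seq,
                 consensus_ucount = consensus,
                 orf_start = if (ok) orf$start else NA_integer_,
                 orf_stop = if (ok) orf$end else NA_integer_,
                 protein = if (!is.null(orf)) orf$protein else "",
                 stop_codon = if (!is.null(orf)) orf$stop_codon else NA_character_,
                 support = support,
                 status = if (ok) "ok" else "failed",
                 expected_protein_len = expected_protein_len),
            class = "edited_orf")
}

#' @export
print.edited_orf <- function(x, ...) {
  cat("Edited ORF reconstruction for ", x$cryptogene_id, ": ", x$status, "\n", sep = "")
  cat(sprintf("  edited sequence %d nt; protein %d aa (expected ~%d); bottleneck support %s\n",
              nchar(x$edited_seq), nchar(x$protein), x$expected_protein_len,
              format(x$support)))
  invisible(x)
}

# longest ATG-initiated ORF ending UAA/UAG under code 4, over 3 frames.
# Returns 0-based half-open [start, end) including the stop codon.
find_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG")
    is_atg <- codons == "ATG"
    open_from <- NA_integer_
    for (k in seq_len(ncod)) {
      if (is_stop[k]) {
        if (!is.na(open_from)) {
          len <- k - open_from    # codons before the stop
          if (is.null(best) || len > best$len)
            best <- list(len = len, start = starts[open_from] - 1L,
                         end = starts[k] + 2L,
                         stop_codon = codons[k],
                         protein = translate_code4(substring(
                           seq, starts[open_from], starts[k] - 1L)))
          open_from <- NA_integer_
        }
      } else if (is.na(open_from) && is_atg[k]) open_from <- k
    }
  }
  best
}

#' Translate under the protistan mitochondrial genetic code (table 4)
#'
#' NCBI translation table 4: UGA encodes tryptophan; UAA and UAG remain
#' stops (rendered `*`).  Ambiguous codons translate to `X`.  A trailing
#' incomplete codon is ignored.
#'
#' @param seq nucleotide sequence (DNA or RNA alphabet).
#' @param frame reading frame 1, 2 or 3.
#' @return the amino-acid string.
#' @export
translate_code4 <- function(seq, frame = 1L) {
  stopifnot(frame %in% 1:3)
  s <- toupper(chartr("U", "T", unname(seq[1])))
  s <- substring(s, frame)
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  s <- substring(s, 1L, n)
  as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("4"),
    if.fuzzy.codon = "X"))
}
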