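# Minicircle / maxicircle structural annotation: IUPAC motif scanning
# (CSB1, CSB3, GRAM), contig circularization, einverted-style inverted
# repeats, class deduplication and orientation normalisation.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

iupac_revcomp <- function(pattern) {
  ch <- rev(strsplit(toupper(pattern), "")[[1L]])
  paste(.IUPAC_COMP[ch], collapse = "")
}

#' Scan a (possibly circular) sequence for an IUPAC motif
#'
#' Exact degenerate-pattern matching: a position matches when every
#' pattern symbol's IUPAC code set contains the corresponding sequence
#' base (`y` = C/T, `r` = A/G, `n` = any; no mismatches).  Circular
#' sequences are scanned across the origin, so hits may wrap.  The
#' canonical minicircle motifs are the universal CSB3 12-mer
#' `ggggttggtgtg` and the CSB1 palindromic hairpin
#' `yyryryrrrryyyyryryrr`.
#'
#' @param seq sequence (character scalar; DNA alphabet, `N` allowed but
#'   never matches a non-`N` pattern symbol).
#' @param pattern IUPAC degenerate pattern.
#' @param motif_name name recorded in the output (default: the pattern).
#' @param both_strands also scan the reverse strand (default `TRUE`);
#'   minus-strand hits are reported by their forward-strand start.
#' @param circular scan across the origin (default `FALSE`).
#' @return a data frame of hits: `motif_name`, `start` (0-based, forward
#'   strand), `length`, `strand`, `pattern`.
#' @export
scan_motif <- function(seq, pattern, motif_name = pattern,
                       both_strands = TRUE, circular = FALSE) {
  s <- toupper(unname(seq[1]))
  pat <- toupper(pattern)
  sym <- strsplit(pat, "")[[1L]]
  bad <- setdiff(sym, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in pattern: ", paste(unique(bad), collapse = ", "))
  pats <- list(`+` = pat)
  if (both_strands) pats[["-"]] <- iupac_revcomp(pat)
  L <- nchar(s)
  plen <- nchar(pat)
  ext <- if (circular && plen > 1L) paste0(s, substring(s, 1L, plen - 1L)) else s
  chars <- strsplit(ext, "")[[1L]]
  out <- list()
  for (strand in names(pats)) {
    psym <- strsplit(pats[[strand]], "")[[1L]]
    nstart <- if (circular) L else L - plen + 1L
    if (nstart < 1L) next
    ok <- rep(TRUE, nstart)
    for (j in seq_len(plen)) {
      allowed <- chars[seq_len(nstart) + j - 1L] %in% .IUPAC[[psym[j]]]
      ok <- ok & allowed
      if (!any(ok)) break
    }
    hit <- which(ok)
    if (length(hit))
      out[[strand]] <- data.frame(motif_name = motif_name,
                                  start = hit - 1L, length = plen,
                                  strand = strand, pattern = pattern)
  }
  if (!length(out))
    return(data.frame(motif_name = character(), start = integer(),
                      length = integer(), strand = character(),
                      pattern = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Circularize a contig with terminal overlapping ends
#'
#' Assembled minicircle contigs often carry a duplicated terminal
#' sequence; if an exact direct repeat of at least `k_min` bp is shared
#' by the contig's ends (prefix equals suffix), one copy is removed and
#' the sequence is marked circular.  A terminal repeat longer than half
#' the contig makes the circular length ambiguous and is an error.
#'
#' @param contig linear contig sequence (character scalar).
#' @param k_min minimum exact terminal repeat (default 20 bp, well above
#'   chance for ~2 kb circles).
#' @return list with `seq` (possibly shortened), `circular` (logical),
#'   `overlap` (bp removed, 0 if none).
#' @export
circularize_contig <- function(contig, k_min = 20L) {
  s <- toupper(unname(contig[1]))
  L <- nchar(s)
  kbig <- 0L
  for (k in (L - 1L):1L) {
    if (substring(s, 1L, k) == substring(s, L - k + 1L, L)) { kbig <- k; break }
  }
  if (kbig > L / 2)
    stop("ambiguous terminal repeat (", kbig, " bp > half the contig length)")
  if (kbig >= k_min)
    list(seq = substring(s, 1L, L - kbig), circular = TRUE, overlap = kbig)
  else
    list(seq = s, circular = FALSE, overlap = 0L)
}

#' Detect inverted repeats
#'
#' Locally aligns the sequence against its own reverse complement
#' (einverted-style dynamic programming) and reports non-overlapping
#' inverted repeats with alignment score at or above `threshold`.
#' Default scoring matches the einverted options used for minicircle
#' annotation: match +4, gap penalty 14; the mismatch penalty (-4) is a
#' package default and configurable.
#'
#' @param seq sequence (character scalar).
#' @param match,mismatch,gap per-position scores (gap is applied per
#'   gapped position; supply negative penalties).
#' @param threshold minimum alignment score (default 40).
#' @param max_hits cap on reported repeats.
#' @return data frame of class `inverted_repeats`: 0-based half-open
#'   `arm1_start`, `arm1_end`, `arm2_start`, `arm2_end`, `score`,
#'   `mismatches`, `gaps`.
#' @export
find_inverted_repeats <- function(seq, match = 4L, mismatch = -4L,
                                  gap = -14L, threshold = 40L,
                                  max_hits = 25L) {
  v <- seq_to_int(unname(seq[1]))
  res <- .inverted_repeat_cpp(v, as.integer(match), as.integer(mismatch),
                              as.integer(gap), as.integer(threshold),
                              as.integer(max_hits))
  out <- data.frame(arm1_start = res$arm1_start, arm1_end = res$arm1_end,
                    arm2_start = res$arm2_start, arm2_end = res$arm2_end,
                    score = res$score, mismatches = res$mismatches,
                    gaps = res$gaps)
  class(out) <- c("inverted_repeats", "data.frame")
  out
}

# best ungapped identity of circle `a` against circle `b` over all
# rotations and both strands, anchored on exact seed words of `a`.
circle_identity <- function(a, b, seed_len = 14L) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) < seed_len) return(0)
  achars <- strsplit(a, "")[[1L]]
  best <- 0
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") b else revcomp(b)
    doubled <- paste0(bs, bs)
    offs <- unique(c(seq(1L, la - seed_len + 1L, by = max(1L, seed_len %/% 2L)),
                     la - seed_len + 1L))
    rots <- integer(0)
    for (o in offs) {
      seed <- substring(a, o, o + seed_len - 1L)
      m <- gregexpr(seed, doubled, fixed = TRUE)[[1L]]
      if (m[1L] != -1L)
        rots <- c(rots, ((m - o) %% lb))
    }
    for (r in unique(rots)) {
      rot <- rotate_seq(bs, r + 1L)
      n <- min(la, lb)
      matches <- sum(achars[seq_len(n)] == strsplit(rot, "")[[1L]][seq_len(n)])
      best <- max(best, matches / max(la, lb))
    }
  }
  best
}

#' Deduplicate minicircles into sequence classes
#'
#' Greedy clustering of circular sequences under rotation- and
#' strand-invariant ungapped identity: circles are processed longest
#' first (ties by id) and each joins the first established class whose
#' representative it matches at or above `identity_threshold`
#' (matches / max length, best over rotations and strands, anchored on
#' exact seed words).  The default threshold 0.97 mirrors the small-RNA
#' clustering identity.
#'
#' @param circles named character vector of circle sequences.
#' @param identity_threshold minimum identity to join a class.
#' @return a data frame: `id`, `class_id`, `representative`, `length`,
#'   `identity` (to the representative).
#' @export
classify_minicircles <- function(circles, identity_threshold = 0.97) {
  stopifnot(!is.null(names(circles)))
  ord <- order(-nchar(circles), names(circles))
  ids <- names(circles)[ord]
  reps <- character(0)
  out <- data.frame(id = ids, class_id = NA_integer_,
                    representative = NA_character_,
                    length = nchar(circles)[ord], identity = NA_real_)
  for (i in seq_along(ids)) {
    s <- circles[[ids[i]]]
    placed <- FALSE
    for (k in seq_along(reps)) {
      idk <- circle_identity(s, circles[[reps[k]]])
      if (idk >= identity_threshold) {
        out$class_id[i] <- k
        out$representative[i] <- reps[k]
        out$identity[i] <- idk
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      out$class_id[i] <- length(reps)
      out$representative[i] <- ids[i]
      out$identity[i] <- 1
    }
  }
  out[order(out$class_id, out$id), , drop = FALSE]
}

#' Re-orient a minicircle on its CSB block
#'
#' Rotates (and strand-flips, if required) an annotated minicircle so
#' that the conserved sequence block closest to the functional gRNA gene
#' sits at position 0 and the gRNA gene lies on the strand opposite the
#' CSBs.  Circular distance ties are broken towards the lower CSB
#' coordinate.  Applying the operation twice is a no-op.
#'
#' @param seq minicircle sequence (character scalar).
#' @param csb_hits data frame of CSB motif hits ([scan_motif()] output).
#' @param grna_genes data frame with `start`, `end`, `strand` (0-based
#'   half-open); the first row is the functional gene.
#' @return list with `seq`, updated `csb_hits` and `grna_genes`,
#'   `rotation` (old 0-based position now at 0) and `flipped`.
#' @export
reorient_minicircle <- function(seq, csb_hits, grna_genes) {
  if (!nrow(csb_hits)) stop("no CSB hit on minicircle")
  if (!nrow(grna_genes)) stop("no gRNA gene on minicircle")
  s <- toupper(unname(seq[1]))
  L <- nchar(s)
  gene <- grna_genes[1L, ]
  flipped <- FALSE
  if (gene$strand == csb_hits$strand[1L]) {
    s <- revcomp(s)
    flipped <- TRUE
    new_start <- L - grna_genes$end
    grna_genes$end <- L - grna_genes$start
    grna_genes$start <- new_start
    grna_genes$strand <- ifelse(grna_genes$strand == "+", "-", "+")
    csb_hits$start <- L - (csb_hits$start + csb_hits$length)
    csb_hits$strand <- ifelse(csb_hits$strand == "+", "-", "+")
    gene <- grna_genes[1L, ]
  }
  dcirc <- function(a, b) pmin((b - a) %% L, (a - b) %% L)
  d <- dcirc(csb_hits$start, gene$start)
  pick <- which(d == min(d))
  pick <- pick[which.min(csb_hits$start[pick])]
  r <- csb_hits$start[pick]
  s2 <- rotate_seq(s, r + 1L)
  rot <- function(p) (p - r) %% L
  csb_hits$start <- rot(csb_hits$start)
  sh <- rot(grna_genes$start)
  grna_genes$end <- sh + (grna_genes$end - grna_genes$start)
  grna_genes$start <- sh
  list(seq = s2, csb_hits = csb_hits, grna_genes = grna_genes,
       rotation = r, flipped = flipped)
}
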