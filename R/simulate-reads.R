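# Read-library simulation on top of a simulate_kdna() ground truth:
# staged mRNA editing intermediates, tailed/adaptered small-RNA pairs,
# decoy editing reads and kDNA fragments.

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, error_rate)
  if (!k) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# Fragment sampling with clipping at the molecule ends: fragment starts
# range over [1 - read_len + min_overlap, L - min_overlap + 1] and are
# clipped to the molecule, so per-base depth is flat across the ends
# (transcript ends are covered by fragments that begin or end there).
.FRAG_MIN_OVERLAP <- 25L

sample_fragment <- function(sq, rl, min_ov = .FRAG_MIN_OVERLAP) {
  L <- nchar(sq)
  if (L <= rl) return(sq)
  a <- sample.int(L + rl - 2L * min_ov + 1L, 1L) - rl + min_ov
  substring(sq, max(1L, a), min(L, a + rl - 1L))
}

n_fragments <- function(coverage, L, rl, min_ov = .FRAG_MIN_OVERLAP) {
  if (L <= rl) return(ceiling(coverage))
  ceiling(coverage * (L + rl - 2L * min_ov) / rl)
}

# per-stage editing state of a cryptogene: stage k means the 3'-most k
# cascade gRNAs have acted; a site is edited iff its U run lies 3' of
# the k-th gRNA's 5' boundary on the edited mRNA.
stage_ucounts <- function(cg, tiles, stage) {
  u <- cg$ucount_pre
  if (stage == 0L) return(u)
  b <- tiles$mrna_start[stage]
  pos <- backbone_positions(cg$ucount_edited)
  nb <- length(pos)
  for (s in cg$edited_sites) {
    run_start <- pos[s] - cg$ucount_edited[s]
    if (s <= nb && run_start >= b) u[s] <- cg$ucount_edited[s]
  }
  u
}

#' Simulate read libraries from a kDNA ground truth
#'
#' Generates (a) an mRNA library of reads sampled from staged editing
#' intermediates of each cryptogene (a read is fully edited 3' of its
#' stage breakpoint and pre-edited 5' of it, reflecting the 3'->5'
#' anchor dependency of the cascade) plus reads of unedited genes and
#' decoy cryptogenes; (b) a paired small-RNA library of the planted
#' gRNAs with 3' poly(U)/poly(A) tails and sequencing adapters; (c) a
#' kDNA fragment library.  Read ids encode the origin
#' (`library|locus|stage|serial`) for ground-truth lookup.  All
#' randomness derives from `config$seed`; sequencing noise is
#' substitution-only.
#'
#' Decoy reads span the whole decoy editing domain: in non-cognate mode
#' every donor-window site carries the donor-guided U count and enough
#' spacer sites are randomly mis-edited to leave a `guided_fraction`
#' share of guided editing events per read; in stochastic mode every
#' site is independently mis-edited with `edit_prob`.
#'
#' @param truth a [simulate_kdna()] result.
#' @param config the same [sim_config()].
#' @param out_dir optional directory; writes `mrna_reads.fastq`,
#'   `srna_R1.fastq`, `srna_R2.fastq`, `kdna_reads.fastq`.
#' @return list with `mrna` (named character vector), `srna_r1`,
#'   `srna_r2`, `kdna`, and `origins` (data frame: read id, library,
#'   locus, stage).
#' @export
simulate_reads <- function(truth, config, out_dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  err <- config$error_rate
  rl <- config$read_len
  mrna <- character(0)
  origins <- list()
  push_origin <- function(id, lib, locus, stage)
    origins[[length(origins) + 1L]] <<-
      data.frame(read_id = id, library = lib, locus = locus, stage = stage)

  ## (a) mRNA reads: staged intermediates per cryptogene
  sd <- config$editing_stage_distribution
  for (id in names(truth$cryptogenes)) {
    cg <- truth$cryptogenes[[id]]
    tiles <- truth$grnas[truth$grnas$cryptogene_id == id, , drop = FALSE]
    tiles <- tiles[order(tiles$cascade_order), , drop = FALSE]
    n_st <- nrow(tiles)
    probs <- c(sd[["pre"]],
               if (n_st > 1L) rep(sd[["intermediate"]] / (n_st - 1L), n_st - 1L),
               sd[["full"]] + if (n_st > 1L) 0 else sd[["intermediate"]])
    stage_seqs <- lapply(0:n_st, function(k) {
      tab <- build_site_table(cg$pre_seq, id = id)
      rebuild_sequence(tab, stage_ucounts(cg, tiles, k))
    })
    L0 <- nchar(cg$edited_seq)
    n_reads <- n_fragments(config$coverage, L0, rl)
    for (r in seq_len(n_reads)) {
      st <- sample(0:n_st, 1L, prob = probs)
      sq <- stage_seqs[[st + 1L]]
      rd <- apply_errors(sample_fragment(sq, rl), err)
      nm <- sprintf("mrna|%s|stage=%d|%05d", id, st, r)
      mrna[[nm]] <- rd
      push_origin(nm, "mrna", id, st)
    }
  }
  ## unedited gene reads
  for (id in names(truth$unedited)) {
    sq <- truth$unedited[[id]]
    n_reads <- n_fragments(config$coverage, nchar(sq), rl)
    for (r in seq_len(n_reads)) {
      nm <- sprintf("mrna|%s|stage=NA|%05d", id, r)
      mrna[[nm]] <- apply_errors(sample_fragment(sq, rl), err)
      push_origin(nm, "mrna", id, NA_integer_)
    }
  }
  ## decoy reads (full-domain, so editing-event proportions are exact)
  for (id in names(truth$decoys)) {
    dc <- truth$decoys[[id]]
    tab <- build_site_table(dc$seq, id = id)
    n_reads <- ceiling(config$coverage * nchar(dc$seq) / rl)
    for (r in seq_len(n_reads)) {
      u <- tab$site_ucount
      if (dc$mode == "noncognate") {
        u[dc$guided$site] <- dc$guided$guided_ucount
        n_g <- sum(dc$guided$guided_ucount !=
                     tab$site_ucount[dc$guided$site])
        f <- dc$guided_fraction
        n_r <- max(0L, round(n_g * (1 - f) / f))
        rz <- sample(dc$random_zone, min(n_r, length(dc$random_zone)))
        for (s in rz) {
          alt <- setdiff(0:3, tab$site_ucount[s])
          u[s] <- sample(alt, 1L)
        }
      } else {
        for (s in dc$random_zone) {
          if (stats::runif(1L) < dc$edit_prob) {
            alt <- setdiff(0:3, tab$site_ucount[s])
            u[s] <- sample(alt, 1L)
          }
        }
      }
      nm <- sprintf("mrna|%s|stage=NA|%05d", id, r)
      mrna[[nm]] <- apply_errors(rebuild_sequence(tab, u), err)
      push_origin(nm, "decoy", id, NA_integer_)
    }
  }

  ## (b) small-RNA paired reads of the gRNAs
  r1 <- character(0); r2 <- character(0)
  tl <- config$tail_len_distribution
  tlens <- as.integer(names(tl))
  for (gi in seq_len(nrow(truth$grnas))) {
    gseq <- truth$grnas$seq[gi]
    gid <- truth$grnas$grna_id[gi]
    # a tail of the same base as the gRNA 3' terminus would merge with
    # genomically encoded sequence; the tail base is chosen to differ so
    # that planted tails stay identifiable in the ground truth
    last <- substring(gseq, nchar(gseq), nchar(gseq))
    for (r in seq_len(config$small_rna_reads_per_grna)) {
      tlen <- if (length(tlens) == 1L) tlens else
        sample(tlens, 1L, prob = unname(tl))
      base <- if (last == "T") "A" else if (last == "A") "T" else
        if (stats::runif(1L) < config$tail_u_fraction) "T" else "A"
      insert <- paste0(gseq, strrep(base, tlen))
      a <- paste0(insert, config$adapter_seq)
      b <- paste0(revcomp(insert), config$adapter_seq)
      nm <- sprintf("srna|%s|%04d", gid, r)
      r1[[nm]] <- apply_errors(substring(a, 1L, rl), err)
      r2[[nm]] <- apply_errors(substring(b, 1L, rl), err)
      push_origin(nm, "srna", gid, NA_integer_)
    }
  }

  ## (c) kDNA fragments (circles sampled across the origin)
  kdna <- character(0)
  sources <- c(truth$minicircles, list(maxicircle = truth$maxicircle$seq))
  for (src in names(sources)) {
    sq <- sources[[src]]
    L <- nchar(sq)
    circular <- src != "maxicircle"
    n_reads <- ceiling(config$kdna_coverage * L / rl)
    ext <- if (circular) paste0(sq, substring(sq, 1L, rl)) else sq
    for (r in seq_len(n_reads)) {
      a <- sample.int(if (circular) L else max(1L, L - rl + 1L), 1L)
      nm <- sprintf("kdna|%s|%05d", src, r)
      kdna[[nm]] <- apply_errors(substring(ext, a, min(nchar(ext), a + rl - 1L)), err)
      push_origin(nm, "kdna", src, NA_integer_)
    }
  }

  out <- list(mrna = mrna, srna_r1 = r1, srna_r2 = r2, kdna = kdna,
              origins = do.call(rbind, origins))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(mrna, file.path(out_dir, "mrna_reads.fastq"))
    write_fastq(r1, file.path(out_dir, "srna_R1.fastq"))
    write_fastq(r2, file.path(out_dir, "srna_R2.fastq"))
    write_fastq(kdna, file.path(out_dir, "kdna_reads.fastq"))
  }
  out
}
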