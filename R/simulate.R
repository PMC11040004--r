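# Ground-truthed synthetic kinetoplast genome / transcriptome generator.
# The generator plants every structure the downstream analyses look for
# (CSB motifs, inverted repeats, gRNA genes with cascades, staged editing
# intermediates, tailed small-RNA reads) and records the planted state so
# that recovery can be tested exactly.

iupac_instance <- function(pattern) {
  sym <- strsplit(toupper(pattern), "")[[1L]]
  paste(vapply(sym, function(s) {
    set <- .IUPAC[[s]]
    set[sample.int(length(set), 1L)]
  }, ""), collapse = "")
}

# random CDS under code 4: ATG start, no internal TAA/TAG, terminal
# TAA/TAG.  `second_codon_gc` forces the second codon to start with G/C
# (used so that the 5' cascade boundary sits on a strong base).
random_cds <- function(ncod, second_codon_gc = FALSE) {
  all_cod <- names(Biostrings::getGeneticCode("4"))
  sense <- setdiff(all_cod, c("TAA", "TAG"))
  body <- sample(sense, ncod - 2L, replace = TRUE)
  if (second_codon_gc) {
    gc_start <- sense[substring(sense, 1L, 1L) %in% c("G", "C")]
    body[1L] <- sample(gc_start, 1L)
  }
  paste(c("ATG", body, sample(c("TAA", "TAG"), 1L)), collapse = "")
}

# overwrite `insert` into `s` at 0-based position `pos0`
replace_at <- function(s, pos0, insert) {
  paste0(substring(s, 1L, pos0), insert,
         substring(s, pos0 + nchar(insert) + 1L))
}

# pick edited sites 5'->3' with a cap on the clean stretch between
# consecutive edited runs (in edited-mRNA nt), so that no ungapped
# self-complementary window survives between pre-edited and edited
# states.  Returns site indices.
pick_edited_sites <- function(ucount_ed, eligible, fraction,
                              max_clean_nt = 16L) {
  if (fraction <= 0) return(integer(0))
  S <- length(ucount_ed)
  ed <- logical(S)
  gap <- 0L
  for (i in seq_len(S)) {
    gap <- gap + 1L + ucount_ed[i]
    if (i %in% eligible && (stats::runif(1L) < fraction || gap >= max_clean_nt)) {
      ed[i] <- TRUE
      gap <- 0L
    }
  }
  which(ed)
}

# 0-based edited-mRNA position of each backbone base
backbone_positions <- function(ucount) {
  nb <- length(ucount) - 1L
  cumsum(ucount[seq_len(nb)]) + seq_len(nb) - 1L
}

# Adaptive 3'->5' cascade tiling of [dstart, D): per step the remaining
# domain is re-planned, interval starts are nudged (<= 6 nt) onto G/C
# mRNA bases so that gRNA 3' termini are never T or A (keeps planted
# poly(U)/poly(A) tails separable), and the anchor overlap is respected.
tile_cascade <- function(mrna, n, dstart, ao, redundancy, len_range) {
  D <- nchar(mrna)
  chars <- strsplit(mrna, "")[[1L]]
  lo <- len_range[1L] + 6L
  hi <- len_range[2L] - 6L
  if (hi < lo) { lo <- len_range[1L]; hi <- len_range[2L] }
  shift_to_gc <- function(s) {
    for (d in 0:6) for (sg in c(1L, -1L)) {
      p <- s + d * sg
      if (p > dstart && p < D && chars[p + 1L] %in% c("G", "C")) return(p)
    }
    s
  }
  D0 <- D - dstart
  len0 <- max(ceiling((D0 + (n - 1L) * ao) / n),
              round(redundancy * D0 / n), lo)
  if (n == 1L) len0 <- D0
  if (len0 > (if (n == 1L) len_range[2L] else hi) || len0 < len_range[1L])
    stop("infeasible tiling: required gRNA length ", len0,
         " outside the usable range [", len_range[1L], ", ",
         if (n == 1L) len_range[2L] else hi, "]")
  e <- integer(n); s <- integer(n)
  cur_e <- D
  for (k in seq_len(n)) {
    rem_n <- n - k + 1L
    rem_D <- cur_e - dstart
    if (k == n) {
      len <- rem_D
      if (len < len_range[1L] || len > len_range[2L])
        stop("infeasible tiling: residual gRNA length ", len,
             " outside [", len_range[1L], ", ", len_range[2L], "]")
      s[k] <- dstart
    } else {
      s[k] <- shift_to_gc(cur_e - len0)
      len <- cur_e - s[k]
    }
    e[k] <- cur_e
    if (k < n) {
      # advance so the remaining intervals stay evenly spaced (the
      # re-derivation absorbs rounding and G/C-nudge drift); the anchor
      # overlap bounds the step from above
      step <- round((rem_D - len0) / (rem_n - 1L))
      step <- max(1L, min(step, len - ao))
      # keep at least the anchor overlap with the (possibly nudged)
      # interval start, and stay 3' of the next interval's start
      cur_e <- min(max(cur_e - step, s[k] + ao), cur_e - 1L)
    }
  }
  data.frame(order = seq_len(n), mrna_start = s, mrna_end = e)
}

#' Simulate a synthetic kinetoplast genome with ground truth
#'
#' Generates a maxicircle (unedited genes, pan-edited cryptogenes,
#' optional decoy cryptogenes and maxicircle gRNA loci), the edited and
#' pre-edited mRNA of every cryptogene, a 3'->5' gRNA cascade tiling
#' each edited mRNA, and the minicircle repertoire carrying the gRNA
#' genes together with CSB1/CSB3 blocks (two conserved regions,
#' head-to-tail at opposite poles), a GRAM motif near each gRNA gene and
#' an inverted repeat (both absent from the short minicircle class).
#' Planted gRNAs are exact Watson-Crick complements of their edited-mRNA
#' interval; identical-base guard columns flank each gene so that the
#' duplex of a planted gRNA with its mRNA ends exactly at the planted
#' boundaries.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes
#'   `maxicircle.fasta`, `minicircles.fasta`, `edited_mrnas.fasta`,
#'   `pre_mrnas.fasta`, `features.gff3` and `ground_truth.json`.
#' @return an object of class `ground_truth` (list): `config`,
#'   `maxicircle` (seq + gene table), `cryptogenes` (per cryptogene:
#'   edited/pre sequences, per-site U counts, edited sites),
#'   `minicircles` (sequences + feature table), `grnas` (gRNA table with
#'   cascade order, mRNA interval and source locus), `cascades` (ordered
#'   gRNA ids per cryptogene), `decoys` (planted decoy editing state).
#' @export
simulate_kdna <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  csb3_seq <- "GGGGTTGGTGTG"
  csb1_pattern <- "YYRYRYRRRRYYYYRYRYRR"
  csb1_seq <- iupac_instance(csb1_pattern)
  dstart <- 3L

  ## cryptogenes: edited CDS, edited sites, pre-edited genomic state
  n_cg <- config$n_cryptogenes
  cg_ids <- sprintf("CG%d", seq_len(n_cg))
  cryptogenes <- list()
  for (id in cg_ids) {
    for (try in 1:40) {
      edited_seq <- random_cds(config$cryptogene_len %/% 3L,
                               second_codon_gc = TRUE)
      tab <- build_site_table(edited_seq, id = id)
      S <- tab$n_sites
      eligible <- if (S >= 8L) 4L:(S - 3L) else integer(0)
      ed_sites <- pick_edited_sites(tab$site_ucount, eligible,
                                    config$edited_fraction_of_sites)
      u_ed <- tab$site_ucount
      u_pre <- u_ed
      for (s in ed_sites) {
        d <- sample(1:3, 1L)
        if (u_ed[s] >= 1L && stats::runif(1L) < 0.7)
          u_pre[s] <- max(0L, u_ed[s] - d)   # net U insertion during editing
        else
          u_pre[s] <- u_ed[s] + d            # net U deletion during editing
      }
      pre_seq <- rebuild_sequence(tab, u_pre)
      # the pre-edited locus must not pair with its own edited mRNA under
      # discovery settings, or the genomic copy would masquerade as a
      # gRNA locus; resample the editing pattern if it does
      if (length(ed_sites) == 0L ||
          nrow(align_duplex(revcomp(pre_seq), edited_seq,
                            duplex_params("canonical"))) == 0L)
        break
    }
    cryptogenes[[id]] <- list(id = id, edited_seq = edited_seq,
                              pre_seq = pre_seq, backbone = tab$backbone,
                              ucount_edited = u_ed, ucount_pre = u_pre,
                              edited_sites = ed_sites,
                              protein_len = config$cryptogene_len %/% 3L - 1L)
  }

  ## Rejection scanning: any random sequence placed on a genome could by
  ## chance form a passing duplex with an edited mRNA and masquerade as a
  ## gRNA locus; every built source is therefore screened with the
  ## discovery alignment settings and rebuilt until only planted loci
  ## remain, so that the planted repertoire is the complete repertoire.
  disc <- duplex_params("canonical")
  mrnas_vec <- stats::setNames(
    vapply(cryptogenes, `[[`, "", "edited_seq"), cg_ids)
  locus_keys <- function(seq) {
    g <- annotate_grna_genes(list(x = seq), mrnas_vec, params = disc)
    paste(g$start, g$end, g$strand)
  }

  ## unedited genes
  unedited <- list()
  if (config$n_unedited_genes > 0L)
    for (i in seq_len(config$n_unedited_genes)) {
      id <- sprintf("ND%d", i)
      for (try in 1:40) {
        cds <- random_cds(config$unedited_len %/% 3L)
        if (length(locus_keys(cds)) == 0L) break
      }
      unedited[[id]] <- cds
    }

  ## gRNA cascades
  capacity <- config$n_minicircles + config$n_two_grna_minicircles
  n_i <- pmax(1L, round(capacity * rep(1, n_cg) / n_cg))
  while (sum(n_i) > capacity) { j <- which.max(n_i); n_i[j] <- n_i[j] - 1L }
  while (sum(n_i) < capacity) { j <- which.min(n_i); n_i[j] <- n_i[j] + 1L }
  n_i[1L] <- n_i[1L] + config$n_maxicircle_grnas
  grna_rows <- list()
  cascades <- list()
  for (ci in seq_len(n_cg)) {
    id <- cg_ids[ci]
    mrna <- cryptogenes[[id]]$edited_seq
    tiles <- tile_cascade(mrna, n_i[ci], dstart, config$anchor_overlap,
                          config$redundancy, config$grna_len_range)
    gids <- sprintf("%s_g%02d", id, tiles$order)
    seqs <- vapply(seq_len(nrow(tiles)), function(k)
      revcomp(substring(mrna, tiles$mrna_start[k] + 1L, tiles$mrna_end[k])), "")
    grna_rows[[id]] <- data.frame(grna_id = gids, cryptogene_id = id,
                                  cascade_order = tiles$order,
                                  mrna_start = tiles$mrna_start,
                                  mrna_end = tiles$mrna_end,
                                  seq = seqs, stringsAsFactors = FALSE)
    cascades[[id]] <- gids
  }
  grnas <- do.call(rbind, grna_rows)
  rownames(grnas) <- NULL
  maxi_grna_ids <- if (config$n_maxicircle_grnas > 0L)
    grnas$grna_id[grnas$cryptogene_id == cg_ids[1L] &
                    grnas$cascade_order <= config$n_maxicircle_grnas]
  else character(0)
  mc_grna_ids <- setdiff(grnas$grna_id, maxi_grna_ids)

  ## decoy cryptogenes
  decoys <- list()
  if (length(config$decoys)) {
    donor_pool <- grnas[grnas$cascade_order > 1L, , drop = FALSE]
    for (di in seq_along(config$decoys)) {
      spec <- config$decoys[[di]]
      id <- sprintf("DECOY%d", di)
      mode <- spec$mode
      if (identical(mode, "noncognate")) {
        nw <- if (!is.null(spec$n_windows)) spec$n_windows else 4L
        picks <- donor_pool[sample.int(nrow(donor_pool), nw), , drop = FALSE]
        guided <- list(); offset <- 0L
        win_sites <- integer(0)   # all sites inside donor windows
        parts <- character(0)
        spacer0 <- random_dna(20L, config$gc)
        parts <- c(parts, spacer0)
        offset <- offset + sum(strsplit(spacer0, "")[[1L]] != "T")
        for (w in seq_len(nrow(picks))) {
          don <- cryptogenes[[picks$cryptogene_id[w]]]
          pos <- backbone_positions(don$ucount_edited)
          i1 <- which(pos >= picks$mrna_start[w] + 1L)[1L]
          i2 <- max(which(pos <= picks$mrna_end[w] - 2L))
          stopifnot(i2 > i1)
          # segment: donor backbone i1..i2 with pre-edited interior runs
          bb <- strsplit(don$backbone, "")[[1L]]
          seg_parts <- bb[i1]
          for (j in (i1 + 1L):i2)
            seg_parts <- c(seg_parts, strrep("T", don$ucount_pre[j]), bb[j])
          seg <- paste(seg_parts, collapse = "")
          gsites <- which(don$ucount_pre[(i1 + 1L):i2] !=
                            don$ucount_edited[(i1 + 1L):i2])
          guided[[w]] <- data.frame(
            site = offset + 1L + gsites,           # decoy 5'->3' site index
            guided_ucount = don$ucount_edited[i1 + gsites],
            donor_grna = picks$grna_id[w])
          win_sites <- c(win_sites, offset + seq_len(i2 - i1 + 2L))
          parts <- c(parts, seg)
          offset <- offset + (i2 - i1 + 1L)
          spacer <- random_dna(20L, config$gc)
          parts <- c(parts, spacer)
          offset <- offset + sum(strsplit(spacer, "")[[1L]] != "T")
        }
        seq <- paste(parts, collapse = "")
        gtab <- do.call(rbind, guided)
        tab <- build_site_table(seq, id = id)
        random_zone <- setdiff(3L:(tab$n_sites - 2L), win_sites)
        decoys[[id]] <- list(id = id, mode = mode, seq = seq,
                             guided = gtab, random_zone = random_zone,
                             guided_fraction =
                               if (!is.null(spec$guided_fraction))
                                 spec$guided_fraction else 0.8)
      } else {
        # a genuine cryptogene (pre-edited state carries no ORF) whose
        # reads will be edited at random -- no gRNA set is planted for it
        ecds <- random_cds(config$cryptogene_len %/% 3L)
        dtab <- build_site_table(ecds, id = id)
        Sd <- dtab$n_sites
        delig <- if (Sd >= 8L) 4L:(Sd - 3L) else integer(0)
        dsites <- pick_edited_sites(dtab$site_ucount, delig,
                                    config$edited_fraction_of_sites)
        du <- dtab$site_ucount
        for (s in dsites) {
          d <- sample(1:3, 1L)
          du[s] <- if (du[s] >= 1L && stats::runif(1L) < 0.7)
            max(0L, dtab$site_ucount[s] - d) else dtab$site_ucount[s] + d
        }
        seq <- rebuild_sequence(dtab, du)   # pre-edited reference
        tab <- build_site_table(seq, id = id)
        decoys[[id]] <- list(id = id, mode = "stochastic", seq = seq,
                             guided = NULL,
                             random_zone = 3L:(tab$n_sites - 2L),
                             edit_prob = if (!is.null(spec$edit_prob))
                               spec$edit_prob else 0.5)
      }
    }
  }

  ## maxicircle assembly (retried until free of chance gRNA-like loci)
  for (maxi_try in 1:40) {
  segs <- list()
  gene_rows <- list()
  cursor <- 0L
  add_spacer <- function(n = 150L) {
    sp <- random_dna(n, config$gc)
    segs[[length(segs) + 1L]] <<- sp
    cursor <<- cursor + n
  }
  add_gene <- function(id, seq, type) {
    segs[[length(segs) + 1L]] <<- seq
    gene_rows[[length(gene_rows) + 1L]] <<-
      data.frame(id = id, start = cursor, end = cursor + nchar(seq),
                 strand = "+", type = type)
    cursor <<- cursor + nchar(seq)
  }
  add_spacer()
  for (id in names(unedited)) { add_gene(id, unedited[[id]], "gene"); add_spacer() }
  for (id in cg_ids) { add_gene(id, cryptogenes[[id]]$pre_seq, "cryptogene"); add_spacer() }
  for (id in names(decoys)) {
    add_gene(id, decoys[[id]]$seq,
             paste0("decoy_", decoys[[id]]$mode))
    add_spacer()
  }
  ## maxicircle gRNA loci (minus strand, with guard columns)
  maxi_grna_loci <- list()
  for (gid in maxi_grna_ids) {
    gr <- grnas[grnas$grna_id == gid, ]
    don <- cryptogenes[[gr$cryptogene_id]]
    ins <- gene_insert_with_guards(don$edited_seq, gr$mrna_start, gr$mrna_end)
    add_spacer(60L)
    st <- cursor
    segs[[length(segs) + 1L]] <- ins$insert
    cursor <- cursor + nchar(ins$insert)
    maxi_grna_loci[[gid]] <- data.frame(grna_id = gid, source_id = "maxicircle",
                                        start = st + ins$lead,
                                        end = st + ins$lead + (gr$mrna_end - gr$mrna_start),
                                        strand = "-")
    add_spacer(60L)
  }
  add_spacer()
  maxicircle_seq <- paste(unlist(segs), collapse = "")
  gene_tab <- do.call(rbind, gene_rows)
  planted_keys <- if (length(maxi_grna_loci))
    vapply(maxi_grna_loci, function(x)
      paste(x$start, x$end, x$strand), "") else character(0)
  found <- locus_keys(maxicircle_seq)
  extra <- setdiff(found, planted_keys)
  # loci inside decoy regions are expected (their windows mirror donor
  # cryptogenes) and tolerated
  if (length(config$decoys) && length(extra)) {
    dec <- gene_tab[grepl("^decoy", gene_tab$type), , drop = FALSE]
    in_decoy <- vapply(extra, function(k) {
      st <- as.integer(strsplit(k, " ")[[1L]][1L])
      any(st >= dec$start - 30L & st < dec$end + 30L)
    }, TRUE)
    extra <- extra[!in_decoy]
  }
  if (!length(extra) && all(planted_keys %in% found)) break
  }

  ## minicircles
  n_mc <- config$n_minicircles
  mc_ids <- sprintf("mc%02d", seq_len(n_mc))
  small_idx <- if (config$n_small_minicircles > 0L)
    unique(pmin(34L, n_mc) + seq_len(config$n_small_minicircles) - 1L)
  else integer(0)
  small_idx <- small_idx[small_idx <= n_mc]
  two_idx <- if (config$n_two_grna_minicircles > 0L) {
    cand <- setdiff(seq_len(n_mc), small_idx)
    cand[pmin(length(cand), 14L) - seq_len(config$n_two_grna_minicircles) + 1L]
  } else integer(0)
  counts <- 1L + as.integer(seq_len(n_mc) %in% two_idx)
  stopifnot(sum(counts) == length(mc_grna_ids))
  dealt <- sample(mc_grna_ids)
  assign_list <- split(dealt, rep(seq_len(n_mc), counts))
  minicircles <- list()
  mc_features <- list()
  source_rows <- list(do.call(rbind, maxi_grna_loci))
  for (mi in seq_len(n_mc)) {
    mc <- mc_ids[mi]
    small <- mi %in% small_idx
    L <- if (small) config$small_minicircle_len
         else sample(config$minicircle_len_range[1L]:config$minicircle_len_range[2L], 1L)
    gids <- assign_list[[as.character(mi)]]
    build <- build_minicircle(L, gids, grnas, cryptogenes, config, csb1_seq,
                              csb3_seq, small, locus_keys)
    minicircles[[mc]] <- build$seq
    ft <- build$features
    ft$seqid <- mc
    mc_features[[mc]] <- ft
    g <- build$genes
    g$source_id <- mc
    source_rows[[length(source_rows) + 1L]] <- g
  }
  grna_loci <- do.call(rbind, source_rows)
  rownames(grna_loci) <- NULL
  grnas <- merge(grnas, grna_loci, by = "grna_id", sort = FALSE)
  grnas <- grnas[order(grnas$cryptogene_id, grnas$cascade_order), ]
  rownames(grnas) <- NULL

  truth <- structure(list(config = config,
                          maxicircle = list(seq = maxicircle_seq, genes = gene_tab),
                          cryptogenes = cryptogenes,
                          unedited = unedited,
                          minicircles = minicircles,
                          minicircle_features = do.call(rbind, mc_features),
                          grnas = grnas, cascades = cascades,
                          decoys = decoys,
                          csb1_seq = csb1_seq, csb3_seq = csb3_seq),
                     class = "ground_truth")
  if (!is.null(out_dir)) write_truth(truth, out_dir)
  truth
}

# Forward-strand insert for a minus-strand gRNA gene: the mRNA segment
# itself, flanked by 3 identical-base guard columns per side (forcing
# duplex mismatches so the planted duplex ends exactly at the gene).
gene_insert_with_guards <- function(mrna, s, e) {
  D <- nchar(mrna)
  left <- character(0); right <- character(0)
  for (j in 1:3) {
    if (s - j >= 0L)
      left <- c(complement(substring(mrna, s - j + 1L, s - j + 1L)), left)
    if (e + j <= D)
      right <- c(right, complement(substring(mrna, e + j, e + j)))
  }
  list(insert = paste0(paste(left, collapse = ""),
                       substring(mrna, s + 1L, e),
                       paste(right, collapse = "")),
       lead = length(left))
}

build_minicircle <- function(L, gids, grnas, cryptogenes, config,
                             csb1_seq, csb3_seq, small,
                             locus_keys = NULL) {
  half <- L %/% 2L
  gram_rc <- revcomp(config$gram_seq)
  for (try in 1:40) {
    s <- random_dna(L, config$gc)
    feats <- list(); genes <- list()
    put <- function(pos, insert, type, strand = "+") {
      s <<- replace_at(s, pos, insert)
      feats[[length(feats) + 1L]] <<-
        data.frame(seqid = NA_character_, type = type, start = pos,
                   end = pos + nchar(insert), strand = strand)
    }
    put(10L, csb1_seq, "CSB1")
    put(10L + nchar(csb1_seq) + 8L, csb3_seq, "CSB3")
    put(half, csb1_seq, "CSB1")
    put(half + nchar(csb1_seq) + 8L, csb3_seq, "CSB3")
    gpos <- c(120L, half + 120L)
    for (k in seq_along(gids)) {
      gr <- grnas[grnas$grna_id == gids[k], ]
      mrna <- cryptogenes[[gr$cryptogene_id]]$edited_seq
      ins <- gene_insert_with_guards(mrna, gr$mrna_start, gr$mrna_end)
      pos <- gpos[k]
      s <- replace_at(s, pos, ins$insert)
      gs <- pos + ins$lead
      ge <- gs + (gr$mrna_end - gr$mrna_start)
      genes[[k]] <- data.frame(grna_id = gids[k], start = gs, end = ge,
                               strand = "-")
      feats[[length(feats) + 1L]] <-
        data.frame(seqid = NA_character_, type = "gRNA_gene", start = gs,
                   end = ge, strand = "-")
      if (!small)
        put(ge + 15L, gram_rc, "GRAM", strand = "-")
    }
    if (!small) {
      arm <- random_dna(15L, 0.5)
      ir_pos <- L - 250L
      put(ir_pos, paste0(arm, random_dna(40L, config$gc), revcomp(arm)),
          "inverted_repeat")
    }
    ## rejection: spurious CSB matches in random backbone force a rebuild
    ## (matches falling inside planted fixed content are tolerated)
    h3 <- scan_motif(s, csb3_seq, both_strands = TRUE, circular = TRUE)
    h1 <- scan_motif(s, "YYRYRYRRRRYYYYRYRYRR", both_strands = TRUE,
                     circular = TRUE)
    exp3 <- c(10L + nchar(csb1_seq) + 8L, half + nchar(csb1_seq) + 8L)
    exp1 <- c(10L, half)
    ftab <- do.call(rbind, feats)
    in_planted <- function(p)
      any(p >= ftab$start - 20L & p < ftab$end)
    spur <- c(setdiff(unique(h3$start), exp3), setdiff(unique(h1$start), exp1))
    if (length(spur) && !all(vapply(spur, in_planted, TRUE))) next
    ## no chance duplex loci beyond the planted genes
    if (!is.null(locus_keys)) {
      gtab <- do.call(rbind, genes)
      if (!setequal(locus_keys(s),
                    paste(gtab$start, gtab$end, gtab$strand))) next
    }
    return(list(seq = s, features = ftab,
                genes = do.call(rbind, genes)))
  }
  stop("could not build a minicircle without spurious CSB matches")
}

write_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(truth$maxicircle$seq, "maxicircle"),
              file.path(out_dir, "maxicircle.fasta"))
  write_fasta(unlist(truth$minicircles),
              file.path(out_dir, "minicircles.fasta"))
  write_fasta(vapply(truth$cryptogenes, `[[`, "", "edited_seq"),
              file.path(out_dir, "edited_mrnas.fasta"))
  write_fasta(vapply(truth$cryptogenes, `[[`, "", "pre_seq"),
              file.path(out_dir, "pre_mrnas.fasta"))
  mf <- truth$minicircle_features
  gx <- truth$maxicircle$genes
  feats <- rbind(
    data.frame(seqid = mf$seqid, source = "kedit_sim", type = mf$type,
               start = mf$start + 1L, end = mf$end, score = NA,
               strand = mf$strand,
               attributes = paste0("ID=", mf$seqid, ":", mf$type, ":", mf$start)),
    data.frame(seqid = "maxicircle", source = "kedit_sim", type = gx$type,
               start = gx$start + 1L, end = gx$end, score = NA,
               strand = gx$strand, attributes = paste0("ID=", gx$id)))
  write_gff3(feats, file.path(out_dir, "features.gff3"))
  tr <- truth
  tr$config <- unclass(tr$config)
  tr$minicircle_features <- NULL
  jsonlite::write_json(
    list(config = tr$config,
         grnas = truth$grnas,
         cascades = truth$cascades,
         maxicircle_genes = truth$maxicircle$genes),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic kDNA ground truth (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  maxicircle %d bp: %d loci; %d minicircle classes; %d gRNAs\n",
              nchar(x$maxicircle$seq), nrow(x$maxicircle$genes),
              length(x$minicircles), nrow(x$grnas)))
  cat(sprintf("  cryptogenes: %s\n",
              paste(names(x$cryptogenes), collapse = ", ")))
  invisible(x)
}
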