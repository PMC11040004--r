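# Codon-level analyses under the protistan mitochondrial genetic code
# (translation table 4): codon incidence, stop-codon usage, read-through
# codon usage, and amino-terminal mitochondrial targeting-signal scans.

.CODE4 <- NULL
code4_table <- function() {
  if (is.null(.CODE4)) {
    tab <- Biostrings::getGeneticCode("4")
    utils::assignInMyNamespace(".CODE4", tab)
  }
  .CODE4
}

codons_of <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Codon incidence across a CDS set
#'
#' Counts codons of each coding sequence under translation table 4 and
#' reports, per amino acid, the synonymous incidence of each codon
#' (codon count / total count of codons for that amino acid, pooled
#' across the set).  Terminal stop codons are tallied separately; UGA is
#' tryptophan, never a stop.  An alternative per-1000-codons
#' normalisation is available since "incidence" can also be read as
#' overall frequency.
#'
#' @param cds named character vector of CDS sequences (each a multiple
#'   of 3, with terminal stop codon).
#' @param mode `"synonymous"` (within-amino-acid fraction, default) or
#'   `"per1000"` (codons per 1000 codons).
#' @return an object of class `codon_table`: data frame `codon`, `aa`,
#'   `count`, `incidence`; attributes `per_gene` (codon x gene count
#'   matrix) and `stop_codons` (named character vector per gene).
#' @export
codon_incidence <- function(cds, mode = c("synonymous", "per1000")) {
  mode <- match.arg(mode)
  if (is.null(names(cds))) names(cds) <- paste0("gene", seq_along(cds))
  code <- code4_table()
  all_codons <- names(code)
  per_gene <- matrix(0L, nrow = length(all_codons), ncol = length(cds),
                     dimnames = list(all_codons, names(cds)))
  stops <- stats::setNames(character(length(cds)), names(cds))
  for (g in names(cds)) {
    s <- toupper(chartr("U", "T", cds[[g]]))
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of ", g, " is not a multiple of 3")
    cod <- codons_of(s)
    aa <- code[cod]
    internal <- head(aa, -1L)
    if (any(internal == "*", na.rm = TRUE))
      stop("internal stop codon in ", g, " at codon ",
           which(internal == "*")[1L])
    stops[g] <- tail(cod, 1L)
    body <- head(cod, -1L)
    t <- table(factor(body, levels = all_codons))
    per_gene[, g] <- as.integer(t)
  }
  count <- rowSums(per_gene)
  aa <- unname(code[all_codons])
  keep <- aa != "*"
  df <- data.frame(codon = all_codons[keep], aa = aa[keep],
                   count = as.integer(count[keep]))
  if (mode == "synonymous") {
    syn_tot <- tapply(df$count, df$aa, sum)[df$aa]
    df$incidence <- ifelse(syn_tot > 0, df$count / syn_tot, NA_real_)
  } else {
    df$incidence <- 1000 * df$count / sum(df$count)
  }
  attr(df, "per_gene") <- per_gene
  attr(df, "stop_codons") <- stops
  attr(df, "mode") <- mode
  class(df) <- c("codon_table", "data.frame")
  df
}

#' Stop-codon usage of a CDS set
#'
#' Tallies terminal UAA versus UAG stop codons under translation table 4.
#' A CDS ending in UGA (tryptophan under code 4) or any other sense codon
#' has no terminal stop and is flagged.
#'
#' @param cds named character vector of CDS sequences.
#' @return list with `UAA`, `UAG` (counts), `flagged` (gene names whose
#'   final codon is not a stop).
#' @export
stop_usage <- function(cds) {
  if (is.null(names(cds))) names(cds) <- paste0("gene", seq_along(cds))
  term <- vapply(cds, function(s) {
    s <- toupper(chartr("U", "T", s))
    substring(s, nchar(s) - 2L, nchar(s))
  }, "")
  list(UAA = sum(term == "TAA"), UAG = sum(term == "TAG"),
       flagged = names(cds)[!term %in% c("TAA", "TAG")])
}

#' Read-through (recoded) codon usage comparison
#'
#' For nuclear gene sets in which in-frame TAA/TAG are read as glutamate
#' and TGA as tryptophan, compares the per-gene proportion of recoded
#' codons against their likely evolutionary predecessor codons
#' (TAA/TAG vs GAA/GAG; TGA vs TGG):
#' `p = recoded / (recoded + predecessor)`.  Group differences are
#' assessed per codon with a two-sided rank-sum test across genes.
#'
#' @param cds named character vector of CDS sequences (internal stops are
#'   expected here -- they are the recoded codons).
#' @param groups factor/character vector (one label per CDS) defining the
#'   two groups to compare.
#' @return list with `per_gene` (data frame: gene, group, counts and
#'   proportions per recoded codon) and `tests` (data frame: codon,
#'   group medians, rank-sum statistic, p-value); `tests` is `NULL` when
#'   `groups` has fewer than two levels.
#' @export
readthrough_usage <- function(cds, groups = NULL) {
  if (!length(cds)) stop("empty CDS set")
  if (is.null(names(cds))) names(cds) <- paste0("gene", seq_along(cds))
  if (is.null(groups)) groups <- rep("all", length(cds))
  groups <- as.character(groups)
  recoded <- list(TAA = c("GAA", "GAG"), TAG = c("GAA", "GAG"),
                  TGA = "TGG")
  rows <- lapply(seq_along(cds), function(i) {
    s <- toupper(chartr("U", "T", cds[[i]]))
    cod <- codons_of(s)
    cod <- head(cod, -1L)   # exclude the terminal (true) stop
    out <- data.frame(gene = names(cds)[i], group = groups[i])
    for (rc in names(recoded)) {
      nr <- sum(cod == rc)
      np <- sum(cod %in% recoded[[rc]])
      out[[paste0("n_", rc)]] <- nr
      out[[paste0("p_", rc)]] <- if (nr + np > 0) nr / (nr + np) else 0
    }
    out
  })
  per_gene <- do.call(rbind, rows)
  tests <- NULL
  lv <- unique(groups)
  if (length(lv) >= 2L) {
    if (length(lv) > 2L) warning("more than two groups; first two compared")
    a <- per_gene[per_gene$group == lv[1L], ]
    b <- per_gene[per_gene$group == lv[2L], ]
    if (!nrow(a) || !nrow(b)) stop("empty group")
    tests <- do.call(rbind, lapply(names(recoded), function(rc) {
      pa <- a[[paste0("p_", rc)]]; pb <- b[[paste0("p_", rc)]]
      wt <- suppressWarnings(stats::wilcox.test(pa, pb))
      data.frame(codon = rc, median_a = stats::median(pa),
                 median_b = stats::median(pb),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
    }))
  }
  list(per_gene = per_gene, tests = tests)
}

#' Scan proteins for an amino-terminal mitochondrial targeting signal
#'
#' Matches the anchored pattern `M - [RHKFL] - x(0,1) - [RKHST] -
#' x(1,10) - [STRK]` at the amino terminus: an initiator methionine,
#' a basic/bulky residue, an optional spacer, a basic/hydroxylated
#' residue, a 1-10 residue spacer and a final hydroxylated/basic
#' residue.  The shortest match (minimal total length; ties towards the
#' shorter first spacer) is reported per protein.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return data frame of class `signal_hits`: `protein_id`, `start`
#'   (always 0), `end` (0-based half-open), `matched` (the matching
#'   prefix).  Proteins without a match are absent.
#' @export
targeting_scan <- function(proteins) {
  if (is.null(names(proteins))) names(proteins) <- paste0("prot", seq_along(proteins))
  set2 <- c("R", "H", "K", "F", "L")
  set4 <- c("R", "K", "H", "S", "T")
  set6 <- c("S", "T", "R", "K")
  hits <- list()
  for (id in names(proteins)) {
    ch <- strsplit(toupper(proteins[[id]]), "")[[1L]]
    if (length(ch) < 4L || ch[1L] != "M" || !(ch[2L] %in% set2)) next
    best <- NULL
    combos <- expand.grid(s1 = 0:1, s2 = 1:10)
    combos <- combos[order(combos$s1 + combos$s2, combos$s1), ]
    for (r in seq_len(nrow(combos))) {
      s1 <- combos$s1[r]; s2 <- combos$s2[r]
      p4 <- 3L + s1          # position of the [RKHST] residue
      p6 <- p4 + s2 + 1L     # position of the final [STRK] residue
      if (p6 > length(ch)) next
      if (ch[p4] %in% set4 && ch[p6] %in% set6) {
        best <- p6
        break
      }
    }
    if (!is.null(best))
      hits[[id]] <- data.frame(protein_id = id, start = 0L, end = best,
                               matched = paste(ch[seq_len(best)], collapse = ""))
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(), start = integer(),
               end = integer(), matched = character())
  rownames(out) <- NULL
  class(out) <- c("signal_hits", "data.frame")
  out
}
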