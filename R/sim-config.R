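#' Simulation configuration for synthetic kinetoplast data
#'
#' Defines the study conditions emulated by the generator: a maxicircle
#' carrying unedited genes and pan-edited cryptogenes, a repertoire of
#' minicircle classes (41 by default, one short 601-bp class, one class
#' carrying two gRNA genes, the rest 1920-2019 bp with one gRNA gene
#' each, i.e. 42 minicircle gRNA genes), gRNA cascades tiling each
#' edited mRNA 3'->5' with a configurable anchor overlap and coverage
#' redundancy, staged editing intermediates in the mRNA reads, and
#' small-RNA reads of the gRNAs with 3' poly(U)/poly(A) tails and
#' sequencing adapters.
#'
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @param n_minicircles number of minicircle classes (default 41,
#'   including the short class).
#' @param minicircle_len_range length range in bp of the main size group
#'   (default 1920-2019).
#' @param n_small_minicircles number of short classes (default 1).
#' @param small_minicircle_len length of the short class (default 601).
#' @param n_two_grna_minicircles classes carrying two gRNA genes
#'   (default 1, so 41 classes carry 42 genes).
#' @param n_cryptogenes pan-edited cryptogenes (default 3).
#' @param cryptogene_len edited CDS length in nt, multiple of 3
#'   (default 480).
#' @param n_unedited_genes never-edited genes on the maxicircle
#'   (default 2).
#' @param unedited_len their CDS length (default 300).
#' @param edited_fraction_of_sites fraction of editing sites carrying a
#'   U-indel difference between pre-edited and edited states
#'   (default 0.35).
#' @param grna_len_range admissible gRNA gene length range in nt
#'   (default 30-55).
#' @param anchor_overlap minimum anchor overlap between successive
#'   cascade gRNAs in nt (default 4).
#' @param redundancy target mean number of gRNAs covering an edited
#'   position (default 1; the tiling always keeps at least the anchor
#'   overlap).
#' @param n_maxicircle_grnas cascade gRNAs encoded on the maxicircle
#'   instead of a minicircle (default 0; they take the 3'-most positions
#'   of the first cryptogene's cascade).
#' @param read_len mRNA/kDNA read length in nt (default 100).
#' @param coverage mean reads per base for the mRNA library (default 30).
#' @param editing_stage_distribution probabilities of a read deriving
#'   from the pre-edited transcript, an intermediate, or the fully
#'   edited mRNA (named numeric `pre`/`intermediate`/`full`; mass on
#'   `intermediate` is spread uniformly over the breakpoints).  The
#'   default (0.05/0.10/0.85) reflects a poly(A)-selected library
#'   dominated by mature, fully edited mRNAs with intermediates present
#'   at low abundance.
#' @param small_rna_reads_per_grna reads per gRNA in the small-RNA
#'   library (default 30).
#' @param tail_len_distribution named probability vector over 3' tail
#'   lengths for small-RNA reads (names are lengths; default uniform
#'   over 3-8 nt).
#' @param tail_u_fraction probability that a tail is poly(U) rather than
#'   poly(A) (default 0.7).
#' @param adapter_seq sequencing adapter appended 3' of small-RNA
#'   inserts.
#' @param error_rate per-base substitution probability (default 0;
#'   sequencing noise is substitution-only so that U-indel ground truth
#'   stays unambiguous).
#' @param gc GC content of random backbone sequence (default 0.35,
#'   AT-rich as in kinetoplast DNA).
#' @param kdna_coverage coverage of the kDNA fragment library
#'   (default 2).
#' @param gram_seq the 12-nt gRNA-associated motif planted near each
#'   gRNA gene (configurable pattern; absent from the short class).
#' @param decoys list of decoy cryptogene specifications, each a list
#'   with `mode` (`"stochastic"` for random U-indels or `"noncognate"`
#'   for editing guided by gRNAs of other transcripts),
#'   `guided_fraction` (non-cognate mode: fraction of edited sites that
#'   follow a donor gRNA; default 0.8), `n_windows` (donor windows;
#'   default 4) and `edit_prob` (stochastic mode per-site edit
#'   probability; default 0.5).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_minicircles = 41L,
                       minicircle_len_range = c(1920L, 2019L),
                       n_small_minicircles = 1L,
                       small_minicircle_len = 601L,
                       n_two_grna_minicircles = 1L,
                       n_cryptogenes = 3L,
                       cryptogene_len = 480L,
                       n_unedited_genes = 2L,
                       unedited_len = 300L,
                       edited_fraction_of_sites = 0.35,
                       grna_len_range = c(30L, 55L),
                       anchor_overlap = 4L,
                       redundancy = 1,
                       n_maxicircle_grnas = 0L,
                       read_len = 100L,
                       coverage = 30,
                       editing_stage_distribution =
                         c(pre = 0.05, intermediate = 0.10, full = 0.85),
                       small_rna_reads_per_grna = 30L,
                       tail_len_distribution =
                         stats::setNames(rep(1 / 6, 6), 3:8),
                       tail_u_fraction = 0.7,
                       adapter_seq = "AGATCGGAAGAGC",
                       error_rate = 0,
                       gc = 0.35,
                       kdna_coverage = 2,
                       gram_seq = "ATAGGGCAGTTA",
                       decoys = list()) {
  cfg <- as.list(environment())
  counts <- c("n_minicircles", "n_small_minicircles", "n_two_grna_minicircles",
              "n_cryptogenes", "n_unedited_genes", "n_maxicircle_grnas",
              "small_rna_reads_per_grna")
  for (nm in counts)
    if (cfg[[nm]] < 0L) stop(nm, " must be non-negative")
  if (any(minicircle_len_range <= 0L) || small_minicircle_len <= 0L)
    stop("minicircle lengths must be positive")
  if (cryptogene_len %% 3L != 0L) stop("cryptogene_len must be a multiple of 3")
  if (unedited_len %% 3L != 0L) stop("unedited_len must be a multiple of 3")
  if (edited_fraction_of_sites < 0 || edited_fraction_of_sites > 1)
    stop("edited_fraction_of_sites must be in [0, 1]")
  if (abs(sum(editing_stage_distribution) - 1) > 1e-8)
    stop("editing_stage_distribution must sum to 1")
  if (abs(sum(tail_len_distribution) - 1) > 1e-8)
    stop("tail_len_distribution must sum to 1")
  if (n_small_minicircles + n_two_grna_minicircles > n_minicircles)
    stop("more special minicircle classes than minicircles")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_genes <- x$n_minicircles + x$n_two_grna_minicircles
  cat("Synthetic kDNA configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d minicircle classes (%d short, %d with two gRNA genes): %d minicircle gRNA genes\n",
              x$n_minicircles, x$n_small_minicircles,
              x$n_two_grna_minicircles, n_genes))
  cat(sprintf("  %d pan-edited cryptogenes (%d nt edited CDS), %d unedited genes, %d decoy(s)\n",
              x$n_cryptogenes, x$cryptogene_len, x$n_unedited_genes,
              length(x$decoys)))
  cat(sprintf("  editing: %.0f%% of sites; reads %d nt at %.0fx; error rate %g\n",
              100 * x$edited_fraction_of_sites, x$read_len, x$coverage,
              x$error_rate))
  invisible(x)
}
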