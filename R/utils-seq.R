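# Internal sequence helpers.  Sequences are plain uppercase character
# scalars in the DNA alphabet (A, C, G, T, N); U is accepted on input and
# normalised to T.  Biostrings handles file IO and translation; these
# helpers keep hot paths on simple vectors.

.BASES <- c("A", "C", "G", "T")

# integer coding A=0 C=1 G=2 T/U=3, anything else -1
seq_to_int <- function(x) {
  stopifnot(length(x) == 1L)
  v <- utf8ToInt(toupper(chartr("U", "T", x)))
  code <- rep(-1L, 128L)
  code[utf8ToInt("A") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L
  code[utf8ToInt("T") + 1L] <- 3L
  code[v + 1L]
}

int_to_seq <- function(v) {
  out <- rep("N", length(v))
  ok <- v >= 0L & v <= 3L
  out[ok] <- .BASES[v[ok] + 1L]
  paste(out, collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTUacgtu", "TGCAAtgcaa", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE))
}

complement <- function(x) chartr("ACGTUacgtu", "TGCAAtgcaa", x)

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

substr1 <- function(x, start, end) substring(x, start, end)

# rotate a circular sequence so 1-based position `pos` becomes position 1
rotate_seq <- function(x, pos) {
  n <- nchar(x)
  pos <- ((pos - 1L) %% n) + 1L
  if (pos == 1L) return(x)
  paste0(substring(x, pos, n), substring(x, 1L, pos - 1L))
}

#' Read and write sequence files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that move between named character
#' vectors (the package's working representation) and FASTA/FASTQ files.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @param qualities optional named character vector of Phred+33 quality
#'   strings (FASTQ only); defaults to constant "I" (Q40).
#' @return `read_fasta` and `read_fastq` return a named character vector;
#'   `read_fastq` carries a `qualities` attribute.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- stats::setNames(toupper(as.character(x)), names(x))
  q <- S4Vectors::mcols(x)$qualities
  attr(out, "qualities") <- stats::setNames(as.character(q), names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(x, path, qualities = NULL) {
  if (is.null(qualities)) qualities <- attr(x, "qualities")
  if (is.null(qualities))
    qualities <- vapply(x, function(s) strrep("I", nchar(s)), character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x))
    writeLines(paste0("@", names(x), "\n", unname(x), "\n+\n", unname(qualities)), con)
  invisible(path)
}

# Minimal GFF3 writer: `features` is a data.frame with columns
# seqid, source, type, start, end (1-based closed), score, strand, attributes.
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    sc <- ifelse(is.na(features$score), ".", as.character(features$score))
    writeLines(paste(features$seqid, features$source, features$type,
                     features$start, features$end, sc, features$strand,
                     ".", features$attributes, sep = "\t"), con)
  }
  invisible(path)
}

read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln))
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      attributes = character()))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  data.frame(seqid = f[, 1], source = f[, 2], type = f[, 3],
             start = as.integer(f[, 4]), end = as.integer(f[, 5]),
             score = f[, 6], strand = f[, 7], attributes = f[, 9])
}

gff_attr <- function(attributes, key) {
  m <- regexpr(paste0("(?:^|;)", key, "=[^;]*"), attributes, perl = TRUE)
  out <- rep(NA_character_, length(attributes))
  hit <- m != -1L
  out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(attributes, m))
  out
}
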