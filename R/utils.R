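#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' A single pipeline seed is fanned out to the stochastic stages so that
#' re-running a stage in isolation reproduces its in-pipeline behaviour.
#'
#' @param seed integer master seed
#' @param name stage name (character scalar)
#' @return an integer seed in \[1, 2^31 - 2\]
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#' @param x character vector of sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  r <- .revcomp_cpp(as.character(x))
  names(r) <- names(x)
  r
}

# Coerce reads (DNAStringSet / named character) to a named character vector.
# Named character vectors pass through untouched (case is normalized at the
# file-reading boundary).
as_read_set <- function(reads) {
  if (is.character(reads) && (!length(reads) || !is.null(names(reads))))
    return(reads)
  if (methods::is(reads, "XStringSet")) {
    x <- toupper(as.character(reads))
    names(x) <- names(reads)
  } else {
    x <- toupper(as.character(reads))
    names(x) <- names(reads)
  }
  if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
    stop("reads must carry unique names")
  x
}

#' Read sequences from FASTA or FASTQ
#' @param path file path
#' @return named character vector of sequences
#' @export
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  names(x) <- sub("\\s.*$", "", names(x))
  as_read_set(x)
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @return invisibly, the path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write sequences to FASTQ with a flat quality
#' @param seqs named character vector
#' @param path output path
#' @param q flat Phred quality character (default "I")
#' @return invisibly, the path
#' @export
write_fastq <- function(seqs, path, q = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep(q, n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

# ops utilities ---------------------------------------------------------

# Split an ops string ("MMXID...") into a character vector of single ops.
ops_chars <- function(ops) strsplit(ops, "", fixed = TRUE)[[1]]

#' Alignment accuracy from base-level operations
#'
#' Accuracy is matches / (matches + mismatches + insertions + deletions),
#' i.e. matches over all alignment columns.
#'
#' @param ops character scalar of operations over \{M, X, I, D\}
#' @return numeric accuracy in \[0, 1\]
#' @export
ops_accuracy <- function(ops) {
  v <- ops_chars(ops)
  sum(v == "M") / length(v)
}

# Banded global alignment wrapper with adaptive banding: a narrow band
# first (indel drift scales like sqrt of the divergence), widened when the
# alignment fails or looks implausibly divergent.
align_global <- function(query, target, max_div = 0.3, free_ends = FALSE,
                         free_query = FALSE) {
  n <- nchar(query); m <- nchar(target)
  # indel drift grows like the square root of the aligned length; the
  # band is capped so the DP matrix stays within a fixed cell budget
  cap <- max(128L, as.integer(1e8 / max(n, 1L)))
  band <- min(cap,
              max(64L, as.integer(abs(n - m) + 4 * sqrt(max(n, m)) + 32)))
  r <- .band_align_cpp(query, target, band, free_ends, free_query)
  if (!r$ok || (!is.na(r$identity) && r$identity < 1 - max_div * 1.2)) {
    wide <- min(cap, as.integer(abs(n - m) + max(n, m) * 0.5 + 50))
    if (wide > band) {
      r2 <- .band_align_cpp(query, target, wide, free_ends, free_query)
      if (r2$ok && (!r$ok || r2$distance <= r$distance)) r <- r2
    }
  }
  r
}
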