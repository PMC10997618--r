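# Synthetic diploid genomes and long noisy reads with truth labels.
# Coordinates are 0-based half-open throughout; heterozygous-site
# coordinates are on haplotype 1.

#' Parameters for the diploid read simulator
#'
#' Defaults emulate a small diploid genome sequenced with long noisy reads:
#' 1\% SNP heterozygosity (the benchmark species span 0.34\%--1.48\%) and a
#' 10\% per-base error rate (long noisy reads carry 5--15\% errors).
#'
#' @param genome_length haplotype length in bases (>= 1000)
#' @param het_rate heterozygous variants per base, in \[0, 0.05\]
#' @param indel_het_fraction fraction of heterozygous variants that are
#'   1--50 bp indels (default 0: SNP-only phasing is modelled downstream)
#' @param depth_per_haplotype fold coverage per haplotype
#' @param read_length_mean,read_length_sd read length model (truncated
#'   normal, minimum 500 bp)
#' @param error_rate per-base error rate in \[0, 0.25\]
#' @param error_mix length-3 proportions (substitution, insertion, deletion)
#' @param repeat_spec optional list of c(length, copies, divergence) vectors
#'   describing near-identical repeats inserted into both haplotypes
#' @param homopolymer_bias if TRUE, indel errors are enriched inside
#'   homopolymer runs (off by default)
#' @param seed integer seed; fixed seed gives byte-identical output
#' @return an object of class \code{sim_params}
#' @export
sim_params <- function(genome_length = 50000, het_rate = 0.01,
                       indel_het_fraction = 0, depth_per_haplotype = 40,
                       read_length_mean = 4000, read_length_sd = 800,
                       error_rate = 0.10,
                       error_mix = c(sub = 0.5, ins = 0.25, del = 0.25),
                       repeat_spec = NULL, homopolymer_bias = FALSE,
                       seed = 1L) {
  stopifnot(het_rate >= 0, het_rate <= 0.05,
            error_rate >= 0, error_rate <= 0.25,
            depth_per_haplotype > 0,
            abs(sum(error_mix) - 1) < 1e-8,
            indel_het_fraction >= 0, indel_het_fraction <= 1)
  if (genome_length < 1000)
    stop("genome_length must be >= 1000 (too small for overlap structure)")
  if (!is.null(repeat_spec)) {
    if (is.matrix(repeat_spec)) repeat_spec <- asplit(repeat_spec, 1)
    if (!is.list(repeat_spec)) repeat_spec <- list(repeat_spec)
  }
  structure(list(genome_length = as.integer(genome_length),
                 het_rate = het_rate,
                 indel_het_fraction = indel_het_fraction,
                 depth_per_haplotype = depth_per_haplotype,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 error_rate = error_rate,
                 error_mix = error_mix,
                 repeat_spec = repeat_spec,
                 homopolymer_bias = isTRUE(homopolymer_bias),
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# substitute bases at 0-based positions `pos` with a different random base
mutate_bases <- function(chars, pos0) {
  if (!length(pos0)) return(chars)
  cur <- chars[pos0 + 1L]
  alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  chars[pos0 + 1L] <- alt
  chars
}

#' Simulate a diploid genome pair with known heterozygous variants
#'
#' Haplotype 2 is derived from haplotype 1 by a sampled variant set
#' (SNPs and, optionally, 1--50 bp indels). Optional near-identical repeats
#' are embedded in haplotype 1 before variants are applied, so both
#' haplotypes contain them.
#'
#' @param params a \code{\link{sim_params}} object
#' @return a list with elements \code{haplotypes} (named character vector
#'   \code{hap1}, \code{hap2}) and \code{truth} (list with
#'   \code{het_sites} data.table: \code{pos} 0-based on haplotype 1,
#'   \code{type}, \code{a1}, \code{a2}, and \code{repeats} table)
#' @export
simulate_diploid_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(substream_seed(params$seed, "genome"))
  g <- params$genome_length
  chars <- sample(DNA_BASES, g, replace = TRUE)

  repeats <- NULL
  if (!is.null(params$repeat_spec)) {
    reps <- list()
    for (spec in params$repeat_spec) {
      len <- as.integer(spec[[1]]); copies <- as.integer(spec[[2]])
      div <- as.numeric(spec[[3]])
      unit <- sample(DNA_BASES, len, replace = TRUE)
      # non-overlapping placements away from the ends
      slots <- floor((g - 2000) / (len + 1000))
      if (slots < copies) stop("genome too small for repeat_spec")
      starts <- sort(sample(seq_len(slots), copies)) - 1L
      starts <- 1000L + starts * (len + 1000L) +
        sample(0:500, copies, replace = TRUE)
      for (i in seq_len(copies)) {
        copy <- unit
        nmut <- stats::rbinom(1, len, div)
        if (nmut > 0) copy <- mutate_bases(copy, sample(len, nmut) - 1L)
        chars[(starts[i] + 1L):(starts[i] + len)] <- copy
        reps[[length(reps) + 1L]] <- data.table::data.table(
          start = starts[i], end = starts[i] + len, copy = i, length = len)
      }
    }
    repeats <- data.table::rbindlist(reps)
  }
  hap1_chars <- chars

  # heterozygous variant set on haplotype-1 coordinates
  pos <- which(runif(g) < params$het_rate) - 1L
  pos <- pos[pos > 0L & pos < g - 60L]   # keep footprints inside the genome
  sites <- data.table::data.table(pos = integer(), type = character(),
                                  a1 = character(), a2 = character(),
                                  indel_len = integer())
  if (length(pos)) {
    type <- ifelse(runif(length(pos)) < params$indel_het_fraction,
                   ifelse(runif(length(pos)) < 0.5, "ins", "del"), "snp")
    ilen <- ifelse(type == "snp", 0L, pmin(50L, 1L + stats::rgeom(length(pos), 0.3)))
    # drop variants whose footprint reaches the next variant
    keep <- c(pos[-1] > pos[-length(pos)] + ilen[-length(pos)], TRUE)
    pos <- pos[keep]; type <- type[keep]; ilen <- ilen[keep]
    ref <- hap1_chars[pos + 1L]
    a1 <- ref; a2 <- ref
    snp <- type == "snp"
    a2[snp] <- vapply(ref[snp], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    ins <- type == "ins"
    a2[ins] <- vapply(which(ins), function(i)
      paste0(ref[i], random_dna(ilen[i])), "")
    del <- type == "del"
    a1[del] <- vapply(which(del), function(i)
      paste(hap1_chars[(pos[i] + 1L):(pos[i] + 1L + ilen[i])], collapse = ""), "")
    sites <- data.table::data.table(pos = pos, type = type, a1 = a1, a2 = a2,
                                    indel_len = ilen)
  }

  # build hap2 left-to-right by splicing a2 alleles over a1 footprints
  if (nrow(sites)) {
    pieces <- character(2L * nrow(sites) + 1L)
    cursor <- 0L
    for (i in seq_len(nrow(sites))) {
      p <- sites$pos[i]
      pieces[2L * i - 1L] <-
        if (p > cursor) paste(hap1_chars[(cursor + 1L):p], collapse = "") else ""
      pieces[2L * i] <- sites$a2[i]
      cursor <- p + 1L + sites$indel_len[i] * (sites$type[i] == "del")
    }
    pieces[2L * nrow(sites) + 1L] <-
      if (cursor < g) paste(hap1_chars[(cursor + 1L):g], collapse = "") else ""
    hap2 <- paste(pieces, collapse = "")
  } else hap2 <- paste(hap1_chars, collapse = "")

  haps <- c(hap1 = paste(hap1_chars, collapse = ""), hap2 = hap2)
  truth <- list(het_sites = sites, repeats = repeats, params = params)
  list(haplotypes = haps, truth = truth)
}

#' Simulate long noisy reads from a haplotype pair
#'
#' Reads are sampled uniformly from both haplotypes and both strands;
#' per-base errors are injected according to \code{error_mix}. Read ids,
#' source haplotype, interval and strand are recorded as truth labels.
#'
#' @param haplotypes named character vector (\code{hap1}, \code{hap2})
#' @param truth truth list from \code{\link{simulate_diploid_genome}}
#' @param params a \code{\link{sim_params}} object
#' @return a list with \code{reads} (named character vector) and
#'   \code{truth} updated with a \code{read_labels} data.table
#'   (\code{read}, \code{hap}, \code{start}, \code{end}, \code{strand})
#' @export
simulate_reads <- function(haplotypes, truth, params) {
  stopifnot(inherits(params, "sim_params"), length(haplotypes) == 2)
  if (params$read_length_mean > params$genome_length)
    stop("read_length_mean exceeds genome_length")
  set.seed(substream_seed(params$seed, "reads"))

  labels <- list(); seqs <- list(); idx <- 0L
  for (h in 1:2) {
    hap <- haplotypes[[h]]
    hlen <- nchar(hap)
    target <- params$depth_per_haplotype * hlen
    total <- 0
    while (total < target) {
      len <- round(rnorm(1, params$read_length_mean, params$read_length_sd))
      len <- max(500L, min(as.integer(len), hlen))
      start <- sample.int(hlen - len + 1L, 1L) - 1L
      strand <- if (runif(1) < 0.5) "+" else "-"
      idx <- idx + 1L
      id <- sprintf("sim%05d", idx)
      frag <- substr(hap, start + 1L, start + len)
      if (strand == "-") frag <- revcomp(frag)
      seqs[[id]] <- inject_errors(frag, params)
      labels[[id]] <- data.table::data.table(
        read = id, hap = h, start = start, end = start + len, strand = strand)
      total <- total + len
    }
  }
  truth$read_labels <- data.table::rbindlist(labels)
  list(reads = unlist(seqs), truth = truth)
}

# Inject substitution/insertion/deletion errors into one sequence.
inject_errors <- function(seq, params) {
  if (params$error_rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  p <- rep(params$error_rate, n)
  if (params$homopolymer_bias) {
    r <- rle(x)
    inhp <- rep(r$lengths >= 3, r$lengths)
    p[inhp] <- pmin(1, p[inhp] * 2)
  }
  err <- which(runif(n) < p)
  if (!length(err)) return(seq)
  kind <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = params$error_mix)
  emit <- x
  sub <- err[kind == "sub"]
  if (length(sub))
    emit[sub] <- vapply(x[sub], function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
  del <- err[kind == "del"]
  if (length(del)) emit[del] <- ""
  ins <- err[kind == "ins"]
  if (length(ins))
    emit[ins] <- paste0(emit[ins],
                        sample(DNA_BASES, length(ins), replace = TRUE))
  paste(emit, collapse = "")
}

#' Run the full simulator and optionally write its outputs
#'
#' @param params a \code{\link{sim_params}} object
#' @param out_dir optional output directory: writes \code{haplotypes.fa},
#'   \code{reads.fq}, \code{het_sites.tsv}, \code{read_labels.tsv}
#' @return list with \code{haplotypes}, \code{reads}, \code{truth}
#' @export
simulate_dataset <- function(params, out_dir = NULL) {
  gen <- simulate_diploid_genome(params)
  rd <- simulate_reads(gen$haplotypes, gen$truth, params)
  res <- list(haplotypes = gen$haplotypes, reads = rd$reads,
              truth = rd$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$haplotypes, file.path(out_dir, "haplotypes.fa"))
    write_fastq(res$reads, file.path(out_dir, "reads.fq"))
    data.table::fwrite(res$truth$het_sites,
                       file.path(out_dir, "het_sites.tsv"), sep = "\t")
    data.table::fwrite(res$truth$read_labels,
                       file.path(out_dir, "read_labels.tsv"), sep = "\t")
  }
  res
}
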