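# Truth-based evaluation: trio-binning read classification from
# haplotype-specific k-mers, consistency/completeness metrics, and
# CIGAR-scan read accuracy. Canonical k-mers throughout.

# canonical k-mer hashes of a sequence (w = 1: every position)
kmer_hashes <- function(seq, k) {
  mm <- .minimizers_cpp(seq, k, 1L)
  mm$hash
}

#' Haplotype-specific k-mer sets from a simulated haplotype pair
#'
#' At desk scale the parental k-mer databases are computed exactly as the
#' symmetric difference of the two haplotypes' canonical k-mer sets.
#'
#' @param haplotypes named character vector (hap1 = "paternal",
#'   hap2 = "maternal")
#' @param k k-mer length (18 for read-level use, 21 for contigs)
#' @return list: paternal, maternal (hash vectors), K_p, K_m, k
#' @export
trio_kmer_sets <- function(haplotypes, k = 18L) {
  h1 <- unique(kmer_hashes(haplotypes[[1]], k))
  h2 <- unique(kmer_hashes(haplotypes[[2]], k))
  pat <- setdiff(h1, h2); mat <- setdiff(h2, h1)
  list(paternal = pat, maternal = mat,
       K_p = length(pat), K_m = length(mat), k = as.integer(k))
}

#' Count haplotype-specific k-mers in each read
#' @param reads named character vector
#' @param ks \code{\link{trio_kmer_sets}} output
#' @return data.table (read, k_p, k_m)
#' @export
count_specific_kmers <- function(reads, ks) {
  reads <- as_read_set(reads)
  data.table::data.table(
    read = names(reads),
    k_p = vapply(reads, function(s) sum(kmer_hashes(s, ks$k) %in%
                                          ks$paternal), 0),
    k_m = vapply(reads, function(s) sum(kmer_hashes(s, ks$k) %in%
                                          ks$maternal), 0))
}

#' Trio-binning read classification
#'
#' Paternal iff k_p / K_p > (k_m + max(10, k_m * 0.1)) / K_m; maternal by
#' the symmetric rule; otherwise untagged.
#'
#' @param reads named character vector (or a precomputed count table with
#'   columns read, k_p, k_m)
#' @param ks \code{\link{trio_kmer_sets}} output
#' @return data.table (read, k_p, k_m, bin in paternal/maternal/untagged)
#' @export
trio_bin_reads <- function(reads, ks) {
  tab <- if (is.data.frame(reads)) data.table::as.data.table(reads)
  else count_specific_kmers(reads, ks)
  tab[, bin := trio_bin_rule(k_p, k_m, ks$K_p, ks$K_m)]
  tab[]
}

#' The trio-binning inequality (vectorized)
#' @param k_p,k_m haplotype-specific k-mer counts in the read
#' @param K_p,K_m haplotype-specific database sizes
#' @return character vector paternal/maternal/untagged
#' @export
trio_bin_rule <- function(k_p, k_m, K_p, K_m) {
  pat <- k_p / K_p > (k_m + pmax(10, k_m * 0.1)) / K_m
  mat <- k_m / K_m > (k_p + pmax(10, k_p * 0.1)) / K_p
  ifelse(pat, "paternal", ifelse(mat, "maternal", "untagged"))
}

# select the longest reads down to a target depth
select_longest <- function(reads, genome_size, depth = 40) {
  lens <- sort(nchar(reads), decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  n <- which(cum >= depth * genome_size)[1]
  if (is.na(n)) n <- length(lens)
  names(reads)[order(-nchar(reads))][seq_len(n)]
}

#' Haplotype-specific k-mer consistency and completeness
#'
#' Consistency = sum(max(k_p, k_m)) / sum(k_p + k_m) over the selected
#' reads. Completeness = fraction of haplotype-specific k-mers observed at
#' least \code{min_occurrence} times in the \code{depth_cap}-fold longest
#' reads.
#'
#' @param reads named character vector
#' @param ks \code{\link{trio_kmer_sets}} output
#' @param genome_size genome size used for the longest-read selection
#' @param depth_cap selection depth (default 40)
#' @param min_occurrence completeness occurrence floor (default 4)
#' @return list(consistency, completeness, n_reads)
#' @export
consistency_completeness <- function(reads, ks, genome_size,
                                     depth_cap = 40, min_occurrence = 4) {
  reads <- as_read_set(reads)
  sel <- select_longest(reads, genome_size, depth_cap)
  if (!length(sel)) stop("empty read selection")
  sub <- reads[sel]
  cnt <- count_specific_kmers(sub, ks)
  denom <- sum(cnt$k_p + cnt$k_m)
  consistency <- if (denom > 0)
    sum(pmax(cnt$k_p, cnt$k_m)) / denom else NA_real_
  specific <- c(ks$paternal, ks$maternal)
  occ <- table(unlist(lapply(sub, function(s) {
    h <- kmer_hashes(s, ks$k)
    h[h %in% specific]
  })))
  completeness <- sum(occ >= min_occurrence) / length(specific)
  list(consistency = consistency, completeness = completeness,
       n_reads = length(sel))
}

#' Alignment-based read accuracy against the truth haplotypes
#'
#' Each read is aligned (banded, global over its truth interval with
#' margins) to its source haplotype; accuracy is matches over all alignment
#' columns, the CIGAR-scan definition.
#'
#' @param reads named character vector (raw or corrected; corrected reads
#'   inherit the raw read's truth label)
#' @param haplotypes truth haplotype pair
#' @param labels truth read_labels table (read, hap, start, end, strand)
#' @param margin extra truth bases on each side of the interval (the
#'   reference flanks are free, so the margin only needs to cover span
#'   mapping inaccuracy)
#' @param spans optional provenance table (read, raw_start, raw_end) for
#'   corrected reads trimmed relative to the raw read
#' @return data.table (read, accuracy, aligned)
#' @export
read_accuracy <- function(reads, haplotypes, labels, margin = 150L,
                          spans = NULL) {
  reads <- as_read_set(reads)
  out <- data.table::data.table(read = names(reads), accuracy = NA_real_,
                                aligned = FALSE)
  for (i in seq_along(reads)) {
    lb <- labels[read == names(reads)[i]]
    if (!nrow(lb)) next
    hap <- haplotypes[[lb$hap[1]]]
    s0 <- lb$start[1]; s1 <- lb$end[1]
    if (!is.null(spans)) {
      sp <- spans[read == names(reads)[i]]
      if (nrow(sp)) {
        rl <- s1 - s0
        if (lb$strand[1] == "+") {
          s1 <- min(s1, s0 + sp$raw_end[1]); s0 <- s0 + sp$raw_start[1]
        } else {
          s0n <- s0 + max(0L, rl - sp$raw_end[1])
          s1 <- min(s1, s0 + rl - sp$raw_start[1]); s0 <- s0n
        }
      }
    }
    t0 <- max(0L, s0 - margin)
    t1 <- min(nchar(hap), s1 + margin)
    win <- substr(hap, t0 + 1L, t1)
    q <- if (lb$strand[1] == "-") revcomp(reads[[i]]) else reads[[i]]
    al <- align_global(q, win, free_ends = TRUE)
    if (!al$ok) next
    out[i, `:=`(accuracy = al$identity, aligned = TRUE)]
  }
  out
}

#' Heterozygous-allele agreement of reads with their source haplotype
#'
#' Each read is aligned to its source haplotype's truth interval; at every
#' truth SNP site the read covers, its base is compared with the source
#' haplotype's allele. Agreement is the fraction of covered sites carrying
#' the source allele (sites with neither allele count as disagreement).
#'
#' @param reads named character vector (raw or corrected)
#' @param sim simulated dataset (haplotypes, truth)
#' @param spans optional provenance spans for corrected reads
#' @param margin truth margin (reference flanks free)
#' @return list: per-read data.table (read, n_sites, n_agree) and overall
#'   \code{agreement}
#' @export
het_allele_agreement <- function(reads, sim, spans = NULL, margin = 150L) {
  reads <- as_read_set(reads)
  labels <- sim$truth$read_labels
  sites <- sim$truth$het_sites
  pos2 <- hap2_positions(sites)
  snp <- sites$type == "snp"
  rows <- list()
  for (i in seq_along(reads)) {
    lb <- labels[read == names(reads)[i]]
    if (!nrow(lb) || !any(snp)) next
    hap <- sim$haplotypes[[lb$hap[1]]]
    s0 <- lb$start[1]; s1 <- lb$end[1]
    if (!is.null(spans)) {
      sp <- spans[read == names(reads)[i]]
      if (nrow(sp)) {
        rl <- s1 - s0
        if (lb$strand[1] == "+") {
          s1 <- min(s1, s0 + sp$raw_end[1]); s0 <- s0 + sp$raw_start[1]
        } else {
          s0n <- s0 + max(0L, rl - sp$raw_end[1])
          s1 <- min(s1, s0 + rl - sp$raw_start[1]); s0 <- s0n
        }
      }
    }
    t0 <- max(0L, s0 - margin); t1 <- min(nchar(hap), s1 + margin)
    q <- if (lb$strand[1] == "-") revcomp(reads[[i]]) else reads[[i]]
    al <- align_global(q, substr(hap, t0 + 1L, t1), free_ends = TRUE)
    if (!al$ok) next
    parsed <- parse_ops_to_calls(al$ops, q, t0 + al$b_start)
    hpos <- if (lb$hap[1] == 1L) sites$pos[snp] else pos2[snp]
    own <- if (lb$hap[1] == 1L) sites$a1[snp] else sites$a2[snp]
    bc <- parsed$calls
    hit <- bc$base[match(hpos, bc$pos)]
    cov <- !is.na(hit)
    if (!any(cov)) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      read = names(reads)[i], n_sites = sum(cov),
      n_agree = sum(hit[cov] == own[cov]))
  }
  tab <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(read = character(), n_sites = integer(),
                           n_agree = integer())
  list(per_read = tab,
       agreement = if (nrow(tab) && sum(tab$n_sites) > 0)
         sum(tab$n_agree) / sum(tab$n_sites) else NA_real_)
}

#' Junction resolution of near-identical repeat copies
#'
#' For each repeat copy, 400-bp unique flanks on both sides are mapped to
#' the assembly; the copy is resolved iff both flanks land on the same
#' contig, in consistent orientation, at a distance matching the repeat
#' length. A collapsed or misjoined assembly fails the pairing.
#'
#' @param contigs named character vector (assembly)
#' @param genome the truth sequence the repeats were embedded in
#' @param repeats truth repeat table (start, end per copy)
#' @param flank flank probe length
#' @param tol distance tolerance in bases
#' @return logical vector, one element per repeat copy
#' @export
repeat_resolution <- function(contigs, genome, repeats, flank = 400L,
                              tol = 250L) {
  out <- logical(nrow(repeats))
  if (!length(contigs)) return(out)
  for (i in seq_len(nrow(repeats))) {
    s <- repeats$start[i]; e <- repeats$end[i]
    if (s - flank < 0 || e + flank > nchar(genome)) next
    up <- substr(genome, s - flank + 1L, s)
    dn <- substr(genome, e + 1L, e + flank)
    mp <- map_reads_to_contigs(c(up = up, dn = dn), contigs,
                               k = 15L, w = 5L, min_shared = 4L)
    pl <- mp$placements
    if (!all(c("up", "dn") %in% pl$read)) next
    pu <- pl[pl$read == "up"][1]; pd <- pl[pl$read == "dn"][1]
    if (pu$contig != pd$contig || pu$strand != pd$strand) next
    gap <- if (pu$strand == "+") pd$start - pu$end else pu$start - pd$end
    out[i] <- abs(gap - (e - s)) <= tol
  }
  out
}

#' Truth-label consistency of supporting-read selection
#'
#' Fraction of (template, support) pairs whose truth haplotypes differ,
#' used to quantify how well selection confines supports to the template's
#' haplotype.
#'
#' @param pairs data.table (template, support)
#' @param labels truth read_labels
#' @return fraction of cross-haplotype pairs (NA when no pairs)
#' @export
cross_haplotype_fraction <- function(pairs, labels) {
  if (!nrow(pairs)) return(NA_real_)
  hap <- setNames(labels$hap, labels$read)
  mean(hap[pairs$template] != hap[pairs$support], na.rm = TRUE)
}
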