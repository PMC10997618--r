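# Candidate overlap discovery, extension to read ends, and the
# overhang / contained / coverage filters applied before graph building.
#
# An overlap set is a data.table with PAF-like columns (0-based half-open,
# minus-strand coordinates on the read's own forward frame):
#   read_a read_b strand a_len a_start a_end b_len b_start b_end
#   shared identity status
# Canonical order: read_a < read_b lexicographically.

#' Overlap filter parameters
#'
#' The overhang rule removes an overlap whose residual inner overhang
#' exceeds min(overhang_abs, overhang_frac * l) on the read of length l
#' carrying it: min(100, 0.01 l) for PacBio, min(300, 0.03 l) for Nanopore.
#'
#' @param platform "pacbio" or "ont"
#' @param overhang_abs absolute overhang bound in bases
#' @param overhang_frac fractional overhang bound
#' @param min_coverage,max_coverage acceptable per-read overlap coverage
#' @return an \code{overlap_filter_params} object
#' @export
overlap_filter_params <- function(platform = c("pacbio", "ont"),
                                  overhang_abs = NULL, overhang_frac = NULL,
                                  min_coverage = 3, max_coverage = 400) {
  platform <- match.arg(platform)
  if (is.null(overhang_abs))
    overhang_abs <- if (platform == "pacbio") 100 else 300
  if (is.null(overhang_frac))
    overhang_frac <- if (platform == "pacbio") 0.01 else 0.03
  stopifnot(overhang_abs > 0, overhang_frac > 0, overhang_frac < 1)
  structure(list(platform = platform, overhang_abs = overhang_abs,
                 overhang_frac = overhang_frac, min_coverage = min_coverage,
                 max_coverage = max_coverage),
            class = "overlap_filter_params")
}

#' Overhang threshold min(abs, frac * l)
#' @param l read length(s)
#' @param params an \code{\link{overlap_filter_params}} object
#' @return numeric threshold(s)
#' @export
overhang_threshold <- function(l, params) {
  pmin(params$overhang_abs, params$overhang_frac * l)
}

#' Find candidate overlaps between reads with shared canonical minimizers
#'
#' Reports each pair once (lexicographically smaller id first), on the
#' relative strand supported by the majority of shared minimizers, with
#' coordinates spanning the minimizer chain on the dominant diagonal.
#'
#' @param reads named character vector or DNAStringSet
#' @param k k-mer size
#' @param w minimizer window (k-mers per window)
#' @param min_shared minimum on-diagonal shared minimizers
#' @param band diagonal clustering tolerance in bases
#' @param max_occ drop minimizers occurring more than this many times
#' @return overlap set data.table, status "candidate"
#' @export
find_candidate_overlaps <- function(reads, k = 15L, w = 10L, min_shared = 4L,
                                    band = 500L, max_occ = 500L) {
  reads <- as_read_set(reads)
  lens <- nchar(reads)
  if (k > min(lens)) stop("k exceeds the shortest read")
  mm <- data.table::as.data.table(.minimizers_cpp(unname(reads), k, w))
  mm <- mm[, N := .N, by = hash][N <= max_occ][, N := NULL]
  data.table::setkey(mm, hash)
  hits <- mm[mm, on = "hash", allow.cartesian = TRUE,
             .(ra = read, rb = i.read, pa = pos, pb = i.pos,
               rel = strand * i.strand)][ra < rb]
  if (!nrow(hits)) return(empty_overlap_set())

  # majority relative strand per pair
  hits[, rel_major := if (sum(rel > 0) >= sum(rel < 0)) 1L else -1L,
       by = .(ra, rb)]
  hits <- hits[rel == rel_major]
  # diagonal: pa - pb on same strand, pa + pb on opposite strand
  hits[, diag := ifelse(rel > 0, pa - pb, pa + pb)]
  hits[, dmed := as.integer(median(diag)), by = .(ra, rb)]
  hits <- hits[abs(diag - dmed) <= band]
  ov <- hits[, .(shared = .N, pa1 = min(pa), pa2 = max(pa) + k,
                 pb1 = min(pb), pb2 = max(pb) + k, rel = rel[1]),
             by = .(ra, rb)][shared >= min_shared]
  if (!nrow(ov)) return(empty_overlap_set())

  ids <- names(reads)
  res <- data.table::data.table(
    read_a = ids[ov$ra], read_b = ids[ov$rb],
    strand = ifelse(ov$rel > 0, "+", "-"),
    a_len = lens[ov$ra], a_start = ov$pa1, a_end = ov$pa2,
    b_len = lens[ov$rb], b_start = ov$pb1, b_end = ov$pb2,
    shared = ov$shared, identity = NA_real_, status = "candidate")
  canonicalize_overlaps(res)
}

empty_overlap_set <- function() {
  data.table::data.table(read_a = character(), read_b = character(),
                         strand = character(), a_len = integer(),
                         a_start = integer(), a_end = integer(),
                         b_len = integer(), b_start = integer(),
                         b_end = integer(), shared = integer(),
                         identity = numeric(), status = character())
}

# Put the lexicographically smaller read id first, swapping coordinates.
canonicalize_overlaps <- function(ovs) {
  sw <- ovs$read_a > ovs$read_b
  if (any(sw)) {
    tmp <- ovs[sw]
    ovs[sw, `:=`(read_a = tmp$read_b, read_b = tmp$read_a,
                 a_len = tmp$b_len, a_start = tmp$b_start, a_end = tmp$b_end,
                 b_len = tmp$a_len, b_start = tmp$a_start, b_end = tmp$a_end)]
  }
  data.table::setorder(ovs, read_a, read_b)
  ovs[]
}

# flank lengths of an overlap on a's frame; b flanks oriented to a's frame
overlap_flanks <- function(ovs) {
  bl <- ifelse(ovs$strand == "+", ovs$b_start, ovs$b_len - ovs$b_end)
  br <- ifelse(ovs$strand == "+", ovs$b_len - ovs$b_end, ovs$b_start)
  list(al = ovs$a_start, ar = ovs$a_len - ovs$a_end, bl = bl, br = br)
}

#' Extend candidate overlaps to the read ends
#'
#' Runs a banded edit-distance extension on the flanking segments only (not
#' the whole overlap). Flanks that align through to the read ends leave zero
#' residual overhang; unalignable flaps (e.g. chimeric junctions) stop the
#' extension and remain as overhangs.
#'
#' @param ovs candidate overlap set
#' @param reads named character vector
#' @param max_flank cap on the flank length examined per side
#' @return overlap set with updated coordinates, status "extended"
#' @export
extend_overlaps <- function(ovs, reads, max_flank = 3000L) {
  reads <- as_read_set(reads)
  if (!nrow(ovs)) return(ovs)
  ovs <- data.table::copy(ovs)
  ai <- match(ovs$read_a, names(reads))
  bi <- match(ovs$read_b, names(reads))
  ext <- .batch_extend_cpp(ai, bi, ovs$strand == "-",
                           ovs$a_start, ovs$a_end, ovs$b_start, ovs$b_end,
                           unname(reads), unname(revcomp(reads)),
                           as.integer(max_flank))
  ovs[, `:=`(a_start = ext$a_start, a_end = ext$a_end,
             b_start = ext$b_start, b_end = ext$b_end,
             status = "extended")]
  ovs[]
}

#' Remove overlaps whose residual overhangs are still long
#'
#' On each side of the overlap, the inner overhang is the smaller of the two
#' reads' unaligned flanks; the overlap is removed iff any inner overhang
#' exceeds min(overhang_abs, overhang_frac * l) for the read of length l
#' carrying it.
#'
#' @param ovs extended overlap set
#' @param params \code{\link{overlap_filter_params}}
#' @return overlap set with statuses "removed_overhang" / "extended"
#' @export
filter_overhangs <- function(ovs, params) {
  if (!nrow(ovs)) return(ovs)
  ovs <- data.table::copy(ovs)
  fl <- overlap_flanks(ovs)
  # carrier read of the inner overhang on each side
  left_inner <- pmin(fl$al, fl$bl)
  left_carrier_len <- ifelse(fl$al <= fl$bl, ovs$a_len, ovs$b_len)
  right_inner <- pmin(fl$ar, fl$br)
  right_carrier_len <- ifelse(fl$ar <= fl$br, ovs$a_len, ovs$b_len)
  bad <- left_inner > overhang_threshold(left_carrier_len, params) |
    right_inner > overhang_threshold(right_carrier_len, params)
  ovs[bad, status := "removed_overhang"]
  ovs[]
}

#' Remove overlaps of contained reads and of reads with aberrant coverage
#'
#' A read is contained if some surviving overlap covers it end-to-end
#' (within its overhang tolerance) inside another read. Overlaps touching
#' contained reads are removed, and contained reads are recorded for later
#' dead-end repair. Reads whose overlap coverage falls outside
#' \[min_coverage, max_coverage\] are removed with their overlaps.
#'
#' @param ovs overlap set after \code{\link{filter_overhangs}}
#' @param params \code{\link{overlap_filter_params}}
#' @return list: \code{overlaps} (statuses updated; survivors "retained"),
#'   \code{contained} (data.table read/container), \code{coverage}
#'   (data.table read/coverage)
#' @export
remove_contained_and_low_coverage <- function(ovs, params) {
  ovs <- data.table::copy(ovs)
  live <- ovs$status %in% c("extended", "candidate")
  if (!any(live)) {
    return(list(overlaps = ovs,
                contained = data.table::data.table(read = character(),
                                                   container = character()),
                coverage = data.table::data.table(read = character(),
                                                  coverage = numeric())))
  }
  sub <- ovs[live]
  fl <- overlap_flanks(sub)
  tol_a <- overhang_threshold(sub$a_len, params)
  tol_b <- overhang_threshold(sub$b_len, params)
  a_cont <- fl$al <= tol_a & fl$ar <= tol_a
  b_cont <- fl$bl <= tol_b & fl$br <= tol_b
  # mutual containment (near-equal reads): the shorter is contained,
  # ties broken toward the lexicographically larger id
  both <- a_cont & b_cont
  keep_a <- sub$a_len > sub$b_len | (sub$a_len == sub$b_len)
  a_cont[both] <- !keep_a[both]
  b_cont[both] <- keep_a[both]
  contained <- rbind(
    data.table::data.table(read = sub$read_a[a_cont],
                           container = sub$read_b[a_cont]),
    data.table::data.table(read = sub$read_b[b_cont],
                           container = sub$read_a[b_cont]))
  contained <- unique(contained, by = "read")
  cset <- unique(contained$read)

  touch <- sub$read_a %in% cset | sub$read_b %in% cset
  idx <- which(live)
  ovs[idx[touch], status := "removed_contained"]

  # coverage over remaining overlaps
  live2 <- ovs$status == "extended"
  sub2 <- ovs[live2]
  cov <- rbind(
    sub2[, .(read = read_a, len = a_len, aln = a_end - a_start)],
    sub2[, .(read = read_b, len = b_len, aln = b_end - b_start)])
  covtab <- cov[, .(coverage = sum(aln) / len[1]), by = read]
  badreads <- covtab[coverage < params$min_coverage |
                       coverage > params$max_coverage, read]
  if (length(badreads)) {
    idx2 <- which(live2)
    badov <- sub2$read_a %in% badreads | sub2$read_b %in% badreads
    ovs[idx2[badov], status := "removed_coverage"]
  }
  ovs[status == "extended", status := "retained"]
  list(overlaps = ovs[], contained = contained, coverage = covtab)
}

#' Status accounting for an overlap set
#' @param ovs overlap set
#' @return data.table of status counts
#' @export
overlap_status_counts <- function(ovs) {
  ovs[, .N, by = status][order(status)]
}

#' Re-run the containment/coverage filter after dropping inconsistent
#' overlaps
#'
#' Round 2 removes inconsistent overlaps from the candidate set and
#' rebuilds the graph; containment is recomputed so that reads contained
#' only within the other haplotype (or another repeat copy) become free
#' and can seed their own haplotype path.
#'
#' @param ovs overlap set with round-1 statuses and an
#'   \code{inconsistent} logical column
#' @param params \code{\link{overlap_filter_params}}
#' @return list as \code{\link{remove_contained_and_low_coverage}}; the
#'   dropped inconsistent rows keep status "removed_inconsistent"
#' @export
refilter_overlaps <- function(ovs, params = overlap_filter_params()) {
  ovs2 <- data.table::copy(ovs)
  refine <- ovs2$status %in% c("retained", "extended", "removed_contained",
                               "removed_coverage")
  ovs2[refine & inconsistent == TRUE, status := "removed_inconsistent"]
  ovs2[status %in% c("retained", "removed_contained", "removed_coverage"),
       status := "extended"]
  remove_contained_and_low_coverage(ovs2, params)
}

#' Run the full overlap stage: find, extend, filter
#' @param reads named character vector
#' @param params \code{\link{overlap_filter_params}}
#' @param ... passed to \code{\link{find_candidate_overlaps}}
#' @param ovs optional externally supplied candidate overlaps (e.g. PAF)
#' @return list as \code{\link{remove_contained_and_low_coverage}}
#' @export
overlap_stage <- function(reads, params = overlap_filter_params(), ...,
                          ovs = NULL) {
  if (is.null(ovs)) ovs <- find_candidate_overlaps(reads, ...)
  ovs <- extend_overlaps(ovs, reads)
  ovs <- filter_overhangs(ovs, params)
  remove_contained_and_low_coverage(ovs, params)
}
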