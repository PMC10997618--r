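# Interchange formats: PAF overlaps (12 standard columns + id:f / st:Z
# tags), GFA 1.0 graphs, VCF heterozygous sites, JSON configuration.

#' Write an overlap set as PAF
#' @param ovs overlap set
#' @param path output path
#' @return invisibly, the path
#' @export
write_paf <- function(ovs, path) {
  if (!nrow(ovs)) { writeLines(character(0), path); return(invisible(path)) }
  nmatch <- pmax(0L, as.integer(
    (ovs$a_end - ovs$a_start) * ifelse(is.na(ovs$identity), 1,
                                       ovs$identity)))
  lines <- paste(ovs$read_a, ovs$a_len, ovs$a_start, ovs$a_end, ovs$strand,
                 ovs$read_b, ovs$b_len, ovs$b_start, ovs$b_end,
                 nmatch, ovs$a_end - ovs$a_start, 255,
                 ifelse(is.na(ovs$identity), "id:f:-1",
                        sprintf("id:f:%.4f", ovs$identity)),
                 paste0("st:Z:", ovs$status), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file into an overlap set
#' @param path PAF path (12+ columns; id:f / st:Z tags recognized)
#' @return overlap set data.table
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_overlap_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 12)
  if (length(bad))
    stop("malformed PAF record at line ", bad[1])
  get <- function(i) vapply(parts, `[[`, "", i)
  tag <- function(prefix, default) {
    vapply(parts, function(p) {
      hit <- grep(paste0("^", prefix), p, value = TRUE)
      if (length(hit)) sub(paste0("^", prefix), "", hit[1]) else default
    }, "")
  }
  idv <- suppressWarnings(as.numeric(tag("id:f:", "-1")))
  idv[idv < 0] <- NA_real_
  ovs <- data.table::data.table(
    read_a = get(1), a_len = as.integer(get(2)),
    a_start = as.integer(get(3)), a_end = as.integer(get(4)),
    strand = get(5),
    read_b = get(6), b_len = as.integer(get(7)),
    b_start = as.integer(get(8)), b_end = as.integer(get(9)),
    shared = as.integer(get(10)), identity = idv,
    status = tag("st:Z:", "candidate"))
  data.table::setcolorder(ovs, c("read_a", "read_b", "strand", "a_len",
                                 "a_start", "a_end", "b_len", "b_start",
                                 "b_end", "shared", "identity", "status"))
  canonicalize_overlaps(ovs)
}

#' Write a string graph as GFA 1.0
#'
#' S lines carry the reads (sequence omitted unless provided), L lines the
#' live and marked edges with their status in an st:Z tag.
#'
#' @param g string graph
#' @param path output path
#' @param reads optional named character vector to embed sequences
#' @return invisibly, the path
#' @export
write_gfa <- function(g, path, reads = NULL) {
  rd <- unique(c(node_read(g$edges$src), node_read(g$edges$dst)))
  slines <- vapply(rd, function(r) {
    seqf <- if (!is.null(reads) && r %in% names(reads)) reads[[r]] else "*"
    ln <- if (r %in% names(g$read_lens)) g$read_lens[[r]] else nchar(seqf)
    paste("S", r, seqf, paste0("LN:i:", ln), sep = "\t")
  }, "")
  ori <- function(node) ifelse(node_end(node) == "E", "+", "-")
  llines <- paste("L", node_read(g$edges$src), ori(g$edges$src),
                  node_read(g$edges$dst), ori(g$edges$dst), "*",
                  paste0("st:Z:", g$edges$status), sep = "\t")
  writeLines(c("H\tVN:Z:1.0", slines, llines), path)
  invisible(path)
}

#' Read heterozygous SNP sites from a VCF
#'
#' Keeps biallelic SNP records; positions are converted to 0-based.
#'
#' @param path VCF path (plain text)
#' @return data.table (contig, pos, allele1, allele2)
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.table::data.table(contig = character(), pos = integer(),
                                  allele1 = character(),
                                  allele2 = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 0L) >= 5
  parts <- parts[ok]
  dt <- data.table::data.table(
    contig = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 2)) - 1L,
    allele1 = vapply(parts, `[[`, "", 4),
    allele2 = vapply(parts, `[[`, "", 5))
  dt[nchar(allele1) == 1 & nchar(allele2) == 1 &
       allele1 %in% DNA_BASES & allele2 %in% DNA_BASES]
}

#' Write heterozygous sites as a minimal VCF
#' @param sites data.table with contig, pos (0-based), allele1, allele2
#' @param path output path
#' @return invisibly, the path
#' @export
write_vcf_sites <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(sites))
    paste(sites$contig, sites$pos + 1L, ".", sites$allele1, sites$allele2,
          ".", "PASS", ".", sep = "\t") else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed master seed fanned out to the stages
#' @param platform "pacbio" or "ont" (overhang rule)
#' @param sim \code{\link{sim_params}}
#' @param overlap_filter \code{\link{overlap_filter_params}}
#' @param correction \code{\link{correction_params}}
#' @param snp_call \code{\link{snp_call_params}}
#' @param grouping \code{\link{grouping_params}}
#' @param bog \code{\link{bog_params}}
#' @param raw_overlap,corrected_overlap minimizer settings per stage
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(seed = 1L, platform = "pacbio",
                            sim = sim_params(seed = seed),
                            overlap_filter =
                              overlap_filter_params(platform),
                            correction =
                              correction_params(max_supporting_reads = 32L),
                            snp_call = snp_call_params(),
                            grouping = grouping_params(),
                            bog = bog_params(),
                            raw_overlap = list(k = 13L, w = 8L,
                                               min_shared = 4L),
                            corrected_overlap = list(k = 15L, w = 10L,
                                                     min_shared = 6L)) {
  structure(list(seed = as.integer(seed), platform = platform, sim = sim,
                 overlap_filter = overlap_filter, correction = correction,
                 snp_call = snp_call, grouping = grouping, bog = bog,
                 raw_overlap = raw_overlap,
                 corrected_overlap = corrected_overlap),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param cfg \code{\link{pipeline_config}}
#' @param path JSON path
#' @return \code{save_config}: the path; \code{load_config}: the config
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass_rec(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ",
                          paste(extra, collapse = ", "))
  rebuild <- function(ctor, x) do.call(ctor, as.list(x))
  pipeline_config(
    seed = raw$seed, platform = raw$platform,
    sim = rebuild(sim_params, raw$sim[setdiff(names(raw$sim), NULL)]),
    overlap_filter = rebuild(overlap_filter_params, raw$overlap_filter),
    correction = rebuild(correction_params, raw$correction),
    snp_call = rebuild(snp_call_params, raw$snp_call),
    grouping = rebuild(grouping_params, raw$grouping),
    bog = rebuild(bog_params, raw$bog),
    raw_overlap = as.list(raw$raw_overlap),
    corrected_overlap = as.list(raw$corrected_overlap))
}
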