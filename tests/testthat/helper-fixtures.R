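# Shared fixture builders. Everything is generated in code; the expensive
# study-condition simulation is built once per session and cached.

suppressMessages(library(data.table))

# overlap-set rows from a known read layout (error-free coordinates).
# intervals: data.frame(read, start, end, strand); reads on a common axis.
layout_overlap_set <- function(intervals, min_ov = 1L) {
  iv <- as.data.table(intervals)
  iv[, len := end - start]
  rows <- list()
  for (i in seq_len(nrow(iv) - 1L)) for (j in (i + 1L):nrow(iv)) {
    s <- max(iv$start[i], iv$start[j]); e <- min(iv$end[i], iv$end[j])
    if (e - s < min_ov) next
    own <- function(k) {
      if (iv$strand[k] == "+") c(s - iv$start[k], e - iv$start[k])
      else c(iv$end[k] - e, iv$end[k] - s)
    }
    a <- own(i); b <- own(j)
    rows[[length(rows) + 1L]] <- data.table(
      read_a = iv$read[i], read_b = iv$read[j],
      strand = if (iv$strand[i] == iv$strand[j]) "+" else "-",
      a_len = iv$len[i], a_start = a[1], a_end = a[2],
      b_len = iv$len[j], b_start = b[1], b_end = b[2],
      shared = as.integer(e - s), identity = NA_real_,
      status = "extended")
  }
  ovs <- rbindlist(rows)
  diphase:::canonicalize_overlaps(ovs)
}

# reads cut from a reference according to a layout
layout_reads <- function(ref, intervals) {
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    s <- substr(ref, intervals$start[i] + 1L, intervals$end[i])
    if (intervals$strand[i] == "-") revcomp(s) else s
  }, "")
  setNames(out, intervals$read)
}

random_genome <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-built POA alignment record
mkaln <- function(read, tstart, ops, qseq) {
  list(read = read, tstart = tstart, ops = ops, qseq = qseq)
}

# cached study-condition run (50 kb diploid, 1% het, 10% error, 40x/hap)
.fixture_cache <- new.env(parent = emptyenv())

study_run <- function() {
  if (is.null(.fixture_cache$run)) {
    cfg <- pipeline_config(seed = 20260101L)
    run <- suppressWarnings(run_pipeline(cfg, progress = FALSE))
    run$phase$groups <- NULL      # large and unused by the tests
    .fixture_cache$run <- run
    gc(verbose = FALSE)
  }
  .fixture_cache$run
}

# near-identical repeat fixture: 26-kb genome with a 2-copy, 2-kb repeat
# at 0.5% divergence, 30x coverage of 1.3-kb reads at 10% error; short
# reads cannot bridge the repeat, so round 1 collapses it
repeat_cfg <- function(seed = 33L) {
  pipeline_config(
    seed = seed, platform = "ont",
    sim = sim_params(genome_length = 26000, het_rate = 0,
                     error_rate = 0.10, depth_per_haplotype = 15,
                     read_length_mean = 1300, read_length_sd = 150,
                     repeat_spec = list(c(2000, 2, 0.005)), seed = seed),
    raw_overlap = list(k = 13L, w = 8L, min_shared = 4L),
    corrected_overlap = list(k = 15L, w = 10L, min_shared = 5L))
}

repeat_run <- function() {
  if (is.null(.fixture_cache$repeat_run)) {
    run <- suppressWarnings(
      run_pipeline(repeat_cfg(), raw_snp = TRUE, progress = FALSE))
    run$phase$groups <- NULL
    .fixture_cache$repeat_run <- run
    gc(verbose = FALSE)
  }
  .fixture_cache$repeat_run
}

# cross-haplotype fraction among live string-graph edges (one per twin)
live_cross_fraction <- function(g, hap) {
  le <- diphase:::live_edges(g)
  le <- le[seq(1, nrow(le), by = 2)]
  ra <- diphase:::node_read(le$src)
  rb <- diphase:::node_read(le$dst)
  mean(hap[ra] != hap[rb])
}

# truth haplotype of each read in a run
truth_hap_of <- function(run) {
  lab <- run$sim$truth$read_labels
  setNames(lab$hap, lab$read)
}
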