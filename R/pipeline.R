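# Pipeline driver: sim -> raw overlaps -> correction -> corrected overlaps
# -> round-1 assembly -> phasing -> round-2 assembly -> evaluation.

#' Run the full diploid assembly pipeline
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @param out_dir optional output directory for FASTA/PAF/GFA/TSV artifacts
#' @param reads optional named character vector of reads (skips simulation;
#'   truth-based evaluation is then skipped too)
#' @param vcf_sites optional raw-read heterozygous sites (data.table from
#'   \code{\link{read_vcf_sites}}); overrides \code{raw_snp}
#' @param raw_snp if TRUE, run the built-in raw-read SNP caller on the
#'   round-1 contigs and use its sites for the loose-threshold
#'   inconsistency pass (the Nanopore-style mode; FALSE is the CLR mode)
#' @param progress emit stage messages
#' @return a list with per-stage results and a \code{report} list of
#'   counters
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         reads = NULL, vcf_sites = NULL, raw_snp = FALSE,
                         progress = TRUE) {
  say <- function(...) if (progress) message("[diphase] ", ...)
  report <- list(seed = cfg$seed)
  outp <- function(f) if (!is.null(out_dir)) file.path(out_dir, f) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # stage 1: simulation (unless reads are supplied)
  sim <- NULL
  if (is.null(reads)) {
    say("simulating diploid dataset")
    sim <- simulate_dataset(cfg$sim, out_dir = outp("sim"))
    reads <- sim$reads
  }
  reads <- as_read_set(reads)
  report$n_reads <- length(reads)
  report$total_bases <- sum(nchar(reads))

  # stage 2: candidate overlaps between raw reads
  say("finding raw-read candidate overlaps")
  raw_ovs <- do.call(find_candidate_overlaps,
                     c(list(reads = reads), cfg$raw_overlap))
  report$raw_candidate_overlaps <- nrow(raw_ovs)

  # stage 3: haplotype-aware correction
  say("correcting ", length(reads), " reads")
  corr <- correct_reads(reads, raw_ovs, cfg$correction)
  creads <- corr$reads
  report$n_corrected <- length(creads)
  if (!is.null(out_dir)) {
    write_fasta(creads, outp("corrected.fa"))
    data.table::fwrite(corr$provenance, outp("provenance.tsv"), sep = "\t")
  }

  # stage 4: overlaps between corrected reads + filters
  say("overlapping corrected reads")
  ostage <- overlap_stage(creads, cfg$overlap_filter,
                          k = cfg$corrected_overlap$k,
                          w = cfg$corrected_overlap$w,
                          min_shared = cfg$corrected_overlap$min_shared)
  ovs <- ostage$overlaps
  report$overlap_status <- as.list(setNames(
    overlap_status_counts(ovs)$N, overlap_status_counts(ovs)$status))
  report$n_contained <- nrow(ostage$contained)
  if (!is.null(out_dir)) write_paf(ovs, outp("overlaps.paf"))

  # singleton contigs only for truly isolated reads: reads whose overlaps
  # were all removed by containment are already represented elsewhere
  touched <- unique(c(ovs$read_a, ovs$read_b))
  loose <- setdiff(names(creads), c(touched, ostage$contained$read))

  # stage 5: round-1 assembly (haplotype-collapsed)
  say("round-1 assembly")
  asm1 <- assemble_round(ovs, creads, ostage$contained,
                         cfg$overlap_filter, pop_bubbles = TRUE,
                         singleton_reads = loose, prefix = "ctg1_")
  report$round1_contigs <- length(asm1$contigs)
  report$round1_total_bp <- sum(nchar(asm1$contigs))
  report$round1_status <- as.list(setNames(asm1$status$N,
                                           asm1$status$status))
  if (!is.null(out_dir)) {
    write_fasta(asm1$contigs, outp("asm1.fa"))
    write_gfa(asm1$graph, outp("asm1.gfa"))
    data.table::fwrite(asm1$layout, outp("asm1_layout.tsv"), sep = "\t")
  }

  # stage 6: phasing and inconsistent-overlap identification against the
  # deduplicated (haplotype-collapsed) round-1 representation
  say("phasing reads on round-1 contigs")
  collapsed <- dedupe_contigs(asm1$contigs)
  report$round1_collapsed_contigs <- length(collapsed)
  if (is.null(vcf_sites) && raw_snp) {
    say("calling raw-read SNP sites on round-1 contigs")
    mp_raw <- map_reads_to_contigs(reads, collapsed)
    vcf_sites <- call_het_sites(mp_raw$basecalls, cfg$snp_call)[
      , .(contig, pos, allele1, allele2)]
    report$raw_het_sites <- nrow(vcf_sites)
  }
  ph <- phase_stage(creads, collapsed, ovs, cfg$snp_call, cfg$grouping,
                    raw_reads = if (!is.null(vcf_sites)) reads else NULL,
                    vcf_sites = vcf_sites)
  report$het_sites <- nrow(ph$sites)
  report$inconsistent_pairs <- nrow(ph$pairs)
  report$inconsistent_overlaps <- sum(ph$overlaps$inconsistent)
  if (!is.null(out_dir)) {
    data.table::fwrite(ph$sites, outp("het_sites_called.tsv"), sep = "\t")
    data.table::fwrite(ph$pairs, outp("inconsistent_pairs.tsv"),
                       sep = "\t")
    write_paf(ph$overlaps[status == "retained" & !inconsistent],
              outp("filtered.paf"))
  }

  # stage 7: round-2 assembly on filtered overlaps; containment is
  # recomputed so reads contained only in the other haplotype become free
  say("round-2 assembly")
  ost2 <- refilter_overlaps(ph$overlaps, cfg$overlap_filter)
  ovs2 <- ost2$overlaps
  report$round2_contained <- nrow(ost2$contained)
  g2 <- build_string_graph(ovs2, cfg$overlap_filter)
  g2 <- mark_transitive(g2)
  idf2 <- identity_filter(g2, ovs2, creads)
  g2 <- idf2$graph
  thr2 <- if (!is.null(idf2$stats)) idf2$stats$threshold else NULL
  g2 <- repair_dead_ends(g2, ovs2, creads, ost2$contained, thr2,
                         cfg$overlap_filter)
  g2 <- best_overlap_select(g2, ph$evidence, ph$pairs, cfg$bog)
  g2 <- simplify_ambiguous(g2, pop_bubbles = FALSE)
  loose2 <- setdiff(names(creads), c(touched, ost2$contained$read))
  pa <- emit_primary_alternate(g2, creads, ph$pairs,
                               singleton_reads = loose2)
  pa$primary <- dedupe_contigs(pa$primary)
  pa$layout <- pa$layout[contig %in% names(pa$primary)]
  dual <- connect_dual_paths(g2, creads, ph$amat, ph$pairs,
                             seed = cfg$seed, singleton_reads = loose2)
  # within each haplotype set, duplicate fragments map into longer contigs
  dual$hap1 <- dedupe_contigs(dual$hap1)
  dual$hap2 <- dedupe_contigs(dual$hap2)
  dual$layout1 <- dual$layout1[contig %in% names(dual$hap1)]
  dual$layout2 <- dual$layout2[contig %in% names(dual$hap2)]
  report$round2_primary <- length(pa$primary)
  report$round2_alternate <- length(pa$alternate)
  report$round2_bubbles <- length(pa$bubbles)
  report$hap1_total_bp <- sum(nchar(dual$hap1))
  report$hap2_total_bp <- sum(nchar(dual$hap2))
  if (length(dual$hap2) == 0)
    warning("no alternate paths found; dual assembly is a single haplotype")
  if (!is.null(out_dir)) {
    write_fasta(pa$primary, outp("primary.fa"))
    if (length(pa$alternate)) write_fasta(pa$alternate, outp("alternate.fa"))
    write_fasta(dual$hap1, outp("hap1.fa"))
    if (length(dual$hap2)) write_fasta(dual$hap2, outp("hap2.fa"))
    write_gfa(g2, outp("asm2.gfa"))
  }

  # stage 8: truth-based evaluation (simulated data only)
  ev <- NULL
  if (!is.null(sim)) {
    say("evaluating against the simulated truth")
    ev <- evaluate_assembly(dual, sim)
    report$eval <- ev$summary
  }
  res <- list(config = cfg, sim = sim, raw_overlaps = raw_ovs,
              corrected = corr, overlap = ostage, asm1 = asm1, phase = ph,
              graph2 = g2, primary_alternate = pa, dual = dual,
              eval = ev, report = report)
  if (!is.null(out_dir))
    jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(res)
}

#' Align dual haplotype contigs to the simulated truth
#'
#' Each assembled haplotype contig is assigned to the truth haplotype it
#' matches best (by haplotype-specific k-mers), aligned, and scored for
#' identity; switch events are counted over the truth heterozygous sites
#' covered by each contig.
#'
#' @param dual output of \code{\link{connect_dual_paths}}
#' @param sim simulated dataset (haplotypes + truth)
#' @return list: per-contig table and a summary list
#' @export
evaluate_assembly <- function(dual, sim) {
  ks <- trio_kmer_sets(sim$haplotypes, k = 21L)
  contigs <- c(dual$hap1, dual$hap2)
  if (!length(contigs))
    return(list(contigs = NULL,
                summary = list(hap_identity = NA_real_)))
  cnt <- count_specific_kmers(contigs, ks)
  rows <- list()
  for (i in seq_len(nrow(cnt))) {
    nm <- cnt$read[i]
    hap <- if (cnt$k_p[i] >= cnt$k_m[i]) 1L else 2L
    tr <- sim$haplotypes[[hap]]
    al <- map_contig_to_truth(contigs[[nm]], tr)
    sw <- switch_events(contigs[[nm]], sim, hap, al)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      contig = nm, set = if (nm %in% names(dual$hap1)) "hap1" else "hap2",
      length = nchar(contigs[[nm]]), truth_hap = hap,
      identity = al$identity, switches = sw$switches,
      het_covered = sw$n_sites)
  }
  tab <- data.table::rbindlist(rows)
  wmean <- function(x, w) if (sum(w) > 0) sum(x * w) / sum(w) else NA_real_
  summary <- list(
    hap_identity = wmean(tab$identity, tab$length),
    total_switches = sum(tab$switches, na.rm = TRUE),
    het_covered = sum(tab$het_covered, na.rm = TRUE),
    hap1_bp = sum(tab$length[tab$set == "hap1"]),
    hap2_bp = sum(tab$length[tab$set == "hap2"]))
  list(contigs = tab, summary = summary)
}

# align a contig to a truth haplotype (orientation chosen by minimizers)
map_contig_to_truth <- function(contig, truth) {
  mp <- map_reads_to_contigs(c(q = contig), c(t = truth))
  if (!nrow(mp$placements))
    return(list(identity = NA_real_, placement = NULL, basecalls = NULL))
  list(identity = mp$placements$identity[1], placement = mp$placements,
       basecalls = mp$basecalls)
}

# haplotype switch events across truth het sites covered by the contig
switch_events <- function(contig, sim, hap, al) {
  sites <- sim$truth$het_sites
  if (is.null(al$basecalls) || !nrow(sites)) {
    return(list(switches = 0L, n_sites = 0L))
  }
  # truth coordinates: hap1 frame; for hap2 contigs shift by indel offsets
  pos2 <- hap2_positions(sites)
  snp <- sites$type == "snp"
  if (!any(snp)) return(list(switches = 0L, n_sites = 0L))
  pos <- if (hap == 1L) sites$pos[snp] else pos2[snp]
  a1 <- if (hap == 1L) sites$a1[snp] else sites$a2[snp]
  a2 <- if (hap == 1L) sites$a2[snp] else sites$a1[snp]
  hit <- al$basecalls$base[match(pos, al$basecalls$pos)]
  ok <- !is.na(hit)
  state <- ifelse(hit[ok] == a1[ok], 1L,
                  ifelse(hit[ok] == a2[ok], 2L, NA_integer_))
  state <- state[!is.na(state)]
  if (length(state) < 2) return(list(switches = 0L,
                                     n_sites = length(state)))
  list(switches = sum(diff(state) != 0), n_sites = length(state))
}

# het-site positions mapped onto the haplotype-2 frame
hap2_positions <- function(sites) {
  off <- ifelse(sites$type == "ins", sites$indel_len,
                ifelse(sites$type == "del", -sites$indel_len, 0L))
  sites$pos + c(0L, cumsum(off)[-nrow(sites)])
}
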