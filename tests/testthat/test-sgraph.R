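test_that("three tiling reads build a two-edge chain with twins", {
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2000, 4000),
                   end = c(3000, 5000, 7000), strand = "+")
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  g <- build_string_graph(ovs)
  expect_equal(nrow(g$edges), 4)    # 2 overlaps x (edge + twin)
  le <- diphase:::live_edges(g)
  expect_true("a:E" %in% le$src)
  # dual symmetry: every edge's twin exists with the same status
  expect_identical(g$edges$status, g$edges$status[g$edges$twin])
})

test_that("an empty overlap set gives an empty graph", {
  g <- build_string_graph(diphase:::empty_overlap_set())
  expect_equal(nrow(g$edges), 0)
  expect_equal(length(extract_contigs(g, character())$contigs), 0)
})

test_that("the defining transitive triangle is marked inactive", {
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 1500, 3000),
                   end = c(4000, 5500, 7000), strand = "+")
  ovs <- layout_overlap_set(iv)   # includes the a-c shortcut (1000 bp)
  ovs[, status := "retained"]
  g <- build_string_graph(ovs)
  g <- mark_transitive(g)
  ed <- g$edges
  ac <- ed[ed$src == "a:E" & ed$dst == "c:E", ]
  expect_equal(ac$status, "transitive")
  ab <- ed[ed$src == "a:E" & ed$dst == "b:E", ]
  expect_equal(ab$status, "active")
})

test_that("a chain without shortcuts keeps all edges active", {
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2500, 5000),
                   end = c(3000, 5500, 8000), strand = "+")
  ovs <- layout_overlap_set(iv)[a_end - a_start >= 400]
  ovs[, status := "retained"]
  g <- mark_transitive(build_string_graph(ovs))
  expect_true(all(g$edges$status == "active"))
})

test_that("transitive marking equals the brute-force oracle", {
  set.seed(31)
  for (trial in 1:40) {
    n <- sample(5:14, 1)
    starts <- sort(sample(0:12000, n))
    iv <- data.frame(read = sprintf("r%02d", 1:n), start = starts,
                     end = starts + sample(2500:5000, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE))
    ovs <- layout_overlap_set(iv, min_ov = 300)
    if (!nrow(ovs)) next
    ovs[, status := "retained"]
    g0 <- build_string_graph(ovs)
    if (!nrow(g0$edges)) next
    g <- mark_transitive(g0, fuzz = 500)
    want <- oracle_transitive(g0$edges, fuzz = 500)
    expect_identical(g$edges$status == "transitive", want,
                     info = paste("trial", trial))
  }
})

test_that("identity threshold formula matches direct evaluation", {
  # zero dispersion: threshold equals the common value
  st <- identity_stats(rep(0.95, 8))
  expect_equal(st$threshold, 0.95)
  # printed worked example
  ids <- c(rep(0.99, 9), 0.80)
  st2 <- identity_stats(ids)
  expect_equal(st2$m1, 0.971)
  expect_equal(st2$m2, 0.99)
  expect_equal(st2$MAD2, 0)
  expect_equal(st2$threshold,
               ((0.971 - 6 * 1.253 * st2$MAD1) + 2 * 0.99) / 3)
  expect_equal(round(st2$threshold, 3), 0.898)
  # randomized conformance
  set.seed(32)
  for (i in 1:120) {
    ids <- runif(sample(3:40, 1), 0.7, 1)
    expect_equal(identity_stats(ids)$threshold,
                 oracle_identity_threshold(ids))
  }
  # duplication invariance of the multiset
  ids3 <- runif(10, 0.8, 1)
  expect_equal(identity_stats(rep(ids3, 2))$threshold,
               identity_stats(ids3)$threshold)
})

test_that("low-identity edges are removed and twins follow", {
  ref <- random_genome(16000, seed = 33)
  n <- 8
  starts <- seq(0, 14000, by = 2000)[1:n]
  iv <- data.frame(read = sprintf("r%02d", 1:n), start = starts,
                   end = pmin(starts + 3500, 16000), strand = "+")
  reads <- layout_reads(ref, iv)
  # corrupt r04's tail so only the r04-r05 overlap has low identity
  rc <- strsplit(reads[["r04"]], "")[[1]]
  set.seed(33)
  mut <- sample(2300:length(rc), 350)
  rc[mut] <- vapply(rc[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  reads[["r04"]] <- paste(rc, collapse = "")
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  g <- mark_transitive(build_string_graph(ovs))
  res <- identity_filter(g, ovs, reads)
  bad <- res$graph$edges[status == "removed_low_quality"]
  expect_gt(nrow(bad), 0)
  expect_true(all(grepl("r04", paste(bad$src, bad$dst))))
  expect_identical(res$graph$edges$status,
                   res$graph$edges$status[res$graph$edges$twin])
})

test_that("dead ends are repaired by reactivating transitive shortcuts", {
  ref <- random_genome(16000, seed = 34)
  n <- 8
  starts <- seq(0, 14000, by = 2000)[1:n]
  iv <- data.frame(read = sprintf("r%02d", 1:n), start = starts,
                   end = pmin(starts + 4500, 16000), strand = "+")
  reads <- layout_reads(ref, iv)
  ovs <- layout_overlap_set(iv, min_ov = 300)
  ovs[, status := "retained"]
  g <- mark_transitive(build_string_graph(ovs))
  # break the chain: remove the direct r04-r05 edges
  brk <- which((g$edges$src == "r04:E" & g$edges$dst == "r05:E") |
                 (g$edges$src == "r05:B" & g$edges$dst == "r04:B"))
  g <- diphase:::set_edge_status(g, brk, "removed_low_quality")
  contained <- data.table::data.table(read = character(),
                                      container = character())
  g2 <- repair_dead_ends(g, ovs, reads, contained, threshold = 0.9)
  expect_gt(nrow(g2$edges[status == "reactivated"]), 0)
  # the break is bridged: one contig spans reads from both sides
  ctg <- extract_contigs(g2, reads)
  main <- ctg$layout[contig ==
                       names(ctg$contigs)[which.max(nchar(ctg$contigs))]]
  expect_true(any(main$read %in% c("r01", "r02", "r03", "r04")) &&
                any(main$read %in% c("r06", "r07", "r08")))
})

test_that("a graph without dead ends is unchanged by repair", {
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2000, 4000),
                   end = c(3000, 5000, 7000), strand = "+")
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  ref <- random_genome(7000, seed = 35)
  reads <- layout_reads(ref, iv)
  g <- mark_transitive(build_string_graph(ovs))
  g2 <- repair_dead_ends(g, ovs, reads,
                         data.table::data.table(read = character(),
                                                container = character()),
                         threshold = NULL)
  expect_identical(g$edges$status, g2$edges$status)
})

test_that("best-overlap selection follows the score and gap rules", {
  # single out-edge is best
  iv <- data.frame(read = c("a", "b"), start = c(0, 2000),
                   end = c(3000, 5000), strand = "+")
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  g <- best_overlap_select(build_string_graph(ovs))
  expect_true(all(g$edges$status == "best"))

  # direct evaluation of the gap bound
  expect_true(oracle_bog_gap_ok(3, 0, C = 4, R1 = 2, R2 = 0.66))
  expect_false(oracle_bog_gap_ok(3, -2, C = 4, R1 = 2, R2 = 0.66))
  set.seed(36)
  p <- bog_params()
  for (i in 1:120) {
    s0 <- runif(1, -5, 10); si <- runif(1, -10, s0)
    bound <- if (si >= 0) max(p$C, si * p$R1) else max(p$C, -si * p$R2)
    expect_equal((s0 - si) < bound, oracle_bog_gap_ok(s0, si, p$C, p$R1,
                                                      p$R2))
  }
})

test_that("inconsistent branches survive best-overlap selection", {
  # a branches into b and c; b/c are mutually inconsistent (two
  # haplotypes), so both branch edges must be kept
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2000, 2000),
                   end = c(3000, 6000, 6000), strand = "+")
  ovs <- layout_overlap_set(iv)[!(read_a == "b" & read_b == "c")]
  ovs[, status := "retained"]
  g <- build_string_graph(ovs)
  ev <- data.table::data.table(read1 = c("a", "a"), read2 = c("b", "c"),
                               n_same = c(6L, 6L), n_diff = c(0L, 0L))
  inc <- data.table::data.table(read1 = "b", read2 = "c")
  g2 <- best_overlap_select(g, ev, inc)
  le <- diphase:::live_edges(g2)
  expect_true(any(le$src == "a:E" & le$dst == "b:E"))
  expect_true(any(le$src == "a:E" & le$dst == "c:E"))
})

test_that("tips and spurs are removed, chains and contigs survive", {
  ref <- random_genome(14000, seed = 37)
  iv <- data.frame(read = sprintf("r%02d", 1:6),
                   start = c(0, 2000, 4000, 6000, 8000, 10000),
                   end = c(3000, 5000, 7000, 9000, 11000, 14000),
                   strand = "+")
  # a short spur branching off r03
  iv <- rbind(iv, data.frame(read = "tip", start = 4500, end = 7500,
                             strand = "+"))
  reads <- layout_reads(ref, iv)
  # corrupt the tip's tail so it dead-ends instead of rejoining
  reads[["tip"]] <- paste0(substr(reads[["tip"]], 1, 1500),
                           random_genome(1500, seed = 38))
  ovs <- find_candidate_overlaps(reads, k = 15, w = 10, min_shared = 4)
  res <- overlap_stage(reads, overlap_filter_params("pacbio",
                                                    min_coverage = 0),
                       ovs = ovs)
  g <- mark_transitive(build_string_graph(res$overlaps))
  g <- simplify_ambiguous(g)
  ctg <- extract_contigs(g, reads)
  main <- ctg$contigs[which.max(nchar(ctg$contigs))]
  expect_false("tip" %in% ctg$layout[contig == names(main), read])
  expect_gt(nchar(main), 12000)
})

test_that("a linear chain is unchanged by simplification", {
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2000, 4000),
                   end = c(3000, 5000, 7000), strand = "+")
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  g <- build_string_graph(ovs)
  g2 <- simplify_ambiguous(g)
  expect_identical(g$edges$status, g2$edges$status)
})

test_that("contig sequence splices reads by coordinate arithmetic", {
  ref <- random_genome(7000, seed = 39)
  iv <- data.frame(read = c("a", "b", "c"), start = c(0, 2000, 4000),
                   end = c(3000, 5000, 7000), strand = c("+", "-", "+"))
  reads <- layout_reads(ref, iv)
  ovs <- layout_overlap_set(iv)
  ovs[, status := "retained"]
  g <- build_string_graph(ovs)
  ctg <- extract_contigs(g, reads)
  expect_equal(length(ctg$contigs), 1)
  expect_equal(nchar(ctg$contigs[[1]]), 7000)
  expect_true(ctg$contigs[[1]] == ref ||
                ctg$contigs[[1]] == revcomp(ref))
})

test_that("error-free homozygous simulation assembles one clean contig", {
  p <- sim_params(genome_length = 50000, het_rate = 0, error_rate = 0,
                  depth_per_haplotype = 10, seed = 40)
  d <- simulate_dataset(p)
  ost <- overlap_stage(d$reads, overlap_filter_params("pacbio"),
                       k = 15, w = 10, min_shared = 6)
  asm <- assemble_round(ost$overlaps, d$reads, ost$contained,
                        overlap_filter_params("pacbio"))
  expect_equal(length(asm$contigs), 1)
  big <- asm$contigs[[1]]
  al1 <- diphase:::align_global(big, d$haplotypes[[1]], free_ends = TRUE)
  al2 <- diphase:::align_global(revcomp(big), d$haplotypes[[1]],
                                free_ends = TRUE)
  expect_gt(max(al1$identity, al2$identity), 0.999)
  expect_gt(nchar(big), 47000)
  # stage accounting partitions the edges
  expect_equal(sum(asm$status$N), nrow(asm$graph$edges))
})
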