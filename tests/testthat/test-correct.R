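test_that("a template alone builds a linear self-chain", {
  g <- build_poa_graph("ACGTT")
  expect_equal(nrow(g$nodes), 5)
  expect_true(all(g$nodes$r == 0))
  expect_identical(g$nodes$b, c("A", "C", "G", "T", "T"))
  expect_true(all(g$edges$support == 1))
  expect_equal(nrow(g$edges), 4)
})

test_that("a substitution creates two parallel r=0 nodes", {
  tpl <- "ACGTACGTAC"
  # support read differs at c = 5 (0-based): G instead of C
  q <- "ACGTAGGTAC"
  g <- build_poa_graph(tpl, list(mkaln("s1", 0, "MMMMMXMMMM", q)))
  fam <- g$nodes[g$nodes$c == 5 & g$nodes$r == 0, ]
  expect_setequal(fam$b, c("C", "G"))
  ids <- fam$id
  ed <- g$edges[g$edges$to %in% ids, ]
  expect_equal(sort(ed$support), c(1, 1))
})

test_that("a 2-bp insertion creates an r = 1,2 chain", {
  tpl <- "ACGTACGT"
  # insertion of "TT" after template position 3
  q <- "ACGTTTACGT"
  g <- build_poa_graph(tpl, list(mkaln("s1", 0, "MMMMIIMMMM", q)))
  ins <- g$nodes[g$nodes$r > 0, ]
  expect_equal(ins$c, c(3, 3))
  expect_equal(sort(ins$r), c(1, 2))
  expect_true(all(ins$b == "T"))
})

test_that("alignments outside the template are rejected with a warning", {
  expect_warning(
    g <- build_poa_graph("ACGT", list(mkaln("bad", 2, "MMMM", "GTAC"))),
    "outside")
  expect_equal(length(g$paths), 1)
})

test_that("important-edge threshold matches the piecewise formula", {
  p <- correction_params()
  # boundary: S = 10, s = 5 -> threshold 0.5*10 = 5, flagged
  expect_equal(piecewise_threshold(10, 0.5, 0.2, 10, 200), 5)
  # interpolation: S = 20 -> ~6.84
  th <- piecewise_threshold(20, 0.5, 0.2, 10, 200)
  expect_equal(th, (0.2 * 200 - 0.5 * 10) / (200 - 10) * 10 + 5)
  expect_equal(round(th, 2), 6.84)
  # high-S regime: S = 1000 -> 200; s = 199 not flagged
  expect_equal(piecewise_threshold(1000, 0.5, 0.2, 10, 200), 200)
  # randomized conformance against the independent oracle
  set.seed(21)
  for (i in 1:120) {
    r_l <- runif(1, 0.3, 0.9); r_h <- runif(1, 0.05, r_l - 0.05)
    S_l <- sample(5:50, 1); S_h <- S_l + sample(50:500, 1)
    S <- sample(1:2000, 5)
    expect_equal(piecewise_threshold(S, r_l, r_h, S_l, S_h),
                 oracle_piecewise(S, r_l, r_h, S_l, S_h))
  }
})

# a template with a clean biallelic site at position 10, half the supports
# carrying each allele
biallelic_graph <- function(n_each = 6, hp = FALSE) {
  set.seed(22)
  base <- strsplit(random_genome(21, seed = 23), "")[[1]]
  base[8:12] <- c("A", "C", "T", "G", "A")   # no homopolymer around c=10
  if (hp) base[9:13] <- c("A", "A", "A", "A", "A")
  tpl <- paste(base, collapse = "")
  alns <- list()
  for (i in seq_len(n_each)) # template allele
    alns[[length(alns) + 1]] <- mkaln(paste0("same", i), 0,
                                      paste(rep("M", 21), collapse = ""),
                                      tpl)
  alt <- base; alt[11] <- setdiff(c("A", "C", "G", "T"), base[11])[1]
  ops <- rep("M", 21); ops[11] <- "X"
  for (i in seq_len(n_each))
    alns[[length(alns) + 1]] <- mkaln(paste0("diff", i), 0,
                                      paste(ops, collapse = ""),
                                      paste(alt, collapse = ""))
  build_poa_graph(tpl, alns)
}

test_that("a balanced biallelic site is an important location", {
  g <- biallelic_graph()
  imp <- mark_important_edges(g)
  iml <- mark_important_locations(g, imp)
  expect_true(10 %in% iml$locations)
})

test_that("a homopolymer site is excluded", {
  g <- biallelic_graph(hp = TRUE)
  imp <- mark_important_edges(g)
  iml <- mark_important_locations(g, imp)
  expect_false(10 %in% iml$locations)
})

test_that("a length-changing bubble is excluded", {
  tpl <- "ACGTACGTACGTACGTACGT"
  alns <- list()
  for (i in 1:6)
    alns[[length(alns) + 1]] <- mkaln(paste0("same", i), 0,
                                      paste(rep("M", 20), collapse = ""), tpl)
  # heterozygous 1-bp deletion at c = 10
  ops <- rep("M", 20); ops[11] <- "D"
  qdel <- paste0(substr(tpl, 1, 10), substr(tpl, 12, 20))
  for (i in 1:6)
    alns[[length(alns) + 1]] <- mkaln(paste0("del", i), 0,
                                      paste(ops, collapse = ""), qdel)
  g <- build_poa_graph(tpl, alns)
  imp <- mark_important_edges(g)
  iml <- mark_important_locations(g, imp)
  expect_false(10 %in% iml$locations)
})

test_that("supporting reads are scored by important-edge agreement", {
  g <- biallelic_graph()
  imp <- mark_important_edges(g)
  iml <- mark_important_locations(g, imp)
  sc <- score_supporting_reads(g, iml)
  same <- sc[grepl("^same", sc$read)]
  diff <- sc[grepl("^diff", sc$read)]
  expect_true(all(same$normalized == 1))
  expect_true(all(diff$normalized == -1))
})

test_that("score normalization divides by covered important locations", {
  # synthetic tally check: 4 agreements, 1 disagreement over 5 locations
  sc <- data.table::data.table(read = "r", raw = 3L, n_important = 5L,
                               normalized = 3 / 5)
  expect_equal(sc$normalized, 0.6)
  # read covering no important location scores 0
  g <- biallelic_graph()
  iml <- mark_important_locations(g, mark_important_edges(g))
  g2 <- build_poa_graph(g$template,
                        list(mkaln("far", 15, "MMMMM",
                                   substr(g$template, 16, 20))))
  sc2 <- score_supporting_reads(g2, iml)
  expect_equal(sc2$normalized, 0)
})

test_that("bimodal scores select the high-score mode", {
  sc <- data.table::data.table(
    read = sprintf("r%02d", 1:20),
    raw = c(rep(9L, 10), rep(-8L, 10)),
    n_important = 10L,
    normalized = c(rep(0.9, 10), rep(-0.8, 10)))
  sw <- select_and_weight(sc)
  expect_identical(sw$selected, c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_true(all(sw$weight[1:10] > 0))
  expect_true(all(sw$weight[11:20] == 0))
})

test_that("unimodal scores select the top half with ties", {
  sc <- data.table::data.table(
    read = sprintf("r%02d", 1:10), raw = 1L, n_important = 10L,
    normalized = seq(0.31, 0.40, by = 0.01))
  sw <- select_and_weight(sc)
  expect_equal(sum(sw$selected), 5)
  expect_true(all(sw$normalized[sw$selected] >=
                    max(sw$normalized[!sw$selected])))
})

test_that("selected scores map linearly onto the weight range", {
  # a clear low mode plus a compact high mode that is selected whole;
  # the three distinct high scores must map onto the range ends/midpoint
  sc <- data.table::data.table(
    read = sprintf("r%02d", 1:9),
    raw = 1L, n_important = 10L,
    normalized = c(rep(-0.8, 6), 0.5, 0.6, 0.7))
  sw <- select_and_weight(sc)
  sel <- sw[sw$selected == TRUE]
  expect_equal(nrow(sel), 3)
  expect_equal(sort(sel$weight), c(0.4, 0.6, 0.8), tolerance = 1e-9)
})

test_that("fewer than two supports select everything at the midpoint", {
  sc <- data.table::data.table(read = "only", raw = 2L, n_important = 3L,
                               normalized = 2 / 3)
  sw <- select_and_weight(sc)
  expect_true(sw$selected)
  expect_equal(sw$weight, 0.6)
})

test_that("consensus of identical supports reproduces the template", {
  tpl <- random_genome(60, seed = 24)
  alns <- lapply(1:5, function(i)
    mkaln(paste0("s", i), 0, paste(rep("M", 60), collapse = ""), tpl))
  g <- build_poa_graph(tpl, alns)
  w <- data.table::data.table(read = paste0("s", 1:5), weight = 0.6)
  cons <- poa_consensus(g, w)
  expect_identical(cons$sequence, tpl)
})

test_that("a template error is outvoted by the supports", {
  tpl0 <- random_genome(60, seed = 25)
  chars <- strsplit(tpl0, "")[[1]]
  true_base <- chars[30]
  chars[30] <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  tpl <- paste(chars, collapse = "")  # template carries the error
  ops <- rep("M", 60); ops[30] <- "X"
  alns <- lapply(1:9, function(i)
    mkaln(paste0("s", i), 0, paste(ops, collapse = ""), tpl0))
  g <- build_poa_graph(tpl, alns)
  w <- data.table::data.table(read = paste0("s", 1:9), weight = 0.6)
  cons <- poa_consensus(g, w)
  expect_identical(substr(cons$sequence, 30, 30), true_base)
  expect_identical(cons$sequence, tpl0)
})

test_that("consensus DP equals exhaustive path enumeration on small graphs", {
  set.seed(26)
  for (trial in 1:30) {
    tlen <- sample(4:6, 1)
    tpl <- random_genome(tlen, seed = 260 + trial)
    nsup <- sample(2:4, 1)
    alns <- lapply(seq_len(nsup), function(i) {
      q <- strsplit(tpl, "")[[1]]
      ops <- rep("M", tlen)
      pos <- sample(tlen, 1)
      kind <- sample(c("X", "I"), 1)
      if (kind == "X") {
        q[pos] <- sample(setdiff(c("A", "C", "G", "T"), q[pos]), 1)
        ops[pos] <- "X"
      } else {
        ops <- append(ops, "I", after = pos)
        q <- append(q, sample(c("A", "C", "G", "T"), 1), after = pos)
      }
      mkaln(paste0("s", i), 0, paste(ops, collapse = ""),
            paste(q, collapse = ""))
    })
    g <- build_poa_graph(tpl, alns)
    if (nrow(g$nodes) > 12) next
    wts <- data.table::data.table(read = paste0("s", seq_len(nsup)),
                                  weight = runif(nsup, 0.4, 0.8))
    cons <- poa_consensus(g, wts)
    # rebuild the weighted edge table exactly as the DP sees it
    eps <- 1e-6
    pe <- diphase:::path_edge_table(g)
    wv <- setNames(wts$weight, wts$read)
    pe[, w := c(eps, wv[g$read_ids])[path]]
    ew <- pe[, .(weight = sum(w)), by = .(from, to)]
    ed <- ew[g$edges, on = c("from", "to")]
    ed[is.na(weight), weight := 0]
    Wc <- rep(0, tlen)
    for (i in seq_len(nrow(g$spans)))
      Wc[(g$spans$tstart[i] + 1):g$spans$tend[i]] <-
      Wc[(g$spans$tstart[i] + 1):g$spans$tend[i]] + wv[g$spans$read[i]]
    best <- oracle_consensus_score(g$nodes, ed, ed$weight, Wc + eps)
    dp <- .Call <- diphase:::.poa_consensus_cpp(g$nodes$c, g$nodes$r,
                                                ed$from, ed$to, ed$weight,
                                                Wc + eps, 0.4, 0.3)
    expect_equal(dp$score, best, tolerance = 1e-9)
  }
})

test_that("selection confines supports to the template's haplotype", {
  p <- sim_params(genome_length = 12000, het_rate = 0.01,
                  depth_per_haplotype = 12, error_rate = 0.10,
                  read_length_mean = 3000, read_length_sd = 400, seed = 27)
  d <- simulate_dataset(p)
  ovs <- find_candidate_overlaps(d$reads, k = 13, w = 8, min_shared = 4)
  hap <- setNames(d$truth$read_labels$hap, d$truth$read_labels$read)
  ids <- names(d$reads)[seq(1, length(d$reads), by = 6)]
  sel_cross <- all_cross <- c()
  for (id in ids) {
    r <- correct_read(id, ovs, d$reads)
    if (!length(r$selected)) next
    sup <- unique(c(ovs[read_a == id, read_b], ovs[read_b == id, read_a]))
    sel_cross <- c(sel_cross, mean(hap[r$selected] != hap[id]))
    all_cross <- c(all_cross, mean(hap[sup] != hap[id]))
  }
  expect_lt(mean(sel_cross), 0.10)
  expect_gt(mean(all_cross), 0.25)
  expect_lt(mean(sel_cross), mean(all_cross) / 3)
})

test_that("unchanged template is returned when no supports exist", {
  reads <- c(lonely = random_genome(2000, seed = 28))
  ovs <- diphase:::empty_overlap_set()
  r <- correct_read("lonely", ovs, reads)
  expect_true(r$flagged)
  expect_identical(r$sequence, reads[["lonely"]])
})
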