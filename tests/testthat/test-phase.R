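# helpers to fabricate base calls and allele matrices ------------------

# basecalls for a single contig position from a named count vector
mk_counts <- function(pos, ...) {
  counts <- c(...)
  data.table::data.table(
    read = sprintf("r%03d", seq_len(sum(counts))),
    contig = "c1", pos = pos,
    base = rep(names(counts), counts))
}

# allele matrix from a 0/1/2 matrix (rows reads, cols sites)
amat_from_matrix <- function(M) {
  dt <- data.table::as.data.table(as.table(M))
  data.table::setnames(dt, c("read", "site_id", "h"))
  dt[, h := as.integer(h)]
  dt[h >= 0]  # keep 0 rows: covered sites
}

# simulate a two-haplotype allele matrix with per-allele noise; the
# groups are deliberately unequal (balanced groups give uninformative
# zero-vote centroids)
sim_amat <- function(n_reads = 24, n_sites = 12, noise = 0.05, seed = 50) {
  set.seed(seed)
  n1 <- ceiling(n_reads * 0.6)
  hap <- rep(1:2, c(n1, n_reads - n1))
  M <- matrix(0L, n_reads, n_sites,
              dimnames = list(sprintf("r%03d", 1:n_reads),
                              sprintf("c1:%d", seq_len(n_sites) * 100)))
  for (i in seq_len(n_reads)) {
    h <- ifelse(hap[i] == 1, 1L, 2L)
    v <- rep(h, n_sites)
    flip <- runif(n_sites) < noise
    v[flip] <- 3L - v[flip]
    M[i, ] <- v
  }
  list(M = M, hap = setNames(hap, rownames(M)))
}

test_that("heterozygous sites follow the coverage-dependent threshold", {
  p <- snp_call_params()
  # c = 10 (= c_l), counts A:6 C:4 -> threshold 4, site called
  s1 <- call_het_sites(mk_counts(100, A = 6, C = 4), p)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$allele1, "A")
  expect_equal(s1$allele2, "C")
  # c = 50: threshold ~11.1 -> 11 fails, 12 passes
  th <- piecewise_threshold(50, 0.4, 0.2, 10, 100)
  expect_equal(th, (0.2 * 100 - 0.4 * 10) / 90 * 40 + 4)
  expect_equal(nrow(call_het_sites(mk_counts(100, A = 39, C = 11), p)), 0)
  expect_equal(nrow(call_het_sites(mk_counts(100, A = 38, C = 12), p)), 1)
  # coverage below the range: never a site
  expect_equal(nrow(call_het_sites(mk_counts(100, A = 4, C = 4), p)), 0)
})

test_that("read alleles encode first/second/other bases as 1/2/0", {
  bc <- mk_counts(100, A = 7, C = 5)
  bc <- rbind(bc, data.table::data.table(read = "odd", contig = "c1",
                                         pos = 100, base = "G"))
  sites <- call_het_sites(bc)
  am <- call_read_alleles(bc, sites)
  expect_true(all(am[read %in% sprintf("r%03d", 1:7), h] == 1))
  expect_true(all(am[read %in% sprintf("r%03d", 8:12), h] == 2))
  expect_equal(am[read == "odd", h], 0L)
  # uncovered reads simply have no row
  expect_false("absent" %in% am$read)
  # H conservation: count(h=1) + count(h=2) <= coverage
  expect_lte(am[h != 0, .N], nrow(bc))
})

test_that("centroid algebra follows the V/A/S/D definitions", {
  M <- rbind(r1 = c(1L, 1L, 2L), r2 = c(1L, 1L, 2L), r3 = c(1L, 2L, 2L))
  colnames(M) <- c("s1", "s2", "s3")
  C <- centroid_of(M)
  expect_equal(unname(C$v), c(3, 1, -3))
  expect_equal(unname(C$n), c(3, 3, 3))
  # identical centroids: D empty, S = A = verified sites
  cs <- centroid_sets(C, C, 0, 0)
  expect_true(all(cs$A))
  expect_true(all(cs$S))
  expect_false(any(cs$D))
  # opposite signs are distance sites
  C2 <- list(v = c(-3, 1, 3), n = c(3, 3, 3))
  cs2 <- centroid_sets(C, C2, 0, 0)
  expect_equal(unname(which(cs2$D)), c(1, 3))
  # |v| below max(p0 n, p1) is not verified
  C3 <- list(v = 2, n = 10)
  expect_equal(unname(diphase:::verified_sign(C3, 0.3, 0)), 0)
  C4 <- list(v = 3, n = 10)
  expect_equal(unname(diphase:::verified_sign(C4, 0.3, 0)), 1)
})

test_that("dividing separates clean haplotype groups and stops on leaves", {
  sim <- sim_amat(n_reads = 20, n_sites = 10, noise = 0)
  leaves <- divide_group(sim$M)
  expect_equal(length(leaves), 2)
  part <- lapply(leaves, function(ix) unname(sort(sim$hap[ix])))
  expect_true(all(vapply(part, function(x) length(unique(x)) == 1, TRUE)))
  # homogeneous group: immediate leaf
  M1 <- matrix(1L, 10, 6)
  expect_equal(length(divide_group(M1)), 1)
  # tiny group: size rule
  M2 <- sim_amat(n_reads = 3, n_sites = 5)$M
  expect_equal(length(divide_group(M2)), 1)
})

test_that("combining merges split same-haplotype leaves into L1", {
  sim <- sim_amat(n_reads = 30, n_sites = 14, noise = 0.03, seed = 51)
  leaves <- divide_group(sim$M)
  L <- combine_subgroups(sim$M, leaves, template_row = 1L)
  expect_true(1L %in% L[[1]])
  hap_of_list <- lapply(L, function(ix) unique(unname(sim$hap[ix])))
  # template's haplotype fully in L1, other haplotype elsewhere
  h1 <- sim$hap[1]
  expect_true(all(sim$hap[L[[1]]] == h1))
  others <- unlist(L[-1])
  if (length(others)) expect_true(all(sim$hap[others] != h1))
})

test_that("verify/correct flips isolated allele errors", {
  sim <- sim_amat(n_reads = 16, n_sites = 8, noise = 0, seed = 52)
  M <- sim$M
  M[1, 3] <- 3L - M[1, 3]        # one sequencing-error flip
  am <- amat_from_matrix(M)
  vr <- verify_correct_alleles(am, grouping_params())
  fixed <- vr$amat[read == "r001" & site_id == colnames(M)[3], h]
  expect_equal(fixed, sim$M[1, 3])
  # noise-free matrix is a fixpoint
  am0 <- amat_from_matrix(sim$M)
  vr0 <- verify_correct_alleles(am0, grouping_params())
  expect_identical(
    vr0$amat[order(read, site_id)],
    am0[order(read, site_id)])
})

test_that("clustering recovers truth partitions on noisy matrices", {
  agree <- c()
  for (seed in 53:55) {
    sim <- sim_amat(n_reads = 24, n_sites = 12, noise = 0.05, seed = seed)
    leaves <- divide_group(sim$M)
    L <- combine_subgroups(sim$M, leaves, template_row = 1L)
    lab <- rep(NA_integer_, nrow(sim$M))
    for (k in seq_along(L)) lab[L[[k]]] <- k
    # adjusted agreement: best mapping of clusters onto haplotypes
    tab <- table(lab, sim$hap)
    agree <- c(agree, sum(apply(tab, 1, max)) / nrow(sim$M))
  }
  expect_gte(mean(agree), 0.9)
})

test_that("inconsistent pairs are symmetric and direction/distance aware", {
  # two haplotype groups of placed reads over shared sites
  sim <- sim_amat(n_reads = 16, n_sites = 12, noise = 0, seed = 56)
  am <- amat_from_matrix(sim$M)
  gp <- grouping_params(p7 = 2, loose_diff = 4L, strict_diff = 6L)
  vr <- verify_correct_alleles(am, gp)
  reads <- rownames(sim$M)
  placements <- data.table::data.table(
    read = reads, contig = "c1",
    start = 0L, end = 1500L, strand = "+", identity = 0.99)
  ovs <- data.table::data.table(
    read_a = reads[1], read_b = reads[2:16],
    strand = "+", a_len = 1500L, a_start = 0L, a_end = 1500L,
    b_len = 1500L, b_start = 0L, b_end = 1500L,
    shared = 10L, identity = NA_real_, status = "retained")
  res <- find_inconsistent_overlaps(vr$groups, ovs, placements, gp,
                                    min_diff = 6)
  pr <- res$pairs
  # symmetry
  expect_true(all(paste(pr$read2, pr$read1) %in%
                    paste(pr$read1, pr$read2)))
  # flagged pairs are exactly cross-haplotype ones
  expect_true(all(sim$hap[pr$read1] != sim$hap[pr$read2]))
  expect_gt(nrow(pr), 0)
  flagged <- res$overlaps[inconsistent == TRUE]
  expect_true(all(sim$hap[flagged$read_a] != sim$hap[flagged$read_b]))
})

test_that("repeat-displaced pairs are spared by the distance check", {
  sim <- sim_amat(n_reads = 16, n_sites = 12, noise = 0, seed = 57)
  am <- amat_from_matrix(sim$M)
  gp <- grouping_params(p7 = 2, loose_diff = 4L, strict_diff = 6L)
  vr <- verify_correct_alleles(am, gp)
  reads <- rownames(sim$M)
  placements <- data.table::data.table(
    read = reads, contig = "c1",
    start = c(0L, rep(c(0L, 5000L), length.out = 15)),
    end = c(1500L, rep(c(1500L, 6500L), length.out = 15)),
    strand = "+", identity = 0.99)
  ovs <- data.table::data.table(
    read_a = reads[1], read_b = reads[2:16],
    strand = "+", a_len = 1500L, a_start = 0L, a_end = 1500L,
    b_len = 1500L, b_start = 0L, b_end = 1500L,
    shared = 10L, identity = NA_real_, status = "retained")
  res <- find_inconsistent_overlaps(vr$groups, ovs, placements, gp,
                                    min_diff = 6)
  flagged <- res$overlaps[inconsistent == TRUE]
  # overlaps whose layout distance differs by 5 kb are never flagged
  far <- placements[match(flagged$read_b, read), start] == 5000L
  expect_false(any(far))
})

test_that("raw-read evidence widens the pair set through the loose pass", {
  # corrected-only result with no pairs; raw VCF evidence adds them
  sim <- sim_amat(n_reads = 12, n_sites = 10, noise = 0, seed = 58)
  empty <- list(pairs = data.table::data.table(read1 = character(),
                                               read2 = character()),
                overlaps = {
                  o <- data.table::data.table(
                    read_a = rownames(sim$M)[1],
                    read_b = rownames(sim$M)[2:12],
                    strand = "+", a_len = 1000L, a_start = 0L,
                    a_end = 1000L, b_len = 1000L, b_start = 0L,
                    b_end = 1000L, shared = 5L, identity = NA_real_,
                    status = "retained")
                  o[, inconsistent := FALSE]
                  o
                })
  expect_identical(merge_raw_snp_evidence(empty, NULL, NULL, NULL,
                                          empty$overlaps),
                   empty)
  expect_identical(
    merge_raw_snp_evidence(empty, NULL, NULL,
                           data.table::data.table(contig = character(),
                                                  pos = integer(),
                                                  allele1 = character(),
                                                  allele2 = character()),
                           empty$overlaps),
    empty)
})

test_that("allele thresholds gate the strict and loose passes", {
  # pair with 7 differing alleles: strict (8) fails, loose (6) flags
  M <- matrix(1L, 2, 12,
              dimnames = list(c("t", "q"), sprintf("c1:%d", 1:12 * 50)))
  M[2, 1:7] <- 2L
  # unequal clean backer groups so votes are informative
  back1 <- matrix(1L, 8, 12, dimnames = list(sprintf("a%d", 1:8),
                                             colnames(M)))
  back2 <- matrix(1L, 6, 12, dimnames = list(sprintf("b%d", 1:6),
                                             colnames(M)))
  back2[, 1:7] <- 2L
  MM <- rbind(M, back1, back2)
  am <- amat_from_matrix(MM)
  gp <- grouping_params(p7 = 2)
  vr <- verify_correct_alleles(am, gp)
  reads <- rownames(MM)
  placements <- data.table::data.table(read = reads, contig = "c1",
                                       start = 0L, end = 700L,
                                       strand = "+", identity = 0.99)
  ovs <- data.table::data.table(
    read_a = "q", read_b = "t", strand = "+",
    a_len = 700L, a_start = 0L, a_end = 700L,
    b_len = 700L, b_start = 0L, b_end = 700L,
    shared = 5L, identity = NA_real_, status = "retained")
  strict <- find_inconsistent_overlaps(vr$groups, ovs, placements, gp,
                                       min_diff = gp$strict_diff)
  loose <- find_inconsistent_overlaps(vr$groups, ovs, placements, gp,
                                      min_diff = gp$loose_diff)
  expect_false(any(strict$pairs$read1 == "t" & strict$pairs$read2 == "q") ||
                 any(strict$pairs$read1 == "q" & strict$pairs$read2 == "t"))
  expect_true(any(loose$pairs$read1 == "q" & loose$pairs$read2 == "t") ||
                any(loose$pairs$read1 == "t" & loose$pairs$read2 == "q"))
})
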