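test_that("two identical reads yield one spanning candidate overlap", {
  g <- random_genome(5000, seed = 10)
  reads <- c(rA = g, rB = g)
  ovs <- find_candidate_overlaps(reads, k = 15, w = 10, min_shared = 4)
  expect_equal(nrow(ovs), 1)
  expect_equal(ovs$read_a, "rA")
  expect_gt(ovs$a_end - ovs$a_start, 4500)
})

test_that("unrelated sequences share no candidate overlap", {
  reads <- c(rA = random_genome(5000, seed = 11),
             rB = random_genome(5000, seed = 12))
  ovs <- find_candidate_overlaps(reads, k = 15, w = 10, min_shared = 4)
  expect_equal(nrow(ovs), 0)
})

test_that("error-free candidates cover all dovetailing truth pairs", {
  p <- sim_params(genome_length = 20000, het_rate = 0, error_rate = 0,
                  depth_per_haplotype = 8, read_length_mean = 2500,
                  read_length_sd = 300, seed = 13)
  d <- simulate_dataset(p)
  ovs <- find_candidate_overlaps(d$reads, k = 15, w = 10, min_shared = 4)
  key <- paste(ovs$read_a, ovs$read_b)
  lab <- d$truth$read_labels
  for (i in seq_len(nrow(lab) - 1)) for (j in (i + 1):nrow(lab)) {
    ov <- min(lab$end[i], lab$end[j]) - max(lab$start[i], lab$start[j])
    if (ov >= 1000) {
      pair <- paste(min(lab$read[i], lab$read[j]),
                    max(lab$read[i], lab$read[j]))
      expect_true(pair %in% key, info = pair)
    }
  }
})

test_that("overhang rule follows min(abs, frac*l) on the carrier read", {
  params <- overlap_filter_params("pacbio")
  # l = 20000, overhang 150: threshold min(100, 200) = 100 -> removed
  ov1 <- data.table::data.table(
    read_a = "a", read_b = "b", strand = "+",
    a_len = 20000L, a_start = 150L, a_end = 20000L,
    b_len = 20000L, b_start = 1000L, b_end = 20000L,
    shared = 10L, identity = NA_real_, status = "extended")
  expect_equal(filter_overhangs(ov1, params)$status, "removed_overhang")
  # l = 5000, overhang 40: threshold min(100, 50) = 50 -> retained
  ov2 <- data.table::data.table(
    read_a = "a", read_b = "b", strand = "+",
    a_len = 5000L, a_start = 40L, a_end = 5000L,
    b_len = 5000L, b_start = 1000L, b_end = 5000L,
    shared = 10L, identity = NA_real_, status = "extended")
  expect_equal(filter_overhangs(ov2, params)$status, "extended")
  # all-zero overhangs always retained
  ov3 <- data.table::data.table(
    read_a = "a", read_b = "b", strand = "+",
    a_len = 5000L, a_start = 0L, a_end = 4000L,
    b_len = 5000L, b_start = 1000L, b_end = 5000L,
    shared = 10L, identity = NA_real_, status = "extended")
  expect_equal(filter_overhangs(ov3, params)$status, "extended")
})

test_that("overhang rule matches direct evaluation over random cases", {
  set.seed(14)
  params <- overlap_filter_params("ont")
  for (i in 1:100) {
    l <- sample(1000:60000, 1)
    expect_equal(overhang_threshold(l, params),
                 oracle_overhang_threshold(l, 300, 0.03))
  }
  params2 <- overlap_filter_params("pacbio")
  for (i in 1:100) {
    l <- sample(1000:60000, 1)
    expect_equal(overhang_threshold(l, params2),
                 oracle_overhang_threshold(l, 100, 0.01))
  }
})

test_that("extension pushes candidate coordinates to the read ends", {
  ref <- random_genome(12000, seed = 15)
  iv <- data.frame(read = c("a", "b"), start = c(0, 3000),
                   end = c(8000, 11000), strand = c("+", "+"))
  reads <- layout_reads(ref, iv)
  ovs <- layout_overlap_set(iv)
  # trim the candidate 400 bp short of the true overlap on each side
  ovs[, `:=`(a_start = a_start + 400L, a_end = a_end - 400L,
             b_start = b_start + 400L, b_end = b_end - 400L)]
  ext <- extend_overlaps(ovs, reads)
  expect_equal(ext$a_start, 3000)
  expect_equal(ext$a_end, 8000)
  expect_equal(ext$b_start, 0)
  expect_equal(ext$b_end, 8000 - 3000)
})

test_that("an unalignable flap survives extension as residual overhang", {
  ref <- random_genome(9000, seed = 16)
  iv <- data.frame(read = c("a", "b"), start = c(0, 3000),
                   end = c(6000, 9000), strand = c("+", "+"))
  reads <- layout_reads(ref, iv)
  # append 150 bp of foreign sequence to a's 3' end (chimeric junction)
  reads[["a"]] <- paste0(reads[["a"]], random_genome(150, seed = 99))
  ovs <- layout_overlap_set(iv)
  ovs[, a_len := nchar(reads[["a"]])]
  ext <- extend_overlaps(ovs, reads)
  resid <- ext$a_len - ext$a_end
  expect_gt(resid, 120)
  expect_lt(resid, 180)
})

test_that("containment is detected and recorded", {
  ref <- random_genome(10000, seed = 17)
  iv <- data.frame(read = c("big", "small", "right"),
                   start = c(0, 2000, 5000), end = c(8000, 6000, 10000),
                   strand = c("+", "+", "+"))
  reads <- layout_reads(ref, iv)
  ovs <- layout_overlap_set(iv)
  res <- remove_contained_and_low_coverage(ovs,
                                           overlap_filter_params("pacbio",
                                                                 min_coverage = 0))
  expect_true("small" %in% res$contained$read)
  expect_false("big" %in% res$contained$read)
  st <- res$overlaps[read_a == "small" | read_b == "small", status]
  expect_true(all(st == "removed_contained"))
  expect_true(all(res$overlaps[read_a == "big" & read_b == "right",
                               status] == "retained"))
})

test_that("filtering is order-independent", {
  ref <- random_genome(20000, seed = 18)
  set.seed(18)
  n <- 12
  starts <- sort(sample(0:14000, n))
  iv <- data.frame(read = sprintf("r%02d", 1:n), start = starts,
                   end = pmin(starts + sample(3000:6000, n, TRUE), 20000),
                   strand = sample(c("+", "-"), n, TRUE))
  ovs <- layout_overlap_set(iv)
  params <- overlap_filter_params("pacbio", min_coverage = 0)
  res1 <- remove_contained_and_low_coverage(filter_overhangs(ovs, params),
                                            params)
  perm <- ovs[sample(nrow(ovs))]
  res2 <- remove_contained_and_low_coverage(filter_overhangs(perm, params),
                                            params)
  key <- function(x) sort(paste(x$read_a, x$read_b, x$a_start, x$status))
  expect_identical(key(res1$overlaps), key(res2$overlaps))
  expect_identical(sort(res1$contained$read), sort(res2$contained$read))
})

test_that("status partition is exhaustive and exclusive", {
  p <- sim_params(genome_length = 15000, het_rate = 0.01, error_rate = 0.02,
                  depth_per_haplotype = 6, read_length_mean = 2500,
                  read_length_sd = 300, seed = 19)
  d <- simulate_dataset(p)
  res <- overlap_stage(d$reads, overlap_filter_params("pacbio"),
                       k = 15, w = 10, min_shared = 4)
  counts <- overlap_status_counts(res$overlaps)
  expect_equal(sum(counts$N), nrow(res$overlaps))
  expect_true(all(counts$status %in%
                    c("retained", "removed_overhang", "removed_contained",
                      "removed_coverage")))
})
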