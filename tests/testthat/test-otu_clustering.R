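reads_df <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  data.frame(id = ids, bases = seqs,
             qual = rep(NA_character_, length(seqs)),
             sample = rep("s", length(seqs)))
}

test_that("preclustering groups reads at the 0.02 denoising threshold", {
  set.seed(21)
  s <- random_seq(150)
  far <- mutate_seq(s, 15)  # 10% distant
  pc <- precluster(reads_df(c(s, s, far)))
  expect_equal(sort(pc$weight), c(1L, 2L))
  expect_equal(nrow(pc), 2)
  # representative of the size-2 precluster is its most abundant sequence
  expect_equal(pc$representative[pc$weight == 2], s)
  expect_equal(nrow(precluster(reads_df(character(0), character(0)))), 0)
})

test_that("single linkage preclustering is transitive along chains", {
  set.seed(22)
  b <- random_seq(200)
  mutate_seq_at <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- setdiff(BASES, ch[p])[1]
    paste(ch, collapse = "")
  }
  a <- mutate_seq_at(b, c(20, 60, 90))    # d(a,b) = 0.015
  c <- mutate_seq_at(b, c(110, 150, 180)) # d(b,c) = 0.015
  expect_lte(global_align_distance(a, b), 0.02)
  expect_lte(global_align_distance(b, c), 0.02)
  expect_gt(global_align_distance(a, c), 0.02)  # a-c linked only via b
  pc <- precluster(reads_df(c(a, b, c)))
  expect_equal(nrow(pc), 1)
  expect_equal(pc$weight, 3L)
  # oracle: connected components of the explicit threshold graph
  oracle <- components_oracle(c(a, b, c), 0.02)
  expect_true(same_partition(oracle, rep(1L, 3)))
})

test_that("single-linkage OTU clustering equals threshold-graph components", {
  set.seed(23)
  cfg <- clustering_config(linkage = "single")
  for (trial in 1:10) {
    n <- sample(3:8, 1)
    base <- random_seq(100)
    seqs <- vapply(seq_len(n), function(i)
      mutate_seq(base, sample(0:10, 1)), character(1))
    cl <- cluster_otus(seqs, cfg)
    got <- membership_from_clusters(cl, sprintf("seq_%03d", seq_len(n)))
    want <- components_oracle(seqs, cfg$otu_threshold, cfg)
    expect_true(same_partition(got, want))
  }
})

test_that("margin-separated OTUs are recovered under every linkage", {
  set.seed(24)
  refs <- make_refs(3, 150)
  seqs <- unlist(lapply(refs, function(r)
    c(r, mutate_seq(r, 1), mutate_seq(r, 1))))  # within <= 1.3%
  truth <- rep(1:3, each = 3)
  for (lk in c("single", "average", "complete")) {
    cl <- cluster_otus(seqs, clustering_config(linkage = lk))
    got <- membership_from_clusters(cl, sprintf("seq_%03d",
                                                seq_along(seqs)))
    expect_true(same_partition(got, truth))
  }
  one <- cluster_otus(rep(random_seq(80), 4))
  expect_equal(nrow(one), 1)
  expect_equal(one$size, 4)
})

test_that("clustering conserves reads and is monotone in the threshold", {
  set.seed(25)
  seqs <- replicate(12, mutate_seq(random_seq(100), sample(0:30, 1)))
  w <- sample(1:5, 12, replace = TRUE)
  cl <- cluster_otus(seqs, weights = w)
  expect_equal(sum(cl$size), sum(w))
  expect_equal(sort(unlist(cl$member_ids)),
               sort(sprintf("seq_%03d", 1:12)))
  counts <- vapply(c(0.01, 0.03, 0.08, 0.2), function(thr)
    nrow(cluster_otus(seqs, clustering_config(otu_threshold = thr,
                                              precluster_threshold =
                                                min(0.02, thr)))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is deterministic for a fixed input order", {
  set.seed(26)
  seqs <- replicate(10, mutate_seq(random_seq(120), sample(0:25, 1)))
  cl1 <- cluster_otus(seqs)
  cl2 <- cluster_otus(seqs)
  expect_identical(cl1$member_ids, cl2$member_ids)
  expect_identical(cl1$size, cl2$size)
})

test_that("read-singleton clusters are removed, order preserved", {
  cl <- data.frame(cluster_id = paste0("OTU_", 1:4), size = c(5, 1, 3, 1))
  cl$member_ids <- I(as.list(paste0("m", 1:4)))
  expect_equal(remove_read_singletons(cl)$size, c(5, 3))
  none <- cl[cl$size > 1, ]
  expect_equal(remove_read_singletons(none)$size, c(5, 3))
  expect_equal(nrow(remove_read_singletons(cl[cl$size == 1, ])), 0)
})

test_that("consensus takes the weighted per-column majority", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  expect_equal(consensus_sequence(c("AACC", "AACC", "CACC")), "AACC")
  # ties go to the alphabetically first base
  expect_equal(consensus_sequence(c("AAAA", "AAAT")), "AAAA")
  # weights count like repeated members
  expect_equal(consensus_sequence(c("AAAA", "TAAA"), weights = c(1, 3)),
               "TAAA")
})

test_that("consensus recovers a reference from mutated copies", {
  set.seed(27)
  ref <- random_seq(200)
  copies <- vapply(1:5, function(i) mutate_seq(ref, 2), character(1))
  expect_equal(consensus_sequence(copies), ref)
  # independent per-column majority oracle on the (gap-free) copies
  mat <- do.call(rbind, strsplit(copies, ""))
  oracle <- paste(apply(mat, 2, function(col)
    names(sort(table(col), decreasing = TRUE))[1]), collapse = "")
  expect_equal(consensus_sequence(copies), oracle)
})

test_that("rarefaction expectation matches edge cases and Monte Carlo", {
  sizes <- c(4, 2, 1)
  expect_equal(rarefaction_curve(sizes, sum(sizes))$expected_otus, 3)
  expect_equal(rarefaction_curve(sizes, 1)$expected_otus, 1)
  expect_error(rarefaction_curve(sizes, 8), "domain error")
  set.seed(28)
  labels <- rep(seq_along(sizes), sizes)
  draws <- replicate(50000, length(unique(sample(labels, 3))))
  mc <- mean(draws)
  se <- stats::sd(draws) / sqrt(length(draws))
  analytic <- rarefaction_curve(sizes, 3)$expected_otus
  expect_lt(abs(analytic - mc), 3 * se)
})

test_that("ACE matches the textbook formula and the vegan oracle", {
  # no rare class: estimate equals observed richness
  expect_equal(ace_richness(c(20, 15, 30))$estimate, 3)
  # hand computation for sizes [1,1,2,3,15]:
  # S_abund=1, rare={1,1,2,3}, N_rare=7, F1=2, C=5/7,
  # sum i(i-1)F_i = 2*1*1 + 3*2*1 = 8,
  # gamma^2 = max(4/(5/7) * 8/42 - 1, 0), ACE = 1 + 4/C + F1/C * gamma^2
  C <- 1 - 2 / 7
  g2 <- max(4 / C * 8 / 42 - 1, 0)
  expect_equal(ace_richness(c(1, 1, 2, 3, 15))$estimate,
               1 + 4 / C + 2 / C * g2)
  # gamma correction floors at zero
  expect_equal(ace_richness(c(1, 2, 15))$estimate, 1 + 2 / (1 - 1 / 3))
  expect_equal(ace_richness(c(1, 2, 15))$gamma2, 0)
  # zero coverage is flagged undefined, not silently numeric
  expect_warning(res <- ace_richness(c(1, 1, 1)), "undefined")
  expect_true(is.na(res$estimate))
  # independent implementation cross-check
  sizes <- c(1, 1, 2, 3, 15, 20, 4, 7)
  expect_equal(ace_richness(sizes)$estimate,
               unname(vegan::estimateR(sizes)["S.ACE"]))
})

test_that("clustering configuration is validated", {
  expect_error(clustering_config(otu_threshold = 0), "config error")
  expect_error(clustering_config(precluster_threshold = 0.05,
                                 otu_threshold = 0.03), "config error")
})
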