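# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals: the alignment oracle is a plain-R
# full dynamic-programming matrix, the clustering oracle is union-find on
# the explicit threshold graph.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, TRUE), collapse = "")

mutate_seq <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# unit-cost global alignment distance: full DP matrix plus a traceback
# using the shared conventions (pair oriented lexicographically; on ties
# diagonal, then up, then left); distance = (mismatches + gaps) / length
nw_oracle <- function(a, b) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  C <- matrix(0L, n + 1, m + 1)
  C[, 1] <- 0:n
  C[1, ] <- 0:m
  for (i in seq_len(n))
    for (j in seq_len(m))
      C[i + 1, j + 1] <- min(C[i, j] + (A[i] != B[j]),
                             C[i, j + 1] + 1L, C[i + 1, j] + 1L)
  i <- n; j <- m; edits <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    cur <- C[i + 1, j + 1]
    if (i > 0 && j > 0 && cur == C[i, j] + (A[i] != B[j])) {
      edits <- edits + (A[i] != B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && cur == C[i, j + 1] + 1L) {
      edits <- edits + 1L; i <- i - 1
    } else {
      edits <- edits + 1L; j <- j - 1
    }
    len <- len + 1L
  }
  if (len == 0) 0 else edits / len
}

# connected components of the graph with edges d <= threshold (union-find)
components_oracle <- function(seqs, threshold,
                              config = clustering_config()) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        if (global_align_distance(seqs[i], seqs[j], config) <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(comp, levels = unique(comp)))
}

# canonical partition (set of sorted member-index sets) for comparing
# clusterings irrespective of labels
partition_sets <- function(groups) {
  unname(lapply(split(seq_along(groups), groups), sort))
}

same_partition <- function(g1, g2) {
  setequal(lapply(partition_sets(g1), paste, collapse = ","),
           lapply(partition_sets(g2), paste, collapse = ","))
}

# membership vector (by input sequence index) from a cluster table whose
# members are index ids "seq_%03d" or explicit integer lists
membership_from_clusters <- function(clusters, ids) {
  g <- integer(length(ids))
  for (i in seq_len(nrow(clusters)))
    g[match(clusters$member_ids[[i]], ids)] <- i
  g
}

# a tiny margin-separated edition for set-algebra tests: OTU references at
# >= 10% mutual divergence
make_edition <- function(label, refs, phyla = NULL) {
  community_edition(label, paste0(label, "_otu", seq_along(refs)), refs,
                    phyla)
}

make_refs <- function(k, len = 150) {
  refs <- character(0)
  while (length(refs) < k) {
    cand <- random_seq(len)
    if (all(vapply(refs, function(r)
      global_align_distance(r, cand) >= 0.10, logical(1))))
      refs <- c(refs, cand)
  }
  refs
}
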