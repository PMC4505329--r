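#' Clustering configuration
#'
#' Bundles the distance thresholds and options used across preclustering,
#' OTU clustering and superset construction: 0.02 (98% identity) for
#' single-linkage preclustering and 0.03 (97% identity) for OTU calling.
#'
#' @param precluster_threshold Fractional distance for preclustering
#'   (default 0.02).
#' @param otu_threshold Fractional distance for OTU clustering
#'   (default 0.03).
#' @param linkage Agglomeration rule for [cluster_otus()]: `"average"`
#'   (default), `"single"` or `"complete"`.
#' @param terminal_gaps_counted Count terminal gap columns in the alignment
#'   distance (default `TRUE`; same-locus amplicons).
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(precluster_threshold = 0.02,
                              otu_threshold = 0.03,
                              linkage = c("average", "single", "complete"),
                              terminal_gaps_counted = TRUE) {
  linkage <- match.arg(linkage)
  if (!(precluster_threshold > 0 && precluster_threshold < 1 &&
        otu_threshold > 0 && otu_threshold < 1))
    stop("config error: thresholds must lie strictly between 0 and 1")
  if (precluster_threshold > otu_threshold)
    stop("config error: precluster_threshold must not exceed otu_threshold")
  structure(list(precluster_threshold = precluster_threshold,
                 otu_threshold = otu_threshold,
                 linkage = linkage,
                 terminal_gaps_counted = isTRUE(terminal_gaps_counted)),
            class = "clustering_config")
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("domain error: ", what, " contains characters outside {A,C,G,T}")
  if (any(!nzchar(x)))
    stop("domain error: empty ", what)
  invisible(x)
}

#' Global-alignment distance between two sequences
#'
#' Needleman-Wunsch global alignment under unit costs (match 0, mismatch 1,
#' indel 1); the distance is (mismatch columns + gap columns) divided by the
#' alignment length, in `[0, 1]`.  Symmetric by construction.
#'
#' @param a,b Non-empty sequences over `{A,C,G,T}`.
#' @param config A [clustering_config()]; only `terminal_gaps_counted` is
#'   used here.
#' @return Fractional distance in `[0, 1]`.
#' @export
global_align_distance <- function(a, b, config = clustering_config()) {
  check_dna(c(a, b))
  nw_distance_cpp(a, b, config$terminal_gaps_counted)
}

# all-pairs NW distances as a "dist" object
nw_dist <- function(seqs, config) {
  d <- nw_distance_matrix_cpp(seqs, config$terminal_gaps_counted)
  attr(d, "Size") <- length(seqs)
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  class(d) <- "dist"
  d
}

# cut a hierarchical tree at `h`, relabelling groups in order of first
# appearance so cluster ids are deterministic in the input order
cut_groups <- function(seqs, config, h, method) {
  n <- length(seqs)
  if (n == 1) return(1L)
  tree <- hclust(nw_dist(seqs, config), method = method)
  g <- cutree(tree, h = h)
  as.integer(factor(g, levels = unique(g)))
}

#' Single-linkage preclustering (denoising)
#'
#' Groups reads into the connected components of the graph whose edges join
#' read pairs at alignment distance `<= precluster_threshold` (default 0.02,
#' i.e. 98% identity).  Identical reads are collapsed first, so each
#' precluster carries its total read count as its weight and is represented
#' by its most-abundant (first-seen on ties) member sequence.
#'
#' @param reads Read table ([read_sequences()]), typically preprocessed.
#' @param config A [clustering_config()].
#' @return A `data.frame` with columns `precluster_id`, `representative`
#'   (sequence), `weight` (read count), and list-column `member_ids`.
#' @export
precluster <- function(reads, config = clustering_config()) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0)
    return(data.frame(precluster_id = character(),
                      representative = character(), weight = integer(),
                      member_ids = I(list())))
  check_dna(reads$bases, "read")
  uniq <- unique(reads$bases)
  counts <- vapply(uniq, function(s) sum(reads$bases == s), integer(1),
                   USE.NAMES = FALSE)
  ids_by_seq <- split(reads$id, factor(reads$bases, levels = uniq))
  grp <- cut_groups(uniq, config, config$precluster_threshold, "single")
  out <- lapply(unique(grp), function(g) {
    sel <- which(grp == g)
    rep_i <- sel[order(-counts[sel], sel)][1]
    list(representative = uniq[rep_i],
         weight = sum(counts[sel]),
         member_ids = unlist(ids_by_seq[sel], use.names = FALSE))
  })
  data.frame(precluster_id = sprintf("PC_%03d", seq_along(out)),
             representative = vapply(out, `[[`, character(1),
                                     "representative"),
             weight = vapply(out, `[[`, integer(1), "weight"),
             member_ids = I(lapply(out, `[[`, "member_ids")),
             stringsAsFactors = FALSE)
}

#' Hierarchical OTU clustering at 97% identity
#'
#' Agglomerative hierarchical clustering of (optionally weighted) sequences
#' under the configured linkage, cutting the dendrogram at `otu_threshold`
#' (default 0.03).  Cluster sizes are read counts, i.e. sums of member
#' weights; cluster ids are assigned in input order, deterministically.
#'
#' @param seqs Character vector of sequences (e.g. precluster
#'   representatives).
#' @param config A [clustering_config()].
#' @param weights Read-count weight per sequence (default 1 each).
#' @param members Optional list of member id vectors per sequence, carried
#'   through to the clusters (defaults to `names(seqs)` or an index id).
#' @return A `data.frame` with columns `cluster_id`, `size`, list-column
#'   `member_ids`, and `consensus` (`NA` until [consensus_sequence()] is
#'   applied; see [pipeline_edition()]).
#' @export
cluster_otus <- function(seqs, config = clustering_config(),
                         weights = NULL, members = NULL) {
  if (length(seqs) == 0)
    return(data.frame(cluster_id = character(), size = numeric(),
                      member_ids = I(list()), consensus = character()))
  check_dna(seqs)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights > 0))
  if (is.null(members)) {
    nm <- names(seqs)
    if (is.null(nm)) nm <- sprintf("seq_%03d", seq_along(seqs))
    members <- as.list(nm)
  }
  stopifnot(length(members) == length(seqs))
  grp <- cut_groups(seqs, config, config$otu_threshold, config$linkage)
  out <- lapply(unique(grp), function(g) {
    sel <- which(grp == g)
    list(size = sum(weights[sel]),
         member_ids = unlist(members[sel], use.names = FALSE),
         seqs = seqs[sel], w = weights[sel])
  })
  res <- data.frame(cluster_id = sprintf("OTU_%04d", seq_along(out)),
                    size = vapply(out, `[[`, numeric(1), "size"),
                    member_ids = I(lapply(out, `[[`, "member_ids")),
                    consensus = NA_character_,
                    stringsAsFactors = FALSE)
  attr(res, "member_seqs") <- lapply(out, `[[`, "seqs")
  attr(res, "member_weights") <- lapply(out, `[[`, "w")
  res
}

#' Remove read-level singleton clusters
#'
#' Drops clusters whose read count is 1 (distinct from edition-multiplicity
#' singletons in the superset census); order is preserved.
#'
#' @param clusters Cluster table from [cluster_otus()].
#' @return The filtered cluster table.
#' @export
remove_read_singletons <- function(clusters) {
  stopifnot(is.data.frame(clusters), "size" %in% names(clusters))
  keep <- clusters$size > 1
  out <- clusters[keep, , drop = FALSE]
  for (a in c("member_seqs", "member_weights"))
    if (!is.null(attr(clusters, a))) attr(out, a) <- attr(clusters, a)[keep]
  out
}

#' Majority-rule consensus sequence of a cluster
#'
#' Builds a progressive multiple alignment by pairwise-aligning every member
#' to the longest member (first seen on ties), then takes the weighted
#' per-column majority base.  Ties go to the alphabetically first base; a
#' column whose weighted majority is a gap is deleted.
#'
#' @param seqs Member sequences.
#' @param weights Read-count weight per member (default 1 each).
#' @return The consensus sequence.
#' @export
consensus_sequence <- function(seqs, weights = NULL) {
  check_dna(seqs, "member")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs))
  if (length(seqs) == 1) return(seqs)
  ref_i <- order(-nchar(seqs), seq_along(seqs))[1]
  ref <- seqs[ref_i]
  L <- nchar(ref)
  total_w <- sum(weights)
  bases <- c("A", "C", "G", "T")
  # votes over reference columns: 4 bases + gap
  votes <- matrix(0, nrow = 5, ncol = L,
                  dimnames = list(c(bases, "-"), NULL))
  ins_votes <- list()  # key "refpos.offset" -> named base weights
  for (k in seq_along(seqs)) {
    w <- weights[k]
    if (k == ref_i) {
      idx <- cbind(match(strsplit(ref, "")[[1]], rownames(votes)), seq_len(L))
      votes[idx] <- votes[idx] + w
      next
    }
    al <- nw_align_cpp(ref, seqs[k])
    ra <- strsplit(al[1], "")[[1]]
    rb <- strsplit(al[2], "")[[1]]
    pos <- 0L
    off <- 0L
    for (j in seq_along(ra)) {
      if (ra[j] != "-") {
        pos <- pos + 1L
        off <- 0L
        votes[rb[j], pos] <- votes[rb[j], pos] + w
      } else {
        off <- off + 1L
        key <- paste0(pos, ".", off)
        cur <- ins_votes[[key]]
        if (is.null(cur)) cur <- setNames(numeric(4), bases)
        cur[rb[j]] <- cur[rb[j]] + w
        ins_votes[[key]] <- cur
      }
    }
  }
  col_base <- function(v, w_here) {
    gap_w <- total_w - w_here        # members without this column vote gap
    if (gap_w * 2 > total_w) return(NA_character_)
    names(v)[order(-v, names(v))][1]
  }
  out <- character(0)
  emit_ins <- function(pos) {
    res <- character(0)
    off <- 1L
    repeat {
      v <- ins_votes[[paste0(pos, ".", off)]]
      if (is.null(v)) break
      b <- col_base(v, sum(v))
      if (!is.na(b)) res <- c(res, b)
      off <- off + 1L
    }
    res
  }
  out <- c(out, emit_ins(0L))
  for (p in seq_len(L)) {
    v <- votes[bases, p]
    gap_w <- votes["-", p] + (total_w - sum(votes[, p]))
    if (!(gap_w * 2 > total_w)) out <- c(out, names(v)[order(-v, names(v))][1])
    out <- c(out, emit_ins(p))
  }
  paste(out, collapse = "")
}

#' Analytic rarefaction curve
#'
#' Expected OTU richness at each subsampling depth `m`, using the
#' hypergeometric expectation
#' `E[S(m)] = sum_k (1 - choose(N - n_k, m) / choose(N, m))`.
#'
#' @param cluster_sizes Reads per OTU (all `>= 1`).
#' @param depths Subsampling depths, each between 1 and `sum(cluster_sizes)`.
#' @return A `data.frame` with columns `depth` and `expected_otus`.
#' @export
rarefaction_curve <- function(cluster_sizes, depths) {
  stopifnot(length(cluster_sizes) > 0, all(cluster_sizes >= 1))
  N <- sum(cluster_sizes)
  if (any(depths > N))
    stop("domain error: depth exceeds total read count (", N, ")")
  if (any(depths < 1)) stop("domain error: depth must be >= 1")
  ex <- vapply(depths, function(m) {
    sum(1 - exp(lchoose(N - cluster_sizes, m) - lchoose(N, m)))
  }, numeric(1))
  data.frame(depth = depths, expected_otus = ex)
}

#' ACE richness estimator
#'
#' Abundance-based Coverage Estimator with the conventional rare/abundant
#' split (default: OTUs with `<= 10` reads are rare).  When every rare read
#' is a singleton the sample coverage is zero and the estimate is undefined
#' (`NA` with a warning).
#'
#' @param cluster_sizes Reads per OTU.
#' @param rare_cutoff Maximum reads for the rare class (default 10).
#' @return A list with `estimate`, `S_abund`, `S_rare`, `C_ace`, `gamma2`.
#' @export
ace_richness <- function(cluster_sizes, rare_cutoff = 10) {
  stopifnot(length(cluster_sizes) > 0, all(cluster_sizes >= 1))
  sizes <- as.numeric(cluster_sizes)
  abund <- sizes[sizes > rare_cutoff]
  rare <- sizes[sizes <= rare_cutoff]
  S_abund <- length(abund)
  S_rare <- length(rare)
  if (S_rare == 0)
    return(list(estimate = S_abund, S_abund = S_abund, S_rare = 0L,
                C_ace = 1, gamma2 = 0))
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0) {
    warning("ACE undefined: zero sample coverage ",
            "(all rare reads are singletons)")
    return(list(estimate = NA_real_, S_abund = S_abund, S_rare = S_rare,
                C_ace = 0, gamma2 = NA_real_))
  }
  Fi <- vapply(seq_len(rare_cutoff), function(i) sum(rare == i), numeric(1))
  ssq <- sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * Fi)
  gamma2 <- if (N_rare > 1)
    max(S_rare / C_ace * ssq / (N_rare * (N_rare - 1)) - 1, 0) else 0
  est <- S_abund + S_rare / C_ace + F1 / C_ace * gamma2
  list(estimate = est, S_abund = S_abund, S_rare = S_rare,
       C_ace = C_ace, gamma2 = gamma2)
}
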