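#' A community edition (one spatiotemporal OTU set)
#'
#' @param label Edition label, e.g. `"2011_GM_SE"`.
#' @param otu_id OTU identifiers, unique within the edition.
#' @param consensus Consensus sequence per OTU.
#' @param phylum Phylum label per OTU (use `"Unclassified Bacteria"` where
#'   classification failed); defaults to all-unclassified.
#' @return A `community_edition` object.
#' @export
community_edition <- function(label, otu_id, consensus, phylum = NULL) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label),
            length(otu_id) == length(consensus))
  if (anyDuplicated(otu_id)) stop("duplicated otu_id in edition ", label)
  if (is.null(phylum)) phylum <- rep("Unclassified Bacteria",
                                     length(otu_id))
  phylum[is.na(phylum) | !nzchar(phylum)] <- "Unclassified Bacteria"
  structure(list(label = label,
                 otus = data.frame(otu_id = as.character(otu_id),
                                   consensus = as.character(consensus),
                                   phylum = as.character(phylum),
                                   stringsAsFactors = FALSE)),
            class = "community_edition")
}

#' @export
print.community_edition <- function(x, ...) {
  cat("Community edition", x$label, "with", nrow(x$otus), "OTUs over",
      length(unique(x$otus$phylum)), "phyla\n")
  invisible(x)
}

#' Per-phylum OTU counts of an edition (n_i)
#'
#' @param edition A [community_edition()].
#' @return Named integer vector, phylum -> OTU count.
#' @export
n_by_phylum <- function(edition) {
  stopifnot(inherits(edition, "community_edition"))
  tab <- table(edition$otus$phylum)
  setNames(as.integer(tab), names(tab))
}

majority_phylum <- function(labels) {
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (!length(labels)) return("Unclassified Bacteria")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("Unclassified Bacteria")
  names(tab)[1]
}

#' Merge edition OTU sets into a cross-edition superset
#'
#' Pools the consensus sequences of two or more editions and clusters them
#' at the OTU threshold (97% identity).  Each superset cluster records its
#' contributing (edition, OTU) pairs, its multiplicity (number of distinct
#' editions represented) and a phylum assigned by member-majority vote
#' (ties -> `"Unclassified Bacteria"`).
#'
#' @param editions List of [community_edition()] objects (length `>= 2`).
#' @param config A [clustering_config()].
#' @return A `data.frame` (class `otu_superset`) with columns
#'   `superset_id`, `multiplicity`, `phylum`, `n_members` and list-column
#'   `members` (each a `data.frame` of `edition`, `otu_id`, `phylum`).
#' @export
build_superset <- function(editions, config = clustering_config()) {
  if (length(editions) < 2)
    stop("domain error: superset construction needs >= 2 editions")
  stopifnot(all(vapply(editions, inherits, logical(1), "community_edition")))
  labels <- vapply(editions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("edition labels must be unique")
  pool <- do.call(rbind, lapply(editions, function(e)
    cbind(edition = e$label, e$otus)))
  clusters <- cluster_otus(pool$consensus, config,
                           members = as.list(seq_len(nrow(pool))))
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    sel <- clusters$member_ids[[i]]
    mem <- pool[sel, c("edition", "otu_id", "phylum")]
    rownames(mem) <- NULL
    list(multiplicity = length(unique(mem$edition)),
         phylum = majority_phylum(mem$phylum),
         members = mem)
  })
  out <- data.frame(superset_id = sprintf("SS_%04d", seq_along(rows)),
                    multiplicity = vapply(rows, `[[`, integer(1),
                                          "multiplicity"),
                    phylum = vapply(rows, `[[`, character(1), "phylum"),
                    n_members = vapply(rows, function(r) nrow(r$members),
                                       integer(1)),
                    stringsAsFactors = FALSE)
  out$members <- I(lapply(rows, `[[`, "members"))
  attr(out, "edition_labels") <- labels
  attr(out, "edition_sizes") <- setNames(
    vapply(editions, function(e) nrow(e$otus), integer(1)), labels)
  class(out) <- c("otu_superset", class(out))
  out
}

#' Multiplicity census of a superset
#'
#' Counts superset clusters by edition multiplicity (singletons, doubletons,
#' tripletons, ...), and checks the weighted identity
#' `sum_k k * count_k == sum of edition sizes`, which holds exactly when no
#' superset cluster absorbed two OTUs of the same edition; any such
#' within-edition collapse is reported, not silently absorbed.
#'
#' @param superset An [build_superset()] result.
#' @param edition_sizes Optional named OTU counts per edition (defaults to
#'   the sizes recorded on the superset).
#' @return A `multiplicity_census` list: `counts` (multiplicity ->
#'   clusters), `total`, `within_edition_collapses`, `weighted_sum`,
#'   `edition_total`, `identity_holds`.
#' @export
multiplicity_census <- function(superset, edition_sizes = NULL) {
  stopifnot(inherits(superset, "otu_superset"))
  if (is.null(edition_sizes)) edition_sizes <- attr(superset,
                                                    "edition_sizes")
  n_editions <- length(attr(superset, "edition_labels"))
  counts <- setNames(integer(n_editions), seq_len(n_editions))
  tab <- table(superset$multiplicity)
  counts[names(tab)] <- as.integer(tab)
  collapses <- sum(vapply(superset$members, function(m)
    anyDuplicated(m$edition) > 0, logical(1)))
  weighted <- sum(as.integer(names(counts)) * counts)
  structure(list(counts = counts,
                 total = nrow(superset),
                 within_edition_collapses = as.integer(collapses),
                 weighted_sum = weighted,
                 edition_total = sum(edition_sizes),
                 identity_holds = weighted == sum(edition_sizes)),
            class = "multiplicity_census")
}

#' @export
print.multiplicity_census <- function(x, ...) {
  nm <- c("singletons", "doubletons", "tripletons")
  lab <- ifelse(seq_along(x$counts) <= 3, nm[seq_along(x$counts)],
                paste0("multiplicity ", seq_along(x$counts)))
  cat("Superset of", x$total, "OTUs:",
      paste(x$counts, lab, collapse = ", "), "\n")
  cat("Weighted identity sum(k*count_k) =", x$weighted_sum, "vs edition",
      "total", x$edition_total,
      if (x$identity_holds) "(holds)" else "(DISCREPANCY)", "\n")
  if (x$within_edition_collapses > 0)
    cat("Warning:", x$within_edition_collapses,
        "cluster(s) merged >= 2 OTUs of one edition\n")
  invisible(x)
}

#' Shared and unique OTUs between two editions
#'
#' Builds the two-edition superset; its doubletons are the OTUs common to
#' the two samples, its singletons the OTUs unique to one of them.
#'
#' @param edition_a,edition_b [community_edition()] objects.
#' @param config A [clustering_config()].
#' @return A list with `unique_a`, `shared`, `unique_b`,
#'   `within_edition_collapses` and the edition `labels`.
#' @export
pairwise_overlap <- function(edition_a, edition_b,
                             config = clustering_config()) {
  ss <- build_superset(list(edition_a, edition_b), config)
  single <- ss[ss$multiplicity == 1, , drop = FALSE]
  from <- vapply(single$members, function(m) m$edition[1], character(1))
  list(unique_a = sum(from == edition_a$label),
       shared = sum(ss$multiplicity == 2),
       unique_b = sum(from == edition_b$label),
       within_edition_collapses =
         multiplicity_census(ss)$within_edition_collapses,
       labels = c(edition_a$label, edition_b$label))
}

#' Per-phylum taxonomic scope of the system (N_i)
#'
#' Counts superset clusters per assigned phylum; `sum(N_i)` equals the
#' superset size.
#'
#' @param superset An [build_superset()] result.
#' @return Named integer vector, phylum -> N_i.
#' @export
phylum_scope <- function(superset) {
  stopifnot(inherits(superset, "otu_superset"))
  tab <- table(superset$phylum)
  setNames(as.integer(tab), names(tab))
}
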