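#' Run the full within-edition OTU pipeline
#'
#' Quality/length filter, primer + barcode screening and trimming (keeping
#' read multiplicities: duplicate removal is left to the abundance-aware
#' preclustering step), single-linkage preclustering at the 0.02 denoising
#' threshold, hierarchical OTU clustering at 0.03, read-singleton removal,
#' and consensus building per OTU.  Each OTU is assigned a phylum by
#' majority vote over its member reads' taxonomy labels.
#'
#' @param reads Read table for one edition.
#' @param label Edition label.
#' @param taxonomy Optional named character vector, read id -> phylum
#'   (ground truth or an external classification).
#' @param config A [clustering_config()].
#' @param min_qv,min_len Quality/length thresholds (defaults 20, 100).
#' @param primer,barcode_length Primer screen parameters (defaults `""`, 0:
#'   no screening).
#' @param drop_read_singletons Remove clusters with a single read
#'   (default `TRUE`).
#' @return A [community_edition()] with attributes `clusters` (the OTU
#'   table) and `reports` (filter reports).
#' @export
pipeline_edition <- function(reads, label, taxonomy = NULL,
                             config = clustering_config(),
                             min_qv = 20, min_len = 100,
                             primer = "", barcode_length = 0L,
                             drop_read_singletons = TRUE) {
  fl <- quality_length_filter(reads, min_qv = min_qv, min_len = min_len)
  pp <- preprocess_reads(fl$reads, primer = primer,
                         barcode_length = barcode_length,
                         drop_duplicates = FALSE)
  pc <- precluster(pp$reads, config)
  cl <- cluster_otus(pc$representative, config, weights = pc$weight,
                     members = pc$member_ids)
  if (drop_read_singletons) cl <- remove_read_singletons(cl)
  if (nrow(cl) == 0)
    stop("pipeline error [", label, "]: no OTUs survived filtering")
  seq_by_id <- setNames(pp$reads$bases, pp$reads$id)
  consensus <- vapply(seq_len(nrow(cl)), function(i) {
    mem <- seq_by_id[cl$member_ids[[i]]]
    uniq <- unique(mem)
    w <- vapply(uniq, function(s) sum(mem == s), numeric(1),
                USE.NAMES = FALSE)
    consensus_sequence(uniq, w)
  }, character(1))
  cl$consensus <- consensus
  phylum <- vapply(seq_len(nrow(cl)), function(i) {
    if (is.null(taxonomy)) return("Unclassified Bacteria")
    majority_phylum(taxonomy[cl$member_ids[[i]]])
  }, character(1))
  ed <- community_edition(label, paste0(label, "_", cl$cluster_id),
                          consensus, phylum)
  attr(ed, "clusters") <- cl
  attr(ed, "reports") <- list(quality_length = fl$report,
                              preprocess = pp$report)
  ed
}

#' Cross-edition taxonomic diversity flux workflow
#'
#' Runs [pipeline_edition()] on every edition, merges the per-edition OTU
#' sets into the system superset, and derives the multiplicity census, all
#' pairwise overlaps, the per-phylum scopes `N_i`, the Relative Taxonomic
#' Diversity Index per edition (exact and table rounding modes) and
#' classical diversity indices on the per-phylum OTU distribution.
#'
#' @param reads_by_edition Named list of read tables, or a single read
#'   table with a `sample` column, or a named character vector of
#'   FASTA/FASTQ paths.
#' @param taxonomy Optional named vector read id -> phylum.
#' @param config A [clustering_config()].
#' @param ... Passed to [pipeline_edition()] (`min_qv`, `min_len`,
#'   `primer`, `barcode_length`, ...).
#' @return A `flux_report` list: `editions`, `edition_sizes`,
#'   `n_by_phylum`, `superset`, `census`, `N_by_phylum`, `overlaps`,
#'   `tr` (per edition, exact and table modes), `diversity` (D, H, E_H per
#'   edition), `config`, `version`.
#' @export
run_flux_workflow <- function(reads_by_edition, taxonomy = NULL,
                              config = clustering_config(), ...) {
  if (is.character(reads_by_edition)) {
    stopifnot(!is.null(names(reads_by_edition)))
    reads_by_edition <- lapply(
      setNames(names(reads_by_edition), names(reads_by_edition)),
      function(ed) read_sequences(reads_by_edition[[ed]], sample = ed))
  }
  if (is.data.frame(reads_by_edition))
    reads_by_edition <- split(reads_by_edition, reads_by_edition$sample)
  if (length(reads_by_edition) < 2)
    stop("domain error: the flux workflow needs >= 2 editions")
  labels <- names(reads_by_edition)
  editions <- lapply(labels, function(ed)
    pipeline_edition(reads_by_edition[[ed]], ed, taxonomy = taxonomy,
                     config = config, ...))
  names(editions) <- labels
  superset <- build_superset(editions, config)
  census <- multiplicity_census(superset)
  N <- phylum_scope(superset)
  n_list <- lapply(editions, n_by_phylum)
  tr <- lapply(n_list, function(n)
    list(exact = tr_index(n, N, "exact"), table = tr_index(n, N, "table")))
  diversity <- lapply(n_list, function(n)
    c(list(D = simpson_dominance(n)), shannon(n)))
  pairs <- if (length(labels) > 1) combn(labels, 2, simplify = FALSE)
           else list()
  overlaps <- lapply(pairs, function(p)
    pairwise_overlap(editions[[p[1]]], editions[[p[2]]], config))
  names(overlaps) <- vapply(pairs, paste, character(1), collapse = " vs ")
  structure(list(editions = editions,
                 edition_sizes = vapply(editions, function(e)
                   nrow(e$otus), integer(1)),
                 n_by_phylum = n_list,
                 superset = superset, census = census, N_by_phylum = N,
                 overlaps = overlaps, tr = tr, diversity = diversity,
                 config = unclass(config),
                 version = as.character(packageVersion("otuflux"))),
            class = "flux_report")
}

#' @export
print.flux_report <- function(x, ...) {
  cat("Taxonomic diversity flux report (otuflux", x$version, ")\n")
  cat("Editions:", paste(names(x$editions), " (", x$edition_sizes,
                         " OTUs)", sep = "", collapse = ", "), "\n")
  print(x$census)
  for (ed in names(x$tr))
    cat(sprintf("T_r[%s]: exact %.4f, table %.2f\n", ed,
                x$tr[[ed]]$exact$T_r, x$tr[[ed]]$table$T_r))
  invisible(x)
}

#' Write a flux report to disk (JSON summary + TSV tables)
#'
#' @param report A `flux_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flux_report <- function(report, dir) {
  stopifnot(inherits(report, "flux_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- report$superset
  ss_tab <- data.frame(superset_id = ss$superset_id,
                       multiplicity = ss$multiplicity,
                       phylum = ss$phylum,
                       members = vapply(ss$members, function(m)
                         paste(m$edition, m$otu_id, sep = ":",
                               collapse = ","), character(1)))
  write.table(ss_tab, file.path(dir, "superset.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (ed in names(report$editions)) {
    cl <- attr(report$editions[[ed]], "clusters")
    tab <- data.frame(cluster_id = cl$cluster_id, size = cl$size,
                      member_ids = vapply(cl$member_ids, paste,
                                          character(1), collapse = ","),
                      consensus = cl$consensus)
    write.table(tab, file.path(dir, paste0(ed, "_otus.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    version = report$version, config = report$config,
    edition_sizes = as.list(report$edition_sizes),
    census = list(counts = as.list(report$census$counts),
                  total = report$census$total,
                  within_edition_collapses =
                    report$census$within_edition_collapses,
                  identity_holds = report$census$identity_holds),
    N_by_phylum = as.list(report$N_by_phylum),
    n_by_phylum = lapply(report$n_by_phylum, as.list),
    tr = lapply(report$tr, function(t)
      list(exact = t$exact$T_r, table = t$table$T_r)),
    diversity = report$diversity,
    overlaps = lapply(report$overlaps, function(o)
      o[c("unique_a", "shared", "unique_b")]))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "flux_report.json"))
  invisible(dir)
}
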