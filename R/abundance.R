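is_unclassified <- function(taxa) {
  grepl("^(unclassified|unassigned)", taxa, ignore.case = TRUE)
}

check_abundance_table <- function(table, sample) {
  stopifnot(is.data.frame(table), "taxon" %in% names(table))
  if (!sample %in% names(table))
    stop("sample not present in abundance table: ", sample)
  counts <- table[[sample]]
  if (any(is.na(counts)) || any(counts < 0))
    stop("domain error: counts must be non-negative and non-missing")
  if (sum(counts) == 0)
    stop("domain error: sample ", sample, " has zero total count")
  invisible(counts)
}

#' Per-sample relative abundances
#'
#' Proportions of a sample's counts.  By default the denominator is the
#' classifiable total: rows whose taxon label starts with "Unclassified" or
#' "Unassigned" are excluded from the denominator (their own proportion is
#' still reported, relative to that denominator).
#'
#' @param table Abundance table: `taxon` column (optionally `rank`) plus one
#'   numeric column per sample.
#' @param sample Sample column name.
#' @param classifiable_only Exclude unclassified rows from the denominator
#'   (default `TRUE`).
#' @return Numeric vector of proportions, named by taxon.
#' @export
relative_abundance <- function(table, sample, classifiable_only = TRUE) {
  counts <- check_abundance_table(table, sample)
  denom <- if (classifiable_only)
    sum(counts[!is_unclassified(table$taxon)]) else sum(counts)
  if (denom == 0) stop("domain error: no classifiable reads in ", sample)
  setNames(counts / denom, table$taxon)
}

#' Significance filter on relative abundance
#'
#' Keeps the taxa that account for at least `cutoff` of the classifiable
#' reads of a sample (default 0.0001, i.e. 0.01%); a taxon at exactly the
#' cutoff is kept.
#'
#' @inheritParams relative_abundance
#' @param cutoff Proportion cutoff in `(0, 1)`.
#' @return The filtered table rows for this sample, with a `proportion`
#'   column appended.
#' @export
significance_filter <- function(table, sample, cutoff = 1e-4,
                                classifiable_only = TRUE) {
  if (!(cutoff > 0 && cutoff < 1))
    stop("config error: cutoff must lie strictly between 0 and 1")
  prop <- relative_abundance(table, sample, classifiable_only)
  keep <- prop >= cutoff
  out <- table[keep, , drop = FALSE]
  out$proportion <- unname(prop[keep])
  out
}

#' Most-abundant taxa of a sample ("leaderboard")
#'
#' Top `n` taxa by count, ties broken lexicographically by taxon name;
#' shorter when fewer than `n` taxa have nonzero counts.
#'
#' @inheritParams relative_abundance
#' @param n Board length (default 50).
#' @return A `data.frame` (`rank`, `taxon`, `count`, `proportion`) with
#'   attribute `sample`.
#' @export
leaderboard <- function(table, sample, n = 50,
                        classifiable_only = TRUE) {
  counts <- check_abundance_table(table, sample)
  prop <- relative_abundance(table, sample, classifiable_only)
  nz <- which(counts > 0)
  ord <- nz[order(-counts[nz], table$taxon[nz])]
  top <- utils::head(ord, n)
  out <- data.frame(rank = seq_along(top), taxon = table$taxon[top],
                    count = counts[top],
                    proportion = unname(prop[top]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sample") <- sample
  out
}

#' Membership transitions across leaderboards
#'
#' Partitions the union of several leaderboards by exact board membership:
#' for three boards this yields the common-to-all set, each pairwise-only
#' set and each unique set.  The returned sets are disjoint and their union
#' is the union of the boards.
#'
#' @param boards Named list (length `>= 2`) of leaderboards
#'   ([leaderboard()] results) or plain character vectors of taxa.
#' @return Named list of character vectors; names are the board labels a
#'   taxon appears on, joined with `" & "`.
#' @export
leaderboard_transitions <- function(boards) {
  stopifnot(is.list(boards), length(boards) >= 2)
  labs <- names(boards)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("boards must be a named list")
  sets <- lapply(boards, function(b)
    if (is.data.frame(b)) b$taxon else as.character(b))
  all_taxa <- sort(unique(unlist(sets)))
  sig <- vapply(all_taxa, function(t)
    paste(labs[vapply(sets, function(s) t %in% s, logical(1))],
          collapse = " & "), character(1))
  split(all_taxa, sig)
}

#' Bray-Curtis similarity between two samples
#'
#' `2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, i.e. one minus the
#' Bray-Curtis dissimilarity; in `[0, 1]` and symmetric.
#'
#' @param x,y Equal-length non-negative abundance vectors, not both
#'   all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0))
    stop("domain error: abundances must be non-negative")
  if (sum(x) + sum(y) == 0)
    stop("domain error: Bray-Curtis undefined for two all-zero vectors")
  1 - as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Euclidean distance between two samples
#'
#' @param x,y Equal-length numeric vectors.
#' @return Distance `>= 0`.
#' @export
euclidean_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  as.numeric(dist(rbind(x, y), method = "euclidean"))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via the t transform.  Constant vectors are a
#' domain error (r undefined), never a silent zero.  With very few samples
#' the p-value is reported but has little power.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, both non-constant.
#' @return A list with `r`, `p_value` and `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("domain error: need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("domain error: Pearson r undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Read an abundance table (taxon x sample TSV)
#'
#' @param path TSV with a `taxon` column (optionally `rank`) and one
#'   numeric column per sample.
#' @return A `data.frame`.
#' @export
read_abundance_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(tab))
    stop("abundance table must have a 'taxon' column: ", path)
  tab
}

#' Read an environment table (variable x sample TSV)
#'
#' The packaged fixture `table1.tsv` holds the hot-water physicochemistry
#' of the mat samples (temperature, pH, TDS, sulfur species, iron species,
#' acetate, formate) in this layout.
#'
#' @param path TSV with `variable` and `unit` columns plus one numeric
#'   column per sample; default is the packaged fixture.
#' @return A `data.frame`.
#' @export
read_environment_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1.tsv", package = "otuflux",
                        mustWork = TRUE)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"variable" %in% names(tab))
    stop("environment table must have a 'variable' column: ", path)
  tab
}
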