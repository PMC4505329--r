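#' Packaged per-phylum OTU reference table
#'
#' Loads the packaged transcription of the three-edition green-mat
#' reference worksheet: per phylum, the system scope `N` and, per edition,
#' the OTU count `n_<edition>`, the printed ratio `p_<edition>`, the printed
#' `sqrtn_<edition>` and the printed product column.  The `_sys` columns
#' hold the hypothetical-superset section (every `p_i` = 1).
#'
#' @param path Optional alternative TSV path (same layout).
#' @return A `data.frame`, one row per phylum.
#' @export
read_table2 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2.tsv", package = "otuflux",
                        mustWork = TRUE)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(c("phylum", "N") %in% names(tab))
  tab
}

table2_summary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2_summary.json",
                        package = "otuflux", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

table2_editions <- function(tab) {
  sub("^n_", "", grep("^n_", names(tab), value = TRUE))
}

#' T_r of a reference-table edition
#'
#' Computes the Relative Taxonomic Diversity Index for one edition of the
#' packaged reference table (or any table with the same layout).  With
#' `use_printed_p = TRUE` the worksheet's own arithmetic is replayed: each
#' printed `p_i` is multiplied by the printed `sqrt(n_i)` and the product
#' rounded half-up to 2 decimals before summation.  This reproduces the
#' archived totals even for the two cells whose printed `p_i` differs from
#' `round(n_i/N_i, 2)` (a transcription-level rounding anomaly; see the
#' methods vignette).  Otherwise `p_i` is recomputed from the counts via
#' [tr_index()] in the requested `mode`.
#'
#' @param edition Edition label, e.g. `"2010_GM_SE"`.
#' @param tab Reference table ([read_table2()]).
#' @param mode Rounding mode for the from-counts path: `"table"` (default)
#'   or `"exact"`.
#' @param use_printed_p Replay the printed `p_i` column (default `FALSE`).
#' @return A `tr_breakdown` object.
#' @export
tr_table2 <- function(edition, tab = read_table2(),
                      mode = c("table", "exact"), use_printed_p = FALSE) {
  mode <- match.arg(mode)
  ncol_name <- paste0("n_", edition)
  if (!ncol_name %in% names(tab))
    stop("edition not present in table: ", edition)
  n <- setNames(tab[[ncol_name]], tab$phylum)
  N <- setNames(tab$N, tab$phylum)
  if (!use_printed_p) return(tr_index(n, N, rounding_mode = mode))
  p <- setNames(tab[[paste0("p_", edition)]], tab$phylum)
  sq <- setNames(tab[[paste0("sqrtn_", edition)]], tab$phylum)
  keep <- n > 0
  product <- round_half_up(p[keep] * sq[keep], 2)
  rows <- data.frame(phylum = tab$phylum[keep], n = as.numeric(n[keep]),
                     N = as.numeric(N[keep]), sqrt_n = as.numeric(sq[keep]),
                     p = as.numeric(p[keep]), product = product,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(rows = rows, T_r = sum(product),
                 T_r_max = tr_max(N, reproduce_table2 = TRUE),
                 rounding_mode = "printed"),
            class = "tr_breakdown")
}

#' Maximum T_r of the packaged reference system
#'
#' @param tab Reference table ([read_table2()]).
#' @param reproduce_table2 Apply the worksheet convention (rounded
#'   square roots; `"Unclassified Bacteria"` contributes 1); default `TRUE`.
#' @return The maximum T_r value.
#' @export
tr_max_table2 <- function(tab = read_table2(), reproduce_table2 = TRUE) {
  tr_max(setNames(tab$N, tab$phylum), reproduce_table2 = reproduce_table2)
}

#' Self-check of the packaged reference fixture
#'
#' Recomputes column sums, phylum presence counts and the multiplicity
#' footnote identities of the packaged reference table and compares them
#' with its transcribed summary: per-edition OTU totals, the superset total,
#' the number of classified phyla per edition, the weighted identity
#' `s + 2d + 3t == sum of edition totals`, `s + d + t == superset total`,
#' and the tripleton per-phylum split.
#'
#' @param tab Reference table ([read_table2()]).
#' @param summary Transcribed summary (internal JSON by default).
#' @return A `data.frame` of checks (`check`, `observed`, `expected`,
#'   `pass`) with attribute `pass` (all checks passed).
#' @export
validate_table2_fixture <- function(tab = read_table2(),
                                    summary = table2_summary()) {
  if (nrow(tab) == 0) stop("missing data: reference table fixture is empty")
  checks <- list()
  add <- function(name, obs, exp)
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, observed = obs, expected = exp,
      pass = isTRUE(all.equal(obs, exp)), stringsAsFactors = FALSE)
  for (ed in table2_editions(tab)) {
    add(paste0("otu_total_", ed), sum(tab[[paste0("n_", ed)]]),
        summary$edition_totals[[ed]])
    add(paste0("classified_phyla_", ed),
        sum(tab[[paste0("n_", ed)]] > 0 &
              tab$phylum != "Unclassified Bacteria"),
        summary$classified_phyla_per_edition[[ed]])
  }
  add("superset_total", sum(tab$N), summary$superset_total)
  cen <- summary$census
  add("census_total", cen$singletons + cen$doubletons + cen$tripletons,
      summary$superset_total)
  add("census_weighted_identity",
      cen$singletons + 2 * cen$doubletons + 3 * cen$tripletons,
      sum(unlist(summary$edition_totals)))
  add("tripleton_phylum_split", sum(unlist(summary$tripleton_phyla)),
      cen$tripletons)
  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  out
}
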