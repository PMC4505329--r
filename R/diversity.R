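normalize_abundance <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("domain error: empty abundance vector")
  if (any(is.na(x)) || any(x < 0))
    stop("domain error: abundances must be non-negative and non-missing")
  s <- sum(x)
  if (s == 0) stop("domain error: all-zero abundance vector")
  x / s
}

#' Simpson dominance index
#'
#' `D = sum(p_i^2)` on normalized proportions; 1 for a single-taxon
#' community, `1/k` for a uniform community of `k` taxa.  High values flag
#' dominated communities.
#'
#' @param x Non-negative abundances (counts or proportions).
#' @return Dominance `D` in `[0, 1]`.
#' @export
simpson_dominance <- function(x) {
  p <- normalize_abundance(x)
  sum(p^2)
}

#' Shannon diversity and equitability
#'
#' `H = -sum(p_i * log(p_i))` (natural log, zero-abundance taxa contribute
#' nothing) and `E_H = H / log(richness)`, defined as 1 for a single-taxon
#' community.
#'
#' @param x Non-negative abundances.
#' @return A list with `H`, `E_H` and `richness` (taxa with nonzero
#'   proportion).
#' @export
shannon <- function(x) {
  p <- normalize_abundance(x)
  p <- p[p > 0]
  H <- -sum(p * log(p))
  richness <- length(p)
  E_H <- if (richness == 1) 1 else H / log(richness)
  list(H = H, E_H = E_H, richness = richness)
}

#' Relative Taxonomic Diversity Index (T_r)
#'
#' For each phylum `i` present in an edition, `p_i = n_i / N_i` relates the
#' edition's OTU count `n_i` to the system-wide taxonomic scope `N_i`
#' (superset OTU count of that phylum), and `T_r = sum_i p_i * sqrt(n_i)`
#' weights the spread across phyla by each phylum's species count.  `T_r`
#' is comparative across editions of one system, not an absolute measure.
#'
#' `rounding_mode = "table"` reproduces worksheet-style arithmetic: `p_i`
#' is rounded half-up to 2 decimals before the multiplication and each
#' product is rounded half-up to 2 decimals before summation.  `"exact"`
#' (default) uses full floating precision.
#'
#' @param n Named per-phylum OTU counts of the edition (n_i); phyla with
#'   zero count may be present and are skipped.
#' @param N Named per-phylum taxonomic scopes (N_i), covering at least every
#'   phylum with `n > 0`.
#' @param rounding_mode `"exact"` or `"table"`.
#' @return A `tr_breakdown` object: per-phylum `rows` (`phylum`, `n`, `N`,
#'   `sqrt_n`, `p`, `product`), `T_r`, `T_r_max` (same mode) and
#'   `rounding_mode`.
#' @export
tr_index <- function(n, N, rounding_mode = c("exact", "table")) {
  rounding_mode <- match.arg(rounding_mode)
  stopifnot(!is.null(names(n)), !is.null(names(N)))
  n <- n[n > 0]
  if (!length(n)) stop("domain error: edition has no OTUs")
  missing_N <- setdiff(names(n), names(N))
  if (length(missing_N))
    stop("domain error: no taxonomic scope N_i for phylum ",
         paste(missing_N, collapse = ", "))
  Ni <- N[names(n)]
  if (any(Ni < n))
    stop("domain error: n_i exceeds N_i for phylum ",
         paste(names(n)[Ni < n], collapse = ", "))
  p <- as.numeric(n) / as.numeric(Ni)
  sqrt_n <- sqrt(as.numeric(n))
  if (rounding_mode == "table") {
    p <- round_half_up(p, 2)
    product <- round_half_up(p * sqrt_n, 2)
  } else {
    product <- p * sqrt_n
  }
  rows <- data.frame(phylum = names(n), n = as.numeric(n),
                     N = as.numeric(Ni), sqrt_n = sqrt_n, p = p,
                     product = product, stringsAsFactors = FALSE,
                     row.names = NULL)
  structure(list(rows = rows, T_r = sum(product),
                 T_r_max = tr_max_mode(N, rounding_mode),
                 rounding_mode = rounding_mode),
            class = "tr_breakdown")
}

tr_max_mode <- function(N, rounding_mode) {
  if (rounding_mode == "table") sum(round_half_up(sqrt(as.numeric(N)), 2))
  else sum(sqrt(as.numeric(N)))
}

#' @export
print.tr_breakdown <- function(x, ...) {
  cat("Relative Taxonomic Diversity Index (", x$rounding_mode,
      " mode)\n", sep = "")
  print(x$rows, digits = 4)
  cat("T_r =", format(x$T_r, digits = 6), "of maximum",
      format(x$T_r_max, digits = 6), "\n")
  invisible(x)
}

#' Maximum attainable T_r of a system
#'
#' `sum(sqrt(N_i))`, reached only if one edition encompassed the whole
#' diversity scope of the system (`n_i == N_i` everywhere).  With
#' `reproduce_table2 = TRUE` the worksheet convention of the packaged
#' reference table is applied: each `sqrt(N_i)` is rounded half-up to two
#' decimals and the `"Unclassified Bacteria"` row contributes 1 instead of
#' `sqrt(N_i)`.
#'
#' @param N Named per-phylum taxonomic scopes.
#' @param reproduce_table2 Apply the archived-table convention (default
#'   `FALSE`).
#' @param unclassified Label of the unclassified bin.
#' @return The maximum T_r value.
#' @export
tr_max <- function(N, reproduce_table2 = FALSE,
                   unclassified = "Unclassified Bacteria") {
  stopifnot(all(N >= 1))
  if (!reproduce_table2) return(sum(sqrt(as.numeric(N))))
  stopifnot(!is.null(names(N)))
  cls <- N[names(N) != unclassified]
  sum(round_half_up(sqrt(as.numeric(cls)), 2)) +
    as.numeric(unclassified %in% names(N))
}
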