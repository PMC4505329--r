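#' Design of a synthetic multi-edition amplicon system
#'
#' Describes a community system with known ground truth: how many system
#' OTUs are present in exactly 1, 2, ... editions
#' (`multiplicity_design`), how the OTUs are distributed over phyla, the
#' sequence length and divergence margins, the read-count distribution and
#' the sequencing error model.  The defaults emulate V3-like amplicons:
#' 150 bp references at pairwise distance `>= 0.10` between OTUs, `<= 0.01`
#' divergence between edition copies of one OTU, and substitution errors at
#' 0.001 per base.  The margin requirement
#' `min_between > 2 * within + otu_threshold` is enforced at construction so
#' that recovery by clustering at `otu_threshold` cannot depend on linkage.
#'
#' @param editions Edition labels (length `E >= 1`).
#' @param multiplicity_design Integer vector of length `E`:
#'   `multiplicity_design[k]` OTUs are present in exactly `k` editions.
#' @param phyla Named integer vector of per-phylum OTU budgets summing to
#'   `sum(multiplicity_design)`.
#' @param seq_length Reference length in bp (default 150).
#' @param within_otu_divergence Maximum fractional divergence of an edition
#'   copy from its OTU reference (default 0.01; applied as
#'   `floor(within_otu_divergence * seq_length)` substitutions).
#' @param min_between_otu_divergence Minimum pairwise distance between OTU
#'   references (default 0.10).
#' @param reads_per_otu_min Minimum reads per OTU copy (default 3, so every
#'   OTU survives read-singleton removal and per-column consensus majorities
#'   are well defined).
#' @param reads_per_otu_meanlog,reads_per_otu_sdlog Lognormal parameters of
#'   the skewed read-count distribution (defaults `log(4)`, 0.5).
#' @param error_rate Substitution error rate per base (default 0.001).
#' @param indel_rate Read indel rate per base (default 0, substitution-only
#'   model).
#' @param primer Primer prefixed to every read (default a 17-mer V3-style
#'   primer).
#' @param barcode_length Barcode bases between primer and insert
#'   (default 8).
#' @param otu_threshold Clustering threshold the margins are checked
#'   against (default 0.03).
#' @return A `system_design` list.
#' @export
system_design <- function(editions = c("2010_GM_SE", "2011_GM_SE",
                                       "2012_GM_SE"),
                          multiplicity_design = c(6L, 3L, 2L),
                          phyla = c(Proteobacteria = 4L, Bacteroidetes = 3L,
                                    Cyanobacteria = 2L,
                                    "Unclassified Bacteria" = 2L),
                          seq_length = 150L,
                          within_otu_divergence = 0.01,
                          min_between_otu_divergence = 0.10,
                          reads_per_otu_min = 3L,
                          reads_per_otu_meanlog = log(4),
                          reads_per_otu_sdlog = 0.5,
                          error_rate = 0.001,
                          indel_rate = 0,
                          primer = "CCTACGGGAGGCAGCAG",
                          barcode_length = 8L,
                          otu_threshold = 0.03) {
  E <- length(editions)
  stopifnot(E >= 1, length(multiplicity_design) == E,
            all(multiplicity_design >= 0),
            sum(multiplicity_design) >= 1,
            !is.null(names(phyla)), all(phyla >= 0),
            seq_length >= 20, reads_per_otu_min >= 1,
            error_rate >= 0, error_rate < 0.5, indel_rate >= 0,
            barcode_length >= 0)
  if (sum(phyla) != sum(multiplicity_design))
    stop("phylum budgets (", sum(phyla), ") must sum to the total OTU ",
         "count (", sum(multiplicity_design), ")")
  if (min_between_otu_divergence <=
      2 * within_otu_divergence + otu_threshold)
    stop("margin check failed: need min_between_otu_divergence > ",
         "2 * within_otu_divergence + otu_threshold")
  structure(list(editions = editions,
                 multiplicity_design = as.integer(multiplicity_design),
                 phyla = phyla, seq_length = as.integer(seq_length),
                 within_otu_divergence = within_otu_divergence,
                 min_between_otu_divergence = min_between_otu_divergence,
                 reads_per_otu_min = as.integer(reads_per_otu_min),
                 reads_per_otu_meanlog = reads_per_otu_meanlog,
                 reads_per_otu_sdlog = reads_per_otu_sdlog,
                 error_rate = error_rate, indel_rate = indel_rate,
                 primer = primer,
                 barcode_length = as.integer(barcode_length),
                 otu_threshold = otu_threshold),
            class = "system_design")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

substitute_positions <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

mutate_copy <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  substitute_positions(seq, sample(nchar(seq), n_sub))
}

add_read_errors <- function(seq, error_rate, indel_rate) {
  L <- nchar(seq)
  n_sub <- rbinom(1, L, error_rate)
  if (n_sub > 0) seq <- substitute_positions(seq, sample(L, n_sub))
  if (indel_rate > 0) {
    n_ind <- rbinom(1, L, indel_rate)
    for (k in seq_len(n_ind)) {
      ch <- strsplit(seq, "")[[1]]
      p <- sample(length(ch), 1)
      ch <- if (runif(1) < 0.5) ch[-p]
            else append(ch, sample(DNA_BASES, 1), after = p)
      seq <- paste(ch, collapse = "")
    }
  }
  seq
}

quality_string <- function(len) {
  intToUtf8(33L + sample(25:38, len, replace = TRUE))
}

#' Generate a synthetic multi-edition amplicon system
#'
#' Draws OTU reference sequences by rejection sampling so that all pairwise
#' reference distances respect `min_between_otu_divergence`, assigns each
#' OTU a phylum and an edition subset matching the designed multiplicity
#' structure, mutates one copy per member edition within
#' `within_otu_divergence`, and emits reads per copy (primer + barcode
#' prefix, substitution errors at `error_rate`, quality strings passing the
#' default filters).  Fully reproducible from `seed`.
#'
#' @param design A [system_design()].
#' @param seed Integer seed; all randomness flows from it.
#' @param dir Optional directory: per-edition FASTQ files, a ground-truth
#'   JSON and an OTU label TSV are written there.
#' @return A list (class `synthetic_system`) with `reads` (one read table,
#'   `sample` column holding the edition), `truth` (references, phylum and
#'   edition membership per OTU, per-read OTU/phylum labels, expected
#'   `n_by_phylum`, `N_by_phylum`, multiplicity census, edition sizes and
#'   exact-mode T_r per edition) and the `design`.
#' @export
generate_system <- function(design, seed = NULL, dir = NULL) {
  stopifnot(inherits(design, "system_design"))
  if (!is.null(seed)) set.seed(seed)
  E <- length(design$editions)
  K <- sum(design$multiplicity_design)
  L <- design$seq_length
  min_sub <- ceiling(design$min_between_otu_divergence * L)
  # rejection-sample references with pairwise Hamming-like separation
  refs <- character(0)
  tries <- 0L
  while (length(refs) < K) {
    cand <- random_dna(L)
    tries <- tries + 1L
    if (tries > 200L * K)
      stop("design infeasible for seq_length ", L,
           ": rejection sampling exceeded its retry budget")
    ok <- all(vapply(refs, function(r) nw_distance_cpp(r, cand, TRUE) >=
                       design$min_between_otu_divergence, logical(1)))
    if (ok) refs <- c(refs, cand)
  }
  otu_ids <- sprintf("SYS_OTU_%03d", seq_len(K))
  names(refs) <- otu_ids
  phylum <- setNames(rep(names(design$phyla), design$phyla), otu_ids)
  # edition membership by designed multiplicity
  multiplicity <- rep(seq_len(E), design$multiplicity_design)
  membership <- lapply(multiplicity, function(k)
    design$editions[sort(sample(E, k))])
  names(membership) <- otu_ids
  k_within <- floor(design$within_otu_divergence * L)
  barcodes <- setNames(vapply(seq_len(E), function(i)
    random_dna(design$barcode_length), character(1)), design$editions)
  reads <- list()
  read_otu <- character(0)
  for (ed in design$editions) {
    in_ed <- otu_ids[vapply(membership, function(m) ed %in% m, logical(1))]
    for (otu in in_ed) {
      copy <- mutate_copy(refs[[otu]], k_within)
      n_reads <- max(design$reads_per_otu_min,
                     round(rlnorm(1, design$reads_per_otu_meanlog,
                                  design$reads_per_otu_sdlog)))
      for (j in seq_len(n_reads)) {
        insert <- add_read_errors(copy, design$error_rate,
                                  design$indel_rate)
        bases <- paste0(design$primer, barcodes[[ed]], insert)
        id <- paste0(ed, "_", otu, "_r", j)
        reads[[length(reads) + 1]] <-
          data.frame(id = id, bases = bases,
                     qual = quality_string(nchar(bases)), sample = ed,
                     stringsAsFactors = FALSE)
        read_otu <- c(read_otu, setNames(otu, id))
      }
    }
  }
  reads <- do.call(rbind, reads)
  rownames(reads) <- NULL
  edition_otus <- lapply(setNames(design$editions, design$editions),
                         function(ed)
    otu_ids[vapply(membership, function(m) ed %in% m, logical(1))])
  count_phyla <- function(ids) {
    tab <- table(factor(phylum[ids], levels = unique(names(design$phyla))))
    setNames(as.integer(tab), names(tab))
  }
  n_by <- lapply(edition_otus, count_phyla)
  N_by <- count_phyla(otu_ids)
  tr_expected <- vapply(n_by, function(n)
    tr_index(n[n > 0], N_by, "exact")$T_r, numeric(1))
  truth <- list(references = refs, phylum = phylum,
                membership = membership,
                read_otu = read_otu,
                read_phylum = setNames(phylum[read_otu], names(read_otu)),
                barcodes = barcodes,
                edition_sizes = lengths(edition_otus),
                n_by_phylum = n_by, N_by_phylum = N_by,
                census = setNames(design$multiplicity_design,
                                  seq_len(E)),
                tr_exact = tr_expected)
  out <- structure(list(reads = reads, truth = truth, design = design),
                   class = "synthetic_system")
  if (!is.null(dir)) write_synthetic_system(out, dir)
  out
}

write_synthetic_system <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ed in system$design$editions) {
    sel <- system$reads[system$reads$sample == ed, , drop = FALSE]
    write_sequences(sel, file.path(dir, paste0(ed, ".fastq")), "fastq")
  }
  labels <- data.frame(read_id = names(system$truth$read_otu),
                       otu = unname(system$truth$read_otu),
                       phylum = unname(system$truth$read_phylum))
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- system$truth
  json <- jsonlite::toJSON(list(references = as.list(tr$references),
                                phylum = as.list(tr$phylum),
                                membership = tr$membership,
                                edition_sizes = as.list(tr$edition_sizes),
                                n_by_phylum = lapply(tr$n_by_phylum,
                                                     as.list),
                                N_by_phylum = as.list(tr$N_by_phylum),
                                census = as.list(tr$census),
                                tr_exact = as.list(tr$tr_exact)),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Environment table and taxon abundances with designed correlations
#'
#' Builds an environment table from a single latent gradient (all variables
#' are noise-free affine images of it, emulating the co-oscillating
#' physicochemistry of a shared outflow) and constructs taxon abundances as
#' `r * g + sqrt(1 - r^2) * eps` on the standardized gradient `g`, with
#' `eps ~ N(0, noise_sd^2)`, so the expected Pearson correlation with each
#' named variable matches its target.  With `noise_sd = 0` the realized
#' correlation is exactly +/-1 (the sign of the target).  Because the
#' variables are collinear, a taxon targeting several variables must imply
#' a single latent correlation; otherwise the target matrix is infeasible
#' and an error is raised.
#'
#' @param target_correlations `data.frame` with columns `taxon`, `variable`,
#'   `r` (each `|r| <= 1`).
#' @param n_samples Number of samples (default 5).
#' @param noise_sd Standard deviation of the abundance noise term
#'   (default 1, which makes the expected realized r equal the target).
#' @param variables Character vector of environment variable names
#'   (defaults to the variables named in `target_correlations`).
#' @param seed Integer seed.
#' @return A list with `environment` (samples x variables), `abundance`
#'   (samples x taxa, non-negative), `gradient`, and the echoed `targets`.
#' @export
generate_env_abundance <- function(target_correlations, n_samples = 5,
                                   noise_sd = 1, variables = NULL,
                                   seed = NULL) {
  stopifnot(is.data.frame(target_correlations),
            all(c("taxon", "variable", "r") %in%
                  names(target_correlations)))
  if (any(abs(target_correlations$r) > 1))
    stop("target correlations must satisfy |r| <= 1")
  if (n_samples < 3) stop("need n_samples >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(variables)) variables <- unique(target_correlations$variable)
  missing_v <- setdiff(target_correlations$variable, variables)
  if (length(missing_v))
    stop("unknown environment variable(s): ",
         paste(missing_v, collapse = ", "))
  g <- rnorm(n_samples)
  z <- as.numeric(scale(g))
  env <- vapply(seq_along(variables), function(i)
    10 * i + (2 + i) * g, numeric(n_samples))
  colnames(env) <- variables
  rownames(env) <- paste0("sample_", seq_len(n_samples))
  taxa <- unique(target_correlations$taxon)
  latent_r <- setNames(numeric(length(taxa)), taxa)
  for (t in taxa) {
    rows <- target_correlations[target_correlations$taxon == t, ]
    # all variables are positive affine images of g, so each target is a
    # direct constraint on the latent correlation
    if (length(unique(round(rows$r, 12))) > 1)
      stop("infeasible target correlation matrix: taxon '", t,
           "' targets incompatible correlations against collinear ",
           "variables")
    latent_r[t] <- rows$r[1]
  }
  ab <- vapply(taxa, function(t) {
    r <- latent_r[[t]]
    y <- r * z + sqrt(1 - r^2) * rnorm(n_samples, 0, noise_sd)
    y - min(y) + 0.05 * (max(y) - min(y) + 1)  # positive affine shift
  }, numeric(n_samples))
  colnames(ab) <- taxa
  rownames(ab) <- rownames(env)
  list(environment = env, abundance = ab, gradient = g,
       targets = target_correlations)
}

#' Random Dirichlet abundance vectors
#'
#' @param n Number of vectors.
#' @param k Number of taxa.
#' @param alpha Concentration (scalar or length-`k`).
#' @return An `n x k` matrix of proportions, rows summing to 1.
#' @export
rdirichlet_abundance <- function(n, k, alpha = 1) {
  a <- rep_len(alpha, k)
  x <- matrix(rgamma(n * k, shape = rep(a, each = n)), nrow = n)
  x / rowSums(x)
}
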