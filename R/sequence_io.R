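#' Read amplicon sequences from FASTA or FASTQ
#'
#' Parses a sequence file into the read table used by the rest of the
#' pipeline.  FASTA records yield `NA` qualities; FASTQ qualities are kept as
#' Sanger phred+33 strings.  Record order is preserved.
#'
#' @param path Path to an existing FASTA or FASTQ file.
#' @param format `"auto"` (default, by extension), `"fasta"` or `"fastq"`.
#' @param sample Optional edition label stored in the `sample` column.
#' @return A `data.frame` with columns `id`, `bases`, `qual` (phred+33
#'   character or `NA`), `sample`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0) return(empty_reads())
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
    qual <- rep(NA_character_, length(x))
  } else {
    parsed <- withCallingHandlers(
      tryCatch({
        x <- Biostrings::readQualityScaledDNAStringSet(path)
        list(x = x, qual = as.character(Biostrings::quality(x)))
      }, error = function(e) stop("FASTQ parse error in '", path, "': ",
                                  conditionMessage(e))),
      # Biostrings notes that FASTQ description metadata is not retained;
      # ids and qualities are, so this is noise for our purposes
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    x <- parsed$x
    qual <- parsed$qual
  }
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("parse error: empty record id in '", path, "'")
  if (anyDuplicated(ids))
    stop("parse error: duplicated read id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bases <- as.character(x)
  bad <- which(!is.na(qual) & nchar(qual) != nchar(bases))
  if (length(bad))
    stop("FASTQ parse error in '", path, "': quality/sequence length ",
         "mismatch for record ", bad[1], " ('", ids[bad[1]], "')")
  data.frame(id = ids, bases = bases, qual = qual,
             sample = rep_len(sample, length(ids)),
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_reads <- function() {
  data.frame(id = character(), bases = character(), qual = character(),
             sample = character(), stringsAsFactors = FALSE)
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads A read table as returned by [read_sequences()].
#' @param path Output file path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on all
#'   reads.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    if (any(is.na(reads$qual)))
      stop("cannot write FASTQ: reads lack quality strings")
    q <- Biostrings::PhredQuality(reads$qual)
    xq <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(xq, path)
  }
  invisible(path)
}

new_filter_report <- function(input, kept, dropped) {
  reasons <- c("quality", "length", "primer", "n_bases", "duplicate",
               "subset")
  full <- setNames(integer(length(reasons)), reasons)
  full[names(dropped)] <- as.integer(dropped)
  stopifnot(kept + sum(full) == input)
  structure(list(input_count = as.integer(input),
                 kept_count = as.integer(kept),
                 dropped_by_reason = full),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Read filter report:", x$kept_count, "of", x$input_count,
      "reads kept\n")
  d <- x$dropped_by_reason[x$dropped_by_reason > 0]
  if (length(d))
    cat(paste0("  dropped (", names(d), "): ", d, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
filter_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  j <- jsonlite::toJSON(list(input_count = report$input_count,
                             kept_count = report$kept_count,
                             dropped_by_reason =
                               as.list(report$dropped_by_reason)),
                        auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Quality and length filtering of raw reads
#'
#' Drops reads whose quality summary falls below `min_qv` or whose length is
#' below `min_len` (defaults QV 20 and 100 bp).  The quality summary is the
#' per-read mean by default; `stat = "min"` uses the minimum base quality
#' instead.  Reads without quality strings are only length-filtered (a
#' message is emitted once).
#'
#' @param reads Read table ([read_sequences()]).
#' @param min_qv Minimum per-read quality summary (phred scale), `>= 0`.
#' @param min_len Minimum read length in bp, `>= 1`.
#' @param stat Quality summary statistic, `"mean"` (default) or `"min"`.
#' @return `list(reads = <kept reads>, report = <filter_report>)`.
#' @export
quality_length_filter <- function(reads, min_qv = 20, min_len = 100,
                                  stat = c("mean", "min")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(reads))
  if (min_len < 1 || min_qv < 0)
    stop("config error: need min_len >= 1 and min_qv >= 0")
  n <- nrow(reads)
  if (n == 0)
    return(list(reads = empty_reads(),
                report = new_filter_report(0L, 0L, integer())))
  if (any(is.na(reads$qual)))
    message("some reads carry no quality scores; ",
            "only the length filter applies to them")
  qv_ok <- vapply(reads$qual, function(q) {
    if (is.na(q)) return(TRUE)
    s <- phred_scores(q)
    if (stat == "mean") mean(s) >= min_qv else min(s) >= min_qv
  }, logical(1), USE.NAMES = FALSE)
  len_ok <- nchar(reads$bases) >= min_len
  drop_quality <- sum(!qv_ok)
  drop_length <- sum(qv_ok & !len_ok)
  keep <- qv_ok & len_ok
  list(reads = reads[keep, , drop = FALSE],
       report = new_filter_report(n, sum(keep),
                                  c(quality = drop_quality,
                                    length = drop_length)))
}

#' Preprocess reads: primer screening, N removal, duplicate/subset pruning
#'
#' Mirrors amplicon preprocessing as used before denoising: only reads that
#' start with the exact primer followed by `barcode_length` barcode bases are
#' kept, the primer+barcode prefix is trimmed off, reads containing `N` are
#' dropped, and (optionally) reads identical to, or exact substrings of,
#' another read are removed, keeping the longest read (first seen on ties).
#'
#' `primer = ""` skips the primer screen (no trimming), which also makes the
#' operation idempotent on its own output.  Abundance-aware workflows keep
#' duplicates (`drop_duplicates = FALSE`) because read multiplicity is the
#' abundance signal consumed by [precluster()].
#'
#' @param reads Read table.
#' @param primer Literal primer string (exact matching, no IUPAC wildcards);
#'   `""` disables the primer screen.
#' @param barcode_length Number of barcode bases following the primer.
#' @param max_mismatch Allowed primer mismatches (default 0, i.e. intact
#'   primer required).
#' @param drop_duplicates Drop exact duplicate and substring reads
#'   (default `TRUE`).
#' @return `list(reads = <kept reads>, report = <filter_report>)`.
#' @export
preprocess_reads <- function(reads, primer, barcode_length = 0L,
                             max_mismatch = 0L, drop_duplicates = TRUE) {
  stopifnot(is.data.frame(reads), is.character(primer), length(primer) == 1,
            barcode_length >= 0, max_mismatch >= 0)
  n <- nrow(reads)
  if (n == 0)
    return(list(reads = empty_reads(),
                report = new_filter_report(0L, 0L, integer())))
  prefix_len <- nchar(primer) + as.integer(barcode_length)
  if (prefix_len > 0) {
    has_primer <- nchar(reads$bases) > prefix_len &
      vapply(substr(reads$bases, 1, nchar(primer)), function(p) {
        if (nchar(p) < nchar(primer)) return(FALSE)
        sum(utf8ToInt(p) != utf8ToInt(primer)) <= max_mismatch
      }, logical(1), USE.NAMES = FALSE)
  } else {
    has_primer <- rep(TRUE, n)
  }
  drop_primer <- sum(!has_primer)
  kept <- reads[has_primer, , drop = FALSE]
  if (prefix_len > 0 && nrow(kept)) {
    kept$bases <- substring(kept$bases, prefix_len + 1)
    kept$qual <- ifelse(is.na(kept$qual), NA_character_,
                        substring(kept$qual, prefix_len + 1))
  }
  has_n <- grepl("N", kept$bases, fixed = TRUE)
  drop_n <- sum(has_n)
  kept <- kept[!has_n, , drop = FALSE]
  drop_dup <- 0L
  drop_sub <- 0L
  if (drop_duplicates && nrow(kept) > 1) {
    ord <- order(-nchar(kept$bases), seq_len(nrow(kept)))
    survivors <- character(0)
    status <- character(nrow(kept))  # "", "duplicate", "subset"
    for (i in ord) {
      b <- kept$bases[i]
      if (b %in% survivors) {
        status[i] <- "duplicate"
      } else if (length(survivors) &&
                 any(vapply(survivors, grepl, logical(1), pattern = b,
                            fixed = TRUE, USE.NAMES = FALSE) &
                     nchar(survivors) > nchar(b))) {
        status[i] <- "subset"
      } else {
        survivors <- c(survivors, b)
      }
    }
    drop_dup <- sum(status == "duplicate")
    drop_sub <- sum(status == "subset")
    kept <- kept[status == "", , drop = FALSE]
  }
  list(reads = kept,
       report = new_filter_report(n, nrow(kept),
                                  c(primer = drop_primer, n_bases = drop_n,
                                    duplicate = drop_dup,
                                    subset = drop_sub)))
}
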