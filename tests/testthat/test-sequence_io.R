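test_that("FASTQ and FASTA records parse with order, qualities and wrapping", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIHHHH",
               "@r2", "TTGGCCAA", "+", "########"), fq)
  reads <- read_sequences(fq)
  expect_equal(reads$id, c("r1", "r2"))
  expect_equal(nchar(reads$qual), nchar(reads$bases))
  expect_equal(otuflux:::phred_scores(reads$qual[1]), c(40, 40, 40, 40,
                                                        39, 39, 39, 39))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 wrapped", "ACGT", "ACGT", "AC", ">s2", "GGGG"), fa)
  fasta <- read_sequences(fa)
  expect_equal(fasta$bases, c("ACGTACGTAC", "GGGG"))
  expect_true(all(is.na(fasta$qual)))
})

test_that("malformed FASTQ records and empty files are handled", {
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "III"), bad)  # qual too short
  expect_error(read_sequences(bad), "parse error")
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_sequences(dup), "duplicated")
  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(read_sequences(empty)), 0)
  expect_error(read_sequences("no/such/file.fastq"), "not found")
})

test_that("sequence round trips preserve reads in both formats", {
  reads <- data.frame(id = c("a", "b"), bases = c("ACGTACGT", "TTTTAAAA"),
                      qual = c("IIIIIIII", "HHHHHHHH"), sample = "s")
  for (fmt in c("fasta", "fastq")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_sequences(reads, f, fmt)
    back <- read_sequences(f)
    expect_equal(back$id, reads$id)
    expect_equal(back$bases, reads$bases)
    if (fmt == "fastq") expect_equal(back$qual, reads$qual)
  }
})

make_read <- function(id, bases, mean_qv) {
  q <- intToUtf8(rep(33L + round(mean_qv), nchar(bases)))
  data.frame(id = id, bases = bases, qual = q, sample = "s")
}

test_that("quality/length filter matches an independent recount", {
  set.seed(11)
  # 50 reads with known mean QVs straddling the QV-20 threshold
  reads <- do.call(rbind, lapply(1:50, function(i) {
    len <- sample(90:120, 1)
    qv <- sample(10:35, 1)
    r <- make_read(paste0("r", i), random_seq(len), 0)
    r$qual <- intToUtf8(33L + sample(c(qv - 2L, qv + 2L),
                                     nchar(r$bases), TRUE))
    r
  }))
  res <- quality_length_filter(reads, min_qv = 20, min_len = 100)
  # independent recount straight from the phred characters
  mean_qv <- vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33),
                    numeric(1), USE.NAMES = FALSE)
  expect_equal(res$reads$id,
               reads$id[mean_qv >= 20 & nchar(reads$bases) >= 100])
  rep <- res$report
  expect_equal(rep$kept_count + sum(rep$dropped_by_reason),
               rep$input_count)
})

test_that("length threshold is exclusive below 100 bp and report reconciles", {
  r99 <- make_read("short", random_seq(99), 30)
  r100 <- make_read("ok", random_seq(100), 30)
  res <- quality_length_filter(rbind(r99, r100))
  expect_equal(res$reads$id, "ok")
  expect_equal(unname(res$report$dropped_by_reason["length"]), 1L)
  empty <- quality_length_filter(
    data.frame(id = character(), bases = character(), qual = character(),
               sample = character()))
  expect_equal(nrow(empty$reads), 0)
  expect_equal(empty$report$input_count, 0L)
  expect_error(quality_length_filter(r100, min_len = 0), "config error")
  expect_error(quality_length_filter(r100, min_qv = -1), "config error")
})

test_that("reads without qualities only pass through the length filter", {
  reads <- data.frame(id = c("a", "b"), qual = NA_character_,
                      bases = c(random_seq(150), random_seq(50)),
                      sample = "s")
  expect_message(res <- quality_length_filter(reads), "no quality")
  expect_equal(res$reads$id, "a")
})

test_that("primer screening keeps and trims only intact-prefix reads", {
  primer <- "ACGTACG"
  reads <- data.frame(id = c("with", "without"),
                      bases = c(paste0(primer, "GG", "ACGT"), "ACGT"),
                      qual = NA_character_, sample = "s")
  res <- preprocess_reads(reads, primer, barcode_length = 2)
  expect_equal(res$reads$id, "with")
  expect_equal(res$reads$bases, "ACGT")
  expect_equal(unname(res$report$dropped_by_reason["primer"]), 1L)
})

test_that("N-containing, duplicate and subset reads are pruned deterministically", {
  reads <- data.frame(id = c("n", "dup1", "dup2", "sub", "long"),
                      bases = c("ACGTN", "ACGT", "ACGT", "TTG", "GTTGGA"),
                      qual = NA_character_, sample = "s")
  res <- preprocess_reads(reads, primer = "")
  # "TTG" is a substring of "GTTGGA"; first-seen duplicate survives
  expect_equal(res$reads$id, c("dup1", "long"))
  d <- res$report$dropped_by_reason
  expect_equal(unname(d[c("n_bases", "duplicate", "subset")]),
               c(1L, 1L, 1L))
  expect_equal(res$report$kept_count + sum(d), res$report$input_count)
})

test_that("preprocessing is idempotent on its own output", {
  set.seed(5)
  reads <- data.frame(id = paste0("r", 1:30),
                      bases = c(replicate(15, random_seq(80)),
                                replicate(15, random_seq(120))),
                      qual = NA_character_, sample = "s")
  reads$bases[4] <- reads$bases[1]                 # duplicate
  reads$bases[5] <- substr(reads$bases[2], 10, 60) # subset
  first <- preprocess_reads(reads, primer = "")
  second <- preprocess_reads(first$reads, primer = "")
  expect_equal(second$reads, first$reads)
  expect_equal(sum(second$report$dropped_by_reason), 0L)
})

test_that("filter reports serialize to JSON with reconciled counts", {
  reads <- data.frame(id = c("a", "b"), bases = c("ACGT", "ACGT"),
                      qual = NA_character_, sample = "s")
  res <- preprocess_reads(reads, primer = "")
  j <- jsonlite::fromJSON(filter_report_json(res$report))
  expect_equal(j$input_count, 2)
  expect_equal(j$kept_count + sum(unlist(j$dropped_by_reason)),
               j$input_count)
})
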