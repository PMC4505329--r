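abund_fixture <- function() {
  data.frame(taxon = c("Thermus", "Chloroflexus", "Synechococcus",
                       "Unclassified Bacteria"),
             rank = "genus",
             s1 = c(9999, 1, 0, 500),
             s2 = c(5000, 4000, 1000, 100))
}

test_that("the significance cutoff is inclusive at 0.01%", {
  tab <- abund_fixture()
  # classifiable total in s1 is 10000: Chloroflexus sits exactly at 0.01%
  res <- significance_filter(tab, "s1", cutoff = 1e-4)
  expect_true("Chloroflexus" %in% res$taxon)
  tab$s1[tab$taxon == "Chloroflexus"] <- 0.9  # 0.009% of 9999.9 -> dropped
  res2 <- significance_filter(tab, "s1", cutoff = 1e-4)
  expect_false("Chloroflexus" %in% res2$taxon)
  expect_error(significance_filter(tab, "s1", cutoff = 0), "config error")
  expect_error(significance_filter(tab, "s1", cutoff = 1), "config error")
})

test_that("significance filtering equals an independent recount", {
  set.seed(51)
  tab <- data.frame(taxon = paste0("g", 1:200),
                    s1 = rpois(200, 40) * sample(0:50, 200, TRUE))
  tab <- tab[order(tab$taxon), ]
  res <- significance_filter(tab, "s1", cutoff = 0.002)
  want <- tab$taxon[tab$s1 / sum(tab$s1) >= 0.002]
  expect_setequal(res$taxon, want)
})

test_that("unclassified reads are excluded from the classifiable denominator", {
  tab <- abund_fixture()
  p <- relative_abundance(tab, "s2")
  expect_equal(sum(p[c("Thermus", "Chloroflexus", "Synechococcus")]), 1)
  p_all <- relative_abundance(tab, "s2", classifiable_only = FALSE)
  expect_equal(sum(p_all), 1)
})

test_that("leaderboards rank by count with lexicographic ties", {
  tab <- abund_fixture()
  lb <- leaderboard(tab, "s2", n = 50)
  expect_equal(lb$taxon[1:2], c("Thermus", "Chloroflexus"))
  expect_equal(nrow(lb), 4)  # shorter than n, zero-count rows excluded
  tie <- data.frame(taxon = c("Zeta", "Alpha", "Mid"),
                    s1 = c(10, 10, 5))
  expect_equal(leaderboard(tie, "s1", n = 2)$taxon, c("Alpha", "Zeta"))
})

test_that("leaderboard equals an independent sort on random tables", {
  set.seed(52)
  tab <- data.frame(taxon = paste0("g", sample(1:999, 300)),
                    s1 = sample(0:5000, 300, TRUE))
  lb <- leaderboard(tab, "s1", n = 50)
  ord <- order(-tab$s1, tab$taxon)
  want <- tab$taxon[ord][tab$s1[ord] > 0][1:50]
  expect_equal(lb$taxon, want)
})

test_that("leaderboard transitions partition the union of boards", {
  b1 <- c("a", "b", "c", "d")
  b2 <- c("b", "c", "e")
  b3 <- c("c", "d", "e", "f")
  tr <- leaderboard_transitions(list(Y1 = b1, Y2 = b2, Y3 = b3))
  expect_setequal(tr[["Y1 & Y2 & Y3"]], "c")
  expect_setequal(tr[["Y1 & Y3"]], "d")
  expect_setequal(tr[["Y2 & Y3"]], "e")
  expect_setequal(tr[["Y1"]], "a")
  # disjoint and exhaustive
  expect_equal(sort(unlist(tr, use.names = FALSE)),
               sort(unique(c(b1, b2, b3))))
  same <- leaderboard_transitions(list(A = b1, B = b1))
  expect_equal(names(same), "A & B")
  disj <- leaderboard_transitions(list(A = c("x"), B = c("y")))
  expect_setequal(names(disj), c("A", "B"))
})

test_that("transitions match brute-force set algebra on random boards", {
  set.seed(53)
  pool <- paste0("g", 1:40)
  boards <- list(A = sample(pool, 15), B = sample(pool, 15),
                 C = sample(pool, 15))
  tr <- leaderboard_transitions(boards)
  for (t in pool) {
    memb <- names(boards)[vapply(boards, function(b) t %in% b,
                                 logical(1))]
    if (!length(memb)) next
    key <- paste(memb, collapse = " & ")
    expect_true(t %in% tr[[key]])
  }
})

test_that("Bray-Curtis similarity matches the 2*min/(sum) formula", {
  x <- c(4, 0, 3, 1)
  expect_equal(bray_curtis_similarity(x, x), 1)
  expect_equal(bray_curtis_similarity(c(1, 2, 0, 0), c(0, 0, 3, 4)), 0)
  set.seed(54)
  for (i in 1:10) {
    a <- runif(6, 0, 10)
    b <- runif(6, 0, 10)
    hand <- 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
    expect_equal(bray_curtis_similarity(a, b), hand)
    expect_equal(bray_curtis_similarity(b, a),
                 bray_curtis_similarity(a, b))
    expect_gte(bray_curtis_similarity(a, b), 0)
    expect_lte(bray_curtis_similarity(a, b), 1)
  }
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "domain error")
})

test_that("Euclidean distance matches the closed form", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
})

test_that("Pearson correlation matches the closed form and flags misuse", {
  x <- c(1, 2, 5)
  res <- pearson_r(x, -2 * x + 7)
  expect_equal(res$r, -1)
  y <- c(2, 9, 4)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, hand)
  # r(x, a x + b) == sign(a)
  set.seed(55)
  z <- rnorm(10)
  expect_equal(pearson_r(z, 3.2 * z - 1)$r, 1)
  expect_equal(pearson_r(z, -0.4 * z + 2)$r, -1)
  # orthogonalized response has r = 0
  w <- rnorm(10)
  w_orth <- w - sum(w * (z - mean(z))) / sum((z - mean(z))^2) *
    (z - mean(z))
  expect_equal(pearson_r(z, w_orth)$r, 0, tolerance = 1e-10)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "domain error")
  expect_error(pearson_r(c(1, 2), c(1, 3)), "domain error")
})
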