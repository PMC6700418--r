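scored_two_class <- function(boundary, metabolic) {
  make_scored(
    ko_a = sprintf("K%05d", seq_along(c(boundary, metabolic))),
    ko_b = sprintf("K%05d", 1000 + seq_along(c(boundary, metabolic))),
    score = c(boundary, metabolic),
    pair_class = rep(c("metabolic_nonmetabolic", "metabolic_metabolic"),
                     c(length(boundary), length(metabolic))))
}

test_that("compare_boundary_scores degenerate and disjoint cases", {
  same <- scored_two_class(c(0.1, 0.5, 0.9), c(0.9, 0.1, 0.5))
  res <- compare_boundary_scores(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  apart <- scored_two_class(rep(0.9, 20), rep(0.1, 20))
  res2 <- compare_boundary_scores(apart)
  expect_equal(res2$statistic, 1)
  expect_lt(res2$p_value, 1e-6)

  one_class <- make_scored("K00001", "K00002", 0.5,
                           pair_class = "metabolic_metabolic")
  expect_error(compare_boundary_scores(one_class),
               "metabolic_nonmetabolic")
})

test_that("the one-sided KS p-value matches a permutation oracle", {
  set.seed(31)
  b <- rnorm(50, mean = 0.3, sd = 0.25)
  m <- rnorm(50, mean = 0.15, sd = 0.25)
  res <- compare_boundary_scores(scored_two_class(b, m))
  p_perm <- ks_perm_p(b, m, n_perm = 10000)
  expect_lt(abs(res$p_value - p_perm), 0.03)
})

test_that("the KS statistic is invariant under monotone transforms", {
  set.seed(32)
  b <- runif(30); m <- runif(40)
  r1 <- compare_boundary_scores(scored_two_class(b, m))
  r2 <- compare_boundary_scores(scored_two_class(exp(2 * b), exp(2 * m)))
  expect_equal(r1$statistic, r2$statistic)
})

simple_modules <- function() {
  data.frame(module_id = c("M1", "M1", "M1"),
             compound_id = c("C00001", "C00002", "C00003"),
             role = c("edge", "internal", "edge"),
             stringsAsFactors = FALSE)
}

test_that("module_linkage_by_window bins pairs by score", {
  sc <- make_scored("K00001", "K00002", 0.65,
                    compounds = list("C00001"))
  wl <- module_linkage_by_window(sc, simple_modules())
  w <- wl$windows
  row <- w[abs(w$score_lo - 0.6) < 1e-9, ]
  expect_equal(row$n_edge, 1)
  expect_equal(sum(w$n_edge) + sum(w$n_non_edge), 1)

  none <- make_scored("K00001", "K00002", 0.65,
                      compounds = list("C09999"))
  w0 <- module_linkage_by_window(none, simple_modules())$windows
  expect_equal(sum(w0$n_edge) + sum(w0$n_non_edge), 0)
})

test_that("window counts match a brute-force double loop", {
  set.seed(33)
  n <- 200
  cpds <- sample(c("C00001", "C00002", "C00009"), n, replace = TRUE)
  sc <- make_scored(sprintf("K%05d", 1:n), sprintf("K%05d", n + 1:n),
                    score = runif(n, -1, 1),
                    compounds = as.list(cpds))
  mods <- simple_modules()
  wl <- module_linkage_by_window(sc, mods, window_width = 0.1)
  breaks <- seq(-1, 1, by = 0.1)
  for (wi in seq_len(nrow(wl$windows))) {
    lo <- breaks[wi]; hi <- breaks[wi + 1]
    in_win <- if (wi == nrow(wl$windows)) {
      sc$score >= lo & sc$score <= hi
    } else {
      sc$score >= lo & sc$score < hi
    }
    expect_equal(wl$windows$n_edge[wi],
                 sum(in_win & cpds == "C00001" | in_win & cpds == "C00003"))
    expect_equal(wl$windows$n_non_edge[wi], sum(in_win & cpds == "C00002"))
  }
  # every pair with a module compound lands in exactly one window
  expect_equal(nrow(wl$pairs), sum(cpds != "C00009"))
  expect_equal(sum(wl$windows$n_edge) + sum(wl$windows$n_non_edge),
               nrow(wl$pairs))
})

test_that("edge_vs_nonedge_test matches exhaustive rank-sum enumeration", {
  # identical distributions: U = n1*n2/2, one-sided p about one half
  sc_same <- make_scored(sprintf("K%05d", 1:6), sprintf("K%05d", 7:12),
                         score = c(1, 2, 3, 1, 2, 3) / 10,
                         compounds = c(rep(list("C00001"), 3),
                                       rep(list("C00002"), 3)))
  res <- edge_vs_nonedge_test(module_linkage_by_window(sc_same,
                                                       simple_modules()))
  expect_equal(res$statistic, 4.5)

  # distinct values at n1 = n2 = 3: exact enumeration oracle
  sc3 <- make_scored(sprintf("K%05d", 1:6), sprintf("K%05d", 7:12),
                     score = c(0.61, 0.45, 0.52, 0.30, 0.38, 0.21),
                     compounds = c(rep(list("C00001"), 3),
                                   rep(list("C00002"), 3)))
  res3 <- edge_vs_nonedge_test(module_linkage_by_window(sc3,
                                                        simple_modules()))
  x <- c(0.61, 0.45, 0.52); y <- c(0.30, 0.38, 0.21)
  expect_equal(res3$statistic, mw_u(x, y))
  expect_equal(res3$p_value, mw_exact_p_greater(x, y))

  # clearly separated classes at n = 30/30
  set.seed(34)
  sc30 <- make_scored(sprintf("K%05d", 1:60), sprintf("K%05d", 61:120),
                      score = c(runif(30, 0.6, 1), runif(30, 0, 0.4)),
                      compounds = c(rep(list("C00001"), 30),
                                    rep(list("C00002"), 30)))
  res30 <- edge_vs_nonedge_test(module_linkage_by_window(sc30,
                                                         simple_modules()))
  expect_lt(res30$p_value, 0.01)

  # too few members in a class
  sc1 <- make_scored(c("K00001", "K00002", "K00003"),
                     c("K00011", "K00012", "K00013"),
                     score = c(0.5, 0.2, 0.3),
                     compounds = list("C00001", "C00002", "C00002"))
  expect_error(edge_vs_nonedge_test(module_linkage_by_window(sc1,
                                                             simple_modules())),
               "fewer than 2")
})

test_that("the fractions mode compares windows across the threshold", {
  set.seed(35)
  n <- 400
  score <- runif(n, -1, 1)
  # edge compounds dominate above tau, internal below
  cpds <- ifelse(score >= 0.6, ifelse(runif(n) < 0.9, "C00001", "C00002"),
                 ifelse(runif(n) < 0.5, "C00001", "C00002"))
  sc <- make_scored(sprintf("K%05d", 1:n), sprintf("K%05d", n + 1:n),
                    score = score, compounds = as.list(cpds))
  wl <- module_linkage_by_window(sc, simple_modules())
  res <- edge_vs_nonedge_test(wl, tau = 0.6, mode = "fractions")
  expect_true(res$p_value < 0.2) # direction only; few windows above tau
})
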