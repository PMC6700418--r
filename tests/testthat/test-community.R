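abund <- function(...) {
  # rows named by KO, columns by genus
  m <- rbind(...)
  m
}

test_that("KO pairs project to genus pairs as the cross product", {
  kg <- abund(K00001 = c(G1 = 1, G2 = 0, G3 = 0),
              K00002 = c(G1 = 0, G2 = 1, G3 = 0))
  sc <- make_scored("K00001", "K00002", 0.8)
  gpt <- ko_pairs_to_genus_pairs(sc, kg)
  expect_equal(nrow(gpt$pairs), 1)
  expect_equal(gpt$pairs$genus_a, "G1")
  expect_equal(gpt$pairs$genus_b, "G2")
  expect_equal(gpt$pairs$n_supporters, 1)
  expect_equal(gpt$pairs$aggregate_score, 0.8)

  # both KOs confined to the same genus: no pair (g != h required)
  kg2 <- abund(K00001 = c(G1 = 1, G2 = 0), K00002 = c(G1 = 1, G2 = 0))
  expect_equal(nrow(ko_pairs_to_genus_pairs(sc, kg2)$pairs), 0)

  # A in {G1, G2}, B in {G2, G3}: three distinct genus pairs
  kg3 <- abund(K00001 = c(G1 = 1, G2 = 1, G3 = 0),
               K00002 = c(G1 = 0, G2 = 1, G3 = 1))
  gpt3 <- ko_pairs_to_genus_pairs(sc, kg3)
  expect_setequal(paste(gpt3$pairs$genus_a, gpt3$pairs$genus_b),
                  c("G1 G2", "G1 G3", "G2 G3"))

  # strict complementarity removes the shared genus G2 from both sides
  gpt3s <- ko_pairs_to_genus_pairs(sc, kg3, strict_complement = TRUE)
  expect_equal(paste(gpt3s$pairs$genus_a, gpt3s$pairs$genus_b), "G1 G3")
})

test_that("genus-pair conversion matches a brute-force cross enumeration", {
  set.seed(51)
  kg <- matrix(rbinom(8 * 6, 1, 0.4) * runif(48), nrow = 8,
               dimnames = list(sprintf("K%05d", 1:8), paste0("G", 1:6)))
  sc <- make_scored(sprintf("K%05d", c(1, 3, 5)),
                    sprintf("K%05d", c(2, 4, 6)),
                    score = c(0.7, 0.8, 0.9))
  gpt <- ko_pairs_to_genus_pairs(sc, kg)
  brute <- new.env()
  for (i in 1:3) {
    a <- sc$ko_a[i]; b <- sc$ko_b[i]
    for (g in colnames(kg)) for (h in colnames(kg)) {
      if (g != h && kg[a, g] > 0 && kg[b, h] > 0) {
        key <- paste(min(g, h), max(g, h))
        cur <- mget(key, envir = brute, ifnotfound = list(character(0)))[[1]]
        assign(key, union(cur, paste(a, b, sc$score[i])), envir = brute)
      }
    }
  }
  keys <- sort(ls(brute))
  expect_equal(paste(gpt$pairs$genus_a, gpt$pairs$genus_b), keys)
  for (k in keys) {
    sup <- get(k, envir = brute)
    row <- gpt$pairs[paste(gpt$pairs$genus_a, gpt$pairs$genus_b) == k, ]
    expect_equal(row$n_supporters, length(sup))
    expect_equal(row$aggregate_score,
                 sum(as.numeric(vapply(strsplit(sup, " "),
                                       `[`, character(1), 3))))
  }
  # conversion is symmetric in KO orientation
  sc_rev <- make_scored(sc$ko_b, sc$ko_a, sc$score)
  sc_rev$ko_a <- sc$ko_b; sc_rev$ko_b <- sc$ko_a
  gpt_rev <- ko_pairs_to_genus_pairs(sc_rev, kg)
  expect_equal(gpt$pairs, gpt_rev$pairs)
})

test_that("donor presence needs one realized supporter per pair", {
  kg <- abund(K00001 = c(G1 = 1, G2 = 0), K00002 = c(G1 = 0, G2 = 1))
  sc <- make_scored("K00001", "K00002", 0.9)
  gpt <- ko_pairs_to_genus_pairs(sc, kg)
  d_full <- kg
  d_missing <- kg; d_missing[, "G2"] <- 0 # donor lacks genus G2
  pres <- donor_presence(gpt, list(d1 = d_full, d2 = d_missing))
  expect_equal(unname(pres["d1", ]), 1L)
  expect_equal(unname(pres["d2", ]), 0L)
})

test_that("donor presence matches brute-force per-cell evaluation", {
  set.seed(52)
  kg <- matrix(rbinom(60, 1, 0.5) * runif(60), nrow = 10,
               dimnames = list(sprintf("K%05d", 1:10), paste0("G", 1:6)))
  sc <- make_scored(sprintf("K%05d", c(1, 3, 5, 7, 9)),
                    sprintf("K%05d", c(2, 4, 6, 8, 10)),
                    score = runif(5, 0.6, 1))
  gpt <- ko_pairs_to_genus_pairs(sc, kg)
  tables <- lapply(1:10, function(d) {
    kg * matrix(rbinom(60, 1, 0.7), nrow = 10)
  })
  names(tables) <- paste0("D", 1:10)
  pres <- donor_presence(gpt, tables)
  for (d in names(tables)) {
    for (ci in seq_len(ncol(pres))) {
      gp <- strsplit(colnames(pres)[ci], "|", fixed = TRUE)[[1]]
      sup <- gpt$support[gpt$support$genus_a == gp[1] &
                         gpt$support$genus_b == gp[2], ]
      want <- FALSE
      for (j in seq_len(nrow(sup))) {
        m <- tables[[d]]
        if ((m[sup$ko_a[j], gp[1]] > 0 && m[sup$ko_b[j], gp[2]] > 0) ||
            (m[sup$ko_b[j], gp[1]] > 0 && m[sup$ko_a[j], gp[2]] > 0)) {
          want <- TRUE
        }
      }
      expect_equal(pres[d, ci] == 1L, want)
    }
  }
})

test_that("split_common partitions pairs by donor prevalence", {
  pres <- cbind(always = rep(1L, 10), never = rep(0L, 10),
                often = c(rep(1L, 9), 0L), rare = c(rep(0L, 9), 1L))
  rownames(pres) <- paste0("D", 1:10)
  sp <- split_common(pres, common_fraction = 0.9)
  expect_setequal(sp$common_pairs, c("always", "often"))
  expect_setequal(colnames(sp$specific_matrix), c("never", "rare"))
  # partition: common and specific cover all columns, disjoint
  expect_setequal(c(sp$common_pairs, colnames(sp$specific_matrix)),
                  colnames(pres))
  sp2 <- split_common(pres, common_fraction = 0.5)
  expect_equal(sort(sp2$common_pairs),
               sort(colnames(pres)[colMeans(pres) >= 0.5]))
})

planted_block_matrix <- function(n_per_block = 4, n_pairs = 6, noise = 0) {
  blocks <- rep(1:3, each = n_per_block)
  m <- matrix(0L, nrow = length(blocks), ncol = 3 * n_pairs)
  for (b in 1:3) {
    cols <- (b - 1) * n_pairs + seq_len(n_pairs)
    m[blocks == b, cols] <- 1L
  }
  if (noise > 0) {
    flip <- matrix(runif(length(m)) < noise, nrow = nrow(m))
    m <- (m + flip) %% 2L
  }
  rownames(m) <- sprintf("D%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("gp%02d", seq_len(ncol(m)))
  list(matrix = m, truth = blocks)
}

test_that("cluster_donors recovers planted donor blocks", {
  two_same <- rbind(d1 = c(1L, 0L, 1L), d2 = c(1L, 0L, 1L))
  colnames(two_same) <- paste0("gp", 1:3)
  expect_equal(cluster_donors(two_same, n_clusters = 1)$n_clusters, 1)
  two_diff <- rbind(d1 = c(1L, 1L, 0L, 0L), d2 = c(0L, 0L, 1L, 1L))
  colnames(two_diff) <- paste0("gp", 1:4)
  cl <- cluster_donors(two_diff, n_clusters = 2)
  expect_equal(cl$n_clusters, 2)
  expect_equal(sort(as.integer(table(cl$clusters))), c(1L, 1L))

  pb <- planted_block_matrix()
  cl3 <- cluster_donors(pb$matrix, n_clusters = 3)
  expect_equal(adjusted_rand_index(cl3$clusters[rownames(pb$matrix)],
                                   pb$truth), 1.0)
  expect_error(cluster_donors(pb$matrix, n_clusters = 99), "exceeds")
})

test_that("clustering is stable under donor permutation", {
  set.seed(53)
  pb <- planted_block_matrix(noise = 0.1)
  cl1 <- cluster_donors(pb$matrix, n_clusters = 3)
  perm <- sample(nrow(pb$matrix))
  cl2 <- cluster_donors(pb$matrix[perm, ], n_clusters = 3)
  donors <- rownames(pb$matrix)
  expect_equal(adjusted_rand_index(cl1$clusters[donors],
                                   cl2$clusters[donors]), 1.0)
})

test_that("adjusted_rand_index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(54)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})

test_that("cluster networks filter edges and weight nodes by incidence", {
  # two clusters of two donors; one genus pair above, one below threshold
  kg <- abund(K00001 = c(G1 = 1, G2 = 0, G3 = 0),
              K00002 = c(G1 = 0, G2 = 1, G3 = 0),
              K00003 = c(G1 = 0, G2 = 0, G3 = 1))
  sc <- make_scored(c("K00001", "K00002"), c("K00002", "K00003"),
                    score = c(10, 0.5))
  gpt <- ko_pairs_to_genus_pairs(sc, kg)
  pres <- matrix(1L, nrow = 2, ncol = 2,
                 dimnames = list(c("d1", "d2"),
                                 genus_pair_key(gpt)))
  clustering <- structure(list(
    tree = NULL, clusters = c(d1 = 1L, d2 = 1L), n_clusters = 1L),
    class = "donor_clustering")
  nets <- export_cluster_network(clustering, gpt, pres,
                                 edge_min_aggregate = 15)
  g <- nets[["1"]]
  # G1-G2 weight = 2 donors x 10 = 20 (kept); G2-G3 = 2 x 0.5 = 1 (dropped)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 20)
  expect_setequal(igraph::V(g)$name, c("G1", "G2"))
  expect_equal(unname(igraph::V(g)$total_score), c(20, 20))

  nets_iso <- export_cluster_network(clustering, gpt, pres,
                                     edge_min_aggregate = 15,
                                     keep_isolated = TRUE)
  expect_setequal(igraph::V(nets_iso[["1"]])$name, c("G1", "G2", "G3"))
  empty <- export_cluster_network(clustering, gpt, pres,
                                  edge_min_aggregate = 1e6)
  expect_equal(igraph::ecount(empty[["1"]]), 0)
})

test_that("node weight equals the incident displayed-edge sum on a fixture", {
  set.seed(55)
  genera <- paste0("G", 1:6)
  pairs <- t(combn(genera, 2))
  gpt <- structure(list(
    pairs = data.frame(genus_a = pairs[, 1], genus_b = pairs[, 2],
                       n_supporters = 1L,
                       aggregate_score = runif(nrow(pairs), 5, 30),
                       mean_score = 0.8, stringsAsFactors = FALSE),
    support = data.frame()), class = "genus_pair_table")
  pres <- matrix(1L, nrow = 1, ncol = nrow(pairs),
                 dimnames = list("d1", genus_pair_key(gpt)))
  clustering <- structure(list(tree = NULL, clusters = c(d1 = 1L),
                               n_clusters = 1L),
                          class = "donor_clustering")
  g <- export_cluster_network(clustering, gpt, pres,
                              edge_min_aggregate = 15)[["1"]]
  el <- igraph::as_data_frame(g)
  for (v in igraph::V(g)$name) {
    want <- sum(el$weight[el$from == v | el$to == v])
    expect_equal(igraph::V(g)$total_score[igraph::V(g)$name == v], want)
  }
})

test_that("network exports round-trip through GraphML, TSV and Newick", {
  set.seed(56)
  pb <- planted_block_matrix(noise = 0.05)
  cl <- cluster_donors(pb$matrix, n_clusters = 3)
  kg <- abund(K00001 = c(G1 = 1, G2 = 0), K00002 = c(G1 = 0, G2 = 1))
  gpt <- ko_pairs_to_genus_pairs(make_scored("K00001", "K00002", 20), kg)
  pres <- matrix(1L, nrow = nrow(pb$matrix), ncol = 1,
                 dimnames = list(rownames(pb$matrix), genus_pair_key(gpt)))
  dir <- withr::local_tempdir()
  export_cluster_network(cl, gpt, pres, edge_min_aggregate = 15, dir = dir)
  gml <- igraph::read_graph(file.path(dir, "cluster_1.graphml"),
                            format = "graphml")
  expect_equal(igraph::ecount(gml), 1)
  expect_equal(igraph::E(gml)$weight, 20 * sum(cl$clusters == 1))
  el <- read.delim(file.path(dir, "cluster_1_edges.tsv"))
  expect_equal(nrow(el), 1)
  tree <- ape::read.tree(file.path(dir, "donor_dendrogram.nwk"))
  expect_setequal(tree$tip.label, rownames(pb$matrix))
  dc <- read.delim(file.path(dir, "donor_clusters.tsv"))
  expect_equal(sort(dc$donor), sort(rownames(pb$matrix)))
})
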