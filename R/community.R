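#' Project interacting KO pairs to genus pairs
#'
#' For an interacting KO pair (A, B), every ordered assignment of the two
#' KOs to two distinct genera that carry them (genus-level abundance above
#' `epsilon`) yields one genus pair. Supporters are deduplicated per
#' (genus pair, KO pair); a genus pair's aggregate score is the sum of its
#' supporting KO-pair scores.
#'
#' @param interacting A `scored_pairs` data frame (typically thresholded
#'   with [select_interacting()]).
#' @param ko_by_genus KO x genus abundance matrix.
#' @param epsilon Detection threshold on genus-level abundance, default 0.
#' @param strict_complement If `TRUE`, a genus carrying both KOs of a pair
#'   is not used on either side (strict complementarity).
#' @return Object of class `genus_pair_table`: list with `pairs` (data
#'   frame `genus_a`, `genus_b`, `n_supporters`, `aggregate_score`,
#'   `mean_score`) and `support` (long data frame `genus_a`, `genus_b`,
#'   `ko_a`, `ko_b`, `score`).
#' @export
ko_pairs_to_genus_pairs <- function(interacting, ko_by_genus, epsilon = 0,
                                    strict_complement = FALSE) {
  genera <- colnames(ko_by_genus)
  rows <- vector("list", nrow(interacting))
  for (i in seq_len(nrow(interacting))) {
    a <- interacting$ko_a[i]; b <- interacting$ko_b[i]
    if (!(a %in% rownames(ko_by_genus)) || !(b %in% rownames(ko_by_genus))) {
      next
    }
    ga <- genera[ko_by_genus[a, ] > epsilon]
    gb <- genera[ko_by_genus[b, ] > epsilon]
    if (strict_complement) {
      both <- intersect(ga, gb)
      ga <- setdiff(ga, both)
      gb <- setdiff(gb, both)
    }
    if (!length(ga) || !length(gb)) next
    grid <- expand.grid(g = ga, h = gb, stringsAsFactors = FALSE)
    grid <- grid[grid$g != grid$h, , drop = FALSE]
    if (!nrow(grid)) next
    df <- data.frame(genus_a = pmin(grid$g, grid$h),
                     genus_b = pmax(grid$g, grid$h),
                     ko_a = a, ko_b = b, score = interacting$score[i],
                     stringsAsFactors = FALSE)
    rows[[i]] <- df[!duplicated(paste(df$genus_a, df$genus_b)), ,
                    drop = FALSE]
  }
  support <- if (any(!vapply(rows, is.null, logical(1)))) {
    do.call(rbind, rows)
  } else {
    data.frame(genus_a = character(0), genus_b = character(0),
               ko_a = character(0), ko_b = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(support) <- NULL
  key <- paste(support$genus_a, support$genus_b)
  ord <- sort(unique(key))
  idx <- unname(split(seq_len(nrow(support)), key)[ord])
  pairs <- data.frame(
    genus_a = vapply(idx, function(j) support$genus_a[j[1]], character(1)),
    genus_b = vapply(idx, function(j) support$genus_b[j[1]], character(1)),
    n_supporters = lengths(idx),
    aggregate_score = vapply(idx, function(j) sum(support$score[j]),
                             numeric(1)),
    mean_score = vapply(idx, function(j) mean(support$score[j]),
                        numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairs = pairs, support = support),
            class = "genus_pair_table")
}

#' @export
print.genus_pair_table <- function(x, ...) {
  cat("genus_pair_table: ", nrow(x$pairs), " genus pairs, ",
      nrow(x$support), " supporting KO-pair assignments\n", sep = "")
  invisible(x)
}

genus_pair_key <- function(gpt) paste(gpt$pairs$genus_a, gpt$pairs$genus_b,
                                      sep = "|")

#' Per-donor presence of interacting genus pairs
#'
#' A genus pair is present in a donor when at least one supporting KO
#' pair is realized there: KO A detected in genus a and KO B in genus b
#' (or swapped) above `epsilon` in the donor's KO x genus abundance
#' table.
#'
#' @param gpt A `genus_pair_table`.
#' @param donor_tables Named list (one element per donor) of KO x genus
#'   abundance matrices.
#' @param epsilon Detection threshold, default 0.
#' @return Binary matrix donors x genus pairs (dimnames: donor ids and
#'   `"genus_a|genus_b"` keys).
#' @export
donor_presence <- function(gpt, donor_tables, epsilon = 0) {
  keys <- genus_pair_key(gpt)
  sup <- gpt$support
  sup_key <- paste(sup$genus_a, sup$genus_b, sep = "|")
  donors <- names(donor_tables)
  out <- matrix(0L, nrow = length(donors), ncol = length(keys),
                dimnames = list(donors, keys))
  for (d in donors) {
    m <- donor_tables[[d]]
    det <- m > epsilon
    cell <- function(ko, g) {
      if (!(ko %in% rownames(det)) || !(g %in% colnames(det))) return(FALSE)
      det[ko, g]
    }
    hit <- vapply(seq_len(nrow(sup)), function(j) {
      (cell(sup$ko_a[j], sup$genus_a[j]) &&
       cell(sup$ko_b[j], sup$genus_b[j])) ||
      (cell(sup$ko_b[j], sup$genus_a[j]) &&
       cell(sup$ko_a[j], sup$genus_b[j]))
    }, logical(1))
    present <- unique(sup_key[hit])
    out[d, keys %in% present] <- 1L
  }
  out
}

#' Split genus pairs into common and group-specific sets
#'
#' Genus pairs present in at least `common_fraction` of donors are common
#' to almost all individuals and are set aside; the remaining
#' (group-specific) pairs form the matrix used for donor clustering.
#'
#' @param presence Donors x genus-pairs binary matrix from
#'   [donor_presence()].
#' @param common_fraction Presence fraction at or above which a pair is
#'   common; default 0.9.
#' @return List with `common_pairs` (character keys) and
#'   `specific_matrix`.
#' @export
split_common <- function(presence, common_fraction = 0.9) {
  stopifnot(common_fraction > 0, common_fraction <= 1)
  frac <- colMeans(presence)
  common <- colnames(presence)[frac >= common_fraction]
  list(common_pairs = common,
       specific_matrix = presence[, !(colnames(presence) %in% common),
                                  drop = FALSE])
}

#' Hierarchically cluster donors by group-specific genus pairs
#'
#' Agglomerative clustering of the donor rows of the binary
#' presence matrix, by default with Jaccard distance and average linkage,
#' cut into `n_clusters` groups (or at height `h`). Donors are put into a
#' canonical (sorted-id) order before clustering, so the result does not
#' depend on input row order even when tied distances occur.
#'
#' @param specific_matrix Donors x genus-pairs binary matrix.
#' @param n_clusters Number of clusters to cut the tree into.
#' @param h Alternative tree-height cut (used when `n_clusters` is
#'   `NULL`).
#' @param linkage_method Linkage for [stats::hclust()], default
#'   `"average"`.
#' @param distance One of `"jaccard"` (binary distance) or
#'   `"euclidean"`.
#' @return Object of class `donor_clustering`: list with `tree`
#'   ([stats::hclust] object), `clusters` (named integer vector) and
#'   `n_clusters`.
#' @export
cluster_donors <- function(specific_matrix, n_clusters = NULL, h = NULL,
                           linkage_method = "average",
                           distance = c("jaccard", "euclidean")) {
  distance <- match.arg(distance)
  if (!nrow(specific_matrix) || !ncol(specific_matrix)) {
    stop("the presence matrix is empty", call. = FALSE)
  }
  if (is.null(n_clusters) && is.null(h)) {
    stop("give either n_clusters or a height h", call. = FALSE)
  }
  if (!is.null(n_clusters) && n_clusters > nrow(specific_matrix)) {
    stop("n_clusters exceeds the number of donors", call. = FALSE)
  }
  m <- specific_matrix[order(rownames(specific_matrix)), , drop = FALSE]
  d <- if (distance == "jaccard") stats::dist(m, method = "binary")
       else stats::dist(m, method = "euclidean")
  tree <- stats::hclust(d, method = linkage_method)
  clusters <- if (!is.null(n_clusters)) stats::cutree(tree, k = n_clusters)
              else stats::cutree(tree, h = h)
  structure(list(tree = tree, clusters = clusters,
                 n_clusters = length(unique(clusters))),
            class = "donor_clustering")
}

#' @export
print.donor_clustering <- function(x, ...) {
  cat("donor_clustering: ", length(x$clusters), " donors in ",
      x$n_clusters, " clusters\n", sep = "")
  print(table(x$clusters))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two cluster assignments over the same
#' items; 1 for identical partitions (up to label permutation), about 0
#' for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Export per-cluster genus interaction networks
#'
#' For each donor cluster, builds the network of genus pairs present in
#' at least one donor of the cluster. The edge weight is the pair's
#' within-cluster aggregate score: the sum of its supporting KO-pair
#' scores, accumulated over the cluster donors in which the pair is
#' present. Edges below `edge_min_aggregate` are filtered out; a node's
#' weight is the summed weight of its displayed incident edges. Networks
#' can be written as GraphML plus TSV edge lists, together with the
#' donor-to-cluster table and the dendrogram in Newick format.
#'
#' @param clustering A `donor_clustering` from [cluster_donors()].
#' @param gpt The `genus_pair_table`.
#' @param presence The donors x genus-pairs presence matrix the clustering
#'   was derived from.
#' @param edge_min_aggregate Minimum within-cluster aggregate score for an
#'   edge to be displayed; default 15.
#' @param keep_isolated Keep genera with no displayed edge as isolated
#'   nodes.
#' @param dir Output directory; when `NULL`, nothing is written.
#' @return Named list (one element per cluster) of `igraph` graphs with
#'   edge attribute `weight` and vertex attribute `total_score`,
#'   invisibly when `dir` is given.
#' @export
export_cluster_network <- function(clustering, gpt, presence,
                                   edge_min_aggregate = 15,
                                   keep_isolated = FALSE, dir = NULL) {
  keys <- genus_pair_key(gpt)
  nets <- list()
  for (cl in sort(unique(clustering$clusters))) {
    donors <- names(clustering$clusters)[clustering$clusters == cl]
    donors <- intersect(donors, rownames(presence))
    sub <- presence[donors, , drop = FALSE]
    n_present <- colSums(sub)
    idx <- match(colnames(presence), keys)
    weight <- n_present * gpt$pairs$aggregate_score[idx]
    show <- !is.na(weight) & n_present > 0 & weight >= edge_min_aggregate
    edges <- data.frame(
      genus_a = gpt$pairs$genus_a[idx][show],
      genus_b = gpt$pairs$genus_b[idx][show],
      weight = weight[show], stringsAsFactors = FALSE)
    vertices <- unique(c(edges$genus_a, edges$genus_b))
    if (keep_isolated) {
      carried <- !is.na(idx) & n_present > 0
      vertices <- unique(c(vertices, gpt$pairs$genus_a[idx][carried],
                           gpt$pairs$genus_b[idx][carried]))
    }
    g <- igraph::graph_from_data_frame(
      edges[, c("genus_a", "genus_b", "weight")], directed = FALSE,
      vertices = if (length(vertices)) data.frame(name = vertices) else NULL)
    total <- vapply(igraph::V(g)$name, function(v) {
      inc <- igraph::incident(g, v)
      if (length(inc)) sum(igraph::edge_attr(g, "weight", inc)) else 0
    }, numeric(1))
    g <- igraph::set_vertex_attr(g, "total_score", value = total)
    nets[[as.character(cl)]] <- g
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (cl in names(nets)) {
      igraph::write_graph(nets[[cl]],
                          file.path(dir, paste0("cluster_", cl, ".graphml")),
                          format = "graphml")
      el <- igraph::as_data_frame(nets[[cl]], what = "edges")
      utils::write.table(el, file.path(dir,
                                       paste0("cluster_", cl, "_edges.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      data.frame(donor = names(clustering$clusters),
                 cluster = unname(clustering$clusters)),
      file.path(dir, "donor_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(ape::as.phylo(clustering$tree),
                    file.path(dir, "donor_dendrogram.nwk"))
    return(invisible(nets))
  }
  nets
}
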