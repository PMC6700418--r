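#' Build a genome catalog from a long table
#'
#' The catalog lists reference genomes with their genus and KO content and
#' backs the random-genome null model: random combinations of genomes
#' emulate a community assembled without ecological selection.
#'
#' @param long_table Data frame with columns `genome_id`, `genus`, `ko_id`
#'   (one row per genome-KO occurrence).
#' @return Object of class `genome_catalog`: list with `genomes` (data
#'   frame `genome_id`, `genus`), `ko_sets` (named list of KO character
#'   vectors) and `membership` (KO x genome logical matrix).
#' @export
genome_catalog <- function(long_table) {
  stopifnot(all(c("genome_id", "genus", "ko_id") %in% names(long_table)))
  ids <- unique(long_table$genome_id)
  genus <- long_table$genus[match(ids, long_table$genome_id)]
  if (any(!nzchar(genus))) stop("empty genus strings", call. = FALSE)
  ko_sets <- split(long_table$ko_id, factor(long_table$genome_id,
                                            levels = ids))
  ko_sets <- lapply(ko_sets, function(k) sort(unique(k)))
  if (any(lengths(ko_sets) == 0)) {
    stop("every genome needs a non-empty KO set", call. = FALSE)
  }
  kos <- sort(unique(long_table$ko_id))
  membership <- vapply(ko_sets, function(k) kos %in% k,
                       logical(length(kos)))
  rownames(membership) <- kos
  structure(list(genomes = data.frame(genome_id = ids, genus = genus,
                                      stringsAsFactors = FALSE),
                 ko_sets = ko_sets, membership = membership),
            class = "genome_catalog")
}

#' @export
print.genome_catalog <- function(x, ...) {
  cat("genome_catalog: ", nrow(x$genomes), " genomes, ",
      length(unique(x$genomes$genus)), " genera, ",
      nrow(x$membership), " KOs\n", sep = "")
  invisible(x)
}

#' Read a genome catalog TSV
#'
#' @param path TSV with columns `genome_id`, `genus`, `ko_id`.
#' @return A `genome_catalog`.
#' @export
read_genome_catalog <- function(path) {
  genome_catalog(utils::read.delim(path, colClasses = "character"))
}

#' Draw a random genome set
#'
#' Rejection sampling: the genome count is drawn uniformly from
#' `[1, n_genomes]`, that many genomes are drawn without replacement, and
#' the draw is accepted when the size of the union KO set falls within
#' `[ko_min, ko_max]` (the envelope observed in the reference community).
#' A genus may contribute several genomes. Uses R's random number
#' generator; seed with [set.seed()] for reproducibility.
#'
#' @param catalog A `genome_catalog`.
#' @param ko_min,ko_max Accepted range of unique-KO counts.
#' @param genus_whitelist Optional genera to restrict the catalog to.
#' @param max_rejections Attempts before giving up (default 10000).
#' @return Object of class `null_draw`: list with `kind = "genome_set"`,
#'   `genome_ids`, `unique_kos` and `n_attempts`.
#' @export
draw_genome_set <- function(catalog, ko_min, ko_max,
                            genus_whitelist = NULL,
                            max_rejections = 10000) {
  stopifnot(ko_min <= ko_max, ko_min >= 1)
  m <- catalog$membership
  ids <- catalog$genomes$genome_id
  if (!is.null(genus_whitelist)) {
    keep <- catalog$genomes$genus %in% genus_whitelist
    if (!any(keep)) stop("genus whitelist matches no genome", call. = FALSE)
    m <- m[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  g <- length(ids)
  for (attempt in seq_len(max_rejections)) {
    n <- sample.int(g, 1L)
    idx <- sample.int(g, n)
    kos <- rownames(m)[rowSums(m[, idx, drop = FALSE]) > 0]
    if (length(kos) >= ko_min && length(kos) <= ko_max) {
      return(structure(list(kind = "genome_set", genome_ids = ids[idx],
                            unique_kos = sort(kos), n_attempts = attempt),
                       class = "null_draw"))
    }
  }
  stop("no genome set with ", ko_min, "-", ko_max, " unique KOs found in ",
       max_rejections, " attempts; widen the KO bounds or raise ",
       "max_rejections", call. = FALSE)
}

#' Draw a random gene set from a genome set
#'
#' Samples a KO count uniformly from `[ko_min, min(ko_max, n)]`, where `n`
#' is the genome set's unique-KO count, then samples that many KOs without
#' replacement from the genome set's KO universe. This second null
#' destroys the genome-level co-membership of KOs while keeping the KO
#' pool.
#'
#' @param genome_draw An accepted `null_draw` of kind `genome_set`.
#' @param ko_min,ko_max KO-count envelope as in [draw_genome_set()].
#' @return A `null_draw` of kind `"gene_set"`.
#' @export
draw_gene_set <- function(genome_draw, ko_min, ko_max) {
  pool <- genome_draw$unique_kos
  if (length(pool) < ko_min) {
    stop("genome set has fewer unique KOs (", length(pool),
         ") than ko_min (", ko_min, ")", call. = FALSE)
  }
  hi <- min(ko_max, length(pool))
  k <- if (hi == ko_min) ko_min else sample(ko_min:hi, 1L)
  kos <- sample(pool, k)
  structure(list(kind = "gene_set", genome_ids = genome_draw$genome_ids,
                 unique_kos = sort(kos), n_attempts = 1L),
            class = "null_draw")
}

#' @export
print.null_draw <- function(x, ...) {
  cat("null_draw (", x$kind, "): ", length(x$unique_kos), " unique KOs\n",
      sep = "")
  invisible(x)
}

#' Count interacting pairs contained in a KO universe
#'
#' A thresholded interacting pair counts when both of its KOs belong to
#' the universe. The count is normalized by the number of unique KOs so
#' that communities of different gene richness are comparable.
#'
#' @param ko_universe Character vector of KO ids.
#' @param interacting_pairs Data frame with `ko_a`, `ko_b` (typically the
#'   output of [select_interacting()]).
#' @return List with `count` and `normalized`.
#' @export
count_interactions <- function(ko_universe, interacting_pairs) {
  ko_universe <- unique(ko_universe)
  if (!length(ko_universe)) stop("empty KO universe", call. = FALSE)
  hit <- interacting_pairs$ko_a %in% ko_universe &
         interacting_pairs$ko_b %in% ko_universe
  list(count = sum(hit), normalized = sum(hit) / length(ko_universe))
}

#' Per-donor KO universes from a sample-abundance table
#'
#' Each KO is called detected in the donors where its abundance exceeds
#' its own detection limit, taken as the `1 - detect_rate` quantile of the
#' KO's abundance across donors (so every KO has prevalence
#' `detect_rate`). Co-detection structure between KOs is inherited from
#' their abundance correlation.
#'
#' @param ko_by_sample KO x sample abundance matrix.
#' @param detect_rate Per-KO detection prevalence, default 0.9.
#' @return Named list (one element per sample) of KO character vectors.
#' @export
donor_ko_universes <- function(ko_by_sample, detect_rate = 0.9) {
  stopifnot(detect_rate > 0, detect_rate <= 1)
  thr <- apply(ko_by_sample, 1, stats::quantile, probs = 1 - detect_rate,
               names = FALSE)
  detected <- ko_by_sample > thr
  lapply(stats::setNames(seq_len(ncol(detected)), colnames(ko_by_sample)),
         function(j) rownames(detected)[detected[, j]])
}

#' Run the random-genome and random-gene null models
#'
#' Draws `n_draws` accepted genome sets (and one gene set from each) and
#' scores each against a fixed interacting-pair list computed once from
#' the structured community.
#'
#' @param catalog A `genome_catalog`.
#' @param interacting_pairs Thresholded pairs (see [select_interacting()]).
#' @param n_draws Number of accepted draws per null, default 1000.
#' @param ko_min,ko_max KO-count envelope.
#' @inheritParams draw_genome_set
#' @return Data frame with one row per draw: `kind`, `n_kos`, `count`,
#'   `normalized`.
#' @export
simulate_null_counts <- function(catalog, interacting_pairs, n_draws = 1000,
                                 ko_min, ko_max, genus_whitelist = NULL,
                                 max_rejections = 10000) {
  stopifnot(n_draws >= 1)
  rows <- vector("list", 2L * n_draws)
  for (i in seq_len(n_draws)) {
    gs <- draw_genome_set(catalog, ko_min, ko_max,
                          genus_whitelist = genus_whitelist,
                          max_rejections = max_rejections)
    cs <- count_interactions(gs$unique_kos, interacting_pairs)
    rows[[2L * i - 1L]] <- data.frame(kind = "genome_set",
                                      n_kos = length(gs$unique_kos),
                                      count = cs$count,
                                      normalized = cs$normalized)
    es <- draw_gene_set(gs, ko_min, ko_max)
    ce <- count_interactions(es$unique_kos, interacting_pairs)
    rows[[2L * i]] <- data.frame(kind = "gene_set",
                                 n_kos = length(es$unique_kos),
                                 count = ce$count,
                                 normalized = ce$normalized)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare structured, random-genome and random-gene groups
#'
#' One-way ANOVA across the three normalized interaction-count samples,
#' plus one-sided pairwise Mann--Whitney tests in the expected direction
#' (structured > genome null, structured > gene null,
#' genome null > gene null).
#'
#' @param real,genome_null,gene_null Numeric vectors of normalized
#'   interaction counts (each of length at least 2).
#' @return Object of class `three_group_comparison`: list with
#'   `anova` (`F`, `p_value`), `pairwise` (data frame `comparison`,
#'   `statistic`, `p_value`) and `means`.
#' @export
compare_three_groups <- function(real, genome_null, gene_null) {
  groups <- list(structured = real, genome_null = genome_null,
                 gene_null = gene_null)
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  pw <- function(a, b, lab) {
    w <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater"))
    data.frame(comparison = lab, statistic = unname(w$statistic),
               p_value = w$p.value, stringsAsFactors = FALSE)
  }
  pairwise <- rbind(
    pw(real, genome_null, "structured > genome_null"),
    pw(real, gene_null, "structured > gene_null"),
    pw(genome_null, gene_null, "genome_null > gene_null"))
  structure(list(anova = list(F = an[["F value"]][1],
                              p_value = an[["Pr(>F)"]][1]),
                 pairwise = pairwise,
                 means = vapply(groups, mean, numeric(1))),
            class = "three_group_comparison")
}

#' @export
print.three_group_comparison <- function(x, ...) {
  cat("three-group comparison of normalized interaction counts\n")
  cat("  means: ", paste(names(x$means), format(x$means, digits = 4),
                         sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  ANOVA: F = ", format(x$anova$F, digits = 4), ", p = ",
      format(x$anova$p_value, digits = 4), "\n", sep = "")
  for (i in seq_len(nrow(x$pairwise))) {
    cat("  ", x$pairwise$comparison[i], ": p = ",
        format(x$pairwise$p_value[i], digits = 4), "\n", sep = "")
  }
  invisible(x)
}
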