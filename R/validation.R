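#' Compare score distributions of boundary vs metabolic pairs
#'
#' Tests whether metabolic--non-metabolic (boundary) pairs have
#' stochastically higher interaction scores than metabolic--metabolic
#' pairs, with a one-sided two-sample Kolmogorov--Smirnov test. High
#' boundary scores support the interpretation of the score as marking
#' interfaces with extracellular metabolism.
#'
#' @param scored A `scored_pairs` data frame with `pair_class` filled in
#'   (see [classify_boundary()]).
#' @param exact Passed to [stats::ks.test()]; `NULL` (default) uses the
#'   asymptotic approximation for large samples and the exact computation
#'   for small ones.
#' @return Object of class `distribution_comparison`: list with
#'   `test`, `statistic`, `p_value`, `sidedness`, `n_boundary`,
#'   `n_metabolic` and the two score vectors.
#' @export
compare_boundary_scores <- function(scored, exact = NULL) {
  ok <- scored$defined
  boundary <- scored$score[ok & scored$pair_class == "metabolic_nonmetabolic"]
  metabolic <- scored$score[ok & scored$pair_class == "metabolic_metabolic"]
  if (!length(boundary)) {
    stop("no defined pairs in class metabolic_nonmetabolic", call. = FALSE)
  }
  if (!length(metabolic)) {
    stop("no defined pairs in class metabolic_metabolic", call. = FALSE)
  }
  # alternative = "less": the CDF of x (boundary) lies below that of y,
  # i.e. boundary scores are stochastically greater.
  ks <- suppressWarnings(stats::ks.test(boundary, metabolic,
                                        alternative = "less", exact = exact))
  structure(list(test = "Kolmogorov-Smirnov (one-sided)",
                 statistic = unname(ks$statistic),
                 p_value = ks$p.value,
                 sidedness = "boundary stochastically greater",
                 n_boundary = length(boundary),
                 n_metabolic = length(metabolic),
                 group_a_scores = boundary,
                 group_b_scores = metabolic),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(x$test, "\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), "\n  ", x$sidedness, "\n", sep = "")
  invisible(x)
}

#' Module edge/non-edge linkage by score window
#'
#' Bins the defined scored pairs into score windows of width
#' `window_width` over `range` (half-open `[lo, hi)`, last window closed)
#' and counts, per window, the pairs whose intermediate compounds are
#' module termini ("edge") versus internal module compounds ("non_edge").
#' Pairs matching no module compound are excluded. High-score windows
#' dominated by edge compounds indicate that strongly scoring pairs link
#' modules to one another.
#'
#' @param scored A `scored_pairs` data frame.
#' @param modules Module definitions (see [read_module_definitions()]).
#' @param window_width Window width, default 0.1.
#' @param range Score range covered, default `c(-1, 1)`.
#' @return Object of class `windowed_linkage`: list with `windows` (data
#'   frame `score_lo`, `score_hi`, `n_edge`, `n_non_edge`,
#'   `edge_fraction`) and `pairs` (per-pair score, linkage and window
#'   index for the pairs with module compounds).
#' @export
module_linkage_by_window <- function(scored, modules, window_width = 0.1,
                                     range = c(-1, 1)) {
  stopifnot(window_width > 0, length(range) == 2, range[1] < range[2])
  breaks <- seq(range[1], range[2], by = window_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  ok <- scored$defined
  sub <- scored[ok, , drop = FALSE]
  linkage <- module_linkage(sub, modules)
  keep <- linkage %in% c("edge", "non_edge")
  sub <- sub[keep, , drop = FALSE]
  linkage <- linkage[keep]
  win <- findInterval(sub$score, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nw <- length(breaks) - 1L
  n_edge <- tabulate(win[linkage == "edge"], nbins = nw)
  n_non <- tabulate(win[linkage == "non_edge"], nbins = nw)
  total <- n_edge + n_non
  windows <- data.frame(score_lo = breaks[-length(breaks)],
                        score_hi = breaks[-1],
                        n_edge = n_edge, n_non_edge = n_non,
                        edge_fraction = ifelse(total > 0, n_edge / total,
                                               NA_real_))
  structure(list(windows = windows,
                 pairs = data.frame(ko_a = sub$ko_a, ko_b = sub$ko_b,
                                    score = sub$score, linkage = linkage,
                                    window = win,
                                    stringsAsFactors = FALSE)),
            class = "windowed_linkage")
}

#' @export
print.windowed_linkage <- function(x, ...) {
  cat("windowed_linkage over ", nrow(x$windows), " windows, ",
      nrow(x$pairs), " pairs with module compounds\n", sep = "")
  print(x$windows[x$windows$n_edge + x$windows$n_non_edge > 0, ])
  invisible(x)
}

#' Rank-sum test of edge- vs non-edge-linked pair scores
#'
#' One-sided Mann--Whitney (Wilcoxon rank-sum) test of whether pairs
#' sharing module-terminus ("edge") compounds score higher than pairs
#' sharing only internal ("non_edge") module compounds. With
#' `mode = "fractions"` the test instead compares the per-window edge
#' fractions of windows at or above `tau` against those below.
#'
#' @param linkage A `windowed_linkage` from [module_linkage_by_window()].
#' @param tau Score threshold splitting windows in `mode = "fractions"`;
#'   unused for `mode = "scores"`.
#' @param mode `"scores"` (default) or `"fractions"`.
#' @return A `distribution_comparison`.
#' @export
edge_vs_nonedge_test <- function(linkage, tau = 0.6,
                                 mode = c("scores", "fractions")) {
  mode <- match.arg(mode)
  if (mode == "scores") {
    x <- linkage$pairs$score[linkage$pairs$linkage == "edge"]
    y <- linkage$pairs$score[linkage$pairs$linkage == "non_edge"]
    lab <- c("edge pairs", "non-edge pairs")
  } else {
    w <- linkage$windows
    w <- w[!is.na(w$edge_fraction), , drop = FALSE]
    x <- w$edge_fraction[w$score_lo >= tau]
    y <- w$edge_fraction[w$score_lo < tau]
    lab <- c("windows at/above tau", "windows below tau")
  }
  if (length(x) < 2) stop("fewer than 2 members in class: ", lab[1],
                          call. = FALSE)
  if (length(y) < 2) stop("fewer than 2 members in class: ", lab[2],
                          call. = FALSE)
  mw <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater"))
  structure(list(test = "Mann-Whitney (one-sided)",
                 statistic = unname(mw$statistic),
                 p_value = mw$p.value,
                 sidedness = paste(lab[1], "greater"),
                 n_boundary = length(x), n_metabolic = length(y),
                 group_a_scores = x, group_b_scores = y),
            class = "distribution_comparison")
}
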