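#' Join KO-pair scores across two cohorts
#'
#' Intersects two scored pair lists (e.g. healthy and disease cohorts,
#' scored on the same candidate-pair universe with cohort-specific sample
#' sets) on the pair key, keeping only pairs defined in both, and records
#' the score difference `delta = score_healthy - score_disease`.
#'
#' @param scored_h,scored_d `scored_pairs` data frames for the two
#'   cohorts.
#' @return Object of class `cohort_score_table`: data frame with `ko_a`,
#'   `ko_b`, `score_healthy`, `score_disease`, `delta`, plus `compounds`
#'   and `pair_class` carried over from the first cohort.
#' @export
shared_pairs <- function(scored_h, scored_d) {
  h <- scored_h[scored_h$defined, , drop = FALSE]
  d <- scored_d[scored_d$defined, , drop = FALSE]
  kh <- paste(h$ko_a, h$ko_b)
  kd <- paste(d$ko_a, d$ko_b)
  common <- intersect(kh, kd)
  if (!length(common)) {
    stop("no KO pair is shared between the two cohorts", call. = FALSE)
  }
  ih <- match(common, kh)
  id <- match(common, kd)
  out <- data.frame(ko_a = h$ko_a[ih], ko_b = h$ko_b[ih],
                    score_healthy = h$score[ih],
                    score_disease = d$score[id],
                    stringsAsFactors = FALSE)
  out$delta <- out$score_healthy - out$score_disease
  out$compounds <- if (!is.null(h$compounds)) h$compounds[ih]
                   else rep(list(character(0)), length(common))
  out$pair_class <- if (!is.null(h$pair_class)) h$pair_class[ih]
                    else rep("unclassified", length(common))
  out <- out[order(out$ko_a, out$ko_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_score_table", "data.frame")
  out
}

#' Extract cohort-specific KO pairs by the two-standard-deviation rule
#'
#' With `mu` and `sigma` the mean and sample standard deviation of the
#' score differences over all shared pairs, a pair is healthy-specific
#' when `delta > mu + k_sd * sigma` and its healthy score exceeds `tau`,
#' and disease-specific when `delta < mu - k_sd * sigma` and its disease
#' score exceeds `tau`. The threshold `tau` applies to the score in the
#' pair's favored cohort; `require_other_below` additionally demands the
#' other cohort's score be at most `tau`.
#'
#' @param table A `cohort_score_table` from [shared_pairs()] with at
#'   least 3 rows.
#' @param tau Score threshold, default 0.6 (strict `>`).
#' @param k_sd Number of standard deviations, default 2.
#' @param require_other_below Also require the non-favored cohort score
#'   `<= tau`; default `FALSE`.
#' @return List with `healthy_specific` and `disease_specific` (subsets
#'   of `table`), and the `mu` and `sigma` used.
#' @export
specific_pairs <- function(table, tau = 0.6, k_sd = 2.0,
                           require_other_below = FALSE) {
  if (nrow(table) < 3) {
    stop("need at least 3 shared pairs to estimate the spread",
         call. = FALSE)
  }
  mu <- mean(table$delta)
  sigma <- stats::sd(table$delta)
  if (sigma == 0) {
    stop("degenerate cohorts: all score differences are identical",
         call. = FALSE)
  }
  hs <- table$delta > mu + k_sd * sigma & table$score_healthy > tau
  ds <- table$delta < mu - k_sd * sigma & table$score_disease > tau
  if (require_other_below) {
    hs <- hs & table$score_disease <= tau
    ds <- ds & table$score_healthy <= tau
  }
  list(healthy_specific = table[hs, , drop = FALSE],
       disease_specific = table[ds, , drop = FALSE],
       mu = mu, sigma = sigma)
}

#' Write a cohort score table as TSV
#'
#' Columns: pair key, compounds (semicolon-joined), score_h, score_d,
#' delta, class.
#'
#' @param table A `cohort_score_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  df <- data.frame(
    pair = paste(table$ko_a, table$ko_b, sep = "-"),
    compounds = vapply(table$compounds, paste, character(1),
                       collapse = ";"),
    score_h = table$score_healthy, score_d = table$score_disease,
    delta = table$delta, class = table$pair_class,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
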