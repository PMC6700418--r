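#' Pearson correlation with explicit undefined handling
#'
#' Product-moment correlation of two equal-length vectors, returning `NA`
#' (undefined) when either vector has zero variance instead of warning.
#' On binary vectors this is the phi coefficient.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Phylogenetic-profile dissimilarity
#'
#' The inverse-correlation signal of the method: two KOs whose genus
#' presence patterns anti-correlate are candidates for an interspecific
#' hand-off. With `r` the phi coefficient of the two binary profiles, the
#' default map `half_one_minus_r` gives `D = (1 - r) / 2`, which is 0 for
#' identical profiles, 1 for perfectly complementary ones, and keeps the
#' product score within `[-1, 1]`. Alternatives: `one_minus_r`
#' (`D = 1 - r`, range `[0, 2]`) and `neg_r` (`D = -r`).
#'
#' @param pa,pb Binary (0/1) vectors over the same genus ordering.
#' @param mode Dissimilarity map; see Details above.
#' @return Dissimilarity, or `NA_real_` when either profile is constant.
#' @export
phylo_dissimilarity <- function(pa, pb,
                                mode = c("half_one_minus_r", "one_minus_r",
                                         "neg_r")) {
  mode <- match.arg(mode)
  if (!all(pa %in% c(0, 1)) || !all(pb %in% c(0, 1))) {
    stop("phylogenetic profiles must be binary (0/1)", call. = FALSE)
  }
  r <- pearson(pa, pb)
  if (is.na(r)) return(NA_real_)
  switch(mode,
         half_one_minus_r = (1 - r) / 2,
         one_minus_r = 1 - r,
         neg_r = -r)
}

#' Score candidate KO pairs for interspecific interaction
#'
#' For each pathway-adjacent pair the interaction score is the product
#' `S = D * R` of the phylogenetic-profile dissimilarity `D` and the
#' co-occurrence correlation `R` of the two KOs' sample-abundance
#' profiles. Pairs whose KOs are missing from the profiles are skipped
#' (with a message); pairs with a constant profile on either side are
#' retained with `defined = FALSE` and no score.
#'
#' @param pairs An `adjacent_pairs` data frame (see [enumerate_pairs()]).
#' @param profiles A `profile_set` from [build_profiles()].
#' @param mode Dissimilarity map, see [phylo_dissimilarity()].
#' @param cooccurrence One of `"pearson"` (default) or `"spearman"` for
#'   the sample-abundance correlation.
#' @param samples Optional character vector restricting the co-occurrence
#'   profile to a sample subset (e.g. one cohort).
#' @return Data frame of class `scored_pairs`: `ko_a`, `ko_b`,
#'   `dissimilarity`, `cooccurrence`, `score`, list column `compounds`,
#'   `pair_class`, `defined`.
#' @export
score_pairs <- function(pairs, profiles,
                        mode = c("half_one_minus_r", "one_minus_r", "neg_r"),
                        cooccurrence = c("pearson", "spearman"),
                        samples = NULL) {
  mode <- match.arg(mode)
  cooccurrence <- match.arg(cooccurrence)
  gp <- profiles$genus_presence
  sa <- profiles$sample_abundance
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(sa))
    if (length(missing)) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sa <- sa[, samples, drop = FALSE]
  }
  ia <- match(pairs$ko_a, profiles$kos)
  ib <- match(pairs$ko_b, profiles$kos)
  keep <- !is.na(ia) & !is.na(ib)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) skipped: KO absent from profiles")
  }
  pairs <- pairs[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  n <- nrow(pairs)
  D <- R <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- phylo_dissimilarity(gp[ia[i], ], gp[ib[i], ], mode = mode)
    xa <- sa[ia[i], ]; xb <- sa[ib[i], ]
    if (cooccurrence == "spearman") {
      xa <- rank(xa); xb <- rank(xb)
    }
    R[i] <- pearson(xa, xb)
  }
  defined <- !is.na(D) & !is.na(R)
  out <- data.frame(ko_a = pairs$ko_a, ko_b = pairs$ko_b,
                    dissimilarity = D, cooccurrence = R,
                    score = D * R, stringsAsFactors = FALSE)
  out$compounds <- if (!is.null(pairs$compounds)) pairs$compounds
                   else rep(list(character(0)), n)
  out$pair_class <- if (!is.null(pairs$pair_class)) pairs$pair_class
                    else rep("unclassified", n)
  out$defined <- defined
  rownames(out) <- NULL
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Select interacting pairs above the score threshold
#'
#' KO pairs with a score of `tau` (default 0.6) or higher are taken as
#' gene pairs likely to interact interspecifically. The comparison is
#' inclusive by default; `strict = TRUE` uses a strict inequality.
#' Undefined pairs are never selected. The result is sorted by descending
#' score with ties broken lexicographically on (`ko_a`, `ko_b`).
#'
#' @param scored A `scored_pairs` data frame.
#' @param tau Score threshold, default 0.6.
#' @param strict Use `score > tau` instead of `score >= tau`.
#' @return The selected subset, sorted.
#' @export
select_interacting <- function(scored, tau = 0.6, strict = FALSE) {
  keep <- scored$defined &
    (if (strict) scored$score > tau else scored$score >= tau)
  keep[is.na(keep)] <- FALSE
  out <- scored[keep, , drop = FALSE]
  out <- out[order(-out$score, out$ko_a, out$ko_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scored pairs as TSV
#'
#' Columns: ko_a, ko_b, dissimilarity, cooccurrence, score, compounds
#' (semicolon-joined), pair_class, defined.
#'
#' @param scored A `scored_pairs` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scored_pairs <- function(scored, path) {
  df <- data.frame(
    ko_a = scored$ko_a, ko_b = scored$ko_b,
    dissimilarity = scored$dissimilarity,
    cooccurrence = scored$cooccurrence,
    score = scored$score,
    compounds = vapply(scored$compounds, paste, character(1),
                       collapse = ";"),
    pair_class = scored$pair_class,
    defined = scored$defined,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
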