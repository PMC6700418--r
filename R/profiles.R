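#' Genus-level KO abundance from a long gene table
#'
#' Collapses a gene-level annotation table to a KO-by-genus abundance
#' matrix. The cell for (KO, genus) is the mean relative abundance over
#' the genes annotated to that KO in that genus; combinations without any
#' gene are 0.
#'
#' @param long_table Data frame with columns `ko_id`, `genus`, `abundance`
#'   (a `gene_id` column may be present and is ignored).
#' @return Numeric matrix, rows = KO ids (sorted), columns = genera
#'   (sorted).
#' @export
genus_level_abundance <- function(long_table) {
  stopifnot(all(c("ko_id", "genus", "abundance") %in% names(long_table)))
  ab <- as.numeric(long_table$abundance)
  if (anyNA(ab)) stop("non-numeric abundance values", call. = FALSE)
  if (any(ab < 0)) stop("negative abundance values are not allowed",
                        call. = FALSE)
  kos <- sort(unique(long_table$ko_id))
  genera <- sort(unique(long_table$genus))
  means <- tapply(ab, list(factor(long_table$ko_id, levels = kos),
                           factor(long_table$genus, levels = genera)),
                  mean)
  means[is.na(means)] <- 0
  m <- matrix(as.numeric(means), nrow = length(kos),
              dimnames = list(kos, genera))
  m
}

#' Read a wide KO abundance table
#'
#' First column = KO id, remaining columns = samples (or genera). Reads
#' gzip-compressed files transparently.
#'
#' @param path TSV file path.
#' @return Numeric matrix with KO rownames.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a long gene annotation table
#'
#' Columns `gene_id`, `ko_id`, `genus`, `abundance` (TSV, gzip
#' transparent).
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_gene_long <- function(path) {
  utils::read.delim(path, colClasses = c(gene_id = "character",
                                         ko_id = "character",
                                         genus = "character",
                                         abundance = "numeric"))
}

#' Build phylogenetic and co-occurrence profiles
#'
#' The phylogenetic profile of a KO is the binary vector of genera that
#' carry it (genus-level abundance above `presence_epsilon`); the
#' co-occurrence profile is its abundance across samples. The KO universe
#' is the intersection of the two tables' KO sets, since the interaction
#' score needs both profiles for each KO. Genera absent from every KO are
#' dropped. KOs whose presence vector is constant are retained but
#' flagged: their phylogenetic correlation is undefined downstream.
#'
#' @param ko_by_genus KO x genus abundance matrix
#'   (e.g. from [genus_level_abundance()]).
#' @param ko_by_sample KO x sample abundance matrix.
#' @param presence_epsilon Abundance strictly above this counts as
#'   presence. Default 0.
#' @return Object of class `profile_set`: list with `kos`,
#'   `genus_presence` (binary matrix), `sample_abundance`, `genera`,
#'   `samples`, and logical flags `constant_presence`,
#'   `constant_abundance` per KO.
#' @export
build_profiles <- function(ko_by_genus, ko_by_sample, presence_epsilon = 0) {
  stopifnot(presence_epsilon >= 0)
  if (any(ko_by_genus < 0) || any(ko_by_sample < 0)) {
    stop("abundance tables must be non-negative", call. = FALSE)
  }
  keep_genus <- colSums(ko_by_genus) > 0
  ko_by_genus <- ko_by_genus[, keep_genus, drop = FALSE]
  kos <- intersect(rownames(ko_by_genus), rownames(ko_by_sample))
  if (!length(kos)) {
    stop("no KO is shared between the genus and sample tables",
         call. = FALSE)
  }
  kos <- sort(kos)
  presence <- (ko_by_genus[kos, , drop = FALSE] > presence_epsilon) * 1L
  abundance <- ko_by_sample[kos, , drop = FALSE]
  const_p <- apply(presence, 1, function(r) length(unique(r)) == 1L)
  const_a <- apply(abundance, 1, function(r) stats::var(r) == 0)
  structure(list(kos = kos,
                 genus_presence = presence,
                 sample_abundance = abundance,
                 genera = colnames(presence),
                 samples = colnames(abundance),
                 constant_presence = const_p,
                 constant_abundance = const_a),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set: ", length(x$kos), " KOs x ", length(x$genera),
      " genera (presence) x ", length(x$samples), " samples (abundance); ",
      sum(x$constant_presence), " constant presence profiles\n", sep = "")
  invisible(x)
}
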