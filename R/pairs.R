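#' Enumerate adjacent KO pairs of a pathway graph
#'
#' Every edge of the reconstructed network is a candidate pair for
#' interaction scoring. The scored universe of the method is the set of
#' pairs that are linked through at least one intermediate compound;
#' `with_compounds = TRUE` restricts to those.
#'
#' @param graph A `pathway_graph` from [build_graph()].
#' @param with_compounds Keep only pairs with a non-empty compound set.
#' @return A data frame of class `adjacent_pairs` with columns `ko_a`,
#'   `ko_b` (lexicographically ordered within each row), list columns
#'   `compounds` and `maps`, and `pair_class` (initially `"unclassified"`).
#' @export
enumerate_pairs <- function(graph, with_compounds = FALSE) {
  pairs <- graph$edges
  if (with_compounds) {
    pairs <- pairs[lengths(pairs$compounds) > 0, , drop = FALSE]
  }
  pairs$pair_class <- rep("unclassified", nrow(pairs))
  rownames(pairs) <- NULL
  class(pairs) <- c("adjacent_pairs", "data.frame")
  pairs
}

#' Derive producer/uptake transporter relations from a pathway graph
#'
#' A transporter (uptake) KO is one that occurs only on the designated
#' non-metabolic maps (ABC transporters, two-component system,
#' phosphotransferase system by default). Each graph edge joining such a
#' KO to a KO of a metabolic map through a compound yields one
#' (uptake KO, compound, producer KO) relation: the producer makes the
#' compound that the transporter takes up, i.e. a candidate interface
#' between intracellular and extracellular metabolism.
#'
#' @param graph A `pathway_graph`.
#' @return Data frame with columns `uptake_ko`, `compound`, `producer_ko`.
#' @export
derive_transporter_relations <- function(graph) {
  cat_of <- graph$map_category
  met_maps <- names(cat_of)[cat_of == "metabolic"]
  nonmet_maps <- names(cat_of)[cat_of == "non_metabolic"]
  on_met <- unique(graph$ko_maps$ko[graph$ko_maps$map_id %in% met_maps])
  on_nonmet <- unique(graph$ko_maps$ko[graph$ko_maps$map_id %in% nonmet_maps])
  transporters <- setdiff(on_nonmet, on_met)
  out <- list()
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    if (!length(e$compounds[[i]])) next
    a <- e$ko_a[i]; b <- e$ko_b[i]
    if (a %in% transporters && b %in% on_met) {
      out[[length(out) + 1L]] <- data.frame(
        uptake_ko = a, compound = e$compounds[[i]], producer_ko = b,
        stringsAsFactors = FALSE)
    } else if (b %in% transporters && a %in% on_met) {
      out[[length(out) + 1L]] <- data.frame(
        uptake_ko = b, compound = e$compounds[[i]], producer_ko = a,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(uptake_ko = character(0), compound = character(0),
                      producer_ko = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify adjacent pairs as metabolic or boundary pairs
#'
#' A pair is `metabolic_nonmetabolic` (a boundary pair) when one side is an
#' uptake KO found only on non-metabolic maps, the other side is a
#' metabolic producer of one of the pair's compounds, and the two are
#' linked by that shared compound. A pair whose endpoints both occur on
#' metabolic maps (and neither is a non-metabolic-only KO) is
#' `metabolic_metabolic`; everything else stays `unclassified`. The three
#' classes partition the pair list.
#'
#' @param pairs An `adjacent_pairs` data frame from [enumerate_pairs()].
#' @param graph The `pathway_graph` the pairs came from.
#' @param transporter_relations Optional data frame as returned by
#'   [derive_transporter_relations()]; derived from `graph` when `NULL`.
#' @return `pairs` with `pair_class` filled in.
#' @export
classify_boundary <- function(pairs, graph, transporter_relations = NULL) {
  if (is.null(transporter_relations)) {
    transporter_relations <- derive_transporter_relations(graph)
  }
  cat_of <- graph$map_category
  met_maps <- names(cat_of)[cat_of == "metabolic"]
  nonmet_maps <- names(cat_of)[cat_of == "non_metabolic"]
  on_met <- unique(graph$ko_maps$ko[graph$ko_maps$map_id %in% met_maps])
  on_nonmet <- unique(graph$ko_maps$ko[graph$ko_maps$map_id %in% nonmet_maps])
  nonmet_only <- setdiff(on_nonmet, on_met)

  tr_key <- character(0)
  if (nrow(transporter_relations)) {
    tr_key <- paste(
      pmin(transporter_relations$uptake_ko, transporter_relations$producer_ko),
      pmax(transporter_relations$uptake_ko, transporter_relations$producer_ko),
      transporter_relations$compound)
  }
  cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$ko_a[i]; b <- pairs$ko_b[i]
    cpds <- pairs$compounds[[i]]
    boundary <- length(cpds) > 0 &&
      xor(a %in% nonmet_only, b %in% nonmet_only) &&
      any(paste(a, b, cpds) %in% tr_key)
    if (boundary) {
      cls[i] <- "metabolic_nonmetabolic"
    } else if (a %in% on_met && b %in% on_met &&
               !(a %in% nonmet_only) && !(b %in% nonmet_only)) {
      cls[i] <- "metabolic_metabolic"
    } else {
      cls[i] <- "unclassified"
    }
  }
  pairs$pair_class <- cls
  pairs
}

#' Read pathway-module definitions
#'
#' A pathway module links initial substrates to final products; its
#' terminal compounds ("edge": initial substrates and final products) and
#' intermediate compounds ("internal", the non-edges) are the reference
#' used to validate interaction scores. The TSV has columns `module_id`,
#' `compound_id` and `role` (`edge` or `internal`).
#'
#' @param path TSV file path.
#' @return Data frame with the three columns, validated so that no module
#'   lists the same compound as both edge and internal.
#' @export
read_module_definitions <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  validate_modules(df)
}

validate_modules <- function(df) {
  stopifnot(all(c("module_id", "compound_id", "role") %in% names(df)))
  if (!all(df$role %in% c("edge", "internal"))) {
    stop("module roles must be 'edge' or 'internal'", call. = FALSE)
  }
  for (m in unique(df$module_id)) {
    sub <- df[df$module_id == m, ]
    both <- intersect(sub$compound_id[sub$role == "edge"],
                      sub$compound_id[sub$role == "internal"])
    if (length(both)) {
      stop("module ", m, " lists compound(s) as both edge and internal: ",
           paste(both, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Look up whether a pair's compounds are module termini
#'
#' Returns `"edge"` when any of the pair's intermediate compounds is a
#' terminal (initial substrate / final product) compound of any module,
#' otherwise `"non_edge"` when any is an internal module compound,
#' otherwise `"absent"`. A compound that is a terminus in one module and
#' internal in another resolves to `"edge"`: a compound that ends any
#' module can link modules to one another.
#'
#' @param compounds Character vector of compound ids for one pair.
#' @param modules Module definition data frame (see
#'   [read_module_definitions()]).
#' @return One of `"edge"`, `"non_edge"`, `"absent"`.
#' @export
module_edge_lookup <- function(compounds, modules) {
  if (!length(compounds)) return("absent")
  edge_cpds <- modules$compound_id[modules$role == "edge"]
  internal_cpds <- modules$compound_id[modules$role == "internal"]
  if (any(compounds %in% edge_cpds)) return("edge")
  if (any(compounds %in% internal_cpds)) return("non_edge")
  "absent"
}

#' Vectorized module linkage over a pair table
#'
#' @param pairs A data frame with a `compounds` list column (adjacent or
#'   scored pairs).
#' @param modules Module definition data frame.
#' @return Character vector, one of edge/non_edge/absent per pair.
#' @export
module_linkage <- function(pairs, modules) {
  vapply(pairs$compounds, module_edge_lookup, character(1),
         modules = modules)
}
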