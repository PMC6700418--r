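#' Parse a KGML pathway map
#'
#' Reads one KGML (KEGG Markup Language) pathway file and extracts the
#' ortholog/compound/map entries together with the `ECrel` (enzyme-enzyme)
#' and `maplink` relations that the pathway-network reconstruction uses.
#' Gene-type entries are ignored: the method works at the KO (KEGG
#' Orthology) level, where isofunctional genes are already collapsed.
#'
#' @param x A file path, a literal XML string, or an `xml2::xml_document`.
#' @return An object of class `kgml_document`: a list with
#'   * `map_id`: 5-digit pathway map identifier,
#'   * `entries`: data frame with `entry_id`, `type`, `kos` (list column of
#'     KO identifiers `Kddddd`), `compound` (compound id `Cddddd` for
#'     compound entries, `NA` otherwise),
#'   * `relations`: data frame with `entry1`, `entry2`,
#'     `type` (`ecrel`, `maplink` or `other`) and `compound_entry` (the
#'     entry id named by a `subtype name="compound"` child, or `NA`).
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:ko00900" number="00900">',
#'   '<entry id="1" name="ko:K00001" type="ortholog"/>',
#'   '<entry id="2" name="cpd:C00022" type="compound"/>',
#'   '<entry id="3" name="ko:K00002" type="ortholog"/>',
#'   '<relation entry1="1" entry2="3" type="ECrel">',
#'   '<subtype name="compound" value="2"/></relation></pathway>')
#' doc <- parse_kgml(kgml)
#' doc$relations
#' @export
parse_kgml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  if (xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document: root element is <", xml2::xml_name(doc),
         ">, expected <pathway>", call. = FALSE)
  }
  number <- xml2::xml_attr(doc, "number")
  if (!is.na(number) && grepl("^[0-9]+$", number)) {
    map_id <- sprintf("%05d", as.integer(number))
  } else {
    nm <- xml2::xml_attr(doc, "name")
    hit <- regmatches(nm, regexpr("[0-9]{5}", nm))
    if (is.na(nm) || length(hit) == 0) {
      stop("cannot determine the pathway map id from the <pathway> element",
           call. = FALSE)
    }
    map_id <- hit
  }

  entry_nodes <- xml2::xml_find_all(doc, "./entry")
  entry_id <- xml2::xml_attr(entry_nodes, "id")
  entry_type <- xml2::xml_attr(entry_nodes, "type")
  entry_name <- xml2::xml_attr(entry_nodes, "name")
  keep <- entry_type %in% c("ortholog", "compound", "map")
  entry_id <- entry_id[keep]
  entry_type <- entry_type[keep]
  entry_name <- entry_name[keep]
  kos <- lapply(seq_along(entry_id), function(i) {
    if (entry_type[i] != "ortholog") return(character(0))
    unique(regmatches(entry_name[i], gregexpr("K[0-9]{5}", entry_name[i]))[[1]])
  })
  compound <- vapply(seq_along(entry_id), function(i) {
    if (entry_type[i] != "compound") return(NA_character_)
    hit <- regmatches(entry_name[i], regexpr("C[0-9]{5}", entry_name[i]))
    if (length(hit)) hit else NA_character_
  }, character(1))
  entries <- data.frame(entry_id = entry_id, type = entry_type,
                        stringsAsFactors = FALSE)
  entries$kos <- kos
  entries$compound <- compound

  rel_nodes <- xml2::xml_find_all(doc, "./relation")
  rel_type_raw <- tolower(xml2::xml_attr(rel_nodes, "type"))
  relations <- data.frame(
    entry1 = xml2::xml_attr(rel_nodes, "entry1"),
    entry2 = xml2::xml_attr(rel_nodes, "entry2"),
    type = ifelse(rel_type_raw == "ecrel", "ecrel",
                  ifelse(rel_type_raw == "maplink", "maplink", "other")),
    compound_entry = vapply(rel_nodes, function(r) {
      sub <- xml2::xml_find_first(r, "./subtype[@name='compound']")
      if (inherits(sub, "xml_missing")) NA_character_ else
        xml2::xml_attr(sub, "value")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(c(relations$entry1, relations$entry2), entries$entry_id)
  if (length(bad)) {
    stop("KGML map ", map_id, ": relations reference unknown entry id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(map_id = map_id, entries = entries, relations = relations),
            class = "kgml_document")
}

#' @export
print.kgml_document <- function(x, ...) {
  cat("KGML map ", x$map_id, ": ", nrow(x$entries), " entries, ",
      nrow(x$relations), " relations\n", sep = "")
  invisible(x)
}

default_nonmetabolic_maps <- function() c("02010", "02020", "02060")

is_overview_map <- function(map_id) grepl("^01[12]", map_id)

#' Reconstruct the merged pathway network from KGML documents
#'
#' Merges a set of parsed KGML maps into one undirected KO graph. `ecrel`
#' and `maplink` relations become edges between every KO of one entry and
#' every KO of the other (KGML boxes group isofunctional KOs; they are
#' expanded combinatorially, self-pairs dropped). An edge is labelled with
#' the compound of the relation's compound entry when one is present, and
#' edge records are collapsed across maps with their compound and map sets
#' merged. Overview ("global") maps are excluded from the reconstruction.
#'
#' @param documents A `kgml_document` or list of them.
#' @param overview_maps Map ids to drop. `NULL` (default) drops ids matching
#'   the KEGG global/overview numbering `011xx`/`012xx`.
#' @param nonmetabolic_maps Map ids treated as non-metabolic (transporter /
#'   signalling) maps when classifying boundary pairs. Defaults to the ABC
#'   transporter (00210-style id "02010"), two-component system ("02020")
#'   and phosphotransferase system ("02060") maps.
#' @return An object of class `pathway_graph`: list with `nodes` (KO ids),
#'   `edges` (data frame `ko_a`, `ko_b`, list columns `compounds`, `maps`),
#'   `ko_maps` (KO-to-map occurrence table) and `map_category` (named
#'   vector: `metabolic`, `non_metabolic` or `overview`).
#' @seealso [parse_kgml()], [enumerate_pairs()], [classify_boundary()]
#' @export
build_graph <- function(documents, overview_maps = NULL,
                        nonmetabolic_maps = default_nonmetabolic_maps()) {
  if (inherits(documents, "kgml_document")) documents <- list(documents)
  stopifnot(length(documents) >= 1)
  map_ids <- vapply(documents, function(d) d$map_id, character(1))
  if (anyDuplicated(map_ids)) {
    warning("duplicate map id(s) across documents: ",
            paste(unique(map_ids[duplicated(map_ids)]), collapse = ", "),
            "; relations from every file are merged", call. = FALSE)
  }
  overview <- if (is.null(overview_maps)) is_overview_map(map_ids)
              else map_ids %in% overview_maps
  map_category <- ifelse(overview, "overview",
                         ifelse(map_ids %in% nonmetabolic_maps,
                                "non_metabolic", "metabolic"))
  names(map_category) <- map_ids
  map_category <- map_category[!duplicated(names(map_category))]

  rows <- list()
  nodes <- character(0)
  ko_map_rows <- list()
  for (d in documents[!overview]) {
    ko_of <- d$entries$kos
    names(ko_of) <- d$entries$entry_id
    cpd_of <- d$entries$compound
    names(cpd_of) <- d$entries$entry_id
    doc_kos <- unique(unlist(ko_of))
    nodes <- union(nodes, doc_kos)
    if (length(doc_kos)) {
      ko_map_rows[[length(ko_map_rows) + 1L]] <-
        data.frame(ko = doc_kos, map_id = d$map_id, stringsAsFactors = FALSE)
    }
    rel <- d$relations[d$relations$type %in% c("ecrel", "maplink"), ,
                       drop = FALSE]
    if (!nrow(rel)) next
    for (i in seq_len(nrow(rel))) {
      k1 <- ko_of[[rel$entry1[i]]]
      k2 <- ko_of[[rel$entry2[i]]]
      if (!length(k1) || !length(k2)) next
      cpd <- NA_character_
      ce <- rel$compound_entry[i]
      if (!is.na(ce) && ce %in% names(cpd_of)) cpd <- cpd_of[[ce]]
      grid <- expand.grid(a = k1, b = k2, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (!nrow(grid)) next
      rows[[length(rows) + 1L]] <- data.frame(
        ko_a = pmin(grid$a, grid$b), ko_b = pmax(grid$a, grid$b),
        compound = cpd, map_id = d$map_id, stringsAsFactors = FALSE)
    }
  }

  if (length(rows)) {
    raw <- do.call(rbind, rows)
    key <- paste(raw$ko_a, raw$ko_b)
    ord <- sort(unique(key))
    idx <- unname(split(seq_len(nrow(raw)), key)[ord])
    edges <- data.frame(
      ko_a = vapply(idx, function(i) raw$ko_a[i[1]], character(1)),
      ko_b = vapply(idx, function(i) raw$ko_b[i[1]], character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    edges$compounds <- lapply(idx, function(i) {
      v <- raw$compound[i]
      sort(unique(v[!is.na(v)]))
    })
    edges$maps <- lapply(idx, function(i) sort(unique(raw$map_id[i])))
  } else {
    edges <- data.frame(ko_a = character(0), ko_b = character(0))
    edges$compounds <- list()
    edges$maps <- list()
  }
  ko_maps <- if (length(ko_map_rows)) {
    km <- do.call(rbind, ko_map_rows)
    km <- km[!duplicated(paste(km$ko, km$map_id)), , drop = FALSE]
    km[order(km$ko, km$map_id), , drop = FALSE]
  } else {
    data.frame(ko = character(0), map_id = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(ko_maps) <- NULL
  structure(list(nodes = sort(nodes), edges = edges, ko_maps = ko_maps,
                 map_category = map_category),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph: ", length(x$nodes), " KO nodes, ", nrow(x$edges),
      " edges over ", sum(x$map_category != "overview"), " maps (",
      sum(x$map_category == "non_metabolic"), " non-metabolic)\n", sep = "")
  invisible(x)
}

#' Write / read a pathway graph as a TSV edge list
#'
#' The edge list carries one row per undirected KO pair with
#' semicolon-joined compound and map sets. Reading the file back yields a
#' `pathway_graph` whose node set is the union of edge endpoints and whose
#' map categories are re-derived from the map ids, so a write/read
#' round-trip reproduces the edge structure exactly.
#'
#' @param graph A `pathway_graph`.
#' @param path Output (input) TSV file.
#' @param nonmetabolic_maps See [build_graph()].
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a `pathway_graph`.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(
    ko_a = graph$edges$ko_a, ko_b = graph$edges$ko_b,
    compounds = vapply(graph$edges$compounds, paste, character(1),
                       collapse = ";"),
    maps = vapply(graph$edges$maps, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path,
                           nonmetabolic_maps = default_nonmetabolic_maps()) {
  df <- utils::read.delim(path, colClasses = "character")
  split_field <- function(v) lapply(strsplit(v, ";", fixed = TRUE),
                                    function(z) z[nzchar(z)])
  edges <- data.frame(ko_a = df$ko_a, ko_b = df$ko_b,
                      stringsAsFactors = FALSE)
  edges$compounds <- split_field(df$compounds)
  edges$maps <- split_field(df$maps)
  map_ids <- sort(unique(unlist(edges$maps)))
  map_category <- ifelse(is_overview_map(map_ids), "overview",
                         ifelse(map_ids %in% nonmetabolic_maps,
                                "non_metabolic", "metabolic"))
  names(map_category) <- map_ids
  km <- unique(rbind(
    data.frame(ko = rep(edges$ko_a, lengths(edges$maps)),
               map_id = unlist(edges$maps), stringsAsFactors = FALSE),
    data.frame(ko = rep(edges$ko_b, lengths(edges$maps)),
               map_id = unlist(edges$maps), stringsAsFactors = FALSE)))
  km <- km[order(km$ko, km$map_id), , drop = FALSE]
  rownames(km) <- NULL
  structure(list(nodes = sort(unique(c(edges$ko_a, edges$ko_b))),
                 edges = edges, ko_maps = km, map_category = map_category),
            class = "pathway_graph")
}
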