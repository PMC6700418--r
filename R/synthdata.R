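#' Specify a synthetic community
#'
#' Bundles the parameters of the synthetic-data generator: community
#' dimensions, the number of planted interacting pairs, and the strength
#' of the two statistical signals the interaction score looks for --
#' complementary genus content (`complementarity_strength`) and shared
#' sample abundance (`cooccurrence_strength`). At strength 1 and zero
#' noise a planted pair has perfectly complementary phylogenetic profiles
#' and identical co-occurrence profiles, hence score exactly 1; at
#' strength 0 it is indistinguishable from background.
#'
#' @param n_genera Number of genera (default 20).
#' @param n_kos Number of KOs, at least 4 (default 300).
#' @param n_samples Number of donors/samples (default 60).
#' @param n_planted_pairs Planted metabolic interaction pairs (default
#'   10).
#' @param n_boundary_pairs Producer/transporter boundary pairs placed on
#'   the non-metabolic map (default 30).
#' @param n_community_types Planted donor community types used for the
#'   genus-carriage structure (default 3).
#' @param background_pair_density Unused pathway edges are generated as
#'   chains; this reserves the fraction of KOs kept as background
#'   (informational, default 1 - planted share).
#' @param noise_sd Standard deviation of the log-abundance noise (default
#'   0.3).
#' @param complementarity_strength,cooccurrence_strength Coupling
#'   strengths in `[0, 1]` (defaults 0.9).
#' @param couple_boundary Give the boundary pairs the planted coupling as
#'   well (default `FALSE`).
#' @param genomes_per_genus Genomes per genus in the synthetic catalog
#'   (default 3).
#' @param genome_ko_retention Probability a genome retains each of its
#'   genus' KOs (strain variation, default 0.9).
#' @param seed Optional seed applied by [generate_dataset()].
#' @return Object of class `community_spec` (a validated list).
#' @export
community_spec <- function(n_genera = 20, n_kos = 300, n_samples = 60,
                           n_planted_pairs = 10, n_boundary_pairs = 30,
                           n_community_types = 3,
                           background_pair_density = NULL,
                           noise_sd = 0.3,
                           complementarity_strength = 0.9,
                           cooccurrence_strength = 0.9,
                           couple_boundary = FALSE,
                           genomes_per_genus = 3,
                           genome_ko_retention = 0.9,
                           seed = NULL) {
  stopifnot(n_genera >= 2, n_kos >= 4, n_samples >= 3,
            n_planted_pairs >= 1, n_boundary_pairs >= 0,
            n_community_types >= 1, noise_sd >= 0,
            complementarity_strength >= 0, complementarity_strength <= 1,
            cooccurrence_strength >= 0, cooccurrence_strength <= 1,
            genomes_per_genus >= 1,
            genome_ko_retention > 0, genome_ko_retention <= 1)
  n_bg <- n_kos - 2 * n_planted_pairs - 2 * n_boundary_pairs
  if (n_bg < 2) {
    stop("n_kos too small for the requested planted and boundary pairs: ",
         "need at least ", 2 * n_planted_pairs + 2 * n_boundary_pairs + 2,
         call. = FALSE)
  }
  if (is.null(background_pair_density)) {
    background_pair_density <- n_bg / n_kos
  }
  structure(list(n_genera = n_genera, n_kos = n_kos, n_samples = n_samples,
                 n_planted_pairs = n_planted_pairs,
                 n_boundary_pairs = n_boundary_pairs,
                 n_community_types = n_community_types,
                 background_pair_density = background_pair_density,
                 noise_sd = noise_sd,
                 complementarity_strength = complementarity_strength,
                 cooccurrence_strength = cooccurrence_strength,
                 couple_boundary = couple_boundary,
                 genomes_per_genus = genomes_per_genus,
                 genome_ko_retention = genome_ko_retention,
                 seed = seed),
            class = "community_spec")
}

#' Preset community specifications
#'
#' `"small"`: 20 genera, 300 KOs, 60 samples, 10 planted pairs, noise 0.3
#' -- a desk-scale community that the whole pipeline runs on in seconds.
#' `"medium"`: 40 genera, 800 KOs, 150 samples, 25 planted pairs.
#'
#' @param name `"small"` or `"medium"`.
#' @param ... Overrides passed to [community_spec()].
#' @return A `community_spec`.
#' @export
community_preset <- function(name = c("small", "medium"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    small = list(),
    medium = list(n_genera = 40, n_kos = 800, n_samples = 150,
                  n_planted_pairs = 25, n_boundary_pairs = 40))
  do.call(community_spec, utils::modifyList(args, list(...)))
}

#' @export
print.community_spec <- function(x, ...) {
  cat("community_spec: ", x$n_genera, " genera, ", x$n_kos, " KOs, ",
      x$n_samples, " samples; ", x$n_planted_pairs, " planted + ",
      x$n_boundary_pairs, " boundary pairs; strengths ",
      x$complementarity_strength, "/", x$cooccurrence_strength,
      ", noise ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

ko_id <- function(i) sprintf("K%05d", i)
cpd_id <- function(i) sprintf("C%05d", i)

kgml_text <- function(map_id, entries, relations) {
  # entries: data.frame(id, name, type); relations: data.frame(e1, e2,
  # type, compound_entry or NA)
  lines <- c(sprintf('<pathway name="path:ko%s" number="%s" title="synthetic map %s">',
                     map_id, map_id, map_id))
  for (i in seq_len(nrow(entries))) {
    lines <- c(lines, sprintf('  <entry id="%s" name="%s" type="%s"/>',
                              entries$id[i], entries$name[i],
                              entries$type[i]))
  }
  for (i in seq_len(nrow(relations))) {
    sub <- if (!is.na(relations$compound_entry[i])) {
      sprintf('<subtype name="compound" value="%s"/>',
              relations$compound_entry[i])
    } else ""
    lines <- c(lines, sprintf('  <relation entry1="%s" entry2="%s" type="%s">%s</relation>',
                              relations$e1[i], relations$e2[i],
                              relations$type[i], sub))
  }
  paste(c(lines, "</pathway>"), collapse = "\n")
}

#' Generate synthetic KGML pathway maps and module definitions
#'
#' Emits a connected KO network as valid KGML: two metabolic maps
#' (chains of `ECrel` relations with compound entries, joined by a
#' `maplink`), and one non-metabolic transporter map (id 02010) whose
#' producer/transporter relations form the planted boundary pairs.
#' Planted metabolic pairs sit on dedicated chain edges; each planted
#' pair's compound is declared a module terminus ("edge" compound), and
#' the remaining chain compounds are grouped into modules of five with
#' terminal and internal roles.
#'
#' @param spec A `community_spec`. Uses R's RNG; seed with [set.seed()]
#'   or use [generate_dataset()].
#' @return List with `kgml` (named character vector of XML documents),
#'   `modules` (module definition data frame), `plan` (data frame
#'   `ko_a`, `ko_b`, `compound`, `role` in planted/boundary/background
#'   for every generated edge) and `spec`.
#' @export
generate_pathway <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  np <- spec$n_planted_pairs
  nb <- spec$n_boundary_pairs
  n <- spec$n_kos
  planted <- matrix(ko_id(seq_len(2 * np)), ncol = 2, byrow = TRUE)
  producers <- ko_id(2 * np + seq_len(nb))
  transporters <- ko_id(2 * np + nb + seq_len(nb))
  background <- ko_id(setdiff(seq_len(n),
                              seq_len(2 * np + 2 * nb)))
  half <- ceiling(length(background) / 2)
  bg1 <- background[seq_len(half)]
  bg2 <- background[-seq_len(half)]
  two_maps <- length(bg2) >= 2
  if (!two_maps) bg1 <- background

  # map 00010: planted pairs woven into a chain with producers and the
  # first half of the background KOs; map 00020 (when there are enough
  # background KOs): the rest, joined by a maplink from the end of chain1
  chain1 <- c(as.vector(t(planted)), producers, bg1)
  chain2 <- if (two_maps) bg2 else character(0)

  next_cpd <- 0L
  new_cpd <- function(k = 1L) {
    ids <- cpd_id(next_cpd + seq_len(k))
    next_cpd <<- next_cpd + k
    ids
  }

  chain_doc <- function(map_id, chain, link_from = NULL) {
    n_edges <- length(chain) - 1L
    cpds <- new_cpd(n_edges)
    ko_entries <- data.frame(id = as.character(seq_along(chain)),
                             name = paste0("ko:", chain), type = "ortholog",
                             stringsAsFactors = FALSE)
    cpd_entries <- data.frame(
      id = as.character(length(chain) + seq_len(n_edges)),
      name = paste0("cpd:", cpds), type = "compound",
      stringsAsFactors = FALSE)
    rel <- data.frame(e1 = as.character(seq_len(n_edges)),
                      e2 = as.character(seq_len(n_edges) + 1L),
                      type = "ECrel",
                      compound_entry = cpd_entries$id,
                      stringsAsFactors = FALSE)
    entries <- rbind(ko_entries, cpd_entries)
    edges <- data.frame(ko_a = chain[-length(chain)], ko_b = chain[-1],
                        compound = cpds, stringsAsFactors = FALSE)
    if (!is.null(link_from)) {
      lid <- as.character(nrow(entries) + 1L)
      lcpd <- new_cpd()
      lcid <- as.character(nrow(entries) + 2L)
      entries <- rbind(entries,
                       data.frame(id = lid, name = paste0("ko:", link_from),
                                  type = "ortholog"),
                       data.frame(id = lcid, name = paste0("cpd:", lcpd),
                                  type = "compound"))
      rel <- rbind(rel, data.frame(e1 = lid, e2 = "1", type = "maplink",
                                   compound_entry = lcid))
      edges <- rbind(edges,
                     data.frame(ko_a = link_from, ko_b = chain[1],
                                compound = lcpd))
    }
    list(xml = kgml_text(map_id, entries, rel), edges = edges)
  }

  d1 <- chain_doc("00010", chain1)
  d2 <- if (two_maps) {
    chain_doc("00020", chain2, link_from = chain1[length(chain1)])
  } else {
    list(xml = NULL, edges = d1$edges[0, , drop = FALSE])
  }

  # transporter map: producer -> compound -> transporter
  b_cpds <- if (nb > 0) new_cpd(nb) else character(0)
  t_entries <- if (nb == 0) NULL else rbind(
    data.frame(id = as.character(seq_len(nb)),
               name = paste0("ko:", producers), type = "ortholog",
               stringsAsFactors = FALSE),
    data.frame(id = as.character(nb + seq_len(nb)),
               name = paste0("ko:", transporters), type = "ortholog",
               stringsAsFactors = FALSE),
    data.frame(id = as.character(2 * nb + seq_len(nb)),
               name = paste0("cpd:", b_cpds), type = "compound",
               stringsAsFactors = FALSE))
  t_rel <- if (nb == 0) NULL else data.frame(e1 = as.character(seq_len(nb)),
                      e2 = as.character(nb + seq_len(nb)),
                      type = "ECrel",
                      compound_entry = as.character(2 * nb + seq_len(nb)),
                      stringsAsFactors = FALSE)
  d3_edges <- if (nb == 0) NULL else
    data.frame(ko_a = producers, ko_b = transporters,
               compound = b_cpds, stringsAsFactors = FALSE)
  kgml <- c("00010" = d1$xml)
  if (two_maps) kgml <- c(kgml, "00020" = d2$xml)
  if (nb > 0) kgml <- c(kgml, "02010" = kgml_text("02010", t_entries, t_rel))

  planted_key <- paste(pmin(planted[, 1], planted[, 2]),
                       pmax(planted[, 1], planted[, 2]))
  all_edges <- rbind(d1$edges, d2$edges,
                     if (nb > 0) d3_edges)
  plan <- data.frame(ko_a = pmin(all_edges$ko_a, all_edges$ko_b),
                     ko_b = pmax(all_edges$ko_a, all_edges$ko_b),
                     compound = all_edges$compound,
                     stringsAsFactors = FALSE)
  plan$role <- "background"
  plan$role[paste(plan$ko_a, plan$ko_b) %in% planted_key] <- "planted"
  plan$role[plan$compound %in% b_cpds] <- "boundary"

  # modules: planted compounds are module termini; remaining chain-1
  # compounds grouped into runs of five (terminus/internal/.../terminus)
  planted_cpds <- plan$compound[plan$role == "planted"]
  mod_rows <- list()
  for (i in seq_along(planted_cpds)) {
    mod_rows[[length(mod_rows) + 1L]] <- data.frame(
      module_id = sprintf("MP%03d", i), compound_id = planted_cpds[i],
      role = "edge", stringsAsFactors = FALSE)
  }
  rest <- setdiff(d1$edges$compound, planted_cpds)
  if (length(rest) >= 5) {
    n_mod <- length(rest) %/% 5
    for (m in seq_len(n_mod)) {
      cpds <- rest[(m - 1) * 5 + 1:5]
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        module_id = sprintf("MB%03d", m), compound_id = cpds,
        role = c("edge", "internal", "internal", "internal", "edge"),
        stringsAsFactors = FALSE)
    }
  }
  modules <- validate_modules(do.call(rbind, mod_rows))
  rownames(modules) <- NULL
  rownames(plan) <- NULL
  list(kgml = kgml, modules = modules, plan = plan, spec = spec)
}

# presence vectors for one coupled pair: exact complement at strength 1,
# independent Bernoulli(1/2) at strength 0
coupled_presence <- function(genera, strength) {
  n <- length(genera)
  block_a <- seq_len(n) %in% sample.int(n, floor(n / 2))
  follow_a <- stats::runif(n) < strength
  follow_b <- stats::runif(n) < strength
  pa <- ifelse(follow_a, block_a, stats::runif(n) < 0.5)
  pb <- ifelse(follow_b, !block_a, stats::runif(n) < 0.5)
  cbind(a = as.integer(pa), b = as.integer(pb))
}

#' Generate a synthetic community with planted interactions
#'
#' Builds, for the pathway plan of [generate_pathway()]:
#' * a KO x genus abundance table in which every KO is carried by about
#'   half of the genera and each planted pair occupies complementary
#'   genus blocks (blended towards independence by
#'   `complementarity_strength`),
#' * a KO x sample abundance table in which the two members of a planted
#'   pair share a latent per-sample factor with weight
#'   `cooccurrence_strength` plus log-normal noise of standard deviation
#'   `noise_sd`,
#' * a donor genus-carriage matrix driven by planted community types
#'   (donors mostly carry the genera of their type),
#' * per-donor KO x genus tables (the genus table masked by carriage),
#' * a synthetic genome catalog (several genomes per genus, each
#'   retaining a random subset of the genus' KOs).
#'
#' Background KOs get independent presence and abundance. Uses R's RNG;
#' call via [generate_dataset()] for seeded, reproducible output.
#'
#' @param spec A `community_spec`.
#' @param pathway Output of [generate_pathway()] for the same spec.
#' @return Object of class `synthetic_community`; see Details. The
#'   `truth` element lists the coupled (planted, and optionally boundary)
#'   pairs.
#' @export
generate_community <- function(spec, pathway) {
  stopifnot(inherits(spec, "community_spec"))
  genera <- sprintf("G%03d", seq_len(spec$n_genera))
  donors <- sprintf("D%03d", seq_len(spec$n_samples))
  kos <- ko_id(seq_len(spec$n_kos))
  plan <- pathway$plan

  coupled <- plan[plan$role == "planted", , drop = FALSE]
  if (spec$couple_boundary) {
    coupled <- rbind(coupled, plan[plan$role == "boundary", , drop = FALSE])
  }

  # genus presence: independent half-blocks for background KOs,
  # complementary blocks for coupled pairs
  presence <- matrix(0L, nrow = spec$n_kos, ncol = spec$n_genera,
                     dimnames = list(kos, genera))
  for (k in kos) {
    presence[k, sample.int(spec$n_genera, floor(spec$n_genera / 2))] <- 1L
  }
  for (i in seq_len(nrow(coupled))) {
    pp <- coupled_presence(genera, spec$complementarity_strength)
    presence[coupled$ko_a[i], ] <- pp[, "a"]
    presence[coupled$ko_b[i], ] <- pp[, "b"]
  }
  ko_by_genus <- presence *
    matrix(stats::rlnorm(length(presence), meanlog = log(1e-4), sdlog = 1),
           nrow = nrow(presence))

  # sample abundance: latent shared factor for coupled pairs
  ns <- spec$n_samples
  w <- spec$cooccurrence_strength
  resid <- sqrt(1 - w^2)
  logx <- matrix(stats::rnorm(spec$n_kos * ns), nrow = spec$n_kos,
                 dimnames = list(kos, donors))
  for (i in seq_len(nrow(coupled))) {
    z <- stats::rnorm(ns)
    for (k in c(coupled$ko_a[i], coupled$ko_b[i])) {
      logx[k, ] <- w * z + resid * stats::rnorm(ns)
    }
  }
  if (spec$noise_sd > 0) {
    logx <- logx + matrix(stats::rnorm(length(logx), sd = spec$noise_sd),
                          nrow = nrow(logx))
  }
  ko_by_sample <- exp(logx)

  # community types and genus carriage
  donor_types <- rep_len(seq_len(spec$n_community_types), ns)
  names(donor_types) <- donors
  genus_group <- rep_len(seq_len(spec$n_community_types), spec$n_genera)
  in_type <- outer(donor_types, genus_group, "==")
  carriage <- matrix(stats::rbinom(length(in_type), 1,
                                   ifelse(in_type, 0.9, 0.1)),
                     nrow = ns, dimnames = list(donors, genera))
  donor_tables <- lapply(donors, function(d) {
    ko_by_genus * rep(carriage[d, ], each = spec$n_kos)
  })
  names(donor_tables) <- donors

  # genome catalog: strain-variable genomes per genus
  cat_rows <- list()
  for (g in seq_along(genera)) {
    gk <- kos[presence[, g] == 1L]
    if (!length(gk)) next
    for (j in seq_len(spec$genomes_per_genus)) {
      keep <- gk[stats::runif(length(gk)) < spec$genome_ko_retention]
      if (!length(keep)) keep <- sample(gk, 1L)
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        genome_id = sprintf("%s.g%d", genera[g], j), genus = genera[g],
        ko_id = keep, stringsAsFactors = FALSE)
    }
  }
  catalog <- genome_catalog(do.call(rbind, cat_rows))

  truth <- coupled
  truth$coupled <- TRUE
  structure(list(spec = spec, pathway = pathway,
                 ko_by_genus = ko_by_genus, ko_by_sample = ko_by_sample,
                 carriage = carriage, donor_types = donor_types,
                 donor_tables = donor_tables, catalog = catalog,
                 truth = truth),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("synthetic_community: ", x$spec$n_kos, " KOs x ", x$spec$n_genera,
      " genera x ", x$spec$n_samples, " donors; ", nrow(x$truth),
      " coupled pairs\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the RNG from `spec$seed` (when set) and runs
#' [generate_pathway()] and [generate_community()].
#'
#' @param spec A `community_spec`.
#' @return A `synthetic_community` (with the pathway embedded).
#' @export
generate_dataset <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pathway <- generate_pathway(spec)
  generate_community(spec, pathway)
}

write_wide_table <- function(m, path, id_col = "ko_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Writes the exact file formats the readers of the package consume:
#' `kgml/map<ID>.xml`, `modules.tsv`, `ko_by_genus.tsv`,
#' `ko_by_sample.tsv`, `catalog.tsv` and `truth.tsv`.
#'
#' @param dataset A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "kgml"), showWarnings = FALSE, recursive = TRUE)
  for (map_id in names(dataset$pathway$kgml)) {
    writeLines(dataset$pathway$kgml[[map_id]],
               file.path(dir, "kgml", paste0("map", map_id, ".xml")))
  }
  utils::write.table(dataset$pathway$modules, file.path(dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_wide_table(dataset$ko_by_genus, file.path(dir, "ko_by_genus.tsv"))
  write_wide_table(dataset$ko_by_sample, file.path(dir, "ko_by_sample.tsv"))
  cat_long <- do.call(rbind, lapply(seq_along(dataset$catalog$ko_sets),
    function(i) data.frame(
      genome_id = dataset$catalog$genomes$genome_id[i],
      genus = dataset$catalog$genomes$genus[i],
      ko_id = dataset$catalog$ko_sets[[i]], stringsAsFactors = FALSE)))
  utils::write.table(cat_long, file.path(dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
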