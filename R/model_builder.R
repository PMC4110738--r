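#' Path to a packaged model data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return file path.
#' @export
pheronet_file <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "pheronet")))
  path <- system.file("extdata", file, package = "pheronet")
  if (path == "") stop("no packaged file called ", file)
  path
}

#' Load and validate the core pathway model
#'
#' Reads a net-definition file (see [read_net_definition()]) and validates it
#' as a core pheromone-pathway model: 46 places, 48 transitions, bipartite
#' arcs, 10 `psi`-tagged core-concentration places, and a component map
#' covering every protein name used by interaction rosters.
#'
#' @param path model file; defaults to the packaged curated model.
#' @return list of class `core_model`: `net`, `m0` (technical-presence
#'   marking), `components`, `psi_places`, `ste_places`, `exempt_transitions`.
#' @export
load_model_definition <- function(path = pheronet_file("pheromone_core.andl")) {
  parsed <- read_net_definition(path)
  net <- parsed$net
  problems <- character()
  if (length(net$places) != 46L)
    problems <- c(problems, sprintf("expected 46 places, found %d",
                                    length(net$places)))
  if (length(net$transitions) != 48L)
    problems <- c(problems, sprintf("expected 48 transitions, found %d",
                                    length(net$transitions)))
  tagged <- function(tags, tag) names(Filter(function(x) tag %in% x, tags))
  psi <- tagged(net$place_tags, "psi")
  if (length(psi) != 10L)
    problems <- c(problems, sprintf("expected 10 psi places, found %d",
                                    length(psi)))
  missing_cmp <- setdiff(parsed$components, net$places)
  if (length(missing_cmp) > 0L)
    problems <- c(problems, paste("component map names unknown places:",
                                  paste(missing_cmp, collapse = ", ")))
  if (length(problems) > 0L)
    stop("model validation failed:\n  ", paste(problems, collapse = "\n  "))
  structure(
    list(net = net, m0 = parsed$m0, components = parsed$components,
         psi_places = psi,
         ste_places = tagged(net$place_tags, "ste"),
         exempt_transitions = tagged(net$transition_tags, "exempt"),
         path = path),
    class = "core_model")
}

#' Load the additional-protein interaction roster
#'
#' Tab-separated file with columns `id` (a1, a2, ...), `name` and `neighbors`
#' (comma-joined core protein names).
#'
#' @param path roster file; defaults to the packaged 41-protein roster.
#' @return data frame with columns `id`, `name`, `neighbors` (list column).
#' @export
load_protein_roster <- function(path = pheronet_file("additional_proteins.tsv")) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "neighbors") %in% names(df)))
  df$neighbors <- strsplit(df$neighbors, ",", fixed = TRUE)
  if (anyDuplicated(df$id)) stop("duplicated roster identifiers")
  df
}

#' Pool the pre-places of multi-reactant transitions
#'
#' For every transition with two or more ordinary pre-places that is not
#' Ste-type exempt, replaces the direct pre-arcs by a single pool place
#' `s_k` fed through per-reactant dummy transitions: each former pre-place
#' `p_j` is wired `p_j -> e_j -> s_k -> t_k`.  One dummy `e_j` is shared by
#' `p_j` across all its pooled targets.  The pool collects the weighted
#' cumulative concentration of the reactants, so the single arc `s_k -> t_k`
#' can carry the reaction's threshold (kd value).  Regulatory (read) arcs
#' are left on the transition.  Pool places are tagged `pool`, dummies
#' `dummy`.
#'
#' @param core a `core_model` from [load_model_definition()].
#' @return a [petri_net] with pools and dummies added.
#' @export
apply_pool_transform <- function(core) {
  stopifnot(inherits(core, "core_model"))
  net <- core$net
  arcs <- net$arcs
  new_places <- character(); new_trans <- character()
  add <- list()
  drop <- logical(nrow(arcs))
  dummies <- character()  # dummy id per source place already created
  for (t in net$transitions) {
    idx <- which(arcs$dst == t & !arcs$read)
    if (length(idx) < 2L || t %in% core$exempt_transitions) next
    k <- sub("^t", "", t)
    pool <- paste0("s", k)
    new_places <- c(new_places, pool)
    add[[length(add) + 1L]] <- data.frame(src = pool, dst = t, weight = 1L,
                                          read = FALSE)
    for (i in idx) {
      p <- arcs$src[i]
      ej <- paste0("e", sub("^p", "", p))
      if (!ej %in% dummies) {
        dummies <- c(dummies, ej)
        new_trans <- c(new_trans, ej)
        add[[length(add) + 1L]] <- data.frame(src = p, dst = ej, weight = 1L,
                                              read = FALSE)
      }
      add[[length(add) + 1L]] <- data.frame(src = ej, dst = pool, weight = 1L,
                                            read = FALSE)
      drop[i] <- TRUE
    }
  }
  arcs <- rbind(arcs[!drop, , drop = FALSE], do.call(rbind, add))
  ptags <- c(net$place_tags,
             setNames(rep(list("pool"), length(new_places)), new_places))
  ttags <- c(net$transition_tags,
             setNames(rep(list("dummy"), length(new_trans)), new_trans))
  petri_net(c(net$places, new_places), c(net$transitions, new_trans), arcs,
            labels = net$labels, place_tags = ptags,
            transition_tags = ttags)
}

# pooled target of a transition, or NA if it has no pool
pool_of <- function(net, t) {
  pre <- net$arcs[net$arcs$dst == t & !net$arcs$read, , drop = FALSE]
  pools <- pre$src[vapply(pre$src, function(p)
    "pool" %in% (net$place_tags[[p]] %||% character()), logical(1))]
  if (length(pools) >= 1L) pools[1L] else NA_character_
}

# core post-transitions of place p in a pooled net: direct ordinary
# post-transitions, plus for each dummy e_j the transitions of the pools it
# feeds.  Regulatory edges do not count as participation.
core_posts <- function(net, p) {
  a <- net$arcs
  direct <- a$dst[a$src == p & !a$read]
  out <- character()
  for (t in direct) {
    if ("dummy" %in% (net$transition_tags[[t]] %||% character())) {
      pools <- a$dst[a$src == t]
      out <- c(out, a$dst[a$src %in% pools & !a$read])
    } else out <- c(out, t)
  }
  unique(out)
}

#' Attach additional interacting proteins
#'
#' Each additional protein becomes a new place `a_n` with a dummy transition
#' `ea_n`; for every neighbor protein `j` in the roster, `a_n` is made a
#' reactant of every reaction `j` participates in, i.e. `ea_n` feeds the
#' pool `s_k` of every post-transition `t_k` of `j`'s place (or `t_k`
#' directly where `t_k` has no pool).  Duplicate edges are collapsed.
#'
#' @param net a pooled [petri_net] from [apply_pool_transform()].
#' @param roster data frame from [load_protein_roster()].
#' @param components named character vector mapping neighbor protein names
#'   to place identifiers (from the model file).
#' @return the augmented [petri_net]; new places are tagged `additional`,
#'   new transitions `dummy`.
#' @export
attach_additional_proteins <- function(net, roster, components) {
  if (nrow(roster) == 0L) return(net)
  add <- list(); new_places <- character(); new_trans <- character()
  for (r in seq_len(nrow(roster))) {
    an <- roster$id[r]
    ean <- paste0("ea", sub("^a", "", an))
    nb <- roster$neighbors[[r]]
    unknown <- setdiff(nb, names(components))
    if (length(unknown) > 0L)
      stop(sprintf("roster %s (%s): unknown neighbor component(s): %s",
                   an, roster$name[r], paste(unknown, collapse = ", ")))
    pooled <- character(); direct <- character()
    for (j in unique(unname(components[nb]))) {
      for (tk in core_posts(net, j)) {
        pool <- pool_of(net, tk)
        if (is.na(pool)) direct <- c(direct, tk)
        else pooled <- c(pooled, pool)
      }
    }
    pooled <- unique(pooled); direct <- unique(direct)
    if (length(pooled) + length(direct) == 0L) next
    new_places <- c(new_places, an)
    if (length(pooled) > 0L) {
      # the dummy routes a_n's supply into the pools of its reactions
      new_trans <- c(new_trans, ean)
      add[[length(add) + 1L]] <- data.frame(src = an, dst = ean,
                                            weight = 1L, read = FALSE)
      for (tg in pooled)
        add[[length(add) + 1L]] <- data.frame(src = ean, dst = tg,
                                              weight = 1L, read = FALSE)
    }
    # where the reaction kept its direct pre-places, a_n joins them directly
    for (tg in direct)
      add[[length(add) + 1L]] <- data.frame(src = an, dst = tg,
                                            weight = 1L, read = FALSE)
  }
  arcs <- rbind(net$arcs, do.call(rbind, add))
  ptags <- c(net$place_tags,
             setNames(rep(list("additional"), length(new_places)),
                      new_places))
  ttags <- c(net$transition_tags,
             setNames(rep(list("dummy"), length(new_trans)), new_trans))
  petri_net(c(net$places, new_places), c(net$transitions, new_trans), arcs,
            labels = net$labels, place_tags = ptags, transition_tags = ttags)
}

#' Add regulatory (read) edges
#'
#' Each `(place, transition)` pair becomes a weight-1 read arc: the
#' transition cannot fire until the place holds at least one token, and
#' firing leaves the place's count unchanged.  Adding an existing pair again
#' is a no-op.
#'
#' @param net a [petri_net].
#' @param reg_list data frame (or 2-column matrix) with columns `place`,
#'   `transition`.
#' @return the augmented [petri_net].
#' @export
add_regulatory_edges <- function(net, reg_list) {
  reg_list <- as.data.frame(reg_list, stringsAsFactors = FALSE)
  if (nrow(reg_list) == 0L) return(net)
  names(reg_list)[1:2] <- c("place", "transition")
  bad <- !(reg_list$place %in% net$places) |
    !(reg_list$transition %in% net$transitions)
  if (any(bad))
    stop("regulatory edge endpoints missing from net: ",
         paste(reg_list$place[bad], reg_list$transition[bad], collapse = "; "))
  existing <- paste(net$arcs$src, net$arcs$dst)[net$arcs$read]
  new <- !duplicated(paste(reg_list$place, reg_list$transition)) &
    !(paste(reg_list$place, reg_list$transition) %in% existing)
  if (!any(new)) return(net)
  arcs <- rbind(net$arcs,
                data.frame(src = reg_list$place[new],
                           dst = reg_list$transition[new],
                           weight = 1L, read = TRUE))
  petri_net(net$places, net$transitions, arcs, labels = net$labels,
            place_tags = net$place_tags, transition_tags = net$transition_tags)
}

#' Build the full pathway net
#'
#' Convenience pipeline: load the core model, pool multi-reactant
#' transitions, attach the additional-protein roster.  Regulatory edges ship
#' flagged in the model file and are carried through.
#'
#' @param model_path,roster_path data files (packaged defaults).
#' @return list of class `pathway_model`: `net` (full [petri_net]), `m0`
#'   (technical-presence marking over the full net), `core` (the
#'   `core_model`), `roster`.
#' @export
build_pathway_model <- function(model_path = pheronet_file("pheromone_core.andl"),
                                roster_path = pheronet_file("additional_proteins.tsv")) {
  core <- load_model_definition(model_path)
  roster <- load_protein_roster(roster_path)
  net <- apply_pool_transform(core)
  net <- attach_additional_proteins(net, roster, core$components)
  m0 <- marking(net, core$m0[as.integer(core$m0) > 0L])
  structure(list(net = net, m0 = m0, core = core, roster = roster),
            class = "pathway_model")
}

#' Edge identifiers
#'
#' Every arc is named `<src>TO<dst>` (e.g. `e4TOs5`, `s5TOt5`, `ea17TOs11`).
#'
#' @param net a [petri_net].
#' @return character vector, one identifier per arc.
#' @export
edge_ids <- function(net) paste0(net$arcs$src, "TO", net$arcs$dst)

# deterministic small-integer seed derivation; keeps everything below 2^31
derive_seed <- function(master, stage, index = 0L) {
  a <- as.double(master) %% 1048573
  a <- (a * 2039 + as.double(stage)) %% 2147483647
  a <- (a * 2039 + as.double(index)) %% 2147483647
  as.integer(a) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Randomize edge weights
#'
#' Draws an independent uniform integer weight in `{1, ..., 100}` for every
#' non-regulatory edge of the net — the unknown reaction thresholds (kd
#' values).  Regulatory edges keep weight 1.  The same seed reproduces the
#' identical assignment.
#'
#' @param net the fully built [petri_net].
#' @param seed integer seed.
#' @param weight_range inclusive integer bounds of the uniform draw.
#' @return list of class `network_config`: `net` (weights applied),
#'   `weights` (named integer vector over randomized edges), `seed`.
#' @export
assign_weights <- function(net, seed, weight_range = c(1L, 100L)) {
  ids <- edge_ids(net)
  if (anyDuplicated(ids)) stop("edge identifiers are not unique")
  random <- !net$arcs$read
  w <- with_seed(seed,
    sample.int(weight_range[2L] - weight_range[1L] + 1L, sum(random),
               replace = TRUE) + weight_range[1L] - 1L)
  arcs <- net$arcs
  arcs$weight[random] <- w
  structure(
    list(net = petri_net(net$places, net$transitions, arcs,
                         labels = net$labels, place_tags = net$place_tags,
                         transition_tags = net$transition_tags),
         weights = setNames(as.integer(w), ids[random]),
         seed = as.integer(seed)),
    class = "network_config")
}

#' Apply a stored weight vector
#'
#' Rebuilds a `network_config` from a named weight vector (e.g. one row of a
#' persisted ensemble), the inverse of extracting `config$weights`.
#'
#' @param net the fully built [petri_net].
#' @param weights named integer vector over the net's non-regulatory edges.
#' @param seed seed recorded with the configuration (provenance only).
#' @return a `network_config`.
#' @export
set_weights <- function(net, weights, seed = NA_integer_) {
  ids <- edge_ids(net)
  random <- !net$arcs$read
  if (!setequal(names(weights), ids[random]))
    stop("weight vector does not match the net's randomized edges")
  arcs <- net$arcs
  arcs$weight[random] <- as.integer(weights[ids[random]])
  structure(
    list(net = petri_net(net$places, net$transitions, arcs,
                         labels = net$labels, place_tags = net$place_tags,
                         transition_tags = net$transition_tags),
         weights = setNames(as.integer(weights[ids[random]]), ids[random]),
         seed = as.integer(seed)),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d randomized edges, seed=%s\n",
              length(x$weights), x$seed))
  invisible(x)
}
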