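# From search tree to ranked, classified pathways.
#
# The scope graph is the bipartite compound/reaction subnetwork lying on
# some root->hit path of the search tree, merged on canonical keys.
# Pathways are read in the forward production direction: the target
# (producible) compound first, the effector (detectable) last. Pathway
# enumeration keeps, at every branched compound, only the shortest
# producing branches, then combines them; ranking inherits each pathway's
# worst step penalty as its global score.

#' Collapse a search tree into a scope graph
#'
#' Keeps exactly the compounds and reactions lying on some root-to-hit
#' path of the tree, merged on canonical keys (duplicate tree nodes
#' collapse into one graph node). Side compounds of retained edges appear
#' as compound nodes of the bipartite graph.
#'
#' @param tree a `ps_tree` with at least one terminal hit.
#' @return a `ps_scope`: list with `compounds` (`data.table`: `key`,
#'   `smiles`, `on_chain`), `reactions` (list of steps with `uid`,
#'   `rule_id`, `penalty_score`, `product_key`, `main_key`, `side_keys`),
#'   `source_key` (effector), `target_key` (producible).
#' @export
build_scope <- function(tree) {
  stopifnot(inherits(tree, "ps_tree"))
  if (length(tree$hits) == 0L) {
    stop(sprintf(
      paste0("pair not connected: no route from %s to %s ",
             "(%d nodes explored, %d iterations, status '%s')"),
      tree$source$key, tree$target$key, length(tree$nodes),
      tree$iterations_run, tree$status), call. = FALSE)
  }
  keep <- logical(length(tree$nodes))
  for (h in tree$hits) {
    i <- h
    while (!is.na(i)) {
      keep[i] <- TRUE
      i <- tree$nodes[[i]]$parent
    }
  }
  comp <- new.env(parent = emptyenv())
  note_compound <- function(key, smiles, on_chain) {
    rec <- get0(key, envir = comp)
    if (is.null(rec)) {
      assign(key, list(smiles = smiles, on_chain = on_chain), envir = comp)
    } else if (on_chain && !rec$on_chain) {
      rec$on_chain <- TRUE
      assign(key, rec, envir = comp)
    }
  }
  rxn <- list()
  rxn_seen <- character(0)
  for (i in which(keep)) {
    n <- tree$nodes[[i]]
    note_compound(n$key, n$smiles, TRUE)
    if (is.null(n$edge)) next
    a <- n$edge
    uid <- paste(a$rule_id, a$product_key,
                 paste(a$reactant_keys, collapse = "."), sep = "|")
    for (j in seq_along(a$reactant_keys)) {
      note_compound(a$reactant_keys[j], a$reactant_smiles[j],
                    a$reactant_keys[j] == n$key)
    }
    if (uid %in% rxn_seen) next
    rxn_seen <- c(rxn_seen, uid)
    rxn[[length(rxn) + 1L]] <- list(
      uid = uid, rule_id = a$rule_id, penalty_score = a$penalty_score,
      product_key = a$product_key, product_smiles = a$product_smiles,
      main_key = n$key, main_smiles = n$smiles,
      side_keys = n$side_keys,
      side_smiles = a$reactant_smiles[match(n$side_keys, a$reactant_keys)]
    )
  }
  keys <- sort(ls(envir = comp), method = "radix")
  compounds <- data.table::data.table(
    smiles = vapply(keys, function(k) get(k, envir = comp)$smiles, character(1)),
    on_chain = vapply(keys, function(k) get(k, envir = comp)$on_chain, logical(1))
  )
  compounds$key <- keys # plain column ("key" is reserved in data.table())
  data.table::setcolorder(compounds, c("key", "smiles", "on_chain"))
  ord <- order(vapply(rxn, function(r) r$uid, character(1)), method = "radix")
  structure(
    list(compounds = compounds, reactions = rxn[ord],
         source_key = tree$source$key, target_key = tree$target$key),
    class = "ps_scope"
  )
}

#' @export
print.ps_scope <- function(x, ...) {
  cat(sprintf("<scope: %d compounds (%d on-chain), %d reactions, %s -> %s>\n",
              nrow(x$compounds), sum(x$compounds$on_chain),
              length(x$reactions), x$target_key, x$source_key))
  invisible(x)
}

ps_pathway <- function(steps, target_key, effector_key) {
  structure(
    list(
      steps = steps,
      length = length(steps),
      global_score = if (length(steps)) {
        max(vapply(steps, function(s) s$penalty_score, numeric(1)))
      } else 0,
      target_key = target_key,
      effector_key = effector_key,
      rule_ids = vapply(steps, function(s) s$rule_id, character(1)),
      roles = NULL
    ),
    class = "ps_pathway"
  )
}

#' @export
print.ps_pathway <- function(x, ...) {
  cat(sprintf("<pathway: %d step(s) [%s], global score %.3f%s>\n",
              x$length, paste(x$rule_ids, collapse = " > "), x$global_score,
              if (is.null(x$roles)) "" else ", classified"))
  invisible(x)
}

# all compound keys touched by a pathway (chain + side compounds)
ps_pathway_keys <- function(p) {
  ks <- c(p$target_key, p$effector_key)
  for (s in p$steps) ks <- c(ks, s$main_key, s$product_key, s$side_keys)
  unique(ks)
}

#' Enumerate detectable pathways within a scope
#'
#' Implements the shortest-branch rule: at every branched compound node
#' only the producing branches of minimal step count survive, and the
#' returned pathways are all their combinations. Concretely, pathways
#' are all routes from the target to the effector along the
#' shortest-path DAG of the scope (each step moves one reaction further
#' from the target than the step before). Pathways with identical
#' ordered rule lists are collapsed; the list is ordered by (global
#' score, length, rule ids) and truncated at `max_pathways` with a
#' warning recording the suppressed count.
#'
#' @param scope a `ps_scope` from [build_scope()].
#' @param max_pathways per-pair cap (default 1000).
#' @return list of `ps_pathway` (forward production direction: target
#'   compound first).
#' @export
enumerate_pathways <- function(scope, max_pathways = 1000L) {
  stopifnot(inherits(scope, "ps_scope"))
  tkey <- scope$target_key
  ekey <- scope$source_key
  if (identical(tkey, ekey)) {
    return(list(ps_pathway(list(), tkey, ekey)))
  }
  # production-direction adjacency: main substrate -> reactions
  by_main <- split(scope$reactions,
                   vapply(scope$reactions, function(r) r$main_key, character(1)))
  # BFS distances (in reaction steps) from the target
  dist <- new.env(parent = emptyenv())
  assign(tkey, 0, envir = dist)
  frontier <- tkey
  while (length(frontier)) {
    nxt <- character(0)
    for (k in frontier) {
      for (r in by_main[[k]] %||% list()) {
        p <- r$product_key
        if (is.null(get0(p, envir = dist))) {
          assign(p, get(k, envir = dist) + 1, envir = dist)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.null(get0(ekey, envir = dist))) {
    stop("scope does not connect target to effector", call. = FALSE)
  }
  # DFS over the shortest-path DAG (edges that advance the BFS level)
  paths <- list()
  walk <- function(key, steps) {
    if (identical(key, ekey)) {
      paths[[length(paths) + 1L]] <<- steps
      return()
    }
    for (r in by_main[[key]] %||% list()) {
      dp <- get0(r$product_key, envir = dist)
      if (is.null(dp) || dp != get(key, envir = dist) + 1) next
      walk(r$product_key, c(steps, list(r)))
    }
  }
  walk(tkey, list())
  out <- lapply(paths, ps_pathway, target_key = tkey, effector_key = ekey)
  # collapse identical ordered rule lists
  sig <- vapply(out, function(p) paste(p$rule_ids, collapse = ">"), character(1))
  out <- out[!duplicated(sig)]
  out <- out[order(
    vapply(out, function(p) p$global_score, numeric(1)),
    vapply(out, function(p) p$length, integer(1)),
    vapply(out, function(p) paste(p$rule_ids, collapse = ">"), character(1)),
    method = "radix"
  )]
  if (length(out) > max_pathways) {
    warning(sprintf("pathway cap reached: %d pathway(s) suppressed",
                    length(out) - max_pathways), call. = FALSE)
    out <- out[seq_len(max_pathways)]
  }
  out
}

#' Chassis metabolome
#'
#' The set of canonical metabolite keys that defines which pathway
#' compounds are endogenous to the host. Keys are stored as given plus,
#' when `ignore_stereo`, their stereochemistry-insensitive skeletons
#' (first InChIKey block), since chassis metabolite lists are
#' inconsistent about stereo annotation.
#'
#' @param metabolite_keys character vector of canonical keys (InChIKeys).
#' @param chassis_id identifier, e.g. a model id.
#' @param display_name human-readable name.
#' @param ignore_stereo match membership on the InChIKey skeleton
#'   (default `TRUE`).
#' @return a `ps_chassis`.
#' @export
chassis_metabolome <- function(metabolite_keys, chassis_id,
                               display_name = chassis_id,
                               ignore_stereo = TRUE) {
  metabolite_keys <- unique(as.character(metabolite_keys))
  if (!length(metabolite_keys)) {
    stop("chassis metabolome is empty", call. = FALSE)
  }
  structure(
    list(chassis_id = chassis_id, display_name = display_name,
         metabolite_keys = metabolite_keys,
         skeletons = unique(ps_key_skeleton(metabolite_keys)),
         ignore_stereo = isTRUE(ignore_stereo)),
    class = "ps_chassis"
  )
}

#' @export
print.ps_chassis <- function(x, ...) {
  cat(sprintf("<chassis %s: %d metabolite keys%s>\n", x$chassis_id,
              length(x$metabolite_keys),
              if (x$ignore_stereo) ", stereo-insensitive" else ""))
  invisible(x)
}

ps_in_chassis <- function(keys, chassis) {
  if (chassis$ignore_stereo) {
    ps_key_skeleton(keys) %in% chassis$skeletons
  } else {
    keys %in% chassis$metabolite_keys
  }
}

#' Classify pathway compounds against a chassis metabolome
#'
#' Assigns every compound of a pathway exactly one role: the producible
#' keeps `target` and the detectable keeps `effector`; any other
#' compound present in the chassis metabolome (or in the optional
#' producible-precursor `whitelist`) is a `precursor`; a compound
#' consumed by some step but produced by none (and not a precursor) must
#' be added to the medium, a `supplement`; everything else (produced by
#' one step, consumed by another) is an `intermediate`. The mapping is
#' total: roles are mutually exclusive and jointly exhaustive.
#'
#' @param pathway a `ps_pathway`.
#' @param chassis a `ps_chassis`.
#' @param whitelist optional character vector of additional canonical
#'   keys to treat as precursors (compounds a production route exists
#'   for, beyond native chassis membership).
#' @return named character vector: compound key -> role.
#' @export
classify_compounds <- function(pathway, chassis, whitelist = NULL) {
  stopifnot(inherits(pathway, "ps_pathway"), inherits(chassis, "ps_chassis"))
  keys <- ps_pathway_keys(pathway)
  consumed <- unique(unlist(lapply(pathway$steps, function(s) c(s$main_key, s$side_keys))))
  produced <- unique(vapply(pathway$steps, function(s) s$product_key, character(1)))
  roles <- stats::setNames(rep(NA_character_, length(keys)), keys)
  roles[pathway$target_key] <- "target"
  roles[pathway$effector_key] <- "effector"
  open <- is.na(roles)
  in_ch <- ps_in_chassis(keys, chassis) |
    (keys %in% (whitelist %||% character(0)))
  roles[open & in_ch] <- "precursor"
  open <- is.na(roles)
  supp <- open & keys %in% consumed & !(keys %in% produced)
  roles[supp] <- "supplement"
  roles[is.na(roles)] <- "intermediate"
  roles
}

#' Attach roles to a pathway
#'
#' Convenience wrapper storing the [classify_compounds()] mapping on the
#' pathway object (required before SBML export and precursor-flux
#' ranking).
#'
#' @inheritParams classify_compounds
#' @return the pathway with `$roles` set.
#' @export
classify_pathway <- function(pathway, chassis, whitelist = NULL) {
  pathway$roles <- classify_compounds(pathway, chassis, whitelist)
  pathway
}

#' Rank pathways
#'
#' The global score of a pathway is its worst step: the maximum rule
#' penalty over its steps (a pathway is only as good as its least
#' reliable reaction), so the primary sort is ascending on global score.
#' Ties are broken by descending estimated steady-state flux summed over
#' the pathway's precursor compounds (default flux 1 per unknown key, so
#' more in-chassis precursors rank higher), then ascending length, then
#' the concatenated rule ids - a strict total order.
#'
#' @param pathways list of `ps_pathway` (classified, for the flux term
#'   to see precursors; unclassified pathways get flux sum 0).
#' @param flux optional named numeric: canonical key -> steady-state
#'   flux estimate (e.g. precomputed FBA values). Keys absent from
#'   `flux` contribute 1.
#' @return the same pathways, reordered.
#' @export
rank_pathways <- function(pathways, flux = NULL) {
  if (!length(pathways)) return(pathways)
  score <- vapply(pathways, function(p) p$global_score, numeric(1))
  fsum <- vapply(pathways, function(p) {
    if (is.null(p$roles)) return(0)
    pre <- names(p$roles)[p$roles == "precursor"]
    if (!length(pre)) return(0)
    sum(vapply(pre, function(k) {
      if (!is.null(flux) && k %in% names(flux)) unname(flux[[k]]) else 1
    }, numeric(1)))
  }, numeric(1))
  len <- vapply(pathways, function(p) p$length, integer(1))
  rid <- vapply(pathways, function(p) paste(p$rule_ids, collapse = ">"),
                character(1))
  pathways[order(score, -fsum, len, rid, method = "radix")]
}

#' Load a flux mapping
#'
#' Two-column delimited file: canonical key, flux value.
#' @param path file path.
#' @return named numeric vector.
#' @export
load_flux <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("key", "flux"))
  stats::setNames(as.numeric(dt$flux), as.character(dt$key))
}

#' Load a precursor whitelist
#'
#' One-column file of canonical keys treated as precursors in
#' [classify_compounds()] beyond native chassis membership.
#' @param path file path.
#' @return character vector of keys.
#' @export
load_whitelist <- function(path) {
  unique(as.character(data.table::fread(path, header = FALSE)[[1]]))
}

#' Summarise pathway results over producible/effector pairs
#'
#' Aggregates a result set into the overall and per-compound summary
#' tables: total connected pairs, total pathways, and distinct
#' intermediate / precursor / supplement compounds (canonical-key union
#' across all pathways), plus per-producible and per-detectable averages
#' (pathways per compound, pairs per compound).
#'
#' @param results list of entries, each a list with `producible` (id or
#'   key), `effector` (id or key) and `pathways` (list of classified
#'   `ps_pathway`). Entries with zero pathways are excluded from the
#'   pair count.
#' @return list with `overall` (one-row `data.frame`: `Pairs`,
#'   `Pathways`, `Intermediates`, `Precursors`, `Supplements`) and
#'   `by_compound` (`data.frame` with rows Producible/Detectable and
#'   columns `Number.of.compounds`, `Average.no.of.pathways`,
#'   `Average.no.of.pairs`).
#' @export
pair_summary <- function(results) {
  stopifnot(length(results) > 0L)
  connected <- Filter(function(e) length(e$pathways) > 0L, results)
  n_pairs <- length(connected)
  n_paths <- sum(vapply(connected, function(e) length(e$pathways), integer(1)))
  role_union <- function(role) {
    ks <- unlist(lapply(connected, function(e) {
      unlist(lapply(e$pathways, function(p) {
        if (is.null(p$roles)) character(0) else names(p$roles)[p$roles == role]
      }))
    }))
    length(unique(ks))
  }
  overall <- data.frame(
    Pairs = n_pairs, Pathways = n_paths,
    Intermediates = role_union("intermediate"),
    Precursors = role_union("precursor"),
    Supplements = role_union("supplement")
  )
  per_side <- function(field) {
    ids <- vapply(connected, function(e) as.character(e[[field]]), character(1))
    n_cmp <- length(unique(ids))
    paths_by <- tapply(
      vapply(connected, function(e) length(e$pathways), integer(1)), ids, sum)
    data.frame(
      Number.of.compounds = n_cmp,
      Average.no.of.pathways = if (n_cmp) mean(paths_by) else 0,
      Average.no.of.pairs = if (n_cmp) n_pairs / n_cmp else 0
    )
  }
  by_compound <- rbind(Producible = per_side("producible"),
                       Detectable = per_side("effector"))
  list(overall = overall, by_compound = by_compound)
}

#' Write a pair summary as delimited text
#'
#' Mirrors the overall / by-compound summary tables as TSV.
#' @param summary result of [pair_summary()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pair_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(summary$overall, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("", con)
  utils::write.table(cbind(Set = rownames(summary$by_compound),
                           summary$by_compound),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
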