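# Tanimoto-guided Monte Carlo tree search.
#
# The search grows backward from the detectable compound (the effector,
# at the tree root) toward the producible target: each tree edge is one
# retro rule application, and new nodes are scored by Tanimoto similarity
# to the target molecule so the budget concentrates on branches that look
# like the target. The emitted pathways later read the chain in the
# forward production direction (target -> effector).
#
# Policy (fixed here, every knob in SearchConfig): UCT selection;
# expansion materialises all rule applications of the selected leaf at
# once; the rollout is depth-0 (the newly expanded child is scored by its
# Tanimoto similarity to the target directly, no random playout), which
# makes the whole search deterministic up to the seed.

#' Search configuration
#'
#' @param max_depth pathway length cap (backward steps from the effector).
#' @param iterations MCTS budget (select-expand-score-backpropagate cycles).
#' @param exploration_constant UCT exploration constant c (default
#'   `1/sqrt(2)`).
#' @param seed RNG seed recorded with the tree; the default policy is
#'   deterministic, so the seed only matters for stochastic variants.
#' @param similarity_threshold target-hit criterion: a node whose Tanimoto
#'   similarity to the target reaches the threshold counts as a hit when
#'   `< 1`; at the default 1 only exact canonical-key identity hits.
#' @param max_expansion_compounds bound on the number of distinct
#'   molecules prefetched from the chemistry kernel per search.
#' @return a `ps_search_config` list.
#' @export
search_config <- function(max_depth = 4L, iterations = 200L,
                          exploration_constant = 1 / sqrt(2), seed = 42L,
                          similarity_threshold = 1.0,
                          max_expansion_compounds = 5000L) {
  stopifnot(iterations > 0L, max_depth >= 1L,
            similarity_threshold >= 0, similarity_threshold <= 1)
  structure(
    list(max_depth = as.integer(max_depth),
         iterations = as.integer(iterations),
         exploration_constant = exploration_constant,
         seed = as.integer(seed),
         similarity_threshold = similarity_threshold,
         max_expansion_compounds = as.integer(max_expansion_compounds)),
    class = "ps_search_config"
  )
}

ps_is_hit <- function(key, fp, target, threshold) {
  if (identical(key, target$key)) return(TRUE)
  threshold < 1 && tanimoto_bits(fp, target$fp) >= threshold
}

#' Monte Carlo tree search from a detectable compound toward a target
#'
#' Runs `config$iterations` select-expand-score-backpropagate cycles (or
#' stops early once the tree is exhausted: every expandable node expanded
#' and every node visited). Nodes whose compound equals the target's
#' canonical key (or whose similarity reaches
#' `config$similarity_threshold`, when below 1) are flagged terminal
#' hits. When a rule application predicts several reactants, the child
#' node follows the reactant most similar to the target and the remaining
#' reactants ride along on the edge as side compounds; they re-enter in
#' pathway classification as precursors or supplements.
#'
#' @param source detectable compound (effector), the tree root.
#' @param target producible compound the search is steering toward.
#' @param rules `ps_ruleset` of retro rules.
#' @param config [search_config()].
#' @return a `ps_tree`: list with `nodes` (each with `key`, `smiles`,
#'   `parent`, `edge`, `side_keys`, `depth`, `visits`, `value_sum`,
#'   `children`, `expanded`, `terminal`), `hits` (node indices), `root`,
#'   `iterations_run`, `status` (`"ok"` or `"no expansion possible"`).
#' @export
mcts_search <- function(source, target, rules, config = search_config()) {
  stopifnot(inherits(source, "ps_compound"), inherits(target, "ps_compound"),
            inherits(rules, "ps_ruleset"), nrow(rules) > 0L)
  # one kernel launch prefetches the reachable space for this search
  ps_prefetch_expansion(source, rules, depth = config$max_depth,
                        max_compounds = config$max_expansion_compounds)
  set_id <- attr(rules, "set_id")

  nodes <- list()
  new_node <- function(key, smiles, fp, parent, edge, side_keys, depth) {
    nodes[[length(nodes) + 1L]] <<- list(
      key = key, smiles = smiles, fp = fp, parent = parent, edge = edge,
      side_keys = side_keys, depth = depth, visits = 0L, value_sum = 0,
      children = integer(0), expanded = FALSE,
      terminal = ps_is_hit(key, fp, target, config$similarity_threshold)
    )
    length(nodes)
  }
  new_node(source$key, source$smiles, source$fp, NA_integer_, NULL,
           character(0), 0L)

  expandable <- function(i) {
    n <- nodes[[i]]
    !n$expanded && !n$terminal && n$depth < config$max_depth
  }

  expand_node <- function(i) {
    n <- nodes[[i]]
    cmp <- structure(list(key = n$key, smiles = n$smiles, fp = n$fp),
                     class = "ps_compound")
    apps <- ps_apps_cached(set_id, n$key)
    if (is.null(apps)) apps <- expand_once(cmp, rules) else {
      # cached raw applications still need the per-ruleset de-dup
      apps <- ps_dedup_apps(apps)
    }
    kid_keys <- character(0)
    for (a in apps) {
      recs <- lapply(a$reactant_smiles, ps_smiles_record)
      sims <- vapply(recs, function(r) tanimoto_bits(r$fp, target$fp), numeric(1))
      exact <- vapply(recs, function(r) identical(r$key, target$key), logical(1))
      sims[exact] <- 1.0
      # chain through the reactant most similar to the target;
      # tie-break: smaller canonical key
      best <- order(-sims, a$reactant_keys, method = "radix")[1]
      side <- a$reactant_keys[-best]
      j <- new_node(a$reactant_keys[best], a$reactant_smiles[best],
                    recs[[best]]$fp, i, a, side, n$depth + 1L)
      kid_keys <- c(kid_keys, a$reactant_keys[best])
    }
    ord <- order(kid_keys, method = "radix")
    nodes[[i]]$children <<- (length(nodes) - length(apps) + seq_along(apps))[ord]
    nodes[[i]]$expanded <<- TRUE
    nodes[[i]]$children
  }

  select_child <- function(i) {
    kids <- nodes[[i]]$children
    visits <- vapply(kids, function(k) nodes[[k]]$visits, integer(1))
    if (any(visits == 0L)) return(kids[visits == 0L][1]) # key-ordered already
    vals <- vapply(kids, function(k) nodes[[k]]$value_sum, numeric(1))
    uct <- vals / visits +
      config$exploration_constant * sqrt(log(nodes[[i]]$visits) / visits)
    keys <- vapply(kids, function(k) nodes[[k]]$key, character(1))
    kids[order(-uct, keys, method = "radix")[1]]
  }

  backprop <- function(path, score) {
    for (i in path) {
      nodes[[i]]$visits <<- nodes[[i]]$visits + 1L
      nodes[[i]]$value_sum <<- nodes[[i]]$value_sum + score
    }
  }

  status <- "ok"
  iterations_run <- 0L
  for (it in seq_len(config$iterations)) {
    # exhaustion check: nothing left to expand and nothing unvisited
    any_open <- any(vapply(seq_along(nodes), function(i) {
      expandable(i) || nodes[[i]]$visits == 0L
    }, logical(1)))
    if (!any_open && it > 1L) break
    i <- 1L
    path <- i
    while (nodes[[i]]$expanded && length(nodes[[i]]$children) &&
           !nodes[[i]]$terminal) {
      i <- select_child(i)
      path <- c(path, i)
    }
    leaf <- i
    if (expandable(leaf)) {
      kids <- expand_node(leaf)
      if (length(kids)) {
        leaf <- kids[1]
        path <- c(path, leaf)
      } else if (nodes[[leaf]]$depth == 0L) {
        status <- "no expansion possible"
      }
    }
    n <- nodes[[leaf]]
    score <- if (n$terminal) 1.0 else tanimoto_bits(n$fp, target$fp)
    backprop(path, score)
    iterations_run <- it
    if (status == "no expansion possible" && !nodes[[1L]]$terminal) break
  }

  hits <- which(vapply(nodes, function(n) n$terminal, logical(1)))
  structure(
    list(nodes = nodes, root = 1L, hits = hits,
         source = source, target = target,
         config = config, set_id = set_id,
         iterations_run = iterations_run, status = status),
    class = "ps_tree"
  )
}

# per-ruleset de-dup shared by expand_once and the prefetched cache
ps_dedup_apps <- function(apps) {
  if (!length(apps)) return(apps)
  setkey <- vapply(apps, function(a) paste(a$reactant_keys, collapse = "."),
                   character(1))
  pen <- vapply(apps, function(a) a$penalty_score, numeric(1))
  rid <- vapply(apps, function(a) a$rule_id, character(1))
  o <- order(setkey, pen, rid, method = "radix")
  apps <- apps[o][!duplicated(setkey[o])]
  ps_order_apps(apps)
}

#' @export
print.ps_tree <- function(x, ...) {
  cat(sprintf(
    "<search tree: %d nodes, %d hit(s), %d iteration(s), status '%s'>\n",
    length(x$nodes), length(x$hits), x$iterations_run, x$status))
  invisible(x)
}

#' UCT child selection
#'
#' Returns the child of `node_id` maximising
#' `value_sum/visits + c * sqrt(log(parent visits)/visits)`. Unvisited
#' children are selected before any visited child; ties break on the
#' child's canonical key.
#'
#' @param tree a `ps_tree` from [mcts_search()].
#' @param node_id index of a node with at least one child.
#' @param c exploration constant.
#' @return index of the selected child.
#' @export
uct_select <- function(tree, node_id, c = 1 / sqrt(2)) {
  kids <- tree$nodes[[node_id]]$children
  stopifnot(length(kids) >= 1L)
  visits <- vapply(kids, function(k) tree$nodes[[k]]$visits, integer(1))
  keys <- vapply(kids, function(k) tree$nodes[[k]]$key, character(1))
  if (any(visits == 0L)) {
    unv <- which(visits == 0L)
    return(kids[unv[order(keys[unv], method = "radix")[1]]])
  }
  vals <- vapply(kids, function(k) tree$nodes[[k]]$value_sum, numeric(1))
  uct <- vals / visits + c * sqrt(log(tree$nodes[[node_id]]$visits) / visits)
  kids[order(-uct, keys, method = "radix")[1]]
}

#' Rollout score of a node
#'
#' The depth-0 rollout: terminal hits score 1, every other node scores
#' its Tanimoto similarity to the target.
#'
#' @param node a tree node (any list with `fp` and optionally `terminal`).
#' @param target target `ps_compound`.
#' @return score in `[0, 1]`.
#' @export
rollout_score <- function(node, target) {
  if (isTRUE(node$terminal)) return(1.0)
  tanimoto_bits(node$fp, target$fp)
}

#' Serialize a search tree to JSON
#'
#' Nodes, edges and visit statistics, for debugging and for downstream
#' visualisation.
#'
#' @param tree a `ps_tree`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
tree_as_json <- function(tree, path = NULL) {
  nodes <- lapply(seq_along(tree$nodes), function(i) {
    n <- tree$nodes[[i]]
    list(id = i, key = n$key, smiles = n$smiles, depth = n$depth,
         visits = n$visits, value_sum = n$value_sum, terminal = n$terminal,
         rule_id = if (!is.null(n$edge)) n$edge$rule_id else NULL,
         parent = if (!is.na(n$parent)) n$parent else NULL,
         side_compounds = as.list(n$side_keys))
  })
  doc <- list(
    source = tree$source$key, target = tree$target$key,
    status = tree$status, iterations = tree$iterations_run,
    nodes = nodes
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
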