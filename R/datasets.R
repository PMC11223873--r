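# Readers for the biological input tables (detectable effectors,
# producible targets, chassis metabolomes) and the synthetic toy-chemistry
# generator that makes the engine testable without any database download.

.effector_col_alias <- list(
  structure = c("structure", "smiles", "SMILES", "inchi", "InChI"),
  tf_name = c("tf_name", "tf", "transcription_factor", "TF"),
  organism = c("organism", "source_organism", "Organism"),
  evidence = c("evidence", "reference", "doi")
)

#' Load detectable compounds and their transcription factors
#'
#' Delimited table with compound structure, transcription-factor name
#' and source organism columns (Sensbio-style; an `evidence` column is
#' kept when present). Rows are merged on the compound's canonical key:
#' one record per distinct molecule, carrying all its transcription
#' factors. Rows with unparsable structures are skipped with a warning.
#'
#' @param path delimited file.
#' @return list of `ps_effector` records (fields `compound`,
#'   `transcription_factors` data.frame, `evidence`).
#' @export
load_effectors <- function(path) {
  if (!file.exists(path)) stop(sprintf("effector file not found: %s", path),
                               call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character")
  idx <- lapply(.effector_col_alias, ps_match_col, nms = names(raw))
  for (m in c("structure", "tf_name", "organism")) {
    if (is.na(idx[[m]])) {
      stop(sprintf("effector table %s lacks mandatory column '%s'", path, m),
           call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) stop(sprintf("effector table %s is empty", path),
                            call. = FALSE)
  structures <- raw[[idx$structure]]
  recs <- ps_canon_batch(structures)
  ok <- !vapply(recs, is.null, logical(1))
  if (any(!ok)) {
    warning(sprintf("skipped %d effector row(s) with unparsable structures",
                    sum(!ok)), call. = FALSE)
  }
  if (!any(ok)) stop(sprintf("no usable effector records in %s", path),
                     call. = FALSE)
  keys <- rep(NA_character_, nrow(raw))
  keys[ok] <- vapply(recs[ok], function(r) r$key, character(1))
  out <- list()
  for (k in unique(keys[ok])) {
    rows <- which(keys == k)
    out[[length(out) + 1L]] <- structure(
      list(
        compound = ps_compound_from_record(recs[[rows[1]]],
                                           structure = structures[rows[1]]),
        transcription_factors = unique(data.frame(
          tf_name = raw[[idx$tf_name]][rows],
          organism = raw[[idx$organism]][rows]
        )),
        evidence = if (!is.na(idx$evidence)) {
          paste(unique(raw[[idx$evidence]][rows]), collapse = "; ")
        } else NA_character_
      ),
      class = "ps_effector"
    )
  }
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' @export
print.ps_effector <- function(x, ...) {
  cat(sprintf("<effector %s: %s via %s>\n", x$compound$key, x$compound$smiles,
              paste(x$transcription_factors$tf_name, collapse = ", ")))
  invisible(x)
}

#' Load producible target compounds
#'
#' Delimited table with an id/name column and a structure column
#' (curated bio-based compound map style).
#'
#' @param path delimited file.
#' @return list of `ps_compound`, ids taken from the id column.
#' @export
load_producibles <- function(path) {
  if (!file.exists(path)) stop(sprintf("producible file not found: %s", path),
                               call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character")
  sidx <- ps_match_col(names(raw), c("structure", "smiles", "SMILES", "inchi"))
  iidx <- ps_match_col(names(raw), c("id", "name", "display_name", "compound"))
  if (is.na(sidx)) stop(sprintf("producible table %s lacks a structure column",
                                path), call. = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("producible table %s is empty", path),
                            call. = FALSE)
  out <- compounds(raw[[sidx]],
                   ids = if (!is.na(iidx)) raw[[iidx]] else NULL)
  if (!length(out)) stop(sprintf("no usable producible records in %s", path),
                         call. = FALSE)
  out
}

.inchikey_re <- "[A-Z]{14}-[A-Z]{10}-[A-Z]"

#' Load a chassis metabolome
#'
#' Accepts either an SBML model file (metabolite species annotated with
#' InChI strings or InChIKey identifier URIs, as in BiGG/BioCyc exports)
#' or a two-column delimited file (id, structure-or-key). Metabolites
#' without a resolvable structure are dropped with a warning; all keys
#' are canonical InChIKeys.
#'
#' @param path SBML or delimited file.
#' @param chassis_id identifier for the metabolome.
#' @param ignore_stereo see [chassis_metabolome()].
#' @return a `ps_chassis`.
#' @export
load_chassis <- function(path, chassis_id = basename(path),
                         ignore_stereo = TRUE) {
  if (!file.exists(path)) stop(sprintf("chassis file not found: %s", path),
                               call. = FALSE)
  head1 <- paste(readLines(path, n = 2L, warn = FALSE), collapse = " ")
  is_xml <- grepl("<\\?xml|<sbml", head1)
  if (is_xml) {
    doc <- xml2::read_xml(path)
    species <- xml2::xml_find_all(doc, "//*[local-name()='species']")
    if (!length(species)) {
      stop(sprintf("SBML file %s contains no species", path), call. = FALSE)
    }
    keys <- character(0)
    n_drop <- 0L
    inchis <- character(0)
    for (sp in species) {
      ann <- xml2::xml_find_first(sp, ".//*[local-name()='annotation']")
      txt <- if (inherits(ann, "xml_missing")) "" else {
        paste(c(xml2::xml_text(ann),
                unlist(xml2::xml_attrs(xml2::xml_find_all(ann, ".//*")))),
              collapse = " ")
      }
      ik <- regmatches(txt, regexpr(paste0("(?<![A-Z])", .inchikey_re),
                                    txt, perl = TRUE))
      inchi <- regmatches(txt, regexpr("InChI=[^\"'[:space:]<]+", txt))
      if (length(ik)) {
        keys <- c(keys, ik)
      } else if (length(inchi)) {
        inchis <- c(inchis, inchi)
      } else {
        n_drop <- n_drop + 1L
      }
    }
    if (length(inchis)) {
      recs <- ps_canon_batch(inchis)
      good <- !vapply(recs, is.null, logical(1))
      n_drop <- n_drop + sum(!good)
      keys <- c(keys, vapply(recs[good], function(r) r$key, character(1)))
    }
    if (n_drop > 0L) {
      warning(sprintf("dropped %d metabolite(s) without resolvable structure in %s",
                      n_drop, path), call. = FALSE)
    }
    if (!length(keys)) {
      stop(sprintf("no resolvable metabolites in %s", path), call. = FALSE)
    }
    return(chassis_metabolome(keys, chassis_id, ignore_stereo = ignore_stereo))
  }
  dt <- data.table::fread(path, header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) stop(sprintf("chassis table %s needs two columns (id, structure)",
                                  path), call. = FALSE)
  vals <- dt[[2L]]
  is_key <- grepl(paste0("^", .inchikey_re, "$"), vals)
  keys <- vals[is_key]
  n_drop <- 0L
  if (any(!is_key)) {
    recs <- ps_canon_batch(vals[!is_key])
    good <- !vapply(recs, is.null, logical(1))
    n_drop <- sum(!good)
    keys <- c(keys, vapply(recs[good], function(r) r$key, character(1)))
  }
  if (n_drop > 0L) {
    warning(sprintf("dropped %d metabolite(s) without resolvable structure in %s",
                    n_drop, path), call. = FALSE)
  }
  if (!length(keys)) stop(sprintf("no resolvable metabolites in %s", path),
                          call. = FALSE)
  chassis_metabolome(keys, chassis_id, ignore_stereo = ignore_stereo)
}

# --- synthetic toy chemistry ------------------------------------------------

# run expr with a private RNG stream, restoring the caller's state
ps_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.toy_groups <- c("alkane", "alcohol", "aldehyde", "acid", "amine")

ps_toy_smiles <- function(len, group) {
  c0 <- strrep("C", len)
  switch(group,
    alkane = c0,
    alcohol = paste0(c0, "O"),
    aldehyde = if (len == 1L) "C=O" else paste0(strrep("C", len - 1L), "C=O"),
    acid = if (len == 1L) "OC=O" else paste0(strrep("C", len - 1L), "C(=O)O"),
    amine = paste0(c0, "N")
  )
}

# Fully specified SMARTS (all H counts pinned) matching exactly this
# molecule and nothing larger: the diameter-16 limit of a retro rule,
# where the pattern covers the whole molecule.
ps_toy_smarts <- function(len, group) {
  chain <- function(k) if (k > 0L) strrep("[CH2]", k) else ""
  switch(group,
    alkane = if (len == 1L) "[CH4]" else if (len == 2L) "[CH3][CH3]" else
      paste0("[CH3]", chain(len - 2L), "[CH3]"),
    alcohol = paste0("[CH3]", chain(len - 1L), "[OX2H1]"),
    aldehyde = if (len == 1L) "[CH2]=[OX1]" else
      paste0("[CH3]", chain(len - 2L), "[CH1]=[OX1]"),
    acid = if (len == 1L) "[CH1](=[OX1])[OX2H1]" else
      paste0("[CH3]", chain(len - 2L), "[CX3](=[OX1])[OX2H1]"),
    amine = paste0("[CH3]", chain(len - 1L), "[NH2]")
  )
}

.toy_sides <- c(water = "O", ammonia = "N")

#' Generate a seeded toy chemistry
#'
#' Builds a closed universe of small linear molecules (alkanes,
#' alcohols, aldehydes, acids, amines of chain length 1-10) connected by
#' fully specified retro rules (each rule's product pattern pins every
#' hydrogen count, the diameter-16 limit where a rule describes one
#' whole molecule), together with the paired forward rules for
#' round-trip testing and exhaustively verified ground-truth pathways.
#'
#' The universe is a random DAG: compounds are ordered and each compound
#' after the first gets one producing edge when `branching <= 1` (from
#' its immediate predecessor: a linear chain) or `1 + rpois(branching-1)`
#' edges from random predecessors otherwise. A third of edges carry a
#' small side reactant (water or ammonia), so multi-reactant steps and
#' the supplement/precursor classification surface in fixtures. The
#' effector (detectable compound) is the last compound; targets are
#' drawn from the set reachable backward from it.
#'
#' At generation time the designed network is verified by an exhaustive
#' backward BFS in the chemistry kernel: the rule applications actually
#' produced by SMARTS matching must equal the designed edges, and
#' ground-truth pathways (per target: all shortest-branch routes to the
#' effector, with multi-reactant steps chained through the reactant most
#' similar to the target) are recomputed from the verified applications.
#'
#' @param seed integer seed; the fixture is a deterministic function of
#'   `(seed, n_compounds, branching)`.
#' @param n_compounds number of molecules (2-50).
#' @param branching expected producing edges per compound (>= 1).
#' @param n_targets how many (target, effector) ground-truth pairs to
#'   select (capped by reachability).
#' @param p_side probability that an edge carries a side reactant.
#' @return a `ps_toy`: list with `compounds` (`data.table`), `rules`
#'   (retro `ps_ruleset`), `forward_rules`, `edges` (`data.table`),
#'   `effector_key`, `pairs` (list of `target_key`, `effector_key`,
#'   `paths` = list of ordered rule-id vectors), `seed`.
#' @export
generate_toy_chemistry <- function(seed, n_compounds = 12L, branching = 1.5,
                                   n_targets = 3L, p_side = 1 / 3) {
  stopifnot(n_compounds >= 2L, n_compounds <= 50L, branching >= 1)
  for (attempt in 0:4) {
    toy <- try(ps_with_seed(seed + 1000L * attempt, {
      ps_build_toy(seed, n_compounds, branching, n_targets, p_side)
    }), silent = TRUE)
    if (!inherits(toy, "try-error")) return(toy)
  }
  stop(sprintf("toy chemistry generation failed after retries: %s",
               attr(toy, "condition")$message), call. = FALSE)
}

ps_build_toy <- function(seed, n_compounds, branching, n_targets, p_side) {
  combos <- expand.grid(len = 1:10, group = .toy_groups,
                        stringsAsFactors = FALSE)
  pick <- sample.int(nrow(combos), n_compounds)
  smiles <- mapply(ps_toy_smiles, combos$len[pick], combos$group[pick])
  smarts <- mapply(ps_toy_smarts, combos$len[pick], combos$group[pick])

  # design the DAG of retro edges
  edges <- list() # product index, reactant index, side name or NA
  for (i in 2:n_compounds) {
    n_in <- if (branching <= 1) 1L else 1L + stats::rpois(1L, branching - 1)
    n_in <- min(n_in, i - 1L)
    parents <- if (branching <= 1) i - 1L else sample.int(i - 1L, n_in)
    for (j in parents) {
      side <- if (stats::runif(1) < p_side) {
        sample(names(.toy_sides), 1L)
      } else NA_character_
      edges[[length(edges) + 1L]] <- list(prod = i, react = j, side = side)
    }
  }
  n_e <- length(edges)
  retro <- data.table::data.table(
    rule_id = sprintf("TR%03d", seq_len(n_e)),
    smarts = vapply(seq_len(n_e), function(k) {
      e <- edges[[k]]
      rhs <- smiles[e$react]
      if (!is.na(e$side)) rhs <- paste(rhs, .toy_sides[[e$side]], sep = ".")
      paste0(smarts[e$prod], ">>", rhs)
    }, character(1)),
    diameter = 16L,
    penalty_score = round(stats::runif(n_e, 0.05, 0.95), 3)
  )
  forward <- data.table::data.table(
    rule_id = sprintf("TF%03d", seq_len(n_e)),
    smarts = vapply(seq_len(n_e), function(k) {
      e <- edges[[k]]
      paste0(smarts[e$react], ">>", smiles[e$prod])
    }, character(1)),
    diameter = 16L,
    penalty_score = retro$penalty_score
  )
  rules <- ps_ruleset(retro)
  forward_rules <- ps_ruleset(forward)

  cmps <- compounds(smiles, ids = sprintf("toy%02d", seq_len(n_compounds)))
  stopifnot(length(cmps) == n_compounds)
  keys <- vapply(cmps, function(c) c$key, character(1))
  if (anyDuplicated(keys)) stop("toy universe has colliding molecules")
  side_keys <- canonicalize(unname(.toy_sides))
  names(side_keys) <- names(.toy_sides)

  # exhaustive kernel-side verification: SMARTS matching must reproduce
  # exactly the designed edge set, starting from the effector
  effector_i <- n_compounds
  ps_prefetch_expansion(cmps[[effector_i]], rules, depth = n_compounds,
                        max_compounds = 5000L)
  seen_apps <- character(0)
  reach <- effector_i
  queue <- effector_i
  edge_sig <- vapply(seq_len(n_e), function(k) {
    e <- edges[[k]]
    rk <- keys[e$react]
    if (!is.na(e$side)) rk <- paste(sort(c(rk, side_keys[[e$side]])), collapse = "+")
    paste(retro$rule_id[k], keys[e$prod], rk, sep = "|")
  }, character(1))
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    apps <- ps_apps_cached(attr(rules, "set_id"), keys[i])
    if (is.null(apps)) apps <- list()
    for (a in apps) {
      sig <- paste(a$rule_id, a$product_key,
                   paste(sort(a$reactant_keys), collapse = "+"), sep = "|")
      seen_apps <- c(seen_apps, sig)
      if (!(sig %in% edge_sig)) {
        stop(sprintf("toy verification: unexpected application %s", sig))
      }
      k <- match(a$rule_id, retro$rule_id)
      j <- edges[[k]]$react
      if (!(j %in% reach)) { reach <- c(reach, j); queue <- c(queue, j) }
    }
  }
  # designed edges whose product is reachable must all have been observed
  for (k in seq_len(n_e)) {
    if (edges[[k]]$prod %in% reach && !(edge_sig[k] %in% seen_apps)) {
      stop(sprintf("toy verification: designed edge %s not reproduced",
                   retro$rule_id[k]))
    }
  }

  reach_targets <- setdiff(reach, effector_i)
  if (!length(reach_targets)) stop("effector has no reachable targets")
  n_targets <- min(n_targets, length(reach_targets))
  # deterministic choice: deepest first, then sampled
  depth_of <- ps_toy_depths(edges, effector_i, n_compounds)
  ordered <- reach_targets[order(-depth_of[reach_targets], reach_targets)]
  chosen <- ordered[seq_len(n_targets)]

  pairs <- lapply(chosen, function(ti) {
    paths <- ps_toy_ground_truth(edges, retro$rule_id, keys, side_keys,
                                 cmps, ti, effector_i)
    list(target_key = keys[ti], target_id = sprintf("toy%02d", ti),
         effector_key = keys[effector_i], paths = paths)
  })
  if (any(vapply(pairs, function(p) length(p$paths) == 0L, logical(1)))) {
    stop("a chosen pair has no ground-truth path")
  }

  edt <- data.table::data.table(
    rule_id = retro$rule_id,
    product_key = keys[vapply(edges, function(e) e$prod, integer(1))],
    reactant_key = keys[vapply(edges, function(e) e$react, integer(1))],
    side = vapply(edges, function(e) e$side, character(1))
  )
  chassis_keys <- unique(c(
    unname(side_keys),
    keys[seq_len(max(1L, floor(n_compounds / 4)))]
  ))
  structure(
    list(compounds = {
           cdt <- data.table::data.table(
             id = sprintf("toy%02d", seq_len(n_compounds)),
             smiles = vapply(cmps, function(c) c$smiles, character(1)),
             group = combos$group[pick], len = combos$len[pick])
           cdt$key <- keys # "key" is reserved in data.table()
           data.table::setcolorder(cdt, c("id", "smiles", "key"))
           cdt
         },
         rules = rules, forward_rules = forward_rules, edges = edt,
         effector_key = keys[effector_i],
         effector_id = sprintf("toy%02d", effector_i),
         chassis_keys = chassis_keys,
         side_keys = side_keys,
         pairs = pairs, seed = seed),
    class = "ps_toy"
  )
}

# depth (longest backward distance) of each node from the effector
ps_toy_depths <- function(edges, effector_i, n) {
  d <- rep(-Inf, n)
  d[effector_i] <- 0
  # products have larger index than reactants: sweep indices descending
  repeat {
    changed <- FALSE
    for (e in edges) {
      if (is.finite(d[e$prod]) && d[e$react] < d[e$prod] + 1) {
        d[e$react] <- d[e$prod] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# Independent ground-truth enumeration for one (target, effector) pair:
# per-pair chain edges (multi-reactant steps chain through the reactant
# most similar to the target, ties to the smaller key), BFS levels from
# the target, all routes along the shortest-branch DAG.
ps_toy_ground_truth <- function(edges, rule_ids, keys, side_keys, cmps,
                                ti, effector_i) {
  target <- cmps[[ti]]
  side_fp <- lapply(names(side_keys), function(nm) {
    ps_smiles_record(.toy_sides[[nm]])$fp
  })
  names(side_fp) <- names(side_keys)
  # chain edge for rule k: reactant -> product, or NULL when the side
  # compound out-scores the designed reactant
  chain <- list()
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    if (is.na(e$side)) {
      chain[[k]] <- c(e$react, e$prod)
      next
    }
    sim_r <- tanimoto_bits(cmps[[e$react]]$fp, target$fp)
    if (identical(keys[e$react], target$key)) sim_r <- 1
    sim_s <- tanimoto_bits(side_fp[[e$side]], target$fp)
    if (identical(side_keys[[e$side]], target$key)) sim_s <- 1
    pick_r <- sim_r > sim_s ||
      (sim_r == sim_s && keys[e$react] < side_keys[[e$side]])
    chain[[k]] <- if (pick_r) c(e$react, e$prod) else NULL
  }
  # BFS levels from target over chain edges
  n <- length(keys)
  lev <- rep(NA_integer_, n)
  lev[ti] <- 0L
  frontier <- ti
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in seq_along(chain)) {
      ce <- chain[[k]]
      if (is.null(ce)) next
      if (ce[1] %in% frontier && is.na(lev[ce[2]])) nxt <- c(nxt, ce[2])
    }
    nxt <- unique(nxt)
    lev[nxt] <- lev[frontier[1]] + 1L
    frontier <- nxt
  }
  if (is.na(lev[effector_i])) return(list())
  paths <- list()
  walk <- function(i, rids) {
    if (i == effector_i) {
      paths[[length(paths) + 1L]] <<- rids
      return()
    }
    for (k in seq_along(chain)) {
      ce <- chain[[k]]
      if (is.null(ce) || ce[1] != i) next
      if (is.na(lev[ce[2]]) || lev[ce[2]] != lev[i] + 1L) next
      walk(ce[2], c(rids, rule_ids[k]))
    }
  }
  walk(ti, character(0))
  unique(paths)
}

#' @export
print.ps_toy <- function(x, ...) {
  cat(sprintf("<toy chemistry seed %d: %d compounds, %d retro rules, %d pair(s)>\n",
              x$seed, nrow(x$compounds), nrow(x$rules), length(x$pairs)))
  invisible(x)
}

#' Write a toy chemistry as a fixture directory
#'
#' Emits the same delimited dialects the real readers consume:
#' `rules.csv`, `forward_rules.csv`, `compounds.tsv`, `effectors.tsv`,
#' `producibles.tsv`, `chassis.tsv`.
#'
#' @param toy a `ps_toy`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_toy_chemistry <- function(toy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(toy$rules, file.path(dir, "rules.csv"))
  data.table::fwrite(toy$forward_rules, file.path(dir, "forward_rules.csv"))
  data.table::fwrite(toy$compounds, file.path(dir, "compounds.tsv"), sep = "\t")
  eff <- toy$compounds[toy$compounds$key == toy$effector_key]
  data.table::fwrite(data.table::data.table(
    structure = eff$smiles,
    tf_name = paste0("TF_", toupper(substr(eff$key, 1, 6))),
    organism = "Synthetica toyensis"
  ), file.path(dir, "effectors.tsv"), sep = "\t")
  tkeys <- vapply(toy$pairs, function(p) p$target_key, character(1))
  prod <- toy$compounds[toy$compounds$key %in% tkeys]
  data.table::fwrite(data.table::data.table(id = prod$id,
                                            structure = prod$smiles),
                     file.path(dir, "producibles.tsv"), sep = "\t")
  chdt <- data.table::data.table(id = paste0("m", seq_along(toy$chassis_keys)))
  chdt$key <- toy$chassis_keys
  data.table::fwrite(chdt, file.path(dir, "chassis.tsv"), sep = "\t")
  invisible(dir)
}
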