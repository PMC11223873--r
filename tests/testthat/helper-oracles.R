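# Independent oracles. These deliberately re-derive expected results
# from first principles (igraph path enumeration, 0/1-vector bit
# counting, plain sorting) rather than calling the engine's own code
# paths.

# Tanimoto via dense 0/1 vectors - brute force
oracle_tanimoto <- function(bits_a, bits_b, nbits = 2048L) {
  va <- integer(nbits); vb <- integer(nbits)
  va[bits_a + 1L] <- 1L; vb[bits_b + 1L] <- 1L
  inter <- sum(va == 1L & vb == 1L)
  uni <- sum(va == 1L | vb == 1L)
  if (uni == 0L) return(1.0)
  inter / uni
}

# All shortest-branch pathways for one toy pair, via igraph:
# all simple target->effector paths, restricted to minimal total length
# (equivalent to the per-node shortest-producing-branch rule), expanded
# over parallel rule edges.
oracle_toy_pathways <- function(toy, pair) {
  target_key <- pair$target_key
  effector_key <- pair$effector_key
  fp_of <- function(key) {
    smi <- toy$compounds$smiles[toy$compounds$key == key]
    if (length(smi)) return(compound(smi)$fp)
    nm <- names(toy$side_keys)[toy$side_keys == key]
    compound(unname(c(water = "O", ammonia = "N")[nm]))$fp
  }
  tfp <- fp_of(target_key)
  sim <- function(key) {
    if (identical(key, target_key)) return(1.0)
    oracle_tanimoto(fp_of(key), tfp)
  }
  # production-direction chain edges: reactant -> product, multi-reactant
  # steps chained through the most target-similar reactant
  e <- toy$edges
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    if (is.na(e$side[i])) { keep[i] <- TRUE; next }
    skey <- unname(toy$side_keys[[e$side[i]]])
    sr <- sim(e$reactant_key[i]); ss <- sim(skey)
    keep[i] <- sr > ss || (sr == ss && e$reactant_key[i] < skey)
  }
  e <- e[keep, ]
  if (!nrow(e)) return(list())
  verts <- unique(c(e$reactant_key, e$product_key, target_key, effector_key))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$reactant_key, to = e$product_key,
               rule_id = e$rule_id), vertices = verts, directed = TRUE)
  sp <- tryCatch(
    igraph::all_simple_paths(g, from = target_key, to = effector_key,
                             mode = "out"),
    error = function(err) list())
  if (!length(sp)) return(list())
  lens <- vapply(sp, length, integer(1))
  sp <- sp[lens == min(lens)]
  # expand parallel rule edges between consecutive vertices
  out <- list()
  for (p in sp) {
    nms <- names(p)
    choices <- lapply(seq_len(length(nms) - 1L), function(i) {
      e$rule_id[e$reactant_key == nms[i] & e$product_key == nms[i + 1L]]
    })
    grid <- expand.grid(choices, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.character(unlist(grid[r, ]))
    }
  }
  unique(out)
}

# backward-reachable compound set (canonical keys) from the effector,
# over the designed toy edges, including side compounds, within `depth`
oracle_reachable_keys <- function(toy, depth = Inf) {
  lev <- stats::setNames(0, toy$effector_key)
  frontier <- toy$effector_key
  keys <- toy$effector_key
  sides <- character(0)
  d <- 0
  while (length(frontier) && d < depth) {
    d <- d + 1
    nxt <- character(0)
    for (k in frontier) {
      rows <- which(toy$edges$product_key == k)
      for (i in rows) {
        rk <- toy$edges$reactant_key[i]
        if (!is.na(toy$edges$side[i])) {
          sides <- c(sides, unname(toy$side_keys[[toy$edges$side[i]]]))
        }
        if (!(rk %in% keys)) { keys <- c(keys, rk); nxt <- c(nxt, rk) }
      }
    }
    frontier <- unique(nxt)
  }
  sort(unique(c(keys, sides)))
}
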