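test_that("search finds the route in a linear chemistry and handles degenerate inputs", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "rule_id,smarts,diameter,penalty_score",
    # retro: propionic acid <= propanal + water ; propanal <= propanol
    "L1,[CH3][CH2][CX3:1](=[OX1:2])[OX2H1]>>[CH3][CH2][CH1:1]=[O:2].[OH2],8,0.3",
    "L2,[CH3][CH2][CH1:1]=[OX1:2]>>[CH3][CH2][CH2:1][OX2H1:2],6,0.6"
  ), f)
  rs <- load_rules(f, 0, 16)
  acid <- compound("CCC(=O)O")
  propanol <- compound("CCCO")
  tree <- mcts_search(acid, propanol, rs,
                      search_config(max_depth = 3, iterations = 50, seed = 1))
  expect_length(tree$hits, 1L)
  hit <- tree$nodes[[tree$hits]]
  expect_identical(hit$key, propanol$key)
  expect_identical(hit$depth, 2L)
  # intermediate on the route is the aldehyde
  expect_identical(tree$nodes[[hit$parent]]$smiles, "CCC=O")

  # source == target: the root itself is a terminal hit, zero-step search
  t2 <- mcts_search(acid, acid, rs, search_config(iterations = 5))
  expect_true(t2$nodes[[1]]$terminal)
  expect_identical(t2$hits, 1L)

  # source matched by no rule: single-node "no expansion possible" tree
  t3 <- mcts_search(compound("c1ccccc1"), propanol, rs,
                    search_config(iterations = 5))
  expect_identical(t3$status, "no expansion possible")
  expect_length(t3$nodes, 1L)
  expect_length(t3$hits, 0L)
})

test_that("uct_select prefers unvisited children, exploits at c = 0, and breaks ties on key", {
  fake_tree <- function(kids) {
    nodes <- c(list(list(key = "ROOT", visits = 10L, value_sum = 5,
                         children = seq_along(kids) + 1L)), kids)
    structure(list(nodes = nodes, root = 1L), class = "ps_tree")
  }
  # pure exploitation: the higher-mean child wins at c = 0
  tr <- fake_tree(list(
    list(key = "AAA", visits = 5L, value_sum = 4.5),  # mean 0.9
    list(key = "BBB", visits = 5L, value_sum = 0.5)   # mean 0.1
  ))
  expect_identical(uct_select(tr, 1L, c = 0), 2L)
  # an unvisited child is always selected first
  tr <- fake_tree(list(
    list(key = "AAA", visits = 5L, value_sum = 4.5),
    list(key = "BBB", visits = 0L, value_sum = 0)
  ))
  expect_identical(uct_select(tr, 1L, c = 2), 3L)
  # symmetric children with equal stats: smaller canonical key wins
  tr <- fake_tree(list(
    list(key = "ZZZ", visits = 3L, value_sum = 1.5),
    list(key = "MMM", visits = 3L, value_sum = 1.5)
  ))
  expect_identical(uct_select(tr, 1L, c = 0.5), 3L)
})

test_that("rollout_score is the Tanimoto guidance with terminal hits pinned at 1", {
  tgt <- compound("CCCO")
  expect_identical(rollout_score(list(fp = tgt$fp), tgt), 1.0)
  expect_identical(rollout_score(list(fp = integer(0), terminal = TRUE), tgt), 1.0)
  expect_identical(rollout_score(list(fp = c(1L, 2L, 3L)),
                                 structure(list(key = "X", fp = c(2L, 3L, 4L)),
                                           class = "ps_compound")), 0.5)
})

test_that("identical seed and config reproduce the identical tree", {
  toy <- local_toy(2)
  pair <- toy$pairs[[1]]
  eff <- toy_compound(toy, pair$effector_key)
  tgt <- toy_compound(toy, pair$target_key)
  cfg <- search_config(max_depth = nrow(toy$compounds), iterations = 150,
                       seed = 11)
  t1 <- mcts_search(eff, tgt, toy$rules, cfg)
  t2 <- mcts_search(eff, tgt, toy$rules, cfg)
  expect_identical(length(t1$nodes), length(t2$nodes))
  expect_identical(vapply(t1$nodes, function(n) n$visits, integer(1)),
                   vapply(t2$nodes, function(n) n$visits, integer(1)))
  expect_identical(vapply(t1$nodes, function(n) n$key, character(1)),
                   vapply(t2$nodes, function(n) n$key, character(1)))
  expect_identical(t1$hits, t2$hits)
})

test_that("root visit count equals the number of completed iterations", {
  toy <- local_toy(2)
  pair <- toy$pairs[[1]]
  eff <- toy_compound(toy, pair$effector_key)
  tgt <- toy_compound(toy, pair$target_key)
  for (iters in c(5L, 37L, 150L)) {
    tr <- mcts_search(eff, tgt, toy$rules,
                      search_config(max_depth = nrow(toy$compounds),
                                    iterations = iters, seed = 3))
    expect_identical(tr$nodes[[1]]$visits, tr$iterations_run)
    expect_lte(tr$iterations_run, iters)
  }
})

test_that("with c = 0 a depth-1 target is found within (root children + 1) iterations", {
  toy <- local_toy(4)
  # choose a compound one retro step below the effector as the target
  eff <- toy_compound(toy, toy$effector_key)
  apps <- expand_once(eff, toy$rules)
  n_children <- length(apps)
  expect_gte(n_children, 1L)
  tgt_key <- intersect(unlist(lapply(apps, function(a) a$reactant_keys)),
                       toy$compounds$key)[1]
  tgt <- toy_compound(toy, tgt_key)
  tr <- mcts_search(eff, tgt, toy$rules,
                    search_config(max_depth = 2,
                                  iterations = n_children + 1L,
                                  exploration_constant = 0, seed = 1))
  expect_gte(length(tr$hits), 1L)
  expect_true(any(vapply(tr$hits, function(h) tr$nodes[[h]]$depth == 1L,
                         logical(1))))
})

test_that("with ample budget the search discovers the exhaustive-BFS compound set", {
  # mono-substrate toys: every reactant is a chain compound, so the
  # tree's node + side keys must equal the BFS-reachable set
  for (sd in c(21L, 22L, 23L)) {
    toy <- local_toy(sd, n_compounds = 9L, branching = 1.6, p_side = 0)
    eff <- toy_compound(toy, toy$effector_key)
    # deepest target: the search never expands past a terminal hit, so no
    # reachable compound may lie strictly behind the target node
    tgt_key <- toy$pairs[[1L]]$target_key
    tgt <- toy_compound(toy, tgt_key)
    tr <- mcts_search(eff, tgt, toy$rules,
                      search_config(max_depth = nrow(toy$compounds),
                                    iterations = 2000, seed = 5))
    seen <- unique(c(
      vapply(tr$nodes, function(n) n$key, character(1)),
      unlist(lapply(tr$nodes, function(n) n$side_keys))
    ))
    expect_setequal(seen, oracle_reachable_keys(toy))
  }
})

test_that("trees serialize to parseable JSON with full node statistics", {
  toy <- local_toy(2)
  pair <- toy$pairs[[1]]
  tr <- mcts_search(toy_compound(toy, pair$effector_key),
                    toy_compound(toy, pair$target_key),
                    toy$rules,
                    search_config(max_depth = 6, iterations = 80, seed = 2))
  js <- tree_as_json(tr)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(length(doc$nodes), length(tr$nodes))
  expect_identical(doc$source, tr$source$key)
  expect_identical(doc$nodes[[1]]$visits, tr$nodes[[1]]$visits)
})
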