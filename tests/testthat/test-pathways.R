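# hand-built tree for scope unit tests (no chemistry kernel involved)
fake_node <- function(key, parent, edge, side = character(0), depth = 0L,
                      terminal = FALSE) {
  list(key = key, smiles = paste0("smi_", key), fp = integer(0),
       parent = parent, edge = edge, side_keys = side, depth = depth,
       visits = 1L, value_sum = 0, children = integer(0), expanded = TRUE,
       terminal = terminal)
}

fake_edge <- function(rule_id, penalty, product, reactants) {
  structure(list(rule_id = rule_id, penalty_score = penalty,
                 product_key = product, product_smiles = paste0("smi_", product),
                 reactant_keys = sort(reactants),
                 reactant_smiles = paste0("smi_", sort(reactants))),
            class = "ps_application")
}

fake_search_tree <- function(nodes, source_key, target_key) {
  mk <- function(key) structure(list(id = key, key = key,
                                     smiles = paste0("smi_", key),
                                     fp = integer(0)),
                                class = "ps_compound")
  structure(
    list(nodes = nodes, root = 1L,
         hits = which(vapply(nodes, function(n) n$terminal, logical(1))),
         source = mk(source_key), target = mk(target_key),
         config = search_config(), iterations_run = 10L, status = "ok"),
    class = "ps_tree"
  )
}

test_that("build_scope transcribes a linear tree and prunes dead branches", {
  # root C <= B <= A(hit), plus a dead branch C <= D
  nodes <- list(
    fake_node("C", NA_integer_, NULL),
    fake_node("B", 1L, fake_edge("r1", 0.3, "C", "B"), depth = 1L),
    fake_node("A", 2L, fake_edge("r2", 0.5, "B", "A"), depth = 2L,
              terminal = TRUE),
    fake_node("D", 1L, fake_edge("r3", 0.9, "C", "D"), depth = 1L)
  )
  nodes[[1]]$children <- c(2L, 4L)
  nodes[[2]]$children <- 3L
  sc <- build_scope(fake_search_tree(nodes, "C", "A"))
  expect_identical(nrow(sc$compounds), 3L)
  expect_length(sc$reactions, 2L)
  expect_false("D" %in% sc$compounds$key)
})

test_that("build_scope merges duplicate compounds reached through distinct branches", {
  # two branches from C reach A through X and Y: A appears twice in the
  # tree but once in the scope
  nodes <- list(
    fake_node("C", NA_integer_, NULL),
    fake_node("X", 1L, fake_edge("r1", 0.2, "C", "X"), depth = 1L),
    fake_node("Y", 1L, fake_edge("r2", 0.4, "C", "Y"), depth = 1L),
    fake_node("A", 2L, fake_edge("r3", 0.3, "X", "A"), depth = 2L,
              terminal = TRUE),
    fake_node("A", 3L, fake_edge("r4", 0.6, "Y", "A"), depth = 2L,
              terminal = TRUE)
  )
  nodes[[1]]$children <- c(2L, 3L)
  nodes[[2]]$children <- 4L
  nodes[[3]]$children <- 5L
  sc <- build_scope(fake_search_tree(nodes, "C", "A"))
  expect_identical(nrow(sc$compounds), 4L) # C, X, Y, A merged once
  expect_length(sc$reactions, 4L)
})

test_that("build_scope on an unconnected pair raises a 'pair not connected' error", {
  nodes <- list(fake_node("C", NA_integer_, NULL))
  expect_error(build_scope(fake_search_tree(nodes, "C", "A")),
               "pair not connected")
})

test_that("pathway enumeration honours the shortest-branch rule", {
  # equal-length diamond: both branches survive
  d <- diamond_run(long_branch = FALSE)
  expect_length(d$pathways, 2L)
  expect_setequal(path_signatures(d$pathways), c("D_XT>D_EX", "D_YT>D_EY"))
  for (p in d$pathways) expect_identical(p$length, 2L)
  # every enumerated compound exists in the scope graph
  for (p in d$pathways) {
    ks <- unique(unlist(lapply(p$steps, function(s)
      c(s$main_key, s$product_key, s$side_keys))))
    expect_true(all(ks %in% d$scope$compounds$key))
  }

  # unequal diamond: only the 2-step branch survives
  d3 <- diamond_run(long_branch = TRUE)
  expect_length(d3$pathways, 1L)
  expect_identical(path_signatures(d3$pathways), "D_XT>D_EX")

  # linear scope: exactly one pathway
  f <- tempfile(fileext = ".csv")
  writeLines(c("rule_id,smarts,diameter,penalty_score",
               "L1,[CH3][CH2][CH1]=[OX1]>>CCCO,16,0.2"), f)
  rs <- load_rules(f)
  tr <- mcts_search(compound("CCC=O"), compound("CCCO"), rs,
                    search_config(max_depth = 2, iterations = 20))
  expect_length(enumerate_pathways(build_scope(tr)), 1L)
})

test_that("the pathway cap truncates with a warning", {
  d <- diamond_run(long_branch = FALSE)
  expect_warning(pw <- enumerate_pathways(d$scope, max_pathways = 1L),
                 "suppressed")
  expect_length(pw, 1L)
})

test_that("pathway chaining holds: consecutive steps share a compound", {
  for (sd in c(2L, 4L)) {
    toy <- local_toy(sd)
    for (pair in toy$pairs) {
      res <- run_engine_pair(toy, pair)
      for (p in res$pathways) {
        expect_identical(p$steps[[1]]$main_key, p$target_key)
        expect_identical(p$steps[[p$length]]$product_key, p$effector_key)
        if (p$length > 1L) {
          for (i in seq_len(p$length - 1L)) {
            expect_identical(p$steps[[i]]$product_key,
                             p$steps[[i + 1L]]$main_key)
          }
        }
      }
    }
  }
})

test_that("global score is the worst step penalty and ranking is a strict total order", {
  p1 <- fake_pathway(list(fake_step("a", 0.2, "T", "M"),
                          fake_step("b", 0.5, "M", "E")), "T", "E")
  expect_identical(p1$global_score, 0.5)

  # flux tie-break: equal scores, precursor flux sums 8 vs 3
  p2 <- fake_pathway(list(fake_step("c", 0.5, "T", "E", sides = "P1")), "T", "E")
  p3 <- fake_pathway(list(fake_step("d", 0.5, "T", "E", sides = "P2")), "T", "E")
  p2$roles <- c(T = "target", E = "effector", P1 = "precursor")
  names(p2$roles)[1:2] <- c("T", "E")
  p3$roles <- c(T = "target", E = "effector", P2 = "precursor")
  names(p3$roles)[1:2] <- c("T", "E")
  flux <- c(P1 = 8.0, P2 = 3.0)
  rk <- rank_pathways(list(p3, p2), flux)
  expect_identical(rk[[1]]$rule_ids, "c") # the 8.0 pathway first

  # brute-force sort oracle on synthetic pathways
  set.seed(99)
  pool <- lapply(1:12, function(i) {
    n <- sample(1:3, 1)
    steps <- lapply(seq_len(n), function(j) {
      fake_step(sprintf("r%02d_%d", i, j), round(runif(1), 3),
                sprintf("c%d_%d", i, j), sprintf("c%d_%d", i, j + 1))
    })
    p <- fake_pathway(steps, steps[[1]]$main_key, steps[[n]]$product_key)
    p$roles <- stats::setNames(
      rep("intermediate", 2), c(p$target_key, p$effector_key))
    p
  })
  ranked <- rank_pathways(pool)
  key_of <- function(p) list(p$global_score, -sum(p$roles == "precursor"),
                             p$length, paste(p$rule_ids, collapse = ">"))
  keys <- lapply(ranked, key_of)
  for (i in seq_len(length(keys) - 1L)) {
    a <- keys[[i]]; b <- keys[[i + 1L]]
    cmp <- (a[[1]] < b[[1]]) ||
      (a[[1]] == b[[1]] && a[[2]] < b[[2]]) ||
      (a[[1]] == b[[1]] && a[[2]] == b[[2]] && a[[3]] < b[[3]]) ||
      (a[[1]] == b[[1]] && a[[2]] == b[[2]] && a[[3]] == b[[3]] &&
         a[[4]] < b[[4]])
    expect_true(cmp)
  }
  # sorting twice yields the identical sequence
  expect_identical(path_signatures(rank_pathways(ranked)),
                   path_signatures(ranked))
  expect_identical(
    vapply(rank_pathways(ranked), function(p) paste(p$rule_ids, collapse = ">"),
           character(1)),
    vapply(ranked, function(p) paste(p$rule_ids, collapse = ">"), character(1)))
})

test_that("classification is a total partition with the specified precedence", {
  # T -r1-> M (+S side) -r2-> E, side compound P in chassis
  p <- fake_pathway(list(
    fake_step("r1", 0.2, "T", "M", sides = c("S", "P")),
    fake_step("r2", 0.4, "M", "E")
  ), "T", "E")
  ch <- chassis_metabolome(c("P", "Q"), "toy", ignore_stereo = FALSE)
  roles <- classify_compounds(p, ch)
  expect_setequal(names(roles), c("T", "E", "M", "S", "P"))
  expect_identical(unname(roles["T"]), "target")
  expect_identical(unname(roles["E"]), "effector")
  expect_identical(unname(roles["M"]), "intermediate")
  expect_identical(unname(roles["P"]), "precursor")  # chassis member
  expect_identical(unname(roles["S"]), "supplement") # consumed, never produced
  # flipping chassis membership flips the role
  ch2 <- chassis_metabolome(c("S"), "toy2", ignore_stereo = FALSE)
  roles2 <- classify_compounds(p, ch2)
  expect_identical(unname(roles2["S"]), "precursor")
  expect_identical(unname(roles2["P"]), "supplement")
  # whitelist admits compounds beyond chassis membership
  roles3 <- classify_compounds(p, ch2, whitelist = "P")
  expect_identical(unname(roles3["P"]), "precursor")
})

test_that("classification partitions every engine pathway across fixture chassis", {
  toy <- local_toy(2)
  ch_all <- chassis_metabolome(toy$chassis_keys, "toy")
  ch_none <- chassis_metabolome("NOSUCHKEY-NOSUCHKEYXX-N", "empty")
  for (pair in toy$pairs) {
    res <- run_engine_pair(toy, pair)
    for (p in res$pathways) {
      for (ch in list(ch_all, ch_none)) {
        roles <- classify_compounds(p, ch)
        all_keys <- unique(c(
          p$target_key, p$effector_key,
          unlist(lapply(p$steps, function(s)
            c(s$main_key, s$product_key, s$side_keys)))))
        expect_setequal(names(roles), all_keys)
        expect_true(all(roles %in% c("target", "effector", "precursor",
                                     "intermediate", "supplement")))
        expect_identical(sum(roles == "target"), 1L)
        expect_identical(sum(roles == "effector"), 1L)
      }
    }
  }
})

test_that("pair_summary reproduces hand-computed totals and averages", {
  mk_entry <- function(prod, eff, n_path, inter = character(0),
                       pre = character(0), supp = character(0)) {
    list(producible = prod, effector = eff,
         pathways = replicate(n_path, {
           roles <- c("target", "effector",
                      rep("intermediate", length(inter)),
                      rep("precursor", length(pre)),
                      rep("supplement", length(supp)))
           names(roles) <- c(paste0("T", prod), paste0("E", eff),
                             inter, pre, supp)
           list(roles = roles)
         }, simplify = FALSE))
  }
  # 2 producibles x 3 effectors, all connected, 1 pathway each
  entries <- list(
    mk_entry("p1", "e1", 1), mk_entry("p1", "e2", 1), mk_entry("p1", "e3", 1),
    mk_entry("p2", "e1", 1), mk_entry("p2", "e2", 1), mk_entry("p2", "e3", 1)
  )
  s <- pair_summary(entries)
  expect_identical(s$overall$Pairs, 6L)
  expect_identical(s$overall$Pathways, 6L)
  expect_identical(s$by_compound["Producible", "Average.no.of.pairs"], 3)
  expect_identical(s$by_compound["Detectable", "Average.no.of.pairs"], 2)

  # shared intermediates count once (distinct-key union)
  entries2 <- list(mk_entry("p1", "e1", 5, inter = c("I1", "I2")))
  s2 <- pair_summary(entries2)
  expect_identical(s2$overall$Intermediates, 2L)
  expect_identical(s2$overall$Pathways, 5L)

  # unconnected pair is excluded from the pair count
  entries3 <- c(entries2, list(list(producible = "p9", effector = "e9",
                                    pathways = list())))
  s3 <- pair_summary(entries3)
  expect_identical(s3$overall$Pairs, 1L)
})
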