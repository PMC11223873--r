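# Shared fixtures. Toy chemistries are memoised per test session: the
# chemistry kernel runs in a subprocess, so re-deriving the same fixture
# in every test file would waste most of the suite's runtime.

.toy_pool <- new.env(parent = emptyenv())

local_toy <- function(seed, n_compounds = 10L, branching = 1.7,
                      p_side = 1 / 3) {
  id <- sprintf("s%d_n%d_b%g_p%g", seed, n_compounds, branching, p_side)
  toy <- get0(id, envir = .toy_pool)
  if (is.null(toy)) {
    toy <- generate_toy_chemistry(seed, n_compounds, branching,
                                  p_side = p_side)
    assign(id, toy, envir = .toy_pool)
  }
  toy
}

toy_compound <- function(toy, key) {
  compound(toy$compounds$smiles[toy$compounds$key == key])
}

# engine run for one toy pair: search -> scope -> enumerate
run_engine_pair <- function(toy, pair, iterations = 600L, seed = 7L) {
  eff <- toy_compound(toy, pair$effector_key)
  tgt <- toy_compound(toy, pair$target_key)
  tree <- mcts_search(eff, tgt, toy$rules,
                      search_config(max_depth = nrow(toy$compounds),
                                    iterations = iterations, seed = seed))
  if (!length(tree$hits)) return(list(tree = tree, pathways = list()))
  list(tree = tree, pathways = enumerate_pathways(build_scope(tree)))
}

path_signatures <- function(pathways_or_ruleid_lists) {
  sort(vapply(pathways_or_ruleid_lists, function(p) {
    ids <- if (inherits(p, "ps_pathway")) p$rule_ids else p
    paste(ids, collapse = ">")
  }, character(1)))
}

# hand-written rule table: 5 usable rules at diameters 2/4/8/16
write_fixture_rules <- function(path) {
  writeLines(c(
    "rule_id,smarts,diameter,penalty_score",
    "R_ald,[CH2:1][OX2H1:2]>>[CH1:1]=[O:2],2,0.2",
    "R_ald_d4,[CH2:1][OX2H1:2]>>[CH1:1]=[O:2],4,0.5",
    "R_acid,[CX3:1](=[OX1:2])[OX2H1]>>[CX3H1:1]=[O:2].[OH2],8,0.4",
    "R_amine,[CH2:1][NH2:2]>>[CH1:1]=[O:2].[NH3],8,0.7",
    "R_est,[CX3:1](=[O:2])[OX2:3][C:4]>>[CX3:1](=[O:2])[OX2H1].[OX2H1:3][C:4],16,0.9"
  ), path)
  path
}

# an explicit diamond chemistry: butanol -> {butanal | butylamine} ->
# butyric acid, both branches two steps; plus a longer third branch for
# the unequal-diamond case
diamond_rules <- function(long_branch = FALSE) {
  rows <- c(
    "rule_id,smarts,diameter,penalty_score",
    # retro: acid <= butanal  /  acid <= butylamine
    "D_EX,[CH3][CH2][CH2][CX3](=[OX1])[OX2H1]>>CCCC=O,16,0.30",
    "D_EY,[CH3][CH2][CH2][CX3](=[OX1])[OX2H1]>>CCCCN,16,0.40",
    # retro: butanal <= butanol  /  butylamine <= butanol
    "D_XT,[CH3][CH2][CH2][CH1]=[OX1]>>CCCCO,16,0.20",
    "D_YT,[CH3][CH2][CH2][CH2][NH2]>>CCCCO,16,0.25"
  )
  if (long_branch) {
    # make the amine branch 3 steps: amine <= nitrile-ish detour via
    # butane (alkane), butane <= butanol
    rows <- c(rows[1:4],
      "D_YW,[CH3][CH2][CH2][CH2][NH2]>>CCCC,16,0.25",
      "D_WT,[CH3][CH2][CH2][CH3]>>CCCCO,16,0.15"
    )
  }
  f <- tempfile(fileext = ".csv")
  writeLines(rows, f)
  load_rules(f, 0, 16)
}

.diamond_pool <- new.env(parent = emptyenv())

diamond_run <- function(long_branch = FALSE, max_pathways = 1000L) {
  id <- sprintf("lb%d_mp%d", long_branch, max_pathways)
  hit <- get0(id, envir = .diamond_pool)
  if (!is.null(hit)) return(hit)
  res <- diamond_run_uncached(long_branch, max_pathways)
  assign(id, res, envir = .diamond_pool)
  res
}

diamond_run_uncached <- function(long_branch = FALSE, max_pathways = 1000L) {
  rules <- diamond_rules(long_branch)
  acid <- compound("CCCC(=O)O")
  butanol <- compound("CCCCO")
  tree <- mcts_search(acid, butanol, rules,
                      search_config(max_depth = 4L, iterations = 200L))
  scope <- build_scope(tree)
  list(rules = rules, tree = tree, scope = scope,
       pathways = enumerate_pathways(scope, max_pathways))
}

# build a synthetic classified pathway object without touching the
# chemistry kernel (for ranking/classification/summary unit tests)
fake_step <- function(rule_id, penalty, main, product, sides = character(0)) {
  list(uid = paste0(rule_id, "|", product, "|", main),
       rule_id = rule_id, penalty_score = penalty,
       product_key = product, product_smiles = paste0("smi_", product),
       main_key = main, main_smiles = paste0("smi_", main),
       side_keys = sides, side_smiles = paste0("smi_", sides))
}

fake_pathway <- function(steps, target, effector) {
  structure(
    list(steps = steps, length = length(steps),
         global_score = if (length(steps)) {
           max(vapply(steps, function(s) s$penalty_score, numeric(1)))
         } else 0,
         target_key = target, effector_key = effector,
         rule_ids = vapply(steps, function(s) s$rule_id, character(1)),
         roles = NULL),
    class = "ps_pathway"
  )
}
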