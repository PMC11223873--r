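# Retro reaction rules: the RetroRules-style rule table and the engine
# that applies a rule to a compound to predict forward-direction
# substrates (one backward expansion step).
#
# Conventions: rules are written in the retro direction (one product
# pattern on the left, one or more reactant templates on the right);
# diameter is the even atom-vicinity radius around the reaction centre
# (larger = more specific rule); penalty_score in [0,1] is the rule
# quality penalty used for ranking (lower = better rule).

RETRO_DIAMETERS <- seq(0L, 16L, by = 2L)

# Accepted column spellings: a minimal dialect plus the RetroRules CSV export.
.rule_col_alias <- list(
  rule_id = c("rule_id", "# Rule_ID", "Rule_ID", "Rule ID", "id"),
  smarts = c("smarts", "Rule_SMARTS", "Rule SMARTS", "reaction_smarts", "SMARTS"),
  diameter = c("diameter", "Diameter"),
  penalty_score = c("penalty_score", "Score", "score", "Penalty", "penalty"),
  source_reaction_id = c("source_reaction_id", "Reaction_ID", "Reaction ID", "reaction_id")
)

ps_match_col <- function(nms, aliases) {
  hit <- which(nms %in% aliases)
  if (length(hit)) hit[1] else NA_integer_
}

ps_ruleset <- function(df) {
  dt <- data.table::as.data.table(df)
  need <- c("rule_id", "smarts", "diameter", "penalty_score")
  stopifnot(all(need %in% names(dt)))
  if (!"source_reaction_id" %in% names(dt)) dt$source_reaction_id <- NA_character_
  dt$rule_id <- as.character(dt$rule_id)
  dt$smarts <- as.character(dt$smarts)
  dt$diameter <- as.integer(dt$diameter)
  dt$penalty_score <- as.numeric(dt$penalty_score)
  data.table::setkeyv(dt, "rule_id")
  # content digest identifies the ruleset in the application cache
  tmp <- tempfile()
  writeLines(paste(dt$rule_id, dt$smarts, sep = "\t"), tmp)
  attr(dt, "set_id") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(dt) <- c("ps_ruleset", class(dt))
  dt
}

#' Load retro reaction rules from a delimited table
#'
#' Reads a RetroRules-style CSV/TSV (columns for rule id, reaction SMARTS,
#' diameter and score; extra columns ignored; a minimal dialect
#' `rule_id,smarts,diameter,penalty_score` is also accepted), validates
#' every SMARTS in the chemistry kernel, and keeps only rules whose
#' diameter lies in `[min_diameter, max_diameter]`. Rules must have
#' exactly one left-hand-side (product) template; malformed rows are
#' skipped with a warning and counted in `attr(,"n_skipped")`.
#'
#' @param path delimited rule table.
#' @param min_diameter,max_diameter inclusive diameter bounds
#'   (RetroRules uses even diameters 0-16; default keeps 2-16).
#' @return a `ps_ruleset` (a keyed `data.table` with columns `rule_id`,
#'   `smarts`, `diameter`, `penalty_score`, `source_reaction_id`).
#' @export
load_rules <- function(path, min_diameter = 2L, max_diameter = 16L) {
  if (!file.exists(path)) stop(sprintf("rule file not found: %s", path), call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character")
  nms <- names(raw)
  idx <- lapply(.rule_col_alias, ps_match_col, nms = nms)
  mandatory <- c("rule_id", "smarts", "diameter", "penalty_score")
  missing <- mandatory[vapply(idx[mandatory], is.na, logical(1))]
  if (length(missing)) {
    stop(sprintf("rule table %s lacks mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- data.table::data.table(
    rule_id = raw[[idx$rule_id]],
    smarts = raw[[idx$smarts]],
    diameter = suppressWarnings(as.integer(raw[[idx$diameter]])),
    penalty_score = suppressWarnings(as.numeric(raw[[idx$penalty_score]])),
    source_reaction_id = if (!is.na(idx$source_reaction_id)) {
      raw[[idx$source_reaction_id]]
    } else NA_character_
  )
  n0 <- nrow(df)
  bad_row <- is.na(df$diameter) | is.na(df$penalty_score) |
    !nzchar(df$rule_id) | !nzchar(df$smarts) |
    !(df$diameter %in% RETRO_DIAMETERS)
  df <- df[!bad_row]
  # kernel-side SMARTS validation, one batch
  n_badsmarts <- 0L
  if (nrow(df)) {
    chk <- ps_chem_call("check_rules", list(
      rules = lapply(seq_len(nrow(df)), function(i) {
        list(rule_id = df$rule_id[i], smarts = df$smarts[i])
      })
    ))
    ok <- vapply(chk$rules, function(r) isTRUE(r$ok) && r$n_lhs == 1L, logical(1))
    n_badsmarts <- sum(!ok)
    df <- df[ok]
  }
  n_skipped <- sum(bad_row) + n_badsmarts
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed rule row(s) in %s", n_skipped, path),
            call. = FALSE)
  }
  df <- df[df$diameter >= min_diameter & df$diameter <= max_diameter]
  if (nrow(df) == 0L) {
    stop(sprintf("no usable rules in %s for diameter range [%d, %d]",
                 path, min_diameter, max_diameter), call. = FALSE)
  }
  rs <- ps_ruleset(df)
  attr(rs, "n_skipped") <- n_skipped
  rs
}

# A RuleApplication: one distinct backward step predicted for `product`.
ps_application <- function(rule_id, penalty_score, product_key, product_smiles,
                           reactant_keys, reactant_smiles) {
  ord <- order(reactant_keys, method = "radix")
  structure(
    list(
      rule_id = rule_id,
      penalty_score = penalty_score,
      product_key = product_key,
      product_smiles = product_smiles,
      reactant_keys = reactant_keys[ord],
      reactant_smiles = reactant_smiles[ord]
    ),
    class = "ps_application"
  )
}

#' @export
print.ps_application <- function(x, ...) {
  cat(sprintf("<step %s: %s <= %s (penalty %.3f)>\n", x$rule_id,
              x$product_smiles, paste(x$reactant_smiles, collapse = " + "),
              x$penalty_score))
  invisible(x)
}

# Convert the kernel's application records into ps_application objects,
# resolving reactant SMILES to canonical keys through the cache.
ps_apps_from_kernel <- function(apps, rules) {
  pen <- stats::setNames(rules$penalty_score, rules$rule_id)
  out <- list()
  for (a in apps) {
    rs <- unlist(a$reactants)
    recs <- lapply(rs, ps_smiles_record)
    if (any(vapply(recs, is.null, logical(1)))) next
    keys <- vapply(recs, function(r) r$key, character(1))
    # collapse duplicate reactants inside one set (set semantics on keys)
    dup <- duplicated(keys)
    prod_rec <- ps_smiles_record(a$product)
    out[[length(out) + 1L]] <- ps_application(
      rule_id = a$rule_id,
      penalty_score = unname(pen[a$rule_id]),
      product_key = prod_rec$key,
      product_smiles = prod_rec$smiles,
      reactant_keys = keys[!dup],
      reactant_smiles = vapply(recs, function(r) r$smiles, character(1))[!dup]
    )
  }
  out
}

#' Apply one retro rule to one compound
#'
#' Matches the rule's product pattern against the compound and returns
#' one `ps_application` per distinct predicted reactant set (symmetric
#' matches yielding the same set are collapsed). The empty list means the
#' pattern does not match. Applications whose fragments fail chemical
#' sanitisation are dropped by the kernel, not raised.
#'
#' @param rule a single-row `ps_ruleset` (or any list with `rule_id`,
#'   `smarts`, `penalty_score`).
#' @param compound a [compound()].
#' @return list of `ps_application`, ordered by reactant canonical keys.
#' @export
apply_rule <- function(rule, compound) {
  stopifnot(inherits(compound, "ps_compound"))
  if (inherits(rule, "ps_ruleset")) {
    stopifnot(nrow(rule) == 1L)
    rule <- as.list(rule[1, ])
  }
  rs <- ps_ruleset(data.table::data.table(
    rule_id = rule$rule_id, smarts = rule$smarts,
    diameter = if (!is.null(rule$diameter)) rule$diameter else 2L,
    penalty_score = rule$penalty_score
  ))
  apps <- ps_expand_compound(compound, rs)
  apps[vapply(apps, function(a) a$rule_id == rule$rule_id, logical(1))]
}

# All applications of `rules` on one compound, memoised per ruleset.
ps_expand_compound <- function(compound, rules) {
  set_id <- attr(rules, "set_id")
  hit <- ps_apps_cached(set_id, compound$key)
  if (!is.null(hit)) return(hit)
  res <- ps_chem_call("apply", list(
    rules = lapply(seq_len(nrow(rules)), function(i) {
      list(rule_id = rules$rule_id[i], smarts = rules$smarts[i])
    }),
    compounds = list(compound$smiles),
    fp_radius = fp_radius(), fp_bits = fp_bits()
  ))
  for (info in res$compounds) {
    rec <- list(smiles = info$smiles, inchi = info$inchi, key = info$inchikey,
                fp = as.integer(unlist(info$fp)))
    assign(info$smiles, rec, envir = .ps_cache$smiles)
  }
  apps <- ps_apps_from_kernel(res$applications, rules)
  apps <- ps_order_apps(apps)
  ps_apps_store(set_id, compound$key, apps)
  apps
}

ps_order_apps <- function(apps) {
  if (!length(apps)) return(apps)
  key <- vapply(apps, function(a) {
    paste(paste(a$reactant_keys, collapse = "."), a$rule_id, sep = "|")
  }, character(1))
  apps[order(key, method = "radix")]
}

# Prefetch: run a bounded breadth-first backward expansion in the kernel
# (one subprocess launch) and memoise per-compound application lists, so
# the subsequent tree search never has to call the kernel per node.
ps_prefetch_expansion <- function(compound, rules, depth, max_compounds = 5000L) {
  set_id <- attr(rules, "set_id")
  res <- ps_chem_call("expand", list(
    rules = lapply(seq_len(nrow(rules)), function(i) {
      list(rule_id = rules$rule_id[i], smarts = rules$smarts[i])
    }),
    seeds = list(compound$smiles),
    depth = depth, max_compounds = max_compounds,
    fp_radius = fp_radius(), fp_bits = fp_bits()
  ))
  for (info in res$compounds) {
    rec <- list(smiles = info$smiles, inchi = info$inchi, key = info$inchikey,
                fp = as.integer(unlist(info$fp)))
    assign(info$smiles, rec, envir = .ps_cache$smiles)
    assign(info$input, rec, envir = .ps_cache$structs)
  }
  apps <- ps_apps_from_kernel(res$applications, rules)
  by_prod <- split(apps, vapply(apps, function(a) a$product_key, character(1)))
  expanded_keys <- vapply(unlist(res$expanded), function(s) {
    ps_smiles_record(s)$key
  }, character(1))
  # every compound the kernel expanded has a complete application list
  # (truncation only stops new molecules from joining the frontier)
  for (k in expanded_keys) {
    ps_apps_store(set_id, k, ps_order_apps(by_prod[[k]] %||% list()))
  }
  invisible(list(n_compounds = length(res$compounds),
                 truncated = isTRUE(res$truncated)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One backward expansion step over a whole ruleset
#'
#' Applies every rule to `compound`, concatenates the applications and
#' de-duplicates them on the predicted reactant set: when several rules
#' (e.g. the same parent reaction encoded at different diameters) predict
#' an identical reactant set, one application is kept, carrying the
#' lowest `penalty_score` (ties broken by lexicographic `rule_id`).
#' Output order is deterministic: sorted on reactant canonical keys.
#'
#' @param compound a [compound()].
#' @param rules a `ps_ruleset` from [load_rules()].
#' @return list of `ps_application`.
#' @export
expand_once <- function(compound, rules) {
  stopifnot(inherits(rules, "ps_ruleset"), nrow(rules) > 0L)
  # de-dup on reactant set, keep lowest penalty then lexicographic rule_id
  ps_dedup_apps(ps_expand_compound(compound, rules))
}
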