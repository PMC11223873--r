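# Interchange writers: SBML pathway documents, Cytoscape-style network
# JSON, and enzyme-selection query links. All exports are deterministic
# byte streams for a given input.

ps_species_id <- function(key) paste0("M_", gsub("-", "_", key))

PS_ANN_NS <- "https://pathsense.invalid/annotation"

# key -> (smiles, inchi, role) over a classified pathway
ps_pathway_species <- function(pathway) {
  smap <- new.env(parent = emptyenv())
  note <- function(key, smiles) {
    if (is.null(get0(key, envir = smap))) assign(key, smiles, envir = smap)
  }
  for (s in pathway$steps) {
    note(s$main_key, s$main_smiles)
    note(s$product_key, s$product_smiles)
    for (j in seq_along(s$side_keys)) note(s$side_keys[j], s$side_smiles[j])
  }
  keys <- sort(names(pathway$roles), method = "radix")
  data.frame(
    key = keys,
    smiles = vapply(keys, function(k) get0(k, envir = smap) %||% NA_character_,
                    character(1)),
    role = unname(pathway$roles[keys]),
    stringsAsFactors = FALSE
  )
}

#' Export a classified pathway as SBML Level 3 Version 1
#'
#' One species per pathway compound (with its role, canonical key and
#' InChI recorded in a namespaced annotation) and one irreversible
#' reaction per step, reactants and product linked in the forward
#' production direction. The chassis id is recorded on the model.
#'
#' @param pathway a classified `ps_pathway` (see [classify_pathway()]).
#' @param chassis the `ps_chassis` the classification was made against.
#' @param path output file.
#' @return invisibly `path`.
#' @export
export_sbml <- function(pathway, chassis, path) {
  stopifnot(inherits(pathway, "ps_pathway"))
  if (is.null(pathway$roles)) {
    stop("pathway is not classified; run classify_pathway() first",
         call. = FALSE)
  }
  sp <- ps_pathway_species(pathway)
  # one batch fetch so the per-species InChI lookups below hit the cache
  ps_canon_batch(sp$smiles[!is.na(sp$smiles)])
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model",
    id = paste0("detectable_pathway_", substr(pathway$target_key, 1, 14)),
    name = sprintf("detectable pathway %s to %s (chassis %s)",
                   pathway$target_key, pathway$effector_key,
                   chassis$chassis_id))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(sp))) {
    rec <- if (!is.na(sp$smiles[i])) ps_smiles_record(sp$smiles[i]) else NULL
    s <- xml2::xml_add_child(los, "species",
      id = ps_species_id(sp$key[i]),
      name = if (!is.na(sp$smiles[i])) sp$smiles[i] else sp$key[i],
      compartment = "c", hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    ann <- xml2::xml_add_child(s, "annotation")
    meta <- xml2::xml_add_child(ann, "compoundInfo", xmlns = PS_ANN_NS)
    xml2::xml_add_child(meta, "role", sp$role[i])
    xml2::xml_add_child(meta, "key", sp$key[i])
    if (!is.null(rec) && !is.null(rec$inchi)) {
      xml2::xml_add_child(meta, "inchi", rec$inchi)
    }
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_along(pathway$steps)) {
    st <- pathway$steps[[i]]
    r <- xml2::xml_add_child(lor, "reaction",
      id = sprintf("R_step%03d", i), name = st$rule_id,
      reversible = "false", fast = "false")
    ann <- xml2::xml_add_child(r, "annotation")
    meta <- xml2::xml_add_child(ann, "reactionInfo", xmlns = PS_ANN_NS)
    xml2::xml_add_child(meta, "ruleId", st$rule_id)
    xml2::xml_add_child(meta, "penaltyScore",
                        format(st$penalty_score, digits = 15))
    lre <- xml2::xml_add_child(r, "listOfReactants")
    for (k in c(st$main_key, st$side_keys)) {
      xml2::xml_add_child(lre, "speciesReference",
        species = ps_species_id(k), stoichiometry = "1", constant = "true")
    }
    lpr <- xml2::xml_add_child(r, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference",
      species = ps_species_id(st$product_key), stoichiometry = "1",
      constant = "true")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back an exported SBML pathway
#'
#' Recovers the species (with role, key, InChI annotations) and the
#' reactions (with reactant/product species) of a document written by
#' [export_sbml()]; used for round-trip checks.
#'
#' @param path SBML file.
#' @return list with `species` (`data.frame`: `id`, `key`, `role`,
#'   `inchi`) and `reactions` (list with `id`, `rule_id`, `reactants`,
#'   `products` species ids).
#' @export
read_sbml_pathway <- function(path) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  species <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    key = vapply(sp, function(s) {
      xml2::xml_text(xml2::xml_find_first(s, ".//*[local-name()='key']"))
    }, character(1)),
    role = vapply(sp, function(s) {
      xml2::xml_text(xml2::xml_find_first(s, ".//*[local-name()='role']"))
    }, character(1)),
    inchi = vapply(sp, function(s) {
      xml2::xml_text(xml2::xml_find_first(s, ".//*[local-name()='inchi']"))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rx <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  reactions <- lapply(rx, function(r) {
    list(
      id = xml2::xml_attr(r, "id"),
      rule_id = xml2::xml_text(
        xml2::xml_find_first(r, ".//*[local-name()='ruleId']")),
      reactants = xml2::xml_attr(xml2::xml_find_all(
        r, ".//*[local-name()='listOfReactants']/*"), "species"),
      products = xml2::xml_attr(xml2::xml_find_all(
        r, ".//*[local-name()='listOfProducts']/*"), "species")
    )
  })
  list(species = species, reactions = reactions)
}

#' Validate an SBML file
#'
#' Uses libsbml (through the python helper) when available for strict
#' schema and consistency checking; otherwise falls back to structural
#' checks (well-formed XML, sbml/model elements, resolvable species
#' references).
#'
#' @param path SBML file.
#' @return list with `valid` (logical), `n_errors`, `checker`
#'   (`"libsbml"` or `"structural"`).
#' @export
validate_sbml <- function(path) {
  res <- tryCatch(ps_chem_call("validate_sbml", list(path = normalizePath(path))),
                  error = function(e) list(available = FALSE))
  if (isTRUE(res$available)) {
    return(list(valid = res$n_errors == 0L, n_errors = res$n_errors,
                checker = "libsbml",
                messages = unlist(res$messages) %||% character(0)))
  }
  ok <- tryCatch({
    doc <- xml2::read_xml(path)
    root_ok <- xml2::xml_name(doc) == "sbml"
    ids <- xml2::xml_attr(
      xml2::xml_find_all(doc, "//*[local-name()='species']"), "id")
    refs <- xml2::xml_attr(
      xml2::xml_find_all(doc, "//*[local-name()='speciesReference']"), "species")
    root_ok && all(refs %in% ids)
  }, error = function(e) FALSE)
  list(valid = ok, n_errors = as.integer(!ok), checker = "structural",
       messages = character(0))
}

#' Export a scope or pathway as Cytoscape-style network JSON
#'
#' Standard `elements` structure: compound and reaction nodes (`data`
#' with `id`, `label`, `type`, plus `role` for classified pathway
#' compounds and `score` for reactions) and directed edges
#' substrate -> reaction -> product carrying the `rule_id`. The node
#' count equals the compound count plus the reaction count of the input.
#'
#' @param x a `ps_scope`, a `ps_pathway`, or a list of pathways (an
#'   empty list gives valid JSON with empty elements).
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
export_network_json <- function(x, path = NULL) {
  nodes <- list()
  edges <- list()
  add_node <- function(id, label, type, role = NULL, score = NULL) {
    d <- list(id = id, label = label, type = type)
    if (!is.null(role)) d$role <- role
    if (!is.null(score)) d$score <- score
    nodes[[id]] <<- list(data = d)
  }
  add_edge <- function(src, tgt, rule_id) {
    eid <- paste0("e", length(edges) + 1L)
    edges[[eid]] <<- list(data = list(
      id = eid, source = src, target = tgt, rule_id = rule_id))
  }
  add_steps <- function(steps, roles = NULL) {
    for (s in steps) {
      rid <- paste0("rx_", substr(s$uid %||% s$rule_id, 1, 60))
      add_node(rid, s$rule_id, "reaction", score = s$penalty_score)
      ks <- c(s$main_key, s$side_keys)
      sm <- c(s$main_smiles, s$side_smiles)
      for (j in seq_along(ks)) {
        add_node(ks[j], sm[j], "compound",
                 role = if (!is.null(roles)) unname(roles[ks[j]]) else NULL)
        add_edge(ks[j], rid, s$rule_id)
      }
      add_node(s$product_key, s$product_smiles, "compound",
               role = if (!is.null(roles)) unname(roles[s$product_key]) else NULL)
      add_edge(rid, s$product_key, s$rule_id)
    }
  }
  if (inherits(x, "ps_scope")) {
    for (i in seq_len(nrow(x$compounds))) {
      add_node(x$compounds$key[i], x$compounds$smiles[i], "compound")
    }
    add_steps(x$reactions)
  } else if (inherits(x, "ps_pathway")) {
    add_steps(x$steps, roles = x$roles)
  } else if (is.list(x)) {
    for (p in x) {
      stopifnot(inherits(p, "ps_pathway"))
      add_steps(p$steps, roles = p$roles)
    }
  } else {
    stop("cannot export object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  doc <- list(elements = list(
    nodes = if (length(nodes)) {
      unname(nodes[sort(names(nodes), method = "radix")])
    } else list(),
    edges = unname(edges)
  ))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Enzyme-selection query links for a pathway
#'
#' One URL per step, embedding the percent-encoded forward reaction
#' (reactant SMILES joined by `.`, then `>>`, then the product SMILES)
#' for an external enzyme-selection service. No network call is made.
#'
#' @param pathway a `ps_pathway`.
#' @param base_url service endpoint, e.g.
#'   `"https://selenzyme.example.org/query"`.
#' @return character vector of URLs, one per step.
#' @export
enzyme_query_links <- function(pathway, base_url) {
  stopifnot(inherits(pathway, "ps_pathway"))
  if (!is.character(base_url) || length(base_url) != 1L || !nzchar(base_url)) {
    stop("base_url must be a non-empty string", call. = FALSE)
  }
  vapply(pathway$steps, function(s) {
    rxn <- paste0(paste(c(s$main_smiles, s$side_smiles), collapse = "."),
                  ">>", s$product_smiles)
    paste0(base_url, if (grepl("\\?", base_url)) "&" else "?",
           "rxn=", utils::URLencode(rxn, reserved = TRUE))
  }, character(1))
}
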