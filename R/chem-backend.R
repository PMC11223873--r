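# Batched bridge to the RDKit helper process (inst/python/chemtool.py).
#
# All chemistry (parsing, canonical identity, fingerprints, SMARTS rule
# application) is computed by RDKit in a short-lived python subprocess.
# Calls are batched and results memoised in a package-level cache, so a
# whole test session typically needs only a handful of process launches.

.ps_cache <- new.env(parent = emptyenv())

.ps_cache_reset <- function() {
  .ps_cache$structs <- new.env(parent = emptyenv()) # input string -> record
  .ps_cache$apps <- new.env(parent = emptyenv())    # "<setid>|<key>" -> app list
  .ps_cache$smiles <- new.env(parent = emptyenv())  # canonical smiles -> record
}
.ps_cache_reset()

ps_python <- function() {
  p <- getOption("pathsense.python", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    if (nzchar(Sys.which(cand))) return(cand)
  }
  stop("no python interpreter found on PATH; set options(pathsense.python=)",
       call. = FALSE)
}

ps_chemtool_path <- function() {
  p <- system.file("python", "chemtool.py", package = "pathsense")
  if (!nzchar(p)) {
    # during development (pkgload) system.file resolves differently
    p <- file.path("inst", "python", "chemtool.py")
  }
  if (!file.exists(p)) stop("chemtool.py helper not found", call. = FALSE)
  normalizePath(p)
}

#' Low-level call into the chemistry kernel
#'
#' Serialises `payload` to JSON, runs one batch op in the RDKit helper
#' process, and parses the JSON response. Exposed mainly for debugging;
#' user code should go through [compound()], [apply_rule()] etc.
#'
#' @param op one of `"canon"`, `"check_rules"`, `"apply"`, `"expand"`,
#'   `"validate_sbml"`.
#' @param payload named list, converted with `jsonlite::toJSON`.
#' @return parsed response list.
#' @keywords internal
#' @export
ps_chem_call <- function(op, payload) {
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA, null = "null")
  err <- tempfile(fileext = ".log")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(system2(
    ps_python(), c(ps_chemtool_path(), op, req, resp),
    stdout = FALSE, stderr = err
  ))
  if (!identical(status, 0L) || !file.exists(resp)) {
    msg <- if (file.exists(err)) paste(readLines(err, warn = FALSE), collapse = "\n") else ""
    stop(sprintf("chemistry kernel failed (op=%s, status=%s): %s", op, status, msg),
         call. = FALSE)
  }
  jsonlite::read_json(resp, simplifyVector = FALSE)
}

fp_bits <- function() getOption("pathsense.fp_bits", 2048L)
fp_radius <- function() getOption("pathsense.fp_radius", 2L)

# Fetch (and cache) canonical records for a vector of structure strings.
# Returns a list parallel to `structures`; failed parses are NULL entries
# and their error strings are kept in attr(,"errors").
ps_canon_batch <- function(structures) {
  structures <- as.character(structures)
  out <- vector("list", length(structures))
  errors <- character(0)
  miss <- character(0)
  for (s in unique(structures)) {
    if (is.null(get0(s, envir = .ps_cache$structs))) miss <- c(miss, s)
  }
  if (length(miss)) {
    res <- ps_chem_call("canon", list(
      items = as.list(miss), fp_radius = fp_radius(), fp_bits = fp_bits()
    ))
    for (item in res$items) {
      rec <- if (isTRUE(item$ok)) {
        list(
          smiles = item$smiles, inchi = item$inchi, key = item$inchikey,
          fp = as.integer(unlist(item$fp))
        )
      } else {
        structure(list(error = item$error), failed = TRUE)
      }
      assign(item$input, rec, envir = .ps_cache$structs)
      if (isTRUE(item$ok)) assign(item$smiles, rec, envir = .ps_cache$smiles)
    }
  }
  for (i in seq_along(structures)) {
    rec <- get0(structures[i], envir = .ps_cache$structs)
    if (is.null(rec) || isTRUE(attr(rec, "failed"))) {
      errors <- c(errors, sprintf(
        "cannot parse structure '%s'%s", structures[i],
        if (!is.null(rec$error)) paste0(" (", rec$error, ")") else ""
      ))
      out[i] <- list(NULL)
    } else {
      out[[i]] <- rec
    }
  }
  attr(out, "errors") <- errors
  out
}

# record for an already-canonical SMILES known to the cache (e.g. produced
# by a rule application); falls back to a kernel call if unseen.
ps_smiles_record <- function(smiles) {
  rec <- get0(smiles, envir = .ps_cache$smiles)
  if (!is.null(rec)) return(rec)
  ps_canon_batch(smiles)[[1]]
}

ps_app_cache_key <- function(set_id, key) paste0(set_id, "|", key)

ps_apps_cached <- function(set_id, key) {
  get0(ps_app_cache_key(set_id, key), envir = .ps_cache$apps)
}

ps_apps_store <- function(set_id, key, apps) {
  assign(ps_app_cache_key(set_id, key), apps, envir = .ps_cache$apps)
}

#' Clear the chemistry cache
#'
#' Drops all memoised canonicalization, fingerprint and rule-application
#' results. Mostly useful in tests or after changing fingerprint options.
#' @return invisibly `NULL`.
#' @export
ps_clear_cache <- function() {
  .ps_cache_reset()
  invisible(NULL)
}
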