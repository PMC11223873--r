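# Chemical identity primitives: compounds, canonical keys, fingerprints,
# Tanimoto similarity. Everything downstream (rule application, search,
# classification) compares molecules through the canonical key built here.

#' Construct a compound
#'
#' Parses a SMILES or InChI string, canonicalizes it, and attaches the
#' canonical key (InChIKey) and a Morgan-style binary fingerprint (stored
#' as the sorted indices of its set bits). Construction fails on an
#' unparsable structure: a `ps_compound` never wraps an invalid molecule.
#'
#' Fingerprint family and size are session-wide options
#' (`pathsense.fp_radius`, default 2; `pathsense.fp_bits`, default 2048).
#'
#' @param structure SMILES (e.g. `"CCO"`) or InChI (`"InChI=..."`) string.
#' @param id optional opaque identifier; defaults to the canonical key.
#' @return object of class `ps_compound` with fields `id`, `structure`
#'   (input as given), `smiles` (canonical), `inchi`, `key` (InChIKey),
#'   `fp` (integer vector of on-bit indices).
#' @examples \dontrun{
#' ethanol <- compound("OCC")
#' ethanol$key == compound("CCO")$key   # TRUE: same molecule
#' }
#' @export
compound <- function(structure, id = NULL) {
  stopifnot(is.character(structure), length(structure) == 1L)
  rec <- ps_canon_batch(structure)[[1]]
  if (is.null(rec)) {
    stop(attr(ps_canon_batch(structure), "errors")[1], call. = FALSE)
  }
  ps_compound_from_record(rec, structure = structure, id = id)
}

ps_compound_from_record <- function(rec, structure = rec$smiles, id = NULL) {
  structure(
    list(
      id = if (is.null(id)) rec$key else as.character(id),
      structure = structure,
      smiles = rec$smiles,
      inchi = rec$inchi,
      key = rec$key,
      fp = rec$fp
    ),
    class = "ps_compound"
  )
}

#' Construct many compounds at once
#'
#' Vectorised, batched version of [compound()]: one kernel call for the
#' whole table. Unparsable rows are dropped with a warning (their count
#' and offending strings are attached as attributes).
#'
#' @param structures character vector of SMILES/InChI.
#' @param ids optional identifiers, recycled against `structures`.
#' @return list of `ps_compound`; attributes `n_skipped`, `errors`.
#' @export
compounds <- function(structures, ids = NULL) {
  recs <- ps_canon_batch(structures)
  errs <- attr(recs, "errors")
  keep <- !vapply(recs, is.null, logical(1))
  if (any(!keep)) {
    warning(sprintf("skipped %d unparsable structure(s)", sum(!keep)), call. = FALSE)
  }
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(recs)) {
    if (!keep[i]) next
    j <- j + 1L
    out[[j]] <- ps_compound_from_record(
      recs[[i]], structure = structures[i],
      id = if (!is.null(ids)) ids[[i]] else NULL
    )
  }
  attr(out, "n_skipped") <- sum(!keep)
  attr(out, "errors") <- errs
  out
}

#' @export
print.ps_compound <- function(x, ...) {
  cat(sprintf("<compound %s: %s (%s), %d fp bits>\n",
              x$id, x$smiles, x$key, length(x$fp)))
  invisible(x)
}

#' Canonical structure key
#'
#' Maps a SMILES or InChI string to the canonical key used for compound
#' equality throughout the package (an InChIKey). Deterministic and
#' idempotent: two renderings of the same molecule give the same key, and
#' canonicalizing a canonical form returns itself.
#'
#' @param structure SMILES or InChI string (vectorised).
#' @return character vector of canonical keys.
#' @export
canonicalize <- function(structure) {
  recs <- ps_canon_batch(structure)
  errs <- attr(recs, "errors")
  if (length(errs)) stop(errs[1], call. = FALSE)
  vapply(recs, function(r) r$key, character(1))
}

#' Tanimoto similarity between two compounds
#'
#' Set-overlap similarity |bits(a) n bits(b)| / |bits(a) u bits(b)| of the
#' two Morgan fingerprints; this is the score that guides the tree search
#' toward the target molecule. Identical canonical keys give 1 exactly.
#' Two all-zero fingerprints (degenerate toy molecules) are defined as
#' similarity 1: identical empty bit sets, avoiding 0/0.
#'
#' @param a,b `ps_compound` objects.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "ps_compound"), inherits(b, "ps_compound"))
  if (identical(a$key, b$key)) return(1.0)
  tanimoto_bits(a$fp, b$fp)
}

#' Tanimoto similarity between two bit sets
#'
#' The fingerprint-level primitive behind [tanimoto()]: takes the set-bit
#' index vectors directly. Both-empty is defined as 1.
#'
#' @param a,b integer vectors of set-bit indices.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_bits <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) return(1.0)
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

# Stereochemistry-insensitive skeleton of an InChIKey (first block).
# Chassis metabolite lists are inconsistent about stereo annotation, so
# metabolome membership can optionally compare on this.
ps_key_skeleton <- function(key) {
  ifelse(grepl("^[A-Z]{14}-", key), substr(key, 1L, 14L), key)
}
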