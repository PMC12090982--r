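# Canonical residue display order used by format_composition(); anything not
# listed is appended alphabetically.
.canonical_order <- c("Hex", "HexNAc", "dHex", "NeuAc")

#' Construct a glycan composition
#'
#' A composition records how many residues of each monosaccharide kind one
#' released N-glycan carries (e.g. Hex:5 HexNAc:4 dHex:1). It says nothing
#' about linkage or branching: many isomeric structures share one composition.
#'
#' @param counts Named numeric vector of non-negative integer residue counts.
#'   Zero counts are dropped; at least one count must be positive.
#' @param source_text Optional annotation string the composition was parsed
#'   from, kept for error messages and provenance.
#'
#' @return An object of class `glycan_composition`: a named integer vector.
#' @examples
#' glycan_composition(c(Hex = 5, HexNAc = 4, dHex = 1))
#' @export
glycan_composition <- function(counts, source_text = NULL) {
  if (length(counts) == 0 || is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("composition counts must be a named vector")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    stop("empty composition: at least one residue count must be positive",
         if (!is.null(source_text)) paste0(" (in \"", source_text, "\")") else "")
  if (anyDuplicated(names(counts)))
    stop("duplicate residue symbol in composition: ",
         paste(unique(names(counts)[duplicated(names(counts))]), collapse = ", "))
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, source_text = source_text, class = "glycan_composition")
}

#' Parse a glycan composition annotation string
#'
#' Accepts both the delimited spelling `"Hex:5 HexNAc:4 dHex:1"` (colons
#' optional, whitespace/comma/semicolon separators) and the concatenated
#' spelling `"Hex5HexNAc4dHex1"`; both appear in METASPACE-style annotation
#' exports. Recognition of known residue symbols is case-insensitive and the
#' canonical casing is restored; unknown symbols are preserved verbatim so
#' downstream classification can treat them conservatively.
#'
#' @param text A single non-empty annotation string.
#' @param registry A [glycan_registry()] supplying the known residue symbols
#'   whose casing is normalised.
#'
#' @return A [glycan_composition()].
#' @examples
#' parse_composition("Hex:5 HexNAc:4 dHex:1")
#' parse_composition("Hex5dHex1HexNAc4")   # same composition
#' @export
parse_composition <- function(text, registry = glycan_registry()) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    stop("composition annotation must be a single non-empty string")
  raw <- text
  body <- trimws(text)

  m <- gregexpr("([A-Za-z]+)[[:space:]]*:?[[:space:]]*([0-9]+)", body)[[1]]
  if (m[1] == -1)
    stop("malformed composition \"", raw,
         "\": unparseable (no symbol:count token found)")
  tokens <- regmatches(body, gregexpr(
    "([A-Za-z]+)[[:space:]]*:?[[:space:]]*([0-9]+)", body))[[1]]

  # every non-separator character must belong to a token, otherwise a token
  # is malformed (e.g. "Hex:-1", "Hex:" or stray text)
  covered <- rep(FALSE, nchar(body))
  for (i in seq_along(m)) {
    covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
  }
  leftover <- strsplit(body, "")[[1]][!covered]
  leftover <- leftover[!grepl("[[:space:],;]", leftover)]
  if (length(leftover) > 0)
    stop("malformed composition \"", raw, "\": unparseable text near \"",
         paste(leftover, collapse = ""), "\"")

  syms <- sub("^([A-Za-z]+).*$", "\\1", tokens)
  cnts <- as.integer(sub("^[A-Za-z]+[[:space:]]*:?[[:space:]]*", "", tokens))

  known <- names(registry$residues)
  hit <- match(tolower(syms), tolower(known))
  syms[!is.na(hit)] <- known[hit[!is.na(hit)]]

  if (anyDuplicated(syms))
    stop("malformed composition \"", raw, "\": duplicate symbol ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  counts <- cnts
  names(counts) <- syms
  glycan_composition(counts, source_text = raw)
}

#' Format a glycan composition as a canonical annotation string
#'
#' Residues appear in the order Hex, HexNAc, dHex, NeuAc, then any remaining
#' symbols alphabetically; zero counts are omitted. `parse_composition()` of
#' the result reproduces the composition exactly.
#'
#' @param comp A [glycan_composition()].
#' @return A single string such as `"Hex:5 HexNAc:4 dHex:1"`.
#' @examples
#' format_composition(glycan_composition(c(dHex = 1, Hex = 5, HexNAc = 4)))
#' @export
format_composition <- function(comp) {
  comp <- as_glycan_composition(comp)
  syms <- names(comp)
  lead <- .canonical_order[.canonical_order %in% syms]
  rest <- sort(setdiff(syms, lead))
  ord <- c(lead, rest)
  paste(sprintf("%s:%d", ord, unclass(comp)[ord]), collapse = " ")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

#' Coerce to a glycan composition
#'
#' Strings are parsed with [parse_composition()]; named numeric vectors are
#' validated with [glycan_composition()].
#'
#' @param x A `glycan_composition`, annotation string, or named count vector.
#' @param registry Registry used when parsing strings.
#' @return A [glycan_composition()].
#' @export
as_glycan_composition <- function(x, registry = glycan_registry()) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x, registry))
  if (is.numeric(x)) return(glycan_composition(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a glycan composition")
}

#' Residue count accessor
#'
#' @param comp A [glycan_composition()].
#' @param symbol Residue symbol, e.g. `"Hex"`.
#' @return Integer count (0 when the residue is absent).
#' @export
residue_count <- function(comp, symbol) {
  comp <- as_glycan_composition(comp)
  cnt <- unname(unclass(comp)[symbol])
  ifelse(is.na(cnt), 0L, as.integer(cnt))
}

#' Neutral monoisotopic mass of a released glycan
#'
#' Sums residue monoisotopic masses and adds one water for the free reducing
#' end that PNGase F release leaves on the glycan.
#'
#' @param comp A [glycan_composition()] (or string / named counts).
#' @param registry A [glycan_registry()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass("Hex:3 HexNAc:2")  # the N-glycan core, 910.3278 Da
#' @export
neutral_mass <- function(comp, registry = glycan_registry()) {
  comp <- as_glycan_composition(comp, registry)
  syms <- names(comp)
  unknown <- setdiff(syms, names(registry$residues))
  if (length(unknown) > 0)
    stop("unknown residue symbol(s) in composition: ",
         paste(unknown, collapse = ", "))
  sum(unclass(comp) * registry$residues[syms]) + registry$water
}

#' m/z of a singly charged adduct ion
#'
#' Computes \eqn{[M+X]^{+}} as neutral mass + cation atomic mass - one
#' electron mass. The electron correction matters at the fourth decimal for
#' high-resolution annotation and lock-mass work.
#'
#' @param comp A [glycan_composition()] (or string / named counts).
#' @param adduct Adduct symbol present in the registry adduct table
#'   (default `"Na"`; `"H"` and `"K"` are also built in).
#' @param registry A [glycan_registry()].
#' @return m/z (charge +1) in Th.
#' @examples
#' adduct_mz("Hex:5 HexNAc:4 dHex:1", "Na")  # 1809.6393, a common lock mass
#' @export
adduct_mz <- function(comp, adduct = "Na", registry = glycan_registry()) {
  if (!is.character(adduct) || length(adduct) != 1)
    stop("adduct must be a single symbol string")
  if (!adduct %in% names(registry$adducts))
    stop("unknown adduct symbol: ", adduct)
  neutral_mass(comp, registry) + registry$adducts[[adduct]] - registry$electron
}

#' Match observed peaks to candidate compositions
#'
#' For every observed m/z, finds all candidate composition / adduct pairs
#' whose theoretical singly charged m/z lies within a ppm tolerance, the way
#' annotation platforms match imaging MS peak lists against a glycan database.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param candidates List of compositions (objects or annotation strings).
#' @param adducts Character vector of adduct symbols to consider.
#' @param tol_ppm Match tolerance in parts per million; must be > 0. The
#'   default 2 ppm suits magnetic-resonance MS mass accuracy.
#' @param registry A [glycan_registry()].
#'
#' @return A data.frame with columns `observed_mz`, `composition`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, sorted by absolute ppm error. Zero rows
#'   when nothing matches.
#' @examples
#' match_mz(1809.6393, list("Hex:5 HexNAc:4 dHex:1"), adducts = "Na")
#' @export
match_mz <- function(observed, candidates, adducts = c("Na", "H", "K"),
                     tol_ppm = 2, registry = glycan_registry()) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || is.na(tol_ppm) || tol_ppm <= 0)
    stop("tol_ppm must be a single positive number")
  if (!is.numeric(observed) || length(observed) == 0)
    stop("observed must be a non-empty numeric vector")
  if (!is.list(candidates)) candidates <- as.list(candidates)
  comps <- lapply(candidates, as_glycan_composition, registry = registry)
  labels <- vapply(comps, format_composition, character(1))

  theo <- expand.grid(candidate = seq_along(comps), adduct = adducts,
                      stringsAsFactors = FALSE)
  theo$mz <- mapply(function(i, a) adduct_mz(comps[[i]], a, registry),
                    theo$candidate, theo$adduct)

  rows <- lapply(observed, function(mz) {
    ppm <- (mz - theo$mz) / theo$mz * 1e6
    hit <- abs(ppm) <= tol_ppm
    if (!any(hit)) return(NULL)
    data.frame(
      observed_mz = mz,
      composition = labels[theo$candidate[hit]],
      adduct = theo$adduct[hit],
      theoretical_mz = theo$mz[hit],
      ppm_error = ppm[hit],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(observed_mz = numeric(0), composition = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm_error), out$observed_mz, out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
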