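# Residues that carry classification information. Anything else in a
# composition (NeuGc, Pent, user extensions) is ignored by the rules, with a
# warning, so that extended registries never silently change class calls.
.rule_residues <- c("Hex", "HexNAc", "dHex", "NeuAc")

.type_labels <- c("PAUCI_MANNOSE", "HIGH_MANNOSE", "HYBRID", "COMPLEX",
                  "UNCLASSIFIED")
.decoration_labels <- c("FUCOSYLATED", "MULTI_FUCOSYLATED", "SIALYLATED",
                        "BISECTING", "TETRA_ANTENNARY", "POLYLACTOSAMINE",
                        "BISECTING_OR_TETRA_ANTENNARY")

.display_names <- c(
  PAUCI_MANNOSE = "pauci-mannose",
  HIGH_MANNOSE = "high-mannose",
  HYBRID = "hybrid",
  COMPLEX = "complex",
  UNCLASSIFIED = "unclassified",
  FUCOSYLATED = "fucosylated",
  MULTI_FUCOSYLATED = "multifucose",
  SIALYLATED = "sialylated",
  BISECTING = "bisecting",
  TETRA_ANTENNARY = "tetra antennary",
  POLYLACTOSAMINE = "polylactosamine",
  BISECTING_OR_TETRA_ANTENNARY = "bisecting or tetra antennary"
)

#' The closed class-label vocabulary
#'
#' @return Character vector of all type-class and decoration labels the
#'   classifier can emit, including the `UNCLASSIFIED` fallback and the
#'   ambiguous `BISECTING_OR_TETRA_ANTENNARY` label.
#' @export
glycan_class_labels <- function() c(.type_labels, .decoration_labels)

#' Human-readable display name for a class label
#'
#' @param label One or more labels from [glycan_class_labels()].
#' @return Display string(s), e.g. `"tetra antennary"` for
#'   `TETRA_ANTENNARY`.
#' @export
class_display_name <- function(label) {
  bad <- setdiff(label, names(.display_names))
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  unname(.display_names[label])
}

# Core rule evaluation on the four informative counts. Vectorised; returns a
# list of parallel vectors. H = Hex, N = HexNAc, F = dHex, S = NeuAc.
.classify_counts <- function(H, N, F, S) {
  n <- length(H)
  type <- rep("UNCLASSIFIED", n)
  # order matters: first match wins
  type[H > 3 & N <= 2 & F == 0 & S == 0] <- "HIGH_MANNOSE"
  type[type == "UNCLASSIFIED" & H < 4 & N < 3 & S == 0] <- "PAUCI_MANNOSE"
  type[type == "UNCLASSIFIED" & N == 3 & H >= 4] <- "HYBRID"
  type[type == "UNCLASSIFIED" & N >= 4] <- "COMPLEX"

  decorated <- type %in% c("HYBRID", "COMPLEX")
  ambiguous <- decorated & H == 6 & N == 6

  deco <- vector("list", n)
  for (i in seq_len(n)) {
    d <- character(0)
    if (decorated[i]) {
      if (F[i] == 1) d <- c(d, "FUCOSYLATED")
      if (F[i] > 1) d <- c(d, "MULTI_FUCOSYLATED")
      if (S[i] >= 1) d <- c(d, "SIALYLATED")
      if (ambiguous[i]) {
        d <- c(d, "BISECTING_OR_TETRA_ANTENNARY")
      } else {
        if (N[i] == H[i] && (N[i] == 5 || N[i] > 6)) d <- c(d, "BISECTING")
        if (N[i] >= 6) d <- c(d, "TETRA_ANTENNARY")
      }
      if (N[i] > 6 && H[i] > 7) d <- c(d, "POLYLACTOSAMINE")
    }
    deco[[i]] <- .decoration_labels[.decoration_labels %in% d]
  }
  list(type = type, decorations = deco, ambiguous = ambiguous)
}

.display_name <- function(type, decorations) {
  if (length(decorations) == 0) return(.display_names[[type]])
  deco <- sort(unname(.display_names[decorations]))
  paste(.display_names[[type]], paste(deco, collapse = "-"))
}

#' Classify one glycan composition into structural classes
#'
#' Applies a numeric rule system to the residue counts H = Hex, N = HexNAc,
#' F = dHex, S = NeuAc:
#'
#' * **high-mannose**: H > 3 and N <= 2 and F = 0 and S = 0 (only hexoses
#'   beyond a full or partial chitobiose core);
#' * **pauci-mannose**: H < 4 and N < 3 and S = 0 (truncated core, fucose
#'   permitted);
#' * **hybrid**: N = 3 and H >= 4 (one antenna on a mannose-extended core;
#'   this compositional cut-off is a package convention, see the vignette);
#' * **complex**: N >= 4; anything else is **unclassified**.
#'
#' Hybrid and complex glycans are additionally screened for decorations:
#' fucosylated (F = 1), multifucosylated (F > 1), sialylated (S >= 1),
#' polylactosamine (N > 6 and H > 7), bisecting (N = H and N = 5 or N > 6)
#' and tetra-antennary (N >= 6). The composition H = 6, N = 6 is compatible
#' with either a bisecting or a tetra-antennary structure and is flagged
#' ambiguous with the single label `BISECTING_OR_TETRA_ANTENNARY` instead of
#' both branching labels. For pauci-mannose glycans the fucosylation state is
#' reported in the `fucosylation` field but kept out of the display name.
#'
#' Residue symbols outside Hex/HexNAc/dHex/NeuAc never block type assignment;
#' they are ignored by the rules with a warning.
#'
#' @param comp A [glycan_composition()], annotation string, or named counts.
#' @param registry A [glycan_registry()] (used only when parsing strings).
#' @return An object of class `glycan_class`: a list with elements
#'   `composition`, `type_class`, `decorations` (character vector),
#'   `ambiguous` (logical), `fucosylation` (`"none"`, `"fucosylated"` or
#'   `"multifucosylated"`), and `display_name`.
#' @examples
#' classify("Hex:8 HexNAc:8 dHex:2")
#' classify("Hex:6 HexNAc:6")   # ambiguous branching
#' @export
classify <- function(comp, registry = glycan_registry()) {
  comp <- as_glycan_composition(comp, registry)
  extra <- setdiff(names(comp), .rule_residues)
  if (length(extra) > 0)
    warning("residue symbol(s) outside the classification rules ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  H <- residue_count(comp, "Hex")
  N <- residue_count(comp, "HexNAc")
  F <- residue_count(comp, "dHex")
  S <- residue_count(comp, "NeuAc")
  r <- .classify_counts(H, N, F, S)
  fuc <- if (F > 1) "multifucosylated" else if (F == 1) "fucosylated" else "none"
  structure(
    list(
      composition = comp,
      type_class = r$type,
      decorations = r$decorations[[1]],
      ambiguous = r$ambiguous,
      fucosylation = fuc,
      display_name = .display_name(r$type, r$decorations[[1]])
    ),
    class = "glycan_class"
  )
}

#' @export
print.glycan_class <- function(x, ...) {
  cat("<glycan_class> ", format_composition(x$composition), "\n", sep = "")
  cat("  class: ", x$display_name,
      if (x$ambiguous) "  [ambiguous branching]" else "", "\n", sep = "")
  invisible(x)
}

#' Classify many compositions into a table
#'
#' Vectorised front end to [classify()].
#'
#' @param comps List (or character vector) of compositions.
#' @param registry A [glycan_registry()].
#' @return A data.frame with one row per input: `composition` (canonical
#'   string), `type_class`, `decorations` (`";"`-joined), `ambiguous`,
#'   `display_name`.
#' @export
classify_compositions <- function(comps, registry = glycan_registry()) {
  if (length(comps) == 0) stop("comps must be non-empty")
  if (!is.list(comps)) comps <- as.list(comps)
  comps <- lapply(comps, as_glycan_composition, registry = registry)
  res <- lapply(comps, classify, registry = registry)
  data.frame(
    composition = vapply(comps, format_composition, character(1)),
    type_class = vapply(res, `[[`, character(1), "type_class"),
    decorations = vapply(res, function(r) paste(r$decorations, collapse = ";"),
                         character(1)),
    ambiguous = vapply(res, `[[`, logical(1), "ambiguous"),
    display_name = vapply(res, `[[`, character(1), "display_name"),
    stringsAsFactors = FALSE
  )
}

#' Ontology terms per glycan, with an inverted index
#'
#' Maps each glycan to its ontology term set (type class plus decorations;
#' the ambiguous branching label is a term of its own) and builds the
#' inverted index term -> member glycans used by [term_enrichment()].
#' Duplicate glycans are kept as separate occurrences (multiset semantics);
#' identifiers come from `names(comps)` or default to `g1..gn`.
#'
#' @param comps Non-empty list (or character vector) of compositions,
#'   optionally named with glycan identifiers.
#' @param registry A [glycan_registry()].
#' @return A list with `terms` (named list: identifier -> character vector of
#'   terms) and `index` (named list: term -> character vector of member
#'   identifiers, terms in canonical label order).
#' @examples
#' ontology_terms(c(g1 = "Hex:7 HexNAc:2", g2 = "Hex:3 HexNAc:6"))$index
#' @export
ontology_terms <- function(comps, registry = glycan_registry()) {
  if (length(comps) == 0) stop("comps must be non-empty")
  tab <- classify_compositions(comps, registry)
  ids <- names(comps)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("g%d", seq_len(nrow(tab)))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
  terms <- lapply(seq_len(nrow(tab)), function(i) {
    deco <- strsplit(tab$decorations[i], ";", fixed = TRUE)[[1]]
    c(tab$type_class[i], deco[nzchar(deco)])
  })
  names(terms) <- ids
  all_terms <- glycan_class_labels()
  index <- lapply(all_terms, function(tm)
    ids[vapply(terms, function(x) tm %in% x, logical(1))])
  names(index) <- all_terms
  index <- index[vapply(index, length, integer(1)) > 0]
  list(terms = terms, index = index)
}

#' Count glycans carrying each ontology term
#'
#' Type-class counts partition the input (each glycan has exactly one type
#' class); decoration counts may overlap across terms.
#'
#' @param comps Non-empty list (or character vector) of compositions.
#' @param registry A [glycan_registry()].
#' @return A data.frame with columns `term` and `count`, in canonical label
#'   order, omitting terms with zero members.
#' @export
class_counts <- function(comps, registry = glycan_registry()) {
  ont <- ontology_terms(comps, registry)
  data.frame(
    term = names(ont$index),
    count = vapply(ont$index, length, integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
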