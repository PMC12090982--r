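#' Construct a region assignment table
#'
#' A region assignment maps glycans (many-to-many) to named anatomical
#' regions or spatial clusters, optionally with a co-localization score.
#'
#' @param df Data.frame with columns `glycan` (identifier), `composition`
#'   (annotation string) and `region`; optional `score` in `[0, 1]`.
#'   `region` may be a factor, in which case empty levels are kept and
#'   reported with zero totals by [summarize_regions()].
#' @return The validated data.frame with class `region_assignment`.
#' @export
region_assignment <- function(df) {
  need <- c("glycan", "composition", "region")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("region assignment is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("region assignment must have at least one row")
  if (any(!nzchar(as.character(df$region))) || any(is.na(df$region)))
    stop("region names must be non-empty")
  if ("score" %in% names(df)) {
    s <- df$score
    if (any(!is.na(s) & (s < 0 | s > 1)))
      stop("co-localization scores must lie in [0, 1]")
  }
  class(df) <- unique(c("region_assignment", class(df)))
  df
}

#' Region-by-class summary of a glycan assignment
#'
#' Classifies every glycan of every region and tabulates, per region, how
#' many glycans carry each class term and what percentage of the region's
#' glycan total that represents. Three views of the class axis are reported:
#'
#' * `type` — the mutually exclusive type classes (their counts sum to the
#'   region total);
#' * `decoration` — marginal decoration terms, the ambiguous branching label
#'   and an explicit `complex (no decorations)` bucket (these may overlap, so
#'   their counts can exceed the total);
#' * `combination` — the exact display-name combination (e.g.
#'   `"complex fucosylated-sialylated"`), which partitions the region total
#'   at full decoration resolution.
#'
#' Percentages use the region's distinct-glycan total as denominator.
#' Duplicated (glycan, region) rows are de-duplicated first, so repeating
#' rows never changes the summary.
#'
#' @param assignment A [region_assignment()] (or plain data.frame with the
#'   same columns).
#' @param registry A [glycan_registry()].
#' @return An object of class `region_class_summary`: a list with
#'   `counts` (data.frame `region`, `view`, `term`, `count`, `percent`) and
#'   `totals` (data.frame `region`, `total`). Regions appear in factor-level
#'   or alphabetical order; empty regions keep a zero total and no count rows.
#' @examples
#' a <- region_assignment(data.frame(
#'   glycan = c("g1", "g2"), composition = c("Hex:7 HexNAc:2", "Hex:3 HexNAc:6"),
#'   region = "adventitia"))
#' summarize_regions(a)
#' @export
summarize_regions <- function(assignment, registry = glycan_registry()) {
  assignment <- region_assignment(as.data.frame(assignment))
  regions <- if (is.factor(assignment$region)) levels(assignment$region)
             else sort(unique(as.character(assignment$region)))
  df <- data.frame(glycan = as.character(assignment$glycan),
                   composition = as.character(assignment$composition),
                   region = as.character(assignment$region),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("glycan", "region")]), , drop = FALSE]

  # classify each distinct composition once
  comps <- unique(df$composition)
  cls <- classify_compositions(comps, registry)
  cls_of <- structure(seq_along(comps), names = comps)

  totals <- data.frame(
    region = regions,
    total = vapply(regions, function(r) sum(df$region == r), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  rows <- lapply(regions, function(r) {
    sub <- df[df$region == r, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    ci <- cls[cls_of[sub$composition], , drop = FALSE]
    total <- nrow(sub)

    type_tab <- table(factor(ci$type_class, levels = .type_labels))
    type_tab <- type_tab[type_tab > 0]

    deco_terms <- c(.decoration_labels, "complex (no decorations)")
    deco_cnt <- vapply(deco_terms, function(tm) {
      if (tm == "complex (no decorations)")
        sum(ci$type_class == "COMPLEX" & !nzchar(ci$decorations))
      else
        sum(vapply(strsplit(ci$decorations, ";", fixed = TRUE),
                   function(d) tm %in% d, logical(1)))
    }, integer(1))
    deco_cnt <- deco_cnt[deco_cnt > 0]

    combo_tab <- table(ci$display_name)

    build <- function(view, terms, counts) {
      if (length(terms) == 0) return(NULL)
      data.frame(region = r, view = view, term = terms,
                 count = as.integer(counts),
                 percent = 100 * as.integer(counts) / total,
                 stringsAsFactors = FALSE)
    }
    rbind(
      build("type", names(type_tab), type_tab),
      build("decoration", names(deco_cnt), deco_cnt),
      build("combination", sort(names(combo_tab)), combo_tab[sort(names(combo_tab))])
    )
  })
  counts <- do.call(rbind, rows)
  if (is.null(counts))
    counts <- data.frame(region = character(0), view = character(0),
                         term = character(0), count = integer(0),
                         percent = numeric(0), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  structure(list(counts = counts, totals = totals),
            class = "region_class_summary")
}

#' @export
print.region_class_summary <- function(x, ...) {
  cat("<region_class_summary> ", nrow(x$totals), " region(s), ",
      sum(x$totals$total), " assignment(s)\n", sep = "")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Cosine co-localization between an ion image and a region mask
#'
#' Flattens both grids and returns their cosine similarity, a simple
#' stand-in for the co-localization measures spatial-metabolomics platforms
#' use to relate an ion image to a reference spatial pattern. An all-zero
#' image scores 0 against every mask.
#'
#' @param image Numeric matrix of non-negative, finite intensities.
#' @param mask Binary (0/1 or logical) matrix of the same dimensions with at
#'   least one positive pixel.
#' @return Similarity score in `[0, 1]`.
#' @examples
#' m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
#' colocalize(m, m)  # 1
#' @export
colocalize <- function(image, mask) {
  if (!is.matrix(image) || !is.matrix(mask))
    stop("image and mask must be matrices")
  if (!all(dim(image) == dim(mask)))
    stop("image and mask dimensions differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  img <- as.numeric(image)
  msk <- as.numeric(mask)
  if (any(!is.finite(img)) || any(img < 0))
    stop("image intensities must be finite and non-negative")
  if (!all(msk %in% c(0, 1)))
    stop("mask must be binary (0/1)")
  if (sum(msk) == 0)
    stop("mask must contain at least one positive pixel")
  ni <- sqrt(sum(img^2))
  if (ni == 0) return(0)
  sum(img * msk) / (ni * sqrt(sum(msk)))
}

#' Assign glycans to regions by ion-image co-localization
#'
#' Scores every ion image against every region mask with [colocalize()] and
#' assigns the glycan to each region whose score reaches the threshold.
#' Assignments shrink monotonically as the threshold grows.
#'
#' @param images Named list of intensity matrices; names are glycan
#'   identifiers.
#' @param masks Named list of binary region masks (same dimensions).
#' @param threshold Score cut-off in `(0, 1]` (default 0.5).
#' @param compositions Optional named character vector mapping glycan
#'   identifiers to composition strings; when supplied the result carries a
#'   `composition` column and is a full [region_assignment()].
#' @return Data.frame `glycan`, `region`, `score` (plus `composition` when
#'   available) of all assignments with `score >= threshold`; zero rows when
#'   nothing reaches the threshold.
#' @export
assign_regions <- function(images, masks, threshold = 0.5, compositions = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (length(images) == 0 || is.null(names(images)))
    stop("images must be a non-empty named list")
  if (length(masks) == 0 || is.null(names(masks)))
    stop("masks must be a non-empty named list")
  rows <- list()
  # small guard against round-off so a score of exactly 1 survives threshold 1
  eps <- 1e-9
  for (g in names(images)) {
    for (r in names(masks)) {
      s <- colocalize(images[[g]], masks[[r]])
      if (s >= threshold - eps)
        rows[[length(rows) + 1]] <- data.frame(
          glycan = g, region = r, score = s, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(glycan = character(0), region = character(0),
                         score = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(compositions) && nrow(out) > 0) {
    out$composition <- unname(compositions[out$glycan])
    out <- region_assignment(out[, c("glycan", "composition", "region", "score")])
  }
  rownames(out) <- NULL
  out
}
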