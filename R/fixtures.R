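# Enumeration grid for fixture sampling: compositions with Hex <= 12,
# HexNAc <= 12, dHex <= 4, NeuAc <= 4 cover everything the rule system
# distinguishes at realistic residue counts.
.fixture_grid <- function() {
  g <- expand.grid(H = 0:12, N = 0:12, F = 0:4, S = 0:4,
                   KEEP.OUT.ATTRS = FALSE)
  g[g$H + g$N + g$F + g$S > 0, , drop = FALSE]
}

# Constructive feasibility predicates per target label. Written directly
# from the structural definitions (not via classify()) so the generator is
# an independent oracle for the classifier in round-trip tests.
.label_predicate <- function(label, g) {
  hm  <- g$H > 3 & g$N <= 2 & g$F == 0 & g$S == 0
  pm  <- !hm & g$H < 4 & g$N < 3 & g$S == 0
  hy  <- !hm & !pm & g$N == 3 & g$H >= 4
  cx  <- !hm & !pm & !hy & g$N >= 4
  base <- hy | cx
  amb <- cx & g$H == 6 & g$N == 6
  switch(label,
    HIGH_MANNOSE = hm,
    PAUCI_MANNOSE = pm,
    HYBRID = hy,
    COMPLEX = cx,
    UNCLASSIFIED = !(hm | pm | hy | cx),
    FUCOSYLATED = base & g$F == 1,
    MULTI_FUCOSYLATED = base & g$F > 1,
    SIALYLATED = base & g$S >= 1,
    TETRA_ANTENNARY = base & g$N >= 6 & !amb,
    BISECTING = base & g$N == g$H & (g$N == 5 | g$N > 6) & !amb,
    POLYLACTOSAMINE = base & g$N > 6 & g$H > 7,
    BISECTING_OR_TETRA_ANTENNARY = amb,
    stop("unknown class label in mix: ", label)
  )
}

#' Generate a synthetic composition table with a target class mix
#'
#' Samples compositions from the grid Hex <= 12, HexNAc <= 12, dHex <= 4,
#' NeuAc <= 4 so that a requested proportion of rows carries each target
#' class label. Feasible compositions per label are selected with
#' constructive structural predicates written independently of
#' [classify()], which makes the emitted `intended_class` column an
#' oracle for classifier round-trip tests.
#'
#' @param n Number of rows to generate (>= 1).
#' @param class_mix Named numeric vector of target proportions (must sum to
#'   1). Names are labels from [glycan_class_labels()]; decoration labels
#'   draw from hybrid/complex compositions carrying that decoration.
#' @param seed Optional integer seed; fixed seed gives identical tables.
#' @param constraints Optional named list: label -> named minimum residue
#'   counts (symbols `Hex`, `HexNAc`, `dHex`, `NeuAc`). A label whose
#'   feasible set becomes empty (e.g. pauci-mannose with `NeuAc >= 1`, which
#'   no rule-consistent composition satisfies) raises an error naming it.
#' @return Data.frame `glycan`, `composition`, `intended_class`, one row per
#'   generated glycan, in label order then sampling order.
#' @examples
#' generate_fixture_compositions(10, c(HIGH_MANNOSE = 0.5, COMPLEX = 0.5),
#'                               seed = 1)
#' @export
generate_fixture_compositions <- function(n, class_mix, seed = NULL,
                                          constraints = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stop("class_mix must be a named vector of proportions")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must be non-negative and sum to 1")
  bad <- setdiff(names(class_mix), glycan_class_labels())
  if (length(bad) > 0)
    stop("unknown class label(s) in mix: ", paste(bad, collapse = ", "))

  g <- .fixture_grid()
  labels <- names(class_mix)

  # largest-remainder apportionment of n over the mix
  raw <- n * class_mix
  quota <- floor(raw)
  left <- n - sum(quota)
  if (left > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(left)]
    quota[extra] <- quota[extra] + 1
  }

  .with_seed(seed, {
    rows <- lapply(labels, function(lb) {
      if (quota[[lb]] == 0) return(NULL)
      ok <- .label_predicate(lb, g)
      cn <- constraints[[lb]]
      if (!is.null(cn)) {
        colmap <- c(Hex = "H", HexNAc = "N", dHex = "F", NeuAc = "S")
        unknown <- setdiff(names(cn), names(colmap))
        if (length(unknown) > 0)
          stop("constraint residue(s) not supported: ",
               paste(unknown, collapse = ", "))
        for (sym in names(cn)) ok <- ok & g[[colmap[[sym]]]] >= cn[[sym]]
      }
      feas <- which(ok)
      if (length(feas) == 0)
        stop("no composition on the grid satisfies class ", lb,
             if (!is.null(cn)) " under the given constraints" else "")
      pick <- feas[sample.int(length(feas), quota[[lb]], replace = TRUE)]
      data.frame(
        composition = apply(g[pick, , drop = FALSE], 1, function(x)
          format_composition(glycan_composition(
            c(Hex = x[["H"]], HexNAc = x[["N"]],
              dHex = x[["F"]], NeuAc = x[["S"]])))),
        intended_class = lb,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out <- cbind(glycan = sprintf("g%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Build non-overlapping rectangular region masks
#'
#' Splits a pixel grid into equal-width vertical bands, one per region, to
#' serve as toy anatomical region masks for the spatial fixtures. Equal-area
#' non-overlapping masks guarantee that a noise-free union image of up to 4
#' regions co-localizes with each member mask at score `1/sqrt(k) >= 0.5`.
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param regions Character vector of region names.
#' @return Named list of 0/1 matrices.
#' @export
make_region_masks <- function(nrow = 40, ncol = 60,
                              regions = c("adventitia", "submucosal_gland",
                                          "cartilage", "parenchyma")) {
  k <- length(regions)
  if (k < 1) stop("at least one region is required")
  if (ncol < k) stop("grid too narrow for ", k, " regions")
  bounds <- round(seq(0, ncol, length.out = k + 1))
  masks <- lapply(seq_len(k), function(i) {
    m <- matrix(0, nrow, ncol)
    m[, (bounds[i] + 1):bounds[i + 1]] <- 1
    m
  })
  names(masks) <- regions
  masks
}

#' Generate toy ion images from an intended region assignment
#'
#' Each glycan's image is the sum of the masks of its intended regions plus
#' optional clipped Gaussian noise, mimicking an ion image whose signal sits
#' on the assigned anatomical regions. With `noise_sd = 0` and equal-area
#' non-overlapping masks, [assign_regions()] at threshold 0.5 recovers the
#' intended assignment exactly for glycans spanning up to 4 regions.
#'
#' @param masks Named list of binary masks (see [make_region_masks()]).
#' @param assignment Data.frame with columns `glycan`, `region` giving the
#'   intended membership (many-to-many).
#' @param noise_sd Standard deviation of additive Gaussian noise; negative
#'   intensities are clipped at 0.
#' @param seed Optional integer seed for the noise.
#' @return Named list of intensity matrices, one per distinct glycan.
#' @export
generate_fixture_images <- function(masks, assignment, noise_sd = 0,
                                    seed = NULL) {
  if (!all(c("glycan", "region") %in% names(assignment)))
    stop("assignment needs columns glycan and region")
  stray <- setdiff(unique(assignment$region), names(masks))
  if (length(stray) > 0)
    stop("assignment references unknown region(s): ",
         paste(stray, collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  glycans <- unique(as.character(assignment$glycan))
  dims <- dim(masks[[1]])
  .with_seed(seed, {
    imgs <- lapply(glycans, function(g) {
      regs <- assignment$region[assignment$glycan == g]
      img <- Reduce(`+`, masks[regs])
      if (noise_sd > 0)
        img <- pmax(img + matrix(stats::rnorm(prod(dims), 0, noise_sd),
                                 dims[1], dims[2]), 0)
      img
    })
    names(imgs) <- glycans
    imgs
  })
}
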