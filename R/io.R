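#' Read a glycan table from CSV or TSV
#'
#' Reads a delimited text file with (at least) a `composition` column of
#' annotation strings. The delimiter is sniffed from the header line (tab
#' when present, comma otherwise) so METASPACE/SCiLS-style exports work
#' unchanged. Every row's composition is parsed; rows that fail to parse are
#' collected with their line numbers instead of aborting the read, unless
#' `all_or_nothing = TRUE`.
#'
#' @param path Path to a CSV/TSV file.
#' @param all_or_nothing When `TRUE`, any parse failure aborts with a message
#'   listing the offending lines.
#' @param registry A [glycan_registry()] used for parsing.
#' @return A data.frame of the successfully parsed rows, with `composition`
#'   rewritten in canonical form and a `glycan` identifier column (taken from
#'   the file if present, generated otherwise). Parse failures are attached
#'   as `attr(, "parse_failures")`: a data.frame `line`, `text`, `message`.
#' @export
read_glycan_table <- function(path, all_or_nothing = FALSE,
                              registry = glycan_registry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!"composition" %in% names(df))
    stop("missing required column 'composition' in ", path)
  if (nrow(df) == 0) stop("no data rows in ", path)

  parsed <- vector("list", nrow(df))
  fail <- list()
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(parse_composition(df$composition[i], registry),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fail[[length(fail) + 1]] <- data.frame(
        line = i + 1L,  # +1 for the header line
        text = df$composition[i],
        message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      parsed[[i]] <- res
    }
  }
  failures <- if (length(fail) > 0) do.call(rbind, fail)
              else data.frame(line = integer(0), text = character(0),
                              message = character(0), stringsAsFactors = FALSE)
  if (all_or_nothing && nrow(failures) > 0)
    stop("parse failure(s) at line(s) ",
         paste(failures$line, collapse = ", "), ": ",
         failures$message[1])

  ok <- !vapply(parsed, is.null, logical(1))
  out <- df[ok, , drop = FALSE]
  out$composition <- vapply(parsed[ok], format_composition, character(1))
  if (!"glycan" %in% names(out))
    out$glycan <- sprintf("g%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "parse_failures") <- failures
  out
}

# deterministic CSV writer used by the pipeline (no row names, no quoting of
# numerics, fixed eol) so reruns under one seed are byte-identical
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# run a block under a local RNG state so library calls never disturb the
# caller's .Random.seed
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
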