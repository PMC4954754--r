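#' Read and write the pipeline's plain-text table dialects
#'
#' All artifacts are plain text: CSV for tables, TSV for expression
#' matrices, JSON for truth/config/report objects.
#'
#' @name uprtriage_io
NULL

#' @rdname uprtriage_io
#' @param plates Plate data.frame (see [generate_plate_set()]).
#' @param path File path.
#' @export
write_plate_csv <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname uprtriage_io
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well_id", "role", "compound_id", "raw_signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plate CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname uprtriage_io
#' @param expr Linear fold-change matrix (genes x conditions).
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname uprtriage_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname uprtriage_io
#' @param catalog A [geneset_catalog()].
#' @export
write_geneset_tsv <- function(catalog, path) {
  df <- data.frame(gene_id = unlist(unclass(catalog), use.names = FALSE),
                   geneset = rep(names(catalog), lengths(catalog)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname uprtriage_io
#' @export
read_geneset_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "geneset") %in% names(df)))
  geneset_catalog(split(df$gene_id, df$geneset))
}

#' @rdname uprtriage_io
#' @param cells Per-cell data.frame (see [generate_cell_ratios()]).
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname uprtriage_io
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "treatment", "nuc_intensity", "er_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cell CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname uprtriage_io
#' @param series Chase data.frame (see [generate_chase_data()]).
#' @export
write_chase_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname uprtriage_io
#' @export
read_chase_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "replicate", "t_hours", "compartment", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("chase CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a blacklist file (one compound id per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of compound ids.
#' @export
read_blacklist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read an external dual-reporter activation table
#'
#' Accepts a delimited table in the layout of a published per-compound
#' dual-reporter summary: a compound-id column plus one percent-activation
#' column per reporter (ERSE-FLuc and XBP1-RLuc, both Tg-normalised).
#' Column matching is case-insensitive on the substrings "erse"/"fluc" and
#' "xbp1"/"rluc"; the first column is taken as the compound id if no
#' id-like column is found.
#'
#' @param path CSV or TSV file path.
#' @return data.frame: compound_id, erse_pct, xbp1_pct.
#' @export
read_dual_reporter_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  find <- function(patterns) {
    hit <- which(Reduce(`|`, lapply(patterns, grepl, x = nm)))
    if (length(hit)) hit[1] else NA_integer_
  }
  i_erse <- find(c("erse", "fluc"))
  i_xbp1 <- find(c("xbp1", "rluc"))
  if (is.na(i_erse) || is.na(i_xbp1)) {
    stop("could not locate ERSE/XBP1 activation columns in ", path,
         call. = FALSE)
  }
  i_id <- find(c("compound", "^id$", "molecule"))
  if (is.na(i_id)) i_id <- setdiff(seq_along(df), c(i_erse, i_xbp1))[1]
  data.frame(compound_id = as.character(df[[i_id]]),
             erse_pct = as.numeric(df[[i_erse]]),
             xbp1_pct = as.numeric(df[[i_xbp1]]),
             stringsAsFactors = FALSE)
}

#' Write an R object as pretty JSON
#'
#' @param x Object (lists/data.frames of plain values).
#' @param path File path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
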