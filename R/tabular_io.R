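# Tabular input/output: delimited-file reading with dialect sniffing,
# per-column number-format sniffing, minimal Skyline XML extraction, and
# round-trippable CSV writing. Cells are kept as raw text at read time;
# numeric interpretation is a separate, explicit classification step.

.num_dot_re     <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
.num_comma_re   <- "^[+-]?[0-9]+,[0-9]+$"
.num_group_re   <- "^[+-]?[0-9]{1,3},[0-9]{3}$"
.num_percent_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)%$"

#' Read a delimited omics table
#'
#' Reads a `.csv`, `.tsv`, `.txt` or `.tabular` file into an `omics_table`
#' (a data frame of character columns with provenance attributes). The first
#' row is the header and must contain unique, non-empty names. The delimiter
#' is chosen by extension (`.csv` comma, `.tsv` tab) and otherwise by
#' sniffing: the candidate among comma, tab and semicolon giving the highest
#' consistent column count over the first 50 lines wins. All cells are read
#' as text; see [coerce_numeric_columns()] for numeric interpretation.
#'
#' @param path Path to the file.
#' @param format_hint Optional delimiter override: `"csv"`, `"tsv"` or a
#'   literal single-character delimiter.
#' @param max_mb Refuse files larger than this many megabytes (default
#'   `Inf`; the command-line workflow applies its own 100 MB default).
#' @return An `omics_table`: a data frame of character columns, with
#'   attributes `source` (path) and `dialect` (the delimiter used).
#' @export
read_table <- function(path, format_hint = NULL, max_mb = Inf) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size_mb <- file.info(path)$size / 1024^2
  if (size_mb > max_mb) {
    stop(sprintf(
      "input is %.1f MB, over the %.0f MB limit; process it through the R functions directly",
      size_mb, max_mb), call. = FALSE)
  }
  delim <- resolve_delimiter(path, format_hint)
  raw <- tryCatch(
    utils::read.table(path, sep = delim, header = FALSE,
                      colClasses = "character", check.names = FALSE,
                      na.strings = character(0), quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      fill = TRUE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (nrow(raw) < 1L) stop("file has no header row: ", path, call. = FALSE)
  headers <- trimws(as.character(raw[1L, ]))
  bad <- which(!nzchar(headers))
  if (length(bad)) {
    stop("empty header at column position ", bad[1L], call. = FALSE)
  }
  dup <- which(duplicated(headers))
  if (length(dup)) {
    stop("duplicate header '", headers[dup[1L]], "' at column position ",
         dup[1L], call. = FALSE)
  }
  body <- raw[-1L, , drop = FALSE]
  if (nrow(body) == 0L) {
    warning("file has a header row but zero data rows: ", path, call. = FALSE)
  }
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- headers
  rownames(df) <- NULL
  as_omics_table(df, source = path, dialect = delim)
}

resolve_delimiter <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) {
    return(switch(format_hint, csv = ",", tsv = "\t", tab = "\t",
                  format_hint))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext == "tsv") return("\t")
  sniff_delimiter(path)
}

# Pick the delimiter that yields the highest column count while staying
# consistent (same count on every non-empty line) over the first 50 lines.
sniff_delimiter <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(",")
  best <- ","; best_n <- 1L
  for (d in c("\t", ",", ";")) {
    counts <- vapply(strsplit(lines, d, fixed = TRUE), length, integer(1))
    if (length(unique(counts)) == 1L && counts[1L] > best_n) {
      best <- d; best_n <- counts[1L]
    }
  }
  best
}

# omics_table constructor: a character-celled data frame plus provenance.
as_omics_table <- function(df, source = NA_character_, dialect = NA_character_) {
  stopifnot(is.data.frame(df))
  df[] <- lapply(df, as.character)
  structure(df, source = source, dialect = dialect,
            class = c("omics_table", "data.frame"))
}

#' @export
as.data.frame.omics_table <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  attr(x, "source") <- NULL
  attr(x, "dialect") <- NULL
  class(x) <- "data.frame"
  x
}

#' Sniff the number format of a column of text cells
#'
#' Decides whether a column of raw text cells can be coerced to numbers, and
#' under which convention. Using only the non-empty cells: if at least 90%
#' match a dot-decimal numeric pattern the column is dot-decimal; if at
#' least 90% match a single-comma pattern with no dots, and the commas are
#' not all consistent with 3-digit thousands grouping (`1,204`), the column
#' is comma-decimal (`3,14` parses as 3.14); if at least 90% are a numeric
#' prefix ending in `%` the column is flagged percent and is not coercible
#' (a percentage is not a plain quantity, so it is excluded from
#' tabulation); anything else is not coercible. Grouping-ambiguous comma
#' columns are deliberately not coercible: misreading `1,204` as 1.204
#' would corrupt sums silently.
#'
#' @param values Character vector of cell texts.
#' @return A list: `decimal` (`"dot"`, `"comma"` or NA), `percent` (flag),
#'   `coercible` (flag).
#' @examples
#' sniff_number_format(c("12.5", "3.0", "0.7"))
#' sniff_number_format(c("3,14", "2,5"))
#' sniff_number_format(c("99%", "100%"))
#' @export
sniff_number_format <- function(values) {
  vals <- trimws(as.character(values))
  vals <- vals[nzchar(vals)]
  rule <- function(decimal, percent, coercible) {
    list(decimal = decimal, percent = percent, coercible = coercible)
  }
  if (!length(vals)) return(rule(NA_character_, FALSE, FALSE))
  frac <- function(re) mean(grepl(re, vals))
  if (frac(.num_dot_re) >= 0.9) return(rule("dot", FALSE, TRUE))
  if (frac(.num_comma_re) >= 0.9) {
    comma_vals <- vals[grepl(.num_comma_re, vals)]
    if (all(grepl(.num_group_re, comma_vals))) {
      # every comma placement is consistent with thousands grouping:
      # ambiguous, refuse to guess
      return(rule(NA_character_, FALSE, FALSE))
    }
    return(rule("comma", FALSE, TRUE))
  }
  if (frac(.num_percent_re) >= 0.9) return(rule(NA_character_, TRUE, FALSE))
  rule(NA_character_, FALSE, FALSE)
}

#' Classify every column of a table for numeric coercion
#'
#' Applies [sniff_number_format()] to each column and labels it
#' `"coercible"`, `"non_coercible"` or `"identifier-like"` (the designated
#' identifier column, if named, is never treated as data). Classification
#' depends only on the multiset of cell values, so it is stable under row
#' permutation and under appending empty cells.
#'
#' @param table An `omics_table` or plain data frame.
#' @param id_column Optional header name to mark `identifier-like`.
#' @return A `numeric_classification`: data frame with one row per column
#'   (`header`, `class`, `decimal`, `percent`).
#' @export
coerce_numeric_columns <- function(table, id_column = NULL) {
  stopifnot(is.data.frame(table))
  rows <- lapply(names(table), function(h) {
    if (!is.null(id_column) && h == id_column) {
      return(data.frame(header = h, class = "identifier-like",
                        decimal = NA_character_, percent = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- sniff_number_format(table[[h]])
    data.frame(header = h,
               class = if (r$coercible) "coercible" else "non_coercible",
               decimal = r$decimal, percent = r$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("numeric_classification", "data.frame")
  out
}

# Parse a character column to numeric under a sniffed rule; empty cells and
# unparseable stragglers (the tolerated <10%) become NA.
parse_numeric_column <- function(values, decimal = "dot") {
  v <- trimws(as.character(values))
  v[!nzchar(v)] <- NA_character_
  if (identical(decimal, "comma")) v <- sub(",", ".", v, fixed = TRUE)
  suppressWarnings(as.numeric(v))
}

#' Extract protein identifiers and peptide counts from a Skyline document
#'
#' Reads a minimal subset of the Skyline targeted-proteomics XML format:
#' every `<protein>` element contributes one row, identified by its `name`,
#' `accession` or `label` attribute (first available in that order), with
#' the number of `<peptide>` child elements as a numeric column. This
#' deliberately small contract covers identifier extraction only, not the
#' full Skyline document model.
#'
#' @param path Path to a `.sky` XML file.
#' @return An `omics_table` with columns `protein` and `peptides`.
#' @export
read_skyline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not a well-formed XML document: ", path, " (",
         conditionMessage(e), ")", call. = FALSE)
  })
  proteins <- xml2::xml_find_all(doc, "//protein")
  if (length(proteins) == 0L) {
    warning("no protein elements found in ", path, call. = FALSE)
    return(as_omics_table(
      data.frame(protein = character(0), peptides = character(0),
                 stringsAsFactors = FALSE),
      source = path, dialect = "skyline"))
  }
  ids <- vapply(proteins, function(p) {
    for (attr in c("name", "accession", "label")) {
      v <- xml2::xml_attr(p, attr)
      if (!is.na(v) && nzchar(v)) return(v)
    }
    ""
  }, character(1))
  counts <- vapply(proteins, function(p) {
    length(xml2::xml_find_all(p, "./peptide"))
  }, integer(1))
  as_omics_table(
    data.frame(protein = ids, peptides = as.character(counts),
               stringsAsFactors = FALSE),
    source = path, dialect = "skyline")
}

#' Write a table as CSV
#'
#' UTF-8, comma-separated, header row first. Cells are quoted only when they
#' contain a delimiter, quote or newline, so `read_table()` on the output
#' reproduces the table exactly (text-level round trip).
#'
#' @param table Data frame (an `omics_table`, annotated table or tabulation
#'   table).
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  quote_cell <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    need <- grepl("[\",\n]", x)
    x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
    x
  }
  header <- paste(quote_cell(names(df)), collapse = ",")
  body <- if (nrow(df)) {
    do.call(paste, c(lapply(df, quote_cell), sep = ","))
  } else {
    character(0)
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}
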