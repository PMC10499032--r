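# matriannotate: match a table's identifier column against a matrisome
# reference and prepend the classification columns.

.div_col  <- "Annotated Matrisome Division"
.cat_col  <- "Annotated Matrisome Category"
.gocc_col <- "Annotated Gene Ontology: Cellular Component"
.non_matrisome <- "Non-matrisome"

#' Annotate an omics table with matrisome divisions and categories
#'
#' For every row, the identifier cell is normalized ([normalize_identifier()])
#' and each of its sub-identifiers is looked up, in cell order, in the
#' reference index; the first hit determines the row's division and category
#' (the proteomics "leading protein" convention for protein-group cells).
#' Rows with no matching key — including blank identifier cells — are
#' classified `Non-matrisome`/`Non-matrisome`.
#'
#' The output keeps every input row (annotation never drops data) and is
#' laid out as: the identifier column first, then "Annotated Matrisome
#' Division" and "Annotated Matrisome Category" (and the GO:CC column when
#' `go_map` is supplied), then all remaining input columns in their original
#' order. Rows are sorted by identifier, byte-wise on the upper-cased text,
#' so output order is deterministic across locales. Any annotation columns
#' already present in the input (e.g. when re-annotating a previous output)
#' are replaced, which makes the operation idempotent.
#'
#' @param table An `omics_table` or data frame.
#' @param id_column Header name of the identifier column.
#' @param species Species tag; must equal `ref$species`.
#' @param ref A `matrisome_reference` from [load_reference()].
#' @param go_map Optional GO:CC map from [read_gocc_map()]; adds a column of
#'   semicolon-joined Cellular Component terms (empty when unmapped).
#' @return An `annotated_table` (data frame, character cells) with attribute
#'   `match_log`: a data frame aligned with the output rows giving the
#'   matched alias, its namespace and the matched entry's gene symbol (NA
#'   for non-matrisome rows).
#' @examples
#' ref <- load_reference("test-human", "human")
#' tab <- data.frame(id = c("COL1A1", "ZZZ999"), count = c("3", "2"))
#' ann <- matriannotate(tab, "id", "human", ref)
#' ann[["Annotated Matrisome Division"]]
#' @export
matriannotate <- function(table, id_column, species, ref, go_map = NULL) {
  stopifnot(is.data.frame(table))
  species <- match.arg(species, .matriomics_species)
  if (!id_column %in% names(table)) {
    stop("id_column '", id_column, "' is not a column of the table",
         call. = FALSE)
  }
  if (!inherits(ref, "matrisome_reference")) {
    stop("ref must be a matrisome_reference", call. = FALSE)
  }
  if (!identical(ref$species, species)) {
    stop("species mismatch: reference is for '", ref$species,
         "', requested '", species, "'", call. = FALSE)
  }

  df <- as.data.frame(table, stringsAsFactors = FALSE)
  df[] <- lapply(df, as.character)
  # replace stale annotation columns so re-annotation is idempotent
  stale <- intersect(c(.div_col, .cat_col, .gocc_col), names(df))
  stale <- setdiff(stale, id_column)
  if (length(stale)) df <- df[setdiff(names(df), stale)]

  ids <- df[[id_column]]
  n <- length(ids)
  division <- rep(.non_matrisome, n)
  category <- rep(.non_matrisome, n)
  alias <- rep(NA_character_, n)
  namespace <- rep(NA_character_, n)
  symbol <- rep(NA_character_, n)

  if (n) {
    keysets <- normalize_identifier_list(ids)
    # flatten to one match() call: rows repeated per sub-identifier
    lens <- lengths(keysets)
    row_of <- rep(seq_len(n), lens)
    flat <- unlist(keysets, use.names = FALSE)
    if (length(flat)) {
      idx_keys <- names(ref$index)
      idx_entry <- vapply(ref$index, function(h) h$entry, numeric(1))
      idx_ns <- vapply(ref$index, function(h) h$namespace, character(1))
      ent_div <- vapply(ref$entries, `[[`, character(1), "division")
      ent_cat <- vapply(ref$entries, `[[`, character(1), "category")
      ent_sym <- vapply(ref$entries, `[[`, character(1), "gene_symbol")
      hit <- match(flat, idx_keys)
      ok <- which(!is.na(hit))
      if (length(ok)) {
        # first matching sub-identifier per row, in cell order
        first <- ok[!duplicated(row_of[ok])]
        rows <- row_of[first]
        e_i <- idx_entry[hit[first]]
        division[rows] <- ent_div[e_i]
        category[rows] <- ent_cat[e_i]
        alias[rows] <- flat[first]
        namespace[rows] <- idx_ns[hit[first]]
        symbol[rows] <- ent_sym[e_i]
      }
    }
    blank <- !nzchar(trimws(ids))
    if (any(blank)) {
      message(sum(blank), " blank identifier cell(s) annotated as ",
              .non_matrisome)
    }
  }

  n_match <- sum(division != .non_matrisome)
  if (n > 0L && n_match == 0L) {
    warning("no identifiers mapped to the ", species,
            " matrisome reference; review input choices ",
            "(identifier column and species)", call. = FALSE)
  }

  out <- data.frame(df[[id_column]], division, category,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(id_column, .div_col, .cat_col)
  if (!is.null(go_map)) {
    out[[.gocc_col]] <- annotate_gocc(ids, go_map)
  }
  rest <- setdiff(names(df), id_column)
  for (h in rest) out[[h]] <- df[[h]]

  # byte-wise order on the upper-cased identifier; ties broken by the row's
  # remaining cells so the sorted output is independent of input row order
  tiebreak <- if (length(rest)) {
    do.call(paste, c(df[rest], list(sep = "\r")))
  } else {
    character(nrow(out))
  }
  ord <- order(toupper(out[[id_column]]), tiebreak, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  match_log <- data.frame(
    identifier = ids[ord], matched_alias = alias[ord],
    namespace = namespace[ord], gene_symbol = symbol[ord],
    stringsAsFactors = FALSE)

  structure(out,
            id_column = id_column, species = species,
            match_log = match_log, n_matched = n_match,
            class = c("annotated_table", "data.frame"))
}

#' Read a local GO Cellular Component mapping table
#'
#' Two-column TSV (header row mandatory): identifier, GO:CC term text. One
#' row per (identifier, term) pair. Identifiers are normalized with the same
#' rule as reference aliases, so lookups are case-insensitive.
#'
#' @param path Path to the TSV.
#' @return A `gocc_map`: named list, normalized key -> character vector of
#'   terms (in file order, de-duplicated).
#' @export
read_gocc_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = character(0))
  if (ncol(df) < 2L) {
    stop("GO:CC map must have two columns (identifier, term)", call. = FALSE)
  }
  map <- list()
  for (i in seq_len(nrow(df))) {
    for (k in normalize_identifier(df[[1L]][i])) {
      term <- trimws(df[[2L]][i])
      if (!nzchar(term)) next
      map[[k]] <- unique(c(map[[k]], term))
    }
  }
  structure(map, class = "gocc_map")
}

#' Look up GO:CC terms for identifiers
#'
#' For each raw identifier, returns the semicolon-joined terms of the first
#' normalized sub-identifier present in the map, or empty text when none is.
#'
#' @param ids Character vector of raw identifiers.
#' @param go_map A `gocc_map` (or plain named list of term vectors keyed by
#'   normalized identifier).
#' @return Character vector, same length as `ids`.
#' @export
annotate_gocc <- function(ids, go_map) {
  vapply(normalize_identifier_list(ids), function(keys) {
    for (k in keys) {
      terms <- go_map[[k]]
      if (!is.null(terms)) return(paste(terms, collapse = ";"))
    }
    ""
  }, character(1))
}

#' @export
as.data.frame.annotated_table <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  for (a in c("id_column", "species", "match_log", "n_matched")) {
    attr(x, a) <- NULL
  }
  class(x) <- "data.frame"
  x
}

#' @export
print.annotated_table <- function(x, ...) {
  n <- nrow(x)
  cat("Annotated table: ", n, " rows, ", attr(x, "n_matched"),
      " matrisome (", if (n) round(100 * attr(x, "n_matched") / n, 1) else 0,
      "%), species ", attr(x, "species"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (n > 10) cat("... (", n - 10, " more rows)\n", sep = "")
  invisible(x)
}
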