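# matrianalyze: sum every coercible column of an annotated table by
# matrisome division and category, and count molecules per annotation.

.tabulation_rows <- c(
  "Core matrisome", "Matrisome-associated", "Non-matrisome",
  "ECM Glycoproteins", "Collagens", "Proteoglycans",
  "ECM-affiliated Proteins", "ECM Regulators", "Secreted Factors",
  "Non-matrisome (category)"
)

#' Tabulate numeric columns by matrisome annotation
#'
#' Sums the content of every numerically coercible column of an annotated
#' table by matrisome division and by matrisome category. Column
#' coercibility is decided by [coerce_numeric_columns()]: percent-formatted
#' columns and otherwise non-coercible text are excluded; any plain-number
#' column — including metadata such as molecular masses — is tabulated, so
#' not every output column is necessarily a meaningful quantity for every
#' dataset (the caller knows which columns are counts). Missing and empty
#' cells contribute 0.
#'
#' The output has a fixed row schema regardless of the data: first the three
#' divisions (Core matrisome, Matrisome-associated, Non-matrisome), then the
#' six categories plus "Non-matrisome (category)", so that outputs from
#' different datasets are directly comparable and diffable; annotations with
#' no member rows appear with sum 0. For integer inputs the sums are exact
#' and conserve the column total: the three division rows add up to the sum
#' of all coercible cells, as do the seven category rows, and each division
#' row equals the sum of its constituent category rows.
#'
#' @param table An `annotated_table` from [matriannotate()].
#' @return A `tabulation_table`: data frame with first column "Matrisome
#'   Annotations" and one numeric column per coercible input column.
#' @export
matrianalyze <- function(table) {
  if (!inherits(table, "annotated_table")) {
    stop("table must be an annotated_table (run matriannotate first)",
         call. = FALSE)
  }
  id_column <- attr(table, "id_column")
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  division <- df[[.div_col]]
  category <- df[[.cat_col]]

  data_cols <- setdiff(names(df), c(id_column, .div_col, .cat_col, .gocc_col))
  cls <- coerce_numeric_columns(df[data_cols], id_column = NULL)
  keep <- cls$header[cls$class == "coercible"]
  if (length(data_cols) && !length(keep)) {
    warning("no numerically coercible columns; tabulation has annotation ",
            "rows only", call. = FALSE)
  }

  out <- data.frame(`Matrisome Annotations` = .tabulation_rows,
                    check.names = FALSE, stringsAsFactors = FALSE)
  div_f <- factor(division, levels = .tabulation_rows[1:3])
  cat_levels <- c(.tabulation_rows[4:9], .non_matrisome)
  cat_f <- factor(category, levels = cat_levels)
  for (h in keep) {
    dec <- cls$decimal[cls$header == h]
    vals <- parse_numeric_column(df[[h]], decimal = dec)
    vals[is.na(vals)] <- 0
    div_sums <- vapply(split(vals, div_f), sum, numeric(1))
    cat_sums <- vapply(split(vals, cat_f), sum, numeric(1))
    out[[h]] <- c(unname(div_sums), unname(cat_sums))
  }
  structure(out, class = c("tabulation_table", "data.frame"))
}

#' Count molecules per matrisome division and category
#'
#' Row counts (molecule counts, not value sums) of an annotated table per
#' division and per category — the quantities behind the matribar charts.
#' Pure and order-free: permuting the input rows does not change the counts.
#'
#' @param table An `annotated_table`.
#' @return A `count_summary`: list with named integer vectors `divisions`
#'   (3 values) and `categories` (7 values, canonical order with
#'   Non-matrisome last), plus `n_rows`.
#' @export
summary_counts <- function(table) {
  if (!inherits(table, "annotated_table")) {
    stop("table must be an annotated_table", call. = FALSE)
  }
  div_levels <- .tabulation_rows[1:3]
  cat_levels <- c(.tabulation_rows[4:9], .non_matrisome)
  divisions <- table(factor(table[[.div_col]], levels = div_levels))
  categories <- table(factor(table[[.cat_col]], levels = cat_levels))
  structure(list(
    divisions  = stats::setNames(as.integer(divisions), div_levels),
    categories = stats::setNames(as.integer(categories), cat_levels),
    n_rows = nrow(table)
  ), class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat("Matrisome molecule counts (", x$n_rows, " rows)\n", sep = "")
  cat(" Divisions:\n")
  for (nm in names(x$divisions)) {
    cat("   ", format(nm, width = 24), x$divisions[[nm]], "\n")
  }
  cat(" Categories:\n")
  for (nm in names(x$categories)) {
    cat("   ", format(nm, width = 24), x$categories[[nm]], "\n")
  }
  invisible(x)
}
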