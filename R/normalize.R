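# Identifier normalization shared by the reference index and the annotator.
# Both sides must normalize identically or lookups silently fail, so this is
# the single definition.

.uniprot_acc_re <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
  "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
)

#' Normalize a raw identifier cell into lookup keys
#'
#' Turns the text of one identifier cell into zero or more normalized keys,
#' in cell order. Multi-identifier cells (common in proteomics exports, where
#' a protein group lists several accessions) are split on `;`, `,` or `|`.
#' Each piece is trimmed, upper-cased, and stripped of decorations that do
#' not change identity: a UniProt isoform suffix (`P02452-2` -> `P02452`,
#' applied only when the stem is a syntactically valid UniProt accession, so
#' nematode gene names such as `unc-52` are untouched) and a trailing
#' `.version` on Ensembl-style gene IDs (`ENSG00000108821.13` ->
#' `ENSG00000108821`).
#'
#' @param raw Character vector of raw identifier cells.
#' @return For a length-1 input, a character vector of normalized keys
#'   (possibly empty). For longer input, a list of such vectors.
#' @examples
#' normalize_identifier("col1a1 ")
#' normalize_identifier("P02452-2;JUNK1")
#' @export
normalize_identifier <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- lapply(strsplit(as.character(raw), "[;,|]"), function(parts) {
    parts <- toupper(trimws(parts))
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return(character(0))
    # Ensembl-style version suffix
    has_ver <- grepl("^ENS[A-Z0-9]+\\.[0-9]+$", parts)
    parts[has_ver] <- sub("\\.[0-9]+$", "", parts[has_ver])
    # UniProt isoform suffix, only when the stem is a real accession shape
    cand <- grepl("-[0-9]+$", parts)
    if (any(cand)) {
      stem <- sub("-[0-9]+$", "", parts[cand])
      ok <- grepl(.uniprot_acc_re, stem)
      parts[cand][ok] <- stem[ok]
    }
    parts
  })
  if (length(out) == 1L) out[[1L]] else out
}

# First normalized key per cell, "" when the cell yields none. Vectorized,
# used on whole identifier columns.
first_keys <- function(raw) {
  vapply(normalize_identifier_list(raw), function(k) {
    if (length(k)) k[[1L]] else ""
  }, character(1))
}

# Always-a-list variant of normalize_identifier.
normalize_identifier_list <- function(raw) {
  if (length(raw) == 0L) return(list())
  if (length(raw) == 1L) return(list(normalize_identifier(raw)))
  normalize_identifier(raw)
}
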