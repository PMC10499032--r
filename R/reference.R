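# Matrisome reference lists: loading, validation, and the normalized
# identifier index every annotation is matched against.

.matriomics_species <- c("human", "mouse", "zebrafish", "fruit_fly", "nematode")

.matriomics_divisions <- c("Core matrisome", "Matrisome-associated")

.matriomics_categories <- c(
  "ECM Glycoproteins", "Collagens", "Proteoglycans",
  "ECM-affiliated Proteins", "ECM Regulators", "Secreted Factors"
)

# namespace -> species allowed to carry it (NULL = all species)
.namespace_species <- list(
  gene_symbol   = NULL,
  ncbi_gene_ids = NULL,
  uniprot_ids   = NULL,
  ensembl_ids   = c("human", "mouse"),
  zfin_ids      = "zebrafish",
  flybase_ids   = "fruit_fly",
  wormbase_ids  = "nematode",
  common_names  = "nematode"
)

.reference_columns <- c(
  "species", "division", "category", "gene_symbol",
  "ncbi_gene_ids", "uniprot_ids", "ensembl_ids", "zfin_ids",
  "flybase_ids", "wormbase_ids", "common_names"
)

#' The fixed category-to-division map of the matrisome classification
#'
#' The matrisome classification is two-level: six categories, each belonging
#' to exactly one of two divisions. Structural components (ECM glycoproteins,
#' collagens, proteoglycans) form the core matrisome; ECM-affiliated
#' proteins, ECM regulators and secreted factors form the matrisome-associated
#' division. The map is constant across species and datasets.
#'
#' @return Named character vector, category -> division, with exactly six
#'   entries.
#' @examples
#' category_division_map()[["Collagens"]]
#' @export
category_division_map <- function() {
  c(
    "ECM Glycoproteins"       = "Core matrisome",
    "Collagens"               = "Core matrisome",
    "Proteoglycans"           = "Core matrisome",
    "ECM-affiliated Proteins" = "Matrisome-associated",
    "ECM Regulators"          = "Matrisome-associated",
    "Secreted Factors"        = "Matrisome-associated"
  )
}

# Canonicalize a division or category label: case/whitespace-insensitive
# match against the canonical spellings, plus the known short variants.
# Returns NA_character_ when the label is not recognizable.
canonical_category <- function(x) {
  key <- tolower(gsub("[[:space:]]+", " ", trimws(x)))
  alias <- c(
    "ecm glycoproteins" = "ECM Glycoproteins",
    "collagens" = "Collagens",
    "proteoglycans" = "Proteoglycans",
    "ecm-affiliated proteins" = "ECM-affiliated Proteins",
    "ecm-affiliated" = "ECM-affiliated Proteins",
    "ecm affiliated proteins" = "ECM-affiliated Proteins",
    "ecm regulators" = "ECM Regulators",
    "secreted factors" = "Secreted Factors"
  )
  unname(alias[key])
}

canonical_division <- function(x) {
  key <- tolower(gsub("[[:space:]]+", " ", trimws(x)))
  alias <- c(
    "core matrisome" = "Core matrisome",
    "matrisome-associated" = "Matrisome-associated",
    "matrisome associated" = "Matrisome-associated"
  )
  unname(alias[key])
}

# Split a ":"-delimited list cell into its (possibly empty) id vector.
split_list_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  parts <- trimws(strsplit(cell, ":", fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

#' Load and index a matrisome reference list
#'
#' Reads a per-species matrisome reference CSV (or one of the bundled test
#' fixtures), validates it with [validate_reference()], and builds the
#' normalized identifier index used for annotation. The CSV schema has one
#' row per matrisome gene with columns `species`, `division`, `category`,
#' `gene_symbol`, and the identifier-list columns `ncbi_gene_ids`,
#' `uniprot_ids`, `ensembl_ids`, `zfin_ids`, `flybase_ids`, `wormbase_ids`,
#' `common_names`; list cells hold zero or more identifiers delimited by
#' `":"`. Species-specific namespaces may only be populated for the species
#' they belong to (Ensembl: human/mouse; ZFIN: zebrafish; FlyBase: fruit
#' fly; WormBase and common names: nematode).
#'
#' Bundled fixtures are addressed by tag: `"test-human"`, `"test-mouse"`,
#' `"test-zebrafish"`, `"test-fruit_fly"`, `"test-nematode"` (12 entries
#' each, two per category, every legal namespace populated). They are small
#' synthetic test lists, not the curated matrisome lists of the Matrisome
#' Project; a real list converted to this schema loads the same way.
#'
#' @param source Path to a reference CSV, or a bundled fixture tag.
#' @param species Species tag, one of `"human"`, `"mouse"`, `"zebrafish"`,
#'   `"fruit_fly"`, `"nematode"`. Must agree with the file's `species`
#'   column.
#' @return A `matrisome_reference` object: entries in file order plus a
#'   normalized-key index recording, for each key, the owning entry and the
#'   namespace of the matching alias.
#' @seealso [validate_reference()], [matriannotate()]
#' @examples
#' ref <- load_reference("test-human", "human")
#' ref$index[["COL1A1"]]
#' @export
load_reference <- function(source, species) {
  species <- match.arg(species, .matriomics_species)
  path <- source
  if (grepl("^test-", source) && !file.exists(source)) {
    path <- system.file("extdata",
                        paste0("reference-", source, ".csv"),
                        package = "matriomics")
    if (!nzchar(path)) {
      stop("unknown bundled reference tag: ", source, call. = FALSE)
    }
  }
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  missing <- setdiff(.reference_columns, names(raw))
  if (length(missing)) {
    stop("reference schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  entries <- lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, , drop = FALSE]
    division <- canonical_division(row$division)
    category <- canonical_category(row$category)
    if (is.na(category)) {
      stop("reference schema error: row ", i, ": unknown category label '",
           row$category, "'", call. = FALSE)
    }
    if (is.na(division)) {
      stop("reference schema error: row ", i, ": unknown division label '",
           row$division, "'", call. = FALSE)
    }
    structure(list(
      species       = trimws(row$species),
      division      = division,
      category      = category,
      gene_symbol   = trimws(row$gene_symbol),
      ncbi_gene_ids = split_list_cell(row$ncbi_gene_ids),
      uniprot_ids   = split_list_cell(row$uniprot_ids),
      ensembl_ids   = split_list_cell(row$ensembl_ids),
      zfin_ids      = split_list_cell(row$zfin_ids),
      flybase_ids   = split_list_cell(row$flybase_ids),
      wormbase_ids  = split_list_cell(row$wormbase_ids),
      common_names  = split_list_cell(row$common_names)
    ), class = "matrisome_entry")
  })

  report <- validate_reference(entries, species = species)
  if (!report$ok) {
    err <- report$issues[report$issues$severity == "error", , drop = FALSE]
    stop("reference validation failed (", nrow(err), " error(s)):\n",
         paste0("  [", err$entry, "] ", err$message, collapse = "\n"),
         call. = FALSE)
  }

  structure(list(
    species = species,
    entries = entries,
    index   = build_reference_index(entries),
    validation = report,
    source  = path
  ), class = "matrisome_reference")
}

# All (normalized key, namespace) aliases of one entry, in namespace order.
entry_aliases <- function(entry) {
  ns <- names(.namespace_species)
  keys <- character(0); spaces <- character(0)
  for (n in ns) {
    vals <- if (n == "gene_symbol") entry$gene_symbol else entry[[n]]
    for (v in vals) {
      for (k in normalize_identifier(v)) {
        keys <- c(keys, k); spaces <- c(spaces, n)
      }
    }
  }
  keep <- !duplicated(keys)
  data.frame(key = keys[keep], namespace = spaces[keep],
             stringsAsFactors = FALSE)
}

# index: named list key -> list(entry = integer index, namespace = chr).
# First-loaded entry wins for keys shared by entries with identical
# classification (validation has already refused conflicting ones).
build_reference_index <- function(entries) {
  index <- list()
  for (i in seq_along(entries)) {
    al <- entry_aliases(entries[[i]])
    for (j in seq_len(nrow(al))) {
      k <- al$key[j]
      if (is.null(index[[k]])) {
        index[[k]] <- list(entry = i, namespace = al$namespace[j])
      }
    }
  }
  index
}

#' Validate a set of matrisome reference entries
#'
#' Checks the structural invariants of a reference list and returns a report
#' rather than throwing: every category label must imply its division under
#' [category_division_map()]; gene symbols must be non-empty; species-specific
#' identifier namespaces may only be populated for their species; and a
#' normalized identifier key shared by two entries is a warning when both
#' entries carry the same (division, category) classification (aliases do
#' legitimately collide in real lists) but an error when the classifications
#' conflict, since a conflicting key would make annotation ambiguous.
#'
#' @param entries List of `matrisome_entry` objects (as built by
#'   [load_reference()]).
#' @param species Optional species tag; when given, every entry's `species`
#'   field and namespace usage is checked against it.
#' @return A `validation_report`: `ok` (TRUE iff no error-severity issue) and
#'   `issues`, a data frame with columns severity, entry, message.
#' @export
validate_reference <- function(entries, species = NULL) {
  sev <- character(0); loc <- character(0); msg <- character(0)
  note <- function(s, l, m) {
    sev <<- c(sev, s); loc <<- c(loc, l); msg <<- c(msg, m)
  }
  cmap <- category_division_map()

  for (i in seq_along(entries)) {
    e <- entries[[i]]
    where <- paste0("entry ", i, " (", e$gene_symbol, ")")
    if (!nzchar(e$gene_symbol)) {
      note("error", paste0("entry ", i), "gene_symbol is empty")
    }
    if (!e$category %in% names(cmap)) {
      note("error", where, paste0("unknown category '", e$category, "'"))
    } else if (!identical(cmap[[e$category]], e$division)) {
      note("error", where, paste0(
        "division '", e$division, "' inconsistent with category '",
        e$category, "': the category/division map requires '",
        cmap[[e$category]], "'"))
    }
    sp <- if (is.null(species)) e$species else species
    if (!is.null(species) && nzchar(e$species) && e$species != species) {
      note("error", where,
           paste0("entry species '", e$species, "' does not match '",
                  species, "'"))
    }
    for (ns in names(.namespace_species)) {
      allowed <- .namespace_species[[ns]]
      if (!is.null(allowed) && length(e[[ns]]) && !(sp %in% allowed)) {
        note("error", where, paste0(
          "namespace ", ns, " is not legal for species '", sp, "'"))
      }
    }
  }

  # cross-entry alias collisions
  all_al <- lapply(entries, entry_aliases)
  keys <- unlist(lapply(all_al, function(a) a$key), use.names = FALSE)
  owner <- rep(seq_along(entries), vapply(all_al, nrow, integer(1)))
  if (length(keys)) {
    dup_keys <- unique(keys[duplicated(keys)])
    for (k in dup_keys) {
      own <- unique(owner[keys == k])
      if (length(own) < 2L) next
      cls <- unique(vapply(entries[own], function(e) {
        paste(e$division, e$category, sep = " / ")
      }, character(1)))
      ents <- paste0("entries ", paste(own, collapse = ","))
      if (length(cls) > 1L) {
        note("error", ents, paste0(
          "conflicting classification for shared key '", k, "': ",
          paste(cls, collapse = " vs ")))
      } else {
        note("warning", ents, paste0(
          "benign alias collision on key '", k, "' (identical classification)"))
      }
    }
  }

  issues <- data.frame(severity = sev, entry = loc, message = msg,
                       stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.matrisome_reference <- function(x, ...) {
  cat("Matrisome reference (", x$species, "): ", length(x$entries),
      " entries, ", length(x$index), " indexed identifier keys\n", sep = "")
  tab <- table(vapply(x$entries, `[[`, character(1), "category"))
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Reference validation:", if (x$ok) "OK" else "FAILED", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      cat("  [", x$issues$severity[i], "] ", x$issues$entry[i], ": ",
          x$issues$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Look up one identifier in a reference index
#'
#' Convenience lookup: normalizes `id` and returns the classification of the
#' first key present in the index, or NULL when none matches.
#'
#' @param ref A `matrisome_reference`.
#' @param id A single raw identifier (may be a multi-ID cell).
#' @return A list (gene_symbol, division, category, matched_alias, namespace)
#'   or NULL.
#' @export
reference_lookup <- function(ref, id) {
  for (k in normalize_identifier(id)) {
    hit <- ref$index[[k]]
    if (!is.null(hit)) {
      e <- ref$entries[[hit$entry]]
      return(list(gene_symbol = e$gene_symbol, division = e$division,
                  category = e$category, matched_alias = k,
                  namespace = hit$namespace))
    }
  }
  NULL
}
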