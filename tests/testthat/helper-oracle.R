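# Shared test helpers: an index-free brute-force annotation oracle, raw
# alias enumeration, and a case-styling utility.

# All raw alias strings of one reference entry, by namespace, in namespace
# order (gene symbol, NCBI, UniProt, then species-specific).
raw_aliases <- function(entry) {
  ns <- c("gene_symbol", "ncbi_gene_ids", "uniprot_ids", "ensembl_ids",
          "zfin_ids", "flybase_ids", "wormbase_ids", "common_names")
  unlist(lapply(ns, function(n) {
    if (n == "gene_symbol") entry$gene_symbol else entry[[n]]
  }), use.names = FALSE)
}

# Brute-force annotation: O(rows x entries x aliases) linear scan, no index.
# For each row, the first normalized sub-identifier (cell order) matching
# any alias of any entry wins; among entries, the first loaded wins.
brute_annotate <- function(ids, ref) {
  entry_keysets <- lapply(ref$entries, function(e) {
    unique(unlist(lapply(raw_aliases(e), normalize_identifier),
                  use.names = FALSE))
  })
  div <- vapply(ref$entries, `[[`, character(1), "division")
  cat <- vapply(ref$entries, `[[`, character(1), "category")
  out_div <- rep("Non-matrisome", length(ids))
  out_cat <- rep("Non-matrisome", length(ids))
  for (i in seq_along(ids)) {
    keys <- normalize_identifier(ids[[i]])
    found <- FALSE
    for (k in keys) {
      if (found) break
      for (j in seq_along(entry_keysets)) {
        if (k %in% entry_keysets[[j]]) {
          out_div[i] <- div[j]
          out_cat[i] <- cat[j]
          found <- TRUE
          break
        }
      }
    }
  }
  data.frame(division = out_div, category = out_cat,
             stringsAsFactors = FALSE)
}

# aLtErNaTiNg-case transform (digits untouched).
mixed_case <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    odd <- seq_along(ch) %% 2 == 1
    ch[odd] <- toupper(ch[odd])
    ch[!odd] <- tolower(ch[!odd])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

bundled_species <- c("human", "mouse", "zebrafish", "fruit_fly", "nematode")

load_test_reference <- function(species = "human") {
  load_reference(paste0("test-", species), species)
}

# Annotate quietly: the generated tables legitimately trigger blank-cell
# messages and zero-match warnings in edge-case fixtures.
annotate_quietly <- function(...) {
  suppressWarnings(suppressMessages(matriannotate(...)))
}
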