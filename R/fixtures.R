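# Deterministic synthetic fixture generator. Emulates the shape of the
# tabular inputs the annotator sees in practice — most importantly a
# label-free proteomics table: an accession column, per-sample integer
# spectral-count columns, a plain-number molecular-mass column and a
# percent-formatted identification-probability column (so the
# percent-exclusion path of the tabulator is always exercised).

#' Generate a synthetic omics table
#'
#' Builds an in-memory test table of the requested kind. A fraction
#' `matrisome_fraction` of rows carries identifiers drawn from the given
#' matrisome reference (random alias, random namespace, random case,
#' occasionally decorated with an isoform suffix or packed into a
#' multi-identifier cell); the remainder are decoy identifiers guaranteed
#' not to match. Fully deterministic under `seed`.
#'
#' Kinds:
#' \describe{
#'   \item{proteomics}{accession column, `n_samples` integer total-spectra
#'     columns, a `Molecular Weight` column (kDa, plain numbers) and an
#'     `Identification Probability` percent column.}
#'   \item{expression}{gene column, a categorical `cluster` column and
#'     `n_samples` decimal mean-expression columns.}
#'   \item{exome-counts}{gene column and `n_samples` integer mutation-count
#'     columns.}
#' }
#'
#' @param kind `"proteomics"`, `"expression"` or `"exome-counts"`.
#' @param n_rows Number of data rows (> 0).
#' @param n_samples Number of per-sample numeric columns.
#' @param matrisome_fraction Fraction of rows with matrisome identifiers,
#'   in `[0, 1]`.
#' @param ref A `matrisome_reference` supplying the identifier pool
#'   (default: the bundled human test reference).
#' @param seed Integer seed.
#' @return An `omics_table` (character cells).
#' @export
make_fixture_table <- function(kind = c("proteomics", "expression",
                                        "exome-counts"),
                               n_rows = 500L, n_samples = 3L,
                               matrisome_fraction = 0.25,
                               ref = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(n_rows) || n_rows < 1) {
    stop("n_rows must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(matrisome_fraction) ||
      matrisome_fraction < 0 || matrisome_fraction > 1) {
    stop("matrisome_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_samples <- as.integer(n_samples)
  if (is.null(ref)) ref <- load_reference("test-human", "human")

  set.seed(as.integer(seed))
  n_mat <- round(n_rows * matrisome_fraction)
  ids <- c(sample_matrisome_ids(ref, n_mat),
           sprintf("DECOY%05d", seq_len(n_rows - n_mat)))
  ids <- ids[sample.int(n_rows)]

  df <- switch(kind,
    proteomics = {
      out <- data.frame(`Protein Accession` = ids, check.names = FALSE,
                        stringsAsFactors = FALSE)
      for (s in seq_len(n_samples)) {
        out[[sprintf("Total Spectra Sample_%d", s)]] <-
          as.character(stats::rnbinom(n_rows, size = 2, mu = 20))
      }
      out[["Molecular Weight"]] <-
        sprintf("%.1f", stats::rlnorm(n_rows, log(50), 0.5))
      out[["Identification Probability"]] <-
        sprintf("%.1f%%", 90 + 10 * stats::runif(n_rows))
      out
    },
    expression = {
      out <- data.frame(gene = ids, stringsAsFactors = FALSE)
      out$cluster <- sample(c("B cells", "NK cells", "Platelets"),
                            n_rows, replace = TRUE)
      for (s in seq_len(n_samples)) {
        out[[sprintf("mean_expr_cluster_%d", s)]] <-
          sprintf("%.3f", stats::rgamma(n_rows, shape = 1.2, rate = 0.8))
      }
      out
    },
    `exome-counts` = {
      out <- data.frame(gene = ids, stringsAsFactors = FALSE)
      for (s in seq_len(n_samples)) {
        out[[sprintf("mutations_subtype_%d", s)]] <-
          as.character(stats::rpois(n_rows, 4))
      }
      out
    })
  as_omics_table(df, source = paste0("synthetic:", kind), dialect = ",")
}

# Draw n identifier cells that are guaranteed to hit the reference:
# random entry, random populated namespace, random case styling, and
# occasional isoform suffix / multi-ID packing.
sample_matrisome_ids <- function(ref, n) {
  if (n == 0L) return(character(0))
  pool <- do.call(rbind, lapply(ref$entries, function(e) {
    # use the raw alias forms, not the normalized keys
    raw <- unlist(lapply(names(.namespace_species), function(ns) {
      if (ns == "gene_symbol") e$gene_symbol else e[[ns]]
    }), use.names = FALSE)
    data.frame(raw = raw, stringsAsFactors = FALSE)
  }))$raw
  picked <- sample(pool, n, replace = TRUE)
  style <- sample.int(4, n, replace = TRUE)
  picked[style == 2] <- tolower(picked[style == 2])
  # isoform decoration only where the normalized form survives it
  iso <- style == 3 & grepl(.uniprot_acc_re, toupper(picked))
  picked[iso] <- paste0(picked[iso], "-2")
  multi <- style == 4
  picked[multi] <- paste0(picked[multi], ";",
                          sprintf("JUNK%03d", seq_len(sum(multi))))
  picked
}

#' Write synthetic fixture files to disk
#'
#' Generates a table with [make_fixture_table()] and writes it as CSV. The
#' output is byte-identical for identical arguments (including `seed`).
#'
#' @inheritParams make_fixture_table
#' @param dir Output directory (created if missing).
#' @param name File name stem (default the kind).
#' @return Invisibly, the path of the written CSV.
#' @export
make_fixture <- function(kind = c("proteomics", "expression",
                                  "exome-counts"),
                         dir, n_rows = 500L, n_samples = 3L,
                         matrisome_fraction = 0.25, ref = NULL,
                         seed = 1L, name = NULL) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- make_fixture_table(kind, n_rows = n_rows, n_samples = n_samples,
                            matrisome_fraction = matrisome_fraction,
                            ref = ref, seed = seed)
  path <- file.path(dir, paste0(if (is.null(name)) kind else name, ".csv"))
  write_csv(tab, path)
  invisible(path)
}
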