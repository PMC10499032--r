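test_that("identifier normalization trims, folds, splits and strips", {
  expect_identical(normalize_identifier("col1a1 "), "COL1A1")
  expect_identical(normalize_identifier("P02452-2"), "P02452")
  expect_identical(normalize_identifier("P02452;Q9XYZ1"),
                   c("P02452", "Q9XYZ1"))
  expect_identical(normalize_identifier("a|b,c"), c("A", "B", "C"))
  expect_identical(normalize_identifier("ENSG00000108821.13"),
                   "ENSG00000108821")
  # nematode-style gene names keep their hyphen-digit suffix
  expect_identical(normalize_identifier("unc-52"), "UNC-52")
  expect_identical(normalize_identifier(""), character(0))
  expect_identical(normalize_identifier("  ;  "), character(0))
})

test_that("matched and unmatched rows get the stored classification", {
  ref <- load_test_reference("human")
  tab <- data.frame(id = c("COL1A1", "ZZZ999", "P02452-2;JUNK1"),
                    count = c("3", "2", "5"), stringsAsFactors = FALSE)
  ann <- matriannotate(tab, "id", "human", ref)
  df <- as.data.frame(ann)
  expect_identical(df[["Annotated Matrisome Division"]],
                   c("Core matrisome", "Core matrisome", "Non-matrisome"))
  expect_identical(df[["Annotated Matrisome Category"]],
                   c("Collagens", "Collagens", "Non-matrisome"))
  log <- attr(ann, "match_log")
  iso <- which(log$identifier == "P02452-2;JUNK1")
  expect_identical(log$matched_alias[iso], "P02452")
  expect_identical(log$namespace[iso], "uniprot_ids")
})

test_that("output layout and row order follow the annotated-table contract", {
  ref <- load_test_reference("human")
  tab <- data.frame(extra1 = letters[1:4],
                    id = c("MMP2", "acan", "ZZZ1", "FN1"),
                    extra2 = as.character(1:4), stringsAsFactors = FALSE)
  ann <- matriannotate(tab, "id", "human", ref)
  expect_identical(names(ann)[1:3],
                   c("id", "Annotated Matrisome Division",
                     "Annotated Matrisome Category"))
  # original non-identifier columns keep their original relative order
  expect_identical(names(ann)[4:5], c("extra1", "extra2"))
  expect_identical(ann$id, c("acan", "FN1", "MMP2", "ZZZ1"))
  # cells travel with their rows
  expect_identical(ann$extra1[ann$id == "acan"], "b")
})

test_that("parameter errors name the problem", {
  ref <- load_test_reference("human")
  tab <- data.frame(id = "FN1", stringsAsFactors = FALSE)
  expect_error(matriannotate(tab, "nope", "human", ref), "id_column")
  expect_error(matriannotate(tab, "id", "mouse", ref), "species mismatch")
})

test_that("zero matches still succeed with a review-input warning", {
  ref <- load_test_reference("human")
  tab <- data.frame(id = c("XX1", "XX2"), stringsAsFactors = FALSE)
  expect_warning(ann <- matriannotate(tab, "id", "human", ref),
                 "review input choices")
  expect_identical(nrow(ann), 2L)
  expect_true(all(ann[["Annotated Matrisome Division"]] == "Non-matrisome"))
})

test_that("blank identifiers are kept, logged and non-matrisome", {
  ref <- load_test_reference("human")
  tab <- data.frame(id = c("FN1", "", "  "), stringsAsFactors = FALSE)
  expect_message(ann <- matriannotate(tab, "id", "human", ref),
                 "blank identifier")
  expect_identical(nrow(ann), 3L)
  blank_rows <- !nzchar(trimws(ann$id))
  expect_true(all(ann[["Annotated Matrisome Category"]][blank_rows] ==
                    "Non-matrisome"))
})

test_that("every fixture alias annotates correctly in any case", {
  for (sp in bundled_species) {
    ref <- load_test_reference(sp)
    for (e in ref$entries) {
      raw <- raw_aliases(e)
      variants <- c(toupper(raw), tolower(raw), mixed_case(raw))
      tab <- data.frame(id = variants, stringsAsFactors = FALSE)
      ann <- matriannotate(tab, "id", sp, ref)
      expect_true(all(ann[["Annotated Matrisome Division"]] == e$division),
                  info = paste(sp, e$gene_symbol))
      expect_true(all(ann[["Annotated Matrisome Category"]] == e$category),
                  info = paste(sp, e$gene_symbol))
    }
  }
})

test_that("annotation conserves rows, ignores input order, and is idempotent", {
  ref <- load_test_reference("human")
  set.seed(5)
  for (i in 1:20) {
    tab <- make_fixture_table("proteomics", n_rows = sample(5:80, 1),
                              matrisome_fraction = runif(1), seed = i)
    ann <- annotate_quietly(tab, "Protein Accession", "human", ref)
    expect_identical(nrow(ann), nrow(tab))

    perm <- tab[sample.int(nrow(tab)), , drop = FALSE]
    ann_perm <- annotate_quietly(perm, "Protein Accession", "human", ref)
    expect_identical(as.data.frame(ann), as.data.frame(ann_perm))

    again <- annotate_quietly(ann, "Protein Accession", "human", ref)
    expect_identical(
      again[["Annotated Matrisome Division"]],
      ann[["Annotated Matrisome Division"]])
    expect_identical(
      again[["Annotated Matrisome Category"]],
      ann[["Annotated Matrisome Category"]])
  }
})

test_that("indexed matching equals the brute-force oracle", {
  ref <- load_test_reference("human")
  set.seed(31)
  for (i in 1:15) {
    tab <- make_fixture_table("proteomics", n_rows = sample(20:300, 1),
                              matrisome_fraction = runif(1), seed = 100 + i)
    ids <- tab[["Protein Accession"]]
    ann <- annotate_quietly(tab, "Protein Accession", "human", ref)
    oracle <- brute_annotate(ids, ref)
    ord <- order(toupper(ids), method = "radix")
    expect_identical(ann[["Annotated Matrisome Division"]],
                     oracle$division[ord])
    expect_identical(ann[["Annotated Matrisome Category"]],
                     oracle$category[ord])
  }
})

test_that("GO:CC terms join per identifier with shared normalization", {
  map_path <- system.file("extdata", "gocc-test.tsv", package = "matriomics")
  gomap <- read_gocc_map(map_path)
  expect_identical(annotate_gocc("ALB", gomap),
                   "extracellular region;blood microparticle")
  expect_identical(annotate_gocc("alb", gomap),
                   "extracellular region;blood microparticle")
  expect_identical(annotate_gocc("UNKNOWN9", gomap), "")
  expect_identical(annotate_gocc(c("ALB", "ACTB"), gomap),
                   c("extracellular region;blood microparticle", "cytoplasm"))

  ref <- load_test_reference("human")
  tab <- data.frame(id = c("ALB", "COL1A1"), stringsAsFactors = FALSE)
  ann <- suppressWarnings(
    matriannotate(tab, "id", "human", ref, go_map = gomap))
  expect_identical(names(ann)[4],
                   "Annotated Gene Ontology: Cellular Component")
  # GO:CC is populated for matrisome rows too
  expect_identical(
    ann[["Annotated Gene Ontology: Cellular Component"]][ann$id == "COL1A1"],
    "collagen type I trimer;extracellular matrix")
})
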