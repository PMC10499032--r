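make_summary <- function(seed, n = 50, frac = 0.5) {
  ref <- load_test_reference("human")
  tab <- make_fixture_table("proteomics", n_rows = n,
                            matrisome_fraction = frac, seed = seed)
  summary_counts(annotate_quietly(tab, "Protein Accession", "human", ref))
}

test_that("matribar heights are the molecule counts in fixed order", {
  cs <- make_summary(1)
  spec <- matribar(cs)
  expect_identical(spec$kind, "matribar")
  div <- spec$groups[spec$groups$panel == "Divisions", ]
  expect_identical(div$label, names(cs$divisions))
  expect_identical(div$value, unname(cs$divisions))
  cat <- spec$groups[spec$groups$panel == "Categories", ]
  expect_identical(cat$value, unname(cs$categories))
  # an all-zero summary still builds a spec
  ref <- load_test_reference("human")
  empty <- annotate_quietly(
    data.frame(id = character(0), stringsAsFactors = FALSE),
    "id", "human", ref)
  spec0 <- matribar(summary_counts(empty))
  expect_true(all(spec0$groups$value == 0))
})

test_that("matriring fractions are count proportions and sum to 1", {
  cs <- make_summary(2)
  spec <- matriring(cs, "categories")
  expect_equal(sum(spec$hints$fraction), 1, tolerance = 1e-9)
  expect_equal(spec$hints$fraction,
               unname(cs$categories) / sum(cs$categories))
  # hand-checked proportions: collagens 8 of 10, non-matrisome 2 of 10
  ref <- load_test_reference("human")
  tab <- data.frame(id = c(rep("COL1A1", 8), "X1", "X2"),
                    stringsAsFactors = FALSE)
  cs2 <- summary_counts(annotate_quietly(tab, "id", "human", ref))
  s2 <- matriring(cs2, "categories")
  f <- stats::setNames(s2$hints$fraction, s2$groups$label)
  expect_equal(f[["Collagens"]], 0.8)
  expect_equal(f[["Non-matrisome"]], 0.2)
  # single non-zero group and the all-zero error
  one <- summary_counts(annotate_quietly(
    data.frame(id = "COL1A1", stringsAsFactors = FALSE), "id", "human", ref))
  expect_equal(max(matriring(one, "divisions")$hints$fraction), 1)
  empty <- summary_counts(annotate_quietly(
    data.frame(id = character(0), stringsAsFactors = FALSE),
    "id", "human", ref))
  expect_error(matriring(empty, "divisions"), "all counts are zero")
})

test_that("matristar widths follow counts and heights follow values", {
  vals <- c("Collagens" = 2, "Proteoglycans" = 2)
  cnts <- c("Collagens" = 1L, "Proteoglycans" = 3L)
  spec <- matristar(vals, cnts)
  w <- spec$hints$width_fraction
  expect_equal(w[2] / w[1], 3)
  vals2 <- c("Collagens" = 2, "Proteoglycans" = 4)
  cnts2 <- c("Collagens" = 2L, "Proteoglycans" = 2L)
  h <- matristar(vals2, cnts2)$hints$height
  expect_equal(h[2] / h[1], 2)
  # zero-count categories are dropped from rendering
  vals3 <- c("Collagens" = 2, "Secreted Factors" = 5)
  cnts3 <- c("Collagens" = 4L, "Secreted Factors" = 0L)
  s3 <- matristar(vals3, cnts3)
  expect_identical(s3$groups$label, "Collagens")
  expect_error(matristar(c("Collagens" = -1), c("Collagens" = 2L)),
               "non-negative")
  expect_error(matristar(c("Weird" = 1), c("Weird" = 1L)),
               "unknown categories")
})

test_that("matriflow weights cross-tabulate rows exactly", {
  ref <- load_test_reference("human")
  set.seed(3)
  tab <- make_fixture_table("expression", n_rows = 120,
                            matrisome_fraction = 0.5, seed = 4)
  ann <- annotate_quietly(tab, "gene", "human", ref)
  spec <- matriflow(ann, "cluster")
  # per-source totals equal per-source row counts
  src_tot <- tapply(spec$groups$weight, spec$groups$source, sum)
  row_tot <- table(ann$cluster)
  for (s in names(src_tot)) {
    expect_identical(as.integer(src_tot[[s]]), as.integer(row_tot[[s]]))
  }
  # triples equal an independent contingency table
  xt <- table(ann$cluster, ann[["Annotated Matrisome Category"]])
  for (i in seq_len(nrow(spec$groups))) {
    g <- spec$groups[i, ]
    expect_identical(as.integer(g$weight), as.integer(xt[g$source, g$target]))
  }
  # single group: flows equal the category counts
  one <- ann
  one$cluster <- "only"
  cs <- summary_counts(ann)
  f1 <- matriflow(one, "cluster")$groups
  nonzero <- cs$categories[cs$categories > 0]
  expect_identical(stats::setNames(as.integer(f1$weight), f1$target),
                   nonzero[f1$target])
  expect_error(matriflow(ann, "nope"), "grouping column")
})

test_that("the palette is a pure constant across charts and datasets", {
  p1 <- matrisome_palette()
  p2 <- matrisome_palette()
  expect_identical(p1, p2)
  s1 <- matribar(make_summary(10))
  s2 <- matribar(make_summary(11, n = 200, frac = 0.1))
  expect_identical(s1$palette[["Collagens"]], s2$palette[["Collagens"]])
  ring <- matriring(make_summary(12), "divisions")
  expect_identical(ring$palette[["Core matrisome"]],
                   p1[["Core matrisome"]])
})

test_that("rendering writes files, returns objects, and is deterministic", {
  cs <- make_summary(6)
  dir <- withr::local_tempdir()
  pdf_path <- file.path(dir, "bar.pdf")
  render_chart(matribar(cs), pdf_path, format = "pdf")
  expect_true(file.exists(pdf_path) && file.info(pdf_path)$size > 0)

  obj <- render_chart(matribar(cs), show = FALSE)
  expect_s3_class(obj, "ggplot")
  expect_identical(list.files(dir), "bar.pdf")

  for (spec in list(matriring(cs, "categories"),
                    matristar(c("Collagens" = 1, "Proteoglycans" = 2),
                              c("Collagens" = 2L, "Proteoglycans" = 1L)))) {
    p <- file.path(dir, paste0(spec$kind, ".pdf"))
    render_chart(spec, p)
    expect_true(file.info(p)$size > 0)
  }

  ref <- load_test_reference("human")
  expr_tab <- make_fixture_table("expression", n_rows = 40,
                                 matrisome_fraction = 0.5, seed = 9)
  flow <- matriflow(annotate_quietly(expr_tab, "gene", "human", ref),
                    "cluster")
  flow_path <- file.path(dir, "flow.pdf")
  render_chart(flow, flow_path)
  expect_true(file.info(flow_path)$size > 0)

  a <- file.path(dir, "a.png"); b <- file.path(dir, "b.png")
  render_chart(matribar(cs), a, format = "png")
  render_chart(matribar(cs), b, format = "png")
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
})

test_that("chart specs serialize to stable JSON", {
  cs <- make_summary(7)
  j1 <- chart_spec_json(matriring(cs, "divisions"))
  j2 <- chart_spec_json(matriring(cs, "divisions"))
  expect_identical(as.character(j1), as.character(j2))
  parsed <- jsonlite::fromJSON(j1)
  expect_identical(parsed$kind, "matriring")
  expect_equal(sum(parsed$hints$fraction), 1, tolerance = 1e-9)
})
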