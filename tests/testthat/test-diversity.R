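toy_table <- function(counts, expected = NULL) {
  clone_count_table(counts, expected_totals = expected)
}

toy_compositions <- function(n_irds_by_gene) {
  lapply(names(n_irds_by_gene), function(g) {
    structure(list(gene_id = g, sp_label = 1L,
                   ird_labels = seq_len(n_irds_by_gene[[g]]),
                   n_irds = n_irds_by_gene[[g]], is_partial = FALSE),
              class = "gene_composition")
  })
}

test_that("column validation reports sums against expected depths", {
  t1 <- canpi_clone_library()
  v <- validate_table(t1$counts)
  expect_equal(v$total[v$treatment == "W+OS"], 60)
  expect_equal(v$total[v$treatment == "UL"], 25)
  expect_true(all(v$expected[v$treatment != "UL"] == 60))

  m <- matrix(c(30L, 29L), 1, 2,
              dimnames = list("g1", c("t1", "t2")))
  v2 <- validate_table(toy_table(m, c(t1 = 30, t2 = 60)))
  expect_identical(v2$matches, c(TRUE, FALSE))   # flagged, not an error

  expect_error(clone_count_table(matrix(-1L, 1, 1,
                                        dimnames = list("g", "t"))),
               "non-negative")
  expect_error(clone_count_table(matrix(1.5, 1, 1,
                                        dimnames = list("g", "t"))),
               "integer")

  empty <- toy_table(matrix(integer(0), 0, 0,
                            dimnames = list(character(0), character(0))))
  expect_equal(nrow(validate_table(empty)), 0)
})

test_that("class abundance reproduces the printed induction percentages", {
  t1 <- canpi_clone_library()
  pct4 <- function(tr) {
    ca <- class_abundance(t1$counts, t1$compositions, tr)
    ca$percent[ca$n_irds == 4]
  }
  expect_equal(pct4("W+OS"), 38)
  expect_equal(pct4("AI"), 12)
  expect_equal(pct4("W+W"), 17)
  ca_wos <- class_abundance(t1$counts, t1$compositions, "W+OS")
  expect_equal(ca_wos$percent[ca_wos$n_irds == 2], 10)
  for (tr in t1$counts$treatments) {
    ca <- class_abundance(t1$counts, t1$compositions, tr)
    expect_gte(ca$percent[ca$n_irds == 3], 40)
    # class counts sum to the column total
    expect_equal(sum(ca$count), sum(t1$counts$counts[, tr]))
  }
})

test_that("toy class abundance uses observed totals when no depth is given", {
  m <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("gA", "gB"), "t"))
  comp <- toy_compositions(c(gA = 4L, gB = 2L))
  ca <- class_abundance(toy_table(m), comp, "t")
  expect_equal(ca$percent[ca$n_irds == 4], 75)
  expect_error(
    class_abundance(toy_table(matrix(0L, 1, 1,
                                     dimnames = list("gA", "t"))),
                    comp, "t"),
    "no clones")
})

test_that("gene frequencies divide by sequencing depth, absent when zero", {
  t1 <- canpi_clone_library()
  gf <- gene_frequency(t1$counts)
  wos <- gf[gf$treatment == "W+OS", ]
  expect_equal(wos$fraction[wos$gene == "CanPI-7"], 12 / 60)
  expect_equal(wos$gene[which.max(wos$fraction)], "CanPI-7")
  expect_false("CanPI-6" %in% gf$gene)           # zero in every treatment
  expect_true(all(gf$count > 0))
})

test_that("expression partition assigns each expressed gene to one region", {
  m <- matrix(c(1L, 1L, 0L, 1L), 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  p <- shared_unique_partition(toy_table(m), c("A", "B"))
  expect_equal(p$regions[["A"]], "g1")
  expect_equal(p$regions[["A&B"]], "g2")
  expect_equal(length(p$regions[["B"]]), 0)

  t1 <- canpi_clone_library()
  p3 <- shared_unique_partition(t1$counts)
  members <- unlist(p3$regions, use.names = FALSE)
  expect_false(anyDuplicated(members) > 0)
  expressed <- rownames(t1$counts$counts)[
    rowSums(t1$counts$counts[, c("AI", "W+W", "W+OS")]) > 0]
  expect_setequal(members, expressed)
  # a gene seen only under aphid infestation sits in the AI-unique region
  only_ai <- expressed[t1$counts$counts[expressed, "AI"] > 0 &
                       t1$counts$counts[expressed, "W+W"] == 0 &
                       t1$counts$counts[expressed, "W+OS"] == 0]
  expect_setequal(p3$regions[["AI"]], only_ai)

  expect_error(shared_unique_partition(toy_table(m), "A"), "at least two")
})

test_that("domain occurrences count clone-weighted multiplicity", {
  m <- matrix(5L, 1, 1, dimnames = list("g", "t"))
  comp <- list(structure(list(gene_id = "g", sp_label = 1L,
                              ird_labels = c(1L, 1L, 17L), n_irds = 3L,
                              is_partial = FALSE),
                         class = "gene_composition"))
  cat17 <- irdkit:::label_only_catalog(c(1, 17))
  f <- ird_frequency(toy_table(m), comp, cat17)
  expect_equal(f["1", "t"], 10)
  expect_equal(f["17", "t"], 5)

  t1 <- canpi_clone_library()
  f1 <- ird_frequency(t1$counts, t1$compositions, t1$catalog)
  expect_true(all(f1["1", ] > 0))
  expect_true(all(f1["17", ] > 0))

  bad <- irdkit:::label_only_catalog(1)
  expect_error(ird_frequency(toy_table(m), comp, bad), "17")
})

test_that("TI/CI clone-weighted fractions match a naive recount", {
  cfg <- synth_config(seed = 77, n_genes = 12)
  ds <- generate_dataset(cfg)
  res <- build_catalog(annotate_set(ds$sim$precursors))
  spec <- class_specificity_summary(ds$clones$table, res$compositions,
                                    res$ird_catalog)
  # independent tally straight from ground truth
  for (tr in ds$clones$table$treatments) {
    ti <- 0; ci <- 0
    for (id in rownames(ds$clones$table$counts)) {
      n <- ds$clones$table$counts[id, tr]
      cls <- ds$sim$ground_truth[[id]]$classes
      ti <- ti + n * sum(cls == "TI")
      ci <- ci + n * sum(cls == "CI")
    }
    row <- spec[spec$treatment == tr, ]
    expect_equal(row$ti_fraction, ti / (ti + ci))
    expect_equal(row$ci_fraction, ci / (ti + ci))
  }

  # symmetry toy: one TI-only and one CI-only gene, equal counts and sizes
  m <- matrix(c(4L, 4L), 2, 1, dimnames = list(c("gT", "gC"), "t"))
  comp <- list(
    structure(list(gene_id = "gT", sp_label = 1L, ird_labels = 1L,
                   n_irds = 1L, is_partial = FALSE),
              class = "gene_composition"),
    structure(list(gene_id = "gC", sp_label = 1L, ird_labels = 2L,
                   n_irds = 1L, is_partial = FALSE),
              class = "gene_composition"))
  cat2 <- irdkit:::label_only_catalog(c(1, 2))
  cat2$class_of[] <- c("TI", "CI")
  sym <- class_specificity_summary(toy_table(m), comp, cat2)
  expect_equal(sym$ti_fraction, 0.5)
  expect_equal(sym$ci_fraction, 0.5)
})

test_that("statistics are linear in clone counts", {
  t1 <- canpi_clone_library()
  doubled <- clone_count_table(t1$counts$counts * 2L,
                               expected_totals = t1$counts$expected_totals * 2)
  for (tr in c("UL", "W+OS")) {
    a <- class_abundance(t1$counts, t1$compositions, tr)
    b <- class_abundance(doubled, t1$compositions, tr)
    expect_equal(b$count, a$count * 2)
    expect_equal(b$percent, a$percent)
  }
  fa <- ird_frequency(t1$counts, t1$compositions, t1$catalog)
  fb <- ird_frequency(doubled, t1$compositions, t1$catalog)
  expect_equal(fb, fa * 2L)
})

test_that("all statistics agree with a brute-force recount on random tables", {
  set.seed(314)
  for (trial in 1:10) {
    n_genes <- sample(2:10, 1)
    genes <- paste0("g", seq_len(n_genes))
    counts <- matrix(sample(0:9, n_genes * 4, replace = TRUE), n_genes, 4,
                     dimnames = list(genes, c("t1", "t2", "t3", "t4")))
    counts[1, ] <- counts[1, ] + 1L    # keep every column non-empty
    nby <- setNames(sample(1:4, n_genes, replace = TRUE), genes)
    comp <- toy_compositions(as.list(nby))
    tab <- toy_table(counts)
    for (tr in colnames(counts)) {
      ca <- class_abundance(tab, comp, tr)
      for (k in ca$n_irds) {
        expect_equal(ca$count[ca$n_irds == k],
                     sum(counts[names(nby)[nby == k], tr]))
      }
      expect_equal(sum(ca$count), sum(counts[, tr]))
    }
    # gene frequencies: naive division
    gf <- gene_frequency(tab)
    for (r in seq_len(nrow(gf))) {
      expect_equal(gf$fraction[r],
                   counts[gf$gene[r], gf$treatment[r]] /
                     sum(counts[, gf$treatment[r]]))
    }
  }
})
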