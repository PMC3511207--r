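# wrap single domains as 1-IRD precursors so they can be annotated
wrap_ird <- function(seqs, sp = strrep("M", 25)) {
  lapply(seq_along(seqs), function(i) {
    precursor(paste0("w", i), paste0(sp, "AAAAA", seqs[[i]], "AAAAA"))
  })
}

test_that("exact-identity deduplication with stable first-occurrence labels", {
  cfg <- synth_config(seed = 31, n_genes = 60)
  pool <- generate_ird_pool(cfg)
  sim <- generate_precursors(pool, cfg)
  anns <- annotate_set(sim$precursors)
  res <- build_catalog(anns)

  used <- unique(unlist(lapply(sim$ground_truth, `[[`, "ird_labels")))
  expect_equal(length(res$ird_catalog$entries), length(used))
  expect_setequal(unname(res$ird_catalog$entries),
                  unname(pool$sequences[used]))
  # labels shared across genes: same sequence, same label
  seq_of <- res$ird_catalog$entries
  for (id in names(anns)) {
    comp <- res$compositions[[match(id, vapply(res$compositions, `[[`, "",
                                               "gene_id"))]]
    expect_identical(unname(seq_of[as.character(comp$ird_labels)]),
                     vapply(anns[[id]]$irds, `[[`, "", "aa_seq"))
    # composition classes agree with generator ground truth
    expect_identical(unname(res$ird_catalog$class_of[
      as.character(comp$ird_labels)]),
      sim$ground_truth[[id]]$classes)
  }
})

test_that("a pool of 28 distinct domains catalogs to 28 entries", {
  cfg <- synth_config(seed = 11, n_genes = 200)   # enough draws to use all 28
  pool <- generate_ird_pool(cfg)
  sim <- generate_precursors(pool, cfg)
  res <- build_catalog(annotate_set(sim$precursors))
  expect_equal(length(res$ird_catalog$entries), 28)
})

test_that("single 1-IRD precursor gives a one-entry catalog", {
  cfg <- synth_config(seed = 2, n_genes = 1, architecture = c(`1` = 1))
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  res <- build_catalog(annotate_set(sim$precursors))
  expect_equal(length(res$ird_catalog$entries), 1)
  expect_equal(res$compositions[[1]]$n_irds, 1)
  expect_equal(res$compositions[[1]]$ird_labels, 1)
})

test_that("cataloging a catalog's own sequences reproduces it", {
  cfg <- synth_config(seed = 6, n_genes = 25)
  pool <- generate_ird_pool(cfg)
  sim <- generate_precursors(pool, cfg)
  res <- build_catalog(annotate_set(sim$precursors))
  again <- build_catalog(annotate_set(wrap_ird(res$ird_catalog$entries)))
  expect_identical(unname(again$ird_catalog$entries),
                   unname(res$ird_catalog$entries))
  expect_identical(unname(again$ird_catalog$class_of),
                   unname(res$ird_catalog$class_of))
})

test_that("input order permutes labels but not the (sequence, class) multiset", {
  cfg <- synth_config(seed = 13, n_genes = 15)
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  anns <- annotate_set(sim$precursors)
  a <- build_catalog(anns)
  b <- build_catalog(rev(anns))
  pairs <- function(cat) {
    sort(paste(unname(cat$entries), unname(cat$class_of)))
  }
  expect_identical(pairs(a$ird_catalog), pairs(b$ird_catalog))
})

test_that("catalog summary reports the packaged gene table correctly", {
  t1 <- canpi_clone_library()
  s <- catalog_summary(t1$catalog, t1$compositions)
  expect_equal(s$n_genes, 47)
  expect_equal(s$n_unique_irds, 28)
  expect_equal(unname(s$genes_by_n_irds[c("4", "3", "2", "1")]),
               c(9, 20, 15, 3))
  expect_equal(s$n_sp_variants, 10)
})

test_that("summary handles empty input and missing labels", {
  empty <- catalog_summary(
    structure(list(entries = setNames(character(0), character(0)),
                   class_of = setNames(character(0), character(0)),
                   deviation_of = setNames(logical(0), character(0))),
              class = "ird_catalog"),
    list())
  expect_equal(empty$n_genes, 0)
  expect_equal(empty$n_unique_irds, 0)
  expect_equal(empty$n_sp_variants, 0)

  t1 <- canpi_clone_library()
  bad <- t1$compositions
  bad[[1]]$ird_labels <- c(bad[[1]]$ird_labels, 999L)
  expect_error(catalog_summary(t1$catalog, bad), "999")
})

test_that("catalog JSON round-trips", {
  cfg <- synth_config(seed = 8, n_genes = 10)
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  res <- build_catalog(annotate_set(sim$precursors))
  path <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(res$ird_catalog, path)
  back <- read_catalog_json(path)
  expect_identical(back$entries, res$ird_catalog$entries)
  expect_identical(back$class_of, res$ird_catalog$class_of)
  expect_identical(back$deviation_of, res$ird_catalog$deviation_of)
})
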