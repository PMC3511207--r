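seg_frame <- function(ann) {
  tab <- annotation_table(ann)
  tab[, c("segment_type", "start", "end")]
}

truth_frame <- function(gt) {
  data.frame(segment_type = gt$segments$type, start = gt$segments$start,
             end = gt$segments$end)
}

test_that("signal peptide extraction handles full and partial precursors", {
  long <- precursor("p1", strrep("ACDEFGHIKL", 20))
  sp <- extract_signal_peptide(long)
  expect_equal(nchar(sp$signal_peptide), 25)
  expect_equal(c(sp$mature_start, sp$mature_end), c(25, 200))

  short <- precursor("p2", strrep("AC", 10))
  expect_error(extract_signal_peptide(short), "sp_length")

  part <- precursor("p3", strrep("AC", 10), is_partial = TRUE)
  sp3 <- extract_signal_peptide(part)
  expect_true(is.na(sp3$signal_peptide))
  expect_equal(c(sp3$mature_start, sp3$mature_end), c(0, 20))
})

test_that("generator architectures are recovered exactly at zero mutation", {
  cfg <- synth_config(seed = 101, n_genes = 100)
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  anns <- annotate_set(sim$precursors)
  for (id in names(anns)) {
    ann <- anns[[id]]
    gt <- sim$ground_truth[[id]]
    expect_equal(ann$n_irds, gt$k)
    expect_equal(seg_frame(ann), truth_frame(gt), ignore_attr = TRUE)
    expect_identical(
      vapply(ann$irds, function(i) i$reactive_site$inhibitor_class, ""),
      gt$classes)
    expect_false(any(vapply(ann$irds, `[[`, NA, "scaffold_deviation")))
  }
})

test_that("segments concatenate back to the input byte-for-byte", {
  cfg <- synth_config(seed = 55, n_genes = 30)
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  anns <- annotate_set(sim$precursors)
  for (ann in anns) {
    tab <- annotation_table(ann)
    tab <- tab[order(tab$start), ]
    expect_equal(tab$start[1], 0)
    expect_equal(tab$end[nrow(tab)], nchar(ann$aa_seq))
    expect_equal(tab$start[-1], tab$end[-nrow(tab)])  # gap-free
    pieces <- substring(ann$aa_seq, tab$start + 1, tab$end)
    expect_identical(paste(pieces, collapse = ""), ann$aa_seq)
  }
})

test_that("a precursor truncated mid-domain yields a partial trailing IRD", {
  cfg <- synth_config(seed = 9, n_genes = 5, architecture = c(`3` = 1))
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  gt <- sim$ground_truth[[1]]
  last_ird <- gt$segments[gt$segments$type == "ird", ]
  cut <- last_ird$start[3] + 20          # 20 residues into the third domain
  trunc <- precursor("trunc", substr(sim$precursors[[1]]$aa_seq, 1, cut),
                     is_partial = TRUE)
  ann <- annotate_precursor(trunc)
  expect_equal(ann$n_irds, 3)
  expect_true(ann$irds[[3]]$is_partial)
  expect_equal(ann$irds[[3]]$end, cut)
  expect_false(ann$irds[[2]]$is_partial)
})

test_that("zero reactive sites gives an empty annotation with a warning record", {
  ann <- annotate_precursor(precursor("flat", strrep("ACDEFGHIKL", 10)))
  expect_equal(ann$n_irds, 0)
  expect_match(ann$warnings, "no repeat domain")
  expect_equal(nrow(ann$linkers), 1)     # whole mature region is linker
})

test_that("up to two substitutions outside anchors never change n_irds", {
  cfg <- synth_config(seed = 23, n_genes = 20)
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  tpl <- ird_template()
  set.seed(977)
  for (trial in 1:60) {
    id <- sample(names(sim$precursors), 1)
    gt <- sim$ground_truth[[id]]
    res <- strsplit(sim$precursors[[id]]$aa_seq, "")[[1]]
    protected <- res == "C"
    for (s in gt$segments$start[gt$segments$type == "ird"]) {
      rs <- (s + tpl$rs_offset + 1):(s + tpl$rs_offset + 5)
      protected[rs] <- TRUE
    }
    k_mut <- sample(1:2, 1)
    at <- sample(which(!protected), k_mut)
    res[at] <- vapply(res[at],
                      function(r) sample(setdiff(AA_LETTERS, r), 1), "")
    ann <- annotate_precursor(precursor(id, paste(res, collapse = "")))
    expect_equal(ann$n_irds, gt$k)
  }
})

test_that("X residues are tolerated and never act as cysteine or P1", {
  cfg <- synth_config(seed = 4, n_genes = 1, architecture = c(`2` = 1))
  sim <- generate_precursors(generate_ird_pool(cfg), cfg)
  res <- strsplit(sim$precursors[[1]]$aa_seq, "")[[1]]
  res[27] <- "X"                          # inside the first linker
  ann <- annotate_precursor(precursor("withx", paste(res, collapse = "")))
  expect_equal(ann$n_irds, 2)
})

test_that("duplicate precursor ids are rejected", {
  p <- precursor("dup", strrep("ACDEFGHIKL", 10))
  expect_error(annotate_set(list(p, p)), "duplicate")
})
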