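write_quant_file <- function(df, env = parent.frame()) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  readr::write_tsv(df, p)
  p
}

# readers --------------------------------------------------------------------

test_that("quantification files read into a long abundance table", {
  p <- write_quant_file(tibble::tibble(Name = c("t1", "t2"), TPM = c(10, 0)))
  ab <- read_quant(p, sample_ids = "s1")
  expect_identical(nrow(ab), 2L)
  expect_identical(ab$tpm, c(10, 0))
})

test_that("negative TPM values are rejected", {
  p <- write_quant_file(tibble::tibble(Name = "t1", TPM = -1))
  expect_error(read_quant(p, sample_ids = "s1"), "negative TPM")
})

test_that("a file without a TPM column is a format error naming the header", {
  p <- write_quant_file(tibble::tibble(Name = "t1", reads = 5))
  expect_error(read_quant(p, sample_ids = "s1"), "header seen: Name, reads")
})

test_that("replicate files keep their given sample order", {
  paths <- character(3)
  for (i in 1:3) {
    p <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(tibble::tibble(Name = "t1", TPM = i), p)
    paths[i] <- p
  }
  ab <- read_quant(paths, sample_ids = c("r1", "r2", "r3"))
  expect_identical(levels(ab$sample_id), c("r1", "r2", "r3"))
  expect_identical(nrow(ab), 3L)
})

test_that("event and peak tables validate their columns and levels", {
  pe <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "IR",
    chrom = "chr1", start = 1L, end = 100L, strand = "+"
  ), pe)
  ev <- read_events(pe)
  expect_identical(ev$event_type, "IR")
  readr::write_tsv(tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "XX",
    chrom = "chr1", start = 1L, end = 100L, strand = "+"
  ), pe)
  expect_error(read_events(pe), "unknown event_type")
  readr::write_tsv(tibble::tibble(event_id = "e1", gene_id = "g1"), pe)
  expect_error(read_events(pe), "lacks column")

  pp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    event_id = "e1", product_label = "e1.fs", category = "fs",
    sample_id = "s1", rfu = 100
  ), pp)
  expect_identical(nrow(read_peaks(pp)), 1L)
  readr::write_tsv(tibble::tibble(
    event_id = "e1", product_label = "x", category = "mystery",
    sample_id = "s1", rfu = 100
  ), pp)
  expect_error(read_peaks(pp), "category")
})

# assign_event_transcripts ----------------------------------------------------

test_that("a two-isoform IR gene partitions into positive and fs", {
  ann <- ann_of(
    tx_rows("t.fs", "g1", list(c(1, 100), c(201, 300))),
    tx_rows("t.ir", "g1", list(c(1, 300)))
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "IR",
    chrom = "chr1", start = 80L, end = 220L, strand = "+"
  )
  asg <- assign_event_transcripts(ev, ann)
  expect_identical(asg$category[asg$transcript_id == "t.ir"], "positive")
  expect_identical(asg$category[asg$transcript_id == "t.fs"], "fs")
})

test_that("a three-isoform gene with an 8-nt alternative 3' site splits into three classes", {
  # fully spliced, an Alt3 isoform whose intron 2 acceptor shifts 8 nt into
  # exon 3, and an intron-2-retention isoform
  ann <- ann_of(
    tx_rows("t.fs", "g1", list(c(1, 100), c(201, 300), c(401, 500))),
    tx_rows("t.alt3", "g1", list(c(1, 100), c(201, 300), c(409, 500))),
    tx_rows("t.i2r", "g1", list(c(1, 100), c(201, 500)))
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "Alt3",
    chrom = "chr1", start = 276L, end = 425L, strand = "+"
  )
  asg <- assign_event_transcripts(ev, ann)
  cat_of <- setNames(asg$category, asg$transcript_id)
  expect_identical(unname(cat_of["t.fs"]), "fs")
  expect_identical(unname(cat_of["t.alt3"]), "positive")
  expect_identical(unname(cat_of["t.i2r"]), "other")
  # the same region assayed as an IR event flips positive and other
  ev_ir <- ev %>% dplyr::mutate(event_id = "e2", event_type = "IR")
  asg2 <- assign_event_transcripts(ev_ir, ann)
  cat2 <- setNames(asg2$category, asg2$transcript_id)
  expect_identical(unname(cat2["t.i2r"]), "positive")
  expect_identical(unname(cat2["t.alt3"]), "other")
})

test_that("alternative donor/acceptor labels are strand-aware", {
  # on the minus strand the intron end is the donor side, so an intron whose
  # genomic end shifts is Alt5' on plus but Alt3' was exercised above
  ann <- ann_of(
    tx_rows("t.fs", "g1", list(c(1, 100), c(201, 300), c(401, 500)), strand = "-"),
    tx_rows("t.var", "g1", list(c(1, 100), c(201, 300), c(409, 500)), strand = "-")
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "Alt5",
    chrom = "chr1", start = 276L, end = 425L, strand = "-"
  )
  asg <- assign_event_transcripts(ev, ann)
  expect_identical(asg$category[asg$transcript_id == "t.var"], "positive")
})

test_that("exon skipping is recognized against the fully spliced chain", {
  ann <- ann_of(
    tx_rows("t.fs", "g1", list(c(1, 100), c(201, 300), c(401, 500))),
    tx_rows("t.es", "g1", list(c(1, 100), c(401, 500)))
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "ES",
    chrom = "chr1", start = 90L, end = 420L, strand = "+"
  )
  asg <- assign_event_transcripts(ev, ann)
  expect_identical(asg$category[asg$transcript_id == "t.es"], "positive")
})

test_that("transcripts outside the event region are excluded entirely", {
  ann <- ann_of(
    tx_rows("t.fs", "g1", list(c(1, 100), c(201, 300))),
    tx_rows("t.ir", "g1", list(c(1, 300))),
    tx_rows("t.up", "g1", list(c(1, 60)))
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "IR",
    chrom = "chr1", start = 80L, end = 220L, strand = "+"
  )
  asg <- assign_event_transcripts(ev, ann)
  expect_false("t.up" %in% asg$transcript_id)
})

test_that("an event no transcript overlaps is an error", {
  ann <- ann_of(tx_rows("t1", "g1", list(c(1, 100))))
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "IR",
    chrom = "chr1", start = 500L, end = 600L, strand = "+"
  )
  expect_error(assign_event_transcripts(ev, ann), "no transcript.*overlaps")
})

test_that("explicit id columns override automatic assignment", {
  ann <- ann_of(
    tx_rows("t1", "g1", list(c(1, 100), c(201, 300))),
    tx_rows("t2", "g1", list(c(1, 300)))
  )
  ev <- tibble::tibble(
    event_id = "e1", gene_id = "g1", event_type = "IR",
    chrom = "chr1", start = 80L, end = 220L, strand = "+",
    positive_ids = "t1", fs_ids = "t2", other_ids = NA_character_
  )
  asg <- assign_event_transcripts(ev, ann)
  expect_identical(asg$category[asg$transcript_id == "t1"], "positive")
  expect_identical(asg$category[asg$transcript_id == "t2"], "fs")
})

# ratios -----------------------------------------------------------------------

asg1 <- function(pos = "p", fs = "f", other = character(0)) {
  tibble::tibble(
    event_id = "e1", gene_id = "g1",
    transcript_id = c(pos, fs, other),
    category = c(rep("positive", length(pos)), rep("fs", length(fs)),
                 rep("other", length(other)))
  )
}

ab1 <- function(...) {
  v <- c(...)
  tibble::tibble(transcript_id = names(v), sample_id = "s1", tpm = unname(v))
}

test_that("of_total is the event-positive share of all assigned transcripts", {
  r <- splicing_ratios(asg1(), ab1(p = 25, f = 75), mode = "of_total")
  expect_identical(r$ratio, 0.25)
  r2 <- splicing_ratios(
    asg1(pos = c("a", "b"), fs = "f", other = "o"),
    ab1(a = 10, b = 5, f = 30, o = 5), mode = "of_total"
  )
  expect_identical(r2$ratio, 0.30)
})

test_that("as_vs_fs ignores the other class; raw quotient is available", {
  r <- splicing_ratios(asg1(), ab1(p = 20, f = 80), mode = "as_vs_fs")
  expect_identical(r$ratio, 0.20)
  r0 <- splicing_ratios(asg1(), ab1(p = 0, f = 80), mode = "as_vs_fs")
  expect_identical(r0$ratio, 0)
  expect_true(r0$valid)
  r2 <- splicing_ratios(asg1(other = "o"), ab1(p = 30, f = 10, o = 60), mode = "as_vs_fs")
  expect_identical(r2$ratio, 0.75)
  rq <- splicing_ratios(asg1(other = "o"), ab1(p = 30, f = 10, o = 60),
                        mode = "as_vs_fs", raw_quotient = TRUE)
  expect_identical(rq$ratio, 3)
})

test_that("zero denominators give invalid records, not errors", {
  r <- splicing_ratios(asg1(), ab1(p = 0, f = 0), mode = "of_total")
  expect_false(r$valid)
  expect_true(is.na(r$ratio))
  rq <- splicing_ratios(asg1(), ab1(p = 5, f = 0), mode = "as_vs_fs",
                        raw_quotient = TRUE)
  expect_false(rq$valid)
})

test_that("missing abundance entries count as zero with a message", {
  ab <- ab1(p = 25)  # no entry for the fs transcript
  expect_message(
    r <- splicing_ratios(asg1(), ab, mode = "of_total"),
    "1 transcript/sample abundance entries missing"
  )
  expect_identical(r$ratio, 1)
})

test_that("peak-area ratios use the same formulas with RFU", {
  peaks <- tibble::tibble(
    event_id = "e1",
    product_label = c("e1.as", "e1.fs"),
    category = c("positive", "fs"),
    sample_id = "s1",
    rfu = c(100, 300)
  )
  r <- pcr_ratios(peaks, mode = "as_vs_fs")
  expect_identical(r$ratio, 0.25)
  expect_identical(r$method, "hrrtpcr")
  peaks3 <- tibble::tibble(
    event_id = "e1",
    product_label = c("e1.fs", "e1.ir", "e1.alt3"),
    category = c("fs", "positive", "other"),
    sample_id = "s1",
    rfu = c(200, 50, 250)
  )
  r3 <- pcr_ratios(peaks3, mode = "of_total")
  expect_identical(r3$ratio, 0.10)
  zero <- peaks %>% dplyr::mutate(rfu = 0)
  rz <- pcr_ratios(zero, mode = "as_vs_fs")
  expect_false(rz$valid)
})

test_that("of_total ratios of a partition sum to one", {
  fx <- generate_annotation_pair(fixture_spec(seed = 31, n_genes = 40))
  events <- generate_events(fixture_spec(seed = 31, n_genes = 40))
  ap <- generate_abundance_and_peaks(fx$truth, events,
                                     fixture_spec(seed = 31, n_genes = 40))
  asg <- assign_event_transcripts(events, fx$truth)
  parts <- lapply(c("positive", "fs", "other"), function(cl) {
    relabelled <- asg %>% dplyr::mutate(
      category = ifelse(category == cl, "positive", "other")
    )
    splicing_ratios(relabelled, ap$abundance, mode = "of_total")$ratio
  })
  total <- parts[[1]] + parts[[2]] + parts[[3]]
  expect_true(all(abs(total - 1) < 1e-12))
  r <- splicing_ratios(asg, ap$abundance, mode = "of_total")
  expect_true(all(r$ratio[r$valid] >= 0 & r$ratio[r$valid] <= 1))
})

test_that("ratios are invariant under positive per-sample scaling", {
  fx <- generate_annotation_pair(fixture_spec(seed = 32, n_genes = 30))
  spec <- fixture_spec(seed = 32, n_genes = 30)
  events <- generate_events(spec)
  ap <- generate_abundance_and_peaks(fx$truth, events, spec)
  asg <- assign_event_transcripts(events, fx$truth)
  r1 <- splicing_ratios(asg, ap$abundance, mode = "as_vs_fs")
  scaled <- ap$abundance %>%
    dplyr::group_by(sample_id) %>%
    dplyr::mutate(tpm = tpm * (3.7 + dplyr::cur_group_id())) %>%
    dplyr::ungroup()
  r2 <- splicing_ratios(asg, scaled, mode = "as_vs_fs")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  p1 <- pcr_ratios(ap$peaks, mode = "of_total")
  p2 <- pcr_ratios(ap$peaks %>% dplyr::mutate(rfu = rfu * 42), mode = "of_total")
  expect_equal(p1$ratio, p2$ratio, tolerance = 1e-12)
})

# aggregation and correlation ---------------------------------------------------

rec <- function(ratios, valid = TRUE, event = "e1", method = "rnaseq") {
  tibble::tibble(
    event_id = event, sample_id = paste0("s", seq_along(ratios)),
    method = method, mode = "as_vs_fs", ratio = ratios,
    valid = rep_len(valid, length(ratios))
  )
}

si <- function(n) tibble::tibble(sample_id = paste0("s", 1:n), time_point = "T1")

test_that("constant replicates aggregate to SD zero", {
  a <- aggregate_replicates(rec(c(0.2, 0.2, 0.2)), si(3))
  expect_equal(a$mean_ratio, 0.2, tolerance = 1e-15)
  expect_identical(a$sd_ratio, 0)
  expect_identical(a$n_replicates, 3L)
})

test_that("a single valid replicate reports no SD", {
  a <- aggregate_replicates(rec(0.4), si(1))
  expect_identical(a$mean_ratio, 0.4)
  expect_true(is.na(a$sd_ratio))
})

test_that("the closed-form sample SD is reproduced", {
  a <- aggregate_replicates(rec(c(0.1, 0.2, 0.3)), si(3))
  expect_equal(a$mean_ratio, 0.2, tolerance = 1e-15)
  expect_equal(a$sd_ratio, 0.1, tolerance = 1e-12)
})

test_that("groups with no valid replicate are dropped with a warning", {
  records <- dplyr::bind_rows(
    rec(c(0.1, 0.2, 0.3)),
    rec(c(NA, NA, NA), valid = FALSE, event = "e2")
  )
  expect_warning(a <- aggregate_replicates(records, si(3)), "no valid replicate")
  expect_identical(a$event_id, "e1")
})

test_that("correlation handles the canonical small cases", {
  cc <- correlate_points(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(cc$pearson_r, 1, tolerance = 1e-15)
  expect_equal(cc$spearman_rho, 1, tolerance = 1e-15)
  cc2 <- correlate_points(c(1, 2, 3), c(3, 2, 1))
  expect_equal(cc2$pearson_r, -1, tolerance = 1e-15)
  expect_equal(cc2$spearman_rho, -1, tolerance = 1e-15)
  # rank-difference formula: rho = 1 - 6*2 / (4*15) = 0.8
  cc3 <- correlate_points(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(cc3$spearman_rho, 0.8, tolerance = 1e-15)
  expect_error(correlate_points(1, 1), "at least 2")
  cc4 <- correlate_points(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(cc4$pearson_r))
  expect_identical(cc4$n_points, 3L)
})

test_that("method correlation pairs only mutually valid records", {
  x <- rec(c(0.1, 0.2, 0.3, NA), valid = c(TRUE, TRUE, TRUE, FALSE))
  y <- rec(c(0.1, 0.25, 0.35, 0.9), method = "hrrtpcr")
  paired <- paired_ratios(x, y)
  expect_identical(nrow(paired), 3L)
  cc <- correlate_ratios(x, y)
  expect_identical(cc$n_points, 3L)
  expect_true(cc$pearson_r > 0.9)
  expect_s3_class(plot_method_correlation(paired), "ggplot")
})
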