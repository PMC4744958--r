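# small builders used across the suite

# one transcript from an exon coordinate list: list(c(start, end), ...)
tx_rows <- function(id, gene, exons, chrom = "chr1", strand = "+", source = "ref") {
  m <- do.call(rbind, exons)
  tibble::tibble(
    chrom = chrom, start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    strand = strand, gene_id = gene, transcript_id = id, source = source
  )
}

ann_of <- function(..., source_label = "ref") {
  as_annotation(dplyr::bind_rows(...), source_label = source_label)
}

# order-insensitive structural comparison of two annotations
expect_same_annotation <- function(a, b, ignore_source = FALSE) {
  key <- function(x) {
    x <- dplyr::arrange(x, transcript_id, start)
    if (ignore_source) x$source <- NULL
    as.data.frame(x)
  }
  expect_identical(key(a), key(b))
}

# annotation pair plus the matching genome, via the exported generators
build_fixture_for_tests <- function(spec) {
  fx <- generate_annotation_pair(spec)
  fx$genome <- generate_genome(spec)
  fx
}

# exhaustive per-gene oracle for the same-chain UTR collapse: keep the
# argmax-spliced-length transcript of every nonempty chain group
brute_chain_survivors <- function(ann) {
  tx <- transcripts(ann)
  spliced <- tx[tx$n_introns > 0, ]
  keep <- character(0)
  for (g in unique(spliced$gene_id)) {
    gt <- spliced[spliced$gene_id == g, ]
    for (ch in unique(gt$chain)) {
      grp <- gt[gt$chain == ch, ]
      best <- grp[order(-grp$spliced_length, grp$transcript_id), ][1, ]
      keep <- c(keep, best$transcript_id)
    }
  }
  sort(c(keep, tx$transcript_id[tx$n_introns == 0]))
}

# exhaustive oracle for mono-exon collapse: survivors are mono-exon
# transcripts not strictly shorter than some overlapping same-strand
# mono-exon transcript of the gene (with id tie-break), checked over all pairs
brute_mono_survivors <- function(ann) {
  tx <- transcripts(ann)
  mono <- tx[tx$n_introns == 0, ]
  removed <- character(0)
  for (g in unique(mono$gene_id)) {
    gt <- mono[mono$gene_id == g, ]
    # transitive overlap closure = clusters
    n <- nrow(gt)
    if (n < 2) next
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      gt$strand[i] == gt$strand[j] &&
        gt$span_start[i] <= gt$span_end[j] && gt$span_start[j] <= gt$span_end[i]
    }))
    cluster <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(cluster[adj[i, ]]), integer(1))
      if (identical(new, cluster)) break
      cluster <- new
    }
    for (cl in unique(cluster)) {
      grp <- gt[cluster == cl, ]
      if (nrow(grp) < 2) next
      best <- grp[order(-grp$spliced_length, grp$transcript_id), ][1, ]
      removed <- c(removed, setdiff(grp$transcript_id, best$transcript_id))
    }
  }
  sort(setdiff(tx$transcript_id, removed))
}

# exhaustive oracle for fragment removal: evaluate the fragment predicate
# over all ordered pairs of a gene, then keep, from longest downwards, every
# transcript that is not a fragment of an already-kept one (a removed
# fragment cannot shield another fragment)
brute_fragment_survivors <- function(ann) {
  tx <- transcripts(ann)
  surv_ids <- character(0)
  for (g in unique(tx$gene_id)) {
    gann <- ann[ann$gene_id == g, ]
    gt <- tx[tx$gene_id == g, ]
    n <- nrow(gt)
    frag <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && gt$strand[i] == gt$strand[j] &&
          gt$spliced_length[i] < gt$spliced_length[j]) {
        frag[i, j] <- is_fragment(gann, gt$transcript_id[i], gt$transcript_id[j])
      }
    }
    kept <- integer(0)
    for (k in order(-gt$spliced_length, gt$transcript_id)) {
      if (!any(frag[k, kept])) kept <- c(kept, k)
    }
    surv_ids <- c(surv_ids, gt$transcript_id[kept])
  }
  sort(surv_ids)
}
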