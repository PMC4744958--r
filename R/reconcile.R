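#' Pair gene models across two annotation sources
#'
#' Genes are matched by shared `gene_id`; spans are the union of each gene's
#' transcript spans in each source. Every gene in the union of the two sets
#' gets one row, labelled with the geometric relation of its two spans:
#'
#' * `ref_only` / `alt_only` — present in one source;
#' * `identical` — equal spans;
#' * `containment_keep_larger` — one span contains the other (the larger one
#'   wins, whichever source it came from);
#' * `partial_overlap_keep_ref` — partial overlap, and also the disjoint
#'   same-id case (the reference span wins; disjoint spans additionally raise
#'   a warning because they usually indicate an annotation problem).
#'
#' @param ref Reference-source annotation tibble (the coordinate authority on
#'   partial overlap).
#' @param alt Alternative/discovery-source annotation tibble.
#' @return A pairing tibble with columns `gene_id`, `chrom`, `ref_start`,
#'   `ref_end`, `alt_start`, `alt_end`, `resolution`.
#' @export
pair_genes <- function(ref, alt) {
  gs_ref <- gene_spans(ref) %>%
    select("gene_id", "chrom", ref_start = "start", ref_end = "end")
  gs_alt <- gene_spans(alt) %>%
    select("gene_id", alt_chrom = "chrom", alt_start = "start", alt_end = "end")
  p <- full_join(gs_ref, gs_alt, by = "gene_id")
  conflict <- !is.na(p$chrom) & !is.na(p$alt_chrom) & p$chrom != p$alt_chrom
  if (any(conflict)) {
    abort(paste0(
      "gene(s) on different chromosomes in the two sources: ",
      paste(p$gene_id[conflict], collapse = ", ")
    ))
  }
  p$chrom <- ifelse(is.na(p$chrom), p$alt_chrom, p$chrom)
  p$alt_chrom <- NULL
  p$resolution <- classify_span_relation(p$ref_start, p$ref_end, p$alt_start, p$alt_end)
  p %>% arrange(.data$chrom, .data$gene_id)
}

classify_span_relation <- function(rs, re, as_, ae) {
  case_when(
    is.na(as_) ~ "ref_only",
    is.na(rs) ~ "alt_only",
    rs == as_ & re == ae ~ "identical",
    (rs <= as_ & ae <= re) | (as_ <= rs & re <= ae) ~ "containment_keep_larger",
    TRUE ~ "partial_overlap_keep_ref"
  )
}

#' Resolve paired gene spans
#'
#' Applies the span-conflict rules to a pairing table: where one span is
#' contained in the other (equality included), the larger span is kept
#' regardless of source (ties go to the reference); where spans overlap
#' partially, the reference span is kept; genes present in one source keep
#' their only span. Disjoint same-id spans resolve to the reference span with
#' a warning.
#'
#' @param pairings Output of [pair_genes()].
#' @return `pairings` with `resolved_start` and `resolved_end` columns added.
#' @export
resolve_spans <- function(pairings) {
  p <- pairings
  disjoint <- !is.na(p$ref_start) & !is.na(p$alt_start) &
    (p$alt_start > p$ref_end | p$alt_end < p$ref_start)
  if (any(disjoint)) {
    warn(paste0(
      "disjoint spans for the same gene id; keeping the reference span: ",
      paste(head(p$gene_id[disjoint], 5), collapse = ", ")
    ))
  }
  ref_len <- p$ref_end - p$ref_start + 1L
  alt_len <- p$alt_end - p$alt_start + 1L
  take_alt <- p$resolution == "containment_keep_larger" & alt_len > ref_len
  p$resolved_start <- dplyr::if_else(
    p$resolution == "alt_only" | take_alt, p$alt_start, p$ref_start
  )
  p$resolved_end <- dplyr::if_else(
    p$resolution == "alt_only" | take_alt, p$alt_end, p$ref_end
  )
  p
}

#' Merge two annotation sources under resolved gene spans
#'
#' Produces the pre-deduplication union: every transcript from both sources,
#' grouped per gene. Source tags are preserved. A transcript id present in
#' both sources with identical exon structure is kept once (tagged with the
#' reference source); structurally different id collisions are disambiguated
#' by suffixing each copy with its source label. A transcript extending
#' beyond its gene's resolved span is retained (the effective span widens)
#' with a warning.
#'
#' @param ref,alt The two annotation tibbles given to [pair_genes()].
#' @param pairings Output of [pair_genes()] or [resolve_spans()] on the same
#'   two sets.
#' @return The merged exon-level annotation tibble.
#' @export
apply_resolutions <- function(ref, alt, pairings) {
  if (!"resolved_start" %in% names(pairings)) pairings <- resolve_spans(pairings)
  uncovered <- setdiff(unique(c(ref$gene_id, alt$gene_id)), pairings$gene_id)
  if (length(uncovered) > 0) {
    abort(paste0("pairings do not cover gene(s): ", paste(head(uncovered, 5), collapse = ", ")))
  }
  both <- intersect(unique(ref$transcript_id), unique(alt$transcript_id))
  if (length(both) > 0) {
    ref_tx <- transcripts(ref %>% filter(.data$transcript_id %in% both))
    alt_tx <- transcripts(alt %>% filter(.data$transcript_id %in% both))
    key_of <- function(a, ids) {
      e <- a %>% filter(.data$transcript_id %in% ids) %>%
        arrange(.data$transcript_id, .data$start)
      vapply(split(paste0(e$chrom, e$strand, e$start, ".", e$end), e$transcript_id),
             paste, character(1), collapse = ";")
    }
    rk <- key_of(ref, both)
    ak <- key_of(alt, both)
    same_structure <- both[rk[both] == ak[both]]
    differ <- setdiff(both, same_structure)
    alt <- alt %>% filter(!.data$transcript_id %in% same_structure)
    if (length(differ) > 0) {
      ref <- ref %>% mutate(transcript_id = ifelse(
        .data$transcript_id %in% differ,
        paste0(.data$transcript_id, ".", .data$source), .data$transcript_id
      ))
      alt <- alt %>% mutate(transcript_id = ifelse(
        .data$transcript_id %in% differ,
        paste0(.data$transcript_id, ".", .data$source), .data$transcript_id
      ))
    }
  }
  merged <- as_annotation(bind_rows(ref, alt))
  gs <- gene_spans(merged) %>%
    left_join(pairings[, c("gene_id", "resolved_start", "resolved_end")], by = "gene_id")
  widened <- gs$start < gs$resolved_start | gs$end > gs$resolved_end
  if (any(widened, na.rm = TRUE)) {
    warn(paste0(
      "transcript(s) extend beyond the resolved gene span; span widened for: ",
      paste(head(gs$gene_id[which(widened)], 5), collapse = ", ")
    ))
  }
  merged
}

#' Reconcile two annotation sources
#'
#' Convenience wrapper: [pair_genes()], [resolve_spans()], then
#' [apply_resolutions()].
#'
#' @inheritParams apply_resolutions
#' @return A list with `annotation` (merged tibble) and `pairings` (the
#'   resolved pairing table).
#' @export
reconcile_annotations <- function(ref, alt) {
  pairings <- resolve_spans(pair_genes(ref, alt))
  list(annotation = apply_resolutions(ref, alt, pairings), pairings = pairings)
}
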