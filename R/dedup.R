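#' @keywords internal
#' @noRd
empty_decisions <- function() {
  tibble(
    removed_transcript_id = character(), kept_transcript_id = character(),
    rule = character(), gene_id = character()
  )
}

# Survivor ordering used by every dedup rule: protected transcripts first,
# then longest spliced length, then reference-source, then smallest id.
rank_transcripts <- function(tx, protected, ref_sources) {
  tx %>%
    mutate(
      .prot = .data$transcript_id %in% protected,
      .is_ref = .data$source %in% ref_sources
    ) %>%
    arrange(desc(.data$.prot), desc(.data$spliced_length),
            desc(.data$.is_ref), .data$transcript_id)
}

# Shared removal logic for a redundancy group: the top-ranked transcript is
# kept; protected transcripts are never removed.
group_removals <- function(tx_ranked, group_cols, rule) {
  tx_ranked %>%
    group_by(across(all_of(group_cols))) %>%
    mutate(.kept = first(.data$transcript_id)) %>%
    filter(row_number() > 1, !.data$.prot) %>%
    ungroup() %>%
    select(removed_transcript_id = "transcript_id",
           kept_transcript_id = ".kept", "gene_id") %>%
    mutate(rule = rule, .before = "gene_id")
}

#' Collapse transcripts sharing an identical intron chain
#'
#' Transcripts of the same gene with the same (nonempty) ordered intron
#' coordinates differ only in the length of their 5'/3' UTR exons; only the
#' one with the largest spliced length (sum of exon lengths) is retained.
#' Ties prefer a protected transcript, then a reference-source transcript,
#' then the lexicographically smallest id. Mono-exon transcripts are not
#' touched (see [collapse_monoexon()]).
#'
#' @param ann An exon-level annotation tibble.
#' @param protected Transcript ids exempt from removal (e.g. curated); they
#'   still displace unprotected duplicates.
#' @param ref_sources Source labels treated as the reference on ties.
#' @return A list with `annotation` (the deduplicated tibble) and `decisions`
#'   (a tibble with columns `removed_transcript_id`, `kept_transcript_id`,
#'   `rule`, `gene_id`; `rule` is `"same_chain_shorter_utr"`).
#' @export
collapse_identical_chains <- function(ann, protected = character(),
                                      ref_sources = character()) {
  tx <- transcripts(ann)
  spliced <- tx %>% filter(.data$n_introns > 0)
  if (nrow(spliced) == 0) {
    return(list(annotation = ann, decisions = empty_decisions()))
  }
  removals <- rank_transcripts(spliced, protected, ref_sources) %>%
    group_removals(c("gene_id", "chain"), "same_chain_shorter_utr")
  list(
    annotation = ann %>% filter(!.data$transcript_id %in% removals$removed_transcript_id),
    decisions = removals %>% select("removed_transcript_id", "kept_transcript_id",
                                    "rule", "gene_id")
  )
}

#' Collapse redundant mono-exon transcripts
#'
#' Within a gene, mono-exon transcripts that mutually overlap on the same
#' strand are UTR-length variants of one another; only the longest survives
#' per overlap cluster. Mono-exon transcripts of the same gene that do not
#' overlap are all retained, as are spliced transcripts.
#'
#' @inheritParams collapse_identical_chains
#' @return As [collapse_identical_chains()]; `rule` is `"monoexon_shorter"`.
#' @export
collapse_monoexon <- function(ann, protected = character(),
                              ref_sources = character()) {
  tx <- transcripts(ann)
  mono <- tx %>% filter(.data$n_introns == 0)
  if (nrow(mono) == 0) {
    return(list(annotation = ann, decisions = empty_decisions()))
  }
  # overlap clusters per gene+strand: a new cluster starts where a transcript
  # begins past the running maximum end of the previous ones
  mono <- mono %>%
    group_by(.data$gene_id, .data$strand) %>%
    arrange(.data$span_start, .data$span_end, .by_group = TRUE) %>%
    mutate(.cluster = cumsum(
      .data$span_start > dplyr::lag(cummax(.data$span_end), default = -1L)
    )) %>%
    ungroup()
  removals <- rank_transcripts(mono, protected, ref_sources) %>%
    group_removals(c("gene_id", "strand", ".cluster"), "monoexon_shorter")
  list(
    annotation = ann %>% filter(!.data$transcript_id %in% removals$removed_transcript_id),
    decisions = removals %>% select("removed_transcript_id", "kept_transcript_id",
                                    "rule", "gene_id")
  )
}

# internal fragment predicate on precomputed structures:
# x = list(span_start, span_end, spliced_length, introns = 2-col matrix)
.is_fragment <- function(short, long) {
  # (a) span containment with at least one end strictly inside
  if (!(long$span_start <= short$span_start && short$span_end <= long$span_end)) return(FALSE)
  if (!(short$span_start > long$span_start || short$span_end < long$span_end)) return(FALSE)
  li <- long$introns
  si <- short$introns
  lkey <- paste(li[, 1], li[, 2])
  skey <- paste(si[, 1], si[, 2])
  # (b) every intron of short occurs in long's chain
  if (nrow(si) > 0 && !all(skey %in% lkey)) return(FALSE)
  # (c) every intron of long strictly inside short's span occurs in short's
  # chain -- an intron of long missing here means short retains it, i.e.
  # short is an intron-retention isoform, not a fragment
  inside <- li[, 1] > short$span_start & li[, 2] < short$span_end
  if (any(inside) && !all(lkey[inside] %in% skey)) return(FALSE)
  TRUE
}

tx_structures <- function(ann) {
  tx <- transcripts(ann)
  ic <- intron_chain(ann)
  introns_by_tx <- split(as.matrix(ic[, c("start", "end")]), ic$transcript_id)
  structs <- lapply(seq_len(nrow(tx)), function(i) {
    m <- introns_by_tx[[tx$transcript_id[i]]]
    m <- if (is.null(m)) matrix(integer(0), ncol = 2) else matrix(m, ncol = 2)
    list(
      span_start = tx$span_start[i], span_end = tx$span_end[i],
      spliced_length = tx$spliced_length[i], introns = m,
      chrom = tx$chrom[i], strand = tx$strand[i], gene_id = tx$gene_id[i]
    )
  })
  names(structs) <- tx$transcript_id
  list(tx = tx, structs = structs)
}

#' Test whether one transcript is a coverage fragment of another
#'
#' A fragment is an incomplete transcript model (typically from low read
#' coverage) whose intron coordinates all occur in a longer transcript of the
#' same gene. `short` is a fragment of `long` iff (a) its span is contained
#' in `long`'s span with at least one end strictly inside, (b) every intron
#' of `short` occurs in `long`'s chain, and (c) every intron of `long` lying
#' strictly within `short`'s span occurs in `short`'s chain. Condition (c)
#' keeps genuine intron-retention isoforms out: a retained intron of `long`
#' inside `short`'s span is absent from `short`'s chain, so `short` is an
#' isoform, not a fragment.
#'
#' @param ann An exon-level annotation tibble containing both transcripts.
#' @param short_id,long_id Transcript ids; they must belong to the same gene,
#'   chromosome and strand, and `short_id` must have strictly smaller spliced
#'   length (contract error otherwise).
#' @return `TRUE` or `FALSE`.
#' @export
is_fragment <- function(ann, short_id, long_id) {
  st <- tx_structures(ann)
  if (!short_id %in% names(st$structs)) abort(paste0("unknown transcript: ", short_id))
  if (!long_id %in% names(st$structs)) abort(paste0("unknown transcript: ", long_id))
  s <- st$structs[[short_id]]
  l <- st$structs[[long_id]]
  if (s$gene_id != l$gene_id || s$chrom != l$chrom || s$strand != l$strand) {
    abort("is_fragment requires transcripts of the same gene, chromosome and strand")
  }
  if (!(s$spliced_length < l$spliced_length)) {
    abort("is_fragment requires the first transcript to have strictly smaller spliced length")
  }
  .is_fragment(s, l)
}

#' Remove coverage fragments from every gene
#'
#' Transcripts are processed per gene in descending spliced-length order
#' (protected first on ties, then reference source, then id); each transcript
#' that satisfies the fragment predicate ([is_fragment()]) against any
#' already-retained transcript is removed, so fragments never shield other
#' fragments. Protected transcripts are never removed.
#'
#' @inheritParams collapse_identical_chains
#' @return As [collapse_identical_chains()]; `rule` is `"fragment"`.
#' @export
remove_fragments <- function(ann, protected = character(),
                             ref_sources = character()) {
  st <- tx_structures(ann)
  tx <- rank_transcripts(st$tx, protected, ref_sources)
  removed <- character(0)
  kept_by <- character(0)
  gene_of <- character(0)
  for (g in unique(tx$gene_id[duplicated(tx$gene_id)])) {
    ids <- tx$transcript_id[tx$gene_id == g]
    prot <- tx$.prot[tx$gene_id == g]
    retained <- list()
    for (k in seq_along(ids)) {
      s <- st$structs[[ids[k]]]
      hit <- NULL
      if (!prot[k]) {
        for (u in retained) {
          if (s$strand == u$struct$strand && s$spliced_length < u$struct$spliced_length &&
              .is_fragment(s, u$struct)) {
            hit <- u$id
            break
          }
        }
      }
      if (is.null(hit)) {
        retained[[length(retained) + 1]] <- list(id = ids[k], struct = s)
      } else {
        removed <- c(removed, ids[k])
        kept_by <- c(kept_by, hit)
        gene_of <- c(gene_of, g)
      }
    }
  }
  decisions <- tibble(
    removed_transcript_id = removed, kept_transcript_id = kept_by,
    rule = rep("fragment", length(removed)), gene_id = gene_of
  )
  list(
    annotation = ann %>% filter(!.data$transcript_id %in% removed),
    decisions = decisions
  )
}

run_dedup_rules <- function(ann, protected = character(), ref_sources = character()) {
  s1 <- collapse_identical_chains(ann, protected, ref_sources)
  s2 <- collapse_monoexon(s1$annotation, protected, ref_sources)
  s3 <- remove_fragments(s2$annotation, protected, ref_sources)
  list(
    annotation = s3$annotation,
    decisions = bind_rows(s1$decisions, s2$decisions, s3$decisions)
  )
}

#' Merge curated transcripts into an annotation set
#'
#' Curated transcripts (e.g. experimentally validated isoforms) are added to
#' the set and protected: re-running the redundancy rules never removes them,
#' but they can displace unprotected duplicates (a same-chain, shorter or
#' longer non-curated transcript is removed in favour of the curated one). A
#' curated transcript id that collides with an existing id raises an error if
#' the exon structures differ; identical structures are kept as one protected
#' copy.
#'
#' @param ann An exon-level annotation tibble (typically a deduplicated RTD).
#' @param curated Annotation tibble of curated transcripts; gene ids may be
#'   new.
#' @param ref_sources Source labels treated as the reference on ties.
#' @return A list with `annotation` and `decisions` (removals triggered by
#'   the curated transcripts).
#' @export
merge_curated <- function(ann, curated, ref_sources = character()) {
  if (nrow(curated) == 0) {
    return(list(annotation = ann, decisions = empty_decisions()))
  }
  both <- intersect(unique(ann$transcript_id), unique(curated$transcript_id))
  if (length(both) > 0) {
    key_of <- function(a, ids) {
      e <- a %>% filter(.data$transcript_id %in% ids) %>%
        arrange(.data$transcript_id, .data$start)
      vapply(split(paste0(e$chrom, e$strand, e$start, ".", e$end), e$transcript_id),
             paste, character(1), collapse = ";")
    }
    differ <- both[key_of(ann, both) != key_of(curated, both)]
    if (length(differ) > 0) {
      abort(paste0(
        "curated transcript id(s) collide with existing transcripts of ",
        "different structure: ", paste(head(differ, 5), collapse = ", ")
      ))
    }
    curated <- curated %>% filter(!.data$transcript_id %in% both)
  }
  protected <- unique(c(both, curated$transcript_id))
  merged <- as_annotation(bind_rows(ann, curated))
  out <- run_dedup_rules(merged, protected = protected, ref_sources = ref_sources)
  out
}

#' Build a nonredundant reference transcript dataset
#'
#' The full construction pipeline: gene spans of the two sources are
#' reconciled ([pair_genes()], [apply_resolutions()]); UTR-length variants of
#' a shared intron chain are collapsed ([collapse_identical_chains()]);
#' overlapping mono-exon variants are collapsed ([collapse_monoexon()]);
#' coverage fragments are removed ([remove_fragments()]); finally curated
#' transcripts, if given, are merged in with protection from removal
#' ([merge_curated()]). The output is nonredundant: re-running the pipeline
#' on it yields zero decisions.
#'
#' @param ref Reference-source annotation tibble (coordinate authority).
#' @param alt Alternative/discovery-source annotation tibble.
#' @param curated Optional curated annotation tibble, protected from removal.
#' @return An object of class `rtd_build`: a list with `annotation` (the
#'   nonredundant exon tibble), `decisions` (audit trail of every removal)
#'   and `pairings` (the gene-span reconciliation table). [tidy()] returns
#'   the decisions, [glance()] a one-row summary.
#' @examples
#' ref <- as_annotation(data.frame(
#'   chrom = "c", start = c(1, 201, 1, 201), end = c(100, 300, 90, 300),
#'   strand = "+", gene_id = "g",
#'   transcript_id = rep(c("t.long", "t.short"), each = 2)
#' ), source_label = "ref")
#' b <- build_rtd(ref, ref[0, ])
#' tidy(b) # t.short removed: same chain, shorter UTR
#' @export
build_rtd <- function(ref, alt, curated = NULL) {
  ref <- as_annotation(ref)
  alt <- as_annotation(alt)
  ref_sources <- unique(ref$source)
  rec <- reconcile_annotations(ref, alt)
  dd <- run_dedup_rules(rec$annotation, ref_sources = ref_sources)
  decisions <- dd$decisions
  ann <- dd$annotation
  if (!is.null(curated) && nrow(curated) > 0) {
    mc <- merge_curated(ann, as_annotation(curated), ref_sources = ref_sources)
    ann <- mc$annotation
    decisions <- bind_rows(decisions, mc$decisions)
  }
  structure(
    list(annotation = ann, decisions = decisions, pairings = rec$pairings),
    class = "rtd_build"
  )
}

#' @export
print.rtd_build <- function(x, ...) {
  g <- glance(x)
  cat("Nonredundant reference transcript dataset\n")
  cat(sprintf("  genes: %d  transcripts: %d  (%.2f transcripts/gene)\n",
              g$n_genes, g$n_transcripts,
              if (g$n_genes > 0) g$n_transcripts / g$n_genes else NA_real_))
  cat(sprintf("  removals: %d (%s)\n", nrow(x$decisions),
              if (nrow(x$decisions) > 0) {
                paste(names(table(x$decisions$rule)), table(x$decisions$rule),
                      sep = "=", collapse = ", ")
              } else "none"))
  invisible(x)
}

#' @rdname build_rtd
#' @param x An `rtd_build` object.
#' @param ... Unused.
#' @export
tidy.rtd_build <- function(x, ...) {
  as_tibble(x$decisions)
}

#' @rdname build_rtd
#' @export
glance.rtd_build <- function(x, ...) {
  s <- summarize_rtd(x$annotation)
  s$n_removed <- nrow(x$decisions)
  s
}
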