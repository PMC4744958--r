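#' Exon-level annotation tables
#'
#' `rtdkit` represents a transcript annotation set as a plain tibble with one
#' row per exon and columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#' `transcript_id`, `source`. Coordinates are 1-based inclusive on both ends
#' (the GFF3 convention); `strand` is `"+"` or `"-"`. `as_annotation()`
#' normalizes and validates a data frame into this shape.
#'
#' Invariants enforced:
#' * `1 <= start <= end` for every exon;
#' * all exons of a transcript lie on one chromosome and strand;
#' * exons of a transcript are pairwise non-overlapping with a gap of at
#'   least 1 bp between consecutive exons (adjacent exons should have been
#'   merged upstream);
#' * a transcript id maps to exactly one gene id.
#'
#' Rows are sorted by chromosome, gene, transcript, then exon start. Unsorted
#' exon input is tolerated (sorted with no complaint at the row level); the
#' other invariants raise errors.
#'
#' @param x A data frame with at least the columns above (`source` is filled
#'   with `source_label` when absent).
#' @param source_label Tag recorded in the `source` column when `x` lacks one.
#' @return A validated, sorted exon tibble.
#' @examples
#' as_annotation(data.frame(
#'   chrom = "chr1", start = c(1, 101), end = c(50, 150), strand = "+",
#'   gene_id = "g1", transcript_id = "t1"
#' ), source_label = "demo")
#' @export
as_annotation <- function(x, source_label = "unknown") {
  x <- as_tibble(x)
  if (!"source" %in% names(x)) x$source <- source_label
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id", "source")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- x[required]
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$strand <- as.character(x$strand)
  x$gene_id <- as.character(x$gene_id)
  x$transcript_id <- as.character(x$transcript_id)
  x$source <- as.character(x$source)
  if (nrow(x) == 0) return(x)
  validate_annotation(x)
  x %>% arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start)
}

#' Validate an exon-level annotation tibble
#'
#' Checks the structural invariants documented in [as_annotation()] and
#' raises an error describing the first violation found. Returns the input
#' invisibly so it can sit in a pipe.
#'
#' @param ann An exon-level annotation tibble.
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann) {
  if (nrow(ann) == 0) return(invisible(ann))
  bad <- ann$start < 1L | ann$end < ann$start
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "exon with invalid coordinates (start %d, end %d) in transcript '%s'",
      ann$start[i], ann$end[i], ann$transcript_id[i]
    ))
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  dedup_pairs <- function(a, b) !duplicated(paste0(a, "\r", b))
  n_tx <- length(unique(ann$transcript_id))
  if (sum(dedup_pairs(ann$transcript_id, ann$chrom)) > n_tx ||
      sum(dedup_pairs(ann$transcript_id, ann$strand)) > n_tx) {
    abort("transcript(s) with exons on multiple chromosomes or strands")
  }
  if (sum(dedup_pairs(ann$transcript_id, ann$gene_id)) > n_tx) {
    abort("transcript_id assigned to multiple genes")
  }
  ord <- order(ann$transcript_id, ann$start)
  tid <- ann$transcript_id[ord]
  same_tx <- tid[-1] == tid[-length(tid)]
  gap <- ann$start[ord][-1] - ann$end[ord][-length(ord)]
  bad_gap <- which(same_tx & gap < 2L)
  if (length(bad_gap) > 0) {
    abort(sprintf("overlapping or adjacent exons in transcript '%s'", tid[bad_gap[1]]))
  }
  invisible(ann)
}

#' Per-transcript summary of an annotation
#'
#' Collapses an exon-level annotation to one row per transcript with its
#' span, exon count, spliced length (sum of exon lengths) and intron-chain
#' key. The chain key is the string `"chrom:strand:s1-e1,s2-e2,..."` over the
#' ordered intron coordinates; mono-exon transcripts get an empty intron part.
#'
#' @param ann An exon-level annotation tibble.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `source`, `n_exons`, `span_start`, `span_end`,
#'   `spliced_length`, `n_introns`, `chain`.
#' @export
transcripts <- function(ann) {
  if (nrow(ann) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), source = character(), n_exons = integer(),
      span_start = integer(), span_end = integer(), spliced_length = integer(),
      n_introns = integer(), chain = character()
    ))
  }
  ord <- order(ann$transcript_id, ann$start)
  a <- ann[ord, ]
  f <- factor(a$transcript_id, levels = unique(a$transcript_id))
  n <- tabulate(f)
  last <- cumsum(n)
  first_i <- last - n + 1L
  # exons are non-overlapping and sorted, so the last end is the max end
  keep <- rep(TRUE, nrow(a))
  keep[last] <- FALSE
  chains <- if (any(keep)) {
    istr <- paste0(a$end[keep] + 1L, "-", a$start[which(keep) + 1L] - 1L)
    vapply(split(istr, f[keep]), paste, character(1), collapse = ",")
  } else {
    rep("", length(n))
  }
  tibble(
    transcript_id = levels(f),
    gene_id = a$gene_id[first_i],
    chrom = a$chrom[first_i],
    strand = a$strand[first_i],
    source = a$source[first_i],
    n_exons = n,
    span_start = a$start[first_i],
    span_end = a$end[last],
    spliced_length = as.integer(rowsum(a$end - a$start + 1L, as.integer(f))[, 1]),
    n_introns = n - 1L,
    chain = paste0(a$chrom[first_i], ":", a$strand[first_i], ":", unname(chains))
  )
}

#' Intron chains of every transcript
#'
#' Derives intron coordinates from consecutive exons:
#' `intron_i = (exon_i.end + 1, exon_{i+1}.start - 1)`, 1-based inclusive.
#' Mono-exon transcripts contribute no rows (their chain is empty).
#'
#' @param ann An exon-level annotation tibble.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `intron_index`, `start`, `end`, one row per intron, ascending
#'   within a transcript.
#' @examples
#' ann <- as_annotation(data.frame(
#'   chrom = "c", start = c(1, 201), end = c(100, 300), strand = "+",
#'   gene_id = "g", transcript_id = "t"
#' ))
#' intron_chain(ann) # one intron: 101-200
#' @export
intron_chain <- function(ann) {
  empty <- tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), intron_index = integer(),
    start = integer(), end = integer()
  )
  if (nrow(ann) == 0) return(empty)
  ord <- order(ann$transcript_id, ann$start)
  a <- ann[ord, ]
  f <- factor(a$transcript_id, levels = unique(a$transcript_id))
  n <- tabulate(f)
  last <- cumsum(n)
  keep <- rep(TRUE, nrow(a))
  keep[last] <- FALSE
  if (!any(keep)) return(empty)
  ki <- which(keep)
  first_of_row <- rep(last - n + 1L, n)
  tibble(
    transcript_id = a$transcript_id[ki],
    gene_id = a$gene_id[ki],
    chrom = a$chrom[ki],
    strand = a$strand[ki],
    intron_index = ki - first_of_row[ki] + 1L,
    start = a$end[ki] + 1L,
    end = a$start[ki + 1L] - 1L
  )
}

#' Gene spans derived from exons
#'
#' One row per gene: the chromosome, strand set, and the union span of all
#' its transcripts.
#'
#' @param ann An exon-level annotation tibble.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `n_transcripts`.
#' @export
gene_spans <- function(ann) {
  if (nrow(ann) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), n_transcripts = integer()
    ))
  }
  chrom_per_gene <- ann %>%
    group_by(.data$gene_id) %>%
    summarise(n_chrom = n_distinct(.data$chrom), .groups = "drop")
  if (any(chrom_per_gene$n_chrom > 1)) {
    abort(paste0(
      "gene(s) with exons on multiple chromosomes: ",
      paste(head(chrom_per_gene$gene_id[chrom_per_gene$n_chrom > 1], 5), collapse = ", ")
    ))
  }
  ann %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = n_distinct(.data$transcript_id),
      .groups = "drop"
    )
}
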