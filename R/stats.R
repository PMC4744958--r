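#' Round half away from zero
#'
#' Dataset tables conventionally round 2.405 to 2.41, not to the even digit
#' as [round()] does; this helper matches that presentation.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Average transcripts per gene
#'
#' `n_transcripts / n_genes`, rounded half away from zero to two decimals —
#' the per-dataset isoform-complexity figure reported in annotation summary
#' tables.
#'
#' @param n_genes Number of genes (> 0).
#' @param n_transcripts Number of transcripts.
#' @return The ratio at two decimals.
#' @examples
#' avg_transcripts_per_gene(33602, 41671) # 1.24
#' @export
avg_transcripts_per_gene <- function(n_genes, n_transcripts) {
  if (any(n_genes <= 0)) abort("avg_transcripts_per_gene is undefined for n_genes = 0")
  round_half_away(n_transcripts / n_genes, 2)
}

#' Summary statistics of a transcript dataset
#'
#' One-row tibble with the headline numbers of an annotation set: gene and
#' transcript counts, average transcripts per gene, single-transcript gene
#' count, intron-containing gene counts, and the alternative-splicing
#' frequency `as_percent` = 100 x (intron-containing genes with >= 2
#' transcripts) / (intron-containing genes), at two decimals. An
#' intron-containing gene is one with at least one transcript having >= 1
#' intron. An empty set yields zeros with `avg_transcripts_per_gene` and
#' `as_percent` as `NA`.
#'
#' @param ann An exon-level annotation tibble.
#' @return A one-row tibble with columns `n_genes`, `n_transcripts`,
#'   `avg_transcripts_per_gene`, `n_single_transcript_genes`,
#'   `n_intron_genes`, `n_intron_genes_multi`, `as_percent`.
#' @export
summarize_rtd <- function(ann) {
  tx <- transcripts(ann)
  if (nrow(tx) == 0) {
    return(tibble(
      n_genes = 0L, n_transcripts = 0L, avg_transcripts_per_gene = NA_real_,
      n_single_transcript_genes = 0L, n_intron_genes = 0L,
      n_intron_genes_multi = 0L, as_percent = NA_real_
    ))
  }
  per_gene <- tx %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_tx = n(),
      has_intron = any(.data$n_introns > 0),
      .groups = "drop"
    )
  n_genes <- nrow(per_gene)
  n_transcripts <- nrow(tx)
  n_intron <- sum(per_gene$has_intron)
  n_intron_multi <- sum(per_gene$has_intron & per_gene$n_tx >= 2)
  tibble(
    n_genes = n_genes,
    n_transcripts = n_transcripts,
    avg_transcripts_per_gene = avg_transcripts_per_gene(n_genes, n_transcripts),
    n_single_transcript_genes = sum(per_gene$n_tx == 1),
    n_intron_genes = n_intron,
    n_intron_genes_multi = n_intron_multi,
    as_percent = if (n_intron > 0) round_half_away(100 * n_intron_multi / n_intron, 2) else NA_real_
  )
}

#' Distribution of transcripts per gene
#'
#' @param ann An exon-level annotation tibble.
#' @return A tibble with columns `transcripts_per_gene` and `n_genes`,
#'   ascending; `sum(n_genes)` equals the gene count and
#'   `sum(transcripts_per_gene * n_genes)` the transcript count.
#' @export
transcripts_per_gene <- function(ann) {
  tx <- transcripts(ann)
  if (nrow(tx) == 0) {
    return(tibble(transcripts_per_gene = integer(), n_genes = integer()))
  }
  tx %>%
    count(.data$gene_id, name = "transcripts_per_gene") %>%
    count(.data$transcripts_per_gene, name = "n_genes") %>%
    arrange(.data$transcripts_per_gene)
}

#' Histogram of transcripts per gene
#'
#' @param ann An exon-level annotation tibble.
#' @param min_transcripts Smallest per-gene transcript count displayed
#'   (default 1; summary figures often start at 2).
#' @return A ggplot object.
#' @export
plot_transcripts_per_gene <- function(ann, min_transcripts = 1L) {
  h <- transcripts_per_gene(ann) %>%
    filter(.data$transcripts_per_gene >= min_transcripts)
  ggplot2::ggplot(h, ggplot2::aes(
    x = factor(.data$transcripts_per_gene), y = .data$n_genes
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Transcripts per gene", y = "Number of genes") +
    ggplot2::theme_classic()
}
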