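#' Read transcript quantification tables
#'
#' Reads one or more tab-delimited quantification files (the Sailfish/Salmon
#' `quant.sf` layout: a transcript-name column plus a `TPM` column; extra
#' columns are ignored) into a long abundance table. Each file is one sample.
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample identifiers, parallel to `paths`; defaults to the
#'   names of `paths`, else the file names without extension.
#' @return A tibble with columns `transcript_id`, `sample_id`, `tpm`.
#'   `sample_id` is a factor ordered as given, so replicate order is kept.
#' @export
read_quant <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(paths))) names(paths) else
      sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(sample_ids) == length(paths))
  name_cols <- c("Name", "name", "transcript_id", "transcript", "target_id")
  out <- purrr::map2(paths, sample_ids, function(p, s) {
    d <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    name_col <- intersect(name_cols, names(d))[1]
    tpm_col <- intersect(c("TPM", "tpm"), names(d))[1]
    if (is.na(name_col) || is.na(tpm_col)) {
      abort(paste0(
        "quantification file '", p, "' lacks a transcript-name or TPM column; ",
        "header seen: ", paste(names(d), collapse = ", ")
      ))
    }
    tpm <- d[[tpm_col]]
    if (any(tpm < 0, na.rm = TRUE)) {
      abort(paste0("negative TPM value(s) in '", p, "'"))
    }
    tibble(transcript_id = as.character(d[[name_col]]), sample_id = s, tpm = tpm)
  })
  out <- bind_rows(out)
  out$sample_id <- factor(out$sample_id, levels = unique(sample_ids))
  out
}

#' Read an alternative-splicing event definition table
#'
#' Tab-delimited with columns `event_id`, `gene_id`, `event_type` (one of
#' `IR`, `Alt5`, `Alt3`, `ES`), `chrom`, `start`, `end`, `strand`, and
#' optional `positive_ids`/`fs_ids`/`other_ids` (comma-separated explicit
#' transcript assignments that override automatic assignment).
#'
#' @param path File path.
#' @return The events tibble.
#' @export
read_events <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("event_id", "gene_id", "event_type", "chrom", "start", "end", "strand")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0) {
    abort(paste0("event table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(d$event_type), c("IR", "Alt5", "Alt3", "ES"))
  if (length(bad) > 0) {
    abort(paste0("unknown event_type value(s): ", paste(bad, collapse = ", ")))
  }
  d
}

#' Read an RT-PCR peak-area table
#'
#' Tab-delimited with columns `event_id`, `product_label`, `category` (one of
#' `positive`, `fs`, `other` — which splicing class the electrophoresis
#' product represents), `sample_id`, `rfu` (peak area, relative fluorescence
#' units).
#'
#' @param path File path.
#' @return The peaks tibble.
#' @export
read_peaks <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("event_id", "product_label", "category", "sample_id", "rfu")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0) {
    abort(paste0("peak table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(d$rfu < 0, na.rm = TRUE)) abort("negative RFU value(s) in peak table")
  bad <- setdiff(unique(d$category), c("positive", "fs", "other"))
  if (length(bad) > 0) {
    abort(paste0("unlabelled or unknown product category value(s): ",
                 paste(bad, collapse = ", ")))
  }
  d
}

# local intron chain of every transcript of a gene within a region
local_chains <- function(introns, region_start, region_end) {
  introns %>% filter(.data$start <= region_end, .data$end >= region_start)
}

classify_against_fs <- function(t_introns, fs_introns, strand) {
  # difference types a transcript shows relative to the fully spliced chain
  fs_key <- paste(fs_introns$start, fs_introns$end)
  t_key <- paste(t_introns$start, t_introns$end)
  diffs <- character(0)
  fs_missing <- fs_introns[!fs_key %in% t_key, , drop = FALSE]
  for (i in seq_len(nrow(fs_missing))) {
    f_s <- fs_missing$start[i]
    f_e <- fs_missing$end[i]
    ovl <- t_introns$start <= f_e & t_introns$end >= f_s
    if (!any(ovl)) {
      diffs <- c(diffs, "IR")
    } else {
      ts <- t_introns$start[ovl]
      te <- t_introns$end[ovl]
      same_start <- ts == f_s & te != f_e
      same_end <- te == f_e & ts != f_s
      if (strand == "+") {
        if (any(same_start)) diffs <- c(diffs, "Alt3")
        if (any(same_end)) diffs <- c(diffs, "Alt5")
      } else {
        if (any(same_start)) diffs <- c(diffs, "Alt5")
        if (any(same_end)) diffs <- c(diffs, "Alt3")
      }
    }
  }
  # exon skipping: a transcript intron spanning an entire fully-spliced
  # internal exon (the gap between two consecutive fs introns)
  if (nrow(fs_introns) >= 2 && nrow(t_introns) > 0) {
    for (i in seq_len(nrow(fs_introns) - 1)) {
      spans <- t_introns$start <= fs_introns$start[i] &
        t_introns$end >= fs_introns$end[i + 1]
      if (any(spans)) diffs <- c(diffs, "ES")
    }
  }
  unique(diffs)
}

#' Assign a gene's transcripts to an alternative-splicing event
#'
#' For each event (a primer-pair region on a gene), the gene's transcripts
#' overlapping the region are partitioned into three classes by comparing
#' their intron structure within the region:
#'
#' * `fs` — transcripts matching the fully spliced local chain, taken as the
#'   local chain with the most introns in the region and, among those, the
#'   least total intron length (ties: smallest chain string);
#' * `positive` — transcripts whose local structure differs from the fully
#'   spliced chain by the event's type (`IR`: a fully-spliced intron is
#'   retained; `Alt5`/`Alt3`: an intron shares one boundary but shifts the
#'   donor/acceptor, strand-aware; `ES`: an intron spans an entire
#'   fully-spliced exon);
#' * `other` — remaining overlapping transcripts (different event type or
#'   complex differences).
#'
#' Transcripts not overlapping the region are excluded entirely. Events with
#' explicit `positive_ids`/`fs_ids`/`other_ids` columns (comma-separated)
#' bypass the automatic comparison.
#'
#' @param events Event tibble (see [read_events()]).
#' @param ann The reference transcript dataset as an exon-level tibble.
#' @return A tibble with columns `event_id`, `gene_id`, `transcript_id`,
#'   `category`.
#' @export
assign_event_transcripts <- function(events, ann) {
  tx <- transcripts(ann)
  introns <- intron_chain(ann)
  out <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    explicit <- all(c("positive_ids", "fs_ids") %in% names(ev)) &&
      !is.na(ev$positive_ids) && !is.na(ev$fs_ids)
    if (explicit) {
      split_ids <- function(s) if (is.na(s) || s == "") character(0) else
        strsplit(s, ",", fixed = TRUE)[[1]]
      other <- if ("other_ids" %in% names(ev)) split_ids(ev$other_ids) else character(0)
      out[[k]] <- tibble(
        event_id = ev$event_id, gene_id = ev$gene_id,
        transcript_id = c(split_ids(ev$positive_ids), split_ids(ev$fs_ids), other),
        category = c(rep("positive", length(split_ids(ev$positive_ids))),
                     rep("fs", length(split_ids(ev$fs_ids))),
                     rep("other", length(other)))
      )
      next
    }
    gtx <- tx %>% filter(.data$gene_id == ev$gene_id,
                         .data$span_start <= ev$end, .data$span_end >= ev$start)
    if (nrow(gtx) == 0) {
      abort(paste0("no transcript of gene '", ev$gene_id,
                   "' overlaps the region of event '", ev$event_id, "'"))
    }
    gin <- introns %>% filter(.data$transcript_id %in% gtx$transcript_id)
    loc <- local_chains(gin, ev$start, ev$end)
    loc_by_tx <- split(loc, factor(loc$transcript_id, levels = gtx$transcript_id))
    chain_str <- vapply(loc_by_tx, function(d) paste(d$start, d$end, sep = "-", collapse = ","),
                        character(1))
    spliced_out <- vapply(loc_by_tx, function(d) sum(d$end - d$start + 1L), integer(1))
    n_in <- vapply(loc_by_tx, nrow, integer(1))
    # fully spliced reference chain: all introns of the region spliced (most
    # introns), at the most conservative extent (least total intron length);
    # ties break on the chain string for determinism
    ord <- order(-n_in, spliced_out, chain_str)
    fs_chain <- chain_str[ord[1]]
    fs_introns <- loc_by_tx[[ord[1]]]
    category <- vapply(seq_len(nrow(gtx)), function(i) {
      id <- gtx$transcript_id[i]
      if (chain_str[[id]] == fs_chain) return("fs")
      diffs <- classify_against_fs(loc_by_tx[[id]], fs_introns, ev$strand)
      if (ev$event_type %in% diffs) "positive" else "other"
    }, character(1))
    out[[k]] <- tibble(
      event_id = ev$event_id, gene_id = ev$gene_id,
      transcript_id = gtx$transcript_id, category = category
    )
  }
  bind_rows(out)
}

ratio_from_sums <- function(pos, fs, other, mode, raw_quotient) {
  if (mode == "of_total") {
    den <- pos + fs + other
    num <- pos
  } else if (raw_quotient) {
    den <- fs
    num <- pos
  } else {
    den <- pos + fs
    num <- pos
  }
  tibble(ratio = ifelse(den > 0, num / den, NA_real_), valid = den > 0)
}

#' Splicing ratios from transcript abundances
#'
#' For every event and sample, sums TPM over the event's transcript classes
#' and forms the splicing ratio. `mode = "of_total"` is the share of
#' event-positive transcripts in all transcripts assigned to the event,
#' `positive / (positive + fs + other)`; `mode = "as_vs_fs"` compares the
#' event-positive (AS) transcripts with the fully spliced ones only,
#' `positive / (positive + fs)` (bounded in \[0, 1\]), or the raw quotient
#' `positive / fs` when `raw_quotient = TRUE`. A zero denominator yields an
#' invalid record (`valid = FALSE`, ratio `NA`) rather than an error.
#' Transcripts with no abundance entry for a sample count as 0 TPM; the
#' number of such missing entries is reported as a message.
#'
#' @param assignments Output of [assign_event_transcripts()].
#' @param abundance Long abundance table from [read_quant()] (columns
#'   `transcript_id`, `sample_id`, `tpm`).
#' @param mode `"of_total"` or `"as_vs_fs"`.
#' @param raw_quotient In `as_vs_fs` mode, return the unbounded `AS/FS`
#'   quotient instead of `AS/(AS+FS)`.
#' @param method Label stored in the `method` column (default `"rnaseq"`).
#' @return A tibble of ratio records: `event_id`, `sample_id`, `method`,
#'   `mode`, `ratio`, `valid`.
#' @export
splicing_ratios <- function(assignments, abundance,
                            mode = c("of_total", "as_vs_fs"),
                            raw_quotient = FALSE, method = "rnaseq") {
  mode <- match.arg(mode)
  samples <- unique(as.character(abundance$sample_id))
  grid <- tidyr::expand_grid(
    assignments[, c("event_id", "transcript_id", "category")],
    sample_id = samples
  )
  ab <- abundance %>%
    mutate(sample_id = as.character(.data$sample_id)) %>%
    distinct(.data$transcript_id, .data$sample_id, .keep_all = TRUE)
  joined <- grid %>% left_join(ab, by = c("transcript_id", "sample_id"))
  n_missing <- sum(is.na(joined$tpm))
  if (n_missing > 0) {
    inform(sprintf("%d transcript/sample abundance entries missing; treated as 0 TPM",
                   n_missing))
  }
  joined$tpm[is.na(joined$tpm)] <- 0
  sums <- joined %>%
    group_by(.data$event_id, .data$sample_id) %>%
    summarise(
      pos = sum(.data$tpm[.data$category == "positive"]),
      fs = sum(.data$tpm[.data$category == "fs"]),
      other = sum(.data$tpm[.data$category == "other"]),
      .groups = "drop"
    )
  bind_rows(list(
    sums %>%
      mutate(ratio_from_sums(.data$pos, .data$fs, .data$other, mode, raw_quotient),
             method = method, mode = mode) %>%
      select("event_id", "sample_id", "method", "mode", "ratio", "valid")
  ))
}

#' Splicing ratios from RT-PCR peak areas
#'
#' Same formulas as [splicing_ratios()], with RFU peak areas in place of TPM:
#' products labelled `positive`, `fs` and `other` are summed per event and
#' sample.
#'
#' @param peaks Peak table from [read_peaks()].
#' @inheritParams splicing_ratios
#' @param method Label stored in the `method` column (default `"hrrtpcr"`).
#' @return A tibble of ratio records, as [splicing_ratios()].
#' @export
pcr_ratios <- function(peaks, mode = c("of_total", "as_vs_fs"),
                       raw_quotient = FALSE, method = "hrrtpcr") {
  mode <- match.arg(mode)
  bad <- setdiff(unique(peaks$category), c("positive", "fs", "other"))
  if (length(bad) > 0) {
    abort(paste0("peak product(s) with unknown category: ", paste(bad, collapse = ", ")))
  }
  sums <- peaks %>%
    group_by(.data$event_id, .data$sample_id) %>%
    summarise(
      pos = sum(.data$rfu[.data$category == "positive"]),
      fs = sum(.data$rfu[.data$category == "fs"]),
      other = sum(.data$rfu[.data$category == "other"]),
      .groups = "drop"
    )
  sums %>%
    mutate(ratio_from_sums(.data$pos, .data$fs, .data$other, mode, raw_quotient),
           method = method, mode = mode) %>%
    select("event_id", "sample_id", "method", "mode", "ratio", "valid")
}

#' Aggregate replicate splicing ratios
#'
#' Groups ratio records by event, time point, method and mode, and reports
#' the mean and the sample standard deviation (n - 1 denominator) over valid
#' replicates. Groups with one valid replicate get `sd = NA`; groups with
#' none are dropped with a warning.
#'
#' @param records Ratio records ([splicing_ratios()] / [pcr_ratios()]).
#' @param sample_info Tibble mapping `sample_id` to `time_point` (and
#'   optionally `replicate`).
#' @return A tibble with `event_id`, `time_point`, `method`, `mode`,
#'   `mean_ratio`, `sd_ratio`, `n_replicates`.
#' @export
aggregate_replicates <- function(records, sample_info) {
  r <- records %>%
    mutate(sample_id = as.character(.data$sample_id)) %>%
    left_join(sample_info %>% mutate(sample_id = as.character(.data$sample_id)),
              by = "sample_id")
  grouped <- r %>%
    group_by(.data$event_id, .data$time_point, .data$method, .data$mode) %>%
    summarise(
      n_replicates = sum(.data$valid),
      mean_ratio = if (sum(.data$valid) > 0) mean(.data$ratio[.data$valid]) else NA_real_,
      sd_ratio = if (sum(.data$valid) > 1) sd(.data$ratio[.data$valid]) else NA_real_,
      .groups = "drop"
    )
  dropped <- grouped %>% filter(.data$n_replicates == 0)
  if (nrow(dropped) > 0) {
    warn(sprintf("%d event/time-point group(s) had no valid replicate and were dropped",
                 nrow(dropped)))
  }
  grouped %>%
    filter(.data$n_replicates > 0) %>%
    select("event_id", "time_point", "method", "mode",
           "mean_ratio", "sd_ratio", "n_replicates")
}

#' Correlate two numeric ratio vectors
#'
#' Pearson product-moment and Spearman rank (average ranks on ties)
#' coefficients over paired points. A vector with zero variance yields `NA`
#' coefficients; fewer than two pairs is an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `pearson_r`, `spearman_rho`, `n_points`.
#' @export
correlate_points <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) abort("correlation needs at least 2 paired points")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(pearson_r = NA_real_, spearman_rho = NA_real_,
                  n_points = length(x)))
  }
  tibble(
    pearson_r = cor(x, y, method = "pearson"),
    spearman_rho = cor(x, y, method = "spearman"),
    n_points = length(x)
  )
}

#' Correlate splicing ratios between two measurement methods
#'
#' Joins two ratio-record tables (e.g. RNA-seq vs RT-PCR) by event, sample
#' and mode, keeps pairs where both records are valid, and computes Pearson
#' and Spearman coefficients over the individual points (each replicate is a
#' point).
#'
#' @param x,y Ratio-record tibbles from [splicing_ratios()] / [pcr_ratios()].
#' @return One-row tibble: `pearson_r`, `spearman_rho`, `n_points`.
#' @export
correlate_ratios <- function(x, y) {
  paired <- paired_ratios(x, y)
  correlate_points(paired$ratio_x, paired$ratio_y)
}

#' Paired valid ratios of two methods
#'
#' @inheritParams correlate_ratios
#' @return A tibble with `event_id`, `sample_id`, `mode`, `method_x`,
#'   `method_y`, `ratio_x`, `ratio_y`, one row per pair where both records
#'   are valid.
#' @export
paired_ratios <- function(x, y) {
  inner_join(
    x %>% mutate(sample_id = as.character(.data$sample_id)),
    y %>% mutate(sample_id = as.character(.data$sample_id)),
    by = c("event_id", "sample_id", "mode"), suffix = c("_x", "_y")
  ) %>%
    filter(.data$valid_x, .data$valid_y) %>%
    select("event_id", "sample_id", "mode",
           method_x = "method_x", method_y = "method_y",
           ratio_x = "ratio_x", ratio_y = "ratio_y")
}

#' Scatter plot of paired splicing ratios
#'
#' @param paired Output of [paired_ratios()].
#' @return A ggplot object with the identity line and the correlation
#'   coefficients in the subtitle.
#' @export
plot_method_correlation <- function(paired) {
  cc <- correlate_points(paired$ratio_x, paired$ratio_y)
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$ratio_x, y = .data$ratio_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = paste0("Splicing ratio (", paired$method_x[1], ")"),
      y = paste0("Splicing ratio (", paired$method_y[1], ")"),
      subtitle = sprintf("Pearson r = %.4f, Spearman rho = %.4f, n = %d",
                         cc$pearson_r, cc$spearman_rho, cc$n_points)
    ) +
    ggplot2::theme_classic()
}
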