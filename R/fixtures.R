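#' Specification for the synthetic fixture generator
#'
#' Describes a synthetic study: a genome, a ground-truth nonredundant
#' transcript set, two annotation sources carrying injected redundancy of the
#' kinds the construction pipeline removes, and paired abundance/peak tables
#' with known true splicing ratios. All generators are pure functions of the
#' spec: the same spec always yields byte-identical output.
#'
#' The defaults mirror the validation design the package targets: three
#' biological replicates at two time points, multiplicative log-normal
#' measurement noise coupling the RT-PCR peak areas to the true transcript
#' abundances.
#'
#' @param seed Integer seed for the generator's private random stream.
#' @param n_genes Number of genes (>= 1).
#' @param redundancy_rates Named list of per-rule injection probabilities in
#'   \[0, 1\]: `utr_variant` (same intron chain, shorter UTR exons),
#'   `monoexon_variant` (shorter overlapping copy of a mono-exon transcript),
#'   `fragment` (truncated transcript with a subset intron chain),
#'   `contained_gene_model` (arrange a gene's alt-source span strictly inside
#'   its ref-source span; requires an injected variant to realize),
#'   `partial_overlap_gene_model` (stagger the spans of a gene's isoforms
#'   across the two sources).
#' @param noise_sd Log-normal (sdlog) scale of the multiplicative noise on
#'   peak areas relative to true abundances; 0 means exact proportionality.
#' @param n_replicates Biological replicates per time point.
#' @param n_timepoints Time points.
#' @param p_mono Probability a gene is mono-exon.
#' @param p_ir,p_alt Probability a spliced gene carries a true
#'   intron-retention / alternative-splice-site isoform (these are genuine
#'   isoforms that must survive deduplication).
#' @return A `fixture_spec` object (validated list).
#' @export
fixture_spec <- function(seed = 1L, n_genes = 50L,
                         redundancy_rates = list(
                           utr_variant = 0.3, monoexon_variant = 0.3,
                           fragment = 0.3, contained_gene_model = 0.3,
                           partial_overlap_gene_model = 0.1
                         ),
                         noise_sd = 0.15, n_replicates = 3L, n_timepoints = 2L,
                         p_mono = 0.2, p_ir = 0.3, p_alt = 0.3) {
  defaults <- list(
    utr_variant = 0.3, monoexon_variant = 0.3, fragment = 0.3,
    contained_gene_model = 0.3, partial_overlap_gene_model = 0.1
  )
  redundancy_rates <- utils::modifyList(defaults, as.list(redundancy_rates))
  rates <- unlist(redundancy_rates[names(defaults)])
  if (any(rates < 0 | rates > 1)) abort("redundancy rates must lie in [0, 1]")
  if (!is.numeric(n_genes) || n_genes < 1) abort("n_genes must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  probs <- c(p_mono = p_mono, p_ir = p_ir, p_alt = p_alt)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if ((seed %% 1) != 0) abort("seed must be an integer")
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      redundancy_rates = as.list(rates), noise_sd = noise_sd,
      n_replicates = as.integer(n_replicates),
      n_timepoints = as.integer(n_timepoints),
      p_mono = p_mono, p_ir = p_ir, p_alt = p_alt
    ),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("fixture_spec: %d genes, seed %d, noise_sd %.3g, %d reps x %d time points\n",
              x$n_genes, x$seed, x$noise_sd, x$n_replicates, x$n_timepoints))
  cat("  redundancy rates:",
      paste(names(x$redundancy_rates), unlist(x$redundancy_rates), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

rint <- function(n, lo, hi) as.integer(lo + floor(runif(n) * (hi - lo + 1L)))

# Lay out genes, truth isoforms, injected redundancy and source assignment.
# Everything downstream (genome, events, tables) derives from this. The
# genome is drawn from its own derived stream so that layout draws are
# identical whether or not sequence is requested.
build_fixture <- function(spec, with_genome = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    rr <- spec$redundancy_rates
    cursor <- c(chr1 = 0L, chr2 = 0L)
    rows <- list()      # exon rows: chrom,start,end,strand,gene_id,transcript_id,source,role
    ledger <- list()    # injected-redundancy truth ledger
    events <- list()    # event definitions for AS genes
    for (g in seq_len(spec$n_genes)) {
      gid <- sprintf("G%04d", g)
      chrom <- if (g %% 2 == 1) "chr1" else "chr2"
      strand <- if (runif(1) < 0.5) "+" else "-"
      gstart <- cursor[[chrom]] + rint(1, 500L, 1500L)
      mono <- runif(1) < spec$p_mono
      if (mono) {
        len <- rint(1, 200L, 1200L)
        exons <- cbind(gstart, gstart + len - 1L)
      } else {
        n_ex <- rint(1, 2L, 6L)
        ex_len <- rint(n_ex, 80L, 300L)
        in_len <- if (n_ex > 1) rint(n_ex - 1, 60L, 200L) else integer(0)
        starts <- gstart + cumsum(c(0L, ex_len[-n_ex] + in_len))
        exons <- cbind(starts, starts + ex_len - 1L)
      }
      base_id <- paste0(gid, ".1")
      iso <- list()   # list of list(id, exons, role)
      iso[[1]] <- list(id = base_id, exons = exons, role = "base")
      ev_g <- list()

      frag_gene <- FALSE
      if (!mono) {
        n_introns <- nrow(exons) - 1L
        frag_gene <- (runif(1) < rr$fragment) && n_introns >= 2
        if (!frag_gene && n_introns >= 1) {
          want_ir <- runif(1) < spec$p_ir
          want_alt <- runif(1) < spec$p_alt
          if (want_ir && want_alt && n_introns < 2) want_alt <- FALSE
          avail <- seq_len(n_introns)
          if (want_ir) {
            r <- avail[rint(1, 1L, length(avail))]
            avail <- setdiff(avail, r)
            # retain intron r: merge exons r and r+1
            e2 <- exons
            e2[r, 2] <- e2[r + 1, 2]
            e2 <- e2[-(r + 1), , drop = FALSE]
            ir_id <- paste0(gid, ".ir")
            iso[[length(iso) + 1]] <- list(id = ir_id, exons = e2, role = "ir")
            ev_g[[length(ev_g) + 1]] <- list(
              event_id = paste0(gid, ".E", length(ev_g) + 1), gene_id = gid,
              event_type = "IR", chrom = chrom,
              start = exons[r, 2] + 1L - 25L, end = exons[r + 1, 1] - 1L + 25L,
              strand = strand
            )
          }
          if (want_alt && length(avail) > 0) {
            j <- avail[rint(1, 1L, length(avail))]
            delta <- rint(1, 6L, 12L)
            exon_len <- exons[j, 2] - exons[j, 1] + 1L
            if (exon_len - delta >= 30) {
              # alternative splice site within exon j: intron j grows at its
              # genomic start, removing delta nt from the exon
              e2 <- exons
              e2[j, 2] <- e2[j, 2] - delta
              alt_id <- paste0(gid, ".alt")
              iso[[length(iso) + 1]] <- list(id = alt_id, exons = e2, role = "alt")
              ev_g[[length(ev_g) + 1]] <- list(
                event_id = paste0(gid, ".E", length(ev_g) + 1), gene_id = gid,
                event_type = if (strand == "+") "Alt5" else "Alt3", chrom = chrom,
                start = exons[j, 2] + 1L - 25L, end = exons[j + 1, 1] - 1L + 25L,
                strand = strand
              )
            }
          }
        }
      }

      # partial-overlap gene-model injection: stagger the alt isoform's span
      partial_gene <- FALSE
      has_alt_iso <- any(vapply(iso, function(x) x$role == "alt", logical(1)))
      if (has_alt_iso && runif(1) < rr$partial_overlap_gene_model) {
        partial_gene <- TRUE
        k <- which(vapply(iso, function(x) x$role == "alt", logical(1)))[1]
        e2 <- iso[[k]]$exons
        trim <- min(40L, e2[1, 2] - e2[1, 1] - 20L)
        if (trim > 0) e2[1, 1] <- e2[1, 1] + trim
        e2[nrow(e2), 2] <- e2[nrow(e2), 2] + 50L
        iso[[k]]$exons <- e2
      }

      # injected redundancy (removed by the pipeline; recorded in the ledger)
      injected <- list()
      if (mono) {
        if (runif(1) < rr$monoexon_variant) {
          d1 <- rint(1, 5L, 40L)
          d2 <- rint(1, 5L, 40L)
          if (exons[1, 2] - d2 - (exons[1, 1] + d1) + 1L >= 50L) {
            vid <- paste0(base_id, "m")
            injected[[1]] <- list(
              id = vid, exons = cbind(exons[1, 1] + d1, exons[1, 2] - d2)
            )
            ledger[[length(ledger) + 1]] <- c(vid, base_id, "monoexon_shorter", gid)
          }
        }
      } else {
        if (runif(1) < rr$utr_variant) {
          k <- rint(1, 1L, length(iso))
          tgt <- iso[[k]]
          e2 <- tgt$exons
          d1 <- min(rint(1, 5L, 30L), e2[1, 2] - e2[1, 1] - 14L)
          d2 <- min(rint(1, 5L, 30L), e2[nrow(e2), 2] - e2[nrow(e2), 1] - 14L)
          if (d1 >= 1 && d2 >= 1) {
            e2[1, 1] <- e2[1, 1] + d1
            e2[nrow(e2), 2] <- e2[nrow(e2), 2] - d2
            vid <- paste0(tgt$id, "u")
            injected[[length(injected) + 1]] <- list(id = vid, exons = e2)
            # a variant of a mono-exon isoform (an IR isoform of a 2-exon
            # gene) has an empty chain, so the mono-exon rule removes it
            ledger[[length(ledger) + 1]] <- c(
              vid, tgt$id,
              if (nrow(tgt$exons) == 1) "monoexon_shorter" else "same_chain_shorter_utr",
              gid
            )
          }
        }
        if (frag_gene) {
          n_ex <- nrow(exons)
          repeat {
            i <- rint(1, 1L, n_ex - 1L)
            j <- rint(1, i + 1L, n_ex)
            if (!(i == 1L && j == n_ex)) break
          }
          e2 <- exons[i:j, , drop = FALSE]
          d1 <- min(rint(1, 3L, 20L), e2[1, 2] - e2[1, 1] - 14L)
          d2 <- min(rint(1, 3L, 20L), e2[nrow(e2), 2] - e2[nrow(e2), 1] - 14L)
          e2[1, 1] <- e2[1, 1] + max(d1, 1L)
          e2[nrow(e2), 2] <- e2[nrow(e2), 2] - max(d2, 1L)
          vid <- paste0(base_id, "f")
          injected[[length(injected) + 1]] <- list(id = vid, exons = e2)
          ledger[[length(ledger) + 1]] <- c(vid, base_id, "fragment", gid)
        }
      }

      # source assignment
      u <- runif(1)
      placement <- if (u < 0.7) "both" else if (u < 0.85) "ref" else "alt"
      if (placement == "both" && length(iso) + length(injected) < 2) placement <- "ref"
      src_iso <- character(length(iso))
      src_inj <- character(length(injected))
      if (placement == "both") {
        contained <- length(injected) > 0 && runif(1) < rr$contained_gene_model &&
          !partial_gene
        if (contained) {
          src_iso[] <- "ref"
          src_inj[] <- "alt"
        } else if (partial_gene) {
          k_alt <- which(vapply(iso, function(x) x$role == "alt", logical(1)))[1]
          src_iso[] <- "ref"
          src_iso[k_alt] <- "alt"
          src_inj <- if (length(injected)) c("ref", "alt")[rint(length(injected), 1L, 2L)] else character(0)
        } else {
          all_src <- c("ref", "alt")[rint(length(iso) + length(injected), 1L, 2L)]
          # guarantee both sources nonempty
          if (!"ref" %in% all_src) all_src[1] <- "ref"
          if (!"alt" %in% all_src) all_src[length(all_src)] <- "alt"
          src_iso <- all_src[seq_along(iso)]
          src_inj <- all_src[length(iso) + seq_along(injected)]
        }
      } else {
        src_iso[] <- placement
        src_inj[] <- placement
      }

      exon_rows <- function(x, src, role) {
        n <- nrow(x$exons)
        list(
          chrom = rep(chrom, n), start = as.integer(x$exons[, 1]),
          end = as.integer(x$exons[, 2]), strand = rep(strand, n),
          gene_id = rep(gid, n), transcript_id = rep(x$id, n),
          source = rep(src, n), role = rep(role, n)
        )
      }
      for (k in seq_along(iso)) {
        rows[[length(rows) + 1]] <- exon_rows(iso[[k]], src_iso[k], paste0("truth_", iso[[k]]$role))
      }
      for (k in seq_along(injected)) {
        rows[[length(rows) + 1]] <- exon_rows(injected[[k]], src_inj[k], "injected")
      }
      events <- c(events, ev_g)
      gene_end <- max(vapply(c(iso, injected), function(x) max(x$exons[, 2]), numeric(1)))
      cursor[[chrom]] <- as.integer(gene_end)
    }

    col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    all_rows <- tibble(
      chrom = col("chrom"), start = col("start"), end = col("end"),
      strand = col("strand"), gene_id = col("gene_id"),
      transcript_id = col("transcript_id"), source = col("source"),
      role = col("role")
    )
    truth <- all_rows %>% filter(startsWith(.data$role, "truth_")) %>% select(-"role")
    ref <- all_rows %>% filter(.data$source == "ref") %>% select(-"role")
    alt <- all_rows %>% filter(.data$source == "alt") %>% select(-"role")
    truth_ledger <- if (length(ledger)) {
      m <- do.call(rbind, ledger)
      tibble(removed_transcript_id = m[, 1], kept_transcript_id = m[, 2],
             rule = m[, 3], gene_id = m[, 4])
    } else empty_decisions()
    events <- if (length(events)) {
      tibble(
        event_id = vapply(events, `[[`, character(1), "event_id"),
        gene_id = vapply(events, `[[`, character(1), "gene_id"),
        event_type = vapply(events, `[[`, character(1), "event_type"),
        chrom = vapply(events, `[[`, character(1), "chrom"),
        start = vapply(events, `[[`, integer(1), "start"),
        end = vapply(events, `[[`, integer(1), "end"),
        strand = vapply(events, `[[`, character(1), "strand")
      )
    } else {
      tibble(event_id = character(), gene_id = character(), event_type = character(),
             chrom = character(), start = integer(), end = integer(), strand = character())
    }

    genome <- NULL
    if (with_genome) {
      chrom_len <- all_rows %>%
        group_by(.data$chrom) %>%
        summarise(len = max(.data$end) + 100L, .groups = "drop")
      genome <- withr::with_seed((spec$seed %% 1000000L) + 2L, {
        g <- Biostrings::DNAStringSet(vapply(chrom_len$len, function(L) {
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
        }, character(1)))
        names(g) <- chrom_len$chrom
        g
      })
    }

    list(
      truth = as_annotation(truth),
      ref = as_annotation(ref),
      alt = as_annotation(alt),
      truth_ledger = truth_ledger %>% arrange(.data$removed_transcript_id),
      events = events,
      genome = genome
    )
  })
}

#' Generate a synthetic genome
#'
#' Random-base chromosomes long enough to host every generated gene model of
#' the spec. Deterministic for a given spec.
#'
#' @param spec A [fixture_spec()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(spec) {
  build_fixture(spec, with_genome = TRUE)$genome
}

#' Generate a redundant annotation pair with known ground truth
#'
#' Produces two annotation sources (`ref`, `alt`) that together contain the
#' nonredundant `truth` set plus injected redundancy of the classes the
#' pipeline removes (UTR-length chain duplicates, overlapping mono-exon
#' variants, coverage fragments) at the spec's per-rule rates, and a
#' `truth_ledger` naming every injected transcript, the transcript that
#' should displace it, and the rule that should fire. Intron-retention and
#' alternative-splice-site isoforms are injected as genuine isoforms of the
#' truth set and must survive construction.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `ref`, `alt`, `truth` (annotation tibbles)
#'   and `truth_ledger` (a decisions tibble).
#' @export
generate_annotation_pair <- function(spec) {
  fx <- build_fixture(spec, with_genome = FALSE)
  fx[c("ref", "alt", "truth", "truth_ledger")]
}

#' Event definitions of a generated fixture
#'
#' One event per true alternative-splicing isoform of the fixture's truth
#' set: the region spans the affected intron plus a 25 bp margin, mimicking
#' an RT-PCR primer pair across the event.
#'
#' @param spec A [fixture_spec()].
#' @return An events tibble (see [read_events()]).
#' @export
generate_events <- function(spec) {
  build_fixture(spec, with_genome = FALSE)$events
}

#' Generate paired abundance and peak tables with known true ratios
#'
#' Emulates the paired measurement design: for every sample (replicates x
#' time points), transcript abundances (TPM) are drawn from per-transcript
#' log-normal levels with a per-time-point fold change and per-replicate
#' biological variation; RT-PCR peak areas are proportional to the true
#' abundances of each event's transcript classes, times multiplicative
#' log-normal noise of scale `spec$noise_sd` (so `noise_sd = 0` makes the two
#' methods agree exactly). True splicing ratios per event/sample/mode are
#' returned for parameter-recovery tests.
#'
#' @param truth Truth annotation tibble (from [generate_annotation_pair()]).
#' @param events Events tibble (from [generate_events()]), assigned against
#'   `truth`.
#' @param spec The [fixture_spec()] that generated `truth`.
#' @return A list with `abundance` (tibble `transcript_id`, `sample_id`,
#'   `tpm`), `peaks` (tibble `event_id`, `product_label`, `category`,
#'   `sample_id`, `rfu`), `sample_info` (tibble `sample_id`, `time_point`,
#'   `replicate`) and `true_ratios` (ratio records, `method = "truth"`, both
#'   modes).
#' @export
generate_abundance_and_peaks <- function(truth, events, spec) {
  assignments <- assign_event_transcripts(events, truth)
  tx_ids <- sort(unique(truth$transcript_id))
  withr::with_seed(spec$seed + 1L, {
    n_tx <- length(tx_ids)
    sample_info <- tidyr::expand_grid(
      time_point = paste0("T", seq_len(spec$n_timepoints)),
      replicate = seq_len(spec$n_replicates)
    ) %>% mutate(sample_id = paste0(.data$time_point, ".R", .data$replicate)) %>%
      select("sample_id", "time_point", "replicate")
    base_level <- rlnorm(n_tx, meanlog = log(30), sdlog = 1)
    tp_fc <- matrix(1, n_tx, spec$n_timepoints)
    if (spec$n_timepoints > 1) {
      for (t in 2:spec$n_timepoints) tp_fc[, t] <- rlnorm(n_tx, 0, 0.4)
    }
    abundance <- purrr::pmap(sample_info, function(sample_id, time_point, replicate) {
      t_idx <- match(time_point, paste0("T", seq_len(spec$n_timepoints)))
      true_ab <- base_level * tp_fc[, t_idx] * rlnorm(n_tx, 0, 0.1)
      tibble(transcript_id = tx_ids, sample_id = sample_id, true_abundance = true_ab)
    }) %>% bind_rows()
    abundance <- abundance %>%
      group_by(.data$sample_id) %>%
      mutate(tpm = .data$true_abundance / sum(.data$true_abundance) * 1e6) %>%
      ungroup()

    cat_sums <- tidyr::expand_grid(
      assignments[, c("event_id", "transcript_id", "category")],
      sample_id = sample_info$sample_id
    ) %>%
      left_join(abundance[, c("transcript_id", "sample_id", "true_abundance")],
                by = c("transcript_id", "sample_id")) %>%
      group_by(.data$event_id, .data$sample_id, .data$category) %>%
      summarise(total = sum(.data$true_abundance), .groups = "drop")
    peaks <- cat_sums %>%
      mutate(
        rfu = .data$total * 20 *
          rlnorm(dplyr::n(), 0, spec$noise_sd),
        product_label = paste0(.data$event_id, ".", .data$category)
      ) %>%
      select("event_id", "product_label", "category", "sample_id", "rfu")

    true_ratios <- bind_rows(
      splicing_ratios(assignments, abundance, mode = "of_total", method = "truth"),
      splicing_ratios(assignments, abundance, mode = "as_vs_fs", method = "truth")
    )
    list(abundance = abundance %>% select("transcript_id", "sample_id", "tpm"),
         peaks = peaks, sample_info = sample_info, true_ratios = true_ratios)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Materializes everything a shell run of the pipeline needs: genome FASTA,
#' the two annotation sources (GFF3 and GTF, exercising both dialects), the
#' truth annotation and ledger, event definitions, per-sample quantification
#' tables in the Sailfish/Salmon layout, the peak-area table, sample
#' metadata, and the true ratios.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
simulate_fixtures <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "quant"), showWarnings = FALSE)
  fx <- build_fixture(spec)
  Biostrings::writeXStringSet(fx$genome, file.path(outdir, "genome.fa"), width = 60)
  write_annotation(fx$ref, file.path(outdir, "ref.gff3"), dialect = "gff3")
  write_annotation(fx$alt, file.path(outdir, "alt.gtf"), dialect = "gtf")
  write_annotation(fx$truth, file.path(outdir, "truth.gff3"), dialect = "gff3")
  readr::write_tsv(fx$truth_ledger, file.path(outdir, "truth_ledger.tsv"))
  readr::write_tsv(fx$events, file.path(outdir, "events.tsv"))
  ap <- generate_abundance_and_peaks(fx$truth, fx$events, spec)
  seq_len_tbl <- transcripts(fx$truth)[, c("transcript_id", "spliced_length")]
  for (s in ap$sample_info$sample_id) {
    d <- ap$abundance %>% filter(.data$sample_id == s) %>%
      left_join(seq_len_tbl, by = "transcript_id") %>%
      mutate(
        Name = .data$transcript_id, Length = .data$spliced_length,
        EffectiveLength = pmax(.data$spliced_length - 150, 1),
        TPM = .data$tpm, NumReads = round(.data$tpm * 10)
      ) %>%
      select("Name", "Length", "EffectiveLength", "TPM", "NumReads")
    readr::write_tsv(d, file.path(outdir, "quant", paste0(s, ".tsv")))
  }
  readr::write_tsv(ap$peaks, file.path(outdir, "peaks.tsv"))
  readr::write_tsv(ap$sample_info, file.path(outdir, "samples.tsv"))
  readr::write_tsv(ap$true_ratios, file.path(outdir, "truth_ratios.tsv"))
  invisible(outdir)
}
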