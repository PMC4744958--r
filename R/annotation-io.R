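#' Read a transcript annotation (GTF or GFF3)
#'
#' Reads exon features from a GTF (`gene_id`/`transcript_id` attributes) or
#' GFF3 (`ID`/`Parent` attributes) file into the exon-level tibble used
#' throughout the package. Both dialects yield the same table, so downstream
#' code never cares which format a source arrived in. Features other than
#' gene/transcript(mRNA)/exon are ignored; their count is reported as a
#' message. Exons listed out of order are sorted with a warning.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"`, `"gff3"`, or `"auto"` (detect from the file
#'   extension, the `##gff-version` header, or the attribute style of the
#'   first feature line).
#' @param source_label Tag stored in the `source` column; defaults to the
#'   file name without extension.
#' @return An exon-level annotation tibble (see [as_annotation()]).
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3"),
                            source_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (is.null(source_label)) {
    source_label <- sub("\\.(gtf|gff3?|gff)$", "", basename(path), ignore.case = TRUE)
  }
  if (dialect == "auto") dialect <- detect_dialect(path)

  lines <- readLines(path, warn = FALSE)
  feature_lines <- which(!grepl("^\\s*(#|$)", lines))
  if (length(feature_lines) == 0) {
    return(as_annotation(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(), transcript_id = character(),
      source = character()
    )))
  }
  check_attribute_column(lines, feature_lines, dialect)

  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)

  if (dialect == "gtf") {
    exons <- df[df$type == "exon", , drop = FALSE]
    n_ignored <- sum(!df$type %in% c("exon", "transcript", "mRNA", "gene"))
    if (is.null(exons$transcript_id) || anyNA(exons$transcript_id) ||
        is.null(exons$gene_id) || anyNA(exons$gene_id)) {
      abort("GTF exon feature without gene_id/transcript_id attributes")
    }
    out <- tibble(
      chrom = as.character(exons$seqnames),
      start = exons$start, end = exons$end,
      strand = as.character(exons$strand),
      gene_id = exons$gene_id, transcript_id = exons$transcript_id,
      source = source_label
    )
  } else {
    parent1 <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
    is_exon <- df$type == "exon"
    tx_types <- c("mRNA", "transcript")
    is_tx <- df$type %in% tx_types
    n_ignored <- sum(!df$type %in% c("exon", tx_types, "gene"))
    tx_to_gene <- setNames(parent1[is_tx], df$ID[is_tx])
    exon_tx <- parent1[is_exon]
    if (anyNA(exon_tx)) abort("GFF3 exon feature without a Parent attribute")
    gene_of <- unname(tx_to_gene[exon_tx])
    orphan <- is.na(gene_of)
    if (any(orphan)) {
      warn(paste0(
        sum(orphan), " exon(s) reference a transcript with no feature line; ",
        "using the transcript id as gene id for those"
      ))
      gene_of[orphan] <- exon_tx[orphan]
    }
    out <- tibble(
      chrom = as.character(df$seqnames[is_exon]),
      start = df$start[is_exon], end = df$end[is_exon],
      strand = as.character(df$strand[is_exon]),
      gene_id = gene_of, transcript_id = exon_tx,
      source = source_label
    )
  }
  if (n_ignored > 0) {
    inform(sprintf("ignored %d feature line(s) that are not gene/transcript/exon", n_ignored))
  }
  unsorted <- out %>%
    group_by(.data$transcript_id) %>%
    summarise(sorted = !is.unsorted(.data$start), .groups = "drop")
  if (any(!unsorted$sorted)) {
    warn(paste0(
      "exons of ", sum(!unsorted$sorted),
      " transcript(s) were not sorted in the file; sorting"
    ))
  }
  as_annotation(out, source_label = source_label)
}

detect_dialect <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "gtf") return("gtf")
  if (ext %in% c("gff", "gff3")) return("gff3")
  lines <- readLines(path, n = 50, warn = FALSE)
  if (any(grepl("^##gff-version\\s*3", lines))) return("gff3")
  feat <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(feat) == 0) return("gff3")
  attr_col <- strsplit(feat[1], "\t", fixed = TRUE)[[1]]
  if (length(attr_col) < 9) abort("cannot detect dialect: first feature line has fewer than 9 columns")
  attrs <- attr_col[9]
  if (grepl("(^|;)\\s*\\w+=", attrs)) "gff3" else "gtf"
}

check_attribute_column <- function(lines, feature_lines, dialect) {
  for (i in feature_lines) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9) {
      abort(sprintf("malformed feature line %d: expected 9 tab-separated columns, found %d",
                    i, length(fields)))
    }
    attrs <- fields[9]
    ok <- if (dialect == "gtf") {
      grepl("\\w+\\s+\"[^\"]*\"", attrs)
    } else {
      grepl("\\w+=", attrs)
    }
    if (!ok) {
      abort(sprintf("malformed attribute column at line %d: '%s'", i, attrs))
    }
  }
  invisible(TRUE)
}

#' Write a transcript annotation (GTF or GFF3)
#'
#' Serializes an exon-level annotation tibble to disk. Output is normalized:
#' features are sorted by chromosome, then gene span start, then transcript
#' and exon start, so writing is a fixed point (writing what was just read
#' back reproduces the file byte for byte). GTF output carries
#' `gene_id`/`transcript_id` attributes with a `transcript` line per
#' transcript; GFF3 output carries `gene`, `mRNA` and `exon` features linked
#' by `ID`/`Parent`. The `source` column fills field 2.
#'
#' @param ann An exon-level annotation tibble.
#' @param path Output file path.
#' @param dialect `"gtf"` or `"gff3"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = NULL) {
  if (is.null(dialect)) {
    ext <- tolower(sub(".*\\.", "", path))
    dialect <- if (ext == "gtf") "gtf" else "gff3"
  }
  dialect <- match.arg(dialect, c("gtf", "gff3"))
  header <- if (dialect == "gff3") "##gff-version 3" else "#!format: gtf"
  if (nrow(ann) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  validate_annotation(ann)
  tx <- transcripts(ann)
  gs <- gene_spans(ann) %>% rename(g_start = "start", g_end = "end")
  tx <- tx %>%
    left_join(gs[, c("gene_id", "g_start", "g_end")], by = "gene_id") %>%
    arrange(.data$chrom, .data$g_start, .data$gene_id, .data$span_start,
            .data$transcript_id)
  exons <- ann %>%
    arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start)
  exons_by_tx <- split(exons, exons$transcript_id)

  out <- character(0)
  if (dialect == "gtf") {
    for (k in seq_len(nrow(tx))) {
      t <- tx[k, ]
      attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", t$gene_id, t$transcript_id)
      out <- c(out, sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, t$source, t$span_start, t$span_end, t$strand, attrs))
      e <- exons_by_tx[[t$transcript_id]]
      out <- c(out, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                            e$chrom, e$source, e$start, e$end, e$strand, attrs))
    }
  } else {
    seen_gene <- character(0)
    for (k in seq_len(nrow(tx))) {
      t <- tx[k, ]
      if (!t$gene_id %in% seen_gene) {
        out <- c(out, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              t$chrom, t$source, t$g_start, t$g_end, t$strand, t$gene_id))
        seen_gene <- c(seen_gene, t$gene_id)
      }
      out <- c(out, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            t$chrom, t$source, t$span_start, t$span_end, t$strand,
                            t$transcript_id, t$gene_id))
      e <- exons_by_tx[[t$transcript_id]]
      out <- c(out, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            e$chrom, e$source, e$start, e$end, e$strand, e$transcript_id))
    }
  }
  writeLines(c(header, out), path)
  invisible(path)
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon subsequences in ascending coordinate order and
#' reverse-complements the whole spliced sequence for minus-strand
#' transcripts, so every sequence reads 5' to 3'.
#'
#' @param ann An exon-level annotation tibble.
#' @param genome A genome FASTA path or a [Biostrings::DNAStringSet]. FASTA
#'   record names are truncated at the first whitespace.
#' @return A [Biostrings::DNAStringSet] named by `transcript_id`; each length
#'   equals the transcript's summed exon length.
#' @export
extract_transcript_sequences <- function(ann, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*", "", names(genome))
  if (nrow(ann) == 0) return(Biostrings::DNAStringSet())
  missing_chrom <- setdiff(unique(ann$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", ")))
  }
  chrom_len <- Biostrings::width(genome)[match(ann$chrom, names(genome))]
  beyond <- ann$end > chrom_len
  if (any(beyond)) {
    i <- which(beyond)[1]
    abort(sprintf("exon %d-%d of transcript '%s' extends beyond the end of %s (%d bp)",
                  ann$start[i], ann$end[i], ann$transcript_id[i], ann$chrom[i], chrom_len[i]))
  }
  ann <- ann %>% arrange(.data$transcript_id, .data$start)
  pieces <- Biostrings::DNAStringSet(rep("", nrow(ann)))
  for (ch in unique(ann$chrom)) {
    idx <- ann$chrom == ch
    pieces[idx] <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(ann$start[idx], ann$end[idx])
    )
  }
  spliced <- Biostrings::unstrsplit(
    S4Vectors::split(pieces, factor(ann$transcript_id, levels = unique(ann$transcript_id)))
  )
  tx <- transcripts(ann)
  minus <- tx$transcript_id[tx$strand == "-"]
  hit <- names(spliced) %in% minus
  if (any(hit)) spliced[hit] <- Biostrings::reverseComplement(spliced[hit])
  spliced
}

#' Write transcript sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet], e.g. from
#'   [extract_transcript_sequences()].
#' @param path Output FASTA path.
#' @param width Line-wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
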