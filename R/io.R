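# Plain-text readers and writers for the standard interchange formats:
# VCF 4.2 and TSV dosages for genotypes, GFF3 for gene models, TSV for plot
# tables and association tables, JSON for truth records and QC reports,
# BED for hotspots.

#' Write genotypes as minimal VCF 4.2
#'
#' Emits one GT sample column per line with the imputation quality in the
#' INFO field (`DR2=`). Dosage 0 becomes `0/0`, 1 becomes `0/1`, 2 becomes
#' `1/1`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  m <- genotypes$snp_meta
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[genotypes$dosages + 1L], nrow = nrow(genotypes$dosages))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=waxomics",
    sprintf("##contig=<ID=%s,length=%d>", names(genotypes$chrom_lengths),
            as.integer(genotypes$chrom_lengths)),
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation dosage r-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$line_ids), collapse = "\t"))
  body <- paste(m$chrom, m$pos, m$snp_id, "A", "T", ".", "PASS",
                sprintf("DR2=%.3f", m$dr2), "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a TSV dosage matrix
#'
#' Lines as rows, SNP ids as columns; the first column holds the line id.
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @return `path` (writer) or a numeric matrix with line-id rownames
#'   (reader).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(line_id = genotypes$line_ids, genotypes$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write gene models as GFF3
#'
#' One `gene` feature per model, 1-based inclusive coordinates.
#' @param layout a `genome_layout`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(layout, path) {
  gm <- layout$gene_models
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", names(layout$chrom_lengths),
            as.integer(layout$chrom_lengths)),
    paste(gm$chrom, "waxomics", "gene", gm$start, gm$end, ".", gm$strand, ".",
          sprintf("ID=%s;Name=%s", gm$gene_id, gm$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene`-type features of a GFF3 file into a `genome_layout`.
#' Chromosome lengths are taken from `##sequence-region` pragmas when
#' present, otherwise from the maximum feature end per chromosome.
#'
#' @param path GFF3 file.
#' @return a `genome_layout`.
#' @export
read_gene_models_gff3 <- function(path) {
  raw <- readLines(path)
  sr <- grep("^##sequence-region", raw, value = TRUE)
  cl <- NULL
  if (length(sr) > 0) {
    parts <- strsplit(sr, "\\s+")
    cl <- stats::setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
                          vapply(parts, function(p) p[2], character(1)))
  }
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(body, "\t")
  f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))]
  ids <- vapply(f, function(x) sub("^.*ID=([^;]+).*$", "\\1", x[9]), character(1))
  gm <- data.frame(
    gene_id = ids,
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 4)),
    end = as.integer(vapply(f, `[`, character(1), 5)),
    strand = vapply(f, `[`, character(1), 7),
    stringsAsFactors = FALSE)
  if (is.null(cl)) {
    cl <- tapply(gm$end, gm$chrom, max)
    cl <- stats::setNames(as.numeric(cl), names(cl))
  }
  gm <- gm[order(match(gm$chrom, names(cl)), gm$start), , drop = FALSE]
  rownames(gm) <- NULL
  structure(list(chrom_lengths = cl, gene_models = gm),
            class = "genome_layout")
}

#' Write / read a plot table as TSV
#' @param plot_table long-format plot table.
#' @param path file path.
#' @return `path` (writer) or a `plot_table` (reader; trait classes are
#'   restored from the `trait_meta` attribute written as a JSON sidecar if
#'   present at `paste0(path, ".meta.json")`).
#' @export
write_plot_table <- function(plot_table, path) {
  utils::write.table(as.data.frame(plot_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- attr(plot_table, "trait_meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    attr(out, "trait_meta") <- as.data.frame(jsonlite::read_json(
      sidecar, simplifyVector = TRUE))
  }
  class(out) <- c("plot_table", "data.frame")
  out
}

#' Write a truth record as JSON
#' @param truth a `truth_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  x <- unclass(truth)
  x$genetic_values <- NULL  # matrices go to TSV, not JSON
  x$gc_genetic <- NULL
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a trait panel as TSV plus JSON sidecar
#'
#' The BLUP matrix goes to `<path>`, the transformed matrix to
#' `<path>.transformed.tsv`, and per-trait metadata (lambda, heritability,
#' variance components) to `<path>.meta.json`.
#'
#' @param panel a `trait_panel`.
#' @param path base output path.
#' @return `path`, invisibly.
#' @export
write_trait_panel <- function(panel, path) {
  wr <- function(m, p) {
    df <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(panel$blups, path)
  wr(panel$transformed, paste0(path, ".transformed.tsv"))
  meta <- list(lambda = as.list(panel$lambda), h2 = as.list(panel$h2),
               vc = lapply(panel$vc, function(v) v$components))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the trait-panel QC report as JSON
#'
#' Serializes the zero-filter report, imputation log, and the per-pass
#' outlier counts produced by [prepare_trait_panel()].
#'
#' @param panel a `trait_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(panel, path) {
  jsonlite::write_json(panel$qc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read an association table as TSV
#' @param assoc an `assoc_table`.
#' @param path file path.
#' @return `path` (writer) or an `assoc_table` (reader).
#' @export
write_assoc_table <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write hotspots as BED (plus JSON members)
#'
#' BED intervals are 0-based half-open, matching the hotspot coordinates.
#' Member loci go to `paste0(path, ".json")`.
#'
#' @param hotspots data frame from [call_hotspots()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  bed <- data.frame(hotspots$chrom, as.integer(hotspots$start),
                    as.integer(hotspots$end),
                    sprintf("%s|n=%d", hotspots$label, hotspots$n_loci))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  members <- lapply(seq_len(nrow(hotspots)), function(i)
    hotspots$members[[i]][, c("trait", "class", "chrom", "peak_pos")])
  jsonlite::write_json(
    list(threshold = attr(hotspots, "threshold"),
         window_bp = attr(hotspots, "window_bp"), hotspots = members),
    paste0(path, ".json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
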