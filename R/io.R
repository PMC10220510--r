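#' Read a whole-population mutation table
#'
#' Reads the tab-delimited mutation-table dialect: metadata columns
#' `lineage`, `replicon`, `position` (1-based), `ref`, `alt`, `gene_id`
#' (empty for intergenic), `mutation_type`, then one `freq_c<k>` column
#' per sampled cycle. Empty frequency cells are missing (cycle not
#' sequenced). Leading `#` comment lines (run headers) are skipped.
#'
#' @param path Path to a TSV file.
#' @return A tibble of typed records.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "symcycle_io_error")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  freq_cols <- grep("^freq_c[0-9]+$", names(df), value = TRUE)
  if (length(freq_cols) == 0L) {
    abort(sprintf("%s: no `freq_c<k>` columns found; not a mutation table.",
                  path),
          class = "symcycle_parse_error")
  }
  for (col in freq_cols) {
    if (nrow(df) == 0L ||
        (is.logical(df[[col]]) && all(is.na(df[[col]])))) {
      df[[col]] <- as.double(df[[col]]) # empty column: type is undetermined
    }
    x <- df[[col]]
    if (!is.numeric(x)) {
      abort(sprintf("%s: column %s is not numeric.", path, col),
            class = "symcycle_parse_error")
    }
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad) > 0L) {
      abort(sprintf("%s: frequency outside [0, 1] in column %s, data line %d.",
                    path, col, bad[1L]),
            class = "symcycle_parse_error")
    }
  }
  site_cols <- c("lineage", "replicon", "position", "alt")
  if (all(site_cols %in% names(df)) && nrow(df) > 0L) {
    key <- do.call(paste, c(df[site_cols], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      abort(sprintf("%s: duplicate (lineage, replicon, position, alt) record at data line %d.",
                    path, dup[1L]),
            class = "symcycle_parse_error")
    }
  }
  df
}

#' Write a mutation table
#'
#' Writes the TSV dialect read by [read_mutation_table()], preceded by
#' comment header lines recording the package version, the seed that
#' produced the data (when given) and the timestamp.
#'
#' @param df The table.
#' @param path Output path.
#' @param seed Optional seed to echo into the header.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(df, path, seed = NULL) {
  writeLines(run_header(seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

run_header <- function(seed = NULL) {
  c(sprintf("# symcycle %s",
            as.character(utils::packageVersion("symcycle"))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Read gene coding lengths
#'
#' Reads a gene-length table from either a TSV (`gene_id`, `length`,
#' optional `replicon`; validated and passed through) or a GFF3 annotation
#' (CDS features, 1-based inclusive coordinates: length is
#' `end - start + 1`, and multi-segment CDS lengths are summed per gene
#' identifier).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return A tibble `gene_id`, `length` (and `replicon` when available).
#' @export
read_gene_lengths <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "symcycle_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    if (!all(c("gene_id", "length") %in% names(df))) {
      abort(sprintf("%s: gene table needs `gene_id` and `length` columns.",
                    path),
            class = "symcycle_parse_error")
    }
    dup <- which(duplicated(df$gene_id))
    if (length(dup) > 0L) {
      abort(sprintf("%s: duplicate gene_id `%s` at data line %d.",
                    path, df$gene_id[dup[1L]], dup[1L]),
            class = "symcycle_parse_error")
    }
    validate_gene_table(df)
    return(df)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GFF3 requires the rtracklayer package.",
          class = "symcycle_io_error")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) {
    abort(sprintf("%s: no CDS features found.", path),
          class = "symcycle_parse_error")
  }
  meta <- as.data.frame(cds)
  gene_id <- meta$gene_id %||% meta$locus_tag
  if (is.null(gene_id) || all(is.na(gene_id))) {
    parent <- meta$Parent
    if (!is.null(parent)) {
      gene_id <- vapply(as.list(parent), function(x) {
        if (length(x)) as.character(x[[1L]]) else NA_character_
      }, character(1))
    }
  }
  if (is.null(gene_id)) {
    gene_id <- meta$ID
  }
  if (is.null(gene_id) || anyNA(gene_id)) {
    abort(sprintf("%s: CDS features lack a usable gene identifier (gene_id, locus_tag, Parent or ID).",
                  path),
          class = "symcycle_parse_error")
  }
  # GRanges width is end - start + 1 (1-based inclusive);
  # multi-segment CDSs are summed per gene
  lengths <- rowsum(as.numeric(meta$width), gene_id)
  out <- tibble::tibble(gene_id = rownames(lengths),
                        length = as.vector(lengths))
  rep_by_gene <- tapply(as.character(meta$seqnames), gene_id,
                        function(x) x[1L])
  out$replicon <- as.vector(rep_by_gene[out$gene_id])
  validate_gene_table(out)
  out
}

#' Write a gene-length table
#'
#' @param df Tibble with `gene_id`, `length` (and optional columns).
#' @param path Output path.
#' @param seed Optional seed to echo into the header.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(df, path, seed = NULL) {
  validate_gene_table(df)
  writeLines(run_header(seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read competitive-index count data
#'
#' Reads the TSV dialect of [summarize_ci()]: `strain`, `assay`,
#' `replicate`, `test_out`, `ref_out`, `test_in`, `ref_in`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_ci_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "symcycle_io_error")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  needed <- c("strain", "replicate", "test_out", "ref_out", "test_in",
              "ref_in")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "symcycle_parse_error")
  }
  count_cols <- c("test_out", "ref_out", "test_in", "ref_in")
  for (col in count_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative count in column %s.", path, col),
            class = "symcycle_parse_error")
    }
  }
  df
}
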