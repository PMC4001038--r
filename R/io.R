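# Plain-text table I/O. All tables are tab-separated with a header line;
# numeric columns round-trip at full double precision (%.17g).

write_tsv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write strain record tables
#'
#' Columns: `strain_id`, `chrom`, `position`, `feature`, `pool1`, `pool2`,
#' `uptag_id`, `downtag_id`, `true_rate`, `start_weight`.
#'
#' @param strains strain records (see [build_barcoded_library]).
#' @param path file path.
#' @return the strain data.frame ([read_strains]) or `path` invisibly.
#' @export
write_strains <- function(strains, path) write_tsv_precise(strains, path)

#' @rdname write_strains
#' @export
read_strains <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$pool1 <- as.logical(df$pool1)
  df$pool2 <- as.logical(df$pool2)
  df
}

#' Read and write intensity tables
#'
#' Columns: `pool`, `tag_id`, `sample` (`START`/`END`), `log2_intensity`.
#'
#' @param intensities intensity table (see [simulate_microarray]).
#' @param path file path.
#' @return the intensity data.frame ([read_intensities]) or `path` invisibly.
#' @export
write_intensities <- function(intensities, path) write_tsv_precise(intensities, path)

#' @rdname write_intensities
#' @export
read_intensities <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read and write insertion tables
#'
#' Columns: `chrom`, `position`, `strand`, `reads`.
#'
#' @param insertions insertion table (see [simulate_tnle]).
#' @param path file path.
#' @return the insertion data.frame ([read_insertions]) or `path` invisibly.
#' @export
write_insertions <- function(insertions, path) write_tsv_precise(insertions, path)

#' @rdname write_insertions
#' @export
read_insertions <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read and write gene fitness tables
#'
#' Columns: `gene_id`, `fitness`, `n_strains`, `intergenic` (barcode
#' pipeline) or `gene_id`, `n_window`, `win_len`, `fitness`, `flagged_zero`
#' (insertion-density pipeline).
#'
#' @param gf gene fitness table.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_gene_fitness <- function(gf, path) write_tsv_precise(gf, path)

#' @rdname write_gene_fitness
#' @export
read_gene_fitness <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname write_gene_fitness
#' @export
write_tnle_fitness <- function(gf, path) write_tsv_precise(gf, path)

#' @rdname write_gene_fitness
#' @export
read_tnle_fitness <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read and write gene x condition fitness tables
#'
#' Wide TSV: `gene_id` plus one column per condition; missing cells are `NA`.
#' Values round-trip exactly.
#'
#' @param table a [assemble_conditions] table.
#' @param path file path.
#' @return the table ([read_condition_table]) or `path` invisibly.
#' @export
write_condition_table <- function(table, path) {
  write_tsv_precise(as.data.frame(table), path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("tn_condition_table", "data.frame"))
}

#' Read and write scenario configurations as YAML
#'
#' @param config a `tn_scenario` (see [scenario_config]).
#' @param path file path.
#' @return the scenario ([read_scenario]) or `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  x$doublings <- as.list(x$doublings)
  x$effects <- lapply(as.list(as.data.frame(x$effects)), unname)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$doublings <- unlist(x$doublings)
  eff <- lapply(x$effects, unlist)
  if (any(lengths(eff) > 0)) {
    x$effects <- as.data.frame(eff, stringsAsFactors = FALSE)
  } else {
    x$effects <- data.frame(gene_index = integer(), condition = character(),
                            s = numeric(), stringsAsFactors = FALSE)
  }
  structure(x, class = "tn_scenario")
}
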