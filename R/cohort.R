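#' Packaged cohort fixtures
#'
#' `load_table1()` returns the per-strain genome-feature table (contig counts,
#' lengths, GC, annotated CDS counts) and `load_table2_ani()` the published
#' 17x17 percent-ANI matrix, both shipped under `inst/extdata/`. Printed
#' thousands separators are stripped on load.
#'
#' @return `load_table1()`: a data.frame with one row per strain;
#'   `load_table2_ani()`: a square numeric matrix with strain dimnames.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "genospecies",
                      mustWork = TRUE)
  df <- read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
  df$sequences <- parse_printed_number(df$sequences)
  df$genome_length <- parse_printed_number(df$genome_length)
  df$gc_content <- parse_printed_number(df$gc_content)
  df$patric_cds <- parse_printed_number(df$patric_cds)
  df
}

#' @rdname load_table1
#' @export
load_table2_ani <- function() {
  path <- system.file("extdata", "table2_ani.tsv", package = "genospecies",
                      mustWork = TRUE)
  read_matrix_tsv(path)
}

#' Summarize a cohort's per-strain statistics
#'
#' Accepts a data.frame with columns `strain_id`, `length`, `gc` and
#' optionally `n_contigs` and `n_cds` (numbers may carry printed thousands
#' separators, which are stripped). Returns the per-strain table plus the
#' aggregates used to characterize a cohort: length range, GC extremes and
#' CDS extremes/mean (mean rounded half-up to 2 decimals, the convention of
#' printed annotation tables).
#'
#' @param rows per-strain stats data.frame.
#' @return list with `per_strain` (data.frame) and `aggregate` (list with
#'   `length_range`, `gc_min`, `gc_max`, and when CDS counts are present
#'   `cds_min`, `cds_max`, `cds_mean`).
#' @export
cohort_summary <- function(rows) {
  gs_assert(is.data.frame(rows) && nrow(rows) >= 1, "need at least one strain row")
  gs_assert("length" %in% names(rows), "missing 'length' column")
  gs_assert("strain_id" %in% names(rows), "missing 'strain_id' column")
  out <- data.frame(strain_id = as.character(rows$strain_id),
                    length = parse_printed_number(rows$length),
                    stringsAsFactors = FALSE)
  gs_assert(!anyNA(out$length), "unparseable genome length")
  if ("n_contigs" %in% names(rows)) out$n_contigs <- parse_printed_number(rows$n_contigs)
  if ("gc" %in% names(rows)) out$gc <- parse_printed_number(rows$gc)
  if ("n_cds" %in% names(rows)) out$n_cds <- parse_printed_number(rows$n_cds)
  agg <- list(length_range = max(out$length) - min(out$length))
  if (!is.null(out$gc)) {
    gs_assert(all(out$gc >= 0 & out$gc <= 100), "gc out of [0,100]")
    agg$gc_min <- min(out$gc)
    agg$gc_max <- max(out$gc)
  }
  if (!is.null(out$n_cds)) {
    agg$cds_min <- min(out$n_cds)
    agg$cds_max <- max(out$n_cds)
    agg$cds_mean <- round_half_up(mean(out$n_cds), 2)
  }
  list(per_strain = out, aggregate = agg)
}

#' Cohort summary for a list of genome records
#'
#' Computes lengths, GC and contig counts with [genome_stats()] and summarizes
#' them with [cohort_summary()].
#'
#' @param genomes list of `genome_record`s.
#' @return as [cohort_summary()].
#' @export
cohort_summary_genomes <- function(genomes) {
  rows <- do.call(rbind, lapply(genomes, function(g) {
    st <- genome_stats(g)
    data.frame(strain_id = g$strain_id, length = st$length, gc = st$gc,
               n_contigs = st$n_contigs, stringsAsFactors = FALSE)
  }))
  cohort_summary(rows)
}
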