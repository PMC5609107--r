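#' Read a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences are
#' uppercased; in nucleotide mode characters outside `A,C,G,T,N,-` are either
#' rejected or mapped to `N` (IUPAC ambiguity codes in draft genomes), per
#' `on_ambiguous`.
#'
#' @param path path to a FASTA file (plain text).
#' @param type `"dna"` or `"protein"`; controls alphabet validation.
#' @param on_ambiguous for `type = "dna"`: `"N"` maps non-`ACGTN-` characters
#'   to `N` with a warning, `"error"` rejects them.
#' @return named character vector of sequences; names are the full headers.
#' @export
read_fasta <- function(path, type = c("dna", "protein"), on_ambiguous = c("N", "error")) {
  type <- match.arg(type)
  on_ambiguous <- match.arg(on_ambiguous)
  gs_assert(file.exists(path), "FASTA file does not exist: %s", path)
  gs_assert(file.size(path) > 0, "FASTA file is empty: %s", path)
  set <- Biostrings::readBStringSet(path)
  gs_assert(length(set) > 0, "no FASTA records in %s", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  gs_assert(!anyDuplicated(headers), "duplicate FASTA header in %s: %s", path,
            paste(unique(headers[duplicated(headers)]), collapse = ", "))
  gs_assert(all(nchar(seqs) > 0), "FASTA record with no sequence in %s: %s", path,
            paste(headers[nchar(seqs) == 0], collapse = ", "))
  if (type == "dna") {
    bad <- grepl("[^ACGTN-]", seqs)
    if (any(bad)) {
      if (on_ambiguous == "error") {
        stop(sprintf("non-ACGTN characters in %s (records: %s)", path,
                     paste(headers[bad], collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("mapping non-ACGTN characters to N in %d record(s) of %s",
                      sum(bad), path))
      seqs[bad] <- gsub("[^ACGTN-]", "N", seqs[bad])
    }
  }
  setNames(seqs, headers)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  gs_assert(!is.null(names(seqs)) && all(nzchar(names(seqs))),
            "all sequences must be named")
  set <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a genome record
#'
#' A strain's contigs plus identifying metadata; the unit handed to the
#' fragmentation, ANI and wgMLST stages.
#'
#' @param strain_id unique strain label.
#' @param contigs character vector of uppercase DNA contigs (may be named).
#' @param source_path optional provenance path.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(strain_id, contigs, source_path = NA_character_) {
  gs_assert(is.character(strain_id) && length(strain_id) == 1 && nzchar(strain_id),
            "strain_id must be a non-empty string")
  contigs <- toupper(as.character(contigs))
  gs_assert(length(contigs) >= 1 && all(nchar(contigs) > 0),
            "genome %s: every contig must be non-empty", strain_id)
  gs_assert(!any(grepl("[^ACGTN]", contigs)),
            "genome %s: contigs restricted to A,C,G,T,N", strain_id)
  if (is.null(names(contigs)) || !all(nzchar(names(contigs)))) {
    names(contigs) <- sprintf("%s_contig%03d", strain_id, seq_along(contigs))
  }
  structure(list(strain_id = strain_id, contigs = contigs, source_path = source_path),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  st <- genome_stats(x)
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp, GC %.2f%%\n",
              x$strain_id, st$n_contigs, format(st$length, big.mark = ","), st$gc))
  invisible(x)
}

#' Read a genome record from a multi-FASTA file
#'
#' @param path FASTA path; the strain id defaults to the file base name.
#' @param strain_id override the strain id.
#' @inheritParams read_fasta
#' @return a `genome_record`.
#' @export
read_genome <- function(path, strain_id = NULL, on_ambiguous = "N") {
  seqs <- read_fasta(path, type = "dna", on_ambiguous = on_ambiguous)
  seqs <- gsub("-", "", seqs, fixed = TRUE)
  id <- strain_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_record(id, seqs, source_path = path)
}

#' Basic genome statistics
#'
#' GC percent is computed over unambiguous bases only:
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#'
#' @param genome a `genome_record`.
#' @return list with `length` (bp), `gc` (percent, `NA` for an all-N genome,
#'   with a warning), and `n_contigs`.
#' @export
genome_stats <- function(genome) {
  gs_assert(inherits(genome, "genome_record"), "genome_stats() expects a genome_record")
  seq_all <- paste(genome$contigs, collapse = "")
  counts <- table(factor(strsplit(seq_all, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (acgt == 0) {
    warning(sprintf("genome %s is all-N; GC undefined", genome$strain_id))
    NA_real_
  } else {
    100 * sum(counts[c("G", "C")]) / acgt
  }
  list(length = sum(nchar(genome$contigs)), gc = gc,
       n_contigs = length(genome$contigs))
}

#' Read every genome FASTA in a directory as a cohort
#'
#' @param dir directory containing one FASTA per strain (`.fa/.fasta/.fna`).
#' @return named list of `genome_record`s, sorted by strain id.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE))
  gs_assert(length(files) > 0, "no FASTA files found under %s", dir)
  genomes <- lapply(files, read_genome)
  ids <- vapply(genomes, `[[`, character(1), "strain_id")
  gs_assert(!anyDuplicated(ids), "duplicate strain ids in %s", dir)
  setNames(genomes, ids)[order(ids)]
}
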